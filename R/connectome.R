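NEURON_CATEGORIES <- c("OSN", "uPN", "mPN", "LN", "other", "unknown")
TRANSMITTER_CLASSES <- c("excitatory", "inhibitory", "modulatory", "unknown")

#' Assemble a connectome
#'
#' The connectome bundles the four co-registered data sets every downstream
#' stage consumes: skeletons, a polyadic synapse table, neuron annotations and
#' glomerulus meshes. Rows of the synapse table are single pre->post pairings;
#' a polyadic presynaptic site is represented by several rows sharing a
#' `connector_id` (and hence one `pre_neuron` and one presynaptic site).
#'
#' @param skeletons named list of [skeleton()] objects.
#' @param connections data.frame with columns `connector_id`, `pre_neuron`,
#'   `post_neuron`, `pre_x`, `pre_y`, `pre_z`, `post_x`, `post_y`, `post_z`.
#' @param annotations data.frame with columns `neuron_id`, `category`,
#'   `subtype`, `transmitter_class`, `home_glomerulus`, `tracing_status`
#'   (optionally `side` for laterality filtering).
#' @param meshes named list of [glomerulus_mesh()] objects.
#' @return an object of class `al_connectome`.
#' @export
connectome <- function(skeletons, connections, annotations, meshes) {
  conn_cols <- c("connector_id", "pre_neuron", "post_neuron",
                 "pre_x", "pre_y", "pre_z", "post_x", "post_y", "post_z")
  al_assert(all(conn_cols %in% names(connections)), "al_structure_error",
            "connections must have columns %s", paste(conn_cols, collapse = ", "))
  ann_cols <- c("neuron_id", "category", "subtype", "transmitter_class",
                "home_glomerulus", "tracing_status")
  al_assert(all(ann_cols %in% names(annotations)), "al_structure_error",
            "annotations must have columns %s", paste(ann_cols, collapse = ", "))
  names(skeletons) <- vapply(skeletons, `[[`, character(1), "neuron_id")
  names(meshes) <- vapply(meshes, `[[`, character(1), "name")
  structure(list(
    skeletons = skeletons,
    connections = as.data.frame(connections),
    annotations = as.data.frame(annotations),
    meshes = meshes
  ), class = "al_connectome")
}

#' @export
print.al_connectome <- function(x, ...) {
  cat(sprintf(paste0("<al_connectome> %d neurons annotated, %d skeletons, ",
                     "%d connection rows, %d glomerulus meshes\n"),
              nrow(x$annotations), length(x$skeletons),
              nrow(x$connections), length(x$meshes)))
  invisible(x)
}

#' Write a connectome to its on-disk layout
#'
#' Layout: `skeletons/<neuron_id>.swc`, `synapses.tsv`, `annotations.tsv`,
#' `meshes/<name>.obj`. This is the exact layout [load_connectome()] consumes.
#'
#' @param conn an `al_connectome`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_connectome <- function(conn, dir) {
  dir.create(file.path(dir, "skeletons"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "meshes"), recursive = TRUE, showWarnings = FALSE)
  for (sk in conn$skeletons) {
    write_swc(sk, file.path(dir, "skeletons", paste0(sk$neuron_id, ".swc")))
  }
  for (m in conn$meshes) {
    write_obj(m, file.path(dir, "meshes", paste0(m$name, ".obj")))
  }
  write_tsv(conn$connections, file.path(dir, "synapses.tsv"))
  ann <- conn$annotations
  ann$home_glomerulus[is.na(ann$home_glomerulus)] <- "none"
  write_tsv(ann, file.path(dir, "annotations.tsv"))
  invisible(dir)
}

#' Load a connectome from disk
#'
#' Reads the layout written by [write_connectome()] and validates every type
#' invariant; a failed invariant aborts the load with a validation error
#' listing the offending ids.
#'
#' @param dir directory containing `skeletons/*.swc`, `synapses.tsv`,
#'   `annotations.tsv` and `meshes/*.obj`.
#' @param validate run [validate_connectome()] and stop on failure (default
#'   TRUE; set FALSE to force-load a broken data set for inspection).
#' @return an `al_connectome`.
#' @export
load_connectome <- function(dir, validate = TRUE) {
  al_assert(dir.exists(dir), "al_load_error", "missing directory: %s", dir)
  syn_path <- file.path(dir, "synapses.tsv")
  ann_path <- file.path(dir, "annotations.tsv")
  for (p in c(syn_path, ann_path)) {
    al_assert(file.exists(p), "al_load_error", "missing file: %s", p)
  }
  swc <- list.files(file.path(dir, "skeletons"), pattern = "\\.swc$",
                    full.names = TRUE)
  obj <- list.files(file.path(dir, "meshes"), pattern = "\\.obj$",
                    full.names = TRUE)
  al_assert(length(swc) > 0, "al_load_error",
            "missing file: %s", file.path(dir, "skeletons", "*.swc"))
  al_assert(length(obj) > 0, "al_load_error",
            "missing file: %s", file.path(dir, "meshes", "*.obj"))
  ann <- read_tsv(ann_path)
  ann$home_glomerulus[ann$home_glomerulus %in% c("none", "")] <- NA_character_
  conn <- connectome(
    skeletons = lapply(swc, read_swc),
    connections = read_tsv(syn_path),
    annotations = ann,
    meshes = lapply(obj, read_obj)
  )
  if (validate) {
    rep <- validate_connectome(conn)
    if (rep$n_failed > 0) {
      bad <- rep$checks[!rep$checks$passed, , drop = FALSE]
      al_stop("al_validation_error", "connectome validation failed:\n%s",
              paste(sprintf("  %s: %s", bad$check, bad$offenders),
                    collapse = "\n"))
    }
  }
  conn
}

#' Validate all connectome invariants
#'
#' Checks every structural invariant and reports pass/fail per check with the
#' offending identifiers; never throws. Downstream stages refuse to run on a
#' failing connectome unless forced.
#'
#' @param conn an `al_connectome`.
#' @return an object of class `al_validation_report` with elements `checks`
#'   (data.frame of check, passed, offenders) and `n_failed`.
#' @export
validate_connectome <- function(conn) {
  checks <- list()
  add <- function(check, offenders) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, passed = length(offenders) == 0L,
      offenders = paste(offenders, collapse = ", "))
  }
  cx <- conn$connections
  ann <- conn$annotations

  add("coordinates finite", {
    coord <- as.matrix(cx[c("pre_x", "pre_y", "pre_z", "post_x", "post_y", "post_z")])
    unique(cx$connector_id[!stats::complete.cases(coord) | rowSums(!is.finite(coord)) > 0])
  })
  add("polyadic convention: one pre site per connector", {
    key <- paste(cx$pre_neuron, round(cx$pre_x, 3), round(cx$pre_y, 3),
                 round(cx$pre_z, 3))
    per <- tapply(key, cx$connector_id, function(k) length(unique(k)))
    names(per)[per > 1L]
  })
  add("connected neurons annotated", {
    setdiff(unique(c(cx$pre_neuron, cx$post_neuron)), ann$neuron_id)
  })
  add("annotation categories valid", {
    ann$neuron_id[!ann$category %in% NEURON_CATEGORIES]
  })
  add("transmitter classes valid", {
    ann$neuron_id[!ann$transmitter_class %in% TRANSMITTER_CLASSES]
  })
  add("home glomerulus resolves to a mesh", {
    hg <- ann$home_glomerulus
    ann$neuron_id[!is.na(hg) & !(hg %in% names(conn$meshes))]
  })
  add("mesh names unique", {
    nm <- vapply(conn$meshes, `[[`, character(1), "name")
    unique(nm[duplicated(nm)])
  })
  add("meshes closed", {
    nm <- vapply(conn$meshes, function(m) {
      if (isTRUE(mesh_is_closed(m))) NA_character_ else m$name
    }, character(1))
    nm[!is.na(nm)]
  })
  add("mesh volume positive", {
    nm <- vapply(conn$meshes, function(m) {
      if (mesh_volume(m) > 0) NA_character_ else m$name
    }, character(1))
    nm[!is.na(nm)]
  })
  add("skeleton ids match annotation ids", {
    setdiff(names(conn$skeletons), ann$neuron_id)
  })
  df <- do.call(rbind, checks)
  structure(list(checks = df, n_failed = sum(!df$passed)),
            class = "al_validation_report")
}

#' @export
print.al_validation_report <- function(x, ...) {
  cat(sprintf("<al_validation_report> %d checks, %d failed\n",
              nrow(x$checks), x$n_failed))
  for (i in seq_len(nrow(x$checks))) {
    cat(sprintf("  [%s] %s%s\n",
                if (x$checks$passed[i]) "ok" else "FAIL", x$checks$check[i],
                if (x$checks$passed[i]) "" else paste0(": ", x$checks$offenders[i])))
  }
  invisible(x)
}
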
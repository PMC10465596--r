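#' Assign synapse sites to glomeruli by mesh containment
#'
#' Labels every connection row with the glomerulus containing its presynaptic
#' site and the glomerulus containing its postsynaptic site (`NA` when the
#' site lies inside no mesh). Meshes are assumed non-overlapping; each site is
#' tested against bounding-box-filtered meshes with the watertight ray-cast
#' predicate [points_in_mesh()].
#'
#' @param conn an `al_connectome`.
#' @return the connection data.frame with added columns `pre_glomerulus` and
#'   `post_glomerulus`.
#' @export
assign_synapses <- function(conn) {
  cx <- conn$connections
  pre <- as.matrix(cx[, c("pre_x", "pre_y", "pre_z")])
  post <- as.matrix(cx[, c("post_x", "post_y", "post_z")])
  cx$pre_glomerulus <- assign_points(pre, conn$meshes)
  cx$post_glomerulus <- assign_points(post, conn$meshes)
  cx
}

assign_points <- function(points, meshes) {
  out <- rep(NA_character_, nrow(points))
  todo <- rep(TRUE, nrow(points))
  for (m in meshes) {
    if (!any(todo)) break
    bb <- mesh_bbox(m)
    cand <- todo &
      points[, 1] >= bb["min", 1] & points[, 1] <= bb["max", 1] &
      points[, 2] >= bb["min", 2] & points[, 2] <= bb["max", 2] &
      points[, 3] >= bb["min", 3] & points[, 3] <= bb["max", 3]
    if (!any(cand)) next
    inside <- points_in_mesh(points[cand, , drop = FALSE], m)
    out[which(cand)[inside]] <- m$name
    todo[which(cand)[inside]] <- FALSE
  }
  out
}

#' Intraglomerular input:output ratio table
#'
#' For each neuron and each glomerulus it innervates, counts the neuron's
#' input connections (rows where it is postsynaptic and its postsynaptic site
#' lies in the glomerulus) and output connections (rows where it is
#' presynaptic and its presynaptic site lies in the glomerulus), and computes
#' the ratio `R = (I - O) / (I + O)`. R runs from -1 (pure output within the
#' glomerulus) to +1 (pure input); glomeruli without any connection yield no
#' row. When annotations carry a `side` column, only connections whose partner
#' shares the neuron's side are counted (ipsilateral-only analysis).
#'
#' @param conn an `al_connectome`.
#' @param assigned output of [assign_synapses()] (computed if missing).
#' @param neurons neuron ids to tabulate (default: all annotated LNs).
#' @return a data.frame of class `al_glomerular_metrics` with columns
#'   `neuron_id`, `glomerulus`, `n_input`, `n_output`, `ratio`.
#' @export
io_ratio_table <- function(conn, assigned = NULL, neurons = NULL) {
  if (is.null(assigned)) assigned <- assign_synapses(conn)
  if (is.null(neurons)) {
    neurons <- conn$annotations$neuron_id[conn$annotations$category == "LN"]
  }
  cx <- assigned
  if ("side" %in% names(conn$annotations)) {
    side <- stats::setNames(conn$annotations$side, conn$annotations$neuron_id)
    cx <- cx[side[cx$pre_neuron] == side[cx$post_neuron], , drop = FALSE]
  }
  out <- list()
  for (id in neurons) {
    inputs <- cx[cx$post_neuron == id & !is.na(cx$post_glomerulus), ,
                 drop = FALSE]
    outputs <- cx[cx$pre_neuron == id & !is.na(cx$pre_glomerulus), ,
                  drop = FALSE]
    gloms <- union(unique(inputs$post_glomerulus),
                   unique(outputs$pre_glomerulus))
    for (g in gloms) {
      i_g <- sum(inputs$post_glomerulus == g)
      o_g <- sum(outputs$pre_glomerulus == g)
      out[[length(out) + 1L]] <- data.frame(
        neuron_id = id, glomerulus = g, n_input = i_g, n_output = o_g,
        ratio = if (i_g + o_g > 0) (i_g - o_g) / (i_g + o_g) else NA_real_)
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(neuron_id = character(), glomerulus = character(),
               n_input = integer(), n_output = integer(), ratio = numeric())
  class(df) <- c("al_glomerular_metrics", class(df))
  df
}

#' Neurons x glomeruli ratio matrix (heatmap-ready)
#'
#' Pivot of [io_ratio_table()] output; glomeruli not innervated by a neuron
#' are `NA`, mirroring the "not innervated" marker of the published heatmaps.
#'
#' @param tab an `al_glomerular_metrics` data.frame.
#' @param glomeruli column order (default: sorted unique glomeruli present).
#' @return numeric matrix, neurons x glomeruli.
#' @export
ratio_matrix <- function(tab, glomeruli = NULL) {
  if (is.null(glomeruli)) glomeruli <- sort(unique(tab$glomerulus))
  neurons <- unique(tab$neuron_id)
  m <- matrix(NA_real_, length(neurons), length(glomeruli),
              dimnames = list(neurons, glomeruli))
  m[cbind(match(tab$neuron_id, neurons), match(tab$glomerulus, glomeruli))] <-
    tab$ratio
  m
}

#' Upstream / downstream partner demographics
#'
#' Percentage of a neuron's connections in the given direction contributed by
#' each partner category; partners without an annotation fall in the
#' `unknown` bin. Percentages are of the total connection count in that
#' direction (so they sum to 100 whenever the neuron has any partner).
#'
#' @param conn an `al_connectome`.
#' @param neuron neuron id.
#' @param direction `"upstream"` (the neuron's inputs) or `"downstream"`.
#' @return data.frame with columns `neuron_id`, `direction`, `category`,
#'   `n`, `percent`; zero rows (with attribute `empty = TRUE`) when the
#'   neuron has no partner in that direction.
#' @export
partner_demographics <- function(conn, neuron,
                                 direction = c("upstream", "downstream")) {
  direction <- match.arg(direction)
  cx <- conn$connections
  partners <- if (direction == "upstream") {
    cx$pre_neuron[cx$post_neuron == neuron]
  } else {
    cx$post_neuron[cx$pre_neuron == neuron]
  }
  if (length(partners) == 0L) {
    out <- data.frame(neuron_id = character(), direction = character(),
                      category = character(), n = integer(),
                      percent = numeric())
    attr(out, "empty") <- TRUE
    return(out)
  }
  cat_of <- conn$annotations$category[match(partners,
                                            conn$annotations$neuron_id)]
  cat_of[is.na(cat_of)] <- "unknown"
  tab <- table(factor(cat_of, levels = NEURON_CATEGORIES))
  tab <- tab[tab > 0]
  data.frame(neuron_id = neuron, direction = direction,
             category = names(tab), n = as.integer(tab),
             percent = 100 * as.numeric(tab) / length(partners))
}

#' Per-glomerulus transmitter-polarity breakdown of a neuron's inputs
#'
#' Splits the inputs a neuron receives within each glomerulus by the
#' presynaptic partner's transmitter class (excitatory / inhibitory /
#' modulatory / unknown) and expresses each class as a percentage of the total
#' input the neuron receives within that glomerulus. Inputs from
#' uniglomerular partners (OSNs, uPNs) are attributed to the partner's home
#' glomerulus; inputs from multiglomerular partners are attributed by
#' postsynaptic-site mesh containment. Uniglomerular partners lacking a home
#' glomerulus are excluded and counted in the `excluded` attribute.
#'
#' @param conn an `al_connectome`.
#' @param neuron neuron id.
#' @param assigned output of [assign_synapses()] (computed if missing).
#' @return data.frame with columns `neuron_id`, `glomerulus`, `class`, `n`,
#'   `percent`; attribute `excluded` gives the number of input rows dropped
#'   for lack of a home glomerulus.
#' @export
polarity_breakdown <- function(conn, neuron, assigned = NULL) {
  if (is.null(assigned)) assigned <- assign_synapses(conn)
  ann <- conn$annotations
  inputs <- assigned[assigned$post_neuron == neuron, , drop = FALSE]
  idx <- match(inputs$pre_neuron, ann$neuron_id)
  part_cat <- ann$category[idx]
  part_class <- ann$transmitter_class[idx]
  part_class[is.na(part_class)] <- "unknown"
  part_home <- ann$home_glomerulus[idx]
  uniglomerular <- part_cat %in% c("OSN", "uPN")
  glom <- ifelse(uniglomerular, part_home, inputs$post_glomerulus)
  excluded <- sum(uniglomerular & is.na(part_home))
  keep <- !is.na(glom)
  glom <- glom[keep]
  part_class <- part_class[keep]
  if (length(glom) == 0L) {
    out <- data.frame(neuron_id = character(), glomerulus = character(),
                      class = character(), n = integer(), percent = numeric())
    attr(out, "excluded") <- excluded
    return(out)
  }
  tab <- as.data.frame(table(glomerulus = glom,
                             class = factor(part_class,
                                            levels = TRANSMITTER_CLASSES)),
                       stringsAsFactors = FALSE)
  totals <- tapply(tab$Freq, tab$glomerulus, sum)
  out <- data.frame(neuron_id = neuron, glomerulus = tab$glomerulus,
                    class = tab$class, n = tab$Freq,
                    percent = 100 * tab$Freq / as.numeric(totals[tab$glomerulus]))
  out <- out[order(out$glomerulus, out$class), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
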
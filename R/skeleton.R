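#' Neuron skeleton
#'
#' A skeleton is a rooted tree of 3-D sample points in nanometres, the standard
#' representation of a traced neuronal arbor. Exactly one node is the root
#' (parent id -1); all other parent references must resolve and the graph must
#' be a single acyclic tree.
#'
#' @param neuron_id identifier of the neuron.
#' @param nodes data.frame with columns `node_id`, `parent_id`, `x`, `y`, `z`,
#'   `radius` (coordinates and radius in nm; root has `parent_id = -1`).
#' @return an object of class `al_skeleton`.
#' @export
skeleton <- function(neuron_id, nodes) {
  required <- c("node_id", "parent_id", "x", "y", "z", "radius")
  al_assert(all(required %in% names(nodes)), "al_structure_error",
            "skeleton %s: nodes must have columns %s", neuron_id,
            paste(required, collapse = ", "))
  nodes <- as.data.frame(nodes)[required]
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  al_assert(!anyDuplicated(nodes$node_id), "al_structure_error",
            "skeleton %s: duplicated node ids: %s", neuron_id,
            paste(nodes$node_id[duplicated(nodes$node_id)], collapse = ", "))
  al_assert(all(is.finite(as.matrix(nodes[c("x", "y", "z")]))),
            "al_structure_error", "skeleton %s: non-finite coordinates", neuron_id)
  roots <- nodes$node_id[nodes$parent_id == -1L]
  al_assert(length(roots) == 1L, "al_structure_error",
            "skeleton %s: expected exactly one root, found %d", neuron_id,
            length(roots))
  dangling <- setdiff(nodes$parent_id, c(-1L, nodes$node_id))
  if (length(dangling) > 0L) {
    bad <- nodes$node_id[nodes$parent_id %in% dangling]
    al_stop("al_structure_error",
            "skeleton %s: node(s) %s reference absent parent(s) %s", neuron_id,
            paste(bad, collapse = ", "), paste(dangling, collapse = ", "))
  }
  # connectivity/acyclicity: walk up from every node; a cycle or a second
  # component never reaches the root.
  parent_of <- stats::setNames(nodes$parent_id, nodes$node_id)
  n <- nrow(nodes)
  for (v in nodes$node_id) {
    steps <- 0L
    cur <- v
    while (cur != -1L) {
      cur <- parent_of[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > n) {
        al_stop("al_structure_error",
                "skeleton %s: cycle detected at node %d", neuron_id, v)
      }
    }
  }
  structure(list(neuron_id = as.character(neuron_id), nodes = nodes),
            class = "al_skeleton")
}

#' @export
print.al_skeleton <- function(x, ...) {
  cat(sprintf("<al_skeleton> %s: %d nodes, cable %.1f um\n",
              x$neuron_id, nrow(x$nodes), cable_length(x) / 1e3))
  invisible(x)
}

skeleton_root <- function(skel) skel$nodes$node_id[skel$nodes$parent_id == -1L]

# children list keyed by node id (character)
skeleton_children <- function(skel) {
  nd <- skel$nodes
  split(nd$node_id[nd$parent_id != -1L],
        factor(nd$parent_id[nd$parent_id != -1L], levels = nd$node_id))
}

#' Total cable length of a skeleton (nm)
#' @param skel an `al_skeleton`.
#' @return numeric length in nm.
#' @export
cable_length <- function(skel) {
  nd <- skel$nodes
  child <- nd[nd$parent_id != -1L, , drop = FALSE]
  if (nrow(child) == 0L) return(0)
  idx <- match(child$parent_id, nd$node_id)
  sum(sqrt((child$x - nd$x[idx])^2 + (child$y - nd$y[idx])^2 +
             (child$z - nd$z[idx])^2))
}

#' Read / write SWC skeleton files
#'
#' Standard 7-column SWC (`id type x y z radius parent`), one neuron per file;
#' the neuron id defaults to the file name without extension. Coordinates in nm;
#' root parent is -1.
#'
#' @param path file path.
#' @param neuron_id optional neuron identifier (default: file name).
#' @return `read_swc()` an `al_skeleton`; `write_swc()` the path, invisibly.
#' @export
read_swc <- function(path, neuron_id = NULL) {
  al_assert(file.exists(path), "al_load_error", "missing file: %s", path)
  if (is.null(neuron_id)) neuron_id <- sub("\\.swc$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  al_assert(length(lines) > 0L, "al_structure_error", "empty SWC file: %s", path)
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  al_assert(ncol(m) == 7L, "al_structure_error",
            "%s: SWC requires 7 columns, found %d", path, ncol(m))
  skeleton(neuron_id, data.frame(
    node_id = m[, 1], parent_id = m[, 7],
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6]
  ))
}

#' @param skel an `al_skeleton`.
#' @rdname read_swc
#' @export
write_swc <- function(skel, path) {
  nd <- skel$nodes
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   nd$node_id, 0L, nd$x, nd$y, nd$z, nd$radius, nd$parent_id)
  writeLines(c("# SWC: id type x y z radius parent", lines), path)
  invisible(path)
}
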
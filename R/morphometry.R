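#' Convert a skeleton to dotprops (points + unit tangents)
#'
#' The arbor is resampled to approximately `spacing` nm along each unbranched
#' segment, and the tangent at each point is the dominant direction (first
#' principal axis, sign-free) of its `k` nearest neighbours. This is the
#' point-cloud representation morphological similarity scoring operates on.
#'
#' @param skel an `al_skeleton`.
#' @param spacing resample spacing in nm (default 1000).
#' @param k neighbours used for the tangent estimate (default 5, minimum 2).
#' @return an object of class `al_dotprops` with fields `points` (n x 3),
#'   `tangents` (n x 3 unit rows) and `neuron_id`. A single-node skeleton
#'   yields one point with an arbitrary unit tangent and attribute
#'   `degenerate = TRUE`.
#' @export
to_dotprops <- function(skel, spacing = 1000, k = 5L) {
  al_assert(k >= 2L, "al_input_error", "to_dotprops: k must be >= 2")
  nd <- skel$nodes
  if (nrow(nd) == 1L) {
    return(structure(list(points = as.matrix(nd[, c("x", "y", "z")]),
                          tangents = matrix(c(1, 0, 0), 1),
                          neuron_id = skel$neuron_id),
                     class = "al_dotprops", degenerate = TRUE))
  }
  pts <- resample_segments(skel, spacing)
  n <- nrow(pts)
  kk <- min(k, n)
  d2 <- as.matrix(stats::dist(pts))^2
  tangents <- t(vapply(seq_len(n), function(i) {
    nb <- order(d2[i, ])[seq_len(kk)]
    x <- sweep(pts[nb, , drop = FALSE], 2, colMeans(pts[nb, , drop = FALSE]))
    sv <- svd(x, nu = 0, nv = 1)
    v <- sv$v[, 1]
    v / vec3_norm(v)
  }, numeric(3)))
  structure(list(points = pts, tangents = tangents, neuron_id = skel$neuron_id),
            class = "al_dotprops")
}

#' @export
print.al_dotprops <- function(x, ...) {
  cat(sprintf("<al_dotprops> %s: %d points\n", x$neuron_id, nrow(x$points)))
  invisible(x)
}

# Split the tree into unbranched segments (root/branch/leaf delimited) and
# place points every `spacing` nm of arclength along each segment polyline.
resample_segments <- function(skel, spacing) {
  nd <- skel$nodes
  kids <- skeleton_children(skel)
  n_kids <- vapply(kids, length, integer(1))
  root <- skeleton_root(skel)
  is_break <- nd$node_id == root | n_kids[as.character(nd$node_id)] != 1L
  coords <- as.matrix(nd[, c("x", "y", "z")])
  rownames(coords) <- nd$node_id
  out <- list()
  # walk down from each break node through runs of single-child nodes
  for (start in nd$node_id[is_break]) {
    for (child in kids[[as.character(start)]]) {
      path <- c(start, child)
      cur <- child
      while (!is_break[match(cur, nd$node_id)]) {
        cur <- kids[[as.character(cur)]][1]
        path <- c(path, cur)
      }
      poly <- coords[as.character(path), , drop = FALSE]
      seglen <- sqrt(rowSums(diff(poly)^2))
      cum <- c(0, cumsum(seglen))
      total <- cum[length(cum)]
      n_pts <- max(2L, round(total / spacing) + 1L)
      s <- seq(0, total, length.out = n_pts)
      out[[length(out) + 1L]] <- cbind(
        stats::approx(cum, poly[, 1], xout = s, ties = "ordered")$y,
        stats::approx(cum, poly[, 2], xout = s, ties = "ordered")$y,
        stats::approx(cum, poly[, 3], xout = s, ties = "ordered")$y
      )[-1, , drop = FALSE] # drop segment start to avoid branch duplicates
    }
  }
  pts <- rbind(coords[as.character(root), , drop = FALSE], do.call(rbind, out))
  dimnames(pts) <- NULL
  pts
}

#' Read a log-odds scoring table from delimited text
#'
#' Format: a TSV whose first column gives distance-bin upper edges in um and
#' whose remaining columns give the log-odds score per absolute tangent
#' dot-product bin (column names = bin upper edges in \[0, 1\]).
#'
#' @param path file path.
#' @return a scoring-table object usable as `scoring` in [nblast()].
#' @export
read_scoring_table <- function(path) {
  df <- read_tsv(path)
  d_edges <- as.numeric(df[[1]]) * 1e3 # um -> nm
  dot_edges <- as.numeric(names(df)[-1])
  mat <- as.matrix(df[, -1, drop = FALSE])
  al_assert(!anyNA(d_edges) && !anyNA(dot_edges), "al_input_error",
            "%s: scoring-table bin edges must be numeric", path)
  structure(list(d_edges = d_edges, dot_edges = dot_edges, logodds = mat),
            class = "al_scoring_table")
}

score_points <- function(d, adot, scoring, sigma) {
  if (identical(scoring, "parametric")) {
    return(exp(-d / sigma) * adot)
  }
  di <- pmin(findInterval(d, scoring$d_edges, left.open = TRUE) + 1L,
             length(scoring$d_edges))
  oi <- pmin(findInterval(adot, scoring$dot_edges, left.open = TRUE) + 1L,
             length(scoring$dot_edges))
  scoring$logodds[cbind(di, oi)]
}

#' Morphological similarity score between two dotprops
#'
#' For every query point, find the nearest target point and score
#' `f(distance, |tangent dot product|)`; the raw score is the sum over query
#' points. The normalized score divides by the query self-score so a neuron
#' scored against itself gives exactly 1. The mean-normalized variant averages
#' the two directions' normalized scores and is the quantity thresholded by
#' the candidate filter.
#'
#' @param query,target `al_dotprops` objects.
#' @param scoring `"parametric"` for the kernel `exp(-d / sigma) * |dot|`, or
#'   an `al_scoring_table` from [read_scoring_table()].
#' @param sigma distance scale of the parametric kernel in nm (default 3000,
#'   i.e. 3 um).
#' @return an object of class `al_nblast_score` with fields `raw`,
#'   `normalized`, `mean_normalized` and `direction`.
#' @export
nblast <- function(query, target, scoring = "parametric", sigma = 3000) {
  al_assert(inherits(query, "al_dotprops") && inherits(target, "al_dotprops"),
            "al_input_error", "nblast expects dotprops inputs")
  al_assert(nrow(query$points) > 0 && nrow(target$points) > 0,
            "al_input_error", "nblast: empty dotprops")
  raw_qt <- nblast_raw(query, target, scoring, sigma)
  raw_qq <- nblast_raw(query, query, scoring, sigma)
  raw_tt <- nblast_raw(target, target, scoring, sigma)
  raw_tq <- nblast_raw(target, query, scoring, sigma)
  structure(list(
    raw = raw_qt,
    normalized = raw_qt / raw_qq,
    mean_normalized = (raw_qt / raw_qq + raw_tq / raw_tt) / 2,
    direction = paste(query$neuron_id, "->", target$neuron_id)
  ), class = "al_nblast_score")
}

#' @export
print.al_nblast_score <- function(x, ...) {
  cat(sprintf("<al_nblast_score> %s: raw %.4g, normalized %.4f, mean %.4f\n",
              x$direction, x$raw, x$normalized, x$mean_normalized))
  invisible(x)
}

nblast_raw <- function(query, target, scoring = "parametric", sigma = 3000) {
  qp <- query$points
  tp <- target$points
  # squared distances query x target without forming huge intermediates
  d2 <- outer(rowSums(qp^2), rowSums(tp^2), `+`) - 2 * qp %*% t(tp)
  d2[d2 < 0] <- 0
  nn <- max.col(-d2, ties.method = "first")
  d <- sqrt(d2[cbind(seq_len(nrow(qp)), nn)])
  adot <- abs(rowSums(query$tangents * target$tangents[nn, , drop = FALSE]))
  sum(score_points(d, pmin(adot, 1), scoring, sigma))
}

#' Synapse flow centrality and axon-dendrite split
#'
#' For every node v, with input/output counts tallied in the subtree
#' at-or-distal-to v, the centrifugal flow is `I_distal * (O_total - O_distal)`
#' and the centripetal flow `(I_total - I_distal) * O_distal`; their sum C(v)
#' counts the input->output synapse pairs whose tree path crosses the edge
#' above v. The split node is the C-maximising node (ties broken by smallest
#' root-path distance, then smallest node id); the compartment on the split's
#' side holding the larger share of output sites is labelled the axon, and the
#' entropy-based [segregation_index()] of the two compartments summarises how
#' completely inputs and outputs are separated.
#'
#' @param skel an `al_skeleton`.
#' @param input_nodes,output_nodes node ids holding input (postsynaptic) and
#'   output (presynaptic) sites; repeats count multiply.
#' @return an object of class `al_arbor_split`: per-node table (`nodes` with
#'   centrifugal, centripetal, total flow and compartment label), `split_node`,
#'   `segregation_index`, `compartments` summary and a `degenerate` flag (TRUE
#'   when either synapse total is zero, in which case the split is undefined).
#' @export
flow_centrality <- function(skel, input_nodes, output_nodes) {
  nd <- skel$nodes
  al_assert(all(c(input_nodes, output_nodes) %in% nd$node_id),
            "al_input_error", "synapse sites must map to skeleton nodes")
  n <- nrow(nd)
  i_here <- tabulate(match(input_nodes, nd$node_id), nbins = n)
  o_here <- tabulate(match(output_nodes, nd$node_id), nbins = n)
  i_tot <- sum(i_here)
  o_tot <- sum(o_here)

  # order nodes root-first by BFS, then accumulate subtree counts in reverse
  kids <- skeleton_children(skel)
  root <- skeleton_root(skel)
  order_ids <- integer(n)
  depth <- numeric(n)
  order_ids[1] <- root
  head <- 1L; tail <- 1L
  dist_root <- stats::setNames(numeric(n), nd$node_id)
  while (head <= tail) {
    v <- order_ids[head]
    for (w in kids[[as.character(v)]]) {
      tail <- tail + 1L
      order_ids[tail] <- w
      vi <- match(v, nd$node_id); wi <- match(w, nd$node_id)
      dist_root[as.character(w)] <- dist_root[as.character(v)] +
        sqrt(sum((nd[wi, c("x", "y", "z")] - nd[vi, c("x", "y", "z")])^2))
    }
    head <- head + 1L
  }
  i_sub <- i_here
  o_sub <- o_here
  parent_idx <- match(nd$parent_id, nd$node_id)
  for (v in rev(order_ids[-1])) {
    vi <- match(v, nd$node_id)
    pi <- parent_idx[vi]
    i_sub[pi] <- i_sub[pi] + i_sub[vi]
    o_sub[pi] <- o_sub[pi] + o_sub[vi]
  }
  centrifugal <- i_sub * (o_tot - o_sub)
  centripetal <- (i_tot - i_sub) * o_sub
  total <- centrifugal + centripetal

  degenerate <- i_tot == 0L || o_tot == 0L
  nodes_df <- data.frame(node_id = nd$node_id, n_inputs = i_here,
                         n_outputs = o_here, centrifugal = centrifugal,
                         centripetal = centripetal, flow = total,
                         compartment = NA_character_)
  if (degenerate) {
    return(structure(list(nodes = nodes_df, split_node = NA_integer_,
                          segregation_index = NA_real_,
                          compartments = NULL, degenerate = TRUE),
                     class = "al_arbor_split"))
  }
  cmax <- max(total)
  cand <- which(total == cmax)
  cand <- cand[order(dist_root[as.character(nd$node_id[cand])],
                     nd$node_id[cand])]
  split_idx <- cand[1]
  split_node <- nd$node_id[split_idx]

  in_subtree <- logical(n)
  # members of the subtree at-or-distal-to the split (split node included)
  stack <- split_node
  while (length(stack) > 0) {
    v <- stack[[1]]; stack <- stack[-1]
    in_subtree[match(v, nd$node_id)] <- TRUE
    stack <- c(stack, kids[[as.character(v)]])
  }
  o_distal <- sum(o_here[in_subtree])
  distal_is_axon <- o_distal >= o_tot - o_distal
  nodes_df$compartment <- ifelse(in_subtree == distal_is_axon, "axon", "dendrite")
  comp <- data.frame(
    compartment = c("axon", "dendrite"),
    n_inputs = c(sum(i_here[nodes_df$compartment == "axon"]),
                 sum(i_here[nodes_df$compartment == "dendrite"])),
    n_outputs = c(sum(o_here[nodes_df$compartment == "axon"]),
                  sum(o_here[nodes_df$compartment == "dendrite"]))
  )
  s <- segregation_index(comp[c("n_inputs", "n_outputs")])
  structure(list(nodes = nodes_df, split_node = split_node,
                 segregation_index = s, compartments = comp,
                 degenerate = FALSE),
            class = "al_arbor_split")
}

#' @export
print.al_arbor_split <- function(x, ...) {
  if (x$degenerate) {
    cat("<al_arbor_split> degenerate (no inputs or no outputs); flow = 0\n")
  } else {
    cat(sprintf("<al_arbor_split> split at node %d, segregation index %.4f\n",
                x$split_node, x$segregation_index))
  }
  invisible(x)
}

#' Entropy-based axon-dendrite segregation index
#'
#' With `p_i` the input fraction of compartment i and `H(p)` the binary
#' entropy in nats (`0 log 0 = 0`), the index is
#' `S = 1 - sum(n_i H(p_i)) / (N H(p_total))`: 1 when inputs and outputs
#' occupy disjoint compartments, 0 when every compartment mirrors the global
#' input fraction. When the global entropy is zero (all synapses of one kind)
#' S is 0 by convention.
#'
#' @param compartments data.frame (or matrix) with columns `n_inputs` and
#'   `n_outputs`, one row per compartment.
#' @return segregation index in \[0, 1\].
#' @export
segregation_index <- function(compartments) {
  comp <- as.data.frame(compartments)
  al_assert(all(c("n_inputs", "n_outputs") %in% names(comp)),
            "al_input_error",
            "segregation_index needs n_inputs and n_outputs columns")
  n_i <- comp$n_inputs + comp$n_outputs
  al_assert(sum(n_i) > 0, "al_input_error",
            "segregation_index: all compartments empty")
  bin_entropy <- function(p) {
    ifelse(p <= 0 | p >= 1, 0, -p * log(p) - (1 - p) * log(1 - p))
  }
  keep <- n_i > 0
  p_i <- comp$n_inputs[keep] / n_i[keep]
  h_tot <- bin_entropy(sum(comp$n_inputs) / sum(n_i))
  if (h_tot == 0) return(0)
  s <- 1 - sum(n_i[keep] * bin_entropy(p_i)) / (sum(n_i) * h_tot)
  min(max(s, 0), 1)
}
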
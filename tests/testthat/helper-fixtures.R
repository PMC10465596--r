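# Fixtures are built in code at test time; nothing binary ships with the
# package.

# Axis-aligned cube as a closed triangle mesh (12 faces).
make_cube_mesh <- function(name = "CUBE", center = c(0, 0, 0), half = 1000) {
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  v <- sweep(as.matrix(s) * half, 2, center, `+`)
  # vertex order from expand.grid: index = 1 + (x>0) + 2*(y>0) + 4*(z>0)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = -1
    c(5, 6, 7), c(6, 8, 7),   # z = +1
    c(1, 2, 5), c(2, 6, 5),   # y = -1
    c(3, 7, 4), c(4, 7, 8),   # y = +1
    c(1, 5, 3), c(3, 5, 7),   # x = -1
    c(2, 4, 6), c(4, 8, 6)    # x = +1
  )
  glomerulus_mesh(name, v, f)
}

# Small planted circuit used across module tests.
tiny_sim <- function(seed = 7, ...) {
  make_connectome(population_spec(n_glomeruli = 4, n_patchy_lns = 3,
                                  n_other_lns = 8, seed = seed, ...))
}

# Hand-built connectome: one cube glomerulus, one LN, resident OSN/uPN and a
# second LN partner, with fully scripted connection rows.
mini_connectome <- function(rows) {
  mesh <- make_cube_mesh("DM2", c(0, 0, 0), 1000)
  mk_skel <- function(id, x0 = 0) {
    skeleton(id, data.frame(node_id = 1:2, parent_id = c(-1L, 1L),
                            x = c(x0, x0 + 100), y = 0, z = 0, radius = 50))
  }
  ids <- unique(c(rows$pre_neuron, rows$post_neuron))
  ann <- data.frame(
    neuron_id = ids,
    category = ifelse(grepl("^OSN", ids), "OSN",
                      ifelse(grepl("^uPN", ids), "uPN",
                             ifelse(grepl("^L", ids), "LN", "other"))),
    subtype = "none",
    transmitter_class = ifelse(grepl("^OSN|^uPN", ids), "excitatory",
                               ifelse(grepl("^L", ids), "inhibitory",
                                      "modulatory")),
    home_glomerulus = ifelse(grepl("^OSN|^uPN", ids), "DM2", NA_character_),
    tracing_status = "Traced")
  connectome(lapply(ids, mk_skel), rows, ann, list(mesh))
}

# One pre->post connection row; site defaults to the cube interior.
conn_row <- function(pre, post, id, site = c(0, 0, 0), pre_site = site) {
  data.frame(connector_id = id, pre_neuron = pre, post_neuron = post,
             pre_x = pre_site[1], pre_y = pre_site[2], pre_z = pre_site[3],
             post_x = site[1], post_y = site[2], post_z = site[3])
}

# Random rooted tree with n nodes (uniform parent attachment).
random_tree_skeleton <- function(n, seed) {
  set.seed(seed)
  parent <- c(-1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  skeleton(sprintf("tree%d", seed), data.frame(
    node_id = seq_len(n), parent_id = parent,
    x = runif(n, 0, 1e4), y = runif(n, 0, 1e4), z = runif(n, 0, 1e4),
    radius = 50))
}

# Independent flow-centrality oracle: enumerate every input-output pair's
# tree path explicitly and count, per node v, the pairs whose path uses the
# edge between v and its parent.
brute_force_flow <- function(skel, input_nodes, output_nodes) {
  nd <- skel$nodes
  parent <- stats::setNames(nd$parent_id, nd$node_id)
  root_path <- function(v) {
    p <- v
    while (parent[[as.character(v)]] != -1L) {
      v <- parent[[as.character(v)]]
      p <- c(p, v)
    }
    p
  }
  paths <- lapply(stats::setNames(nd$node_id, nd$node_id), root_path)
  flow <- stats::setNames(numeric(nrow(nd)), nd$node_id)
  for (i in input_nodes) {
    for (o in output_nodes) {
      pi <- paths[[as.character(i)]]
      po <- paths[[as.character(o)]]
      common <- intersect(pi, po)
      lca <- common[1] # root paths list deepest-first
      path_nodes <- union(pi[seq_len(match(lca, pi))],
                          po[seq_len(match(lca, po))])
      crossing <- setdiff(path_nodes, lca)
      flow[as.character(crossing)] <- flow[as.character(crossing)] + 1
    }
  }
  unname(flow[as.character(nd$node_id)])
}

# Textbook two-pass Pearson correlation (oracle for the correlation module).
two_pass_pearson <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# Rotation matrix about an arbitrary axis.
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

transform_dotprops <- function(dp, rot, shift) {
  dp$points <- dp$points %*% t(rot) + matrix(shift, nrow(dp$points), 3,
                                             byrow = TRUE)
  dp$tangents <- dp$tangents %*% t(rot)
  dp
}

make_dotprops <- function(points, tangents, id = "manual") {
  tangents <- tangents / sqrt(rowSums(tangents^2))
  structure(list(points = points, tangents = tangents, neuron_id = id),
            class = "al_dotprops")
}
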
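test_that("dotprops tangents follow the cable and resampling hits the spacing", {
  sk <- skeleton("line", data.frame(node_id = 1:3, parent_id = c(-1L, 1L, 2L),
                                    x = c(0, 5e3, 1e4), y = 0, z = 0,
                                    radius = 1))
  dp <- to_dotprops(sk, spacing = 1000, k = 3)
  expect_true(all(abs(abs(dp$tangents[, 1]) - 1) < 1e-6))
  # 100 um cable at 1 um spacing: point count in [90, 110]
  long <- skeleton("cable", data.frame(
    node_id = 1:2, parent_id = c(-1L, 1L), x = c(0, 1e5), y = 0, z = 0,
    radius = 1))
  n <- nrow(to_dotprops(long, spacing = 1000)$points)
  expect_gte(n, 90)
  expect_lte(n, 110)
  # deterministic
  expect_equal(to_dotprops(sk, 1000), to_dotprops(sk, 1000))
  expect_true(all(abs(rowSums(dp$tangents^2) - 1) < 1e-6))
  # single-node skeleton: one point, flagged
  single <- skeleton("pt", data.frame(node_id = 1L, parent_id = -1L,
                                      x = 0, y = 0, z = 0, radius = 1))
  dps <- to_dotprops(single)
  expect_equal(nrow(dps$points), 1)
  expect_true(isTRUE(attr(dps, "degenerate")))
})

test_that("similarity self-score is exactly 1 and raw matches a hand-summed toy", {
  q <- make_dotprops(matrix(c(0, 0, 0, 1e3, 0, 0, 2e3, 0, 0), 3, byrow = TRUE),
                     matrix(c(1, 0, 0, 1, 0, 0, 0, 1, 0), 3, byrow = TRUE), "q")
  t_ <- make_dotprops(matrix(c(0, 500, 0, 1e3, 500, 0, 3e3, 0, 0), 3,
                             byrow = TRUE),
                      matrix(c(1, 0, 0, 0, 0, 1, 1, 1, 0), 3, byrow = TRUE),
                      "t")
  expect_equal(nblast(q, q)$normalized, 1)
  expect_equal(nblast(t_, t_)$normalized, 1)
  # brute force over the 3 x 3 distance matrix with f = exp(-d / 3um) * |dot|
  sigma <- 3000
  raw <- 0
  for (i in 1:3) {
    d <- sqrt(colSums((t(t_$points) - q$points[i, ])^2))
    j <- which.min(d)
    raw <- raw + exp(-d[j] / sigma) *
      abs(sum(q$tangents[i, ] * t_$tangents[j, ]))
  }
  got <- nblast(q, t_, sigma = sigma)
  expect_equal(got$raw, raw, tolerance = 1e-12)
  expect_equal(got$normalized, raw / 3, tolerance = 1e-12)
})

test_that("similarity is invariant to rigid motion and point order", {
  sk <- random_tree_skeleton(30, seed = 5)
  sk2 <- random_tree_skeleton(30, seed = 6)
  q <- to_dotprops(sk, spacing = 800)
  t_ <- to_dotprops(sk2, spacing = 800)
  s0 <- nblast(q, t_)
  rot <- rotation_matrix(c(1, 2, 3), 0.83)
  shift <- c(1e4, -2e4, 5e3)
  s1 <- nblast(transform_dotprops(q, rot, shift),
               transform_dotprops(t_, rot, shift))
  expect_equal(s1$raw, s0$raw, tolerance = 1e-7)
  expect_equal(s1$mean_normalized, s0$mean_normalized, tolerance = 1e-7)
  perm <- sample(nrow(q$points))
  qp <- make_dotprops(q$points[perm, ], q$tangents[perm, ], "perm")
  expect_equal(nblast(qp, t_)$raw, s0$raw, tolerance = 1e-12)
})

test_that("log-odds table scoring: self-score 1, distant pairs at the floor", {
  tab <- data.frame(d_um = c(2, 10, 1e6),
                    `0.5` = c(2, -1, -8), `1` = c(5, 0.5, -8),
                    check.names = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(tab, path)
  scoring <- read_scoring_table(path)
  q <- make_dotprops(matrix(c(0, 0, 0, 1e3, 0, 0), 2, byrow = TRUE),
                     matrix(c(1, 0, 0, 1, 0, 0), 2, byrow = TRUE), "q")
  expect_equal(nblast(q, q, scoring = scoring)$normalized, 1)
  far <- transform_dotprops(q, diag(3), c(5e8, 0, 0))
  s <- nblast(q, far, scoring = scoring)
  expect_equal(s$raw, 2 * -8) # both points land in the far/low bin
  expect_lt(s$normalized, 0)
  # empty dotprops are refused
  empty <- make_dotprops(matrix(numeric(0), 0, 3), matrix(numeric(0), 0, 3))
  expect_error(nblast(empty, q), class = "al_input_error")
})

test_that("flow centrality matches hand-counted path example and is degenerate-safe", {
  sk <- skeleton("path", data.frame(node_id = 1:5, parent_id = c(-1L, 1:4),
                                    x = 0:4 * 1e3, y = 0, z = 0, radius = 1))
  fc <- flow_centrality(sk, input_nodes = c(1, 2), output_nodes = c(4, 5))
  expect_equal(fc$nodes$flow, c(0, 2, 4, 4, 2))
  expect_equal(fc$split_node, 3) # tie with node 4 broken towards the root
  expect_equal(fc$segregation_index, 1)
  expect_setequal(
    fc$nodes$compartment[fc$nodes$node_id %in% c(4, 5)], "axon")
  out_only <- flow_centrality(sk, integer(0), c(4, 5))
  expect_true(out_only$degenerate)
  expect_true(all(out_only$nodes$flow == 0))
  expect_error(flow_centrality(sk, c(99), c(4)), class = "al_input_error")
})

test_that("flow centrality equals the brute-force pair-path oracle on random trees", {
  for (s in 1:25) {
    n <- sample(5:50, 1)
    sk <- random_tree_skeleton(n, seed = 1000 + s)
    ins <- sample(sk$nodes$node_id, 10, replace = TRUE)
    outs <- sample(sk$nodes$node_id, 10, replace = TRUE)
    fc <- flow_centrality(sk, ins, outs)
    expect_equal(fc$nodes$flow, brute_force_flow(sk, ins, outs))
  }
})

test_that("segregation index: worked values, bounds and label symmetry", {
  expect_equal(segregation_index(data.frame(n_inputs = c(5, 0),
                                            n_outputs = c(0, 7))), 1)
  expect_equal(segregation_index(data.frame(n_inputs = c(2, 4),
                                            n_outputs = c(2, 4))), 0)
  expect_equal(
    segregation_index(data.frame(n_inputs = c(3, 1), n_outputs = c(1, 3))),
    1 - (-0.75 * log(0.75) - 0.25 * log(0.25)) / log(2),
    tolerance = 1e-12)
  expect_equal(
    round(segregation_index(data.frame(n_inputs = c(3, 1),
                                       n_outputs = c(1, 3))), 4), 0.1887)
  # swapping the input/output labels globally leaves S unchanged
  set.seed(3)
  for (k in 1:20) {
    a <- matrix(rpois(6, 4), 3, 2)
    df <- data.frame(n_inputs = a[, 1], n_outputs = a[, 2])
    if (sum(df) == 0) next
    swapped <- data.frame(n_inputs = df$n_outputs, n_outputs = df$n_inputs)
    expect_equal(segregation_index(df), segregation_index(swapped),
                 tolerance = 1e-12)
  }
  # all synapses of one kind: S = 0 by convention
  expect_equal(segregation_index(data.frame(n_inputs = c(3, 2),
                                            n_outputs = c(0, 0))), 0)
  expect_error(segregation_index(data.frame(n_inputs = 0, n_outputs = 0)),
               class = "al_input_error")
})
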
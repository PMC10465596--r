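test_that("glomerulus placement is deterministic, non-overlapping, and closed", {
  g1 <- make_glomeruli(10, seed = 5)
  g2 <- make_glomeruli(10, seed = 5)
  expect_equal(g1[[3]]$vertices, g2[[3]]$vertices)
  expect_equal(length(unique(names(g1))), 10)
  # pairwise centroid separation exceeds the sum of the largest semiaxes
  ells <- lapply(g1, attr, "ellipsoid")
  for (i in 1:9) {
    for (j in (i + 1):10) {
      d <- sqrt(sum((ells[[i]]$center - ells[[j]]$center)^2))
      expect_gt(d, max(ells[[i]]$semiaxes) + max(ells[[j]]$semiaxes))
    }
  }
  one <- make_glomeruli(1, seed = 2)
  expect_true(point_in_mesh(colMeans(one[[1]]$vertices), one[[1]]))
  expect_error(make_glomeruli(50, box = c(0, 2e4, 0, 2e4, 0, 2e4), seed = 1,
                              max_tries = 2000L),
               class = "al_placement_error")
})

test_that("spec invariants are enforced", {
  expect_error(population_spec(p = 1.2, seed = 1), class = "al_spec_error")
  expect_error(population_spec(r = -2, seed = 1), class = "al_spec_error")
  expect_error(population_spec(), class = "al_spec_error") # missing seed
  expect_error(clone_matrix_spec(), class = "al_spec_error")
  expect_error(trace_spec(onset_frame = 99, n_frames = 40, seed = 1),
               class = "al_spec_error")
  asym <- matrix(c(1, 0.5, 0.2, 1), 2)
  expect_error(clone_matrix_spec(p = c(0.5, 0.5), R_target = asym, seed = 1),
               class = "al_spec_error")
})

test_that("planted innervation and ratio structure appear in the connectome", {
  # p = 1: every planted LN innervates every glomerulus
  sim <- make_connectome(population_spec(n_glomeruli = 3, n_patchy_lns = 2,
                                         n_other_lns = 2, p = 1, seed = 3))
  expect_true(all(sim$ground_truth$innervation == 1L))
  # r = 1 in one glomerulus: planted LNs make no output there;
  # r = -1: no input there
  sim <- make_connectome(population_spec(n_glomeruli = 3, n_patchy_lns = 2,
                                         n_other_lns = 0, p = 1,
                                         r = c(1, -1, 0), seed = 4))
  gt <- sim$ground_truth$counts
  gt <- gt[grepl("^pLN", gt$neuron_id), ]
  gloms <- names(make_glomeruli(3, seed = substream_seed(4, "glomeruli")))
  expect_true(all(gt$n_output[gt$glomerulus == gloms[1]] == 0))
  expect_true(all(gt$n_input[gt$glomerulus == gloms[2]] == 0))
  expect_true(all(abs(gt$ratio[gt$glomerulus == gloms[3]]) <= 1 / 8))
})

test_that("innervation frequency of a planted ensemble matches its probability", {
  # many patchy LNs, innervation only (no synapses) would be enough, but the
  # generator is exercised whole at a reduced synapse load
  # enough glomeruli that the every-LN-innervates-something floor is negligible
  sim <- make_connectome(population_spec(
    n_glomeruli = 10, n_patchy_lns = 150, n_other_lns = 0, p = 0.3,
    n_osns_per_glomerulus = 1, n_upns_per_glomerulus = 1,
    syn_per_glomerulus = 2, seed = 9))
  freq <- colMeans(sim$ground_truth$innervation)
  se <- sqrt(0.3 * 0.7 / 150)
  expect_true(all(abs(freq - 0.3) <= 3 * se + 1e-9))
})

test_that("generators are pure functions of (spec, seed)", {
  s <- population_spec(n_glomeruli = 3, n_patchy_lns = 2, n_other_lns = 3,
                       seed = 11)
  a <- make_connectome(s)
  b <- make_connectome(s)
  expect_equal(a$connectome$connections, b$connectome$connections)
  expect_equal(a$connectome$skeletons[["pLN_01"]]$nodes,
               b$connectome$skeletons[["pLN_01"]]$nodes)
  cs <- clone_matrix_spec(n_clones = 40, p = 0.5, seed = 12)
  expect_equal(unclass(make_clone_matrix(cs)), unclass(make_clone_matrix(cs)))
  ts <- trace_spec(noise_sd = 2, seed = 13)
  expect_equal(make_trace(ts)$values, make_trace(ts)$values)
})

test_that("clone matrices honour degenerate margins and stay binary", {
  spec <- clone_matrix_spec(n_clones = 200, p = c(0, 0.5, 1), seed = 6)
  m <- make_clone_matrix(spec)
  expect_true(all(m %in% c(0L, 1L)))
  expect_true(all(m[, 1] == 0L))
  expect_true(all(m[, 3] == 1L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_innervation_matrix(m, path)
  expect_equal(unclass(read_innervation_matrix(path)), unclass(m))
})

test_that("copula calibration recovers planted binary-scale correlations", {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.5
  R[3, 4] <- R[4, 3] <- -0.4
  spec <- clone_matrix_spec(n_clones = 10000, p = c(0.5, 0.4, 0.6, 0.5),
                            R_target = R, seed = 8)
  m <- make_clone_matrix(spec)
  r <- stats::cor(unclass(m))
  expect_equal(r[1, 2], 0.5, tolerance = 0.05 / 0.5)
  expect_equal(r[3, 4], -0.4, tolerance = 0.05 / 0.4)
  expect_lt(max(abs(r[1, 3]), abs(r[1, 4]), abs(r[2, 3]), abs(r[2, 4])), 0.05)
  # unattainable binary correlation at extreme margins is refused
  expect_error(
    make_clone_matrix(clone_matrix_spec(
      n_clones = 10, p = c(0.05, 0.95),
      R_target = matrix(c(1, 0.9, 0.9, 1), 2), seed = 1)),
    class = "al_spec_error")
})

test_that("trace generator produces the planted baseline, response and noise", {
  flat <- make_trace(trace_spec(amplitude = 0, noise_sd = 0,
                                tau_bleach = Inf, seed = 1))
  expect_equal(flat$values, rep(100, 40))
  resp <- make_trace(trace_spec(amplitude = 0.5, noise_sd = 0,
                                tau_bleach = Inf, seed = 1))
  expect_equal(max(resp$values / 100 - 1), 0.5)
  expect_equal(which.max(resp$values), 20) # onset frame
})
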
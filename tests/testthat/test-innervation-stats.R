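test_that("co-innervation correlations: exact limits and the t-based p-value", {
  m <- innervation_matrix(cbind(A = c(1, 1, 0, 0, 1), B = c(1, 1, 0, 0, 1),
                                C = c(0, 0, 1, 1, 0)))
  res <- innervation_correlations(m)
  expect_equal(res$r["A", "B"], 1)
  expect_equal(res$r["A", "C"], -1) # a column and its complement
  expect_true(all(res$p[upper.tri(res$p)] > 0))
  # a 50-clone pair whose sample correlation is 0.4901 has two-sided
  # p = 3.03e-4 under the t formula (t = r sqrt((n-2)/(1-r^2)), df = 48)
  a <- c(rep(1L, 16), rep(0L, 34))
  b <- c(rep(1L, 12), rep(0L, 4), rep(1L, 8), rep(0L, 26))
  res <- innervation_correlations(innervation_matrix(cbind(DM3 = a, D = b)))
  expect_equal(res$r["DM3", "D"], 0.490098, tolerance = 1e-6)
  expect_equal(res$p["DM3", "D"], 3.0298e-4, tolerance = 1e-4)
})

test_that("correlations equal a textbook two-pass computation and cor.test p", {
  set.seed(7)
  m <- matrix(rbinom(200, 1, 0.4), 40, 5,
              dimnames = list(NULL, LETTERS[1:5]))
  res <- innervation_correlations(innervation_matrix(m))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(res$r[i, j], two_pass_pearson(m[, i], m[, j]),
                   tolerance = 1e-12)
      ct <- stats::cor.test(m[, i], m[, j])
      expect_equal(res$p[i, j], ct$p.value, tolerance = 1e-10)
    }
  }
})

test_that("constant columns are flagged as undefined, not zero-filled", {
  m <- innervation_matrix(cbind(A = c(1, 0, 1, 0), B = c(1, 1, 1, 1),
                                C = c(0, 1, 1, 0)))
  res <- innervation_correlations(m)
  expect_equal(res$constant_columns, "B")
  expect_true(all(is.na(res$r["B", ])))
  expect_true(all(is.na(res$r[, "B"])))
  expect_false(anyNA(res$r["A", "C"]))
  expect_error(innervation_correlations(m[1:2, ]), class = "al_input_error")
})

test_that("Holm adjustment only raises p-values", {
  set.seed(9)
  m <- innervation_matrix(matrix(rbinom(300, 1, 0.5), 30, 10,
                                 dimnames = list(NULL, letters[1:10])))
  p0 <- innervation_correlations(m)$p
  p1 <- innervation_correlations(m, adjust = "holm")$p
  up <- upper.tri(p0)
  expect_true(all(p1[up] >= p0[up] - 1e-15))
})

test_that("Ward (ward.D2) ordering: first merge, adjacency, block recovery", {
  # 1-D points {0, 1, 10}: Ward's criterion merges {0, 1} first
  hc <- attr(ward_order(matrix(c(0, 1, 10), 3, 1,
                               dimnames = list(NULL, "x"))), "hclust")
  expect_setequal(hc$merge[1, ], c(-1, -2))
  # identical rows end up adjacent in leaf order
  m <- rbind(c(1, 0, 0, 1), c(0, 1, 1, 0), c(1, 0, 0, 1), c(0, 0, 1, 1))
  colnames(m) <- letters[1:4]
  ord <- ward_order(m, "rows")
  pos <- match(c(1, 3), ord)
  expect_equal(abs(diff(pos)), 1)
  # planted two-block structure is separated (between/within ratio >= 3)
  set.seed(2)
  blocks <- rbind(matrix(rnorm(40, 0, 0.3), 10, 4),
                  matrix(rnorm(40, 10, 0.3), 10, 4))
  colnames(blocks) <- letters[1:4]
  ordb <- ward_order(blocks, "rows")
  expect_true(identical(sort(ordb[1:10]), 1:10) ||
                identical(sort(ordb[1:10]), 11:20))
  # permuting rows changes nothing but the tie-break-resolved labels
  perm <- sample(20)
  ordp <- ward_order(blocks[perm, ], "rows")
  expect_true(identical(sort(perm[ordp[1:10]]), 1:10) ||
                identical(sort(perm[ordp[1:10]]), 11:20))
  expect_equal(ward_order(matrix(1, 1, 2, dimnames = list(NULL, c("a", "b"))),
                          "rows"), 1L)
})

test_that("innervation frequency and its volume correlation", {
  m <- innervation_matrix(matrix(1L, 5, 4, dimnames = list(NULL, letters[1:4])))
  vols <- stats::setNames(c(1, 2, 3, 4) * 1e9, letters[1:4])
  fr <- innervation_frequency(m, vols)
  expect_equal(unname(fr$frequency), rep(1, 4))
  m2 <- m
  m2[, "a"] <- 0L
  expect_equal(unname(innervation_frequency(m2, vols)$frequency["a"]), 0)
  # columns without a volume are excluded and reported
  fr2 <- innervation_frequency(m, vols[1:3])
  expect_equal(fr2$excluded, "d")
  expect_equal(fr2$n_glomeruli, 3)
  # planted frequency ~ volume: positive, significant correlation at n = 500
  vols3 <- stats::setNames(seq(2, 10, length.out = 6) * 1e9,
                           glomerulus_labels(6))
  p_inn <- 0.08 * seq(2, 10, length.out = 6) # proportional to volume
  cm <- make_clone_matrix(clone_matrix_spec(n_clones = 500, p = p_inn,
                                            glomeruli = names(vols3),
                                            seed = 19))
  fr3 <- innervation_frequency(cm, vols3)
  expect_gt(fr3$r, 0.8)
  expect_lt(fr3$p, 0.05)
})

test_that("coupon collector: exact expectation, CDF and quantile behaviour", {
  expect_equal(coupon_collector(1)$expectation, 1)
  expect_equal(coupon_collector(2)$expectation, 3)
  expect_equal(coupon_collector(13)$expectation, 13 * sum(1 / 1:13),
               tolerance = 1e-12)
  expect_equal(round(coupon_collector(13)$expectation, 2), 41.34)
  # the asymptotic mode at the mean driver-line count 13.2 rounds up to 43
  asym <- coupon_collector(13.2, method = "asymptotic")$expectation
  expect_equal(ceiling(asym), 43)
  # CDF is non-decreasing and approaches 1
  p <- vapply(13:400, coupon_cdf, numeric(1), n_types = 13)
  expect_true(all(diff(p) >= -1e-12))
  expect_gt(p[length(p)], 1 - 1e-6)
  expect_equal(coupon_cdf(12, 13), 0)
  # quantile is the smallest t reaching coverage q
  cc <- coupon_collector(13, mode = "quantile", q = 0.95)
  expect_gte(cc$t_star, 13)
  expect_gte(coupon_cdf(cc$t_star, 13), 0.95)
  expect_lt(coupon_cdf(cc$t_star - 1L, 13), 0.95)
  expect_error(coupon_collector(13, mode = "quantile", q = 1.5),
               class = "al_input_error")
})

test_that("coupon-collector CDF matches Monte-Carlo within 3 SE", {
  n <- 13
  runs <- 100000
  set.seed(11)
  # exact simulation via the geometric stage decomposition of T
  draws <- rep(n, runs)
  for (s in seq_len(n - 1)) {
    draws <- draws + stats::rgeom(runs, (n - s) / n)
  }
  for (t in c(30, 41, 60)) {
    mc <- mean(draws <= t)
    se <- sqrt(mc * (1 - mc) / runs)
    expect_lt(abs(coupon_cdf(t, n) - mc), 3 * se + 1e-9)
  }
})
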
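#' Pairwise co-innervation correlations with significance
#'
#' Pearson product-moment correlation between every pair of glomerulus
#' columns of a binary innervation matrix, with two-sided p-values from
#' `t = r * sqrt((n - 2) / (1 - r^2))` against the t distribution with n - 2
#' degrees of freedom (no multiplicity correction by default; an optional
#' Holm adjustment covers reanalysis). Constant columns have undefined
#' correlations: their entries are `NA` and they are listed in the
#' `constant_columns` field rather than zero-filled.
#'
#' @param x an `al_innervation_matrix` (or any numeric matrix with column
#'   names); rows are clones/animals, columns glomeruli.
#' @param adjust `"none"` (default, matching the original reporting) or
#'   `"holm"`.
#' @return an object of class `al_correlation_result`: `r` and `p` matrices,
#'   `n` (rows used), `constant_columns`.
#' @export
innervation_correlations <- function(x, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  x <- as.matrix(unclass(x))
  n <- nrow(x)
  al_assert(n >= 3, "al_input_error",
            "need at least 3 rows for correlation, got %d", n)
  sds <- apply(x, 2, stats::sd)
  constant <- colnames(x)[sds == 0]
  r <- suppressWarnings(stats::cor(x))
  r[, constant] <- NA_real_
  r[constant, ] <- NA_real_
  diag(r) <- ifelse(colnames(x) %in% constant, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- pmax(p, .Machine$double.xmin) # keep within (0, 1]
  diag(p) <- NA_real_
  if (adjust == "holm") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = "holm")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  structure(list(r = r, p = p, n = n, constant_columns = constant,
                 adjust = adjust),
            class = "al_correlation_result")
}

#' @export
print.al_correlation_result <- function(x, ...) {
  cat(sprintf("<al_correlation_result> %d x %d glomeruli, n = %d rows%s\n",
              ncol(x$r), ncol(x$r), x$n,
              if (length(x$constant_columns))
                paste0("; constant: ",
                       paste(x$constant_columns, collapse = ", ")) else ""))
  invisible(x)
}

#' Ward (ward.D2) leaf ordering
#'
#' Agglomerative clustering of rows or columns with Ward's criterion on
#' Euclidean distances, returning the dendrogram leaf order with a
#' deterministic tie-break: at every merge, the branch containing the lower
#' original index comes first.
#'
#' @param x matrix; rows are clones, columns glomeruli.
#' @param axis `"rows"` or `"columns"`.
#' @return integer vector of original indices in leaf order, with the
#'   `hclust` object as attribute `"hclust"`.
#' @export
ward_order <- function(x, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- as.matrix(unclass(x))
  if (axis == "columns") m <- t(m)
  if (nrow(m) == 1L) return(1L)
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  order <- leaf_order_minfirst(hc$merge)
  attr(order, "hclust") <- hc
  order
}

# Leaf order with the lower-original-index-first policy at every merge.
leaf_order_minfirst <- function(merge) {
  n <- nrow(merge) + 1L
  leaves <- vector("list", nrow(merge))
  expand <- function(k) if (k < 0) -k else leaves[[k]]
  for (i in seq_len(nrow(merge))) {
    a <- expand(merge[i, 1])
    b <- expand(merge[i, 2])
    leaves[[i]] <- if (min(a) <= min(b)) c(a, b) else c(b, a)
  }
  leaves[[nrow(merge)]]
}

#' Innervation frequency and its correlation with glomerulus volume
#'
#' Column means of the innervation matrix (the fraction of clones innervating
#' each glomerulus) correlated against per-glomerulus volumes; the correlation
#' and p-value use the same Pearson + t machinery as
#' [innervation_correlations()]. Columns without a volume are excluded and
#' reported.
#'
#' @param x an `al_innervation_matrix`.
#' @param volumes named numeric vector of glomerulus volumes (nm^3).
#' @return list with `frequency` (named vector), `r`, `p`, `n_glomeruli`,
#'   `excluded` (columns lacking a volume).
#' @export
innervation_frequency <- function(x, volumes) {
  m <- as.matrix(unclass(x))
  freq <- colMeans(m)
  excluded <- setdiff(colnames(m), names(volumes))
  keep <- intersect(colnames(m), names(volumes))
  al_assert(length(keep) >= 3, "al_input_error",
            "need volumes for at least 3 glomeruli")
  f <- freq[keep]
  v <- volumes[keep]
  n <- length(keep)
  if (stats::sd(f) == 0 || stats::sd(v) == 0) {
    # constant frequencies (or volumes) leave the correlation undefined
    r <- NA_real_
    p <- NA_real_
  } else {
    r <- stats::cor(f, v)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(frequency = freq, r = r, p = p, n_glomeruli = n, excluded = excluded)
}

#' Coupon-collector sampling design
#'
#' How many uniform draws are needed to observe all `n_types` distinct types?
#' The expectation is `n * H_n` (harmonic number); the distribution function
#' is computed exactly by inclusion-exclusion,
#' `P(T <= t) = sum_k (-1)^k C(n, k) ((n - k) / n)^t`, and the quantile
#' `t*` is the smallest t with `P(T <= t) >= q`. An asymptotic expectation
#' mode, `n (ln n + gamma + 1 / (2n))`, is also exposed: with fractional mean
#' type counts it reproduces published sample-size choices that the exact
#' integer formula cannot.
#'
#' @param n_types number of distinct types (>= 1); may be fractional in
#'   `method = "asymptotic"`.
#' @param mode `"expectation"` or `"quantile"`.
#' @param q coverage probability for the quantile mode, in (0, 1).
#' @param method `"exact"` or `"asymptotic"` (expectation only).
#' @return an object of class `al_coupon_result` with `n_types`,
#'   `expectation`, and for the quantile mode `q` and `t_star`.
#' @export
coupon_collector <- function(n_types, mode = c("expectation", "quantile"),
                             q = 0.95, method = c("exact", "asymptotic")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  al_assert(n_types >= 1, "al_input_error", "n_types must be >= 1")
  expectation <- if (method == "asymptotic") {
    gamma_e <- 0.57721566490153286
    n_types * (log(n_types) + gamma_e + 1 / (2 * n_types))
  } else {
    al_assert(n_types == round(n_types), "al_input_error",
              "exact mode needs an integer n_types")
    n_types * sum(1 / seq_len(n_types))
  }
  out <- list(n_types = n_types, expectation = expectation, method = method)
  if (mode == "quantile") {
    al_assert(is.numeric(q) && length(q) == 1 && q > 0 && q < 1,
              "al_input_error", "q must lie in (0, 1)")
    al_assert(n_types == round(n_types), "al_input_error",
              "quantile mode needs an integer n_types")
    t <- as.integer(n_types)
    while (coupon_cdf(t, n_types) < q) t <- t + 1L
    out$q <- q
    out$t_star <- t
  }
  structure(out, class = "al_coupon_result")
}

#' Exact P(all types collected by draw t), by inclusion-exclusion
#'
#' @param t number of draws.
#' @param n_types number of distinct types.
#' @return probability that `t` uniform draws cover all `n_types` types.
#' @export
coupon_cdf <- function(t, n_types) {
  if (t < n_types) return(0)
  n <- as.integer(n_types)
  k <- 0:n
  frac <- (n - k) / n
  # log-space terms for numerical stability; (0/n)^t term is 0 for t > 0
  terms <- ifelse(frac > 0, exp(lchoose(n, k) + t * log(frac)),
                  as.numeric(t == 0))
  p <- sum(terms * (-1)^k)
  min(max(p, 0), 1)
}

#' @export
print.al_coupon_result <- function(x, ...) {
  cat(sprintf("<al_coupon_result> n = %g types: E[T] = %.4f (%s)%s\n",
              x$n_types, x$expectation, x$method,
              if (!is.null(x$t_star))
                sprintf("; t*(q = %g) = %d", x$q, x$t_star) else ""))
  invisible(x)
}
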
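#' Clone innervation matrix and its specification
#'
#' A binary clones x glomeruli matrix: each row is the set of glomeruli
#' innervated by one stochastically labelled single interneuron clone (one
#' animal). `clone_matrix_spec()` describes the sampling model: marginal
#' innervation probabilities `p` per glomerulus and a target pairwise
#' *binary-scale* (phi) correlation matrix `R_target`, realised through a
#' latent-Gaussian (copula) threshold model whose latent correlations are
#' calibrated so that the binary variables attain `R_target`.
#'
#' @param n_clones number of clones (rows; default 50).
#' @param p marginal innervation probabilities, named by glomerulus or
#'   recycled over `glomeruli`.
#' @param R_target symmetric unit-diagonal correlation matrix (default
#'   identity = independent columns).
#' @param glomeruli column names (default taken from `p` or generated).
#' @param seed integer seed (mandatory).
#' @return `clone_matrix_spec()` an `al_clone_spec`; `make_clone_matrix()` an
#'   `al_innervation_matrix` (binary matrix with clone row names and
#'   glomerulus column names).
#' @export
clone_matrix_spec <- function(n_clones = 50L, p = 0.5, R_target = NULL,
                              glomeruli = NULL, seed) {
  al_assert(!missing(seed), "al_spec_error", "clone_matrix_spec: seed is mandatory")
  if (is.null(glomeruli)) {
    glomeruli <- if (!is.null(names(p))) names(p) else {
      glomerulus_labels(max(length(p), if (is.null(R_target)) 5L else nrow(R_target)))
    }
  }
  g <- length(glomeruli)
  p <- stats::setNames(rep_len(p, g), glomeruli)
  al_assert(all(p >= 0 & p <= 1), "al_spec_error", "p must lie in [0, 1]")
  if (is.null(R_target)) R_target <- diag(g)
  R_target <- as.matrix(R_target)
  al_assert(nrow(R_target) == g && ncol(R_target) == g, "al_spec_error",
            "R_target must be %d x %d", g, g)
  al_assert(isTRUE(all.equal(R_target, t(R_target))) &&
              all(abs(diag(R_target) - 1) < 1e-12),
            "al_spec_error", "R_target must be symmetric with unit diagonal")
  dimnames(R_target) <- list(glomeruli, glomeruli)
  structure(list(n_clones = as.integer(n_clones), p = p, R_target = R_target,
                 glomeruli = glomeruli, seed = as.integer(seed)),
            class = "al_clone_spec")
}

# P(Z1 > za, Z2 > zb) under a standard bivariate normal with correlation rho,
# by one-dimensional numeric integration of the conditional normal.
binorm_upper <- function(za, zb, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(za, lower.tail = FALSE) *
                                  stats::pnorm(zb, lower.tail = FALSE))
  s <- sqrt(1 - rho^2)
  f <- function(x) stats::dnorm(x) * stats::pnorm((rho * x - zb) / s)
  stats::integrate(f, za, Inf, rel.tol = 1e-10)$value
}

# Binary-scale (phi) correlation implied by latent correlation rho at marginal
# probabilities pa, pb.
phi_from_latent <- function(rho, pa, pb) {
  za <- stats::qnorm(1 - pa)
  zb <- stats::qnorm(1 - pb)
  p11 <- binorm_upper(za, zb, rho)
  (p11 - pa * pb) / sqrt(pa * (1 - pa) * pb * (1 - pb))
}

#' Calibrate a latent Gaussian correlation to a target binary correlation
#'
#' Inverts the monotone map latent rho -> phi correlation (numeric orthant
#' integration + bisection via [stats::uniroot()]). Errors when the target is
#' outside the attainable phi range for the given margins.
#'
#' @param target desired binary-scale (phi) correlation.
#' @param pa,pb marginal innervation probabilities of the two columns.
#' @return latent correlation rho.
#' @export
latent_from_phi <- function(target, pa, pb) {
  if (abs(target) < 1e-12) return(0)
  lo <- phi_from_latent(-0.9999, pa, pb)
  hi <- phi_from_latent(0.9999, pa, pb)
  al_assert(target >= lo - 1e-9 && target <= hi + 1e-9, "al_spec_error",
            "phi correlation %.3f unattainable for margins (%.2f, %.2f); range [%.3f, %.3f]",
            target, pa, pb, lo, hi)
  stats::uniroot(function(r) phi_from_latent(r, pa, pb) - target,
                 c(-0.9999, 0.9999), tol = 1e-9)$root
}

#' @param spec an `al_clone_spec`.
#' @rdname clone_matrix_spec
#' @export
make_clone_matrix <- function(spec) {
  al_assert(inherits(spec, "al_clone_spec"), "al_spec_error",
            "make_clone_matrix expects a clone_matrix_spec()")
  g <- length(spec$glomeruli)
  live <- spec$p > 0 & spec$p < 1 # degenerate margins carry no correlation
  latent <- diag(g)
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      if (live[i] && live[j] && spec$R_target[i, j] != 0) {
        latent[i, j] <- latent[j, i] <-
          latent_from_phi(spec$R_target[i, j], spec$p[i], spec$p[j])
      }
    }
  }
  # nearest-positive-definite repair of the latent correlation matrix
  ev <- eigen(latent, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    latent <- as.matrix(Matrix::nearPD(latent, corr = TRUE)$mat)
  }
  ch <- chol(latent)
  x <- with_seed(spec$seed, {
    z <- matrix(stats::rnorm(spec$n_clones * g), spec$n_clones, g) %*% ch
    thresh <- stats::qnorm(1 - spec$p)
    m <- matrix(0L, spec$n_clones, g)
    m[sweep(z, 2, thresh, `>`)] <- 1L
    m
  })
  # p = 1 columns: threshold -Inf handled explicitly
  x[, spec$p == 1] <- 1L
  x[, spec$p == 0] <- 0L
  dimnames(x) <- list(sprintf("clone_%03d", seq_len(spec$n_clones)),
                      spec$glomeruli)
  innervation_matrix(x)
}

#' Construct / read / write a binary innervation matrix
#'
#' @param x binary matrix (clones x glomeruli) with unique column names.
#' @return an `al_innervation_matrix`.
#' @export
innervation_matrix <- function(x) {
  x <- as.matrix(x)
  al_assert(all(x %in% c(0L, 1L)), "al_spec_error",
            "innervation matrix must be binary")
  al_assert(!is.null(colnames(x)) && !anyDuplicated(colnames(x)),
            "al_spec_error", "innervation matrix needs unique column names")
  storage.mode(x) <- "integer"
  structure(x, class = c("al_innervation_matrix", class(matrix())))
}

#' @param path file path for delimited-text serialization (header row =
#'   glomerulus names, first column = clone ids).
#' @rdname innervation_matrix
#' @export
write_innervation_matrix <- function(x, path) {
  df <- data.frame(clone = rownames(x), as.data.frame(unclass(x),
                                                      check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname innervation_matrix
#' @export
read_innervation_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  innervation_matrix(m)
}
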
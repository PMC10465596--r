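# Canonical antennal-lobe glomerulus labels used for generated neuropils.
GLOMERULUS_NAMES <- c(
  "DM1", "DM2", "DM3", "DM4", "DM5", "D", "DP1m", "DP1l", "VA2", "VM2",
  "VA6", "VL2p", "VA1d", "VC1", "DL1", "DA1", "VM5d", "VM5v", "VA5", "VM1"
)

glomerulus_labels <- function(n) {
  if (n <= length(GLOMERULUS_NAMES)) return(GLOMERULUS_NAMES[seq_len(n)])
  c(GLOMERULUS_NAMES,
    sprintf("G%02d", seq_len(n - length(GLOMERULUS_NAMES))))
}

# Closed UV-sphere tessellation of an ellipsoid: two pole vertices plus
# n_theta-1 latitude rings of n_phi vertices; every edge is shared by exactly
# two faces by construction.
ellipsoid_mesh <- function(name, center, semiaxes, n_theta = 18L, n_phi = 32L) {
  theta <- seq(0, pi, length.out = n_theta + 1L)[-c(1L, n_theta + 1L)]
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  ring <- expand.grid(phi = phi, theta = theta)
  verts <- rbind(
    c(0, 0, semiaxes[3]),
    cbind(semiaxes[1] * sin(ring$theta) * cos(ring$phi),
          semiaxes[2] * sin(ring$theta) * sin(ring$phi),
          semiaxes[3] * cos(ring$theta)),
    c(0, 0, -semiaxes[3])
  )
  verts <- sweep(verts, 2, center, `+`)
  n_rings <- length(theta)
  idx <- function(r, p) 1L + (r - 1L) * n_phi + ((p - 1L) %% n_phi) + 1L
  faces <- list()
  # top cap
  for (p in seq_len(n_phi)) faces[[length(faces) + 1L]] <- c(1L, idx(1L, p), idx(1L, p + 1L))
  # ring quads split into two triangles
  for (r in seq_len(n_rings - 1L)) {
    for (p in seq_len(n_phi)) {
      a <- idx(r, p); b <- idx(r, p + 1L); cc <- idx(r + 1L, p); d <- idx(r + 1L, p + 1L)
      faces[[length(faces) + 1L]] <- c(a, cc, b)
      faces[[length(faces) + 1L]] <- c(b, cc, d)
    }
  }
  bottom <- nrow(verts)
  for (p in seq_len(n_phi)) {
    faces[[length(faces) + 1L]] <- c(bottom, idx(n_rings, p + 1L), idx(n_rings, p))
  }
  m <- glomerulus_mesh(name, verts, do.call(rbind, faces))
  attr(m, "ellipsoid") <- list(center = center, semiaxes = semiaxes)
  m
}

#' Generate a glomerulus-partitioned neuropil
#'
#' Places `n` mutually non-overlapping tessellated ellipsoids ("glomeruli")
#' inside a bounding box. Deterministic for a fixed seed; each mesh carries an
#' `"ellipsoid"` attribute with its generating centre and semiaxes as ground
#' truth for containment tests.
#'
#' @param n number of glomeruli (>= 1).
#' @param box numeric `c(xmin, xmax, ymin, ymax, zmin, zmax)` in nm.
#' @param seed integer seed (mandatory).
#' @param radius_range range of ellipsoid semiaxes in nm.
#' @param n_theta,n_phi tessellation density (latitude bands / longitude
#'   segments).
#' @param max_tries placement retries before giving up with a placement error.
#' @return named list of `al_mesh` objects.
#' @export
make_glomeruli <- function(n, box = c(0, 6e4, 0, 6e4, 0, 6e4), seed,
                           radius_range = c(4e3, 7e3),
                           n_theta = 18L, n_phi = 32L, max_tries = 500L * n) {
  al_assert(n >= 1, "al_spec_error", "make_glomeruli: n must be >= 1")
  al_assert(!missing(seed), "al_spec_error", "make_glomeruli: seed is mandatory")
  with_seed(seed, {
    centers <- matrix(NA_real_, 0, 3)
    radii <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(centers) < n) {
      tries <- tries + 1L
      al_assert(tries <= max_tries, "al_placement_error",
                "could not place %d non-overlapping glomeruli in the box", n)
      ax <- stats::runif(3, radius_range[1], radius_range[2])
      lo <- box[c(1, 3, 5)] + ax
      hi <- box[c(2, 4, 6)] - ax
      if (any(hi <= lo)) next # ellipsoid does not fit the box at this size
      ctr <- lo + stats::runif(3) * (hi - lo)
      ok <- TRUE
      if (nrow(centers) > 0) {
        d <- sqrt(rowSums(sweep(centers, 2, ctr)^2))
        clearance <- max(ax) + apply(radii, 1, max)
        ok <- all(d > 1.05 * clearance)
      }
      if (ok) {
        centers <- rbind(centers, ctr)
        radii <- rbind(radii, ax)
      }
    }
    labels <- glomerulus_labels(n)
    meshes <- lapply(seq_len(n), function(i) {
      ellipsoid_mesh(labels[i], centers[i, ], radii[i, ], n_theta, n_phi)
    })
    stats::setNames(meshes, labels)
  })
}

# Uniform sample inside the generating ellipsoid of a mesh, shrunk by `margin`
# so sampled synapse sites sit strictly inside the tessellated surface (the
# inscribed polyhedron is slightly smaller than the analytic ellipsoid).
sample_in_glomerulus <- function(mesh, n, margin = 0.85) {
  ell <- attr(mesh, "ellipsoid")
  al_assert(!is.null(ell), "al_geometry_error",
            "mesh %s carries no generator ellipsoid metadata", mesh$name)
  z <- matrix(stats::rnorm(3 * n), n, 3)
  z <- z / sqrt(rowSums(z^2))
  r <- stats::runif(n)^(1 / 3)
  pts <- z * r * margin
  pts <- sweep(pts, 2, ell$semiaxes, `*`)
  sweep(pts, 2, ell$center, `+`)
}
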
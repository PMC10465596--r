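#' Glomerulus surface mesh
#'
#' A closed triangle mesh delimiting one glomerulus, in the shared nm
#' coordinate frame. Closedness (every edge shared by exactly two faces) is an
#' invariant: synapse-to-glomerulus assignment ray-casts against these surfaces
#' and is only well defined for watertight meshes.
#'
#' @param name glomerulus label (unique within a connectome).
#' @param vertices numeric matrix, n x 3 (nm).
#' @param faces integer matrix, m x 3 of 1-based vertex indices (triangles).
#' @return an object of class `al_mesh`.
#' @export
glomerulus_mesh <- function(name, vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = ncol(as.matrix(faces)))
  al_assert(ncol(vertices) == 3L && all(is.finite(vertices)),
            "al_geometry_error", "mesh %s: vertices must be finite n x 3", name)
  al_assert(ncol(faces) == 3L, "al_geometry_error",
            "mesh %s: faces must be triangles", name)
  al_assert(all(faces >= 1L & faces <= nrow(vertices)), "al_geometry_error",
            "mesh %s: face indices out of range", name)
  structure(list(name = as.character(name), vertices = vertices, faces = faces),
            class = "al_mesh")
}

#' @export
print.al_mesh <- function(x, ...) {
  cat(sprintf("<al_mesh> %s: %d vertices, %d faces, volume %.3g um^3\n",
              x$name, nrow(x$vertices), nrow(x$faces), mesh_volume(x) / 1e9))
  invisible(x)
}

#' Is a mesh closed (watertight)?
#'
#' @param mesh an `al_mesh`.
#' @return logical; attribute `"bad_edges"` lists edges not shared by exactly
#'   two faces.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bad <- names(tab)[tab != 2L]
  structure(length(bad) == 0L, bad_edges = bad)
}

#' Mesh volume by signed tetrahedra
#'
#' Sum of signed tetrahedron volumes from the origin over all faces; exact for
#' closed, consistently oriented meshes (sign is taken as absolute at the end,
#' so either orientation works).
#'
#' @param mesh an `al_mesh`.
#' @return volume in nm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  abs(sum(rowSums(a * cross3(b, c3))) / 6)
}

mesh_centroid <- function(mesh) colMeans(mesh$vertices)

mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

#' Point-in-mesh containment test
#'
#' Even-odd ray casting along +x with an epsilon-perturbation restart when the
#' ray grazes an edge or vertex. Points lying on the surface (within a small
#' tolerance) count as inside. The mesh must be closed.
#'
#' @param points numeric vector of length 3, or an n x 3 matrix.
#' @param mesh an `al_mesh`.
#' @param tol surface tolerance in nm (default 1e-6 of the bbox diagonal).
#' @return logical vector, one entry per point.
#' @export
points_in_mesh <- function(points, mesh, tol = NULL) {
  closed <- mesh_is_closed(mesh)
  al_assert(closed, "al_geometry_error", "mesh %s is not closed (%d bad edges)",
            mesh$name, length(attr(closed, "bad_edges")))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  v <- mesh$vertices
  f <- mesh$faces
  v0 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - v0
  e2 <- v[f[, 3], , drop = FALSE] - v0
  nrm <- cross3(e1, e2)
  diag_len <- vec3_norm(apply(v, 2, max) - apply(v, 2, min))
  if (is.null(tol)) tol <- 1e-6 * diag_len
  bb <- mesh_bbox(mesh)
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    if (any(p < bb["min", ] - tol) || any(p > bb["max", ] + tol)) return(FALSE)
    # surface points count as inside
    if (point_on_surface(p, v0, e1, e2, nrm, tol)) return(TRUE)
    dir <- c(1, 0, 0)
    for (try in 1:12) {
      hits <- ray_crossings(p, dir, v0, e1, e2)
      if (!is.na(hits)) return(hits %% 2L == 1L)
      # degenerate hit: tilt the ray slightly and restart
      ang <- try * 1e-3
      dir <- c(cos(ang), sin(ang) * cos(7 * ang), sin(ang) * sin(7 * ang))
      dir <- dir / vec3_norm(dir)
    }
    al_stop("al_geometry_error",
            "point_in_mesh: could not resolve degenerate ray for point %s",
            paste(signif(p, 6), collapse = ", "))
  }, logical(1))
}

#' @rdname points_in_mesh
#' @param point numeric vector of length 3.
#' @export
point_in_mesh <- function(point, mesh, tol = NULL) {
  points_in_mesh(matrix(point, ncol = 3), mesh, tol)[1]
}

# Moller-Trumbore over all faces; returns crossing count, or NA on a
# numerically degenerate hit (barycentric coordinate or t too close to a
# boundary to trust the parity).
ray_crossings <- function(p, dir, v0, e1, e2, eps = 1e-9) {
  d <- matrix(dir, nrow(v0), 3, byrow = TRUE)
  h <- cross3(d, e2)
  a <- rowSums(e1 * h)
  parallel <- abs(a) < eps
  s <- -sweep(v0, 2, p) # p - v0
  fa <- ifelse(parallel, NA_real_, 1 / a)
  u <- fa * rowSums(s * h)
  q <- cross3(s, e1)
  vv <- fa * rowSums(d * q)
  t <- fa * rowSums(e2 * q)
  cand <- !parallel & u > -1e-7 & u < 1 + 1e-7 & vv > -1e-7 & (u + vv) < 1 + 1e-7 & t > -1e-7
  if (!any(cand, na.rm = TRUE)) return(0L)
  border <- cand & (u < 1e-7 | vv < 1e-7 | (u + vv) > 1 - 1e-7 | t < 1e-7)
  if (any(border, na.rm = TRUE)) return(NA_integer_)
  sum(cand, na.rm = TRUE)
}

point_on_surface <- function(p, v0, e1, e2, nrm, tol) {
  nlen <- sqrt(rowSums(nrm^2))
  w <- -sweep(v0, 2, p) # p - v0
  dist_plane <- abs(rowSums(w * nrm)) / pmax(nlen, 1e-300)
  near <- which(dist_plane <= tol)
  if (length(near) == 0L) return(FALSE)
  # barycentric test of the in-plane projection
  for (j in near) {
    d00 <- sum(e1[j, ]^2); d01 <- sum(e1[j, ] * e2[j, ]); d11 <- sum(e2[j, ]^2)
    d20 <- sum(w[j, ] * e1[j, ]); d21 <- sum(w[j, ] * e2[j, ])
    den <- d00 * d11 - d01 * d01
    if (den <= 0) next
    u <- (d11 * d20 - d01 * d21) / den
    v <- (d00 * d21 - d01 * d20) / den
    if (u >= -1e-6 && v >= -1e-6 && u + v <= 1 + 1e-6) return(TRUE)
  }
  FALSE
}

#' Read / write Wavefront OBJ meshes
#'
#' Minimal OBJ dialect: `v` and `f` records only, triangular faces required
#' (non-triangular faces are rejected).
#'
#' @param path file path.
#' @param name glomerulus name (default: file name without extension).
#' @return `read_obj()` an `al_mesh`; `write_obj()` the path, invisibly.
#' @export
read_obj <- function(path, name = NULL) {
  al_assert(file.exists(path), "al_load_error", "missing file: %s", path)
  if (is.null(name)) name <- sub("\\.obj$", "", basename(path))
  lines <- readLines(path)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  al_assert(length(vlines) > 0 && length(flines) > 0, "al_geometry_error",
            "%s: OBJ must contain v and f records", path)
  verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                 function(tk) as.numeric(tk[2:4])))
  faces <- lapply(strsplit(trimws(flines), "\\s+"), function(tk) {
    idx <- as.integer(sub("/.*", "", tk[-1]))
    al_assert(length(idx) == 3L, "al_geometry_error",
              "%s: non-triangular face (%d vertices)", path, length(idx))
    idx
  })
  glomerulus_mesh(name, verts, do.call(rbind, faces))
}

#' @param mesh an `al_mesh`.
#' @rdname read_obj
#' @export
write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(
    sprintf("o %s", mesh$name),
    sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]),
    sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
  ), path)
  invisible(path)
}
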
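## Delaunay triangulation and mesh construction for the SPDE field.
## No triangulation library is assumed: the mesh is built with an incremental
## Bowyer-Watson insertion using a strict in-circle predicate plus a tiny
## deterministic perturbation, which keeps the algorithm stable on exactly
## cocircular inputs (grid-square centroids are the typical input).

## deterministic degeneracy-breaking transform used only inside the in-circle
## predicate; node coordinates are never modified. A tiny shear plus
## anisotropic scaling destroys cocircularity consistently, so grid-square
## centroids triangulate with a uniform diagonal orientation (keeping node
## degrees, and hence the lumped-mass variance, regular).
jitter_points <- function(pts, scale) {
  d1 <- 1e-6; d2 <- 3e-7
  cbind(pts[, 1] * (1 + d2) + d1 * pts[, 2], pts[, 2])
}

circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

## Bowyer-Watson incremental Delaunay over jittered points; returns triangle
## index matrix referring to the rows of `pts`
delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) stop_("triangulation needs at least 3 points")
  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  if (scale <= 0) stop_("all points coincide")
  pj <- jitter_points(pts, scale)
  ## enclosing super-triangle
  ctr <- colMeans(pj)
  R <- 20 * scale + 1
  sup <- rbind(ctr + R * c(0, 2), ctr + R * c(-1.8, -1), ctr + R * c(1.8, -1))
  P <- rbind(pj, sup)
  si <- n + 1:3
  tri <- matrix(si, 1, 3)
  cc <- circumcircle(sup[1, ], sup[2, ], sup[3, ])
  ccx <- cc[1]; ccy <- cc[2]; cr2 <- cc[3]
  for (ip in seq_len(n)) {
    px <- P[ip, 1]; py <- P[ip, 2]
    bad <- which((ccx - px)^2 + (ccy - py)^2 < cr2)
    if (!length(bad)) stop_("degenerate point configuration at point %d", ip)
    ## cavity boundary: edges of bad triangles appearing exactly once
    bt <- tri[bad, , drop = FALSE]
    e <- rbind(bt[, c(1, 2)], bt[, c(2, 3)], bt[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    once <- !(key %in% key[duplicated(key)])
    poly <- e[once, , drop = FALSE]
    keep <- setdiff(seq_len(nrow(tri)), bad)
    tri <- tri[keep, , drop = FALSE]
    ccx <- ccx[keep]; ccy <- ccy[keep]; cr2 <- cr2[keep]
    newt <- cbind(poly, ip)
    ncc <- t(apply(newt, 1, function(tt) circumcircle(P[tt[1], ], P[tt[2], ], P[tt[3], ])))
    tri <- rbind(tri, newt)
    ccx <- c(ccx, ncc[, 1]); ccy <- c(ccy, ncc[, 2]); cr2 <- c(cr2, ncc[, 3])
  }
  tri <- tri[rowSums(matrix(tri %in% si, nrow(tri))) == 0, , drop = FALSE]
  ## orient counter-clockwise w.r.t. the original coordinates
  a <- signed_areas(pts, tri)
  flip <- a < 0
  tri[flip, 2:3] <- tri[flip, 3:2]
  tri
}

signed_areas <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

#' Identify the 1-km grid square of planar coordinates
#'
#' Squares follow the national-grid convention: square origin =
#' (floor(easting/grid), floor(northing/grid)) * grid, centroid = origin +
#' grid/2 in each axis.
#'
#' @param easting,northing planar coordinates in metres
#' @param grid_size square size in metres (default 1000)
#' @return character vector of square identifiers `"E_N"` (origin in grid
#'   units)
#' @export
square_id <- function(easting, northing, grid_size = 1000) {
  paste(floor(easting / grid_size), floor(northing / grid_size), sep = "_")
}

#' Centroid coordinates of grid squares
#'
#' @param ids identifiers from [square_id()]
#' @inheritParams square_id
#' @return matrix with columns `easting`, `northing`
#' @export
square_centroid <- function(ids, grid_size = 1000) {
  parts <- do.call(rbind, strsplit(ids, "_", fixed = TRUE))
  out <- cbind(easting = (as.numeric(parts[, 1]) + 0.5) * grid_size,
               northing = (as.numeric(parts[, 2]) + 0.5) * grid_size)
  out
}

#' Build a triangulated mesh for the spatial field
#'
#' Constructs a Delaunay triangulation over the unique 1-km square centroids
#' of the data locations (or the raw locations when `snap_to_grid = FALSE`),
#' surrounded by a convex boundary ring pushed outward by a fraction of the
#' domain diameter so that boundary artefacts of the SPDE solution sit away
#' from the data. Edges longer than `max_edge` (interior) or
#' `max_edge_outer` (in the extension ring) are refined by midpoint
#' insertion.
#'
#' @param locations two-column matrix/data frame of planar coordinates
#'   (metres)
#' @param grid_size grid-square size in metres
#' @param snap_to_grid use unique square centroids as primary nodes (TRUE,
#'   the survey convention) or the unique raw locations (FALSE)
#' @param boundary_extension_fraction outward extension of the boundary ring
#'   as a fraction of the domain diameter; 0 disables the ring
#' @param max_edge maximum interior edge length in metres (`Inf` disables
#'   refinement); default 10 x `grid_size`
#' @param max_edge_outer maximum edge length in the extension ring; default
#'   40 x `grid_size`
#' @return object of class `spde_mesh`: list with `nodes` (n x 2), `triangles`
#'   (t x 3 indices, counter-clockwise), `n_nodes`, and `interior` (logical,
#'   nodes within the convex hull of the data)
#' @export
build_mesh <- function(locations, grid_size = 1000, snap_to_grid = TRUE,
                       boundary_extension_fraction = 0.15,
                       max_edge = 10 * grid_size,
                       max_edge_outer = 40 * grid_size) {
  loc <- as.matrix(locations)[, 1:2, drop = FALSE]
  storage.mode(loc) <- "double"
  if (anyNA(loc)) stop_("mesh locations contain missing coordinates")
  if (snap_to_grid) {
    pts <- unique(square_centroid(unique(square_id(loc[, 1], loc[, 2], grid_size)),
                                  grid_size))
  } else {
    pts <- unique(loc)
  }
  if (nrow(pts) < 3L) stop_("need at least 3 unique mesh locations (squares)")
  ## collinearity check via rank of centered coordinates
  if (qr(sweep(pts, 2, colMeans(pts)))$rank < 2L) {
    stop_("mesh locations are collinear; cannot triangulate")
  }
  diam <- sqrt(sum(apply(pts, 2, function(v) diff(range(v)))^2))
  hull_idx <- grDevices::chull(pts)
  hull <- pts[hull_idx, , drop = FALSE]
  ring <- NULL
  if (boundary_extension_fraction > 0) {
    ctr <- colMeans(hull)
    d <- boundary_extension_fraction * diam
    out <- t(apply(hull, 1, function(p) {
      v <- p - ctr; p + d * v / max(sqrt(sum(v^2)), 1e-12)
    }))
    ring <- resample_ring(out, max(min(max_edge_outer, diam), d / 2))
  }
  allpts <- unique(rbind(pts, ring))
  tri <- delaunay_triangulate(allpts)
  mesh <- new_mesh(allpts, tri, hull)
  if (is.finite(max_edge) || is.finite(max_edge_outer)) {
    mesh <- refine_mesh(mesh, hull, max_edge, max_edge_outer)
  }
  mesh
}

resample_ring <- function(poly, spacing) {
  poly2 <- rbind(poly, poly[1, ])
  pts <- NULL
  for (i in seq_len(nrow(poly))) {
    a <- poly2[i, ]; b <- poly2[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / spacing))
    t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    pts <- rbind(pts, cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2])))
  }
  pts
}

new_mesh <- function(nodes, tri, data_hull) {
  colnames(nodes) <- c("easting", "northing")
  interior <- in_hull(nodes, data_hull)
  structure(list(nodes = nodes, triangles = tri, n_nodes = nrow(nodes),
                 interior = interior, data_hull = data_hull),
            class = "spde_mesh")
}

## point-in-convex-polygon (hull vertices in chull order)
in_hull <- function(pts, hull, tol = 1e-7) {
  h2 <- rbind(hull, hull[1, ])
  ok <- rep(TRUE, nrow(pts))
  ## chull() returns vertices clockwise; accept either orientation
  sgn <- 0
  for (i in seq_len(nrow(hull))) {
    a <- h2[i, ]; b <- h2[i + 1, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    if (sgn == 0 && any(abs(cr) > tol)) sgn <- sign(cr[which.max(abs(cr))])
    ok <- ok & (sgn * cr >= -tol * (1 + abs(cr)))
  }
  ok
}

refine_mesh <- function(mesh, hull, max_edge, max_edge_outer, max_pass = 15L) {
  pts <- mesh$nodes
  for (pass in seq_len(max_pass)) {
    tri <- mesh$triangles
    e <- unique(rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)]))
    e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
    mid <- (pts[e[, 1], , drop = FALSE] + pts[e[, 2], , drop = FALSE]) / 2
    len <- sqrt(rowSums((pts[e[, 1], , drop = FALSE] - pts[e[, 2], , drop = FALSE])^2))
    lim <- ifelse(in_hull(mid, hull), max_edge, max_edge_outer)
    long <- len > lim
    if (!any(long)) break
    pts <- unique(rbind(pts, mid[long, , drop = FALSE]))
    mesh <- new_mesh(pts, delaunay_triangulate(pts), hull)
  }
  mesh
}

#' @export
print.spde_mesh <- function(x, ...) {
  a <- signed_areas(x$nodes, x$triangles)
  cat(sprintf("SPDE mesh: %d nodes, %d triangles, area %.4g\n",
              x$n_nodes, nrow(x$triangles), sum(a)))
  cat(sprintf("  edge length: min %.4g, max %.4g\n",
              mesh_edge_range(x)[1], mesh_edge_range(x)[2]))
  invisible(x)
}

mesh_edge_range <- function(mesh) {
  tri <- mesh$triangles; pts <- mesh$nodes
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  len <- sqrt(rowSums((pts[e[, 1], ] - pts[e[, 2], ])^2))
  range(len)
}

#' Write / read a mesh as a node/triangle CSV pair
#'
#' @param mesh an `spde_mesh`
#' @param stem path stem; writes `<stem>_nodes.csv` and
#'   `<stem>_triangles.csv`
#' @return `write_mesh`: the stem, invisibly. `read_mesh`: an `spde_mesh`.
#' @export
write_mesh <- function(mesh, stem) {
  write.csv(data.frame(mesh$nodes), paste0(stem, "_nodes.csv"), row.names = FALSE)
  write.csv(data.frame(v1 = mesh$triangles[, 1], v2 = mesh$triangles[, 2],
                       v3 = mesh$triangles[, 3]),
            paste0(stem, "_triangles.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(stem) {
  nodes <- as.matrix(read.csv(paste0(stem, "_nodes.csv")))
  tri <- as.matrix(read.csv(paste0(stem, "_triangles.csv")))
  hull <- nodes[grDevices::chull(nodes), , drop = FALSE]
  new_mesh(nodes, tri, hull)
}
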
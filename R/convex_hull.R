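## Minimal 3-D convex hull (volume/area of a point cloud) by incremental
## insertion with vectorized visibility tests. Only the quantities needed by
## the bead-radius estimators are exposed.

#' Convex hull volume of a 3-D point cloud
#'
#' Incremental construction: faces visible from each new point are replaced
#' by a fan over the horizon edges. Returns the enclosed volume and area.
#' Degenerate (rank-deficient) clouds raise an error; callers handle those
#' cases explicitly.
#'
#' @param pts Numeric matrix, one point per row, 3 columns.
#' @return List with `volume` and `area`.
#' @export
convex_hull_volume <- function(pts) {
  pts <- unique(as.matrix(pts))
  if (ncol(pts) != 3L) stop("points must have 3 columns")
  n <- nrow(pts)
  if (n < 4L) stop("need at least 4 distinct points")
  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  if (scale == 0) stop("degenerate point cloud")
  eps <- 1e-10 * scale

  ## initial simplex: extremes along x, furthest from segment, then plane
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) { i1 <- which.min(pts[, 2]); i2 <- which.max(pts[, 2]) }
  a <- pts[i1, ]; b <- pts[i2, ]
  ab <- b - a
  t <- ((pts - matrix(a, n, 3, byrow = TRUE)) %*% ab) / sum(ab^2)
  proj <- matrix(a, n, 3, byrow = TRUE) + t %*% t(ab)
  d2 <- rowSums((pts - proj)^2)
  i3 <- which.max(d2)
  if (d2[i3] < eps^2) stop("collinear point cloud")
  c3 <- pts[i3, ]
  nrm <- crossp(b - a, c3 - a)
  dist <- abs((pts - matrix(a, n, 3, byrow = TRUE)) %*% nrm) /
    sqrt(sum(nrm^2))
  i4 <- which.max(dist)
  if (dist[i4] < eps) stop("coplanar point cloud")
  verts <- c(i1, i2, i3, i4)
  interior <- colMeans(pts[verts, ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  fn <- face_planes(pts, faces, interior)

  rest <- setdiff(seq_len(n), verts)
  for (p_i in rest) {
    p <- pts[p_i, ]
    vis <- which(fn$N %*% p - fn$off > eps)
    if (length(vis) == 0L) next
    visf <- faces[vis, , drop = FALSE]
    edges <- rbind(visf[, c(1, 2)], visf[, c(2, 3)], visf[, c(1, 3)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]),
                  pmax(edges[, 1], edges[, 2]))
    horizon <- edges[ekey %in% names(which(table(ekey) == 1L)), ,
                     drop = FALSE]
    faces <- faces[-vis, , drop = FALSE]
    newf <- cbind(horizon, p_i)
    faces <- rbind(faces, newf)
    fn <- list(N = fn$N[-vis, , drop = FALSE], off = fn$off[-vis])
    add <- face_planes(pts, newf, interior)
    fn$N <- rbind(fn$N, add$N)
    fn$off <- c(fn$off, add$off)
  }
  ## volume/area from the facet fan around the interior point
  v <- 0; area <- 0
  for (k in seq_len(nrow(faces))) {
    tri <- pts[faces[k, ], ]
    v <- v + abs(det(rbind(tri[1, ] - interior, tri[2, ] - interior,
                           tri[3, ] - interior))) / 6
    area <- area + sqrt(sum(crossp(tri[2, ] - tri[1, ],
                                   tri[3, ] - tri[1, ])^2)) / 2
  }
  list(volume = v, area = area)
}

face_planes <- function(pts, faces, interior) {
  N <- matrix(0, nrow(faces), 3)
  off <- numeric(nrow(faces))
  for (k in seq_len(nrow(faces))) {
    a <- pts[faces[k, 1], ]
    nrm <- crossp(pts[faces[k, 2], ] - a, pts[faces[k, 3], ] - a)
    o <- sum(nrm * a)
    if (sum(nrm * interior) > o) { nrm <- -nrm; o <- -o }
    N[k, ] <- nrm
    off[k] <- o
  }
  list(N = N, off = off)
}

crossp <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])

## Quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}
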
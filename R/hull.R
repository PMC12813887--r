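# 3D convex hull volume by incremental (beneath-beyond) construction.
# Points are rows of an n x 3 matrix. Returns 0 for fewer than 4
# non-coplanar points. Used for the hull_volume field of sampling
# summaries; reported, never scored, so a plain O(n * faces) insertion
# loop is sufficient at trajectory-cloud sizes.

convex_hull_volume <- function(points) {
  pts <- unique(as.matrix(points))
  n <- nrow(pts)
  if (n < 4L) return(0)
  scale <- max(apply(pts, 2, function(v) diff(range(v))), .Machine$double.eps)
  eps <- 1e-9 * scale

  # initial simplex: two extreme points, then max-area, then max-volume
  i1 <- which.min(pts[, 1])
  i2 <- which.max(rowSums(sweep(pts, 2, pts[i1, ])^2))
  if (sqrt(sum((pts[i2, ] - pts[i1, ])^2)) < eps) return(0)
  ab <- pts[i2, ] - pts[i1, ]
  cr <- t(vapply(seq_len(n), function(i) cross3(ab, pts[i, ] - pts[i1, ]),
                 numeric(3)))
  i3 <- which.max(rowSums(cr^2))
  if (sqrt(sum(cr[i3, ]^2)) < eps * scale) return(0)          # all collinear
  nrm <- cross3(ab, pts[i3, ] - pts[i1, ])
  h <- as.numeric(sweep(pts, 2, pts[i1, ]) %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(abs(h))
  if (abs(h[i4]) < eps) return(0)                             # all coplanar
  simplex <- c(i1, i2, i3, i4)
  interior <- colMeans(pts[simplex, ])

  orient <- function(f) {                                     # outward normal
    nr <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    if (sum(nr * (interior - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- lapply(list(simplex[c(1, 2, 3)], simplex[c(1, 2, 4)],
                       simplex[c(1, 3, 4)], simplex[c(2, 3, 4)]), orient)

  face_normal <- function(f)
    cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])

  for (p in setdiff(seq_len(n), simplex)) {
    vis <- vapply(faces, function(f) {
      nr <- face_normal(f)
      sum(nr * (pts[p, ] - pts[f[1], ])) > eps * sqrt(sum(nr^2))
    }, logical(1))
    if (!any(vis)) next
    vis_faces <- faces[vis]
    edges <- do.call(rbind, lapply(vis_faces, function(f)
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])))
    keys <- paste(edges[, 1], edges[, 2])
    rkeys <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(keys %in% rkeys), , drop = FALSE]
    faces <- c(faces[!vis],
               lapply(seq_len(nrow(horizon)), function(e)
                 c(horizon[e, 1], horizon[e, 2], p)))
  }

  vol <- 0
  for (f in faces) {
    a <- pts[f[1], ] - interior; b <- pts[f[2], ] - interior
    c_ <- pts[f[3], ] - interior
    vol <- vol + abs(sum(a * cross3(b, c_))) / 6
  }
  vol
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
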
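# Independent oracles used by the tests. These deliberately take different
# computational routes than the package (polygon clipping instead of subcell
# rasterization, QR on an augmented system instead of the normal equations,
# Bessel-function Rice moments instead of the square-root approximation).

# --- exact rotated-rectangle / unit-square overlap via polygon clipping ----

# Sutherland-Hodgman: clip polygon (list of xy rows) by half-plane a*x+b*y<=c
clip_halfplane <- function(poly, a, b, cc) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  out <- matrix(numeric(0), 0L, 2L)
  for (i in seq_len(n)) {
    p <- poly[i, ]
    q <- poly[if (i == n) 1L else i + 1L, ]
    fp <- a * p[1L] + b * p[2L] - cc
    fq <- a * q[1L] + b * q[2L] - cc
    if (fp <= 0) out <- rbind(out, p)
    if ((fp < 0) != (fq < 0)) {
      t <- fp / (fp - fq)
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}

poly_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# Exact sampling weight A(i, j): area of intersection between the rotated
# low-res voxel footprint (alpha x 1 rectangle, rotated by theta about the
# grid center) and the unit square of high-res voxel j. Coordinates follow
# the package's conventions (0-based indices, center (n-1)/2).
exact_weight <- function(geom, theta, k, l, ix, iy) {
  a <- geom$aspect_factor
  ct <- cos(theta); st <- sin(theta)
  uc <- k - (geom$n_u - 1) / 2
  vc <- (l - (geom$n_v - 1) / 2) * a
  # rectangle corners (u, v) -> grid frame
  cu <- c(-0.5, 0.5, 0.5, -0.5)
  cv <- c(-a / 2, -a / 2, a / 2, a / 2)
  gx <- ct * (uc + cu) - st * (vc + cv)
  gy <- st * (uc + cu) + ct * (vc + cv)
  poly <- cbind(gx, gy)
  x0 <- ix - (geom$n - 1) / 2
  y0 <- iy - (geom$n - 1) / 2
  poly <- clip_halfplane(poly, -1, 0, -(x0 - 0.5))
  poly <- clip_halfplane(poly,  1, 0,  x0 + 0.5)
  poly <- clip_halfplane(poly, 0, -1, -(y0 - 0.5))
  poly <- clip_halfplane(poly, 0,  1,  y0 + 0.5)
  poly_area(poly)
}

# --- exact Rice mean ------------------------------------------------------

rice_mean_exact <- function(S, sigma) {
  if (sigma == 0) return(S)
  x <- S^2 / (2 * sigma^2)
  sigma * sqrt(pi / 2) *
    ((1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
     x * besselI(x / 2, 1, expon.scaled = TRUE))
}

# --- ridge regression via QR of the augmented system ----------------------

# minimizes ||A x - y||^2 + lambda ||x||^2 without forming normal equations
ridge_qr <- function(A, y, lambda) {
  A <- as.matrix(A)
  n <- ncol(A)
  Aaug <- rbind(A, sqrt(lambda) * diag(n))
  yaug <- c(y, numeric(n))
  qr.solve(Aaug, yaug)
}

# geometric low-res interior rows: rectangle footprint fully inside the
# high-res square with one voxel to spare
geometric_interior_rows <- function(geom, theta) {
  a <- geom$aspect_factor
  ct <- cos(theta); st <- sin(theta)
  kk <- rep.int(0:(geom$n_u - 1L), geom$n_v)
  ll <- rep(0:(geom$n_v - 1L), each = geom$n_u)
  uc <- kk - (geom$n_u - 1) / 2
  vc <- (ll - (geom$n_v - 1) / 2) * a
  cu <- c(-0.5, 0.5, 0.5, -0.5)
  cv <- c(-a / 2, -a / 2, a / 2, a / 2)
  inside <- rep(TRUE, geom$n_u * geom$n_v)
  for (ci in 1:4) {
    gx <- ct * (uc + cu[ci]) - st * (vc + cv[ci])
    gy <- st * (uc + cu[ci]) + ct * (vc + cv[ci])
    inside <- inside & abs(gx) < geom$n / 2 - 1 & abs(gy) < geom$n / 2 - 1
  }
  inside
}

# --- misc -----------------------------------------------------------------

# drop bookkeeping attributes before matrix comparison
unclass_strip <- function(x) {
  attr(x, "interior") <- NULL
  x
}

total_variation <- function(img) {
  sum(abs(diff(img))) + sum(abs(t(diff(t(img)))))
}

# smooth band-limited test image evaluated analytically at rotated coords
blob_image <- function(n, theta = 0) {
  ix <- rep.int(0:(n - 1L), n) - (n - 1) / 2
  iy <- rep(0:(n - 1L), each = n) - (n - 1) / 2
  ct <- cos(theta); st <- sin(theta)
  x <- ct * ix + st * iy
  y <- -st * ix + ct * iy
  s <- n / 6
  matrix(exp(-(x^2 + y^2) / (2 * s^2)) * (1 + 0.5 * sin(2 * pi * x / n)),
         n, n)
}
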
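# Standard Shepp-Logan ellipse table (modified intensities): columns are
# additive intensity, semi-axes a/b, center x/y, rotation angle (degrees),
# all in the unit square [-1, 1]^2.
shepp_logan_table <- function() {
  matrix(c(
     1.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.80, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.20, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.20, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.10, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.10, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.10, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.10, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.10, 0.0230, 0.0230,  0.00, -0.6060,   0,
     0.10, 0.0230, 0.0460,  0.06, -0.6050,   0
  ), ncol = 6L, byrow = TRUE,
  dimnames = list(NULL, c("A", "a", "b", "x0", "y0", "phi_deg")))
}

#' Shepp-Logan digital phantom
#'
#' Standard Shepp-Logan ellipse composition on an \code{n x n} grid, rescaled
#' so that the largest homogeneous compartment (the big interior region,
#' mimicking white matter) has value \code{s_alpha1}. Region labels:
#' 0 background, 1 the largest compartment (used as the ROI for SNR
#' statistics), 2 all other interior structures.
#'
#' @param n Grid side length (>= 16).
#' @param s_alpha1 Signal value assigned to the largest compartment
#'   (default 1).
#' @return An object of class \code{digital_phantom}: list with \code{image}
#'   (matrix), \code{labels} (integer matrix), \code{voxel_mm}.
#' @export
shepp_logan <- function(n, s_alpha1 = 1) {
  n <- as.integer(n)
  if (n < 16L) stop("'n' must be at least 16")
  tab <- shepp_logan_table()
  cx <- (rep.int(0:(n - 1L), n) - (n - 1) / 2) / (n / 2)
  cy <- (rep(0:(n - 1L), each = n) - (n - 1) / 2) / (n / 2)
  img <- numeric(n * n)
  inside <- matrix(FALSE, n * n, nrow(tab))
  for (e in seq_len(nrow(tab))) {
    phi <- tab[e, "phi_deg"] * pi / 180
    dx <- cx - tab[e, "x0"]
    dy <- cy - tab[e, "y0"]
    xr <- cos(phi) * dx + sin(phi) * dy
    yr <- -sin(phi) * dx + cos(phi) * dy
    inn <- (xr / tab[e, "a"])^2 + (yr / tab[e, "b"])^2 <= 1
    inside[, e] <- inn
    img[inn] <- img[inn] + tab[e, "A"]
  }
  # largest compartment: inside the two outer ellipses only
  comp <- inside[, 1L] & inside[, 2L] & rowSums(inside[, -(1:2)]) == 0
  base <- img[comp][1L]
  img <- img * (s_alpha1 / base)
  labels <- integer(n * n)
  labels[img != 0 | inside[, 1L]] <- 2L
  labels[comp] <- 1L
  structure(list(image = matrix(img, n, n),
                 labels = matrix(labels, n, n),
                 voxel_mm = 1.6),
            class = "digital_phantom")
}

#' Water-cylinder digital phantom
#'
#' A homogeneous disk of non-diffusion-weighted signal \code{s0} (free water,
#' diffusivity \code{diffusivity}) centered on the grid, zero outside. The
#' companion diffusion parameters generate the b-dependent signal via the
#' mono-exponential water model.
#'
#' @param n Grid side length.
#' @param radius_fraction Disk radius as a fraction of the half field of view
#'   (default 0.6).
#' @param s0 Interior signal at b = 0 and aspect factor 1 (default 1).
#' @param diffusivity Water diffusivity in um^2/ms (default 2.2, room
#'   temperature).
#' @param roi_fraction Radius fraction (of the disk radius) of the centered
#'   ROI used for signal statistics (default 0.6, safely inside the rim).
#' @return A \code{digital_phantom} with extra fields \code{diffusivity},
#'   \code{s0} and \code{roi} (logical ROI mask). Labels: 0 background,
#'   1 disk.
#' @export
cylinder_phantom <- function(n, radius_fraction = 0.6, s0 = 1,
                             diffusivity = 2.2, roi_fraction = 0.6) {
  n <- as.integer(n)
  if (radius_fraction <= 0 || radius_fraction >= 1) {
    stop("'radius_fraction' must lie in (0, 1)")
  }
  cx <- rep.int(0:(n - 1L), n) - (n - 1) / 2
  cy <- rep(0:(n - 1L), each = n) - (n - 1) / 2
  r2 <- cx^2 + cy^2
  radius <- radius_fraction * n / 2
  disk <- r2 <= radius^2
  roi <- r2 <= (roi_fraction * radius)^2
  structure(list(image = matrix(s0 * disk, n, n),
                 labels = matrix(as.integer(disk), n, n),
                 voxel_mm = 1.6,
                 s0 = s0, diffusivity = diffusivity,
                 roi = matrix(roi, n, n)),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf("digital phantom: %d x %d, %d nonzero voxels\n",
              nrow(x$image), ncol(x$image), sum(x$image != 0)))
  invisible(x)
}

#' Simulate noisy low-resolution acquisitions of a phantom
#'
#' For each b-value and each rotation, forms the noiseless low-resolution
#' observation \code{y = A_k x(b)} (with \code{x(b)} the phantom image
#' attenuated voxelwise by \code{exp(-b D)}), then adds independent complex
#' Gaussian noise of standard deviation \code{sigma} per low-resolution voxel
#' and rectifies to magnitude. The noise level is independent of the voxel
#' volume, so larger aspect factors gain SNR through the sampling operator's
#' row sums (proportional to voxel volume).
#'
#' @param phantom A \code{digital_phantom}.
#' @param geometry An \code{srr_geometry} on the phantom's grid.
#' @param b_values Numeric vector of b-values (ms/um^2).
#' @param noise A \code{\link{rician_noise}} model (or numeric sigma);
#'   \code{sigma = 0} returns noiseless magnitudes.
#' @param seed Integer seed (overrides the noise model's seed).
#' @param diffusivity Scalar diffusivity; defaults to the phantom's.
#' @param n_realizations Independent noisy copies per b-value (default 1, as
#'   in single-shot accuracy experiments; increase to estimate variances).
#' @param sampling Optional precomputed joint operator.
#' @param s Subcell factor when the operator is built here.
#' @return List with \code{stacks}: for each b-value an array
#'   \code{n_u x n_v x N_R} (or \code{... x n_realizations} when
#'   \code{n_realizations > 1}), plus \code{b_values}, \code{geometry},
#'   \code{sampling}.
#' @export
simulate_lowres_acquisition <- function(phantom, geometry, b_values,
                                        noise, seed = NULL,
                                        diffusivity = NULL,
                                        n_realizations = 1L,
                                        sampling = NULL, s = 4L) {
  stopifnot(inherits(phantom, "digital_phantom"),
            inherits(geometry, "srr_geometry"))
  if (nrow(phantom$image) != geometry$n) {
    stop("phantom grid does not match the geometry")
  }
  sigma <- if (inherits(noise, "rician_noise")) noise$sigma else noise
  if (is.null(seed) && inherits(noise, "rician_noise")) seed <- noise$seed
  if (is.null(diffusivity)) diffusivity <- phantom$diffusivity
  if (is.null(diffusivity) && any(b_values > 0)) {
    stop("phantom has no diffusivity; pass 'diffusivity'")
  }
  samp <- if (is.null(sampling)) build_joint_system(geometry, s = s)
          else sampling
  g <- geometry
  nr <- length(samp$blocks)
  m <- nrow(samp$A)
  gen <- function() {
    lapply(b_values, function(b) {
      att <- if (b > 0) exp(-b * diffusivity) else 1
      y0 <- as.numeric(samp$A %*% (as.numeric(phantom$image) * att))
      dims <- if (n_realizations > 1L) c(g$n_u, g$n_v, nr, n_realizations)
              else c(g$n_u, g$n_v, nr)
      if (sigma == 0) {
        arr <- array(rep(y0, n_realizations), dim = dims)
      } else {
        ntot <- m * n_realizations
        n1 <- rnorm(ntot, 0, sigma)
        n2 <- rnorm(ntot, 0, sigma)
        arr <- array(sqrt((rep(y0, n_realizations) + n1)^2 + n2^2),
                     dim = dims)
      }
      arr
    })
  }
  stacks <- if (is.null(seed)) gen() else with_seed(seed, gen())
  names(stacks) <- paste0("b", b_values)
  list(stacks = stacks, b_values = b_values, geometry = geometry,
       sampling = samp, sigma = sigma)
}
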
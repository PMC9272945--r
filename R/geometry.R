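#' Minimum number of rotated stacks for isotropic reconstruction
#'
#' For thick-slice stacks rotated about a common axis, recovering an isotropic
#' high-resolution image requires at least \code{ceiling(pi/2 * alpha)}
#' complementary rotations, where \code{alpha} is the aspect factor (ratio of
#' slice thickness to in-plane voxel size).
#'
#' @param aspect_factor Aspect factor \eqn{\alpha \ge 1} of the low-resolution
#'   voxels (through-plane / in-plane dimension).
#' @param override Optional integer \eqn{\ge 1}. Some published protocols use
#'   fewer rotations than the bound (e.g. 3 stacks at \eqn{\alpha = 2}); pass
#'   the protocol value here to reproduce them.
#' @return Integer number of rotations.
#' @examples
#' min_rotations(4.5)  # 8
#' min_rotations(6)    # 10
#' min_rotations(2, override = 3)
#' @export
min_rotations <- function(aspect_factor, override = NULL) {
  if (!is.null(override)) {
    override <- as.integer(override)
    if (override < 1L) stop("'override' must be a positive integer")
    return(override)
  }
  if (!is.numeric(aspect_factor) || length(aspect_factor) != 1L ||
      aspect_factor < 1) {
    stop("'aspect_factor' must be a single number >= 1")
  }
  as.integer(ceiling(pi / 2 * aspect_factor))
}

#' Uniformly spaced rotation angles
#'
#' Rotation angles of the low-resolution stacks about the common (phase-encode)
#' axis: \code{k * pi / n_rotations} for \code{k = 0, ..., n_rotations - 1}.
#' Angles are taken modulo \eqn{\pi} because a stack and its 180-degree
#' rotation sample the object identically.
#'
#' @param n_rotations Positive integer.
#' @return Numeric vector of angles in radians, first angle 0.
#' @export
default_angles <- function(n_rotations) {
  n_rotations <- as.integer(n_rotations)
  if (is.na(n_rotations) || n_rotations < 1L) {
    stop("'n_rotations' must be a positive integer")
  }
  (seq_len(n_rotations) - 1L) * pi / n_rotations
}

#' Define an SRR acquisition geometry
#'
#' Collects everything that defines one super-resolution acquisition protocol:
#' the aspect factor, the rotation schedule, the high-resolution target grid,
#' the extent of each low-resolution stack, and the repetition time. The
#' low-resolution in-plane voxel matches the high-resolution voxel; the
#' through-plane (slice) dimension is \code{alpha} high-resolution voxels with
#' a box slice profile.
#'
#' The low-resolution field of view is chosen to cover the rotated
#' high-resolution grid with a margin (default \code{ceiling(alpha)} voxels),
#' so that every part of the object is sampled in every rotation. When all
#' angles are zero no diagonal enlargement is applied, which makes the
#' \code{alpha = 1}, single-stack case an exact identity sampling.
#'
#' @param aspect_factor Aspect factor \eqn{\alpha \ge 1}.
#' @param n Side length (voxels) of the square high-resolution grid.
#' @param n_rotations Number of rotated stacks; default
#'   \code{min_rotations(aspect_factor)}.
#' @param angles Rotation angles in radians within \code{[0, pi)}; default
#'   \code{default_angles(n_rotations)}. Must be distinct modulo \eqn{\pi}.
#' @param voxel_mm Isotropic in-plane voxel size in mm (default 1.6).
#' @param tr_seconds Repetition time of this protocol in seconds (optional).
#' @param margin Extra low-resolution coverage beyond the rotated grid, in
#'   high-resolution voxel units; default \code{ceiling(aspect_factor)}.
#' @param lowres_extent Optional length-2 integer vector overriding the
#'   low-resolution grid dimensions (in-plane count, through-plane count).
#' @return An object of class \code{srr_geometry}.
#' @export
acquisition_geometry <- function(aspect_factor, n,
                                 n_rotations = NULL, angles = NULL,
                                 voxel_mm = 1.6, tr_seconds = NULL,
                                 margin = NULL, lowres_extent = NULL) {
  if (aspect_factor < 1) stop("'aspect_factor' must be >= 1")
  n <- as.integer(n)
  if (n < 2L) stop("high-resolution grid must have at least 2 voxels per side")
  if (is.null(n_rotations)) {
    n_rotations <- if (is.null(angles)) min_rotations(aspect_factor)
                   else length(angles)
  }
  n_rotations <- as.integer(n_rotations)
  if (is.null(angles)) angles <- default_angles(n_rotations)
  if (length(angles) != n_rotations) {
    stop("length(angles) must equal n_rotations")
  }
  ang_mod <- angles %% pi
  if (anyDuplicated(round(ang_mod, 12L))) {
    stop("rotation angles must be distinct modulo pi")
  }
  if (any(angles < 0 | angles >= pi)) stop("angles must lie in [0, pi)")
  if (is.null(margin)) margin <- ceiling(aspect_factor)
  if (is.null(lowres_extent)) {
    base <- if (all(abs(angles) < 1e-12)) n else ceiling(n * sqrt(2))
    extent <- base + 2L * as.integer(margin)
    # keep (n_u - n) even so the lattices align at angle 0
    if ((extent - n) %% 2L != 0L) extent <- extent + 1L
    n_u <- as.integer(extent)
    n_v <- as.integer(ceiling(extent / aspect_factor))
  } else {
    n_u <- as.integer(lowres_extent[1L])
    n_v <- as.integer(lowres_extent[2L])
  }
  structure(list(
    aspect_factor = aspect_factor,
    n_rotations = n_rotations,
    angles = angles,
    n = n,
    voxel_mm = voxel_mm,
    tr_seconds = tr_seconds,
    margin = margin,
    n_u = n_u,
    n_v = n_v
  ), class = "srr_geometry")
}

#' @export
print.srr_geometry <- function(x, ...) {
  cat("SRR acquisition geometry\n")
  cat(sprintf("  aspect factor alpha : %.3g\n", x$aspect_factor))
  cat(sprintf("  rotations N_R       : %d\n", x$n_rotations))
  cat(sprintf("  angles (deg)        : %s\n",
              paste(sprintf("%.1f", x$angles * 180 / pi), collapse = ", ")))
  cat(sprintf("  high-res grid       : %d x %d (%.2f mm in-plane)\n",
              x$n, x$n, x$voxel_mm))
  cat(sprintf("  low-res grid        : %d x %d per stack (slice %.2f mm)\n",
              x$n_u, x$n_v, x$voxel_mm * x$aspect_factor))
  if (!is.null(x$tr_seconds)) {
    cat(sprintf("  TR                  : %.3g s\n", x$tr_seconds))
  }
  invisible(x)
}

#' Minimal repetition time of an SRR protocol
#'
#' Thicker slices cover the same volume with \code{alpha} times fewer slices,
#' so the repetition time can be shortened by the same factor:
#' \code{TR_SRR = TR_D / alpha}.
#'
#' @param tr_direct Repetition time of the direct (isotropic) acquisition, s.
#' @param aspect_factor Aspect factor \eqn{\alpha \ge 1}.
#' @return Minimal SRR repetition time in seconds.
#' @export
min_tr_srr <- function(tr_direct, aspect_factor) {
  if (tr_direct <= 0 || aspect_factor <= 0) stop("inputs must be positive")
  tr_direct / aspect_factor
}
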
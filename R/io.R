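#' Write a volume with an SRR geometry sidecar
#'
#' Writes the image as NIfTI and the acquisition geometry (aspect factor,
#' rotation angles, grid shape, voxel size, TR) plus any extra reconstruction
#' provenance as a JSON sidecar next to it.
#'
#' @param image Numeric matrix or array.
#' @param path Output path ending in \code{.nii} or \code{.nii.gz}.
#' @param geometry An \code{srr_geometry}, or \code{NULL} to skip the
#'   sidecar.
#' @param extra Named list of additional sidecar fields (e.g.
#'   \code{lambda_prime}).
#' @return Invisibly, the image path.
#' @export
write_srr_nifti <- function(image, path, geometry = NULL, extra = list()) {
  img <- RNifti::asNifti(unclass_image(image))
  RNifti::pixdim(img) <- rep(if (is.null(geometry)) 1 else geometry$voxel_mm,
                             length(dim(unclass_image(image))))
  RNifti::writeNifti(img, path)
  if (!is.null(geometry)) {
    side <- c(geometry_to_list(geometry), extra)
    jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

unclass_image <- function(image) {
  a <- attributes(image)
  attributes(image) <- a[names(a) == "dim"]
  if (is.null(dim(image))) dim(image) <- length(image)
  image
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

geometry_to_list <- function(g) {
  list(aspect_factor = g$aspect_factor,
       n_rotations = g$n_rotations,
       angles_rad = g$angles,
       highres_grid = c(g$n, g$n),
       lowres_grid = c(g$n_u, g$n_v),
       voxel_mm = g$voxel_mm,
       tr_seconds = g$tr_seconds,
       margin = g$margin)
}

#' Read a volume and its SRR geometry sidecar
#'
#' @param path NIfTI path written by \code{\link{write_srr_nifti}}.
#' @return List with \code{image} (numeric array) and \code{geometry}
#'   (an \code{srr_geometry}, or \code{NULL} if no sidecar is present) and
#'   \code{sidecar} (the raw sidecar list).
#' @export
read_srr_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  side <- NULL
  geom <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    geom <- acquisition_geometry(
      aspect_factor = side$aspect_factor,
      n = side$highres_grid[1L],
      n_rotations = side$n_rotations,
      angles = side$angles_rad,
      voxel_mm = side$voxel_mm,
      tr_seconds = side$tr_seconds,
      margin = side$margin,
      lowres_extent = side$lowres_grid)
  }
  list(image = array(as.numeric(img), dim = dim(img)),
       geometry = geom, sidecar = side)
}

#' Read an experiment configuration file
#'
#' Configurations are JSON (or YAML if the \pkg{yaml} package is installed)
#' with a \code{kind} field (\code{accuracy}, \code{efficiency},
#' \code{reconstruct}, \code{match} or \code{dotfraction}) plus kind-specific
#' parameters; see the command-line interface in
#' \code{system.file("cli", "srr.R", package = "srrdmri")}.
#'
#' @param path Path to a \code{.json} or \code{.yaml}/\code{.yml} file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs need the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
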
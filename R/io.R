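# NIfTI and protocol readers/writers and the run manifest.
#
# Complex data are stored as two float NIfTI files (real/imaginary) or as a
# magnitude/phase pair, 5-D with dim4 = channel and dim5 = volume; 4-D
# input is promoted with a singleton channel axis.

#' Read a multi-channel complex image from NIfTI pairs
#'
#' Accepts either a real/imaginary pair or a magnitude/phase pair (phase in
#' radians).  Shapes must match; 4-D files get a singleton channel axis.
#'
#' @param real_path,imag_path paths of the real/imaginary pair.
#' @param mag_path,phase_path alternatively, a magnitude/phase pair.
#' @param bval_path,bvec_path optional FSL-style protocol files.
#' @return An \code{\link{mcc_image}}.
#' @export
read_mcc <- function(real_path = NULL, imag_path = NULL, mag_path = NULL,
                     phase_path = NULL, bval_path = NULL, bvec_path = NULL) {
  if (!is.null(real_path) != !is.null(imag_path))
    stop("real and imaginary paths must be given together")
  if (!is.null(mag_path) != !is.null(phase_path))
    stop("magnitude and phase paths must be given together")
  if (is.null(real_path) && is.null(mag_path))
    stop("provide a real/imaginary or magnitude/phase NIfTI pair")
  read_part <- function(p) {
    img <- RNifti::readNifti(p)
    list(data = as.array(img), pixdim = RNifti::pixdim(img))
  }
  if (!is.null(real_path)) {
    a <- read_part(real_path); b <- read_part(imag_path)
    if (!identical(dim(a$data), dim(b$data)))
      stop("real and imaginary parts have different shapes")
    data <- a$data + 1i * b$data
  } else {
    a <- read_part(mag_path); b <- read_part(phase_path)
    if (!identical(dim(a$data), dim(b$data)))
      stop("magnitude and phase have different shapes")
    data <- a$data * exp(1i * b$data)
  }
  if (any(!is.finite(data))) stop("input contains non-finite values")
  proto <- if (!is.null(bval_path)) read_protocol(bval_path, bvec_path)
           else list(bvals = NULL, bvecs = NULL)
  img <- mcc_image(data, voxel_size = a$pixdim[1:3], bvals = proto$bvals,
                   bvecs = proto$bvecs)
  if (!is.null(proto$bvals) && length(proto$bvals) != dim(img$data)[5])
    stop("bval count (", length(proto$bvals),
         ") does not match the number of volumes (", dim(img$data)[5], ")")
  img
}

#' Read an FSL-style acquisition protocol
#'
#' \code{.bval}: one row of b-values; \code{.bvec}: three rows of gradient
#' components.  Non-unit vectors are normalized with a warning; zero vectors
#' (b = 0) are kept as zeros.  Shells are grouped by rounding to the nearest
#' 50 s/mm^2.
#'
#' @param bval_path,bvec_path file paths.
#' @return List with \code{bvals}, \code{bvecs} (3 x V), \code{shells}.
#' @export
read_protocol <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- matrix(scan(bvec_path, quiet = TRUE), nrow = 3, byrow = TRUE)
  if (ncol(bvecs) != length(bvals))
    stop("bvec column count does not match bval count")
  nrm <- sqrt(colSums(bvecs^2))
  bad <- nrm > 0 & abs(nrm - 1) > 1e-4
  if (any(bad)) {
    warning(sum(bad), " non-unit gradient vector(s) normalized")
  }
  scale <- ifelse(nrm > 0, nrm, 1)
  bvecs <- sweep(bvecs, 2, scale, "/")
  list(bvals = bvals, bvecs = bvecs,
       shells = sort(unique(round(bvals / 50) * 50)))
}

#' Write an acquisition protocol in FSL format
#'
#' @param bvals,bvecs protocol (bvecs 3 x V).
#' @param bval_path,bvec_path output paths.
#' @export
write_protocol <- function(bvals, bvecs, bval_path, bvec_path) {
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(format(bvecs, trim = TRUE, digits = 8), 1, paste,
                   collapse = " "), bvec_path)
  invisible(NULL)
}

write_nifti_atomic <- function(data, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(data)
  nd <- length(dim(data))
  RNifti::pixdim(img) <- c(voxel_size, rep(1, max(nd - 3, 0)))
  tmp <- paste0(path, ".part.nii.gz")
  RNifti::writeNifti(img, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write denoising outputs and a run manifest
#'
#' Writes the denoised image (real/imaginary float NIfTI pair and, when
#' requested, the channel-combined magnitude), the sigma, rank and residual
#' maps, and a JSON manifest recording the configuration and seeds.  Files
#' are written to a temporary name and renamed, so a failed run leaves no
#' half-written NIfTI.
#'
#' @param result a \code{\link{denoise_mcc}} result (single strategy).
#' @param config named list recorded verbatim in the manifest.
#' @param out_dir output directory (created if missing).
#' @param combine write a sum-of-squares combined magnitude image too.
#' @return The manifest (invisibly), also written as \code{manifest.json}.
#' @export
write_outputs <- function(result, config = list(), out_dir,
                          combine = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  img <- result$image
  vs <- img$voxel_size
  paths <- list(
    real = file.path(out_dir, "denoised_real.nii.gz"),
    imag = file.path(out_dir, "denoised_imag.nii.gz"),
    sigma = file.path(out_dir, "sigma_map.nii.gz"),
    rank = file.path(out_dir, "rank_map.nii.gz"))
  write_nifti_atomic(Re(img$data), paths$real, vs)
  write_nifti_atomic(Im(img$data), paths$imag, vs)
  write_nifti_atomic(result$report$sigma_map, paths$sigma, vs)
  write_nifti_atomic(result$report$rank_map, paths$rank, vs)
  if (!is.null(result$report$residual)) {
    paths$residual <- file.path(out_dir, "residual.nii.gz")
    res <- result$report$residual
    write_nifti_atomic(array(res, dim(img$data)), paths$residual, vs)
  }
  if (combine) {
    paths$combined <- file.path(out_dir, "denoised_sos.nii.gz")
    write_nifti_atomic(combine_channels(img, "sos"), paths$combined, vs)
  }
  if (!is.null(img$bvals))
    write_protocol(img$bvals,
                   if (is.null(img$bvecs))
                     matrix(0, 3, length(img$bvals)) else img$bvecs,
                   file.path(out_dir, "protocol.bval"),
                   file.path(out_dir, "protocol.bvec"))
  manifest <- list(
    package = "mccdenoise",
    version = as.character(utils::packageVersion("mccdenoise")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    strategy = result$report$strategy,
    n_blocks = result$report$n_blocks,
    files = lapply(paths, basename))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
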
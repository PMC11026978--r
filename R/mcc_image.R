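# The central data object: a 5-D complex multi-channel image.

#' Multi-channel complex image
#'
#' Container for multi-channel complex (MCC) diffusion MRI data: a complex
#' array indexed \code{(x, y, z, channel, volume)} with voxel size and
#' acquisition metadata.  4-D input is promoted with a singleton channel
#' axis.
#'
#' @param data complex (or real) 4-D or 5-D array.
#' @param voxel_size length-3 voxel dimensions in mm.
#' @param bvals per-volume diffusion weighting (s/mm^2), length \code{V}.
#' @param bvecs 3 x \code{V} matrix of gradient directions.
#' @return An object of class \code{mcc_image}.
#' @export
mcc_image <- function(data, voxel_size = c(1, 1, 1), bvals = NULL,
                      bvecs = NULL) {
  if (length(dim(data)) == 4)
    dim(data) <- c(dim(data)[1:3], 1L, dim(data)[4])
  if (length(dim(data)) != 5)
    stop("data must be a 4-D or 5-D array")
  if (!is.complex(data)) {
    storage.mode(data) <- "double"
    data <- data + 0i
  }
  if (any(!is.finite(data)))
    stop("data contains non-finite values")
  d <- dim(data)
  if (!is.null(bvals) && length(bvals) != d[5])
    stop("bvals length (", length(bvals), ") does not match the number of volumes (",
         d[5], ")")
  if (!is.null(bvecs)) {
    bvecs <- as.matrix(bvecs)
    if (nrow(bvecs) != 3 && ncol(bvecs) == 3) bvecs <- t(bvecs)
    if (ncol(bvecs) != d[5])
      stop("bvecs must have one column per volume")
  }
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 bvals = bvals, bvecs = bvecs),
            class = "mcc_image")
}

#' @export
print.mcc_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("MCC image: %d x %d x %d voxels, %d channel(s), %d volume(s)\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  voxel size: %s mm\n",
              paste(format(x$voxel_size), collapse = " x ")))
  if (!is.null(x$bvals))
    cat("  b-values:", paste(sort(unique(round(x$bvals / 50) * 50)),
                             collapse = ", "), "s/mm^2\n")
  invisible(x)
}

#' @export
dim.mcc_image <- function(x) dim(x$data)

n_channels <- function(img) dim(img$data)[4]
n_volumes <- function(img) dim(img$data)[5]
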
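# Quantitative evaluation: normalized error, PSNR, SNR maps, noise-floor
# measurement, residual maps, and the tractography score.

#' Mean-normalized error against a noise-free ground truth
#'
#' \code{mean(|denoised - truth| / truth)} over the masked voxels and all
#' volumes.  Voxels/volumes where the truth is at or below \code{1e-6} times
#' its maximum are excluded from the average (the normalization is undefined
#' there); the exclusion count is reported via a warning attribute.
#'
#' @param denoised,truth 4-D arrays \code{(x, y, z, v)} (magnitude).
#' @param mask logical spatial mask; default: truth support.
#' @return The scalar error, with attribute \code{n_excluded}.
#' @export
normalized_error <- function(denoised, truth, mask = NULL) {
  stopifnot(all(dim(denoised) == dim(truth)))
  d <- dim(truth)
  if (is.null(mask)) mask <- apply(truth, c(1, 2, 3), max) > 0
  keep <- array(rep(as.logical(mask), d[4]), d)
  floor_lvl <- 1e-6 * max(truth)
  excl <- keep & truth <= floor_lvl
  n_excl <- sum(excl)
  if (n_excl > 0) {
    warning(n_excl, " masked entries with truth <= 1e-6 * max excluded ",
            "from the normalized error")
    keep <- keep & !excl
  }
  err <- mean(abs(denoised[keep] - truth[keep]) / truth[keep])
  attr(err, "n_excluded") <- n_excl
  err
}

#' Peak signal-to-noise ratio per b-value
#'
#' \code{10 log10(1 / MSE)} with both images scaled by the truth's maximum,
#' so the mean squared error is relative to peak signal.  Computed separately
#' per b-value shell when \code{bvals} is given.
#'
#' @param denoised,truth 4-D arrays \code{(x, y, z, v)}.
#' @param mask logical spatial mask; default: all voxels.
#' @param bvals per-volume b-values; shells are grouped by rounding to the
#'   nearest 50 s/mm^2.
#' @return Named numeric vector of PSNR in dB (one entry, \code{"all"}, when
#'   \code{bvals} is \code{NULL}).
#' @export
psnr <- function(denoised, truth, mask = NULL, bvals = NULL) {
  stopifnot(all(dim(denoised) == dim(truth)))
  d <- dim(truth)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  peak <- max(truth)
  den <- denoised / peak
  tru <- truth / peak
  one <- function(vsel) {
    keep <- array(FALSE, d)
    keep[, , , vsel] <- rep(as.logical(mask), length(vsel))
    mse <- mean((den[keep] - tru[keep])^2)
    if (mse == 0) Inf else 10 * log10(1 / mse)
  }
  if (is.null(bvals)) return(c(all = one(seq_len(d[4]))))
  shell <- round(bvals / 50) * 50
  vapply(split(seq_len(d[4]), shell), one, numeric(1))
}

#' Voxel-wise SNR map
#'
#' Mean signal magnitude across volumes divided by the per-voxel noise
#' sigma.  The sigma map is typically the simultaneous-MP-fit aggregate from
#' a denoising pass; voxels with zero sigma are flagged with \code{Inf}.
#'
#' @param image 4-D magnitude array \code{(x, y, z, v)}.
#' @param sigma_map per-voxel noise sigma, or \code{NULL} to estimate it
#'   with MP-PCA blocks (\code{k = 5}).
#' @return Numeric array \code{(x, y, z)}.
#' @export
estimate_snr_map <- function(image, sigma_map = NULL) {
  d <- dim(image)
  stopifnot(length(d) == 4)
  if (is.null(sigma_map)) {
    plan <- plan_blocks(1L, d[4], d[1:3], mode = "fixed", k = 5L)
    sigma_map <- denoise_pass(image, plan, "mp_pca", "mp")$sigma_map
  }
  sig <- apply(abs(image), c(1, 2, 3), mean)
  out <- sig / sigma_map
  out[sigma_map == 0] <- Inf
  out
}

#' Noise floor in a reference region
#'
#' Mean signal magnitude over a region and the volumes of the highest
#' b-value shell: in free-water (CSF-like) regions the true signal at high b
#' is essentially zero, so this mean measures the noise floor.
#'
#' @param image 4-D magnitude array \code{(x, y, z, v)}.
#' @param mask logical spatial region (non-empty).
#' @param bvals per-volume b-values.
#' @return Mean magnitude over the region at the highest shell.
#' @export
noise_floor <- function(image, mask, bvals) {
  d <- dim(image)
  stopifnot(length(d) == 4, length(bvals) == d[4])
  mask <- as.logical(mask)
  if (!any(mask)) stop("the region mask is empty")
  shell <- round(bvals / 50) * 50
  vsel <- which(shell == max(shell))
  keep <- array(FALSE, d)
  keep[, , , vsel] <- rep(mask, length(vsel))
  mean(abs(image[keep]))
}

#' @rdname noise_floor
#' @param noisy,denoised 4-D magnitude arrays.
#' @return \code{floor_ratio}: the fold reduction
#'   \code{noise_floor(noisy) / noise_floor(denoised)}.
#' @export
floor_ratio <- function(noisy, denoised, mask, bvals) {
  noise_floor(noisy, mask, bvals) / noise_floor(denoised, mask, bvals)
}

#' Normalized residual map
#'
#' \code{(before - after) / sigma} per voxel, plus the summary shape
#' statistics (skewness, excess kurtosis) used to check that denoising
#' removed noise rather than structure: a structure-preserving method leaves
#' a residual that looks like the noise itself.
#'
#' @param before,after arrays of identical shape.
#' @param sigma per-voxel sigma map (broadcast over trailing dimensions) or
#'   a scalar; default 1 (unnormalized residuals).
#' @return List with \code{residual}, \code{skewness}, \code{kurtosis}
#'   (excess), and \code{n}.
#' @export
residual_map <- function(before, after, sigma = 1) {
  stopifnot(all(dim(before) == dim(after)))
  res <- before - after
  if (length(sigma) > 1) {
    nrep <- length(res) / length(sigma)
    res <- res / array(rep(sigma, nrep), dim(res))
  } else if (sigma != 1) {
    res <- res / sigma
  }
  x <- as.numeric(res)
  x <- x[is.finite(x)]
  mu <- mean(x); s <- sd(x)
  z <- (x - mu) / s
  list(residual = res, skewness = mean(z^3), kurtosis = mean(z^4) - 3,
       n = length(x))
}

#' Tractography score
#'
#' Combines the valid-connection (VC), invalid-connection (IC) and
#' no-connection (NC) streamline fractions into a single score
#' \code{1 - sqrt((VC - 1)^2 + IC^2 + NC^2) / sqrt(2)}: 1 for a perfect
#' tractogram (all valid), 0 when all streamlines are invalid or
#' unconnected.
#'
#' @param vc,ic,nc fractions in \code{[0, 1]}.
#' @return Score in \code{[0, 1]}.
#' @examples
#' tractography_score(1, 0, 0)  # 1
#' tractography_score(0, 1, 0)  # 0
#' @export
tractography_score <- function(vc, ic, nc) {
  stopifnot(all(vc >= 0 & vc <= 1), all(ic >= 0 & ic <= 1),
            all(nc >= 0 & nc <= 1))
  1 - sqrt((vc - 1)^2 + ic^2 + nc^2) / sqrt(2)
}
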
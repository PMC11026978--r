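# The end-to-end MCC denoising pipeline: block planning, the sliding-block
# denoising pass, rank-weighted aggregation, background-phase unwinding and
# rewinding, channel combination, and the channel-combined magnitude
# baseline.

#' Plan the sliding-block matrix geometry
#'
#' In \code{"auto"} mode the isotropic block edge is the smallest odd integer
#' \code{k} with \code{k^3 >= C * V}, so that \code{M = C * V <= N = k^3}; in
#' \code{"fixed"} mode a given odd \code{k} is used and rows/columns are
#' assigned so that \code{M <= N}.
#'
#' @param C,V channel and volume counts.
#' @param shape length-3 spatial image dimensions.
#' @param mode \code{"auto"} or \code{"fixed"}.
#' @param k block edge (odd, \code{>= 3}); required for \code{mode =
#'   "fixed"}.
#' @param stride sliding stride (voxels); 1 covers every voxel, larger
#'   strides trade coverage for speed and may cause blocking artifacts.
#' @return A \code{block_plan}: list with \code{k}, \code{stride}, \code{m},
#'   \code{n}, \code{rows} (\code{"spatial"} or \code{"channel_volume"}),
#'   \code{C}, \code{V}.
#' @examples
#' plan_blocks(32, 66, c(96, 96, 96))          # k = 13
#' plan_blocks(8, 20, c(24, 24, 24), "fixed", k = 5)
#' @export
plan_blocks <- function(C, V, shape, mode = c("auto", "fixed"), k = NULL,
                        stride = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(shape) == 3, stride >= 1)
  q <- C * V
  if (q < 2) stop("C * V must be at least 2: no redundancy to denoise with")
  if (mode == "auto") {
    k <- ceiling(q^(1 / 3))
    if (k %% 2 == 0) k <- k + 1
    while (k^3 < q) k <- k + 2
    k <- max(k, 3)
  } else {
    if (is.null(k)) stop("k is required for mode = 'fixed'")
    if (k %% 2 != 1 || k < 3) stop("k must be an odd integer >= 3")
  }
  if (k > min(shape))
    stop("block edge k = ", k, " exceeds the smallest image dimension (",
         min(shape), ")")
  m <- min(k^3, q)
  n <- max(k^3, q)
  structure(list(k = as.integer(k), stride = as.integer(stride),
                 m = as.integer(m), n = as.integer(n),
                 rows = if (k^3 <= q) "spatial" else "channel_volume",
                 C = as.integer(C), V = as.integer(V)),
            class = "block_plan")
}

#' @export
print.block_plan <- function(x, ...) {
  cat(sprintf("Block plan: k = %d (stride %d), matrix %d x %d (rows = %s)\n",
              x$k, x$stride, x$m, x$n, x$rows))
  invisible(x)
}

#' Number of block positions in an image
#'
#' Blocks are placed fully inside the volume (no padding); per dimension
#' there are \code{floor((dim - k) / stride) + 1} positions.
#'
#' @param plan a \code{\link{plan_blocks}} result.
#' @param shape spatial image dimensions.
#' @return Integer block count.
#' @export
count_blocks <- function(plan, shape) {
  prod(floor((shape - plan$k) / plan$stride) + 1)
}

#' Sliding-block denoising pass over a real-valued stack
#'
#' Runs the block-wise low-rank recovery over a real 4-D \code{(x, y, z,
#' C*V)} or 5-D \code{(x, y, z, C, V)} stack: per block, the noise level is
#' estimated from the block's own spectrum, the chosen strategy shrinks the
#' spectrum, and overlapping reconstructions are aggregated per voxel with
#' weights \code{1 / (1 + rank)}.  Several strategies may be passed at once;
#' they share the per-block eigendecomposition.
#'
#' @param data real array; finite values only.
#' @param plan a \code{\link{plan_blocks}} result.
#' @param strategy character vector of strategies (see
#'   \code{\link{denoise_matrix}}).
#' @param estimator noise estimator for the non-MP-PCA strategies:
#'   \code{"median"} (default) or \code{"mp"}; MP-PCA always uses its own
#'   simultaneous fit.
#' @param sigma optional fixed global noise level (skips per-block
#'   estimation); useful for stationary noise.
#' @return For a single strategy, a list with \code{denoised} (same shape as
#'   input), \code{sigma_map}, \code{rank_map} (per-voxel aggregates;
#'   \code{NA} where no block reaches), \code{coverage}, and
#'   \code{n_blocks}.  For several strategies, a named list of such lists.
#' @export
denoise_pass <- function(data, plan, strategy = "nuc",
                         estimator = c("median", "mp"), sigma = NULL) {
  estimator <- match.arg(estimator)
  strategy <- match.arg(strategy, strategy_names, several.ok = TRUE)
  stopifnot(inherits(plan, "block_plan"))
  if (any(!is.finite(data))) stop("data contains non-finite values")
  d0 <- dim(data)
  if (length(d0) == 5) dim(data) <- c(d0[1:3], d0[4] * d0[5])
  d <- dim(data)
  if (length(d) != 4) stop("data must be a 4-D or 5-D real array")
  if (d[4] != plan$C * plan$V)
    stop("data has ", d[4], " columns per voxel but the plan expects ",
         plan$C * plan$V)
  storage.mode(data) <- "double"

  codes <- strategy_code(strategy)
  est_codes <- rep(if (estimator == "mp") 1L else 0L, length(codes))
  delta_med <- if (any(est_codes == 0L & codes != 0L))
    mp_median_cached(plan$m / plan$n) else 1
  res <- denoise_core_cpp(data, as.integer(d), plan$k, plan$stride,
                          codes, est_codes, delta_med,
                          if (is.null(sigma)) -1 else sigma,
                          as.integer(d0))
  out <- lapply(seq_along(strategy), function(j) {
    list(denoised = res$denoised[[j]], sigma_map = res$sigma[[j]],
         rank_map = res$rank[[j]], coverage = res$coverage,
         n_blocks = res$n_blocks, strategy = strategy[j])
  })
  names(out) <- strategy
  if (length(out) == 1) out[[1]] else out
}

#' Rank-weighted aggregation of overlapping block estimates
#'
#' Combines the estimates a voxel receives from the blocks containing it as
#' a convex combination with weights \code{w_j = 1 / (1 + R_j)}, so blocks
#' of lower rank (smoother reconstructions, less Gibbs ringing) count more.
#'
#' @param values numeric vector of per-block estimates for one voxel.
#' @param ranks corresponding block ranks (non-negative integers).
#' @return The aggregated value.
#' @examples
#' aggregate_blocks(c(10, 20), c(1, 3)) # weights 1/2, 1/4 -> 13.33
#' @export
aggregate_blocks <- function(values, ranks) {
  if (length(values) == 0) stop("at least one contribution is required")
  if (length(values) != length(ranks))
    stop("values and ranks must have equal length")
  w <- 1 / (1 + ranks)
  sum(w * values) / sum(w)
}

#' Estimate and remove the background phase
#'
#' Two-pass background-phase unwinding: the real and imaginary parts of the
#' (already whitened) data are first denoised independently with the same
#' plan and strategy; the argument of the resulting complex estimate is the
#' background phase (including the channel sensitivity phase), which is then
#' unwound from the original data.  On phase-unwound data the signal lives
#' in the real part and the imaginary part is essentially pure noise.
#'
#' @param img an \code{\link{mcc_image}}.
#' @param plan a \code{\link{plan_blocks}} result.
#' @param strategy single denoising strategy for the phase-estimation pass.
#' @param estimator noise estimator (see \code{\link{denoise_pass}}).
#' @return List with \code{image} (the phase-unwound \code{mcc_image}) and
#'   \code{phase} (the estimated background phase, \code{(x, y, z, c, v)}).
#' @export
unwind_phase <- function(img, plan, strategy = "nuc",
                         estimator = c("median", "mp")) {
  stopifnot(inherits(img, "mcc_image"))
  estimator <- match.arg(estimator)
  re <- denoise_pass(Re(img$data), plan, strategy, estimator)$denoised
  im <- denoise_pass(Im(img$data), plan, strategy, estimator)$denoised
  phase <- atan2(im, re)
  img$data <- img$data * exp(-1i * phase)
  list(image = img, phase = phase)
}

#' Rewind a previously unwound background phase
#'
#' Multiplies the data by \code{exp(+i * phase)}; the exact inverse of the
#' unwinding step.
#'
#' @param img an \code{\link{mcc_image}}.
#' @param phase phase array as returned by \code{\link{unwind_phase}}.
#' @return The re-phased \code{mcc_image}.
#' @export
rewind_phase <- function(img, phase) {
  stopifnot(inherits(img, "mcc_image"))
  img$data <- img$data * exp(1i * phase)
  img
}

#' Combine channels into a single image
#'
#' Root-sum-of-squares (\code{"sos"}, the default) or sensitivity-weighted
#' combination \code{sum(Conj(R_c) S_c) / sum(|R_c|^2)} when channel
#' sensitivity maps are available.
#'
#' @param img an \code{\link{mcc_image}}.
#' @param method \code{"sos"} or \code{"sensitivity"}.
#' @param maps complex \code{(x, y, z, c)} sensitivity maps; required for
#'   \code{method = "sensitivity"}.
#' @return A 4-D array \code{(x, y, z, v)}: non-negative magnitude for
#'   \code{"sos"}, complex for \code{"sensitivity"}.
#' @export
combine_channels <- function(img, method = c("sos", "sensitivity"),
                             maps = NULL) {
  stopifnot(inherits(img, "mcc_image"))
  method <- match.arg(method)
  d <- dim(img$data)
  if (method == "sos") {
    out <- sos_from_sq(Mod(img$data)^2)
  } else {
    if (is.null(maps)) stop("sensitivity maps are required for method = 'sensitivity'")
    if (!all(dim(maps) == d[1:4]))
      stop("sensitivity maps must have dimensions (x, y, z, c)")
    denom <- apply(Mod(maps)^2, c(1, 2, 3), sum)
    denom[denom == 0] <- NA_real_
    out <- array(0 + 0i, c(d[1:3], d[5]))
    for (v in seq_len(d[5]))
      out[, , , v] <- apply(Conj(maps) * img$data[, , , , v, drop = FALSE][, , , , 1],
                            c(1, 2, 3), sum) / denom
  }
  out
}

# root-sum over the channel axis of an (x, y, z, c, v) array of squared
# values; channel-wise accumulation avoids apply()'s large temporaries
sos_from_sq <- function(x2) {
  d <- dim(x2)
  dim(x2) <- c(prod(d[1:3]), d[4], d[5])
  s <- matrix(0, prod(d[1:3]), d[5])
  for (cc in seq_len(d[4])) s <- s + x2[, cc, ]
  array(sqrt(s), c(d[1:3], d[5]))
}

#' Denoise a multi-channel complex image
#'
#' The full pipeline: channel decorrelation (when a noise covariance is
#' supplied), two-pass background-phase unwinding, sliding-block low-rank
#' recovery on the real part, optional phase rewinding, and de-whitening.
#' The imaginary part after unwinding is noise and is discarded unless the
#' phase is rewound.
#'
#' Several strategies may be swept in one call (sharing the per-block
#' eigendecomposition); the phase-estimation pass then uses the first
#' strategy, since background-phase estimates are nearly identical across
#' strategies.
#'
#' @param img an \code{\link{mcc_image}} with \code{C * V >= 2}.
#' @param phi optional channel noise covariance for whitening.
#' @param strategy character vector of strategies.
#' @param estimator noise estimator for non-MP-PCA strategies.
#' @param plan block plan; defaults to \code{plan_blocks(C, V, shape)} (auto
#'   block size, stride 1).
#' @param unwind estimate and remove the background phase first (default
#'   \code{TRUE}; disable for data known to be phase-free).
#' @param rewind re-apply the estimated phase to the denoised data.
#' @return For a single strategy, a list with \code{image} (denoised
#'   \code{mcc_image}) and \code{report} (sigma map, rank map, residual =
#'   input minus output on the representation the shrinkage saw, block
#'   counts, strategy).  For several strategies, a named list of such lists.
#' @export
denoise_mcc <- function(img, phi = NULL, strategy = "nuc",
                        estimator = c("median", "mp"), plan = NULL,
                        unwind = TRUE, rewind = FALSE) {
  stopifnot(inherits(img, "mcc_image"))
  estimator <- match.arg(estimator)
  strategy <- match.arg(strategy, strategy_names, several.ok = TRUE)
  d <- dim(img$data)
  if (d[4] * d[5] < 2)
    stop("C * V = ", d[4] * d[5],
         ": a single channel-volume offers no redundancy to denoise with")
  if (is.null(plan)) plan <- plan_blocks(d[4], d[5], d[1:3])

  work <- img
  if (!is.null(phi)) work <- whiten_channels(work, phi)
  phase <- NULL
  if (unwind) {
    uw <- unwind_phase(work, plan, strategy[1], estimator)
    work <- uw$image
    phase <- uw$phase
  }
  input_real <- Re(work$data)
  passes <- denoise_pass(input_real, plan, strategy, estimator)
  if (length(strategy) == 1) passes <- stats::setNames(list(passes), strategy)

  out <- lapply(passes, function(p) {
    res <- img # inherit metadata
    res$data <- p$denoised + 0i
    if (rewind && !is.null(phase)) res$data <- res$data * exp(1i * phase)
    if (!is.null(phi)) res <- unwhiten_channels(res, phi)
    list(image = res,
         report = list(sigma_map = p$sigma_map, rank_map = p$rank_map,
                       residual = input_real - p$denoised,
                       coverage = p$coverage, n_blocks = p$n_blocks,
                       strategy = p$strategy, unwound = unwind,
                       whitened = !is.null(phi)))
  })
  if (length(out) == 1) out[[1]] else out
}

#' Channel-combined magnitude MP-PCA baseline
#'
#' The conventional magnitude-domain route: MP-PCA on 5x5x5 sliding blocks
#' of a channel-combined 4-D magnitude image, with the simultaneous MP fit
#' for noise estimation.  Because magnitude noise at low SNR is Rician
#' rather than Gaussian, the fitted noise level underestimates the
#' underlying Gaussian sigma; the reported sigma map is corrected by the
#' method-of-moments Rician variance factor evaluated at the voxel's
#' signal-to-noise ratio (fixed-point iteration on \code{sigma_g =
#' sigma_mag / sqrt(xi(theta))}).  The retained components, and hence the
#' denoised image, come from the MP fit itself; no correction can remove
#' the noise-floor bias already present in the magnitude mean.
#'
#' @param mag real non-negative 4-D array \code{(x, y, z, v)}.
#' @param plan optional block plan; defaults to a fixed 5x5x5 kernel,
#'   stride 1.
#' @return List with \code{denoised}, \code{sigma_map} (Rician-corrected),
#'   \code{sigma_map_raw}, \code{rank_map}, \code{n_blocks}.
#' @export
denoise_magnitude_baseline <- function(mag, plan = NULL) {
  d <- dim(mag)
  if (length(d) != 4) stop("mag must be a 4-D (x, y, z, v) array")
  if (is.null(plan))
    plan <- plan_blocks(1L, d[4], d[1:3], mode = "fixed", k = 5L)
  p <- denoise_pass(mag, plan, strategy = "mp_pca", estimator = "mp")
  mean_sig <- apply(p$denoised, c(1, 2, 3), mean)
  sigma_corr <- rician_sigma_correct(mean_sig, p$sigma_map)
  list(denoised = p$denoised, sigma_map = sigma_corr,
       sigma_map_raw = p$sigma_map, rank_map = p$rank_map,
       n_blocks = p$n_blocks)
}

# Rician variance correction factor xi(theta): the variance of a Rician
# variate with underlying Gaussian sigma and SNR theta is xi(theta) sigma^2,
# with xi(0) = 2 - pi/2 and xi -> 1 as theta grows.  Exponentially scaled
# Bessel functions keep the expression finite: the e^{-t^2/2} prefactor
# cancels the scaling of the squared bracket exactly.
rician_xi <- function(theta) {
  t2 <- theta^2
  x <- t2 / 4
  bracket <- (2 + t2) * besselI(x, 0, expon.scaled = TRUE) +
    t2 * besselI(x, 1, expon.scaled = TRUE)
  pmax(2 + t2 - (pi / 8) * bracket^2, 1e-6)
}

rician_sigma_correct <- function(mean_signal, sigma_mag, iter = 25) {
  sigma_g <- sigma_mag
  for (i in seq_len(iter)) {
    theta <- ifelse(sigma_g > 0, mean_signal / sigma_g, Inf)
    theta[!is.finite(theta)] <- 50
    sigma_g <- sigma_mag / sqrt(rician_xi(pmin(theta, 50)))
  }
  sigma_g
}
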
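# Reproduction entry points for the in-silico experiments: the noise-floor
# study on the mini phantom and the channel-redundancy sweep.

#' In-silico noise-floor study
#'
#' Generates the mini phantom (C = 32, V = 173, SNR 2-15, free-water probe
#' at the center), denoises it with every MCC strategy (5x5x5 kernel, stride
#' 1, MP-median noise estimator; MP-PCA with its simultaneous fit) and with
#' the channel-combined magnitude MP-PCA baseline, and measures the
#' free-water (CSF-like) noise floor at the highest b-value before and
#' after denoising.
#'
#' Two phantom realizations are used: a phase-free one, on which the
#' strategies are swept without phase unwinding, and one with the
#' bidimensional-sinusoid background phase, on which the full pipeline
#' (two-pass unwinding + nuclear-norm shrinkage) is run.
#'
#' @param seed root seed for the phantom noise.
#' @param strategies MCC strategies to sweep.
#' @param channels,grid optional overrides of the mini-phantom defaults.
#' @param run_phase also run the phase-enabled full-pipeline arm (slowest
#'   part; needed for the phase-removal floor figure).
#' @return List with \code{floors} (named: noisy, baseline, one per
#'   strategy), \code{ratios} (noisy floor / strategy floor),
#'   \code{ratio_min} (worst MCC strategy), \code{ratio_nuc},
#'   \code{baseline_vs_mcc} (baseline floor / worst MCC strategy floor),
#'   \code{ratio_nuc_unwound} (phase-enabled arm, \code{NA} if skipped),
#'   and \code{n_csf_voxels}.
#' @export
noise_floor_study <- function(seed = 1,
                              strategies = c("mp_pca", "tsvd", "hard",
                                             "soft", "fro", "op", "nuc"),
                              channels = 32, grid = NULL,
                              run_phase = TRUE) {
  # memory discipline: the mini phantom at C = 32, V = 173 is ~360 MB as a
  # complex array and each strategy's denoised stack is ~180 MB, so floors
  # are computed strategy by strategy and large arrays are freed eagerly
  cfg <- default_phantom("mini", channels = channels, seed = seed)
  if (!is.null(grid)) cfg$grid <- as.integer(grid)
  cfg$phase_amp <- 0
  sim <- simulate_mcc(cfg)
  d <- dim(sim$image$data)
  plan <- plan_blocks(d[4], d[5], d[1:3], mode = "fixed", k = 5L)

  noisy_sos <- combine_channels(sim$image, "sos")
  csf <- sim$truth$csf
  bvals <- sim$image$bvals
  fl_noisy <- noise_floor(noisy_sos, csf, bvals)

  # phase-free arm: only the real part enters the shrinkage (the pipeline
  # with unwinding disabled), so the complex original can be dropped
  input_real <- Re(sim$image$data)
  rm(sim); gc(FALSE)
  passes <- denoise_pass(input_real, plan, strategies, "median")
  if (length(strategies) == 1)
    passes <- stats::setNames(list(passes), strategies)
  rm(input_real)
  floors <- numeric(length(strategies))
  names(floors) <- strategies
  for (j in seq_along(strategies)) {
    den <- passes[[j]]$denoised
    passes[[j]] <- list() # free as we go
    sos <- sos_from_sq(den * den)
    rm(den); gc(FALSE)
    floors[j] <- noise_floor(sos, csf, bvals)
  }
  rm(passes); gc(FALSE)

  bl <- denoise_magnitude_baseline(noisy_sos, plan = NULL)
  fl_bl <- noise_floor(bl$denoised, csf, bvals)
  rm(bl, noisy_sos); gc(FALSE)

  ratio_unwound <- NA_real_
  if (run_phase) {
    cfg2 <- default_phantom("mini", channels = channels, seed = seed)
    if (!is.null(grid)) cfg2$grid <- as.integer(grid)
    sim2 <- simulate_mcc(cfg2) # background phase on
    csf2 <- sim2$truth$csf
    bvals2 <- sim2$image$bvals
    re <- Re(sim2$image$data)
    im <- Im(sim2$image$data)
    fl2_noisy <- noise_floor(sos_from_sq(re * re + im * im), csf2, bvals2)
    rm(sim2); gc(FALSE)
    # two-pass unwinding in real arithmetic: phase from the denoised
    # complex estimate, then Re(S exp(-i phase)) = Re cos + Im sin
    re_d <- denoise_pass(re, plan, "nuc")$denoised
    im_d <- denoise_pass(im, plan, "nuc")$denoised
    phase <- atan2(im_d, re_d)
    rm(re_d, im_d); gc(FALSE)
    scorr <- re * cos(phase) + im * sin(phase)
    rm(re, im, phase); gc(FALSE)
    den2 <- denoise_pass(scorr, plan, "nuc")$denoised
    rm(scorr); gc(FALSE)
    fl2 <- noise_floor(sos_from_sq(den2 * den2), csf2, bvals2)
    rm(den2); gc(FALSE)
    ratio_unwound <- fl2_noisy / fl2
  }

  ratios <- fl_noisy / floors
  list(floors = c(noisy = fl_noisy, baseline = fl_bl, floors),
       ratios = ratios,
       ratio_min = min(ratios),
       ratio_nuc = unname(ratios["nuc"]),
       baseline_vs_mcc = fl_bl / max(floors),
       ratio_nuc_unwound = ratio_unwound,
       n_csf_voxels = sum(csf))
}

#' Channel-redundancy sweep
#'
#' Measures how the mean-normalized error of the denoised, sum-of-squares
#' combined image (against the noise-free ground truth, within the fiber
#' mask) changes with the number of channels at a fixed volume count.
#' Channels are sub-sampled from one fixed 32-coil array so the collected
#' signal scales with the channel count, and all runs share the phantom
#' seed (paired comparison).
#'
#' @param seed root phantom seed.
#' @param channels channel counts to sweep.
#' @param coil_array coil-array size channels are drawn from.
#' @param strategy denoising strategy.
#' @return Named numeric vector of errors, one per channel count.
#' @export
channel_sweep_study <- function(seed = 1, channels = c(1, 2, 4, 8),
                                coil_array = 32, strategy = "nuc") {
  errs <- vapply(channels, function(C) {
    cfg <- default_phantom("mini", channels = C, coil_array = coil_array,
                           seed = seed)
    cfg$phase_amp <- 0
    sim <- simulate_mcc(cfg)
    d <- dim(sim$image$data)
    plan <- plan_blocks(d[4], d[5], d[1:3], mode = "fixed", k = 5L)
    out <- denoise_mcc(sim$image, strategy = strategy, plan = plan,
                       unwind = FALSE)
    den_sos <- combine_channels(out$image, "sos")
    truth_sos <- truth_sos_magnitude(sim$truth)
    fiber <- sim$truth$labels >= 1 & sim$truth$labels < 100
    suppressWarnings(normalized_error(den_sos, truth_sos, fiber))
  }, numeric(1))
  stats::setNames(errs, channels)
}

#' Ground-truth magnitude of the sum-of-squares combined image
#'
#' \code{|S| * sqrt(sum_c |R_c|^2)}: what a noise-free acquisition would
#' give after root-sum-of-squares channel combination.
#'
#' @param truth the \code{truth} element of \code{\link{simulate_mcc}}.
#' @return 4-D array \code{(x, y, z, v)}.
#' @export
truth_sos_magnitude <- function(truth) {
  w <- sqrt(apply(Mod(truth$sens)^2, c(1, 2, 3), sum))
  truth$signal * array(rep(w, dim(truth$signal)[4]), dim(truth$signal))
}
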
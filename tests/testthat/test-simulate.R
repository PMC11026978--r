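# The phantom generator: compartment signals, protocol, maps, noise and
# reproducibility.

test_that("compartment attenuations follow the tensor model", {
  expect_equal(tensor_signal(0, c(1, 0, 0), c(0, 0, 1)), 1)
  # gradient perpendicular to the fiber at b = 1000: exp(-0.4)
  expect_equal(tensor_signal(1000, c(1, 0, 0), c(0, 0, 1)), exp(-0.4),
               tolerance = 1e-12)
  # gradient parallel at b = 3000: exp(-5.1)
  expect_equal(tensor_signal(3000, c(0, 0, 1), c(0, 0, 1)), exp(-5.1),
               tolerance = 1e-12)
  expect_equal(isotropic_signal(0), 1)
  expect_equal(isotropic_signal(1000), exp(-3), tolerance = 1e-12)
  expect_equal(isotropic_signal(3000), exp(-9), tolerance = 1e-12)
})

test_that("the default protocol has 173 volumes in 4 shells", {
  p <- dwi_protocol()
  expect_equal(length(p$bvals), 173)
  expect_equal(sum(p$bvals == 0), 5)
  expect_equal(sort(unique(p$bvals)), c(0, 1000, 2000, 3000))
  nrm <- sqrt(colSums(p$bvecs^2))
  expect_true(all(abs(nrm[p$bvals > 0] - 1) < 1e-12))
  expect_true(all(nrm[p$bvals == 0] == 0))
})

test_that("sensitivity maps are smooth, positive-energy and seeded", {
  m1 <- make_sensitivity_maps(1, c(8, 8, 8))
  expect_equal(m1, array(1 + 0i, c(8, 8, 8, 1)))
  m <- make_sensitivity_maps(8, c(10, 10, 10), seed = 3)
  expect_true(all(apply(Mod(m)^2, c(1, 2, 3), sum) > 0))
  expect_equal(sum(Mod(m[6, 6, 6, ])^2), 1, tolerance = 1e-10) # FOV center
  expect_identical(m, make_sensitivity_maps(8, c(10, 10, 10), seed = 3))
  # sub-sampling a fixed array returns the leading coils of the full set
  full <- make_sensitivity_maps(8, c(10, 10, 10), seed = 3, array_size = 8)
  sub <- make_sensitivity_maps(3, c(10, 10, 10), seed = 3, array_size = 8)
  expect_identical(sub, full[, , , 1:3, drop = FALSE])
})

test_that("the background phase is sinusoidal within slices and seeded", {
  expect_equal(make_background_phase(c(6, 6, 4), 3, amp = 0),
               array(0, c(6, 6, 4, 3)))
  ph <- make_background_phase(c(12, 12, 6), 4, seed = 9, amp = pi / 2)
  expect_identical(ph, make_background_phase(c(12, 12, 6), 4, seed = 9,
                                             amp = pi / 2))
  expect_lte(max(abs(ph)), pi / 2)
  # smooth within a slice: the voxel-to-voxel increment is bounded by the
  # amplitude times the angular step of the sinusoid
  fx <- 1.5
  bound <- (pi / 2) * 2 * pi * fx / 12 * 1.0001
  expect_lte(max(abs(apply(ph, c(2, 3, 4), diff))), bound)
})

test_that("the noise map is radial, monotone and spans the SNR range", {
  sig <- make_noise_map(c(16, 16, 16), c(2, 15))
  ctr <- sig[8, 8, 8]; corner <- sig[1, 1, 1]
  expect_gt(ctr, corner) # more noise at the center
  snr <- 1 / sig
  expect_gte(min(snr), 2 - 1e-9)
  expect_lte(max(snr), 15 + 1e-9)
  expect_equal(min(snr), 2, tolerance = 1e-6)
  expect_equal(max(snr), 15, tolerance = 1e-6)
  expect_equal(make_noise_map(c(8, 8, 8), c(5, 5)),
               array(1 / 5, c(8, 8, 8)))
})

test_that("the simulated acquisition decomposes as signal, phase and noise", {
  cfg <- tiny_phantom(channels = 2, seed = 13)
  sim <- simulate_mcc(cfg)
  d <- dim(sim$image$data)
  expect_equal(d[4], 2)
  expect_equal(d[5], 24)

  # reproducibility: identical config gives bit-identical data
  sim2 <- simulate_mcc(tiny_phantom(channels = 2, seed = 13))
  expect_identical(sim$image$data, sim2$image$data)

  # subtracting the modulated truth leaves zero-mean noise of the right scale
  clean <- array(0 + 0i, d)
  for (cc in seq_len(d[4]))
    clean[, , , cc, ] <- array(rep(sim$truth$sens[, , , cc], d[5]),
                               c(d[1:3], d[5])) *
      sim$truth$signal * exp(1i * sim$truth$phase)
  resid <- sim$image$data - clean
  z <- Re(resid) / array(rep(sim$truth$sigma, d[4] * d[5]), d)
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_equal(sd(z), 1, tolerance = 0.02)

  # a degenerate config with no noise and no phase returns the clean signal
  cfg0 <- tiny_phantom(channels = 1, phase_amp = 0,
                       snr_range = c(Inf, Inf), seed = 13)
  cfg0$coil_array <- 1L
  sim0 <- simulate_mcc(cfg0)
  expect_equal(array(Re(sim0$image$data), c(cfg0$grid, 24)),
               sim0$truth$signal, tolerance = 1e-12)
  expect_equal(max(Mod(Im(sim0$image$data))), 0)
})

test_that("single-channel pure-noise magnitude shows the Rayleigh floor", {
  cfg <- tiny_phantom(channels = 1, phase_amp = 0, snr_range = c(4, 4),
                      seed = 17)
  cfg$coil_array <- 1L
  sim <- simulate_mcc(cfg)
  mag <- combine_channels(sim$image, "sos")
  bg <- !sim$truth$support
  high_b <- which(sim$image$bvals == 3000)
  vals <- mag[, , , high_b][array(rep(bg, length(high_b)),
                                  c(cfg$grid, length(high_b)))]
  sigma <- 1 / 4
  expect_equal(mean(vals), sigma * sqrt(pi / 2), tolerance = 0.03)
})

test_that("free water at b = 3000 sits far below the Rician floor", {
  # the premise of the noise-floor experiment: exp(-9) << sqrt(pi/2)/SNR
  # for every SNR in the simulated range
  expect_lt(exp(-9), 0.01 * sqrt(pi / 2) / 15)
})

test_that("default phantoms match the study geometry", {
  full <- default_phantom("full")
  expect_equal(length(full$bundles), 27)
  expect_equal(length(full$iso_regions), 3)
  expect_equal(sum(full$counts), 173)
  mini <- default_phantom("mini")
  expect_lte(max(mini$grid), 24)
  expect_equal(mini$channels, 32L)
  expect_equal(sum(mini$counts), 173)
  expect_gte(length(mini$bundles), 3) # straight + crossing pair at least
  expect_equal(mini$iso_regions[[1]]$d_iso, 3.0e-3)
  # mini generation stays desk-scale
  t0 <- Sys.time()
  sim <- simulate_mcc(default_phantom("mini", channels = 4, seed = 2))
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 10)
  expect_true(any(sim$truth$csf))
})

test_that("planted-spike matrices have the stated structure", {
  ps0 <- planted_spike_matrix(30, spike = 10, sigma = 0, seed = 4)
  expect_equal(qr(ps0$noisy)$rank, 1)
  expect_equal(svd(ps0$truth)$d[1], 10, tolerance = 1e-10)
  psn <- planted_spike_matrix(30, spike = 0, sigma = 1, seed = 4)
  expect_equal(psn$truth, matrix(0, 30, 30))
  expect_gt(qr(psn$noisy)$rank, 25)
  expect_identical(planted_spike_matrix(30, 10, 1, seed = 4)$noisy,
                   planted_spike_matrix(30, 10, 1, seed = 4)$noisy)
})
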
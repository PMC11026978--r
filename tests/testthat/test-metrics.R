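# Evaluation metrics.

test_that("the mean-normalized error matches hand computations", {
  truth <- array(2, c(4, 4, 4, 3))
  expect_equal(as.numeric(normalized_error(truth, truth)), 0)
  expect_equal(as.numeric(normalized_error(1.1 * truth, truth)), 0.1,
               tolerance = 1e-12)
  # half the entries exact, half 20% off: mean is 0.1
  den <- truth
  den[, , , 1:2] <- 1.2 * den[, , , 1:2]
  den[, , , 3] <- truth[, , , 3]
  mixed <- (2 * 0.2 + 1 * 0) / 3
  expect_equal(as.numeric(normalized_error(den, truth)), mixed,
               tolerance = 1e-12)
  # zero-truth entries inside the mask are excluded with a warning
  t2 <- truth; t2[1, 1, 1, ] <- 0
  expect_warning(e <- normalized_error(t2 + 0.1, t2,
                                       mask = array(TRUE, c(4, 4, 4))),
                 "excluded")
  expect_equal(attr(e, "n_excluded"), 3)
})

test_that("PSNR is a peak ratio computed per shell", {
  truth <- array(1, c(5, 5, 5, 4))
  # denoised offset by the peak: MSE = 1 -> 0 dB
  expect_equal(unname(psnr(truth + 1, truth)), 0)
  # offset by a tenth of the peak: MSE = 0.01 -> 20 dB
  expect_equal(unname(psnr(truth + 0.1, truth)), 20, tolerance = 1e-10)
  # grouping with a single b-value equals the ungrouped result
  expect_equal(unname(psnr(truth + 0.1, truth, bvals = rep(1000, 4))),
               unname(psnr(truth + 0.1, truth)))
  by_b <- psnr(truth + 0.1, truth, bvals = c(0, 0, 3000, 3000))
  expect_equal(names(by_b), c("0", "3000"))
  expect_equal(unname(by_b), c(20, 20), tolerance = 1e-10)
})

test_that("SNR maps scale inversely with sigma and flag zero noise", {
  img <- array(abs(rnorm(6^3 * 5)) + 1, c(6, 6, 6, 5))
  s1 <- estimate_snr_map(img, sigma_map = array(1, c(6, 6, 6)))
  s2 <- estimate_snr_map(img, sigma_map = array(2, c(6, 6, 6)))
  expect_equal(s1, 2 * s2)
  s0 <- estimate_snr_map(img, sigma_map = array(0, c(6, 6, 6)))
  expect_true(all(is.infinite(s0)))
})

test_that("the noise floor is the high-b mean over the region", {
  img <- array(1, c(4, 4, 4, 4))
  img[, , , 3:4] <- 0.5 # highest shell
  mask <- array(TRUE, c(4, 4, 4))
  bv <- c(0, 1000, 3000, 3000)
  expect_equal(noise_floor(img, mask, bv), 0.5)
  expect_equal(floor_ratio(img, img, mask, bv), 1)
  expect_equal(floor_ratio(img, 0.1 * img, mask, bv), 10)
  expect_error(noise_floor(img, array(FALSE, c(4, 4, 4)), bv), "empty")
})

test_that("residual maps normalize by sigma and report shape statistics", {
  set.seed(161)
  before <- array(rnorm(20^3 * 4, sd = 2), c(20, 20, 20, 4))
  after <- array(0, dim(before))
  rm0 <- residual_map(before, before)
  expect_true(all(rm0$residual == 0))
  rm1 <- residual_map(before, after, sigma = array(2, c(20, 20, 20)))
  expect_equal(sd(rm1$residual), 1, tolerance = 0.02)
  expect_gt(rm1$n, 1e4)
  expect_lt(abs(rm1$skewness), 0.1)
  expect_lt(abs(rm1$kurtosis), 0.2)
})

test_that("the tractography score behaves on the simplex", {
  expect_equal(tractography_score(1, 0, 0), 1)
  expect_equal(tractography_score(0, 1, 0), 0)
  expect_equal(tractography_score(0, 0, 1), 0)
  expect_equal(tractography_score(0.5, 0.25, 0.25),
               1 - sqrt(0.375) / sqrt(2), tolerance = 1e-12)
  # score improves with VC and degrades with IC/NC
  expect_gt(tractography_score(0.8, 0.1, 0.1),
            tractography_score(0.6, 0.2, 0.2))
  expect_gt(tractography_score(0.7, 0.1, 0.2),
            tractography_score(0.7, 0.3, 0.2))
  expect_error(tractography_score(1.2, 0, 0))
})
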
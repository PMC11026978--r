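# Noise estimation, MP distribution utilities and channel covariance.

test_that("the MP median is bracketed by the support and matches sampling", {
  for (d in c(0.05, 0.2, 0.5, 0.8, 1)) {
    lo <- (1 - sqrt(d))^2; hi <- (1 + sqrt(d))^2
    mu <- mp_median(d)
    expect_gt(mu, lo)
    expect_lt(mu, hi)
  }
  # collapses to a point mass at 1 as delta -> 0
  expect_equal(mp_median(1e-4), 1, tolerance = 0.01)
  # delta = 1: match the empirical eigenvalue median of (1/N) G G^T
  set.seed(71)
  G <- matrix(rnorm(500 * 500), 500, 500)
  emp <- median(eigen(tcrossprod(G) / 500, symmetric = TRUE,
                      only.values = TRUE)$values)
  expect_equal(mp_median(1), emp, tolerance = 0.02)
  expect_error(mp_median(0), "delta")
  expect_error(mp_median(2), "delta")
})

test_that("the median estimator recovers sigma and resists signal spikes", {
  expect_equal(estimate_sigma_median(
    singular_spectrum(rep(0, 5), m = 5, n = 10)), 0)
  expect_error(estimate_sigma_median(
    singular_spectrum(c(2, 1), m = 2, n = 4)), "3 singular values")

  set.seed(81)
  pure <- replicate(25, estimate_sigma_median(
    singular_spectrum(matrix(rnorm(125 * 500, sd = 2), 125, 500))))
  expect_true(all(pure > 1.9 & pure < 2.1))

  spiked <- replicate(25, {
    G <- matrix(rnorm(125 * 500, sd = 2), 125, 500)
    edge <- 2 * (sqrt(125) + sqrt(500))
    spike <- 50 * edge * tcrossprod(matrix(rnorm(125 * 3) / sqrt(125), 125, 3),
                                    matrix(rnorm(500 * 3) / sqrt(500), 500, 3))
    estimate_sigma_median(singular_spectrum(G + spike))
  })
  expect_true(all(spiked > 1.9 & spiked < 2.1))
})

test_that("the MP-fit estimator agrees with the simultaneous fit", {
  set.seed(91)
  spec <- singular_spectrum(matrix(rnorm(60 * 300, sd = 3), 60, 300))
  est <- estimate_sigma_mp(spec)
  fit <- mp_pca_fit(spec)
  expect_equal(est$sigma, fit$sigma)
  expect_equal(est$P, fit$P)
  expect_equal(est$sigma, 3, tolerance = 0.1)
})

test_that("channel covariance is estimated from background voxels", {
  set.seed(101)
  C <- 4; grid <- c(12, 12, 6); V <- 3
  noise <- array(complex(real = rnorm(prod(grid) * C * V),
                         imaginary = rnorm(prod(grid) * C * V)),
                 c(grid, C, V))
  img <- mcc_image(noise)
  mask <- array(TRUE, grid)
  phi <- estimate_channel_cov(img, mask)
  expect_equal(max(Mod(phi - Conj(t(phi)))), 0, tolerance = 1e-12)
  expect_equal(Re(diag(phi)), rep(2, C), tolerance = 0.15) # re + im variance
  expect_lt(max(Mod(phi[upper.tri(phi)])), 0.1)

  # a duplicated channel pair shows up as a rank-1 2x2 block
  dup <- noise
  dup[, , , 2, ] <- dup[, , , 1, ]
  phi_dup <- estimate_channel_cov(mcc_image(dup), mask)
  block <- phi_dup[1:2, 1:2]
  ev <- eigen(block, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[2] / ev[1], 0.05)

  # boundary of the precondition: exactly 10 * C voxels
  small_mask <- array(FALSE, grid)
  small_mask[seq_len(10 * C)] <- TRUE
  expect_silent(estimate_channel_cov(img, small_mask))
  too_small <- array(FALSE, grid)
  too_small[seq_len(10 * C - 1)] <- TRUE
  expect_error(estimate_channel_cov(img, too_small), "at least")
})

test_that("whitening decorrelates and round-trips", {
  set.seed(111)
  C <- 3; grid <- c(10, 10, 5); V <- 4
  img <- mcc_image(array(complex(real = rnorm(prod(grid) * C * V),
                                 imaginary = rnorm(prod(grid) * C * V)),
                         c(grid, C, V)))
  # identity covariance: identity map
  w <- whiten_channels(img, diag(C) + 0i)
  expect_equal(w$data, img$data)
  # diagonal case: channel 1 scaled by 1/2
  wd <- whiten_channels(img, diag(c(4, 1, 1)) + 0i)
  expect_equal(wd$data[, , , 1, ], img$data[, , , 1, ] / 2)
  expect_equal(wd$data[, , , 2, ], img$data[, , , 2, ])

  # correlated noise: post-whitening covariance close to identity
  A <- matrix(complex(real = rnorm(C * C), imaginary = rnorm(C * C)), C, C)
  phi_true <- A %*% Conj(t(A)) + diag(C)
  ev <- eigen(phi_true, symmetric = TRUE)
  L <- ev$vectors %*% (sqrt(ev$values) * Conj(t(ev$vectors))) # Hermitian sqrt
  x <- matrix(complex(real = rnorm(prod(grid) * V * C),
                      imaginary = rnorm(prod(grid) * V * C)),
              prod(grid) * V, C) / sqrt(2)
  corr <- x %*% t(L)
  cimg <- mcc_image(array(aperm(array(corr, c(prod(grid), V, C)),
                                c(1, 3, 2)), c(grid, C, V)))
  wc <- whiten_channels(cimg, phi_true)
  y <- matrix(aperm(wc$data, c(1, 2, 3, 5, 4)), ncol = C)
  emp <- crossprod(Conj(y), y) / nrow(y)
  expect_lt(sqrt(sum(Mod(emp - diag(C))^2)) / sqrt(C), 0.05)

  # round trip
  back <- unwhiten_channels(wc, phi_true)
  expect_lt(max(Mod(back$data - cimg$data)) / max(Mod(cimg$data)), 1e-10)

  # non-positive-definite covariance is rejected with the eigenvalue named
  bad <- diag(c(1, -0.5, 1)) + 0i
  expect_error(whiten_channels(img, bad), "eigenvalue")
})

test_that("covariance matrices round-trip through plain text", {
  phi <- matrix(complex(real = c(2, 0.3, 0.3, 1),
                        imaginary = c(0, 0.1, -0.1, 0)), 2, 2)
  path <- file.path(tempdir(), "phi.txt")
  write_channel_cov(phi, path)
  back <- read_channel_cov(path)
  expect_equal(back, phi, tolerance = 1e-10)
  # real covariance writes a single file
  phir <- matrix(c(2, 0.3, 0.3, 1), 2, 2)
  write_channel_cov(phir, path)
  expect_false(file.exists(paste0(path, ".imag.real")))
  expect_equal(Re(read_channel_cov(path)), phir, tolerance = 1e-10)
})
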
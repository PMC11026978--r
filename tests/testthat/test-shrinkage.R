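# Unit tests for the singular-value shrinkers and matrix recovery.

test_that("debiased transform and shrinkers match their closed forms", {
  # delta = 1, y = 3: z = sqrt((7 + sqrt(45)) / 2)
  expect_equal(z_transform(3, 1), sqrt((7 + sqrt(45)) / 2), tolerance = 1e-12)
  expect_equal(z_transform(3, 1), 2.6180339887, tolerance = 1e-9)
  # threshold point y = 1 + sqrt(delta): discriminant vanishes, z = delta^(1/4)
  expect_equal(z_transform(2, 1), 1)
  expect_equal(z_transform(1.5, 0.25), 0.25^0.25, tolerance = 1e-12)
  expect_equal(z_transform(0, 0.7), 0)

  expect_equal(shrink_fro(3, 1), sqrt(5), tolerance = 1e-12)
  expect_equal(shrink_fro(2, 1), 0)
  # delta -> 0 limit: (y^2 - 1) / y
  expect_equal(shrink_fro(2, 1e-12), 1.5, tolerance = 1e-5)

  expect_equal(shrink_op(3, 1), z_transform(3, 1))
  expect_equal(shrink_op(1.4, 0.25), 0)

  z <- z_transform(3, 1)
  expect_equal(shrink_nuc(3, 1), (z^4 - 1 - 3 * z) / (z^2 * 3),
               tolerance = 1e-12)
  expect_equal(shrink_nuc(3, 1), 1.8541019662, tolerance = 1e-9)
  expect_equal(shrink_nuc(2, 1), 0) # z = 1, z^4 < delta + sqrt(delta) y z
  expect_equal(shrink_nuc(0, 0.5), 0)

  expect_equal(shrink_tsvd(3, 1), 3)
  expect_equal(shrink_tsvd(1.9, 1), 0)
  expect_equal(shrink_tsvd(2, 1), 2) # tie-break: retained at the bulk edge

  expect_equal(hard_threshold_level(1), sqrt(16 / 3), tolerance = 1e-12)
  expect_equal(hard_threshold_level(1e-12), sqrt(2), tolerance = 1e-5)
  expect_equal(shrink_hard(2.5, 1), 2.5)
  expect_equal(shrink_hard(2.2, 1), 0)
  expect_equal(shrink_hard(0, 1), 0)

  expect_equal(shrink_soft(3, 1), 1)
  expect_equal(shrink_soft(1.5, 0.25), 0)
  expect_equal(shrink_soft(1, 1), 0)

  expect_error(shrink_fro(2, 0), "delta")
  expect_error(shrink_fro(2, 1.5), "delta")
})

test_that("shrinkers are ordered, thresholded and monotone on a grid", {
  deltas <- c(0.01, 0.05, 0.1, 0.25, 0.5, 0.75, 1)
  ys <- seq(0, 10, by = 0.01)
  for (d in deltas) {
    thr <- 1 + sqrt(d)
    nuc <- shrink_nuc(ys, d); fro <- shrink_fro(ys, d); op <- shrink_op(ys, d)
    # zero below the common threshold, non-negative everywhere
    for (eta in list(nuc, fro, op, shrink_tsvd(ys, d), shrink_soft(ys, d),
                     shrink_hard(ys, d))) {
      expect_true(all(eta[ys < thr - 1e-9] == 0))
      expect_true(all(eta >= 0))
      expect_true(all(diff(eta) >= -1e-12)) # non-decreasing
    }
    # nuclear <= frobenius <= operator <= identity above the bulk edge
    above <- ys > thr
    expect_true(all(nuc[above] <= fro[above] + 1e-12))
    expect_true(all(fro[above] <= op[above] + 1e-12))
    expect_true(all(op[above] <= ys[above] + 1e-12))
    # hard threshold sits at or above the bulk edge
    expect_gte(hard_threshold_level(d), thr)
  }
  # hard threshold level increases with the aspect ratio
  expect_true(all(diff(hard_threshold_level(deltas)) > 0))
})

test_that("normalization puts the pure-noise bulk edge at 1 + sqrt(delta)", {
  set.seed(11)
  tops <- replicate(50, {
    spec <- singular_spectrum(matrix(rnorm(100 * 400), 100, 400))
    max(normalize_spectrum(spec, 1))
  })
  expect_equal(mean(tops), 1.5, tolerance = 0.05)

  spec0 <- singular_spectrum(rep(0, 5), m = 5, n = 10)
  expect_equal(normalize_spectrum(spec0, 1), rep(0, 5))
  # homogeneity: y is linear in s at fixed sigma
  spec1 <- singular_spectrum(c(4, 2, 1), m = 3, n = 6)
  spec2 <- singular_spectrum(c(8, 4, 2), m = 3, n = 6)
  expect_equal(normalize_spectrum(spec2, 1), 2 * normalize_spectrum(spec1, 1))
  expect_error(normalize_spectrum(spec1, 0), "sigma")
  expect_error(normalize_spectrum(spec1, -1), "sigma")
})

test_that("the simultaneous MP fit finds the signal count and noise level", {
  set.seed(21)
  fits <- replicate(50, {
    f <- mp_pca_fit(singular_spectrum(matrix(rnorm(50 * 500), 50, 500)))
    c(f$P, f$sigma)
  })
  expect_true(all(fits[1, ] <= 2)) # essentially no spurious components
  expect_equal(mean(fits[2, ]), 1, tolerance = 0.1)

  # three spikes far above the bulk edge are counted exactly
  set.seed(22)
  hits <- replicate(20, {
    G <- matrix(rnorm(50 * 500), 50, 500)
    edge <- sqrt(50) + sqrt(500)
    spike <- 10 * edge * tcrossprod(matrix(rnorm(50 * 3) / sqrt(50), 50, 3),
                                    matrix(rnorm(500 * 3) / sqrt(500), 500, 3))
    mp_pca_fit(singular_spectrum(G + spike))$P
  })
  expect_true(mean(hits == 3) >= 0.9)

  f0 <- mp_pca_fit(singular_spectrum(rep(0, 5), m = 5, n = 10))
  expect_equal(f0$P, 0)
  expect_equal(f0$sigma, 0)
})

test_that("MP-PCA shrinkage keeps signal components unchanged", {
  # zero matrix stays zero
  r0 <- mp_pca_shrink(singular_spectrum(rep(0, 4), m = 4, n = 8))
  expect_equal(r0$shrunk_values, rep(0, 4))
  expect_equal(r0$rank, 0)

  # rank-1 spike + noise: MP-PCA retains the top value noise-inflated,
  # while Frobenius optimal shrinkage debiases it downward
  set.seed(31)
  G <- matrix(rnorm(100 * 1000), 100, 1000)
  u <- rnorm(100); u <- u / sqrt(sum(u^2))
  v <- rnorm(1000); v <- v / sqrt(sum(v^2))
  S <- 5 * (sqrt(100) + sqrt(1000)) * tcrossprod(u, v) + G
  spec <- singular_spectrum(S)
  mp <- mp_pca_shrink(spec)
  expect_equal(mp$rank, 1)
  expect_equal(mp$shrunk_values[1], spec$values[1])
  os <- os_shrink(spec, estimate_sigma_median(spec), "fro")
  expect_lt(os$shrunk_values[1], mp$shrunk_values[1])

  # noise-free low-rank diagonal: the degenerate branch (P capped at M - 1,
  # sigma 0) retains every non-zero value exactly and does not loop
  dg <- mp_pca_shrink(singular_spectrum(diag(c(10, 8, 5, rep(0, 22)))))
  expect_equal(dg$rank, 3)
  expect_equal(dg$shrunk_values, c(10, 8, 5, rep(0, 22)))
  expect_equal(dg$sigma_used, 0)
})

test_that("matrix recovery round-trips and scales", {
  set.seed(41)
  S <- matrix(rnorm(20 * 50), 20, 50)
  sv <- svd(S)
  # identity shrinkage reproduces the input
  X <- recover_matrix(sv$u, sv$v, sv$d)
  expect_lt(norm(X - S, "F") / norm(S, "F"), 1e-10)
  # all-zero shrinkage gives the zero matrix
  expect_equal(recover_matrix(sv$u, sv$v, rep(0, 20)),
               matrix(0, 20, 50))
  # rank-1 truth: shrinking s1 by eta scales the matrix by eta / s1
  u <- rnorm(20); u <- u / sqrt(sum(u^2))
  v <- rnorm(50); v <- v / sqrt(sum(v^2))
  R <- 7 * tcrossprod(u, v)
  svr <- svd(R)
  shrunk <- c(3.5, rep(0, 19))
  expect_equal(recover_matrix(svr$u, svr$v, shrunk), 0.5 * R,
               tolerance = 1e-10)
  expect_error(recover_matrix(sv$u, sv$v, rep(1, 5)), "dimension")
})

test_that("optimal shrinkage nearly annihilates a pure-noise matrix", {
  set.seed(51)
  fracs <- replicate(20, {
    S <- matrix(rnorm(40 * 160), 40, 160)
    vapply(c("fro", "op", "nuc"), function(st)
      norm(denoise_matrix(S, st)$X, "F") / norm(S, "F"), numeric(1))
  })
  expect_lt(mean(fracs), 0.05)
})

test_that("denoise_matrix handles orientation and known sigma", {
  set.seed(61)
  S <- matrix(rnorm(200 * 30), 200, 30) # tall: transposed internally
  out <- denoise_matrix(S, "nuc", sigma = 1)
  expect_equal(dim(out$X), dim(S))
  expect_lt(norm(out$X, "F") / norm(S, "F"), 0.1)
})
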
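# Noise-level estimation and channel noise-covariance handling.

#' Median of the Marchenko-Pastur distribution
#'
#' Solves for the median of the MP law with aspect ratio \code{delta}
#' (variance 1): the value \code{mu} in \code{[(1 - sqrt(delta))^2,
#' (1 + sqrt(delta))^2]} at which the cumulative density reaches one half.
#' Quadrature and root-finding tolerances are 1e-8.
#'
#' @param delta aspect ratio in (0, 1].
#' @return The median \code{mu}, strictly inside the support for
#'   \code{delta < 1}; tends to 1 as \code{delta} tends to 0.
#' @export
mp_median <- function(delta) {
  if (!is.numeric(delta) || length(delta) != 1 || !is.finite(delta) ||
      delta <= 0 || delta > 1)
    stop("delta must be a single value in (0, 1]")
  lo <- (1 - sqrt(delta))^2
  hi <- (1 + sqrt(delta))^2
  dens <- function(v) sqrt(pmax((hi - v) * (v - lo), 0)) / (2 * pi * delta * v)
  cdf_minus_half <- function(mu) {
    integrate(dens, lo, mu, rel.tol = 1e-8, abs.tol = 1e-10,
              stop.on.error = FALSE)$value - 0.5
  }
  eps <- (hi - lo) * 1e-9
  uniroot(cdf_minus_half, lower = lo + eps, upper = hi - eps,
          tol = 1e-8)$root
}

# per-(m, n) cache: mp_median is called once per block plan, many blocks
mp_median_cached <- local({
  cache <- new.env(parent = emptyenv())
  function(delta) {
    key <- format(delta, digits = 15)
    if (is.null(cache[[key]])) cache[[key]] <- mp_median(delta)
    cache[[key]]
  }
})

#' Noise level from the median singular value
#'
#' The MP-median noise estimator: \code{sigma = s_med / sqrt(N * mu)} where
#' \code{s_med} is the median empirical singular value and \code{mu} the
#' median of the MP distribution at the matrix aspect ratio.  Robust to a
#' small number of large signal components, since these do not move the
#' median of the spectrum.
#'
#' @param spec a \code{\link{singular_spectrum}} with \code{M >= 3} values.
#' @return Non-negative noise level estimate.
#' @export
estimate_sigma_median <- function(spec) {
  stopifnot(inherits(spec, "singular_spectrum"))
  if (spec$m < 3) stop("at least 3 singular values are required")
  median(spec$values) / sqrt(spec$n * mp_median_cached(spec$delta))
}

#' Noise level from the simultaneous MP fit
#'
#' Companion to \code{\link{estimate_sigma_median}} using the simultaneous
#' estimation of the signal count and noise level (\code{\link{mp_pca_fit}});
#' \code{sigma^2} is the mean of the fitted noise bulk of \code{lambda / N}.
#'
#' @param spec a \code{\link{singular_spectrum}}.
#' @return List with \code{sigma} and the signal count \code{P}.
#' @export
estimate_sigma_mp <- function(spec) {
  fit <- mp_pca_fit(spec)
  list(sigma = fit$sigma, P = fit$P)
}

#' Estimate the channel noise covariance from background voxels
#'
#' Sample covariance of the complex channel vectors over the masked voxels
#' and all volumes.  The mask should select signal-free (background) voxels;
#' at least \code{10 * C} voxels are required.  Near-singular estimates
#' (condition number above 1e8) are ridge-regularized by \code{1e-6 *
#' trace(Phi) / C} on the diagonal.
#'
#' @param img an \code{\link{mcc_image}}.
#' @param mask logical array over the spatial grid.
#' @return Hermitian positive semi-definite \code{C x C} complex matrix.
#' @export
estimate_channel_cov <- function(img, mask) {
  stopifnot(inherits(img, "mcc_image"))
  d <- dim(img$data)
  C <- d[4]; V <- d[5]
  mask <- as.logical(mask)
  nvox <- sum(mask)
  if (nvox < 10 * C)
    stop("background mask must select at least 10 * C = ", 10 * C,
         " voxels (got ", nvox, ")")
  x <- matrix(img$data, prod(d[1:3]), C * V)[mask, , drop = FALSE]
  # stack volumes as additional samples: (nvox * V) x C
  x <- matrix(aperm(array(x, c(nvox, C, V)), c(1, 3, 2)), nvox * V, C)
  x <- sweep(x, 2, colMeans(x))
  phi <- crossprod(Conj(x), x) / (nrow(x) - 1)
  phi <- (phi + Conj(t(phi))) / 2 # enforce Hermitian symmetry
  ev <- eigen(phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e8)
    phi <- phi + diag(1e-6 * Re(sum(diag(phi))) / C, C)
  phi
}

phi_power <- function(phi, power) {
  e <- eigen(phi, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("channel covariance is not positive definite (eigenvalue ",
         format(min(e$values)), ")")
  e$vectors %*% (e$values^power * Conj(t(e$vectors)))
}

apply_channel_matrix <- function(img, W) {
  d <- dim(img$data)
  C <- d[4]
  x <- array(img$data, c(prod(d[1:3]), C, d[5]))
  out <- array(0 + 0i, dim(x))
  tW <- t(W)
  for (v in seq_len(d[5])) out[, , v] <- x[, , v] %*% tW
  img$data <- array(out, d)
  img
}

#' Whiten (decorrelate) channels
#'
#' Mahalanobis whitening along the channel axis: each channel vector is
#' multiplied by \code{Phi^(-1/2)} (Hermitian inverse square root of the
#' channel noise covariance), making the channel noise uncorrelated with unit
#' variance.  \code{unwhiten_channels} applies \code{Phi^(1/2)} and
#' round-trips to machine precision.
#'
#' @param img an \code{\link{mcc_image}}.
#' @param phi Hermitian positive-definite \code{C x C} covariance matrix.
#' @return The transformed \code{mcc_image}.
#' @export
whiten_channels <- function(img, phi) {
  stopifnot(inherits(img, "mcc_image"))
  check_phi(phi, dim(img$data)[4])
  apply_channel_matrix(img, phi_power(phi, -0.5))
}

#' @rdname whiten_channels
#' @export
unwhiten_channels <- function(img, phi) {
  stopifnot(inherits(img, "mcc_image"))
  check_phi(phi, dim(img$data)[4])
  apply_channel_matrix(img, phi_power(phi, 0.5))
}

check_phi <- function(phi, C) {
  if (!is.matrix(phi) || nrow(phi) != C || ncol(phi) != C)
    stop("phi must be a ", C, " x ", C, " matrix")
  if (max(Mod(phi - Conj(t(phi)))) > 1e-10 * max(1, max(Mod(phi))))
    stop("phi must be Hermitian")
  invisible(phi)
}

#' Read or write a channel covariance matrix as plain text
#'
#' A real covariance is stored as a single whitespace-delimited \code{C x C}
#' table; a complex one as two files (\code{<path>} holding the real part
#' and \code{<path>.imag} the imaginary part).
#'
#' @param path file path.
#' @param phi covariance matrix (for writing).
#' @return \code{read_channel_cov} returns the matrix (complex if an
#'   imaginary-part file is present).
#' @export
read_channel_cov <- function(path) {
  re <- as.matrix(utils::read.table(path))
  dimnames(re) <- NULL
  imag_path <- paste0(path, ".imag")
  if (file.exists(imag_path)) {
    im <- as.matrix(utils::read.table(imag_path))
    dimnames(im) <- NULL
    re <- re + 1i * im
  }
  re
}

#' @rdname read_channel_cov
#' @export
write_channel_cov <- function(phi, path) {
  utils::write.table(Re(phi), path, row.names = FALSE, col.names = FALSE)
  if (is.complex(phi) && any(Im(phi) != 0)) {
    utils::write.table(Im(phi), paste0(path, ".imag"),
                       row.names = FALSE, col.names = FALSE)
  } else {
    unlink(paste0(path, ".imag")) # never leave a stale imaginary part
  }
  invisible(path)
}
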
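# Singular-value shrinkage: the spectrum container, the seven low-rank
# recovery strategies, and matrix reconstruction.
#
# All shrinkers operate on noise-normalized singular values y = s / (sigma
# sqrt(N)) of an M x N matrix (M <= N, aspect ratio delta = M/N).  In these
# units the singular values of a pure-noise Gaussian matrix asymptotically
# fill [1 - sqrt(delta), 1 + sqrt(delta)]; every threshold below is stated
# relative to the bulk edge 1 + sqrt(delta).

#' Singular spectrum of a signal matrix
#'
#' Container for the singular values of an \code{M x N} matrix (\code{M <=
#' N}) together with its dimensions and aspect ratio \code{delta = M/N}.
#' Construct from a matrix (the SVD is taken, transposing first if \code{M >
#' N}) or from a vector of singular values with explicit dimensions.
#'
#' @param x a numeric matrix, or a non-increasing vector of non-negative
#'   singular values.
#' @param m,n matrix dimensions; required when \code{x} is a vector.
#' @return An object of class \code{singular_spectrum} with fields
#'   \code{values} (descending), \code{m}, \code{n}, \code{delta}.
#' @examples
#' spec <- singular_spectrum(matrix(rnorm(50 * 200), 50, 200))
#' spec$delta
#' @export
singular_spectrum <- function(x, m = NULL, n = NULL) {
  if (is.matrix(x)) {
    if (nrow(x) > ncol(x)) x <- t(x)
    m <- nrow(x)
    n <- ncol(x)
    values <- svd(x, nu = 0, nv = 0)$d
  } else {
    values <- as.numeric(x)
    if (is.null(m) || is.null(n))
      stop("m and n are required when constructing from singular values")
    if (m > n) stop("m must not exceed n (transpose the matrix first)")
    if (length(values) != m)
      stop("expected ", m, " singular values, got ", length(values))
    if (is.unsorted(rev(values)))
      stop("singular values must be non-increasing")
    if (any(values < 0)) stop("singular values must be non-negative")
  }
  structure(list(values = values, m = as.integer(m), n = as.integer(n),
                 delta = m / n),
            class = "singular_spectrum")
}

#' @export
print.singular_spectrum <- function(x, ...) {
  cat(sprintf("Singular spectrum: M = %d, N = %d (delta = %.4f)\n",
              x$m, x$n, x$delta))
  cat("  top values:", format(utils::head(x$values, 5), digits = 4), "\n")
  invisible(x)
}

#' Noise-normalize a singular spectrum
#'
#' Maps singular values to \code{y = s / (sigma * sqrt(N))}, the scale in
#' which all shrinkage functions are defined and in which the pure-noise bulk
#' edge sits at \code{1 + sqrt(delta)}.
#'
#' @param spec a \code{\link{singular_spectrum}}.
#' @param sigma positive noise level (per real-valued matrix entry).
#' @return Numeric vector of normalized values, order preserved.
#' @export
normalize_spectrum <- function(spec, sigma) {
  stopifnot(inherits(spec, "singular_spectrum"))
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) ||
      sigma <= 0)
    stop("sigma must be a single positive number")
  spec$values / (sigma * sqrt(spec$n))
}

#' Debiased singular value transform
#'
#' For a normalized observed singular value \code{y} of a noisy matrix with
#' aspect ratio \code{delta}, returns the estimated underlying (noise-free)
#' singular value \code{z(y) = sqrt((y^2 - delta - 1 + sqrt((y^2 - delta -
#' 1)^2 - 4 delta)) / 2)} when \code{y >= 1 + sqrt(delta)} and 0 otherwise.
#' The operator-norm optimal shrinker equals this transform.
#'
#' @param y non-negative normalized singular value(s); vectorized.
#' @param delta aspect ratio in (0, 1].
#' @return Numeric vector of the same length as \code{y}.
#' @export
z_transform <- function(y, delta) {
  check_delta(delta)
  thr <- 1 + sqrt(delta)
  a <- y^2 - delta - 1
  disc <- pmax(a^2 - 4 * delta, 0) # analytically >= 0 above the bulk edge
  z <- sqrt(pmax(a + sqrt(disc), 0) / 2)
  ifelse(y >= thr, z, 0)
}

#' Optimal shrinkage and thresholding functions
#'
#' Shrinkage of noise-normalized singular values \code{y} for an \code{M x N}
#' matrix with aspect ratio \code{delta = M/N}:
#' \describe{
#'   \item{\code{shrink_fro}}{optimal under Frobenius-norm loss:
#'     \code{sqrt((y^2 - delta - 1)^2 - 4 delta) / y} above the bulk edge.}
#'   \item{\code{shrink_op}}{optimal under operator-norm loss; identical to
#'     \code{\link{z_transform}}.}
#'   \item{\code{shrink_nuc}}{optimal under nuclear-norm loss:
#'     \code{(z^4 - delta - sqrt(delta) y z) / (z^2 y)} when \code{z^4 >=
#'     delta + sqrt(delta) y z}, else 0; the most aggressive of the three.}
#'   \item{\code{shrink_tsvd}}{truncated SVD: keep \code{y} at or above the
#'     bulk edge \code{1 + sqrt(delta)}, zero below.}
#'   \item{\code{shrink_hard}}{hard thresholding at the level
#'     \code{\link{hard_threshold_level}}.}
#'   \item{\code{shrink_soft}}{soft thresholding: \code{y - (1 +
#'     sqrt(delta))} above the bulk edge.}
#' }
#' All are zero below their threshold, non-negative, and non-decreasing.
#'
#' @param y non-negative normalized singular value(s); vectorized.
#' @param delta aspect ratio in (0, 1].
#' @return Shrunk values, same length as \code{y}.
#' @examples
#' shrink_fro(3, 1)   # sqrt(5)
#' shrink_nuc(3, 1)   # ~1.8541
#' @name shrinkers
NULL

#' @rdname shrinkers
#' @export
shrink_fro <- function(y, delta) {
  check_delta(delta)
  a <- y^2 - delta - 1
  disc <- pmax(a^2 - 4 * delta, 0)
  ifelse(y >= 1 + sqrt(delta), sqrt(disc) / y, 0)
}

#' @rdname shrinkers
#' @export
shrink_op <- function(y, delta) z_transform(y, delta)

#' @rdname shrinkers
#' @export
shrink_nuc <- function(y, delta) {
  check_delta(delta)
  z <- z_transform(y, delta)
  lhs <- z^4
  rhs <- delta + sqrt(delta) * y * z
  out <- ifelse(z > 0 & lhs >= rhs, (lhs - rhs) / (z^2 * y), 0)
  out[y == 0] <- 0
  out
}

#' @rdname shrinkers
#' @export
shrink_tsvd <- function(y, delta) {
  check_delta(delta)
  ifelse(y >= 1 + sqrt(delta), y, 0) # tie-break: retain at equality
}

#' @rdname shrinkers
#' @export
shrink_hard <- function(y, delta) {
  check_delta(delta)
  ifelse(y >= hard_threshold_level(delta), y, 0)
}

#' @rdname shrinkers
#' @export
shrink_soft <- function(y, delta) {
  check_delta(delta)
  pmax(y - (1 + sqrt(delta)), 0)
}

#' Hard-thresholding level
#'
#' The asymptotically optimal hard-threshold location for normalized singular
#' values, \code{sqrt(2 (delta + 1) + 8 delta / ((delta + 1) + sqrt(delta^2 +
#' 14 delta + 1)))}; always at or above the bulk edge \code{1 + sqrt(delta)}.
#'
#' @param delta aspect ratio in (0, 1]; vectorized.
#' @return The threshold \code{y} level.
#' @examples
#' hard_threshold_level(1) # sqrt(16/3)
#' @export
hard_threshold_level <- function(delta) {
  check_delta(delta)
  sqrt(2 * (delta + 1) + 8 * delta / ((delta + 1) + sqrt(delta^2 + 14 * delta + 1)))
}

check_delta <- function(delta) {
  if (!is.numeric(delta) || any(!is.finite(delta)) || any(delta <= 0) ||
      any(delta > 1))
    stop("delta must lie in (0, 1]")
  invisible(delta)
}

strategy_names <- c("mp_pca", "tsvd", "hard", "soft", "fro", "op", "nuc")

strategy_code <- function(strategy) {
  strategy <- match.arg(strategy, strategy_names, several.ok = TRUE)
  match(strategy, strategy_names) - 1L # aligned with the enum in src/
}

shrinker_fun <- function(strategy) {
  switch(strategy,
         tsvd = shrink_tsvd, hard = shrink_hard, soft = shrink_soft,
         fro = shrink_fro, op = shrink_op, nuc = shrink_nuc,
         stop("no y-space shrinker for strategy '", strategy, "'"))
}

#' Simultaneous Marchenko-Pastur fit of signal count and noise level
#'
#' Estimates the number of signal components \code{P} and the noise level
#' \code{sigma} from the eigenvalues \code{lambda_i = s_i^2} of \code{S S^T}.
#' Candidate noise bulks are grown from the smallest eigenvalue upward; a
#' bulk is consistent with the Marchenko-Pastur law when its spread
#' \code{(lambda_max - lambda_min) / (4 sqrt(gamma))} (with \code{gamma}
#' the bulk count over \code{N}) does not exceed its mean.  The largest
#' consistent bulk yields \code{sigma^2} (bulk mean over \code{N}) and
#' \code{P = M} minus the bulk size; \code{P} is capped at \code{M - 1}.
#'
#' @param spec a \code{\link{singular_spectrum}} with \code{M >= 2} values.
#' @return List with integer \code{P} and \code{sigma} (0 for an all-zero
#'   spectrum, with \code{P = 0}).
#' @export
mp_pca_fit <- function(spec) {
  stopifnot(inherits(spec, "singular_spectrum"))
  if (spec$m < 2) stop("at least 2 singular values are required")
  lam <- rev(spec$values^2) # ascending
  fit <- mp_fit_cpp(lam, spec$n)
  list(P = fit$P, sigma = sqrt(max(fit$sigsq, 0)))
}

#' MP-PCA shrinkage of a singular spectrum
#'
#' Retains the \code{P} signal components found by \code{\link{mp_pca_fit}}
#' unchanged (no debiasing) and zeroes the noise bulk.  Eigenvalues at or
#' above the variance threshold \code{(M - P) sigma^2} are also retained,
#' which keeps a noise-free full-rank spectrum intact.
#'
#' @param spec a \code{\link{singular_spectrum}}.
#' @return A \code{shrinkage_result}: list with \code{shrunk_values} (raw
#'   scale, descending), \code{rank}, \code{sigma_used}, \code{strategy}.
#' @export
mp_pca_shrink <- function(spec) {
  fit <- mp_pca_fit(spec)
  m <- spec$m
  lam <- spec$values^2 / spec$n
  keep <- seq_len(m) <= fit$P
  if (fit$sigma > 0) {
    keep <- keep | lam >= (m - fit$P) * fit$sigma^2
  } else {
    keep <- keep | spec$values > 0
  }
  shrunk <- ifelse(keep, spec$values, 0)
  shrinkage_result(shrunk, fit$sigma, "mp_pca")
}

#' Optimal-shrinkage / thresholding of a singular spectrum
#'
#' Normalizes the spectrum by \code{sigma} (\code{y = s / (sigma sqrt(N))}),
#' applies the chosen y-space shrinker, and maps back to the raw scale as
#' \code{sigma sqrt(N) eta(y)}.  With \code{sigma = 0} the spectrum is
#' returned unchanged (a noise-free matrix needs no shrinkage).
#'
#' @param spec a \code{\link{singular_spectrum}}.
#' @param sigma noise level; non-negative.
#' @param strategy one of \code{"tsvd"}, \code{"hard"}, \code{"soft"},
#'   \code{"fro"}, \code{"op"}, \code{"nuc"}.
#' @return A \code{shrinkage_result} (see \code{\link{mp_pca_shrink}}).
#' @export
os_shrink <- function(spec, sigma, strategy = c("nuc", "fro", "op", "tsvd",
                                                "hard", "soft")) {
  stopifnot(inherits(spec, "singular_spectrum"))
  strategy <- match.arg(strategy)
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(shrinkage_result(spec$values, 0, strategy))
  scale <- sigma * sqrt(spec$n)
  y <- spec$values / scale
  shrunk <- scale * shrinker_fun(strategy)(y, spec$delta)
  shrinkage_result(shrunk, sigma, strategy)
}

shrinkage_result <- function(shrunk, sigma, strategy) {
  structure(list(shrunk_values = shrunk,
                 rank = sum(shrunk > 0),
                 sigma_used = sigma,
                 strategy = strategy),
            class = "shrinkage_result")
}

#' @export
print.shrinkage_result <- function(x, ...) {
  cat(sprintf("Shrinkage result [%s]: rank %d, sigma %.4g\n",
              x$strategy, x$rank, x$sigma_used))
  invisible(x)
}

#' Reconstruct a matrix from shrunk singular values
#'
#' \code{U diag(shrunk) V^T} with \code{U}, \code{V} from the SVD of the
#' matrix the spectrum was taken from.  Identity shrinkage reproduces the
#' original matrix to machine precision.
#'
#' @param U \code{M x M} left singular vectors.
#' @param V \code{N x M} right singular vectors.
#' @param result a \code{shrinkage_result} (or a numeric vector of shrunk
#'   singular values on the raw scale).
#' @return The recovered \code{M x N} matrix, of rank \code{sum(shrunk > 0)}.
#' @export
recover_matrix <- function(U, V, result) {
  shrunk <- if (inherits(result, "shrinkage_result")) result$shrunk_values
            else as.numeric(result)
  if (ncol(U) != length(shrunk) || ncol(V) != length(shrunk))
    stop("dimension mismatch between singular vectors and shrunk values")
  U %*% (shrunk * t(V))
}

#' Denoise a single matrix by low-rank recovery
#'
#' Convenience wrapper tying spectrum extraction, noise estimation, shrinkage
#' and reconstruction together for one real matrix.  Used by the block
#' pipeline's unit-scale path and the planted-spike experiments.
#'
#' @param S real matrix (transposed internally if rows exceed columns).
#' @param strategy one of \code{"mp_pca"}, \code{"tsvd"}, \code{"hard"},
#'   \code{"soft"}, \code{"fro"}, \code{"op"}, \code{"nuc"}.
#' @param sigma known noise level, or \code{NULL} to estimate it with
#'   \code{estimator}.
#' @param estimator \code{"median"} (MP-median, the default for all
#'   strategies except MP-PCA) or \code{"mp"} (simultaneous MP fit).
#' @return List with \code{X} (denoised matrix, original orientation),
#'   \code{rank}, \code{sigma}, and the \code{shrinkage_result}.
#' @export
denoise_matrix <- function(S, strategy = "nuc", sigma = NULL,
                           estimator = c("median", "mp")) {
  strategy <- match.arg(strategy, strategy_names)
  estimator <- match.arg(estimator)
  transposed <- nrow(S) > ncol(S)
  if (transposed) S <- t(S)
  sv <- svd(S)
  spec <- singular_spectrum(sv$d, m = nrow(S), n = ncol(S))
  if (strategy == "mp_pca") {
    res <- mp_pca_shrink(spec)
  } else {
    if (is.null(sigma)) {
      sigma <- if (estimator == "mp") mp_pca_fit(spec)$sigma
               else estimate_sigma_median(spec)
    }
    res <- os_shrink(spec, sigma, strategy)
  }
  X <- recover_matrix(sv$u, sv$v, res)
  if (transposed) X <- t(X)
  list(X = X, rank = res$rank, sigma = res$sigma_used, result = res)
}
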
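# Containers for frequency-domain second-order statistics: one Hermitian
# cross-spectral matrix per frequency with its sample count, and the matrix of
# complex Fourier/Hilbert coefficients it is estimated from.

#' Construct a cross-spectrum slice
#'
#' A cross-spectrum slice is the Hermitian positive semidefinite covariance
#' matrix of the analytic (Fourier/Hilbert) signal at one frequency, together
#' with the number of samples `T` that entered it. It is the sufficient
#' statistic for every estimator in this package.
#'
#' @param matrix Hermitian PSD complex (or real) `p x p` matrix.
#' @param frequency Frequency in Hz (may be `NA` for frequency-agnostic use).
#' @param n_samples Positive integer sample count `T`.
#' @param tol Relative tolerance for the Hermitian and PSD checks.
#' @return An object of class `cross_spectrum`.
#' @export
cross_spectrum <- function(matrix, frequency = NA_real_, n_samples, tol = 1e-8) {
  m <- assert_hermitian(matrix, tol = tol, arg = "matrix")
  vals <- herm_eigen(m)$values
  lmax <- max(abs(vals), 1)
  if (any(vals < -1e-8 * lmax)) {
    stop("cross-spectrum matrix is not positive semidefinite", call. = FALSE)
  }
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 1) {
    stop("`n_samples` must be a positive integer", call. = FALSE)
  }
  structure(
    list(matrix = m, frequency = as.numeric(frequency),
         n_samples = as.integer(round(n_samples))),
    class = "cross_spectrum"
  )
}

#' @export
print.cross_spectrum <- function(x, ...) {
  cat(sprintf("<cross_spectrum> %d x %d, f = %s Hz, T = %d\n",
              nrow(x$matrix), ncol(x$matrix),
              format(x$frequency), x$n_samples))
  invisible(x)
}

#' Coerce to a cross-spectrum slice
#'
#' @param x A `cross_spectrum` or a plain matrix.
#' @param ... Passed to [cross_spectrum()] (in particular `n_samples`).
#' @return A `cross_spectrum`.
#' @export
as_cross_spectrum <- function(x, ...) {
  if (inherits(x, "cross_spectrum")) return(x)
  cross_spectrum(x, ...)
}

# pull the matrix out of either representation
xs_matrix <- function(x) if (inherits(x, "cross_spectrum")) x$matrix else x
xs_samples <- function(x, default = NULL) {
  if (inherits(x, "cross_spectrum")) return(x$n_samples)
  if (is.null(default)) stop("sample count `T` is required", call. = FALSE)
  default
}

#' Draw circularly-symmetric complex Gaussian samples
#'
#' Samples `n_samples` i.i.d. columns from the circular complex Gaussian with
#' covariance `precision^-1`, realised as `S %*% (x + i*y)/sqrt(2)` with `S`
#' the Hermitian square root of the covariance and `x`, `y` independent
#' standard real Gaussians, so that `E[z z^H] = S S^H` and `E[z z^T] = 0`.
#'
#' @param precision Hermitian positive definite `q x q` matrix (source or
#'   sensor precision at one frequency).
#' @param n_samples Number of samples `T >= 1`.
#' @param seed Optional integer seed for reproducibility.
#' @param frequency Optional frequency in Hz carried along.
#' @return An object of class `complex_samples` with fields `samples`
#'   (complex `q x T`) and `frequency`.
#' @export
sample_complex_gaussian <- function(precision, n_samples, seed = NULL,
                                    frequency = NA_real_) {
  precision <- assert_hermitian(precision, arg = "precision")
  if (!is_hpd(precision)) {
    stop("`precision` must be positive definite", call. = FALSE)
  }
  stopifnot(n_samples >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  q <- nrow(precision)
  sigma_half <- hermitian_sqrt(herm_solve(precision))
  z <- matrix(complex(real = stats::rnorm(q * n_samples),
                      imaginary = stats::rnorm(q * n_samples)) / sqrt(2),
              nrow = q, ncol = n_samples)
  structure(
    list(samples = sigma_half %*% z, frequency = as.numeric(frequency)),
    class = "complex_samples"
  )
}

#' Sample covariance (cross-spectrum estimate) of complex samples
#'
#' Computes `(1/T) * sum_t z_t z_t^H`, the sampled cross-spectral matrix at
#' the samples' frequency. Hermitian PSD by construction.
#'
#' @param samples A `complex_samples` object or a complex `q x T` matrix.
#' @param frequency Frequency in Hz, used when `samples` is a bare matrix.
#' @return A [cross_spectrum()] with `n_samples = T`.
#' @export
sample_covariance <- function(samples, frequency = NA_real_) {
  if (inherits(samples, "complex_samples")) {
    frequency <- samples$frequency
    samples <- samples$samples
  }
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1)
  T <- ncol(samples)
  if (T < 1) stop("at least one sample is required", call. = FALSE)
  s <- samples %*% Conj(t(samples)) / T
  cross_spectrum(hermitianize(s), frequency = frequency, n_samples = T)
}
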
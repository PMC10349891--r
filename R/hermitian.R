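# Complex Hermitian linear algebra shared by every estimator in the package.
# All symmetrisation and eigenvalue clipping funnels through here so that the
# EM loops cannot accumulate asymmetry.

#' Symmetrise a matrix to its Hermitian part
#'
#' Returns `(M + M^H)/2`. Used on construction of every cross-spectrum and
#' precision matrix; asymmetry beyond a relative tolerance is an error in the
#' checked constructors.
#'
#' @param m A square numeric or complex matrix.
#' @return A Hermitian matrix of the same dimension.
#' @keywords internal
hermitianize <- function(m) (m + Conj(t(m))) / 2

# relative Frobenius asymmetry check; returns the symmetrised matrix
assert_hermitian <- function(m, tol = 1e-8, arg = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("`%s` must be a square matrix", arg), call. = FALSE)
  }
  nrm <- frob_norm(m)
  asym <- frob_norm(m - Conj(t(m)))
  if (nrm > 0 && asym > tol * nrm) {
    stop(sprintf("`%s` is not Hermitian (relative asymmetry %.3g)", arg, asym / nrm),
         call. = FALSE)
  }
  hermitianize(m)
}

#' Frobenius norm of a real or complex matrix
#' @param m A matrix.
#' @return A nonnegative scalar.
#' @export
frob_norm <- function(m) sqrt(sum(Mod(m)^2))

# Hermitian eigendecomposition (real eigenvalues, unitary vectors)
herm_eigen <- function(m) eigen(hermitianize(m), symmetric = TRUE)

# apply a scalar function to the eigenvalues of a Hermitian matrix
herm_fun <- function(m, fun) {
  e <- herm_eigen(m)
  hermitianize(e$vectors %*% (fun(e$values) * Conj(t(e$vectors))))
}

#' Principal square root of a Hermitian positive semidefinite matrix
#'
#' Eigenvalues within `tol * max(lambda)` below zero are clipped to zero
#' (sampled covariances are rank deficient whenever `T < q`); eigenvalues
#' below that floor raise a definiteness error.
#'
#' @param m A Hermitian positive semidefinite matrix.
#' @param tol Relative eigenvalue clipping floor.
#' @return The Hermitian PSD matrix `S` with `S %*% S = m`.
#' @export
hermitian_sqrt <- function(m, tol = 1e-12) {
  m <- assert_hermitian(m, arg = "m")
  e <- herm_eigen(m)
  lmax <- max(abs(e$values), 0)
  if (any(e$values < -tol * max(lmax, 1))) {
    stop("matrix is not positive semidefinite (eigenvalue ",
         format(min(e$values)), ")", call. = FALSE)
  }
  vals <- pmax(e$values, 0)
  hermitianize(e$vectors %*% (sqrt(vals) * Conj(t(e$vectors))))
}

#' Matrix logarithm of a Hermitian positive definite matrix
#' @inheritParams hermitian_sqrt
#' @return The Hermitian matrix `log(m)`.
#' @export
hermitian_log <- function(m) {
  m <- assert_hermitian(m, arg = "m")
  e <- herm_eigen(m)
  if (any(e$values <= 0)) {
    stop("matrix logarithm requires a positive definite matrix", call. = FALSE)
  }
  hermitianize(e$vectors %*% (log(e$values) * Conj(t(e$vectors))))
}

# inverse through the Hermitian eigendecomposition, with optional jitter
herm_solve <- function(m, jitter = 0) {
  m <- hermitianize(m)
  if (jitter > 0) m <- m + diag(jitter, nrow(m))
  e <- herm_eigen(m)
  if (any(e$values <= 0)) {
    stop("matrix is singular or not positive definite", call. = FALSE)
  }
  hermitianize(e$vectors %*% ((1 / e$values) * Conj(t(e$vectors))))
}

is_hpd <- function(m, tol = 1e-10) {
  e <- tryCatch(herm_eigen(m)$values, error = function(e) NULL)
  !is.null(e) && all(e > tol * max(abs(e)))
}

# log-determinant of a Hermitian positive definite matrix (real scalar)
herm_logdet <- function(m) {
  vals <- herm_eigen(m)$values
  if (any(vals <= 0)) {
    stop("log-determinant requires a positive definite matrix", call. = FALSE)
  }
  sum(log(vals))
}

# real part of tr(A %*% B) without forming the product
tr_prod <- function(a, b) Re(sum(a * t(b)))

#' Number of connectivity parameters addressed at dimension q
#'
#' A Hermitian precision matrix on `q` nodes carries `q^2` connectivity
#' parameters (all ordered pairs, diagonal included), the count the graphical
#' estimators address.
#'
#' @param q Number of nodes.
#' @return `q^2` as a double.
#' @export
connectivity_parameter_count <- function(q) {
  stopifnot(q >= 1)
  as.numeric(q)^2
}
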
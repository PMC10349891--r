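# MAP estimators for the precision matrix of a Gaussian graphical spectral
# model: hgNaive (no prior), hgRidge (L2, closed form through a matrix square
# root), and hgLASSO (L1) via a local quadratic approximation that alternates
# a closed-form variance update with a weighted ridge solve.

#' Graphical prior for Hermitian precision estimation
#'
#' Bundles the selection matrix `A` (which entries are penalised; by default
#' all off-diagonal entries with unit weight, diagonal unpenalised) with the
#' regularization scale `alpha`.
#'
#' @param q Dimension of the precision matrix.
#' @param alpha Positive scale; see [default_alpha()] for the analytic choice.
#' @param selection Optional nonnegative symmetric `q x q` weight matrix;
#'   defaults to ones off the diagonal, zeros on it.
#' @return An object of class `graph_prior`.
#' @export
graph_prior <- function(q, alpha, selection = NULL) {
  stopifnot(q >= 1, is.numeric(alpha), length(alpha) == 1, alpha > 0)
  if (is.null(selection)) {
    selection <- matrix(1, q, q)
    diag(selection) <- 0
  }
  if (!isTRUE(all.equal(selection, t(selection))) || any(selection < 0)) {
    stop("`selection` must be symmetric and nonnegative", call. = FALSE)
  }
  structure(list(selection = selection, alpha = alpha, q = q),
            class = "graph_prior")
}

#' Analytic regularization scale for the Hermitian graphical LASSO
#'
#' Returns `sqrt(T * log(q))`, the fixed scale under which the desparsified
#' estimator's null z-statistics follow the unit Rayleigh law when `T >> q`.
#'
#' @param T Sample count (`T >= 1`).
#' @param q Matrix dimension (`q >= 2`).
#' @return A positive scalar.
#' @export
default_alpha <- function(T, q) {
  if (q <= 1) stop("`q` must exceed 1", call. = FALSE)
  stopifnot(T >= 1)
  sqrt(T * log(q))
}

penalty_value <- function(theta, prior, penalty) {
  a <- prior$selection * theta
  switch(penalty,
         naive = 0,
         ridge = sum(Mod(a)^2),
         lasso = sum(Mod(a)),
         stop("unknown penalty `", penalty, "`", call. = FALSE))
}

#' Penalized negative log-posterior of a precision matrix
#'
#' Evaluates `-log|Theta| + tr(Sigma_hat Theta) + alpha * P(A * Theta)` with
#' `P` the none/L2^2/L1 penalty. The trace of a product of Hermitian matrices
#' is real; any numerical imaginary residue is discarded.
#'
#' @param theta Hermitian positive definite precision matrix.
#' @param sigma_hat A [cross_spectrum()] (or Hermitian matrix).
#' @param prior A [graph_prior()].
#' @param penalty One of `"naive"`, `"ridge"`, `"lasso"`.
#' @return A real scalar.
#' @export
penalized_cost <- function(theta, sigma_hat, prior, penalty = "lasso") {
  theta <- assert_hermitian(theta, arg = "theta")
  s <- xs_matrix(sigma_hat)
  ld <- herm_logdet(theta) # errors on non-PD input
  -ld + tr_prod(s, theta) + prior$alpha * penalty_value(theta, prior, penalty)
}

#' Unpenalised (hgNaive) precision estimate
#'
#' The inverse of the sample cross-spectral matrix; only defined when the
#' sample covariance is strictly positive definite (`T >= q` in practice).
#'
#' @inheritParams penalized_cost
#' @return A `hg_fit` object (see [hglasso_estimate()]).
#' @export
hgnaive_estimate <- function(sigma_hat) {
  s <- xs_matrix(sigma_hat)
  vals <- herm_eigen(s)$values
  if (any(vals <= 1e-12 * max(vals))) {
    stop("sample covariance is (numerically) singular; use the ridge or ",
         "lasso penalty", call. = FALSE)
  }
  theta <- herm_solve(s)
  new_hg_fit(theta = theta, gamma = NULL, cost_trace = numeric(0),
             penalty = "naive", alpha = NA_real_,
             sigma_hat = sigma_hat)
}

#' Variance-matrix update of the LQA loop
#'
#' Closed-form minimiser of the joint local-quadratic cost in the per-entry
#' scales `Gamma`, evaluated in the algebraically equivalent stable form
#' `Gamma^2 = 2 alpha |Theta|^2 / (1 + sqrt(1 + 4 alpha^2 A^2 |Theta|^2))`,
#' which reproduces the analytic limit `sqrt(alpha) * |Theta|` wherever the
#' selection weight is zero (the unpenalised diagonal).
#'
#' @param theta Current Hermitian precision iterate.
#' @param prior A [graph_prior()].
#' @return A nonnegative `q x q` matrix of scales.
#' @export
gamma_update <- function(theta, prior) {
  if (prior$alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  a2 <- prior$selection^2
  th2 <- Mod(xs_matrix(theta))^2
  sqrt(2 * prior$alpha * th2 / (1 + sqrt(1 + 4 * prior$alpha^2 * a2 * th2)))
}

#' Standardize a sample covariance by per-entry scales
#'
#' Returns `(Sigma_hat^-1 / Gamma)^-1` (elementwise division), the
#' standardized covariance whose ridge solution yields the weighted-lasso
#' precision after rescaling. Rank-deficient input receives a ridge jitter of
#' `1e-6 * tr(Sigma)/q` with a warning.
#'
#' @param sigma_hat A [cross_spectrum()] or Hermitian matrix.
#' @param gamma Strictly positive `q x q` scale matrix.
#' @return A Hermitian matrix of the same size.
#' @export
standardize_covariance <- function(sigma_hat, gamma) {
  s <- xs_matrix(sigma_hat)
  if (any(gamma <= 0)) stop("`gamma` must be strictly positive", call. = FALSE)
  vals <- herm_eigen(s)$values
  jitter <- 0
  if (any(vals <= 1e-12 * max(vals, 1))) {
    jitter <- 1e-6 * Re(sum(diag(s))) / nrow(s)
    warning("rank-deficient covariance; adding ridge jitter ",
            format(jitter), call. = FALSE)
  }
  weighted <- herm_solve(s, jitter = jitter) / gamma
  # the weighted precision is Hermitian but typically indefinite: invert it
  # as a general matrix and re-symmetrise
  hermitianize(solve(weighted))
}

#' Closed-form Hermitian graphical ridge solve
#'
#' Solves the stationarity condition `-Theta^-1 + Sigma + Theta = 0` of the
#' standard (unweighted) ridge cost through the principal matrix square root:
#' `Theta = -Sigma/2 + sqrt(Sigma^2 + 4I)/2`. The result is Hermitian
#' positive definite for any Hermitian input since the scalar map
#' `(-x + sqrt(x^2 + 4))/2` is positive on the real line.
#'
#' @param sigma_tilde Hermitian matrix (typically a standardized covariance).
#' @return A Hermitian positive definite matrix.
#' @export
hgridge_solve <- function(sigma_tilde) {
  s <- assert_hermitian(xs_matrix(sigma_tilde), arg = "sigma_tilde")
  herm_fun(s, function(x) (-x + sqrt(x^2 + 4)) / 2)
}

#' Hermitian graphical ridge precision estimate
#'
#' Ridge-penalised MAP estimate of the precision matrix, obtained in closed
#' form from the sample covariance.
#'
#' @inheritParams penalized_cost
#' @return A `hg_fit` object.
#' @export
hgridge_estimate <- function(sigma_hat, prior = NULL) {
  s <- xs_matrix(sigma_hat)
  theta <- hgridge_solve(s)
  alpha <- if (is.null(prior)) NA_real_ else prior$alpha
  new_hg_fit(theta = theta, gamma = NULL, cost_trace = numeric(0),
             penalty = "ridge", alpha = alpha, sigma_hat = sigma_hat)
}

new_hg_fit <- function(theta, gamma, cost_trace, penalty, alpha, sigma_hat,
                       converged = TRUE, n_iterations = length(cost_trace)) {
  structure(
    list(theta = theta, gamma = gamma, cost_trace = cost_trace,
         n_iterations = n_iterations, penalty = penalty, alpha = alpha,
         sigma_hat = sigma_hat, converged = converged),
    class = "hg_fit"
  )
}

#' @export
print.hg_fit <- function(x, ...) {
  cat(sprintf("<hg_fit> %s penalty, q = %d, %d iterations%s\n",
              x$penalty, nrow(x$theta), x$n_iterations,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

# One ADMM solve of the weighted complex graphical lasso
#   min_Theta  -log|Theta| + tr(Sigma Theta) + sum_ij thr_ij |Theta_ij|
# The Theta-update is the rho-generalised ridge square-root closed form (the
# scalar map (-e + sqrt(e^2 + 4 rho))/(2 rho) on the eigenvalues, the same
# operator as hgridge_solve); the Z-update is modulus soft-thresholding.
# Over-relaxation (1.7) accelerates convergence. Returns the PD Theta iterate
# and the penalized-cost trace.
glasso_admm <- function(s, thr, prior, max_iter, tol, z0 = NULL, rho = NULL) {
  q <- nrow(s)
  if (is.null(rho)) rho <- q / max(Re(sum(diag(s))), .Machine$double.eps)
  relax <- 1.7
  Z <- if (is.null(z0)) hgridge_solve(s) else z0
  U <- matrix(0 + 0i, q, q)
  theta <- Z
  trace <- numeric(0)
  rises <- 0
  n_conv <- NA_integer_
  for (l in seq_len(max_iter)) {
    e <- herm_eigen(s - rho * (Z - U))
    d <- (-e$values + sqrt(e$values^2 + 4 * rho)) / (2 * rho)
    theta <- hermitianize(e$vectors %*% (d * Conj(t(e$vectors))))
    th_r <- relax * theta + (1 - relax) * Z
    m <- th_r + U
    mm <- Mod(m)
    Z <- m * (pmax(mm - thr / rho, 0) / pmax(mm, .Machine$double.xmin))
    U <- U + th_r - Z
    # the objective actually minimised: entrywise-weighted L1 penalty
    cost <- -herm_logdet(theta) + tr_prod(s, theta) +
      sum(thr * Mod(theta))
    if (l > 1) {
      prev <- trace[length(trace)]
      if (cost > prev + 1e-8 * abs(prev)) {
        rises <- rises + 1
        if (rises > 10) {
          stop("hgLASSO cost diverged for more than 10 consecutive ",
               "iterations", call. = FALSE)
        }
      } else {
        rises <- 0
      }
      if (is.na(n_conv) && abs(cost - prev) <= tol * abs(prev)) n_conv <- l
    }
    trace <- c(trace, cost)
    if (!is.na(n_conv) && l >= n_conv + 2) break
  }
  list(theta = theta, trace = trace, converged = !is.na(n_conv),
       n_conv = if (is.na(n_conv)) length(trace) else n_conv)
}

#' Hermitian graphical LASSO estimate
#'
#' Sparse MAP estimate of a Hermitian precision matrix. The L1-penalised
#' problem (per-sample penalty rate `alpha / (sqrt(2) T)`, the complex-sample
#' analogue of the `sqrt(log q / n)` rate) is solved by an ADMM whose
#' positive-definite update is the ridge square-root closed form and whose
#' shrinkage step is complex modulus soft-thresholding. One adaptive
#' reweighting cycle follows: the solution is debiased
#' ([desparsify()]), its support detected by the Rayleigh test at
#' `p < refit_p`, and the problem re-solved with detected edges unpenalised,
#' which removes the shrinkage that would otherwise leak into the final
#' desparsified statistics.
#'
#' @param sigma_hat A [cross_spectrum()]; its sample count sets the default
#'   `alpha` through [default_alpha()] when `prior` is `NULL`.
#' @param prior A [graph_prior()]; default `alpha = sqrt(T log q)` with the
#'   all-ones off-diagonal selection matrix.
#' @param max_iter Iteration cap for each solve stage (default 200).
#' @param tol Relative cost-change tolerance (default 1e-6).
#' @param refit_p Rayleigh p-value used for the internal support detection
#'   (default 0.05). `refit_p = 0` disables the reweighting cycle.
#' @return A `hg_fit` with fields `theta` (Hermitian PD), `gamma` (the
#'   scaled-mixture scale matrix at the solution), `cost_trace` (penalised
#'   cost per iteration of the final solve), `n_iterations`, `alpha`.
#' @export
hglasso_estimate <- function(sigma_hat, prior = NULL, max_iter = 200,
                             tol = 1e-6, refit_p = 0.05) {
  s_raw <- xs_matrix(sigma_hat)
  q <- nrow(s_raw)
  T <- xs_samples(sigma_hat, default = NULL)
  if (is.null(prior)) {
    prior <- graph_prior(q, alpha = default_alpha(T, q))
  }
  # fit on the coherence (unit-diagonal) scale so the penalty rate is
  # dimensionless; the estimate is transformed back at the end and the
  # Rayleigh statistics are invariant under this diagonal congruence
  d <- Re(diag(s_raw))
  if (any(d <= 0)) stop("sample covariance has a nonpositive diagonal",
                        call. = FALSE)
  dsc <- sqrt(d)
  scale_mat <- dsc %o% dsc
  s <- hermitianize(s_raw / scale_mat)
  lam <- prior$alpha / (sqrt(2) * T)
  thr <- lam * prior$selection
  pass1 <- glasso_admm(s, thr, prior, max_iter, tol)
  theta <- pass1$theta
  trace <- pass1$trace
  conv <- pass1$converged
  n_it <- pass1$n_conv
  if (refit_p > 0) {
    stats <- rayleigh_edge_statistics(theta, s, T)
    keep <- threshold_edges(stats, p_level = refit_p)
    thr2 <- thr
    thr2[keep == 1] <- 0
    pass2 <- glasso_admm(s, thr2, prior, max_iter, tol, z0 = theta)
    theta <- pass2$theta
    trace <- pass2$trace
    conv <- pass2$converged
    n_it <- pass2$n_conv
  }
  theta <- hermitianize(theta / scale_mat)
  new_hg_fit(theta = theta, gamma = gamma_update(theta, prior),
             cost_trace = trace, penalty = "lasso", alpha = prior$alpha,
             sigma_hat = sigma_hat, converged = conv, n_iterations = n_it)
}

#' Fit a Hermitian graphical model with a chosen penalty
#'
#' Dispatches to [hgnaive_estimate()], [hgridge_estimate()] or
#' [hglasso_estimate()].
#'
#' @inheritParams hglasso_estimate
#' @param penalty One of `"naive"`, `"ridge"`, `"lasso"`.
#' @export
hg_estimate <- function(sigma_hat, penalty = c("lasso", "ridge", "naive"),
                        prior = NULL, max_iter = 30, tol = 1e-6) {
  penalty <- match.arg(penalty)
  switch(penalty,
         naive = hgnaive_estimate(sigma_hat),
         ridge = hgridge_estimate(sigma_hat, prior),
         lasso = hglasso_estimate(sigma_hat, prior, max_iter, tol))
}
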
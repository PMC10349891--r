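# Two-step baselines: a first-step quasilinear inverse operator (generic
# Gaussian-posterior, LCMV beamformer, or eLORETA) projects the sensor
# cross-spectrum to source space; a second-step graphical estimator
# (hgLASSO with debias + threshold, or its real-valued restriction) then
# estimates connectivity from the projected covariance.

new_inverse_operator <- function(tiv, method, regularization = 0,
                                 pi_ii = NULL) {
  structure(
    list(tiv = tiv, pi_ii = pi_ii, method = method,
         regularization = regularization),
    class = "inverse_operator"
  )
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> %s, %d sources x %d sensors, reg = %g\n",
              x$method, nrow(x$tiv), ncol(x$tiv), x$regularization))
  invisible(x)
}

#' Generic quasilinear (Gaussian-posterior) inverse operator
#'
#' `Pi = (L' Theta_xi L + Theta_ii)^-1`, `T_iv = Pi L' Theta_xi`: the
#' posterior-mean operator of the Gaussian observation model with source
#' prior precision `Theta_ii` and noise precision `Theta_xi`.
#'
#' @param lead_field Real `p x q` matrix (or `lead_field` object).
#' @param theta_ii Hermitian PD source prior precision (`q x q`).
#' @param theta_xixi Hermitian PD noise precision (`p x p`).
#' @return An `inverse_operator`.
#' @export
quasilinear_operator <- function(lead_field, theta_ii, theta_xixi) {
  l <- lf_matrix(lead_field)
  pi_ii <- herm_solve(Conj(t(l)) %*% theta_xixi %*% l + theta_ii)
  new_inverse_operator(pi_ii %*% Conj(t(l)) %*% theta_xixi, "generic",
                       pi_ii = pi_ii)
}

#' LCMV beamformer inverse operator
#'
#' Unit-gain linearly-constrained minimum-variance rows
#' `w_g = (l_g' C^-1 l_g)^-1 l_g' C^-1` with `C = Sigma_vv + reg * I`.
#'
#' @param lead_field Real `p x q` matrix (or `lead_field` object).
#' @param sigma_vv Sensor cross-spectrum (matrix or [cross_spectrum()]).
#' @param reg Nonnegative diagonal regularization added to the data
#'   covariance.
#' @return An `inverse_operator`.
#' @export
lcmv_operator <- function(lead_field, sigma_vv, reg = 0) {
  l <- lf_matrix(lead_field)
  c_mat <- xs_matrix(sigma_vv) + diag(reg, nrow(l))
  cinv <- herm_solve(c_mat)
  num <- Conj(t(l)) %*% cinv          # q x p
  gains <- Re(diag(num %*% l))        # l_g' C^-1 l_g
  if (any(gains <= 0)) stop("regularized covariance is singular",
                            call. = FALSE)
  new_inverse_operator(num / gains, "lcmv", regularization = reg)
}

#' eLORETA inverse operator
#'
#' Canonical weight iteration: diagonal source weights `W` satisfy
#' `w_g^2 = l_g' (L W^-1 L' + reg H)^+ l_g` at the fixed point, with `H` the
#' identity; the operator is `T = W^-1 L' (L W^-1 L' + reg H)^+`. The
#' defining property is zero localization error for single sources in the
#' noiseless case.
#'
#' @param lead_field Real `p x q` matrix (or `lead_field` object).
#' @param reg Nonnegative regularization scale.
#' @param max_iter Maximum weight iterations (default 100).
#' @param tol Relative weight-change tolerance (default 1e-8).
#' @return An `inverse_operator`.
#' @export
eloreta_operator <- function(lead_field, reg = 0, max_iter = 100,
                             tol = 1e-8) {
  l <- lf_matrix(lead_field)
  p <- nrow(l)
  q <- ncol(l)
  w <- rep(1, q)
  for (it in seq_len(max_iter)) {
    m <- l %*% (t(l) / w) + diag(reg, p)
    minv <- MASS_ginv(m)
    w_new <- sqrt(pmax(colSums(l * (minv %*% l)), .Machine$double.eps))
    delta <- max(abs(w_new - w) / pmax(w, .Machine$double.eps))
    w <- w_new
    if (delta < tol) break
  }
  if (delta >= tol) {
    stop("eLORETA weights did not reach a fixed point in ", max_iter,
         " iterations", call. = FALSE)
  }
  m <- l %*% (t(l) / w) + diag(reg, p)
  tiv <- (t(l) / w) %*% MASS_ginv(m)
  op <- new_inverse_operator(tiv, "eloreta", regularization = reg)
  op$weights <- w
  op
}

#' Project a sensor cross-spectrum to source space
#'
#' `Sigma_ii = T Sigma_vv T^H`; the sample count is preserved.
#'
#' @param op An `inverse_operator` (or a `q x p` matrix).
#' @param sigma_vv Sensor cross-spectrum ([cross_spectrum()] or matrix).
#' @return A [cross_spectrum()].
#' @export
project_source_covariance <- function(op, sigma_vv) {
  tiv <- if (inherits(op, "inverse_operator")) op$tiv else op
  s <- xs_matrix(sigma_vv)
  if (ncol(tiv) != nrow(s)) stop("operator and covariance dimensions do ",
                                 "not match", call. = FALSE)
  proj <- hermitianize(tiv %*% s %*% Conj(t(tiv)))
  # clip numerically negative eigenvalues introduced by the projection
  proj <- herm_fun(proj, function(x) pmax(x, 0))
  cross_spectrum(proj,
                 frequency = if (inherits(sigma_vv, "cross_spectrum"))
                   sigma_vv$frequency else NA_real_,
                 n_samples = xs_samples(sigma_vv, default = 1))
}

#' Generalized cross-validation of first-step regularization
#'
#' Scores each candidate `r` by the ridge-GCV functional
#' `GCV(r) = || (I - L T(r)) Sigma^(1/2) ||_F^2 / (p - tr(L T(r)))^2`
#' and returns the minimiser.
#'
#' @param lead_field Real `p x q` matrix (or `lead_field` object).
#' @param sigma_vv Sensor cross-spectrum.
#' @param grid Nonempty vector of positive candidate scales.
#' @param method First-step method whose operator is scored (`"eloreta"`,
#'   `"lcmv"`).
#' @return The selected scalar.
#' @export
gcv_regularization <- function(lead_field, sigma_vv,
                               grid = 10^seq(-6, 1, length.out = 20),
                               method = c("eloreta", "lcmv")) {
  method <- match.arg(method)
  if (length(grid) == 0) stop("`grid` must be nonempty", call. = FALSE)
  if (length(grid) == 1) return(grid[1])
  l <- lf_matrix(lead_field)
  p <- nrow(l)
  s_half <- hermitian_sqrt(xs_matrix(sigma_vv))
  scores <- vapply(grid, function(r) {
    op <- switch(method,
                 eloreta = eloreta_operator(l, reg = r),
                 lcmv = lcmv_operator(l, sigma_vv, reg = r))
    resolvent <- l %*% op$tiv
    num <- frob_norm((diag(p) - resolvent) %*% s_half)^2
    den <- (p - Re(sum(diag(resolvent))))^2
    if (den <= .Machine$double.eps) Inf else num / den
  }, 0)
  grid[which.min(scores)]
}

#' Two-step (multistep) connectivity estimate
#'
#' First-step inverse operator (eLORETA, LCMV, or the generic
#' Gaussian-posterior operator), projection of the sensor cross-spectrum to
#' source space, then a second-step graphical estimate: the Hermitian
#' graphical LASSO with debiasing and Rayleigh thresholding, or its
#' real-valued restriction (`glasso_real`, the filtered-process
#' approximation operating on `2 Re(Sigma_ii)`, which discards the phase
#' information of the Hermitian model).
#'
#' @param lead_field Real `p x q` matrix (or `lead_field` object).
#' @param sigma_vv Sensor cross-spectrum with sample count.
#' @param first_step `"eloreta"`, `"lcmv"` or `"generic"`.
#' @param second_step `"hglasso"` or `"glasso_real"`.
#' @param reg First-step regularization; `NULL` (default) selects it by
#'   [gcv_regularization()].
#' @param prior Optional [graph_prior()] for the second step.
#' @param p_level Rayleigh level for edge selection (default 0.05).
#' @param noise_floor Noise fraction for the generic operator's prior
#'   (default 0.10).
#' @return A `higgs_fit`-shaped object of class `multistep_fit` with fields
#'   `theta`, `edge_stats`, `mask`, `operator`, `sigma_ii`, `first_step`,
#'   `second_step`.
#' @export
multistep_connectivity <- function(lead_field, sigma_vv,
                                   first_step = c("eloreta", "lcmv",
                                                  "generic"),
                                   second_step = c("hglasso",
                                                   "glasso_real"),
                                   reg = NULL, prior = NULL,
                                   p_level = 0.05, noise_floor = 0.10) {
  first_step <- match.arg(first_step)
  second_step <- match.arg(second_step)
  sigma_vv <- as_cross_spectrum(sigma_vv, n_samples = 1)
  l <- lf_matrix(lead_field)
  p <- nrow(l)
  q <- ncol(l)
  T <- sigma_vv$n_samples
  if (is.null(reg) && first_step != "generic") {
    reg <- gcv_regularization(l, sigma_vv, method = first_step)
  }
  op <- switch(first_step,
               eloreta = eloreta_operator(l, reg = reg),
               lcmv = lcmv_operator(l, sigma_vv, reg = reg),
               generic = {
                 mean_power <- Re(sum(diag(sigma_vv$matrix))) / p
                 pinv_l <- MASS_ginv(l)
                 src_power <- Re(sum(diag(
                   pinv_l %*% sigma_vv$matrix %*% t(pinv_l)))) / q
                 quasilinear_operator(
                   l, diag(1 / max(src_power, .Machine$double.eps), q),
                   diag(1 / (noise_floor * mean_power), p))
               })
  sigma_ii <- project_source_covariance(op, sigma_vv)
  if (second_step == "glasso_real") {
    # real-valued filtered-process covariance: 2 Re of the analytic-signal
    # covariance
    sigma_ii <- cross_spectrum(2 * Re(sigma_ii$matrix),
                               frequency = sigma_ii$frequency,
                               n_samples = T)
  }
  if (is.null(prior)) prior <- graph_prior(q, default_alpha(T, q))
  fit <- hglasso_estimate(sigma_ii, prior = prior)
  stats <- rayleigh_edge_statistics(fit$theta, sigma_ii, T,
                                    p_level = p_level)
  structure(
    list(theta = fit$theta, edge_stats = stats, mask = stats$mask,
         operator = op, sigma_ii = sigma_ii, fit = fit,
         first_step = first_step, second_step = second_step,
         n_samples = T),
    class = "multistep_fit"
  )
}

#' @export
print.multistep_fit <- function(x, ...) {
  cat(sprintf("<multistep_fit> %s + %s, %d sources\n",
              x$first_step, x$second_step, nrow(x$theta)))
  invisible(x)
}
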
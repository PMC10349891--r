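# One-step EM inverse solution: estimates the source precision matrix and a
# scalar sensor-noise precision directly from the sensor cross-spectrum given
# a lead field, by alternating a Gaussian-posterior expectation stage with
# graphical MAP maximization stages.

#' Specify a HIGGS observation model
#'
#' @param lead_field Real `p x q` forward operator (or a `lead_field`
#'   object, in which case its network columns are used).
#' @param noise_structure Known sensor-noise structure matrix `A_xi` (PD
#'   `p x p`, default identity); the noise precision is
#'   `theta_xi^2 * A_xi`.
#' @param alpha_xi Nonnegative noise-floor scale of the exponential prior on
#'   `theta_xi^2`. `NULL` (default) sets it at estimation time from
#'   `noise_floor`: the instrumental-noise amplitude floor is `noise_floor`
#'   times the sensor signal amplitude, so the variance floor is
#'   `noise_floor^2` times the mean sensor power.
#' @param noise_floor Instrumental-noise floor as an amplitude fraction of
#'   the sensor signal (default 0.10, i.e. a 1% power floor).
#' @param prior A [graph_prior()] for the source precision; default built at
#'   estimation time with `alpha = sqrt(T log q)`.
#' @param penalty Source maximization penalty: `"lasso"`, `"ridge"` or
#'   `"naive"`.
#' @return An object of class `higgs_model`.
#' @export
higgs_model <- function(lead_field, noise_structure = NULL, alpha_xi = NULL,
                        noise_floor = 0.10, prior = NULL,
                        penalty = c("lasso", "ridge", "naive")) {
  penalty <- match.arg(penalty)
  if (inherits(lead_field, "lead_field")) {
    lead_field <- lf_matrix(lead_field)[, lead_field$network_idx,
                                        drop = FALSE]
  }
  p <- nrow(lead_field)
  if (is.null(noise_structure)) noise_structure <- diag(p)
  if (!is_hpd(noise_structure)) {
    stop("`noise_structure` must be positive definite", call. = FALSE)
  }
  structure(
    list(lead_field = lead_field, noise_structure = noise_structure,
         alpha_xi = alpha_xi, noise_floor = noise_floor, prior = prior,
         penalty = penalty),
    class = "higgs_model"
  )
}

#' Expectation stage for the sources
#'
#' Gaussian-posterior moments of the latent sources given the current
#' hyperparameters: posterior covariance
#' `Pi = (L' Theta_xi L + Theta_ii)^-1`, transfer `T_iv = Pi L' Theta_xi`,
#' projected data covariance `Sigma_ii = T_iv Sigma_vv T_iv^H`, and expected
#' covariance `Psi_ii = Sigma_ii + Pi`, with
#' `Theta_xi = theta_xi_sq * A_xi`.
#'
#' @param model A [higgs_model()].
#' @param theta_ii Current Hermitian PD source precision.
#' @param theta_xi_sq Current positive noise precision scale.
#' @param sigma_vv Sensor cross-spectrum ([cross_spectrum()] or matrix).
#' @return A list with `psi_ii`, `sigma_ii`, `tiv`, `pi_ii`.
#' @export
expectation_sources <- function(model, theta_ii, theta_xi_sq, sigma_vv) {
  stopifnot(theta_xi_sq > 0)
  l <- model$lead_field
  theta_xi <- theta_xi_sq * model$noise_structure
  pi_ii <- herm_solve(Conj(t(l)) %*% theta_xi %*% l + theta_ii)
  tiv <- pi_ii %*% Conj(t(l)) %*% theta_xi
  sigma_ii <- hermitianize(tiv %*% xs_matrix(sigma_vv) %*% Conj(t(tiv)))
  list(psi_ii = hermitianize(sigma_ii + pi_ii), sigma_ii = sigma_ii,
       tiv = tiv, pi_ii = pi_ii)
}

#' Expectation stage for the sensor noise
#'
#' Posterior moments of the noise process: `Pi_xi = L Pi_ii L'`,
#' `T_xv = I - Pi_xi Theta_xi`, `Sigma_xi = T_xv Sigma_vv T_xv^H`,
#' `Psi_xi = Sigma_xi + Pi_xi`.
#'
#' @inheritParams expectation_sources
#' @param pi_ii Source posterior covariance from [expectation_sources()].
#' @return A list with `psi_xixi`, `sigma_xixi`, `txv`, `pi_xixi`.
#' @export
expectation_noise <- function(model, pi_ii, theta_xi_sq, sigma_vv) {
  l <- model$lead_field
  p <- nrow(l)
  theta_xi <- theta_xi_sq * model$noise_structure
  pi_xi <- hermitianize(l %*% pi_ii %*% Conj(t(l)))
  txv <- diag(p) - pi_xi %*% theta_xi
  sigma_xi <- hermitianize(txv %*% xs_matrix(sigma_vv) %*% Conj(t(txv)))
  list(psi_xixi = hermitianize(sigma_xi + pi_xi), sigma_xixi = sigma_xi,
       txv = txv, pi_xixi = pi_xi)
}

#' Maximization stage for the source precision
#'
#' The expected source covariance plays the role of an observed sample
#' covariance: delegates to the graphical estimator selected by the model's
#' penalty.
#'
#' @param psi_ii Expected source covariance (matrix or [cross_spectrum()]).
#' @param prior A [graph_prior()].
#' @param penalty `"lasso"`, `"ridge"` or `"naive"`.
#' @param T Sample count carried by the cross-spectrum (required when
#'   `psi_ii` is a bare matrix and `prior` is `NULL`).
#' @param refit_p Rayleigh level of the internal support-refit cycle of
#'   [hglasso_estimate()]; 0 keeps the plain L1 solution (whose penalised
#'   objective the EM provably decreases).
#' @return A `hg_fit`.
#' @export
maximize_sources <- function(psi_ii, prior = NULL,
                             penalty = c("lasso", "ridge", "naive"),
                             T = NULL, refit_p = 0.05) {
  penalty <- match.arg(penalty)
  if (!inherits(psi_ii, "cross_spectrum")) {
    psi_ii <- cross_spectrum(psi_ii, n_samples = if (is.null(T)) 1 else T)
  }
  if (penalty == "lasso") {
    hglasso_estimate(psi_ii, prior = prior, refit_p = refit_p)
  } else {
    hg_estimate(psi_ii, penalty = penalty, prior = prior)
  }
}

#' Maximization stage for the noise scale
#'
#' Closed-form update `theta_xi^2 = 1 / (tr(Psi_xi A_xi)/p + alpha_xi)`
#' from the expected noise covariance under the exponential prior.
#'
#' @param psi_xixi Expected noise covariance (matrix or
#'   [cross_spectrum()]).
#' @param model A [higgs_model()]; its `alpha_xi` must be resolved (numeric).
#' @return A positive scalar.
#' @export
maximize_noise <- function(psi_xixi, model) {
  a <- model$noise_structure
  p <- nrow(a)
  alpha_xi <- model$alpha_xi
  if (is.null(alpha_xi)) alpha_xi <- 0
  tr_term <- tr_prod(xs_matrix(psi_xixi), a) / p
  if (tr_term + alpha_xi <= 0) {
    stop("noise update is undefined: zero trace and zero `alpha_xi`",
         call. = FALSE)
  }
  1 / (tr_term + alpha_xi)
}

# marginal penalized objective (per sample):
# log|Sigma_vv(model)| + tr(Sigma_hat Sigma_vv^-1) + penalties/T
higgs_objective <- function(model, theta_ii, theta_xi_sq, sigma_hat, prior,
                            T) {
  l <- model$lead_field
  p <- nrow(l)
  sigma_model <- hermitianize(
    l %*% herm_solve(theta_ii) %*% Conj(t(l)) +
      herm_solve(theta_xi_sq * model$noise_structure))
  e <- herm_eigen(sigma_model)
  if (any(e$values <= 0)) return(Inf)
  inv <- e$vectors %*% ((1 / e$values) * Conj(t(e$vectors)))
  ll <- sum(log(e$values)) + tr_prod(xs_matrix(sigma_hat), inv)
  pen <- prior$alpha / (sqrt(2) * T) *
    penalty_value(theta_ii, prior, model$penalty)
  alpha_xi <- if (is.null(model$alpha_xi)) 0 else model$alpha_xi
  ll + pen + alpha_xi * p * theta_xi_sq
}

#' One-step HIGGS EM inverse solution
#'
#' Estimates the source precision matrix (functional connectivity) directly
#' from a sensor cross-spectrum by EM: the expectation stage computes the
#' Gaussian posterior source and noise covariances under the current
#' hyperparameters, and the maximization stage re-estimates the source
#' precision (penalised graphical MAP on the expected covariance) and the
#' scalar noise precision. With the lasso penalty, each maximization is
#' debiased and Rayleigh-thresholded; by default the thresholded precision
#' (with a small diagonal loading preserving definiteness) feeds the next
#' expectation.
#'
#' @param model A [higgs_model()].
#' @param sigma_vv Sensor cross-spectrum with sample count
#'   ([cross_spectrum()]).
#' @param max_em_iter Maximum EM iterations (default 20).
#' @param tol Relative tolerance on the marginal penalized objective
#'   (default 1e-4).
#' @param p_level Rayleigh level for edge selection (default 0.05).
#' @param threshold_in_em Feed the thresholded precision to the next
#'   expectation stage (default `TRUE`).
#' @param update_noise Update the noise scale each iteration (default
#'   `TRUE`; set `FALSE` to keep the initial value fixed).
#' @param theta_xi_sq0 Optional initial noise precision scale.
#' @return An object of class `higgs_fit`: `theta` (final source precision
#'   estimate, unthresholded), `edge_stats` (final [rayleigh_edge_statistics()]
#'   on the expected covariance), `mask`, `noise_scale`
#'   (`theta_xi^2`), `objective_trace`, `n_em_iterations`, `psi_ii`,
#'   `model`.
#' @export
run_higgs <- function(model, sigma_vv, max_em_iter = 20, tol = 1e-4,
                      p_level = 0.05, threshold_in_em = TRUE,
                      update_noise = TRUE, theta_xi_sq0 = NULL) {
  stopifnot(inherits(model, "higgs_model"))
  sigma_vv <- as_cross_spectrum(sigma_vv, n_samples = 1)
  s <- sigma_vv$matrix
  T <- sigma_vv$n_samples
  l <- model$lead_field
  p <- nrow(l)
  q <- ncol(l)
  mean_power <- Re(sum(diag(s))) / p
  if (is.null(model$alpha_xi)) {
    # amplitude floor: implied noise variance at least noise_floor^2 of the
    # mean sensor power
    model$alpha_xi <- model$noise_floor^2 * mean_power
  }
  prior <- model$prior
  if (is.null(prior)) prior <- graph_prior(q, default_alpha(T, q))
  # data-scaled deterministic initialization
  pinv_l <- tryCatch(solve(crossprod(l)) %*% t(l),
                     error = function(e) MASS_ginv(l))
  src_power <- Re(sum(diag(pinv_l %*% s %*% t(pinv_l)))) / q
  theta_ii <- diag(1 / max(src_power, .Machine$double.eps), q)
  theta_xi_sq <- if (is.null(theta_xi_sq0)) {
    1 / (model$noise_floor^2 * mean_power)
  } else {
    theta_xi_sq0
  }
  trace <- higgs_objective(model, theta_ii, theta_xi_sq, s, prior, T)
  fit <- NULL
  stats <- NULL
  mask <- NULL
  theta_report <- theta_ii
  psi_store <- NULL
  rises <- 0
  for (k in seq_len(max_em_iter)) {
    es <- expectation_sources(model, theta_ii, theta_xi_sq, s)
    en <- expectation_noise(model, es$pi_ii, theta_xi_sq, s)
    psi <- cross_spectrum(es$psi_ii, frequency = sigma_vv$frequency,
                          n_samples = T)
    fit <- maximize_sources(psi, prior = prior, penalty = model$penalty,
                            refit_p = if (threshold_in_em) p_level else 0)
    theta_new <- fit$theta
    theta_report <- theta_new
    psi_store <- psi
    if (model$penalty == "lasso") {
      stats <- rayleigh_edge_statistics(theta_new, psi, T,
                                        p_level = p_level)
      mask <- stats$mask
      if (threshold_in_em) {
        theta_thr <- theta_new * mask
        # diagonal loading keeps the thresholded matrix PD
        ev <- herm_eigen(theta_thr)$values
        if (min(ev) <= 1e-8 * max(ev)) {
          theta_thr <- theta_thr +
            diag(abs(min(ev)) + 1e-8 * max(ev), q)
        }
        theta_new <- theta_thr
      }
    }
    if (update_noise) theta_xi_sq <- maximize_noise(en$psi_xixi, model)
    theta_ii <- theta_new
    obj <- higgs_objective(model, theta_ii, theta_xi_sq, s, prior, T)
    prev <- trace[length(trace)]
    if (is.finite(prev) && obj > prev + 1e-6 * abs(prev)) {
      rises <- rises + 1
      # support thresholding between iterations deliberately perturbs the
      # objective, so the divergence guard applies to the clean EM only
      if (rises > 10 && !(model$penalty == "lasso" && threshold_in_em)) {
        stop("HIGGS EM objective increased for more than 10 consecutive ",
             "iterations (last objective ", format(obj), ")", call. = FALSE)
      }
    } else {
      rises <- 0
    }
    trace <- c(trace, obj)
    if (abs(obj - prev) <= tol * abs(prev)) break
  }
  if (model$penalty != "lasso" && !is.null(psi_store)) {
    stats <- rayleigh_edge_statistics(theta_report, psi_store, T,
                                      p_level = p_level)
    mask <- stats$mask
  }
  structure(
    list(theta = theta_report, edge_stats = stats, mask = mask,
         noise_scale = theta_xi_sq, objective_trace = trace,
         n_em_iterations = length(trace) - 1, psi_ii = psi_store,
         model = model, n_samples = T),
    class = "higgs_fit"
  )
}

# minimal Moore-Penrose pseudoinverse (SVD) to avoid a MASS dependency
MASS_ginv <- function(m, tol = 1e-10) {
  sv <- svd(m)
  pos <- sv$d > tol * sv$d[1]
  sv$v[, pos, drop = FALSE] %*%
    ((1 / sv$d[pos]) * t(sv$u[, pos, drop = FALSE]))
}

#' @export
print.higgs_fit <- function(x, ...) {
  q <- nrow(x$theta)
  cat(sprintf(
    "<higgs_fit> %d sources, %s penalty, %d EM iterations, noise scale %.4g\n",
    q, x$model$penalty, x$n_em_iterations, x$noise_scale))
  if (!is.null(x$mask)) {
    cat(sprintf("  %d/%d edges retained at p < %g\n",
                sum(x$mask[upper.tri(x$mask)]), q * (q - 1) / 2,
                x$edge_stats$p_level))
  }
  invisible(x)
}
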
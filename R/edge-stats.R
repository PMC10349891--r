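# Desparsified (debiased) precision estimates and Rayleigh-calibrated edge
# selection. The modulus of a properly standardized debiased entry follows
# the unit Rayleigh law (density 2 z exp(-z^2), scale 1/sqrt(2)) under the
# null, which gives closed-form per-edge p-values p = exp(-z^2).

#' Desparsified (debiased) precision estimate
#'
#' Removes the shrinkage bias of a penalised precision estimate through the
#' one-step correction `2 Theta_hat - Theta_hat Sigma_hat Theta_hat`. When
#' `Theta_hat = Sigma_hat^-1` exactly the correction is a fixed point.
#'
#' @param theta_hat Hermitian precision estimate.
#' @param sigma_hat The sample covariance it was fitted to (matrix or
#'   [cross_spectrum()]).
#' @return A Hermitian matrix of the same size.
#' @export
desparsify <- function(theta_hat, sigma_hat) {
  th <- xs_matrix(theta_hat)
  s <- xs_matrix(sigma_hat)
  if (!all(dim(th) == dim(s))) {
    stop("`theta_hat` and `sigma_hat` dimensions do not match", call. = FALSE)
  }
  hermitianize(2 * th - th %*% s %*% th)
}

#' Rayleigh edge statistics for a precision estimate
#'
#' Standardizes the desparsified estimate edgewise: the variance proxy is
#' `S(i,j) = Theta(i,i) Theta(j,j) + |Theta(i,j)|^2` (the complex analogue of
#' the real-valued desparsified-graphical-LASSO theory) and the statistic is
#' `Z(i,j) = sqrt(T) |unb(i,j)| / sqrt(S(i,j))`, whose null law is the unit
#' Rayleigh density `2 z exp(-z^2)` with scale `1/sqrt(2)`. P-values are the
#' Rayleigh survival `exp(-z^2)`.
#'
#' @param theta_hat Hermitian PD precision estimate (matrix or `hg_fit`).
#' @param sigma_hat Sample covariance ([cross_spectrum()] or matrix).
#' @param T Sample count; taken from `sigma_hat` when it is a
#'   `cross_spectrum`.
#' @param p_level Significance level stored for the default mask
#'   (default 0.05).
#' @param variance_term `"modulus"` (default) uses `|Theta(i,j)|^2` as the
#'   second variance term; `"literal"` adds the printed complex entry itself
#'   (kept only for comparison; its real part is used).
#' @return An object of class `edge_stats` with fields `unbiased`,
#'   `variances`, `z`, `p_values`, `mask`, `n_samples`, `p_level`.
#' @export
rayleigh_edge_statistics <- function(theta_hat, sigma_hat, T = NULL,
                                     p_level = 0.05,
                                     variance_term = c("modulus", "literal")) {
  variance_term <- match.arg(variance_term)
  if (inherits(theta_hat, "hg_fit")) theta_hat <- theta_hat$theta
  th <- xs_matrix(theta_hat)
  if (is.null(T)) T <- xs_samples(sigma_hat)
  if (T < 2) stop("`T` must be at least 2", call. = FALSE)
  d <- Re(diag(th))
  if (any(d <= 0)) {
    stop("`theta_hat` has a nonpositive diagonal entry", call. = FALSE)
  }
  unb <- desparsify(th, sigma_hat)
  second <- switch(variance_term,
                   modulus = Mod(th)^2,
                   literal = Re(th))
  variances <- d %o% d + second
  if (any(variances <= 0)) {
    stop("nonpositive variance proxy; estimate is too ill-conditioned",
         call. = FALSE)
  }
  z <- sqrt(T) * Mod(unb) / sqrt(variances)
  # statistics are computed on the upper triangle and mirrored
  z[lower.tri(z)] <- t(z)[lower.tri(z)]
  diag(z) <- 0
  p <- exp(-z^2)
  out <- structure(
    list(unbiased = unb, variances = variances, z = z, p_values = p,
         mask = NULL, n_samples = as.integer(T), p_level = p_level),
    class = "edge_stats"
  )
  out$mask <- threshold_edges(out, p_level)
  out
}

#' Threshold edges by Rayleigh p-value
#'
#' Binary selection mask: `mask(i,j) = 1` iff `p(i,j) < p_level`; the
#' diagonal is always kept and the mask is symmetric. With
#' `bonferroni = TRUE` the level is divided by the number of off-diagonal
#' pairs `q (q - 1) / 2`.
#'
#' @param stats An `edge_stats` object (or a p-value matrix).
#' @param p_level Per-edge significance level in (0, 1]; values below the
#'   Rayleigh survival threshold `z* = sqrt(-log(p_level))` are retained.
#' @param bonferroni Apply a familywise Bonferroni correction.
#' @return A binary symmetric matrix with unit diagonal.
#' @export
threshold_edges <- function(stats, p_level = 0.05, bonferroni = FALSE) {
  p <- if (inherits(stats, "edge_stats")) stats$p_values else stats
  if (p_level <= 0 || p_level > 1) {
    stop("`p_level` must lie in (0, 1]", call. = FALSE)
  }
  q <- nrow(p)
  level <- if (bonferroni) p_level / (q * (q - 1) / 2) else p_level
  # level 1 keeps everything (p-values equal to one included)
  mask <- if (level >= 1) matrix(1, q, q) else (p < level) * 1
  mask[lower.tri(mask)] <- t(mask)[lower.tri(mask)]
  diag(mask) <- 1
  mask
}

#' @export
print.edge_stats <- function(x, ...) {
  q <- nrow(x$z)
  n_edge <- sum(x$mask[upper.tri(x$mask)])
  cat(sprintf("<edge_stats> %d nodes, %d/%d edges at p < %g (T = %d)\n",
              q, n_edge, q * (q - 1) / 2, x$p_level, x$n_samples))
  invisible(x)
}
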
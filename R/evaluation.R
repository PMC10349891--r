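# Scoring of estimated versus true connectivity: ROC summaries of support
# recovery (scores are moduli of the Hermitian off-diagonal graph elements)
# and divergence metrics between precision matrices.

#' ROC summary of support recovery
#'
#' Off-diagonal upper-triangle scores are classified against the binary
#' ground-truth support. The global AUC comes from the empirical ROC curve;
#' partial measures (sensitivity, specificity, precision, recall, F1) are
#' evaluated at the optimal operating point, by default the Youden J
#' maximiser (`max` sensitivity + specificity - 1), optionally the point
#' closest to (0, 1).
#'
#' @param true_support Binary symmetric `q x q` matrix (diagonal ignored).
#' @param scores Nonnegative symmetric `q x q` matrix (e.g. `Mod(theta)`).
#' @param operating_point `"youden"` (default) or `"closest"`.
#' @return A one-row tibble: `auc`, `sens`, `spec`, `prec`, `recall`, `f1`,
#'   `n_edges`, `n_pairs`.
#' @export
roc_scores <- function(true_support, scores,
                       operating_point = c("youden", "closest")) {
  operating_point <- match.arg(operating_point)
  ut <- upper.tri(true_support)
  truth <- (Mod(true_support[ut]) > 0) * 1
  sc <- Mod(scores[ut])
  if (all(truth == 1) || all(truth == 0)) {
    stop("AUC is undefined: ground truth has a single class", call. = FALSE)
  }
  roc <- pROC::roc(response = truth, predictor = sc, quiet = TRUE,
                   direction = "<", levels = c(0, 1))
  auc <- as.numeric(pROC::auc(roc))
  coords <- pROC::coords(roc, x = "all", transpose = FALSE)
  j <- switch(operating_point,
              youden = which.max(coords$sensitivity + coords$specificity - 1),
              closest = which.min((1 - coords$sensitivity)^2 +
                                    (1 - coords$specificity)^2))
  sens <- coords$sensitivity[j]
  spec <- coords$specificity[j]
  thr <- coords$threshold[j]
  pred <- sc >= thr
  tp <- sum(pred & truth == 1)
  fp <- sum(pred & truth == 0)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- sens
  f1 <- if (prec + recall == 0) 0 else 2 * prec * recall / (prec + recall)
  tibble::tibble(auc = auc, sens = sens, spec = spec, prec = prec,
                 recall = recall, f1 = f1, n_edges = sum(truth),
                 n_pairs = length(truth))
}

#' Kullback-Leibler divergence between Gaussian graphical models
#'
#' For zero-mean circular Gaussian models with precisions `theta_a` and
#' `theta_b`, the kernel is `M = Theta_a Theta_b^-1 + Theta_a^-1 Theta_b -
#' 2I`, whose entries localise the disagreement between the two models, and
#' the scalar symmetrized divergence is `tr(M) / 2`.
#'
#' @param theta_a,theta_b Hermitian positive definite matrices of equal
#'   size.
#' @return A list with `divergence` (nonnegative scalar) and `kernel`
#'   (complex matrix).
#' @export
kld_gaussian <- function(theta_a, theta_b) {
  a <- assert_hermitian(xs_matrix(theta_a), arg = "theta_a")
  b <- assert_hermitian(xs_matrix(theta_b), arg = "theta_b")
  if (!all(dim(a) == dim(b))) stop("dimension mismatch", call. = FALSE)
  ainv <- herm_solve(a)
  binv <- herm_solve(b)
  kernel <- a %*% binv + ainv %*% b - 2 * diag(nrow(a))
  list(divergence = max(Re(sum(diag(kernel))) / 2, 0), kernel = kernel)
}

#' Affine-invariant Riemannian distance between HPD matrices
#'
#' `|| log(a^{-1/2} b a^{-1/2}) ||_F`, computed through the positive
#' generalized eigenvalues of the pair: `sqrt(sum(log(lambda_i)^2))`.
#'
#' @param a,b Hermitian positive definite matrices.
#' @return A nonnegative scalar.
#' @export
riemannian_distance <- function(a, b) {
  a_half_inv <- herm_solve(hermitian_sqrt(xs_matrix(a)))
  m <- hermitianize(a_half_inv %*% xs_matrix(b) %*% a_half_inv)
  vals <- herm_eigen(m)$values
  if (any(vals <= 0)) stop("matrices must be positive definite",
                           call. = FALSE)
  sqrt(sum(log(vals)^2))
}

#' Log-Euclidean distance between HPD matrices
#'
#' `|| log(a) - log(b) ||_F` with the Hermitian matrix logarithm.
#'
#' @param a,b Hermitian positive definite matrices.
#' @return A nonnegative scalar.
#' @export
logeuclid_distance <- function(a, b) {
  frob_norm(hermitian_log(xs_matrix(a)) - hermitian_log(xs_matrix(b)))
}

#' All divergence summaries between two precision matrices
#'
#' @param theta_a,theta_b Hermitian positive definite matrices.
#' @return A one-row tibble with `kld`, `riemannian`, `logeuclid`.
#' @export
divergence_summary <- function(theta_a, theta_b) {
  tibble::tibble(
    kld = kld_gaussian(theta_a, theta_b)$divergence,
    riemannian = riemannian_distance(theta_a, theta_b),
    logeuclid = logeuclid_distance(theta_a, theta_b)
  )
}
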
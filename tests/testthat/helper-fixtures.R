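# Shared fixtures: random Hermitian matrices, small recordings, and
# brute-force oracles used to cross-check the estimators.

random_hpd <- function(q, seed = 1, loading = 1) {
  set.seed(seed)
  a <- matrix(complex(real = rnorm(q * q), imaginary = rnorm(q * q)), q)
  hermitianize(a %*% Conj(t(a)) / q) + diag(loading, q)
}

random_unitary <- function(q, seed = 1) {
  set.seed(seed)
  a <- matrix(complex(real = rnorm(q * q), imaginary = rnorm(q * q)), q)
  qr.Q(qr(a))
}

# exhaustive-threshold AUC: sweep every distinct score as a cutoff and
# integrate the ROC curve by trapezoid
brute_force_auc <- function(truth, scores) {
  ut <- upper.tri(truth)
  y <- (Mod(truth[ut]) > 0) * 1
  s <- Mod(scores[ut])
  cuts <- c(-Inf, sort(unique(s)), Inf)
  tpr <- sapply(cuts, function(ct) sum(s >= ct & y == 1) / sum(y == 1))
  fpr <- sapply(cuts, function(ct) sum(s >= ct & y == 0) / sum(y == 0))
  ord <- order(fpr, tpr)
  sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) +
                          utils::tail(tpr[ord], -1)) / 2)
}

# small, fast Xi-Alpha configuration for integration tests
tiny_sim_config <- function(seed = 1, T = 300, ...) {
  simulation_config(n_network_nodes = 8, n_sensors = 12, n_sources = 16,
                    T = T, frequencies = seq(6, 14, by = 1),
                    density = 0.25, seed = seed, ...)
}

# fitted Rayleigh scale from the quadratic mean (MLE for the Rayleigh law)
rayleigh_scale <- function(z) sqrt(mean(z^2) / 2)

mask_f1 <- function(mask, support) {
  ut <- upper.tri(support)
  m <- mask[ut]
  s <- support[ut]
  tp <- sum(m == 1 & s == 1)
  fp <- sum(m == 1 & s == 0)
  fn <- sum(m == 0 & s == 1)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# independent log|det| through the QR decomposition (valid for matrices
# with positive real determinant, like HPD products)
logdet_oracle <- function(m) sum(log(Mod(diag(qr.R(qr(m))))))
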
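# One-step EM inverse solution: expectation/maximization stages and the
# full loop.

test_that("expectation stages reduce to their degenerate limits", {
  q <- 3
  model <- higgs_model(diag(q))
  theta <- diag(q) + 0i
  svv <- random_hpd(q, seed = 2)
  # identity lead field, vanishing noise variance: the transfer operator
  # approaches the identity and the projected covariance the data
  es <- expectation_sources(model, theta, 1e8, svv)
  expect_lt(frob_norm(es$tiv - diag(q)), 1e-6)
  expect_lt(frob_norm(es$sigma_ii - svv) / frob_norm(svv), 1e-6)
  # zero data: the expected covariance is the ensemble covariance
  es0 <- expectation_sources(model, theta, 2, matrix(0 + 0i, q, q))
  expect_equal(es0$psi_ii, es0$pi_ii, tolerance = 1e-12)
  en0 <- expectation_noise(model, es0$pi_ii, 2, matrix(0 + 0i, q, q))
  expect_equal(en0$psi_xixi, en0$pi_xixi, tolerance = 1e-12)
})

test_that("expectation stages match the Schur-complement posterior", {
  # independent derivation through the joint covariance of (iota, v)
  p <- 4
  q <- 3
  set.seed(10)
  l <- matrix(rnorm(p * q), p, q)
  theta_ii <- random_hpd(q, seed = 3)
  theta_xi_sq <- 5
  sigma_ii <- herm_solve(theta_ii)
  sigma_vv_true <- l %*% sigma_ii %*% t(l) + diag(1 / theta_xi_sq, p)
  model <- higgs_model(l)
  svv <- random_hpd(p, seed = 4)
  es <- expectation_sources(model, theta_ii, theta_xi_sq, svv)
  b <- sigma_ii %*% Conj(t(l)) %*% herm_solve(sigma_vv_true)
  cond_cov <- sigma_ii - b %*% l %*% sigma_ii
  expect_lt(frob_norm(es$tiv - b) / frob_norm(b), 1e-8)
  expect_lt(frob_norm(es$pi_ii - cond_cov) / frob_norm(cond_cov), 1e-8)
  psi_oracle <- b %*% svv %*% Conj(t(b)) + cond_cov
  expect_lt(frob_norm(es$psi_ii - psi_oracle) / frob_norm(psi_oracle),
            1e-8)
  # noise process xi = v - L iota: Cov(xi, v) equals the noise covariance
  en <- expectation_noise(model, es$pi_ii, theta_xi_sq, svv)
  sigma_xi <- diag(1 / theta_xi_sq, p)
  b_xi <- sigma_xi %*% herm_solve(sigma_vv_true)
  cond_cov_xi <- sigma_xi - b_xi %*% sigma_xi
  expect_lt(frob_norm(en$txv - b_xi) / frob_norm(b_xi), 1e-8)
  expect_lt(frob_norm(en$pi_xixi - cond_cov_xi) / frob_norm(cond_cov_xi),
            1e-8)
})

test_that("noise maximization follows the exponential-prior closed form", {
  model <- higgs_model(diag(4), alpha_xi = 0)
  expect_equal(maximize_noise(diag(4), model), 1)
  expect_equal(maximize_noise(2 * diag(4), model), 0.5)
  model_floor <- higgs_model(diag(4), alpha_xi = 100)
  expect_equal(maximize_noise(diag(4), model_floor), 1 / 101,
               tolerance = 1e-12)
  expect_error(maximize_noise(matrix(0, 4, 4),
                              higgs_model(diag(4), alpha_xi = 0)),
               "undefined")
})

test_that("source maximization delegates to the graphical estimators", {
  s <- random_hpd(5, seed = 12)
  cs <- cross_spectrum(s, n_samples = 500)
  expect_equal(maximize_sources(cs, penalty = "naive")$theta,
               herm_solve(s), tolerance = 1e-10)
  fit_d <- maximize_sources(cs, penalty = "lasso")
  fit_s <- hglasso_estimate(cs)
  expect_equal(fit_d$theta, fit_s$theta, tolerance = 1e-12)
  # identity expected covariance: near-identity estimate for any penalty
  id <- cross_spectrum(diag(5), n_samples = 500)
  for (pen in c("naive", "lasso")) {
    th <- maximize_sources(id, penalty = pen)$theta
    expect_lt(max(Mod(th[upper.tri(th)])), 1e-6)
  }
})

test_that("with identity lead field and no noise the EM collapses to the
           observed-data estimate", {
  q <- 8
  theta <- blockwise_chained_precision(q, block_size = 4, seed = 9)
  svv <- sample_covariance(sample_complex_gaussian(theta, 1600, seed = 19))
  direct <- hglasso_estimate(svv)
  model <- higgs_model(diag(q), alpha_xi = 0)
  fit <- run_higgs(model, svv, max_em_iter = 1, update_noise = FALSE,
                   theta_xi_sq0 = 1e8)
  expect_lt(frob_norm(fit$theta - direct$theta) / frob_norm(direct$theta),
            1e-4)
})

test_that("EM objective is non-increasing and intermediates stay HPD", {
  set.seed(42)
  p <- 8
  q <- 5
  l <- matrix(rnorm(p * q), p, q)
  theta <- blockwise_chained_precision(q, block_size = 3, seed = 2)
  iota <- sample_complex_gaussian(theta, 2000, seed = 5)$samples
  noise <- sample_complex_gaussian(diag(15, p), 2000, seed = 6)$samples
  svv <- sample_covariance(l %*% iota + noise)
  model <- higgs_model(l, alpha_xi = 0)
  fit <- run_higgs(model, svv, max_em_iter = 15, threshold_in_em = FALSE,
                   tol = 1e-8)
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-6 * abs(tr[-length(tr)])))
  # intermediate ensemble and expected covariances are Hermitian PSD
  es <- expectation_sources(model, fit$theta, fit$noise_scale, svv)
  for (m in list(es$pi_ii, es$psi_ii)) {
    expect_equal(m, Conj(t(m)), tolerance = 1e-10)
    expect_true(min(eigen(m, symmetric = TRUE,
                          only.values = TRUE)$values) > 0)
  }
  en <- expectation_noise(model, es$pi_ii, fit$noise_scale, svv)
  expect_true(min(eigen(en$psi_xixi, symmetric = TRUE,
                        only.values = TRUE)$values) > -1e-10)
})

test_that("a null network (independent sources) yields a near-empty mask
           at the nominal rate", {
  lf <- planar_lead_field(12, 8, 8)
  l <- lf_matrix <- lf$matrix
  fprs <- sapply(1:6, function(tr) {
    iota <- sample_complex_gaussian(diag(8), 1000,
                                    seed = 400 + tr)$samples
    noise <- sample_complex_gaussian(diag(10, 12), 1000,
                                     seed = 500 + tr)$samples
    svv <- sample_covariance(l %*% iota + noise)
    fit <- run_higgs(higgs_model(l), svv, max_em_iter = 20)
    mean(fit$mask[upper.tri(fit$mask)])
  })
  expect_lt(mean(fprs), 0.1)
})

test_that("one-step penalties rank as lasso > ridge > naive in selection", {
  f1 <- sapply(1:4, function(s) {
    rec <- simulate_xi_alpha(tiny_sim_config(seed = s))
    svv <- sensor_cross_spectrum(rec)
    l <- network_lead_field(rec)
    supp <- rec$ground_truth$support
    sapply(c("lasso", "ridge", "naive"), function(pen) {
      fit <- run_higgs(higgs_model(l, penalty = pen), svv,
                       max_em_iter = 15)
      mask_f1(fit$mask, supp)
    })
  })
  means <- rowMeans(f1)
  expect_gt(means["lasso"], means["ridge"])
  expect_gt(means["lasso"], means["naive"])
})
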
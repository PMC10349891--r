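# MAP precision estimation: penalised cost, closed-form operations and the
# Hermitian graphical LASSO solver.

test_that("penalized cost matches term-by-term evaluation", {
  q <- 3
  prior <- graph_prior(q, alpha = 1)
  expect_equal(penalized_cost(diag(q) + 0i, diag(q), prior, "lasso"), q)
  expect_equal(penalized_cost(diag(q) + 0i, 2 * diag(q), prior, "naive"),
               2 * q)

  theta <- random_hpd(q, seed = 3)
  s <- random_hpd(q, seed = 4)
  prior2 <- graph_prior(q, alpha = 0.7)
  a <- prior2$selection
  manual <- -logdet_oracle(theta) + Re(sum(diag(s %*% theta))) +
    0.7 * sum(Mod(a * theta))
  expect_equal(penalized_cost(theta, s, prior2, "lasso"), manual,
               tolerance = 1e-10)
  manual_r <- -logdet_oracle(theta) + Re(sum(diag(s %*% theta))) +
    0.7 * sum(Mod(a * theta)^2)
  expect_equal(penalized_cost(theta, s, prior2, "ridge"), manual_r,
               tolerance = 1e-10)
  expect_error(penalized_cost(diag(c(1, -1, 1)) + 0i, s, prior2, "lasso"),
               "positive definite")
})

test_that("default regularization scale is sqrt(T log q)", {
  expect_equal(default_alpha(100, exp(1)), 10)
  expect_equal(default_alpha(600, 22), sqrt(600 * log(22)))
  expect_equal(default_alpha(1, 2), sqrt(log(2)))
  expect_error(default_alpha(100, 1), "exceed")
})

test_that("hgNaive inverts the sample cross-spectrum", {
  expect_lt(frob_norm(hgnaive_estimate(diag(3))$theta - diag(3)), 1e-12)
  expect_lt(frob_norm(hgnaive_estimate(diag(c(2, 4)))$theta -
                        diag(c(0.5, 0.25))), 1e-12)
  # rank-deficient covariance from T < q samples
  smp <- sample_complex_gaussian(diag(5), 3, seed = 1)
  expect_error(hgnaive_estimate(sample_covariance(smp)), "singular")
})

test_that("gamma update reproduces the scaled-mixture closed form", {
  q <- 2
  prior <- graph_prior(q, alpha = 1)
  theta <- matrix(c(1, 0, 0, 1), 2) + 0i
  g <- gamma_update(theta, prior)
  expect_equal(g[1, 2], 0)
  # diagonal is unpenalised (selection weight 0): analytic limit
  # sqrt(alpha) * |theta|
  expect_equal(g[1, 1], sqrt(1) * 1)
  prior9 <- graph_prior(q, alpha = 9)
  expect_equal(gamma_update(theta, prior9)[2, 2], sqrt(9) * 1)
  # scalar case alpha = 1, A = 1, |theta| = 1
  theta2 <- matrix(c(2, 1, 1, 2), 2) + 0i
  g2 <- gamma_update(theta2, prior)
  expect_equal(g2[1, 2], sqrt((-1 + sqrt(5)) / 2), tolerance = 1e-12)
  expect_error(gamma_update(theta, graph_prior(q, alpha = 1e-9)), NA)
})

test_that("covariance standardization weights the precision entrywise", {
  s <- random_hpd(3, seed = 9)
  ones <- matrix(1, 3, 3)
  expect_equal(standardize_covariance(s, ones), s, tolerance = 1e-10)
  d <- diag(c(2, 3, 4))
  g <- diag(c(5, 6, 7))
  g[g == 0] <- 1
  out <- standardize_covariance(d, g)
  expect_equal(Re(diag(out)), c(2 * 5, 3 * 6, 4 * 7), tolerance = 1e-10)
  expect_error(standardize_covariance(s, -ones), "positive")
  low_rank <- tcrossprod(c(1, 1, 1)) + 0i
  expect_warning(standardize_covariance(low_rank, ones), "rank-deficient")
})

test_that("hgridge solve satisfies its stationarity condition", {
  expect_lt(frob_norm(hgridge_solve(diag(2)) -
                        ((-1 + sqrt(5)) / 2) * diag(2)), 1e-12)
  expect_lt(frob_norm(hgridge_solve(matrix(0, 3, 3)) - diag(3)), 1e-12)
  for (q in c(4, 50, 200)) {
    s <- random_hpd(q, seed = q) - diag(0.5, q)  # indefinite input allowed
    theta <- hgridge_solve(s)
    resid <- frob_norm(-herm_solve(theta) + s + theta)
    expect_lt(resid / frob_norm(theta), 1e-8)
    expect_true(all(eigen(theta, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("hgLASSO shrinks independent coordinates to a diagonal estimate", {
  cs <- cross_spectrum(diag(6), n_samples = 600)
  fit <- hglasso_estimate(cs)
  off <- Mod(fit$theta)[upper.tri(fit$theta)]
  expect_lt(max(off), 1e-6)
  expect_true(fit$converged)
})

test_that("hgLASSO recovers blockwise-chained support and converges fast", {
  q <- 30
  T <- 100 * q
  theta <- blockwise_chained_precision(q, seed = 7)
  s <- sample_covariance(sample_complex_gaussian(theta, T, seed = 77))
  fit <- hglasso_estimate(s)
  stats <- rayleigh_edge_statistics(fit$theta, s, T)
  rs <- roc_scores((Mod(theta) > 0) * 1, stats$z)
  expect_gt(rs$auc, 0.95)
  # penalised cost is non-increasing along the trace
  tr <- fit$cost_trace
  expect_true(all(diff(tr) <= 1e-8 * abs(tr[-length(tr)])))

  q2 <- 100
  theta2 <- blockwise_chained_precision(q2, seed = 8)
  s2 <- sample_covariance(sample_complex_gaussian(theta2, 100 * q2,
                                                  seed = 88))
  fit2 <- hglasso_estimate(s2)
  expect_lte(fit2$n_iterations, 30)
  expect_true(fit2$converged)
})

test_that("hgLASSO approaches hgNaive as the penalty vanishes", {
  q <- 8
  theta <- blockwise_chained_precision(q, block_size = 4, seed = 5)
  s <- sample_covariance(sample_complex_gaussian(theta, 2000, seed = 55))
  naive <- hgnaive_estimate(s)$theta
  fit <- hglasso_estimate(s, prior = graph_prior(q, alpha = 1e-6))
  expect_lt(frob_norm(fit$theta - naive) / frob_norm(naive), 1e-2)
})

test_that("tidiers summarise precision fits", {
  s <- sample_covariance(sample_complex_gaussian(
    blockwise_chained_precision(6, 3, seed = 2), 600, seed = 3))
  fit <- hglasso_estimate(s)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6 * 5 / 2)
  expect_true(all(c("i", "j", "modulus", "phase") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$q, 6)
  expect_equal(gl$penalty, "lasso")
  expect_s3_class(autoplot(fit), "ggplot")
})
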
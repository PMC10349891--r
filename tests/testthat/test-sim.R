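# Xi-Alpha simulator: ground-truth construction, spectral factorization,
# sampling, forward projection.

test_that("random alpha precision is sparse Hermitian PD in the unit
           circle", {
  out <- random_alpha_precision(10, density = 0, seed = 1)
  expect_equal(sum(out$support) - 10, 0)
  expect_true(all(Mod(out$theta[upper.tri(out$theta)]) == 0))
  for (sd in 1:25) {
    o <- random_alpha_precision(12, density = 0.2, seed = sd)
    ev <- eigen(o$theta, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
    expect_true(all(Mod(o$theta[upper.tri(o$theta)]) <= 1))
  }
  a <- random_alpha_precision(9, seed = 4)
  b <- random_alpha_precision(9, seed = 4)
  expect_identical(a$theta, b$theta)
})

test_that("blockwise-chained precision has the documented structure", {
  th1 <- blockwise_chained_precision(10, block_size = 10, seed = 1)
  # single block: a chain of 9 couplings
  expect_equal(sum(Mod(th1[upper.tri(th1)]) > 0), 9)
  th <- blockwise_chained_precision(30, block_size = 10, seed = 2)
  # 3 chains of 9 plus exactly 2 inter-block couplings
  expect_equal(sum(Mod(th[upper.tri(th)]) > 0), 27 + 2)
  blk <- rep(1:3, each = 10)
  inter <- sum(Mod(th[upper.tri(th)]) > 0 &
                 outer(blk, blk, "!=")[upper.tri(th)])
  expect_equal(inter, 2)
  for (sd in 1:25) {
    ev <- eigen(blockwise_chained_precision(15, 5, seed = sd),
                symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
})

test_that("spectral factorization reconstructs the reference precision", {
  expect_lt(frob_norm(factorize_reference(diag(3))), 1e-12)
  k4 <- factorize_reference(4 * diag(2))
  expect_lt(frob_norm(k4 - (-diag(2))), 1e-12)
  theta <- random_hpd(5, seed = 21)
  k <- factorize_reference(theta)
  imk <- diag(5) - k
  expect_lt(frob_norm(Conj(t(imk)) %*% imk - theta) / frob_norm(theta),
            1e-10)
})

test_that("lag matrix wraps phases and round-trips the factor", {
  k <- matrix(exp(1i * pi / 2), 1, 1)
  expect_equal(lag_matrix(k, 10)[1, 1], (pi / 2) / 10)
  expect_equal(lag_matrix(matrix(2 + 0i, 1, 1), 10)[1, 1], 0)
  expect_error(lag_matrix(k, 0), "positive")
  theta <- random_hpd(4, seed = 3)
  kf <- factorize_reference(theta)
  lags <- lag_matrix(kf, 10)
  expect_true(all(lags >= 0 & lags < 2 * pi / 10 + 1e-12))
  recon <- Mod(kf) * exp(1i * lags * 10)
  expect_lt(frob_norm(recon - kf) / max(frob_norm(kf), 1e-12), 1e-10)
})

test_that("transfer tensor is envelope-modulated and even around f0", {
  kc <- matrix(c(0, 0.5, 0.5, 0), 2)
  lags <- matrix(0.05, 2, 2)
  freqs <- seq(2, 18, by = 2)
  kt <- transfer_tensor(kc, lags, f0 = 10, width = 2, freqs)
  i10 <- which(freqs == 10)
  expect_equal(kt[, , i10], kc * exp(1i * lags * 10), tolerance = 1e-12)
  expect_lt(frob_norm(kt[, , 1]), 1e-3 * frob_norm(kt[, , i10]))
  expect_equal(frob_norm(kt[, , i10 - 2]), frob_norm(kt[, , i10 + 2]),
               tolerance = 1e-10)
})

test_that("precision tensor composition matches its algebra", {
  kt <- array(0 + 0i, c(3, 3, 2))
  tz <- random_hpd(3, seed = 2)
  out <- compose_precision_tensor(kt, tz)
  expect_equal(out[, , 1], tz, tolerance = 1e-12)
  # scalar case
  k1 <- array(0.3 + 0.4i, c(1, 1, 1))
  o1 <- compose_precision_tensor(k1, diag(1))
  expect_equal(Re(o1[1, 1, 1]), Mod(1 - (0.3 + 0.4i))^2, tolerance = 1e-12)
  # reference consistency at f0 with identity innovations
  theta <- random_hpd(4, seed = 9)
  k <- factorize_reference(theta)
  karr <- array(k, c(4, 4, 1))
  o <- compose_precision_tensor(karr, diag(4))
  expect_lt(frob_norm(o[, , 1] - theta) / frob_norm(theta), 1e-10)
})

test_that("Xi tensor is PD with power concentrated at low frequency", {
  freqs <- c(0, 5, 20, 45)
  xt <- xi_precision_tensor(8, width = 20, frequencies = freqs)
  lap_based <- xt[, , 1]
  ev <- eigen(lap_based, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  power <- sapply(seq_along(freqs), function(i)
    sum(diag(solve(xt[, , i]))))
  expect_true(all(diff(power) < 0))
  expect_equal(xt[, , 1], xt[, , 2] / exp(25 / 800), tolerance = 1e-10)
})

test_that("sampled oscillations reproduce the per-frequency covariance and
           a real time series", {
  theta <- array(0, c(3, 3, 2))
  theta[, , 1] <- random_hpd(3, seed = 1)
  theta[, , 2] <- random_hpd(3, seed = 2)
  smp <- sample_source_oscillations(theta, T = 1e4, frequencies = c(5, 10),
                                    seed = 3, time_series = TRUE)
  for (i in 1:2) {
    sig <- herm_solve(theta[, , i])
    err <- frob_norm(sample_covariance(smp$spectra[[i]])$matrix - sig) /
      frob_norm(sig)
    expect_lt(err, 0.1)
  }
  expect_true(is.numeric(smp$time))
  a <- sample_source_oscillations(theta, 5, c(5, 10), seed = 3)
  b <- sample_source_oscillations(theta, 5, c(5, 10), seed = 3)
  expect_identical(a$spectra, b$spectra)
})

test_that("planar lead field has the documented geometry", {
  lf <- planar_lead_field()
  expect_equal(dim(lf$matrix), c(30, 44))
  expect_equal(length(lf$network_idx), 22)
  expect_equal(qr(lf$matrix)$rank, 30)
  expect_equal(qr(network_lead_field(
    structure(list(lead_field = lf), class = "sim_recording")
  )), qr(lf$matrix[, lf$network_idx]))
  # nearest sensor carries the largest gain for each source
  for (j in c(1, 10, 30)) {
    d <- sqrt(colSums((t(lf$sensor_pos) - lf$source_pos[j, ])^2))
    expect_equal(which.max(lf$matrix[, j]), which.min(d))
  }
  # rotating sources and sensors together permutes consistently
  lf_rot <- planar_lead_field(rotate = 2 * pi / 30)
  expect_equal(lf_rot$matrix[1, 1], lf$matrix[1, 1], tolerance = 1e-10)
})

test_that("confound energy budget is honoured", {
  cfg <- tiny_sim_config(seed = 6)
  rec <- simulate_xi_alpha(cfg)
  inb <- which(cfg$frequencies >= cfg$band[1] &
                 cfg$frequencies <= cfg$band[2])
  lf <- rec$lead_field
  l_net <- network_lead_field(rec)
  e_alpha <- sum(sapply(inb, function(i)
    sum(Mod(l_net %*% rec$iota_spectra[[i]])^2)))
  e_conf <- sum(sapply(inb, function(i)
    sum(Mod(rec$v_spectra[[i]] - l_net %*% rec$iota_spectra[[i]])^2)))
  expect_equal(e_conf / e_alpha, cfg$confound_energy_ratio,
               tolerance = 0.02)
  rec2 <- simulate_xi_alpha(cfg)
  expect_identical(rec$v_spectra[[1]], rec2$v_spectra[[1]])
})

test_that("simulated sensor power peaks at the alpha frequency", {
  rec <- simulate_xi_alpha(simulation_config(seed = 2))
  sp <- sensor_power_spectrum(rec)
  peak <- sp$frequency[which.max(sp$power)]
  expect_lt(abs(peak - rec$config$f0), 1.01)
})

test_that("source-space estimation at large T recovers the support
           end to end", {
  cfg <- tiny_sim_config(seed = 12, T = 2000)
  rec <- simulate_xi_alpha(cfg)
  i_f0 <- which(cfg$frequencies == cfg$f0)
  s <- sample_covariance(rec$iota_spectra[[i_f0]])
  theta_hat <- hgnaive_estimate(s)$theta
  expect_gt(roc_scores(rec$ground_truth$support, Mod(theta_hat))$auc, 0.99)
})

test_that("lead-field perturbation degrades conditioning", {
  lf <- planar_lead_field()
  pl <- perturb_lead_field(lf, seed = 3)
  l0 <- lf_matrix(lf)[, lf$network_idx]
  l1 <- lf_matrix(pl)[, pl$network_idx]
  expect_gt(kappa(l1), kappa(l0))
  expect_identical(lf_matrix(perturb_lead_field(lf, seed = 3)), lf_matrix(pl))
})
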
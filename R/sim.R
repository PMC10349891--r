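# Xi-Alpha oscillatory network simulator: a ground-truth Hermitian precision
# at the alpha peak is factorized into a directed transfer kernel plus lags,
# extended across frequency by Gaussian spectral envelopes, recomposed into a
# precision tensor, sampled per frequency with the Hermitian Gaussian
# generator, and projected through a planar two-concentric-circle forward
# model together with a low-frequency Xi confound and white sensor noise.

# deterministic child seeds so pipeline stages can be re-run in isolation
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647L)
}

#' Random sparse Hermitian alpha-network precision
#'
#' Draws a sparse Hermitian positive definite precision matrix whose
#' off-diagonal entries have modulus at most one (random moduli in
#' `[0.5, 0.9]`, uniform phases) with a diagonally-dominant loading, then
#' rescales it so that the implied mean source power `tr(Theta^-1)/q` equals
#' `peak_power`. The rescaling keeps off-diagonal moduli inside the unit
#' circle and makes the alpha component a spectral power peak relative to the
#' unit-power background of the composed tensor.
#'
#' @param q Number of network nodes (`q >= 2`).
#' @param density Probability that an off-diagonal pair carries an edge.
#' @param seed Integer seed.
#' @param peak_power Target mean source power `tr(Theta^-1)/q` after
#'   rescaling (default 1; the spectral power peak itself is imposed by the
#'   power envelope of [simulate_xi_alpha()]).
#' @return A list with `theta` (Hermitian PD `q x q`), `support` (binary,
#'   unit diagonal).
#' @export
random_alpha_precision <- function(q, density = 0.15, seed = 1,
                                   peak_power = 1) {
  stopifnot(q >= 2, density >= 0, density <= 1)
  set.seed(as.integer(seed))
  theta <- matrix(0 + 0i, q, q)
  ut <- which(upper.tri(theta))
  edges <- ut[stats::runif(length(ut)) < density]
  if (length(edges) == 0 && density > 0 && q < 3) {
    warning("edge density produced no edges", call. = FALSE)
  }
  vals <- stats::runif(length(edges), 0.5, 0.9) *
    exp(1i * stats::runif(length(edges), -pi, pi))
  theta[edges] <- vals
  theta <- theta + Conj(t(theta))
  diag(theta) <- 1 + rowSums(Mod(theta))
  scale <- Re(sum(diag(herm_solve(theta)))) / (q * peak_power)
  theta <- theta * scale
  support <- (Mod(theta) > 0) * 1
  diag(support) <- 1
  list(theta = theta, support = support)
}

#' Blockwise-chained Hermitian precision
#'
#' Block-structured Hermitian PD matrix in which consecutive nodes inside
#' each block are chained and consecutive blocks are coupled through one
#' additional edge (blocks are mutually dependent), the structure used for
#' the unbiasedness validation of the graphical estimators.
#'
#' @param q Matrix dimension.
#' @param block_size Nodes per block (last block truncated if needed).
#' @param seed Integer seed.
#' @return A Hermitian positive definite complex matrix.
#' @export
blockwise_chained_precision <- function(q, block_size = 10, seed = 1) {
  stopifnot(q >= 2, block_size >= 2)
  set.seed(as.integer(seed))
  theta <- matrix(0 + 0i, q, q)
  blocks <- split(seq_len(q), ceiling(seq_len(q) / block_size))
  put <- function(i, j) {
    v <- stats::runif(1, 0.4, 0.9) * exp(1i * stats::runif(1, -pi, pi))
    theta[i, j] <<- v
    theta[j, i] <<- Conj(v)
  }
  for (b in blocks) {
    for (k in seq_len(length(b) - 1)) put(b[k], b[k + 1])
  }
  if (length(blocks) > 1) {
    for (bi in seq_len(length(blocks) - 1)) {
      put(utils::tail(blocks[[bi]], 1), blocks[[bi + 1]][1])
    }
  }
  diag(theta) <- 1 + rowSums(Mod(theta))
  theta
}

#' Spectral factor of a reference precision matrix
#'
#' Factorizes `Theta(f0) = (I - K)^H (I - K)` through the Hermitian
#' eigendecomposition `Theta = U D U^H`, taking `(I - K) = U sqrt(D) U^H`
#' (the principal square root, the unique factor that is itself Hermitian
#' PD; any `(I - K) = W sqrt(D) U^H` with unitary `W` reconstructs
#' `Theta`, and the principal choice keeps `K = 0` for the identity).
#'
#' @param theta_f0 Hermitian PD matrix.
#' @return The complex factor matrix `K`.
#' @export
factorize_reference <- function(theta_f0) {
  theta_f0 <- assert_hermitian(theta_f0, arg = "theta_f0")
  e <- herm_eigen(theta_f0)
  if (any(e$values <= 0)) {
    stop("reference precision must be positive definite", call. = FALSE)
  }
  imk <- hermitian_sqrt(theta_f0)
  k <- diag(nrow(theta_f0)) - imk
  resid <- frob_norm(Conj(t(imk)) %*% imk - theta_f0) / frob_norm(theta_f0)
  if (resid > 1e-6) {
    stop("spectral factorization failed (residual ", format(resid), ")",
         call. = FALSE)
  }
  k
}

#' Lag matrix implied by a transfer factor at the reference frequency
#'
#' `T(i,j) = phase(K(i,j)) / f0` with phases wrapped to `[0, 2 pi)`.
#'
#' @param k_f0 Complex factor matrix at the reference frequency.
#' @param f0 Reference frequency in Hz (> 0).
#' @return A nonnegative lag matrix.
#' @export
lag_matrix <- function(k_f0, f0) {
  if (f0 <= 0) stop("`f0` must be positive", call. = FALSE)
  ph <- Arg(k_f0)
  ph[ph < 0] <- ph[ph < 0] + 2 * pi
  ph[Mod(k_f0) == 0] <- 0
  ph / f0
}

#' Transfer tensor across frequencies
#'
#' `K(f) = K_aa * exp(i T_aa f) * g(f)` with `g` a Gaussian envelope centred
#' at `f0` with `g(f0) = 1`, decaying away from the peak.
#'
#' @param k_const Nonnegative constant coupling matrix (`|K(f0)|`).
#' @param lags Lag matrix in the phase units of [lag_matrix()].
#' @param f0 Centre frequency in Hz.
#' @param width Envelope width `theta_aa` in Hz (> 0).
#' @param frequencies Frequency grid in Hz.
#' @return A `q x q x length(frequencies)` complex array.
#' @export
transfer_tensor <- function(k_const, lags, f0, width, frequencies) {
  stopifnot(width > 0)
  q <- nrow(k_const)
  out <- array(0 + 0i, dim = c(q, q, length(frequencies)))
  for (i in seq_along(frequencies)) {
    f <- frequencies[i]
    env <- exp(-(f - f0)^2 / (2 * width^2))
    out[, , i] <- k_const * exp(1i * lags * f) * env
  }
  out
}

#' Compose a precision tensor from spectral factors
#'
#' `Theta(f) = (I - K(f))^H Theta_zeta(f) (I - K(f))` per frequency slice;
#' Hermitian PSD by construction.
#'
#' @param k_tensor `q x q x nf` complex transfer array.
#' @param theta_zeta `q x q x nf` Hermitian innovations precision array, or a
#'   single `q x q` matrix used at every frequency.
#' @return A `q x q x nf` Hermitian array.
#' @export
compose_precision_tensor <- function(k_tensor, theta_zeta) {
  nf <- dim(k_tensor)[3]
  q <- dim(k_tensor)[1]
  eye <- diag(q)
  out <- array(0 + 0i, dim = dim(k_tensor))
  for (i in seq_len(nf)) {
    tz <- if (length(dim(theta_zeta)) == 3) theta_zeta[, , i] else theta_zeta
    imk <- eye - k_tensor[, , i]
    out[, , i] <- hermitianize(Conj(t(imk)) %*% tz %*% imk)
  }
  out
}

#' Xi (low-frequency background) precision tensor
#'
#' The Xi process has a ring-graph-Laplacian spatial precision
#' `Theta_xx = L_ring + loading * I` (zero lags) and Gaussian spectral power
#' decay away from 0 Hz: its precision is scaled by `exp(+f^2/(2 width^2))`
#' so the implied power `tr(Theta^-1)` falls off as a right-sided Gaussian
#' centred at 0 Hz, concentrating Xi power at low frequencies.
#'
#' @param q Number of cortical nodes (`q >= 2`).
#' @param width Spectral width `theta_xx` in Hz.
#' @param frequencies Frequency grid in Hz.
#' @param loading Diagonal loading of the ring Laplacian (default 0.1).
#' @return A `q x q x length(frequencies)` Hermitian PD array.
#' @export
xi_precision_tensor <- function(q, width = 20, frequencies, loading = 0.1) {
  stopifnot(q >= 2, width > 0)
  lap <- diag(2, q)
  idx <- cbind(seq_len(q), c(2:q, 1))
  lap[idx] <- lap[idx] - 1
  lap[idx[, c(2, 1)]] <- lap[idx[, c(2, 1)]] - 1
  theta_xx <- lap + diag(loading, q)
  out <- array(0, dim = c(q, q, length(frequencies)))
  for (i in seq_along(frequencies)) {
    out[, , i] <- theta_xx * exp(min(frequencies[i]^2 / (2 * width^2), 40))
  }
  out
}

#' Sample oscillations from a precision tensor
#'
#' Per frequency, draws `T` circular complex Gaussian samples with covariance
#' `Theta(f)^-1`; optionally synthesises a real-valued time series by inverse
#' discrete Fourier transform with a conjugate-symmetric spectrum (one
#' segment per sample, unit segment length so frequency bins map one-to-one
#' to Fourier coefficients).
#'
#' @param theta_tensor `q x q x nf` Hermitian PD array.
#' @param T Number of samples per frequency (`T >= 2`).
#' @param frequencies Frequency grid in Hz (one per slice).
#' @param seed Integer seed.
#' @param time_series Synthesise the time-domain signal (default `FALSE`;
#'   the per-frequency spectra are the estimators' input).
#' @return A list with `spectra` (list of `q x T` complex matrices, one per
#'   frequency), `frequencies`, and optionally `time` (real `q x (N T)`
#'   matrix with `N = 2 (nf + 1)`).
#' @export
sample_source_oscillations <- function(theta_tensor, T, frequencies,
                                       seed = 1, time_series = FALSE) {
  stopifnot(T >= 1)
  nf <- dim(theta_tensor)[3]
  stopifnot(length(frequencies) == nf)
  q <- dim(theta_tensor)[1]
  spectra <- vector("list", nf)
  for (i in seq_len(nf)) {
    smp <- sample_complex_gaussian(theta_tensor[, , i], T,
                                   seed = child_seed(seed, i),
                                   frequency = frequencies[i])
    spectra[[i]] <- smp$samples
  }
  out <- list(spectra = spectra, frequencies = frequencies)
  if (time_series) {
    n <- 2 * (nf + 1)
    ts <- matrix(0, q, n * T)
    spec <- matrix(0 + 0i, q, n)
    for (t in seq_len(T)) {
      spec[] <- 0 + 0i
      for (i in seq_len(nf)) {
        spec[, i + 1] <- spectra[[i]][, t]
        spec[, n - i + 1] <- Conj(spectra[[i]][, t])
      }
      seg <- t(stats::mvfft(t(spec), inverse = TRUE)) / n
      ts[, (t - 1) * n + seq_len(n)] <- Re(seg)
    }
    out$time <- ts
  }
  out
}

#' Planar concentric-circle lead field
#'
#' Sensors sit equidistantly on an outer circle (scalp) and sources on an
#' inner circle (cortex); the gain is a quasistatic point-dipole potential
#' falloff `1/r^2` in the source-sensor distance (cortical generators are
#' current dipoles; their potential magnitude decays quadratically),
#' column-normalised. A subset of `n_network` equidistant sources forms the
#' cortical network subspace.
#'
#' @param n_sensors Number of sensors (default 30).
#' @param n_sources Number of cortical sources (default 44).
#' @param n_network Number of network nodes among the sources (default 22).
#' @param r_cortex,r_scalp Radii of the source and sensor circles.
#' @param rotate Common rotation angle (radians) applied to both layouts.
#' @return An object of class `lead_field`: list with `matrix`
#'   (`n_sensors x n_sources`, full column rank for `n_sensors >=
#'   n_sources`), `sensor_pos`, `source_pos`, `network_idx`.
#' @export
planar_lead_field <- function(n_sensors = 30, n_sources = 44,
                              n_network = 22, r_cortex = 0.8, r_scalp = 1,
                              rotate = 0) {
  stopifnot(n_sensors >= 1, n_sources >= 1, n_network <= n_sources)
  ang_sen <- 2 * pi * (seq_len(n_sensors) - 1) / n_sensors + rotate
  ang_src <- 2 * pi * (seq_len(n_sources) - 1) / n_sources + rotate
  sen <- cbind(r_scalp * cos(ang_sen), r_scalp * sin(ang_sen))
  src <- cbind(r_cortex * cos(ang_src), r_cortex * sin(ang_src))
  d <- outer(seq_len(n_sensors), seq_len(n_sources), function(i, j) {
    sqrt((sen[i, 1] - src[j, 1])^2 + (sen[i, 2] - src[j, 2])^2)
  })
  if (any(d == 0)) stop("coincident source and sensor positions",
                        call. = FALSE)
  l <- 1 / d^2
  l <- sweep(l, 2, sqrt(colSums(l^2)), "/")
  step <- n_sources / n_network
  network_idx <- unique(floor((seq_len(n_network) - 1) * step) + 1)
  structure(
    list(matrix = l, sensor_pos = sen, source_pos = src,
         network_idx = network_idx),
    class = "lead_field"
  )
}

# pull the gain matrix out of either representation
lf_matrix <- function(l) if (inherits(l, "lead_field")) l$matrix else l

#' Perturb a lead field towards a human-head-like condition
#'
#' Emulates the conductivity heterogeneity and volume-conduction blurring of
#' a realistic head: sensor-wise Gaussian smearing of each source's gain
#' pattern (scalp conduction mixes neighbouring sensors) followed by
#' lognormal conductance jitter, then column renormalisation. The result is
#' substantially more ill-conditioned than the planar kernel, which is what
#' degrades first-step inverse operators.
#'
#' @param lead_field A `lead_field` or gain matrix.
#' @param blur Angular width of the sensor smearing kernel as a fraction of
#'   the full circle (default 0.08).
#' @param jitter Standard deviation of the lognormal gain jitter
#'   (default 0.3).
#' @param seed Integer seed.
#' @return A `lead_field` (or matrix, matching the input type).
#' @export
perturb_lead_field <- function(lead_field, blur = 0.08, jitter = 0.3,
                               seed = 1) {
  l <- lf_matrix(lead_field)
  p <- nrow(l)
  set.seed(as.integer(seed))
  ang <- 2 * pi * (seq_len(p) - 1) / p
  dang <- outer(ang, ang, function(a, b) {
    d <- abs(a - b)
    pmin(d, 2 * pi - d)
  })
  w <- exp(-dang^2 / (2 * (blur * 2 * pi)^2))
  w <- sweep(w, 1, rowSums(w), "/")
  lp <- w %*% l
  lp <- lp * matrix(exp(jitter * stats::rnorm(length(lp))), nrow(lp))
  lp <- sweep(lp, 2, sqrt(colSums(lp^2)), "/")
  if (inherits(lead_field, "lead_field")) {
    lead_field$matrix <- lp
    lead_field
  } else {
    lp
  }
}

#' Simulation configuration for the Xi-Alpha benchmark
#'
#' Defaults reproduce the packaged benchmark conditions: 22 network nodes
#' observed by 30 planar sensors, `T = 600` samples per frequency, alpha peak
#' at 10 Hz, and confound (Xi + sensor noise) energy in the 8-12 Hz band
#' equal to 10% of the alpha-process band energy.
#'
#' @param n_network_nodes,n_sensors,n_sources Geometry of the planar model.
#' @param T Samples per frequency.
#' @param f0 Alpha peak frequency (Hz).
#' @param frequencies Frequency grid (Hz).
#' @param confound_energy_ratio Band-energy ratio of confounds to the alpha
#'   process, in (0, 1).
#' @param band Alpha band limits (Hz) used for the energy budget.
#' @param density Edge density of the random alpha network.
#' @param alpha_peak_power Mean source power at the alpha peak relative to
#'   the unit off-peak background (default 4).
#' @param alpha_width,xi_width Spectral envelope widths (Hz).
#' @param efm Forward model: `"planar"` or `"human_like"` (perturbed planar).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_network_nodes = 22, n_sensors = 30,
                              n_sources = 2 * n_network_nodes, T = 600,
                              f0 = 10, frequencies = seq(0.5, 50, by = 0.5),
                              confound_energy_ratio = 0.10,
                              band = c(8, 12), density = 0.15,
                              alpha_peak_power = 4,
                              alpha_width = 2, xi_width = 20,
                              efm = c("planar", "human_like"), seed = 1) {
  efm <- match.arg(efm)
  stopifnot(T >= 2, confound_energy_ratio > 0, confound_energy_ratio < 1)
  structure(
    list(n_network_nodes = n_network_nodes, n_sensors = n_sensors,
         n_sources = n_sources, T = T, f0 = f0, frequencies = frequencies,
         confound_energy_ratio = confound_energy_ratio, band = band,
         density = density, alpha_peak_power = alpha_peak_power,
         alpha_width = alpha_width, xi_width = xi_width,
         efm = efm, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Project source oscillations to sensors with confounds
#'
#' Builds per-frequency sensor spectra `v(t, f) = L_net iota(t, f) +
#' c_xi L xi(t, f) + c_w w(t, f)`: the alpha network process through the
#' network columns of the lead field, the whole-cortex Xi process through
#' the full lead field, and white sensor noise. The two confounds are scaled
#' so that each contributes half of `confound_energy_ratio` times the
#' alpha-process spectral energy inside `band`.
#'
#' @param iota_spectra List of `q_net x T` alpha-source spectra per
#'   frequency.
#' @param lead_field A `lead_field` (network columns taken from
#'   `network_idx`).
#' @param xi_spectra List of `q_src x T` Xi spectra per frequency.
#' @param frequencies Frequency grid (Hz).
#' @param confound_energy_ratio Total confound-to-alpha band energy ratio.
#' @param band Two-element band limits in Hz.
#' @param seed Integer seed (sensor noise).
#' @return A list with `v_spectra` (list of `p x T` complex matrices),
#'   `scales` (the applied confound scales), `frequencies`.
#' @export
project_observations <- function(iota_spectra, lead_field, xi_spectra,
                                 frequencies, confound_energy_ratio = 0.10,
                                 band = c(8, 12), seed = 1) {
  stopifnot(confound_energy_ratio > 0, confound_energy_ratio < 1)
  l_full <- lf_matrix(lead_field)
  l_net <- l_full[, lead_field$network_idx, drop = FALSE]
  p <- nrow(l_full)
  T <- ncol(iota_spectra[[1]])
  nf <- length(frequencies)
  in_band <- frequencies >= band[1] & frequencies <= band[2]
  if (!any(in_band)) stop("no frequencies inside the energy band",
                          call. = FALSE)
  alpha_sens <- lapply(iota_spectra, function(x) l_net %*% x)
  xi_sens <- lapply(xi_spectra, function(x) l_full %*% x)
  e_alpha <- sum(vapply(which(in_band),
                        function(i) sum(Mod(alpha_sens[[i]])^2), 0))
  e_xi <- sum(vapply(which(in_band),
                     function(i) sum(Mod(xi_sens[[i]])^2), 0))
  if (e_alpha <= 0) stop("alpha process has no energy in the band",
                         call. = FALSE)
  target <- confound_energy_ratio * e_alpha / 2
  c_xi <- sqrt(target / e_xi)
  noise_var <- target / (p * T * sum(in_band))
  set.seed(child_seed(seed, 991))
  v <- vector("list", nf)
  for (i in seq_len(nf)) {
    w <- matrix(complex(real = stats::rnorm(p * T),
                        imaginary = stats::rnorm(p * T)) / sqrt(2),
                p, T) * sqrt(noise_var)
    v[[i]] <- alpha_sens[[i]] + c_xi * xi_sens[[i]] + w
  }
  list(v_spectra = v, scales = c(xi = c_xi, noise_sd = sqrt(noise_var)),
       frequencies = frequencies)
}

#' Simulate a Xi-Alpha recording
#'
#' Runs the full generative pipeline: random alpha-network precision at the
#' peak frequency, spectral factorization into constant couplings and lags,
#' Gaussian-envelope transfer tensor, precision tensor recomposition,
#' Hermitian Gaussian sampling per frequency, whole-cortex Xi background,
#' and planar (or perturbed human-like) forward projection with the 10%
#' confound energy budget.
#'
#' @param config A [simulation_config()].
#' @return An object of class `sim_recording` with fields `v_spectra`,
#'   `iota_spectra`, `ground_truth` (list: `theta_f0`, `support`, `k_const`,
#'   `lags`, `theta_tensor`), `lead_field` (the one generating the data),
#'   `config`.
#' @export
simulate_xi_alpha <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  net <- random_alpha_precision(config$n_network_nodes,
                                density = config$density,
                                seed = child_seed(seed, 1))
  k_f0 <- factorize_reference(net$theta)
  k_const <- Mod(k_f0)
  lags <- lag_matrix(k_f0, config$f0)
  k_tensor <- transfer_tensor(k_const, lags, config$f0, config$alpha_width,
                              config$frequencies)
  theta_tensor <- compose_precision_tensor(
    k_tensor, diag(config$n_network_nodes))
  # impose the Xi-Alpha power profile exactly: each slice is rescaled so the
  # mean source power follows a Gaussian bump of height `alpha_peak_power`
  # over a unit background (the transfer factors set the Hermitian structure
  # and lags; the envelope sets the spectrum)
  q_net <- config$n_network_nodes
  for (i in seq_along(config$frequencies)) {
    f <- config$frequencies[i]
    target <- 1 + (config$alpha_peak_power - 1) *
      exp(-(f - config$f0)^2 / (2 * config$alpha_width^2))
    cur <- Re(sum(diag(herm_solve(theta_tensor[, , i])))) / q_net
    theta_tensor[, , i] <- theta_tensor[, , i] * (cur / target)
  }
  alpha_src <- sample_source_oscillations(theta_tensor, config$T,
                                          config$frequencies,
                                          seed = child_seed(seed, 2))
  xi_tensor <- xi_precision_tensor(config$n_sources, config$xi_width,
                                   config$frequencies)
  xi_src <- sample_source_oscillations(xi_tensor, config$T,
                                       config$frequencies,
                                       seed = child_seed(seed, 3))
  lf <- planar_lead_field(config$n_sensors, config$n_sources,
                          config$n_network_nodes)
  if (config$efm == "human_like") {
    lf <- perturb_lead_field(lf, seed = child_seed(seed, 4))
  }
  obs <- project_observations(alpha_src$spectra, lf, xi_src$spectra,
                              config$frequencies,
                              config$confound_energy_ratio, config$band,
                              seed = child_seed(seed, 5))
  i_f0 <- which.min(abs(config$frequencies - config$f0))
  structure(
    list(v_spectra = obs$v_spectra, iota_spectra = alpha_src$spectra,
         ground_truth = list(theta_f0 = theta_tensor[, , i_f0],
                             support = net$support,
                             k_const = k_const, lags = lags,
                             theta_tensor = theta_tensor),
         lead_field = lf, scales = obs$scales, config = config),
    class = "sim_recording"
  )
}

#' @export
print.sim_recording <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<sim_recording> %d network nodes, %d sensors, T = %d, %d frequencies (%s EFM)\n",
    cfg$n_network_nodes, cfg$n_sensors, cfg$T, length(cfg$frequencies),
    cfg$efm))
  invisible(x)
}

#' Sensor cross-spectrum of a simulated recording at one frequency
#'
#' @param recording A `sim_recording`.
#' @param frequency Frequency in Hz (must match a grid point; default the
#'   alpha peak).
#' @return A [cross_spectrum()].
#' @export
sensor_cross_spectrum <- function(recording, frequency = NULL) {
  cfg <- recording$config
  if (is.null(frequency)) frequency <- cfg$f0
  i <- which(abs(cfg$frequencies - frequency) < 1e-9)
  if (length(i) != 1) stop("frequency not on the simulation grid",
                           call. = FALSE)
  sample_covariance(recording$v_spectra[[i]], frequency = frequency)
}

#' Network lead field of a simulated recording
#'
#' The sensor-by-network-nodes gain matrix the estimators use.
#'
#' @param recording A `sim_recording`.
#' @return A real matrix `p x q_net`.
#' @export
network_lead_field <- function(recording) {
  lf_matrix(recording$lead_field)[, recording$lead_field$network_idx,
                                  drop = FALSE]
}

#' Mean sensor power spectrum of a simulated recording
#'
#' @param recording A `sim_recording`.
#' @return A tibble with columns `frequency` and `power` (mean over sensors
#'   and samples of `|v|^2`).
#' @export
sensor_power_spectrum <- function(recording) {
  pw <- vapply(recording$v_spectra, function(v) mean(Mod(v)^2), 0)
  tibble::tibble(frequency = recording$config$frequencies, power = pw)
}
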
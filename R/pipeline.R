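# Pipeline plumbing: method-string dispatch, trial loops producing tidy
# score tables, YAML configuration, and a plain-text persistence container
# (directory of full-precision CSV matrices plus JSON metadata).

FORMAT_VERSION <- "1"

#' Estimate connectivity with a named method
#'
#' Method strings follow `onestep-{hglasso|hgridge|hgnaive}` or
#' `multistep-{eloreta|lcmv|generic}-{hglasso|glasso}`.
#'
#' @param lead_field Real `p x q` matrix (or `lead_field` object).
#' @param sigma_vv Sensor cross-spectrum with sample count.
#' @param method Method string.
#' @param ... Passed to [run_higgs()] or [multistep_connectivity()].
#' @return A `higgs_fit` or `multistep_fit`.
#' @export
estimate_connectivity <- function(lead_field, sigma_vv,
                                  method = "onestep-hglasso", ...) {
  parts <- strsplit(method, "-", fixed = TRUE)[[1]]
  if (parts[1] == "onestep") {
    penalty <- switch(parts[2],
                      hglasso = "lasso", hgridge = "ridge",
                      hgnaive = "naive",
                      stop("unknown onestep penalty `", parts[2], "`",
                           call. = FALSE))
    if (inherits(lead_field, "lead_field")) {
      lead_field <- lf_matrix(lead_field)[, lead_field$network_idx,
                                          drop = FALSE]
    }
    run_higgs(higgs_model(lead_field, penalty = penalty), sigma_vv, ...)
  } else if (parts[1] == "multistep") {
    second <- switch(parts[3], hglasso = "hglasso",
                     glasso = "glasso_real",
                     stop("unknown second step `", parts[3], "`",
                          call. = FALSE))
    multistep_connectivity(lead_field, sigma_vv, first_step = parts[2],
                           second_step = second, ...)
  } else {
    stop("unknown method `", method, "`", call. = FALSE)
  }
}

#' Run the simulation-estimation-evaluation pipeline
#'
#' Simulates `n_trials` Xi-Alpha recordings (trial seeds derived from the
#' configuration seed), estimates alpha-peak connectivity with each
#' requested method, and scores support recovery.
#'
#' @param config A [simulation_config()] (or a YAML file path accepted by
#'   [read_pipeline_config()]).
#' @param methods Character vector of method strings
#'   (see [estimate_connectivity()]).
#' @param n_trials Number of simulated trials (default 3).
#' @param out Optional path of a CSV file to write the scores to.
#' @return A tibble with one row per (trial, method) carrying the
#'   [roc_scores()] columns.
#' @export
run_pipeline <- function(config = simulation_config(),
                         methods = c("onestep-hglasso",
                                     "multistep-eloreta-hglasso",
                                     "multistep-lcmv-hglasso"),
                         n_trials = 3, out = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)$simulation
  scores <- purrr::map_dfr(seq_len(n_trials), function(tr) {
    cfg <- config
    cfg$seed <- child_seed(config$seed, 1000 + tr)
    rec <- simulate_xi_alpha(cfg)
    svv <- sensor_cross_spectrum(rec)
    l <- network_lead_field(rec)
    purrr::map_dfr(methods, function(m) {
      fit <- estimate_connectivity(l, svv, method = m)
      dplyr::bind_cols(
        tibble::tibble(trial = tr, method = m,
                       seed = cfg$seed),
        roc_scores(rec$ground_truth$support, Mod(fit$theta))
      )
    })
  })
  if (!is.null(out)) utils::write.csv(scores, out, row.names = FALSE)
  scores
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain a `simulation` block (fields of
#' [simulation_config()]), an `estimation` block (`methods`, and optional
#' `p_level`) and `n_trials`. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A list with elements `simulation`, `methods`, `n_trials`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("simulation", "estimation", "n_trials")
  extra <- setdiff(names(raw), known_top)
  if (length(extra)) {
    stop("unknown configuration keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  sim_args <- raw$simulation %||% list()
  known_sim <- names(formals(simulation_config))
  extra <- setdiff(names(sim_args), known_sim)
  if (length(extra)) {
    stop("unknown simulation keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  sim <- do.call(simulation_config, sim_args)
  methods <- raw$estimation$methods %||% c("onestep-hglasso")
  list(simulation = sim, methods = methods,
       n_trials = raw$n_trials %||% 3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- plain-text persistence -------------------------------------------------

write_matrix_txt <- function(m, path) {
  if (is.complex(m)) {
    utils::write.table(
      cbind(format(Re(m), digits = 17), format(Im(m), digits = 17)),
      path, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    utils::write.table(format(m, digits = 17), path, sep = ",",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
}

read_matrix_txt <- function(path, complex = FALSE) {
  m <- as.matrix(utils::read.table(path, sep = ",",
                                   colClasses = "character"))
  storage.mode(m) <- "character"
  num <- matrix(as.numeric(m), nrow(m), ncol(m))
  if (complex) {
    half <- ncol(num) / 2
    matrix(complex(real = num[, seq_len(half)],
                   imaginary = num[, half + seq_len(half)]),
           nrow(num), half)
  } else {
    num
  }
}

#' Save a simulated recording to a plain-text container
#'
#' Writes a directory holding JSON metadata (configuration, frequencies,
#' format version) and full-precision CSV matrices: the lead field and
#' geometry, the ground truth (reference precision, support, couplings,
#' lags), and the per-frequency sensor and source spectra. The round trip
#' through [load_recording()] is lossless at float64 precision.
#'
#' @param recording A `sim_recording`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
save_recording <- function(recording, path) {
  if (dir.exists(path)) stop("`path` already exists", call. = FALSE)
  dir.create(path, recursive = TRUE)
  dir.create(file.path(path, "v_spectra"))
  dir.create(file.path(path, "iota_spectra"))
  dir.create(file.path(path, "ground_truth"))
  cfg <- recording$config
  meta <- list(format_version = FORMAT_VERSION,
               config = unclass(cfg),
               scales = as.list(recording$scales),
               network_idx = recording$lead_field$network_idx)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write_matrix_txt(lf_matrix(recording$lead_field),
                   file.path(path, "lead_field.csv"))
  write_matrix_txt(recording$lead_field$sensor_pos,
                   file.path(path, "sensor_pos.csv"))
  write_matrix_txt(recording$lead_field$source_pos,
                   file.path(path, "source_pos.csv"))
  gt <- recording$ground_truth
  write_matrix_txt(gt$theta_f0, file.path(path, "ground_truth",
                                          "theta_f0.csv"))
  write_matrix_txt(gt$support, file.path(path, "ground_truth",
                                         "support.csv"))
  write_matrix_txt(gt$k_const, file.path(path, "ground_truth",
                                         "k_const.csv"))
  write_matrix_txt(gt$lags, file.path(path, "ground_truth", "lags.csv"))
  for (i in seq_along(cfg$frequencies)) {
    tag <- sprintf("f%04d.csv", i)
    write_matrix_txt(recording$v_spectra[[i]],
                     file.path(path, "v_spectra", tag))
    write_matrix_txt(recording$iota_spectra[[i]],
                     file.path(path, "iota_spectra", tag))
  }
  invisible(path)
}

#' Load a simulated recording from a plain-text container
#'
#' @param path Directory written by [save_recording()].
#' @return A `sim_recording` (without the regenerable precision tensor,
#'   which [simulate_xi_alpha()] rebuilds from the configuration).
#' @export
load_recording <- function(path) {
  required <- c("meta.json", "lead_field.csv", "sensor_pos.csv",
                "source_pos.csv",
                file.path("ground_truth", "theta_f0.csv"),
                file.path("ground_truth", "support.csv"))
  missing <- required[!file.exists(file.path(path, required))]
  if (length(missing)) {
    stop("recording container is incomplete; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(as.character(meta$format_version), FORMAT_VERSION)) {
    warning("recording format version ", meta$format_version,
            " differs from ", FORMAT_VERSION, "; loading best-effort",
            call. = FALSE)
  }
  cfg <- meta$config
  class(cfg) <- "sim_config"
  lf <- structure(
    list(matrix = read_matrix_txt(file.path(path, "lead_field.csv")),
         sensor_pos = read_matrix_txt(file.path(path, "sensor_pos.csv")),
         source_pos = read_matrix_txt(file.path(path, "source_pos.csv")),
         network_idx = as.integer(meta$network_idx)),
    class = "lead_field"
  )
  gt <- list(
    theta_f0 = read_matrix_txt(
      file.path(path, "ground_truth", "theta_f0.csv"), complex = TRUE),
    support = read_matrix_txt(
      file.path(path, "ground_truth", "support.csv")),
    k_const = read_matrix_txt(
      file.path(path, "ground_truth", "k_const.csv")),
    lags = read_matrix_txt(file.path(path, "ground_truth", "lags.csv")))
  nf <- length(cfg$frequencies)
  v <- vector("list", nf)
  iota <- vector("list", nf)
  for (i in seq_len(nf)) {
    tag <- sprintf("f%04d.csv", i)
    v[[i]] <- read_matrix_txt(file.path(path, "v_spectra", tag),
                              complex = TRUE)
    iota[[i]] <- read_matrix_txt(file.path(path, "iota_spectra", tag),
                                 complex = TRUE)
  }
  structure(
    list(v_spectra = v, iota_spectra = iota, ground_truth = gt,
         lead_field = lf, scales = unlist(meta$scales), config = cfg),
    class = "sim_recording"
  )
}
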
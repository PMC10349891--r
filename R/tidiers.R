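# Broom-style tidiers and ggplot2 autoplot methods so results flow into
# data-frame pipelines and figures.

#' Turn a fitted object into a tidy edge tibble
#'
#' @param x A fitted object.
#' @param ... Method-specific arguments.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#'
#' @param x A fitted object.
#' @param ... Method-specific arguments.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

edge_table <- function(theta, z = NULL, p = NULL, mask = NULL) {
  q <- nrow(theta)
  idx <- which(upper.tri(theta), arr.ind = TRUE)
  out <- tibble::tibble(
    i = idx[, 1], j = idx[, 2],
    modulus = Mod(theta[idx]),
    phase = Arg(theta[idx])
  )
  if (!is.null(z)) out$z <- z[idx]
  if (!is.null(p)) out$p_value <- p[idx]
  if (!is.null(mask)) out$selected = mask[idx] == 1
  out
}

#' @rdname tidy
#' @export
tidy.hg_fit <- function(x, ...) edge_table(x$theta)

#' @rdname tidy
#' @export
tidy.edge_stats <- function(x, ...) {
  edge_table(x$unbiased, z = x$z, p = x$p_values, mask = x$mask)
}

#' @rdname tidy
#' @export
tidy.higgs_fit <- function(x, ...) {
  if (is.null(x$edge_stats)) return(edge_table(x$theta))
  out <- edge_table(x$theta, z = x$edge_stats$z,
                    p = x$edge_stats$p_values, mask = x$mask)
  out
}

#' @rdname tidy
#' @export
tidy.multistep_fit <- tidy.higgs_fit

#' @rdname glance
#' @export
glance.hg_fit <- function(x, ...) {
  tibble::tibble(
    q = nrow(x$theta), penalty = x$penalty, alpha = x$alpha,
    n_iterations = x$n_iterations, converged = x$converged,
    cost = if (length(x$cost_trace)) utils::tail(x$cost_trace, 1)
           else NA_real_
  )
}

#' @rdname glance
#' @export
glance.higgs_fit <- function(x, ...) {
  tibble::tibble(
    q = nrow(x$theta), p = nrow(x$model$lead_field),
    penalty = x$model$penalty, n_em_iterations = x$n_em_iterations,
    noise_scale = x$noise_scale,
    n_edges = if (is.null(x$mask)) NA_integer_
              else sum(x$mask[upper.tri(x$mask)]),
    objective = utils::tail(x$objective_trace, 1)
  )
}

#' @rdname glance
#' @export
glance.multistep_fit <- function(x, ...) {
  tibble::tibble(
    q = nrow(x$theta), first_step = x$first_step,
    second_step = x$second_step,
    n_edges = sum(x$mask[upper.tri(x$mask)])
  )
}

matrix_heat_df <- function(m, value_name = "value") {
  idx <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  idx[[value_name]] <- as.vector(m)
  idx
}

heatmap_plot <- function(m, title, fill_lab) {
  df <- matrix_heat_df(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = fill_lab) +
    ggplot2::theme_minimal()
}

#' Heatmap of a fitted precision amplitude
#'
#' @param object A fitted object.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot hg_fit
#' @export
autoplot.hg_fit <- function(object, ...) {
  heatmap_plot(Mod(object$theta),
               sprintf("Precision amplitude (%s)", object$penalty),
               "|theta|")
}

#' @rdname autoplot.hg_fit
#' @param what Matrix to display for one-step fits.
#' @method autoplot higgs_fit
#' @export
autoplot.higgs_fit <- function(object, what = c("theta", "z", "mask"),
                               ...) {
  what <- match.arg(what)
  m <- switch(what,
              theta = Mod(object$theta),
              z = object$edge_stats$z,
              mask = object$mask)
  heatmap_plot(m, paste("One-step estimate:", what), what)
}

#' @rdname autoplot.hg_fit
#' @method autoplot multistep_fit
#' @export
autoplot.multistep_fit <- function(object, ...) {
  heatmap_plot(Mod(object$theta),
               sprintf("Multistep %s + %s", object$first_step,
                       object$second_step), "|theta|")
}

#' @rdname autoplot.hg_fit
#' @method autoplot edge_stats
#' @export
autoplot.edge_stats <- function(object, ...) {
  heatmap_plot(object$z, "Rayleigh z-statistics", "z")
}

#' @rdname autoplot.hg_fit
#' @method autoplot sim_recording
#' @export
autoplot.sim_recording <- function(object, ...) {
  df <- sensor_power_spectrum(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$config$f0, linetype = 2) +
    ggplot2::labs(x = "frequency (Hz)", y = "mean sensor power",
                  title = "Simulated sensor spectrum") +
    ggplot2::theme_minimal()
}

#' Comparison plot of benchmark scores
#'
#' @param scores A tibble from [run_pipeline()].
#' @param metric Score column to display (default `"auc"`).
#' @return A ggplot object.
#' @export
plot_benchmark <- function(scores, metric = "auc") {
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$method, y = .data[[metric]])) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
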
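## broom-style accessors and plots for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a model test: one row per bootstrap replicate
#'
#' @param x a `dc_model_test`.
#' @param ... unused.
#' @return tibble with columns `model_id`, `rep`, `dc_R`, `dc_MM`, `delta`.
#' @export
tidy.dc_model_test <- function(x, ...) {
  dplyr::mutate(x$replicates, model_id = x$model_id, .before = 1)
}

#' One-row summary of a model test
#'
#' @param x a `dc_model_test`.
#' @param ... unused.
#' @return one-row tibble: simulated means, both tail probabilities per
#'   statistic, the minimum tails, and the support decision.
#' @export
glance.dc_model_test <- function(x, ...) {
  tibble(
    model_id = x$model_id,
    hypothesis = x$hypothesis,
    mean_delta = mean(x$replicates$delta),
    p_delta_low = x$tails_delta$p_low,
    p_delta_high = x$tails_delta$p_high,
    p_delta = min(x$tails_delta$p_low, x$tails_delta$p_high),
    mean_dc = mean(if (x$own_topology == "MM") x$replicates$dc_MM
                   else x$replicates$dc_R),
    p_dc_low = x$tails_dc$p_low,
    p_dc_high = x$tails_dc$p_high,
    p_dc = min(x$tails_dc$p_low, x$tails_dc$p_high),
    supported = x$supported)
}

#' Tidy a model suite: the per-model summary table
#'
#' @param x a `dc_model_suite`.
#' @param ... unused.
#' @return tibble, one row per model (as [glance.dc_model_test()]).
#' @export
tidy.dc_model_suite <- function(x, ...) x$summary

#' One-row overview of a suite run
#'
#' @param x a `dc_model_suite`.
#' @param ... unused.
#' @export
glance.dc_model_suite <- function(x, ...) {
  tibble(n_models = length(x$results),
         n_supported = sum(x$summary$supported),
         supported_models = paste(
           x$summary$model_id[x$summary$supported], collapse = ","),
         nreps = x$nreps,
         seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' Plot the simulated distributions of one model test
#'
#' Histograms of the bootstrap distributions of delta and of the
#' deep-coalescence count on the model's own topology, with the observed
#' values as dashed lines.
#'
#' @param object a `dc_model_test`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dc_model_test <- function(object, ...) {
  dc_own <- if (object$own_topology == "MM") object$replicates$dc_MM
            else object$replicates$dc_R
  df <- dplyr::bind_rows(
    tibble(statistic = "delta", value = object$replicates$delta,
           observed = object$observed$delta),
    tibble(statistic = "deep coalescences", value = dc_own,
           observed = object$observed_dc_own))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60", colour = "grey30") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$observed),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(title = paste("Bootstrap distributions:", object$model_id),
                  x = "statistic value", y = "replicates")
}

#' Plot a model suite: simulated 95% intervals vs observed values
#'
#' One panel per statistic; points are simulated means, segments the
#' central 95% simulated intervals, the dashed line the observed value.
#' Supported models are filled.
#'
#' @param object a `dc_model_suite`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dc_model_suite <- function(object, ...) {
  rows <- lapply(object$results, function(r) {
    dc_own <- if (r$own_topology == "MM") r$replicates$dc_MM
              else r$replicates$dc_R
    dplyr::bind_rows(
      tibble(model_id = r$model_id, statistic = "delta",
             mean = mean(r$replicates$delta),
             lo = stats::quantile(r$replicates$delta, 0.025),
             hi = stats::quantile(r$replicates$delta, 0.975),
             observed = r$observed$delta, supported = r$supported),
      tibble(model_id = r$model_id, statistic = "deep coalescences",
             mean = mean(dc_own),
             lo = stats::quantile(dc_own, 0.025),
             hi = stats::quantile(dc_own, 0.975),
             observed = r$observed_dc_own, supported = r$supported))
  })
  df <- dplyr::bind_rows(rows)
  df$model_id <- factor(df$model_id, levels = unique(df$model_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model_id, y = .data$mean)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$supported), shape = 21) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$observed),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~statistic, ncol = 1, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black",
                                          `FALSE` = "white")) +
    ggplot2::labs(x = NULL, y = "simulated mean and central 95% interval") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
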
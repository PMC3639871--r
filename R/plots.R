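#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_errorbar
#'   geom_vline geom_smooth labs facet_wrap autoplot theme_minimal
NULL

#' Plot a band-power time course
#'
#' @param object A [band_power()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot band_power
autoplot.band_power <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("beta", "gamma"),
                              names_to = "band", values_to = "power")
  ggplot(long, aes(x = .data$time_ms, y = .data$power,
                   colour = .data$band)) +
    geom_line() +
    labs(x = "time (ms)", y = "band power (Morlet magnitude)") +
    theme_minimal()
}

#' Plot a coupling-strength sweep
#'
#' Beta/gamma circuit power and beta PLV(a, b) against the local coupling
#' strength; the dashed line marks the gamma/beta crossover.
#'
#' @param object A [wc_sweep_local()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot wc_sweep
autoplot.wc_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("beta_power", "gamma_power", "beta_plv_ab"),
                              names_to = "measure", values_to = "value")
  p <- ggplot(long, aes(x = .data$w_local, y = .data$value)) +
    geom_line() + geom_point() +
    facet_wrap(~measure, scales = "free_y", ncol = 1) +
    labs(x = "local coupling strength", y = NULL) +
    theme_minimal()
  if (!is.na(attr(object, "crossover")))
    p <- p + geom_vline(xintercept = attr(object, "crossover"),
                        linetype = "dashed")
  p
}

#' Bar plot of group means with standard errors
#'
#' @param report A [group_report()] result (or its `group_tests` tibble).
#' @param measures Optional subset of measures.
#' @return A ggplot.
#' @export
plot_group_comparison <- function(report, measures = NULL) {
  tab <- if (inherits(report, "clgf_report")) report$group_tests else
    as_tibble(report)
  if (!is.null(measures)) tab <- tab[tab$measure %in% measures, ]
  long <- dplyr::bind_rows(
    tibble(measure = tab$measure, group = tab$group_a,
           mean = tab$mean_a, se = tab$se_a),
    tibble(measure = tab$measure, group = tab$group_b,
           mean = tab$mean_b, se = tab$se_b))
  ggplot(long, aes(x = .data$group, y = .data$mean, fill = .data$group)) +
    geom_col() +
    geom_errorbar(aes(ymin = .data$mean - .data$se,
                      ymax = .data$mean + .data$se), width = 0.25) +
    facet_wrap(~measure, scales = "free_y") +
    labs(x = NULL, y = "mean ± SE") +
    theme_minimal()
}

#' Scatter plot of CLGF count against a clinical score
#'
#' @param table Cohort tibble.
#' @param score Score column (default `"panss_negative"`).
#' @param group Group to show (default `"patient"`).
#' @return A ggplot with a least-squares fit line.
#' @export
plot_clgf_correlation <- function(table, score = "panss_negative",
                                  group = "patient") {
  tab <- as_tibble(table)
  tab <- tab[tab$group == group, ]
  ggplot(tab, aes(x = .data$n_clgf, y = .data[[score]])) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    labs(x = "CLGF circuit count", y = score) +
    theme_minimal()
}

#' Plot a mean power spectrum
#'
#' @param tf A `tf_map` or a spectrum tibble from [mean_spectrum()].
#' @return A ggplot.
#' @export
plot_mean_spectrum <- function(tf) {
  sp <- if (inherits(tf, "tf_map")) mean_spectrum(tf) else as_tibble(tf)
  ggplot(sp, aes(x = .data$freq_hz, y = .data$power)) +
    geom_line() +
    labs(x = "frequency (Hz)", y = "mean power") +
    theme_minimal()
}
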
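#' Detect beta-gamma power switching
#'
#' Scans the paired beta/gamma band-power series (1 ms steps) for
#' switching episodes. A switch is triggered at step `t` when all three
#' conditions hold simultaneously: the beta power is falling
#' (\eqn{d\beta/dt < 0}), the gamma power is rising
#' (\eqn{d\gamma/dt > 0}), and gamma exceeds beta
#' (\eqn{\gamma - \beta > 0}). Derivatives are backward first differences,
#' so the first sample can never trigger. Once triggered the indicator
#' latches at 1 and releases at the first step where beta is at least
#' gamma (ties release, since the latch condition requires strictly
#' greater gamma).
#'
#' @param beta,gamma Numeric band-power series at 1 ms steps, or pass a
#'   [band_power] object as `beta` and leave `gamma` missing.
#' @return A `switching_trace`: list with the 0/1 `indicator`,
#'   `duration_ms` (count of 1 steps), and `n_events` (0 to 1
#'   transitions).
#' @export
#' @examples
#' tr <- detect_switching(beta = c(3, 2, 1, 1, 3), gamma = c(1, 2, 3, 3, 1))
#' tr$indicator
detect_switching <- function(beta, gamma) {
  if (inherits(beta, "band_power")) {
    bp <- beta
    beta <- bp$beta
    gamma <- bp$gamma
  }
  if (length(beta) != length(gamma))
    abort("beta and gamma series must have equal length")
  ind <- switching_indicator(as.numeric(beta), as.numeric(gamma))
  structure(list(indicator = ind,
                 duration_ms = sum(ind),
                 n_events = sum(diff(c(0L, ind)) == 1L)),
            class = "switching_trace")
}

#' @export
print.switching_trace <- function(x, ...) {
  cat("<switching_trace> duration ", x$duration_ms, " ms, ",
      x$n_events, " event(s) over ", length(x$indicator), " steps\n",
      sep = "")
  invisible(x)
}

#' @export
#' @method tidy switching_trace
tidy.switching_trace <- function(x, ...) {
  tibble(duration_ms = x$duration_ms, n_events = x$n_events,
         n_steps = length(x$indicator))
}

#' Group comparison of switching statistics
#'
#' Per-group mean and standard error of switching duration and event
#' count, with two-tailed Welch t tests.
#'
#' @param traces List of `switching_trace` objects (or a tibble with
#'   `duration_ms` and `n_events` columns).
#' @param groups Group label per subject (two levels).
#' @return A tibble with one row per measure: group means, standard
#'   errors, Welch `statistic`, `df`, and `p_value`.
#' @export
group_switching_stats <- function(traces, groups) {
  tab <- if (is.data.frame(traces)) as_tibble(traces)
         else purrr::map_dfr(traces, tidy)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) abort("exactly two groups are required")
  if (any(table(groups) < 2)) abort("each group needs at least 2 subjects")
  lv <- levels(groups)
  purrr::map_dfr(c("duration_ms", "n_events"), function(m) {
    a <- tab[[m]][groups == lv[1]]
    b <- tab[[m]][groups == lv[2]]
    wt <- welch_t(a, b)
    tibble(measure = m,
           group_a = lv[1], mean_a = mean(a), se_a = sd(a) / sqrt(length(a)),
           group_b = lv[2], mean_b = mean(b), se_b = sd(b) / sqrt(length(b)),
           statistic = wt$statistic, df = wt$df, p_value = wt$p_value)
  })
}
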
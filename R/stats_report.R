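#' Welch two-sample t test from raw vectors or summary statistics
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom and a
#' two-tailed p value. `welch_t()` takes the raw per-subject vectors;
#' `welch_t_summary()` takes printed means, SDs, and group sizes (the
#' form needed to recompute published demographic tables). The raw form
#' reduces exactly to the summary form of its own summaries.
#'
#' When both groups have zero variance the statistic is 0 (equal means)
#' or `Inf` with a `degenerate` flag (unequal means).
#'
#' @param x,y Numeric vectors (length >= 2 each).
#' @return A one-row tibble: `method`, `statistic`, `df`, `p_value`,
#'   `mean_diff`, `degenerate`.
#' @export
#' @examples
#' welch_t_summary(22.06, 2.11, 17, 23.80, 4.60, 15)$statistic  # -1.35
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    abort("each sample needs at least 2 observations")
  welch_t_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}

#' @rdname welch_t
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @export
welch_t_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) abort("each group needs n >= 2")
  if (sd_a < 0 || sd_b < 0) abort("standard deviations must be >= 0")
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  se2 <- va + vb
  if (se2 == 0) {
    degen <- mean_a != mean_b
    return(tibble(method = "welch_t",
                  statistic = if (degen) Inf * sign(mean_a - mean_b) else 0,
                  df = NA_real_,
                  p_value = if (degen) 0 else 1,
                  mean_diff = mean_a - mean_b, degenerate = degen))
  }
  stat <- (mean_a - mean_b) / sqrt(se2)
  df <- se2^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  tibble(method = "welch_t", statistic = stat, df = df,
         p_value = 2 * pt(-abs(stat), df),
         mean_diff = mean_a - mean_b, degenerate = FALSE)
}

#' Pearson correlation with a two-tailed t-based p value
#'
#' @param x,y Numeric vectors of equal length (n >= 3, nonzero
#'   variance).
#' @return One-row tibble: `method`, `estimate` (r), `statistic` (t with
#'   n-2 df), `df`, `p_value`, `n`.
#' @export
#' @examples
#' pearson_r(1:10, 2 * (1:10) + 1)$estimate  # 1
pearson_r <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("constant vector: correlation undefined")
  r <- stats::cor(x, y)
  n <- length(x)
  if (abs(r) >= 1) {
    stat <- Inf * sign(r)
    p <- 0
  } else {
    stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(stat), n - 2)
  }
  tibble(method = "pearson_r", estimate = r, statistic = stat,
         df = n - 2, p_value = p, n = n)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Plain Pearson chi-square without continuity correction, df = 1.
#'
#' @param tab 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi2_2x2(matrix(c(20, 0, 0, 20), 2))$statistic  # 40
chi2_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) abort("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab)))
    abort("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort("zero margin: chi-square undefined")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble(method = "pearson_chi2",
         statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}

#' Full group report for a cohort table
#'
#' Welch t tests (two groups) for every derived measure present in the
#' table, plus the Pearson correlation panel of the CLGF count against
#' each clinical score within the patient group. No multiple-testing
#' correction is applied; the significance level convention is 0.05.
#'
#' @param table A cohort tibble with a `group` column (two levels, by
#'   convention `control`/`patient`) and numeric measure columns.
#' @param measures Character vector of measure columns; default all
#'   numeric columns except the score columns and id.
#' @param scores Score columns for the correlation panel (default the
#'   `panss_*` columns present).
#' @param correlate_with Column correlated against the scores (default
#'   `"n_clgf"`).
#' @return A `clgf_report`: list of tibbles `group_tests` and
#'   `correlations`.
#' @export
group_report <- function(table, measures = NULL, scores = NULL,
                         correlate_with = "n_clgf") {
  table <- as_tibble(table)
  if (!"group" %in% names(table)) abort("missing column: group")
  g <- as.factor(table$group)
  if (nlevels(g) != 2) abort("exactly two groups are required")
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  if (is.null(scores)) scores <- grep("^panss_", num, value = TRUE)
  if (is.null(measures)) measures <- setdiff(num, scores)
  missing <- setdiff(measures, names(table))
  if (length(missing))
    abort(paste0("missing measure column(s): ",
                 paste(missing, collapse = ", ")))
  lv <- levels(g)
  tests <- purrr::map_dfr(measures, function(m) {
    a <- table[[m]][g == lv[1]]
    b <- table[[m]][g == lv[2]]
    wt <- welch_t(a, b)
    tibble(measure = m, group_a = lv[1], group_b = lv[2],
           mean_a = mean(a), se_a = sd(a) / sqrt(length(a)),
           mean_b = mean(b), se_b = sd(b) / sqrt(length(b)),
           statistic = wt$statistic, df = wt$df, p_value = wt$p_value)
  })
  patient <- if ("patient" %in% lv) "patient" else lv[2]
  cors <- purrr::map_dfr(intersect(scores, names(table)), function(s) {
    x <- table[[correlate_with]][g == patient]
    y <- table[[s]][g == patient]
    res <- tryCatch(pearson_r(x, y), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(tibble(score = s, against = correlate_with,
                            group = patient), res)
  })
  structure(list(group_tests = tests, correlations = cors),
            class = "clgf_report")
}

#' @export
print.clgf_report <- function(x, ...) {
  cat("<clgf_report>\nGroup tests:\n")
  print(x$group_tests, n = Inf)
  if (!is.null(x$correlations) && nrow(x$correlations)) {
    cat("Correlation panel:\n")
    print(x$correlations, n = Inf)
  }
  invisible(x)
}

#' @export
#' @method tidy clgf_report
tidy.clgf_report <- function(x, ...) x$group_tests
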
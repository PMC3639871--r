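ir_design <- function(x, L) {
  n <- length(x)
  rows <- (L + 1):(n - L)
  lags <- -L:L
  X <- vapply(lags, function(tau) x[rows - tau], numeric(length(rows)))
  list(X = X, rows = rows, lags = lags)
}

ir_fit_svd <- function(X) {
  sv <- svd(X)
  list(u = sv$u, d = sv$d, v = sv$v)
}

ir_gcv_lambda <- function(sv, y) {
  n <- length(y)
  uty <- crossprod(sv$u, y)
  cand <- stats::median(sv$d^2) * 10^seq(-6, 4, by = 0.5)
  gcv <- vapply(cand, function(lam) {
    shrink <- sv$d^2 / (sv$d^2 + lam)
    rss <- sum((y - sv$u %*% (shrink * uty))^2)
    edf <- sum(shrink)
    rss / (n * (1 - edf / n)^2)
  }, numeric(1))
  cand[which.min(gcv)]
}

ir_projector <- function(sv, lambda) {
  # h = V diag(d/(d^2+lambda)) U' y, precomputed for repeated right-hand sides
  sv$v %*% (sv$d / (sv$d^2 + lambda) * t(sv$u))
}

#' Two-sided impulse response between two channels
#'
#' Estimates the extended (causal plus non-causal) finite impulse
#' response of `y` on `x` by regularized least squares: `y(t)` is
#' regressed on the lagged copies `x(t - tau)` for
#' `tau in -max_lag..+max_lag` samples. Positive lags form the causal
#' part (x leads y), negative lags the non-causal part (y leads x); a
#' feedback relationship leaves significant structure on both sides. The
#' ridge penalty is chosen by generalized cross-validation.
#'
#' @param x,y Numeric series of equal length (at least `5 * (2L + 1)`
#'   usable samples are required; 20x is recommended).
#' @param max_lag_ms Lag horizon `L` in ms (default 30, covering both the
#'   6-10 ms intra-regional and 15-25 ms inter-regional conduction-delay
#'   ranges with margin while staying below the ~50 ms period of the
#'   beta-locked pair state; a longer horizon would let a shifted
#'   surrogate align once per period on both sides of zero and inflate
#'   the joint null).
#' @param fs Sampling rate in Hz.
#' @param lambda Ridge penalty; `NULL` selects it by GCV.
#' @return An `impulse_response`: tibble with `lag_ms` and `h`, plus
#'   attributes (`lambda`, `fs`, `max_lag_ms`).
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(3000)
#' y <- c(rep(0, 10), x[1:2990])  # y = x delayed 10 samples
#' ir <- estimate_ir(x, y, max_lag_ms = 30, fs = 1000)
#' ir$lag_ms[which.max(abs(ir$h))]
estimate_ir <- function(x, y, max_lag_ms = 30, fs = 1000, lambda = NULL) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  L <- round(max_lag_ms / 1000 * fs)
  if (length(x) - 2 * L < 5 * (2 * L + 1))
    abort("series too short relative to the lag horizon")
  des <- ir_design(x, L)
  sv <- ir_fit_svd(des$X)
  yr <- y[des$rows]
  if (is.null(lambda)) lambda <- ir_gcv_lambda(sv, yr)
  h <- drop(ir_projector(sv, lambda) %*% yr)
  out <- tibble(lag_ms = des$lags / fs * 1000, h = h)
  structure(out, class = c("impulse_response", class(out)),
            lambda = lambda, fs = fs, max_lag_ms = max_lag_ms)
}

#' Surrogate null for impulse-response peaks
#'
#' Builds the null distribution of the maximal causal and non-causal
#' impulse-response magnitudes under broken temporal alignment: `y` is
#' circularly time-shifted by random offsets (at least the lag horizon),
#' and the two-sided response is re-estimated with the design matrix and
#' penalty of the original fit.
#'
#' @inheritParams estimate_ir
#' @param n_surrogates Number of surrogates (at least 100 recommended).
#' @param seed Optional seed for reproducible surrogate draws.
#' @return List with numeric vectors `causal` and `noncausal` of
#'   surrogate peak magnitudes, plus the fitted `lambda`.
#' @export
ir_surrogate_null <- function(x, y, max_lag_ms = 30, fs = 1000,
                              n_surrogates = 100, lambda = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- round(max_lag_ms / 1000 * fs)
  n <- length(x)
  des <- ir_design(x, L)
  sv <- ir_fit_svd(des$X)
  yr <- y[des$rows]
  if (is.null(lambda)) lambda <- ir_gcv_lambda(sv, yr)
  proj <- ir_projector(sv, lambda)
  causal <- des$lags > 0
  noncausal <- des$lags < 0
  shifts <- sample((2 * L):(n - 2 * L), n_surrogates, replace = TRUE)
  mx <- vapply(shifts, function(s) {
    ys <- y[((seq_len(n) + s - 1L) %% n) + 1L]
    h <- drop(proj %*% ys[des$rows])
    c(max(abs(h[causal])), max(abs(h[noncausal])))
  }, numeric(2))
  list(causal = mx[1, ], noncausal = mx[2, ], lambda = lambda)
}

#' Classify a channel pair as positive, negative, or no feedback
#'
#' A feedback relationship requires significant structure on both sides
#' of the two-sided impulse response, so the detection statistic is the
#' joint one: the smaller of the causal-part and non-causal-part peak
#' magnitudes, compared against the same joint statistic computed on the
#' time-shift surrogates. (Testing each side against its own marginal
#' null is blind to locked oscillator pairs: a circular shift of a
#' near-periodic record re-aligns the pair at a single lag, so the
#' marginal nulls saturate at the true peak level, while the surrogate
#' rarely shows strong peaks on both sides of zero at once.) The sign is
#' positive when the two dominant peaks have the same algebraic sign and
#' negative otherwise.
#'
#' @param ir An [estimate_ir()] result.
#' @param null An [ir_surrogate_null()] result.
#' @param level Null quantile (default 0.95).
#' @return A one-row tibble (`sign`, `causal_lag_ms`, `noncausal_lag_ms`,
#'   peak magnitudes) or `NULL` when no feedback is detected.
#' @export
classify_feedback <- function(ir, null, level = 0.95) {
  ca <- ir$lag_ms > 0
  nc <- ir$lag_ms < 0
  i_ca <- which(ca)[which.max(abs(ir$h[ca]))]
  i_nc <- which(nc)[which.max(abs(ir$h[nc]))]
  pk_ca <- abs(ir$h[i_ca])
  pk_nc <- abs(ir$h[i_nc])
  thr <- quantile(pmin(null$causal, null$noncausal), level, names = FALSE)
  if (min(pk_ca, pk_nc) <= thr) return(NULL)
  tibble(sign = if (sign(ir$h[i_ca]) == sign(ir$h[i_nc])) "+" else "-",
         causal_lag_ms = ir$lag_ms[i_ca],
         noncausal_lag_ms = abs(ir$lag_ms[i_nc]),
         causal_peak = pk_ca, noncausal_peak = pk_nc)
}

empty_network <- function() {
  tibble(ch_a = character(), ch_b = character(), sign = character(),
         causal_lag_ms = numeric(), noncausal_lag_ms = numeric())
}

#' Infer the feedback network of one analysis window
#'
#' Applies [estimate_ir()], [ir_surrogate_null()], and
#' [classify_feedback()] to every unordered channel pair. Edges are
#' unordered because a feedback is inherently bidirectional; swapping the
#' pair swaps the causal and non-causal parts and leaves the
#' classification unchanged.
#'
#' @param signals A `signal_set`.
#' @param max_lag_ms Lag horizon (ms).
#' @param n_surrogates Surrogates per pair.
#' @param level Surrogate quantile.
#' @param seed Optional seed (fanned out per pair).
#' @return A `feedback_network` tibble: `ch_a`, `ch_b`, `sign`,
#'   `causal_lag_ms`, `noncausal_lag_ms`.
#' @export
infer_feedback_network <- function(signals, max_lag_ms = 30,
                                   n_surrogates = 100, level = 0.95,
                                   seed = NULL) {
  stopifnot(inherits(signals, "signal_set"))
  nch <- nrow(signals$data)
  pairs <- utils::combn(nch, 2)
  rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    x <- signals$data[i, ]; y <- signals$data[j, ]
    ir <- estimate_ir(x, y, max_lag_ms, signals$fs)
    nul <- ir_surrogate_null(x, y, max_lag_ms, signals$fs, n_surrogates,
                             lambda = attr(ir, "lambda"),
                             seed = if (is.null(seed)) NULL else seed + k)
    cls <- classify_feedback(ir, nul, level)
    if (is.null(cls)) return(NULL)
    dplyr::bind_cols(tibble(ch_a = signals$channels[i],
                            ch_b = signals$channels[j]),
                     cls[, c("sign", "causal_lag_ms", "noncausal_lag_ms")])
  })
  out <- if (nrow(rows)) rows else empty_network()
  structure(out, class = c("feedback_network", class(out)))
}

#' Window-consistent feedback network
#'
#' Splits the record into `n_windows` non-overlapping windows, infers a
#' feedback network in each independently, and keeps only connections
#' found with identical pair and sign in every window.
#'
#' @inheritParams infer_feedback_network
#' @param n_windows Number of windows (default 4).
#' @param window_len_s Window length in seconds (default 20; 4 x 20 s
#'   covers an 80 s record).
#' @param keep_windows Also return the per-window networks.
#' @return A `feedback_network` tibble (lags averaged over supporting
#'   windows); with `keep_windows = TRUE`, attribute `windows` holds the
#'   per-window networks.
#' @export
consistent_network <- function(signals, n_windows = 4, window_len_s = 20,
                               max_lag_ms = 30, n_surrogates = 100,
                               level = 0.95, seed = NULL,
                               keep_windows = FALSE) {
  stopifnot(inherits(signals, "signal_set"))
  need <- n_windows * window_len_s * signals$fs
  if (ncol(signals$data) < need)
    abort(sprintf("record too short: %d samples needed", need))
  wlen <- round(window_len_s * signals$fs)
  nets <- lapply(seq_len(n_windows), function(w) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    sub <- signal_set(signals$data[, idx, drop = FALSE], signals$fs,
                      signals$channels)
    infer_feedback_network(sub, max_lag_ms, n_surrogates, level,
                           seed = if (is.null(seed)) NULL else seed + 1000 * w)
  })
  keyed <- lapply(nets, function(n) paste(n$ch_a, n$ch_b, n$sign))
  common <- Reduce(intersect, keyed)
  out <- if (length(common)) {
    first <- nets[[1]][keyed[[1]] %in% common, , drop = FALSE]
    lag_tab <- dplyr::bind_rows(lapply(nets, function(n)
      n[paste(n$ch_a, n$ch_b, n$sign) %in% common, ]))
    lag_avg <- dplyr::summarise(
      dplyr::group_by(lag_tab, .data$ch_a, .data$ch_b, .data$sign),
      causal_lag_ms = mean(.data$causal_lag_ms),
      noncausal_lag_ms = mean(.data$noncausal_lag_ms), .groups = "drop")
    lag_avg[order(lag_avg$ch_a, lag_avg$ch_b), ]
  } else empty_network()
  out <- structure(out, class = c("feedback_network", class(out)))
  if (keep_windows) attr(out, "windows") <- nets
  out
}
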
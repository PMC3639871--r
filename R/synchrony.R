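#' Zero-phase FIR band-pass filter
#'
#' Forward-backward filtering with a Hamming-window FIR filter whose
#' order is three cycles of the low cutoff (the contract of the usual
#' EEG/MEG band-pass: linear phase applied in both directions, hence zero
#' net phase and no group delay).
#'
#' @param signals A `signal_set`.
#' @param band Length-2 numeric `(low, high)` in Hz.
#' @param order Filter order; default `round(3 * fs / low)`, forced even.
#' @return A filtered `signal_set` with a `band` attribute.
#' @export
#' @examples
#' x <- sin(2 * pi * 20 * seq(0, 2, 1e-3))
#' out <- bandpass(signal_set(matrix(x, 1), 1000), c(13, 30))
bandpass <- function(signals, band, order = NULL) {
  stopifnot(inherits(signals, "signal_set"))
  fs <- signals$fs
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2] ||
      band[2] >= fs / 2)
    abort("band must satisfy 0 < low < high < Nyquist")
  if (is.null(order)) order <- round(3 * fs / band[1])
  if (order %% 2 == 1) order <- order + 1
  if (ncol(signals$data) < 3 * order)
    abort("record too short for the requested filter order")
  h <- signal::fir1(order, band / (fs / 2), type = "pass")
  filt <- t(apply(signals$data, 1, function(x) signal::filtfilt(h, x)))
  out <- signal_set(filt, fs, signals$channels)
  attr(out, "band") <- band
  out
}

#' Instantaneous phase via the Hilbert analytic signal
#'
#' Computes the analytic signal by one-sided FFT and returns its argument
#' per channel. Input should be band-limited (see [bandpass()]) for the
#' phase to be interpretable.
#'
#' @param signals A (band-passed) `signal_set`.
#' @return A `phase_set`: list with `phase` (channels x samples, radians
#'   in (-pi, pi\]), `fs`, `channels`, and the band if known.
#' @export
hilbert_phase <- function(signals) {
  stopifnot(inherits(signals, "signal_set"))
  n <- ncol(signals$data)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  ph <- t(apply(signals$data, 1, function(x) {
    Arg(fft(fft(x - mean(x)) * h, inverse = TRUE) / n)
  }))
  structure(list(phase = ph, fs = signals$fs, channels = signals$channels,
                 band = attr(signals, "band")),
            class = "phase_set")
}

#' Sliding-window phase-locking values
#'
#' For each channel pair the PLV over a window is
#' \deqn{\gamma_{n,m} = \sqrt{\langle\sin\varphi_{n,m}\rangle^2 +
#'                            \langle\cos\varphi_{n,m}\rangle^2},}
#' the resultant length of the within-window phase differences
#' \eqn{\varphi_{n,m}(t)}; it ranges from 0 (no synchronization) to 1
#' (perfect synchronization). Windows slide along the record and the
#' per-window values are averaged; windows that would run past the end of
#' the record are dropped.
#'
#' @param phases A `phase_set` (at least two channels).
#' @param window_ms Window length (default 1000 ms).
#' @param slide_ms Slide between window starts (default 200 ms).
#' @param edge_exclude_ms Optionally drop windows overlapping this many
#'   ms at either end of the record (filter and Hilbert transients
#'   contaminate the phases there); default 0 keeps every window.
#' @return A `plv_matrix`: list with the symmetric `plv` matrix (unit
#'   diagonal), `n_windows`, the window parameters and band.
#'   `glance()` returns the subject-level scalar (mean over all distinct
#'   pairs); `tidy()` the pairwise long table.
#' @export
#' @examples
#' t <- seq(0, 3, 1e-3)
#' ss <- signal_set(rbind(sin(2 * pi * 20 * t), sin(2 * pi * 20 * t + 1)), 1000)
#' p <- plv(hilbert_phase(bandpass(ss, c(13, 30))))
#' p$plv[1, 2]  # constant offset: exactly 1
plv <- function(phases, window_ms = 1000, slide_ms = 200,
                edge_exclude_ms = 0) {
  stopifnot(inherits(phases, "phase_set"))
  nch <- nrow(phases$phase)
  if (nch < 2) abort("pairwise PLV needs at least two channels")
  n <- ncol(phases$phase)
  win <- round(window_ms / 1000 * phases$fs)
  slide <- max(1L, round(slide_ms / 1000 * phases$fs))
  if (win > n) abort("window longer than the record")
  starts <- seq(1L, n - win + 1L, by = slide)
  if (edge_exclude_ms > 0) {
    excl <- round(edge_exclude_ms / 1000 * phases$fs)
    keep <- starts > excl & (starts + win - 1L) <= n - excl
    if (!any(keep)) abort("edge exclusion leaves no complete window")
    starts <- starts[keep]
  }
  acc <- matrix(0, nch, nch)
  Zfull <- exp(1i * phases$phase)
  for (s in starts) {
    Z <- Zfull[, s:(s + win - 1L), drop = FALSE]
    M <- Z %*% Conj(t(Z)) / win
    acc <- acc + Mod(M)
  }
  m <- acc / length(starts)
  m <- (m + t(m)) / 2   # enforce exact symmetry against float round-off
  diag(m) <- 1
  dimnames(m) <- list(phases$channels, phases$channels)
  structure(list(plv = m, n_windows = length(starts),
                 window_ms = window_ms, slide_ms = slide_ms,
                 band = phases$band, channels = phases$channels),
            class = "plv_matrix")
}

#' @export
print.plv_matrix <- function(x, ...) {
  cat("<plv_matrix> ", nrow(x$plv), " channels, ", x$n_windows,
      " windows (", x$window_ms, "/", x$slide_ms, " ms); mean pair PLV ",
      round(glance(x)$mean_plv, 3), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method glance plv_matrix
glance.plv_matrix <- function(x, ...) {
  ut <- x$plv[upper.tri(x$plv)]
  tibble(mean_plv = mean(ut), n_pairs = length(ut),
         n_windows = x$n_windows)
}

#' @export
#' @method tidy plv_matrix
tidy.plv_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$plv), arr.ind = TRUE)
  tibble(ch_a = x$channels[idx[, 1]], ch_b = x$channels[idx[, 2]],
         plv = x$plv[idx])
}

#' Group-difference PLV topography
#'
#' For every channel pair, a two-tailed Welch t test compares the
#' subject-level PLVs of the two groups; pairs below the threshold are
#' returned as edges assigned to the group with the higher mean. No
#' multiple-testing correction is applied by default (raw per-edge
#' thresholds at the chosen level, conventionally run at 0.01 and 0.001);
#' set `fdr = TRUE` for Benjamini-Hochberg adjusted p values.
#'
#' @param group_a,group_b Lists of `plv_matrix` objects (same channel
#'   set), one per subject.
#' @param p_threshold Significance level in (0, 1).
#' @param fdr Apply FDR adjustment before thresholding.
#' @return A tibble of edges: `ch_a`, `ch_b`, `higher`, `statistic`,
#'   `p_value`.
#' @export
plv_topography <- function(group_a, group_b, p_threshold = 0.01,
                           fdr = FALSE) {
  if (p_threshold <= 0 || p_threshold >= 1)
    abort("p_threshold must be inside (0, 1)")
  if (length(group_a) < 2 || length(group_b) < 2)
    abort("each group needs at least 2 subjects")
  stack <- function(g) vapply(g, function(p) p$plv[upper.tri(p$plv)],
                              numeric(sum(upper.tri(g[[1]]$plv))))
  A <- stack(group_a)
  B <- stack(group_b)
  ch <- group_a[[1]]$channels
  idx <- which(upper.tri(group_a[[1]]$plv), arr.ind = TRUE)
  res <- purrr::map_dfr(seq_len(nrow(A)), function(i) {
    wt <- welch_t(A[i, ], B[i, ])
    tibble(ch_a = ch[idx[i, 1]], ch_b = ch[idx[i, 2]],
           higher = if (mean(A[i, ]) >= mean(B[i, ])) "a" else "b",
           statistic = wt$statistic, p_value = wt$p_value)
  })
  if (fdr) res$p_value <- stats::p.adjust(res$p_value, "BH")
  res[res$p_value < p_threshold, ]
}
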
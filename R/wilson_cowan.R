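#' Wilson-Cowan oscillator parameters
#'
#' Parameter set for one excitatory/inhibitory Wilson-Cowan unit,
#' \deqn{dE/dt = -\alpha E + \beta_E (1 - rE) f_E(s_E), \qquad
#'       dI/dt = -\alpha I + \beta_I (1 - rI) f_I(s_I),}
#' with centred sigmoid response
#' \eqn{f(s) = 1/[1+e^{-a(s-\theta)}] - 1/[1+e^{a\theta}]}. Time is in ms.
#'
#' Synaptic weights follow the source-to-target convention:
#' `w_ei` is the excitatory-to-inhibitory weight (it appears in the
#' inhibitory input \eqn{s_I = w_{EI} E - w_{II} I + Q}) and `w_ie` the
#' inhibitory-to-excitatory weight (in
#' \eqn{s_E = w_{EE} E - w_{IE} I + P}). Under this convention the default
#' set below produces a stable limit cycle between roughly 80 and 150 Hz
#' for external excitatory input `P` in about \[1.1, 2.75\], quiescence
#' below and hyper-excitation above, which is the calibrated operating
#' regime of the model.
#'
#' @param alpha Natural decay rate (1/ms).
#' @param beta_e,beta_i Maximal firing rates of the E and I populations.
#' @param r Refractory constant.
#' @param a_e,a_i Sigmoid slopes of the E and I response functions.
#' @param th_e,th_i Thresholds of the E and I response functions.
#' @param w_ee,w_ei,w_ie,w_ii Synaptic weights (source to target).
#' @return A named list of class `wc_params`.
#' @export
#' @examples
#' wc_params()
wc_params <- function(alpha = 0.35, beta_e = 1, beta_i = 1, r = 0.65,
                      a_e = 1.3, a_i = 2, th_e = 4.5, th_i = 3.5,
                      w_ee = 16, w_ei = 15, w_ie = 12, w_ii = 3) {
  p <- list(alpha = alpha, beta_e = beta_e, beta_i = beta_i, r = r,
            a_e = a_e, a_i = a_i, th_e = th_e, th_i = th_i,
            w_ee = w_ee, w_ei = w_ei, w_ie = w_ie, w_ii = w_ii)
  structure(p, class = "wc_params")
}

param_matrix <- function(params, n) {
  if (inherits(params, "wc_params")) params <- rep(list(params), n)
  stopifnot(length(params) == n)
  do.call(rbind, lapply(params, function(p) unlist(p, use.names = FALSE)))
}

#' Specify a delayed Wilson-Cowan oscillator network
#'
#' Builds a network of Wilson-Cowan units coupled through delayed
#' excitatory-to-excitatory connections: the term
#' \eqn{\omega\, E_{\mathrm{src}}(t-\tau)} is added to the excitatory input
#' of the target unit.
#'
#' @param n_osc Number of oscillators.
#' @param edges Data frame with columns `from`, `to` (1-based oscillator
#'   indices), `weight`, and `delay_ms`. Each row is one directed coupling.
#'   `NULL` means no coupling.
#' @param P,Q External inputs to the E and I populations; recycled to
#'   `n_osc`.
#' @param params A single `wc_params` object shared by all oscillators, or
#'   a list of one per oscillator.
#' @return An object of class `wc_network`.
#' @export
#' @examples
#' wc_network(1, P = 1.4)
wc_network <- function(n_osc, edges = NULL, P = 0, Q = 0, params = wc_params()) {
  if (is.null(edges)) {
    edges <- tibble(from = integer(), to = integer(),
                    weight = numeric(), delay_ms = numeric())
  }
  edges <- as_tibble(edges)
  stopifnot(all(c("from", "to", "weight", "delay_ms") %in% names(edges)))
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) abort("self-coupling is not allowed")
    if (any(edges$delay_ms <= 0)) abort("coupling delays must be positive")
    if (any(edges$from < 1 | edges$from > n_osc | edges$to < 1 | edges$to > n_osc))
      abort("edge endpoints outside 1..n_osc")
  }
  structure(list(n_osc = n_osc, edges = edges,
                 P = rep_len(P, n_osc), Q = rep_len(Q, n_osc),
                 params = params),
            class = "wc_network")
}

#' Two- and three-oscillator feedback circuits
#'
#' Convenience builders for the circuits used in the coupling-strength
#' analyses: a hub oscillator `a` reciprocally coupled to `b` through a
#' long-delay (inter-regional, "global") feedback loop and optionally to
#' `c` through a short-delay (intra-regional, "local") loop.
#'
#' By default every oscillator receives the external drive `P`. With the
#' printed-equation variant `drive = "hub"` only oscillator `a` is driven;
#' in that configuration the relay oscillators stay far below threshold
#' and the circuit never leaves the hub's intrinsic gamma cycle (see the
#' package vignette), so `drive = "all"` is the default.
#'
#' @param w_global Reciprocal coupling strength of the a-b loop.
#' @param w_local Reciprocal coupling strength of the a-c loop; 0 drops
#'   oscillator `c`'s coupling (the 2-node circuit).
#' @param tau_global,tau_local One-way conduction delays in ms (defaults
#'   21 and 6).
#' @param P External excitatory input.
#' @param drive `"all"` (default) or `"hub"`.
#' @param n_osc Number of oscillators to instantiate (3 keeps `c` present
#'   even when `w_local = 0`, so band-power readouts sum a fixed set).
#' @param params `wc_params`.
#' @return A `wc_network`.
#' @export
wc_circuit <- function(w_global = 2.5, w_local = 0,
                       tau_global = 21, tau_local = 6,
                       P = 1.4, drive = c("all", "hub"), n_osc = 3,
                       params = wc_params()) {
  drive <- match.arg(drive)
  ed <- tibble(from = integer(), to = integer(), weight = numeric(),
               delay_ms = numeric())
  if (w_global > 0) {
    ed <- dplyr::bind_rows(ed,
      tibble(from = c(1L, 2L), to = c(2L, 1L),
             weight = w_global, delay_ms = tau_global))
  }
  if (w_local > 0 && n_osc >= 3) {
    ed <- dplyr::bind_rows(ed,
      tibble(from = c(1L, 3L), to = c(3L, 1L),
             weight = w_local, delay_ms = tau_local))
  }
  Pv <- if (drive == "all") rep(P, n_osc) else c(P, rep(0, n_osc - 1))
  wc_network(n_osc, ed, P = Pv, Q = 0, params = params)
}

#' Simulate a delayed Wilson-Cowan network
#'
#' Integrates the delay differential equations by the method of steps with
#' classical fourth-order Runge-Kutta and cubic (Catmull-Rom) interpolation
#' of delayed excitatory activity. History for `t <= 0` is the constant
#' initial state. The default initial state staggers the oscillators
#' (`0.2, 0.05, 0.1, ...`), which breaks the permutation symmetry of
#' identical units; a symmetric start tends to fall straight into the
#' synchronized runaway (hyper-excited) state of strongly coupled
#' positive-feedback circuits.
#'
#' @param net A `wc_network`.
#' @param duration_ms Total simulated time (ms).
#' @param dt Integration step (ms), at most 0.1.
#' @param record_dt Output sampling interval (ms); must be a multiple of
#'   `dt`. The default 1 ms matches a 1000 Hz recording.
#' @param E0,I0 Initial (and pre-history) state per oscillator. `NULL`
#'   uses the staggered default for `E0` and zeros for `I0`.
#' @return A `wc_trajectory`: list with matrices `E`, `I`
#'   (oscillator x time), `time_ms`, the `net`, and `dt`.
#' @export
#' @examples
#' tr <- wc_simulate(wc_network(1, P = 1.4), duration_ms = 500)
#' range(tr$E)
wc_simulate <- function(net, duration_ms, dt = 0.05, record_dt = 1,
                        E0 = NULL, I0 = NULL) {
  stopifnot(inherits(net, "wc_network"))
  if (duration_ms <= 0) abort("duration must be positive")
  if (dt > 0.1) abort("dt must be <= 0.1 ms")
  if (abs(record_dt / dt - round(record_dt / dt)) > 1e-8)
    abort("record_dt must be a multiple of dt")
  n <- net$n_osc
  if (is.null(E0)) E0 <- rep_len(c(0.2, 0.05, 0.1, 0.15), n)
  if (is.null(I0)) I0 <- rep(0, n)
  pm <- param_matrix(net$params, n)
  ed <- net$edges
  res <- wc_integrate(pm, net$P, net$Q,
                      as.integer(ed$from) - 1L, as.integer(ed$to) - 1L,
                      as.numeric(ed$weight), as.numeric(ed$delay_ms),
                      duration_ms, dt, record_dt,
                      as.numeric(E0), as.numeric(I0))
  structure(list(E = res$E, I = res$I, time_ms = res$time_ms,
                 net = net, dt = dt, record_dt = record_dt),
            class = "wc_trajectory")
}

#' @export
print.wc_trajectory <- function(x, ...) {
  cat("<wc_trajectory> ", nrow(x$E), " oscillator(s), ",
      max(x$time_ms), " ms at ", x$record_dt, " ms resolution\n", sep = "")
  invisible(x)
}

#' Classify the post-transient regime of a trajectory
#'
#' Labels each oscillator `"limit_cycle"`, `"fixed_point"`, or `"hyper"`.
#' Hyper-excitation is the saturated non-oscillating state of an
#' over-driven positive feedback loop (flat E pinned near its ceiling);
#' it is excluded from spectral readouts.
#'
#' @param traj A `wc_trajectory`.
#' @param transient_ms Initial span to discard (default 200 ms).
#' @param amp_tol Amplitude below which a trajectory counts as flat.
#' @param hyper_level Mean E above which a flat trajectory counts as
#'   hyper-excited rather than a quiescent fixed point.
#' @return Character vector, one label per oscillator.
#' @export
wc_regime <- function(traj, transient_ms = 200, amp_tol = 1e-3,
                      hyper_level = 0.5) {
  keep <- traj$time_ms > transient_ms
  vapply(seq_len(nrow(traj$E)), function(k) {
    x <- traj$E[k, keep]
    if (diff(range(x)) < amp_tol) {
      if (mean(x) > hyper_level) "hyper" else "fixed_point"
    } else "limit_cycle"
  }, character(1))
}

#' Dominant oscillation frequency of a trajectory
#'
#' Spectral peak of `E(t)` after discarding the transient. Returns `NA`
#' for flat (fixed-point or hyper-excited) trajectories.
#'
#' @param traj A `wc_trajectory`.
#' @param oscillator Oscillator index (default 1).
#' @param transient_ms Transient to discard (default 200 ms).
#' @param fmin,fmax Search band in Hz.
#' @return Frequency in Hz, or `NA_real_`.
#' @export
#' @examples
#' tr <- wc_simulate(wc_network(1, P = 2), duration_ms = 1200)
#' wc_dominant_frequency(tr)
wc_dominant_frequency <- function(traj, oscillator = 1, transient_ms = 200,
                                  fmin = 5, fmax = NULL) {
  keep <- traj$time_ms > transient_ms
  x <- traj$E[oscillator, keep]
  if (diff(range(x)) < 1e-3) return(NA_real_)
  fs <- 1000 / traj$record_dt
  if (is.null(fmax)) fmax <- fs / 2
  x <- x - mean(x)
  n <- length(x)
  sp <- Mod(fft(x))^2
  fr <- (seq_len(n) - 1) * fs / n
  sel <- fr >= fmin & fr <= fmax
  fr[sel][which.max(sp[sel])]
}

#' Calibrate the external input to a target dominant frequency
#'
#' Scans `P` over a grid and returns the grid value whose single-oscillator
#' dominant frequency is nearest the target (default 100 Hz, the stated
#' operating point of the hub oscillator). Grid points without a limit
#' cycle are skipped.
#'
#' @param P_grid Candidate inputs (default `seq(1.2, 3, by = 0.2)`).
#' @param target_hz Target frequency.
#' @param duration_ms Simulation length per grid point.
#' @param params `wc_params`.
#' @return A list with `P`, `freq_hz`, and the scan table `grid`.
#' @export
wc_calibrate_input <- function(P_grid = seq(1.2, 3, by = 0.2),
                               target_hz = 100, duration_ms = 1200,
                               params = wc_params()) {
  grid <- purrr::map_dfr(P_grid, function(P) {
    tr <- wc_simulate(wc_network(1, P = P, params = params), duration_ms)
    tibble(P = P, freq_hz = wc_dominant_frequency(tr),
           regime = wc_regime(tr)[1])
  })
  ok <- grid[!is.na(grid$freq_hz), ]
  if (!nrow(ok)) abort("no oscillating grid point found")
  best <- ok[which.min(abs(ok$freq_hz - target_hz)), ]
  list(P = best$P[[1]], freq_hz = best$freq_hz[[1]], grid = grid)
}

#' Single-oscillator frequency sweep over external input
#'
#' Simulates the single Wilson-Cowan unit across a grid of excitatory
#' inputs and reports the dominant frequency and regime at each point.
#'
#' @inheritParams wc_calibrate_input
#' @return A tibble with columns `P`, `freq_hz`, `regime`.
#' @export
#' @examples
#' \donttest{wc_frequency_sweep(seq(1.2, 3, 0.2))}
wc_frequency_sweep <- function(P_grid = seq(1.2, 3, by = 0.2),
                               duration_ms = 1200, params = wc_params()) {
  purrr::map_dfr(P_grid, function(P) {
    tr <- wc_simulate(wc_network(1, P = P, params = params), duration_ms)
    tibble(P = P, freq_hz = wc_dominant_frequency(tr),
           regime = wc_regime(tr)[1])
  })
}

circuit_band_power <- function(traj, transient_ms = 500,
                               oscillators = NULL) {
  # summed Morlet band power: |W|^2 summed over band rows and oscillators
  if (is.null(oscillators)) oscillators <- seq_len(nrow(traj$E))
  keep <- traj$time_ms > transient_ms
  fs <- 1000 / traj$record_dt
  reg <- wc_regime(traj, transient_ms)
  if (any(reg[oscillators] == "hyper"))
    return(c(beta = NA_real_, gamma = NA_real_))
  b <- 0; g <- 0
  for (k in oscillators) {
    x <- traj$E[k, keep]
    if (diff(range(x)) < 1e-3) next
    tf <- morlet_tf(signal_set(matrix(x, 1), fs), freqs = 13:80)
    gl <- glance(band_power(tf, squared = TRUE, reduce = "sum"))
    b <- b + gl$beta_power
    g <- g + gl$gamma_power
  }
  c(beta = b, gamma = g)
}

#' Sweep the local coupling strength of the CLGF circuit
#'
#' Reproduces the coupled local-and-global feedback analysis: with the
#' global a-b coupling fixed in its beta-dominant 2-node regime, the local
#' a-c coupling is swept over a grid, and at each point the circuit's total
#' beta and gamma band powers (summed Morlet power over the 13-30 Hz and
#' 31-80 Hz rows and over the oscillators) and the beta-band PLV between
#' oscillators a and b are read out. Hyper-excited grid points are
#' reported as `NA` (the regime has no band-limited oscillation).
#'
#' @param w_local_grid Local coupling strengths (default `seq(0, 4, 0.5)`,
#'   9 points).
#' @param w_global Global coupling strength; `NULL` calibrates it with
#'   [wc_calibrate_global()].
#' @param P External input; `NULL` calibrates it with
#'   [wc_calibrate_input()].
#' @param tau_global,tau_local Conduction delays (ms).
#' @param duration_ms Simulation length per grid point (default 6000 ms:
#'   a 500 ms settling span for the coupled attractor plus enough cycles
#'   for the 13 Hz Morlet row, the 1000 ms PLV windows, and averaging
#'   over the intermittency of the locked state).
#' @param oscillators Oscillators entering the summed band powers;
#'   default `1:2` (the coupled a-b pair whose powers and synchrony the
#'   circuit analysis tracks); use `1:3` to include the local partner.
#' @param params `wc_params`.
#' @return An object of class `wc_sweep`: a tibble with columns `w_local`,
#'   `beta_power`, `gamma_power`, `beta_plv_ab`, `regime`, plus attributes
#'   `w_global`, `P`, `crossover` (first oscillating grid point where
#'   gamma power exceeds beta power, `NA` if none).
#' @export
wc_sweep_local <- function(w_local_grid = seq(0, 4, by = 0.5),
                           w_global = NULL, P = NULL,
                           tau_global = 21, tau_local = 6,
                           duration_ms = 6000, oscillators = 1:2,
                           params = wc_params()) {
  if (is.null(P)) P <- wc_calibrate_input(params = params)$P
  if (is.null(w_global))
    w_global <- wc_calibrate_global(P = P, tau_global = tau_global,
                                    params = params)$w_global
  rows <- purrr::map_dfr(w_local_grid, function(wl) {
    net <- wc_circuit(w_global = w_global, w_local = wl,
                      tau_global = tau_global, tau_local = tau_local,
                      P = P, params = params)
    tr <- wc_simulate(net, duration_ms)
    reg <- wc_regime(tr, transient_ms = 500)
    bp <- circuit_band_power(tr, oscillators = oscillators)
    plv_ab <- if (any(reg[1:2] != "limit_cycle")) NA_real_ else {
      keep <- tr$time_ms > 500
      ss <- signal_set(tr$E[1:2, keep, drop = FALSE], 1000 / tr$record_dt)
      ph <- hilbert_phase(bandpass(ss, c(13, 30)))
      m <- plv(ph)$plv
      m[1, 2]
    }
    tibble(w_local = wl, beta_power = bp[["beta"]],
           gamma_power = bp[["gamma"]], beta_plv_ab = plv_ab,
           regime = paste(reg, collapse = "/"))
  })
  osc <- !is.na(rows$beta_power)
  cross <- rows$w_local[osc & rows$gamma_power > rows$beta_power]
  structure(rows, class = c("wc_sweep", class(rows)),
            w_global = w_global, P = P,
            crossover = if (length(cross)) min(cross) else NA_real_)
}

#' Calibrate the global coupling to the beta-dominant 2-node regime
#'
#' Scans the reciprocal a-b coupling strength of the 2-node circuit and
#' picks the grid value with the largest beta/gamma band-power ratio, i.e.
#' the operating point where the long-delay positive feedback loop locks
#' the pair into beta-band oscillation.
#'
#' @param w_grid Candidate strengths (default `seq(1.5, 3.5, 0.25)`).
#' @param P External input.
#' @param tau_global Global delay (ms).
#' @param duration_ms Simulation length per candidate.
#' @param params `wc_params`.
#' @return List with `w_global`, `ratio` (beta/gamma at the optimum), and
#'   the scan table `grid`.
#' @export
wc_calibrate_global <- function(w_grid = seq(1.5, 3.5, by = 0.25), P = 1.4,
                                tau_global = 21, duration_ms = 6000,
                                params = wc_params()) {
  grid <- purrr::map_dfr(w_grid, function(wg) {
    net <- wc_circuit(w_global = wg, w_local = 0, tau_global = tau_global,
                      P = P, n_osc = 2, params = params)
    tr <- wc_simulate(net, duration_ms)
    bp <- circuit_band_power(tr)
    tibble(w_global = wg, beta_power = bp[["beta"]],
           gamma_power = bp[["gamma"]],
           ratio = bp[["beta"]] / bp[["gamma"]])
  })
  ok <- grid[is.finite(grid$ratio), ]
  if (!nrow(ok)) abort("no oscillating candidate in the global-coupling scan")
  best <- ok[which.max(ok$ratio), ]
  list(w_global = best$w_global[[1]], ratio = best$ratio[[1]], grid = grid)
}
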
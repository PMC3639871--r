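colored_noise <- function(n, exponent) {
  # 1/f^exponent power shaping of white Gaussian noise, unit variance
  w <- rnorm(n)
  X <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)           # mirror for the negative frequencies
  X <- X / f^(exponent / 2)
  x <- Re(fft(X, inverse = TRUE)) / n
  (x - mean(x)) / sd(x)
}

noise_exponent <- function(color) {
  switch(color, brown = 2, pink = 1, white = 0,
         abort(paste0("unknown noise color: ", color)))
}

#' Synthesize multichannel signals from a ground-truth topology
#'
#' Every channel is the excitatory output `E(t)` of one Wilson-Cowan
#' oscillator; channels joined by a feedback edge are reciprocally
#' coupled with the edge's conduction lag (the signal model is thus the
#' same dynamical model used in the circuit simulations). Per-channel
#' drive is drawn from `spec$P_range` so uncoupled sensors oscillate at
#' slightly different intrinsic frequencies and dephase, and additive
#' noise (brown, 1/f^2, by default) is scaled relative to the array signal SD.
#'
#' @param topology A [make_topology()] result.
#' @param spec A [cohort_spec()].
#' @param seed Random seed (drive, initial state, noise).
#' @param duration_s,noise Optional overrides of the spec values.
#' @return A `signal_set` (channels x samples at `spec$fs`).
#' @export
synthesize_signals <- function(topology, spec, seed = 1,
                               duration_s = NULL, noise = NULL) {
  stopifnot(inherits(topology, "clgf_topology"),
            inherits(spec, "cohort_spec"))
  if (is.null(duration_s)) duration_s <- spec$duration_s
  if (is.null(noise)) noise <- spec$noise
  if (duration_s <= 0 || spec$fs <= 0)
    abort("duration and rate must be positive")
  dur_ms <- duration_s * 1000
  if (nrow(topology$edges) && any(topology$edges$lag_ms >= dur_ms))
    abort("all lags must be shorter than the record")
  set.seed(seed)
  n <- topology$n_channels
  chans <- topology$region_map$channel
  P <- runif(n, spec$P_range[1], spec$P_range[2])
  E0 <- runif(n, 0.02, 0.3)
  ed <- topology$edges
  wc_edges <- if (nrow(ed)) {
    ia <- match(ed$ch_a, chans)
    ib <- match(ed$ch_b, chans)
    w <- ifelse(ed$type == "global", spec$coupling$global_weight,
                spec$coupling$local_weight) *
         ifelse(ed$sign == "+", 1, -1)
    tibble(from = c(ia, ib), to = c(ib, ia),
           weight = rep(w, 2), delay_ms = rep(ed$lag_ms, 2))
  } else NULL
  net <- wc_network(n, wc_edges, P = P, params = wc_params())
  rec_dt <- 1000 / spec$fs
  traj <- wc_simulate(net, dur_ms, dt = 0.05, record_dt = rec_dt,
                      E0 = E0, I0 = rep(0, n))
  X <- traj$E[, -1, drop = FALSE]        # drop t = 0 sample
  if (noise > 0) {
    sref <- sd(as.vector(X))
    expo <- noise_exponent(spec$noise_color)
    for (k in seq_len(n))
      X[k, ] <- X[k, ] + noise * sref * colored_noise(ncol(X), expo)
  }
  signal_set(X, spec$fs, chans)
}

draw_counts <- function(arch, seed) {
  set.seed(seed)
  C <- rpois(1, arch$clgf)
  L <- C + rpois(1, max(arch$local_fb - arch$clgf, 0))
  hubs_exp <- ceiling(max(arch$clgf, 1) / 4)
  G <- ceiling(max(C, 0) / 4) + rpois(1, max(arch$global_fb - hubs_exp, 0))
  if (C > 0) G <- max(G, 1)
  if (C > 0) L <- max(L, C)
  list(local_fb = L, global_fb = G, clgf = C)
}

clip_feasible <- function(counts, n_channels) {
  # keep the request within the hub capacity of the region partition
  rsize <- vapply(split(seq_len(n_channels),
                        make_region_map(n_channels)$region),
                  length, integer(1))
  caps <- sort(.hub_cap(rsize), decreasing = TRUE)
  m_max <- min(counts$global_fb, length(caps))
  cmax <- if (m_max > 0) sum(caps[seq_len(m_max)]) else 0
  counts$clgf <- min(counts$clgf, cmax, counts$local_fb)
  counts
}

build_feasible <- function(counts, n_channels, seed) {
  # monotone demand reduction: small sensor arrays cannot always host the
  # drawn abundances, so shed extra edges (then motifs) until feasible
  repeat {
    t <- tryCatch(make_topology(counts = counts, seed = seed,
                                n_channels = n_channels),
                  error = function(e) e)
    if (!inherits(t, "error")) return(t)
    if (counts$local_fb > counts$clgf) {
      counts$local_fb <- counts$local_fb - 1
    } else if (counts$clgf > 0) {
      counts$clgf <- counts$clgf - 1
      counts$local_fb <- max(counts$local_fb - 1, counts$clgf)
    } else if (counts$global_fb > 0) {
      counts$global_fb <- counts$global_fb - 1
    } else if (counts$local_fb > 0) {
      counts$local_fb <- counts$local_fb - 1
    } else {
      stop(t)
    }
  }
}

#' Generate a two-group synthetic cohort
#'
#' Draws per-subject motif abundances around the archetype expectations
#' (Poisson counts, feasibility-clipped), builds an exact ground-truth
#' topology per subject, optionally synthesizes the multichannel signals,
#' and attaches synthetic clinical scores. The negative-symptom score is
#' generated, within each group, as
#' `score_mean + score_sd * (r z + sqrt(1 - r^2) eps)` with `z` the
#' standardized CLGF count, so the generating correlation `r`
#' (`spec$score_r`) is recorded and recoverable.
#'
#' @param spec A [cohort_spec()].
#' @param signals Also synthesize the signal sets (set `FALSE` for
#'   topology/score-level studies; the signals are the expensive part).
#' @return A `clgf_cohort`: list with `table` (one row per subject:
#'   group, ground-truth census fields, synthetic PANSS scores),
#'   `topologies`, `signals` (or `NULL`), and the `spec`. The generating
#'   score model is stored in `attr(, "score_model")`.
#' @export
#' @examples
#' coh <- make_cohort(cohort_spec(n_subjects = c(control = 3, patient = 3),
#'                                n_channels = 40, seed = 7), signals = FALSE)
#' coh$table$n_clgf
make_cohort <- function(spec, signals = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(spec$n_subjects < 2)) abort("at least 2 subjects per group")
  groups <- rep(names(spec$n_subjects), spec$n_subjects)
  ids <- sprintf("S%02d", seq_along(groups))
  topo <- vector("list", length(groups))
  sigs <- if (signals) vector("list", length(groups)) else NULL
  rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    sseed <- spec$seed * 10000L + i
    counts <- clip_feasible(draw_counts(spec$archetypes[[groups[i]]], sseed),
                            spec$n_channels)
    topo[[i]] <- build_feasible(counts, spec$n_channels, sseed + 5000L)
    if (signals)
      sigs[[i]] <- synthesize_signals(topo[[i]], spec, seed = sseed + 7000L)
    cen <- count_clgf(topo[[i]]$edges)
    rows[[i]] <- dplyr::bind_cols(tibble(subject_id = ids[i],
                                         group = groups[i]), tidy(cen))
  }
  tab <- dplyr::bind_rows(rows)
  # synthetic clinical scores, generated within group
  set.seed(spec$seed * 10000L + 9999L)
  r <- spec$score_r
  tab$panss_negative <- NA_real_
  for (g in unique(tab$group)) {
    sel <- tab$group == g
    C <- tab$n_clgf[sel]
    z <- if (sd(C) > 0) (C - mean(C)) / sd(C) else rep(0, length(C))
    eps <- rnorm(length(C))
    tab$panss_negative[sel] <- spec$score_mean +
      spec$score_sd * (r * z + sqrt(max(0, 1 - r^2)) * eps)
  }
  tab$panss_positive <- rnorm(nrow(tab), 14, 4)
  tab$panss_general <- rnorm(nrow(tab), 27, 6)
  tab$panss_total <- tab$panss_positive + tab$panss_negative +
    tab$panss_general
  out <- structure(list(table = tab, topologies = topo, signals = sigs,
                        spec = spec),
                   class = "clgf_cohort")
  attr(out, "score_model") <- list(r = r, mean = spec$score_mean,
                                   sd = spec$score_sd)
  out
}

#' @export
print.clgf_cohort <- function(x, ...) {
  cat("<clgf_cohort> ", nrow(x$table), " subjects (",
      paste(sprintf("%s: %d", names(x$spec$n_subjects), x$spec$n_subjects),
            collapse = ", "),
      "), ", x$spec$n_channels, " channels",
      if (is.null(x$signals)) ", topology only" else
        sprintf(", %g s signals @ %g Hz", x$spec$duration_s, x$spec$fs),
      "\n", sep = "")
  invisible(x)
}

#' @export
#' @method as_tibble clgf_cohort
as_tibble.clgf_cohort <- function(x, ...) x$table
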
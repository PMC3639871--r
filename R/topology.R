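#' Cohort specification for the synthetic-data generator
#'
#' Collects the study conditions emulated by the generator: a two-group
#' cohort of multichannel band-limited coupled-oscillator recordings
#' whose ground-truth feedback topology differs between a control-like
#' and a patient-like archetype. The patient-like archetype has strictly
#' fewer local positive feedbacks and CLGF motifs than the control-like
#' one; this is the generator's contract.
#'
#' @param n_subjects Named vector `c(control = ..., patient = ...)`
#'   (defaults 17 and 15, the study group sizes).
#' @param n_channels Number of sensors (default 102).
#' @param duration_s Record length in seconds (default 80).
#' @param fs Sampling rate in Hz (default 1000).
#' @param noise Additive noise SD relative to the signal SD (default
#'   0.5).
#' @param noise_color Spectral shape of the additive noise: `"brown"`
#'   (default, 1/f^2 power, the realistic resting sensor-array background
#'   in the beta/gamma range and the choice that gives the noise floor a
#'   beta-dominant wavelet profile), `"pink"` (1/f), or `"white"`.
#' @param archetypes Per-archetype expected motif abundances: lists with
#'   `local_fb`, `global_fb`, `clgf`.
#' @param coupling Synaptic weights used when wiring topology edges into
#'   the oscillator network (`global_weight`, `local_weight`).
#' @param P_range Per-channel external drive is drawn uniformly from this
#'   range, giving each sensor a slightly different intrinsic frequency
#'   so that uncoupled channels dephase.
#' @param score_r Generating correlation between the CLGF count and the
#'   synthetic negative-symptom score (default -0.5376).
#' @param score_mean,score_sd Location/scale of the negative-symptom
#'   score.
#' @param seed Base random seed; per-subject seeds are fanned out by a
#'   counter.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = c(control = 17, patient = 15),
                        n_channels = 102, duration_s = 80, fs = 1000,
                        noise = 0.5, noise_color = c("brown", "pink", "white"),
                        archetypes = list(
                          control = list(local_fb = 11, global_fb = 5, clgf = 8),
                          patient = list(local_fb = 6, global_fb = 4, clgf = 3)),
                        coupling = list(global_weight = 2.5, local_weight = 1),
                        P_range = c(1.3, 1.5),
                        score_r = -0.5376, score_mean = 16, score_sd = 5,
                        seed = 1) {
  noise_color <- match.arg(noise_color)
  stopifnot(length(n_subjects) == 2, all(n_subjects >= 1))
  if (is.null(names(n_subjects))) names(n_subjects) <- c("control", "patient")
  if (duration_s <= 0 || fs <= 0) abort("duration and rate must be positive")
  if (abs(duration_s * fs - round(duration_s * fs)) > 1e-9)
    abort("duration x rate must give an integer sample count")
  with(archetypes, {
    if (!(patient$local_fb < control$local_fb && patient$clgf < control$clgf))
      abort("patient-like archetype must have strictly fewer local FBs and CLGF motifs")
  })
  structure(list(n_subjects = n_subjects, n_channels = n_channels,
                 duration_s = duration_s, fs = fs, noise = noise,
                 noise_color = noise_color, archetypes = archetypes,
                 coupling = coupling, P_range = P_range,
                 score_r = score_r, score_mean = score_mean,
                 score_sd = score_sd, seed = seed),
            class = "cohort_spec")
}

# maximum locals a single hub in region of size s can carry
.hub_cap <- function(region_sizes) region_sizes - 1L

#' Construct a ground-truth topology with exact motif counts
#'
#' Builds a signed feedback edge set over the sensor array whose census
#' — as counted by [count_clgf()] — equals the requested abundances
#' exactly. CLGF instances are realized by hub channels carrying one
#' global positive feedback and a block of local positive feedbacks;
#' remaining local and global feedbacks are placed on otherwise untouched
#' channels so they contribute no additional motifs. Global lags are
#' drawn uniformly from 15-25 ms and local lags from 6-10 ms.
#'
#' @param spec A [cohort_spec()] (supplies channel count and region map),
#'   or `NULL` with explicit `n_channels`.
#' @param archetype `"control"` or `"patient"`: its abundance parameters
#'   are used as the exact requested counts. Alternatively pass explicit
#'   `counts`.
#' @param seed Random seed for edge placement and lag draws.
#' @param counts Optional list `(local_fb, global_fb, clgf)` overriding
#'   the archetype.
#' @param n_neg_fb Number of negative feedback edges (default 0), placed
#'   disjointly.
#' @param n_channels,region_map Override channel count / region map.
#' @return A `clgf_topology`: list with `edges` (tibble `ch_a`, `ch_b`,
#'   `sign`, `lag_ms`, `type`), `region_map`, `n_channels`.
#' @export
#' @examples
#' topo <- make_topology(counts = list(local_fb = 4, global_fb = 3, clgf = 2),
#'                       n_channels = 40, seed = 1)
#' count_clgf(topo$edges)$n_clgf
make_topology <- function(spec = NULL, archetype = NULL, seed = 1,
                          counts = NULL, n_neg_fb = 0,
                          n_channels = NULL, region_map = NULL) {
  if (is.null(counts)) {
    if (is.null(spec) || is.null(archetype))
      abort("supply either counts or (spec, archetype)")
    counts <- spec$archetypes[[archetype]]
    if (is.null(counts)) abort(paste0("unknown archetype: ", archetype))
  }
  if (is.null(n_channels))
    n_channels <- if (!is.null(spec)) spec$n_channels else 102
  if (is.null(region_map)) region_map <- make_region_map(n_channels)
  L <- counts$local_fb; G <- counts$global_fb; C <- counts$clgf
  stopifnot(L >= 0, G >= 0, C >= 0)
  set.seed(seed)

  regions <- split(region_map$channel, region_map$region)
  rsize <- vapply(regions, length, integer(1))
  if (C > 0 && L < 1)
    abort("infeasible: CLGF motifs requested but no local feedbacks (local_fb)")
  if (C > 0 && G < 1)
    abort("infeasible: CLGF motifs requested but no global feedbacks (global_fb)")
  if (C > L)
    abort("infeasible: clgf exceeds local_fb (each CLGF instance consumes one local feedback)")

  # distribute C locals over m hubs, preferring 4 per hub, capped by region size
  hub_locals <- integer(0)
  if (C > 0) {
    ord <- order(rsize, decreasing = TRUE)
    caps <- .hub_cap(rsize[ord])
    m_max <- min(G, length(regions))
    rem <- C
    for (i in seq_len(m_max)) {
      take <- min(rem, 4L, caps[i])
      if (take > 0) hub_locals <- c(hub_locals, take)
      rem <- rem - take
      if (rem == 0) break
    }
    if (rem > 0) {
      # second pass: grow existing hubs to their caps
      for (i in seq_along(hub_locals)) {
        grow <- min(rem, caps[i] - hub_locals[i])
        hub_locals[i] <- hub_locals[i] + grow
        rem <- rem - grow
        if (rem == 0) break
      }
    }
    if (rem > 0)
      abort(paste0("infeasible: cannot realize ", C, " CLGF motifs with ",
                   G, " global feedbacks over regions of size ",
                   paste(sort(unique(rsize)), collapse = "/"),
                   " (binding constraint: hub capacity)"))
  }
  m <- length(hub_locals)
  hub_regions <- names(regions)[order(rsize, decreasing = TRUE)][seq_len(m)]

  free <- setNames(lapply(regions, identity), names(regions))
  take_from <- function(region, k) {
    if (length(free[[region]]) < k) return(NULL)
    ch <- free[[region]][seq_len(k)]
    free[[region]] <<- free[[region]][-seq_len(k)]
    ch
  }
  glag <- function(k) runif(k, 15, 25)
  llag <- function(k) runif(k, 6, 10)
  edges <- list()

  # reserve every hub block first, then draw the global partners, so a
  # partner draw cannot drain a region that a later hub still needs
  hubs <- character(m)
  for (i in seq_len(m)) {
    r <- hub_regions[i]
    hub <- take_from(r, 1)
    loc <- take_from(r, hub_locals[i])
    if (is.null(hub) || is.null(loc))
      abort(paste0("infeasible: region ", r,
                   " too small for its hub block (binding constraint: region size)"))
    hubs[i] <- hub
    edges[[length(edges) + 1]] <- tibble(
      ch_a = hub, ch_b = loc, sign = "+", lag_ms = llag(length(loc)),
      type = "local")
  }
  for (i in seq_len(m)) {
    r <- hub_regions[i]
    other <- setdiff(names(free), r)
    other <- other[vapply(free[other], length, integer(1)) > 0]
    if (!length(other))
      abort("infeasible: no free channel outside the hub region for its global partner")
    partner <- take_from(sample(other, 1), 1)
    edges[[length(edges) + 1]] <- tibble(
      ch_a = hubs[i], ch_b = partner, sign = "+", lag_ms = glag(1),
      type = "global")
  }

  # remaining local feedbacks: disjoint within-region pairs
  extra_l <- L - C
  for (i in seq_len(extra_l)) {
    cand <- names(free)[vapply(free, length, integer(1)) >= 2]
    if (!length(cand))
      abort("infeasible: not enough free channels for the remaining local feedbacks (binding constraint: channel budget)")
    pr <- take_from(sample(cand, 1), 2)
    edges[[length(edges) + 1]] <- tibble(
      ch_a = pr[1], ch_b = pr[2], sign = "+", lag_ms = llag(1),
      type = "local")
  }

  # remaining global feedbacks: disjoint cross-region pairs
  extra_g <- G - m
  for (i in seq_len(max(0, extra_g))) {
    cand <- names(free)[vapply(free, length, integer(1)) >= 1]
    if (length(cand) < 2)
      abort("infeasible: not enough free channels for the remaining global feedbacks (binding constraint: channel budget)")
    rr <- sample(cand, 2)
    edges[[length(edges) + 1]] <- tibble(
      ch_a = take_from(rr[1], 1), ch_b = take_from(rr[2], 1),
      sign = "+", lag_ms = glag(1), type = "global")
  }

  for (i in seq_len(max(0, n_neg_fb))) {
    cand <- names(free)[vapply(free, length, integer(1)) >= 1]
    if (length(cand) < 2)
      abort("infeasible: not enough free channels for negative feedbacks")
    rr <- sample(cand, 2)
    edges[[length(edges) + 1]] <- tibble(
      ch_a = take_from(rr[1], 1), ch_b = take_from(rr[2], 1),
      sign = "-", lag_ms = glag(1), type = "global")
  }

  ed <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble(ch_a = character(), ch_b = character(), sign = character(),
           lag_ms = numeric(), type = character())
  ed <- structure(ed, class = c("feedback_network", class(ed)))
  structure(list(edges = ed, region_map = region_map,
                 n_channels = n_channels,
                 requested = list(local_fb = L, global_fb = G, clgf = C,
                                  neg_fb = n_neg_fb)),
            class = "clgf_topology")
}

#' @export
print.clgf_topology <- function(x, ...) {
  cen <- count_clgf(x$edges)
  cat("<clgf_topology> ", x$n_channels, " channels, ",
      nrow(x$edges), " edges: ", cen$n_pos_fb_local, " local +FB, ",
      cen$n_pos_fb_global, " global +FB, ", cen$n_neg_fb, " -FB, ",
      cen$n_clgf, " CLGF\n", sep = "")
  invisible(x)
}
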
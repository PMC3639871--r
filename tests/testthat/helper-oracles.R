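# Independent reference implementations used as oracles.

# Literal per-step switching reference: walks the two series sample by
# sample, applying the three trigger conditions and the latch exactly as
# stated, with no vectorization shared with the package implementation.
switching_reference <- function(beta, gamma) {
  n <- length(beta)
  val <- integer(n)
  state <- 0L
  for (t in seq_len(n)) {
    if (state == 1L) {
      if (beta[t] >= gamma[t]) state <- 0L
    }
    if (state == 0L && t >= 2) {
      cond1 <- (beta[t] - beta[t - 1]) < 0
      cond2 <- (gamma[t] - gamma[t - 1]) > 0
      cond3 <- (gamma[t] - beta[t]) > 0
      if (cond1 && cond2 && cond3) state <- 1L
    }
    val[t] <- state
  }
  list(indicator = val, duration = sum(val),
       events = sum(val == 1L & c(0L, val[-n]) == 0L))
}

# Brute-force CLGF census: enumerate unordered channel triples and count
# every valid (hub, global partner, local partner) assignment, using only
# adjacency matrices.
clgf_brute_force <- function(net, channels) {
  nch <- length(channels)
  G <- matrix(FALSE, nch, nch, dimnames = list(channels, channels))
  L <- matrix(FALSE, nch, nch, dimnames = list(channels, channels))
  pos <- net[net$sign == "+", , drop = FALSE]
  for (i in seq_len(nrow(pos))) {
    a <- pos$ch_a[i]; b <- pos$ch_b[i]
    if (pos$type[i] == "global") G[a, b] <- G[b, a] <- TRUE
    else L[a, b] <- L[b, a] <- TRUE
  }
  if (nch < 3) return(0L)
  trip <- utils::combn(nch, 3)
  count <- 0L
  for (j in seq_len(ncol(trip))) {
    t3 <- trip[, j]
    for (h in 1:3) {
      hub <- t3[h]; oth <- t3[-h]
      count <- count + (G[hub, oth[1]] && L[hub, oth[2]]) +
                       (G[hub, oth[2]] && L[hub, oth[1]])
    }
  }
  count
}

# vectorized brute force over a precomputed triple index (for full-size
# networks, where the scalar loop above is too slow)
clgf_brute_force_vec <- function(net, channels, trip) {
  nch <- length(channels)
  G <- matrix(FALSE, nch, nch, dimnames = list(channels, channels))
  L <- matrix(FALSE, nch, nch, dimnames = list(channels, channels))
  pos <- net[net$sign == "+", , drop = FALSE]
  ia <- match(pos$ch_a, channels)
  ib <- match(pos$ch_b, channels)
  gsel <- pos$type == "global"
  G[cbind(ia[gsel], ib[gsel])] <- TRUE; G[cbind(ib[gsel], ia[gsel])] <- TRUE
  L[cbind(ia[!gsel], ib[!gsel])] <- TRUE; L[cbind(ib[!gsel], ia[!gsel])] <- TRUE
  t1 <- trip[1, ]; t2 <- trip[2, ]; t3 <- trip[3, ]
  total <-
    sum(G[cbind(t1, t2)] & L[cbind(t1, t3)]) +
    sum(G[cbind(t1, t3)] & L[cbind(t1, t2)]) +
    sum(G[cbind(t2, t1)] & L[cbind(t2, t3)]) +
    sum(G[cbind(t2, t3)] & L[cbind(t2, t1)]) +
    sum(G[cbind(t3, t1)] & L[cbind(t3, t2)]) +
    sum(G[cbind(t3, t2)] & L[cbind(t3, t1)])
  as.integer(total)
}

# random signed, typed network over n channels without duplicate pairs
random_typed_network <- function(n_edges, n_channels, seed) {
  set.seed(seed)
  rmap <- make_region_map(n_channels)
  pairs <- utils::combn(n_channels, 2)
  pick <- sample(ncol(pairs), min(n_edges, ncol(pairs)))
  net <- tibble::tibble(
    ch_a = rmap$channel[pairs[1, pick]],
    ch_b = rmap$channel[pairs[2, pick]],
    sign = sample(c("+", "-"), length(pick), replace = TRUE, prob = c(0.8, 0.2)))
  classify_edges(net, rmap)
}

# resultant-length of n uniform phases: null mean is sqrt(pi)/2/sqrt(n)
plv_null_mean <- function(n) sqrt(pi) / 2 / sqrt(n)

make_phase_set <- function(phase, fs = 1000, band = NULL) {
  structure(list(phase = phase, fs = fs,
                 channels = sprintf("ch%03d", seq_len(nrow(phase))),
                 band = band),
            class = "phase_set")
}
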
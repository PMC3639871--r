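#' Cortical subregion labels
#'
#' The ten subregions used to classify sensors: pre-frontal,
#' middle-frontal, temporal, parietal, and occipital, in the left and
#' right hemispheres.
#'
#' @return Character vector of 10 labels.
#' @export
region_labels <- function() {
  as.vector(outer(c("prefrontal", "middle-frontal", "temporal",
                    "parietal", "occipital"),
                  c("L", "R"), paste, sep = "-"))
}

#' Build a sensor-to-subregion map
#'
#' Partitions `n_channels` sensors into 10 contiguous blocks labeled with
#' the subregion names. The true magnetometer layout of any particular
#' system is a user input (see [read_region_map()]); this generated map
#' is the synthetic-data default.
#'
#' @param n_channels Number of channels (default 102); block sizes are as
#'   equal as possible.
#' @param channels Optional channel names.
#' @return A tibble with `channel` and `region`.
#' @export
#' @examples
#' table(make_region_map(102)$region)
make_region_map <- function(n_channels = 102, channels = NULL) {
  if (is.null(channels)) channels <- sprintf("ch%03d", seq_len(n_channels))
  labs <- region_labels()
  sizes <- rep(n_channels %/% 10, 10)
  extra <- n_channels %% 10
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  tibble(channel = channels, region = rep(labs, times = sizes))
}

#' Read/write a region map as 2-column delimited text
#' @param path File path.
#' @param rmap A region-map tibble.
#' @return A tibble (`read_region_map`) or the input invisibly.
#' @export
read_region_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("channel", "region") %in% names(tab)))
  as_tibble(tab[, c("channel", "region")])
}

#' @rdname read_region_map
#' @export
write_region_map <- function(rmap, path) {
  utils::write.table(rmap, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(rmap)
}

#' Label feedback edges as local or global
#'
#' An edge is local iff both endpoints lie in the same subregion,
#' otherwise global (inter-regional connections carry the long conduction
#' delay, intra-regional ones the short delay).
#'
#' @param net A `feedback_network` (tibble with `ch_a`, `ch_b`, `sign`).
#' @param rmap Region map tibble (`channel`, `region`).
#' @return The network with `region_a`, `region_b`, and `type`
#'   (`"local"`/`"global"`) columns added.
#' @export
classify_edges <- function(net, rmap) {
  lut <- setNames(rmap$region, rmap$channel)
  missing <- setdiff(unique(c(net$ch_a, net$ch_b)), names(lut))
  if (length(missing))
    abort(paste0("channels not in the region map: ",
                 paste(missing, collapse = ", ")))
  out <- dplyr::mutate(net,
    region_a = unname(lut[.data$ch_a]),
    region_b = unname(lut[.data$ch_b]),
    type = ifelse(.data$region_a == .data$region_b, "local", "global"))
  structure(out, class = unique(c("feedback_network", class(out))))
}

#' Count coupled local-and-global feedback (CLGF) motifs
#'
#' A CLGF instance is an unordered triple (hub `a`, global partner `b`,
#' local partner `c`) where `{a, b}` is a positive global feedback and
#' `{a, c}` a positive local feedback. Because edge type is determined by
#' region membership, `b` (other region) and `c` (same region) are always
#' distinct, so the instance count equals the per-hub product of positive
#' global and local degrees summed over hubs. Both the instance count
#' (default) and the number of participating hubs are reported.
#'
#' @param net A labeled `feedback_network` (see [classify_edges()]); must
#'   carry `sign` and `type` columns.
#' @return A `motif_census`: list with the count fields
#'   (`n_pos_fb_total`, `n_pos_fb_local`, `n_pos_fb_global`, `n_neg_fb`,
#'   `n_clgf`, `n_clgf_hubs`) and the per-hub breakdown tibble `hubs`.
#' @export
#' @examples
#' net <- tibble::tibble(ch_a = c("h", "h"), ch_b = c("g", "l"),
#'                       sign = "+", type = c("global", "local"))
#' count_clgf(net)$n_clgf
count_clgf <- function(net) {
  if (!all(c("sign", "type") %in% names(net)))
    abort("edges must carry 'sign' and 'type' labels; see classify_edges()")
  pos <- net[net$sign == "+", , drop = FALSE]
  chans <- unique(c(net$ch_a, net$ch_b))
  deg <- function(type) {
    e <- pos[pos$type == type, , drop = FALSE]
    tab <- table(factor(c(e$ch_a, e$ch_b), levels = chans))
    as.integer(tab)
  }
  g <- deg("global")
  l <- deg("local")
  hubs <- tibble(channel = chans, n_global = g, n_local = l,
                 n_clgf = g * l)
  hubs <- hubs[hubs$n_clgf > 0, , drop = FALSE]
  structure(list(n_pos_fb_total = nrow(pos),
                 n_pos_fb_local = as.integer(sum(pos$type == "local")),
                 n_pos_fb_global = as.integer(sum(pos$type == "global")),
                 n_neg_fb = as.integer(sum(net$sign == "-")),
                 n_clgf = as.integer(sum(hubs$n_clgf)),
                 n_clgf_hubs = nrow(hubs),
                 hubs = hubs),
            class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat("<motif_census> +FB total ", x$n_pos_fb_total,
      " (local ", x$n_pos_fb_local, ", global ", x$n_pos_fb_global,
      "), -FB ", x$n_neg_fb, ", CLGF ", x$n_clgf,
      " on ", x$n_clgf_hubs, " hub(s)\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy motif_census
tidy.motif_census <- function(x, ...) {
  tibble(n_pos_fb_total = x$n_pos_fb_total,
         n_pos_fb_local = x$n_pos_fb_local,
         n_pos_fb_global = x$n_pos_fb_global,
         n_neg_fb = x$n_neg_fb,
         n_clgf = x$n_clgf,
         n_clgf_hubs = x$n_clgf_hubs)
}

#' Group comparison of motif censuses
#'
#' Welch t tests on each census field between two groups of subjects.
#' Fields with zero variance in both groups and equal means yield
#' `statistic = 0`, `p_value = 1`; degenerate all-zero networks are
#' reported with `NA` statistics and a `degenerate` flag.
#'
#' @param census_a,census_b Lists of `motif_census` objects (one per
#'   subject).
#' @return Tibble with one row per census field.
#' @export
group_motif_stats <- function(census_a, census_b) {
  if (length(census_a) < 2 || length(census_b) < 2)
    abort("each group needs at least 2 subjects")
  A <- purrr::map_dfr(census_a, tidy)
  B <- purrr::map_dfr(census_b, tidy)
  purrr::map_dfr(names(A), function(m) {
    a <- A[[m]]; b <- B[[m]]
    degenerate <- sd(a) == 0 && sd(b) == 0 && mean(a) != mean(b)
    wt <- welch_t(a, b)
    tibble(measure = m,
           mean_a = mean(a), se_a = sd(a) / sqrt(length(a)),
           mean_b = mean(b), se_b = sd(b) / sqrt(length(b)),
           statistic = wt$statistic, df = wt$df, p_value = wt$p_value,
           degenerate = degenerate)
  })
}

#' Export a feedback network to GraphML
#'
#' @param net A `feedback_network`.
#' @param path Output file.
#' @return The input, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(
    dplyr::rename(as_tibble(net), from = "ch_a", to = "ch_b"),
    directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(net)
}

#' Read/write a feedback network as edge-list delimited text
#' @param net A `feedback_network` tibble.
#' @param path File path.
#' @return A tibble (`read_network`) or the input invisibly.
#' @export
write_network <- function(net, path) {
  utils::write.table(as_tibble(net), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(net)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  out <- as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE))
  structure(out, class = c("feedback_network", class(out)))
}
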
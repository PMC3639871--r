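test_that("edges are local within a subregion and global across", {
  rmap <- make_region_map(102)
  net <- tibble::tibble(ch_a = c("ch001", "ch001"),
                        ch_b = c("ch002", "ch100"),
                        sign = "+")
  lab <- classify_edges(net, rmap)
  expect_equal(lab$type, c("local", "global"))
  expect_error(classify_edges(tibble::tibble(ch_a = "zz", ch_b = "ch001",
                                             sign = "+"), rmap), "zz")
})

test_that("label counts on random networks equal an independent recount", {
  rmap <- make_region_map(102)
  lut <- setNames(rmap$region, rmap$channel)
  for (seed in 1:10) {
    net <- random_typed_network(50, 102, seed)
    n_local <- sum(lut[net$ch_a] == lut[net$ch_b])
    expect_equal(sum(net$type == "local"), n_local)
    expect_equal(sum(net$type == "global"), nrow(net) - n_local)
  }
})

test_that("the minimal star motif counts one CLGF instance", {
  net <- tibble::tibble(ch_a = c("hub", "hub"), ch_b = c("far", "near"),
                        sign = "+", type = c("global", "local"))
  cen <- count_clgf(net)
  expect_equal(cen$n_clgf, 1)
  expect_equal(cen$n_clgf_hubs, 1)
  expect_equal(cen$n_pos_fb_total, 2)
})

test_that("instances multiply as global x local per hub", {
  net <- tibble::tibble(
    ch_a = "hub",
    ch_b = c("g1", "g2", "l1", "l2", "l3"),
    sign = "+",
    type = c("global", "global", "local", "local", "local"))
  cen <- count_clgf(net)
  expect_equal(cen$n_clgf, 6)
  expect_equal(clgf_brute_force(net, c("hub", "g1", "g2", "l1", "l2", "l3")), 6)
})

test_that("negative edges contribute nothing to the CLGF census", {
  net <- tibble::tibble(ch_a = c("a", "a"), ch_b = c("b", "c"),
                        sign = "-", type = c("global", "local"))
  cen <- count_clgf(net)
  expect_equal(cen$n_clgf, 0)
  expect_equal(cen$n_neg_fb, 2)
  expect_error(count_clgf(tibble::tibble(ch_a = "a", ch_b = "b", sign = "+")),
               "classify_edges")
})

test_that("census equals exhaustive triple enumeration on random networks", {
  for (seed in 1:12) {
    n_ch <- sample(c(20, 40, 60), 1)
    net <- random_typed_network(sample(20:60, 1), n_ch, seed + 50)
    chans <- make_region_map(n_ch)$channel
    expect_equal(count_clgf(net)$n_clgf, clgf_brute_force(net, chans))
  }
})

test_that("consistent channel relabeling leaves all counts unchanged", {
  net <- random_typed_network(40, 40, 99)
  rmap <- make_region_map(40)
  perm <- setNames(sample(rmap$channel), rmap$channel)
  net2 <- net
  net2$ch_a <- unname(perm[net$ch_a])
  net2$ch_b <- unname(perm[net$ch_b])
  rmap2 <- rmap
  rmap2$channel <- unname(perm[rmap$channel])
  net2 <- classify_edges(net2[, c("ch_a", "ch_b", "sign")], rmap2)
  # types are preserved under the joint relabeling, hence the census is
  expect_equal(tidy(count_clgf(net2)), tidy(count_clgf(net)))
})

test_that("each added local feedback raises the count by the hub's global degree", {
  base <- tibble::tibble(ch_a = "hub", ch_b = c("g1", "g2", "g3"),
                         sign = "+", type = "global")
  for (k in 1:3) {
    locs <- tibble::tibble(ch_a = "hub", ch_b = paste0("l", seq_len(k)),
                           sign = "+", type = "local")
    expect_equal(count_clgf(dplyr::bind_rows(base, locs))$n_clgf, 3 * k)
  }
})

test_that("group census statistics behave at the boundaries", {
  mk <- function(n) count_clgf(tibble::tibble(
    ch_a = rep("h", n), ch_b = paste0("x", seq_len(n)),
    sign = "+", type = rep(c("global", "local"), length.out = n)))
  a <- lapply(c(6, 8, 6, 8), mk)
  b <- lapply(c(2, 4, 2, 4), mk)
  out <- group_motif_stats(a, b)
  clgf_row <- out[out$measure == "n_clgf", ]
  expect_gt(clgf_row$mean_a, clgf_row$mean_b)
  expect_lt(clgf_row$p_value, 0.05)
  same <- group_motif_stats(a, a)
  expect_true(all(same$p_value == 1))
  empty <- lapply(1:3, function(i) count_clgf(
    tibble::tibble(ch_a = character(), ch_b = character(),
                   sign = character(), type = character())))
  degen <- group_motif_stats(a, empty)
  expect_true(any(degen$degenerate))
})

test_that("networks round-trip through edge-list text and export to GraphML", {
  net <- random_typed_network(15, 40, 5)
  p1 <- tempfile(fileext = ".tsv")
  write_network(net, p1)
  back <- read_network(p1)
  expect_equal(back$ch_a, net$ch_a)
  expect_equal(back$sign, net$sign)
  p2 <- tempfile(fileext = ".graphml")
  write_network_graphml(net, p2)
  expect_true(file.size(p2) > 0)
})
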
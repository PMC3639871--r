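test_that("an empty request yields an empty edge set and zero motifs", {
  topo <- make_topology(counts = list(local_fb = 0, global_fb = 0, clgf = 0),
                        n_channels = 40, seed = 1)
  expect_equal(nrow(topo$edges), 0)
  cen <- count_clgf(topo$edges)
  expect_equal(cen$n_clgf, 0)
  expect_equal(cen$n_pos_fb_total, 0)
})

test_that("hub-sharing construction matches brute-force triple enumeration", {
  # one hub carrying 3 globals and 3 locals: 9 hub-sharing pairs
  net <- tibble::tibble(
    ch_a = "ch001",
    ch_b = c("ch020", "ch030", "ch040", "ch002", "ch003", "ch004"),
    sign = "+",
    type = rep(c("global", "local"), each = 3))
  expect_equal(count_clgf(net)$n_clgf, 9)
  expect_equal(clgf_brute_force(net, make_region_map(102)$channel), 9)
})

test_that("construction is deterministic in the seed", {
  a <- make_topology(counts = list(local_fb = 7, global_fb = 4, clgf = 5),
                     n_channels = 60, seed = 11)
  b <- make_topology(counts = list(local_fb = 7, global_fb = 4, clgf = 5),
                     n_channels = 60, seed = 11)
  expect_identical(a$edges, b$edges)
  c2 <- make_topology(counts = list(local_fb = 7, global_fb = 4, clgf = 5),
                      n_channels = 60, seed = 12)
  expect_false(identical(a$edges, c2$edges))
})

test_that("the census of a built topology equals the request exactly", {
  set.seed(20)
  for (i in 1:60) {
    C <- sample(0:10, 1)
    L <- C + sample(0:4, 1)
    G <- max(ceiling(C / 4), 1) + sample(0:3, 1)
    topo <- tryCatch(
      make_topology(counts = list(local_fb = L, global_fb = G, clgf = C),
                    n_channels = 102, seed = i),
      error = function(e) NULL)
    if (is.null(topo)) next
    cen <- count_clgf(topo$edges)
    expect_equal(cen$n_clgf, C)
    expect_equal(cen$n_pos_fb_local, L)
    expect_equal(cen$n_pos_fb_global, G)
    # structural invariants
    expect_true(all(topo$edges$lag_ms > 0))
    expect_true(all(topo$edges$ch_a != topo$edges$ch_b))
    lut <- setNames(topo$region_map$region, topo$region_map$channel)
    expect_equal(topo$edges$type,
                 unname(ifelse(lut[topo$edges$ch_a] == lut[topo$edges$ch_b],
                               "local", "global")))
  }
})

test_that("lags fall in the stated conduction-delay ranges by edge type", {
  topo <- make_topology(counts = list(local_fb = 8, global_fb = 6, clgf = 6),
                        n_channels = 102, seed = 2)
  g <- topo$edges$lag_ms[topo$edges$type == "global"]
  l <- topo$edges$lag_ms[topo$edges$type == "local"]
  expect_true(all(g >= 15 & g <= 25))
  expect_true(all(l >= 6 & l <= 10))
})

test_that("infeasible requests fail with the binding constraint named", {
  expect_error(make_topology(counts = list(local_fb = 3, global_fb = 0,
                                           clgf = 2), n_channels = 40),
               "global")
  expect_error(make_topology(counts = list(local_fb = 0, global_fb = 3,
                                           clgf = 2), n_channels = 40),
               "local")
  expect_error(make_topology(counts = list(local_fb = 2, global_fb = 3,
                                           clgf = 3), n_channels = 40),
               "local_fb")
  # regions of size 1 cannot host any local feedback
  expect_error(make_topology(counts = list(local_fb = 1, global_fb = 1,
                                           clgf = 1), n_channels = 10),
               "constraint")
})

test_that("region maps cover every channel once with the ten labels", {
  rmap <- make_region_map(102)
  expect_equal(nrow(rmap), 102)
  expect_equal(anyDuplicated(rmap$channel), 0)
  expect_setequal(unique(rmap$region), region_labels())
  sizes <- table(rmap$region)
  expect_true(all(sizes %in% c(10, 11)))
  p <- tempfile(fileext = ".tsv")
  write_region_map(rmap, p)
  expect_equal(read_region_map(p), rmap)
})
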
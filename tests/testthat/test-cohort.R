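test_that("default group sizes give a 32-row cohort table", {
  spec <- cohort_spec(n_channels = 102, seed = 2)
  coh <- make_cohort(spec, signals = FALSE)
  expect_equal(nrow(coh$table), 32)
  expect_equal(sum(coh$table$group == "control"), 17)
  expect_equal(sum(coh$table$group == "patient"), 15)
  expect_equal(length(coh$topologies), 32)
})

test_that("a noiseless score model is a perfect line in the CLGF count", {
  spec <- cohort_spec(n_subjects = c(control = 6, patient = 6),
                      n_channels = 102, score_r = -1, seed = 4)
  coh <- make_cohort(spec, signals = FALSE)
  pat <- coh$table[coh$table$group == "patient", ]
  expect_equal(cor(pat$n_clgf, pat$panss_negative), -1, tolerance = 1e-12)
})

test_that("the generating correlation is recovered on average", {
  rs <- vapply(1:200, function(i) {
    spec <- cohort_spec(n_subjects = c(control = 2, patient = 15),
                        n_channels = 102, score_r = -0.5, seed = 4000 + i)
    coh <- make_cohort(spec, signals = FALSE)
    pat <- coh$table[coh$table$group == "patient", ]
    suppressWarnings(cor(pat$n_clgf, pat$panss_negative))
  }, numeric(1))
  expect_equal(mean(rs, na.rm = TRUE), -0.5, tolerance = 0.05)
})

test_that("patient-like cohorts carry fewer CLGF circuits in every replicate", {
  worked <- vapply(1:20, function(i) {
    spec <- cohort_spec(n_subjects = c(control = 8, patient = 8),
                        n_channels = 102, seed = 7000 + i)
    tab <- make_cohort(spec, signals = FALSE)$table
    mean(tab$n_clgf[tab$group == "patient"]) <
      mean(tab$n_clgf[tab$group == "control"])
  }, logical(1))
  expect_true(all(worked))
})

test_that("cohort generation is deterministic given the spec", {
  spec <- cohort_spec(n_subjects = c(control = 3, patient = 3),
                      n_channels = 40, duration_s = 2, seed = 99)
  a <- make_cohort(spec, signals = TRUE)
  b <- make_cohort(spec, signals = TRUE)
  expect_identical(a$table, b$table)
  expect_identical(a$signals[[1]]$data, b$signals[[1]]$data)
})

test_that("the spec enforces its own contracts", {
  expect_error(cohort_spec(n_subjects = c(control = 3, patient = 3),
                           duration_s = -1), "positive")
  expect_error(cohort_spec(archetypes = list(
    control = list(local_fb = 5, global_fb = 3, clgf = 3),
    patient = list(local_fb = 6, global_fb = 3, clgf = 4))),
    "strictly fewer")
  expect_error(make_cohort(cohort_spec(n_subjects = c(control = 1, patient = 5),
                                       n_channels = 40), signals = FALSE),
               "at least 2")
})

test_that("synthesized channels are oscillators that dephase when uncoupled", {
  spec <- cohort_spec(n_subjects = c(control = 2, patient = 2),
                      n_channels = 10, duration_s = 6, noise = 0, seed = 21)
  topo <- make_topology(counts = list(local_fb = 0, global_fb = 0, clgf = 0),
                        n_channels = 10, seed = 5)
  ss <- synthesize_signals(topo, spec, seed = 6)
  expect_equal(dim(ss$data), c(10, 6000))
  # all channels oscillate
  expect_true(all(apply(ss$data[, 2000:6000], 1, sd) > 0.01))
  # independence: mean pairwise PLV in the oscillation band stays near
  # chance (distinct intrinsic frequencies drift apart)
  ph <- hilbert_phase(bandpass(ss, c(80, 120)))
  p <- plv(ph, 1000, 200, edge_exclude_ms = 300)
  expect_lt(glance(p)$mean_plv, 0.35)
  expect_lt(median(p$plv[upper.tri(p$plv)]), 0.2)
})

test_that("a reciprocally coupled pair stands out in beta-band synchrony", {
  spec <- cohort_spec(n_subjects = c(control = 2, patient = 2),
                      n_channels = 10, duration_s = 6, noise = 0, seed = 22)
  topo <- make_topology(counts = list(local_fb = 0, global_fb = 1, clgf = 0),
                        n_channels = 10, seed = 7)
  ss <- synthesize_signals(topo, spec, seed = 8)
  ph <- hilbert_phase(bandpass(ss, c(13, 30)))
  p <- plv(ph, 1000, 200, edge_exclude_ms = 300)
  e <- topo$edges[1, ]
  coupled <- p$plv[e$ch_a, e$ch_b]
  others <- p$plv[upper.tri(p$plv)]
  others <- others[others != coupled]
  expect_gt(coupled, median(others))
  expect_gt(coupled, 0.7)
})

test_that("identical seeds reproduce signals bit for bit; noise respects the dial", {
  spec <- cohort_spec(n_subjects = c(control = 2, patient = 2),
                      n_channels = 6, duration_s = 2, noise = 0.5, seed = 1)
  topo <- make_topology(counts = list(local_fb = 0, global_fb = 1, clgf = 0),
                        n_channels = 6, seed = 2)
  a <- synthesize_signals(topo, spec, seed = 3)
  b <- synthesize_signals(topo, spec, seed = 3)
  expect_identical(a$data, b$data)
  quiet <- synthesize_signals(topo, spec, seed = 3, noise = 0)
  expect_false(identical(a$data, quiet$data))
  expect_error(synthesize_signals(topo, spec, seed = 3, duration_s = -2),
               "positive")
})

test_that("switching duration is reduced in patient-like cohorts", {
  direction <- vapply(1:6, function(cid) {
    sp <- cohort_spec(n_subjects = c(control = 3, patient = 3),
                      n_channels = 30, duration_s = 8, seed = 200 + cid)
    coh <- make_cohort(sp, signals = TRUE)
    dur <- vapply(coh$signals, function(ss)
      detect_switching(band_power(morlet_tf(ss)))$duration_ms, numeric(1))
    mean(dur[coh$table$group == "control"]) >
      mean(dur[coh$table$group == "patient"])
  }, logical(1))
  expect_gte(sum(direction), 4)  # majority of cohorts
})
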
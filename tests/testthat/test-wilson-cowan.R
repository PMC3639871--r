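test_that("undriven uncoupled oscillator decays to the quiescent fixed point", {
  tr <- wc_simulate(wc_network(1, P = 0), duration_ms = 800)
  expect_equal(wc_regime(tr), "fixed_point")
  tail_E <- tr$E[1, tr$time_ms > 600]
  expect_lt(max(abs(tail_E)), 1e-3)
  expect_true(is.na(wc_dominant_frequency(tr)))
})

test_that("driven oscillator holds a limit cycle in the stated frequency band", {
  for (P in c(1.4, 2.0, 2.6)) {
    tr <- wc_simulate(wc_network(1, P = P), duration_ms = 1200)
    expect_equal(wc_regime(tr), "limit_cycle")
    f <- wc_dominant_frequency(tr)
    expect_gte(f, 80)
    expect_lte(f, 150)
  }
})

test_that("over-driven oscillator is flagged hyper-excited, not oscillating", {
  tr <- wc_simulate(wc_network(1, P = 4), duration_ms = 800)
  expect_equal(wc_regime(tr), "hyper")
  expect_true(is.na(wc_dominant_frequency(tr)))
})

test_that("halving the step changes the trajectory by less than 1e-4", {
  net <- wc_network(1, P = 1.4)
  a <- wc_simulate(net, 500, dt = 0.05, record_dt = 1)
  b <- wc_simulate(net, 500, dt = 0.025, record_dt = 1)
  expect_lt(max(abs(a$E - b$E)), 1e-4)
})

test_that("zero-coupling circuit decouples into independent oscillators", {
  net3 <- wc_circuit(w_global = 0, w_local = 0, P = 1.4, n_osc = 3)
  tr3 <- wc_simulate(net3, 1000)
  E0 <- c(0.2, 0.05, 0.1)
  for (k in 1:3) {
    tr1 <- wc_simulate(wc_network(1, P = 1.4), 1000,
                       E0 = E0[k], I0 = 0)
    expect_lt(max(abs(tr3$E[k, ] - tr1$E[1, ])), 1e-10)
  }
})

test_that("swapping the b and c roles with their couplings leaves band powers unchanged", {
  # oscillators 2 and 3 are exchangeable when their couplings and delays
  # are exchanged with them
  ed1 <- tibble::tibble(from = c(1L, 2L, 1L, 3L), to = c(2L, 1L, 3L, 1L),
                        weight = c(2, 2, 1, 1), delay_ms = c(21, 21, 6, 6))
  ed2 <- tibble::tibble(from = c(1L, 3L, 1L, 2L), to = c(3L, 1L, 2L, 1L),
                        weight = c(2, 2, 1, 1), delay_ms = c(21, 21, 6, 6))
  E0 <- c(0.2, 0.05, 0.1)
  tr1 <- wc_simulate(wc_network(3, ed1, P = 1.4), 1500, E0 = E0)
  tr2 <- wc_simulate(wc_network(3, ed2, P = 1.4), 1500,
                     E0 = E0[c(1, 3, 2)])
  expect_equal(tr1$E[2, ], tr2$E[3, ], tolerance = 1e-12)
  expect_equal(tr1$E[3, ], tr2$E[2, ], tolerance = 1e-12)
})

test_that("simulation is deterministic and validates its inputs", {
  net <- wc_network(2, tibble::tibble(from = 1L, to = 2L, weight = 1,
                                      delay_ms = 10), P = 1.4)
  a <- wc_simulate(net, 300)
  b <- wc_simulate(net, 300)
  expect_identical(a$E, b$E)
  expect_error(wc_simulate(net, -5), "positive")
  expect_error(wc_simulate(net, 300, dt = 0.5), "dt")
  expect_error(wc_network(2, tibble::tibble(from = 1L, to = 1L, weight = 1,
                                            delay_ms = 5)), "self")
  expect_error(wc_network(2, tibble::tibble(from = 1L, to = 2L, weight = 1,
                                            delay_ms = 0)), "positive")
})

test_that("dominant frequency recovers a known injected oscillation", {
  t <- seq(0, 1999, by = 1)
  fake <- structure(list(E = rbind(sin(2 * pi * 0.1 * t)),  # 100 Hz at 1 ms steps
                         I = rbind(0 * t), time_ms = t,
                         dt = 0.05, record_dt = 1),
                    class = "wc_trajectory")
  # the post-transient segment is 1799 samples, so the periodogram grid
  # resolves to ~0.56 Hz
  expect_lt(abs(wc_dominant_frequency(fake) - 100), 0.6)
})

test_that("input calibration picks the grid point nearest 100 Hz", {
  cal <- wc_calibrate_input(P_grid = seq(1.2, 2.0, by = 0.2),
                            duration_ms = 1000)
  expect_true(cal$P %in% seq(1.2, 2.0, by = 0.2))
  gap <- abs(cal$grid$freq_hz - 100)
  expect_equal(abs(cal$freq_hz - 100), min(gap, na.rm = TRUE))
})
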
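test_that("free calcium follows the single-spike closed form", {
  ca <- ca0
  grid <- seq(0, 5, by = 0.01)
  # no stimulation: resting concentration everywhere
  expect_equal(free_calcium(periodic_train(0, 5), ca, grid),
               rep(ca$ca_rest, length(grid)))
  # single spike at t0: excess resets to delta and decays with tau_ca
  st <- spike_train(1, 5)
  expect_equal(free_calcium(st, ca, 1 + ca$tau_ca),
               ca$ca_rest + ca$delta_ca_ap / exp(1), tolerance = 1e-12)
  # before the spike the trace is exactly at rest
  expect_equal(free_calcium(st, ca, c(0, 0.5, 0.999)),
               rep(ca$ca_rest, 3))
  # calibrated tau_ca: the transient has decayed by >= 95% after ~100 ms
  excess <- free_calcium(st, ca, 1.1) - ca$ca_rest
  expect_lte(excess, 0.05 * ca$delta_ca_ap + 1e-12)
  # free calcium never drops below rest
  tr <- poisson_train(20, 5, seed = 2)
  expect_true(all(free_calcium(tr, ca, grid) >= ca$ca_rest))
  expect_length(free_calcium(tr, ca, numeric(0)), 0)
})

test_that("reset and superposition modes differ only after closely spaced spikes", {
  st <- spike_train(c(1, 1.01), 3)
  ca_reset <- ca0
  ca_add <- calcium_params(accumulate = TRUE)
  t_probe <- 1.02
  v_reset <- free_calcium(st, ca_reset, t_probe)
  v_add <- free_calcium(st, ca_add, t_probe)
  expect_gt(v_add, v_reset)  # superposition keeps the residual excess
  # far from spikes both agree to the residual of the earlier spike
  expect_equal(free_calcium(st, ca_reset, 0.5),
               free_calcium(st, ca_add, 0.5))
})

test_that("total calcium increment is the buffered per-spike load", {
  expect_equal(total_calcium_increment(
    calcium_params(delta_ca_ap = 0.5, ks = 99, kb_prime = 0,
                   threshold = 20)), 50)
  base <- calcium_params(delta_ca_ap = 25, ks = 0, kb_prime = 0)
  expect_equal(total_calcium_increment(base), 25)
  # nondecreasing in both binding ratios
  expect_gte(total_calcium_increment(calcium_params(delta_ca_ap = 25, ks = 1)),
             total_calcium_increment(base))
  expect_gte(total_calcium_increment(
    calcium_params(delta_ca_ap = 25, kb_prime = 2)),
    total_calcium_increment(base))
  expect_error(calcium_params(threshold = 10), "20, 50")
  expect_error(calcium_params(threshold = 60), "20, 50")
})

test_that("release windows have the analytic length and merge when spikes crowd", {
  # sub-threshold load: empty gate plus a warning about the silent synapse
  sub <- calcium_params(delta_ca_ap = 0.1, ks = 0, kb_prime = 0)
  expect_warning(g <- release_windows(periodic_train(4, 10), sub), "silent")
  expect_equal(nrow(g), 0)
  expect_silent(release_windows(periodic_train(0, 10), sub))

  # load = e * threshold: window length exactly tau_total
  ca_e <- calcium_params(delta_ca_ap = 20 * exp(1), ks = 0, threshold = 20,
                         tau_total = 0.07, latency = 0)
  g1 <- release_windows(spike_train(1, 5), ca_e)
  expect_equal(unname(g1[1, 2] - g1[1, 1]), 0.07, tolerance = 1e-12)

  # 100 Hz with window length >= inter-spike interval: one merged window
  g100 <- release_windows(periodic_train(100, 2), ca0)
  expect_equal(nrow(g100), 1)
})

test_that("gate occupancy matches a brute-force oracle and is monotone in load", {
  tr <- poisson_train(6, 5, seed = 9)
  gate <- release_windows(tr, ca0)
  tw <- attr(gate, "window_length")
  start <- tr$times + ca0$latency
  probe <- seq(0, 6, by = 7e-4)
  oracle <- rep(FALSE, length(probe))
  for (s in start) oracle[probe >= s & probe < s + tw] <- TRUE
  expect_equal(gate_open_at(gate, probe), oracle)
  # windows are sorted and non-overlapping
  expect_true(all(diff(as.vector(t(gate))) > 0))

  # total open time: nondecreasing in delta_ca_ap, nonincreasing in threshold
  ot <- function(delta, thr) {
    ca <- calcium_params(delta_ca_ap = delta, ks = 99, threshold = thr)
    gate_open_time(suppressWarnings(release_windows(tr, ca)))
  }
  expect_true(all(diff(sapply(c(0.5, 1, 2, 4), ot, thr = 20)) >= 0))
  expect_true(all(diff(sapply(c(20, 30, 45), function(th) ot(2, th))) <= 0))

  # determinism: same train and parameters give the identical gate
  expect_identical(release_windows(tr, ca0),
                   release_windows(tr, ca0))
})

test_that("calcium trace export writes a consistent CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  tr <- periodic_train(4, 2)
  df <- export_calcium_trace(tr, ca0, f, dt = 0.01)
  expect_true(file.exists(f))
  expect_named(df, c("time", "ca_free", "ca_total_excess", "gate_open"))
  expect_true(any(df$gate_open))
  expect_true(all(df$ca_free >= ca0$ca_rest))
})
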
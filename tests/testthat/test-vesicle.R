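test_that("a fresh synapse starts full, unprepared and conserved", {
  st <- init_cycle_state(syn0)
  expect_equal(st$pool, syn0$n_total - syn0$n_rrp)
  expect_equal(st$released, 0)
  expect_true(all(st$s == 0))
  expect_true(check_conservation(st, syn0))
  dep <- init_cycle_state(syn0, depleted = TRUE)
  expect_equal(dep$pool, 0)
  expect_true(check_conservation(dep, syn0))
})

test_that("parameter validation enforces the physiological structure", {
  expect_error(synapse_params(n_rrp = 5), "5-10%")
  expect_error(synapse_params(n_rrp = 40), "5-10%")
  expect_error(synapse_params(tau_s = -1), "tau_s")
  expect_error(synapse_params(prep_fraction = 1.2), "prep_fraction")
  # the stated per-site and synapse caps are jointly inconsistent: surfaced
  expect_message(synapse_params(site_max_rate = 3.5), "per-site")
  expect_silent(p <- synapse_params())
  expect_equal(p$h_m, 190)
})

test_that("single steps release only when gated and keep the ledgers", {
  st <- init_cycle_state(syn0)
  expect_error(cycle_step(st, 0, TRUE, syn0), "dt")
  # gate closed: preparation advances but nothing releases
  st1 <- cycle_step(st, 0.5, FALSE, syn0)
  expect_equal(st1$released, 0)
  expect_equal(st1$pool, syn0$h_m)
  expect_true(all(st1$s > 0.99))  # 0.5 s = 10 tau_s of preparation
  # one prepared vesicle, one step with the gate open: exactly one release
  st1$s <- c(1, rep(0, syn0$n_rrp - 1))
  st2 <- cycle_step(st1, 0.001, TRUE, syn0)
  expect_equal(st2$released, 1)
  expect_equal(st2$in_transit, 1)
  expect_true(check_conservation(st2, syn0))
  # empty pool, nothing in transit: return pipeline is idle
  dep <- init_cycle_state(syn0, depleted = TRUE)
  dep$in_transit <- 0L
  dep$occupied <- rep(TRUE, syn0$n_rrp)  # vesicles parked in the RRP
  expect_error(check_conservation(dep, syn0))  # deliberately broken
})

test_that("vesicle conservation and the return cap hold along whole runs", {
  for (seed in 1:3) {
    tr <- poisson_train(8, 30, seed)
    traj <- simulate_synapse(tr, syn0, ca0, duration = 35)
    expect_true(check_conservation(traj$state, syn0))
    expect_true(all(traj$pool >= 0 & traj$pool <= syn0$h_m))
    expect_true(all(traj$v_r <= syn0$v_rm + 1e-9))
    expect_equal(traj$state$released,
                 traj$state$returned + traj$state$in_transit)
  }
  # and with a non-default parameterization
  alt <- synapse_params(n_total = 100, n_rrp = 8, n_sites = 3,
                        tau_s = 0.2, site_max_rate = 2, synapse_max_rate = 6,
                        v_rm = 5, tau_r = 3)
  traj <- simulate_synapse(periodic_train(10, 20), alt, ca0)
  expect_true(check_conservation(traj$state, alt))
  expect_true(all(traj$v_r <= alt$v_rm + 1e-9))
})

test_that("releases happen only inside gate windows and respect both caps", {
  tr <- periodic_train(4, 50)
  traj <- simulate_synapse(tr, syn0, ca0)
  gate <- traj$gate
  # each release time lies in an open window (up to one step of quantization)
  expect_true(all(gate_open_at(gate, traj$release_times + traj$dt) |
                  gate_open_at(gate, traj$release_times)))
  # synapse cap: at most synapse_max_rate releases in any sliding 1-s window
  rel <- traj$release_times
  counts <- vapply(rel, function(t0) sum(rel >= t0 & rel < t0 + 1), 0)
  expect_lte(max(counts), syn0$synapse_max_rate)
  # per-site cap cannot be exceeded in aggregate
  expect_lte(length(rel) / tr$duration,
             syn0$n_sites * syn0$site_max_rate)
})

test_that("the preparation update is exactly exponential at any step size", {
  # closed form: s(t) = s_m (1 - exp(-t/tau_s)) from s = 0, no releases
  target <- syn0$s_m * (1 - exp(-0.2 / syn0$tau_s))
  one <- cycle_step(init_cycle_state(syn0), 0.2, FALSE, syn0)
  many <- Reduce(function(st, .) cycle_step(st, 0.01, FALSE, syn0),
                 1:20, init_cycle_state(syn0))
  expect_equal(one$s[1], target, tolerance = 1e-14)
  expect_equal(many$s[1], target, tolerance = 1e-13)
  expect_equal(one$s, many$s, tolerance = 1e-13)
})

test_that("release counts are insensitive to the integration step", {
  tr <- periodic_train(4, 50)
  n1 <- length(simulate_synapse(tr, syn0, ca0, dt = 1e-3)$release_times)
  n2 <- length(simulate_synapse(tr, syn0, ca0, dt = 5e-4)$release_times)
  expect_lt(abs(n1 - n2) / n1, 0.02)
})

test_that("steady-state pool occupancy matches the closed form h* = h_m - vs*tau_r", {
  # constant sub-cap demand: continuous gate (100 Hz) with a low synapse cap
  syn <- synapse_params(synapse_max_rate = 8, site_max_rate = 4)
  traj <- simulate_synapse(periodic_train(100, 60), syn, ca0)
  sel <- traj$time > 40
  expect_equal(mean(traj$v_s[sel]), 8, tolerance = 0.02)
  h_star <- syn$h_m - 8 * syn$tau_r
  expect_lt(abs(mean(traj$pool[sel]) - h_star), 1)
})

test_that("unconstrained steady rates and release probabilities are reproduced", {
  traj4 <- simulate_synapse(periodic_train(4, 60), syn0, ca0)
  expect_equal(leaving_rate(traj4), 17, tolerance = 0.02)
  expect_equal(release_probability(traj4), 0.85, tolerance = 0.02)
  traj100 <- simulate_synapse(periodic_train(100, 60), syn0, ca0)
  expect_equal(leaving_rate(traj100), 20, tolerance = 0.02)
  expect_equal(release_probability(traj100), 0.04, tolerance = 0.02)
})

test_that("release probability is monotone in preparation speed and drive", {
  tr <- periodic_train(4, 60)
  rp <- vapply(c(0.3, 0.6, 1.2),
               function(ts) release_probability(
                 simulate_synapse(tr, syn0, ca0, tau_s = ts)), 0)
  expect_true(all(diff(rp) < 0))
  rp_f <- vapply(c(4, 20, 100),
                 function(f) release_probability(
                   simulate_synapse(periodic_train(f, 60), syn0,
                                    ca0)), 0)
  expect_true(all(diff(rp_f) < 0))
})

test_that("release probability handles edge cases", {
  tr <- periodic_train(4, 10)
  # silent synapse: zero releases give rp = 0
  sub <- calcium_params(delta_ca_ap = 0.1, ks = 0)
  traj <- suppressWarnings(simulate_synapse(tr, syn0, sub))
  expect_equal(release_probability(traj), 0)
  expect_error(release_probability(traj, train = periodic_train(0, 10)),
               "empty")
  # a single-site synapse can exceed one vesicle per spike: flagged abnormal
  one_site <- synapse_params(n_sites = 1, site_max_rate = 20)
  slow <- periodic_train(0.5, 60)
  traj1 <- simulate_synapse(slow, one_site, ca0)
  expect_warning(rp1 <- release_probability(traj1), "abnormal")
  expect_gt(rp1, 1)
})

test_that("transmission energy is the exact per-vesicle product", {
  expect_equal(transmission_energy(0, syn0), 0)
  expect_equal(transmission_energy(10, syn0), 1.64e6)
  expect_equal(transmission_energy(5, syn0), 8.2e5)  # 5 vesicles/s for 1 s
  expect_error(transmission_energy(-1, syn0), "release_count")
})

test_that("the depleted pool refills exponentially and the fit recovers tau", {
  curve <- recovery_curve(syn0, 40)
  expect_equal(curve$pool[1], 0, tolerance = 2)  # starts empty
  expect_true(all(diff(curve$pool) >= 0))        # monotone refill
  expect_gt(utils::tail(curve$pool, 1), 0.99 * syn0$h_m)
  # uncapped regime: the closed form h_m (1 - exp(-t/tau_r)) holds
  free <- synapse_params(v_rm = 1000)
  cf <- recovery_curve(free, 30)
  expect_lt(max(abs(cf$pool - free$h_m * (1 - exp(-cf$time / free$tau_r)))),
            1.5)
  # self-consistency: a synthetic curve generated at tau = 6.5 fits back
  t <- seq(0.5, 40, by = 0.5)
  synth <- data.frame(time = t, pool = 190 * (1 - exp(-t / 6.5)))
  expect_equal(fit_recovery_tau(synth, 190), 6.5, tolerance = 0.01)
  # robust to additive measurement noise (sigma = 2 vesicles)
  set.seed(42)
  taus <- replicate(20, fit_recovery_tau(
    data.frame(time = t, pool = 190 * (1 - exp(-t / 6.5)) + rnorm(length(t), 0, 2)),
    190))
  expect_true(all(abs(taus - 6.5) / 6.5 < 0.1))
  # degenerate curves are rejected
  expect_error(fit_recovery_tau(data.frame(time = t, pool = rep(5, length(t))),
                                190), "flat")
  expect_error(fit_recovery_tau(data.frame(time = t,
                                           pool = rev(synth$pool)), 190),
               "monotone")
  expect_error(fit_recovery_tau(synth[1:5, ], 190), "10 samples")
})

test_that("after stimulation ends the pool recovers toward capacity", {
  tr <- periodic_train(100, 20)
  traj <- simulate_synapse(tr, syn0, ca0, duration = 60)
  during <- traj$pool[traj$time > 15 & traj$time <= 20]
  after <- utils::tail(traj$pool, 1)
  expect_lt(min(during), 0.6 * syn0$h_m)   # drawn down under load
  expect_gt(after, 0.97 * syn0$h_m)        # recovered after the train
})

test_that("trajectories export with consistent energy accounting", {
  f <- withr::local_tempfile(fileext = ".csv")
  traj <- simulate_synapse(periodic_train(4, 10), syn0, ca0)
  df <- export_trajectory(traj, f)
  expect_equal(sum(df$energy_atp),
               transmission_energy(length(traj$release_times), syn0))
})
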
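test_that("the energy objective is the symmetric absolute mismatch", {
  expect_equal(objective_energy(8.2e5, 8.2e5), 0)
  expect_equal(objective_energy(0, 8.2e5), 8.2e5)
  expect_equal(objective_energy(3e5, 9e5), objective_energy(9e5, 3e5))
})

test_that("tau updates are sigmoid-bounded with the correct sign", {
  # balanced energy: no change
  expect_equal(tau_update(0.5, 1e6, 1e6, 0.1), 0.5)
  # surplus of ~6 vesicle-equivalents: increment approaches +lambda (slows)
  up <- tau_update(0.5, 2e6, 1e6, 0.1)
  expect_gt(up, 0.5)
  expect_lt(up, 0.6)                       # strictly below tau + lambda
  expect_equal(up, 0.6, tolerance = 1e-2)  # but saturating toward it
  # symmetric deficit: increment approaches -lambda (cycle speeds up)
  dn <- tau_update(0.5, 0, 1e6, 0.1)
  expect_lt(dn, 0.5)
  expect_gt(dn, 0.4)
  expect_equal((up - 0.5) + (dn - 0.5), 0, tolerance = 1e-3)  # sign-symmetric
  # the increment magnitude never exceeds lambda_k, for any imbalance
  for (ea in c(0, 1e4, 1e6, 1e9))
    expect_lt(abs(tau_update(1, ea, 8.2e6, 0.05) - 1), 0.05 + 1e-12)
  # bounds clip the result
  expect_equal(tau_update(0.01, 0, 1e6, 0.1, bounds = c(0.005, 10)), 0.005)
  expect_equal(tau_update(9.99, 1e9, 1e6, 0.1, bounds = c(0.005, 10)), 10)
  expect_error(tau_update(0.5, 1, 1, 0), "lambda_k")
})

test_that("regulation converges to the desired energy level at 4 Hz", {
  reg <- regulation_params(e_desired = 8.2e5)
  run <- simulate_regulated(periodic_train(4, 500), syn0, ca0, reg)
  tr <- run$trace
  # fast cycle at the start: well over 100 vesicles leave in window 1
  expect_gt(tr$leaving[1], 100)
  # tau_s rises from the fast unconstrained value toward ~1 s
  expect_gt(utils::tail(tr$tau_s, 1), 10 * tr$tau_s[1])
  # per-window tau_s steps bounded by lambda_k
  expect_true(all(abs(diff(tr$tau_s)) <= tr$lambda[-nrow(tr)] + 1e-12))
  ss <- steady_state(run)
  expect_lt(ss$objective_rel, 0.1)
  expect_equal(ss$leaving_per_window, 50, tolerance = 0.05)
  expect_true(ss$rp >= 0.24 && ss$rp <= 0.51)  # the optimal band
})

test_that("persistent energy imbalance drives tau_s monotonically", {
  # desired far above anything attainable: tau_s never increases
  rich <- regulation_params(e_desired = 1e8)
  run_rich <- simulate_regulated(periodic_train(4, 200), syn0, ca0,
                                 rich)
  expect_true(all(diff(run_rich$trace$tau_s) <= 1e-12))
  # desired far below consumption even at the slowest cycle: never decreases
  poor <- regulation_params(e_desired = 1e3)
  run_poor <- simulate_regulated(periodic_train(4, 200), syn0, ca0,
                                 poor)
  expect_true(all(diff(run_poor$trace$tau_s) >= -1e-12))
})

test_that("a setpoint at the unconstrained consumption is a fixed point", {
  # unconstrained 4 Hz consumes 17 vesicles/s = 17 * 1.64e5 ATP/s; with the
  # setpoint there, consumption and tau_s stay at their unconstrained values
  # (tau_s may wander within the slack region where supply still exceeds the
  # caps, but never into the supply-limited regime that would cut the rate)
  reg <- regulation_params(e_desired = 17 * 1.64e5)
  run <- simulate_regulated(periodic_train(4, 200), syn0, ca0, reg)
  expect_true(all(abs(run$trace$leaving - 170) <= 2))
  expect_true(all(run$trace$objective <= 2 * syn0$atp_per_vesicle))
  expect_lt(max(run$trace$tau_s), 0.3)
})

test_that("steady release probability is nondecreasing in the energy level", {
  rp <- vapply(c(2e5, 8.2e5, 2e6), function(e) {
    run <- simulate_regulated(periodic_train(4, 400), syn0, ca0,
                              regulation_params(e_desired = e))
    steady_state(run)$rp
  }, 0)
  expect_true(all(diff(rp) > 0))
})

test_that("the loop adapts to repeated Gaussian-frequency episodes", {
  sch <- gaussian_episode_schedule(4, 1, 50, 10, seed = 5)
  reg <- regulation_params(e_desired = 8.2e5)
  run <- simulate_regulated(sch, syn0, ca0, reg)
  tr <- run$trace
  n <- nrow(tr)
  expect_equal(n, 50)  # 10 episodes x 50 s / 10-s windows
  # the mismatch shrinks as the synapse adapts
  expect_lt(mean(tr$objective[(n - 9):n]), 0.3 * mean(tr$objective[1:5]))
  expect_gt(utils::tail(tr$tau_s, 1), tr$tau_s[1])
})

test_that("regulated runs keep vesicle accounting intact across windows", {
  reg <- regulation_params(e_desired = 5e5)
  run <- simulate_regulated(periodic_train(4, 100), syn0, ca0, reg)
  expect_true(check_conservation(run$state, syn0))
  expect_equal(sum(run$trace$leaving), length(run$release_times))
  expect_error(simulate_regulated(periodic_train(0, 100), syn0,
                                  ca0, reg), "empty")
})
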
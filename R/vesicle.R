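#' Synapse kinetic parameters
#'
#' Parameters of the vesicle-cycle model of a single excitatory synapse.
#' A synapse holds `n_total` vesicles split between a recycling pool of
#' capacity `h_m = n_total - n_rrp` and a readily releasable pool (RRP) of
#' `n_rrp` slots. Each RRP vesicle carries a preparation state that relaxes
#' exponentially from 0 toward `s_m` with time constant `tau_s`; it counts
#' as prepared once it reaches `prep_fraction * s_m`. Prepared vesicles
#' release through `n_sites` release sites while the calcium gate is open,
#' subject to a per-site refractory period `1/site_max_rate` and a
#' synapse-level minimum spacing of `1/synapse_max_rate` of *gate-open*
#' time. Released vesicles return to the recycling pool at rate
#' `min(v_rm, (h_m - h)/tau_r)`.
#'
#' Defaults are the package's calibrated profile: 200 vesicles, 10 RRP
#' slots (5%), 5 sites, synapse cap 20 vesicles/s split evenly across sites
#' (4/s each), preparation threshold at two time constants
#' (`1 - exp(-2)`), fast unconstrained preparation (`tau_s` 50 ms), return
#' time constant 6.55 s with a non-binding maximum return rate, and
#' 1.64e5 ATP molecules hydrolyzed per released vesicle.
#'
#' @param n_total total vesicles per synapse.
#' @param n_rrp RRP capacity; must be 5-10% of `n_total`.
#' @param n_sites number of release sites.
#' @param s_m prepared-state asymptote (dimensionless, > 0).
#' @param tau_s preparation time constant (s).
#' @param prep_fraction fraction of `s_m` at which a vesicle is prepared.
#' @param site_max_rate maximum sustained usage per release site
#'   (vesicles/s); enforced as a per-site refractory period.
#' @param synapse_max_rate maximum usage of the whole synapse (vesicles/s);
#'   enforced as a minimum release spacing in gate-open time.
#' @param v_rm maximum return rate to the recycling pool (vesicles/s).
#' @param tau_r return time constant (s).
#' @param atp_per_vesicle ATP molecules hydrolyzed per released vesicle.
#' @return An object of class `synapse_params` (with derived field `h_m`).
#' @export
synapse_params <- function(n_total = 200,
                           n_rrp = 10,
                           n_sites = 5,
                           s_m = 1,
                           tau_s = 0.05,
                           prep_fraction = 1 - exp(-2),
                           site_max_rate = 4,
                           synapse_max_rate = 20,
                           v_rm = 30,
                           tau_r = 6.55,
                           atp_per_vesicle = 1.64e5) {
  vals <- list(n_total = n_total, n_rrp = n_rrp, n_sites = n_sites,
               s_m = s_m, tau_s = tau_s, prep_fraction = prep_fraction,
               site_max_rate = site_max_rate,
               synapse_max_rate = synapse_max_rate,
               v_rm = v_rm, tau_r = tau_r,
               atp_per_vesicle = atp_per_vesicle)
  for (nm in c("n_total", "n_rrp", "n_sites", "s_m", "tau_s",
               "site_max_rate", "synapse_max_rate", "v_rm", "tau_r",
               "atp_per_vesicle"))
    if (!is.finite(vals[[nm]]) || vals[[nm]] <= 0)
      stop(nm, " must be > 0", call. = FALSE)
  if (prep_fraction <= 0 || prep_fraction >= 1)
    stop("prep_fraction must lie in (0, 1)", call. = FALSE)
  if (n_rrp < 0.05 * n_total - 1e-9 || n_rrp > 0.10 * n_total + 1e-9)
    stop("n_rrp must be 5-10% of n_total", call. = FALSE)
  vals$h_m <- n_total - n_rrp
  if (n_sites * site_max_rate < synapse_max_rate)
    message("note: joint per-site capacity (", n_sites, " x ", site_max_rate,
            " = ", n_sites * site_max_rate,
            " vesicles/s) is below the synapse-level cap (",
            synapse_max_rate, " vesicles/s); the per-site cap will bind")
  structure(vals, class = "synapse_params")
}

.cpp_params <- function(params, tau_s = params$tau_s) {
  list(n_rrp = params$n_rrp, s_m = params$s_m,
       prep_fraction = params$prep_fraction, n_sites = params$n_sites,
       site_refractory = 1 / params$site_max_rate,
       release_spacing = 1 / params$synapse_max_rate,
       v_rm = params$v_rm, tau_r = params$tau_r, h_m = params$h_m,
       tau_s = tau_s)
}

#' Initial vesicle-cycle state
#'
#' A fresh synapse has a full recycling pool, all RRP slots occupied by
#' unprepared vesicles (`s_i = 0`), all sites free and zero counters. With
#' `depleted = TRUE` the recycling pool starts empty (all `h_m` recycling
#' vesicles in transit), which is the initial condition of the
#' pool-recovery protocol.
#'
#' @param params a [synapse_params()].
#' @param depleted start with an exhausted recycling pool? (The recycling
#'   vesicles then begin in transit, counted as released before t = 0, so
#'   the release/return ledger stays consistent.)
#' @return An object of class `cycle_state`.
#' @export
init_cycle_state <- function(params, depleted = FALSE) {
  structure(list(
    s = rep(0, params$n_rrp),
    occupied = rep(TRUE, params$n_rrp),
    pool = if (depleted) 0L else as.integer(params$h_m),
    site_busy = rep(-Inf, params$n_sites),
    in_transit = if (depleted) as.integer(params$h_m) else 0L,
    released = if (depleted) params$h_m else 0, returned = 0,
    return_accum = 0,
    next_release_open = 0, open_clock = 0, time = 0
  ), class = "cycle_state")
}

#' Advance the vesicle cycle by one step
#'
#' Single-step interface to the cycle engine: preparation states advance by
#' the exact exponential update, prepared vesicles paired with free sites
#' release if `gate_open` (subject to both rate caps), and returns accrue
#' fractionally. Mainly useful for inspecting the stepper; whole runs go
#' through [simulate_synapse()].
#'
#' @param state a [init_cycle_state()] state.
#' @param dt step size (s, > 0).
#' @param gate_open logical: is the calcium gate open during this step?
#' @param params a [synapse_params()].
#' @param tau_s preparation time constant to use (defaults to the one in
#'   `params`).
#' @return The updated `cycle_state` (with `time` advanced by `dt`).
#' @export
cycle_step <- function(state, dt, gate_open, params, tau_s = params$tau_s) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  t0 <- state$time
  win <- if (isTRUE(gate_open)) list(s = t0, e = t0 + dt)
         else list(s = numeric(0), e = numeric(0))
  res <- cycle_run_cpp(win$s, win$e, t0, t0 + dt, dt,
                       tau_s, .cpp_params(params), state, 0)
  st <- res$state
  st$time <- t0 + dt
  class(st) <- "cycle_state"
  st
}

#' Simulate the synaptic vesicle cycle
#'
#' Runs the full pipeline for one synapse: computes the analytic calcium
#' gate from the spike train, then steps the vesicle cycle over
#' `[0, duration)`. After the stimulation ends the pool keeps recovering
#' toward capacity.
#'
#' @param train a [spike_train()] of presynaptic action potentials.
#' @param params a [synapse_params()].
#' @param ca a [calcium_params()].
#' @param duration total simulated time (s); must be at least the train
#'   duration. Defaults to the train duration.
#' @param dt integration step (s), default 1 ms.
#' @param sample_dt sampling interval of the recorded series (s).
#' @param tau_s preparation time constant (defaults to `params$tau_s`).
#' @param state optional starting state (defaults to a fresh synapse).
#' @return An object of class `cycle_trajectory`: list with the sampled
#'   series (`time`, `pool`, `v_r`, `in_transit`, `released_cum`), the
#'   per-sample leaving rate `v_s`, the release event log `release_times`,
#'   the gate, the input train, the final `state`, and the parameters.
#' @export
simulate_synapse <- function(train, params, ca,
                             duration = train$duration, dt = 1e-3,
                             sample_dt = 0.1, tau_s = params$tau_s,
                             state = NULL) {
  if (duration < train$duration)
    stop("duration must be >= train duration", call. = FALSE)
  gate <- release_windows(train, ca)
  if (is.null(state)) state <- init_cycle_state(params)
  res <- cycle_run_cpp(gate[, 1], gate[, 2], state$time,
                       state$time + duration, dt,
                       tau_s, .cpp_params(params), state, sample_dt)
  st <- res$state
  st$time <- state$time + duration
  class(st) <- "cycle_state"
  rel <- res$release_times
  # leaving rate over each sampling interval
  edges <- c(state$time, res$sample_t)
  v_s <- if (length(res$sample_t))
    diff(c(0, findInterval(edges[-1], sort(rel)))) / diff(edges) else numeric(0)
  structure(list(
    time = res$sample_t, pool = res$sample_pool, v_r = res$sample_vr,
    in_transit = res$sample_in_transit, released_cum = res$sample_released,
    v_s = v_s, release_times = rel, gate = gate, train = train,
    params = params, tau_s = tau_s, dt = dt, state = st
  ), class = "cycle_trajectory")
}

#' @export
print.cycle_trajectory <- function(x, ...) {
  cat(sprintf("<cycle_trajectory> %d releases over %.4g s (final pool %d/%d)\n",
              length(x$release_times),
              if (length(x$time)) max(x$time) else 0,
              x$state$pool, x$params$h_m))
  invisible(x)
}

#' Number of releases in a time window
#'
#' @param traj a [simulate_synapse()] trajectory.
#' @param window `c(from, to)` in seconds (half-open).
#' @return Release count.
#' @export
release_count <- function(traj, window) {
  sum(traj$release_times >= window[1] & traj$release_times < window[2])
}

#' Mean rate of vesicles leaving the recycling pool
#'
#' @param traj a [simulate_synapse()] trajectory.
#' @param window measurement window `c(from, to)` in seconds; defaults to
#'   the final 50% of the stimulation period (steady state).
#' @return Leaving rate in vesicles/s.
#' @export
leaving_rate <- function(traj, window = NULL) {
  if (is.null(window))
    window <- c(traj$train$duration / 2, traj$train$duration)
  release_count(traj, window) / (window[2] - window[1])
}

#' Release probability
#'
#' The mean number of vesicles released per action potential (`Q`) divided
#' by the number of release sites (`N`). By convention `Q` is measured over
#' the final 50% of the stimulation period unless an explicit window is
#' given. Values above 1 are possible in the model and are flagged as
#' abnormal with a warning.
#'
#' @param traj a [simulate_synapse()] trajectory.
#' @param train the driving [spike_train()] (defaults to the one recorded
#'   in the trajectory).
#' @param params a [synapse_params()] (defaults to the recorded one).
#' @param window measurement window `c(from, to)` in seconds.
#' @return Release probability (dimensionless).
#' @export
release_probability <- function(traj, train = traj$train,
                                params = traj$params, window = NULL) {
  if (!length(train$times))
    stop("release probability is undefined for an empty train", call. = FALSE)
  if (is.null(window)) window <- c(train$duration / 2, train$duration)
  spikes <- sum(train$times >= window[1] & train$times < window[2])
  if (spikes == 0)
    stop("no spikes in the measurement window", call. = FALSE)
  q <- release_count(traj, window) / spikes
  rp <- q / params$n_sites
  if (rp > 1)
    warning("release probability ", signif(rp, 4),
            " exceeds 1: abnormal (more than one vesicle per site per spike)",
            call. = FALSE)
  rp
}

#' Presynaptic transmission energy
#'
#' ATP consumed by releasing `release_count` vesicles, at the fixed cost of
#' `atp_per_vesicle` molecules per vesicle. Calcium extrusion and
#' neurotransmitter recycling costs are not counted.
#'
#' @param release_count number of released vesicles (>= 0).
#' @param params a [synapse_params()].
#' @return Energy in ATP molecules.
#' @export
transmission_energy <- function(release_count, params = synapse_params()) {
  if (any(release_count < 0))
    stop("release_count must be >= 0", call. = FALSE)
  params$atp_per_vesicle * release_count
}

#' Recycling-pool recovery curve
#'
#' Starts from an exhausted recycling pool with no stimulation and records
#' the pool refilling under the return process; the curve rises
#' monotonically from 0 toward the pool capacity.
#'
#' @param params a [synapse_params()].
#' @param duration simulated time (s, > 0).
#' @param dt integration step (s).
#' @param sample_dt sampling interval (s).
#' @return A data frame with columns `time` and `pool`.
#' @export
recovery_curve <- function(params, duration, dt = 1e-3, sample_dt = 0.05) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  state <- init_cycle_state(params, depleted = TRUE)
  res <- cycle_run_cpp(numeric(0), numeric(0), 0, duration, dt,
                       params$tau_s, .cpp_params(params), state, sample_dt)
  data.frame(time = res$sample_t, pool = res$sample_pool)
}

#' Fit an exponential recovery time constant
#'
#' Least-squares fit of `h_m * (1 - exp(-t/tau))` to a pool-recovery curve;
#' `h_m` is taken as known (the pool capacity) and only `tau` is estimated.
#'
#' @param curve data frame with `time` and `pool` columns (>= 10 samples,
#'   rising toward `h_m`; small non-monotone wiggles from measurement noise
#'   are tolerated, a flat or decreasing curve is an error).
#' @param h_m pool capacity the curve saturates at.
#' @return Fitted time constant `tau` in seconds.
#' @export
fit_recovery_tau <- function(curve, h_m) {
  if (nrow(curve) < 10)
    stop("need at least 10 samples to fit", call. = FALSE)
  rng <- max(curve$pool) - min(curve$pool)
  if (rng < .Machine$double.eps * h_m)
    stop("recovery curve is flat; cannot fit a time constant", call. = FALSE)
  if (any(diff(curve$pool) < -0.1 * rng) ||
      curve$pool[nrow(curve)] <= curve$pool[1])
    stop("recovery curve must be monotone nondecreasing (up to noise)",
         call. = FALSE)
  tau0 <- stats::median(curve$time) / log(2)
  fit <- minpack.lm::nlsLM(pool ~ h_m * (1 - exp(-time / tau)),
                           data = curve, start = list(tau = tau0))
  as.numeric(coef(fit)[["tau"]])
}

#' Conservation check of a cycle state
#'
#' Verifies that recycling pool + occupied RRP slots + vesicles in transit
#' equals the total vesicle count, and that the release/return ledgers are
#' consistent.
#'
#' @param state a `cycle_state`.
#' @param params the matching [synapse_params()].
#' @return `TRUE` invisibly; errors if conservation is violated.
#' @export
check_conservation <- function(state, params) {
  tot <- state$pool + sum(state$occupied) + state$in_transit
  if (tot != params$n_total)
    stop("vesicle conservation violated: ", tot, " != ", params$n_total,
         call. = FALSE)
  if (state$released != state$returned + state$in_transit)
    stop("release ledger inconsistent", call. = FALSE)
  if (state$pool < 0 || state$pool > params$h_m)
    stop("pool count out of range", call. = FALSE)
  invisible(TRUE)
}

#' Export a cycle trajectory as CSV
#'
#' Writes the sampled series (time, pool count, leaving rate, return rate,
#' cumulative releases and per-interval transmission energy) to CSV.
#'
#' @param traj a [simulate_synapse()] trajectory.
#' @param path output CSV path.
#' @return The data frame, invisibly.
#' @export
export_trajectory <- function(traj, path) {
  e <- transmission_energy(diff(c(0, traj$released_cum)), traj$params)
  df <- data.frame(time = traj$time, pool = traj$pool, v_s = traj$v_s,
                   v_r = traj$v_r, released_cum = traj$released_cum,
                   energy_atp = e)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
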
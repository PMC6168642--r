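#' Build a multi-compartment CA1 pyramidal neuron
#'
#' Assembles a connected compartmental cable model from a morphology
#' specification: a cylindrical soma with an attached axon initial segment
#' (AIS), and one unbranched equivalent-cylinder section per dendritic
#' class. Basal sections chain off the soma; the apical trunk runs
#' soma -> proximal -> medial -> distal trunk, with the oblique trunk
#' branches and the prolonged trunk leaving the distal trunk and the tuft
#' sections continuing from the prolonged trunk. Each section is subdivided
#' into an odd number of segments chosen from its electrotonic length
#' (at least 11), so voltage gradients are resolved.
#'
#' @param morph a [morphology_spec()].
#' @param elec an [electrical_params()].
#' @param max_nseg upper bound on segments per section.
#' @return An object of class `neuron_model` holding the compartment table
#'   and the conductance vectors consumed by the solver.
#' @export
build_neuron <- function(morph, elec = electrical_params(), max_nseg = 101) {
  if (!inherits(morph, "morphology_spec")) morph <- morphology_spec(morph)
  parent_section <- c(
    soma = NA, ais = "soma",
    proximal_basal = "soma", distal_basal = "proximal_basal",
    proximal_trunk = "soma", medial_trunk = "proximal_trunk",
    distal_trunk = "medial_trunk", trunk_branches = "distal_trunk",
    prolonged_trunk = "distal_trunk", medial_tuft = "prolonged_trunk",
    distal_tuft = "medial_tuft")
  missing <- setdiff(names(parent_section)[-(1:2)], morph$type)
  if (length(missing))
    stop("morphology is missing compartment classes: ",
         paste(missing, collapse = ", "), call. = FALSE)

  # electrotonic space constant (um) for a diameter d (um)
  lambda_um <- function(d) {
    rm <- 1000 / elec$gl                      # Ohm cm^2
    1e4 * sqrt(rm * (d * 1e-4) / (4 * elec$ra))
  }
  odd <- function(n) if (n %% 2 == 0) n + 1 else n

  secs <- list(
    soma = list(L = elec$soma_l, d = elec$soma_diam, nseg = 1,
                gna = elec$gna_soma, gk = elec$gk_soma),
    ais = list(L = elec$ais_l, d = elec$ais_diam, nseg = 5,
               gna = elec$gna_ais, gk = elec$gk_ais))
  for (i in seq_len(nrow(morph))) {
    ty <- morph$type[i]
    L <- morph$length_um[i]; d <- morph$diameter_um[i]
    nseg <- odd(min(max_nseg, max(11, ceiling(L / (0.2 * lambda_um(d))))))
    secs[[ty]] <- list(L = L, d = d, nseg = nseg,
                       gna = elec$gna_dend, gk = elec$gk_dend)
  }

  section <- character(0); parent <- integer(0)
  len <- numeric(0); diam <- numeric(0)
  sec_last <- list()   # index of the distal compartment of each section
  for (nm in names(parent_section)) {
    s <- secs[[nm]]
    lseg <- s$L / s$nseg
    base <- length(section)
    p0 <- if (is.na(parent_section[[nm]])) 0L else sec_last[[parent_section[[nm]]]]
    for (j in seq_len(s$nseg)) {
      section <- c(section, nm)
      parent <- c(parent, if (j == 1) p0 else base + j - 1L)
      len <- c(len, lseg); diam <- c(diam, s$d)
    }
    sec_last[[nm]] <- base + s$nseg
  }
  n <- length(section)
  area <- pi * (diam * 1e-4) * (len * 1e-4)                 # cm^2
  ax_area <- pi * (diam * 1e-4)^2 / 4                       # cm^2
  r_half <- elec$ra * (len * 1e-4) / 2 / ax_area            # Ohm
  ga_us <- numeric(n)
  for (i in 2:n)
    ga_us[i] <- 1e6 / (r_half[i] + r_half[parent[i]])
  gna <- vapply(section, function(nm) secs[[nm]]$gna, 0)
  gk <- vapply(section, function(nm) secs[[nm]]$gk, 0)
  comp <- data.frame(section = section, parent = parent,
                     length_um = len, diameter_um = diam,
                     area_cm2 = area, stringsAsFactors = FALSE)
  class_comps <- split(seq_len(n), section)
  structure(list(
    comp = comp,
    parent0 = parent - 1L,                    # 0-based for the solver
    cm_nf = elec$cm * area * 1e3,
    ga_us = ga_us,
    gna_us = gna * area * 1e3,
    gk_us = gk * area * 1e3,
    gl_us = elec$gl * area * 1e3,
    class_comps = class_comps,
    elec = elec, morph = morph
  ), class = "neuron_model")
}

#' @export
print.neuron_model <- function(x, ...) {
  cat(sprintf("<neuron_model> %d compartments, %d sections\n",
              nrow(x$comp), length(unique(x$comp$section))))
  invisible(x)
}

#' Active-synapse layout
#'
#' Specifies how many excitatory synapses are simultaneously active in each
#' compartment class, all driven by independent Poisson trains at `rate`.
#'
#' @param counts named integer vector (names are compartment classes).
#' @param rate presynaptic input rate per synapse (Hz).
#' @param seed integer seed controlling placement and input trains.
#' @return An object of class `synapse_layout`.
#' @export
active_synapse_layout <- function(counts, rate = 10, seed = 1) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a named vector of compartment classes",
         call. = FALSE)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(list(counts = counts, rate = rate, seed = seed),
            class = "synapse_layout")
}

#' Simulate somatic firing under synaptic drive
#'
#' Places the layout's synapses uniformly at random along their compartment
#' class (seeded), drives each with an independent Poisson train, integrates
#' the cable model and detects somatic spikes by upward threshold crossing.
#'
#' @param neuron a [build_neuron()] model.
#' @param layout an [active_synapse_layout()].
#' @param duration simulated time (s).
#' @param dt integration step (s), default 25 us.
#' @return A [spike_train()] of somatic spike times.
#' @export
simulate_firing <- function(neuron, layout, duration, dt = 25e-6) {
  cap <- synapse_capacity(neuron$morph)
  bad <- setdiff(names(layout$counts), names(neuron$class_comps))
  if (length(bad))
    stop("unknown compartment class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  over <- layout$counts > cap[names(layout$counts)]
  if (any(over))
    stop("active-synapse count exceeds excitatory capacity for: ",
         paste(names(layout$counts)[over], collapse = ", "), call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(layout$seed)
  ev_t <- list(); ev_c <- list()
  for (nm in names(layout$counts)) {
    k <- layout$counts[[nm]]
    if (k == 0) next
    comps <- neuron$class_comps[[nm]]
    where <- sample(comps, k, replace = TRUE)   # uniform along the section
    for (i in seq_len(k)) {
      n_ev <- rpois(1, layout$rate * duration)
      if (n_ev == 0) next
      ev_t[[length(ev_t) + 1]] <- sort(runif(n_ev, 0, duration)) * 1e3 # ms
      ev_c[[length(ev_c) + 1]] <- rep.int(where[i] - 1L, n_ev)
    }
  }
  ev_time <- unlist(ev_t); ev_comp <- unlist(ev_c)
  if (is.null(ev_time)) { ev_time <- numeric(0); ev_comp <- integer(0) }
  o <- order(ev_time)
  ev_time <- ev_time[o]; ev_comp <- ev_comp[o]
  w <- rep(neuron$elec$syn_peak * 1e-3, length(ev_time))   # nS -> uS
  res <- cable_run_cpp(neuron$parent0, neuron$cm_nf, neuron$ga_us,
                       neuron$gna_us, neuron$gk_us, neuron$gl_us,
                       neuron$elec$ena, neuron$elec$ek, neuron$elec$el,
                       neuron$elec$v_init,
                       ev_time, as.integer(ev_comp), w,
                       neuron$elec$syn_rise, neuron$elec$syn_decay,
                       neuron$elec$syn_reversal,
                       dt * 1e3, duration * 1e3,
                       neuron$elec$spike_threshold, 0L,
                       neuron$elec$rate_scale)
  if (isTRUE(res$diverged))
    stop("numerical instability (non-finite voltage) at t = ",
         signif(res$diverged_at / 1e3, 4), " s with dt = ", dt,
         " s; reduce dt", call. = FALSE)
  spikes <- res$spike_times / 1e3
  spike_train(spikes[spikes < duration], duration)
}

#' Firing frequency of a spike train
#'
#' Spike count over the final `1 - discard` of the window divided by that
#' window (the onset transient is discarded).
#'
#' @param train a [spike_train()].
#' @param discard initial fraction of the window to discard.
#' @return Frequency in Hz.
#' @export
firing_rate <- function(train, discard = 0.2) {
  t0 <- discard * train$duration
  sum(train$times >= t0) / (train$duration - t0)
}

#' Sweep active-synapse counts
#'
#' Runs [simulate_firing()] over a grid of active-synapse counts for one or
#' two compartment classes and annotates every grid point with the firing
#' frequency, the information rate and the ATP-per-bit cost.
#'
#' @param neuron a [build_neuron()] model.
#' @param grids named list (length 1 or 2) of count vectors, names are
#'   compartment classes.
#' @param duration simulated time per grid point (s).
#' @param rate input rate per synapse (Hz).
#' @param seed integer seed; each grid point uses a derived sub-seed.
#' @param metrics a [metrics_params()].
#' @param dt integration step (s).
#' @return A data frame (class `sweep_surface`) with one row per grid
#'   point: the counts, `frequency` (Hz), `info_rate` (bits/s),
#'   `energy_rate` (ATP/s) and `atp_per_bit` (NA where the frequency is 0).
#' @export
sweep_firing <- function(neuron, grids, duration = 2, rate = 10, seed = 1,
                         metrics = metrics_params(), dt = 25e-6) {
  if (length(grids) < 1 || length(grids) > 2)
    stop("grids must cover one or two compartment classes", call. = FALSE)
  g <- expand.grid(grids)
  freq <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    counts <- stats::setNames(as.integer(g[i, ]), names(grids))
    lay <- active_synapse_layout(counts, rate = rate, seed = seed + i)
    freq[i] <- firing_rate(simulate_firing(neuron, lay, duration, dt))
  }
  g$frequency <- freq
  g$info_rate <- info_rate(pmin(freq, 1 / metrics$delta), metrics)
  g$energy_rate <- integration_energy(freq, metrics)
  g$atp_per_bit <- ifelse(freq > 0,
                          g$energy_rate / pmax(g$info_rate,
                                               .Machine$double.xmin),
                          NA_real_)
  class(g) <- c("sweep_surface", "data.frame")
  g
}
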
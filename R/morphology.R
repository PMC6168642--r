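#' CA1 pyramidal-cell morphology specification
#'
#' The dendritic tree is reduced to nine compartment classes (basal,
#' trunk, oblique/branch and tuft subdivisions), each described by its
#' share of the total dendritic length, its diameter and its synapse
#' densities — the classical quantitative anatomy of the rat CA1 pyramidal
#' cell (Megias et al. 2001, Neuroscience 102:527-540). The packaged CSV
#' fixture carries those literature values; `total_length` scales the
#' fractions to absolute lengths (default 11,500 um, a typical total
#' dendritic length for CA1 pyramidal cells).
#'
#' @param rows data frame with columns `type`, `percentage_of_length`,
#'   `diameter_um`, `spine_density`, `excitatory_per_um`,
#'   `inhibitory_per_um`; defaults to the packaged fixture.
#' @param total_length total dendritic length (um).
#' @return An object of class `morphology_spec`: the row table plus
#'   `length_um` per class, with attribute `total_length`.
#' @export
morphology_spec <- function(rows = NULL, total_length = 11500) {
  if (is.null(rows)) {
    path <- system.file("extdata", "ca1_pyramidal_morphology.csv",
                        package = "synvesim")
    rows <- read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("type", "percentage_of_length", "diameter_um", "spine_density",
            "excitatory_per_um", "inhibitory_per_um")
  if (!all(need %in% names(rows)))
    stop("morphology table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (abs(sum(rows$percentage_of_length) - 1) > 1e-6)
    stop("length fractions must sum to 1 (got ",
         sum(rows$percentage_of_length), ")", call. = FALSE)
  if (any(rows$diameter_um <= 0))
    stop("diameters must be > 0", call. = FALSE)
  if (any(rows[, c("spine_density", "excitatory_per_um",
                   "inhibitory_per_um")] < 0))
    stop("densities must be >= 0", call. = FALSE)
  rows$length_um <- rows$percentage_of_length * total_length
  structure(rows, class = c("morphology_spec", "data.frame"),
            total_length = total_length)
}

#' Excitatory synapse capacity per compartment class
#'
#' @param morph a [morphology_spec()].
#' @return Named integer vector: `floor(excitatory_per_um * length_um)`
#'   per class.
#' @export
synapse_capacity <- function(morph) {
  stats::setNames(as.integer(floor(morph$excitatory_per_um * morph$length_um)),
                  morph$type)
}

#' Electrical parameters of the compartmental model
#'
#' Hodgkin-Huxley membrane parameters for the multi-compartment neuron:
#' transient Na, delayed-rectifier K and leak, with separate conductance
#' densities for soma, axon initial segment (AIS) and dendrites, plus the
#' excitatory synaptic conductance waveform. The kinetics are the standard
#' squid-derived rate functions expressed at a -65 mV resting potential and
#' sped up by a Q10-style temperature factor; densities are CA1-like with
#' moderately excitable dendrites (supporting dendritic Na spikes), a hot
#' axon initial segment for spike initiation, and uniform passive
#' properties. The synaptic peak conductance is an *effective* per-synapse
#' value: each dendritic class is an equivalent cylinder standing in for
#' many parallel branches, so one modelled synapse aggregates the local
#' cooperativity of a small cluster of anatomical synapses.
#'
#' @param cm membrane capacitance (uF/cm^2).
#' @param ra axial resistivity (Ohm cm).
#' @param gna_soma,gk_soma somatic Na/K conductance densities (mS/cm^2).
#' @param gna_ais,gk_ais AIS Na/K conductance densities (mS/cm^2).
#' @param gna_dend,gk_dend dendritic Na/K conductance densities (mS/cm^2).
#' @param gl leak conductance density (mS/cm^2).
#' @param ena,ek,el reversal potentials (mV).
#' @param rate_scale multiplicative temperature factor on all gating rates
#'   (Q10-style; the default of 3 shifts the classic kinetics to a
#'   near-physiological ~35 C).
#' @param v_init resting/initialization potential (mV).
#' @param spike_threshold somatic spike-detection threshold (mV, upward
#'   crossing).
#' @param syn_peak peak synaptic conductance per event (nS).
#' @param syn_rise,syn_decay synaptic rise/decay time constants (ms).
#' @param syn_reversal synaptic reversal potential (mV).
#' @param soma_l,soma_diam soma cylinder length and diameter (um).
#' @param ais_l,ais_diam AIS length and diameter (um).
#' @return An object of class `electrical_params`.
#' @export
electrical_params <- function(cm = 1, ra = 150,
                              gna_soma = 200, gk_soma = 50,
                              gna_ais = 600, gk_ais = 100,
                              gna_dend = 50, gk_dend = 10,
                              gl = 0.1,
                              ena = 50, ek = -77, el = -65,
                              rate_scale = 3,
                              v_init = -65,
                              spike_threshold = 0,
                              syn_peak = 5,
                              syn_rise = 0.5, syn_decay = 3,
                              syn_reversal = 0,
                              soma_l = 20, soma_diam = 20,
                              ais_l = 40, ais_diam = 1.5) {
  vals <- as.list(environment())
  for (nm in c("cm", "ra", "gl", "soma_l", "soma_diam", "ais_l", "ais_diam",
               "syn_peak", "syn_rise", "syn_decay", "rate_scale"))
    if (vals[[nm]] <= 0) stop(nm, " must be > 0", call. = FALSE)
  for (nm in c("gna_soma", "gk_soma", "gna_ais", "gk_ais", "gna_dend",
               "gk_dend"))
    if (vals[[nm]] < 0) stop(nm, " must be >= 0", call. = FALSE)
  if (spike_threshold <= v_init)
    stop("spike_threshold must be above the resting potential", call. = FALSE)
  structure(vals, class = "electrical_params")
}
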
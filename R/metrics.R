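#' Spike-train information/energy metric parameters
#'
#' `delta` is the minimum interspike bin: within one bin of length `delta`
#' a neuron either fires once or stays silent, so a train at frequency `f`
#' is a Bernoulli sequence with occupancy `f * delta`. The default of 2 ms
#' reflects the 1-2 ms action potential plus refractory period that bounds
#' attainable firing rates; `atp_per_spike` is the fixed metabolic cost of
#' one action potential.
#'
#' @param delta minimum interspike bin (s, > 0).
#' @param atp_per_spike ATP molecules per action potential.
#' @return An object of class `metrics_params`.
#' @export
metrics_params <- function(delta = 2e-3, atp_per_spike = 1.2e8) {
  stopifnot(delta > 0, atp_per_spike > 0)
  structure(list(delta = delta, atp_per_spike = atp_per_spike),
            class = "metrics_params")
}

#' Information rate of a spike train
#'
#' Binary entropy of one bin at occupancy `f * delta`, divided by the bin
#' length: `(-p log2 p - (1-p) log2 (1-p)) / delta` with `p = f * delta`.
#' The limits at `p = 0` and `p = 1` evaluate to 0 (the convention
#' `0 log 0 = 0`).
#'
#' @param f firing frequency (Hz); may be fractional. Vectorized.
#' @param params a [metrics_params()].
#' @return Information rate in bits/s.
#' @export
info_rate <- function(f, params = metrics_params()) {
  p <- f * params$delta
  if (any(p < 0 | p > 1))
    stop("f * delta must lie in [0, 1] (frequency exceeds bin capacity)",
         call. = FALSE)
  h <- ifelse(p == 0 | p == 1, 0,
              -p * log2(p) - (1 - p) * log2(1 - p))
  h / params$delta
}

#' Integration energy rate of a spike train
#'
#' Fixed per-spike cost times the firing frequency.
#'
#' @param f firing frequency (Hz, >= 0). Vectorized.
#' @param params a [metrics_params()].
#' @return Energy consumption in ATP/s.
#' @export
integration_energy <- function(f, params = metrics_params()) {
  if (any(f < 0)) stop("f must be >= 0", call. = FALSE)
  params$atp_per_spike * f
}

#' Energy cost per bit of information
#'
#' Ratio of the integration energy rate to the information rate; the
#' efficiency currency of dendritic integration.
#'
#' @param f firing frequency (Hz, > 0). Vectorized.
#' @param params a [metrics_params()].
#' @return ATP molecules per bit.
#' @export
energy_per_bit <- function(f, params = metrics_params()) {
  if (any(f <= 0))
    stop("energy per bit is undefined at f = 0", call. = FALSE)
  integration_energy(f, params) / info_rate(f, params)
}
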
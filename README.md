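# synvesim

Energy-constrained simulation of synaptic transmission and dendritic
integration in pyramidal neurons, for computational neuroscientists who
want a mechanistic, testable account of why central synapses keep a low
release probability and why neurons fire at low rates.

## The model

**Synaptic vesicle cycle.** A synapse holds 200 vesicles split between a
recycling pool (capacity *h*ₘ) and a readily releasable pool (RRP) of
*n*ᵣᵣₚ slots. Each RRP vesicle matures toward release readiness by the
first-order law τₛ·dsᵢ/dt + sᵢ = sₘ (sᵢ(0) = 0). Release is gated by the
total presynaptic Ca²⁺ transient: each spike adds
Δ[Ca²⁺]ₐₚ·(1 + Kₛ + K′_B) of total calcium, and exocytosis is permitted
while that transient exceeds a 20 µmol/L threshold. Prepared vesicles fuse
at 5 release sites subject to per-site and per-synapse usage caps, and
return to the pool at rate vᵣ = min(vᵣₘ, (hₘ − h)/τᵣ). Releasing one
vesicle costs 1.64×10⁵ ATP. Release probability is rp = Q/N, the mean
vesicles released per action potential over the number of sites.

**Metabolic regulation.** Over consecutive windows the actual ATP
consumption E_a is steered toward a desired level E_d by a sigmoid-bounded
update of the preparation time constant:

    τₛ(k+1) = τₛ(k) + λₖ · (2 / (1 + exp(−(E_a − E_d)/c)) − 1)

so an energy surplus slows the vesicle cycle and a deficit accelerates it.
The release probability thereby adapts to the synaptic energy level.

**Dendritic integration.** A multi-compartment Hodgkin–Huxley CA1
pyramidal neuron (soma, axon initial segment, nine dendritic compartment
classes with literature-derived geometry and synapse densities) receives
10 Hz Poisson excitatory input on a configurable number of active
synapses per class. Somatic firing at frequency *f* carries
I = [−fδ·log₂(fδ) − (1−fδ)·log₂(1−fδ)]/δ bits/s at a cost of 1.2×10⁸·f
ATP/s, giving the ATP-per-bit efficiency of integration.

## Worked example

```r
library(synvesim)
syn <- synapse_params()    # calibrated profile: 200 vesicles, 5 sites, ...
ca  <- calcium_params()

# sustained 4 Hz drive without the energy constraint
traj <- simulate_synapse(periodic_train(4, 100), syn, ca)
leaving_rate(traj)         # 17       vesicles/s leaving the recycling pool
release_probability(traj)  # 0.85     (4.25 vesicles per spike over 5 sites)

# the same synapse under a 8.2e5 ATP/s energy budget
run <- simulate_regulated(periodic_train(4, 600), syn, ca,
                          regulation_params(e_desired = 8.2e5))
run
#> <regulation_run> 60 windows of 10 s; tau_s 0.05 -> 0.9514 s; final |Ea-Ed|/Ed = 0.06
run$trace$leaving[1]       # 169      vesicles leave in the first 10 s window
steady_state(run)$leaving_per_window   # 50.3  vesicles per 10 s at steady state
steady_state(run)$rp       # 0.252    release probability, now in the optimal band
```

The unconstrained synapse releases freely (rp ≈ 0.85, 17 vesicles/s); the
energy constraint slows preparation (τₛ rises to ≈ 1 s) until consumption
matches the budget, leaving ≈ 50 vesicles per 10 s and a release
probability of ≈ 0.25 — the low-release-probability regime observed at
hippocampal synapses emerges from the energy budget alone.

A command-line interface wraps the same functions:

```sh
Rscript inst/exec/synvesim simulate-regulated --e-desired 8.2e5 --duration 600 --out out/
Rscript inst/exec/synvesim metrics --freq 50 --delta 0.002
Rscript inst/exec/synvesim sweep-dendrite --classes proximal_basal --grid 0:240:60 --duration 2 --out out/
```

## Package layout

- `R/`, `src/` — stimulus generators, calcium gate, vesicle-cycle engine
  (Rcpp), regulation loop, information/energy metrics, morphology and the
  Hines-solver neuron model (Rcpp), config/experiment runners
- `inst/extdata/ca1_pyramidal_morphology.csv` — the nine-class CA1
  morphology table (type, length fraction, diameter, synapse densities)
- `vignettes/energy-constrained-synapse.Rmd` — the methods vignette:
  model assumptions, calibration rationale, numerical choices, limitations
- `tests/testthat/` — unit, property and acceptance tests
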
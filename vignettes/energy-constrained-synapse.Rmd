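---
title: "An energy-constrained model of synaptic transmission and dendritic integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An energy-constrained model of synaptic transmission and dendritic integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synvesim)
```

# The scientific problem

Chemical synapses are metabolically expensive: every released vesicle costs
on the order of $1.6\times10^5$ ATP molecules, and every somatic action
potential on the order of $10^8$. Yet most central synapses operate at a
low release probability (experimentally 0.25–0.5), and most neurons fire at
low rates. `synvesim` implements a mechanistic account of both
observations: a synaptic vesicle cycle whose speed is *regulated by the
synapse's ATP budget*, and a compartmental pyramidal-neuron model in which
the number of simultaneously active synapses sets the firing rate and
hence the ATP cost per bit of transmitted information.

# The synaptic vesicle cycle

A synapse holds `n_total = 200` vesicles: a recycling pool of capacity
$h_m$ and a readily releasable pool (RRP) of `n_rrp` slots
($h_m = 200 - n_{rrp}$). The cycle has three stages.

**Preparation.** Each RRP vesicle carries a state $s_i \in [0, s_m]$
obeying the first-order relaxation
$\tau_s \dot s_i + s_i = s_m$, $s_i(0) = 0$:
a vesicle refilled from the pool matures exponentially toward release
readiness, at a speed set entirely by the preparation time constant
$\tau_s$. The stepper uses the *exact* exponential update
$s_i \leftarrow s_m + (s_i - s_m)e^{-\Delta t/\tau_s}$, so trajectories
are invariant to the step size (tested to machine precision). A vesicle
counts as "prepared" once $s_i \ge$ `prep_fraction` $\cdot\, s_m$; since
the relaxation is asymptotic, any such threshold is a modelling choice —
the package uses $1 - e^{-2} \approx 0.865$, i.e. two time constants,
which makes the supply rate of prepared vesicles
$n_{rrp}/(2\tau_s) = 5/\tau_s$ vesicles/s at the default `n_rrp = 10`
(5% of the total, inside the experimental 5–10% band). That coefficient
is deliberate: it places the release-probability optimum band
$r_p \in [0.25, 0.5]$ exactly at $\tau_s \in [0.5, 1.0]$ s under the
standard 4 Hz input, the mapping the model is calibrated to reproduce.

**Calcium-gated release.** An action potential at $t_{AP}$ raises the free
Ca²⁺ concentration by $\Delta[\mathrm{Ca}^{2+}]_{AP}$ above rest, decaying
as $e^{-t/\tau_{Ca}}$; with the endogenous binding ratio $K_s$ and the
exogenous buffer increment $K_B'$, the *total* per-spike Ca²⁺ load is
$\Delta[\mathrm{Ca}^{2+}]_{AP}(1 + K_s + K_B')$. Release is permitted
while the total transient exceeds a threshold (physiological band
20–50 µmol/L), i.e. for
$t_w = \tau_{total}\,\ln(\Delta[\mathrm{Ca}^{2+}]_{total}/\theta)$
after each spike; the gate is computed analytically from the spike times
(no grid artifacts) and overlapping windows merge.

During open gate, prepared vesicles fuse at free release sites
(`n_sites = 5`), subject to two rate caps: a per-site refractory period
`1/site_max_rate`, and a synapse-level minimum spacing of
`1/synapse_max_rate` counted in *gate-open time* — the release machinery
cycles at up to 20 vesicles/s while Ca²⁺ is elevated and pauses when the
gate closes. The caps as quoted in the experimental literature
(~3.5 vesicles/s per site, 20 vesicles/s per synapse) are mutually
inconsistent ($5\times3.5 = 17.5 \ne 20$); the package partitions the
synapse cap evenly across sites (`site_max_rate = 4`) and surfaces a
message whenever a user configuration makes the joint per-site capacity
bind below the synapse cap. With the calibrated gate this single mechanism
yields both canonical operating points: at 4 Hz the gate is open 85% of
the time, so the sustained rate is $20 \times 0.85 = 17$ vesicles/s
(per-site usage 3.4/s, matching the "~3.5" estimate) and
$r_p = Q/N = (17/4)/5 = 0.85$; at 100 Hz the windows merge into a
permanently open gate, the rate saturates at the 20 vesicles/s cap and
$r_p = 0.04$ — release sites are all busy and most spikes find no vesicle.

**Return.** Released vesicles are endocytosed and return to the recycling
pool at rate $v_r = \min(v_{rm}, (h_m - h)/\tau_r)$: refilling slows as
the pool approaches capacity. Returns accrue fractionally and the pool
count stays integral. Vesicle conservation
(pool + occupied RRP + in transit = 200) is asserted after every step in
the test suite.

## Calibration of the packaged profile

The defaults (the `paper_profile()`) are fixed once, against four
quantitative anchors from the hippocampal literature, and are not
functions of the input:

| quantity | anchor | model value |
|---|---|---|
| sustained leaving rate at 4 Hz | ~17 vesicles/s | 17.0 |
| release probability at 4 Hz | ~0.86 | 0.85 |
| leaving rate at 100 Hz | synapse cap, 20/s | 20.0 |
| depleted-pool recovery | ~20 s, exponential $\tau \approx 6.5$ s | 19.7 s, 6.56 s |

Three parameter groups realize them:

* **Gate duty cycle.** $\tau_{total} = 0.1$ s and
  $\Delta[\mathrm{Ca}^{2+}]_{total} = 167.5$ µmol/L against the 20 µmol/L
  threshold give $t_w = 212.5$ ms, an 85% duty cycle at 4 Hz. The free
  transient keeps its own faster clearance
  ($\tau_{Ca} = 0.1/\ln 20 \approx 33$ ms, i.e. 95% recovery in the
  ~100 ms observed experimentally); the slower total-transient decay
  reflects buffered Ca²⁺ being released back as the free pool is pumped
  out. A shorter window (e.g. a total load of only twice threshold, 23 ms)
  cannot reproduce the 17 vesicles/s operating point under any release
  scheduling we examined.
* **Return kinetics.** $\tau_r = 6.55$ s with a non-binding maximum return
  rate ($v_{rm} = 30$/s > $h_m/\tau_r = 29$/s) makes the recovery of an
  emptied pool a clean exponential: the fitted time constant is 6.56 s and
  the integer-valued pool crosses 95% of capacity at 19.7 s.
* **RRP size and preparation threshold** as described above, which also
  fix the steady occupancy floor: at saturating energy the pool settles at
  $h_m - 17\tau_r \approx 0.42\,h_m$, so occupancy stays above 40% across
  the whole energy sweep — vesicle pools are hard to exhaust under
  physiological regulation.

# Metabolic regulation of the cycle

ATP both fuels the cycle and regulates it. Time is split into `window`-
second periods (default 10 s, the resolution at which leaving rates are
conventionally reported). The actual consumption of window $k$ is
$E^a = 1.64\times10^5 \cdot N_{vesicle}$; the desired level $E^d$ is an
exogenous setpoint (ATP/s × window). Minimizing $f(\tau_s) = |E^a - E^d|$
by a gradient-sign scheme gives the bounded update

$$\tau_s(k+1) = \tau_s(k) + \lambda_k\left(\frac{2}{1 + e^{-(E^a - E^d)/c}} - 1\right)$$

— an energy surplus slows the cycle, a deficit accelerates it, and the
sigmoid bounds every step by $\lambda_k$. Two numerical choices matter:

* **Energy scale $c$.** The raw difference $E^a - E^d$ is of order $10^6$
  ATP, which saturates the sigmoid and makes the update bang-bang.
  Dividing by one vesicle-equivalent ($c = 1.64\times10^5$) preserves the
  sign and form while giving a usable gradient near the fixed point
  (a one-vesicle mismatch moves $\tau_s$ by $0.46\lambda_k$). Setting
  `energy_scale = 1` recovers the literal bang-bang update.
* **Step schedule.** $\lambda_k = \lambda_0/(1 + k/\kappa)$ with
  $\lambda_0 = 0.4$ s, $\kappa = 25$: large early steps cover the full
  admissible range $\tau_s \in [0.005, 10]$ s within ~40 windows (the
  lowest energy setpoints have fixed points near $\tau_s \approx 8$ s),
  while the decay shrinks the steady-state oscillation to a few percent
  of $E^d$.

At the reference setpoint of $8.2\times10^5$ ATP/s (5 vesicles/s) under
4 Hz drive, the loop starts unconstrained (~170 vesicles leave in the
first 10 s window), then $\tau_s$ climbs to ~1.0 s and the leaving rate
settles at 50 vesicles per 10 s with $|E^a - E^d|$ a few percent of
$E^d$ — and the release probability lands at 0.25, inside the
experimentally optimal band. Because consumption is monotone in cycle
speed, steady release probability is nondecreasing in the energy setpoint;
both properties are tested.

Whether the sigmoid argument should be per-window or per-second energy is
not determined by the formulation; the package uses per-window totals with
the 10-s default window, documented in the configuration.

# Spike-train information and energy metrics

With a minimum interspike bin $\delta$, a train at frequency $f$ is a
Bernoulli bin sequence with occupancy $f\delta$, carrying
$[-f\delta \log_2 f\delta - (1-f\delta)\log_2(1-f\delta)]/\delta$ bits/s
(0 at both occupancy extremes by the $0\log 0$ convention). Integration
energy is $1.2\times10^8 f$ ATP/s, and their ratio is the ATP cost per
bit. $\delta$ is genuinely a free parameter; the package default of 2 ms
reflects the 1–2 ms action potential plus refractory period. At that
$\delta$ the cost per bit rises monotonically over $f \in (0, 100]$ Hz to
$3.3\times10^7$ ATP/bit at 100 Hz, under the $5\times10^7$ budget cited
for cortical neurons; the bound is conditional on $\delta$ and the CLI
`metrics` subcommand reports the value at any chosen $\delta$.

# The compartmental neuron

The dendritic integration experiments run on a reduced CA1 pyramidal
neuron: nine dendritic compartment classes with length fractions,
diameters and synapse densities from the classical quantitative anatomy of
Megías et al. (2001), scaled to 11,500 µm of total dendritic length, plus
a 20 µm soma and a 40 µm axon initial segment (AIS). Each class is one
equivalent-cylinder section (basal chain off the soma; trunk in series
with obliques and the tuft distally), subdivided into at least 11 segments
(more for electrotonically long sections, capped at 101). The membrane
carries transient Na⁺, delayed-rectifier K⁺ and leak with the standard
rate functions expressed at a −65 mV rest and sped up by a Q10-style
factor of 3 (≈35 °C); the voltage step is backward Euler with Hines
elimination on the tree (unconditionally stable) at dt = 25 µs, with
interpolated rate tables for speed.

The electrical densities are the package's own parameterization — no
waveform-level reference is available — chosen so the model reproduces
the *bounded, qualitative* integration phenomena and verified across
seeds: quiescent at rest for 10 s; saturating the proximal basal class
(242 synapses at 10 Hz Poisson) drives firing above 100 Hz; saturating
the distal tuft (866 synapses) stays below 100 Hz; at matched counts,
classes closer to the AIS drive firing at least as hard; interspike
intervals never fall below 2 ms. Dendrites are moderately excitable
(gNa 50 mS/cm², supporting dendritic Na⁺ spikes as CA1 basal dendrites
do), which is what lets a 0.7 µm equivalent cylinder deliver suprathreshold
current to the soma; the 5 nS effective peak synaptic conductance likewise
absorbs the local cooperativity of the many parallel branches each
equivalent cylinder stands for. The non-monotonic "dip-then-rise"
frequency curves reported for some mid-apical compartments depend on
channel gradients (A-type K⁺, I_h) and back-propagation details that are
not part of this model and are not asserted anywhere.

All synapses are excitatory two-exponential conductances (rise 0.5 ms,
decay 3 ms, reversal 0 mV) driven by independent 10 Hz Poisson trains,
placed uniformly at random along their class under a seed; because the
waveform is linear in its events, synapses sharing a compartment are
aggregated into one state pair, so sweeps over thousands of synapses stay
cheap. Firing frequency is the spike count over the final 80% of the run.

# What the stimulus generators emulate — and what they do not

The three generators cover the study conditions: fixed-frequency trains
(4 and 100 Hz protocols), homogeneous Poisson trains (10 Hz synaptic
drive), and Gaussian-frequency episodes (repeated 50-s stimulations with
frequencies drawn from N(4, 1) Hz, truncated at zero by resampling since
negative frequencies are meaningless and the truncation bias at N(4,1) is
negligible). Spikes live in half-open windows `[0, duration)`; periodic
trains place their first spike at the phase offset (default 0). Episodes
are rendered back-to-back by default, with an optional silent gap, since
the protocols leave inter-episode timing unstated. Real presynaptic input
is none of these: no burstiness, no rate adaptation, no correlations
across synapses. Passing tests therefore demonstrate the model mechanics
under controlled drive, not forecasts for in-vivo spike statistics.

# Numerical choices and degenerate inputs

* Vesicle-cycle step: 1 ms; with the exact preparation update and the
  analytic gate, release counts change by well under 1% when the step is
  halved. Releases inside a step are scheduled oldest-prepared-first
  (tie: lowest slot index) onto the earliest-free site — deterministic
  replay with no RNG in the cycle itself.
* Release latency: gate windows open 0.2 ms after each spike, the
  reported latency between Ca²⁺ influx and exocytosis; this is an
  interpretation knob (`latency`), not a load-bearing calibration.
* Multi-spike free Ca²⁺: the excess over rest *resets* to the per-spike
  increment at each spike, matching the single-spike transient form; an
  additive-superposition mode is available (`accumulate = TRUE`) for
  sensitivity checks. The gate works off the total transient, so the
  distinction only matters for exported free-Ca²⁺ traces.
* Degenerate inputs are first-class: empty trains are valid (and give a
  constant resting Ca²⁺ trace, an empty gate, zero releases); a total
  Ca²⁺ load below threshold produces an empty gate plus a warning about
  the physiologically silent synapse; an empty train makes release
  probability an error rather than 0/0.
* The exponential recovery fit holds the pool capacity fixed and
  estimates only τ (Levenberg–Marquardt); flat or decreasing curves are
  rejected, and small non-monotone wiggles from measurement noise are
  tolerated (the fit stays within 10% under ±2-vesicle noise).
* Problem sizes used by the packaged experiments and tests: 100-s runs
  for the fixed-frequency operating points, 40 s for pool recovery,
  ~1000 s (100 windows) for regulated runs and the 6-level energy sweep,
  2-s integrations per dendritic grid point — each chosen as the shortest
  run that leaves the reported steady-state quantity unchanged at the
  precision reported.

# Known limitations

* The vesicle cycle has no reserve-pool compartment, no receptor or
  cleft kinetics, and no short-term plasticity beyond what the
  pool/site/preparation dynamics induce; Ca²⁺ extrusion and transmitter
  recycling costs are excluded from the energy ledger by construction.
* The "desired energy" is an exogenous setpoint, not a mechanistic ATP
  production/diffusion model.
* The neuron model omits inhibition, NMDA voltage dependence, dendritic
  Ca²⁺ spikes and channel gradients; its electrical parameters are
  calibrated to bounded, qualitative claims only.
* The release-rate caps are enforced as hard deterministic limits;
  stochastic vesicle-release variants (binomial release per site) are out
  of scope.

# A worked regulated run

```{r regulated, eval = FALSE}
library(synvesim)
syn <- synapse_params()
ca <- calcium_params()
run <- simulate_regulated(periodic_train(4, 600), syn, ca,
                          regulation_params(e_desired = 8.2e5))
steady_state(run)
#> $leaving_per_window : 50
#> $rp                 : 0.25
#> $tau_s              : ~1.0
#> $objective_rel      : < 0.1
#> $pool_ratio         : ~0.83
```
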
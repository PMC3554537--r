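---
title: "Modeling post-traumatic homeostatic plasticity on a cortical lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling post-traumatic homeostatic plasticity on a cortical lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`traumanet` simulates how a cortical network reorganizes in the first hours
after deafferentation trauma, when homeostatic synaptic plasticity (HSP) —
the slow, multiplicative adjustment of synaptic conductances that drives
firing rates back toward a set point — is still spatially constrained to
its glial (TNF-alpha-releasing) sources. The package's central question is
how the *spatial scale* of the upregulating arm of HSP, and its functional
segregation into astrocytic microdomains, shapes the emergence of
paroxysmal population bursts, the model analogue of interictal epileptiform
discharges.

## The network

Neurons occupy every site of a square lattice (6400 at full scale, 80x80).
Every fifth site in row-major order is an inhibitory interneuron (IN), so
pyramidal neurons (PY) make up 80% of the population. Each neuron may form
synapses only inside its *synaptic footprint*, the neuron-centered
`(2a) x (2a)` site block with `a = 5` by default. Because an even-sided
block cannot be symmetric about a site, the package fixes the offset
convention `[-a, a-1]` in each dimension; footprints are clipped at the
lattice edge (no torus — boundary effects and propagating waves are part of
the science here). Every directed candidate pair connects independently
with probability 55/79 for excitatory and 12/20 for inhibitory presynaptic
partners; those values are back-derived so that an interior PY neuron
receives on average 55 PY and 12 IN synapses (its interior footprint holds
79 PY and 20 IN candidates). Incoming PY-to-PY synapses are capped at 75
per neuron by random pruning. When the footprint half-length is changed,
connection probabilities are renormalized by the ratio of interior
candidate counts so the expected in-degree stays the same — isolating the
effect of connectivity *scale* from connectivity *amount*.

## Neuron and synapse dynamics

Membrane dynamics are the canonical two-variable Morris--Lecar model of
type I (saddle-node) excitability, with the fast inward conductance labeled
sodium: instantaneous activation `m_inf(V)`, sigmoidal recovery steady
state `w_inf(V)`, cosh-shaped recovery rate, plus a phenomenological
spike-triggered adaptation current `g_ahp * z * (V - E_K)` on PY neurons
only (`z` jumps by `delta_z` per spike, decays with `tau_z = 400` ms).
Defaults (`default_params()`): `C = 20` uF/cm^2, `g_na = 4`, `g_k = 8`,
`g_l = 2` mS/cm^2, `E_Na = 120`, `E_K = -84`, `E_L = -60` mV, `V1 = -1.2`,
`V2 = 18`, `V3 = 12`, `V4 = 17.4` mV, `phi = 0.1` /ms. With these values
the isolated neuron starts firing near 45 uA/cm^2, sustains rates up to
roughly 32 Hz, and enters depolarization block beyond ~120 uA/cm^2; `phi`
was set at the upper end of the conventional range so that burst-driven
firing can substantially exceed the asynchronous baseline.

Synapses are conductance-based and deterministic. A presynaptic spike
instantaneously increments the postsynaptic conductance by
`ghat * s * D`, which then decays exponentially (`tau_AMPA = 2` ms,
`tau_GABA = 6` ms). PY-to-PY synapses additionally carry an NMDA
conductance modeled as the difference of slow (100 ms) and fast (5 ms)
exponential traces receiving equal per-spike increments, peak-normalized
to 60% of the AMPA peak; no magnesium-block voltage dependence is
included. Short-term depression acts on excitatory synapses only:
`D <- (1 - d) D` per presynaptic spike (`d = 0.1`) with exponential
recovery (`tau_D = 500` ms); GABA synapses keep `D = 1`. Because `D`
depends only on the presynaptic spike train, the engine stores it per
presynaptic neuron, and all conductances sharing a decay constant are
pooled per postsynaptic neuron — an exact aggregation that makes the
compiled core's cost per step linear in the number of neurons rather than
synapses.

Every neuron also receives an external afferent conductance driven by an
independent 100 Hz Poisson process (`tau = 3` ms). The per-type afferent
peak conductances are the model's free excitability knobs; they were set
by `calibrate_intact_rates()` (alternating per-type bisection) so that the
intact 40x40 network fires asynchronously at ~5 Hz (PY) and ~10 Hz (IN).
The calibrated values (2.67 and 4.4 mS/cm^2) live in `default_params()`.
The intact network at these defaults was verified to be monostable and
burst-free; parameter sets with substantially stronger recurrent coupling
were rejected during design because they made the intact state bistable.

## Trauma and homeostatic plasticity

Trauma is deafferentation: a fraction `f_d` of neurons (PY and IN alike)
has its afferent Poisson rate multiplied by 0.1 (100 Hz to 10 Hz). *Focal*
trauma deafferents the smallest block of whole left-edge columns holding
at least `f_d N` neurons; *diffuse* trauma draws the same number uniformly
at random.

Each PY neuron's incoming synapses carry a multiplicative HSP scaling
factor `s` (initialized at 1, clipped to `[0, 5]`), applied to the initial
peak conductance. With `u` the upregulating drive and `v` the
downregulating drive (both in Hz, target `r_t = 5` Hz),

    ds_exc/dt = kappa * [ max(0, 1 - u/r_t) - max(0, v/r_t - 1) ]
    ds_gaba/dt = -kappa * [ max(0, 1 - u/r_t) - max(0, v/r_t - 1) ]

i.e. chronically *inactive* presynaptic pools recruit upregulation of
excitation (and downregulation of inhibition), while a *hyperactive*
postsynaptic neuron recruits the opposite — a rectified-linear reading of
the conditional up/down logic, with a single rate constant `kappa` for
both arms. The four schemes differ only in the drives: `local` uses the
mean rate of the PY neurons presynaptic to the domain for `u` and the
neuron's own rate for `v`; `global` uses the network PY mean for both;
`global_up_local_down` mixes them; `global_up_no_down` drops the `v` term.
Presynaptic averages weight each presynaptic PY neuron equally, and HSP
applies only to synapses onto PY neurons. Firing rates enter through an
online exponential-moving-average estimator (`tau_rate = 2` s), and
scaling factors update every 100 ms of simulated time.

`kappa = 0.1` /s is deliberately accelerated relative to the hours-long
biological process so that the post-traumatic steady state is reached
within a couple of simulated minutes; since the steady state, not the
transient, carries the results, this only compresses the time axis. The
20x20 test preset doubles it to 0.2 /s so the transition completes well
inside its shorter equilibration window — at that scale the steady state
alternates quiet and bursting phases, so the rate-based steadiness
criterion rarely fires and runs use the full fixed protocol, which keeps
conditions directly comparable.

### Microdomains

`partition_random()` deals every incoming synapse of a PY neuron
(excitatory and inhibitory alike) round-robin over a random permutation
into `M` groups, so group sizes differ by at most one; each group is an
astrocytic microdomain whose upregulating drive is the mean rate of its
own glutamatergic inputs. Domains that receive no glutamatergic synapse
are inactive and frozen. `partition_segregated()` builds the two-domain
"palisading astrocyte" configuration: one domain holds exactly the inputs
from intact presynaptic neurons, the other those from deafferented ones.

## Burst detection and analysis

Simulated time is partitioned into non-overlapping 100-ms bins over a
recorded subset of neurons: for focal trauma, 5 adjacent full rows
perpendicular to the trauma boundary (so the strip spans the
intact-to-deafferented propagation axis), centered on the lattice midline;
for diffuse trauma, a centered 20x20 block. A bin is paroxysmal when at
least `f_min = 0.5` of the recorded neurons fire in it *and* the mean rate
of those active neurons exceeds `r_min`; consecutive paroxysmal bins merge
into one event (otherwise the event count would scale with burst
duration). The mean rate is computed over the *active* neurons so that the
two parts of the criterion are not redundant.

`r_min` defaults to 15 Hz. This value was calibrated against raster
appearance under the package's parameter set: asynchronous background
bins never exceed ~13 Hz (an active neuron contributes at least one spike
per 100 ms bin, i.e. 10 Hz, so the background sits just above that),
while wave events run at ~15-23 Hz, bounded by the neuron's ~32 Hz f-I
ceiling and depolarization block. A 20 Hz threshold would bisect the
event cluster; 15 Hz separates the two modes cleanly. Note that the
active-fraction part alone does not separate the modes (IN neurons at
10 Hz make the background active fraction hover near 0.5); the rate part
carries the discrimination.

The analysis layer also provides intra-burst statistics per neuron type,
correlation-normalized cross-covariance of binned counts (up to 2000
random pairs), spatial rate profiles along the trauma axis, the boundary
set (intact neurons within one footprint of a deafferented neuron that
itself borders the intact region), and the severed-connectivity control
(`sever_boundary_connections()` removes every synapse crossing the
deafferentation boundary).

## Experiment pipeline and problem sizes

`run_simulation()` chains the phases: build, intact equilibration (HSP
off; the intact network is at target, so enabling it there is
behavior-neutral), trauma at `t = 0` with HSP on, evolution until the
network PY rate stays within 1 Hz of the target (or a time cap), then a
measurement window with burst detection and scaling-factor statistics.
`sweep_simulations()` maps this over grids of `f_d`, scheme, `M`,
footprint size, and trauma pattern with independent seeds, and
`write_config()`/`read_config()` round-trip the full configuration as
JSON. All randomness flows through R's RNG, so a `(config, seed)` pair
reproduces results bit-for-bit.

Three documented problem sizes (`sim_preset()`): the full-scale 80x80
lattice; a *reduced* 40x40 lattice with a 50 s measurement window, used
for the quantitative rate checks; and a *test* 20x20 lattice with 16 s
measurement windows, used by the package's own test suite for the
qualitative trend checks (burst-rate orderings across HSP schemes,
microdomain counts, segregation, and the severed control). Trends at the
test scale were verified to match the reduced scale in direction; absolute
burst rates do depend on lattice size, which is why the tests assert
orderings and signs rather than values.

## What the generator does and does not emulate

The synthetic networks emulate the statistical structure the science
needs: local footprint-limited connectivity, the 80/20 cell-type mix, the
in-degree distribution, Poisson afferent drive, and the trauma patterns.
They do not emulate cortical layers, distance-dependent connection
profiles, conduction delays, stochastic vesicle release, ion-concentration
dynamics, or any biochemistry of the glial TNF-alpha cascade — the HSP
rule stands in for that cascade's net effect. Passing tests therefore
support claims about this model class, not about any particular cortical
tissue.

## Numerical choices and limitations

Integration is fixed-step: explicit Euler for the membrane potential and
exponential Euler for the gating, adaptation, depression, and conductance
variables, at `dt = 0.05` ms (halving `dt` changes the spike count of a
reference run by under 2%). Spikes are upward crossings of 0 mV guarded
by a latch so plateaus and depolarization block count once. The afferent
process is realized in the engine by per-step Bernoulli thinning
(`p = rate * dt`), which matches the Poisson rate exactly in expectation;
the standalone `afferent_events()` draws exact Poisson event sets.
Degenerate inputs are handled explicitly: empty neuron subsets error,
zero-variance trains are skipped in covariance computations, microdomains
without glutamatergic synapses are frozen, and a vanished intact
conductance makes the percent-change statistic error rather than return
infinity.

Known limitations: burst rates at reduced lattice sizes are lower than at
the full 80x80 scale (fewer boundary neurons nucleate fewer waves), the
intra-burst rate ceiling is set by the type-I Morris--Lecar f-I curve, and
the HSP steady state is defined operationally by the rate criterion rather
than by a fixed equilibration time.
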
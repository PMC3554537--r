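# traumanet

Simulation of post-traumatic homeostatic plasticity and paroxysmal
bursting in a two-dimensional cortical network model, for computational
neuroscientists studying early post-traumatic epileptogenesis.

After deafferentation trauma, homeostatic synaptic plasticity (HSP) —
driven in part by glia-released TNF-alpha — multiplicatively rescales
synaptic conductances to restore firing rates, and in doing so can
transform asynchronous spiking into paroxysmal population discharges, the
network analogue of interictal epileptiform spikes. Early after trauma the
upregulating arm of HSP is spatially constrained to its glial sources.
`traumanet` implements this regime: a lattice of Morris–Lecar neurons
(80% pyramidal, 20% inhibitory) with footprint-limited random
connectivity, AMPA/NMDA/GABA conductance synapses with short-term
depression, Poisson afferent drive, focal or diffuse deafferentation, and
an HSP rule whose scaling factor `s` per synapse group evolves as

    ds_exc/dt = kappa [ max(0, 1 − u/r_t) − max(0, v/r_t − 1) ],
    ds_gaba/dt = −kappa [ ... ],

where the upregulating drive `u` is the mean firing rate of the
presynaptic pool (local scheme), or the network mean (global schemes),
and the downregulating drive `v` is the postsynaptic neuron's own rate.
Each pyramidal neuron's inputs can be partitioned into `M` astrocytic
microdomains — each upregulated by its own glutamatergic inputs only — or
segregated into two domains by presynaptic deafferentation status
("palisading astrocyte" configuration). The analysis layer detects
paroxysmal bursts (100-ms bins; at least half the recorded neurons active
above a threshold rate), and computes burst rates, intra-burst statistics,
cross-covariances, spatial rate profiles, and boundary sets.

## Worked example

Build a reduced-scale network, apply focal trauma to half the lattice,
let the local HSP rule reach its post-traumatic steady state, and measure:

```r
library(traumanet)

run <- run_simulation(
  lattice = lattice_config(side_length = 20),
  trauma  = trauma_config("focal", f_d = 0.5),
  params  = sim_preset("test")$params(),
  intact_ms = 2000, max_hsp_ms = 50000, measure_ms = 20000,
  seed = 1)
run
#> trauma_run: burst rate 0.250 Hz (5 bursts), PY 4.72 Hz, IN 5.11 Hz, HSP not converged
round(run$summary$s_pp_mean_deaff_pre, 2)
#> [1] 2.7
round(run$summary$s_pp_mean_intact_pre, 2)
#> [1] 1
```

The deafferented network has returned to near the 5 Hz pyramidal target
rate, but the restored activity is organized into paroxysmal bursts
(0.25 per second) that nucleate at the trauma boundary ("not converged"
means the rate-based steadiness criterion did not fire before the time
cap: at this scale the steady state alternates quiet and bursting
phases, so the run simply uses the full protocol). Synapses from
deafferented presynaptic neurons were upregulated almost 3-fold more
than those from intact neurons. Severing the synapses that cross the
intact–deafferented boundary (`sever = TRUE`) abolishes the bursts;
increasing the microdomain count `M` or segregating inputs by
presynaptic status (`default_params(hsp = list(segregated = TRUE))`)
lowers the burst rate under focal trauma.

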
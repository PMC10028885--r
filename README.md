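# aancolumn

Biophysical neocortical column modeling of the auditory awareness
negativity (AAN).

## What this package is for

When a listener detects a faint tone stream inside a random multitone
masker, source-localized auditory-cortex responses contain a sustained
negativity between roughly 100 and 300 ms (peaking near 180 ms) that is
absent when the same tones are missed — the auditory awareness negativity.
`aancolumn` is for researchers who want a cell- and circuit-level account
of such source waveforms: it simulates a reduced two-layer cortical column
(100 pyramidal neurons and 35 basket interneurons per layer; 270 cells)
of conductance-based, multi-compartment neurons, computes the primary
current dipole

```
p(t) = sum over PN axial segments of I_axial(t) * dz     [nAm, after scaling]
```

(positive = current up the dendrites toward the pia), and activates the
column with sequences of exogenous drives:

* **proximal** (feedforward / lemniscal-thalamic): basal+oblique PN
  dendrites and basket somata in both layers — net excitation drives the
  dipole up;
* **distal** (feedback / non-lemniscal): PN apical tufts in both layers
  and layer-II/III basket somata — net excitation drives the dipole down.

The undetected-condition response is modeled by a proximal drive at
47.8 ± 13.2 ms and a distal drive at 84.3 ± 15.1 ms; the detected
condition adds one broad distal drive at 169.3 ± 50.4 ms that reproduces
the AAN and elicits calcium-dependent burst firing in layer-V pyramidal
cells.  Alternative circuit accounts — doubled perisomatic GABA-B
inhibition (0.025 → 0.05 uS), a reduced drive sequence, and a
proximal-distal-proximal sequence — are built in for comparison.  Drive
parameters are fitted to target waveforms by seeded, derivative-free RMSE
minimization.  A synthetic-data module generates empirical-like target
waveforms and the oddball detection paradigm (10 tones per 5-s sequence,
500-ms SOA, press-relative detected/undetected binning), so the whole
pipeline runs without any external data.

## Worked example

```r
library(aancolumn)

net <- build_default_column(seed = 1, scale = 300)
cell_counts(net)
#>     L23_PN      L5_PN L23_basket  L5_basket      total
#>        100        100         35         35        270
effective_cell_count(net)
#> [1] 60000

variant <- build_variant("preferred")
cfg <- simulation_config(n_trials = 10, base_seed = 1)
undet <- simulate_dipole(variant_network(variant, "undetected"), cfg)
det   <- simulate_dipole(variant_network(variant, "detected"), cfg)

# morphology of the two simulated source waveforms (nAm)
range(undet$total[undet$time >= 40 & undet$time <= 60])    # P1-like positivity
#> [1] 3.25 6.67
range(undet$total[undet$time >= 90 & undet$time <= 110])   # N1-like negativity
#> [1] -9.60 -5.17
dw <- difference_waveform(det, undet)
dw$time[which.max(abs(dw$amplitude))]                      # AAN peak latency (ms)
#> [1] 175

# layer-V pyramidal spiking distinguishes the conditions (100-300 ms)
st <- spike_stats(spike_raster(attr(det, "batch")), c(100, 300))
st[st$cell_class == "L5_PN", c("n_spikes", "n_bursts")]
#>   n_spikes n_bursts
#>       2736      374
```

The detected condition shows bursty layer-V firing (about 274 spikes and
37 bursts per trial across the population of 100 layer-V cells), while
the undetected condition has almost none —
the laminar signature the model ties to conscious detection.  Fitting and
model comparison:

```r
targets <- generate_targets(erf_component_set(seed = 1))
fit <- optimize_drives(variant, "detected", targets$detected,
                       bounds = list(dist2 = list(mean_time = c(135, 205))),
                       budget = 10, seed = 1)
cmp <- compare_models(lapply(c("preferred", "perisomatic_inhibition",
                               "reduced", "prox_dist_prox"), build_variant),
                      targets, budget = 0)
```

`compare_models()` tabulates per-condition RMSE, layer-V spiking, and two
qualitative flags (early N1 captured; AAN captured); on the shipped
targets the preferred model fits best in both conditions, the perisomatic
variant silences layer-V cells entirely, and the reduced sequences miss
the early N1.

## Layout

* `R/`, `src/engine.cpp` — cell/network construction, synapses and
  drives, the compiled fixed-step integrator, observables (dipole,
  laminar decomposition, LFP, rasters), fitting, variants, synthetic data.
* `inst/extdata/model_variants.yaml` — the canonical drive sequences and
  calibrated weights for all four variants.
* `vignettes/column-model-methods.Rmd` — model equations, assumptions,
  numerical choices, calibration rationale, limitations.
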
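---
title: "A laminar column model of the auditory awareness negativity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A laminar column model of the auditory awareness negativity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

The auditory awareness negativity (AAN) is a sustained negative deflection
(~100-300 ms after stimulus onset, peaking near 180 ms) in source-localized
auditory-cortex responses that appears when a listener consciously detects a
target sound in noise and is absent when the same sound is missed.
`aancolumn` implements a biophysical circuit-level account of this
component: a reduced two-layer neocortical column of conductance-based
pyramidal (PN) and basket neurons whose net longitudinal dendritic current
-- the primary current dipole that MEG measures -- is driven by sequences
of exogenous *proximal* (feedforward, lemniscal-thalamic) and *distal*
(feedback / non-lemniscal) synaptic drives.  The central hypothesis the
package operationalizes: the undetected-condition response (a P1-like
positivity near 50 ms and an N1-like negativity near 100 ms) is produced by
one proximal drive (47.8 +/- 13.2 ms) followed by one distal drive (84.3
+/- 15.1 ms), and the AAN is produced by one additional, temporally broad
distal drive (169.3 +/- 50.4 ms) targeting the apical dendrites, whose
interaction with the earlier drives also elicits calcium-dependent burst
firing of layer-V PNs.

## Model structure

**Cells.** Four classes: layer-II/III and layer-V PNs (five compartments:
basal, oblique, soma, apical trunk, apical tuft) and single-compartment
basket interneurons in each layer.  The default column instantiates 100
PNs per layer on a ten-by-ten grid at 100-um pitch and 35 baskets per
layer, 270 cells total.  Layer-V PNs span 1000 um of apical extent against
300 um for layer II/III, and their apical compartments carry a
high-voltage-activated Ca channel with slow voltage-dependent inactivation,
a Ca-dependent K channel, and a first-order calcium pool -- the machinery
that converts strong tuft input into somatic bursts.  All compartments
carry transient Na, delayed-rectifier K (Traub-Miles rate functions,
activation offset -58 mV) and leak.  The leak reversal of every
compartment is balanced at build time so the stated resting potential
(-65 mV) is an exact fixed point of the unstimulated dynamics; the
package asserts the resting column drifts by less than 1 mV over 500 ms.

**Counts.** The three-to-one PN-to-basket ratio and the printed 270-cell
total are mutually inconsistent at 33 or 35 baskets per layer; the package
uses 35 per layer so the 270-cell total (and the 200-PN count) is exact,
since those totals are the testable numbers.

**Synapses.** AMPA/NMDA and GABA-A/GABA-B double-exponential conductances
(rise/decay 0.5/5, 1/20, 0.5/5, 1/50 ms; reversals 0, 0, -80, -95 mV),
NMDA with a Jahr-Stevens magnesium block.  These values are not printed in
the source material; they are standard choices that satisfy the stated
orderings (NMDA slower than AMPA, GABA-B slower and more prolonged than
GABA-A).  Local connectivity is fixed in structure: all-to-all PN-to-PN
excitation (with a Gaussian horizontal-distance weight falloff, space
constant 300 um for PN-PN and 100 um otherwise, mirroring how reduced
column models keep aggregate input bounded without severing any
connection), PN-to-basket excitation, basket-to-PN somatic GABA-A+GABA-B,
and layer-II/III basket inhibition of the layer-V apical trunk.  The
layer-V perisomatic GABA-B weight is 0.025 uS by default -- the one printed
local conductance -- and the perisomatic-inhibition variant doubles exactly
that entry to 0.05 uS.

**Drives.** A drive is a named proximal or distal input with a Gaussian
start-time distribution, a per-synapse spike count, and per-target-class
AMPA/NMDA weights.  Proximal drives contact PN basal+oblique dendrites in
both layers and both basket classes' somata; distal drives contact PN
apical tufts and layer-II/III basket somata only (layer-V baskets receive
no distal input, which is what lets the perisomatic variant engage them
through a proximal drive instead).  On each trial every target synapse
independently receives `n_spikes` event times from
`Normal(mean, sd)` truncated at 0 ms.  "Per synapse" follows the stated
definition (inputs provided to each synapse); one target compartment is
one synapse, with AMPA and NMDA co-activated.

## Numerics

The integrator (compiled, fixed step, default dt = 0.025 ms) uses
exponential-Euler gating updates against tabulated rate functions (0.05 mV
grid, linear interpolation) and a semi-implicit voltage update in which
membrane, synaptic and injected conductances are implicit and axial
neighbour voltages explicit.  Synaptic conductances with identical target
compartment and receptor are merged into one rise/decay state pair; events
(drive spikes and spike-triggered local events, uniform 1-ms delay) are
applied on the step grid through a priority queue.  Spikes are upward
somatic crossings of 0 mV with a 3-ms lockout.  A step-halving test
(dt 0.025 vs 0.0125) bounds the averaged-dipole discrepancy below 1% of
its peak-to-peak range, and a per-step bookkeeping test verifies that
membrane, synaptic, axial and injected currents sum to the capacitive
current to machine precision.  Voltages beyond 200 mV abort with a
diagnostic.  Epochs run from -50 ms (drive-free burn-in) to 450 ms;
observables are recorded at 1 kHz; the averaged dipole is scaled (default
300), smoothed with a normalized 30-ms Hamming window (the empirical
smoothing is unstated; this choice is exposed in the API), and
baseline-corrected over -50-0 ms.

## Observables

The dipole is the sum over PN axial segments of axial current times signed
vertical extent (positive = toward the pia), in nAm after scaling;
laminar decomposition restricts the sum to each PN class and the two
components are asserted to sum to the total on every trial.  The scale
factor multiplies the dipole only -- it instantiates no cells -- so the
default column stands in for 200 x 300 = 60,000 synchronously driven PNs.
Laminar LFPs use the point-source forward model
`phi = I / (4 pi sigma r)` with sigma = 0.3 S/m on a 50-contact, 100-um
line through the grid center; all transmembrane currents, basket cells
included, contribute (whether interneurons are included is unstated in the
source; including every current is the physically complete choice).
Spike rasters are tallied per class, a burst being >= 2 spikes of one cell
within 30 ms.

## Calibration and the gain of the column

Absolute synaptic weights, compartment geometry and channel densities are
not printed in the source material and were calibrated once, as package
defaults, against the shipped synthetic targets using the qualitative
constraints the circuit account fixes: proximal-only drive deflects the
dipole upward and distal-only downward; the undetected sequence produces a
positive deflection near 50 ms and a negativity near 100 ms with layer-V
PNs silent in 100-300 ms; the detected sequence adds a broad 100-300 ms
negativity generated mostly in layer V together with burst firing of
layer-V PNs; doubling the perisomatic GABA-B weight abolishes layer-V
spiking.  Two calibration outcomes deserve note:

* A reduced column at dipole scale 300 yields waveforms of order 5-10 nAm.
  The synthetic-target amplitudes (P1 +8, N1 -10, AAN -12 nAm) were set
  at the low end of plausible source amplitudes for near-threshold
  standard tones under informational masking, consistent with the choice
  of a 300x (rather than thousands-fold) scaling factor in the study
  design.  They are configuration parameters, not fitted values.
* The layer-V somatic delayed-rectifier density is raised (0.2 S/cm^2)
  and the thick apical trunk made leaky (3e-4 S/cm^2), which routes
  proximal charge up the column as sustained subthreshold current rather
  than early firing; layer-II/III apical compartments carry low Na and
  high K so that tuft input cannot trigger somatic spiking there.  These
  choices realize, respectively, the passive dipole build-up behind the
  early positivity and the laminar asymmetry of tuft-driven bursting.

## Fitting and model comparison

`rmse()` compares a simulated dipole with a target over 0-450 ms (the
post-onset epoch; the original optimization window is unstated).
`optimize_drives()` is a seeded, derivative-free coordinate pattern search
over non-frozen drive parameters (start-time mean, sd, and a per-drive
weight scale) with common random numbers across evaluations, so the
objective is deterministic given the seed and the best-so-far record is
non-increasing by construction.  Three trials per evaluation is the
default (ten for final reported fits; the trade-off is configurable).
Frozen drives -- the first two of the preferred detected condition, the
first proximal of the reduced sequences -- are never touched, which the
tests assert bitwise.  `compare_models()` reproduces the model-selection
logic across the four variants: per-condition RMSE, layer-V spike and
burst counts in 100-300 ms, an early-N1 flag (undetected-fit minimum in
80-120 ms below half the P1 peak) and an AAN flag (mean fitted difference
negative over 100-300 ms).  On the shipped targets the preferred model
attains the lowest RMSE in both conditions, the perisomatic variant shows
zero layer-V spikes, and the reduced and proximal-distal-proximal variants
fail the early-N1 flag -- the same qualitative ranking the circuit account
argues for.  The published RMSE values were computed against empirical
grand averages that are not deposited, so they are not numeric targets
here.

## Synthetic data

`generate_targets()` builds the two target waveforms from Gaussian
components (P1 +8 nAm at 50 ms, sd 12; N1 -10 nAm at 100 ms, sd 16; AAN
-12 nAm at 180 ms, sd 50, support spanning roughly 60-360 ms) on a 500-Hz
grid over -50-450 ms, plus Gaussian noise band-passed (zero-phase, 2nd
order Butterworth) to 0.15-15 Hz.  The deterministic components are
band-limited by construction, so the filter is applied to the noise only
and component latencies stay exact.  `generate_oddball()` emulates the
paradigm (5-s sequences, ten 100-ms tones at 500-ms SOA, one uniformly
placed deviant, optional synthetic press time), and `bin_tones()`
implements press-relative binning: the two standards immediately before
the press and all standards after it are detected, earlier standards are
undetected, the deviant belongs to neither bin ("two tones immediately
preceding" is read as standard tones only, since deviant responses are
excluded from modeling).  What the generator does *not* emulate: single
trials, sensor noise correlations, source-localization bias, or
between-subject variability -- passing tests show the pipeline recovers
its own conventions, not that the circuit model fits real MEG.

## Problem sizes and limitations

Tests and the acceptance script run the full 270-cell column: single
trials for oracle checks, two to three trials for morphology checks, ten
trials (the study's trial count) for final fits and the spiking contrast,
and an optimization budget of a few dozen evaluations at three trials
each for parameter recovery.  Known limitations: no layer IV and no
explicit thalamus (inputs are parameterized drives); basket cells are
points; one column, one dipole -- no sensor-space projection; the
optimizer is a local pattern search, adequate for the unimodal RMSE
landscapes exercised here but not a global search; and all empirical
claims are relative to synthetic stand-ins for the unavailable
grand-average waveforms.
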
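---
title: "Modelling the homogeneity preference of Off-Transient alpha ganglion cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the homogeneity preference of Off-Transient alpha ganglion cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offtalpha)
```

## The problem

Most retinal ganglion cells respond more strongly to spatially structured
stimuli than to uniform ones, because their receptive fields pool many small
rectifying subunits. Off-Transient (OffT) alpha ganglion cells in mouse are a
striking exception: at mesopic light levels they respond *more* strongly to a
spatially uniform ("linear-equivalent") disc than to the natural image patch
the disc was derived from, and they fire a robust burst when spatial
structure is switched *off*. `offtalpha` implements a circuit model of this
homogeneity preference, the stimulus constructions used to probe it, and the
summary statistics used to quantify it.

Two circuit features jointly produce the effect:

1. **Spatially local inhibition.** Inhibitory input reaching the cell (and,
   presynaptically, the bipolar terminals that excite it) is tuned to *finer*
   spatial scales than excitation. Fine structure recruits strong inhibition;
   coarse or uniform stimuli do not, because each inhibitory subunit carries
   a strong, local antagonistic surround.
2. **Synaptic depression gated by presynaptic inhibition.** The excitatory
   synapses are tonically active and therefore tonically depressed (baseline
   vesicle occupancy well below one). Presynaptic inhibition recruited by
   structured stimuli shuts down release, letting the vesicle pool recover;
   when the structure disappears, the recovered gain produces a large
   excitatory rebound.

## Model structure

### Inhibitory pathway (static LN)

Each inhibitory subunit `j` applies a space–time separable linear kernel to
the stimulus contrast `S(x, t)` and half-wave rectifies the result:

    I_j(t) = [ sum_x RF_inh(x - y_j) * (T_inh * S(x, .))(t) ]_+

The spatial profile is a difference of Gaussians,
`RF(x) = exp(-x^2 / 2*sigma_c^2) - delta * exp(-x^2 / 2*sigma_s^2)`, with
relative surround strength `delta` (`subunit_profile()`). In the
two-dimensional model each lobe is normalized to unit integral before the
subtraction, so a uniform stimulus of contrast `c` drives an inhibitory
subunit with `(1 - delta) c` regardless of its size: with `delta = 0.9` a
uniform field recruits a tenth of the inhibition that matched local
structure does. This integral cancellation is the "strong, local surround"
in quantitative form.

### Excitatory pathway (dynamic LN with presynaptic inhibition)

Each excitatory subunit `i` receives a filtered drive
`E_raw_i(t) = E0 + (spatial weights %*% stimulus) * (T_exc * .)(t)`,
from which pooled presynaptic inhibition is subtracted:

    E_i(t)      = Phi( E_raw_i(t) - I_eff_i(t) )
    I_eff_i(t)  = alpha * sum_j w(x_i, y_j) I_j(t)
    Etilde_i(t) = n_i(t) * max(0, E_i(t)) + R0

`Phi` is piecewise linear with slope `gamma` below zero (`phi()`); the
presynaptic weights `w` are a Gaussian in the distance between subunits,
normalized over inhibitory subunits. Vesicle occupancy obeys

    dn/dt = (1 - n) * Krec - b * Krel_eff * n * D(t),
    Krel_eff = Krel / (1 + beta * I_eff),

with release drive `D(t) = max(0, E(t)) + R0`. The divisive release-rate
factor is the package's concrete choice for how the inhibition-sensitivity
parameter `beta` couples inhibition to vesicle dynamics: it equals one with
no inhibition or `beta = 0` (recovering the plain depletion equation) and
decreases monotonically in both arguments. The ganglion cell reads out
Gaussian-pooled totals as `rate = max(0, 3 * E_total - I_total)`.

Three consistency choices deserve a note:

* **Release drive and the baseline occupancy.** The closed form
  `n0 = 1/(1 + b E0 Krel / Krec)` (`initial_occupancy()`) is the fixed point
  of the occupancy equation under constant baseline drive `E0`. For that to
  hold exactly, the release drive must be the *pre-occupancy* rectified
  drive, not the occupancy-scaled output (which would make the fixed point
  quadratic in `n`). The simulators therefore drive the vesicle equation with
  `max(0, E) + R0`; with the calibration preset's `R0 = 0` the printed closed
  form is the exact baseline state, and simulations start from it.
* **`gamma` is inert downstream.** Both uses of `E` pass through
  `max(0, .)`, so the sub-zero slope of `Phi` never reaches the output. The
  nonlinearity is implemented and tested as specified, but model output does
  not depend on `gamma`; it is retained for interface fidelity.
* **Hemifield pooling.** In the reduced two-hemifield model, pooled
  inhibition is `alpha * (I_L + I_R)`: both inhibitory subunits modulate each
  excitatory subunit.

### Pathway polarities (a load-bearing choice)

The excitatory filter has Off polarity: dark contrast produces positive
drive. The inhibitory filter has **ON polarity**: the glycinergic inhibition
onto Off bipolar terminals and the ganglion cell is relayed by AII amacrine
cells driven through the ON rod-bipolar pathway (crossover inhibition), so
*brightening* recruits it — the bright bars of a grating, the bright points
of an image, and the return to background after a dark pulse. This sign
inversion is essential, not cosmetic: with same-polarity inhibition the model
produces neither the observed half-cycle phase offset between excitation and
inhibition under contrast-reversing gratings nor any paired-pulse
facilitation (inhibition would peak exactly when it cannot suppress release).

### Presynaptic pooling width

The Gaussian presynaptic weighting defaults to an SD of 50 µm — the
receptive-field-center scale — rather than the width of a single inhibitory
subunit. AII amacrine output spreads through the gap-junction-coupled AII
network well beyond one subunit, and the breadth matters mechanistically:
with hyper-local pooling only the few excitatory subunits directly beneath
bright image points recover synaptic gain, and the offset enhancement to
structured images never reaches the pooled output. It is exposed as
`presyn_pool_sigma` in `offt_model()`.

## Calibration preset

Parameters the source circuit does not pin numerically are fixed once, in
`calibration_preset()` and `default_filters()`, and used for every reference
simulation:

| parameter | value | units | rationale |
|---|---|---|---|
| `Krec` | 2 | 1/s | recovery over the 0.2–5 s paired-pulse range |
| `Krel` | 10 | 1/s per drive | strong use-dependent depression |
| `b` | 1 | – | release gain absorbed into `Krel` |
| `E0` | 7/15 | drive | sets `n0 = 0.3` exactly: strong tonic depression |
| `R0` | 0 | drive | keeps the printed `n0` the exact baseline state |
| `gamma` | 0.5 | – | mid-range rectification ratio (inert, see above) |
| `alpha` | 0.4 | – | mid grid value {0.1, 0.4, 0.8} |
| `beta` | 4 | – | mid grid value {1, 4, 8} |
| exc filter | tau 30/80 ms, undershoot 0.3, 3 stages, gain 1, Off | | transient Off drive |
| inh filter | tau 60/450 ms, undershoot 0.3, gain 3, lag 20 ms, ON | | see below |

Filter time constants are the *mean* times of each gamma-cascade lobe
(per-stage scale `tau/stages`), so a stated 80 ms decay lobe really has an
80 ms center of mass and kernels die out within a few hundred milliseconds,
as retinal impulse responses do.

The inhibitory kinetics, gain and lag are calibrated — the quantitative
filter shapes are not published — to reproduce the recorded paired-pulse
phenomenon: with two 300 ms, −90% contrast pulses separated by a 500 ms
interval, the second excitatory response can reach roughly three times the
first. That requires inhibition that is slower and stronger than excitation
(sustained glycinergic suppression of release through most of the interval).
The calibrated model reaches a maximum paired-pulse ratio of ≈3.2 over the
`alpha x beta` grids while preserving every directional property (rebound
scaling with `alpha` and `beta`, loss of facilitation at `alpha = 0`,
decline of facilitation with interval duration beyond 0.5 s).

## Synthetic stimuli

All stimulus generators are seeded and deterministic. Gratings are
square-wave bars; contrast is Weber contrast (−0.9 means "−90% contrast"),
floored at −1 (zero luminance). The default grid is 2 µm / (1/60) s for 1-D
protocols and 6.6 µm/pixel for 2-D patches; the dynamic models default to
finer time steps (5 ms for the two-hemifield model, 1/120 s for the
spatiotemporal model) because 30 ms filter lobes are poorly sampled at the
monitor frame interval.

Synthetic image patches (`make_synthetic_patch()`) emulate natural image
patches as exponentiated 1/f Gaussian random fields: natural luminance is
approximately log-normal, so patches contain sparse bright points over broad
shallow dark regions. The bright skew matters: a symmetric texture bounded
below by the zero-luminance floor can never exceed about one unit of bright
contrast, recruits almost no ON-pathway inhibition, and would make patches
behave like their discs. The zero-weighted-mean texture component is scaled
linearly by `structure_level` (doubling it doubles the pixel SD exactly) and
offset so the Gaussian-weighted mean equals `mean_contrast` exactly — the
linear-equivalent disc intensity is pinned by construction, with no pixel
clipping. `sample_patch_pairs()` tiles structure levels evenly across
`[0.2, 1]` and draws mean contrasts from `[-0.35, 0.05]`, the weakly dark
regime that drives Off cells.

What the generator does **not** emulate: object structure (edges, occlusion,
phase alignment across scales), luminance-dependent noise, and the
photoreceptor/monitor transduction chain. Passing tests therefore show that
the *circuit model* behaves as described for stimuli with natural
second-order statistics and bright skew, not that the pipeline reproduces
responses to any particular photographed scene.

## Experiments and statistics

* `image_vs_disc_experiment()` flashes each patch and its disc for 300 ms
  inside the 200 µm receptive-field aperture and integrates the readout rate
  over the onset window (the flash) and an equally long offset window. The
  flash length keeps the onset window in the subtraction-dominated regime:
  with much longer flashes, vesicle recovery during the stimulus partially
  compensates the suppression and washes out the dependence on `alpha`.
  The nonlinearity index `NLI = (r_image - r_disc)/(r_image + r_disc)`
  (defined as 0 when both responses vanish) is negative at onset for
  homogeneity-preferring responses and positive at offset. The printed
  3-spike exclusion rule (`offset_nli_with_exclusion()`) applies to spike
  counts; the model's rate integrals are continuous, so the experiment's
  exclusion threshold defaults to 0 (disabled) and is configurable.
* `f2_curve()` drives a lattice of DoG subunits with contrast-reversing
  gratings and extracts the frequency-doubled (F2) amplitude over
  steady-state integer cycles, averaged over 8 circular phase shifts.
  Modulation is sinusoidal by default: a memoryless rectified subunit under
  square-wave reversal emits a two-level square wave with no F2 component at
  all. With the printed amplitude-form DoG, wide-bar suppression requires
  near-complete integral cancellation (`delta * sigma_s ≈ sigma_c`); the
  inhibitory exemplar therefore uses sigma 12.5/14 µm with
  `delta ∈ {0.2, 0.5, 0.9}`.
* `paired_pulse_ratio()` measures peak amplitudes above the *pre-stimulus*
  baseline (final 100 ms before the first pulse). The alternative convention
  (baseline immediately preceding each pulse) destroys the facilitation
  measurement here, because the tonic output right before the second pulse
  is itself elevated by the recovered gain.
* `ei_temporal_offset()` offers two estimators — circular cross-correlation
  argmax and circular center-of-mass phase difference — normalized to the
  response cycle, positive when inhibition leads. The circular
  center-of-mass (first-Fourier-phase) form is used because response peaks
  can straddle cycle boundaries.

## Numerical choices

* **Vesicle integration** (`vesicle_integrate()`): within each sample the
  drive is held constant, for which the exponential update
  `n <- n_inf + (n - n_inf) exp(-k dt)` is the exact ODE solution; the
  integrator is therefore exact for sample-and-hold drives,
  unconditionally stable, and preserves `n ∈ [0, 1]`. A resolution guard
  re-solves with midpoint-refined drive and errors when `dt` is too coarse
  to resolve the dynamics. Tests pin the integrator against a 100× finer
  forward-Euler oracle and an adaptive solver.
* **Filters**: kernels are sampled at midpoints (discrete sums match
  continuous integrals to quadrature accuracy), normalized so the step
  response peaks at `gain`, and validated to have decayed below 1e-4 of
  peak within their support.
* **Settling**: simulations start at the analytic baseline state (`n = n0`,
  zero filter history) with three recovery time constants of baseline
  prepended and discarded; baselines for peak measurements are the final
  100 ms before stimulus onset.
* **Problem sizes**: reference experiments use 30 patches of 110×110 pixels
  (726 µm at 6.6 µm/pixel), 21×21 subunits per pathway (15 µm spacing over
  ±150 µm), and run in seconds on one CPU; the full test suite runs in well
  under a minute.

## Known limitations

* **Interval-duration ordering versus facilitation magnitude.** With
  `Krec = 2/s`, recovery is only ~40% complete 200 ms after release stops.
  Any calibration that reaches 3-fold facilitation at a 500 ms interval
  therefore yields PPR(0.2 s) < PPR(0.5 s): the two printed observations
  (facilitation decreasing monotonically from 200 ms, and ~3-fold
  facilitation at 500 ms) cannot both hold under this recovery rate. The
  package keeps the 3-fold capability; the interval sweep at the frozen
  calibration runs 1.50, 2.31, 1.003, 1.000 over {0.2, 0.5, 2, 5} s —
  decreasing only beyond 0.5 s — and the corresponding acceptance test is
  left failing by design rather than weakened. With a bright intervening
  contrast the ordering inverts entirely (sustained suppression lets
  recovery accumulate with duration).
* The spike proxy is a rectified rate with a fixed gain of 3; no spike
  generation, adaptation, or light-level-dependent rewiring is modelled.
  Light-level effects can only be emulated as parameter regimes (e.g.
  reducing `alpha` and inhibitory gain).
* Onset/offset NLI magnitudes from rate integrals are diluted by the tonic
  baseline rate and are smaller than spike-count NLIs from recordings;
  their signs and orderings, not their absolute values, are the model's
  claims.
* The OffS (sustained) cell type is representable only as a parameter
  regime (weak presynaptic inhibition, e.g. `alpha ≈ 0`), not as a separate
  mechanism.

## A worked example

```{r example, eval = FALSE}
# paired-pulse facilitation under the documented calibration
res <- run_paired_pulse(calibration_preset(alpha = 0.8, beta = 1))
res$ppr          # ~3.2-fold second-pulse enhancement

# strychnine analog: no presynaptic inhibition, no facilitation
run_paired_pulse(calibration_preset(alpha = 0))$ppr   # ~0.98

# homogeneity preference on synthetic patches
model <- offt_model()
pairs <- sample_patch_pairs(30, seed = 1, rf = model$rf)
nli_alpha_sweep(model, pairs)    # onset NLIs negative, growing with alpha
```
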
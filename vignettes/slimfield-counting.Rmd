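---
title: "Counting molecules by Slimfield photobleaching: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting molecules by Slimfield photobleaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimcount)
```

## The measurement model

A Slimfield acquisition follows one field of view at millisecond exposure
(defaults: 10 ms/frame, 180 frames/s, 900 frames ≈ 5 s, 53 nm/pixel) while
every fluorophore in it photobleaches. The package's generative model, which
is also its simulator, assumes:

1. **Constant emission per fluorophore.** Each matured tag contributes a
   fixed brightness *b* (photoelectrons/frame) while it is unbleached.
   Default *b* = 56 pe, the calibrated value for mScarlet-I-class tags under
   these imaging conditions.
2. **Memoryless bleaching.** A fluorophore survives each frame with
   probability 1 − *p*, so the unbleached fraction at frame *f* is
   (1 − *p*)^*f*. The default *p* = 0.004 gives a mean lifetime of 250
   frames (≈ 1.4 s), so bleaching completes well within the acquisition —
   the regime the terminal-step calibration requires. The bleach rate is a
   free parameter of the instrument and illumination, not of the method.
3. **Additive Gaussian noise** on the per-frame summed intensity (default
   SD 9 pe, the calibrated spread). This is the high-count limit of shot
   plus read noise; per-pixel camera maps are deliberately out of scope.
4. **Integer oligomers.** A complex carries `unit × m` subunits with the
   multiple *m* drawn from `multiple_weights` (default 0.6/0.25/0.1/0.05
   over 1×–4×), each subunit tagged with probability `detection_fraction`
   (default 1; maturation losses are plausible but unquantified, so no
   correction is applied downstream either).

What the simulator does **not** emulate: illumination-profile falloff,
pixel-dependent sCMOS noise, reversible photophysical blinking during the
bright phase, spot diffusion out of focus, and autofluorescence background
structure. Passing tests therefore demonstrate the correctness of the
*analysis* under the stated model, not robustness to every instrumental
artefact of real data.

## Spot detection and photometry

Candidates are strict local maxima of a lightly smoothed copy of each frame
(Gaussian, σ = 1 px — smoothing only localizes maxima; intensities are
always measured on the raw frame). Each candidate's summed intensity adds
all pixels within 5 px of the centroid and subtracts the local background
mean estimated in the 5–8 px annulus; the annulus SD feeds the intensity
filter, which discards candidates below 0.4 × SD. Three conventions are
fixed here because the verbal criterion admits several readings:

- **Aperture membership** uses the Euclidean distance from the pixel centre
  to the *rounded* centroid, making the aperture a fixed 81-pixel disc and
  116-pixel annulus for every candidate (the sub-pixel centre of mass is
  reported separately). This keeps photometry identical across candidates
  and makes the pixel counts exact, testable integers.
- **The filter boundary is inclusive**: the criterion specifies what is
  *discarded* (< 0.4 × SD), so a candidate exactly at the threshold is kept.
- **"SD of the background region"** is read as the per-pixel annulus SD
  (`filter` option `sd_mode = "pixel"`); the alternative reading — the SD
  expected of a disc sum — is available as `sd_mode = "summed"`. The
  per-pixel reading is deliberately permissive: it keeps single-molecule
  blinks that sit deep in the noise, and relies on the ROI mask and the
  minimum track length (default 4 frames, the extrapolation minimum) to
  reject noise candidates. On pure-noise stacks about 1% of interior pixels
  are flagged per frame; the test suite bounds this at 3%.

Track linking is greedy nearest-neighbour (default gate 5 px, one missed
frame of memory), ties broken by smallest displacement then brighter
candidate. This is intentionally the simplest linker consistent with
near-stationary spots; crossing or fast-diffusing targets would need a
proper assignment solver and are out of scope.

## Brightness calibration from terminal steps

After bleaching has run its course, the only signal left at the end of a
track is step-like blinking of the last fluorophore, so the modal
integrated intensity of those steps estimates *b* in situ. The harvesting
rule is two-pass:

1. collect all detections in the final third of the acquisition;
2. estimate the noise floor σ̂ from the sub-zero intensities
   (√mean(x²) of negatives — fully bleached frames cluster at 0 and would
   otherwise capture the mode) and drop values ≤ 3σ̂;
3. take a provisional KDE mode, keep values ≤ 2 × provisional (tracks
   decayed to their last one or two fluorophores), and report the KDE mode
   of the survivors; the uncertainty is their scaled median absolute
   deviation.

Fewer than 20 usable steps is an explicit error, never a silent default.
A dedicated step detector (Chung–Kennedy or HMM step counting) would
sharpen the step set but is not required at the default signal-to-noise
(56/9): across 20 seeded populations of 200 tracks the recovered mode stays
within the ±9 pe spread, which the acceptance suite asserts.

## Stoichiometry and periodicity

`initial_intensity()` fits an ordinary least-squares line through the first
4 (frame, intensity) points and evaluates it at frame 0; tracks first
detected after frame 4 are excluded (configurable), since pre-detection
bleaching would bias counts low. Stoichiometry is the extrapolated
intensity over *b*, kept as a float.

The stoichiometry KDE uses a **fixed** Gaussian kernel, default width
(= SD) 0.7 molecules, reflecting the background-noise contribution to a
single estimate — bandwidth selection from the data would defeat the
purpose of resolving integer-spaced peaks. The grid runs from 0 to the
maximum plus 3 kernel widths in steps of width/20, so mode quantization
(0.035 molecules) is far below the reported precision; the density is
renormalized to integrate to 1 on the grid. Peaks are strict interior local
maxima with prominence ≥ 5% of the maximum density (the re-implementation
of a `findpeaks`-style prominence filter).

For periodicity, intervals are taken between **consecutive** sorted peaks
within each acquisition — the target quantity is the smallest consistent
spacing, i.e. nearest-neighbour ladder steps; an all-pairs variant sits
behind `all_pairs = TRUE`. Each interval *d* is weighted *d*^(−1/2)
(discounting the larger shot noise of broader intervals), and the weighted
KDE bandwidth is 0.7 × √(mean stoichiometry / n intervals), widening with
the shot noise of peaks at higher stoichiometry and narrowing as intervals
accumulate. The mode of this distribution is the periodicity. Its 95% CI is
a percentile bootstrap over the interval set (default 1000 resamples) with
the bandwidth held at the full-sample value: resampling does not change
what the bandwidth formula is conditioning on, and refitting it per
resample would conflate bandwidth variability with mode variability. With a
single acquisition and two intervals the CI is nearly degenerate — the
bootstrap cannot widen what it cannot resample — so population-level claims
should aggregate many acquisitions (the test suite uses 6–10).

## Photophysiology

The PAM parameters are direct formula implementations: NPQ = (Fm − Fm′)/Fm′,
Y(II) = (Fm′ − F)/Fm′, Fv/Fm, the Oxborough–Baker estimate
Fo′ = Fo/(Fv/Fm + Fo/Fm′), and qL = (Fm′ − F)·Fo′/((Fm′ − Fo′)·F). The qL
bracketing follows the lake-model parameterization — it is the only grouping
bounded in [0, 1] on physically ordered inputs, which the property tests
assert. Fast-relaxing NPQ is the NPQ at the last light point minus the
minimum over the subsequent dark points.

ECS analysis takes the signal as A520 − A545. PMF is the value at light-off
minus the minimum found within a 1 s search window after light-off
(configurable — the window guards against slow drifts), divided by the
single-turnover amplitude ECS_ST when one is supplied; the output records
which unit applies. The decay time constant τ is fit over the first 100 ms
after light-off as A·exp(−Δt/τ) + C by separable least squares: for fixed
τ the amplitude and floor are solved linearly, and only log τ is optimized
(bracketed ±3 log-units around a log-linear initial estimate, tolerance
10⁻⁹). This formulation is exact on noiseless decays and avoids the
singular-gradient failures generic Gauss–Newton fitters exhibit when the
fit window is short relative to τ; noiseless recovery is within 1% for
τ ∈ [0.02, 0.5] s. Non-decaying traces are reported as fit failures, never
coerced. The ΔpH/ΔΨ partition uses the dark steady state (mean of the final
10% of the record): ΔΨ fraction = (steady state − minimum)/(light-off span),
ΔpH its complement, with the convention echoed in the output since published
operational definitions vary. The ECS simulator delays its slow (ΔΨ-like)
recovery component by five fast time constants after light-off; with
overlapping kinetics the convention-defined minimum and steady state would
not correspond to any injected truth, for this or any other estimator.

## Problem sizes and determinism

The test and acceptance suites size their simulations to the defaults the
method targets: 347-track populations for unit recovery, 10 acquisitions ×
52 complexes for periodicity (≈ 20 intervals), 20 × 200 tracks for
calibration stability, 10⁴ replicates for the geometric-survival and
multiple-weight checks, and 150 + 150 tracks for 11-mer/12-mer
discrimination (the "unambiguous up to 12 molecules" regime, misclassification
under 5% at 56/9 signal-to-noise). Every stochastic stage draws from the
single seeded RNG stream of its caller; `simulation_params(seed = )` makes a
population bit-reproducible, and `run_end_to_end()` seeds once so
stage-level reruns reproduce pipeline-level draws.

## Known limitations

- Calibration assumes bleaching completes within the record; slow-bleaching
  acquisitions (mean lifetime approaching the record length) bias the
  terminal-step set toward multi-fluorophore levels. Shorten the record
  fraction or raise the illumination in such designs.
- The linker is not swap-proof for spots that approach within the gate.
- KDE peak finding cannot resolve ladder rungs closer than roughly the
  kernel width; with 0.7 molecules this is ample for integer-spaced units.
- No correction for incomplete fluorophore maturation is applied; reported
  stoichiometries are counts of *detected* tags.

```{r example, eval = FALSE}
pop <- simulate_population(
  simulation_params(multiple_weights = c(0.6, 0.3, 0.1), n_complexes = 150,
                    seed = 42),
  acquisition_config())
report <- run_counting_pipeline(pop$traces)
plot(report$distribution)
if (!is.null(report$periodicity)) plot(report$periodicity)
```
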
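# slimcount

Single-molecule stoichiometry, oligomer periodicity and photophysiology
analysis for Slimfield microscopy, in R.

## What problem this solves

Slimfield (narrow-field laser) microscopy resolves individual
fluorescent-protein-tagged complexes in live cells at millisecond exposure,
fast enough to watch every fluorophore in a diffraction-limited spot
photobleach over a few seconds. Because each fluorophore contributes a
characteristic integrated brightness *b* (photoelectrons/frame/molecule),
the number of tagged subunits in a complex — its **stoichiometry** — can be
counted optically:

- the **initial intensity** *I₀* of a spot is recovered by linear backward
  extrapolation of its summed intensity over the first 4 frames (undoing
  bleaching during early exposure);
- the **brightness** *b* is calibrated in situ as the modal integrated
  intensity of the step-like blinks left at the end of each track, when only
  one fluorophore survives;
- the stoichiometry is *S = I₀ / b* (not rounded);
- the population's **stoichiometry distribution** is a Gaussian
  kernel-density estimate with a fixed 0.7-molecule kernel, and its peaks
  are located with a prominence-filtered peak finder;
- the **periodicity** — the repeating oligomeric unit behind a ladder of
  peaks — is the mode of the distribution of consecutive inter-peak
  intervals, each interval *d* weighted by *d*^(−1/2), smoothed with a
  second kernel of width 0.7·√(mean stoichiometry / n intervals), with a
  bootstrap 95% CI.

This is the analysis used to show that the pyrenoid-tubule bestrophin-like
channel of *Chlamydomonas* assembles in pentameric units. The package also
implements the standard photophysiology calculations used alongside such
work: PAM chlorophyll-fluorescence parameters (NPQ, Y(II), Fv/Fm, Fo′
estimate, qL, fast-relaxing NPQ), electrochromic-shift (ECS = A520 − A545)
proton-motive-force analysis (PMF, gH⁺ = 1/τ, vH⁺ = PMF·gH⁺, ΔpH/ΔΨ
partition), culture growth rate μ = ln(N₂/N₁)/t and total chlorophyll
22.12·A652 + 2.71·A665.

Because no raw imaging data accompany such studies, the package ships a
first-class simulator (photobleaching traces with geometric fluorophore
lifetimes, rendered TIFF image stacks, PAM and ECS records) so every stage
is testable against known ground truth.

## Worked example

```r
library(slimcount)

# a population mixing pentamers, decamers and 15-mers (60/30/10%),
# imaged at 10 ms/frame, 180 fps, ~5 s, 56 pe/frame/molecule, 9 pe noise
params <- simulation_params(multiple_weights = c(0.6, 0.3, 0.1),
                            n_complexes = 150, seed = 42)
pop <- simulate_population(params, acquisition_config())
report <- run_counting_pipeline(pop$traces, n_boot = 500)
print(report)
#> Slimfield molecular counting report
#> Single-fluorophore brightness: 56.9 +/- 9.7 photoelectrons/frame (n = 13894 steps)
#>   150 tracks counted; pooled KDE peaks at: 4.9, 9.835, 14.77
#> Periodicity: mode 4.91 molecules (95% CI 4.91-4.91, n = 2 intervals)
```

The calibration recovers the simulated 56 pe brightness from terminal blink
steps; the KDE peaks sit at 5, 10 and 15 molecules; and the inter-peak
interval analysis reports the pentameric unit. (With a single acquisition
there are only two consecutive intervals, hence the degenerate CI; real
analyses aggregate intervals across many acquisitions.)

Photophysiology functions are plain formulas over trace objects:

```r
tr <- simulate_ecs_trace(pmf_true = 1.0, tau_true = 0.1, ecs_st = 1.0)
pmf(tr)                    # 0.99995 (ECS_ST-normalized)
g_h(tr)                    # 10 s^-1  (= 1 / tau)
v_h(pmf(tr), g_h(tr))      # 9.99955
npq(1.0, 0.4)              # 1.5
q_l(0.3, 0.8, fo_prime(0.2, 0.8, 0.8))$qL   # 0.5208
```

For image-stack input, `render_image_stack()` → `detect_stack()` →
`link_tracks()` produce the track table `run_counting_pipeline()` consumes;
`make_fixtures()` writes a small self-contained bundle (traces, TIFF stack,
PAM/ECS CSVs, ground-truth sidecars), and `run_end_to_end()` drives a whole
run from a YAML config.

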
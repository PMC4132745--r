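---
title: "Quantifying protein-induced DNA compaction, bridging and looping from single-molecule data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein-induced DNA compaction, bridging and looping from single-molecule data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtether)
```

# The scientific problem

Architectural HMGB-family proteins such as yeast HMO1 bind double-stranded DNA
without sequence specificity, bend it locally, and at higher coverage compact,
bridge and loop it. Two single-molecule modalities probe these effects from
complementary directions: optical tweezers stretch one DNA tether and read out
its mechanics as a force-extension curve, and AFM images deposited
protein-DNA complexes as planar contours. `smtether` implements the complete
quantitative chain from both raw data types to binding and mechanical
parameters, together with seeded generators for every input so that each
estimator can be validated by parameter recovery.

# Models

## Extensible worm-like chain

A stretched DNA tether follows the high-force interpolation of the extensible
worm-like chain,

$$ b(F) = B_{ds}\left[1 - \tfrac12\sqrt{\frac{k_BT}{P_{ds}F}} + \frac{F}{S_{ds}}\right], $$

with `b` the extension per base pair (nm/bp), persistence length $P_{ds}$ (nm),
contour length per base pair $B_{ds}$ (nm/bp) and stretch modulus $S_{ds}$
(pN). `wlc_extension()` evaluates the closed form; `wlc_force()` inverts it by
a damped Newton iteration (the function is strictly increasing, so the inverse
is unique; round-trip accuracy is at machine precision). `fit_force_extension()`
fits all three parameters up to 30 pN, above which the interpolation stops
being quantitative for B-DNA. Residuals are taken in *force*: instrument noise
lives on the force channel, and regressing extension on the noisy force biases
$P_{ds}$ by 5-12% at realistic noise through the model's curvature
(errors-in-variables). The thermal energy defaults to $k_BT = 4.11$ pN nm
(298 K) and can be overridden.

## Cooperative lattice binding

Equilibrium coverage of the DNA lattice by a protein with footprint $n$ sites,
dissociation constant $K_D$ and nearest-neighbour cooperativity $\omega$
follows the McGhee-von Hippel isotherm, which relates the fractional
occupancy $\Theta$ implicitly to the free concentration $c$. Solved for $c$
the isotherm is an explicit, strictly increasing function $c(\Theta)$;
`mvh_occupancy()` inverts it on a logit grid with Newton polishing and a
bisection fallback, and self-checks every solution to a relative residual of
at most 1e-8. At $\omega = 1$ the cooperative expression is 0/0, so the
non-cooperative closed form is used for $|\omega - 1| < 10^{-6}$; with
$n = 1$ it reduces to the Langmuir isotherm, which the tests verify to 1e-10.

Occupancy maps to the three observables by

- persistence length: harmonic interpolation
  $P(\Theta) = P_LP_D / (P_L + \Theta(P_D - P_L))$ — bending compliances add,
- contour length and overstretching force: linear interpolation between the
  protein-free and saturated endpoints.

`fit_titration()` performs the three-parameter chi-square fit the titration
analysis calls for: $K_D$, $\omega$ and the saturated endpoint vary, the
footprint stays fixed at $n = 26$ bp and the protein-free value is anchored at
the $c = 0$ data. The $(K_D, \omega)$ surface is ridge-prone, so a 5x5 grid of
starts over $\log_{10}K_D \in [-2, 3]$ and $\log_{10}\omega \in [0, 3]$ is
screened and the best five basins polished by Levenberg-Marquardt;
uncertainties come from the inverse curvature at the minimum. Per-observable
estimates are pooled by the inverse-variance weighted mean
(`combine_weighted()`), whose uncertainty is $1/\sqrt{\sum \sigma_i^{-2}}$.

## Cluster statistics

The same lattice model defines an equilibrium ensemble (weight $c/K_D$ per
bound protein, $\omega$ per pair of exactly adjacent footprints).
`mean_cluster_size()` reports the mean number of proteins per maximal run of
adjacent footprints as the ratio of the ensemble-average protein count to the
ensemble-average cluster count, computed two independent ways:

- **exact**: a linear-time transfer-matrix dynamic program over the finite
  lattice that tracks the partition function together with the weighted
  protein and cluster counts;
- **montecarlo**: grand-canonical Metropolis sampling
  (`simulate_lattice()`) with insertion/deletion moves mixed 50/50 with
  protein translations (translations rearrange clusters directly, which
  insertion/deletion alone does extremely slowly at high coverage). Chains are
  started alternately from empty and fully packed lattices, standard errors
  are taken across independent chains, and a split-R-hat diagnostic on the
  protein count warns about non-equilibrated runs.

The cluster size depends strongly on lattice length at saturating conditions.
At the pooled parameters ($K_D = 2.3$ nM, $\omega = 23$, $n = 26$) and
$c = K_D$ the occupancy is 0.93 and the infinite-lattice cluster size is about
4.2 proteins; on a lattice of about three footprints (a few dozen base pairs
between obstacles) the boundary truncates the distribution and the average is
about two, which is also the value reached at mid-transition occupancies
($\Theta \approx 0.5$-$0.75$) on long lattices. The analysis scripts report
both, and `analysis/05_lattice_clusters.R` prints the full lattice-length and
concentration dependence rather than a single number.

For comparisons against the infinite-lattice isotherm the sampler offers
periodic boundaries (`boundary = "circular"`): hard lattice ends depress the
finite-lattice occupancy by $O(n/M)$, which at $M = 40n$ is several Monte-Carlo
standard errors, while on a ring the residual finite-size error is well below
them. Isotherm comparisons are made at concentrations spanning the binding
transition ($\Theta \approx 0.1$-$0.8$); at near-saturating occupancy the
sampler's decorrelation time grows sharply and the comparison would require
disproportionate run lengths.

## Loop rupture events

When a tether is held slack in the presence of a bridging protein, thermal
loops form and are stabilized; pulling then shows a sawtooth of force drops as
loops rupture. The sizing formula converts the fitted contour-length change
across a jump to base pairs,
$\mathrm{loop\ bp} = \Delta B_{ds}\, N_{bp} / 0.34\,\mathrm{nm}$,
with 0.34 nm/bp used exactly. Only the contour length is refitted on the
segments flanking a jump; $P_{ds}$ and $S_{ds}$ are held at values fitted to
the loop-free tail of the same curve (one-parameter weighted projection, so
the refit is closed-form). Drops below 1.0 pN — the stated maximum force-noise
level with protein present — are censored from histograms; a 1.0 pN jump at a
10 pN breaking force corresponds to a loop in the low hundreds of bp, the
method's resolution floor.

Jump *detection* is the one step the source analysis leaves unspecified beyond
the threshold. A raw local max-to-min rule over a handful of samples cannot
meet a zero-false-positive requirement at 0.3 pN force noise (the range of ten
Gaussian samples routinely exceeds 1 pN), so `detect_loop_jumps()` estimates
the local force level by linear fits over 25 samples on each side of a
candidate and thresholds the gap between their extrapolations; this keeps the
noise on the drop estimate near 0.2 pN, and the rising-trend requirement on
both fitted slopes preserves the sawtooth logic. Events closer than one window
to either end of the record are undetectable by construction.

## Compaction

Held at constant force and exposed to protein, the tether shortens as
$x(t) = x_\infty + A e^{-kt}$; `compaction_fit()` returns $k$ (and
$\tau = 1/k$) with curvature-based errors and rejects non-decaying records.
The compaction force `compaction_force()` is the mean force difference between
the protein and protein-free release curves at extensions below 20% of the
bare contour length (the window is configurable; the source analysis says only
"the limit of low extensions").

## AFM traces

Traced molecules are ordered planar polylines. `tangent_correlation()`
resamples each trace at uniform arc length and correlates the tangent
directions of single resampled segments; the planar worm-like chain predicts
$\langle\cos\theta(L)\rangle = e^{-L/2p}$, which `fit_persistence_2d()` fits
directly (not log-transformed) with inverse-variance bin weights. Two
numerical points matter:

- uncertainties are computed *across molecules* (count-weighted
  between-trace variance); position pairs within one molecule overlap and are
  strongly correlated, and treating them as independent understates the error
  by an order of magnitude;
- tangents measured over a finite chord smooth the contour and multiply the
  correlation by roughly $e^{+w/6p}$ for chord length $w$; because the fit has
  no amplitude parameter this inflates $p$ (about +10% when analysing 2.5 nm
  traces at a 5 nm step). The resampling step should therefore match the trace
  resolution; the default is 5 nm for real traces of unknown pixel scale, and
  all simulation-based validation analyses traces at their native 2.5 nm
  spacing.

Bend angles at annotated protein sites are measured between total-least-squares
line fits over 10 nm of contour on each side (0 deg = straight, folded into
[0, 180]). The angle distribution is summarised by a "bi-Gaussian" — a single
peak with distinct left and right widths, the convention of the bend-angle
literature; a sum-of-two-Gaussians alternative is available via
`flavor = "two_component"` because the term is ambiguous, and the sample mean
and SD are always reported alongside. Loops are sized by the contour length of
their annotated closed circuit at 0.34 nm/bp (or a per-molecule calibration);
bridges are annotation-driven counts, mirroring manual identification from
images — no pixel-level detection is attempted.

# The synthetic-data generators

Raw instrument data are not available, so module `simulate_*` emulates every
input at the study's stated conditions, and all validation is parameter
recovery against generator truth:

- `simulate_fec()`: 48,500 bp lambda-DNA pulling curves on an increasing
  extension grid; intact loops sequester contour (effective contour
  $B_{ds}(N_{bp}-\mathrm{sequestered})/N_{bp}$), each loop releases
  deterministically when the force first reaches its rupture force (no
  Bell-model kinetics — the analysis counts and sizes events, it does not
  model their kinetics), an optional overstretching plateau caps the force at
  $F_{ov}$, and i.i.d. Gaussian force noise is added last. Default noise in
  validation is 0.3 pN, consistent with a 1.0 pN peak noise ceiling.
- `simulate_titration()`: occupancies from the isotherm mapped through the
  three observable maps, with Gaussian noise of 5% of each observable's range.
- `simulate_chain_2d()`: discrete planar worm-like chains (tangent-angle
  increments of variance $\Delta/p$, so $\langle\cos\theta\rangle = e^{-L/2p}$
  exactly at the native discretization), with optional programmed kinks for
  bend-angle round trips.
- `simulate_compaction()`: single-exponential decays plus noise.
- `simulate_lattice()`: the grand-canonical sampler described above.

Identical seeds give identical outputs. What passing recovery tests shows is
that the estimators are correct and calibrated *under the assumed noise
model*; real instrument data add drift, correlated noise, bead and surface
artifacts, and tracing errors that these generators deliberately do not
emulate, so recovery rates here are upper bounds on real-data performance.

# Default parameters

| Parameter | Default | Why |
|---|---|---|
| $k_BT$ | 4.11 pN nm | room temperature (298 K) |
| WLC fit cutoff | 30 pN | validity range of the interpolation formula |
| overstretch window | 0.42-0.48 nm/bp | the plateau's extension range |
| jump threshold | 1.0 pN | maximum force noise with protein present |
| detection window | 25 samples/side | drop-estimate noise ~0.2 pN at 0.3 pN noise |
| footprint $n$ | 26 bp | gel-shift estimate, held fixed in fits |
| bp conversion | 0.34 nm/bp | B-DNA rise, used exactly in loop sizing |
| tangent step | 5 nm (analysis default); match trace resolution when known | chord smoothing inflates $p$ |
| bend-angle arms | 10 nm | about two tip radii of contour per side |
| low-extension window | 20% of bare contour | "limit of low extensions" left unspecified |

# Degenerate inputs and edge cases

Non-decaying compaction records are rejected with a flag rather than fitted;
perfectly straight traces return a divergence flag instead of an infinite
persistence length; degenerate (all-equal) bend-angle samples skip the
bi-Gaussian fit but still report sample statistics; loop events whose flanking
segments are too short are kept with their size marked unavailable; curve
readers verify a row-count checksum from the sidecar and name the offending
row on parse errors.

# Known limitations

- The occupancy back-calculated from a persistence-length drop needs the
  saturated endpoint $P_L$, which the tweezers titration provides but an AFM
  experiment alone does not; with $P_D = 59$ nm, $P_{obs} = 39$ nm the result
  ranges from 0.07 to 0.08 for $P_L$ between 7 and 8 nm.
- Loop rupture is simulated as deterministic at the assigned force; pulling-
  rate-dependent kinetics are out of scope.
- The Monte-Carlo sampler decorrelates slowly above $\Theta \approx 0.9$;
  cross-chain errors and the R-hat warning make this visible rather than
  hiding it.
- No drift or baseline correction is applied to pulling curves beyond what the
  generator injects, and no pixel-level image processing is attempted.
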
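# smtether

Quantitative analysis of single-molecule DNA-protein mechanics, built around
the two workhorse experiments for architectural DNA-binding proteins such as
the yeast HMGB protein HMO1: optical-tweezers force spectroscopy of a single
48,500 bp bacteriophage-lambda DNA tether, and AFM imaging of traced
protein-DNA complexes. The package is aimed at single-molecule biophysicists
who need the full chain from raw curves and traces to binding and mechanical
parameters, with every estimator validated by parameter recovery on seeded
synthetic data.

## What it computes

**Tether mechanics.** Force-extension curves are fitted up to 30 pN to the
extensible worm-like chain,

    b(F) = B_ds [ 1 - (1/2) sqrt(kT / (P_ds F)) + F / S_ds ],

giving the apparent persistence length `P_ds` (nm), contour length per base
pair `B_ds` (nm/bp) and stretch modulus `S_ds` (pN). The overstretching force
`F_ov` is the mean force over the 0.42-0.48 nm/bp extension window.

**Equilibrium binding.** Concentration series of `P_ds`, `B_ds` and `F_ov`
are fitted to the cooperative McGhee-von Hippel lattice isotherm
(occupancy Θ(c) at dissociation constant `K_D`, cooperativity `ω`, footprint
`n = 26` bp held fixed), through a harmonic map for persistence length and
linear maps for the other two observables. The three independent `(K_D, ω)`
estimates are pooled by inverse-variance weighting. Mean bound-cluster sizes
in the same ensemble come from an exact transfer matrix and a grand-canonical
Monte-Carlo sampler that cross-check each other.

**Loops and compaction.** Protein-stabilized DNA loops rupture as force jumps
on the pulling curve; jumps of at least 1.0 pN are detected by flanking
linear-fit change detection and sized by refitting the contour length on each
side: `loop_bp = ΔB_ds · N_bp / 0.34 nm`. Constant-force compaction records
are fitted to a single exponential `x(t) = baseline + A·exp(-k t)`, and the
compaction force is the low-extension force difference between release curves.

**AFM traces.** Traced molecules give the 2D worm-like-chain persistence
length via the tangent correlation `<cos θ(L)> = exp(-L/2p)`, protein-induced
bend angles at annotated sites (with a bi-Gaussian distribution fit), loop
sizes from traced circuit contours, and bridge statistics.

**Synthetic data.** `simulate_fec()`, `simulate_titration()`,
`simulate_chain_2d()`, `simulate_compaction()` and `simulate_lattice()`
generate every input type under the study conditions, seeded and
byte-reproducible, so the whole pipeline is testable without instrument data.

## Worked example

```r
library(smtether)

# a lambda-DNA pulling curve with two protein-stabilized loops
dna <- wlc_params(P_ds = 50, B_ds = 0.34, S_ds = 1200)
curve <- simulate_fec(dna, n_bp = 48500,
                      loops = data.frame(size_bp = c(600, 500),
                                         rupture_pN = c(6, 10)),
                      noise_F = 0.3, seed = 42)
analyze_loops(curve, min_delta_F = 1.0)[, c("F_before", "delta_F", "delta_B", "loop_bp")]
#>   F_before delta_F delta_B  loop_bp
#> 1   6.2149  2.4262  0.0043 613.0719
#> 2  10.4685  3.4363  0.0035 493.6580

# occupancy of the DNA lattice at the pooled binding parameters
hmo1 <- binding_params(K_D = 2.3, omega = 23, n = 26)
mvh_occupancy(c(0.07, 2.3), hmo1)
#>      c     theta        R     residual
#> 1 0.07 0.5020595 1.055314 2.211338e-16
#> 2 2.30 0.9308882 0.478286 1.669709e-15

# pooling the three per-observable affinity estimates
kd <- combine_weighted(c(2.1, 1.9, 2.8), c(0.8, 0.7, 0.6))
sprintf("pooled K_D = %.1f +/- %.1f nM", kd$value, kd$uncertainty)
#> [1] "pooled K_D = 2.3 +/- 0.4 nM"
```

The two loops injected at 600 and 500 bp are detected at their rupture forces
and sized to 613 and 494 bp; the occupancy solver shows the isotherm at
mid-transition (Θ = 0.50 at 0.07 nM) and near saturation at `c = K_D`
(Θ = 0.93), each solution self-checked to a residual below 1e-8.

## The analysis workflow

The numbered scripts under `analysis/` run the complete study on synthetic
data and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_data.R` | generates all datasets (curves, titrations, compaction record, AFM traces) |
| `02_wlc_titration.R` | WLC fits, three titration fits, pooled `K_D` and `ω` |
| `03_loops_compaction.R` | loop detection/sizing, histograms, compaction rate and force |
| `04_afm_traces.R` | 2D persistence lengths, bend angles, bridges, implied occupancy |
| `05_lattice_clusters.R` | occupancy isotherm, Monte-Carlo cross-checks, cluster sizes |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate_data.R`.

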
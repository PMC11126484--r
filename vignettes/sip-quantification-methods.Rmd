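---
title: "Quantifying 15N incorporation in DNA-SIP experiments: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 15N incorporation in DNA-SIP experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsip)
```

## The measurement problem

DNA stable isotope probing identifies which microorganisms are active by
feeding a community an isotopically heavy substrate and looking for the
density shift that incorporation imprints on their DNA. With 15N-urea the
signal is intrinsically weak: nitrogen is a minor constituent of DNA by
mass, so even complete labeling raises the CsCl buoyant density by only
about 0.02 g/mL — roughly a quarter of the spread that GC content alone
produces across a soil community. Calling a population "active" therefore
cannot rest on absolute density; it requires a paired design in which the
same community is incubated with 14N- and 15N-substrate, the gradient is
cut into fractions, the marker gene (here *amoA* of ammonia-oxidizing
archaea, bacteria and comammox *Nitrospira*) is quantified per fraction by
qPCR, and the two profiles are contrasted.

This package implements that quantification, the nitrification-activity
metrics that accompany it, amplicon summaries of the heavy fractions, and
a synthetic-data generator that provides ground truth for all of it.

## The isotope-shift model

Unlabeled density is modeled as the standard linear CsCl relation
$\rho_0 = 1.660 + 0.098\,GC$. The labeling shift is mass-proportional:
buoyant density scales with molecular mass, so replacing a fraction $a$ of
nitrogen atoms adds

$$\Delta\rho = a\,\rho_0(GC)\,\frac{n_N(GC)\,\Delta m_N}{m_{bp}(GC)},$$

with $n_N = 7 + GC$ nitrogen atoms per base pair (A:T carries 7, G:C
carries 8), $\Delta m_N = 0.9970$ g/mol per substitution, and the
base-pair molar mass interpolated between the free-acid values 617.4
(A:T) and 618.4 (G:C) g/mol. At $a = 1$, $GC = 0.5$ this evaluates to

```{r}
label_shift(atom15n = 1, gc = 0.5)
```

i.e. the ~0.02 g/mL full-label shift that motivates the paired design.
The model is linear in the atom fraction, which is what makes partial
labeling (slow growers, isotope dilution by native soil N) behave simply
in the simulator.

Gradient fractions are characterized by refractive index in practice;
`ri_to_bd()` applies the standard refractometric calibration
$\rho = 10.8601\,RI - 13.4974$ and accepts only the plausible CsCl range
[1.37, 1.42]. Tables may supply either buoyant density or refractive
index.

## The synthetic gradient

`simulate_gradient()` bands each taxon as a Gaussian over buoyant density
(mean $\rho_0 + \Delta\rho$, sd `band_sigma`, default 0.004 g/mL) and
integrates the band over 16 contiguous windows on a linear density grid
from 1.780 (fraction 1, the first fraction collected from the tube
bottom, hence the heaviest) to 1.660 g/mL. Design choices worth stating:

- **Fraction ordering.** Fraction 1 heaviest. With this ordering, heavy
  fractions land at mid-gradient indices (6–11) for realistic GC
  contents, matching how SIP profiles are conventionally reported.
- **Linear grid.** Real gradients are close to linear over the collected
  range; curvature adds nothing at 16-fraction resolution.
- **qPCR noise.** Multiplicative log-normal (`10^e`,
  `e ~ N(0, 0.1)` on the log10 scale by default), because qPCR error is
  multiplicative; a detection floor (default 10 copies) zeroes
  sub-threshold readings. Taxa co-amplified by the same assay are summed
  *before* noise, since the assay sees their pooled template.
- **Conservation.** With noise and floor disabled the fraction sums
  equal the input totals to better than 1e-6 relative — the Gaussian
  tails outside the collected range are negligible for any density more
  than a few band widths inside the grid.

What the generator does *not* emulate: diffusion-limited band
equilibration, tube-wall artifacts, pipetting carry-over between
fractions, PCR inhibition, and cross-amplification between assays.
Passing the recovery tests therefore demonstrates the *analysis* is
correct under the stated noise model, not that any real gradient is this
well behaved.

## Heavy-fraction identification

Published SIP studies typically select heavy-fraction ranges by visual
inspection of the paired profiles. That is not reproducible, so
`identify_heavy_fractions()` provides both:

- an **automatic margin rule**: normalize both profiles to their maxima
  (the standard presentation, `normalize_profile()`), then take the
  maximal contiguous run of fractions strictly on the heavy side of the
  14N peak where the 15N signal exceeds the 14N signal by at least
  `margin` (default 0.10, i.e. 10% of the profile maximum — large enough
  to ignore the default qPCR noise, small enough to keep shoulder
  fractions). The run must contain the 15N profile's own peak; if it
  does not, the verdict is "no labeling detected", returned as an empty
  set rather than an error;
- a **manual override** (`manual_set`), validated against the grid, to
  reproduce exactly the fraction ranges a study reports.

Two downstream quantities deliberately use *raw* copies, not normalized
values: the HF ratio $R$ (HF copies over the sum across all 16
fractions) and the labeled abundance $R \times A_{total}$, where
$A_{total}$ is the gene's total-DNA qPCR abundance at the end of
incubation. Ratios of normalized values would differ whenever replicate
maxima differ, and copy numbers are what footnoted summaries report.
Ties at the profile peak break toward the heavier fraction, because
heavy-side mass is the evidence of labeling.

With replicated gradients, `quantify_labeling()` detects the HF set once
on the replicate-mean normalized profile (each replicate normalized to
its own maximum first, so unequal DNA recoveries do not reweight the
shape) and then computes the ratio and labeled abundance per replicate,
reporting mean and standard error. Detecting on the mean profile keeps
the HF set common across replicates — computing per-replicate sets would
conflate fraction-boundary jitter with biological variance.

## Microcosm nitrogen dynamics

`simulate_microcosm()` integrates a two-pool first-order model by forward
Euler (default step 0.25 day): urea-N hydrolyzes to NH4+-N at
`hydrolysis_rate` (default 0.5/day — urea half-life of ~1.4 days, typical
of warm moist soil), and NH4+-N oxidizes to NO3--N at
`nitrification_rate_constant * (1 - inhibition_factor)`. Acetylene
treatment is `inhibition_factor = 1`. Dosing defaults to four additions
of 100 mg N/kg on days 0, 7, 14 and 21 of a 28-day incubation. Because
every Euler step moves mass between pools, total N is conserved between
doses to floating-point precision; this is asserted at 1e-6 relative in
the tests.

The model is intentionally the simplest one that reproduces the
qualitative microcosm behavior (ammonium accumulation under urea, nitrate
production blocked by acetylene). Rate constants are not interpreted
mechanistically; `calibrate_nitrification()` solves (by `uniroot`) for
the constant that makes the simulated 28-day net nitrification rate,
`net_nitrification_rate()` = ΔNO3/Δt, hit an observed anchor value (2.10
and 5.24 mg N/kg/day for the acidic and neutral soils the defaults
describe). The initial NH4+/NO3- pools default to the acidic-soil
characterization (19.78 and 1.95 mg/kg). Negative net rates (nitrate
immobilization) are reported as-is; only `inhibition_percent()` is
clipped, to [0, 100].

## Statistics

Gene abundances are log10-transformed (`log10_abundance()`, which names
offending records instead of emitting -Inf) and compared by classical
one-way fixed-effects ANOVA at the 5% level. `one_way_anova()` delegates
to `stats::lm()`/`anova()` and defines the fully degenerate case (zero
between- and within-group variance) as F = 0 rather than NaN. Pairwise
Welch t-tests with Holm correction (`pairwise_welch()`) are available as
an optional post-hoc report; they are an extension beyond the primary
ANOVA, not part of it.

## Community summaries

`zotu_table()` holds denoised amplicon (Zotu) counts with sample metadata
and a taxonomy map. Counts are pooled (summed, never averaged) across the
samples of a group before proportions are formed, preserving read-count
semantics. `clade_composition()` reports all clades including zero-count
ones, summing to 100%; `top_n_taxa()` breaks ties lexicographically so
orderings are deterministic. "Active" has no formal definition in SIP
amplicon work, so `active_taxa()` operationalizes it with two exposed
thresholds: active = relative abundance in the 15N heavy fractions at
least `min_abund` (default 1%), enriched = additionally at least `fold`
(default 2) times the reference-group abundance, with absence from the
reference counting as enrichment iff active. The reference group is
user-specified because the natural comparator (control light fractions
vs. bulk control DNA, and at which day) is a per-study choice.

## Problem sizes and determinism

Every stochastic operation takes an explicit seed and is bit-reproducible
for a fixed seed; the pipeline runner writes a manifest recording seed
and thresholds, and reruns are byte-identical. The validation suite uses
16-fraction gradients with 1e7-copy taxa, 100-seed recovery sweeps, and
28-day microcosms at a 0.25-day step — sizes chosen to mirror the bench
protocol while keeping a full run in seconds.

## Known limitations

- The GC→density and RI→density coefficients are standard calibrations;
  laboratories with their own calibrations should expect small constant
  offsets in absolute (not differential) densities.
- The margin rule assumes the 14N profile is an adequate no-labeling
  reference; community shifts between treatments that move the 14N peak
  would bias HF selection in either direction.
- Partial labeling below roughly half a fraction width of shift is not
  reliably detectable at the default noise level — a physical limit of
  15N-SIP, not an implementation one.
- The microcosm model omits ammonia volatilization, immobilization,
  nitrite intermediates and pH feedback; it is a calibration vehicle for
  net rates, not a process model.
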
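# nsip

Quantitative analysis of **15N-DNA stable isotope probing (DNA-SIP)**
experiments on nitrifying soil communities: ammonia-oxidizing archaea
(AOA), ammonia-oxidizing bacteria (AOB) and comammox *Nitrospira*.

DNA-SIP feeds a soil community an isotopically heavy substrate (here
15N-urea) and detects activity as the buoyant-density shift that isotope
incorporation imprints on DNA in a CsCl gradient. The 15N signal is small —
full labeling shifts density by only

Δρ = a · ρ₀(GC) · n_N(GC) · Δm_N / m_bp(GC)  ≈ 0.02 g/mL

(a = 15N atom fraction, n_N = 7 + GC nitrogen atoms per base pair,
Δm_N = 0.9970 g/mol, m_bp the base-pair molar mass) — so quantification
rests on contrasting paired ¹⁵N vs ¹⁴N per-fraction qPCR profiles. The
package provides:

- **SIP quantification** — refractive-index → buoyant-density conversion,
  max-normalization of fraction profiles, heavy-fraction (HF) detection by
  a reproducible margin rule (with manual override), the HF ratio
  R = HF copies / Σ all-fraction copies, and the ¹⁵N-labeled abundance
  R × A_total (`identify_heavy_fractions()`, `hf_ratio()`,
  `labeled_abundance()`, `quantify_labeling()`);
- **nitrification metrics** — net nitrification rate ΔNO₃⁻-N/Δt, percent
  inhibition by acetylene, log10 transforms and one-way ANOVA
  (`net_nitrification_rate()`, `inhibition_percent()`, `one_way_anova()`);
- **community summaries** — Zotu relative abundance, clade composition,
  top-N taxa and active/enriched classification of heavy-fraction
  communities (`clade_composition()`, `active_taxa()`);
- **a synthetic-data generator** — Gaussian banding of GC- and
  label-dependent DNA over a 16-fraction CsCl gradient with multiplicative
  qPCR noise, and two-pool urea → NH₄⁺ → NO₃⁻ microcosm kinetics
  (`simulate_gradient()`, `simulate_microcosm()`) — giving every analysis
  stage a ground-truth harness.

See the methods vignette (`vignettes/sip-quantification-methods.Rmd`) for
the models, defaults and design decisions.

## Worked example

```r
library(nsip)

# a fully 15N-labeled population at 50% GC, 1e7 amoA copies/g dry soil
tx  <- taxon_spec("AOB", total_copies = 1e7, gc = 0.5, atom15n = 1)
sim <- simulate_sip_experiment(tx, gradient_protocol(), seed = 1)
p15 <- sim$label15N$profiles[[1]]
p14 <- sim$label14N$profiles[[1]]

(hf <- identify_heavy_fractions(p15, p14))
#> [1] 6 7 8
hf_ratio(p15, hf)
#> [1] 0.9940543
labeled_abundance(hf_ratio(p15, hf), sum(p15$copies))
#> [1] 9752830
peak_bd(p15) - peak_bd(p14)
#> [1] 0.0225
label_shift(1, 0.5)
#> [1] 0.02068141
```

The labeled band is recovered in mid-gradient heavy fractions 6–8: ~99% of
the gene copies sit in the HF, the estimated labeled abundance (~0.98e7
copies/g) recovers the true 1e7 within qPCR noise, and the observed peak
shift (0.0225 g/mL, quantized to the 0.0075 g/mL fraction width) matches
the predicted full-label shift of 0.0207 g/mL.

## Analysis workflow

Numbered drivers under `analysis/` run the full study desk-scale and write
tables under `results/`:

1. `01_simulate.R` — synthetic gradients for an acidic and a neutral soil
   (labeled peaks placed at 1.7243 / 1.7162 g/mL) and 28-day urea ± C₂H₂
   microcosms calibrated to net nitrification rates 2.10 / 5.24 mg N/kg/d;
2. `02_quantify.R` — HF detection and labeled-abundance estimation per
   gene and soil;
3. `03_rates.R` — net rates, acetylene inhibition, C/N ratios and the
   treatment ANOVA;
4. `04_community.R` — clade composition, top taxa and active/enriched
   calls on the bundled synthetic Zotu dataset.

`run_pipeline()` exposes the same stages through a single validated YAML
configuration and writes a deterministic run manifest.

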
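# pancslice

Quantitative analysis of long-term organotypic pancreatic slice culture.

Live pancreatic slices (~120 µm sections) preserve the native
cytoarchitecture of the organ, but their survival in culture is limited by
oxygen: tissue consumes oxygen far faster than still medium can supply it.
`pancslice` is aimed at researchers modelling and measuring slice culture —
it implements, as tested reusable functions:

* a **2D oxygen reaction–diffusion model** of the two standard culture
  geometries — transwell (slice suspended in medium, oxygen entering only
  at the free surface) and PFC membrane (gas-permeable dish base acting as
  a direct oxygen source) — with anoxic-volume statistics and parametric
  sweeps over the oxygen consumption rate (OCR);
* **evaporation-corrected metabolic flux equations**: glucose consumption
  and lactate production rates, normalised per µg DNA, plus an
  ATP-per-glucose efficiency index and daily-series AUC summaries;
* **perifusion trace analysis**: stimulation indices (SI) and windowed AUCs
  for insulin/glucagon/amylase under the standard stimulus sequence;
* **calcium-imaging quantification**: ΔF/F, response AUC above baseline,
  the ≥2-elicitations / ≥2×-baseline-fluctuation acceptance rule, and
  β-cell vs acinar classification by secretagogue profile;
* **longitudinal lineage-tracing image quantification**: tissue
  segmentation, red/green/yellow (co-localisation) area fractions,
  viability, nuclei counting, MFI per cell, marker-positive composition;
* **seeded synthetic-data generators** for all of the above, each carrying
  exact ground truth for recovery testing.

## The model at the core

Oxygen transport is solved in partial-pressure form,

    alpha dp/dt = div(K grad p) - r_max p/(p + km)   [tissue only]

with diffusive permeability K = D·alpha, so p (mmHg) is continuous across
the medium–tissue interface. Tissue below 0.1 mmHg counts as anoxic. The
solver is a finite-volume, backward-Euler scheme with harmonic-mean
interface permeabilities and positivity-preserving linearised kinetics; it
is validated against the closed-form zeroth-order slab profile
p(z) = p0 + (r_max/2K)(z² − Lz) and conserves mass to machine precision.

The flux equations are the osmolarity-corrected differences

    GCR = (G_blank − G_culture·Osm_blank/Osm_culture) / ΔTime
    LPR = (L_culture·Osm_blank/Osm_culture − L_blank) / ΔTime

each divided by µg DNA.

## Worked example

```r
library(pancslice)

# Oxygen: 24 h of each culture mode at the average pancreatic OCR
kin <- oxygen_kinetics(r_max = 0.03, km = 0.44)
res <- domain_resolution(nx = 41, nz_medium = 16, nz_tissue = 10)
tw  <- simulate_oxygen(build_domain(culture_config("transwell"), resolution = res), kin, 24)
pfc <- simulate_oxygen(build_domain(culture_config("pfc"), resolution = res), kin, 24)
anoxia_onset(tw)                #> 0.1666667   (transwell core anoxic within minutes)
anoxia_onset(pfc)               #> NA          (PFC: no anoxia in 24 h)
max(pfc$anoxic_fraction)        #> 0

# Metabolic flux: hand-sized example
gcr(g_blank = 1000, g_culture = 800, osm_blank = 300, osm_culture = 330,
    delta_time = 12, dna_mass = 10)
#> 2.272727    (µg glucose / h / µg DNA, evaporation-corrected)

# 2-NBDG uptake fold difference between group MFI/cell means
fold_change(0.53, 0.075)        #> 7.066667

# Calcium: recover known labels from a synthetic population at SNR 4
cs <- synth_calcium_set(amplitude = 20, noise_sd = 5, seed = 1)
r  <- analyze_calcium_set(cs$time, cs$traces, cs$windows, cs$baseline_window)
mean(r$class == cs$truth$expected_class)
#> 1
```

The transwell onset above is the model's honest prediction at the
documented aqueous transport coefficients: the oxygen demand of the slice
exceeds diffusive supply through 1 mm of medium roughly seven-fold, so the
local oxygen store collapses within minutes. The methods vignette
(`vignettes/slice-culture-quantification.Rmd`) documents the calibration
envelope explored for the unprinted coefficients and why much later onsets
are not reachable under a pure diffusion–consumption model, while the
transwell/PFC contrast itself is robust.

## Analysis workflow

The `analysis/` directory contains numbered drivers that exercise each
stage end to end and write tidy tables under `results/`:

    analysis/01_oxygen_model.R     # 24 h transients, OCR sweep, calibration envelope
    analysis/02_metabolic_flux.R   # synthetic assays -> GCR/LPR recovery, AUC comparison
    analysis/03_secretion.R        # synthetic perifusion traces -> SI + window AUCs
    analysis/04_calcium.R          # classification accuracy across SNR
    analysis/05_lineage_imaging.R  # treated vs control timelapse quantification

Each run writes a JSON manifest (config + seed + package version);
identical config and seed reproduce outputs byte-identically.

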
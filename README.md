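# otomigrant

Life-history reconstruction and size-selective mortality analysis for
migratory salmon, from otolith and eye-lens chemistry.

Juvenile fall-run Chinook salmon leave their natal river either as newly
emerged fry (**early migrants**, roughly ≤ 47 mm fork length) or later as
larger parr/smolts (**late migrants**). Because dead juveniles are never
observed, mortality has to be inferred from survivors: otolith
⁸⁷Sr/⁸⁶Sr transects record each fish's movement between isotopically
distinct waters, so the fork length at which every sampled fish — juvenile
or returning adult — originally left its natal river can be back-calculated
and compared across sequential sampling points (Delta entry → within Delta
→ Delta exit → spawning grounds). A rising mean natal-exit size along that
chain is the signature of size-selective mortality. This package is aimed
at fisheries and movement ecologists using archival-structure chemistry to
study migratory life histories.

## What it implements

* **Profile reconstruction** — natal exit as the first downward crossing of
  the natal-river minimum ratio (0.7085), freshwater exit as the first
  upward crossing of the estuary-boundary mean (0.70785), both linearly
  interpolated; normalized-SrV fallback (52% of the within-fish range) for
  rapid migrants that cross neither threshold, plus the total-radius and
  measured-length fallbacks by sampling context.
* **Back-calculation** — the broken-stick regression
  FL = 0.021259·OR + 31.08748 (OR < 256 µm), 0.165660·OR − 5.8799
  (OR ≥ 256 µm), its exact inverse, and mass apportionment between natal
  and non-natal freshwater habitats as fractions of total freshwater
  growth.
* **Phenotype model** — Hartigan's dip test (GCM/LCM construction, uniform
  bootstrap null) and a two-component normal mixture fitted by multi-start
  EM; the early/late cutoff is the density crossing between the component
  means.
* **Provenance rules** — eye-lens δ³⁴S prescreen (wild ≤ 10.5‰,
  estuarine check > 16‰), juvenile constraints (fry size, hatchery release
  dates, site geography) with probability zeroing and renormalisation, the
  exogenous-feeding-check reassignment, and adult age fallbacks.
* **Selection statistics** — standardized selection differentials
  i = (z̄\* − z̄)/v between sequential sampling points (Delta, Ocean, All
  segments), covariate regressions, and catch-expansion resampling.
* **Demography** — hatchery fractions with the exact 1/(1 − 0.25) = 1.33
  marking expansion, natural escapement, and cohort replacement rates
  (age-apportioned returns per natural spawner) with flow regressions.
* **Synthetic cohorts** — a seed-deterministic generator producing true
  histories, noisy otolith profiles and sampling-point catches with the
  statistical structure the analysis assumes, so the whole chain is
  testable offline.

## Worked example

Reconstruct one fish, then run the full synthetic pipeline:

```r
library(otomigrant)
iso <- isoscape_config()

pr <- profile_from_history("fish-1", natal_fl = 40, fw_fl = 80, iso,
                           noise_seed = 3)
reconstruct_exits(pr, iso, "adult")
#>   natal_exit_radius natal_exit_method natal_exit_fl natal_never_crossed
#> 1             278.3    ratio-crossing         40.23               FALSE
#>   fw_exit_radius fw_exit_method fw_exit_fl fw_never_crossed
#> 1          516.9 ratio-crossing      79.75           FALSE
```

The fish truly left the natal river at 40 mm (radius 277 µm) and
freshwater at 80 mm (518.4 µm); with realistic measurement noise the
thresholds recover 40.2 mm and 79.8 mm.

```r
res <- run_pipeline(years = 2014:2016, seed = 7)
res$cutoff
#> <phenotype_cutoff> 48.5 mm (328 um); dip D = 0.0405, p = 0.001996
res$all_years[, c("point", "n", "natal_mean", "pct_early", "fw_mean")]
#>         point   n natal_mean pct_early fw_mean
#> 1       adult  51       67.0      18.7    81.6
#> 2 delta-entry 300       47.1      75.0      NA
#> 3  delta-exit 150       54.1      54.7    80.3
#> 4 delta-seine 180       49.5      69.4      NA
aggregate(i ~ segment, data = res$selection, FUN = mean)
#>   segment     i
#> 1     All 0.129
#> 2   Delta 0.046
#> 3   Ocean 0.055
```

Read: natal-exit sizes are bimodal (dip p ≈ 0.002) with an estimated
early/late cutoff of 48.5 mm; early migrants fall from 75% of juveniles
entering the Delta to 55% leaving it to 19% of adult returns, freshwater
exit stays unimodal near 80 mm everywhere, and the positive selection
differentials quantify the survivor shift per segment.

## Analysis workflow

`analysis/` holds the numbered end-to-end study on synthetic cohorts —
run from the repository root after installing the package:

```sh
Rscript analysis/01_simulate_cohorts.R    # six cohort-years, flow-linked selection
Rscript analysis/02_reconstruct_exits.R   # thresholds + fallbacks + provenance
Rscript analysis/03_phenotype_cutoff.R    # dip test, mixture, cutoff
Rscript analysis/04_sampling_summaries.R  # annual + all-years summary tables
Rscript analysis/05_selection.R           # differentials + covariate regressions
Rscript analysis/06_demography.R          # hatchery fractions + replacement rates
```

Each script narrates what it finds and writes tidy tables under
`results/`.

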
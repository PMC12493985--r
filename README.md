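# sedmicro

Tools for asking how coastal eutrophication reshapes benthic microbial
communities — their diversity, their assembly processes, and their
life-history strategies — from the tabular summaries such studies produce:
water and sediment chemistry tables, OTU count tables with a phylogeny,
and per-sample metagenome summaries.

The package is aimed at microbial ecologists comparing a nutrient-impacted
system (an estuary receiving riverine nitrogen and carbon) with an
adjacent oligotrophic one, and wanting every step of the standard
inference chain reproducible and testable:

* **Trophic state.** The TRIX index for overlying water,
  `TRIX = (log10(Chl-a · aD%O · DIN · P) + 1.5) / 1.2`, with molar-to-mass
  nutrient conversion and a Weiss oxygen-solubility model for the
  saturation deviation; sediment organic nitrogen (`ON = TN × 0.95`) and
  organic index (`OI = TOC × ON`) with pollution levels I–IV.
* **Community metrics.** Observed richness, Chao1, Shannon, Simpson;
  Levins niche breadth `B_j = 1/Σ_i P_ij²` and its community mean `Bcom`;
  Bray–Curtis dissimilarity; distance–decay regressions; mean pairwise
  phylogenetic distance; Spearman co-occurrence networks (top-1000 OTUs,
  ρ > 0.6, FDR-corrected P < 0.001).
* **Assembly inference.** The Sloan neutral community model
  `Freq_i = 1 − I(1/N | Nm·p_i, Nm·(1−p_i))` fitted by bounded least
  squares with Wilson prediction envelopes; and the βNTI / Raup–Crick
  (Bray–Curtis) null-model framework partitioning site pairs into
  variable selection, homogeneous selection, dispersal limitation,
  homogenizing dispersal, and undominated processes.
* **Life-history traits.** Genome equivalents from 35 single-copy
  markers, community-average 16S rRNA copy number and genome size, GC
  content, codon usage bias as the reciprocal mean ENC′
  (background-corrected effective number of codons) of ribosomal genes,
  a configurable codon-bias → growth-rate calibration, and transposase
  content — the r- vs K-strategist axis.
* **Synthetic data.** Generators for Sloan-stationary metacommunities,
  selection-structured metacommunities with a phylogenetically conserved
  niche, regional chemistry within published ranges, and genome
  communities with planted traits, so every estimator is tested
  closed-loop against known truth.

Functions take data frames (or sites × OTUs count matrices, the
vegan convention) and return tibbles; fitted objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

Simulate chemistry for six estuarine sites and classify their trophic
state, then fit the neutral model to a simulated metacommunity:

```r
library(sedmicro)

chem <- simulate_chemistry("YRE", 6, seed = 7)
trophic_status(chem$water)
#> # A tibble: 6 × 6
#>   site_id   din   srp   ado  trix trix_class
#>   <chr>   <dbl> <dbl> <dbl> <dbl> <fct>
#> 1 YRE001  1628.  97.4  64.5  6.95 eutrophic
#> 2 YRE002   368.  32.3  48.8  5.66 eutrophic
#> 3 YRE003   956.  63.7  48.1  6.17 eutrophic
#> 4 YRE004   298.  30.3  68.1  5.60 eutrophic
#> 5 YRE005  1162.  98.5  50.4  6.58 eutrophic
#> 6 YRE006   234.  89.7  71.8  6.33 eutrophic
```

`din` and `srp` are the nutrient concentrations converted to µg/L, `ado`
the absolute % deviation of oxygen from saturation; every simulated
estuarine site exceeds the TRIX = 5 eutrophy threshold, as chemistry in
these ranges should.

```r
sediment_status(chem$sediment)
#> # A tibble: 6 × 7
#>   site_id    on    oi on_report oi_report on_level oi_level
#>   <chr>   <dbl> <dbl>     <dbl>     <dbl> <fct>    <fct>
#> 1 YRE001  0.204 0.460      0.2       0.46 IV       III
#> 2 YRE002  0.305 0.457      0.31      0.46 IV       III
#> # ... moderately-to-heavily eutrophic sediment, levels III-IV
```

```r
tab <- simulate_neutral_metacommunity(50, 500, N = 50000, m = 0.2, seed = 1)
fit <- ncm_fit(tab)
fit
#> Sloan neutral community model fit
#>   m = 0.18329  N = 50000  Nm = 9164.6  R2 = 0.2707 (centered)
#>   500 OTUs over 50 sites
autoplot(fit)   # occupancy vs abundance with the fitted curve and envelope
```

The planted migration rate was `m = 0.2` (`Nm = 10,000`); the fit
recovers `Nm ≈ 9,165`, within the ~10% downward bias that detection
sampling imposes on all such fits (see the methods vignette).

Null-model assembly analysis runs from a count table and tree:

```r
sel <- simulate_selection_metacommunity(10, 600, mode = "homogeneous", seed = 1)
res <- assembly_processes(sel$table, sel$tree, reps = 999, seed = 101)
res$fractions   # five-process partition; here dominated by
                # homogeneous selection (median betaNTI < -2)
```

## Documentation

The methods vignette (`vignettes/eutrophication-assembly.Rmd`) documents
the models and their assumptions, all tunable parameters with units and
defaults, what the synthetic generators do and do not emulate, and the
design decisions taken where the methods literature leaves choices open.
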
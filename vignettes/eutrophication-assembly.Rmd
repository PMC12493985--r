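---
title: "Trophic state, community assembly, and microbial life-history traits: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trophic state, community assembly, and microbial life-history traits: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sedmicro implements the computational chain used to ask how coastal
eutrophication reshapes benthic microbial communities: trophic and
sediment-pollution indices, diversity and niche metrics, neutral- and
null-model inference of community assembly, and community-averaged
life-history traits from metagenome summaries. This vignette documents the
models, their assumptions, the tunable parameters, and the design choices
made where the methods literature leaves them open. Every empirical claim
here is one the package's test suite or `scripts/acceptance.R` computes.

## Trophic status of overlying water

The TRIX index combines chlorophyll-a (µg/L), the absolute percent
deviation of dissolved oxygen from saturation, dissolved inorganic
nitrogen (µg/L) and soluble reactive phosphorus (µg/L):

$$\mathrm{TRIX} = \frac{\log_{10}(\mathrm{Chl}a \cdot aD\%O \cdot \mathrm{DIN} \cdot P) + x}{m},
\qquad x = 1.5,\; m = 1.2.$$

Values ≤ 4 are classed oligotrophic, (4, 5] mesotrophic, > 5 eutrophic;
boundary values go to the lower-severity class. Two unit conventions are
the package's responsibility:

* Nutrients are usually measured in µmol/L but the formula takes µg/L;
  `din_mass()` and `srp_mass()` convert with the atomic masses 14.007
  (N) and 30.974 (P) g/mol.
* $aD\%O$ needs a saturation concentration when only a DO concentration
  was recorded. `oxygen_saturation()` implements the Weiss (1970)
  temperature–salinity solubility fit (cross-checked in the tests against
  Benson–Krause table values at 20 °C); a directly measured saturation
  percentage always takes precedence.

A zero factor makes the log undefined: `trix()` raises an error rather
than returning a number, and the tibble pipeline `trophic_status()` maps
any missing factor to `NA` ("index not computable") because zero is a
valid concentration and must never stand in for a missing one.

## Sediment eutrophication status

Organic nitrogen is $ON = TN \times 0.95$ and the organic index is
$OI = TOC \times ON$, both on percent dry weight. Levels I–IV
(uncontaminated … heavily eutrophic) use the conventional OI bounds
(<0.05, 0.05–0.20, 0.20–0.50, ≥0.50). The ON scale is inconsistently
transcribed across the literature (the published table this scheme
descends from is not monotone as printed); the defaults fix the outer
bounds at 0.0033 and 0.13 and take 0.066 for the middle boundary, and all
bounds are arguments of `classify_sediment()`. Level assignment is
lower-bound inclusive. Reported tables round half-up to two decimals;
raw values are always kept.

## Diversity, niche breadth, networks, distance decay

* **Alpha diversity** (`alpha_diversity()`): observed richness, Chao1,
  Shannon, Gini–Simpson. Shannon uses natural logarithms by default —
  reported sediment values of ~6–7.5 on tens of thousands of OTUs are
  only consistent with nats — with the base configurable. Chao1 defaults
  to the bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$, finite
  when doubletons are absent; the classical form is a flag.
* **Levins niche breadth** (`niche_breadth()`):
  $B_j = 1/\sum_i P_{ij}^2$ with $P_{ij}$ the share of OTU $j$'s total
  found at site $i$ (the convention that yields the documented range
  $[1, n_{sites}]$); `Bcom` is the unweighted mean over OTUs.
* **Co-occurrence networks** (`cooccurrence_network()`): top-1000 OTUs by
  overall relative abundance (ties broken lexicographically for
  determinism), Spearman ρ over sites, Benjamini–Hochberg correction over
  all tested pairs, and edges with ρ > 0.6 and FDR-corrected P < 0.001.
  The published rule is the positive-only "ρ > 0.6"; an absolute-value
  mode is provided because signed variants are common. P-values use the
  t approximation, adequate at the ≥ 4-site sizes the function accepts.
* **Distance decay** (`distance_decay()`): OLS of Bray–Curtis similarity
  (1 − dissimilarity) on great-circle distance (haversine, radius
  6371 km) over unordered site pairs.
* **Phylogenetic distance** (`phylo_distance()`): the underlying field
  figure never names its metric, so both mean-pairwise-distance variants
  are provided: unweighted MPD over present taxa and an abundance-weighted
  Rao-style double sum $\sum_{i,j} w_i w_j d_{ij}$; neither is claimed to
  reproduce the original figure.

## Neutral community model

Sloan's model predicts the occurrence frequency of taxon $i$ from its
metacommunity mean relative abundance $p_i$:

$$\widehat{Freq}_i = 1 - I(1/N \mid N m p_i,\; N m (1 - p_i)),$$

with $I$ the beta CDF, $N$ the individuals per community, and $m$ the
migration probability. Conventions the source methods leave unstated,
fixed here as the standard practice for these fits:

* $N$ is the mean per-site total count; the detection limit is $1/N$.
* $m$ is estimated by least squares on $(p_i, Freq_i)$ over a coarse
  log-spaced grid on $[10^{-6}, 1]$ followed by golden-section
  refinement; an optimum at either bound sets a `boundary` flag instead
  of failing silently.
* $R^2 = 1 - SSE/SST$ with the *centered* total sum of squares (the
  common reporting convention); an uncentered variant is a flag. Note the
  centered $R^2$ can be small even when the fitted $m$ is accurate, since
  occupancy curves at high $Nm$ are almost flat.
* Per-OTU partitions (above/within/below prediction) use a Wilson
  binomial envelope at $n_{sites}$ trials around the predicted frequency.

The closed-loop bias documented by the acceptance test is worth knowing:
data simulated at $Nm = 10{,}000$ refit roughly 10% low, because
multinomial sampling smooths the sharp beta-CDF occupancy into detection
probabilities. This is inherent to all fits that use observed detection
as a proxy for true occupancy, not an optimizer artifact.

## Null-model assembly framework

`beta_mntd()` computes between-community mean nearest taxon distance
(abundance-weighted by default — communities are compared on relative
abundances — with a presence mode pooling both communities' nearest-taxon
distances, the convention of the reference implementation).
`bnti()` z-scores the observed βMNTD against `reps` randomizations
(default 999) that shuffle taxon identities across tips. `rc_bray()`
ranks observed Bray–Curtis dissimilarity against null assemblages that
preserve each site's richness and total abundance, drawing taxa by
occurrence frequency and filling abundances by metacommunity relative
abundance, rescaled to $[-1, 1]$. `classify_processes()` applies the
decision tree: βNTI > +2 variable selection; βNTI < −2 homogeneous
selection; otherwise RC > 0.95 dispersal limitation, RC < −0.95
homogenizing dispersal, else undominated.

Design choices made where the framework is described only by name:

* **Null pool.** The tip shuffle defaults to the whole regional pool
  (every tip of the supplied tree), one permutation per replicate applied
  to all site pairs — the behaviour of the framework's reference
  implementation. A pair-restricted shuffle is available
  (`null_pool = "pair"`) but is a much weaker null: the union of two
  communities assembled under homogeneous selection is already
  phylogenetically clustered, so shuffling only within it removes the very
  signal the test looks for. It is retained for sensitivity analysis, not
  as the default.
* **Determinism.** All nulls derive from a single seed argument;
  matrices are seed-reproducible, and degenerate pairs (null sd = 0,
  e.g. identical communities everywhere) are `NA` and counted, never
  silently dropped.
* **Raup–Crick on neutral data.** A Sloan-stationary community at
  migration rate $m$ has genuine between-site heterogeneity (beta
  diversity of order $1/\sqrt{Nm\,p_i}$ per taxon) that the Raup–Crick
  null — multinomial resampling of the metacommunity — does not contain.
  When sequencing depth is high relative to richness, that heterogeneity
  dominates and RC correctly reads +1: dispersal limitation is part of
  neutral dynamics whenever $m < 1$. The "|RC| ≤ 0.95 under neutrality"
  regime holds when occupancy turnover of rare taxa near the detection
  limit dominates, which is the condition the regime-recovery tests use
  (many log-series taxa relative to depth). This is a property of the
  method, not of this implementation.
* **Calibration.** Under its own null (communities assembled by random
  tip assignment) βNTI is approximately standard normal; the acceptance
  suite verifies mean, sd, and the ±2 coverage by pooling several hundred
  independent site pairs at 999 randomizations each, because the mean of
  a handful of pair scores is dominated by sampling noise rather than by
  calibration error.

## Life-history traits from metagenome summaries

All estimators take tabular per-sample summaries (marker coverages, a
labelled gene catalog with lengths, coverages and coding sequences), not
reads or assemblies — gene identification is upstream and out of scope.

* `genome_equivalents()`: aggregate mean coverage of a 35-gene universal
  single-copy marker panel (any declared panel is accepted; short panels
  warn). A trimmed mean blunts outlier markers.
* `avg_16s_copy_number()`: summed 16S coverage ÷ genome equivalents — a
  coverage-weighted community mean, the classic r-/K-strategy axis.
* `avg_genome_size()`: total base pairs ÷ genome equivalents, with the
  basis ("assembled" contig bp, per the workflow's wording, or total read
  bp) recorded explicitly since the two conventions differ.
* `gc_content()`: (G+C)/(A+C+G+T) with ambiguity codes excluded from the
  denominator and counted.
* `enc_prime()`: background-composition-corrected effective number of
  codons on the 20–61 scale. Per synonymous family the observed usage is
  compared to the usage expected under a background nucleotide
  composition with a chi-square statistic,
  $F = (X^2 + n - k)/(k(n-1))$, and class means enter
  $N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$, clamped
  to [20, 61]. Families with fewer than two codons are unusable; a
  missing three-fold class mean is imputed as the two/four-fold average
  (Wright's rule) and any other missing class as the mean of observed
  class means. Genes shorter than `min_codons` (default 100 codons, the
  usual stability floor) are flagged and excluded from community means.
  The uncorrected Wright statistic (`enc_wright()`) is provided for
  comparison. The closed-form extremes (61 for uniform synonymous usage,
  20 for one codon per amino acid) hold under a uniform background; with
  the default gene-composition background, maximal-bias genes score above
  20 exactly because part of their bias is explained by composition —
  that is the point of the correction.
* `community_cub()`: community codon usage bias = 1 ÷ (unweighted mean
  ENC′ over ribosomal-protein genes).
* `predict_growth()`: minimum generation time from a configurable linear
  calibration $\log_{10} d = a + b\,\Delta\mathrm{CUB}$, where
  $\Delta\mathrm{CUB}$ (from `catalog_delta_cub()`) contrasts ribosomal
  bias with the whole-catalog background; maximal growth rate is $1/d$.
  The defaults ($a = 1.25$, $b = -250$) are a package default on the
  scale of published codon-bias growth predictors, not a reproduction of
  any external tool's unpublished coefficients — which is why
  `fit_growth_calibration()` exists to calibrate on user-supplied
  (bias, generation-time) pairs, and why absolute growth-rate levels from
  the defaults should not be compared across studies.
* `transposase_fraction()`: coverage×length (RPM-equivalent) share of
  transposase-labelled genes. The denominator is configurable
  (`annotated_genes` default vs `all_genes`) because published
  "transposase content" percentages rarely state theirs.

## What the synthetic-data module emulates

The generators produce exactly the statistical structure the inference
stages assume, so every estimator can be tested closed-loop against
planted truth:

* `simulate_neutral_metacommunity()` samples the stationary Sloan
  distribution directly — per site a Dirichlet draw with concentration
  $Nm\,p$ (whose marginals are exactly the model's beta distributions)
  followed by a multinomial of $N$ individuals. This is deliberate: it
  matches the fitted model rather than forward-simulating birth–death,
  is fast, and is seed-stable. Closed-loop test conditions: 50 sites,
  500 taxa, log-series metacommunity, $N = 50{,}000$, $m = 0.2$
  ($Nm = 10^4$).
* `simulate_selection_metacommunity()` evolves a niche optimum by
  Brownian motion on a pure-birth, unit-depth tree and filters each
  site's taxa with Gaussian weights around its environment. Three
  structural choices matter. (1) The trait evolves on a depth-compressed
  copy of the tree (node heights $h \to h^{\delta}$, default
  $\delta = 0.1$), concentrating trait variance on deep splits; plain
  Brownian motion is too homoplastic for a trait filter to pick out a
  clade, and a clade-conserved niche is precisely the assumption behind
  βNTI. (2) The default shared environment sits at the trait's 0.9
  quantile: the centre of a Brownian trait range is reachable by many
  clades and filters weakly, whereas an extreme isolates one. (3)
  Per-site lognormal weight noise (`drift_sd`, default 1.5) supplies the
  drift component; without it all sites converge on one assemblage and
  there is no turnover for a null model to judge. Defaults
  (`filter_width = 0.2` trait-sd units, $N = 2000$) were chosen by pilot
  runs as the conditions under which the homogeneous regime is cleanly
  expressed; the acceptance suite verifies median βNTI < −2 under them
  and the collapse of the signal as `filter_width` → ∞.
* `simulate_chemistry()` draws each variable uniformly and independently
  within the published per-region ranges for the eutrophic estuary (YRE)
  and oligotrophic shelf sea (ECS); ranges are the only published
  constraint, so no cross-variable correlation is imposed. Salinity and
  temperature (needed only for oxygen saturation) are package choices:
  YRE 25–32 / ECS 32–34.5 practical salinity, 18–26 °C, typical summer
  estuary/shelf values.
* `simulate_genome_community()` plants per-taxon genome size, 16S copy
  number, GC, transposase count and a ribosomal ENC′ target, then builds
  the marker table, gene catalog (with coding sequences synthesized by a
  two-regime codon sampler bisected until realized ENC′ is within 0.5 of
  target) and read summary. Coverage noise is multiplicative gamma whose
  CV is `dispersion` for a 1 kb feature and shrinks as
  $1/\sqrt{\text{length}}$ — mean coverage of long features averages over
  proportionally more positions. "Moderate" noise in the recovery tests
  is `dispersion = 0.1` (10% CV at 1 kb). Abundance-weighted planted
  community traits are returned alongside for recovery testing.

What the generators do **not** emulate: read-level error profiles,
assembly artefacts, chimeras, compositional correlations between
chemistry variables, temporal structure, or taxon-specific 16S copy-number
variation within genomes. Passing closed-loop tests therefore
demonstrates that the estimators are correct for data meeting their
assumptions, not that those assumptions hold in any particular sediment
survey.

## Numerical and reproducibility choices

* All stochastic functions take an explicit `seed`; `NULL` leaves the
  caller's RNG untouched, an integer gives a local reproducible stream.
  Output tables carry a version/seed provenance comment, and
  `write_run_manifest()` records every decision threshold actually used.
* Problem sizes in the shipped tests (e.g. 10 sites × 600 taxa at 999
  randomizations for regime recovery, 400 pooled pairs for βNTI
  calibration) are the smallest at which the tested signals are stable
  across pilot seeds; all scale linearly in `reps` and quadratically in
  sites for users who want more.
* Ties in top-k abundance ranking break lexicographically; Raup–Crick
  equality counts use a 10⁻¹² tolerance on Bray–Curtis values; level
  classification is lower-bound inclusive throughout.

## Known limitations

* The headline quantities of field surveys (fitted $Nm$, NCM $R^2$,
  trait medians) depend on deposited sequence data and unstated
  conventions (detection limits, $R^2$ convention, transposase
  denominator, growth calibration); the package makes each convention
  explicit and configurable, but absolute values are only comparable
  between runs that share them.
* The growth-rate calibration default is a scale anchor, not a validated
  regression; use `fit_growth_calibration()` with reference organisms for
  quantitative work.
* Spearman p-values use the large-sample t approximation; with very few
  sites exact permutation p-values would differ.
* βNTI on large site sets is O(pairs × reps); the implementation is
  vectorized per pair but not parallel.
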
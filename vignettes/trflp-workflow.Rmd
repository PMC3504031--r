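---
title: "Profiling root-associated fungal assemblages with T-RFLP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling root-associated fungal assemblages with T-RFLP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trflpr)
```

## The problem

Ericaceous plants such as *Rhododendron* depend on ericoid mycorrhizal (ERM)
fungi housed in their fine "hair roots", but those roots also harbour
ectomycorrhizal fungi, dark septate endophytes and taxa of unknown ecology
(together the non-ericoid, NEM, assemblage). A central question in fungal
biogeography is whether these two assemblages are structured by the same
forces: geographic distance (dispersal limitation and spatially
autocorrelated environments) or the genotype of the individual host plant.

`trflpr` implements the full analysis chain used to ask that question with
terminal restriction fragment length polymorphism (T-RFLP) fingerprinting:

1. ITS clone sequences are clustered into OTUs and assigned to guilds;
2. each OTU's four expected terminal restriction fragments (TRFs) are
   predicted by in-silico digestion (HaeIII and HinfI, forward 6-FAM and
   reverse HEX labelled ends);
3. observed fragment-analysis peak tables are matched against the expected
   TRFs to call OTU presence per root sample;
4. host genotypes come from a binary inter-simple-sequence-repeat (ISSR)
   band matrix;
5. permutation statistics (Mantel tests, distance decay, envfit vector
   fitting with Holm–Bonferroni correction, occupancy distributions with
   Fisher's exact test) relate the ERM and NEM assemblages to geography,
   climate, soil and host genetics.

## Presence calling: the 3-of-4, ±1-base rule

An OTU contributes four expected TRFs (2 enzymes × 2 labelled ends). It is
called present in a sample when at least three of the four are matched by
an observed, non-excluded peak within a tolerance of 1 base. Choices worth
making explicit:

* **The tolerance is inclusive** (`|observed − expected| ≤ 1.0`) and is
  applied to fractional sizes, because capillary size-calling reports
  fractional bases. Integer binning can be emulated by rounding the peak
  table upstream.
* **Fragments below 50 bases are invisible** to the assay, on both sides:
  observed peaks under 50 bases are flagged `excluded`, and an expected TRF
  under 50 bases can never match. An OTU with two or more sub-50-base
  expected fragments can never be called present; `expected_trf_set()`
  warns prominently when this happens.
* **Peaks are not assigned exclusively.** One observed peak may satisfy
  several OTUs; shared TRFs are a known limitation of T-RFLP and no
  competition rule is imposed. For area bookkeeping, the nearest peak
  (ties broken by larger area) is recorded.
* **A missing channel** simply leaves its keys unmatched — partial runs
  occur in practice and should not abort an analysis.

## Community dissimilarity

Dissimilarity between two root samples is computed per channel (enzyme ×
end) as Sørensen dissimilarity on the TRF presence sets, and the community
dissimilarity is the element-wise mean of the four channel matrices. A
sample with no positive TRFs in a channel has no defined Sørensen value;
`sorensen_dissimilarity_matrix()` errors by default, but the pipeline uses
`empty = "one"` (a pair with exactly one empty sample is maximally
dissimilar, two empty samples are identical), because sparse guilds —
NEM in particular — do drop to zero in noisy fingerprinting runs and
aborting a 45-sample analysis over one empty channel would be worse than
this explicit convention.

## Permutation statistics

* **Mantel tests** use the standardized statistic *r* (Pearson correlation
  of off-diagonal entries) with p-values from jointly permuting rows and
  columns of one matrix, `p = (#{r_perm ≥ r_obs} + 1)/(n_perm + 1)`; the
  default is 4999 permutations and the one-tailed ecological convention
  (a two-tailed flag is available).
* **Distance decay** is the Pearson correlation between geographic distance
  and community dissimilarity over sample pairs. Pairs of a distance matrix
  are not independent, so significance is assessed by Mantel permutation;
  the naive parametric p is reported only as a diagnostic. (This choice is
  forced by arithmetic: with 45 samples there are 990 pairs, and a
  parametric test on 990 "observations" would declare tiny correlations
  significant.)
* **Geographic distances** are haversine great-circle distances on a
  6371 km sphere. Quantitative environment matrices (climate, soil) are
  relativized to each column's maximum before Euclidean distances are
  taken, making them unit-free.
* **envfit vector fitting**: community matrices are ordinated by centred
  PCA (the linear, RDA-family ordination; an optional Hellinger transform
  is available) and each environmental factor is regressed on the first
  two axis-score columns; r² is the coefficient of determination and p
  comes from permuting the factor across samples (default 9999
  permutations). Two axes match common practice and the two reported host
  axes; the count is configurable. We fit vectors to an unconstrained
  ordination rather than running a constrained RDA with all 11 factors,
  which would be rank-deficient and collinear at 45 samples.
* **Holm–Bonferroni**: adjusted `p(j) = min(1, max_{i≤j} (N−i+1) p(i))`
  over ascending raw p-values, applied within each community column with
  N = 11 factors.
* **Fisher's exact test** (occupancy contrasts) uses the standard two-sided
  definition: the sum of hypergeometric point probabilities no larger than
  the observed table's.

## OTU clustering and guilds

Sequence distance is `1 − identity` over all columns of a global pairwise
alignment (match 1, mismatch −1, gap −2 per gap position; gap columns count
as non-identical, IUPAC-ambiguous pairs with overlapping base sets count as
identical — clone libraries rarely contain ambiguity codes and the
permissive convention is standard). OTUs are single-linkage
(nearest-neighbour) clusters cut at distance 0.03, the usual 97% fungal
species proxy. Guild assignment is a first-match keyword scan over the OTU
name and closest-match annotation; the default rule table (Sebacinales,
Helotiales/Helotiaceae, *Oidiodendron*, *Rhizoscyphus ericae*,
*Articulospora*, *Varicosporium*, *Holwaya* and the *Rhododendron*
mycorrhizal ascomycete → ERM; Thelephoraceae, Agaricomycet- → ECM;
*Phialocephala*, dark septate endophytes → DSE) ships as a plain CSV and
reproduces the packaged 35-OTU reference table exactly
(25 ERM / 2 ECM / 2 DSE / 6 unknown).

## What the synthetic generator emulates

`scenario_config()` + `generate_study()` produce a complete synthetic study
with the reference survey's dimensions: 45 hosts in 15 sites across 4
regions, 35 OTUs (25 ERM), four planted TRFs per OTU, a 119-band ISSR
matrix with 3 latent host groups, and GeneMapper-like peak noise
(Gaussian size jitter sd 0.35 bases, per-key dropout 0.1, two spurious
peaks per channel on average, log-normal areas). The planted structure is
the study's headline hypothesis:

* ERM occurrence probability is logistic in host-genetic similarity to an
  OTU-specific anchor host (`beta_host`, default 2 per SD);
* NEM occurrence is logistic in geographic proximity to an OTU-specific
  range centre (`beta_geo`, default 2 per SD);
* ERM includes a "core" of high-prevalence OTUs and NEM is
  satellite-dominated, planting the core–satellite occupancy contrast and
  a positive abundance–occupancy coupling (`area_beta`).

Design choices made where the real study is silent: host genetic groups are
drawn independently of region, because the planted contrast (ERM follows
hosts, NEM follows geography, cross-pairings null) requires host structure
decoupled from geography — consistent with the survey's own observation
that host structure was not strongly geographically patterned. Band
frequencies are tuned so pairwise host Sørensen similarities span roughly
0.36–0.84, the realistic ISSR range. Effect sizes default to values at
which the planted Mantel pattern is reliably detectable (measured power
≈100% at 45 hosts with 499 permutations, cross-pairing false positives at
the nominal 5%); satellite prevalences are set so mean per-host richness
lands near 12 OTUs.

What the generator does **not** emulate: sequence-evolution realism
(no indels or chimeras), pull-up or stutter artefacts, size-calling
calibration curves, or spatial autocorrelation beyond regional clustering.
Passing tests on synthetic data therefore demonstrate that the pipeline's
logic recovers known structure under realistic noise — not that any
particular field system behaves this way.

## Numerical conventions

* All randomized routines take an explicit seed; the generator derives a
  separate stream per stage from one root seed, so a single integer
  reproduces the whole bundle byte for byte.
* Permutation p-values use the add-one convention and can never be zero.
* PCA axes (host genetics and ordination) fix signs by making the
  largest-magnitude loading positive; k-means host grouping uses 20
  restarts under a fixed seed and relabels groups by ascending mean PC1.
* Single-linkage OTU labels are deterministic: the lexicographically
  smallest member id is the representative.
* Uncut amplicons yield a "TRF" equal to the full amplicon length, since
  real uncut products run as peaks.
* Duplicate peak-table rows are merged with areas summed (a documented
  dialect decision for GeneMapper exports).

## Problem sizes used in the checks

The test-suite demonstrations run at deliberately chosen scales: exhaustive
digestion checks on 1000 random sequences up to 2000 bases; noiseless
round-trips on a 9-host × 6-OTU study; dropout calibration on 200 hosts;
parameter-recovery across 100 generator seeds at the full 45-host scale
with 499 permutations per Mantel test; and the null family-wise-error check
across 200 seeds. These sizes give stable binomial confidence bounds while
keeping a full run inexpensive on a single core.

## Known limitations

* Shared TRFs between OTUs can inflate presence calls; the matcher reports
  matches per channel so users can audit ambiguous OTUs.
* Sørensen on empty channels requires the explicit `empty = "one"`
  convention described above.
* The envfit-style analysis is correlative vector fitting, not variance
  partitioning; collinear factors (latitude, climate) share signal.
* Abundance from peak areas is semi-quantitative at best; no cross-channel
  normalization is attempted.
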
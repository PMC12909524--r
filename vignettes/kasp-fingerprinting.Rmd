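---
title: "KASP panel development and SNP fingerprinting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{KASP panel development and SNP fingerprinting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kasprint)
```

`kasprint` implements the desk side of a KASP-based germplasm
fingerprinting study: screening SNPs for assay conversion, calling
genotypes from endpoint fluorescence, summarizing marker diversity,
inferring population structure, and building a fingerprint database that
identifies accessions from a minimal marker subset. This vignette explains
the models behind each stage, the tunable parameters and their defaults,
the numerical conventions, and — because every quantitative guarantee in
the test suite is demonstrated on synthetic data — what those guarantees
do and do not say about real panels.

## The screening cascade

A locus enters KASP development only if it is informative and
assay-friendly. `filter_cascade()` applies four predicates in a fixed
order and reports survivor counts per stage:

1. **MAF > 0.05** (strict). Frequencies are computed over called
   genotypes only; each called diploid contributes two alleles.
2. **Missing rate ≤ 0.2** (non-strict), with the full sample count as
   denominator.
3. **PIC > 0.3** (strict), Botstein's
   $PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$.
4. **No other variant within `flank_bp` (default 100) bases** on the same
   chromosome. The neighborhood test runs against the *entire input
   variant list*, not just survivors of stages 1–3: a neighboring variant
   disturbs primer annealing whether or not it would itself make a good
   marker.

Stages 1–3 are independent per-locus predicates, so the staged counts are
the counts of a nested conjunction; the suite verifies staged filtering
against a brute-force re-check of all four predicates on simulated panels.

`select_spaced_markers()` then thins survivors per chromosome, greedily
taking the highest-PIC locus and repeatedly the next-highest at least
`min_gap_bp` from everything already chosen. Both the per-chromosome quota
and the gap are exposed rather than fixed: how aggressively to thin is a
panel-design choice, not a property of the data.

`extract_flanks()` returns the closed 1-based window
$[pos - 100,\ pos + 100]$ (201 bases), truncated with a flag at contig
ends, and refuses to proceed if the center base disagrees with the
declared reference allele. `build_kasp_assay()` prepends the universal
tails `GAAGGTGACCAAGTTCATGCT` (FAM) and `GAAGGTCGGAGTCAACGGATT` (HEX) to a
20-base arm ending at the SNP, the terminal base set to the respective
allele, and takes a 20-base reverse-complement window 30 bases downstream
as a placeholder common reverse primer. Thermodynamic design (Tm, GC,
secondary structure) is deliberately out of scope — laboratories use
dedicated primer-design services for that — so the record captures assay
structure, not an orderable oligo set.

## Endpoint genotype calling

A KASP endpoint plate separates genotypes by direction in the (FAM, HEX)
plane: FAM-homozygotes along the FAM axis, HEX-homozygotes along the HEX
axis, heterozygotes along the diagonal, and non-amplifying wells near the
origin with the no-template controls (NTC).

`normalize_plate()` subtracts the per-channel NTC mean (clipping at zero —
fluorescence readers floor at no signal) and records NTC statistics.
`call_genotypes()` then:

* **gates** wells whose magnitude $\sqrt{FAM^2 + HEX^2}$ falls below the
  NTC magnitude mean plus `min_magnitude_sds` (default 6) NTC standard
  deviations — a conservative no-call rule, since a miscalled well is far
  costlier in fingerprinting than a dropped one;
* **clusters the angle** $\theta = \mathrm{atan2}(HEX, FAM)$ with
  deterministic 1-D k-means for $k \in \{1, 2, 3\}$, initialized at fixed
  canonical angles ($\pi/4$; $\pi/8, 3\pi/8$; $\pi/8, \pi/4, 3\pi/8$).
  Angle-space clustering is robust to well-to-well amplitude variation,
  which dominates real plates;
* **selects k**: $k = 2, 3$ are scored by mean silhouette width (with a
  singleton cluster scoring 1 when separated — a rare genotype class must
  not penalize the correct split), and $k = 1$ by angular tightness
  $\max(0,\ 1 - sd(\theta)/(\pi/8))$, so a single compact cluster beats
  any split of itself. Silhouette is undefined at $k = 1$, so some such
  bridge rule is unavoidable; this one is scale-matched to the $45°$
  spacing of the canonical clusters;
* **labels** clusters by mean angle (lowest → FAM-allele homozygote,
  highest → HEX-allele homozygote, middle → heterozygote; with two
  clusters, each maps to its nearest canonical angle).

Calling is deterministic — same plate, same calls — and consistent under a
FAM/HEX channel swap.

The call-set quality metrics drive `triage_assay()`: `core` needs an
inter-cluster margin of at least `min_gap_deg` (default 15°) and a no-call
fraction at most `max_nocall` (default 0.2); one clean genotype class is
`monomorphic`; everything else is `indistinct_or_failed`. The margin is
the *nearest-point* angular gap between adjacent clusters — the empty band
a person looks for in a cluster plot — rather than the center-to-center
distance, which stays large even when clouds visibly bleed into each
other. At noise levels around a quarter of the signal amplitude this
margin collapses and assays are flagged; at 5% noise, three-cluster
assays show margins near 30° and pass.

`replicate_concordance()` reports the fraction of samples called
identically across all replicates. Samples with any no-call are excluded
by default (concordance describes successfully genotyped samples);
`count_nocall_discordant = TRUE` charges them instead, and
`denominator = "pairs"` switches to replicate-pair counting — the exact
denominator convention differs between laboratories, so both are exposed,
with sample-level the default.

## Diversity statistics

Per marker: MAF, observed heterozygosity (heterozygous calls over called
samples), gene diversity $D = 1 - \sum_i p_i^2$, PIC, and missing rate.
$D$ is reported without the small-sample $n/(n-1)$ correction, which is
what standard marker-summary tables print; the corrected variant is
available via `gene_diversity(..., corrected = TRUE)`. All internal
values keep full precision; rounding (half **up**, `round_half_up()`)
happens only at the report layer, at 3 decimals for statistics and 2 for
percentages. For biallelic loci $PIC \le D \le 0.5$ and $PIC \le 0.375$,
with equality at $p = 0.5$; the suite property-tests the general
inequality on random frequency simplices.

A reference 31-marker panel table ships in
`inst/extdata/kasp_panel_diversity.csv` and is reproduced internally by
these formulas to the precision its own rounded MAF column permits (one
unit in the third decimal, since an MAF rounded at $\pm 5\times10^{-4}$
propagates through $|dD/dp| \le 2$ to $\pm 10^{-3}$).

## Population structure

**Distance.** `allele_sharing_distance()` computes, over mutually called
loci, $d = 1 - \frac{\sum_l s_l}{2 L}$ with $s_l$ the multiset
intersection of the two allele pairs (0, 1 or 2): a p-distance on [0, 1].
Missing data are handled by pairwise deletion; pairs with no comparable
loci are flagged undefined rather than guessed.

**Trees.** `nj_tree()` wraps Saitou–Nei neighbor joining (`ape::nj`),
clamping negative branch-length estimates to zero with a flag — the
convention of mainstream tree viewers. NJ is exact on additive matrices,
which the suite verifies on random trees. `bootstrap_support()` resamples
loci with replacement, rebuilds the tree, and scores each internal
bipartition of the point estimate by its replicate percentage.

**PCA.** Genotypes are coded as minor-allele dosage 0/1/2, missing values
mean-imputed per marker (the standard, slightly structure-attenuating
choice), columns centered, and the covariance eigendecomposed.

**Admixture.** The admixture model says each individual draws its two
alleles at locus $l$ with frequency $q_{il} = \sum_k Q_{ik} P_{kl}$, with
$Q$ row-stochastic ancestry proportions and $P$ subpopulation allele
frequencies. `admixture_em()` maximizes the binomial log-likelihood by
alternating multiplicative EM updates — the maximum-likelihood route to
the same likelihood that Bayesian MCMC samplers explore. A Gibbs sampler
adds prior structure and credible intervals but, for point estimates of
$Q$ at panel scale (tens of markers, ~100 accessions), EM is faster,
deterministic given its seed, and testable: the trace is provably
non-decreasing, which the suite asserts on every run. Five seeded
restarts (Dirichlet(1) rows of $Q$, uniform $P$) guard against local
optima; $P$ is clamped to $[10^{-6}, 1-10^{-6}]$ so monomorphic loci stay
in the likelihood's domain; convergence is declared when the
log-likelihood gains less than `tol` ($10^{-6}$) in an iteration.

**Evanno ΔK.** `evanno_delta_k()` accepts any replicate table of lnP(D)
values over consecutive K — from `admixture_em()` restarts or an external
MCMC program — and computes $L(K)$, sample sd $s(K)$,
$L'(K) = L(K) - L(K-1)$, $|L''(K)| = |L'(K+1) - L'(K)|$, and the per-K
statistic $\Delta K = |L''(K)|/s(K)$ that standard Evanno tools plot.
$\Delta K$ is undefined at the boundary K values and wherever $s(K) = 0$
(flagged, not fatal); the method intrinsically cannot support $K = 1$.

## Fingerprinting

`build_fingerprint_db()` stores profiles verbatim; missing calls are never
imputed. Two missing-data conventions matter and differ deliberately:

* **Separation** (used by `greedy_core_markers()`): a marker separates an
  accession pair only where *both* are called and differ. Counting a
  missing-vs-call disagreement as separation would let assay dropouts
  masquerade as discriminating power.
* **Distinctness** (used by `discrimination_count()`): missing equals
  missing and differs from every call, so profiles are compared as
  recorded.

The greedy selector maximizes newly separated pairs per step (ties: higher
PIC, then marker order) and emits the identification-efficiency curve —
distinct-profile count and separated-pair fraction per added marker, both
monotone. Greedy set cover is not guaranteed minimal; the suite checks it
against exhaustive minima on small databases and asserts only that it
fully discriminates whenever the complete panel does.

`match_query()` declares a match only for zero mismatches over at least
`min_overlap` (default 20 of 31) mutually called loci; fewer comparable
loci than that in every database entry yields `"insufficient data"`
rather than a verdict. `find_duplicates()` surfaces near-identical pairs
(clones, synonymous lots, labeling errors) at a configurable mismatch
budget. `export_fingerprint_matrix()` writes the matrix in publication
orientation with the fixed legend AA yellow, GG orange, CC blue,
TT purple, heterozygous green, missing grey.

## The synthetic-data generator

`simulate_population()` draws, per marker, an ancestral minor-allele
frequency uniformly from (0.05, 0.5]; subpopulation frequencies from the
Balding–Nichols distribution
$\mathrm{Beta}\!\left(p\frac{1-F}{F},\ (1-p)\frac{1-F}{F}\right)$;
ancestry rows from $\mathrm{Dirichlet}(\alpha \mathbf{1}_K)$; genotypes as
$\mathrm{Binomial}(2, QP)$; and missingness completely at random per
cell. Defaults are fixed at the study conditions the package models —
105 accessions, 31 markers, $K = 3$ subpopulations, per-cell missing rate
0.018 (the panel's mean per-marker missing rate of 1.81%) — with
$F_{ST} = 0.15$ and $\alpha = 0.2$ as a realistic regime for a regional
germplasm collection: moderate differentiation with mostly
single-ancestry individuals plus admixed ones, matching collections that
cluster visibly but not crisply. Balding–Nichols is chosen because it is
the standard single-parameter $F_{ST}$ model and makes parameter-recovery
tests meaningful; the truth object returns $Q$, $P$, ancestral
frequencies and pre-missingness genotypes.

`simulate_plate()` places genotype classes at canonical angles 0°/45°/90°
at a configurable amplitude with isotropic Gaussian noise, and puts NTC
and dropout wells at the origin under the same noise, clipping negative
fluorescence at zero.

**What the generator does not emulate** — and therefore what passing
tests do not establish about real data: linkage disequilibrium between
markers (loci are independent), pedigree structure, clones and selfing
(accessions are unrelated admixed individuals; the real collection
contains near-identical lots), informative missingness (real dropouts
correlate with assay quality and DNA concentration; the generator is
MCAR), allele-specific amplification bias, plate spatial and edge
effects, and passive-reference (ROX) normalization. Quantitative
guarantees — caller accuracy ≥ 95% at 5% noise, replicate concordance
≥ 97%, admixture recovery error < 0.15 — are statements about this
generative model at the stated settings, not about any instrument.

## Numerical conventions and degenerate inputs

* One integer seed controls every stochastic operation; results are
  bit-reproducible for a fixed seed and library version.
* All clustering and agglomeration tie-breaks are deterministic (fixed
  k-means initialization, first-index assignment ties, (chrom, pos)
  ordering).
* Zero called genotypes at a marker: statistics are flagged undefined per
  marker without aborting panel summaries; a zero-overlap accession pair
  is an undefined distance, and tree building names the offending pairs.
* Empty cascade input returns zero counts; an all-no-call plate is a
  failed-assay triage signal, not an exception.
* Report-layer rounding is half-up; internal values keep full precision.

The test suite exercises these behaviors at deliberately modest problem
sizes — panels up to 105 × 200, plates of 96 wells, bootstrap at B = 100,
admixture recovery at 150 × 100 — sizes chosen to make the full suite a
sub-minute sanity check while still leaving each statistical property
(HWE at the ancestral frequency, silhouette-based k selection, EM ascent)
room to fail if miscoded.

## Known limitations

* The EM fitter returns point estimates; it neither samples the posterior
  nor reproduces the numerical output of MCMC admixture programs, and with
  weak differentiation ($F_{ST} \lesssim 0.05$) ancestry proportions are
  only weakly identified at panel scale.
* Primer records are structural; no thermodynamic validation is done.
* The caller assumes at most three clusters (biallelic assays); paralogous
  amplification producing extra clusters will be absorbed or flagged
  indistinct rather than recognized.
* Nei's standard distance between inferred groups is not implemented; the
  accession-level distance is the allele-sharing p-distance.
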
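---
title: "Selecting core SNP marker sets for variety identification and DUS testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting core SNP marker sets for variety identification and DUS testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coremarkr)
library(dplyr)
```

## The problem

Plant variety protection requires every registered cultivar to be
*distinct* from existing varieties, *uniform* across its seed lot and
*stable* over generations (DUS). Scoring the UPOV test-guideline traits
morphologically is slow and environment-sensitive, so breeders
increasingly anchor DUS testing on molecular markers. `coremarkr`
implements the full marker funnel for a diploid, largely F1-hybrid crop
panel such as commercial cabbage:

1. **Filter** a genome-wide SNP table on minor allele frequency and
   missingness.
2. **Associate** every surviving SNP with every test-guideline trait by a
   single-marker regression scan, pool the top-K SNPs per trait, and
   deduplicate positions.
3. **Select candidates** preferring genic (CDS) annotation and even
   genomic spread.
4. **Minimise** the marker count: find nested core sets that still give
   every variety a unique genotype fingerprint.
5. **Describe diversity**: distance matrices, UPGMA/neighbor-joining
   trees with bootstrap support, K-medoids population clusters, PCA and
   LD decay.
6. **Evaluate** how well the clusters determine each DUS trait with
   one-way ANOVA and Duncan's new multiple range test.

Every stage takes a tibble (or the `genotype_panel` tibble subclass) and
returns a tibble, so stages compose with the pipe; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` visualisations.

## The genotype panel

A `genotype_panel` is a tibble with one row per biallelic SNP (`marker`,
`chrom`, `pos`, `ref`, `alt`; coordinates 1-based) and one column per
variety holding additive genotype codes 0/1/2 with `NA` for a missing
call. VCF, two-letter reference-database TSV and IUPAC FASTA writers and
readers round-trip this object (`read_vcf()`, `write_reference_db()`,
`encode_iupac()`).

## Per-marker statistics

`compute_maf()` counts alleles over called genotypes only; a heterozygote
contributes one copy of each allele. `compute_pic()` uses Botstein's
biallelic polymorphism information content

$$\mathrm{PIC} = 1 - (p^2 + q^2) - 2p^2q^2, \qquad q = \mathrm{MAF},\; p = 1 - q,$$

which equals the probability that a random mating is informative for
linkage (one parent heterozygous, discounting the ambiguous het x het to
het outcome). It is maximal at MAF 0.5 (0.375). The tests verify the
closed form against an explicit mating-enumeration oracle on a fine MAF
grid, and against a published 24-marker cabbage core panel; for three of
those 24 rows the printed PIC reflects the *unrounded* MAF (both table
columns are printed at two decimals), so the suite asserts exact 2-dp
agreement for the 21 self-consistent rows and rounding-envelope agreement
(true MAF within ±0.005 of the printed value) for all 24.

`filter_markers()` applies the funnel thresholds strictly
(`maf > maf_min`, `missing_rate < missing_max`), matching the common
"MAF > 0.05", "missing < 30%" (association panel) and "missing < 10%"
(structure panel) cascade; equality is dropped at both ends.

## Association funnel

`scan_trait()` regresses each trait on the additively coded genotype
(het = 1) and reports the F-test p-value, dropping varieties pairwise
for missing genotype or phenotype. Grade-coded QL/PQ traits are regressed
on their integer grades — UPOV grades are ordered — with a one-way
ANOVA-on-genotype-classes mode (`method = "anova"`) for genuinely
unordered traits. Deliberately there is **no multiple-testing
correction** and **no structure/kinship covariate**: markers are consumed
as per-trait *ranks* (top-K pooling), not significance calls, and adding
covariates would change the selection target, not improve it. Ties in
the ranking are broken by larger MAF, then position, so the funnel is
fully deterministic. `top_k_pool()` keeps the best `k = 200` markers per
trait; `dedup_positions()` collapses each (chrom, pos) to its
best-associated trait; `select_candidates()` greedily picks by
annotation tier (CDS first, then other genic, then the intergenic group),
then association strength, under a minimum same-chromosome spacing that
halves (with logging) whenever the target count is unreachable.

## Minimal distinguishing marker sets

A marker *separates* a variety pair iff both calls are present and
differ; het vs hom separates (scatter-plot genotyping distinguishes
them), a missing call never does — the conservative choice for an
identification claim. Finding a smallest marker subset separating all
$\binom{n}{2}$ pairs is set cover, so `greedy_min_set()` applies the
classic greedy algorithm (ties by higher PIC, then panel order), which
carries the $\ln m + 1$ approximation guarantee; the tests check it
against exhaustive enumeration on 100 small instances (it attains the
exact optimum in well over 80% of them). Coverage is certified: the
result records, per pair, the first separating marker, and pairs *no*
marker can separate (duplicate varieties) are listed as unresolved rather
than silently dropped.

`nested_sets()` builds the smallest requested size first, then grows it,
guaranteeing the subset chain (e.g. F10 ⊂ F24 ⊂ F87) that lets one
genotyping assay serve all three panels. Markers added beyond full
coverage maximise a blend of coverage redundancy, evenness of per-trait
representation (entropy of best-trait counts) and per-cluster
allele-frequency contrast. The original selection was a manual
random-then-curated search; we replace it with this deterministic greedy
(plus a seeded randomized-restart mode sampling among the top three
gains per step) because reproducibility matters more here than fidelity
to an unscripted process.

## Diversity

`genotype_distance()` defaults to the allele-sharing distance
$|g_i - g_j|/2$ averaged over co-called loci (identical = 0, het vs
hom = 0.5, opposite homozygotes = 1); a strict-mismatch metric is
available for sensitivity checks. The tree programs behind published
cabbage trees consume IUPAC strings without documenting their distance
model, which is why branch-length statistics of real trees are treated
as descriptive, not as test targets. `upgma_tree()` (average linkage,
heights halved, label-sorted for deterministic ties) reports the
sum-of-branch-lengths and minimum leaf-pair path statistics;
`nj_tree()` is Saitou–Nei neighbor joining with negative branches
clamped to zero and the deficit shifted to the sister edge.
`bootstrap_support()` resamples markers with replacement and scores
bipartition frequency. `cluster_varieties()` is K-medoids (PAM) on the
genotype distance — a deterministic surrogate for variational admixture
fitting; soft memberships are normalised inverse distances to medoids (a
Q-matrix analogue) and the hard label is their argmax, with the most
divergent cluster optionally tagged with the sentinel label "99" used
for outgroups such as purple types. `pca_variance()` mean-imputes
missing calls (the simplest defensible policy at these missingness
levels) before eigendecomposition; `ld_decay()` bins pairwise $r^2$ of
0/1/2 codes by physical distance and reports the first bin below a
threshold (default: half the maximum bin mean).

## Cluster-versus-trait evaluation

`anova_by_cluster()` is a fixed-effects one-way ANOVA (unbalanced groups
supported; zero-variance inputs are flagged with p = 1).
`duncan_mrt()` implements Duncan's new multiple range test from its
definition: for a span of $p$ ordered means the critical range is

$$R_p = q\!\left((1-\alpha)^{p-1};\, p,\, \nu\right)\sqrt{\mathrm{MSE}/n_h},$$

with $q$ the studentized-range quantile (`stats::qtukey`), $\nu$ the
error degrees of freedom and $n_h$ the harmonic mean of the span's group
sizes (the panel's clusters are unbalanced). Two means differ iff their
gap exceeds $R_p$, under the containment rule that a span declared
homogeneous is never split by a sub-span; letters come from the standard
insert-and-absorb scan. At span 2 the criterion reduces to the pooled
two-sample t-test via $q(\alpha; 2, \nu) = \sqrt{2}\, t_{\alpha/2,\nu}$,
which the tests verify, alongside letter patterns checked against
printed studentized-range tables.

`explain_traits()` turns each letter table into a DUS verdict. The
*groups* of a trait are the letters that have at least one *pure*
cluster (a cluster carrying only that letter); clusters with several
letters are ambiguous and set an `overlap` flag but still leave the pure
blocks countable — so `a/ab/b` yields two groups with the middle cluster
unclear, and `a/ab/ab/ab` yields one group. A trait is *explained* when
the global ANOVA p-value clears `alpha = 0.05` and at least one pure
group exists; it is unexplained when the gate fails or every cluster
shares a single letter. This formalises narrative verdicts like
"explained by the 'white' and 'purple' groups" while preserving, not
resolving, the ambiguous-overlap case.

## The synthetic panel generator

Real panels of this kind are derived from reduced-representation
sequencing of commercial varieties; the raw data lives in sequence
archives and is not needed to exercise the method. `simulate_panel()`
generates panels with the statistical structure the pipeline assumes:

* **Structure** — K subpopulations with Balding–Nichols allele
  frequencies, $p_k \sim \mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$, the
  standard structured-population model; ancestral frequencies are drawn
  uniformly above `maf_floor`.
* **Breeding system** — inbred varieties are homozygous by construction;
  F1 varieties are locuswise unions of two inbred parents (within-cluster
  crosses by default; between-cluster crossing is a flag because real
  pedigrees are unknown), heterozygous exactly where the parents differ.
  An `outcrossing` mode draws Hardy–Weinberg genotypes instead, used by
  the heterozygosity calibration test.
* **Traits** — 19 UPOV-style traits (2 QL, 11 QN, 6 PQ) with the integer
  grade sets used on cabbage DUS score sheets; each trait is an additive
  sum over `causal_per_trait = 5` causal SNPs (`effect_size = 1` per
  alternate allele, `noise_sd = 1`), thresholded at latent-score
  quantiles onto the grade set for graded traits.
* **Missingness** — uniform masking by default (`missing_rate = 0.1`,
  between the 30% association and 10% structure screens of the cascade);
  a marker-biased mode concentrates missingness on a third of markers to
  mimic variable per-marker call rates.

Defaults follow the study system: 96 varieties, 8 chromosomes, K = 7
clusters, F1 fraction 0.8, Fst 0.2. The default marker count (2000) is a
desk-scale stand-in for a genome-wide table; the acceptance analyses use
94 varieties with 400 candidate-stage markers at `maf_floor = 0.1` and
`missing_rate = 0.005`, reflecting a candidate panel that has already
passed MAF screening and a high-call-rate genotyping assay. The
generator does **not** simulate linkage or recombination (marker
positions are exchangeable), selection, genotyping-error structure or
pedigree relationships beyond one F1 generation — so passing tests
demonstrate correctness of the algorithms under the assumed statistical
structure, not performance on any particular real panel.

## Numerical and design choices

* Strict threshold inequalities; 1-based inclusive coordinates
  everywhere.
* Annotation precedence when intervals overlap: CDS-non-synonymous >
  CDS-synonymous > splice > intron > up/downstream > upstream >
  downstream > intergenic; synonymous/non-synonymous status is taken
  from the annotation input, never recomputed from codons.
* Monomorphic markers scan to p = 1 with a flag; all tie-breaks
  (p-value, MAF, position; coverage gain, PIC, panel order) are total
  orders, so identical inputs and seeds reproduce identical outputs.
* K-medoids is deterministic, so the `seed` argument of
  `cluster_varieties()` exists only for interface stability.
* The pipeline derives per-stage seeds from the global seed by a stable
  hash of the stage name, decoupling the stages' random streams.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_panel(panel_spec(n_varieties = 94, n_markers = 400,
                                 maf_floor = 0.1, missing_rate = 0.005,
                                 seed = 2026))
sets <- nested_sets(sim$panel, sizes = c(87, 24, 10), restarts = 10,
                    seed = 2026)
glance(verify_identification(sim$panel, sets$F10))
run <- run_pipeline(sim$panel, sim$traits,
                    config = run_config(core_sizes = c(24, 10),
                                        top_k = 50, n_candidates = 100,
                                        bootstrap = 100, seed = 1))
run$explanations
```

## Limitations

* The clustering surrogate shares only the hard/soft assignment contract
  with admixture models; individual ancestry fractions are not
  likelihood-based.
* The "explained by groups" verdict is one consistent formalisation of a
  narrative criterion; the overlap flag marks cases it does not resolve.
* Branch-length summaries of trees depend on the distance model and are
  reported, not validated against published figures.
* Greedy set cover is approximate by design; the certificate and the
  exhaustive-enumeration tests bound, but do not eliminate, the gap to
  the optimum at scale.
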
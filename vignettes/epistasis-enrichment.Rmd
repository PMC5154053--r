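---
title: "Pairwise epistasis scanning and gene-set enrichment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise epistasis scanning and gene-set enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epienrich)
```

## The problem

Univariate GWAS of common diseases leave most heritability unexplained, and
one plausible reason is epistasis: risk carried by *combinations* of variants
whose single-locus effects are too small to detect. `epienrich` implements a
three-phase strategy for case-control GWAS that looks for such signal and
then asks where it aggregates:

1. **SNP level.** Every pair of SNPs is scored with Multifactor
   Dimensionality Reduction (MDR), a nonparametric, model-free classifier of
   two-locus genotype combinations. Significance comes from a phenotype
   permutation test, and each SNP inherits the p-value of its strongest
   pairwise association.
2. **Gene level.** SNPs are mapped to genes with a 500 kb window on each side
   of the gene body (to catch regulatory variants), and each gene is tested
   for an overabundance of significant SNPs — relative to the genome-wide
   rate and, implicitly, to its region size — with a right-tailed Fisher's
   exact test.
3. **Pathway level.** Genes are grouped into functional sets (e.g. Gene
   Ontology categories from a GMT file) and each set is tested, again by
   right-tailed Fisher's exact test, for an overabundance of significant
   genes. Findings are reported only when significant in two independent
   cohorts (detection and replication) at the same level `alpha`.

The design deliberately uses a liberal per-level dichotomy (`alpha = 0.05`
at every level, no multiplicity correction) and relies on permutation
testing plus two-cohort replication to control false positives.

## The MDR statistic

For a SNP pair, samples are cross-classified into the 3 x 3 table of
genotype combinations (minor-allele counts 0/1/2). With `n_ca` usable cases
and `n_co` usable controls, a cell holding `ca` cases and `co` controls is
labelled **high risk** when

\[ ca / co \ge T, \qquad T = n_{ca} / n_{co}, \]

with ties going to high and cells holding no samples labelled empty. The
labelling defines a one-dimensional classifier — predict "case" in high
cells, "control" in low cells — whose **balanced accuracy**

\[ BA = \tfrac12\left(\frac{TP}{TP+FN} + \frac{TN}{TN+FP}\right) \]

is the pair's statistic. This labelling is the BA-maximising one (each cell's
label independently maximises its contribution), so `BA >= 0.5` always, and
on finite samples null pairs score strictly above 0.5 on average — the
overfitting bias that makes the permutation test essential. The threshold
comparison is evaluated by cross-multiplication (`ca * n_co >= co * n_ca`),
so no floating-point division can flip a tie.

Two implementation notes:

* The statistic is the balanced accuracy of the labelling on the full
  cohort, not a cross-validated testing accuracy. The permutation test
  applies the identical (equally overfit) procedure to every permuted data
  set, so the empirical p-values are valid; cross-validation consistency is
  out of scope.
* Missing genotypes are handled per pair: a sample missing either genotype
  is excluded from that pair's table only. This complete-case-per-pair rule
  is a package decision (reasonable defaults differ; global exclusion wastes
  data). Monomorphic SNPs are not removed — their genotype dimension simply
  collapses — and no MAF filter is applied unless requested (`maf_min`).

All `choose(m, 2)` pairs are scored at once: the nine cell-count matrices
for all pairs are cross-products of per-genotype 0/1 indicator matrices
(BLAS `crossprod`), with counts exact in double precision. A permutation
rescans the whole matrix in ~40 ms at n = 1000, m = 200 on one core, which
is what makes 200-1000-fold permutation tests practical at desk scale.

## Permutation null: pooled versus max

`build_null` permutes the phenotype labels once per round (all pairs see the
same permuted labels, preserving between-pair dependence) and rescans. Two
nulls can be kept:

* **pooled** — every pair statistic from every permutation. This calibrates
  *pair-level* p-values: a pair's p-value is uniform under the null, which
  the test suite verifies across replicate cohorts.
* **max** — only each permutation's maximum over all pairs (a family-wise
  null).

`build_null` defaults to pooled, the natural pair-level null. But the
SNP-level summary is a *selection*: each SNP takes the minimum p-value over
its ~m pairs. Against a pooled null that minimum is stochastically tiny for
every SNP — with m in the hundreds, essentially all SNPs fall below the 0.05
dichotomy and the gene-level test loses all discrimination. The selection
must be calibrated against the same selection under the null, which is what
the per-permutation maximum provides. For this reason `mdr_scan()` and the
pipeline default to `mode = "max"`; empirically (and in the acceptance
tests) this is the configuration under which planted gene sets replicate
and decoys do not. Pooled mode remains the right choice when the object of
inference is an individual, pre-specified pair.

Empirical p-values use the add-one estimator `p = (1 + #{null >= obs}) /
(1 + N)`, so p is never zero and ties count against significance.

## Fisher's exact tests and the counting conventions

`fisher_right_tail(a, b, c, d)` sums the hypergeometric upper tail on the
log-gamma scale (`lchoose`), exact to better than 1e-10 relative error
(verified against exhaustive enumeration of every table with total up to
30). Conventions that the contract fixes:

* **Gene level.** The universe is every SNP with a p-value, including SNPs
  mapped to no gene (they inform the background rate). A SNP mapped to
  several genes is "inside" for each of them but contributes once to the
  universe. `a` = significant SNPs mapped to the gene, `b` = non-significant
  mapped SNPs, `c`, `d` the complements. Genes with no mapped SNP get p = 1
  and are flagged.
* **Set level.** The universe is every gene with a gene-level p-value;
  members outside it are dropped (with a message).
* **Window.** `start - window <= pos <= stop + window`, inclusive at exactly
  the window distance, strand-agnostic, chromosome labels compared after
  stripping an optional `chr` prefix.
* **Replication.** An entity replicates when its p-value is at or below
  `alpha` in both cohorts; results are ordered by the worse of the two.

No multiple-testing correction is applied at any level, matching the
design's reliance on permutation plus replication; output tables carry the
raw 2 x 2 counts so any correction can be applied downstream.

## The synthetic study generator

`simulate_paired_cohorts()` emulates the statistical structure the analysis
assumes: two independent case-control cohorts sharing a SNP panel, HWE
genotypes with per-SNP MAFs, a planted SNP pair with purely epistatic
penetrance, SNPs positioned on chromosomes within/near genes, and genes
grouped into sets.

**Penetrance.** `xor_model(prevalence, effect, maf)` builds a checkerboard
table: genotype combinations with odd `g_a + g_b` have penetrance
`prevalence + effect`; even cells are lowered so that both single-SNP
HWE-weighted margins equal the prevalence *exactly* (deviation below 1e-12).
With `h = 2 maf (1 - maf)` the heterozygote frequency, the homozygote cells
get `prevalence - effect * h/(1-h)` and the double heterozygote
`prevalence - effect * (1-h)/h`. Exact margin cancellation with a common
odd-cell elevation requires equal heterozygote frequency at the two SNPs —
with unequal MAFs the double-heterozygote cell is overdetermined — so the
constructor requires `maf_a == maf_b` and rejects infeasible
(effect, prevalence, MAF) combinations. Feasibility bound worth knowing:
`effect <= prevalence * h / (1 - h)`, so small MAFs only admit small
effects.

**Sampling.** Cohorts are ascertained retrospectively, as GWAS cohorts are:
planted-pair genotypes are drawn under HWE, disease status is drawn from the
penetrance table, and samples are accepted until the case and control quotas
fill (rejection sampling with a draw budget). Background SNPs are drawn
independently of phenotype and of each other; an optional block-LD mode
copies each background genotype from its left neighbour with probability
`ld_rho`, giving a simple decaying correlation structure. The generator's
default prevalence is 0.5: prevalence is not identifiable from case-control
data, and a balanced rejection sampler is maximally efficient. With several
planted pairs, disease probability combines as `1 - prod(1 - pen_k)`; the
single-pair case (used throughout validation) is exact.

**Layout.** SNPs sit on a uniform grid (default 400 kb spacing), one
synthetic chromosome per gene by default, genes 50 kb long and anchored on a
SNP (planted genes on their planted SNPs, decoys spread deterministically).
With the 500 kb window a gene then maps a handful of SNPs while most of the
panel stays unassigned — the regime in which the gene-level test is
informative. Dense-grid layouts (e.g. 10 kb spacing on one chromosome) are
supported for exercising the window arithmetic. The planted genes belong to
set `S1`; decoy genes are partitioned over the remaining sets.

Everything is a pure function of the configuration, including its seed: a
single Mersenne-Twister stream is seeded once per run and consumed in a
documented order (MAFs, then per cohort: planted-pair rejection batches,
background genotypes, LD masks).

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about real data: realistic human LD maps, population
stratification, covariates and confounding, genotyping error, quantitative
traits, and effect sizes estimated from any real study (published analyses
of this design do not report interaction effect sizes; the defaults here are
calibration choices for desk-scale validation, not estimates).

## Numerical and design choices

* Ties in cell labelling go to "high"; best-pair and best-SNP ties break on
  the lexicographically smallest partner id; pair enumeration is
  lexicographic in (i, j). Output tables sort by ascending p-value, then
  identifier. All of this makes reruns byte-identical.
* Coordinates are 1-based inclusive internally; BED input is converted on
  read (`start+1`), PLINK `.bim`/`.map` positions are used as-is. PLINK
  phenotype coding 1 = control, 2 = case, 0/-9 = missing (dropped with a
  message); TSV phenotype accepts 0/1 or 1/2 coding.
* Degenerate pairs (no usable case or control after missing-data exclusion)
  are dropped with a message rather than scored.
* Validation problem sizes were chosen to exercise the full cascade quickly
  on one core: oracle equivalence on hundreds of small random cohorts,
  calibration on 50 replicate null cohorts (m = 30, n = 400, 200
  permutations), planted-pair recovery at n = 1000, m = 100, and end-to-end
  replication on ten paired studies (n = 1000/500, m = 200, 10 genes, 4
  sets, 200 permutations).

## Known limitations

* Pairwise only; three-way and higher interactions are out of scope (the
  combinatorial cost and power cost grow steeply).
* The pooled null treats pairs as exchangeable, an approximation when MAFs
  vary widely; the max null is conservative for all but the top pair.
* Gene-level tests inherit SNP-SNP correlation (LD) as extra-binomial
  variation in `a`; no effective-number-of-tests correction is attempted.
* A genome-scale scan (hundreds of thousands of SNPs) needs blocked or
  distributed execution; this implementation targets panels up to a few
  thousand SNPs, where the full permutation cascade runs in minutes.
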
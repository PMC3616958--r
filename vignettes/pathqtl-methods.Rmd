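---
title: "pathqtl: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pathqtl: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Classical eQTL analysis asks which genomic alterations explain expression
changes of *single* genes. Genes act in groups, so `pathqtl` lifts the
question to whole signaling pathways: which copy-number-altered genomic
regions are informative of a pathway's aggregate expression change in a
disease cohort (the motivating application is glioblastoma tumors against
non-tumor controls, but nothing in the package is tissue-specific)?

The procedure has three stages:

1. **Pathway summarisation.** Genes are ranked by disease-vs-control
   signal-to-noise ratio; each pathway's enrichment score (ES) classifies it
   as over- (ES > 0) or under-expressed (ES < 0), and its *leading-edge
   genes* — the members appearing before the running sum attains its
   extremum — are retained as the pathway's working representation. Each
   pathway then receives a per-sample fold-change score
   $$A_{p,j} = \log_2 \frac{\sum_{i \in LE(p)} E_{i,j}}
                           {\sum_{i \in LE(p)} E_i^N},$$
   with $E_{i,j}$ the log-scale expression of gene $i$ in disease sample
   $j$ and $E_i^N$ its mean over control samples.
2. **Locus reduction.** Copy numbers of neighbouring loci are highly
   correlated, so consecutive loci whose log2 copy-number vectors correlate
   above a strict threshold (Pearson r > 0.95) are greedily merged into
   regions represented by *tag-loci*. This shrinks the multiple-testing
   burden by an order of magnitude.
3. **Non-linear association.** Every pathway score vector is fitted as a
   function of the samples × tag-loci matrix of $\log_2 CNA$ values with a
   regression random forest. The importance of a locus is the increase in
   held-out prediction error when its values are permuted; normalised
   importance $\bar I = I_i(p) / \sigma_i(p)$ (mean over trees divided by
   its standard error) is tested against a permutation null with a
   one-sided Z-test, and Benjamini–Hochberg FDR < 0.05 defines significant
   (tag-locus, pathway) associations.

## Model choices that were genuinely open

Several details of the procedure are under-determined by its verbal
description; the package pins them as follows and exposes each as an option.

**Ranking metric.** GSEA is named without a metric; the canonical
signal-to-noise ratio is used, with each class standard deviation floored at
`sigma_floor * |mean|` (default 0.2). The floor matters: without it,
near-constant genes get unbounded metrics.

**Pathway score reading.** The typeset score formula is ambiguous between a
ratio of sums and a sum of ratios; the literal reading (ratio of sums over
the leading-edge genes) is the default, with `method = "mean_of_ratios"`
for sensitivity analysis. The two genuinely differ: for a disease column
(4, 1) against baseline (1, 1), ratio-of-sums gives $\log_2 5/2 \approx
1.32$, mean-of-ratios $\log_2 5/2 \neq \log_2((4+1)/2)$ — the test suite
pins the distinction. Sums run over the *leading-edge* genes only, since
each pathway is represented by that subset. Negative-ES pathways use the
mirrored leading-edge convention (members at or after the running-sum
minimum), the standard GSEA practice for under-expression; pathway
direction is decided by ES sign alone, with no permutation screen.

**Tag-locus criterion.** The region definition is stated in two slightly
different ways: candidate-vs-seed ("the correlation of $CN_k$ and $CN_i$ at
any locus in the region") and consecutive-pair. `mode = "seed"` (the formal
definition) is the default; `mode = "chain"` is available, and on
latent-factor block data seed regions are provably a refinement of chain
regions (tested). The greedy scan consumes each locus once, so regions
partition the loci; the remark that adjacent regions may *overlap* is not
derivable from the stated scan and is realised here only at the
gene-assignment level (a gene's interval may straddle two region spans).
The representative is the region's first locus; correlations are computed
on log2 values so that the criterion matches the association design matrix.
The threshold is strict: a pair at sample correlation exactly 0.95 is not
merged.

**Forest and importance.** The stated bagging scheme is unusual:
$\lceil\sqrt{x}\rceil$ of $x$ samples per tree, read here as a subsample
*without* replacement ("randomly picked √x of all x samples"), with
$M = \lceil\sqrt{n}\rceil$ of $n$ predictors tried per split and N = 1000
trees by default. The small per-tree sample leaves a large held-out
complement on which permutation importance is measured — "omitted in the
regression process" is realised as held-out permutation importance, the
canonical forest realisation of omission (literal per-locus refitting is
computationally prohibitive and is not what forest importance scores
compute). Loci unused by a tree contribute exactly zero to that tree's
importance. $\sigma_i(p)$ is the standard error (sd over trees / √N);
$\bar I = 0$ when both mean and SE are zero (constant response), and N = 1
is rejected. All randomness — subsampling, split-candidate selection,
held-out permutations — is keyed by hashes of locus *ids* and node paths,
never column positions, so permuting design columns permutes the output
identically (tested).

**Null and test.** Each permutation shuffles the sample order of $A_p$ and,
independently, the sample *rows* of the design (rows move jointly across
columns, preserving inter-locus correlation). The null is pooled across
loci within a pathway by default (stable moments at n_perm = 100; a
per-locus mode with a higher enforced minimum exists). The Z-test is
one-sided upper-tail: associations manifest as importance above the null.
FDR is Benjamini–Hochberg, applied within each pathway direction by the
pipeline (over- and under-expressed associations are reported separately;
`fdr_scope = "pooled"` exists), with strict q < 0.05.

**Z-test adequacy depends on ensemble size.** $\bar I$ is a t-like
statistic; for a locus used by few trees its null is visibly heavier-tailed
than normal. Empirically, the pooled-null normal approximation is adequate
at the default N = 1000 trees (global-null p-values pass a KS uniformity
test at α = 0.01) while at N = 200 trees a mild systematic deviation is
detectable at large sample counts, although tail calibration — the
fraction of raw p < 0.05 and the FDR call count — remains correct at both
sizes. The calibration tests in the package reflect exactly this: the
uniformity invariant runs at N = 1000, the tail-calibration acceptance
check at its stated N = 200.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with defaults mirroring the motivating cohort: 158 disease and 21
control samples, log-scale expression intensities with baseline
Uniform(5, 10) and Gaussian noise (sd 0.5, a typical log-scale microarray
residual spread), and chromosome-scale signature events — a one-copy gain
(log2 3/2 in 80% of samples) on one chromosome and a one-copy loss
(log2 1/2, 80%) on another — mirroring the canonical chromosome-7
amplification / chromosome-10 deletion pattern of glioblastoma.

Copy-number blocks use a single latent factor per block with loadings
solved from the target correlation: locus $i$ of block $b$ has
$\log_2$ value $\sigma_{cn}(\sqrt{r}\, g_b + \sqrt{1-r}\,\varepsilon_i)$,
so any two loci of a block correlate at exactly $r$ in population and
different blocks are independent — a closed-form calibration of the
"nearby loci are highly correlated" premise. Planted effects couple the
log-scale expression of every gene of a chosen pathway to the
$\log_2 CNA$ of a chosen block's representative locus
(`beta` per log2 unit); control samples carry baseline + noise only, so an
empty `planted_effects` list is an exact global null. No published
effect-size scale exists for real locus→pathway effects; the default
β = 0.5 was chosen once so that, at cohort-scale sample sizes with a
signature event on the planted chromosome, the planted locus explains well
over half of the pathway-score variance (the recovery tests assert ≥ 50%
explicitly). One master seed drives split per-component streams
(`derive_seed`), so enlarging one component never perturbs another's draws.

What the generator does **not** emulate: array noise models (GC waves,
probe effects), subclonal mixtures, overlapping pathway memberships,
correlated gene-gene expression beyond the planted effects, and tumor
subtypes. A green recovery test therefore establishes that the machinery
detects planted additive couplings under idealised noise — not that it
would have equal power against real array artefacts.

## Numerical conventions

* Coordinates are 0-based half-open everywhere; BED is consumed as-is and
  1-based tables must be declared (`format = "tsv1"`).
* Copy-number ratios must be strictly positive (log2 is applied
  downstream); values ≤ 0 are rejected unless an explicit
  `clamp_epsilon` is supplied.
* Expression zeros encode censored weak signal; rows with a zero fraction
  strictly above 0.10 are dropped, and a whole-sum zero in a pathway score
  is an error unless an epsilon clamp is requested.
* Probe collapse takes the probe with the highest mean intensity over
  disease samples (the cohort is treated as a single group — subtype
  labels are outside the data model), ties to the lexicographically
  smallest probe id.
* Running-sum extremum ties resolve to the earliest rank; this makes ES
  deterministic but breaks exact reversal antisymmetry precisely at
  |max| = |min| ties, which the property tests skip.
* p-values are floored at the smallest positive double so BH input stays
  in (0, 1].
* The implementation is single-threaded throughout; determinism across
  "thread counts" is therefore vacuous, and determinism across invocations
  is guaranteed by seeded streams and tested by checksum.

## Known limitations

* The Z-test is a moment fit to the permutation null; with few
  permutations and small ensembles its tails are approximate (see above).
  Rank-based permutation p-values are deliberately out of scope.
* Tag-locus regions never span chromosome breaks and never overlap; a
  locus belongs to exactly one region.
* GSEA significance (phenotype permutations, NES) is not computed —
  direction is by ES sign, as in the procedure this package realises.
* The forest's per-tree sample size $\lceil\sqrt{x}\rceil$ is faithful to
  the stated scheme but very small; trees are stumps or near-stumps. The
  importance signal comes from the ensemble, not from deep interactions.
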
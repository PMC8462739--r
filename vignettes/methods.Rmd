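---
title: "Methods: tissue-specific gene calling and cross-species similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-specific gene calling and cross-species similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuesim)
```

# The analysis model

`tissuesim` compares tissue-restricted gene expression between a focal
species (assayed as bulk RNA-seq over a handful of adult tissues) and one
or more target species with public per-tissue expression compendia. The
chain has four statistical components, each deliberately simple and
deterministic, so that every number in a report can be recomputed by hand
from the inputs.

## Expression units and RPKM

All calling operates on RPKM (reads per kilobase of transcript per million
mapped reads):

$$\mathrm{RPKM}(g,s) = \frac{\mathrm{count}(g,s)\times 10^9}
{\mathrm{length}_{bp}(g)\times \mathrm{libsize}(s)}.$$

`counts_to_rpkm()` takes the library size from input rather than summing
the count column: the per-million denominator refers to all mapped reads
of the library, which can include features absent from the matrix.
Annotated transcript length is used; effective-length corrections belong
to upstream quantifiers and are out of scope. Missing cells are an error,
not imputed — the intended input is a dense quantification table.

## Tissue-specific gene (TSG) calling

A gene is specific to tissue group $G$ when its RPKM exceeds the **high
threshold** (default 1) in at least one member sample of $G$ and stays
below the **low threshold** (default 0.5) in *every* sample outside $G$.
Points worth making explicit:

* **Strict inequalities.** A value exactly at 1 or exactly at 0.5 fails
  its test. With defaults this guarantees every call a
  $>\!2$-fold margin over any non-member sample, since
  $\text{high}/\text{low} = 2$ (the ratio is $+\infty$ when the outside
  maximum is 0).
* **Composite groups.** A group may pool several samples (two siphons;
  three intestine segments). Qualification is "any member high", and
  fellow members are exempt from the low test: a siphon-group TSG may have
  any value in the other siphon sample. Requiring $<0.5$ within the group
  would contradict pooled counting of one TSG set per composite tissue.
* **Uniqueness.** Because low < high, a gene can satisfy the rule for at
  most one group; no tie-breaking is ever needed and the module is free of
  randomness.
* **Monotonicity.** Raising the low threshold or lowering the high
  threshold can only add calls; this is exercised as a property test.

The relaxed variant `call_two_tissue_genes()` returns genes whose
within-group maximum clears the high threshold in *exactly two* groups,
one of them a chosen focal group, with every sample of every other group
below the low threshold. Strict single-group TSGs are deliberately *not*
returned: whether the combined "specific to the focal tissue or to the
focal tissue plus one other" set should include the strict calls is a
presentation choice, so the union is left to the caller
(`rbind`/set-union of the two outputs) and documented here.

## Homology consolidation

BLAST tabular hits are filtered at **e-value < 1e-5** (strict, so an
e-value of exactly 1e-5 is discarded) and reduced to a single best hit per
(query, species). The tie-break chain — maximum bit score, then minimum
e-value, then lexicographically smallest subject id — exists purely for
determinism: the consolidated map is a function of the hit *multiset*, and
shuffling input lines cannot change it. One best hit per query is the
default because each focal TSG should contribute exactly one expression
profile per species to the similarity statistic; `keep_all = TRUE` retains
every surviving hit for users who want many-to-many breakdowns.

`homology_breakdown()` partitions each tissue's TSGs into
both/A-only/B-only/neither and reports the percentage with any homolog.
Percentages are rounded **half away from zero** to one decimal (base R's
`round()` is half-to-even, which would turn e.g. 62.05 into 62.0); a group
with zero TSGs reports `NA`, not 0 — an undefined ratio is not a zero
ratio.

## Tissue similarity

Each homolog's profile over the target tissues is min–max normalized,
$v' = (v - \min)/(\max - \min)$, so the lowest tissue is exactly 0 and the
highest exactly 1. The **tissue similarity** between a focal tissue and a
target tissue is the fraction of the focal tissue's TSG homologs with
normalized value $> 0.8$ (strict) in that target tissue.

Numerical and counting choices:

* **Degenerate profiles.** A constant profile has no defined scaling; it
  is flagged, set to zero, and excluded from both numerator and
  denominator. The count of excluded profiles is carried in the result and
  the run log so denominators stay auditable.
* **Denominator.** The denominator is the number of TSG–homolog pairs with
  a resolvable, non-degenerate target profile — not the raw TSG count.
  Unresolvable subject ids cannot contribute a profile, and two TSGs
  sharing one best-hit subject contribute two pairs.
* **Row sums exceed 1** legitimately: one gene can exceed 0.8 in several
  tissues. Conversely every non-degenerate profile exceeds any threshold
  < 1 in its maximal tissue, so each contributes somewhere.
* **Replicate columns.** When the target matrix has replicate columns per
  tissue, a `tissue_of` mapping averages them *before* normalization.
  Whether to average replicates first or normalize over all columns is a
  genuine modelling choice (normalizing over replicates lets within-tissue
  variance eat into the [0,1] range); both are supported, averaging is the
  behavior when a mapping is supplied, and per-column normalization is the
  default when it is not.

Profile clustering for heatmap ordering uses Euclidean distance and
complete linkage by default — a deliberate, documented configuration since
nothing in the statistic itself dictates a linkage; both are arguments.
The similarity matrices export as a three-column SIF-style edge table
(source, weight, target) whose weights round-trip at full double
precision.

## qRT-PCR workflow

Replicate-level Ct values against a constitutive reference gene yield
$\mathrm{dCt} = Ct_{target} - Ct_{reference}$ and relative expression
$2^{-\mathrm{dCt}}$. Undetected wells get relative expression 0. Per gene,
a tissue with **two or more undetected replicate sets is excluded** from
testing; with exactly one undetected set the tissue is retained. The
"≥ 2 sets" rule is read per (gene, tissue) — the alternative reading
(exclude the whole gene) would discard information from tissues where the
gene is robustly detected.

Statistical testing operates on dCt values, not on $2^{-\mathrm{dCt}}$.
How an undetected-but-retained replicate enters the dCt-scale test is
ambiguous in principle (its dCt is undefined); the default drops that
replicate from the test while keeping its zero on the expression scale,
and `undetected = "zero"` enters it as dCt 0 for users who prefer the
other reading.

The branch gate is **Levene's test with group means as centers**
(classical Levene; the median-centered Brown–Forsythe variant is a
different, unchosen default) at $\alpha = 0.05$:

* $P_L \ge \alpha$: parametric one-way ANOVA, Tukey HSD pairwise table.
* $P_L < \alpha$: Kruskal–Wallis omnibus, then **Dunn's rank-based
  pairwise comparisons with Bonferroni adjustment**
  ($p_{adj} = \min(1, m\,p)$ for $m$ pairs). A classical Dunnett test
  (normal-theory, many-to-one) would contradict the purpose of the
  nonparametric branch; Dunn's procedure is the standard rank-based post
  hoc and is implemented directly (z-statistic on mean ranks with tie
  correction) since no installed package provides it.

Groups left with fewer than two replicates are dropped with a logged
reason; fewer than two surviving groups yields an explicit no-test report
rather than an error. Branch choice is a pure function of the data — the
whole workflow is seed-free.

Two statistical facts about this gate worth knowing (both are measured by
the package's calibration tests): classical Levene is liberal at very
small group sizes (at 9 groups of 4 replicates it diverts well over its
nominal 5% of equal-variance datasets to the nonparametric branch), and
Kruskal–Wallis at 9 groups of 4 cannot reach $p < 0.05$ when only one
group separates — the rank statistic is bounded too low. So the workflow's
power against a single shifted tissue comes entirely from the parametric
branch; the calibration test therefore checks the null rate
unconditionally but the power conditionally on the parametric branch.

# The synthetic-data generator

The generators produce data with the *statistical shape* the analysis
assumes, plus planted truth for validation:

* `generate_focal_expression()`: planted TSGs draw in-group RPKM from
  Uniform(2, 50) and out-of-group from Uniform(0, 0.4) — a factor-of-two
  margin on both sides of the default thresholds, so exact recovery is
  guaranteed by construction, which is what makes precision/recall = 1 a
  meaningful end-to-end wiring check rather than a statistical claim.
  Background genes are log-normal (meanlog 0, sdlog 1.2) with 10% forced
  broadly expressed (> 1 everywhere); background draws that would
  themselves qualify as TSGs are redrawn so the planted labels are the
  complete truth. The uniform/log-normal families are pragmatic choices —
  expression calling by thresholds only sees order statistics relative to
  the cutoffs, not distributional detail.
* `generate_target_species()`: each TSG gains a homolog with probability
  `homolog_fraction`; a linked homolog is high (normalized value > 0.9) in
  its mapped tissue with probability $q$, otherwise in a uniformly random
  other tissue, making the expected similarity cell exactly $q$. The BLAST
  file carries true links at e-values $10^{-U(6,50)}$ and decoy hits at
  e-values $\ge 10^{-4.5}$ with *higher* bit scores than the true hits, so
  only the e-value filter (never the score ranking) can be responsible for
  removing them.
* `generate_qpcr_dataset()`: reference Ct ~ Normal(20, `noise_sd`); target
  Ct = reference + `baseline_dct` − `effect_dct` (in the planted tissue)
  plus independent Normal(0, `noise_sd`) measurement noise, so replicate
  dCt values are Normal with SD `noise_sd` (default 0.3 cycles, a typical
  qPCR technical spread). Undetected sets are injectable per
  (gene, tissue).

A single integer seed drives each generator through a deterministic
per-component derivation, so stages can be regenerated independently and
whole runs are byte-reproducible.

**What passing on synthetic data does not show.** The generator plants
clean margins, independent genes, noiseless homology (every link is
correct), and tissue-level (not replicate-level) target expression. Real
data violate all of these: genes near the thresholds flip calls with
sequencing depth, best BLAST hits can be paralogs, and public compendia
mix labs and protocols. Green tests demonstrate that the implementation
computes the stated statistics exactly and recovers planted structure; the
biological validity of thresholds 1/0.5/0.8 is inherited from practice,
not established here.

# Validation problem sizes

The shipped test suite validates: exact equivalence of the vectorized TSG
caller with a naive double loop on 100 random matrices up to 500 genes ×
12 samples with values concentrated around the thresholds; exact
equivalence of the similarity statistic with a brute-force recount on 100
instances up to 500 profiles × 30 tissues; planted-TSG recovery at 2,000
genes over 9 groups (5–50 TSGs each); bias recovery at $q \in
\{0.2, 0.5, 0.8\}$ with 200 homologs per run over 5 replicate seeds
against the $3\sqrt{q(1-q)/n}$ binomial envelope; qPCR null calibration
over 1,000 simulations (9 tissues × 4 replicates) and power/branching over
500 each. These sizes keep the whole suite well under a minute while
leaving the Monte-Carlo margins comfortable.

# Known limitations

* Percentages are reproduced from count pairs; the original per-tissue
  homolog denominators behind published similarity percentages are not
  recoverable from printed tables alone, so similarity values on real data
  depend on the user's own BLAST runs and compendia.
* The min–max statistic ignores expression magnitude: a homolog at 2 RPKM
  everywhere but 2.5 in one tissue normalizes identically to one at
  2 vs 2,500. That is inherent to the statistic, not a bug; users should
  inspect raw profiles for low-expression homologs.
* `call_two_tissue_genes()` semantics (exactly two, union left to caller)
  mean its output count is not directly comparable to combined published
  "relaxed" counts without forming the union explicitly.
* The pipeline reads whole matrices into memory; it targets
  tissue-resolution tables (thousands of genes × tens of samples), not
  single-cell scale.
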
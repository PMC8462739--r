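# tissuesim

Cross-species comparison of tissue-specific gene expression.

`tissuesim` is for transcriptomics researchers who profile the adult tissues
of a non-model organism (the motivating system is an ascidian assayed over
nine adult tissues) and want to ask: *which genes are exclusive to one
tissue, and do their vertebrate homologs keep that tissue preference?* The
package implements the full analysis chain:

1. **Tissue-specific gene (TSG) calling.** From a gene × sample RPKM matrix,
   gene *g* is specific to tissue group *G* iff

   max<sub>s∈G</sub> RPKM(g, s) > 1  and  RPKM(g, s) < 0.5 for every sample s ∉ G

   (strict inequalities). Groups may be composite — e.g. oral + atrial
   siphon, or three intestine segments — with "any member high" semantics:
   fellow members of the group are exempt from the low test. Because
   high/low = 2, every call is guaranteed a more than 2-fold margin over
   every other tissue. A relaxed two-tissue variant
   (`call_two_tissue_genes()`) screens genes specific to exactly two groups.
2. **Homology consolidation.** BLAST tabular (outfmt 6) hits against one or
   more target species are filtered at e-value < 1e-5 (strict) and reduced
   to one deterministic best hit per (query, species): max bit score, then
   min e-value, then lexicographic subject id. `homology_breakdown()`
   classifies each tissue's TSGs as homologous to species A, B, both, or
   neither.
3. **Tissue similarity.** Each homolog's expression profile over the target
   species' tissues is min–max normalized to [0, 1]; for each target tissue
   the *tissue similarity* is the fraction of a focal tissue's TSG homologs
   whose normalized value exceeds 0.8. Constant (degenerate) profiles are
   excluded from numerator and denominator. Profiles are clustered
   (Euclidean distance, complete linkage by default) for heatmap ordering,
   and similarity matrices export as a SIF-style weighted network.
4. **qRT-PCR dCt workflow.** dCt = Ct(target) − Ct(reference), relative
   expression 2^(−dCt); undetected wells are zero, and a tissue with ≥ 2
   undetected replicate sets is excluded per gene. Testing on dCt values is
   gated by Levene's test (mean-centered) at α = 0.05: equal variances →
   one-way ANOVA + Tukey HSD; otherwise Kruskal–Wallis + Dunn's rank-based
   pairwise comparisons with Bonferroni adjustment.
5. **Synthetic data with planted truth** (`generate_focal_expression()`,
   `generate_target_species()`, `generate_qpcr_dataset()`) so every stage —
   and the pipeline end-to-end via `run_pipeline()` — can be validated
   against known ground truth.

## Worked example

Plant 8 TSGs in each of 8 tissue groups, link 90% of them to mouse
homologs with a 0.6 probability of high expression in the brain for
neural-complex TSGs, and recover the structure:

```r
library(tissuesim)

scheme <- tissue_scheme(list(
  siphons = c("oral_siphon", "atrial_siphon"),
  neural_complex = "neural_complex", endostyle = "endostyle",
  heart = "heart", ovary = "ovary", pharynx = "pharynx",
  stomach = "stomach",
  intestine = c("intestine_prox", "intestine_mid", "intestine_dist")))

sim <- generate_focal_expression(500, scheme, 8, seed = 42)
calls <- call_tsgs(sim$matrix, scheme)
summary(calls)
#> TSG calls per tissue group:
#>      endostyle          heart      intestine neural_complex          ovary
#>              8              8              8              8              8
#>        pharynx        siphons        stomach
#>              8              8              8

tg <- generate_target_species(sim$truth, "mouse",
  c("brain", "liver", "kidney", "heart", "muscle"),
  bias_map = list(neural_complex = list(tissue = "brain", q = 0.6)),
  homolog_fraction = 0.9, seed = 42)
f <- tempfile(); write_blast_tabular(tg$blast, f)
map <- best_hits(read_blast_tabular(f, "mouse"))
sm <- similarity_matrix(calls, map, tg$expr, "mouse")
print(sm, digits = 2)
#> Tissue similarity vs mouse (fraction of homologs > 0.8):
#>                brain liver kidney heart muscle
#> endostyle       0.00  0.12   0.12  0.12   0.62
#> heart           0.17  0.17   0.17  0.33   0.17
#> intestine       0.17  0.33   0.00  0.50   0.00
#> neural_complex  0.50  0.12   0.12  0.12   0.12
#> ovary           0.40  0.00   0.00  0.60   0.00
#> pharynx         0.38  0.38   0.00  0.25   0.00
#> siphons         0.12  0.00   0.12  0.00   0.75
#> stomach         0.12  0.25   0.50  0.12   0.00
#> Homologs per focal group (denominators):
#>      endostyle          heart      intestine neural_complex          ovary
#>              8              6              6              8              5
#>        pharynx        siphons        stomach
#>              8              8              8
```

All 64 planted TSGs are recovered (8 per group, no false positives). The
neural-complex row peaks in brain at 0.50 over 8 homologs — the planted
bias q = 0.6 realized over a small sample; unmapped groups scatter over the
five tissues. The denominators below the matrix show how many resolvable,
non-degenerate homolog profiles each fraction is computed over (only 90% of
TSGs were linked, so some groups have fewer than 8).

`run_pipeline(config, out_dir)` drives the same stages from a YAML
configuration and writes a fixed-name report bundle (TSG table, breakdown,
per-species similarity matrices, clustering leaf orders, network
edges/nodes, optional qPCR report, run log) deterministically.

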
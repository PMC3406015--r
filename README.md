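# lncturnover

Comparative analysis of long intergenic noncoding RNA (lncRNA)
transcriptional turnover between closely related species, and of its
consequences for sequence constraint and neighbouring gene expression.

## The problem

Most lncRNA loci are tissue-specific and lowly expressed, and their
transcription can be gained or lost far faster than their DNA sequence
diverges. Measuring that turnover requires matched data in homologous
tissues of closely related species — e.g. two mouse taxa and rat liver
— and a pipeline that (a) builds a high-confidence lncRNA catalogue by
anchoring assembled RNA-seq fragments on H3K4me3 promoter marks,
(b) projects loci across genomes and classifies transcriptional
conservation, (c) asks whether transcribed sequence is under
purifying selection, and (d) asks whether lineage-specific lncRNAs
associate with expression changes of adjacent protein-coding genes.
`lncturnover` implements that pipeline as composable, tibble-in /
tibble-out functions, with a synthetic multi-species generator that
plants known truth for every stage.

## The statistics at the core

* **Catalogue rule** — a transcript is an intergenic lncRNA if its
  length ≥ 200 nt, an H3K4me3 peak contains its TSS, its span overlaps
  no protein-coding gene by ≥ 1 bp, and its coding-potential score
  (z-score of longest-ORF length against *k* = 50
  dinucleotide-preserving shuffles) is < 0. Span-overlapping
  transcripts cluster transitively into loci.
* **Conservation categories** — for focal/sister/outgroup evidence
  (peak overlap ≥ 1 bp AND ≥ 1 stranded read at the projected
  position): I all three, II focal+sister, III focal only, IV sister
  only, V outgroup only; loci without outgroup orthologous sequence
  are excluded. Class contrasts use the exact two-tailed Fisher test.
* **Constraint** — pairwise substitution rate *d* under the general
  time-reversible (REV) model (closed-form maximum likelihood via the
  matrix logarithm of the symmetrized divergence matrix, with a
  bounded 1-D likelihood polish), normalized by the pooled rate
  *d*<sub>AR</sub> of nearby (< 500 kb), G+C-matched (±0.05),
  locus-free ancestral repeats: *d*/*d*<sub>AR</sub> < 1 indicates
  purifying selection. Group comparisons use two-tailed Mann–Whitney
  tests.
* **Expression** — constitutive-exon counts, length adjustment,
  trimmed-mean-of-M-values normalization assuming 60 % of expressed
  genes are similarly transcribed, FPKM, and natural-log
  fold-differences oriented so the lncRNA-bearing species is the
  numerator (random orientation for the housekeeping baseline).
* **Association** — gene territories (bases nearer a gene than its
  flanks) and GAT-style permutation enrichment: length-preserving
  uniform re-placement within a workspace, optionally inside G+C
  decile bins, empirical `p = (1 + #{perm ≥ obs}) / (n_perms + 1)`.

## A worked example

```r
library(lncturnover)

# Turnover contrast between locus classes: 160/268 lncRNA loci vs
# 6169/6723 protein-coding loci with rodent-conserved transcription
turnover_contingency(rep(c("I", "other"), c(160, 108)),
                     rep(c("I", "other"), c(6169, 554)), "I")
#> Turnover contingency (category I): p = 1.3e-43
#>        in_category not_in_category
#> group1         160             108
#> group2        6169             554

# A complete synthetic three-species study, then classify conservation
sc <- generate_scenario(scenario_config(seed = 1))
calls <- classify_scenario_loci(sc, mode = "strict")
table(predicted = calls$category, truth = calls$true_category)
#>          truth
#> predicted  I II III IV  V
#>       I   10  0   0  0  0
#>       II   0 10   0  0  0
#>       III  0  0  10  0  0
#>       IV   0  0   0 10  0
#>       V    0  0   0  0 10

# Rate estimation round trip at the neutral ancestral-repeat rate
pair <- evolve_pair(20000, d = 0.164, rev_params(), seed = 8)
rev_distance(pair$seq1, pair$seq2)
#> REV pairwise fit: d = 0.16513 over 20000 sites (p-distance 0.1482)

# Expression comparison with a planted +25% elevation of the genes
# nearest lineage-specific lncRNAs (ln 1.25 = 0.223)
study <- simulate_expression_study(seed = 2)
res <- analyze_expression_study(study, seed = 3)
res$tests
#> # A tibble: 4 x 5
#>   group           n   median     p_value note
#>   <chr>       <int>    <dbl>       <dbl> <chr>
#> 1 background   1351  0.0205  0.754       NA
#> 2 conserved_A   148 -0.00176 0.463       NA
#> 3 gene_B        119  0.00419 0.724       NA
#> 4 lineage_A     137  0.221   0.000000942 NA

# Territory enrichment with a planted 1.6-fold excess
en <- simulate_enrichment_scenario(fold = 1.6, seed = 4)
permutation_enrichment(en$segments, en$annotation, en$workspace,
                       n_perms = 1000, seed = 5)
#> Permutation enrichment: observed 48,000 bp, expected 30061.0 +- 2927.9,
#>   fold 1.60, p = 0.000999 (1000 perms)
```

The elevation planted on the genes nearest lineage-specific lncRNAs is
recovered (median ln fold-difference 0.221 ≈ ln 1.25, strongly
significant against the housekeeping baseline), while the next gene
out (gene B) and genes near conserved lncRNAs sit on the baseline —
the association is local, not regional.

Result objects follow broom conventions (`tidy()`, `glance()`) and
have `autoplot()` / `plot_*()` displays; `write_scenario()` exports a
bundle as BED/narrowPeak/GFF3/FASTA/TSV for interoperability.

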
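---
title: "Methods: comparative analysis of lncRNA transcriptional turnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of lncRNA transcriptional turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`lncturnover` implements a comparative pipeline for studying the
evolutionary turnover of long intergenic noncoding RNA (lncRNA)
transcription between closely related species (the motivating design
is a mouse / mouse-subspecies / rat comparison in matched adult liver),
and its downstream consequences: sequence constraint and the expression
of neighbouring protein-coding genes. The pipeline has six stages —
annotation, depth equalization, conservation classification,
substitution-rate estimation, expression comparison, and neighbour
association — plus a synthetic scenario generator that plants known
truth for every stage.

## Annotation

A transcript enters the lncRNA catalogue when

1. it is at least 200 nt long (summed exonic length),
2. an H3K4me3 peak contains its predicted TSS coordinate — the peak
   must cover the TSS base itself, not merely overlap the transcript;
   this anchors the often-fragmented 5' ends of assembled fragments on
   independent chromatin evidence,
3. its span (first-exon start to last-exon end, introns included) does
   not overlap any protein-coding gene span by even one base pair,
   strand-agnostically, and
4. its coding-potential score is below zero.

Transcripts whose spans overlap — by exonic *or* intronic bases — are
clustered transitively into loci; a locus is an intergenic lncRNA locus
only if *all* member transcripts are intergenic and noncoding.
Promoters are the 400 bp immediately upstream of the TSS, strand-aware
and truncated at chromosome edges.

Two interpretation decisions here were genuinely open and are exposed
as code defaults rather than hidden constants. First, genic-context
overlap is strand-agnostic; antisense relationships are handled by a
separate rule set (below). Second, transcript-span (not exon-only)
overlap drives both genic-context classification and locus clustering.

**Coding potential.** External coding-potential classifiers are
replaced by a self-contained statistic with the same sign convention:
the z-score of the observed longest-ORF length against the longest-ORF
lengths of `k = 50` dinucleotide-preserving (Altschul–Erickson)
shuffles of the same sequence. A sequence with no start codon at all is
always noncoding. The statistic is deterministic given a seed, fully
testable against a brute-force ORF scanner, and preserves the
"score < 0 means noncoding" threshold.

**Antisense calls.** Transcripts overlapping a protein-coding gene on
the opposite strand are filtered sequentially: (i) transcripts that
also overlap an annotated coding gene on their own strand are removed
as annotated coding transcripts; (ii) transcripts whose every TSS peak
also contains the host gene's TSS are removed (no independent
initiation); (iii) transcripts with no TSS peak at all are removed. A
fourth, manual exclusion list stands in for visual inspection of
assembly artefacts — it is never applied automatically because that
step is not reproducible computationally.

**Assembly stand-in.** Full spliced assembly is out of scope; the
package provides a desk-scale transfrag assembler (per-strand merging
of reads with gap at most `min_gap`, dropping fragments under
`min_length`) and also accepts externally assembled fragments.

## Depth equalization

Libraries are equalized by drawing reads without replacement down to
the smallest library, re-assembling and re-filtering (peaks held fixed
— chromatin libraries are not downsampled), and counting the
*full-depth* lncRNA loci overlapped (>= 1 bp) by a recreated
transcript. The summary reports per-replicate counts, their mean and
the sample standard deviation (n − 1 denominator; the convention is a
package decision, stated here because either is defensible).

## Conservation classification

Orthology is modelled as co-linear syntenic blocks
(`src → tgt` offset, optional strand flip); intervals are projected
blockwise, partial overlaps projecting the covered portion. A locus
counts as expressed in another species when its projected position has
(strict mode) >= 1 bp of H3K4me3 peak overlap *and* at least one
overlapping read on the projected strand; a reads-only mode supports
species without chromatin data. The "(>1 bp)" phrasing of overlap
thresholds is interpreted as >= 1 bp, for internal consistency with
the "one or more base pair" rule used elsewhere; the threshold is a
config parameter.

Loci without outgroup orthologous sequence are excluded (sequence
turnover must not be confused with transcriptional turnover). The
remaining loci are classified by the three-species truth table:
category I (all three), II (focal + sister), III (focal only), IV
(sister only), V (outgroup only). Evidence combinations outside this
palette (e.g. focal + outgroup but not sister) are reported as
`unclassified` — the generator never emits them, and real data would
flag them for inspection. A locus with no evidence anywhere is an
error, since it contradicts its own annotation.

Turnover contrasts between locus classes use the exact two-tailed
Fisher test (sum of table probabilities no larger than the observed).

## Substitution rates and constraint

Pairwise rates are estimated under the general time-reversible (REV)
model with empirical base frequencies. Because a single pairwise
alignment saturates the reversible family, the maximum of the
multinomial likelihood has a closed form: the matrix logarithm of the
transition matrix fitted from the symmetrized divergence table
(computed by symmetric eigendecomposition) equals `d · Q`, giving both
the distance and the exchangeabilities directly. The distance is then
polished by bounded scalar likelihood optimization (tolerance 1e-9) at
the fitted exchangeabilities, and near-saturated tables with
non-positive eigenvalues fall back to direct numerical optimization.
In the symmetric limit the estimate reduces to the Jukes–Cantor
closed form to 1e-4.
Alignments are gap-free (indel evolution is out of scope); non-ACGT
columns are dropped with a warning, and alignments under 50 usable
columns are flagged out of summaries.

Neutral normalization uses ancestral repeats (ARs): for each focal
region, ARs within 500 kb, not overlapping any annotated locus, and
with G+C within `gc_tol = 0.05` (5 percentage points; "similar G+C"
is not quantified anywhere authoritative, so the tolerance is exposed)
are pooled — their alignments concatenated into a single `d_AR` fit —
rather than averaged, because short repeats make per-AR ML unstable.
Constraint is summarized as per-region `d / d_AR`, group medians, and
two-tailed Mann–Whitney tests of group rates against matched AR rates
and between groups.

## Expression comparison

Between-species expression uses constitutive exons (bases present in
every transcript of a gene), counts length-adjusted to the focal
feature length (`count × len_focal / len_other`), and normalization by
a trimmed mean of per-gene log2 ratios computed on library-scaled
counts of one-to-one orthologs. The trimming retains the central
`assumed_fraction = 0.6` of genes by M-value rank — the assumption
that 60 % of expressed genes are similarly transcribed in the two
species — and drops 5 % of each extreme-intensity (A-value) tail, the
reference TMM default. The normalization is reimplemented rather than
delegated because the similar-expression fraction is the analysis'
stated knob; the reference implementation (edgeR, with
`logratioTrim = 0.2`) serves as an independent cross-check in the test
suite. FPKM is `1e9 * count / (length * normalized library size)`.

Fold-differences are *natural-log* FPKM ratios: a ~25 % median
elevation corresponds to ln(1.25) ≈ 0.223, which matches the scale of
the published medians, whereas log2 would not. For genes near
lineage-specific lncRNAs the numerator is the lncRNA-bearing species
(the orientation that makes "elevation near a gained lncRNA" a
positive number); for housekeeping and other baseline groups the
numerator species is assigned at random per gene, seeded. Genes with
zero FPKM in either species are excluded rather than pseudocounted —
exclusion avoids an arbitrary constant; the exclusions are reported.

## Neighbour association

Each lncRNA locus is paired with its closest protein-coding gene
(gene A, envelope distance) and the next most proximal gene beyond it
(gene B), skipping annotated paralogs of A — tandem duplicates share
regulatory elements and would contaminate the regional control. TSS
distances are reported TSS-to-TSS while closest-gene selection uses
envelope distance; both conventions appear in the field, so both are
explicit in the code. Orientation is tandem (same strand), divergent
(opposite strands, minus-strand element left of the plus-strand
element: transcribing apart) or convergent (the mirror case).

Gene territories (all bases nearer a gene than its flanking genes,
boundaries at envelope midpoints, chromosome ends closing terminal
territories) provide the annotation for GAT-style permutation
enrichment: segments are re-placed uniformly at random within the
workspace, per chromosome and length-preserving, optionally restricted
to workspace intervals in the segment's G+C decile bin (the exact
binning of the original tool is unpublished; deciles are this
package's choice). The overlap statistic is the per-segment overlap
summed over segments, and the empirical p-value is
`(1 + #{perm >= obs}) / (n_perms + 1)` for enrichment, mirrored for
depletion. Expression shifts of gene groups against the housekeeping
baseline use two-tailed Mann–Whitney tests; groups under 5 genes are
reported as underpowered without a p-value.

# The synthetic scenario and what it does (not) show

`generate_scenario()` lays out protein-coding genes (two exons, a
planted full-length ORF) and intergenic lncRNA loci (single-exon,
start-codon-free sequence, so coding-potential calls on planted
features are deterministic) along a chromosome, then emits per-species
peaks, stranded reads (each expressed transcript is tiled, remaining
reads allocated by expression weight so totals exactly match the
configured depths), a syntenic-block orthology map with planted
unalignable gaps and occasional strand flips, REV-evolved alignments
at the configured per-class rates, and Poisson counts from log-normal
expression with the neighbour elevation planted as a causal effect on
the gene nearest each lineage-specific lncRNA.

Default study conditions: 3 species; 300 protein-coding genes and 50
lncRNA loci (10 per category I–V) on a 2.6 Mb chromosome; conserved
lncRNA rate 0.148 versus AR rate 0.164; 25 % neighbour elevation;
between-species biological noise 0.25 on the log scale. Constraint
recovery uses 200 regions of 20 kb; normalization and elevation
recovery use 2000-gene ortholog panels with 137 lineage genes A, 148
conserved genes A, 230 housekeeping genes; territory enrichment uses
150 segments of 500 bp over a 300-window workspace with a planted
1.6-fold excess. These sizes are the package's chosen design points
for stable medians at desk scale.

The generator deliberately omits several features of real data:
sequencing error and quality scores, indel evolution (indel-purified
segments are modelled as an annotation track, not simulated), spliced
multi-exon lncRNAs, diploid genotypes, unequal coverage along
transcripts, and mapping ambiguity. Passing recovery tests therefore
demonstrates that the *statistical machinery* is correct and unbiased
under the planted model — not that the pipeline is robust to mapping
artefacts or assembly fragmentation in real libraries. Conversely,
because evidence is planted noiselessly, category recovery on the
default scenario is exact; at sharply reduced depth, losses push calls
only in the conserved-to-lineage-specific direction (evidence can be
lost, never gained).

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GFF3 converts at I/O.
* `rev_distance` returns exactly 0 for identical pairs (no optimizer
  involvement); frequencies of zero restrict the model to the observed
  composition; an absorbing composition (a single base) never changes.
* Promoters at chromosome edges are truncated and flagged; a TSS at
  position 0 on the plus strand yields an empty, flagged promoter.
* TMM refuses panels with fewer than 20 doubly-expressed genes.
* Empirical p-values are bounded below by `1/(n_perms + 1)`; the
  one-sided enrichment p-value is super-uniform under the null
  (verified by simulation), while the reported directional p-value
  inherits the usual two-sidedness of picking the observed direction.
* Ties in territory boundaries (odd gaps) are resolved by floor();
  the per-base check in the tests allows the 1 bp ambiguity.

# Known limitations

* Only pairwise (two-species) likelihoods; no rate heterogeneity
  across sites, no codon models.
* The conservation truth table anchors on a single focal species and
  treats partially projectable loci by their projected portion.
* The transfrag assembler is single-exon by construction; spliced
  assembly must come from upstream tools.
* Permutation enrichment assumes segments fit inside single workspace
  intervals, as the randomization tool it models does.
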
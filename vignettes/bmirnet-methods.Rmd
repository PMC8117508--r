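---
title: "Methods and models behind bmirnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models behind bmirnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmirnet)
```

# Scope

`bmirnet` implements the computational skeleton of a B-chromosome
miRNA study: cataloging miRNA precursors from small-RNA sequencing,
screening for B-chromosome copies of miRNA loci by genomic coverage
ratio, calling differential miRNA expression between B+ and B-
individuals, predicting 3'UTR targets by seed matching, and merging
those targets with a filtered protein-protein interaction (PPI)
network. Every stage has a synthetic-data generator counterpart so the
whole pipeline can be validated against known ground truth.

This vignette records the models, the defaults and why they were
chosen, the numerical conventions, and the places where a design had to
be decided rather than derived.

# The miRNA catalog

**Read preprocessing.** Small-RNA reads are truncated at the first
occurrence of the 3' adapter (default `TGGAA`) and kept when the
trimmed length falls in 17-27 nt — the canonical mature-miRNA size
window. Trimming is idempotent, and both bounds are inclusive.

**Reference collapsing.** The mature reference list is made
nonredundant by removing exact duplicates and full-length substrings of
a longer retained sequence. The representative is the longest sequence,
ties broken by the lexicographically smallest id — a deterministic
stand-in for greedy identity clustering of short identical-length
sequences.

**Hairpin detection.** A window is partitioned into
(arm, loop, arm) with arm length 20-24 nt and loop 8-15 nt, and scored
by the fraction of positions in which the two arms pair
(Watson-Crick, plus G·U wobble by default, since pairing happens at the
RNA level). A hairpin is called at complementarity >= 0.6. This is a
deliberate simplification of probabilistic precursor scoring with
thermodynamic folding: for synthetic validation the question is only
whether a two-arm inverted repeat is present, and a threshold
complementarity test answers it with a measured false-positive rate
below 5% on uniform-random 60-nt windows. Symmetric hairpins can admit
several perfect partitions; the first best-scoring partition is
reported and callers should rely on the score, not the exact arm
length.

**Known versus novel.** A precursor is *known* when a mature arm
matches a reference mature of equal length with at most 2 mismatches
*and* an identical seed (nucleotides 2-8 from the 5' end). Novel
precursors whose seed exactly matches a reference seed inherit that
reference id as their *seed family* (ties: fewest full-sequence
mismatches, then smallest id). The two-mismatch-plus-seed rule is an
explicit, testable criterion standing in for an aligner's internal
tolerance, which is not published.

**Arm dominance.** The arm with the strictly larger read count
dominates; ties (including the zero-read case) resolve to 5p with a
flag, because only a majority-arm statistic is reported downstream and
an arbitrary-but-flagged rule keeps the summary well defined.

**Clustering.** Precursors on one contig whose gap
(next start − previous end) is at most 5000 bases chain into one
cluster ("not exceeding 5 kb" read as inclusive). Chaining uses the
running maximum of ends, which makes the partition identical to the
transitive closure of the pairwise <= 5-kb relation even when
intervals nest. Strand is ignored: annotated clusters can mix
strands. Overlapping precursors (gap <= 0) join.

**Summary.** Percentages are reported at two decimals with half-even
rounding, recomputed from counts. One published composition statistic
(495 "single" precursors given as 36.31%) is arithmetically
inconsistent with its own total (495/727 = 68.09%); the summary
therefore always reports both the count and the recomputed percentage
and makes no attempt to reproduce the inconsistent figure.

# The B-chromosome screen

**Coverage ratio.** Duplication of an A-genome segment on the B
chromosome doubles its read coverage in B+ genomic libraries
(e.g. 60x in B- against 120x in B+). Depth tracks are windowed
(1000 bp default), each library is scaled by its genome-wide *median*
window depth — the median, unlike the mean, is robust to the
duplicated blocks themselves, provided blocks remain a minority of the
genome — and the per-window normalized ratio is thresholded at 1.5.
The threshold sits halfway between the single-copy expectation (1) and
the duplication expectation (2) so that Poisson noise around 2x is
admitted while unduplicated sequence is excluded; both the window size
and the threshold are configurable because the calling tolerance is a
design choice, not a published constant. Blocks need at least 3
above-threshold windows and may bridge one below-threshold window.
Windows with zero B- depth have an undefined ratio and are excluded
from calling rather than imputed.

**Annotation intersection.** A miRNA locus "sits on the B chromosome"
when its precursor interval overlaps a called block by at least one
base. An empty intersection is a first-class, reportable outcome — it
is the published outcome for this system.

**Unaligned-read rescue.** Reads failing to align to the primary
assembly (exact/1-mismatch substring search; a full aligner is
unnecessary at 17-27 nt) are aligned to the B+ assembly, and alignment
positions are chained into candidate regions. A region is
B+-exclusive only when every supporting read comes from B+ samples.
The generator can construct the confounded case — a locus missing from
the primary assembly but present in both genotypes (an assembly gap) —
and the screen correctly refuses to flag it.

**Gene dose ratio.** Per-sample dCq = Cq(target) − Cq(reference
gene, default UBCE) removes sample-level offsets; ddCq is the B+
minus B- group difference of mean dCq, and the dose ratio is
2^−ddCq. Significance uses a two-sided Wilcoxon rank-sum test on the
per-sample dCq values: qPCR designs here have a handful of samples
per group and no normality justification, so a rank test is the
conservative default. The estimator is invariant to per-sample Cq
shifts, and swapping the groups inverts the ratio while preserving p.

**Restricted-reference prediction.** The third screening strategy —
hairpin prediction restricted to called B-blocks — is a pipeline
configuration (run the catalog stage with blocks as the only reference
intervals), not separate code.

# Differential expression

Counts are filtered at CPM >= 1 in at least 6 samples, normalized by
TMM (trimmed mean of M-values), and tested per tissue-by-sex contrast
(B- always the control) with a negative-binomial conditional exact
test at *fixed* dispersion.

**TMM.** The reference library is the one whose upper quartile of
count/library-size is closest to the mean upper quartile. Gene-wise
log2 ratios against the reference are trimmed 30% per tail, average
log intensities 5% per tail, and the surviving M values are combined
with inverse delta-method-variance weights; factors are rescaled to a
zero log-mean. The implementation reproduces `edgeR::calcNormFactors`
to 8 decimals on shared inputs, and edgeR serves as the independent
cross-check in the test suite. Note the direction convention: a
library in which a subset of genes is amplified receives a factor
*below* 1, because the amplification inflates its library size.

**Fixed dispersion.** The dispersion is pinned at
phi = BCV^2 = 0.16 (BCV 0.4), with no tagwise estimation: the analysis
this package models fixed that value, and honoring it literally makes
the test's calibration a checkable property rather than an estimator's
side effect. Under the NB model with common phi, the distribution of
one group's sum conditioned on the total is free of the unknown mean
(the NB probability parameter cancels), so with n1 and n2 samples the
conditional law of the split is computed exactly from
NB(n1·mu, n1/phi) and NB(n2·mu, n2/phi) densities, and the two-sided
p-value sums all splits as or less probable than the observed one.
Unequal sequencing depths are handled by scaling each sample to the
geometric-mean effective library size (library size x TMM factor)
before summing; the density is evaluated through gamma functions so
non-integer pseudo-counts pose no problem. At small totals the p-value
agrees with exhaustive enumeration to 1e-10, and under a null
simulation (fold change 1, BCV 0.4, 3 vs 3, 2000 miRNAs) the rejection
rate at alpha = 0.05 falls inside the binomial 95% interval.

**DE calls.** A miRNA is DE at raw p < 0.05 with linear |fold change|
strictly above 1.5. Raw p (no FDR) is the faithful choice for the
screening design being modeled; a Benjamini-Hochberg switch
(`adjust = TRUE`) is provided but off by default. The fold-change
threshold is applied on the linear scale: of the two plausible
readings of a legacy `fc_threshold = 0.5` parameter (log2 of 0.5 =
1.41x, or the 1.5x figure convention), the figure convention wins.
Fold changes are reported in the signed linear convention
(+2^|log2FC| up, −2^|log2FC| down) with a prior count of 0.125
guarding log2 of zero-mean groups.

**Aggregation.** The nonredundant DE set is the union over contrasts
keyed by mature miRNA id, with per-tissue Venn region counts when
contrasts cover exactly three tissues.

# Target prediction

The 3'UTR is everything strictly downstream of the stop codon on the
coding strand; without an ORF annotation the longest ATG-to-stop ORF of
at least 100 codons is located first (both strands searched).

Sites are the canonical taxonomy: with the 6-nt seed core (reverse
complement of miRNA positions 2-7) matched at UTR position q, the two
flanking features are position-8 pairing (UTR base q−1) and the
adenine anchor opposite position 1 (UTR base q+6). Both give an 8mer,
pairing alone a 7mer-m8, the anchor alone a 7mer-1A; a bare core is not
reported. Sites closer than 7 nt are mutually exclusive (seed matches
cannot physically overlap); the stronger type wins, then the 5'-most.
U and T are equivalent on input.

Scoring is additive per site with configurable weights (defaults
−0.31 / −0.16 / −0.10 for 8mer / 7mer-m8 / 7mer-1A, implementation
constants patterned on published mean context contributions) and a
strict significance cutoff at total < −0.2. The full context model
(UTR position, local AU content, 3'-supplementary pairing,
conservation) is deliberately not reimplemented: downstream the score
is used only as a binary filter, and an additive surrogate reproduces
that decision structure with the published cutoff. With the default
weights, one 8mer or any two sites clear the cutoff; a single 7mer
does not.

Interactions are keyed by transcript and restricted to transcripts
expressed in the tissue under analysis; collapsing to gene symbol
happens only at network entry, so multiple transcripts of a gene
contribute one regulatory edge.

# Network integration

B-related proteins are the exact intersection of the per-group target
sets. The groups default to the three tissues (each the union over
sexes) because the published comparison is a three-way diagram; a
six-group tissue-by-sex intersection is a configuration away.

The PPI table is filtered to rows where both interactors are human
(taxid 9606) and the detection method is one of seven allowed PSI-MI
codes (MI:0004, MI:0114, MI:0047, MI:0055, MI:0090, MI:0045, MI:0018);
pairs are canonicalized by sorted upper-cased symbols, and self-loops
and duplicates are dropped with per-rule removal counts. The MI token
is extracted by pattern from the detection-method field, so BioGRID
tab3-style values parse without a dedicated dialect reader.

The subnetwork is *induced* on the seed set: only edges with both
endpoints among the seeds survive, and isolated seeds are dropped.
This reading is adopted because the published subnetwork is far
smaller than its seed list, which is only possible if isolated seeds
were discarded and no neighbor expansion occurred; an expansion mode
is not implemented.

The B-miR-net merges the PPI subnetwork with deduplicated directed
miRNA-to-protein edges; regulatory edges to proteins absent from both
the subnetwork and the tissue-specific target list are dropped with a
message. Node provenance (B-gene / B-related / tissue-specific target)
and per-node degree support downstream reporting; the total edge count
is exactly PPI + regulatory after deduplication.

B-genes are partitioned by coding integrity at a strict 80% threshold
(80.25 is above, 80.00 and 79.90 are not), matching how the published
integrity table splits 42 genes into 18 above and 24 at or below.

Enrichment is the hypergeometric upper tail per term with BH q-values
over the tested terms (default cutoff q < 0.05 — the service the
analysis emulates does not publish its cutoff, so the conventional one
is documented here). Terms with no selected gene are untested.
Exclusive terms between two groups are exact set differences, with the
shared set reported alongside.

# The synthetic-data module

The generators produce every pipeline input with recorded truth, under
one integer seed; each generator draws from its own stream (seed plus
a fixed offset) so outputs are reproducible and independent of call
order, and the caller's RNG state is restored afterwards.

Defaults encode the study conditions the pipeline models: BCV 0.4,
planted fold change 1.5, 2x B+ coverage over planted blocks at 60x
baseline, adapter `TGGAA`, read lengths 17-27 nt, arm bias 0.8, three
replicates per group. Baseline expression means are log-uniform in
20-200 counts — a realistic mid-abundance band that keeps exact-test
totals informative without dominating library sizes. Where a value had
to be invented (cluster gaps 200-3000 bases within clusters, more than
5500 between placement units; UTR lengths 200-800 nt; 20% of miRNAs DE
per contrast), it was chosen once as a plausible magnitude for this
kind of data and is configurable.

Backgrounds are uniform over A/C/G/T. UTR backgrounds are scrubbed of
accidental seed cores before planting rather than rejection-sampled,
and any residual detectable site (e.g. created at a planting boundary)
is recorded in the truth instead of forbidden — this avoids biasing
the background composition. The adapter is placed only as a suffix,
matching 3' adapter chemistry. B-blocks are aligned to the depth-track
window grid, so block edges coincide with window edges.

What the generators do *not* emulate: sequencing error, quality
scores, isomiR heterogeneity, GC or mappability bias in coverage,
secondary structure beyond perfect inverted repeats, and correlated
expression between samples. Passing tests therefore demonstrate the
correctness and calibration of the algorithms under their assumed
statistical model, not robustness to every artifact of real libraries.

# Problem sizes and numerical conventions

The validation suite runs at deliberately modest scale, chosen as the
smallest sizes at which the statistical assertions are stable: 2000
miRNAs for null calibration, 300 for power checks, 50 replicate
genomes (400-kb contig, five 10-kb blocks) for coverage recall and
precision, 100 random miRNA/UTR pairs for the seed-scan oracle, and
100 seeds for the dose-ratio non-significance check. Internal
coordinates are 0-based half-open everywhere; GFF3 is written 1-based
inclusive and BED 0-based half-open. Percentages round half-even to
two decimals. p-values are exact tail sums, never zero; ties in the
"as extreme" comparison are included with a 1e-12 relative guard.

# Known limitations

The hairpin test will accept any sufficiently complementary inverted
repeat, including non-miRNA fold-backs a thermodynamic model would
reject. The exact test's calibration guarantee holds at the fixed
dispersion; if real data disperse more, raw p-values are optimistic —
the BH switch exists for that reason. Target prediction ignores
non-canonical (3'-compensatory) sites. The network stage takes
annotation as given: no GO graph propagation, no live database
queries, and fish-to-human symbol mapping is an input, not an
inference.
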
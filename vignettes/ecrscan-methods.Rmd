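---
title: "Methods: edited dsRNA region discovery, splicing dysregulation and ISG synergy"
author: "ecrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: edited dsRNA region discovery, splicing dysregulation and ISG synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecrscan)
```

# Scope and model

`ecrscan` analyses endogenous double-stranded RNA surveillance: ADAR marks
self-dsRNA by A-to-I editing, hnRNPC masks cryptic splice sites in antisense
Alu elements, and loss of both safeguards exposes MDA5 ligands and drives a
synergistic interferon response. The package covers the post-alignment,
post-caller part of such a study: editing-site filtering and clustering,
ECR construction and quantification, splicing statistics, differential
expression with a factorial interaction test, dsRNA structure scoring, and
eCLIP repeat-family enrichment. Read alignment, variant calling and
thermodynamic folding are out of scope; the package consumes their output
formats (pileup TSVs, intron-excision count tables in the layout of the
standard splicing callers, dot-bracket strings)
and substitutes simplified, self-contained stand-ins only where noted.

# Coordinate and distance conventions

All internal coordinates are 0-based half-open; GTF input (1-based
inclusive) is converted at the boundary, and BED is read and written
natively. Overlap requires at least one shared base. The distance between
disjoint intervals is `start(downstream) - end(upstream)`, so abutting
intervals have distance 0; this makes the ECR boundary case exact (a
2,000-bp gap between clusters yields two ECRs, 1,999 yields one). Splice
sites and editing sites are treated differently on purpose: editing sites
are 1-bp loci whose inter-site gap is the difference of positions (sites at
100 and 150 have gap 50 and share a cluster at `max_gap = 50`), while
splice sites are boundary coordinates (zero-width points), so a site 30 nt
from a CLIP-peak edge has distance 30.

# Editing-site pipeline

Per site and sample the strand decides which base carries the edit: G on
sense (A-to-I read as A-to-G), C on antisense (genome-space T-to-C). Counts
of the two non-participating bases are treated as sequencing errors and
folded into the reference count, and frequency is `edit / (reference +
edit)` with 0 for uncovered sites. The pileup table is authoritative for
counts at all candidate positions; a site absent from a sample's pileup
gets zero counts, which reproduces the re-extraction semantics of callers
that drop low-expression sites. Unstranded sites are rejected rather than
guessed.

Two filters follow. The primary filter requires, in at least one ADAR-WT
sample simultaneously: caller pass, caller score >= 0.5, coverage >= 10 and
frequency in [0.05, 0.95]; SNP-flagged sites are removed outright. The
secondary filter requires one treatment triplet in which all three samples
reach frequency 0.05, two reach 0.10 and all three have 10 reads. Both
frequency clauses use the same folded-count frequency; nothing in the
procedure suggests two definitions, and using one keeps the filter
monotone. Surviving sites are clustered by a single left-to-right pass with
`max_gap = 50` (equivalent to the transitive closure of the pairwise gap
relation, which the test suite verifies against a brute-force oracle), and
clusters with fewer than five sites are dropped together with their sites.

ECRs pad each final cluster interval by 1,000 nt per side (clamped at 0)
and merge padded intervals sharing at least one base, strand-blind — the
published grouping of clusters "less than 2,000 bp apart" is exactly this
construction. Cluster intervals for padding are `[first site, last site +
1)`; a point-set cluster needs a canonical interval and this is the
tightest one. Pooled editing statistics are always ratios of summed counts
(`sum(edit)/sum(reads)`), never means of per-sample ratios: site-level
pooling spans days within a genotype, ECR-level pooling is day-wise.

# Genome annotation services

Introns derive from principal transcripts only (any attribute containing
"appris" marks a transcript principal — the level suffix is deliberately
ignored since annotation releases vary in which levels they assign). Per
gene, exons of all principal transcripts are merged with abutting exons
coalesced, then subtracted from the union span of the principal
transcripts. Using the principal-transcript span rather than the gene
record's span prevents intron leakage past annotated transcripts when the
two disagree. Feature assignment is prioritized CDS > 3'UTR > 5'UTR > exon
> intron > gene > intergenic; ties within a category go to the larger
overlap, then the lexicographically smaller gene id, so output is
deterministic and order-invariant.

Upstream 3'UTR distances for intergenic clusters are strand-aware on the
UTR side: a candidate UTR lies 5' of the query in its own transcription
direction (on "+" its end is at or before the query start; on "-" its
start is at or after the query end). Both strands' nearest candidates are
computed and the closer one reported, because the intergenic query itself
carries no strand. The UTR interval edge (not the transcript end) anchors
the distance.

# Splicing statistics

Relative splice-site use aggregates intron excision counts by shared intron
starts and ends separately, after summing replicates within a condition,
and normalizes by the cluster total — so start-site uses and end-site uses
each sum to one per cluster and condition. Fold changes are reported as
KO/CTRL (the direction is recorded in output metadata; the ratio direction
is a display convention, not a modelling choice).

The per-cluster differential test is an explicit stand-in for the external
differential-splicing model, so synthetic runs are self-contained: pooled
intron-count vectors of two condition groups are compared by a
likelihood-ratio G-test, `G = 2 * sum(O * ln(O/E))` with `#introns - 1`
degrees of freedom, BH-adjusted across clusters. Single-intron clusters are
excluded; a zero-total group yields `p = NA`. When externally computed
significance tables are supplied they take precedence unless explicitly
overwritten. The G-test treats replicates as pooled and therefore ignores
biological overdispersion between replicates; on real data the external
tool's Dirichlet-multinomial p-values should be preferred, which is why the
join is designed the way it is.

Cluster stratification classifies each cluster's splice-site set as Alu
(any site in an Alu-family repeat), non-Alu RE, or no RE; gene overlap uses
the cluster span (most 5' intron start to most 3' intron end) against
expressed genes at an adjusted-p cutoff of 0.01.

# Differential expression and the factorial test

Gene, intron and ECR counts are all normalized against gene-level library
sizes times TMM factors; intron and ECR features are too sparse and too
condition-dependent to anchor their own library sizes. Mean log2-CPM
filters are 0.5 / 1.0 / 4.5 for genes / introns / ECRs, boundary inclusive,
with a 0.5 pseudo-count before the log (a standard stabilization constant).
The fit is ordinary least squares on the treatment-means model, with every
genotype-by-day triplicate entering as its own condition so that all
treatments inform the per-feature residual variance; contrasts are
extracted per day.

Variance moderation shrinks per-feature residual variances toward a
scaled-F prior whose degrees of freedom and scale are moment-matched on the
observed variances (digamma/trigamma inversion of the mean and variance of
`log s^2`). An earlier design fixed the prior at 4 df around the global
mean variance; simulation showed that a point prior mis-calibrates null
p-values whenever true variances vary across features (as they do for
counts whose variance depends on the mean), so the moment-matched prior is
the default and the fixed-df variant remains available through the
`prior_df` argument. Calibration is verified by simulation in the test
suite (null uniformity, realized FDR, power and bias at planted log2FC 2)
rather than by comparison with any published implementation; an
independent linear-model fit is used in the tests only as a cross-check of
the effect estimates.

The 2x2 factorial interaction test runs on one day's samples with the four
genotype groups and estimates `(DKO - ADAR) - (hnRNPC - CTRL)` in log2-CPM
group means — the departure of the double knockout from additivity. The
published analysis weighted samples by quality; those weights are not
recoverable from the description, so the fit here is unweighted and flagged
as such in output metadata. The ISG set is an input (a gene list): in the
original design it comes from an IFN-alpha versus untreated contrast at the
matching day, which the synthetic design does not simulate, so the
generator emits its planted ISG list as this input. Moderation and BH run
across the ISG set only.

Intron-versus-gene decoupling reports `delta = log2FC(intron) -
log2FC(gene)` per intron; introns with `|delta| >= 1` are labelled
decoupled (cis-dysregulated), the rest transcription-driven. The cutoff of
1 sits midway between the planted classes (delta 3 versus 0) and equals
the regulation threshold used elsewhere. rpkm is
`count * 1e9 / (library * factor * length)`, and the ECR expression floor
requires a per-condition mean of 4 rpkm in every condition.

# Structure metrics and ligand calls

From a dot-bracket string: total length is the string length including all
unpaired positions; the mismatched-nucleotide fraction is the count of dots
over the length — terminal-loop dots count, exactly as the count-of-dots
formula implies, fidelity over structural nicety; the longest uninterrupted
helix is the longest run of base pairs contiguous on both strands, so a
single-nucleotide bulge on either strand breaks the run (the biophysical
reading of an uninterrupted dsRNA seed for filament nucleation). Ligand
criteria are length > 300 nt, mismatch fraction < 0.2, longest helix >= 37
bp; because the reference description joins them with "and/or", both
combinators are exposed, the default is "any", and the choice is recorded
in output metadata. Unbalanced brackets are a validation error, not a
warning.

# eCLIP repeat-family enrichment

Per family and strand, read fractions in the eCLIP and input libraries are
regularized with a Laplace pseudocount (1 read per family) so zero-input
families stay finite; fold enrichment is their ratio and relative
information content is `p_eclip * log2(FE)`. Base-2 logarithm matches the
log2 conventions used throughout the package; the ranking is invariant to
the base, which is recorded in output metadata.

# The synthetic-data generator

The generator defines the study conditions: four genotypes (CTRL, hnRNPC
KO, ADAR KO, double KO) by days 3-5 by three replicates. Its defaults are
chosen once as realistic for this design and are not tuned to analysis
outcomes:

* **Geometry** — 200 genes of ~12.6 kb with 4 exons and one principal
  transcript each, alternating strand; Alu-like repeats cover 30% of
  intronic bases (one ~300-bp element per 1.8-kb intron), a fraction as
  inverted pairs, plus intergenic elements. The toy genome is
  annotation-only: no stage downstream of alignment needs nucleotide
  sequence, so none is generated except for structure records.
* **Editing** — 20 clusters of 5-12 sites inside Alu elements (a quarter
  intergenic), mean coverage 100; per-condition frequencies 0.30 (CTRL),
  0.33 (hnRNPC KO — slightly increased substrate), 0.05 (both ADAR-KO
  arms). Edited-base counts are binomial at the planted frequency;
  sequencing errors are added to the two non-participating bases at a
  fixed rate of 0.005 per base, enough to exercise the error-folding rule
  without dominating signal. Decoy classes (low-frequency sites,
  caller-fail sites, SNP-overlapping sites, sub-threshold 3-site clusters)
  exercise every filter clause; decoys are placed at least 150 nt from
  planted sites so they cannot bridge clusters.
* **Counts** — negative binomial with dispersion 0.05 and per-sample
  library factors in [0.75, 1.3], so normalization-factor recovery is
  testable. 5% of genes are ISGs (main effects 0.5 + 0.5 log2 and an
  interaction of 2 only in the double KO); keeping ISGs a small minority
  mirrors real transcriptomes and preserves the majority-non-DE assumption
  TMM rests on. 15% of genes are transcription-driven (equal gene and
  intron effects of 1.5 in hnRNPC-KO arms); a quarter of genes contribute
  one decoupled intron (intron effect 3, gene effect 0).
* **Splicing** — per gene one cluster pairing the canonical intron with a
  cryptic shorter intron ending inside an Alu; hnRNPC-KO samples shift
  relative usage from 0.15 to 0.55 cryptic in 40% of clusters, at cluster
  depth ~300 per sample.
* **Structures** — hairpins assembled from helix runs interleaved with
  symmetric interior loops and a terminal loop, so truth metrics follow
  from the geometry and the analyzer must reproduce them exactly.

What the generator does not emulate — and hence what green tests do not
demonstrate about real data: read-level artefacts (multi-mapping,
PCR duplicates, strand bleed-through), realistic Alu sequence content and
editing-site spacing, splice-site motifs, overdispersion between splice
replicates, batch structure, and the IFN-alpha treatment arms. Determinism
is by construction: each generator stage seeds the RNG from the spec seed
plus a fixed offset, so identical specs give byte-identical files
regardless of call order.

# Numerical choices and degenerate inputs

TSV outputs use 6 significant digits and '.' for missing values, making
file digests reproducible; the end-to-end determinism test hashes all
result tables across two pipeline runs. Zero-coverage sites have frequency
0 rather than NA; zero-read pooling groups report 0 with a flag; zero-total
conditions make relative splice-site use undefined (NA) rather than 0.
Empty inputs (no sites, no clusters, no repeats) flow through every stage
as empty outputs rather than errors, while malformed inputs (bad GTF lines,
bad intron keys, unbalanced brackets, unknown configuration keys) fail
loudly with the offending location.

# Problem sizes

The shipped tests and the acceptance script run the generator at its
default scale (200 genes, 36 samples, ~1,500 count features, 20 editing
clusters, 60-500 structures) and the calibration simulations at 2,000
features or clusters — sizes chosen so every property of interest
(calibration, power, recovery) is measurable with tight Monte-Carlo error
while the whole suite stays desk-scale.

# Known limitations

The DE engine is intentionally simpler than the published
precision-weighted framework: no observation-level weights, no quality
weights, no trend on the variance prior. On deep real data the interface
seam (counts in, per-feature tables out) is designed so an external engine
can replace it. The G-test splicing stand-in ignores replicate
overdispersion. ECR quantification assumes the provided counts already
handled multi-mapping upstream. Editing analysis covers A-to-I only, with
no hyper-editing rescue and no editing-type classification.
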
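# ecrscan

Discovery and quantification of ADAR-edited, endogenous double-stranded RNA
regions from RNA-seq-derived inputs.

## The problem

Inverted-repeat Alu elements in introns and 3'UTRs fold into long dsRNA
hairpins. Cells mark these self-RNAs by ADAR-mediated A-to-I editing and mask
them by RNA-binding proteins such as hnRNPC; when both safeguards fail, the
dsRNA sensor MDA5 triggers a type I interferon response. Studying this axis
computationally requires a chain of specialised steps that no single existing
tool covers:

* turning per-site pileup base counts from an editing caller into a
  high-confidence set of **A-to-I editing sites** via a strict filter cascade,
* grouping sites into **editing clusters** (gap-constrained) and building
  **editing-cluster-rich regions (ECRs)** — padded, merged regions that can be
  quantified despite multi-mapping reads,
* quantifying **intron retention and cryptic splice-site usage** attributable
  to loss of hnRNPC,
* **feature-level differential expression** for genes, introns and ECRs with
  library sizes anchored on gene counts,
* a **2x2 factorial interaction test** asking whether interferon-stimulated
  genes (ISGs) respond synergistically to combined hnRNPC/ADAR loss,
* scoring folded dsRNA stretches as candidate **MDA5 ligands** against
  irAlu-reference criteria, and
* ranking repeat families by **eCLIP enrichment** to nominate Alu-binding
  proteins.

`ecrscan` implements this pipeline for R, and ships a seedable synthetic-data
generator that plants known ground truth for every stage, so the full analysis
is testable end to end without any sequencing data.

## The statistics at the core

**Editing frequency with error folding.** At a site with strand *s* and base
counts (A, C, G, T), the edited base is G on the sense strand (A-to-I read as
A-to-G) and C on the antisense strand; counts of the two non-participating
bases are treated as sequencing errors and folded into the reference:

    sense:      edit = G,  reference = A + T + C
    antisense:  edit = C,  reference = T + A + G
    frequency  = edit / (reference + edit)

**Filter cascade.** A site survives if (1) in at least one ADAR-WT sample it
has caller pass, caller score >= 0.5, coverage >= 10 and frequency in
[0.05, 0.95]; and (2) for at least one treatment triplet, all three samples
have frequency >= 0.05, two have frequency >= 0.10, and all three have >= 10
reads. Surviving sites are clustered with a maximum inter-site gap of 50 nt;
only clusters with >= 5 sites are kept.

**ECRs.** Cluster intervals are padded by 1,000 nt on both sides and merged
when they share at least one base, which groups clusters less than 2,000 nt
apart (a gap of exactly 2,000 stays split). Pooled editing is always
`sum(edit counts) / sum(read counts)` over the group — never a mean of
per-sample ratios.

**Differential expression.** Responses are log2-CPM against gene-level
library sizes times TMM factors, with a 0.5 pseudo-count. A treatment-means
OLS fit is moderated by shrinking per-feature residual variances toward a
moment-matched scaled-F prior; calls require |log2FC| >= 1 and BH-adjusted
p <= 0.05. The factorial interaction coefficient for the 2x2 genotype design
is `(DKO - ADAR) - (hnRNPC - CTRL)` in group means.

**Ligand scoring.** From a dot-bracket structure: total length, mismatch
fraction = (count of '.')/length, and the longest helix uninterrupted on both
strands. Ligand-like: length > 300 nt, mismatch fraction < 0.2, and/or
longest helix >= 37 bp.

**eCLIP ranking.** Per repeat family and strand, fold enrichment
FE = p_eclip / p_input on pseudocounted read fractions, and relative
information content RIC = p_eclip * log2(FE).

## Worked example

```r
library(ecrscan)

# gap clustering: positions 100,140,190,250 with maxGap 50
cluster_sites("chr1", "+", c(100, 140, 190, 250), max_gap = 50)
#> [1] 1 1 1 2        # gaps 40 and 50 join; 60 starts a new cluster

# strand-aware editing frequency with error folding
str(compute_site_frequency(a = 80, c = 5, g = 10, t = 5, strand = "+"))
#> List of 3
#>  $ reference: num 90   # A + T + C
#>  $ edit     : num 10   # G
#>  $ frequency: num 0.1

# dsRNA metrics: two 4-bp helices around an interior loop
str(structure_metrics("((((..((((....))))..))))"))
#> List of 3
#>  $ total_length     : int 24
#>  $ mismatch_fraction: num 0.333
#>  $ longest_helix    : int 4
```

A full synthetic run generates every input, executes all stages and writes
one TSV per result (with the parameter set and seed in header comments):

```r
spec <- sim_spec(seed = 1)
generate_dataset(spec, "data")
cfg <- list(output_dir = "out", seed = 1, stages = "all",
            inputs = list(gtf = "data/annotation.gtf",
                          repeats = "data/repeats.bed",
                          clip_peaks = "data/clip_peaks.bed",
                          snps = "data/snps.bed",
                          pileup_dir = "data/pileups",
                          design = "data/design.tsv",
                          gene_counts = "data/gene_counts.tsv",
                          intron_counts = "data/intron_counts.tsv",
                          ecr_counts = "data/ecr_counts.tsv",
                          splice_counts = "data/splice_counts.txt",
                          structures = "data/structures.txt",
                          isg_set = "data/isg_set.txt",
                          family_counts = "data/family_counts.tsv"))
res <- run_pipeline(cfg)
res$report
```

On this dataset the report shows, among others, 158 final editing sites in 20
clusters and 20 ECRs, mean pooled editing ~0.30 in ADAR-WT arms versus ~0.05
after ADAR loss, and a mean ISG interaction estimate of ~2.1 log2 units
(planted: 2). The same pipeline is scriptable per stage via the thin CLI in
`inst/exec/ecr-scan`:

```sh
ecr-scan all --config cfg.yaml [--seed N] [--out DIR]
```

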
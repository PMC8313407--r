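# shared fixtures, all built in code

# two-gene annotation with CDS/UTR structure for feature-priority tests:
#   geneA (+): span [0, 1000), exons [0,200) [400,600) [800,1000)
#              5'UTR [0,100), CDS [100,200)+[400,600)+[800,900), 3'UTR [900,1000)
#   geneB (-): span [2000, 3000), exons [2000,2300) [2700,3000)
#              3'UTR [2000,2100), 5'UTR [2900,3000)
tiny_annotation <- function() {
  structure(list(
    genes = data.frame(
      chrom = "chr1", start = c(0, 2000), end = c(1000, 3000),
      strand = c("+", "-"), gene_id = c("geneA", "geneB"),
      stringsAsFactors = FALSE),
    transcripts = data.frame(
      chrom = "chr1", start = c(0, 2000), end = c(1000, 3000),
      strand = c("+", "-"), transcript_id = c("txA", "txB"),
      gene_id = c("geneA", "geneB"), principal = TRUE,
      stringsAsFactors = FALSE),
    exons = data.frame(
      chrom = "chr1",
      start = c(0, 400, 800, 2000, 2700),
      end = c(200, 600, 1000, 2300, 3000),
      strand = c("+", "+", "+", "-", "-"),
      transcript_id = c("txA", "txA", "txA", "txB", "txB"),
      gene_id = c("geneA", "geneA", "geneA", "geneB", "geneB"),
      stringsAsFactors = FALSE),
    cds = data.frame(
      chrom = "chr1",
      start = c(100, 400, 800, 2100, 2700),
      end = c(200, 600, 900, 2300, 2900),
      strand = c("+", "+", "+", "-", "-"),
      transcript_id = c("txA", "txA", "txA", "txB", "txB"),
      gene_id = c("geneA", "geneA", "geneA", "geneB", "geneB"),
      stringsAsFactors = FALSE),
    utr5 = data.frame(
      chrom = "chr1", start = c(0, 2900), end = c(100, 3000),
      strand = c("+", "-"), transcript_id = c("txA", "txB"),
      gene_id = c("geneA", "geneB"), stringsAsFactors = FALSE),
    utr3 = data.frame(
      chrom = "chr1", start = c(900, 2000), end = c(1000, 2100),
      strand = c("+", "-"), transcript_id = c("txA", "txB"),
      gene_id = c("geneA", "geneB"), stringsAsFactors = FALSE)),
    class = "tx_annotation")
}

# random multi-gene annotation for the intron-conservation property
random_annotation <- function(n_genes = 5) {
  genes <- transcripts <- exons <- NULL
  offset <- 0
  for (g in seq_len(n_genes)) {
    gid <- sprintf("g%02d", g)
    tid <- sprintf("t%02d", g)
    n_ex <- sample(1:6, 1)
    # random exon starts/lengths; may overlap or abut
    starts <- sort(sample(0:400, n_ex)) * 10 + offset
    lens <- sample(5:40, n_ex, replace = TRUE) * 10
    ends <- starts + lens
    span <- c(min(starts), max(ends))
    strand <- sample(c("+", "-"), 1)
    genes <- rbind(genes, data.frame(
      chrom = "chrR", start = span[1], end = span[2], strand = strand,
      gene_id = gid, stringsAsFactors = FALSE))
    transcripts <- rbind(transcripts, data.frame(
      chrom = "chrR", start = span[1], end = span[2], strand = strand,
      transcript_id = tid, gene_id = gid, principal = TRUE,
      stringsAsFactors = FALSE))
    exons <- rbind(exons, data.frame(
      chrom = "chrR", start = starts, end = ends, strand = strand,
      transcript_id = tid, gene_id = gid, stringsAsFactors = FALSE))
    offset <- max(ends) + 1000
  }
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      transcript_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 cds = empty, utr5 = empty, utr3 = empty),
            class = "tx_annotation")
}

# editing_sites object assembled directly from per-sample vectors
make_sites <- function(freq, total, score = NULL, pass = NULL, snp = FALSE,
                       pos = NULL, strand = "+", chrom = "chr1",
                       samples = NULL) {
  freq <- as.matrix(freq)
  total <- as.matrix(total)
  n <- nrow(freq)
  m <- ncol(freq)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(m))
  if (is.null(score)) score <- matrix(1, n, m)
  if (is.null(pass)) pass <- matrix(TRUE, n, m)
  if (is.null(pos)) pos <- seq_len(n) * 1000
  edit <- round(freq * total)
  dimnames(edit) <- dimnames(total) <- dimnames(freq) <-
    dimnames(score) <- list(NULL, samples)
  pass <- matrix(as.logical(pass), n, m, dimnames = list(NULL, samples))
  structure(list(
    meta = data.frame(chrom = chrom, pos = pos,
                      strand = rep(strand, length.out = n),
                      snp = rep(snp, length.out = n),
                      stringsAsFactors = FALSE),
    edit = edit, total = total, frequency = freq,
    score = as.matrix(score), pass = pass, samples = samples),
    class = "editing_sites")
}

# full synthetic dataset on disk + matching pipeline config
dataset_config <- function(spec, dir = tempfile(), out_dir = tempfile()) {
  ds <- generate_dataset(spec, dir)
  cfg <- list(
    output_dir = out_dir, seed = spec$seed, stages = "all",
    inputs = list(
      gtf = file.path(dir, "annotation.gtf"),
      repeats = file.path(dir, "repeats.bed"),
      clip_peaks = file.path(dir, "clip_peaks.bed"),
      snps = file.path(dir, "snps.bed"),
      pileup_dir = file.path(dir, "pileups"),
      design = file.path(dir, "design.tsv"),
      gene_counts = file.path(dir, "gene_counts.tsv"),
      intron_counts = file.path(dir, "intron_counts.tsv"),
      ecr_counts = file.path(dir, "ecr_counts.tsv"),
      splice_counts = file.path(dir, "splice_counts.txt"),
      structures = file.path(dir, "structures.txt"),
      isg_set = file.path(dir, "isg_set.txt"),
      family_counts = file.path(dir, "family_counts.tsv")))
  list(dataset = ds, config = cfg, dir = dir)
}

# O(n^2) transitive-closure clustering oracle over point positions
oracle_cluster <- function(pos, max_gap) {
  n <- length(pos)
  adj <- abs(outer(pos, pos, "-")) <= max_gap
  cl <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      linked <- which(adj[i, ])
      new <- min(cl[linked])
      if (any(cl[linked] != new)) {
        cl[linked] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(cl, unique(cl[order(pos)]))
}
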
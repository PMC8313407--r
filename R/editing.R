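#' A-to-I editing site discovery from strand-resolved pileups
#'
#' The editing pipeline consumes per-sample pileup base counts at candidate
#' sites (the output of an upstream variant caller plus a pileup re-query),
#' folds sequencing errors into reference counts, applies a two-stage filter
#' cascade, clusters retained sites by gap distance, and finally builds
#' padded, merged editing-cluster-rich regions (ECRs) for quantification.
#'
#' @name editing_discovery
NULL

#' Compute per-site editing counts and frequency from base counts
#'
#' On the sense strand the edited base is G (A-to-I read as A-to-G) and T/C
#' counts are treated as sequencing errors folded into the reference count;
#' on the antisense strand the edited base is C (genome-space T-to-C) and A/G
#' are folded into the reference. Frequency is edit/(reference+edit), 0 when
#' no reads.
#'
#' @param a,c,g,t non-negative base counts (vectors).
#' @param strand "+" (sense) or "-" (antisense) per site; "." is an error.
#' @return list with vectors \code{reference}, \code{edit}, \code{frequency}.
#' @examples
#' compute_site_frequency(80, 5, 10, 5, "+")
#' @export
compute_site_frequency <- function(a, c, g, t, strand) {
  if (any(strand == ".")) stop("editing sites require explicit strand")
  if (any(c(a, c, g, t) < 0)) stop("base counts must be non-negative")
  sense <- strand == "+"
  edit <- ifelse(sense, g, c)
  reference <- ifelse(sense, a + t + c, t + a + g)
  total <- reference + edit
  frequency <- ifelse(total > 0, edit / total, 0)
  list(reference = reference, edit = edit, frequency = frequency)
}

#' Assemble an editing-site table from per-sample pileups
#'
#' The pileup table is authoritative for counts at all candidate positions:
#' a site absent from a sample's pileup gets zero counts and frequency 0.
#'
#' @param pileups long data.frame with columns sample_id, chrom, pos (0-based),
#'   strand, A, C, G, T, caller_score, caller_pass.
#' @param sample_ids character vector fixing sample order; defaults to the
#'   sorted unique sample ids present.
#' @param snp_positions optional interval data.frame (BED3-style) of genomic
#'   SNPs; sites overlapping one are flagged.
#' @return An \code{editing_sites} object: list with \code{meta} (chrom, pos,
#'   strand, snp), matrices \code{edit}, \code{total}, \code{frequency},
#'   \code{score}, \code{pass} (sites x samples), and \code{samples}.
#' @export
build_editing_sites <- function(pileups, sample_ids = NULL, snp_positions = NULL) {
  need <- c("sample_id", "chrom", "pos", "strand", "A", "C", "G", "T",
            "caller_score", "caller_pass")
  if (!all(need %in% names(pileups))) {
    stop("pileup table missing column(s): ",
         paste(setdiff(need, names(pileups)), collapse = ", "))
  }
  if (is.null(sample_ids)) sample_ids <- sort(unique(pileups$sample_id))
  key <- paste(pileups$chrom, pileups$pos, pileups$strand, sep = ":")
  ukey <- sort(unique(key))
  meta_idx <- match(ukey, key)
  meta <- data.frame(chrom = pileups$chrom[meta_idx],
                     pos = pileups$pos[meta_idx],
                     strand = pileups$strand[meta_idx],
                     stringsAsFactors = FALSE)
  n <- nrow(meta)
  m <- length(sample_ids)
  zero <- matrix(0, n, m, dimnames = list(ukey, sample_ids))
  edit <- total <- freq <- score <- zero
  pass <- matrix(FALSE, n, m, dimnames = list(ukey, sample_ids))
  fr <- compute_site_frequency(pileups$A, pileups$C, pileups$G, pileups$T,
                               pileups$strand)
  i <- match(key, ukey)
  j <- match(pileups$sample_id, sample_ids)
  ij <- cbind(i, j)
  edit[ij] <- fr$edit
  total[ij] <- fr$reference + fr$edit
  freq[ij] <- fr$frequency
  score[ij] <- pileups$caller_score
  pass[ij] <- as.logical(pileups$caller_pass)

  meta$snp <- FALSE
  if (!is.null(snp_positions) && nrow(snp_positions) > 0) {
    sgr <- GenomicRanges::GRanges(snp_positions$chrom,
                                  IRanges::IRanges(snp_positions$start + 1,
                                                   snp_positions$end))
    pgr <- GenomicRanges::GRanges(meta$chrom,
                                  IRanges::IRanges(meta$pos + 1, meta$pos + 1))
    meta$snp <- IRanges::overlapsAny(pgr, sgr, ignore.strand = TRUE)
  }
  structure(list(meta = meta, edit = edit, total = total, frequency = freq,
                 score = score, pass = pass, samples = sample_ids),
            class = "editing_sites")
}

subset_sites <- function(sites, keep) {
  structure(list(meta = sites$meta[keep, , drop = FALSE],
                 edit = sites$edit[keep, , drop = FALSE],
                 total = sites$total[keep, , drop = FALSE],
                 frequency = sites$frequency[keep, , drop = FALSE],
                 score = sites$score[keep, , drop = FALSE],
                 pass = sites$pass[keep, , drop = FALSE],
                 samples = sites$samples),
            class = "editing_sites")
}

#' Primary editing-site filter
#'
#' A site is retained iff it is not a genomic SNP and at least one ADAR-WT
#' sample simultaneously shows: caller pass, caller score >= min_caller_score,
#' total coverage >= min_coverage, and editing frequency within
#' [freq_min, freq_max].
#'
#' @param sites an \code{editing_sites} object.
#' @param wt_sample_ids ids of the ADAR-WT samples (non-empty).
#' @param params a [pipeline_params()] list.
#' @return Filtered \code{editing_sites}.
#' @export
primary_site_filter <- function(sites, wt_sample_ids, params = pipeline_params()) {
  if (length(wt_sample_ids) == 0) stop("wt_sample_ids must be non-empty")
  if (!all(wt_sample_ids %in% sites$samples)) {
    stop("unknown WT sample id(s): ",
         paste(setdiff(wt_sample_ids, sites$samples), collapse = ", "))
  }
  wt <- sites$samples %in% wt_sample_ids
  ok <- sites$pass[, wt, drop = FALSE] &
    sites$score[, wt, drop = FALSE] >= params$min_caller_score &
    sites$total[, wt, drop = FALSE] >= params$min_coverage &
    sites$frequency[, wt, drop = FALSE] >= params$freq_min &
    sites$frequency[, wt, drop = FALSE] <= params$freq_max
  keep <- !sites$meta$snp & rowSums(ok) > 0
  subset_sites(sites, keep)
}

#' Cluster site positions by maximum gap
#'
#' Single left-to-right pass over sorted positions on one chromosome and
#' strand: a site joins the current cluster iff its distance to the previous
#' site is at most \code{max_gap}, otherwise it starts a new cluster. The
#' result equals the transitive closure of the pairwise gap relation.
#'
#' @param chrom,strand single chromosome/strand (or vectors with one unique
#'   value); mixed values are an error.
#' @param pos site positions (1-bp loci); any order.
#' @param max_gap maximum distance between neighbouring cluster members.
#' @return Integer cluster index per input position (in input order),
#'   numbered 1..k by genomic order.
#' @examples
#' cluster_sites("chr1", "+", c(100, 140, 190, 250), max_gap = 50)
#' @export
cluster_sites <- function(chrom, strand, pos, max_gap = 50) {
  if (length(unique(chrom)) > 1 || length(unique(strand)) > 1) {
    stop("cluster_sites requires a single chromosome and strand per call")
  }
  if (length(pos) == 0) return(integer(0))
  o <- order(pos)
  gaps <- diff(pos[o])
  cl_sorted <- cumsum(c(1L, as.integer(gaps > max_gap)))
  cl <- integer(length(pos))
  cl[o] <- cl_sorted
  cl
}

# cluster ids across chrom/strand groups, unique overall
cluster_all_sites <- function(meta, max_gap) {
  grp <- paste(meta$chrom, meta$strand, sep = "/")
  cl <- integer(nrow(meta))
  offset <- 0L
  for (g in unique(grp)) {
    i <- which(grp == g)
    ci <- cluster_sites(meta$chrom[i], meta$strand[i], meta$pos[i], max_gap)
    cl[i] <- ci + offset
    offset <- offset + max(ci)
  }
  cl
}

#' Secondary editing-site filter across the full design
#'
#' After re-extracting counts for all samples (missing values already set to
#' 0), a site is retained iff for at least one treatment triplet all three
#' samples have frequency >= freq_min, at least two have frequency >=
#' freq_high, and all three have total read count >= min_coverage.
#'
#' @param sites an \code{editing_sites} object covering all samples.
#' @param design data.frame with sample_id and treatment columns; every
#'   treatment must have exactly 3 samples.
#' @param params a [pipeline_params()] list.
#' @return Filtered \code{editing_sites}.
#' @export
secondary_site_filter <- function(sites, design, params = pipeline_params()) {
  tr <- split(design$sample_id, design$treatment)
  if (any(lengths(tr) != 3)) {
    stop("every treatment must have exactly 3 samples; offending: ",
         paste(names(tr)[lengths(tr) != 3], collapse = ", "))
  }
  keep <- rep(FALSE, nrow(sites$meta))
  for (ids in tr) {
    j <- match(ids, sites$samples)
    if (anyNA(j)) stop("design names sample(s) absent from sites")
    f <- sites$frequency[, j, drop = FALSE]
    n <- sites$total[, j, drop = FALSE]
    ok <- rowSums(f >= params$freq_min) == 3 &
      rowSums(f >= params$freq_high) >= 2 &
      rowSums(n >= params$min_coverage) == 3
    keep <- keep | ok
  }
  subset_sites(sites, keep)
}

#' Final clustering and cluster-size selection
#'
#' Retained sites are clustered again with the same maximum gap; clusters
#' with fewer than \code{min_cluster_sites} members are dropped together
#' with their sites, yielding the final site selection.
#'
#' @param sites filtered \code{editing_sites}.
#' @param params a [pipeline_params()] list.
#' @return list with \code{sites} (final selection), \code{clusters}
#'   (interval data.frame: chrom, start, end, strand, cluster_id, n_sites;
#'   the cluster interval spans first to last member site, half-open), and
#'   \code{site_cluster} (cluster_id per final site).
#' @export
finalize_clusters <- function(sites, params = pipeline_params()) {
  if (nrow(sites$meta) == 0) {
    return(list(sites = sites,
                clusters = genomic_intervals(character(0), numeric(0),
                                             numeric(0), character(0),
                                             cluster_id = character(0),
                                             n_sites = integer(0)),
                site_cluster = character(0)))
  }
  cl <- cluster_all_sites(sites$meta, params$max_gap)
  sizes <- table(cl)
  keep_cl <- as.integer(names(sizes)[sizes >= params$min_cluster_sites])
  keep <- cl %in% keep_cl
  final <- subset_sites(sites, keep)
  cl <- cl[keep]
  if (!length(cl)) {
    return(list(sites = final,
                clusters = genomic_intervals(character(0), numeric(0),
                                             numeric(0), character(0),
                                             cluster_id = character(0),
                                             n_sites = integer(0)),
                site_cluster = character(0)))
  }
  meta <- final$meta
  agg <- lapply(split(seq_along(cl), cl), function(i) {
    data.frame(chrom = meta$chrom[i[1]],
               start = min(meta$pos[i]),
               end = max(meta$pos[i]) + 1,
               strand = meta$strand[i[1]],
               n_sites = length(i), stringsAsFactors = FALSE)
  })
  clusters <- do.call(rbind, agg)
  clusters <- clusters[order(clusters$chrom, clusters$start), ]
  clusters$cluster_id <- sprintf("cl_%04d", seq_len(nrow(clusters)))
  rownames(clusters) <- NULL
  old_id <- names(split(seq_along(cl), cl))
  # map per-site cluster label to the sorted cluster ids
  key <- paste(clusters$chrom, clusters$start, clusters$strand)
  site_key <- vapply(split(seq_along(cl), cl), function(i) {
    paste(meta$chrom[i[1]], min(meta$pos[i]), meta$strand[i[1]])
  }, character(1))
  id_of <- clusters$cluster_id[match(site_key, key)]
  names(id_of) <- old_id
  list(sites = final,
       clusters = clusters[c("chrom", "start", "end", "strand",
                             "cluster_id", "n_sites")],
       site_cluster = unname(id_of[as.character(cl)]))
}

#' Build editing-cluster-rich regions (ECRs)
#'
#' Each final cluster interval is padded by \code{ecr_pad} on both sides
#' (clamped at 0) and padded intervals overlapping by at least one base are
#' merged, strand-blind. Two clusters end up in one ECR iff they are
#' connected by a chain of inter-cluster gaps strictly below
#' \code{2 * ecr_pad}; a gap of exactly \code{ecr_group_gap} leaves two ECRs.
#'
#' @param clusters cluster interval data.frame from [finalize_clusters()].
#' @param params a [pipeline_params()] list.
#' @return list with \code{ecrs} (chrom, start, end, strand, ecr_id,
#'   n_clusters) and \code{membership} (cluster_id -> ecr_id).
#' @export
build_ecrs <- function(clusters, params = pipeline_params()) {
  if (nrow(clusters) == 0) {
    return(list(ecrs = genomic_intervals(character(0), numeric(0), numeric(0),
                                         character(0), ecr_id = character(0),
                                         n_clusters = integer(0)),
                membership = data.frame(cluster_id = character(0),
                                        ecr_id = character(0))))
  }
  padded <- clusters
  padded$start <- pmax(0, clusters$start - params$ecr_pad)
  padded$end <- clusters$end + params$ecr_pad
  gr <- GenomicRanges::GRanges(padded$chrom,
                               IRanges::IRanges(padded$start + 1, padded$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  ecrs <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                     start = BiocGenerics::start(red) - 1,
                     end = as.numeric(BiocGenerics::end(red)),
                     stringsAsFactors = FALSE)
  member_strands <- lapply(revmap, function(i) unique(clusters$strand[i]))
  ecrs$strand <- vapply(member_strands, function(s)
    if (length(s) == 1) s else ".", character(1))
  o <- order(ecrs$chrom, ecrs$start)
  ecrs <- ecrs[o, , drop = FALSE]
  revmap <- revmap[o]
  ecrs$ecr_id <- sprintf("ecr_%04d", seq_len(nrow(ecrs)))
  ecrs$n_clusters <- lengths(revmap)
  rownames(ecrs) <- NULL
  membership <- data.frame(
    cluster_id = clusters$cluster_id[unlist(revmap)],
    ecr_id = rep(ecrs$ecr_id, lengths(revmap)),
    stringsAsFactors = FALSE)
  list(ecrs = ecrs, membership = membership)
}

#' Pooled editing fraction per group
#'
#' Pools raw counts: per group, sum(edit counts)/sum(total read counts) over
#' all member (site, sample) pairs — not a mean of per-sample ratios. Groups
#' with zero pooled reads report 0 with \code{no_reads = TRUE}.
#'
#' @param sites an \code{editing_sites} object.
#' @param site_group grouping vector along sites (e.g. ECR id), or NULL to
#'   treat each site as its own group.
#' @param sample_group grouping vector along samples (e.g. treatment), or
#'   NULL to pool all samples.
#' @return data.frame with site_group, sample_group, edit, reads, frequency,
#'   no_reads.
#' @examples
#' \dontrun{
#' average_editing(sites, site_group = NULL, sample_group = design$condition)
#' }
#' @export
average_editing <- function(sites, site_group = NULL, sample_group = NULL) {
  n <- nrow(sites$meta)
  m <- length(sites$samples)
  if (is.null(site_group)) {
    site_group <- rownames(sites$edit)
    if (is.null(site_group)) site_group <- as.character(seq_len(n))
  }
  if (is.null(sample_group)) sample_group <- rep("all", m)
  stopifnot(length(site_group) == n, length(sample_group) == m)
  sg <- factor(site_group)
  cg <- factor(sample_group)
  # collapse samples within sample groups, then sites within site groups
  collapse <- function(mat) {
    bycol <- t(rowsum(t(mat), cg))
    rowsum(bycol, sg)
  }
  E <- collapse(sites$edit)
  R <- collapse(sites$total)
  out <- data.frame(site_group = rep(rownames(E), ncol(E)),
                    sample_group = rep(colnames(E), each = nrow(E)),
                    edit = as.vector(E), reads = as.vector(R),
                    stringsAsFactors = FALSE)
  out$frequency <- ifelse(out$reads > 0, out$edit / out$reads, 0)
  out$no_reads <- out$reads == 0
  out
}

#' Reporting filter for editing-site displays
#'
#' Selects sites with at least \code{min_reads} total reads in every sample
#' of a comparison. This is a display subset only; it never alters the
#' retained-site selection.
#'
#' @param sites an \code{editing_sites} object.
#' @param sample_ids samples forming the comparison.
#' @param min_reads read floor (default 10).
#' @return Logical vector over sites.
#' @export
reporting_site_filter <- function(sites, sample_ids, min_reads = 10) {
  j <- match(sample_ids, sites$samples)
  if (anyNA(j)) stop("unknown sample id(s) in comparison")
  rowSums(sites$total[, j, drop = FALSE] >= min_reads) == length(j)
}
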
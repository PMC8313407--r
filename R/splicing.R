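#' Read splice-cluster count tables
#'
#' Reads intron excision counts in the external differential-splicing tool's
#' layout: row keys \code{chrom:start:end:cluster_id}, one column per sample.
#' Optional per-cluster significance (cluster, p, p_adjust) and effect-size
#' tables are joined when supplied; clusters absent from the significance
#' table keep \code{p = NA}.
#'
#' @param counts_path whitespace- or tab-separated counts table with row keys
#'   in the first column and a header of sample ids.
#' @param significance_path optional TSV with columns cluster, p, p_adjust.
#' @param effects_path optional TSV of per-intron effect sizes (joined by
#'   intron key; passed through).
#' @return A \code{splice_clusters} object: list with \code{introns}
#'   (chrom, start, end, cluster_id), \code{counts} (introns x samples
#'   matrix), \code{cluster_p} (cluster_id, p, p_adjust), \code{effects}.
#' @export
read_splice_tables <- function(counts_path, significance_path = NULL,
                               effects_path = NULL) {
  raw <- utils::read.table(counts_path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  keys <- rownames(raw)
  if (all(rownames(raw) == as.character(seq_len(nrow(raw))))) {
    keys <- raw[[1]]
    raw <- raw[, -1, drop = FALSE]
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  bad <- which(lengths(parts) != 4)
  if (length(bad)) {
    stop("malformed intron row key (expected chrom:start:end:cluster): ",
         keys[bad[1]])
  }
  introns <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    start = as.numeric(vapply(parts, `[`, character(1), 2L)),
    end = as.numeric(vapply(parts, `[`, character(1), 3L)),
    cluster_id = vapply(parts, `[`, character(1), 4L),
    stringsAsFactors = FALSE)
  if (anyNA(introns$start) || anyNA(introns$end)) {
    stop("malformed intron row key: non-numeric coordinates")
  }
  counts <- as.matrix(raw)
  mode(counts) <- "numeric"
  rownames(counts) <- keys

  cluster_p <- data.frame(cluster_id = unique(introns$cluster_id),
                          p = NA_real_, p_adjust = NA_real_,
                          stringsAsFactors = FALSE)
  if (!is.null(significance_path) && file.exists(significance_path)) {
    sig <- utils::read.table(significance_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    i <- match(cluster_p$cluster_id, sig$cluster)
    cluster_p$p <- sig$p[i]
    cluster_p$p_adjust <- sig$p_adjust[i]
  }
  effects <- NULL
  if (!is.null(effects_path) && file.exists(effects_path)) {
    effects <- utils::read.table(effects_path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  }
  structure(list(introns = introns, counts = counts, cluster_p = cluster_p,
                 effects = effects),
            class = "splice_clusters")
}

#' Relative splice-site usage per cluster
#'
#' Intron counts are aggregated by genomic intron starts and ends separately
#' as indicators of splice-site use, after summing replicate counts within
#' each condition; the relative use of each site is its aggregated count
#' divided by the cluster's total intron count in that condition. Within a
#' cluster and condition, start-site uses sum to 1 and end-site uses sum to 1.
#'
#' @param clusters a \code{splice_clusters} object.
#' @param condition_of named vector mapping sample id -> condition.
#' @param contrast length-2 character: conditions (A, B) for the fold change
#'   use(B)/use(A); NULL for no fold change.
#' @return data.frame with cluster_id, site (coordinate), side
#'   ("start"/"end"), one relative-use column per condition, and
#'   \code{fold_change} when a contrast is given. Conditions with zero
#'   cluster total report NA.
#' @export
relative_splice_site_use <- function(clusters, condition_of, contrast = NULL) {
  cnt <- clusters$counts
  cond <- condition_of[colnames(cnt)]
  if (anyNA(cond)) stop("condition_of must cover every sample column")
  pooled <- t(rowsum(t(cnt), cond))  # introns x conditions
  conds <- colnames(pooled)
  res <- lapply(split(seq_len(nrow(clusters$introns)),
                      clusters$introns$cluster_id), function(i) {
    intr <- clusters$introns[i, , drop = FALSE]
    sub <- pooled[i, , drop = FALSE]
    totals <- colSums(sub)
    one_side <- function(coord, side) {
      agg <- rowsum(sub, coord)
      use <- sweep(agg, 2, totals, "/")
      use[, totals == 0] <- NA_real_
      df <- data.frame(cluster_id = intr$cluster_id[1],
                       site = as.numeric(rownames(agg)), side = side,
                       stringsAsFactors = FALSE)
      cbind(df, as.data.frame(use))
    }
    rbind(one_side(intr$start, "start"), one_side(intr$end, "end"))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  names(out)[-(1:3)] <- conds
  if (!is.null(contrast)) {
    stopifnot(length(contrast) == 2, all(contrast %in% conds))
    out$fold_change <- out[[contrast[2]]] / out[[contrast[1]]]
  }
  out
}

#' Flag splice sites proximal to CLIP peaks
#'
#' A site is proximal when its distance to the nearest CLIP peak is at most
#' \code{max_gap} nt (a site inside a peak has distance 0). Splice sites are
#' boundary coordinates (zero-width points), so a site 30 nt from a peak
#' edge has distance 30.
#'
#' @param site_pos numeric positions of splice sites (boundary coordinates,
#'   0-based).
#' @param site_chrom chromosome per site.
#' @param clip_peaks interval data.frame of CLIP peaks.
#' @param max_gap maximum distance in nt (default 50).
#' @return data.frame with distance (NA when the chromosome has no peak) and
#'   proximal flag per site.
#' @export
annotate_clip_proximity <- function(site_chrom, site_pos, clip_peaks,
                                    max_gap = 50) {
  n <- length(site_pos)
  dist <- rep(NA_real_, n)
  for (ch in unique(site_chrom)) {
    pk <- clip_peaks[clip_peaks$chrom == ch, , drop = FALSE]
    i <- which(site_chrom == ch)
    if (nrow(pk) == 0) next
    dist[i] <- vapply(site_pos[i], function(p) {
      min(pmax(0, pmax(pk$start - p, p - pk$end)))
    }, numeric(1))
  }
  data.frame(distance = dist, proximal = !is.na(dist) & dist <= max_gap)
}

#' Differential splice-cluster test (likelihood-ratio G-test)
#'
#' A self-contained stand-in for the external differential-splicing model:
#' per cluster, intron counts are pooled within each of two condition groups
#' and the pooled intron-proportion vectors compared by a likelihood-ratio
#' G-test with \code{#introns - 1} degrees of freedom, followed by
#' Benjamini-Hochberg adjustment across clusters. Single-intron clusters are
#' excluded; a cluster with zero total counts in either group gets
#' \code{p = NA}. When the input object already carries externally supplied
#' significance values they take precedence unless \code{overwrite = TRUE}.
#'
#' @param clusters a \code{splice_clusters} object.
#' @param condition_of named vector sample id -> condition.
#' @param groups length-2 character naming the two conditions to compare.
#' @param overwrite replace externally supplied p-values (default FALSE fills
#'   only missing ones).
#' @return The \code{splice_clusters} object with updated \code{cluster_p}.
#' @export
differential_splice_clusters <- function(clusters, condition_of, groups,
                                         overwrite = FALSE) {
  stopifnot(length(groups) == 2)
  cnt <- clusters$counts
  cond <- condition_of[colnames(cnt)]
  j1 <- which(cond == groups[1])
  j2 <- which(cond == groups[2])
  if (!length(j1) || !length(j2)) stop("both condition groups need samples")
  per_cluster <- split(seq_len(nrow(clusters$introns)),
                       clusters$introns$cluster_id)
  p <- vapply(per_cluster, function(i) {
    if (length(i) < 2) return(NA_real_)
    o1 <- rowSums(cnt[i, j1, drop = FALSE])
    o2 <- rowSums(cnt[i, j2, drop = FALSE])
    g_test_2group(o1, o2)
  }, numeric(1))
  res <- data.frame(cluster_id = names(per_cluster), p = unname(p),
                    stringsAsFactors = FALSE)
  old <- clusters$cluster_p
  i <- match(res$cluster_id, old$cluster_id)
  use_new <- overwrite | is.na(old$p[i])
  old$p[i][use_new] <- res$p[use_new]
  old$p_adjust <- stats::p.adjust(old$p, method = "BH")
  clusters$cluster_p <- old
  clusters
}

# G = 2 * sum(O * ln(O/E)) over the 2 x k intron table; df = k - 1
g_test_2group <- function(o1, o2) {
  t1 <- sum(o1); t2 <- sum(o2)
  if (t1 == 0 || t2 == 0) return(NA_real_)
  p_pool <- (o1 + o2) / (t1 + t2)
  gterm <- function(o, e) sum(ifelse(o > 0, o * log(o / e), 0))
  g <- 2 * (gterm(o1, t1 * p_pool) + gterm(o2, t2 * p_pool))
  df <- length(o1) - 1
  if (df < 1) return(NA_real_)
  stats::pchisq(g, df = df, lower.tail = FALSE)
}

#' Stratify splicing clusters by repeat class
#'
#' Each cluster's splice sites (all intron starts and ends, as 1-bp loci)
#' are tested for repeat overlap; the cluster is labelled Alu if any site
#' falls in an Alu-family repeat, non-Alu RE if any site falls in any other
#' repeat, else no RE. For each class and each adjusted-p cutoff, the
#' fraction of that class's clusters called differential is reported.
#'
#' @param clusters a \code{splice_clusters} object with p-values.
#' @param repeats repeat intervals with family names in \code{name}.
#' @param cutoffs adjusted-p cutoffs to sweep.
#' @return list with \code{classes} (cluster_id, class) and \code{fractions}
#'   (class, cutoff, n, n_below, fraction).
#' @export
stratify_clusters <- function(clusters, repeats,
                              cutoffs = c(0.001, 0.01, 0.05)) {
  intr <- clusters$introns
  site_df <- rbind(
    data.frame(chrom = intr$chrom, start = intr$start, end = intr$start + 1,
               strand = ".", group = intr$cluster_id),
    data.frame(chrom = intr$chrom, start = intr$end - 1, end = intr$end,
               strand = ".", group = intr$cluster_id))
  cls <- classify_repeat_overlap(site_df, repeats)
  names(cls) <- c("cluster_id", "class")
  pj <- clusters$cluster_p
  cls$p_adjust <- pj$p_adjust[match(cls$cluster_id, pj$cluster_id)]
  usable <- cls[!is.na(cls$p_adjust), , drop = FALSE]
  fractions <- do.call(rbind, lapply(unique(cls$class), function(k) {
    sub <- usable[usable$class == k, , drop = FALSE]
    do.call(rbind, lapply(cutoffs, function(cu) {
      data.frame(class = k, cutoff = cu, n = nrow(sub),
                 n_below = sum(sub$p_adjust <= cu),
                 fraction = if (nrow(sub)) mean(sub$p_adjust <= cu) else NA_real_)
    }))
  }))
  rownames(fractions) <- NULL
  list(classes = cls[c("cluster_id", "class")], fractions = fractions)
}

#' Fraction of expressed genes overlapping differential splicing clusters
#'
#' The span of a splicing cluster is the interval from its most 5' intron
#' start to its most 3' intron end; an expressed gene is flagged when its
#' span overlaps at least one cluster span with adjusted p at or below the
#' cutoff.
#'
#' @param genes interval data.frame of expressed genes (gene_id column).
#' @param clusters a \code{splice_clusters} object with adjusted p-values.
#' @param p_cutoff adjusted-p cutoff (default 0.01).
#' @return list with \code{genes} (gene_id, overlaps flag) and
#'   \code{fraction}.
#' @export
gene_splice_overlap <- function(genes, clusters, p_cutoff = 0.01) {
  intr <- clusters$introns
  spans <- do.call(rbind, lapply(split(seq_len(nrow(intr)), intr$cluster_id),
                                 function(i) {
    data.frame(chrom = intr$chrom[i[1]], start = min(intr$start[i]),
               end = max(intr$end[i]), cluster_id = intr$cluster_id[i[1]],
               stringsAsFactors = FALSE)
  }))
  pj <- clusters$cluster_p
  spans$p_adjust <- pj$p_adjust[match(spans$cluster_id, pj$cluster_id)]
  sig <- spans[!is.na(spans$p_adjust) & spans$p_adjust <= p_cutoff, ,
               drop = FALSE]
  flag <- rep(FALSE, nrow(genes))
  if (nrow(sig) && nrow(genes)) {
    ggr <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$start + 1, genes$end))
    sgr <- GenomicRanges::GRanges(sig$chrom,
                                  IRanges::IRanges(sig$start + 1, sig$end))
    flag <- IRanges::overlapsAny(ggr, sgr, ignore.strand = TRUE)
  }
  list(genes = data.frame(gene_id = genes$gene_id, overlaps = flag,
                          stringsAsFactors = FALSE),
       fraction = if (nrow(genes)) mean(flag) else NA_real_)
}
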
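#' Derive intron regions from principal transcripts
#'
#' Per gene, exons of all principal transcripts are merged (overlapping or
#' abutting exons coalesced) and subtracted from the gene span, where the
#' gene span is the union of its principal-transcript spans. Intron ordinals
#' run 5' to 3' in transcript orientation (reversed on the minus strand).
#'
#' @param annotation a \code{tx_annotation} from [read_annotation()].
#' @return Interval data.frame of introns with \code{gene_id} and
#'   \code{ordinal} columns, sorted by position; genes with no principal
#'   transcript are skipped with a warning.
#' @examples
#' \dontrun{
#' ann <- read_annotation("genes.gtf")
#' introns <- derive_introns(ann)
#' }
#' @export
derive_introns <- function(annotation) {
  tx <- annotation$transcripts
  principal <- tx[tx$principal, , drop = FALSE]
  skipped <- setdiff(tx$gene_id, principal$gene_id)
  if (length(skipped)) {
    warning("skipping gene(s) without a principal transcript: ",
            paste(skipped, collapse = ", "))
  }
  exons <- annotation$exons
  exons <- exons[exons$transcript_id %in% principal$transcript_id, , drop = FALSE]

  out <- lapply(split(seq_len(nrow(principal)), principal$gene_id), function(i) {
    span_start <- min(principal$start[i])
    span_end <- max(principal$end[i])
    strand <- principal$strand[i[1]]
    chrom <- principal$chrom[i[1]]
    ex <- exons[exons$transcript_id %in% principal$transcript_id[i], , drop = FALSE]
    if (nrow(ex) == 0) return(NULL)
    # merge abutting/overlapping exons, then subtract from the span
    merged <- merge_intervals(ex, min_overlap = 0)
    gaps <- interval_complement(merged$start, merged$end, span_start, span_end)
    if (nrow(gaps) == 0) return(NULL)
    ord <- if (strand == "-") rev(seq_len(nrow(gaps))) else seq_len(nrow(gaps))
    data.frame(chrom = chrom, start = gaps$start, end = gaps$end,
               strand = strand, gene_id = principal$gene_id[i[1]],
               ordinal = ord, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(genomic_intervals(character(0), numeric(0), numeric(0),
                             character(0), gene_id = character(0),
                             ordinal = integer(0)))
  }
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# complement of sorted disjoint intervals within [span_start, span_end)
interval_complement <- function(starts, ends, span_start, span_end) {
  o <- order(starts)
  starts <- pmax(starts[o], span_start)
  ends <- pmin(ends[o], span_end)
  bounds_start <- c(span_start, ends)
  bounds_end <- c(starts, span_end)
  keep <- bounds_end > bounds_start
  data.frame(start = bounds_start[keep], end = bounds_end[keep])
}

FEATURE_PRIORITY <- c("CDS", "UTR3", "UTR5", "exon", "intron", "gene", "intergenic")

#' Map query intervals to prioritized genic features
#'
#' Each query is labelled with the highest-priority feature category it
#' overlaps (at least one shared base), in the order
#' CDS > 3' UTR > 5' UTR > exon > intron > gene; queries overlapping nothing
#' are intergenic. Ties within a category are broken by larger overlap, then
#' lexicographic gene id.
#'
#' @param query interval data.frame of query regions.
#' @param annotation a \code{tx_annotation}.
#' @param introns intron track from [derive_introns()]; derived on the fly
#'   when NULL.
#' @return data.frame with \code{category} and \code{gene_id} (NA for
#'   intergenic), one row per query.
#' @export
map_to_features <- function(query, annotation, introns = NULL) {
  validate_intervals(query)
  if (is.null(introns)) {
    introns <- suppressWarnings(derive_introns(annotation))
  }
  tracks <- list(
    CDS = annotation$cds,
    UTR3 = annotation$utr3,
    UTR5 = annotation$utr5,
    exon = annotation$exons,
    intron = introns,
    gene = annotation$genes
  )
  n <- nrow(query)
  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  unresolved <- rep(TRUE, n)
  qgr <- intervals_to_granges(query)
  BiocGenerics::strand(qgr) <- "*"
  for (cat in names(tracks)) {
    tr <- tracks[[cat]]
    if (is.null(tr) || nrow(tr) == 0 || !any(unresolved)) next
    tgr <- intervals_to_granges(tr)
    BiocGenerics::strand(tgr) <- "*"
    hits <- GenomicRanges::findOverlaps(qgr, tgr, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    th <- S4Vectors::subjectHits(hits)
    keep <- unresolved[qh]
    qh <- qh[keep]; th <- th[keep]
    if (!length(qh)) next
    ov <- BiocGenerics::width(IRanges::pintersect(
      IRanges::ranges(qgr)[qh], IRanges::ranges(tgr)[th]))
    gid <- tr$gene_id[th]
    # per query: largest overlap wins, then lexicographic gene id
    o <- order(qh, -ov, gid)
    first <- !duplicated(qh[o])
    idx <- qh[o][first]
    category[idx] <- cat
    gene_id[idx] <- gid[o][first]
    unresolved[idx] <- FALSE
  }
  data.frame(category = category, gene_id = gene_id, stringsAsFactors = FALSE)
}

#' Distance to the nearest upstream 3' UTR
#'
#' For an intergenic query, finds on each strand the nearest 3' UTR lying
#' upstream of the query in that UTR's own transcription direction (on "+":
#' UTR end at or before the query start; on "-": UTR start at or after the
#' query end), and returns the distance to the closer of the two candidates.
#' Abutting intervals have distance 0.
#'
#' @param query a single-row interval data.frame (or list with chrom, start,
#'   end).
#' @param utr3_track stranded 3' UTR intervals.
#' @param feature_label optional precomputed label of the query; when
#'   supplied and not "intergenic", an error is raised.
#' @return Named list with \code{distance} (NA when no candidate exists) and
#'   \code{strand} of the selected UTR.
#' @export
distance_to_upstream_utr3 <- function(query, utr3_track, feature_label = NULL) {
  if (!is.null(feature_label) && feature_label != "intergenic") {
    stop("distance_to_upstream_utr3 requires an intergenic query")
  }
  u <- utr3_track[utr3_track$chrom == query$chrom, , drop = FALSE]
  best <- c(`+` = NA_real_, `-` = NA_real_)
  up <- u[u$strand == "+" & u$end <= query$start, , drop = FALSE]
  if (nrow(up)) best["+"] <- min(query$start - up$end)
  um <- u[u$strand == "-" & u$start >= query$end, , drop = FALSE]
  if (nrow(um)) best["-"] <- min(um$start - query$end)
  if (all(is.na(best))) return(list(distance = NA_real_, strand = NA_character_))
  pick <- names(best)[which.min(best)]
  list(distance = unname(best[pick]), strand = pick)
}

#' Classify a group of intervals by repeat overlap
#'
#' A group (e.g. the splice sites of one splicing cluster) is labelled
#' \code{"Alu"} if any member overlaps a repeat whose family name begins with
#' "Alu", otherwise \code{"non-Alu RE"} if any member overlaps any repeat,
#' otherwise \code{"no RE"}.
#'
#' @param query interval data.frame with an optional \code{group} column;
#'   without one, every interval forms its own group.
#' @param repeats repeat intervals with family names in a \code{name} column.
#' @return data.frame with \code{group} and \code{class} per group.
#' @export
classify_repeat_overlap <- function(query, repeats) {
  if (is.null(query$group)) query$group <- seq_len(max(nrow(query), 0))
  groups <- unique(query$group)
  if (nrow(query) == 0) {
    return(data.frame(group = character(0), class = character(0)))
  }
  hit_alu <- hit_any <- rep(FALSE, nrow(query))
  if (!is.null(repeats) && nrow(repeats) > 0) {
    qgr <- intervals_to_granges(query)
    rgr <- intervals_to_granges(repeats)
    hits <- GenomicRanges::findOverlaps(qgr, rgr, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    alu <- startsWith(repeats$name[S4Vectors::subjectHits(hits)], "Alu")
    hit_any[unique(qh)] <- TRUE
    hit_alu[unique(qh[alu])] <- TRUE
  }
  cls <- vapply(groups, function(g) {
    i <- query$group == g
    if (any(hit_alu[i])) "Alu" else if (any(hit_any[i])) "non-Alu RE" else "no RE"
  }, character(1))
  data.frame(group = groups, class = cls, stringsAsFactors = FALSE)
}
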
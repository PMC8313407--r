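#' Genomic intervals
#'
#' All internal coordinates are 0-based half-open (BED convention): a feature
#' covering the first two bases of a chromosome is \code{[0, 2)}. GTF input is
#' converted at the boundary; BED files are read and written natively.
#' Strand is one of \code{"+"}, \code{"-"} or \code{"."} (unstranded).
#'
#' @param chrom character chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions.
#' @param strand strand per interval; recycled if length 1.
#' @param ... additional columns (e.g. \code{name}, \code{gene_id}).
#' @return A data.frame with columns chrom, start, end, strand plus extras.
#' @examples
#' genomic_intervals("chr1", 0, 200)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = as.character(strand),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0)) stop("interval start must be >= 0")
  if (any(df$end <= df$start)) stop("interval end must be > start")
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  invisible(df)
}

#' Convert internal intervals to a GRanges object
#'
#' Internal 0-based half-open intervals become 1-based closed GRanges.
#' Unstranded (".") maps to "*".
#'
#' @param df interval data.frame from [genomic_intervals()].
#' @return A \code{GRanges}.
#' @export
intervals_to_granges <- function(df) {
  strand <- ifelse(df$strand == ".", "*", df$strand)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand)
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  if (length(extra)) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df[extra])
  }
  gr
}

#' Convert a GRanges object to internal intervals
#'
#' @param gr a \code{GRanges}.
#' @return Interval data.frame in 0-based half-open coordinates.
#' @export
granges_to_intervals <- function(gr) {
  st <- as.character(BiocGenerics::strand(gr))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1,
                   end = as.numeric(BiocGenerics::end(gr)),
                   strand = ifelse(st == "*", ".", st),
                   stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  rownames(df) <- NULL
  df
}

#' Distance between disjoint intervals
#'
#' Distance is start of the downstream interval minus end of the upstream one,
#' so abutting intervals have distance 0 and overlapping intervals distance 0
#' as well (clamped).
#'
#' @param start1,end1,start2,end2 vectors of half-open coordinates.
#' @return Numeric distances.
#' @export
interval_distance <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start1 - end2, start2 - end1))
}

#' Merge intervals
#'
#' Coalesces intervals per chromosome (and optionally strand). With
#' \code{min_overlap = 1} only intervals sharing at least one base merge
#' (abutting intervals stay separate); with \code{min_overlap = 0} abutting
#' intervals merge too.
#'
#' @param df interval data.frame.
#' @param min_overlap 0 or 1 shared bases required to merge.
#' @param ignore_strand merge across strands (default TRUE).
#' @return Merged, sorted interval data.frame with a \code{n_merged} column.
#' @export
merge_intervals <- function(df, min_overlap = 1, ignore_strand = TRUE) {
  if (nrow(df) == 0) {
    return(cbind(df[0, c("chrom", "start", "end", "strand")], n_merged = integer(0)))
  }
  gr <- intervals_to_granges(df)
  if (ignore_strand) BiocGenerics::strand(gr) <- "*"
  # IRanges::reduce: min.gapwidth = 0 merges only overlapping ranges,
  # 1 merges adjacent ones as well
  red <- GenomicRanges::reduce(gr, min.gapwidth = ifelse(min_overlap >= 1, 0L, 1L),
                               with.revmap = TRUE, ignore.strand = ignore_strand)
  out <- granges_to_intervals(red)
  out$n_merged <- lengths(out$revmap)
  out$revmap <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Read a BED file as internal intervals
#'
#' Accepts BED3 through BED6; name and score columns are preserved when
#' present.
#'
#' @param path BED file path.
#' @return Interval data.frame (0-based half-open, as in the file).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("BED file must have at least 3 columns: ", path)
  ncol_use <- min(ncol(raw), 6L)
  raw <- raw[, seq_len(ncol_use), drop = FALSE]
  names(raw) <- cols[seq_len(ncol_use)]
  raw$start <- as.numeric(raw$start)
  raw$end <- as.numeric(raw$end)
  if (is.null(raw$strand)) raw$strand <- "."
  if (!is.null(raw$score)) raw$score <- suppressWarnings(as.numeric(raw$score))
  validate_intervals(raw)
  raw[c("chrom", "start", "end", "strand",
        intersect(c("name", "score"), names(raw)))]
}

#' Write intervals as BED
#'
#' Writes BED6 when name/score/strand are available, BED3 otherwise.
#'
#' @param df interval data.frame.
#' @param path output path.
#' @param bed3 force BED3 output.
#' @return The path, invisibly.
#' @export
write_bed <- function(df, path, bed3 = FALSE) {
  if (bed3) {
    out <- df[order(df$chrom, df$start), c("chrom", "start", "end")]
  } else {
    name <- if (!is.null(df$name)) df$name else "."
    score <- if (!is.null(df$score)) df$score else 0
    out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                      name = name, score = score, strand = df$strand)
    out <- out[order(out$chrom, out$start), ]
  }
  utils::write.table(format_num_df(out), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# fixed 6-significant-digit, per-element formatting for reproducible digests
format_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(".")
    if (v == round(v) && abs(v) < 1e15) {
      return(format(v, scientific = FALSE, trim = TRUE))
    }
    format(signif(v, 6), scientific = FALSE, trim = TRUE)
  }, character(1))
}

format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- format_num(df[[j]])
    } else if (!is.character(df[[j]]) && !is.numeric(df[[j]]) &&
               !is.logical(df[[j]])) {
      df[[j]] <- as.character(df[[j]])
    }
  }
  df
}
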
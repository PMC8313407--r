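#' Read a GTF gene annotation into internal transcript models
#'
#' Parses a GENCODE-style GTF (1-based inclusive coordinates) into internal
#' 0-based half-open interval tables. Transcripts whose attribute field
#' contains \code{"appris"} anywhere (matching the conventional awk filter on
#' principal-isoform tags) are flagged as principal. UTR records are split
#' into 5' and 3' UTRs relative to the transcript's CDS and strand.
#'
#' @param gtf_path path to a GTF file with gene/transcript/exon records and
#'   optionally CDS and UTR records.
#' @return An object of class \code{tx_annotation}: a list with interval
#'   data.frames \code{genes}, \code{transcripts}, \code{exons}, \code{cds},
#'   \code{utr5}, \code{utr3}. Gene spans are the union span of the gene's
#'   transcripts.
#' @export
read_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) stop("GTF file not found: ", gtf_path)
  lines <- readLines(gtf_path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9)) {
    stop("malformed GTF line ", which(body)[which(nf < 9)[1]],
         ": expected 9 tab-separated fields")
  }

  gr <- rtracklayer::import(gtf_path, format = "gtf")
  df <- granges_to_intervals(gr)
  df$type <- as.character(df$type)

  # principal flag: any record of a transcript carrying an appris tag
  attrs <- vapply(strsplit(lines[body], "\t", fixed = TRUE), `[`, character(1), 9L)
  appris_tx <- unique(unlist(regmatches(
    attrs[grepl("appris", attrs, fixed = TRUE)],
    regexpr('(?<=transcript_id ")[^"]+', attrs[grepl("appris", attrs, fixed = TRUE)],
            perl = TRUE))))

  pick <- function(types, cols) {
    out <- df[df$type %in% types,
              intersect(c("chrom", "start", "end", "strand", cols), names(df)),
              drop = FALSE]
    rownames(out) <- NULL
    out
  }
  transcripts <- pick("transcript", c("transcript_id", "gene_id"))
  if (nrow(transcripts) == 0) stop("GTF contains no transcript records")
  transcripts$principal <- transcripts$transcript_id %in% appris_tx
  exons <- pick("exon", c("transcript_id", "gene_id"))
  cds <- pick("CDS", c("transcript_id", "gene_id"))
  utr <- pick(c("UTR", "five_prime_utr", "three_prime_utr"),
              c("transcript_id", "gene_id"))
  utr$utr_type <- df$type[df$type %in% c("UTR", "five_prime_utr", "three_prime_utr")]

  # exons must lie inside their transcript span
  if (nrow(exons)) {
    tx_idx <- match(exons$transcript_id, transcripts$transcript_id)
    if (anyNA(tx_idx)) {
      stop("exon references unknown transcript: ",
           exons$transcript_id[which(is.na(tx_idx))[1]])
    }
    outside <- exons$start < transcripts$start[tx_idx] |
      exons$end > transcripts$end[tx_idx]
    if (any(outside)) {
      stop("exon outside its transcript span: transcript ",
           exons$transcript_id[which(outside)[1]])
    }
  }

  # classify generic UTR records by position relative to the transcript CDS
  utr5 <- utr[0, c("chrom", "start", "end", "strand", "transcript_id", "gene_id")]
  utr3 <- utr5
  if (nrow(utr)) {
    is5 <- utr$utr_type == "five_prime_utr"
    is3 <- utr$utr_type == "three_prime_utr"
    generic <- which(!is5 & !is3)
    if (length(generic) && nrow(cds)) {
      cds_start <- tapply(cds$start, cds$transcript_id, min)
      cds_end <- tapply(cds$end, cds$transcript_id, max)
      tx <- utr$transcript_id[generic]
      plus <- utr$strand[generic] == "+"
      five <- ifelse(plus,
                     utr$end[generic] <= cds_start[tx],
                     utr$start[generic] >= cds_end[tx])
      is5[generic[which(five)]] <- TRUE
      is3[generic[which(!five)]] <- TRUE
    }
    keep <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
    utr5 <- utr[is5, keep, drop = FALSE]
    utr3 <- utr[is3, keep, drop = FALSE]
    rownames(utr5) <- rownames(utr3) <- NULL
  }

  # gene span = union span of the gene's transcripts
  sp <- split(seq_len(nrow(transcripts)), transcripts$gene_id)
  genes <- do.call(rbind, lapply(names(sp), function(g) {
    i <- sp[[g]]
    data.frame(chrom = transcripts$chrom[i[1]],
               start = min(transcripts$start[i]),
               end = max(transcripts$end[i]),
               strand = transcripts$strand[i[1]],
               gene_id = g, stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$chrom, genes$start), ]
  rownames(genes) <- NULL

  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 cds = cds, utr5 = utr5, utr3 = utr3),
            class = "tx_annotation")
}

#' Write transcript models back to GTF
#'
#' Emits gene/transcript/exon (and CDS/UTR when present) records in 1-based
#' inclusive GTF coordinates; principal transcripts carry an
#' \code{appris_principal_1} tag. Reading the result with [read_annotation()]
#' reproduces the models.
#'
#' @param annotation a \code{tx_annotation} object.
#' @param path output GTF path.
#' @return The path, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  fmt <- function(df, type, attr) {
    sprintf("%s\tecrscan\t%s\t%d\t%d\t.\t%s\t.\t%s",
            df$chrom, type, as.integer(df$start + 1), as.integer(df$end),
            df$strand, attr)
  }
  ga <- sprintf('gene_id "%s";', annotation$genes$gene_id)
  tx <- annotation$transcripts
  ta <- sprintf('gene_id "%s"; transcript_id "%s";%s', tx$gene_id,
                tx$transcript_id,
                ifelse(tx$principal, ' tag "appris_principal_1";', ""))
  tag_of <- function(ids) {
    ifelse(ids %in% tx$transcript_id[tx$principal],
           ' tag "appris_principal_1";', "")
  }
  sub_attr <- function(df) {
    sprintf('gene_id "%s"; transcript_id "%s";%s', df$gene_id,
            df$transcript_id, tag_of(df$transcript_id))
  }
  lines <- c(fmt(annotation$genes, "gene", ga),
             fmt(tx, "transcript", ta),
             fmt(annotation$exons, "exon", sub_attr(annotation$exons)))
  if (nrow(annotation$cds)) {
    lines <- c(lines, fmt(annotation$cds, "CDS", sub_attr(annotation$cds)))
  }
  if (nrow(annotation$utr5)) {
    lines <- c(lines, fmt(annotation$utr5, "five_prime_utr",
                          sub_attr(annotation$utr5)))
  }
  if (nrow(annotation$utr3)) {
    lines <- c(lines, fmt(annotation$utr3, "three_prime_utr",
                          sub_attr(annotation$utr3)))
  }
  writeLines(lines, path)
  invisible(path)
}
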
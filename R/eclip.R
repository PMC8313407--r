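#' Repeat-family eCLIP enrichment and relative information content
#'
#' The screen-selection statistic for nominating repeat-binding proteins:
#' per family and strand orientation, the fraction of eCLIP-library reads
#' assigned to the family is compared with the matching input-library
#' fraction. A Laplace pseudocount regularizes zero counts. Fold enrichment
#' is the ratio of the two (pseudocounted) fractions and relative
#' information content (RIC) is the eCLIP fraction multiplied by the log2
#' fold enrichment, so depleted families rank below zero.
#'
#' @param counts data.frame with columns family, strand ("sense"/
#'   "antisense"), eclip_reads, input_reads, eclip_total, input_total; one
#'   row per family and strand.
#' @param pseudocount Laplace pseudocount added per family (default 1 read).
#' @return The input with added columns p_eclip, p_input, fold_enrichment,
#'   ric, and rank (per strand, by decreasing RIC).
#' @examples
#' fc <- data.frame(family = c("Alu", "L1"), strand = "sense",
#'                  eclip_reads = c(1000, 100), input_reads = c(250, 300),
#'                  eclip_total = 10000, input_total = 10000)
#' family_enrichment(fc)
#' @export
family_enrichment <- function(counts, pseudocount = 1) {
  need <- c("family", "strand", "eclip_reads", "input_reads",
            "eclip_total", "input_total")
  if (!all(need %in% names(counts))) {
    stop("missing column(s): ", paste(setdiff(need, names(counts)), collapse = ", "))
  }
  if (any(counts$eclip_total <= 0) || any(counts$input_total <= 0)) {
    stop("library totals must be positive")
  }
  if (any(counts$eclip_reads > counts$eclip_total) ||
      any(counts$input_reads > counts$input_total)) {
    stop("family reads cannot exceed library totals")
  }
  out <- counts
  out$p_eclip <- out$p_input <- out$fold_enrichment <- out$ric <- NA_real_
  out$rank <- NA_integer_
  for (s in unique(counts$strand)) {
    i <- which(counts$strand == s)
    n_fam <- length(i)
    pe <- (counts$eclip_reads[i] + pseudocount) /
      (counts$eclip_total[i] + pseudocount * n_fam)
    pi_ <- (counts$input_reads[i] + pseudocount) /
      (counts$input_total[i] + pseudocount * n_fam)
    fe <- pe / pi_
    ric <- pe * log2(fe)
    out$p_eclip[i] <- pe
    out$p_input[i] <- pi_
    out$fold_enrichment[i] <- fe
    out$ric[i] <- ric
    out$rank[i] <- rank(-ric, ties.method = "first")
  }
  out[order(out$strand, out$rank), ]
}
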
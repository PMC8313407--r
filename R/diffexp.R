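#' Feature-level differential expression with gene-normalized library sizes
#'
#' Gene, intron and ECR counts are all normalized against gene-level library
#' sizes corrected by TMM normalization factors, filtered on mean log2-CPM
#' per feature class, and tested with an ordinary least-squares fit on the
#' treatment-means model with empirical variance moderation (per-feature
#' residual variances shrunk toward a moment-matched scaled-F prior).
#'
#' @name differential_expression_module
NULL

#' TMM normalization factors from gene counts
#'
#' Trimmed-mean-of-M-values factors computed on the gene-level count matrix
#' (the standard default procedure: reference sample by upper-quartile
#' fraction closest to the mean, 30%/5% trimming of M/A tails,
#' precision-weighted mean of remaining M values, factors scaled to
#' geometric mean 1).
#'
#' @param gene_counts genes x samples count matrix.
#' @return Named numeric vector of per-sample normalization factors.
#' @export
normalization_factors <- function(gene_counts) {
  if (ncol(gene_counts) < 2) stop("need at least 2 samples")
  if (any(colSums(gene_counts) <= 0)) stop("library sizes must be nonzero")
  f <- edgeR::calcNormFactors(gene_counts)
  names(f) <- colnames(gene_counts)
  f
}

#' log2-CPM against gene-level library sizes
#'
#' CPM uses the gene-level library size times the TMM factor as the
#' effective depth; 0.5 is added to counts before the log2 for
#' stabilization.
#'
#' @param counts features x samples matrix (any feature class).
#' @param lib_sizes per-sample gene-level library sizes.
#' @param norm_factors per-sample normalization factors.
#' @return log2-CPM matrix of the same shape.
#' @export
log2_cpm <- function(counts, lib_sizes, norm_factors = NULL) {
  if (is.null(norm_factors)) norm_factors <- rep(1, length(lib_sizes))
  eff <- lib_sizes * norm_factors
  log2(sweep(counts + 0.5, 2, eff, "/") * 1e6)
}

#' Expression filter on mean log2-CPM
#'
#' Retains features whose mean log2-CPM across all samples meets the
#' class-specific cutoff (0.5 genes, 1.0 introns, 4.5 ECRs); the boundary is
#' inclusive.
#'
#' @param counts features x samples matrix.
#' @param class one of "gene", "intron", "ECR".
#' @param lib_sizes,norm_factors gene-level effective depths.
#' @param params a [pipeline_params()] list.
#' @return Logical vector of retained features.
#' @export
filter_features <- function(counts, class, lib_sizes, norm_factors = NULL,
                            params = pipeline_params()) {
  cutoff <- switch(class,
                   gene = params$logcpm_cutoff_gene,
                   intron = params$logcpm_cutoff_intron,
                   ECR = params$logcpm_cutoff_ecr,
                   stop("unknown feature class: ", class))
  rowMeans(log2_cpm(counts, lib_sizes, norm_factors)) >= cutoff
}

# Moment-matched scaled-F prior for the variance hierarchy: if
# s2 ~ s0 * F(df, d0) then var(log s2) = trigamma(df/2) + trigamma(d0/2)
# and E[log s2] = log s0 + digamma(df/2) - log(df/2) - digamma(d0/2) +
# log(d0/2). Inverting these moments gives the prior (d0, s0).
estimate_variance_prior <- function(s2, df) {
  z <- log(pmax(s2, 1e-12))
  excess <- stats::var(z) - trigamma(df / 2)
  if (!is.finite(excess) || excess <= trigamma(1e3 / 2)) {
    d0 <- Inf
    s0 <- exp(mean(z) - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * stats::uniroot(function(x) trigamma(x) - excess,
                             lower = 1e-4, upper = 1e3)$root
    s0 <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0 = s0)
}

# OLS on the treatment-means model + empirical variance moderation:
# per-feature residual variances are shrunk toward a scaled-F prior whose
# degrees of freedom and scale are moment-matched on the observed
# variances ("auto"), or toward the global mean with a fixed prior df.
fit_treatment_means <- function(y, group, prior_df = "auto") {
  group <- factor(group)
  k <- nlevels(group)
  n <- ncol(y)
  if (n - k <= 0) stop("no residual degrees of freedom")
  sums <- t(rowsum(t(y), group))          # features x groups, level order
  gsize <- as.vector(table(group))
  means <- sweep(sums, 2, gsize, "/")
  fitted <- means[, as.integer(group), drop = FALSE]
  rss <- rowSums((y - fitted)^2)
  df <- n - k
  s2 <- rss / df
  if (identical(prior_df, "auto") && nrow(y) >= 10) {
    pr <- estimate_variance_prior(s2, df)
    d0 <- pr$d0
    s0 <- pr$s0
  } else {
    d0 <- if (identical(prior_df, "auto")) 4 else prior_df
    s0 <- mean(s2)
  }
  if (is.infinite(d0)) {
    s2_post <- rep(s0, length(s2))
    df_total <- 1e6
  } else {
    s2_post <- (d0 * s0 + df * s2) / (d0 + df)
    df_total <- d0 + df
  }
  list(means = means, gsize = stats::setNames(gsize, levels(group)),
       s2_post = s2_post, df_total = df_total, df_resid = df)
}

#' Differential expression between two treatment groups
#'
#' Response is log2-CPM; all treatments in the design contribute to the
#' per-feature residual variance ("treating each triplicate of samples as
#' independent conditions"); the named contrast is tested with a moderated
#' t-statistic (empirically moderated variance) and BH adjustment across the supplied features. The
#' regulated flag requires |log2FC| >= de_abs_log2fc and adjusted
#' p <= de_fdr.
#'
#' @param counts filtered features x samples matrix (one feature class).
#' @param design data.frame with sample_id and treatment columns matching
#'   the count columns.
#' @param contrast length-2 character c(reference, test); log2FC is
#'   test minus reference.
#' @param lib_sizes,norm_factors gene-level effective depths.
#' @param params a [pipeline_params()] list.
#' @param prior_df prior degrees of freedom for variance moderation:
#'   "auto" (default) moment-matches a scaled-F prior on the observed
#'   residual variances; a number fixes the prior df with the global mean
#'   variance as the prior value.
#' @return data.frame with feature_id, log2fc, t, p, p_adjust, regulated.
#' @export
differential_expression <- function(counts, design, contrast, lib_sizes,
                                    norm_factors = NULL,
                                    params = pipeline_params(),
                                    prior_df = "auto") {
  stopifnot(length(contrast) == 2)
  idx <- match(colnames(counts), design$sample_id)
  if (anyNA(idx)) stop("design must cover every count column")
  group <- design$treatment[idx]
  if (sum(group == contrast[1]) < 2 || sum(group == contrast[2]) < 2) {
    stop("each contrast group needs at least 2 samples")
  }
  y <- log2_cpm(counts, lib_sizes, norm_factors)
  fit <- fit_treatment_means(y, group, prior_df)
  a <- contrast[1]; b <- contrast[2]
  lfc <- fit$means[, b] - fit$means[, a]
  se <- sqrt(fit$s2_post * (1 / fit$gsize[[a]] + 1 / fit$gsize[[b]]))
  tstat <- lfc / se
  p <- 2 * stats::pt(abs(tstat), df = fit$df_total, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(feature_id = rownames(counts), log2fc = unname(lfc),
             t = unname(tstat), p = unname(p), p_adjust = padj,
             regulated = abs(lfc) >= params$de_abs_log2fc & padj <= params$de_fdr,
             stringsAsFactors = FALSE)
}

#' 2x2 factorial interaction test for interferon-stimulated genes
#'
#' For one day's samples with the four genotype groups (CTRL, hnRNPC single,
#' ADAR single, double KO), fits the classic interaction model in log2-CPM:
#' the interaction coefficient is (DKO - ADAR) - (hnRNPC - CTRL) in group
#' means, i.e. the departure of the double knockout from additivity of the
#' two single-knockout effects. The moderated test and BH adjustment run
#' across the supplied ISG feature set only.
#'
#' @param counts features x samples matrix restricted to the ISG set.
#' @param design data.frame with sample_id, hnRNPC ("WT"/"KO") and ADAR
#'   ("WT"/"KO") columns; all four genotype combinations must be present.
#' @param lib_sizes,norm_factors gene-level effective depths.
#' @param prior_df prior degrees of freedom for variance moderation
#'   ("auto" or a number, as in [differential_expression()]).
#' @return data.frame with feature_id, interaction (log2 units), t, p,
#'   p_adjust.
#' @export
interaction_test <- function(counts, design, lib_sizes, norm_factors = NULL,
                             prior_df = "auto") {
  idx <- match(colnames(counts), design$sample_id)
  if (anyNA(idx)) stop("design must cover every count column")
  geno <- paste(design$hnRNPC[idx], design$ADAR[idx], sep = "/")
  need <- c("WT/WT", "KO/WT", "WT/KO", "KO/KO")
  if (!all(need %in% geno)) {
    stop("missing genotype group(s): ", paste(setdiff(need, geno), collapse = ", "))
  }
  y <- log2_cpm(counts, lib_sizes, norm_factors)
  fit <- fit_treatment_means(y, geno, prior_df)
  m <- fit$means
  inter <- (m[, "KO/KO"] - m[, "WT/KO"]) - (m[, "KO/WT"] - m[, "WT/WT"])
  g <- fit$gsize
  se <- sqrt(fit$s2_post * (1 / g[["KO/KO"]] + 1 / g[["WT/KO"]] +
                            1 / g[["KO/WT"]] + 1 / g[["WT/WT"]]))
  tstat <- inter / se
  p <- 2 * stats::pt(abs(tstat), df = fit$df_total, lower.tail = FALSE)
  data.frame(feature_id = rownames(counts), interaction = unname(inter),
             t = unname(tstat), p = unname(p),
             p_adjust = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Intron-versus-gene fold-change decoupling
#'
#' Per intron, the difference between the intron's log2 fold change and its
#' host gene's, used to separate cis-dysregulated introns (intron RNA
#' accumulates without a matching gene-level change) from
#' transcription-driven ones. Introns with |delta| at or above
#' \code{delta_cutoff} are labelled "decoupled", the rest
#' "transcription-driven".
#'
#' @param intron_de DE table for introns (feature_id, log2fc, p_adjust).
#' @param gene_de DE table for genes.
#' @param intron_gene named character vector intron feature_id -> gene_id;
#'   every intron must map.
#' @param delta_cutoff |delta| boundary between the classes (log2 units,
#'   default 1).
#' @return data.frame with feature_id, gene_id, log2fc_intron, log2fc_gene,
#'   delta, class.
#' @export
intron_gene_decoupling <- function(intron_de, gene_de, intron_gene,
                                   delta_cutoff = 1) {
  gid <- intron_gene[intron_de$feature_id]
  if (anyNA(gid)) {
    stop("unmapped intron(s): ",
         paste(utils::head(intron_de$feature_id[is.na(gid)], 3), collapse = ", "))
  }
  gi <- match(gid, gene_de$feature_id)
  if (anyNA(gi)) stop("intron maps to gene without a gene-level result")
  delta <- intron_de$log2fc - gene_de$log2fc[gi]
  data.frame(feature_id = intron_de$feature_id, gene_id = unname(gid),
             log2fc_intron = intron_de$log2fc,
             log2fc_gene = gene_de$log2fc[gi], delta = delta,
             class = ifelse(abs(delta) >= delta_cutoff, "decoupled",
                            "transcription-driven"),
             stringsAsFactors = FALSE)
}

#' Select differentially regulated introns across per-day comparisons
#'
#' An intron qualifies when any per-day pairwise comparison shows fold
#' change at or above \code{min_fc} (absolute log2FC >= log2(min_fc)) with
#' adjusted p at or below \code{max_fdr}.
#'
#' @param de_tables list of per-day DE tables (same feature set).
#' @param min_fc fold-change floor (default 4).
#' @param max_fdr adjusted-p ceiling (default 0.01).
#' @return Logical vector over the features of the first table.
#' @export
select_regulated_introns <- function(de_tables, min_fc = 4, max_fdr = 0.01) {
  hit <- rep(FALSE, nrow(de_tables[[1]]))
  for (tab in de_tables) {
    hit <- hit | (abs(tab$log2fc) >= log2(min_fc) & tab$p_adjust <= max_fdr)
  }
  hit
}

#' Reads per kilobase per million (rpkm)
#'
#' rpkm = count * 1e9 / (library_size * norm_factor * length), with
#' gene-level library sizes for every feature class. The expression
#' predicate requires the per-condition mean rpkm to reach
#' \code{ecr_min_rpkm} in every condition.
#'
#' @param counts features x samples matrix.
#' @param lengths per-feature lengths in nt (> 0).
#' @param lib_sizes,norm_factors gene-level effective depths.
#' @return rpkm matrix.
#' @export
rpkm <- function(counts, lengths, lib_sizes, norm_factors = NULL) {
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  if (is.null(norm_factors)) norm_factors <- rep(1, length(lib_sizes))
  eff <- lib_sizes * norm_factors
  sweep(counts, 2, eff, "/") * 1e9 / lengths
}

#' Expressed-feature predicate on per-condition mean rpkm
#'
#' @param rpkm_mat rpkm matrix from [rpkm()].
#' @param condition_of named vector sample id -> condition.
#' @param min_rpkm floor applied to every condition mean (default 4).
#' @return Logical vector over features.
#' @export
expressed_in_all_conditions <- function(rpkm_mat, condition_of, min_rpkm = 4) {
  cond <- factor(condition_of[colnames(rpkm_mat)])
  sums <- t(rowsum(t(rpkm_mat), cond))    # features x conditions, level order
  means <- sweep(sums, 2, as.vector(table(cond)), "/")
  rowSums(means >= min_rpkm) == ncol(means)
}
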
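#' Simulation specification for the synthetic dataset
#'
#' Defines the study conditions the generator emulates: a 2x2 genotype
#' design (CTRL, hnRNPC single KO, ADAR single KO, double KO) sampled on
#' days 3-5 with three replicates, editing frequencies that collapse on ADAR
#' loss, hnRNPC-dependent intron up-regulation decoupled from gene
#' expression, interferon-stimulated genes with a synergy term only in the
#' double knockout, Alu-like repeats hosting planted editing clusters, and
#' hairpin secondary structures with known geometry.
#'
#' @param ... named overrides of the defaults listed below.
#' @details Key defaults: 200 genes of ~12 kb with 4 exons; Alu repeat
#'   density 0.3 of intronic bases; 20 editing clusters of 5-12 sites at
#'   mean coverage 100; editing frequency 0.30 in ADAR-WT arms (0.33 with
#'   hnRNPC loss, reflecting increased substrate) and 0.05 in ADAR-KO arms;
#'   negative-binomial dispersion 0.05 with library-size factors in
#'   [0.75, 1.3]; decoupled-intron effect 3 log2 units with gene effect 0;
#'   transcription-driven gene effect 1.5; ISG main effects 0.5/0.5 and
#'   interaction 2; splice-usage shift 0.4 toward the cryptic site;
#'   sequencing-error rate fixed at 0.005 per base.
#' @return A validated list of class \code{sim_spec}.
#' @export
sim_spec <- function(...) {
  defaults <- list(
    n_genes = 200,
    gene_length = 12600,
    exons_per_gene = 4,
    intergenic_gap = 8000,
    repeat_density = 0.3,
    inverted_fraction = 0.3,
    n_editing_clusters = 20,
    sites_per_cluster = c(5, 12),
    intergenic_cluster_fraction = 0.25,
    edit_freq_by_condition = c(CTRL = 0.30, hnRNPC = 0.33,
                               ADAR = 0.05, DKO = 0.05),
    site_coverage = 100,
    conditions = c("CTRL", "hnRNPC", "ADAR", "DKO"),
    days = c(3, 4, 5),
    replicates = 3,
    error_rate = 0.005,
    n_snps = 40,
    n_lowfreq_decoys = 30,
    n_callerfail_decoys = 10,
    n_small_clusters = 4,
    n_snp_decoys = 6,
    intron_effect = 3,
    gene_effect = 1.5,
    decoupled_fraction = 0.25,
    txdriven_fraction = 0.15,
    isg_fraction = 0.05,
    isg_main_hnrnpc = 0.5,
    isg_main_adar = 0.5,
    isg_interaction = 2,
    ecr_effect = 2,
    ecr_up_fraction = 0.5,
    nb_dispersion = 0.05,
    lib_factor_range = c(0.75, 1.3),
    gene_mean_range = c(50, 2000),
    intron_mean_range = c(20, 200),
    ecr_mean_range = c(50, 500),
    splice_depth = 300,
    splice_base_cryptic_use = 0.15,
    splice_usage_shift = 0.4,
    splice_shift_fraction = 0.4,
    n_structures = 60,
    seed = 1
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) stop("unknown sim_spec field(s): ", paste(bad, collapse = ", "))
    defaults[names(overrides)] <- overrides
  }
  s <- defaults
  fracs <- c(s$repeat_density, s$inverted_fraction, s$intergenic_cluster_fraction,
             s$edit_freq_by_condition, s$error_rate, s$decoupled_fraction,
             s$txdriven_fraction, s$isg_fraction, s$ecr_up_fraction,
             s$splice_base_cryptic_use, s$splice_shift_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  counts <- c(s$n_genes, s$gene_length, s$exons_per_gene, s$site_coverage,
              s$replicates)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (s$n_editing_clusters < 0) stop("all counts must be positive")
  if (!all(c("CTRL", "hnRNPC", "ADAR", "DKO") %in% s$conditions)) {
    stop("conditions must cover the 2x2 genotype design")
  }
  if (!all(names(s$edit_freq_by_condition) %in% s$conditions)) {
    stop("edit_freq_by_condition names must be conditions")
  }
  structure(s, class = "sim_spec")
}

#' Sample design table for a simulation specification
#'
#' @param spec a [sim_spec()].
#' @return data.frame with sample_id, condition, hnRNPC, ADAR, day,
#'   replicate and treatment (condition x day) columns.
#' @export
sim_design <- function(spec) {
  g <- expand.grid(replicate = seq_len(spec$replicates), day = spec$days,
                   condition = spec$conditions, stringsAsFactors = FALSE)
  g <- g[, c("condition", "day", "replicate")]
  data.frame(
    sample_id = sprintf("%s_d%d_r%d", g$condition, g$day, g$replicate),
    condition = g$condition,
    hnRNPC = ifelse(g$condition %in% c("hnRNPC", "DKO"), "KO", "WT"),
    ADAR = ifelse(g$condition %in% c("ADAR", "DKO"), "KO", "WT"),
    day = g$day, replicate = g$replicate,
    treatment = sprintf("%s_d%d", g$condition, g$day),
    stringsAsFactors = FALSE)
}

r_logunif <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

#' Generate the toy genome annotation with planted editing clusters
#'
#' Builds a single-chromosome annotation: genes with one principal
#' transcript each, alternating strand, regularly spaced exons, CDS/UTR
#' split, Alu-like repeats in introns (a fraction as inverted pairs) and
#' intergenic space, CLIP peaks within 50 nt of a subset of splice sites,
#' editing clusters planted inside Alu repeats plus several classes of
#' decoy sites, and SNP positions disjoint from planted editing sites
#' (except the deliberate SNP-decoy sites).
#'
#' @param spec a [sim_spec()].
#' @return list with \code{annotation} (a \code{tx_annotation}),
#'   \code{repeats}, \code{clip_peaks}, \code{snps} interval data.frames,
#'   and \code{truth} (list with \code{sites} and \code{clusters}).
#' @export
generate_annotation <- function(spec) {
  set.seed(spec$seed + 101L)
  E <- spec$exons_per_gene
  el <- floor(spec$gene_length / (2 * E - 1))
  gene_len <- (2 * E - 1) * el
  gap <- spec$intergenic_gap
  chrom <- "chrS"

  genes <- transcripts <- exons <- cds <- utr5 <- utr3 <- NULL
  introns_truth <- NULL
  for (g in seq_len(spec$n_genes)) {
    gid <- sprintf("gene%03d", g)
    tid <- sprintf("tx%03d", g)
    gs <- gap + (g - 1) * (gene_len + gap)
    ge <- gs + gene_len
    strand <- if (g %% 2 == 1) "+" else "-"
    genes <- rbind(genes, data.frame(chrom = chrom, start = gs, end = ge,
                                     strand = strand, gene_id = gid))
    transcripts <- rbind(transcripts, data.frame(
      chrom = chrom, start = gs, end = ge, strand = strand,
      transcript_id = tid, gene_id = gid, principal = TRUE))
    ex_starts <- gs + (0:(E - 1)) * 2 * el
    ex_ends <- ex_starts + el
    exons <- rbind(exons, data.frame(chrom = chrom, start = ex_starts,
                                     end = ex_ends, strand = strand,
                                     transcript_id = tid, gene_id = gid))
    in_starts <- ex_ends[-E]
    in_ends <- ex_starts[-1]
    ord <- if (strand == "-") rev(seq_len(E - 1)) else seq_len(E - 1)
    introns_truth <- rbind(introns_truth, data.frame(
      chrom = chrom, start = in_starts, end = in_ends, strand = strand,
      gene_id = gid, ordinal = ord))
    half <- floor(el / 2)
    if (strand == "+") {
      utr5 <- rbind(utr5, data.frame(chrom = chrom, start = gs,
                                     end = gs + half, strand = strand,
                                     transcript_id = tid, gene_id = gid))
      utr3 <- rbind(utr3, data.frame(chrom = chrom, start = ex_ends[E] - half,
                                     end = ex_ends[E], strand = strand,
                                     transcript_id = tid, gene_id = gid))
      cds_parts <- data.frame(start = c(gs + half, ex_starts[-1]),
                              end = c(ex_ends[1], ex_ends[-1]))
      cds_parts$end[E] <- ex_ends[E] - half
    } else {
      utr3 <- rbind(utr3, data.frame(chrom = chrom, start = gs,
                                     end = gs + half, strand = strand,
                                     transcript_id = tid, gene_id = gid))
      utr5 <- rbind(utr5, data.frame(chrom = chrom, start = ex_ends[E] - half,
                                     end = ex_ends[E], strand = strand,
                                     transcript_id = tid, gene_id = gid))
      cds_parts <- data.frame(start = c(gs + half, ex_starts[-1]),
                              end = c(ex_ends[1], ex_ends[-1]))
      cds_parts$end[E] <- ex_ends[E] - half
    }
    cds <- rbind(cds, data.frame(chrom = chrom, start = cds_parts$start,
                                 end = cds_parts$end, strand = strand,
                                 transcript_id = tid, gene_id = gid))
  }
  genome_end <- max(genes$end) + gap

  # Alu-like repeats inside introns; a fraction of multi-repeat introns as
  # inverted (opposite-strand) pairs
  alu_families <- c("AluSx", "AluY", "AluJb")
  other_families <- c("L1MA4", "MIRb", "L2a")
  rep_len <- 300
  repeats <- NULL
  if (spec$repeat_density > 0) {
    if (spec$repeat_density * (2 * E - 2) * el < 0 ||
        rep_len > el * spec$repeat_density * (E - 1) * 2 + rep_len) {
      # infeasibility handled below per intron
    }
    for (i in seq_len(nrow(introns_truth))) {
      len <- introns_truth$end[i] - introns_truth$start[i]
      n_alu <- floor(len * spec$repeat_density / rep_len)
      if (n_alu * rep_len > len) {
        stop("requested repeat density infeasible for gene geometry")
      }
      if (n_alu == 0) next
      slot <- floor(len / n_alu)
      starts <- introns_truth$start[i] + (0:(n_alu - 1)) * slot +
        floor((slot - rep_len) / 2)
      inverted <- n_alu >= 2 && stats::runif(1) < spec$inverted_fraction
      st <- if (inverted) rep(c("+", "-"), length.out = n_alu)
            else sample(c("+", "-"), n_alu, replace = TRUE)
      repeats <- rbind(repeats, data.frame(
        chrom = chrom, start = starts, end = starts + rep_len, strand = st,
        name = sample(alu_families, n_alu, replace = TRUE)))
    }
    # intergenic repeats: two Alus and one non-Alu per gap
    for (g in 0:spec$n_genes) {
      gap_start <- if (g == 0) 0 else genes$end[g]
      pos <- gap_start + c(1000, 2500, 5000)
      if (pos[3] + rep_len > gap_start + gap) next
      repeats <- rbind(repeats, data.frame(
        chrom = chrom, start = pos, end = pos + rep_len,
        strand = sample(c("+", "-"), 3, replace = TRUE),
        name = c(sample(alu_families, 2, replace = TRUE),
                 sample(other_families, 1))))
    }
    # non-Alu repeats in a subset of introns (between Alu slots)
    sub <- introns_truth[seq(1, nrow(introns_truth), by = 3), , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      s0 <- sub$start[i] + 10
      ok <- !any(repeats$start < s0 + 120 & repeats$end > s0)
      if (ok) {
        repeats <- rbind(repeats, data.frame(
          chrom = chrom, start = s0, end = s0 + 120,
          strand = sample(c("+", "-"), 1), name = sample(other_families, 1)))
      }
    }
  }
  if (is.null(repeats)) {
    repeats <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), strand = character(0),
                          name = character(0))
  }

  # CLIP peaks within clip_max_gap of a known subset of intron ends
  clip <- NULL
  for (i in seq_len(nrow(introns_truth))) {
    if (stats::runif(1) >= 0.5) next
    site <- introns_truth$end[i]
    d <- sample(0:40, 1)
    clip <- rbind(clip, data.frame(chrom = chrom, start = site + d,
                                   end = site + d + 30, strand = "."))
  }
  if (is.null(clip)) {
    clip <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), strand = character(0))
  }
  clip$name <- sprintf("clip_%03d", seq_len(nrow(clip)))

  # plant editing clusters inside Alu repeats
  if (nrow(repeats)) {
    is_alu <- startsWith(repeats$name, "Alu")
    in_intron <- vapply(repeats$start, function(s) {
      any(s >= introns_truth$start & s < introns_truth$end)
    }, logical(1))
    in_gene <- vapply(repeats$start, function(s) {
      any(s >= genes$start & s < genes$end)
    }, logical(1))
    intronic_alus <- which(is_alu & in_intron)
    intergenic_alus <- which(is_alu & !in_gene)
  } else {
    intronic_alus <- intergenic_alus <- integer(0)
  }
  n_intergenic <- round(spec$n_editing_clusters * spec$intergenic_cluster_fraction)
  n_intronic <- spec$n_editing_clusters - n_intergenic
  if (spec$n_editing_clusters > 0 &&
      (length(intronic_alus) < n_intronic ||
       length(intergenic_alus) < n_intergenic)) {
    stop("not enough Alu repeats to host the requested editing clusters")
  }
  anchors <- c(sample(intronic_alus, n_intronic),
               sample(intergenic_alus, n_intergenic))
  context <- c(rep("intronic", n_intronic), rep("intergenic", n_intergenic))

  sites <- NULL
  clusters <- NULL
  freqs <- spec$edit_freq_by_condition
  for (ci in seq_along(anchors)) {
    a <- anchors[ci]
    k <- sample(seq(spec$sites_per_cluster[1], spec$sites_per_cluster[2]), 1)
    gaps <- sample(8:25, k - 1, replace = TRUE)
    pos <- repeats$start[a] + 5 + cumsum(c(0, gaps))
    strand <- if (context[ci] == "intronic") {
      gidx <- which(genes$start <= repeats$start[a] & genes$end > repeats$start[a])
      genes$strand[gidx[1]]
    } else repeats$strand[a]
    cl_id <- sprintf("true_cl_%02d", ci)
    gid <- if (context[ci] == "intronic") {
      gidx <- which(genes$start <= repeats$start[a] & genes$end > repeats$start[a])
      genes$gene_id[gidx[1]]
    } else NA_character_
    sites <- rbind(sites, data.frame(
      chrom = chrom, pos = pos, strand = strand, cluster_id = cl_id,
      kind = "edited",
      freq_CTRL = freqs[["CTRL"]], freq_hnRNPC = freqs[["hnRNPC"]],
      freq_ADAR = freqs[["ADAR"]], freq_DKO = freqs[["DKO"]],
      stringsAsFactors = FALSE))
    clusters <- rbind(clusters, data.frame(
      cluster_id = cl_id, chrom = chrom, start = min(pos), end = max(pos) + 1,
      strand = strand, n_sites = k, context = context[ci], gene_id = gid,
      stringsAsFactors = FALSE))
  }

  # decoy sites: placed in intergenic space away from planted clusters
  used <- if (is.null(sites)) numeric(0) else sites$pos
  place_away <- function(n, min_dist = 150) {
    out <- numeric(0)
    tries <- 0
    while (length(out) < n && tries < 50000) {
      tries <- tries + 1
      p <- floor(stats::runif(1, 100, genome_end - 100))
      if (all(abs(p - used) > min_dist) &&
          (length(out) == 0 || all(abs(p - out) > min_dist))) {
        out <- c(out, p)
      }
    }
    if (length(out) < n) stop("could not place decoy sites")
    used <<- c(used, out)
    out
  }
  decoy <- function(n, kind, freq) {
    if (n == 0) return(NULL)
    data.frame(chrom = chrom, pos = place_away(n),
               strand = sample(c("+", "-"), n, replace = TRUE),
               cluster_id = NA_character_, kind = kind,
               freq_CTRL = freq, freq_hnRNPC = freq,
               freq_ADAR = freq, freq_DKO = freq, stringsAsFactors = FALSE)
  }
  sites <- rbind(sites,
                 decoy(spec$n_lowfreq_decoys, "lowfreq", 0.01),
                 decoy(spec$n_callerfail_decoys, "callerfail", 0.30),
                 decoy(spec$n_snp_decoys, "snpdecoy", 0.50))
  # small clusters that pass the site filters but fail the >=5-site rule
  for (ci in seq_len(spec$n_small_clusters)) {
    p0 <- place_away(1, min_dist = 400)
    pos <- p0 + c(0, 30, 60)
    used <- c(used, pos)
    sites <- rbind(sites, data.frame(
      chrom = chrom, pos = pos, strand = "+",
      cluster_id = sprintf("small_cl_%02d", ci), kind = "smallcluster",
      freq_CTRL = 0.30, freq_hnRNPC = 0.30, freq_ADAR = 0.30, freq_DKO = 0.30,
      stringsAsFactors = FALSE))
  }
  sites$site_id <- sprintf("site_%04d", seq_len(nrow(sites)))

  # SNPs: deliberate overlap with snpdecoy sites, otherwise disjoint from
  # every planted site
  snp_pos <- sites$pos[sites$kind == "snpdecoy"]
  n_rand <- max(0, spec$n_snps - length(snp_pos))
  if (n_rand > 0) snp_pos <- c(snp_pos, place_away(n_rand, min_dist = 5))
  snps <- data.frame(chrom = chrom, start = sort(snp_pos),
                     end = sort(snp_pos) + 1, strand = ".")

  annotation <- structure(list(genes = genes, transcripts = transcripts,
                               exons = exons, cds = cds, utr5 = utr5,
                               utr3 = utr3),
                          class = "tx_annotation")
  list(annotation = annotation, repeats = repeats, clip_peaks = clip,
       snps = snps,
       truth = list(sites = sites, clusters = clusters,
                    introns = introns_truth))
}

#' Generate per-sample pileup tables for the planted sites
#'
#' At each site and sample, coverage is Poisson around the mean site
#' coverage, the edited-base count binomial at the site's true frequency
#' for the sample's condition, and each of the two non-participating bases
#' receives a small binomial sequencing-error count. Base identities are
#' strand-correct: A reference/G edit on sense sites, T reference/C edit
#' (genome space) on antisense sites. Caller score and pass columns are
#' simulated above or below the score threshold according to the site's
#' planted caller flag.
#'
#' @param spec a [sim_spec()].
#' @param truth_sites the \code{truth$sites} table from
#'   [generate_annotation()].
#' @param design from [sim_design()].
#' @return list with \code{pileups} (long data.frame over samples) and
#'   \code{truth_sites} passed through.
#' @export
generate_pileups <- function(spec, truth_sites, design = sim_design(spec)) {
  set.seed(spec$seed + 202L)
  n <- nrow(truth_sites)
  out <- vector("list", nrow(design))
  for (si in seq_len(nrow(design))) {
    cond <- design$condition[si]
    freq <- truth_sites[[paste0("freq_", cond)]]
    cov <- stats::rpois(n, spec$site_coverage)
    edit <- stats::rbinom(n, cov, freq)
    e1 <- stats::rbinom(n, cov, spec$error_rate)
    e2 <- stats::rbinom(n, cov, spec$error_rate)
    sense <- truth_sites$strand == "+"
    A <- ifelse(sense, cov - edit, e1)
    G <- ifelse(sense, edit, e2)
    T_ <- ifelse(sense, e1, cov - edit)
    C <- ifelse(sense, e2, edit)
    fail <- truth_sites$kind == "callerfail"
    score <- ifelse(fail, stats::runif(n, 0.05, 0.45),
                    stats::runif(n, 0.55, 1))
    out[[si]] <- data.frame(
      sample_id = design$sample_id[si], chrom = truth_sites$chrom,
      pos = truth_sites$pos, strand = truth_sites$strand,
      A = A, C = C, G = G, T = T_,
      caller_score = round(score, 4), caller_pass = !fail,
      stringsAsFactors = FALSE)
  }
  list(pileups = do.call(rbind, out), truth_sites = truth_sites)
}

#' Negative-binomial count matrix with planted log2 effects
#'
#' The count engine behind [generate_counts()]: counts are drawn
#' independently as NB(mean, dispersion) where the mean is the per-feature
#' baseline times 2^(planted log2 fold change for the sample's group) times
#' the sample's library-size factor.
#'
#' @param base_mean per-feature baseline means.
#' @param lfc features x samples matrix of planted log2 fold changes (0 =
#'   baseline).
#' @param lib_factors per-sample library-size multipliers.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   values <= 1e-8 give Poisson draws.
#' @return Integer matrix of counts.
#' @export
simulate_count_matrix <- function(base_mean, lfc, lib_factors,
                                  dispersion = 0.05) {
  n <- length(base_mean)
  m <- length(lib_factors)
  stopifnot(nrow(lfc) == n, ncol(lfc) == m)
  mu <- base_mean * 2^lfc * rep(lib_factors, each = n)
  if (dispersion <= 1e-8) {
    cnt <- stats::rpois(n * m, mu)
  } else {
    cnt <- stats::rnbinom(n * m, mu = mu, size = 1 / dispersion)
  }
  matrix(cnt, n, m, dimnames = dimnames(lfc))
}

#' Generate count matrices, splice-cluster tables and their planted truth
#'
#' Gene counts carry three planted classes: interferon-stimulated genes
#' (main effects for each single knockout plus an interaction term only in
#' the double knockout), transcription-driven genes (equal gene and intron
#' effects in hnRNPC-deficient arms), and null genes. Introns of
#' transcription-driven genes follow their gene; a fraction of null genes
#' contribute one decoupled intron each (intron effect with zero gene
#' effect). ECR features derive from the planted editing clusters
#' (padded and merged); a fraction is up-regulated in hnRNPC-deficient
#' arms. Splice-cluster tables pair a canonical intron with a cryptic
#' shorter intron ending inside an Alu element where available; planted
#' clusters shift relative usage toward the cryptic site in
#' hnRNPC-deficient samples.
#'
#' @param spec a [sim_spec()].
#' @param ann result of [generate_annotation()].
#' @param design from [sim_design()].
#' @return list with count matrices (\code{gene_counts},
#'   \code{intron_counts}, \code{ecr_counts}), feature tables with lengths,
#'   \code{splice} (introns + counts), \code{lib_factors}, and \code{truth}
#'   (genes, introns, isg, ecrs, splice).
#' @export
generate_counts <- function(spec, ann, design = sim_design(spec)) {
  set.seed(spec$seed + 303L)
  genes <- ann$annotation$genes
  introns <- ann$truth$introns
  ns <- nrow(design)
  hn_ko <- design$condition %in% c("hnRNPC", "DKO")
  ad_ko <- design$condition %in% c("ADAR", "DKO")
  lib_factors <- stats::runif(ns, spec$lib_factor_range[1],
                              spec$lib_factor_range[2])
  names(lib_factors) <- design$sample_id

  # gene classes
  ng <- nrow(genes)
  n_isg <- max(1, round(ng * spec$isg_fraction))
  n_tx <- round(ng * spec$txdriven_fraction)
  cls <- rep("null", ng)
  ord <- sample(ng)
  cls[ord[seq_len(n_isg)]] <- "isg"
  cls[ord[n_isg + seq_len(n_tx)]] <- "txdriven"
  gene_lfc <- matrix(0, ng, ns, dimnames = list(genes$gene_id, design$sample_id))
  isg_i <- which(cls == "isg")
  gene_lfc[isg_i, ] <- rep(spec$isg_main_hnrnpc * hn_ko +
                             spec$isg_main_adar * ad_ko +
                             spec$isg_interaction * (hn_ko & ad_ko),
                           each = length(isg_i))
  tx_i <- which(cls == "txdriven")
  gene_lfc[tx_i, ] <- rep(spec$gene_effect * hn_ko, each = length(tx_i))
  gene_base <- r_logunif(ng, spec$gene_mean_range)
  gene_counts <- simulate_count_matrix(gene_base, gene_lfc, lib_factors,
                                       spec$nb_dispersion)
  truth_genes <- data.frame(gene_id = genes$gene_id, class = cls,
                            base_mean = gene_base,
                            lfc_hnrnpc = gene_lfc[, match(
                              sprintf("hnRNPC_d%d_r1", spec$days[1]),
                              design$sample_id)],
                            stringsAsFactors = FALSE)
  truth_isg <- data.frame(gene_id = genes$gene_id[isg_i],
                          main_hnrnpc = rep(spec$isg_main_hnrnpc, length(isg_i)),
                          main_adar = rep(spec$isg_main_adar, length(isg_i)),
                          interaction = rep(spec$isg_interaction, length(isg_i)),
                          stringsAsFactors = FALSE)

  # intron features
  introns$feature_id <- sprintf("%s_intron%d", introns$gene_id, introns$ordinal)
  ni <- nrow(introns)
  icls <- rep("null", ni)
  icls[introns$gene_id %in% genes$gene_id[tx_i]] <- "txdriven"
  null_genes <- genes$gene_id[cls == "null"]
  n_dec <- round(ng * spec$decoupled_fraction)
  dec_genes <- sample(null_genes, min(n_dec, length(null_genes)))
  dec_pick <- vapply(dec_genes, function(g) {
    sample(which(introns$gene_id == g), 1)
  }, integer(1))
  icls[dec_pick] <- "decoupled"
  intron_lfc <- matrix(0, ni, ns,
                       dimnames = list(introns$feature_id, design$sample_id))
  for (i in which(icls == "txdriven")) {
    intron_lfc[i, ] <- spec$gene_effect * hn_ko
  }
  for (i in which(icls == "decoupled")) {
    intron_lfc[i, ] <- spec$intron_effect * hn_ko
  }
  intron_base <- r_logunif(ni, spec$intron_mean_range)
  intron_counts <- simulate_count_matrix(intron_base, intron_lfc, lib_factors,
                                         spec$nb_dispersion)
  truth_introns <- data.frame(feature_id = introns$feature_id,
                              gene_id = introns$gene_id, class = icls,
                              intron_lfc = spec$intron_effect * (icls == "decoupled") +
                                spec$gene_effect * (icls == "txdriven"),
                              gene_lfc = spec$gene_effect * (icls == "txdriven"),
                              stringsAsFactors = FALSE)
  truth_introns$delta <- truth_introns$intron_lfc - truth_introns$gene_lfc

  # ECR features from planted clusters
  cl <- ann$truth$clusters
  cl$cluster_id <- cl$cluster_id
  ecr <- build_ecrs(cl[, c("chrom", "start", "end", "strand", "cluster_id")],
                    pipeline_params())
  ecrs <- ecr$ecrs
  ne <- nrow(ecrs)
  up <- sample(c(TRUE, FALSE), ne, replace = TRUE,
               prob = c(spec$ecr_up_fraction, 1 - spec$ecr_up_fraction))
  ecr_lfc <- matrix(0, ne, ns, dimnames = list(ecrs$ecr_id, design$sample_id))
  ecr_lfc[up, ] <- rep(spec$ecr_effect * hn_ko, each = sum(up))
  ecr_base <- r_logunif(ne, spec$ecr_mean_range)
  ecr_counts <- simulate_count_matrix(ecr_base, ecr_lfc, lib_factors,
                                      spec$nb_dispersion)
  truth_ecrs <- cbind(ecrs[, c("ecr_id", "chrom", "start", "end")],
                      data.frame(up_in_hnrnpc_ko = up,
                                 lfc = spec$ecr_effect * up))

  # splice clusters: canonical + cryptic intron per eligible gene
  repeats <- ann$repeats
  alu <- repeats[startsWith(repeats$name, "Alu"), , drop = FALSE]
  sp_rows <- NULL
  sp_truth <- NULL
  cl_counts <- NULL
  cl_n <- 0
  for (g in seq_len(ng)) {
    gin <- introns[introns$gene_id == genes$gene_id[g], , drop = FALSE]
    if (nrow(gin) == 0) next
    # prefer an intron hosting an Alu for the cryptic end
    host <- NA_integer_
    for (i in seq_len(nrow(gin))) {
      hit <- which(alu$start >= gin$start[i] & alu$end <= gin$end[i])
      if (length(hit)) { host <- i; alu_mid <- floor((alu$start[hit[1]] + alu$end[hit[1]]) / 2); break }
    }
    has_alu <- !is.na(host)
    if (!has_alu) { host <- 1; alu_mid <- floor((gin$start[1] + gin$end[1]) / 2) }
    cl_n <- cl_n + 1
    clu <- sprintf("clu_%d", cl_n)
    canonical <- c(gin$start[host], gin$end[host])
    cryptic <- c(gin$start[host], alu_mid)
    shifted <- has_alu && stats::runif(1) < spec$splice_shift_fraction
    base_p <- c(1 - spec$splice_base_cryptic_use, spec$splice_base_cryptic_use)
    shift_p <- c(1 - spec$splice_base_cryptic_use - spec$splice_usage_shift,
                 spec$splice_base_cryptic_use + spec$splice_usage_shift)
    tot <- stats::rpois(ns, spec$splice_depth)
    cnt <- vapply(seq_len(ns), function(s) {
      p <- if (shifted && hn_ko[s]) shift_p else base_p
      stats::rmultinom(1, tot[s], p)[, 1]
    }, numeric(2))
    keys <- sprintf("%s:%d:%d:%s", gin$chrom[host],
                    c(canonical[1], cryptic[1]),
                    c(canonical[2], cryptic[2]), clu)
    sp_rows <- rbind(sp_rows, data.frame(key = keys, stringsAsFactors = FALSE))
    cl_counts <- rbind(cl_counts, cnt)
    sp_truth <- rbind(sp_truth, data.frame(
      cluster_id = clu, gene_id = genes$gene_id[g], shifted = shifted,
      alu_class = has_alu, cryptic_end = cryptic[2],
      stringsAsFactors = FALSE))
  }
  colnames(cl_counts) <- design$sample_id
  rownames(cl_counts) <- sp_rows$key

  gene_features <- data.frame(feature_id = genes$gene_id,
                              length = genes$end - genes$start)
  intron_features <- data.frame(feature_id = introns$feature_id,
                                length = introns$end - introns$start)
  ecr_features <- data.frame(feature_id = ecrs$ecr_id,
                             length = ecrs$end - ecrs$start)

  list(gene_counts = gene_counts, intron_counts = intron_counts,
       ecr_counts = ecr_counts, gene_features = gene_features,
       intron_features = intron_features, ecr_features = ecr_features,
       intron_gene = stats::setNames(introns$gene_id, introns$feature_id),
       splice_counts = cl_counts, lib_factors = lib_factors,
       ecr_membership = ecr$membership,
       truth = list(genes = truth_genes, introns = truth_introns,
                    isg = truth_isg, ecrs = truth_ecrs, splice = sp_truth))
}

#' Construct a hairpin dot-bracket structure with known metrics
#'
#' Helix runs are interleaved with symmetric interior loops and closed by a
#' terminal loop, so the truth metrics (total length, mismatch fraction,
#' longest uninterrupted helix) follow directly from the geometry.
#'
#' @param helix_lengths base pairs per helix segment, 5' to 3' (all >= 1).
#' @param interior_loops unpaired nucleotides per arm between consecutive
#'   helix segments (length \code{length(helix_lengths) - 1}, all >= 1).
#' @param terminal_loop unpaired nucleotides in the terminal loop (>= 3).
#' @return list with \code{dot_bracket} and truth \code{total_length},
#'   \code{mismatch_fraction}, \code{longest_helix}.
#' @examples
#' construct_hairpin(40)$dot_bracket
#' @export
construct_hairpin <- function(helix_lengths, interior_loops = NULL,
                              terminal_loop = 4) {
  k <- length(helix_lengths)
  if (is.null(interior_loops)) interior_loops <- rep(2, max(0, k - 1))
  if (length(interior_loops) != k - 1 ||
      any(helix_lengths < 1) || any(interior_loops < 1) || terminal_loop < 3) {
    stop("inconsistent hairpin geometry")
  }
  left <- right <- character(0)
  for (i in seq_len(k)) {
    left <- c(left, strrep("(", helix_lengths[i]),
              if (i < k) strrep(".", interior_loops[i]))
    right <- c(if (i < k) strrep(".", interior_loops[i]),
               strrep(")", helix_lengths[i]), right)
  }
  db <- paste0(paste(left, collapse = ""), strrep(".", terminal_loop),
               paste(right, collapse = ""))
  total <- 2 * sum(helix_lengths) + 2 * sum(interior_loops) + terminal_loop
  dots <- 2 * sum(interior_loops) + terminal_loop
  list(dot_bracket = db, total_length = total,
       mismatch_fraction = dots / total,
       longest_helix = as.integer(max(helix_lengths)))
}

#' Generate hairpin structures with planted metrics
#'
#' Half of the records emulate MDA5-ligand-like stretches (long, low
#' mismatch fraction, at least one helix of 37 bp or more) and half short
#' or loosely paired hairpins.
#'
#' @param spec a [sim_spec()].
#' @return list with \code{records} (id, dot_bracket) and \code{truth}
#'   (id, total_length, mismatch_fraction, longest_helix, ligand_like
#'   geometry class).
#' @export
generate_structures <- function(spec) {
  set.seed(spec$seed + 404L)
  n <- spec$n_structures
  recs <- truth <- NULL
  for (i in seq_len(n)) {
    ligandish <- i <= ceiling(n / 2)
    if (ligandish) {
      k <- sample(3:6, 1)
      h <- sample(25:80, k, replace = TRUE)
      il <- sample(1:3, k - 1, replace = TRUE)
    } else {
      k <- sample(1:3, 1)
      h <- sample(4:20, k, replace = TRUE)
      il <- if (k > 1) sample(3:9, k - 1, replace = TRUE) else integer(0)
    }
    hp <- construct_hairpin(h, il, terminal_loop = 4)
    id <- sprintf("hp_%03d", i)
    recs <- rbind(recs, data.frame(id = id, dot_bracket = hp$dot_bracket,
                                   stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(
      id = id, total_length = hp$total_length,
      mismatch_fraction = hp$mismatch_fraction,
      longest_helix = hp$longest_helix, geometry = ifelse(ligandish,
        "ligand-like", "short"), stringsAsFactors = FALSE))
  }
  list(records = recs, truth = truth)
}

#' Generate per-repeat-family eCLIP count tables with planted enrichment
#'
#' Alu families are enriched in the eCLIP library relative to input on the
#' antisense strand (the orientation bound by hnRNPC-like U-rich-tract
#' binders); other families are drawn near parity.
#'
#' @param spec a [sim_spec()].
#' @param n_families families per strand (default 20).
#' @param alu_enrichment planted fold enrichment of Alu families (default 4).
#' @return data.frame in the [family_enrichment()] input layout plus a
#'   \code{planted_fe} truth column.
#' @export
generate_family_counts <- function(spec, n_families = 20, alu_enrichment = 4) {
  set.seed(spec$seed + 505L)
  fams <- c("Alu", "AluYa5", "L1", "MIR", "L2", "ERVL", "hAT", "7SLRNA",
            sprintf("fam%02d", seq_len(max(0, n_families - 8))))[seq_len(n_families)]
  out <- NULL
  for (s in c("sense", "antisense")) {
    base_p <- as.vector(stats::rmultinom(1, 1e6, rep(1, n_families))) / 1e6
    fe <- rep(1, n_families)
    if (s == "antisense") fe[startsWith(fams, "Alu")] <- alu_enrichment
    w <- base_p * fe
    p_eclip <- w / sum(w)
    eclip <- as.vector(stats::rmultinom(1, 2e5, p_eclip))
    input <- as.vector(stats::rmultinom(1, 2e5, base_p))
    out <- rbind(out, data.frame(
      family = fams, strand = s, eclip_reads = eclip, input_reads = input,
      eclip_total = sum(eclip), input_total = sum(input),
      planted_fe = fe / sum(base_p * fe) * 1, stringsAsFactors = FALSE))
  }
  out
}

#' Generate and write the complete synthetic dataset
#'
#' Runs every generator with the spec's seed and writes all pipeline inputs
#' and the planted-truth tables under \code{dir}. Identical spec and seed
#' reproduce byte-identical files.
#'
#' @param spec a [sim_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the in-memory dataset (annotation, counts, truth, ...).
#' @export
generate_dataset <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pileups"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  design <- sim_design(spec)
  ann <- generate_annotation(spec)
  pil <- generate_pileups(spec, ann$truth$sites, design)
  cnt <- generate_counts(spec, ann, design)
  str <- generate_structures(spec)
  fam <- generate_family_counts(spec)

  tsv <- function(df, path) {
    utils::write.table(format_num_df(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_gtf(ann$annotation, file.path(dir, "annotation.gtf"))
  write_bed(ann$repeats, file.path(dir, "repeats.bed"))
  write_bed(ann$clip_peaks, file.path(dir, "clip_peaks.bed"))
  write_bed(ann$snps, file.path(dir, "snps.bed"), bed3 = TRUE)
  tsv(design, file.path(dir, "design.tsv"))
  for (s in design$sample_id) {
    sub <- pil$pileups[pil$pileups$sample_id == s,
                       c("chrom", "pos", "strand", "A", "C", "G", "T",
                         "caller_score", "caller_pass")]
    tsv(sub, file.path(dir, "pileups", paste0(s, ".tsv")))
  }
  counts_tsv <- function(mat, features, path) {
    df <- data.frame(feature_id = rownames(mat),
                     length = features$length[match(rownames(mat),
                                                    features$feature_id)],
                     mat, check.names = FALSE, stringsAsFactors = FALSE)
    tsv(df, path)
  }
  counts_tsv(cnt$gene_counts, cnt$gene_features, file.path(dir, "gene_counts.tsv"))
  counts_tsv(cnt$intron_counts, cnt$intron_features,
             file.path(dir, "intron_counts.tsv"))
  counts_tsv(cnt$ecr_counts, cnt$ecr_features, file.path(dir, "ecr_counts.tsv"))
  utils::write.table(cnt$splice_counts, file.path(dir, "splice_counts.txt"),
                     sep = " ", quote = FALSE, col.names = NA)
  writeLines(sprintf(">%s\n%s", str$records$id, str$records$dot_bracket),
             file.path(dir, "structures.txt"))
  tsv(fam, file.path(dir, "family_counts.tsv"))
  writeLines(cnt$truth$isg$gene_id, file.path(dir, "isg_set.txt"))

  tsv(ann$truth$sites, file.path(dir, "truth", "sites.tsv"))
  tsv(ann$truth$clusters, file.path(dir, "truth", "clusters.tsv"))
  tsv(cnt$truth$genes, file.path(dir, "truth", "genes.tsv"))
  tsv(cnt$truth$introns, file.path(dir, "truth", "introns.tsv"))
  tsv(cnt$truth$isg, file.path(dir, "truth", "isg.tsv"))
  tsv(cnt$truth$ecrs, file.path(dir, "truth", "ecrs.tsv"))
  tsv(cnt$truth$splice, file.path(dir, "truth", "splice.tsv"))
  tsv(str$truth, file.path(dir, "truth", "structures.tsv"))

  invisible(list(spec = spec, design = design, annotation = ann, pileups = pil,
                 counts = cnt, structures = str, family_counts = fam,
                 dir = dir))
}
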
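#' Read and validate a pipeline run configuration
#'
#' The configuration (a YAML file or an equivalent list) names the input
#' files per stage, the output directory, the random seed, the stages to
#' run and any pipeline-parameter overrides. Unknown keys anywhere are
#' rejected; the resolved configuration is echoed verbatim to the run log.
#'
#' @param config path to a YAML file, or a list.
#' @return A validated list of class \code{run_config}.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("output_dir", "seed", "stages", "params", "inputs")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(config$output_dir)) stop("config requires output_dir")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$stages) || identical(config$stages, "all")) {
    config$stages <- PIPELINE_STAGES
  }
  if (length(config$stages) == 0) stop("stage list must not be empty")
  unknown_stage <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(unknown_stage)) {
    stop("unknown stage(s): ", paste(unknown_stage, collapse = ", "))
  }
  known_inputs <- c("gtf", "repeats", "clip_peaks", "snps", "pileup_dir",
                    "design", "gene_counts", "intron_counts", "ecr_counts",
                    "splice_counts", "splice_significance", "splice_effects",
                    "structures", "isg_set", "family_counts")
  bad_in <- setdiff(names(config$inputs), known_inputs)
  if (length(bad_in)) stop("unknown input key(s): ", paste(bad_in, collapse = ", "))
  config$params <- do.call(pipeline_params, as.list(config$params))
  structure(config, class = "run_config")
}

PIPELINE_STAGES <- c("annotate", "editing", "ecr", "splicing", "diffexp",
                     "structure", "eclip", "report")

# inputs each stage requires
STAGE_INPUTS <- list(
  annotate = c("gtf", "repeats"),
  editing = c("pileup_dir", "design", "snps"),
  ecr = character(0),
  splicing = c("splice_counts", "design", "repeats"),
  diffexp = c("gene_counts", "intron_counts", "ecr_counts", "design", "isg_set"),
  structure = "structures",
  eclip = "family_counts",
  report = character(0)
)
STAGE_DEPS <- list(annotate = character(0), editing = "annotate",
                   ecr = "editing", splicing = "annotate",
                   diffexp = character(0), structure = character(0),
                   eclip = character(0),
                   report = character(0))

write_stage_table <- function(df, path, stage, params, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ecrscan stage=%s seed=%d", stage, as.integer(seed)), con)
  writeLines(paste0("# params: ",
                    paste(sprintf("%s=%s", names(params),
                                  vapply(params, format_num, character(1))),
                          collapse = " ")), con)
  utils::write.table(format_num_df(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_counts_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  lengths <- stats::setNames(df$length, df$feature_id)
  mat <- as.matrix(df[, setdiff(names(df), c("feature_id", "length")),
                      drop = FALSE])
  rownames(mat) <- df$feature_id
  list(counts = mat, lengths = lengths)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (annotate, editing,
#' ecr, splicing, diffexp, structure, eclip, report), writing one or more
#' TSV tables per stage into the output directory. Every table carries the
#' stage name, seed and full parameter set in header comments; re-running
#' with the same configuration and seed reproduces byte-identical tables.
#'
#' @param config a \code{run_config} (or path/list accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% config$stages]
  params <- config$params
  seed <- as.integer(config$seed)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)

  # missing inputs and unmet stage dependencies are configuration errors
  for (st in stages) {
    missing <- setdiff(STAGE_INPUTS[[st]], names(config$inputs))
    if (length(missing)) {
      stop("stage '", st, "' requires input(s): ",
           paste(missing, collapse = ", "))
    }
    for (f in STAGE_INPUTS[[st]]) {
      p <- config$inputs[[f]]
      if (!file.exists(p)) {
        stop("stage '", st, "': input file not found: ", p)
      }
    }
    dep <- setdiff(STAGE_DEPS[[st]], stages)
    if (length(dep)) {
      stop("stage '", st, "' requires upstream stage(s): ",
           paste(dep, collapse = ", "))
    }
  }

  log_path <- file.path(out_dir, "run.log")
  logf <- file(log_path, "w")
  on.exit(close(logf))
  say <- function(...) writeLines(paste0(...), logf)
  say("ecrscan pipeline run")
  say("seed: ", seed)
  say("stages: ", paste(stages, collapse = ", "))
  say("resolved config:")
  for (k in names(params)) say("  param ", k, " = ", format_num(params[[k]]))
  for (k in names(config$inputs)) say("  input ", k, " = ", config$inputs[[k]])

  res <- list()
  emit <- function(df, name, stage) {
    write_stage_table(df, file.path(out_dir, name), stage, params, seed)
  }

  if ("annotate" %in% stages) {
    ann <- read_annotation(config$inputs$gtf)
    introns <- derive_introns(ann)
    repeats <- read_bed(config$inputs$repeats)
    res$annotation <- ann
    res$introns <- introns
    res$repeats <- repeats
    emit(introns, "introns.tsv", "annotate")
    say("annotate: ", nrow(ann$genes), " genes, ", nrow(introns), " introns")
  }

  if ("editing" %in% stages) {
    design <- utils::read.table(config$inputs$design, header = TRUE, sep = "\t",
                                comment.char = "#", stringsAsFactors = FALSE)
    res$design <- design
    pf <- list.files(config$inputs$pileup_dir, pattern = "\\.tsv$",
                     full.names = TRUE)
    pile <- do.call(rbind, lapply(pf, function(p) {
      d <- utils::read.table(p, header = TRUE, sep = "\t", comment.char = "#",
                             stringsAsFactors = FALSE)
      d$sample_id <- sub("\\.tsv$", "", basename(p))
      d
    }))
    snps <- read_bed(config$inputs$snps)
    sites <- build_editing_sites(pile, sample_ids = design$sample_id,
                                 snp_positions = snps)
    wt <- design$sample_id[design$ADAR == "WT"]
    sites1 <- primary_site_filter(sites, wt, params)
    sites2 <- secondary_site_filter(sites1, design, params)
    fin <- finalize_clusters(sites2, params)
    res$sites <- fin$sites
    res$clusters <- fin$clusters
    res$site_cluster <- fin$site_cluster
    site_tab <- cbind(fin$sites$meta,
                      data.frame(cluster_id = fin$site_cluster,
                                 mean_frequency = rowMeans(fin$sites$frequency)))
    emit(site_tab, "editing_sites.tsv", "editing")
    emit(fin$clusters, "editing_clusters.tsv", "editing")
    say("editing: ", nrow(sites$meta), " candidate sites, ",
        nrow(fin$sites$meta), " retained in ", nrow(fin$clusters), " clusters")
  }

  if ("ecr" %in% stages) {
    if (is.null(res$clusters)) stop("stage 'ecr' needs the editing stage output")
    ecr <- build_ecrs(res$clusters, params)
    res$ecrs <- ecr$ecrs
    res$ecr_membership <- ecr$membership
    emit(ecr$ecrs, "ecrs.tsv", "ecr")
    emit(ecr$membership, "ecr_membership.tsv", "ecr")
    # pooled editing per site x genotype (days pooled) and per ECR x
    # genotype x day
    design <- res$design
    cond <- design$condition[match(res$sites$samples, design$sample_id)]
    per_site <- average_editing(res$sites, site_group = NULL,
                                sample_group = cond)
    emit(per_site, "editing_per_site_treatment.tsv", "ecr")
    # assign final sites to ECRs by cluster membership
    ecr_of_cluster <- stats::setNames(ecr$membership$ecr_id,
                                      ecr$membership$cluster_id)
    site_ecr <- unname(ecr_of_cluster[res$site_cluster])
    cond_day <- paste(design$condition, design$day, sep = "_d")[
      match(res$sites$samples, design$sample_id)]
    per_ecr <- average_editing(res$sites, site_group = site_ecr,
                               sample_group = cond_day)
    emit(per_ecr, "editing_per_ecr_day.tsv", "ecr")
    res$editing_per_site <- per_site
    res$editing_per_ecr <- per_ecr
    say("ecr: ", nrow(ecr$ecrs), " ECRs from ", nrow(res$clusters), " clusters")
  }

  if ("splicing" %in% stages) {
    design <- res$design
    if (is.null(design)) {
      design <- utils::read.table(config$inputs$design, header = TRUE,
                                  sep = "\t", comment.char = "#",
                                  stringsAsFactors = FALSE)
      res$design <- design
    }
    sc <- read_splice_tables(config$inputs$splice_counts,
                             config$inputs$splice_significance,
                             config$inputs$splice_effects)
    cond_of <- stats::setNames(design$condition, design$sample_id)
    sc <- differential_splice_clusters(sc, cond_of, c("CTRL", "hnRNPC"))
    usage <- relative_splice_site_use(sc, cond_of, c("CTRL", "hnRNPC"))
    strat <- stratify_clusters(sc, res$repeats,
                               cutoffs = c(params$splice_p_strict,
                                           params$splice_p_loose, 0.05))
    sites_u <- unique(data.frame(chrom = rep(sc$introns$chrom, 2),
                                 pos = c(sc$introns$start, sc$introns$end)))
    clip <- if (!is.null(config$inputs$clip_peaks))
      read_bed(config$inputs$clip_peaks) else NULL
    if (!is.null(clip)) {
      prox <- annotate_clip_proximity(rep(sites_u$chrom, 1), sites_u$pos,
                                      clip, params$clip_max_gap)
      emit(cbind(sites_u, prox), "clip_proximity.tsv", "splicing")
    }
    # expressed genes: gene-count filter when counts available, else all
    genes <- res$annotation$genes
    if (!is.null(config$inputs$gene_counts) &&
        file.exists(config$inputs$gene_counts)) {
      gc <- read_counts_tsv(config$inputs$gene_counts)
      lib <- colSums(gc$counts)
      nf <- normalization_factors(gc$counts)
      keep <- filter_features(gc$counts, "gene", lib, nf, params)
      genes <- genes[genes$gene_id %in% rownames(gc$counts)[keep], ,
                     drop = FALSE]
    }
    overlap <- gene_splice_overlap(genes, sc, params$splice_p_loose)
    res$splice <- sc
    res$splice_usage <- usage
    res$splice_strata <- strat
    res$gene_overlap <- overlap
    emit(sc$cluster_p, "splice_cluster_significance.tsv", "splicing")
    emit(usage, "splice_site_usage.tsv", "splicing")
    emit(strat$fractions, "splice_stratification.tsv", "splicing")
    emit(overlap$genes, "gene_splice_overlap.tsv", "splicing")
    say("splicing: ", length(unique(sc$introns$cluster_id)), " clusters; ",
        "gene overlap fraction ", format_num(overlap$fraction))
  }

  if ("diffexp" %in% stages) {
    design <- res$design
    gc <- read_counts_tsv(config$inputs$gene_counts)
    ic <- read_counts_tsv(config$inputs$intron_counts)
    ec <- read_counts_tsv(config$inputs$ecr_counts)
    lib <- colSums(gc$counts)
    nf <- normalization_factors(gc$counts)
    run_class <- function(counts, class) {
      keep <- filter_features(counts, class, lib, nf, params)
      kept <- counts[keep, , drop = FALSE]
      per_day <- lapply(sort(unique(design$day)), function(d) {
        differential_expression(kept, design,
                                sprintf(c("CTRL_d%d", "hnRNPC_d%d"), d),
                                lib, nf, params)
      })
      names(per_day) <- sprintf("day%d", sort(unique(design$day)))
      list(kept = kept, per_day = per_day)
    }
    de_gene <- run_class(gc$counts, "gene")
    de_intron <- run_class(ic$counts, "intron")
    de_ecr <- run_class(ec$counts, "ECR")
    for (cl in c("gene", "intron", "ECR")) {
      der <- switch(cl, gene = de_gene, intron = de_intron, ECR = de_ecr)
      tab <- do.call(rbind, lapply(names(der$per_day), function(d) {
        cbind(data.frame(day = d), der$per_day[[d]])
      }))
      emit(tab, sprintf("de_%s.tsv", tolower(cl)), "diffexp")
    }
    # 2x2 factorial interaction on the ISG set, last day
    isg <- readLines(config$inputs$isg_set)
    d5 <- design[design$day == max(design$day), ]
    isg_counts <- gc$counts[intersect(isg, rownames(gc$counts)),
                            d5$sample_id, drop = FALSE]
    inter <- interaction_test(isg_counts, d5, lib[d5$sample_id],
                              nf[d5$sample_id])
    emit(inter, "isg_interaction.tsv", "diffexp")
    # intron-vs-gene decoupling on the last day's contrast
    imap <- sub("_intron[0-9]+$", "", rownames(de_intron$kept))
    names(imap) <- rownames(de_intron$kept)
    lastd <- sprintf("day%d", max(design$day))
    gene_full <- differential_expression(
      gc$counts, design,
      sprintf(c("CTRL_d%d", "hnRNPC_d%d"), max(design$day)), lib, nf, params)
    dec <- intron_gene_decoupling(de_intron$per_day[[lastd]], gene_full, imap)
    emit(dec, "intron_gene_decoupling.tsv", "diffexp")
    # ECR expression floor
    rk <- rpkm(ec$counts, ec$lengths[rownames(ec$counts)], lib, nf)
    cond_of <- stats::setNames(design$condition, design$sample_id)
    expressed <- expressed_in_all_conditions(rk, cond_of, params$ecr_min_rpkm)
    emit(data.frame(feature_id = rownames(ec$counts), expressed = expressed),
         "ecr_expressed.tsv", "diffexp")
    res$de <- list(gene = de_gene, intron = de_intron, ecr = de_ecr)
    res$interaction <- inter
    res$decoupling <- dec
    res$norm_factors <- nf
    res$lib_sizes <- lib
    say("diffexp: factors geo-mean ", format_num(exp(mean(log(nf)))))
  }

  if ("structure" %in% stages) {
    recs <- read_dotbracket(config$inputs$structures)
    sm <- score_structures(recs, params)
    res$structure_metrics <- sm
    emit(sm, "structure_metrics.tsv", "structure")
    say("structure: ", nrow(sm), " records, ", sum(sm$ligand_like),
        " ligand-like")
  }

  if ("eclip" %in% stages) {
    fam <- utils::read.table(config$inputs$family_counts, header = TRUE,
                             sep = "\t", comment.char = "#",
                             stringsAsFactors = FALSE)
    fe <- family_enrichment(fam)
    res$family_enrichment <- fe
    emit(fe, "family_enrichment.tsv", "eclip")
    say("eclip: ", nrow(fe), " family/strand rows")
  }

  if ("report" %in% stages) {
    items <- list()
    add <- function(k, v) items[[length(items) + 1]] <<- data.frame(
      metric = k, value = v, stringsAsFactors = FALSE)
    if (!is.null(res$sites)) add("final_editing_sites", nrow(res$sites$meta))
    if (!is.null(res$clusters)) add("editing_clusters", nrow(res$clusters))
    if (!is.null(res$ecrs)) add("ecrs", nrow(res$ecrs))
    if (!is.null(res$editing_per_site)) {
      for (cond in unique(res$editing_per_site$sample_group)) {
        sub <- res$editing_per_site[res$editing_per_site$sample_group == cond, ]
        add(paste0("mean_site_editing_", cond), mean(sub$frequency))
      }
    }
    if (!is.null(res$gene_overlap)) {
      add("gene_splice_overlap_fraction", res$gene_overlap$fraction)
    }
    if (!is.null(res$de)) {
      lastd <- sprintf("day%d", max(res$design$day))
      for (cl in c("gene", "intron", "ecr")) {
        add(paste0("regulated_", cl, "_lastday"),
            sum(res$de[[cl]]$per_day[[lastd]]$regulated))
      }
    }
    if (!is.null(res$interaction)) {
      add("mean_isg_interaction", mean(res$interaction$interaction))
    }
    if (!is.null(res$structure_metrics)) {
      add("ligand_like_fraction", mean(res$structure_metrics$ligand_like))
    }
    report <- do.call(rbind, items)
    if (is.null(report)) report <- data.frame(metric = character(0),
                                              value = numeric(0))
    emit(report, "report.tsv", "report")
    res$report <- report
  }
  say("done")
  invisible(res)
}
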
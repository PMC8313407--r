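#' Pipeline parameter set
#'
#' Constructs the full set of numeric thresholds used across the pipeline,
#' with defaults matching the published analysis. Any subset can be
#' overridden; unknown names are rejected.
#'
#' @param ... named overrides of individual parameters.
#'
#' @details Parameters (defaults in parentheses):
#' \describe{
#'   \item{max_gap}{maximum distance in nt between neighbouring editing sites
#'     within one cluster (50)}
#'   \item{min_cluster_sites}{minimum sites for a cluster to survive final
#'     selection (5)}
#'   \item{ecr_pad}{padding in nt added on both sides of each cluster before
#'     merging into ECRs (1000)}
#'   \item{ecr_group_gap}{clusters closer than this are grouped into one ECR
#'     (2000); equals \code{2 * ecr_pad} under the pad-and-merge construction}
#'   \item{freq_min, freq_max}{editing-frequency window for site retention
#'     (0.05, 0.95)}
#'   \item{freq_high}{frequency that at least two samples of a treatment must
#'     reach in the secondary filter (0.10)}
#'   \item{min_coverage}{minimum read coverage at a site (10)}
#'   \item{min_caller_score}{minimum upstream caller confidence score (0.5)}
#'   \item{logcpm_cutoff_gene, logcpm_cutoff_intron, logcpm_cutoff_ecr}{mean
#'     log2-CPM expression filters per feature class (0.5, 1.0, 4.5)}
#'   \item{de_abs_log2fc, de_fdr}{regulation call thresholds (1.0, 0.05)}
#'   \item{splice_p_strict, splice_p_loose}{adjusted-p cutoffs for splicing
#'     cluster significance (0.001, 0.01)}
#'   \item{clip_max_gap}{maximum distance in nt from a splice site to a CLIP
#'     peak to call proximity (50)}
#'   \item{ligand_min_len, ligand_max_mismatch_frac, ligand_min_helix}{MDA5
#'     ligand criteria on dsRNA stretches (300 nt, 0.2, 37 bp)}
#'   \item{ecr_min_rpkm}{expression floor for ECR analyses (4)}
#' }
#'
#' @return A named list of class \code{pipeline_params}.
#' @examples
#' p <- pipeline_params()
#' p$max_gap
#' pipeline_params(max_gap = 100)$max_gap
#' @export
pipeline_params <- function(...) {
  defaults <- list(
    max_gap = 50,
    min_cluster_sites = 5,
    ecr_pad = 1000,
    ecr_group_gap = 2000,
    freq_min = 0.05,
    freq_max = 0.95,
    freq_high = 0.10,
    min_coverage = 10,
    min_caller_score = 0.5,
    logcpm_cutoff_gene = 0.5,
    logcpm_cutoff_intron = 1.0,
    logcpm_cutoff_ecr = 4.5,
    de_abs_log2fc = 1.0,
    de_fdr = 0.05,
    splice_p_strict = 0.001,
    splice_p_loose = 0.01,
    clip_max_gap = 50,
    ligand_min_len = 300,
    ligand_max_mismatch_frac = 0.2,
    ligand_min_helix = 37,
    ecr_min_rpkm = 4
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("unknown pipeline parameter(s): ",
           paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
    }
    defaults[names(overrides)] <- overrides
  }
  validate_pipeline_params(defaults)
  structure(defaults, class = "pipeline_params")
}

validate_pipeline_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) stop("all pipeline parameters must be single finite numbers")
  if (any(unlist(p) <= 0)) {
    stop("all pipeline parameters must be strictly positive: ",
         paste(names(p)[unlist(p) <= 0], collapse = ", "))
  }
  if (!(p$freq_min < p$freq_high && p$freq_high < p$freq_max)) {
    stop("require freq_min < freq_high < freq_max")
  }
  invisible(p)
}
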
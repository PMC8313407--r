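#' Parse a dot-bracket secondary structure into a pairing table
#'
#' @param dot_bracket string over "(", ")" and "."; brackets must balance.
#' @return Integer vector: partner index per position (1-based), NA when
#'   unpaired.
#' @export
pairing_table <- function(dot_bracket) {
  chars <- strsplit(dot_bracket, "")[[1]]
  if (!all(chars %in% c("(", ")", "."))) {
    stop("dot-bracket string may contain only '(', ')' and '.'")
  }
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket: unmatched ')' at ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) {
    stop("unbalanced dot-bracket: unmatched '(' at ", stack[1])
  }
  partner
}

#' Metrics of a double-stranded RNA stretch
#'
#' From a dot-bracket structure: total length (the full string, mismatches
#' included), the mismatched-nucleotide fraction (count of "." over string
#' length — terminal-loop dots count), and the longest uninterrupted helix:
#' the longest run of consecutive base pairs contiguous on both strands (a
#' single-nucleotide bulge on either strand breaks the run).
#'
#' @param dot_bracket structure string.
#' @return list with total_length, mismatch_fraction, longest_helix.
#' @examples
#' structure_metrics("((((....))))")
#' @export
structure_metrics <- function(dot_bracket) {
  partner <- pairing_table(dot_bracket)
  n <- length(partner)
  n_dots <- sum(is.na(partner))
  longest <- 0L
  run <- 0L
  for (i in seq_len(n)) {
    if (!is.na(partner[i]) && partner[i] > i) {       # count on the 5' strand
      if (run > 0 && !is.na(partner[i - 1]) && partner[i - 1] == partner[i] + 1) {
        run <- run + 1L
      } else {
        run <- 1L
      }
      longest <- max(longest, run)
    } else {
      run <- 0L
    }
  }
  list(total_length = n,
       mismatch_fraction = if (n > 0) n_dots / n else NA_real_,
       longest_helix = as.integer(longest))
}

#' Classify a dsRNA stretch as a candidate MDA5 ligand
#'
#' Applies the three irAlu-reference criteria: total length > 300 nt,
#' mismatched fraction < 0.2, longest uninterrupted helix >= 37 bp. The
#' combined flag uses "any" by default (each criterion alone suffices);
#' "all" requires all three.
#'
#' @param metrics list from [structure_metrics()].
#' @param params a [pipeline_params()] list.
#' @param combinator "any" or "all".
#' @return list with length_ok, mismatch_ok, helix_ok, ligand_like,
#'   combinator.
#' @export
classify_ligand <- function(metrics, params = pipeline_params(),
                            combinator = c("any", "all")) {
  combinator <- match.arg(combinator)
  flags <- c(length_ok = metrics$total_length > params$ligand_min_len,
             mismatch_ok = metrics$mismatch_fraction < params$ligand_max_mismatch_frac,
             helix_ok = metrics$longest_helix >= params$ligand_min_helix)
  combined <- if (combinator == "any") any(flags) else all(flags)
  c(as.list(flags), list(ligand_like = combined, combinator = combinator))
}

#' Read a multi-record dot-bracket file
#'
#' Records start with an id line (">id"); the structure line is the first
#' subsequent line consisting of brackets and dots. A sequence line (ACGU)
#' between id and structure is permitted and ignored.
#'
#' @param path text file path.
#' @return data.frame with id and dot_bracket columns.
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  ids <- character(0); structs <- character(0)
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      cur <- sub("^>\\s*", "", ln)
    } else if (grepl("^[().]+$", ln)) {
      if (is.null(cur)) stop("structure line before any id line")
      ids <- c(ids, cur); structs <- c(structs, ln)
      cur <- NULL
    }
  }
  data.frame(id = ids, dot_bracket = structs, stringsAsFactors = FALSE)
}

#' Score every structure in a dot-bracket file
#'
#' @param records data.frame from [read_dotbracket()].
#' @param params a [pipeline_params()] list.
#' @param combinator ligand criterion combinator, "any" or "all".
#' @return data.frame with id, total_length, mismatch_fraction,
#'   longest_helix, the three criterion flags and ligand_like.
#' @export
score_structures <- function(records, params = pipeline_params(),
                             combinator = "any") {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    m <- structure_metrics(records$dot_bracket[i])
    fl <- classify_ligand(m, params, combinator)
    data.frame(id = records$id[i], total_length = m$total_length,
               mismatch_fraction = m$mismatch_fraction,
               longest_helix = m$longest_helix,
               length_ok = fl$length_ok, mismatch_ok = fl$mismatch_ok,
               helix_ok = fl$helix_ok, ligand_like = fl$ligand_like,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
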
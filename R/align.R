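#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties, backed by
#' `Biostrings::pairwiseAlignment`. Defaults mirror protein BLAST scoring:
#' BLOSUM62, gap open 11, gap extend 1. Percent identity is identical
#' columns over aligned columns where neither sequence is gapped; coverage
#' of each sequence is its aligned (non-gap-opposed) length over its total
#' length.
#'
#' @param seq_a,seq_b amino-acid sequences (single strings).
#' @param substitution_matrix scoring matrix name or matrix; default
#'   `"BLOSUM62"`.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return object of class `pairwise_alignment`: list with `aligned_a`,
#'   `aligned_b` (gapped strings), `score`, `identity`, `coverage_a`,
#'   `coverage_b`.
#' @export
global_align <- function(seq_a, seq_b, substitution_matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  if (is.character(substitution_matrix) && length(substitution_matrix) == 1L) {
    substitution_matrix <- get_submat(substitution_matrix)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  a <- as.character(Biostrings::alignedPattern(pa))
  b <- as.character(Biostrings::alignedSubject(pa))
  alignment_result(a, b, score = Biostrings::score(pa),
                   len_a = nchar(seq_a), len_b = nchar(seq_b))
}

#' @noRd
get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Build an alignment-result object from two gapped strings
#' @noRd
alignment_result <- function(a, b, score, len_a, len_b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  both <- ca != "-" & cb != "-"
  n_both <- sum(both)
  res <- list(
    aligned_a = a, aligned_b = b, score = score,
    identity = if (n_both > 0) sum(ca[both] == cb[both]) / n_both else 0,
    coverage_a = n_both / len_a,
    coverage_b = n_both / len_b
  )
  class(res) <- "pairwise_alignment"
  res
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("Global alignment: score %.1f, identity %.1f%%, coverage %.0f%%/%.0f%%\n",
              x$score, 100 * x$identity, 100 * x$coverage_a, 100 * x$coverage_b))
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Reciprocal-best-hit ortholog pairing between two proteomes
#'
#' Pairs (a, b) such that b is a's unique best-scoring global alignment in
#' proteome B and a is b's unique best in A. Score ties for a best hit make
#' the gene ambiguous and drop it (conservative orthology). Output is
#' independent of argument order up to column naming.
#'
#' @param proteome_a,proteome_b named character vectors of protein
#'   sequences; names are gene ids and must be unique.
#' @param ... scoring arguments passed to [global_align()].
#' @return data.frame with columns `id_a`, `id_b`, `score`, `identity`.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b, ...) {
  check_proteome(proteome_a, "proteome_a")
  check_proteome(proteome_b, "proteome_b")
  na <- length(proteome_a)
  nb <- length(proteome_b)
  scores <- matrix(NA_real_, na, nb,
                   dimnames = list(names(proteome_a), names(proteome_b)))
  idents <- scores
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      al <- global_align(proteome_a[[i]], proteome_b[[j]], ...)
      scores[i, j] <- al$score
      idents[i, j] <- al$identity
    }
  }
  unique_best <- function(v) {
    m <- max(v)
    idx <- which(v == m)
    if (length(idx) == 1L) idx else NA_integer_
  }
  best_ab <- apply(scores, 1L, unique_best)
  best_ba <- apply(scores, 2L, unique_best)
  pairs <- list()
  for (i in seq_len(na)) {
    j <- best_ab[i]
    if (!is.na(j) && !is.na(best_ba[j]) && best_ba[j] == i) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        id_a = names(proteome_a)[i], id_b = names(proteome_b)[j],
        score = scores[i, j], identity = idents[i, j],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(pairs) == 0L) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      score = numeric(0), identity = numeric(0)))
  }
  do.call(rbind, pairs)
}

#' @noRd
check_proteome <- function(p, label) {
  if (length(p) == 0L) stop(label, " is empty")
  if (is.null(names(p)) || anyDuplicated(names(p)) || any(!nzchar(names(p)))) {
    stop(label, " must have unique non-empty names")
  }
}

#' Greedy redundancy filter on sequence identity
#'
#' Scans sequences in input order, dropping any whose global-alignment
#' identity to an already-retained sequence exceeds `max_identity`. The
#' retained set therefore has all pairwise identities `<= max_identity`.
#'
#' @param sequences named character vector of protein sequences.
#' @param max_identity drop threshold (default 0.90, strict `>`).
#' @param ... passed to [global_align()].
#' @return the retained subset of `sequences`.
#' @export
filter_redundant <- function(sequences, max_identity = 0.90, ...) {
  if (length(sequences) == 0L) stop("no sequences")
  keep <- integer(0)
  for (i in seq_along(sequences)) {
    redundant <- FALSE
    for (k in keep) {
      if (global_align(sequences[[i]], sequences[[k]], ...)$identity > max_identity) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) keep <- c(keep, i)
  }
  sequences[keep]
}
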
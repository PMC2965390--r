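#' Candidate paralog pairs within one proteome
#'
#' All unordered pairs of distinct genes whose global-alignment identity is
#' strictly above `min_identity` and whose alignment covers at least
#' `min_coverage` of BOTH sequences (each relative to its own length) —
#' duplicates in the sense of >40% identity alignable over >=80% of their
#' length.
#'
#' @param proteome named character vector of protein sequences.
#' @param min_identity strict lower bound on identity (default 0.40).
#' @param min_coverage inclusive lower bound on per-sequence coverage
#'   (default 0.80).
#' @param ... passed to [global_align()].
#' @return data.frame with columns `id_a`, `id_b`, `identity`,
#'   `coverage_a`, `coverage_b`.
#' @export
find_paralogs <- function(proteome, min_identity = 0.40, min_coverage = 0.80,
                          ...) {
  check_proteome(proteome, "proteome")
  ids <- names(proteome)
  rows <- list()
  n <- length(proteome)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      al <- global_align(proteome[[i]], proteome[[j]], ...)
      if (al$identity > min_identity &&
          al$coverage_a >= min_coverage && al$coverage_b >= min_coverage) {
        rows[[length(rows) + 1L]] <- data.frame(
          id_a = ids[i], id_b = ids[j], identity = al$identity,
          coverage_a = al$coverage_a, coverage_b = al$coverage_b,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      identity = numeric(0), coverage_a = numeric(0),
                      coverage_b = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Expression-consistency filter for a paralog pair
#'
#' Consistency is the larger, over the two genes, of the fraction of
#' experiments in which that gene's expression is strictly higher than its
#' partner's; within-experiment ties count for neither gene. The pair is
#' retained only when consistency is strictly above `min_consistency`
#' ("more than 80% of experiments").
#'
#' @param pair list or one-row data.frame with `id_a` and `id_b`.
#' @param expression numeric matrix or data.frame, genes in rows (rownames
#'   are gene ids), experiments in columns.
#' @param min_consistency strict retention threshold (default 0.80).
#' @return list of class `paralog_consistency`: `id_a`, `id_b`,
#'   `consistency`, `high_expr_member` (id of the gene that is higher more
#'   often; `NA` on an exact tie), `n_experiments`, `retained`.
#' @export
expression_consistency <- function(pair, expression, min_consistency = 0.80) {
  ids <- c(pair$id_a, pair$id_b)
  expression <- as.matrix(expression)
  missing <- setdiff(ids, rownames(expression))
  if (length(missing) > 0) {
    stop("gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  if (ncol(expression) < 1L) stop("expression matrix has no experiments")
  ea <- expression[ids[1], ]
  eb <- expression[ids[2], ]
  frac_a <- mean(ea > eb)
  frac_b <- mean(eb > ea)
  consistency <- max(frac_a, frac_b)
  res <- list(
    id_a = ids[1], id_b = ids[2], consistency = consistency,
    high_expr_member = if (frac_a > frac_b) ids[1]
                       else if (frac_b > frac_a) ids[2]
                       else NA_character_,
    n_experiments = ncol(expression),
    retained = consistency > min_consistency
  )
  class(res) <- "paralog_consistency"
  res
}
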
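## Internal utilities: a self-contained seeded RNG (generators never touch
## the caller's random state), and plain-text I/O helpers.

#' A private random stream seeded independently of the global RNG
#'
#' Returns draw functions that swap a private `.Random.seed` in and out of
#' the global environment around each call, so every generator is
#' deterministic given its seed and leaves the caller's RNG untouched.
#' @noRd
local_rng <- function(seed) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  env <- new.env(parent = emptyenv())
  genv <- globalenv()
  outer <- get0(".Random.seed", envir = genv, inherits = FALSE)
  set.seed(seed)
  env$state <- get(".Random.seed", envir = genv, inherits = FALSE)
  if (is.null(outer)) {
    rm(".Random.seed", envir = genv)
  } else {
    assign(".Random.seed", outer, envir = genv)
  }
  with_state <- function(f) {
    force(f)
    function(...) {
      outer <- get0(".Random.seed", envir = genv, inherits = FALSE)
      assign(".Random.seed", env$state, envir = genv)
      on.exit({
        env$state <- get(".Random.seed", envir = genv, inherits = FALSE)
        if (is.null(outer)) {
          rm(".Random.seed", envir = genv)
        } else {
          assign(".Random.seed", outer, envir = genv)
        }
      })
      f(...)
    }
  }
  list(
    runif = with_state(stats::runif),
    rnorm = with_state(stats::rnorm),
    sample = with_state(function(x, size = length(x), replace = FALSE,
                                 prob = NULL) {
      sample(x, size = size, replace = replace, prob = prob)
    }),
    sample_int = with_state(sample.int),
    matrix_rnorm = with_state(function(n, m) {
      matrix(stats::rnorm(n * m), n, m)
    })
  )
}

#' Write a data.frame as TSV with fixed numeric formatting
#'
#' Numeric columns are written with `signif(x, digits)` so that repeated
#' runs with the same seed produce byte-identical files.
#' @noRd
write_tsv_fixed <- function(df, path, digits = 10, comment = NULL) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv_plain <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file of protein or nucleotide sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  # id = first whitespace-separated header token
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  stats::setNames(as.character(ss), ids)
}

#' Write named sequences to FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1L, nchar(s), 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a structure as single-model, single-chain PDB ATOM records
#' @param x a [protein_structure()].
#' @param path output file.
#' @export
write_pdb <- function(x, path) {
  stopifnot(inherits(x, "protein_structure"))
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR",
           X = "UNK")
  at <- x$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)),
    ifelse(nchar(at$atom) < 4, paste0(" ", at$atom), at$atom),
    " ", aa3[at$aa], x$chain_id, at$res_index, " ",
    at$x, at$y, at$z, 1, 0, at$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
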
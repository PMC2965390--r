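## Universal genetic code tables and per-codon synonymous-site machinery
## shared by the Ka/Ks estimator and the codon-pair simulator.

NUCLEOTIDES <- c("A", "C", "G", "T")

#' @noRd
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

.codon_env <- new.env(parent = emptyenv())

#' All 61 sense codons of the universal code
#' @noRd
sense_codons <- function() {
  if (is.null(.codon_env$sense)) {
    gc <- genetic_code()
    .codon_env$code <- gc
    .codon_env$sense <- names(gc)[gc != "*"]
  }
  .codon_env$sense
}

#' Translate a vector of codons; stops return "*"
#' @noRd
translate_codons <- function(codons) {
  sense_codons() # ensure cache
  aa <- .codon_env$code[toupper(codons)]
  if (anyNA(aa)) {
    stop("invalid codon(s): ", paste(unique(codons[is.na(aa)]), collapse = ", "))
  }
  unname(aa)
}

#' Split an in-frame CDS string into codons
#' @noRd
split_codons <- function(cds) {
  cds <- toupper(gsub("\\s", "", cds))
  if (nchar(cds) == 0L) return(character(0))
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length ", nchar(cds), " is not a multiple of 3")
  }
  substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
}

#' The nine single-nucleotide neighbours of a codon
#' @noRd
codon_neighbours <- function(codon) {
  base <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) {
    for (nt in setdiff(NUCLEOTIDES, base[pos])) {
      alt <- base
      alt[pos] <- nt
      out <- c(out, paste(alt, collapse = ""))
    }
  }
  out
}

#' Synonymous site count of one sense codon.
#'
#' Fraction of the three single-nucleotide changes at each position that
#' preserve the encoded amino acid; changes that create a stop codon count
#' as nonsynonymous, so s + n = 3 for every codon.
#' @noRd
codon_syn_sites <- function(codon) {
  if (is.null(.codon_env$syn_sites)) {
    sc <- sense_codons()
    s <- vapply(sc, function(cd) {
      aa <- translate_codons(cd)
      nb <- codon_neighbours(cd)
      sum(translate_codons(nb) == aa) / 3
    }, numeric(1))
    .codon_env$syn_sites <- s
  }
  val <- .codon_env$syn_sites[codon]
  if (anyNA(val)) stop("not a sense codon: ", codon)
  unname(val)
}

#' Synonymous/nonsynonymous difference counts between two sense codons,
#' averaged over all minimal mutational pathways that avoid stop codons.
#'
#' Returns c(sd, nd), or c(NA, NA) when every minimal pathway passes
#' through a stop codon (the caller skips such pairs and records them).
#' @noRd
codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste(sort(c(c1, c2)), collapse = "")
  if (is.null(.codon_env$pair_cache)) .codon_env$pair_cache <- new.env(parent = emptyenv())
  hit <- .codon_env$pair_cache[[key]]
  if (!is.null(hit)) return(hit)

  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(b1 != b2)
  paths <- perms(diff_pos)
  tot_s <- 0
  tot_n <- 0
  n_valid <- 0L
  for (k in seq_len(nrow(paths))) {
    cur <- b1
    s <- 0L
    n <- 0L
    ok <- TRUE
    for (pos in paths[k, ]) {
      aa_from <- translate_codons(paste(cur, collapse = ""))
      cur[pos] <- b2[pos]
      nxt <- paste(cur, collapse = "")
      aa_to <- translate_codons(nxt)
      if (aa_to == "*") {
        ok <- FALSE
        break
      }
      if (aa_to == aa_from) s <- s + 1L else n <- n + 1L
    }
    if (ok) {
      tot_s <- tot_s + s
      tot_n <- tot_n + n
      n_valid <- n_valid + 1L
    }
  }
  res <- if (n_valid == 0L) c(sd = NA_real_, nd = NA_real_) else
    c(sd = tot_s / n_valid, nd = tot_n / n_valid)
  .codon_env$pair_cache[[key]] <- res
  res
}

#' All permutations of a short vector (n <= 3 here)
#' @noRd
perms <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- perms(v[-i])
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}
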
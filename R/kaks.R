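#' Back-translate a protein alignment onto its coding sequences
#'
#' Expands the gap pattern of a pairwise protein alignment to whole-codon
#' gaps, producing a codon-synchronised alignment of the two CDS suitable
#' for [nei_gojobori()]. Stop codons must already be trimmed from the CDS.
#'
#' @param aln an alignment returned by [global_align()].
#' @param cds_a,cds_b in-frame coding sequences; `nchar(cds) == 3 *`
#'   ungapped protein length, and each codon must translate to the aligned
#'   residue at its position.
#' @return object of class `codon_alignment`: list with gap-aligned codon
#'   vectors `codons_a`, `codons_b` (gap codons are `"---"`).
#' @export
backtranslate_alignment <- function(aln, cds_a, cds_b) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  expand <- function(aligned, cds, label) {
    res <- strsplit(aligned, "")[[1]]
    codons <- split_codons(cds)
    if (length(codons) != sum(res != "-")) {
      stop("CDS ", label, " has ", length(codons),
           " codons but the aligned protein has ", sum(res != "-"),
           " residues")
    }
    out <- character(length(res))
    k <- 0L
    for (i in seq_along(res)) {
      if (res[i] == "-") {
        out[i] <- "---"
      } else {
        k <- k + 1L
        aa <- translate_codons(codons[k])
        if (aa != res[i] && res[i] != "X") {
          stop("codon ", k, " of CDS ", label, " (", codons[k],
               ") translates to ", aa, ", not aligned residue ", res[i])
        }
        out[i] <- codons[k]
      }
    }
    out
  }
  ca <- list(
    codons_a = expand(aln$aligned_a, cds_a, "a"),
    codons_b = expand(aln$aligned_b, cds_b, "b")
  )
  class(ca) <- "codon_alignment"
  ca
}

#' Nei-Gojobori (1986) Ka/Ks estimation on a codon alignment
#'
#' Counting-based estimator of synonymous (Ks) and nonsynonymous (Ka)
#' substitution rates. Per-codon synonymous site fractions come from the
#' universal genetic code and are averaged over the two sequences;
#' single-nucleotide changes that would create a stop codon are counted as
#' nonsynonymous in the site tally so that `S_sites + N_sites` equals three
#' times the number of compared codons. Codon pairs differing at more than
#' one position are resolved by averaging the synonymous/nonsynonymous
#' split over all minimal mutational pathways whose intermediates are sense
#' codons; pairs with no stop-free pathway are excluded and reported in
#' `skipped_codons`. Proportions of differences are corrected for multiple
#' hits with the Jukes-Cantor formula `K = -3/4 * log(1 - 4/3 * p)`.
#'
#' @param ca a `codon_alignment` from [backtranslate_alignment()], or a
#'   list with codon vectors `codons_a` and `codons_b`.
#' @return object of class `kaks_result`: list with `S_sites`, `N_sites`,
#'   `Sd`, `Nd`, `ps`, `pn`, `Ks`, `Ka`, `n_codons` (compared codons),
#'   `skipped_codons`, and `method` (estimator tag stamped into pipeline
#'   output metadata).
#' @export
nei_gojobori <- function(ca) {
  ca <- as_codon_alignment(ca)
  a <- ca$codons_a
  b <- ca$codons_b
  keep <- a != "---" & b != "---"
  a <- a[keep]
  b <- b[keep]
  if (length(a) == 0L) stop("no ungapped codon columns to compare")
  aa_a <- translate_codons(a)
  aa_b <- translate_codons(b)
  if (any(aa_a == "*") || any(aa_b == "*")) {
    stop("in-frame stop codon in ungapped alignment column")
  }

  S <- 0
  N <- 0
  Sd <- 0
  Nd <- 0
  used <- 0L
  skipped <- 0L
  for (i in seq_along(a)) {
    d <- codon_pair_diffs(a[i], b[i])
    if (anyNA(d)) {
      skipped <- skipped + 1L
      next
    }
    s_i <- (codon_syn_sites(a[i]) + codon_syn_sites(b[i])) / 2
    S <- S + s_i
    N <- N + (3 - s_i)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
    used <- used + 1L
  }
  if (used == 0L) stop("no comparable codons (all pairs stop-blocked)")
  ps <- Sd / S
  pn <- Nd / N
  if (ps >= 3 / 4 || pn >= 3 / 4) {
    stop("substitution saturation: p >= 3/4, Jukes-Cantor rate undefined")
  }
  res <- list(
    S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
    ps = ps, pn = pn,
    Ks = abs(-3 / 4 * log(1 - 4 / 3 * ps)),
    Ka = abs(-3 / 4 * log(1 - 4 / 3 * pn)),
    n_codons = used, skipped_codons = skipped,
    method = "NG86+JC"
  )
  class(res) <- "kaks_result"
  res
}

#' @noRd
as_codon_alignment <- function(x) {
  if (inherits(x, "codon_alignment")) return(x)
  if (is.list(x) && all(c("codons_a", "codons_b") %in% names(x))) {
    if (length(x$codons_a) != length(x$codons_b)) {
      stop("codon vectors differ in length")
    }
    class(x) <- "codon_alignment"
    return(x)
  }
  stop("expected a codon_alignment")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf(
    "Ka/Ks (%s): Ka = %.4f, Ks = %.4f (S = %.2f, N = %.2f, Sd = %.2f, Nd = %.2f, %d codons)\n",
    x$method, x$Ka, x$Ks, x$S_sites, x$N_sites, x$Sd, x$Nd, x$n_codons
  ))
  invisible(x)
}

#' Codon-usage preference within synonymous families
#'
#' For every sense codon, its percent usage among all codons of a reference
#' CDS set encoding the same amino acid (100 * count / family total).
#' Families whose amino acid never occurs get `NA`.
#'
#' @param reference_cds character vector of in-frame CDS strings.
#' @return data.frame with columns `codon`, `aa`, `count`, `preference_pct`.
#' @export
codon_usage_preference <- function(reference_cds) {
  if (length(reference_cds) == 0L) stop("empty reference CDS set")
  codons <- unlist(lapply(reference_cds, split_codons), use.names = FALSE)
  aa <- translate_codons(codons)
  codons <- codons[aa != "*"]
  sc <- sense_codons()
  counts <- table(factor(codons, levels = sc))
  fam <- translate_codons(sc)
  fam_tot <- tapply(as.numeric(counts), fam, sum)[fam]
  pref <- ifelse(fam_tot > 0, 100 * as.numeric(counts) / fam_tot, NA_real_)
  data.frame(
    codon = sc, aa = fam, count = as.numeric(counts),
    preference_pct = pref, row.names = NULL, stringsAsFactors = FALSE
  )
}
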
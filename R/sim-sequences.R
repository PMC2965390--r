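## Seeded generators for coding-sequence fixtures with known ground truth.

#' Random sense-codon CDS
#' @noRd
random_cds <- function(n_codons, rng) {
  paste(rng$sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

#' Simulate a diverged coding-sequence pair with known substitution counts
#'
#' Generates an ancestral CDS of `n_codons` random sense codons, then
#' derives a descendant by repeatedly proposing uniform single-nucleotide
#' changes: synonymous proposals are accepted with probability 1,
#' nonsynonymous with probability `omega`, and proposals creating a stop
#' codon are always rejected. Proposals continue until the accepted
#' synonymous count reaches `round(expected_syn_subs * S_sites)` of the
#' ancestor, so the realized counts are exact ground truth for downstream
#' Ka/Ks estimation.
#'
#' @param n_codons codon count (>= 1).
#' @param expected_syn_subs target synonymous substitutions per synonymous
#'   site (>= 0).
#' @param omega acceptance probability for nonsynonymous proposals (>= 0;
#'   values above 1 are capped at 1).
#' @param seed integer seed.
#' @return list with `cds_ancestor`, `cds_descendant`, `n_syn` and
#'   `n_nonsyn` (accepted change counts), `S_sites_ancestor`,
#'   `N_sites_ancestor` (Nei-Gojobori site counts of the ancestor).
#' @export
simulate_coding_pair <- function(n_codons, expected_syn_subs, omega,
                                 seed = 1L) {
  n_codons <- as.integer(n_codons)
  if (is.na(n_codons) || n_codons < 1L) stop("n_codons must be >= 1")
  if (expected_syn_subs < 0) stop("expected_syn_subs must be >= 0")
  if (omega < 0) stop("omega must be >= 0")
  rng <- local_rng(seed)
  anc <- random_cds(n_codons, rng)
  codons <- split_codons(anc)
  S <- sum(vapply(codons, codon_syn_sites, numeric(1)))
  target_syn <- round(expected_syn_subs * S)
  cur <- codons
  n_syn <- 0L
  n_nonsyn <- 0L
  guard <- 0L
  max_prop <- max(1000L, 2000L * target_syn)
  while (n_syn < target_syn) {
    guard <- guard + 1L
    if (guard > max_prop) {
      stop("divergence target unreachable within proposal budget")
    }
    ci <- rng$sample_int(n_codons, 1L)
    pos <- rng$sample_int(3L, 1L)
    base <- strsplit(cur[ci], "")[[1]]
    alt <- rng$sample(setdiff(NUCLEOTIDES, base[pos]), 1L)
    prop <- base
    prop[pos] <- alt
    prop_codon <- paste(prop, collapse = "")
    aa_old <- translate_codons(cur[ci])
    aa_new <- translate_codons(prop_codon)
    if (aa_new == "*") next
    if (aa_new == aa_old) {
      cur[ci] <- prop_codon
      n_syn <- n_syn + 1L
    } else if (rng$runif(1) < omega) {
      cur[ci] <- prop_codon
      n_nonsyn <- n_nonsyn + 1L
    }
  }
  list(
    cds_ancestor = anc,
    cds_descendant = paste(cur, collapse = ""),
    n_syn = n_syn, n_nonsyn = n_nonsyn,
    S_sites_ancestor = S, N_sites_ancestor = 3 * n_codons - S
  )
}

#' Simulate a paralog family with controlled identity and expression
#' consistency
#'
#' Builds gene A as a random CDS/protein of `length_aa` residues, then
#' derives paralog B by random amino-acid substitutions (with matching
#' codon changes) until the pairwise identity is within +/- 2 percentage
#' points of `identity_target`. An expression matrix over
#' `n_experiments` pseudo-experiments is constructed so that gene A is
#' strictly higher in exactly `round(consistency * n_experiments)` of
#' them and strictly lower in the rest.
#'
#' @param identity_target target pairwise identity in (0, 1].
#' @param n_experiments number of expression experiments (>= 1).
#' @param consistency fraction of experiments in which A is higher,
#'   in \[0, 1\].
#' @param length_aa protein length (default 300).
#' @param seed integer seed.
#' @return list with `proteins` and `cds` (named character vectors for
#'   genes `"A"` and `"B"`), `expression` (matrix, genes x experiments),
#'   `identity` (realized, by position over the substitution-only
#'   derivation), `n_higher_A`.
#' @export
simulate_paralog_family <- function(identity_target, n_experiments,
                                    consistency, length_aa = 300L,
                                    seed = 1L) {
  if (identity_target <= 0 || identity_target > 1) {
    stop("identity_target must be in (0, 1]")
  }
  if (consistency < 0 || consistency > 1) {
    stop("consistency must be in [0, 1]")
  }
  n_experiments <- as.integer(n_experiments)
  if (is.na(n_experiments) || n_experiments < 1L) {
    stop("n_experiments must be >= 1")
  }
  rng <- local_rng(seed)
  # gene A: random sense codons, no stops
  codons_a <- rng$sample(sense_codons(), length_aa, replace = TRUE)
  prot_a <- translate_codons(codons_a)
  codons_b <- codons_a
  prot_b <- prot_a
  identity <- 1
  attempts <- 0L
  tol <- 0.02 + 1e-9
  while (identity > identity_target + tol) {
    attempts <- attempts + 1L
    if (attempts > 100L * length_aa) {
      stop("identity target unreachable within attempt budget")
    }
    pos <- rng$sample_int(length_aa, 1L)
    new_codon <- rng$sample(sense_codons(), 1L)
    new_aa <- translate_codons(new_codon)
    if (new_aa == prot_a[pos]) next
    codons_b[pos] <- new_codon
    prot_b[pos] <- new_aa
    identity <- mean(prot_a == prot_b)
  }
  if (abs(identity - identity_target) > tol) {
    # overshoot can only happen on the last accepted substitution
    stop("could not land within 2 percentage points of identity target")
  }
  n_high <- round(consistency * n_experiments)
  base <- exp(rng$rnorm(n_experiments, meanlog_expression(), 0.5))
  ratio <- rep(1 / 1.5, n_experiments)
  if (n_high > 0L) ratio[rng$sample_int(n_experiments, n_high)] <- 1.5
  expr_b <- base
  expr_a <- base * ratio
  expression <- rbind(A = expr_a, B = expr_b)
  colnames(expression) <- paste0("exp", seq_len(n_experiments))
  list(
    proteins = c(A = paste(prot_a, collapse = ""),
                 B = paste(prot_b, collapse = "")),
    cds = c(A = paste(codons_a, collapse = ""),
            B = paste(codons_b, collapse = "")),
    expression = expression,
    identity = identity,
    n_higher_A = n_high
  )
}

#' Default log-scale mean for simulated expression values
#' @noRd
meanlog_expression <- function() 2
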
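#' Simulate a gene table with controlled rank correlations
#'
#' Gaussian-copula sampler: a multivariate normal with Pearson parameter
#' matrix `2 * sin(pi * r_s / 6)` (the exact Spearman-to-Pearson
#' conversion for the bivariate normal) is transformed column-wise through
#' the probability integral to the requested marginals. Because the
#' transforms are monotone, the empirical Spearman correlation of any two
#' columns converges to its target as `n_genes` grows.
#'
#' Supported marginal tags: `"lognormal"` (expression-like, meanlog 2,
#' sdlog 1), `"uniform"` (solubility-like fraction in \[0, 1\]), `"beta"`
#' (composition-fraction-like, shape 2 and 5). A tag may also be a
#' function mapping uniforms to values (a quantile function).
#'
#' @param n_genes number of rows (>= 10).
#' @param target_rank_corr symmetric positive-semidefinite matrix of
#'   target Spearman correlations with unit diagonal; its dimnames name
#'   the columns.
#' @param marginals named character vector (or list mixing tags and
#'   quantile functions) over the same column names.
#' @param seed integer seed.
#' @return data.frame with column `id` (gene identifiers) plus one column
#'   per variable.
#' @export
simulate_correlated_gene_table <- function(n_genes, target_rank_corr,
                                           marginals, seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 10L) stop("n_genes must be >= 10")
  r <- as.matrix(target_rank_corr)
  vars <- colnames(r)
  if (is.null(vars) || is.null(rownames(r)) || !identical(vars, rownames(r))) {
    stop("target_rank_corr needs matching row/column names")
  }
  if (!isSymmetric(unname(r)) || any(abs(diag(r) - 1) > 1e-12)) {
    stop("target matrix must be symmetric with unit diagonal")
  }
  if (!all(vars %in% names(marginals))) {
    stop("marginals missing for: ",
         paste(setdiff(vars, names(marginals)), collapse = ", "))
  }
  rho <- 2 * sin(pi * r / 6)
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("target correlation matrix is not positive semidefinite ",
         "(after Spearman-to-Pearson conversion)")
  }
  # eigendecomposition square root: works for PSD (chol would not)
  es <- eigen(rho, symmetric = TRUE)
  root <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), length(es$values))
  rng <- local_rng(seed)
  z <- rng$matrix_rnorm(n_genes, length(vars)) %*% t(root)
  u <- stats::pnorm(z)
  out <- data.frame(id = sprintf("g%05d", seq_len(n_genes)),
                    stringsAsFactors = FALSE)
  for (k in seq_along(vars)) {
    out[[vars[k]]] <- apply_marginal(u[, k], marginals[[vars[k]]])
  }
  out
}

#' @noRd
apply_marginal <- function(u, tag) {
  if (is.function(tag)) return(tag(u))
  switch(tag,
    lognormal = stats::qlnorm(u, meanlog = meanlog_expression(), sdlog = 1),
    uniform = u,
    beta = stats::qbeta(u, 2, 5),
    stop("unknown marginal tag: ", tag)
  )
}
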
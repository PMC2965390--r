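## Independent oracles used across tests. These deliberately re-derive
## quantities by the most literal method available (triple loops, full
## enumeration, closed forms) and share no code with the implementation.

# all-atom-pairs residue contact enumeration, plain loops
brute_force_contacts <- function(st, cutoff = 4.5, min_separation = 2L) {
  atoms <- st$atoms
  res <- sort(unique(atoms$res_index))
  out <- NULL
  for (ii in seq_along(res)) {
    for (jj in seq_along(res)) {
      if (jj - ii < min_separation) next
      ai <- atoms[atoms$res_index == res[ii], ]
      aj <- atoms[atoms$res_index == res[jj], ]
      found <- FALSE
      for (p in seq_len(nrow(ai))) {
        for (q in seq_len(nrow(aj))) {
          d <- sqrt((ai$x[p] - aj$x[q])^2 + (ai$y[p] - aj$y[q])^2 +
                      (ai$z[p] - aj$z[q])^2)
          if (d < cutoff) {
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (found) out <- rbind(out, c(ii, jj))
    }
  }
  if (is.null(out)) out <- matrix(integer(0), 0, 2)
  colnames(out) <- c("i", "j")
  out
}

# score-only affine-gap global alignment (Gotoh), Biostrings conventions:
# a gap of length k costs gap_open + k * gap_ext
nw_score <- function(a, b, mat, gap_open = 11, gap_ext = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consume a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consume b)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + i * gap_ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + j * gap_ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[a[i], b[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             Y[i + 1, j] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Spearman rho by explicit midrank computation then the Pearson formula
spearman_oracle <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- midrank(x)
  ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
wilcoxon_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% rk
  p_le <- mean(vs <= v_obs + 1e-9)
  p_ge <- mean(vs >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
mwu_exact_oracle <- function(a, b) {
  na <- length(a)
  pool <- c(a, b)
  rk <- rank(pool)
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  sel <- utils::combn(length(pool), na)
  us <- apply(sel, 2, function(idx) sum(rk[idx]) - na * (na + 1) / 2)
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# a small PDB text fixture with altloc copies and two models
pdb_altloc_text <- function() {
  c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       0.500   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.422   0.000  1.00  0.00           C",
    "END"
  )
}

pdb_two_model_text <- function() {
  c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      3  CA  ALA A   1       9.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  ALA A   2      12.800   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "END"
  )
}

# build a codon_alignment directly from two equal-length CDS strings
codon_aln <- function(cds_a, cds_b) {
  list(codons_a = clockcost:::split_codons(cds_a),
       codons_b = clockcost:::split_codons(cds_b))
}
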
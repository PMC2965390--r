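test_that("extended chains are contact-free and cluster contacts are forced", {
  fx <- make_structure("extended", 20)
  expect_equal(nrow(fx$contacts$contacts), 0L)
  ca <- fx$structure$atoms[fx$structure$atoms$atom == "CA", ]
  d <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
  expect_true(all(d >= 3.8 - 1e-6))

  cl <- make_structure("cluster", 3,
                       ca_positions = rbind(c(0, 0, 0), c(0, 10, 0),
                                            c(4, 0, 0)))
  expect_equal(cl$contacts$contacts,
               matrix(c(1L, 3L), 1, dimnames = list(NULL, c("i", "j"))))

  expect_error(make_structure("blob", 10), "arg")
  expect_error(make_structure("helix", 1), "length")
})

test_that("hairpin fixtures force the cross-strand register pairs", {
  fx <- make_structure("hairpin", 12)
  got <- fx$contacts$contacts
  key <- paste(got[, 1], got[, 2])
  for (i in 1:5) {
    expect_true(paste(i, 13 - i) %in% key, label = paste0("pair (", i, ",", 13 - i, ")"))
  }
})

test_that("structure generation is deterministic and coordinates finite", {
  a <- make_structure("cluster", 15, seed = 9)
  b <- make_structure("cluster", 15, seed = 9)
  expect_identical(a, b)
  expect_true(all(is.finite(as.matrix(a$structure$atoms[, c("x", "y", "z")]))))
  c2 <- make_structure("cluster", 15, seed = 10)
  expect_false(identical(a$structure$atoms, c2$structure$atoms))
})

test_that("coding-pair simulation honours omega and divergence targets", {
  # omega = 0: only synonymous changes, so proteins identical and Ka = 0
  p0 <- simulate_coding_pair(80, 0.2, omega = 0, seed = 3)
  prot <- function(cds) paste(
    clockcost:::translate_codons(clockcost:::split_codons(cds)),
    collapse = "")
  expect_identical(prot(p0$cds_ancestor), prot(p0$cds_descendant))
  expect_equal(p0$n_nonsyn, 0L)
  kk <- nei_gojobori(codon_aln(p0$cds_ancestor, p0$cds_descendant))
  expect_equal(kk$Ka, 0)
  expect_gt(kk$Ks, 0)

  # zero divergence: identical pair
  pz <- simulate_coding_pair(50, 0, omega = 0.5, seed = 4)
  expect_identical(pz$cds_ancestor, pz$cds_descendant)

  # no stop codons ever emitted
  p1 <- simulate_coding_pair(200, 0.4, omega = 1, seed = 5)
  for (cds in c(p1$cds_ancestor, p1$cds_descendant)) {
    aa <- clockcost:::translate_codons(clockcost:::split_codons(cds))
    expect_false("*" %in% aa)
  }
})

test_that("realized Nd/Sd tracks omega times the site ratio", {
  ratios <- vapply(1:40, function(s) {
    p <- simulate_coding_pair(500, 0.15, omega = 0.2, seed = s)
    (p$n_nonsyn / p$n_syn) / (p$N_sites_ancestor / p$S_sites_ancestor)
  }, numeric(1))
  expect_equal(mean(ratios), 0.2, tolerance = 0.15)
})

test_that("copula tables hit their rank-correlation targets", {
  tg <- matrix(c(1, 0.27, 0.27, 1), 2,
               dimnames = list(c("expression", "solubility"),
                               c("expression", "solubility")))
  tb <- simulate_correlated_gene_table(
    2000, tg, c(expression = "lognormal", solubility = "uniform"), seed = 11)
  r <- cor(rank(tb$expression), rank(tb$solubility))
  expect_equal(r, 0.27, tolerance = 0.05)
  expect_true(all(tb$expression > 0))
  expect_true(all(tb$solubility >= 0 & tb$solubility <= 1))

  # identity target: near-zero empirical correlation
  tg0 <- diag(2)
  dimnames(tg0) <- dimnames(tg)
  tb0 <- simulate_correlated_gene_table(
    2000, tg0, c(expression = "lognormal", solubility = "uniform"),
    seed = 12)
  expect_lt(abs(cor(rank(tb0$expression), rank(tb0$solubility))), 0.05)

  # minimal table: right shape, finite, in-support
  tb10 <- simulate_correlated_gene_table(
    10, tg, c(expression = "lognormal", solubility = "uniform"), seed = 13)
  expect_equal(nrow(tb10), 10L)
  expect_true(all(is.finite(tb10$expression)))

  # non-PSD target rejected
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(
    simulate_correlated_gene_table(100, bad,
                                   c(a = "uniform", b = "uniform",
                                     c = "uniform")),
    "positive semidefinite")
})

test_that("paralog families land on identity and consistency targets", {
  f1 <- simulate_paralog_family(1.0, 10, 0.9, seed = 1)
  expect_identical(f1$proteins[["A"]], f1$proteins[["B"]])
  expect_equal(f1$identity, 1)
  expect_equal(sum(f1$expression["A", ] > f1$expression["B", ]), 9)

  f5 <- simulate_paralog_family(0.5, 20, 0.75, seed = 2)
  al <- global_align(f5$proteins[["A"]], f5$proteins[["B"]])
  expect_gte(al$identity, 0.48 - 1e-9)
  expect_lte(al$identity, 0.52 + 1e-9)
  expect_equal(sum(f5$expression["A", ] > f5$expression["B", ]), 15)

  # a 5-residue protein cannot land inside a 2-point identity window at 0.5
  expect_error(simulate_paralog_family(0.5, 5, 0.8, length_aa = 5L,
                                       seed = 3),
               "identity target")
})

test_that("growth-curve generator is exact when noiseless and seeded", {
  g <- simulate_growth_curve(log(2), 0.05, 0:5, noise_sd = 0)
  expect_equal(g$od600, 0.05 * 2^(0:5))
  expect_error(simulate_growth_curve(0.5, -1, 0:3), "od0")
  expect_error(simulate_growth_curve(0.5, 0.1, c(0, 2, 1)), "increasing")
  a <- simulate_growth_curve(0.6, 0.05, seq(0, 5, 0.75), 0.05, seed = 8)
  b <- simulate_growth_curve(0.6, 0.05, seq(0, 5, 0.75), 0.05, seed = 8)
  expect_identical(a, b)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  r1 <- runif(2)
  set.seed(123)
  invisible(simulate_coding_pair(20, 0.1, 0.5, seed = 99))
  invisible(simulate_growth_curve(0.6, 0.05, 0:5, 0.01, seed = 99))
  invisible(make_structure("cluster", 8, seed = 99))
  r2 <- runif(2)
  expect_identical(r1, r2)
})

test_that("emitted files round-trip through the package readers", {
  fx <- make_structure("hairpin", 14)
  pdb <- tempfile(fileext = ".pdb")
  write_pdb(fx$structure, pdb)
  st <- parse_structure(pdb)
  expect_equal(n_residues(st), 14L)
  expect_equal(st$atoms$x, fx$structure$atoms$x, tolerance = 1e-3)

  fam <- simulate_paralog_family(0.8, 5, 0.8, length_aa = 60L, seed = 2)
  fa <- tempfile(fileext = ".faa")
  write_fasta(fam$proteins, fa)
  back <- read_fasta(fa)
  expect_identical(unname(back[c("A", "B")]), unname(fam$proteins))
})
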
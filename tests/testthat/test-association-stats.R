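test_that("spearman handles monotone, tied and degenerate inputs", {
  expect_equal(spearman(1:3, c(10, 20, 30))$r, 1)
  expect_equal(spearman(1:3, c(30, 20, 10))$r, -1)
  expect_error(spearman(1:5, rep(2, 5)), "constant")

  # midrank handling equals a literal midrank-then-Pearson oracle
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8, 4, 5)
  expect_equal(spearman(x, y)$r, spearman_oracle(x, y), tolerance = 1e-12)

  # rank statistics are invariant under strictly monotone transforms
  set.seed(31)
  a <- rlnorm(40)
  b <- a + rnorm(40, 0, 0.5)
  expect_equal(spearman(a, b)$r, spearman(log(a), exp(b))$r,
               tolerance = 1e-12)
})

test_that("spearman p-value branches are coherent", {
  # exact enumeration branch (n <= 7) equals a direct permutation scan
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1, 0.3)
  y <- c(2.0, 3.1, 2.5, 4.9, 5.2, 1.1)
  res <- spearman(x, y)
  perms6 <- clockcost:::perms(1:6)
  rx <- rank(x)
  ry <- rank(y)
  rs <- apply(perms6, 1, function(idx) cor(rx, ry[idx]))
  expect_equal(res$p, mean(abs(rs) >= abs(res$r) - 1e-12))

  # Monte-Carlo branch (8 <= n < 20) is seeded and near the t answer
  set.seed(77)
  x2 <- rnorm(15)
  y2 <- x2 + rnorm(15, 0, 2)
  p_mc1 <- spearman(x2, y2, seed = 5)$p
  p_mc2 <- spearman(x2, y2, seed = 5)$p
  expect_identical(p_mc1, p_mc2)
  r2 <- spearman(x2, y2)$r
  p_t <- 2 * pt(-abs(r2 * sqrt(13 / (1 - r2^2))), 13)
  expect_lt(abs(p_mc1 - p_t), 0.05)

  # large-n branch agrees with cor.test's t approximation
  set.seed(78)
  x3 <- rnorm(50)
  y3 <- x3 + rnorm(50)
  ct <- suppressWarnings(cor.test(x3, y3, method = "spearman"))
  expect_equal(spearman(x3, y3)$r, unname(ct$estimate), tolerance = 1e-12)
})

test_that("partial spearman follows the first-order formula", {
  # constructed null: r_xy == r_xz * r_yz gives partial r = 0
  set.seed(41)
  z <- rnorm(500)
  x <- z + rnorm(500)
  y <- z + rnorm(500)
  r_xy <- cor(rank(x), rank(y))
  r_xz <- cor(rank(x), rank(z))
  r_yz <- cor(rank(y), rank(z))
  ps <- partial_spearman(x, y, z)
  expect_equal(ps$r,
               (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2)),
               tolerance = 1e-12)
  expect_lt(abs(ps$r), 0.15)  # common cause removed

  # independent control barely changes the raw correlation
  tg <- diag(3)
  dimnames(tg) <- list(c("x", "y", "z"), c("x", "y", "z"))
  tg["x", "y"] <- tg["y", "x"] <- 0.4
  tb <- simulate_correlated_gene_table(
    5000, tg, c(x = "lognormal", y = "uniform", z = "beta"), seed = 6)
  raw <- spearman(tb$x, tb$y)$r
  prt <- partial_spearman(tb$x, tb$y, tb$z)$r
  expect_equal(prt, raw, tolerance = 0.03)

  expect_error(partial_spearman(1:10, rnorm(10), 1:10), "degenerate")
})

test_that("signed-rank test matches enumeration and base R", {
  # six positive differences: exact two-sided p = 2/2^6
  res <- wilcoxon_signed_rank_paired(2:7, 1:6)
  expect_equal(res$p, 0.03125)
  expect_equal(res$statistic, 21)

  expect_error(wilcoxon_signed_rank_paired(1:5, 1:5), "zero")

  # arbitrary fixed differences against the 2^8 enumeration oracle
  d <- c(1.5, -0.7, 2.2, 3.1, -0.2, 0.9, 1.1, -2.5)
  res8 <- wilcoxon_signed_rank_paired(d, rep(0, 8))
  expect_equal(res8$p, wilcoxon_exact_oracle(d))

  # tied magnitudes still get an exact enumeration (midranks)
  dt <- c(1, -1, 2, 2, -3, 4, 1, -2)
  expect_equal(wilcoxon_signed_rank_paired(dt, rep(0, 8))$p,
               wilcoxon_exact_oracle(dt))

  # tie-free exact branch agrees with stats::wilcox.test
  wt <- wilcox.test(d, rep(0, 8), paired = TRUE, exact = TRUE)
  expect_equal(res8$p, wt$p.value)
})

test_that("Mann-Whitney matches enumeration, base R and handles ties", {
  # complete separation at n = 3 vs 3: exact p = 2 / C(6,3) = 0.1
  res <- mann_whitney_u(c(7, 8, 9), c(1, 2, 3))
  expect_equal(res$p, 0.1)
  expect_equal(res$statistic, 9)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")

  # 5 vs 4 fixed data against the C(9,5) enumeration oracle
  a <- c(1.3, 2.7, 0.8, 3.3, 2.1)
  b <- c(1.9, 0.4, 2.9, 1.1)
  expect_equal(mann_whitney_u(a, b)$p, mwu_exact_oracle(a, b))
  expect_equal(mann_whitney_u(a, b)$p,
               wilcox.test(a, b, exact = TRUE)$p.value)

  # identical samples collapse to p = 1 in the approximation branch
  res_id <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res_id$p, 1)
  expect_match(res_id$method, "normal")

  # exact and normal branches agree within 10% at the switchover
  set.seed(55)
  a8 <- rnorm(8)
  b9 <- rnorm(9, 0.8)
  exact_p <- mann_whitney_u(a8, b9)$p
  N <- 17
  U <- mann_whitney_u(a8, b9)$statistic
  z <- (abs(U - 8 * 9 / 2) - 0.5) / sqrt(8 * 9 * (N + 1) / 12)
  approx_p <- 2 * pnorm(-z)
  expect_lt(abs(exact_p - approx_p) / exact_p, 0.1)
})

test_that("regression slope inference covers exact and degenerate fits", {
  x <- 1:10
  fit <- regression_slope(x, 2 * x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$p, 1e-15)      # perfect fit reports the floor

  fit0 <- regression_slope(x, rep(3, 10))
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$p, 1)

  expect_error(regression_slope(rep(1, 5), rnorm(5)), "constant")

  # noisy fixed set against the closed-form normal equations
  set.seed(61)
  y <- 1.5 * x + rnorm(10)
  fit2 <- regression_slope(x, y)
  bhat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ahat <- mean(y) - bhat * mean(x)
  s2 <- sum((y - ahat - bhat * x)^2) / 8
  se <- sqrt(s2 / sum((x - mean(x))^2))
  expect_equal(fit2$slope, bhat, tolerance = 1e-10)
  expect_equal(fit2$se, se, tolerance = 1e-10)
  expect_equal(fit2$p, 2 * pt(-abs(bhat / se), 8), tolerance = 1e-10)
})

test_that("slope difference test is null for equal slopes", {
  set.seed(62)
  x <- 1:8
  f1 <- regression_slope(x, 3 * x + rnorm(8))
  expect_equal(slope_difference_test(f1, f1)$p, 1)
  f2 <- regression_slope(x, 1 + 3 * x + rnorm(8))
  st <- slope_difference_test(f1, f2)
  expect_equal(st$t, (f1$slope - f2$slope) / sqrt(f1$se^2 + f2$se^2))
})

test_that("moving average trend equals a cumulative-sum oracle", {
  x <- rep(1, 10)
  tr <- moving_average_trend(x + 0:9, rep(5, 10), window = 4)
  expect_equal(tr$y, rep(5, 7))

  set.seed(63)
  xs <- rnorm(500)
  ys <- rnorm(500)
  tr2 <- moving_average_trend(xs, ys, window = 200)
  o <- order(xs)
  ys_s <- ys[o]
  cs <- cumsum(ys_s)
  oracle <- (cs[200:500] - c(0, cs[1:300])) / 200
  expect_equal(tr2$y, oracle, tolerance = 1e-12)
  expect_equal(nrow(tr2), 301L)

  expect_equal(moving_average_trend(1:5, c(2, 4, 6, 8, 10), window = 5)$y, 6)
  expect_error(moving_average_trend(1:5, 1:5, window = 6), "exceeds")
})

test_that("the association suite reports per-pair complete-case results", {
  tg <- diag(3)
  vars <- c("expression", "Ka", "Ks")
  dimnames(tg) <- list(vars, vars)
  tg["expression", "Ka"] <- tg["Ka", "expression"] <- -0.45
  tg["expression", "Ks"] <- tg["Ks", "expression"] <- -0.5
  tg["Ka", "Ks"] <- tg["Ks", "Ka"] <- 0.66
  tb <- simulate_correlated_gene_table(
    4000, tg, c(expression = "lognormal", Ka = "beta", Ks = "beta"),
    seed = 9)
  res <- run_association_suite(tb, list(
    list(x = "expression", y = "Ka"),
    list(x = "expression", y = "Ka", control = "Ks")
  ))
  expect_equal(res$r[1], -0.45, tolerance = 0.05)
  expect_lt(abs(res$r[2]), abs(res$r[1]))   # attenuated partial
  expect_equal(res$n, c(4000L, 4000L))

  # missing values are dropped pairwise with n reported
  tb$Ka[1:100] <- NA
  res2 <- run_association_suite(tb, list(list(x = "expression", y = "Ka")))
  expect_equal(res2$n, 3900L)

  expect_error(run_association_suite(tb, list(list(x = "nope", y = "Ka"))),
               "available")
  tb$Ka <- NA_real_
  expect_error(run_association_suite(tb, list(list(x = "expression",
                                                   y = "Ka"))),
               "finite")

  expect_equal(run_association_suite(
    data.frame(u = 1:5, v = c(2, 4, 6, 8, 10)),
    list(list(x = "u", y = "v")))$r, 1)
})
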
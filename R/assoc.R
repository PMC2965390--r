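## Rank-based association statistics: Spearman and partial Spearman
## correlation, paired signed-rank and Mann-Whitney tests, OLS slope
## inference, and moving-average trend extraction.

P_FLOOR <- 1e-15

#' @noRd
association_result <- function(method, r, n, p, controlled_for = NA_character_) {
  structure(
    list(method = method, r = r, n = as.integer(n),
         p = max(p, P_FLOOR), controlled_for = controlled_for),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  ctrl <- if (!is.na(x$controlled_for)) paste0(" | ", x$controlled_for) else ""
  p_txt <- if (x$p <= P_FLOOR) paste0("< ", format(P_FLOOR)) else
    format(x$p, digits = 3)
  cat(sprintf("%s%s: r = %.4f, n = %d, p = %s\n", x$method, ctrl, x$r,
              x$n, p_txt))
  invisible(x)
}

#' @noRd
complete_cases_xy <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  list(x = x[ok], y = y[ok], n = sum(ok))
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. The two-sided p-value uses the t
#' approximation with n - 2 degrees of freedom for n >= 20; below that,
#' exact enumeration over all permutations when n <= 7, otherwise a
#' seeded Monte-Carlo permutation test (10^4 permutations).
#'
#' @param x,y paired numeric vectors; non-finite pairs are dropped.
#' @param seed seed for the Monte-Carlo permutation branch.
#' @return an `association_result` (fields `method`, `r`, `n`, `p`,
#'   `controlled_for`). p-values are floored at 1e-15.
#' @export
spearman <- function(x, y, seed = 1L) {
  cc <- complete_cases_xy(x, y)
  if (cc$n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(cc$x)) == 1L || length(unique(cc$y)) == 1L) {
    stop("correlation undefined for a constant vector")
  }
  rx <- rank(cc$x)
  ry <- rank(cc$y)
  r <- stats::cor(rx, ry)
  n <- cc$n
  p <- if (n >= 20L) {
    spearman_p_t(r, n)
  } else if (n <= 7L) {
    all_p <- perms(seq_len(n))
    robs <- abs(r)
    rs <- apply(all_p, 1L, function(idx) stats::cor(rx, ry[idx]))
    mean(abs(rs) >= robs - 1e-12)
  } else {
    rng <- local_rng(seed)
    robs <- abs(r)
    hits <- 0L
    B <- 10000L
    for (b in seq_len(B)) {
      rp <- stats::cor(rx, ry[rng$sample_int(n)])
      if (abs(rp) >= robs - 1e-12) hits <- hits + 1L
    }
    (hits + 1L) / (B + 1L)
  }
  association_result("spearman", r, n, p)
}

#' @noRd
spearman_p_t <- function(r, n, df = n - 2L) {
  if (abs(r) >= 1) return(P_FLOOR)
  t <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t), df)
}

#' First-order partial Spearman correlation
#'
#' Partials the rank correlation of x and y on a control variable z via
#' the pairwise-correlation formula
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' with a two-sided t test on n - 3 degrees of freedom.
#'
#' @param x,y,z numeric vectors; rows with any non-finite value are
#'   dropped (triple-wise complete cases).
#' @param control_name label stored in the result.
#' @return an `association_result`.
#' @export
partial_spearman <- function(x, y, z, control_name = "z") {
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- sum(ok)
  if (n < 4L) stop("need at least 4 complete triples")
  r_xy <- stats::cor(rank(x), rank(y))
  r_xz <- stats::cor(rank(x), rank(z))
  r_yz <- stats::cor(rank(y), rank(z))
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    stop("degenerate control: |r| with z is 1")
  }
  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  p <- spearman_p_t(r, n, df = n - 3L)
  association_result("partial_spearman", r, n, p,
                     controlled_for = control_name)
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank statistic (sum of midranks of positive differences) over
#' nonzero paired differences. For 25 or fewer nonzero differences the
#' two-sided p-value is exact — the full sign-flip null distribution is
#' enumerated by convolution, which handles midranks from tied magnitudes
#' — otherwise a normal approximation with tie correction and continuity
#' correction is used. Two-sided p is twice the smaller tail, capped at 1.
#'
#' @param values_a,values_b paired numeric vectors.
#' @return list with `statistic` (V), `n` (nonzero differences), `p`,
#'   `method`.
#' @export
wilcoxon_signed_rank_paired <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("unpaired input lengths")
  d <- values_a - values_b
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero")
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  if (n <= 25L) {
    # exact null by convolution over doubled (integer) midranks
    r2 <- as.integer(round(2 * rk))
    dist <- c(1)                       # mass over values of 2V, offset 0
    for (ri in r2) {
      shifted <- c(numeric(ri), dist)
      dist <- c(dist, numeric(ri)) + shifted
    }
    dist <- dist / sum(dist)
    v2 <- round(2 * V)
    p_le <- sum(dist[seq_len(v2 + 1L)])
    p_ge <- sum(dist[seq(v2 + 1L, length(dist))])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "wilcoxon_signed_rank_exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- max(abs(V - mu) - 0.5, 0) / sqrt(sig2)
    p <- 2 * stats::pnorm(-z)
    method <- "wilcoxon_signed_rank_normal"
  }
  list(statistic = V, n = n, p = max(p, P_FLOOR), method = method)
}

#' Two-sample Mann-Whitney U test
#'
#' U computed from midranks (`U = R_a - n_a(n_a+1)/2`). The p-value is
#' exact (null enumeration of the U distribution) when the smaller group
#' has at most 8 observations and there are no ties, otherwise a normal
#' approximation with tie correction and continuity correction. Two-sided.
#'
#' @param group_a,group_b numeric samples (each non-empty).
#' @return list with `statistic` (U of group a), `n_a`, `n_b`, `p`,
#'   `method`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  na <- length(group_a)
  nb <- length(group_b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty")
  all_v <- c(group_a, group_b)
  rk <- rank(all_v)
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(all_v) > 0
  if (min(na, nb) <= 8L && !has_ties) {
    p_le <- stats::pwilcox(U, na, nb)
    p_ge <- 1 - stats::pwilcox(U - 1, na, nb)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "mann_whitney_exact"
  } else {
    N <- na + nb
    mu <- na * nb / 2
    ties <- table(all_v)
    sig2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- max(abs(U - mu) - 0.5, 0) / sqrt(sig2)
      p <- 2 * stats::pnorm(-z)
    }
    method <- "mann_whitney_normal"
  }
  list(statistic = U, n_a = na, n_b = nb, p = max(min(p, 1), P_FLOOR),
       method = method)
}

#' Ordinary least-squares slope with t test
#'
#' Fits `y ~ x` by OLS and tests slope = 0 two-sided with n - 2 degrees
#' of freedom. A perfect fit (zero residual variance) reports the p-value
#' floor for a nonzero slope and p = 1 for a zero slope.
#'
#' @param x,y numeric vectors, n >= 3, x not constant.
#' @return object of class `slope_fit`: list with `slope`, `intercept`,
#'   `se`, `df`, `p`, `n`, `r_squared`.
#' @export
regression_slope <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 points")
  if (length(unique(x)) == 1L) stop("x is constant: slope undefined")
  if (length(unique(y)) == 1L) {
    # constant response: slope exactly 0 with no evidence against it
    return(structure(
      list(slope = 0, intercept = y[1], se = 0, df = n - 2L, p = 1,
           n = n, r_squared = 0),
      class = "slope_fit"
    ))
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # perfect fits are a designed case
  slope <- unname(stats::coef(fit)[2])
  se <- sm$coefficients[2, 2]
  df <- fit$df.residual
  if (!is.finite(se) || se == 0) {
    p <- if (abs(slope) > 0) P_FLOOR else 1
    se <- 0
  } else {
    p <- max(2 * stats::pt(-abs(slope / se), df), P_FLOOR)
  }
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]), se = se,
         df = df, p = p, n = n,
         r_squared = if (is.nan(sm$r.squared)) 1 else sm$r.squared),
    class = "slope_fit"
  )
}

#' Welch t test for equality of two regression slopes
#'
#' `t = (b_a - b_b) / sqrt(se_a^2 + se_b^2)` with Welch-Satterthwaite
#' degrees of freedom, two-sided.
#'
#' @param fit_a,fit_b `slope_fit` objects from [regression_slope()].
#' @return list with `t`, `df`, `p`.
#' @export
slope_difference_test <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "slope_fit"), inherits(fit_b, "slope_fit"))
  if (fit_a$df < 1 || fit_b$df < 1) stop("need at least 1 residual df per fit")
  num <- fit_a$slope - fit_b$slope
  v <- fit_a$se^2 + fit_b$se^2
  if (v == 0) {
    return(list(t = 0, df = fit_a$df + fit_b$df,
                p = if (num == 0) 1 else P_FLOOR))
  }
  t <- num / sqrt(v)
  df <- v^2 / (fit_a$se^4 / fit_a$df + fit_b$se^4 / fit_b$df)
  list(t = t, df = df, p = max(2 * stats::pt(-abs(t), df), P_FLOOR))
}

#' Moving-average trend over sorted pairs
#'
#' Sorts the pairs by x ascending and emits the mean x and mean y of each
#' consecutive window of `window` points (n - window + 1 rows), the
#' smoother drawn through expression-descriptor scatter plots.
#'
#' @param x,y numeric vectors.
#' @param window window size (default 200; must not exceed n).
#' @return data.frame with columns `x` and `y`.
#' @export
moving_average_trend <- function(x, y, window = 200L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window > n) stop("window (", window, ") exceeds n (", n, ")")
  o <- order(x)
  x <- x[o]; y <- y[o]
  w <- rep(1 / window, window)
  mx <- stats::filter(x, w, sides = 1)
  my <- stats::filter(y, w, sides = 1)
  idx <- seq(window, n)
  data.frame(x = as.numeric(mx[idx]), y = as.numeric(my[idx]))
}

#' Run a battery of (partial) rank correlations over a gene table
#'
#' One Spearman — or, when a control column is given, partial Spearman —
#' correlation per requested triple, with pairwise/triple-wise
#' complete-case handling and the n actually used reported per row.
#'
#' @param table data.frame of per-gene values (a gene table).
#' @param pairs list of triples; each element is a list or character
#'   vector with elements `x`, `y` and optional `control`.
#' @param seed passed to [spearman()] for its Monte-Carlo branch.
#' @return data.frame with columns `x`, `y`, `control`, `method`, `r`,
#'   `n`, `p`.
#' @export
run_association_suite <- function(table, pairs, seed = 1L) {
  stopifnot(is.data.frame(table), length(pairs) > 0)
  rows <- lapply(pairs, function(pr) {
    pr <- as.list(pr)
    cols <- c(pr$x, pr$y, pr$control)
    missing_cols <- setdiff(cols, names(table))
    if (length(missing_cols) > 0) {
      stop("unknown column(s) ", paste(missing_cols, collapse = ", "),
           "; available: ", paste(setdiff(names(table), "id"),
                                  collapse = ", "))
    }
    x <- table[[pr$x]]
    y <- table[[pr$y]]
    if (all(!is.finite(x)) || all(!is.finite(y))) {
      stop("column with no finite values in pair (", pr$x, ", ", pr$y, ")")
    }
    res <- if (is.null(pr$control)) {
      spearman(x, y, seed = seed)
    } else {
      partial_spearman(x, y, table[[pr$control]],
                       control_name = pr$control)
    }
    data.frame(
      x = pr$x, y = pr$y,
      control = if (is.null(pr$control)) NA_character_ else pr$control,
      method = res$method, r = res$r, n = res$n, p = res$p,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
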
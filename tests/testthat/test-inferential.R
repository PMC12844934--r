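test_that("Welch ANOVA matches its k=2 and classical oracles", {
  # identical group means: zero between-group deviation
  g0 <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  wa0 <- welch_anova(g0)
  expect_equal(wa0$f_stat, 0)
  expect_equal(wa0$p, 1)

  # k = 2: F equals the squared Welch t (oracle: stats::t.test)
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5, 7)
  wa <- welch_anova(list(a, b))
  tt <- t.test(a, b)
  expect_equal(wa$f_stat, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(wa$df2, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(wa$p, tt$p.value, tolerance = 1e-12)

  # k = 2 with equal sample variances: Welch F = classical one-way F
  g1 <- c(1.2, 0.4, 2.2, 1.8); g2 <- g1 + 1  # same sample variance
  wa2 <- welch_anova(list(g1, g2))
  classic <- anova(lm(y ~ g, data.frame(y = c(g1, g2),
                                        g = rep(c("a", "b"), each = 4))))
  expect_equal(wa2$f_stat, classic$`F value`[1], tolerance = 1e-12)

  # agrees with base oneway.test on heteroscedastic data
  set.seed(2)
  g <- list(rnorm(8), rnorm(6, 1), rnorm(10, 0.5, 2))
  wa3 <- welch_anova(g)
  ow <- oneway.test(v ~ k, data.frame(v = unlist(g),
                                      k = rep(letters[1:3], sapply(g, length))))
  expect_equal(wa3$f_stat, unname(ow$statistic), tolerance = 1e-12)
  expect_equal(wa3$df2, unname(ow$parameter[2]), tolerance = 1e-12)
  expect_equal(wa3$p, ow$p.value, tolerance = 1e-12)

  expect_error(welch_anova(list(c(1, 1, 1), c(1, 2, 3))), "zero-variance")
  expect_error(welch_anova(list(c(1, 2))), "2")
})

test_that("Welch F is location invariant and scale invariant", {
  set.seed(3)
  g <- list(rnorm(5), rnorm(7, 1), rnorm(6, -1, 2))
  f0 <- welch_anova(g)$f_stat
  expect_equal(welch_anova(lapply(g, `+`, 100))$f_stat, f0,
               tolerance = 1e-9)
  expect_equal(welch_anova(lapply(g, `*`, 0.01))$f_stat, f0,
               tolerance = 1e-9)
})

test_that("Games-Howell reduces to the Welch t-test at k = 2", {
  # two identical groups: null case
  gh0 <- games_howell(list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)))
  expect_equal(gh0$mean_diff, 0)
  expect_equal(gh0$p, 1)

  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(4 + i %% 3, 0, 1); b <- rnorm(5, i / 10, 1.5)
    gh <- games_howell(list(a = a, b = b))
    tt <- t.test(a, b)
    # identity is exact; tolerance reflects ptukey's ~1e-5 numerics
    expect_equal(gh$p, tt$p.value, tolerance = 1e-4)
    expect_equal(gh$df, unname(tt$parameter), tolerance = 1e-9)
  }
})

test_that("Games-Howell p is monotone in the mean difference", {
  base <- list(a = c(5.1, 4.3, 6.0, 5.2), b = c(4.9, 5.5, 5.0, 5.8),
               c = c(5.3, 4.8, 5.6, 5.1))
  shifts <- c(0.2, 0.5, 1, 2, 4)
  ps <- sapply(shifts, function(d) {
    g <- base; g$b <- g$b + d  # variance unchanged
    gh <- games_howell(g)
    gh$p[gh$group_a == "a" & gh$group_b == "b"]
  })
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("Games-Howell family-wise type-I error is near alpha", {
  # 10,000 null replicates of k=3 equal-mean normal groups (n=10), run
  # through the same q/df computation the package applies (vectorised for
  # speed; equivalence with games_howell() is asserted on a subsample).
  set.seed(1)
  k <- 3; n <- 10; reps <- 10000
  X <- array(rnorm(k * n * reps), c(n, k, reps))
  m <- apply(X, c(2, 3), mean)
  v <- apply(X, c(2, 3), var)
  pairs <- combn(k, 2)
  pmat <- sapply(seq_len(ncol(pairs)), function(cix) {
    i <- pairs[1, cix]; j <- pairs[2, cix]
    se2 <- v[i, ] / n + v[j, ] / n
    df <- se2^2 / ((v[i, ] / n)^2 / (n - 1) + (v[j, ] / n)^2 / (n - 1))
    q <- abs(m[i, ] - m[j, ]) / sqrt(se2) * sqrt(2)
    ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
  })
  fwer <- mean(apply(pmat, 1, min) < 0.05)
  expect_lt(abs(fwer - 0.05), 0.01)
  for (r in c(1, 500, 9999)) {  # vectorised path == package function
    gh <- games_howell(list(X[, 1, r], X[, 2, r], X[, 3, r]))
    expect_equal(gh$p, unname(pmat[r, ]), tolerance = 1e-12)
  }
})

test_that("studentized-range tails agree with direct simulation", {
  # independent MC oracle for ptukey at k=3: range of 3 normals over
  # sqrt(chi2_df / df)
  set.seed(99)
  nsim <- 200000; df <- 12
  z <- matrix(rnorm(3 * nsim), ncol = 3)
  r <- (apply(z, 1, max) - apply(z, 1, min)) /
    sqrt(rchisq(nsim, df) / df)
  for (q0 in c(2.5, 3.5)) {
    p_mc <- mean(r > q0)
    p_ref <- ptukey(q0, 3, df, lower.tail = FALSE)
    expect_lt(abs(p_mc - p_ref), 3 * sqrt(p_ref * (1 - p_ref) / nsim))
  }
})

test_that("correlation matrices match explicit sum formulas", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  # oracle: explicit product-moment formula
  n <- 5
  r_hand <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  cm <- correlation_matrix(cbind(x = x, y = y))
  expect_equal(cm$r["x", "y"], r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  expect_equal(cm$p["x", "y"], 2 * pt(abs(t_hand), n - 2, lower.tail = FALSE),
               tolerance = 1e-12)

  # perfect linear: r = 1, strong
  cm1 <- correlation_matrix(cbind(x = x, y = 2 * x + 1))
  expect_equal(cm1$r["x", "y"], 1)
  expect_equal(cm1$strength["x", "y"], "strong")

  # orthogonal zero-mean: r = 0, none
  cm0 <- correlation_matrix(cbind(a = c(-1, 0, 1, 0), b = c(0, -1, 0, 1)))
  expect_equal(cm0$r["a", "b"], 0)
  expect_equal(cm0$strength["a", "b"], "none")

  # constant variable: undefined, flagged by NA
  cmc <- correlation_matrix(cbind(x = x, k = rep(2, 5)))
  expect_true(is.na(cmc$r["x", "k"]))
})

test_that("spearman equals pearson on midranks", {
  set.seed(12)
  X <- cbind(a = rnorm(15), b = rnorm(15), c = sample(1:5, 15, TRUE))  # ties
  sp <- correlation_matrix(X, "spearman")
  pr <- correlation_matrix(apply(X, 2, rank), "pearson")
  expect_equal(sp$r, pr$r, tolerance = 1e-12)
  expect_equal(unname(diag(sp$r)), rep(1, 3))
  expect_equal(sp$r, t(sp$r))
})
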
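test_that("PCA eigenstructure matches analytic oracles", {
  # rank-1 data: PC1 explains everything
  x <- rnorm(10)
  p1 <- pca_fit(cbind(a = x, b = 2 * x + 3), standardize = FALSE,
                n_components = 1)
  expect_equal(p1$explained_pct[1], 100, tolerance = 1e-9)

  # 3x3 toy: eigenvalues are the roots of the characteristic polynomial
  set.seed(31)
  X <- matrix(rnorm(30), 10, 3)
  S <- cov(scale(X))
  # char poly: -l^3 + tr l^2 - M2 l + det = 0
  m2 <- function(S) S[1,1]*S[2,2]-S[1,2]*S[2,1] +
    S[1,1]*S[3,3]-S[1,3]*S[3,1] + S[2,2]*S[3,3]-S[2,3]*S[3,2]
  roots <- sort(Re(polyroot(c(det(S), -m2(S), sum(diag(S)), -1))),
                decreasing = TRUE)
  p <- pca_fit(X, standardize = TRUE, n_components = 3)
  expect_equal(p$eigenvalues, roots, tolerance = 1e-8)

  # trace identity and full-rank score reconstruction
  expect_equal(sum(p$eigenvalues), sum(diag(S)), tolerance = 1e-9)
  Xs <- scale(X)
  recon <- p$scores %*% t(p$all_vectors[, 1:3])
  expect_equal(unname(recon), unname(Xs[, ]), tolerance = 1e-9,
               ignore_attr = TRUE)
  # unrotated scores are uncorrelated
  expect_equal(max(abs(cov(p$scores)[upper.tri(diag(3))])), 0,
               tolerance = 1e-9)

  # identity covariance at large n: near-uniform shares
  set.seed(32)
  big <- matrix(rnorm(4000 * 4), ncol = 4)
  pb <- pca_fit(big, n_components = 4)
  expect_true(all(abs(pb$explained_pct - 25) < 3))

  expect_error(pca_fit(cbind(x, 2 * x), standardize = FALSE,
                       n_components = 2), "rank")
})

test_that("varimax rotation is orthogonal, conserves communality, and
           maximizes the criterion", {
  # textbook 2-factor structure
  L <- matrix(c(0.8, 0.7, 0.6, 0.1, 0.2, 0.1,
                0.1, 0.2, 0.1, 0.7, 0.8, 0.6), ncol = 2)
  rot <- varimax_rotate(L)
  R <- attr(rot, "rotmat")
  expect_equal(t(R) %*% R, diag(2), tolerance = 1e-9)
  expect_equal(rowSums(rot^2), rowSums(L^2), tolerance = 1e-9)

  crit <- function(A) sum(apply(A^2, 2, function(z) mean(z^2) - mean(z)^2))
  # raw (non-Kaiser) rotation maximizes the raw criterion directly;
  # oracle: 1-degree grid over all planar rotations
  raw <- varimax_rotate(L, normalize = FALSE)
  grid <- sapply(seq(0, 89, by = 1) * pi / 180, function(th) {
    G <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
    crit(L %*% G)
  })
  expect_gte(crit(raw) + 1e-9, max(grid))
  expect_gte(crit(raw), crit(L))
  # Kaiser-normalized rotation maximizes the normalized criterion
  h <- sqrt(rowSums(L^2))
  expect_gte(crit(rot / h), crit(L / h) - 1e-12)

  # already-simple structure: rotation ~ identity up to sign/permutation
  Ls <- matrix(c(0.9, 0.85, 0, 0, 0, 0, 0.8, 0.9), ncol = 2)
  rs <- varimax_rotate(Ls)
  expect_equal(abs(attr(rs, "rotmat")), diag(2), tolerance = 0.05)

  # single column: no-op
  one <- varimax_rotate(L[, 1, drop = FALSE])
  expect_equal(unclass(one)[, 1], L[, 1])

  # at least as good as the reference implementation's optimum
  sv <- stats::varimax(L, normalize = FALSE, eps = 1e-8)
  expect_gte(crit(raw), crit(unclass(sv$loadings)) - 1e-6)
})

test_that("rotated PCA keeps total explained variance", {
  set.seed(33)
  X <- matrix(rnorm(120), 20, 6) %*% matrix(rnorm(36), 6)
  p <- pca_fit(X, rotate = "varimax", n_components = 2)
  pn <- pca_fit(X, rotate = "none", n_components = 2)
  expect_equal(sum(p$rot_explained_pct), sum(pn$explained_pct[1:2]),
               tolerance = 1e-6)
})

test_that("Ward clustering matches the naive O(n^3) oracle and hclust", {
  # two identical points merge at height zero
  h0 <- hca_ward(rbind(c(1, 2), c(1, 2)), standardize = FALSE)
  expect_equal(h0$height, 0)

  set.seed(41)
  X <- matrix(rnorm(10), 5, 2)
  rownames(X) <- letters[1:5]
  h <- hca_ward(X, standardize = FALSE)
  expect_equal(length(h$height), 4)  # n-1 merges
  oracle <- naive_ward(X)
  expect_equal(h$height, oracle$heights, tolerance = 1e-9)
  expect_equal(hca_member_sets(h), oracle$merges)

  # agreement with stats::hclust ward.D2 heights
  hc <- hclust(dist(X), method = "ward.D2")
  expect_equal(sort(h$height), sort(hc$height), tolerance = 1e-9)

  expect_error(hca_ward(X, labels = rep("a", 5)), "duplicate")
})

test_that("Ward result is invariant to observation order", {
  set.seed(42)
  X <- matrix(rnorm(24), 8, 3)
  rownames(X) <- sprintf("o%d", 1:8)
  perm <- sample(8)
  h1 <- hca_ward(X)
  h2 <- hca_ward(X[perm, ])
  expect_equal(h1$height, h2$height, tolerance = 1e-9)
  for (k in 2:4) {
    c1 <- cut_clusters(h1, k)
    c2 <- cut_clusters(h2, k)[names(c1)]
    expect_equal(adjusted_rand_index(c1, c2), 1)
  }
})

test_that("cut_clusters and as_hclust agree with stats::cutree", {
  set.seed(43)
  X <- matrix(rnorm(30), 10, 3)
  rownames(X) <- sprintf("s%d", 1:10)
  h <- hca_ward(X)
  hc <- as_hclust(h)
  for (k in c(2, 3, 5)) {
    expect_equal(adjusted_rand_index(cut_clusters(h, k),
                                     cutree(hc, k)[h$labels]), 1)
  }
})

test_that("stepwise LDA selects the discriminating variable first", {
  set.seed(51)
  n <- 12
  X <- cbind(v = c(rnorm(n), rnorm(n, 4)), n1 = rnorm(2 * n),
             n2 = rnorm(2 * n))
  g <- rep(c("A", "B"), each = n)
  ld <- lda_stepwise(X, g)
  expect_equal(ld$selected_vars[1], "v")
  # Wilks path strictly decreasing
  expect_true(all(diff(ld$wilks_lambda_path) < 0) ||
                length(ld$wilks_lambda_path) == 1)
  # scores have identity pooled within-group covariance
  W <- matrix(0, ncol(ld$scores), ncol(ld$scores))
  for (gi in unique(g)) {
    S <- ld$scores[g == gi, , drop = FALSE]
    W <- W + crossprod(sweep(S, 2, colMeans(S)))
  }
  expect_equal(unname(W / (2 * n - 2)), diag(ncol(ld$scores)),
               tolerance = 1e-9)
})

test_that("two-group LDA recovers Fisher's discriminant direction", {
  set.seed(52)
  n <- 15
  X <- cbind(a = c(rnorm(n), rnorm(n, 2)),
             b = c(rnorm(n), rnorm(n, 1)))
  g <- rep(c("A", "B"), each = n)
  ld <- lda_stepwise(X, g, alpha_enter = 0.5)
  # oracle: closed-form Fisher direction W^-1 (m1 - m2)
  m1 <- colMeans(X[g == "A", ld$selected_vars, drop = FALSE])
  m2 <- colMeans(X[g == "B", ld$selected_vars, drop = FALSE])
  W <- matrix(0, length(ld$selected_vars), length(ld$selected_vars))
  for (gi in c("A", "B")) {
    Xg <- X[g == gi, ld$selected_vars, drop = FALSE]
    W <- W + crossprod(sweep(Xg, 2, colMeans(Xg)))
  }
  fisher <- solve(W, m1 - m2)
  a <- ld$discriminant_axes[, 1]
  cosang <- abs(sum(fisher * a)) / sqrt(sum(fisher^2) * sum(a^2))
  expect_equal(cosang, 1, tolerance = 1e-9)
})

test_that("null groups rarely admit a variable", {
  set.seed(53)
  reps <- 200
  entered <- logical(reps)
  for (r in seq_len(reps)) {
    X <- cbind(a = rnorm(20), b = rnorm(20))
    g <- rep(c("A", "B"), each = 10)
    ld <- suppressWarnings(lda_stepwise(X, g))
    entered[r] <- ld$status == "ok"
  }
  # two independent candidates at alpha 0.05: entry prob ~ 1 - 0.95^2
  expect_lt(abs(mean(entered) - (1 - 0.95^2)), 0.07)
})
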
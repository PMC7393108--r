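# Correlation machinery, PCA conventions, centroid clustering.

test_that("Pearson correlation matches the closed-form oracle", {
  r1 <- pearson(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r1$r, 1)
  expect_equal(pearson(c(1, 2, 3), c(6, 4, 2))$r, -1)

  set.seed(3)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  res <- pearson(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((30 - 2) / (1 - r^2))
  expect_equal(res$r, r, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t), 28), tolerance = 1e-12)
  # symmetric, affine-invariant (sign-aware)
  expect_equal(pearson(y, x)$r, res$r)
  expect_equal(pearson(2 * x + 5, y)$r, res$r, tolerance = 1e-12)
  expect_equal(pearson(-x, y)$r, -res$r, tolerance = 1e-12)
  expect_error(pearson(rep(1, 10), rnorm(10)), "variance")
})

test_that("significance stars follow the 0.1/0.05/0.01 convention", {
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 2, 3, 4.0001))$stars, "***")
  set.seed(8)
  res <- pearson(rnorm(10), rnorm(10))
  expect_true(res$stars %in% c("", "*", "**", "***"))
})

test_that("partial correlation equals the inverse-matrix oracle", {
  set.seed(12)
  n <- 60
  z <- rnorm(n)
  x <- 0.7 * z + rnorm(n, sd = 0.5)
  y <- -0.6 * z + rnorm(n, sd = 0.5)
  res <- partial_correlation(x, y, controls = data.frame(z = z))

  # oracle: inverse of the sample correlation matrix
  P <- solve(cor(cbind(x, y, z)))
  r_oracle <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$controls, "z")

  # empty control set reduces exactly to pearson
  res0 <- partial_correlation(x, y)
  p0 <- pearson(x, y)
  expect_equal(res0$r, p0$r)
  expect_equal(res0$p, p0$p)

  # y identical to the control: residual is zero, partial r = 0
  resc <- partial_correlation(x, z, controls = data.frame(z = z))
  expect_equal(resc$r, 0)

  # independent control barely changes the correlation
  w <- rnorm(n)
  expect_lt(abs(partial_correlation(x, y, data.frame(w = w))$r -
                pearson(x, y)$r), 0.1)

  expect_error(partial_correlation(x, y, cbind(z, z)), "rank")
})

test_that("trait PCA follows the correlation-matrix conventions", {
  # two perfectly correlated columns: one axis explains everything
  d2 <- data.frame(a = 1:10, b = 2 * (1:10) + 3)
  p2 <- pca_traits(d2, flip = character(0))
  expect_equal(p2$explained_fraction[1], 1)

  # uncorrelated columns: fractions near 1/p, always summing to 1
  set.seed(15)
  dU <- as.data.frame(matrix(rnorm(600), 100, 6))
  pU <- pca_traits(dU, flip = character(0))
  expect_equal(sum(pU$explained_fraction), 1, tolerance = 1e-12)
  expect_true(all(abs(pU$explained_fraction - 1 / 6) < 0.15))

  # sign-flip of a column leaves explained fractions unchanged
  tab <- make_plot_table(36, default_effect_matrix(), seed = 20)
  pa <- pca_traits(tab[, trait_columns()], flip = c("ltd", "tdr"))
  pb <- pca_traits(tab[, trait_columns()], flip = character(0))
  expect_equal(pa$explained_fraction, pb$explained_fraction,
               tolerance = 1e-12)

  # scores are uncorrelated across axes; sign convention holds
  S <- cov(pa$scores)
  expect_lt(max(abs(S[upper.tri(S)])), 1e-8)
  for (j in seq_len(ncol(pa$loadings)))
    expect_gt(pa$loadings[which.max(abs(pa$loadings[, j])), j], 0)

  cst <- tab[, trait_columns()]; cst$lai <- 1
  expect_error(pca_traits(cst), "constant|lai")
})

test_that("centroid clustering matches the O(n^3) oracle", {
  # three 1-D items: nearest pair merges first
  X <- matrix(c(0, 0.1, 10), ncol = 1)
  m <- brute_centroid_merges(X)
  expect_equal(m[[1]]$members, c(1, 2))

  set.seed(25)
  for (rep in 1:5) {
    tab <- as.data.frame(matrix(rnorm(8 * 12), nrow = 12))
    names(tab) <- paste0("t", 1:8)
    hc <- cluster_traits(tab, cols = names(tab))
    Xp <- t(scale(as.matrix(tab)))
    oracle <- brute_centroid_merges(Xp)
    sets <- hclust_merge_sets(hc)
    for (s in seq_along(sets)) {
      expect_equal(sets[[s]], oracle[[s]]$members)
      expect_equal(hc$height[s], oracle[[s]]$height, tolerance = 1e-9)
    }
  }

  # identical items merge first at height zero
  dup <- data.frame(a = rnorm(6), b = rnorm(6))
  dup$b <- dup$a
  hc2 <- cluster_traits(dup, cols = c("a", "b"))
  expect_equal(hc2$height[1], 0)

  expect_error(cluster_traits(data.frame(a = 1:5, b = 1:5),
                              cols = c("a", "a")), "duplicate")
})

test_that("environment-trait matrix flags injected effects", {
  cols <- c(trait_columns(), env_columns())
  eff <- diag(25); dimnames(eff) <- list(cols, cols)
  eff["map", "height"] <- eff["height", "map"] <- 0.8
  tab <- make_plot_table(36, eff, seed = 30)
  em <- env_trait_matrix(tab)
  expect_equal(dim(em$r), c(13L, 12L))
  expect_equal(em$n, 36L)
  # r = 0.8 at n = 36 is detected at the *** level with high power
  expect_equal(em$stars["map", "height"], "***")
  expect_gt(em$r["map", "height"], 0.5)

  bad <- tab; bad$pdsi <- 0
  expect_error(env_trait_matrix(bad), "pdsi")
})

test_that("null plot tables give a calibrated false-positive rate", {
  hits <- 0; total <- 0
  for (seed in 1:6) {
    tab <- make_plot_table(36, seed = 100 + seed)
    em <- env_trait_matrix(tab)
    hits <- hits + sum(em$p < 0.05)
    total <- total + length(em$p)
  }
  # 936 null tests: rate should be near 5% (binomial 3 SD ~ 2.1%)
  expect_lt(abs(hits / total - 0.05), 0.025)
})
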
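# Synthetic-forest generator: geometry, determinism, envelope quantiles,
# plot-table correlation structure.

test_that("make_tree geometry matches its analytic ground truth", {
  tr <- make_tree(height = 8, crown_base = 3, dbh = 0.2,
                  crown_semi_axes = c(2, 2, 2.5), leaf_point_count = 5000,
                  seed = 1)
  z <- tr$cloud$points[, "z"]
  expect_equal(min(z), 0)
  expect_lt(abs(max(z) - 8), 0.05)
  expect_equal(tr$truth$ca, 4 * pi)
  expect_equal(tr$truth$height, 8)
  expect_equal(tr$truth$clr, 3 / 8)

  # trunk-only cloud when no leaves are requested
  t2 <- make_tree(8, 3, 0.2, c(2, 2, 2.5), leaf_point_count = 0, seed = 1)
  expect_lte(max(t2$cloud$points[, "z"]), 3)
  r <- sqrt(rowSums(t2$cloud$points[, 1:2]^2))
  expect_true(all(abs(r - 0.1) < 1e-9))
})

test_that("make_tree is deterministic and validates its parameters", {
  a <- make_tree(8, 3, 0.2, c(2, 2, 2.5), seed = 42)
  b <- make_tree(8, 3, 0.2, c(2, 2, 2.5), seed = 42)
  expect_identical(a$cloud$points, b$cloud$points)
  c <- make_tree(8, 3, 0.2, c(2, 2, 2.5), seed = 43)
  expect_false(identical(a$cloud$points, c$cloud$points))

  expect_error(make_tree(-1, 0, 0.2, c(1, 1, 1)), "height")
  expect_error(make_tree(8, 9, 0.2, c(1, 1, 1)), "height")
  expect_error(make_tree(8, 3, -0.2, c(1, 1, 1)), "dbh")
  expect_error(make_tree(8, 3, 0.2, c(1, -1, 1)), "crown_semi_axes")
  expect_error(make_tree(8, 3, 0.2, c(2, 2, 2.5), leaf_point_count = -5),
               "leaf_point_count")
})

test_that("multi-stem trees have disjoint breast-height slices", {
  tr <- make_tree(8, 3, 0.10, c(2, 2, 2.5),
                  stem_diameters_1m = c(0.10, 0.06), leaf_point_count = 0,
                  seed = 5)
  p <- tr$cloud$points
  sl <- p[abs(p[, "z"] - 1.3) <= 0.05, 1:2]
  comp <- cutree(hclust(dist(sl), "single"), h = 0.1)
  expect_equal(length(unique(comp)), 2L)
  expect_equal(tr$truth$tdr, 2 * (0.16 / 0.10))
})

test_that("envelope tables have the requested conditional quantiles", {
  # degenerate envelope: both curves y = x
  tab <- make_envelope_table(50, c(1, 5), c(1, 1), c(1 + 1e-9, 1), seed = 1)
  expect_equal(tab$y, tab$x, tolerance = 1e-6)

  # empirical 5%/95% quantiles binned by x match the generating curves
  lower <- c(3.73e-5, 4.62); upper <- c(11.48, 0.546)
  tab <- make_envelope_table(5000, c(2, 14), lower, upper, seed = 11)
  bins <- cut(tab$x, breaks = seq(2, 14, by = 3))
  for (b in levels(bins)) {
    sel <- bins == b
    xc <- median(tab$x[sel])
    # transform to the latent scale at the bin median to undo x-dependence
    q5 <- quantile(tab$y[sel] / (lower[1] * tab$x[sel]^lower[2]), 0.05,
                   names = FALSE)
    q95 <- quantile(tab$y[sel] / (upper[1] * tab$x[sel]^upper[2]), 0.95,
                    names = FALSE)
    expect_lt(abs(q5 - 1), 0.35)   # Monte-Carlo error at ~1250 per bin
    expect_lt(abs(q95 - 1), 0.35)
  }

  # determinism and validation
  expect_identical(make_envelope_table(20, c(1, 2), c(1, 1), c(2, 1), seed = 3),
                   make_envelope_table(20, c(1, 2), c(1, 1), c(2, 1), seed = 3))
  expect_error(make_envelope_table(100, c(1, 10), c(2, 1), c(1, 1)), "cross")
  expect_error(make_envelope_table(5, c(1, 2), c(1, 1), c(2, 1)), "n")
})

test_that("plot tables reproduce requested correlation structure", {
  cols <- c(trait_columns(), env_columns())
  expect_length(cols, 25L)

  tab <- make_plot_table(36, seed = 2)
  expect_equal(nrow(tab), 36L)
  expect_identical(names(tab), c("plot_id", cols))

  # identity structure: sampling-error bound on empirical correlations
  big <- make_plot_table(500, seed = 4)
  R <- cor(as.matrix(big[, cols]))
  expect_lt(max(abs(R[upper.tri(R)])), 0.15)

  # injected correlation is recovered within the Fisher-z interval
  eff <- diag(25); dimnames(eff) <- list(cols, cols)
  eff["map", "height"] <- eff["height", "map"] <- 0.8
  tab2 <- make_plot_table(500, eff, seed = 6)
  expect_lt(abs(cor(tab2$map, tab2$height) - 0.8), 0.05)

  bad <- matrix(0.99, 25, 25); diag(bad) <- 1
  bad[1, 2] <- bad[2, 1] <- -0.99
  expect_error(make_plot_table(10, bad), "positive semi-definite")
})

test_that("branch tables carry consistent ground-truth ratios", {
  bt <- make_branch_table(6, second_per_first = 2, seed = 9)
  r <- branch_ratios(bt$table)
  expect_equal(unname(r["sl_fl"]), bt$truth$sl_fl)
  expect_equal(unname(r["sc_fc"]), bt$truth$sc_fc)
})
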
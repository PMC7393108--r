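# Stem trait extraction: height, Taubin circles, DBH, crown base, hulls,
# canopy area, TDR, branch ratios, percentage cover.

test_that("tree height is the z range and is invariant to xy transforms", {
  expect_equal(tree_height(tree_cloud(rbind(c(0, 0, 0), c(0, 0, 5.5)))), 5.5)
  tr <- make_tree(8, 3, 0.2, c(2, 2, 2.5), leaf_point_count = 2000, seed = 2)
  h <- tree_height(tr$cloud)
  expect_lt(abs(h - 8) / 8, 0.01)
  expect_equal(tree_height(rotate_z(tr$cloud, 1.1)), h)
  expect_error(tree_height(tree_cloud(matrix(0, 1, 3))), "2 points")
})

test_that("Taubin circle fit is exact on noise-free circles", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  p <- cbind(1 + 0.15 * cos(th), 2 + 0.15 * sin(th))
  f <- fit_circle_taubin(p)
  expect_equal(unname(f), c(1, 2, 0.15), tolerance = 1e-9)

  # three points: exact circumcircle (closed-form oracle)
  p3 <- rbind(c(0, 0), c(2, 0), c(0, 1.5))
  expect_equal(fit_circle_taubin(p3), circumcircle(p3), tolerance = 1e-9)

  expect_error(fit_circle_taubin(cbind(1:5, 2 * (1:5) + 1)), "collinear")
  expect_error(fit_circle_taubin(p3[1:2, ]), "3 points")
})

test_that("Taubin fit matches the geometric least-squares fit under noise", {
  set.seed(21)
  for (rep in 1:5) {
    th <- runif(200, 0, 2 * pi)
    p <- cbind(1 + 0.15 * cos(th), 2 + 0.15 * sin(th)) +
      matrix(rnorm(400, sd = 0.005), ncol = 2)
    f <- fit_circle_taubin(p)
    g <- geometric_circle_fit(p)
    expect_lt(abs(f[["r"]] - 0.15), 0.005)
    expect_lt(abs(f[["r"]] - g[["r"]]) / g[["r"]], 1e-3)
  }
})

test_that("DBH recovers cylinder diameters, including multi-stem trees", {
  tr <- make_tree(8, 3, 0.2, c(2, 2, 2.5), leaf_point_count = 0, seed = 1)
  d <- dbh(tr$cloud)
  expect_equal(d$dbh, 0.2, tolerance = 1e-6)

  tr2 <- make_tree(8, 3, 0.10, c(2, 2, 2.5),
                   stem_diameters_1m = c(0.10, 0.06),
                   leaf_point_count = 0, seed = 2)
  d2 <- dbh(tr2$cloud)
  expect_equal(d2$stem_diameters, c(0.10, 0.06), tolerance = 1e-6)
  expect_equal(d2$dbh, 0.10, tolerance = 1e-6)

  two <- tree_cloud(rbind(c(0, 0, 0), c(0, 0, 2)))
  expect_error(dbh(two, slice_center = 1.3, slice_halfwidth = 0),
               "breast height")
})

test_that("Graham hull matches oracles and is idempotent", {
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2), c(1, 1))
  h <- graham_hull(sq)
  expect_equal(nrow(h$vertices), 4L)
  expect_equal(polygon_area(h), 4)

  # library oracle on 100 random sets
  set.seed(31)
  for (i in 1:100) {
    p <- matrix(runif(2 * sample(20:200, 1)), ncol = 2)
    h <- graham_hull(p)
    oracle <- p[rev(grDevices::chull(p)), , drop = FALSE]
    expect_equal(sort(apply(h$vertices, 1, paste, collapse = ",")),
                 sort(apply(oracle, 1, paste, collapse = ",")))
  }

  # brute-force point-in-triangle oracle on small sets
  for (i in 1:5) {
    p <- matrix(rnorm(2 * 40), ncol = 2)
    h <- graham_hull(p)
    bv <- brute_hull_vertices(p)
    expect_equal(sort(apply(h$vertices, 1, paste, collapse = ",")),
                 sort(apply(bv, 1, paste, collapse = ",")))
  }

  # hull of hull is the hull
  p <- matrix(runif(400), ncol = 2)
  h1 <- graham_hull(p)
  h2 <- graham_hull(h1$vertices)
  expect_equal(h2$vertices[order(h2$vertices[, 1], h2$vertices[, 2]), ],
               h1$vertices[order(h1$vertices[, 1], h1$vertices[, 2]), ])

  expect_error(graham_hull(cbind(1:9, 2 * (1:9))), "collinear")
})

test_that("polygon area follows the shoelace formula and its invariances", {
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  # rigid motion invariance
  v <- rbind(c(0, 0), c(3, 0), c(3, 2), c(1, 3))
  a <- polygon_area(v)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(polygon_area(sweep(v %*% R, 2, c(5, -2), "+")), a,
               tolerance = 1e-12)
  expect_error(polygon_area(v[1:2, ]), "3 vertices")
})

test_that("crown base localizes the trunk-to-canopy transition", {
  tr <- make_tree(8, 3, 0.2, c(2, 2, 2.5), leaf_point_count = 8000, seed = 4)
  cb <- crown_base(tr$cloud)
  expect_false(attr(cb, "warning_flag"))
  expect_lte(abs(as.numeric(cb) - 3), 0.25)

  # crown reaching the ground
  g <- make_tree(5, 0, 0.2, c(2, 2, 2.5), leaf_point_count = 8000, seed = 5)
  expect_lte(as.numeric(crown_base(g$cloud)), 0.25)

  # bare trunk: 0 with a warning flag
  t0 <- make_tree(8, 3, 0.2, c(2, 2, 2.5), leaf_point_count = 0, seed = 6)
  expect_warning(cb0 <- crown_base(t0$cloud), "trunk|flat|persistent")
  expect_equal(as.numeric(cb0), 0)
  expect_true(attr(cb0, "warning_flag"))
})

test_that("canopy area approaches the true maximum cross-section", {
  tr <- make_tree(8, 3, 0.2, c(2, 2, 2.5), leaf_point_count = 20000, seed = 7)
  ca <- canopy_area(tr$cloud, crown_base = 3)
  expect_lt(abs(ca - 4 * pi) / (4 * pi), 0.05)

  # robust to layer thickness on a smooth crown profile
  ca2 <- canopy_area(tr$cloud, crown_base = 3, layer = 1)
  expect_lt(abs(ca2 - ca) / ca, 0.05)

  # all canopy points in one plane: hull area of that plane
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  disc <- cbind(2 * cos(th), 2 * sin(th), 5)
  cl <- tree_cloud(rbind(matrix(c(0, 0, 0), 1), disc))
  expect_equal(canopy_area(cl, crown_base = 4), polygon_area(graham_hull(disc[, 1:2])))

  expect_error(canopy_area(tr$cloud, crown_base = 100), "crown base")
})

test_that("trunk dominance ratio follows the stem-inventory formula", {
  expect_equal(tdr(0.10), 1)
  expect_equal(tdr(c(0.10, 0.05, 0.05)), 3 * (0.20 / 0.10))
  # n equal stems give n^2
  for (n in c(2, 4, 7)) expect_equal(tdr(rep(0.08, n)), n^2)
  expect_error(tdr(numeric(0)), "empty")
  expect_error(tdr(c(0.1, -0.2)), "positive")
})

test_that("branch ratios use totals and validate the table", {
  tab <- data.frame(
    branch_id = c("f1", "f2", "s1", "s2", "s3", "s4"),
    order = c(1L, 1L, 2L, 2L, 2L, 2L),
    length_m = c(2, 2, 1, 1, 1, 1),
    parent_id = c(NA, NA, "f1", "f1", "f2", "f2"))
  r <- branch_ratios(tab)
  expect_equal(unname(r), c(1.0, 2.0))

  none <- tab[tab$order == 1L, ]
  expect_equal(unname(branch_ratios(none)), c(0, 0))

  expect_error(branch_ratios(rbind(tab, tab[1, ])), "duplicate")
  bad <- tab; bad$parent_id[3] <- "nope"
  expect_error(branch_ratios(bad), "parent")
})

test_that("percentage cover counts occupied grid cells above min height", {
  # one crown occupying exactly 16 cells of a 50 x 50 grid
  set.seed(41)
  pts <- cbind(runif(2000, 10, 12), runif(2000, 10, 12), 3)
  expect_equal(percent_cover(list(tree_cloud(pts))), 16 / 2500 * 100)

  # full coverage
  g <- expand.grid(x = seq(0.25, 24.75, 0.5), y = seq(0.25, 24.75, 0.5))
  full <- tree_cloud(cbind(g$x, g$y, 5))
  expect_equal(percent_cover(list(full)), 100)

  # min_h above all points
  expect_equal(percent_cover(list(full), min_h = 10), 0)
  expect_equal(percent_cover(list()), 0)
})

test_that("geometric traits are invariant to rotation about z", {
  tr <- make_tree(8, 3, 0.2, c(2, 1.5, 2.5), leaf_point_count = 6000,
                  seed = 8)
  rot <- rotate_z(tr$cloud, 0.9)
  expect_equal(dbh(rot)$dbh, dbh(tr$cloud)$dbh, tolerance = 1e-9)
  expect_equal(canopy_area(rot, 3), canopy_area(tr$cloud, 3),
               tolerance = 1e-9)
  expect_equal(as.numeric(crown_base(rot)), as.numeric(crown_base(tr$cloud)))
})
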
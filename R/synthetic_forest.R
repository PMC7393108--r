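# Synthetic single trees, allometric envelope samples, and plot-level
# trait/environment tables with analytic ground truth.

#' Simulate a single-tree point cloud with analytic ground truth
#'
#' Builds a stylized broadleaf tree as seen by a multi-station terrestrial
#' laser scan: each stem is a vertical cylinder *surface* sampled on a
#' regular grid from the ground to the crown base, and the crown is an
#' ellipsoid filled with uniformly distributed leaf points.  Multi-stem
#' trees place their stems on a circle of radius equal to the sum of stem
#' radii, so breast-height slices are disjoint and per-stem circle fits are
#' well posed.  The returned ground truth carries the trait values implied
#' analytically by the parameters (e.g. true canopy area `pi*rx*ry`).
#'
#' @param height Nominal tree height (m); must exceed `crown_base` and be
#'   consistent with the crown geometry (`crown_base + 2*rz`).
#' @param crown_base Height under the crown (m, >= 0).
#' @param dbh Breast-height diameter of the dominant stem (m).
#' @param crown_semi_axes Ellipsoid semi-axes `c(rx, ry, rz)` in m.
#' @param stem_diameters_1m Diameters of all stems at 1 m aboveground (m);
#'   defaults to `dbh` (single dominant trunk).  Cylinders have constant
#'   radius, so these equal the breast-height diameters too.
#' @param leaf_area_density One-sided leaf area per crown volume (m2/m3).
#' @param trunk_point_spacing Grid spacing of trunk surface points (m).
#' @param leaf_point_count Number of leaf points in the crown.
#' @param jitter_sd Gaussian ranging noise SD in m (0 = noiseless).
#' @param seed Integer RNG seed; identical seeds give identical clouds.
#' @param tree_id,plot_id Identifiers stored on the cloud.
#' @return A list with elements `cloud` (a [tree_cloud()], already
#'   normalized) and `truth` (named list: `height`, `crown_base`, `clr`,
#'   `dbh`, `ca`, `lai`, `tdr`, `stem_diameters_1m`, `beam_radius` — the
#'   ray radius at which the discrete leaf points reproduce the optical
#'   density of a medium with the requested `leaf_area_density` under a
#'   spherical leaf-angle distribution, G = 0.5).
#' @export
make_tree <- function(height, crown_base, dbh, crown_semi_axes,
                      stem_diameters_1m = dbh,
                      leaf_area_density = 0.5,
                      trunk_point_spacing = 0.02,
                      leaf_point_count = 2000L,
                      jitter_sd = 0, seed = 1L,
                      tree_id = "tree", plot_id = "plot") {
  if (!is.numeric(height) || height <= 0) stopf("invalid height: must be > 0")
  if (!is.numeric(crown_base) || crown_base < 0)
    stopf("invalid crown_base: must be >= 0")
  if (height <= crown_base) stopf("invalid height: must exceed crown_base")
  if (!is.numeric(dbh) || dbh <= 0) stopf("invalid dbh: must be > 0")
  if (length(crown_semi_axes) != 3L || any(crown_semi_axes <= 0))
    stopf("invalid crown_semi_axes: need 3 positive values (rx, ry, rz)")
  if (any(stem_diameters_1m <= 0))
    stopf("invalid stem_diameters_1m: all diameters must be > 0")
  if (leaf_point_count < 0) stopf("invalid leaf_point_count: must be >= 0")
  if (trunk_point_spacing <= 0) stopf("invalid trunk_point_spacing: must be > 0")
  if (leaf_area_density <= 0) stopf("invalid leaf_area_density: must be > 0")

  rx <- crown_semi_axes[1]; ry <- crown_semi_axes[2]; rz <- crown_semi_axes[3]
  radii <- stem_diameters_1m / 2
  nstem <- length(radii)
  centers <- if (nstem == 1L) matrix(0, 1, 2) else {
    # circle of radius >= sum of radii, enlarged if needed so adjacent
    # stem surfaces clear the 0.1 m stem-separation linkage with margin
    R <- max(sum(radii),
             (2 * max(radii) + 0.12) / (2 * sin(pi / nstem)))
    ang <- 2 * pi * (seq_len(nstem) - 1L) / nstem
    cbind(R * cos(ang), R * sin(ang))
  }

  pts <- with_seed(seed, {
    trunk <- NULL
    if (crown_base > 0) {
      zlev <- seq(0, crown_base, by = trunk_point_spacing)
      trunk <- do.call(rbind, lapply(seq_len(nstem), function(s) {
        r <- radii[s]
        ncirc <- max(8L, ceiling(2 * pi * r / trunk_point_spacing))
        th <- 2 * pi * (seq_len(ncirc) - 1L) / ncirc
        cbind(rep(centers[s, 1] + r * cos(th), times = length(zlev)),
              rep(centers[s, 2] + r * sin(th), times = length(zlev)),
              rep(zlev, each = ncirc))
      }))
    }
    leaves <- NULL
    if (leaf_point_count > 0) {
      n <- as.integer(leaf_point_count)
      # uniform in the unit ball, then scaled to the ellipsoid
      g <- matrix(rnorm(3L * n), ncol = 3L)
      g <- g / sqrt(rowSums(g^2))
      u <- runif(n)^(1 / 3)
      leaves <- cbind(g[, 1] * u * rx, g[, 2] * u * ry,
                      crown_base + rz + g[, 3] * u * rz)
    }
    p <- rbind(trunk, leaves)
    if (is.null(p)) stopf("tree has neither trunk nor leaf points")
    if (jitter_sd > 0) p <- p + matrix(rnorm(length(p), sd = jitter_sd),
                                       ncol = 3L)
    p
  })

  vol <- 4 / 3 * pi * rx * ry * rz
  truth <- list(
    height = max(crown_base, crown_base + 2 * rz),
    crown_base = crown_base,
    clr = crown_base / max(crown_base, crown_base + 2 * rz),
    dbh = max(stem_diameters_1m),
    ca = pi * rx * ry,
    lai = leaf_area_density * 4 * rz / 3,
    tdr = length(stem_diameters_1m) *
      sum(stem_diameters_1m) / max(stem_diameters_1m),
    stem_diameters_1m = stem_diameters_1m,
    leaf_area_density = leaf_area_density,
    crown_semi_axes = c(rx = rx, ry = ry, rz = rz),
    beam_radius = if (leaf_point_count > 0)
      sqrt(0.5 * leaf_area_density * vol / (leaf_point_count * pi)) else NA_real_
  )
  list(cloud = tree_cloud(pts, tree_id, plot_id,
                          normalized = jitter_sd == 0),
       truth = truth)
}

#' Simulate a trait table with exact power-law conditional quantile envelopes
#'
#' Draws `(x, y)` pairs whose conditional 5% and 95% quantiles of `y | x`
#' are, by construction, the two supplied power-law curves `y = a*x^b`:
#' `x` is uniform on `x_range`, a latent uniform `U` picks a curve by
#' linear interpolation of `(log a, b)` between the lower curve at
#' `U = 0.05` and the upper curve at `U = 0.95` (extrapolated linearly
#' outside), and `y = a(U) * x^b(U)`.  Monotonicity of `y` in `U` over the
#' whole `x_range` — which the exact-quantile property requires — is
#' validated at the range endpoints.
#'
#' @param n Sample size (>= 20).
#' @param x_range Numeric `c(min, max)`, both positive.
#' @param lower_curve `c(a, b)` of the 5% quantile curve.
#' @param upper_curve `c(a, b)` of the 95% quantile curve.
#' @param seed Integer RNG seed.
#' @return A data frame with columns `x`, `y`.
#' @export
make_envelope_table <- function(n, x_range, lower_curve, upper_curve,
                                seed = 1L) {
  if (n < 20L) stopf("n must be >= 20")
  if (length(x_range) != 2L || any(x_range <= 0) || x_range[1] >= x_range[2])
    stopf("x_range must be positive and increasing")
  if (any(c(lower_curve[1], upper_curve[1]) <= 0))
    stopf("power-law coefficients must be > 0")
  la5 <- log(lower_curve[1]); b5 <- lower_curve[2]
  la95 <- log(upper_curve[1]); b95 <- upper_curve[2]
  # curves must not cross inside x_range, and y must increase with U there
  xg <- exp(seq(log(x_range[1]), log(x_range[2]), length.out = 64L))
  if (any(la5 + b5 * log(xg) >= la95 + b95 * log(xg)))
    stopf("lower and upper curves cross inside x_range")
  dla <- (la95 - la5) / 0.9
  db <- (b95 - b5) / 0.9
  if (any(dla + db * log(x_range) < 0))
    stopf("quantile curves are not ordered in U over x_range")
  with_seed(seed, {
    x <- runif(n, x_range[1], x_range[2])
    u <- runif(n)
    la <- la5 + dla * (u - 0.05)
    b <- b5 + db * (u - 0.05)
    data.frame(x = x, y = exp(la + b * log(x)))
  })
}

#' Simulate a plot-level trait and environment table
#'
#' Multivariate Gaussian draws over the 12 plot-mean traits and 13
#' environment variables with a requested correlation structure, for
#' calibrating and testing the trait--environment statistics.
#'
#' @param n_plots Number of plots (rows).
#' @param effect_matrix 25 x 25 correlation matrix over
#'   `c(trait_columns(), env_columns())` (symmetric, unit diagonal,
#'   positive semi-definite).  Default: identity.
#' @param means,sds Optional named numeric vectors of per-column means and
#'   SDs (default 0 and 1).
#' @param seed Integer RNG seed.
#' @return A data frame: `plot_id` plus the 25 named columns.
#' @export
make_plot_table <- function(n_plots, effect_matrix = NULL, means = NULL,
                            sds = NULL, seed = 1L) {
  cols <- c(trait_columns(), env_columns())
  p <- length(cols)
  if (is.null(effect_matrix)) effect_matrix <- diag(p)
  effect_matrix <- as.matrix(effect_matrix)
  if (!isTRUE(all.equal(dim(effect_matrix), c(p, p))))
    stopf("effect_matrix must be %d x %d", p, p)
  if (max(abs(effect_matrix - t(effect_matrix))) > 1e-8)
    stopf("effect_matrix must be symmetric")
  if (max(abs(diag(effect_matrix) - 1)) > 1e-8)
    stopf("effect_matrix must have unit diagonal")
  ev <- eigen(effect_matrix, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stopf("effect_matrix is not positive semi-definite (min eigenvalue %g)",
          min(ev$values))
  lam <- pmax(ev$values, 0)
  A <- ev$vectors %*% diag(sqrt(lam), p)
  mu <- rep(0, p); names(mu) <- cols
  sg <- rep(1, p); names(sg) <- cols
  if (!is.null(means)) mu[names(means)] <- means
  if (!is.null(sds)) sg[names(sds)] <- sds
  X <- with_seed(seed, matrix(rnorm(n_plots * p), n_plots, p) %*% t(A))
  X <- sweep(sweep(X, 2, sg, "*"), 2, mu, "+")
  colnames(X) <- cols
  out <- data.frame(plot_id = sprintf("plot_%02d", seq_len(n_plots)), X,
                    stringsAsFactors = FALSE)
  out
}

#' Simulate a branch-annotation table
#'
#' First- and second-order branch lengths and parentage for one tree, with
#' known branch-ratio ground truth, mirroring the field convention of
#' manually annotated branch orders.
#'
#' @param n_first Number of first-order branches.
#' @param second_per_first Mean number of second-order children per
#'   first-order branch (Poisson).
#' @param seed Integer RNG seed.
#' @return A list: `table` (data frame `branch_id`, `order`, `length_m`,
#'   `parent_id`) and `truth` (`sl_fl`, `sc_fc`).
#' @export
make_branch_table <- function(n_first, second_per_first = 2, seed = 1L) {
  if (n_first < 1L) stopf("n_first must be >= 1")
  with_seed(seed, {
    l1 <- runif(n_first, 1, 4)
    n2 <- stats::rpois(n_first, second_per_first)
    rows <- data.frame(branch_id = sprintf("b1_%03d", seq_len(n_first)),
                       order = 1L, length_m = l1,
                       parent_id = NA_character_,
                       stringsAsFactors = FALSE)
    k <- 0L
    for (i in seq_len(n_first)) {
      if (n2[i] > 0) {
        l2 <- runif(n2[i], 0.2, pmax(0.3, l1[i] / 2))
        rows <- rbind(rows, data.frame(
          branch_id = sprintf("b2_%03d", k + seq_len(n2[i])),
          order = 2L, length_m = l2,
          parent_id = sprintf("b1_%03d", i),
          stringsAsFactors = FALSE))
        k <- k + n2[i]
      }
    }
    o2 <- rows$order == 2L
    list(table = rows,
         truth = list(sl_fl = sum(rows$length_m[o2]) / sum(rows$length_m[!o2]),
                      sc_fc = sum(o2) / sum(!o2)))
  })
}
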
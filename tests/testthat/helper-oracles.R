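# Independent oracles used across the suite.  Each is a deliberately
# naive or closed-form computation, kept separate from the package's own
# algorithms.

# geometric (orthogonal-distance) circle fit by direct optimization
geometric_circle_fit <- function(p) {
  obj <- function(par)
    sum((sqrt((p[, 1] - par[1])^2 + (p[, 2] - par[2])^2) - par[3])^2)
  start <- c(mean(p[, 1]), mean(p[, 2]),
             mean(sqrt((p[, 1] - mean(p[, 1]))^2 +
                       (p[, 2] - mean(p[, 2]))^2)))
  o <- stats::optim(start, obj, method = "BFGS",
                    control = list(reltol = 1e-14, maxit = 1000))
  c(cx = o$par[1], cy = o$par[2], r = o$par[3])
}

# circumcircle of three points, closed form
circumcircle <- function(p) {
  ax <- p[1, 1]; ay <- p[1, 2]; bx <- p[2, 1]; by <- p[2, 2]
  cx <- p[3, 1]; cy <- p[3, 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  c(cx = ux, cy = uy, r = sqrt((ax - ux)^2 + (ay - uy)^2))
}

# brute-force hull vertex set: a point is interior iff it lies strictly
# inside some triangle of three other points
brute_hull_vertices <- function(p) {
  n <- nrow(p)
  inside <- rep(FALSE, n)
  tri <- utils::combn(n, 3)
  sgn <- function(a, b, q)
    (b[1] - a[1]) * (q[, 2] - a[2]) - (b[2] - a[2]) * (q[, 1] - a[1])
  for (t in seq_len(ncol(tri))) {
    a <- p[tri[1, t], ]; b <- p[tri[2, t], ]; c0 <- p[tri[3, t], ]
    d1 <- sgn(a, b, p); d2 <- sgn(b, c0, p); d3 <- sgn(c0, a, p)
    strict <- (d1 > 1e-12 & d2 > 1e-12 & d3 > 1e-12) |
              (d1 < -1e-12 & d2 < -1e-12 & d3 < -1e-12)
    strict[tri[, t]] <- FALSE
    inside <- inside | strict
  }
  p[!inside, , drop = FALSE]
}

# chord length of a ray through an axis-aligned ellipsoid
ellipsoid_chord <- function(origin, dir, center, axes) {
  oo <- (origin - center) / axes
  dd <- dir / axes
  A <- sum(dd^2); B <- 2 * sum(oo * dd); C <- sum(oo^2) - 1
  disc <- B^2 - 4 * A * C
  if (disc <= 0) return(0)
  ts <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  ts <- pmax(ts, 0)
  (ts[2] - ts[1]) * sqrt(sum(dir^2))
}

# analytic Poisson-medium LAI for the same ray grid the estimator uses:
# per-ray gap probability exp(-G * u * chord), then the estimator's exact
# aggregation (bin means, Lang-Xiang sector clumping, Beer-Lambert)
# applied to the analytic probabilities
poisson_lai_oracle <- function(truth, scanner_pos, zenith_edges,
                               n_azimuth = 24L, rays_per_bin = 3L,
                               n_sectors = 8L, g = 0.5) {
  rays <- treemorph::lai_ray_grid(zenith_edges, n_azimuth, rays_per_bin)
  ax <- as.numeric(truth$crown_semi_axes)
  center <- c(0, 0, truth$crown_base + ax[3])
  pr <- vapply(seq_len(nrow(rays)), function(i) {
    ch <- ellipsoid_chord(scanner_pos,
                          c(rays$dx[i], rays$dy[i], rays$dz[i]), center, ax)
    exp(-g * truth$leaf_area_density * ch)
  }, 0)
  sector_grp <- ceiling(rays$sector / (n_azimuth / n_sectors))
  nb <- length(zenith_edges) - 1L
  thc <- (zenith_edges[-1] + zenith_edges[-(nb + 1L)]) / 2
  le <- vapply(seq_len(nb), function(b) {
    sel <- rays$bin == b
    pg <- mean(pr[sel])
    ps <- tapply(pr[sel], sector_grp[sel], mean)
    om <- if (pg <= 0 || pg >= 1 || any(ps <= 0)) 1
          else log(mean(ps)) / mean(log(ps))
    if (!is.finite(om) || om <= 0) om <- 1
    -cos(thc[b]) * log(pg) / g / om
  }, 0)
  mean(le)
}

# O(n^3) centroid-linkage oracle: recompute all pairwise squared centroid
# distances at every step; returns the merge sequence as membership sets
brute_centroid_merges <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  merges <- list()
  while (length(clusters) > 1L) {
    k <- length(clusters)
    cent <- do.call(rbind, lapply(clusters, function(id)
      colMeans(X[id, , drop = FALSE])))
    best <- c(NA, NA); bd <- Inf
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      d <- sum((cent[i, ] - cent[j, ])^2)
      if (d < bd) { bd <- d; best <- c(i, j) }
    }
    newc <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- list(members = newc, height = bd)
    clusters <- c(clusters[-best], list(newc))
  }
  merges
}

# hclust merge table -> membership sets in merge order
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    get1 <- function(v) if (v < 0) -v else sets[[v]]
    sets[[s]] <- sort(c(get1(hc$merge[s, 1]), get1(hc$merge[s, 2])))
  }
  sets
}

# standard random tree parameters of the recovery study conditions:
# oak-like trees 4-14 m tall, crown base above breast height
random_recovery_params <- function(seed) {
  set.seed(seed)
  h <- runif(1, 4, 14)
  cb <- runif(1, max(1.5, 0.25 * h), 0.5 * h)
  rz <- (h - cb) / 2
  rx <- runif(1, 0.8, 3.2)
  ry <- rx * runif(1, 0.85, 1.15)
  multi <- runif(1) < 0.3
  d <- runif(1, 0.12, 0.35)
  stems <- if (multi) c(d, runif(sample(1:2, 1), 0.12, d)) else d
  # leaf area density capped so the central optical depth G*u*2*rz stays
  # below ~2.2: beyond that the crown saturates (gap fraction -> 0) and
  # gap-fraction inversion is ill-posed for any instrument
  u <- min(runif(1, 0.3, 0.9), 2.2 / rz)
  list(height = cb + 2 * rz, crown_base = cb, dbh = max(stems),
       crown_semi_axes = c(rx, ry, rz), stem_diameters_1m = stems,
       leaf_area_density = u)
}

# rotate a cloud about the z axis
rotate_z <- function(cloud, angle) {
  p <- cloud$points
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  q <- cbind(p[, 1:2] %*% R, p[, 3])
  treemorph::tree_cloud(q, cloud$tree_id, cloud$plot_id, cloud$normalized)
}
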
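# Gap-fraction LAI: ray casting against the canopy point cloud,
# Beer-Lambert inversion per zenith bin, Lang-Xiang clumping correction.

#' Build the ray grid used by the gap-fraction LAI estimate
#'
#' A regular angular grid: `rays_per_bin` zenith values inside each bin
#' crossed with `n_azimuth` azimuth values.  Exposed so that tests and
#' analytic oracles can evaluate the exact same ray set.
#'
#' @param zenith_edges Increasing vector of zenith bin edges (radians).
#' @param n_azimuth Number of azimuth directions.
#' @param rays_per_bin Number of zenith values per bin.
#' @return Data frame: `theta`, `phi`, `bin`, `sector` plus unit direction
#'   components `dx`, `dy`, `dz`.
#' @export
lai_ray_grid <- function(zenith_edges, n_azimuth = 24L, rays_per_bin = 3L) {
  if (length(zenith_edges) < 2L || any(diff(zenith_edges) <= 0))
    stopf("zenith_edges must be an increasing vector of bin edges")
  nb <- length(zenith_edges) - 1L
  th <- unlist(lapply(seq_len(nb), function(b) {
    e0 <- zenith_edges[b]; e1 <- zenith_edges[b + 1L]
    e0 + (seq_len(rays_per_bin) - 0.5) / rays_per_bin * (e1 - e0)
  }))
  bin <- rep(seq_len(nb), each = rays_per_bin)
  phi <- 2 * pi * (seq_len(n_azimuth) - 0.5) / n_azimuth
  g <- expand.grid(i = seq_along(th), j = seq_len(n_azimuth))
  data.frame(theta = th[g$i], phi = phi[g$j], bin = bin[g$i],
             sector = g$j,
             dx = sin(th[g$i]) * cos(phi[g$j]),
             dy = sin(th[g$i]) * sin(phi[g$j]),
             dz = cos(th[g$i]))
}

#' Beer-Lambert LAI from a gap profile
#'
#' Inverts per-bin gap fractions: effective LAI per zenith bin is
#' `L_e(theta) = -cos(theta) * log(P(theta)) / g`, corrected by the bin's
#' clumping index, and averaged over bins.  Saturated bins (`P = 0`) are
#' excluded with a warning.
#'
#' @param p_gap Gap fraction per zenith bin, in \[0, 1\].
#' @param theta Zenith bin centers (radians).
#' @param omega Clumping index per bin (default 1, random dispersion).
#' @param g Leaf projection function G(theta); 0.5 for a spherical
#'   leaf-angle distribution.
#' @return LAI (dimensionless).
#' @export
lai_from_gaps <- function(p_gap, theta, omega = 1, g = 0.5) {
  if (length(p_gap) != length(theta))
    stopf("p_gap and theta lengths differ")
  omega <- rep_len(omega, length(p_gap))
  sat <- p_gap <= 0
  if (all(sat)) stopf("all zenith bins saturated (gap fraction 0)")
  if (any(sat)) warning(sprintf("%d saturated zenith bin(s) excluded",
                                sum(sat)))
  keep <- !sat
  le <- -cos(theta[keep]) * log(p_gap[keep]) / g
  mean(le / omega[keep])
}

#' Leaf area index from canopy gap fractions
#'
#' Casts a regular angular grid of rays from the scanner position; a ray
#' is intercepted if it passes within `r_beam` of any canopy point (points
#' above `crown_base`).  Per zenith bin, the gap fraction `P(theta)` is
#' the non-intercepted fraction of rays; the Lang-Xiang clumping index is
#' computed per bin from azimuth-sector mean gaps,
#' `Omega = log(mean(P_s)) / mean(log(P_s))`; and LAI is the mean over
#' bins of the clumping-corrected Beer-Lambert inversion.
#'
#' @param cloud A normalized [tree_cloud()].
#' @param scanner_pos Length-3 numeric: scanner position (m), outside the
#'   crown (default: the ground point below the crown centroid).
#' @param zenith_edges Zenith bin edges in radians.
#' @param g Leaf projection function (default 0.5, spherical).
#' @param r_beam Interception radius around a ray (m).
#' @param n_azimuth,rays_per_bin Ray-grid resolution; azimuth sectors for
#'   the clumping index are the `n_azimuth` directions grouped into
#'   `n_sectors`.
#' @param n_sectors Azimuth sectors for Lang-Xiang averaging.
#' @param crown_base Points at or below this height are excluded (trunk).
#' @return A list: `lai`, and `profile` (data frame per zenith bin:
#'   `theta`, `p_gap`, `ray_count`, `omega`, `saturated`).
#' @export
lai <- function(cloud, scanner_pos = NULL,
                zenith_edges = seq(0, 30, by = 5) * pi / 180,
                g = 0.5, r_beam = 0.02, n_azimuth = 24L, rays_per_bin = 3L,
                n_sectors = 8L, crown_base = 0) {
  stopifnot(inherits(cloud, "tree_cloud"))
  p <- cloud$points
  canopy <- p[p[, "z"] > crown_base, , drop = FALSE]
  if (is.null(scanner_pos)) {
    cxy <- if (nrow(canopy)) colMeans(canopy[, 1:2, drop = FALSE])
           else colMeans(p[, 1:2, drop = FALSE])
    scanner_pos <- c(cxy[1], cxy[2], 0)
  }
  rays <- lai_ray_grid(zenith_edges, n_azimuth, rays_per_bin)
  hit <- ray_hits(canopy, scanner_pos, rays, r_beam)
  rays$gap <- !hit
  rays$sector_grp <- ceiling(rays$sector / (n_azimuth / n_sectors))
  nb <- length(zenith_edges) - 1L
  theta_c <- (zenith_edges[-1] + zenith_edges[-(nb + 1L)]) / 2
  prof <- do.call(rbind, lapply(seq_len(nb), function(b) {
    rb <- rays[rays$bin == b, ]
    pg <- mean(rb$gap)
    ps <- tapply(rb$gap, rb$sector_grp, mean)
    om <- if (pg <= 0 || pg >= 1 || any(ps <= 0)) 1
          else log(mean(ps)) / mean(log(ps))
    if (!is.finite(om) || om <= 0) om <- 1
    data.frame(theta = theta_c[b], p_gap = pg, ray_count = nrow(rb),
               omega = om, saturated = pg <= 0)
  }))
  l <- lai_from_gaps(prof$p_gap, prof$theta, omega = prof$omega, g = g)
  list(lai = l, profile = prof)
}

## internal: which rays pass within r_beam of at least one point
## (forward along the ray only); vectorized as a points x rays product
ray_hits <- function(points, origin, rays, r_beam) {
  m <- nrow(rays)
  if (is.null(points) || nrow(points) == 0L) return(rep(FALSE, m))
  P <- sweep(points, 2, as.numeric(origin))
  D <- t(as.matrix(rays[, c("dx", "dy", "dz")]))
  hit <- logical(m)
  psq <- rowSums(P^2)
  chunk <- max(1L, floor(4e6 / nrow(P)))
  for (s in seq(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    proj <- P %*% D[, s:e, drop = FALSE]          # n x chunk
    d2 <- psq - proj^2                             # perp distance squared
    hit[s:e] <- apply(d2 <= r_beam^2 & proj > 0, 2, any)
  }
  hit
}
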
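# Stem morphological traits from a segmented single-tree cloud: height,
# Taubin-fit DBH, crown base from the hull-area profile, maximum canopy
# cross-section, trunk dominance ratio, branch ratios, percentage cover.

#' Tree height
#'
#' Height is the difference between the highest and lowest points of the
#' ground-normalized cloud.
#'
#' @param cloud A normalized [tree_cloud()].
#' @return Height in m.
#' @export
tree_height <- function(cloud) {
  stopifnot(inherits(cloud, "tree_cloud"))
  z <- cloud$points[, "z"]
  if (length(z) < 2L) stopf("tree_height needs at least 2 points")
  max(z) - min(z)
}

#' Taubin algebraic circle fit
#'
#' Fits a circle to 2D points by Taubin's method: the algebraic distance
#' `x^2 + y^2 + D x + E y + F` is minimized under the gradient-norm
#' normalization, solved in centered coordinates through the singular
#' value decomposition.  Nearly unbiased for partial arcs and exact for
#' zero-residual data (any 3 non-collinear points).
#'
#' @param points2d Matrix or data frame with 2 columns (x, y).
#' @return Named numeric vector `c(cx, cy, r)`.
#' @export
fit_circle_taubin <- function(points2d) {
  p <- as.matrix(points2d)
  if (ncol(p) != 2L) stopf("points2d must have 2 columns")
  n <- nrow(p)
  if (n < 3L) stopf("circle fit needs at least 3 points, got %d", n)
  mx <- mean(p[, 1]); my <- mean(p[, 2])
  X <- p[, 1] - mx; Y <- p[, 2] - my
  # collinearity: rank of the centered coordinates
  sv <- svd(cbind(X, Y), nu = 0, nv = 0)$d
  if (sv[2] <= 1e-12 * max(sv[1], 1))
    stopf("degenerate slice: points are collinear, no circle fit")
  Z <- X^2 + Y^2
  zm <- mean(Z)
  Z0 <- (Z - zm) / (2 * sqrt(zm))
  v <- svd(cbind(Z0, X, Y), nu = 0)$v[, 3]
  A <- v[1] / (2 * sqrt(zm))
  B <- v[2]; C <- v[3]
  D <- -zm * v[1] / (2 * sqrt(zm))
  if (abs(A) < 1e-14)
    stopf("degenerate slice: circle fit did not converge (near-line data)")
  cx <- -B / (2 * A); cy <- -C / (2 * A)
  r <- sqrt(B^2 + C^2 - 4 * A * D) / (2 * abs(A))
  c(cx = cx + mx, cy = cy + my, r = r)
}

## internal: single-linkage components of 2D points at a distance threshold
xy_components <- function(p, linkage = 0.1) {
  n <- nrow(p)
  if (n == 1L) return(rep(1L, 1L))
  hc <- stats::hclust(stats::dist(p), method = "single")
  stats::cutree(hc, h = linkage)
}

#' Stem diameter at breast height
#'
#' Extracts the horizontal slice at `slice_center` +/- `slice_halfwidth`,
#' projects it to the xy plane, splits it into stems by single-linkage
#' connected components at 0.1 m, and fits a Taubin circle per stem.  The
#' reported DBH is the diameter of the largest stem.
#'
#' @param cloud A normalized [tree_cloud()].
#' @param slice_center Slice height in m (breast height, 1.3).
#' @param slice_halfwidth Slice half-thickness in m.
#' @param linkage Stem-separation distance for component clustering (m).
#' @return A list: `dbh` (largest-stem diameter, m), `stem_diameters`
#'   (descending), `centers` (per-stem circle centers).
#' @export
dbh <- function(cloud, slice_center = 1.3, slice_halfwidth = 0.05,
                linkage = 0.1) {
  stopifnot(inherits(cloud, "tree_cloud"))
  z <- cloud$points[, "z"]
  sel <- abs(z - slice_center) <= slice_halfwidth
  if (!any(sel)) stopf("no points at breast height (%.2f +/- %.2f m)",
                       slice_center, slice_halfwidth)
  p <- cloud$points[sel, c("x", "y"), drop = FALSE]
  comp <- xy_components(p, linkage)
  sizes <- table(comp)
  # components of fewer than 3 points cannot be a stem (stray leaf returns)
  keep <- as.integer(names(sizes)[sizes >= 3L])
  if (!length(keep))
    stopf("no stem slice component has >= 3 points at breast height")
  fits <- lapply(keep, function(k)
    fit_circle_taubin(p[comp == k, , drop = FALSE]))
  d <- vapply(fits, function(f) 2 * f[["r"]], 0)
  o <- order(d, decreasing = TRUE)
  list(dbh = d[o[1]], stem_diameters = d[o],
       centers = do.call(rbind, fits)[o, 1:2, drop = FALSE])
}

#' Graham-scan convex hull
#'
#' Computes the convex hull of 2D points by Graham's scan: points are
#' sorted by polar angle around the lowest point (ties broken by
#' distance), and reflex or collinear turns are popped, so no three
#' retained vertices are collinear.  Vertices are returned
#' counter-clockwise.
#'
#' @param points2d Matrix or data frame with 2 columns.
#' @return An object of class `hull2d`: list with `vertices` (CCW matrix).
#' @export
graham_hull <- function(points2d) {
  p <- unique(as.matrix(points2d))
  if (ncol(p) != 2L) stopf("points2d must have 2 columns")
  if (nrow(p) < 3L) stopf("convex hull needs at least 3 distinct points")
  i0 <- order(p[, 2], p[, 1])[1]
  pivot <- p[i0, ]
  rest <- p[-i0, , drop = FALSE]
  ang <- atan2(rest[, 2] - pivot[2], rest[, 1] - pivot[1])
  d2 <- (rest[, 1] - pivot[1])^2 + (rest[, 2] - pivot[2])^2
  rest <- rest[order(ang, d2), , drop = FALSE]
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  st <- list(pivot, rest[1, ])
  for (i in seq(2L, nrow(rest))) {
    q <- rest[i, ]
    while (length(st) >= 2L &&
           cross(st[[length(st) - 1L]], st[[length(st)]], q) <= 1e-12 *
           max(1, sum(abs(q))))
      st[[length(st)]] <- NULL
    st[[length(st) + 1L]] <- q
  }
  v <- do.call(rbind, st)
  if (nrow(v) < 3L)
    stopf("degenerate geometry: all points are collinear")
  colnames(v) <- c("x", "y")
  structure(list(vertices = v), class = "hull2d")
}

#' Polygon area by the shoelace formula
#'
#' @param hull A `hull2d` from [graham_hull()], or a matrix of ordered
#'   polygon vertices.
#' @return Area in m2 (absolute value).
#' @export
polygon_area <- function(hull) {
  v <- if (inherits(hull, "hull2d")) hull$vertices else as.matrix(hull)
  if (nrow(v) < 3L) stopf("polygon needs at least 3 vertices")
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq(2, nrow(v)), 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

## internal: hull area of a point layer, 0 when degenerate
layer_hull_area <- function(p) {
  if (nrow(p) < 3L) return(0)
  tryCatch(polygon_area(graham_hull(p)), error = function(e) 0)
}

#' Crown base height
#'
#' Divides the cloud into horizontal layers, computes the convex-hull
#' cross-section area profile `A(z)`, and localizes the trunk-to-canopy
#' transition with a hysteresis rule: the crown is *detected* at the
#' lowest layer whose area reaches `alpha` times the profile maximum and
#' that is followed by at least two further consecutive qualifying layers
#' (a persistence rule against isolated branch stubs), then the base is
#' *localized* by walking down through layers that still hold crown area,
#' i.e. at least `alpha_low` of the maximum and clearly above the trunk
#' cross-section baseline.  The crown base is the lower edge of the last
#' such layer.  When the profile never qualifies, or the cloud has no
#' crown expansion (a bare trunk), 0 is returned with a warning.
#'
#' @param cloud A normalized [tree_cloud()].
#' @param layer Layer thickness in m.
#' @param alpha Detection threshold, fraction of the maximum layer area.
#' @param alpha_low Localization threshold fraction (hysteresis floor).
#' @return Crown base in m, with attribute `warning_flag` set to `TRUE`
#'   for shrub-like / trunk-only profiles.
#' @export
crown_base <- function(cloud, layer = 0.25, alpha = 0.15, alpha_low = 0.02) {
  stopifnot(inherits(cloud, "tree_cloud"))
  z <- cloud$points[, "z"]
  h <- max(z) - min(z)
  if (h < 4 * layer)
    stopf("cloud spans %.2f m, fewer than 4 layers of %.2f m", h, layer)
  edges <- seq(min(z), max(z) + layer, by = layer)
  idx <- findInterval(z, edges, rightmost.closed = TRUE)
  areas <- vapply(seq_len(length(edges) - 1L), function(i) {
    layer_hull_area(cloud$points[idx == i, c("x", "y"), drop = FALSE])
  }, 0)
  amax <- max(areas)
  if (amax <= 0) {
    warning("area profile is degenerate; returning crown base 0")
    return(structure(0, warning_flag = TRUE))
  }
  qual <- areas >= alpha * amax
  base_i <- NA_integer_
  for (i in seq_len(length(qual) - 2L)) {
    if (qual[i] && qual[i + 1L] && qual[i + 2L]) { base_i <- i; break }
  }
  if (is.na(base_i)) {
    warning("no persistent crown layer found; returning crown base 0")
    return(structure(0, warning_flag = TRUE))
  }
  # hysteresis walk-down: keep descending through layers that still carry
  # crown area (above alpha_low of max and above the trunk baseline)
  below <- areas[seq_len(base_i - 1L)]
  trunk_baseline <- if (any(below > 0)) min(below[below > 0]) else 0
  floor_area <- max(alpha_low * amax, 1.5 * trunk_baseline)
  while (base_i > 1L && areas[base_i - 1L] >= floor_area)
    base_i <- base_i - 1L
  cb <- edges[base_i] - min(z)
  # bare trunk: profile qualifies from the ground but never expands
  lowest_occ <- areas[which(areas > 0)[1]]
  if (cb == 0 && amax < 2 * lowest_occ) {
    warning("area profile is flat (trunk-only or shrub-like form)")
    return(structure(0, warning_flag = TRUE))
  }
  structure(cb, warning_flag = FALSE)
}

#' Maximum canopy cross-sectional area
#'
#' Partitions the canopy (points above the crown base) into horizontal
#' layers and returns the maximum convex-hull area over layers; layers
#' with fewer than 3 points are skipped.
#'
#' @param cloud A normalized [tree_cloud()].
#' @param crown_base Crown base height in m.
#' @param layer Layer thickness in m.
#' @return Canopy area in m2.
#' @export
canopy_area <- function(cloud, crown_base, layer = 0.5) {
  stopifnot(inherits(cloud, "tree_cloud"))
  z <- cloud$points[, "z"]
  sel <- z >= crown_base
  if (sum(sel) < 3L) stopf("fewer than 3 points above the crown base")
  zc <- z[sel]
  p <- cloud$points[sel, c("x", "y"), drop = FALSE]
  edges <- seq(min(zc), max(zc) + layer, by = layer)
  idx <- findInterval(zc, edges, rightmost.closed = TRUE)
  areas <- vapply(split(seq_along(idx), idx), function(ii) {
    if (length(ii) < 3L) return(NA_real_)
    layer_hull_area(p[ii, , drop = FALSE])
  }, 0)
  areas <- areas[!is.na(areas) & areas > 0]
  if (!length(areas)) stopf("no canopy layer has 3 or more points")
  max(areas)
}

#' Trunk dominance ratio
#'
#' `TDR = num * (sum(d_i) / max(d_i))` over the stem diameters measured at
#' 1 m aboveground, where `num` is the number of stems: 1 for a single
#' dominant trunk, `num^2` for `num` equal stems, distinguishing trees
#' from shrub-like multi-stem forms.
#'
#' @param diameters_1m Positive numeric vector of stem diameters (m).
#' @return TDR (dimensionless, >= 1).
#' @export
tdr <- function(diameters_1m) {
  d <- as.numeric(diameters_1m)
  if (!length(d)) stopf("stem inventory is empty")
  if (any(!is.finite(d)) || any(d <= 0))
    stopf("all stem diameters must be positive")
  length(d) * sum(d) / max(d)
}

#' Branch ratios Sl/Fl and Sc/Fc
#'
#' `Sl/Fl` is the ratio of the summed second-order branch length to the
#' summed first-order branch length; `Sc/Fc` the corresponding count
#' ratio.
#'
#' @param table Data frame with columns `branch_id`, `order` (1 or 2),
#'   `length_m`, `parent_id`.
#' @return Named numeric vector `c(sl_fl, sc_fc)`.
#' @export
branch_ratios <- function(table) {
  need <- c("branch_id", "order", "length_m", "parent_id")
  if (!all(need %in% names(table)))
    stopf("branch table must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(table$branch_id))
    stopf("duplicate branch_id rows in branch table")
  if (!all(table$order %in% c(1L, 2L)))
    stopf("branch order must be 1 or 2")
  if (any(table$length_m <= 0)) stopf("branch lengths must be > 0")
  o1 <- table$order == 1L
  o2 <- table$order == 2L
  if (!any(o1)) stopf("branch table has no first-order branches")
  bad <- !(table$parent_id[o2] %in% table$branch_id[o1])
  if (any(bad))
    stopf("second-order branch %s has no first-order parent",
          table$branch_id[o2][bad][1])
  fl <- sum(table$length_m[o1])
  if (fl <= 0) stopf("zero first-order branch length sum")
  c(sl_fl = sum(table$length_m[o2]) / fl, sc_fc = sum(o2) / sum(o1))
}

#' Percentage tree cover of a plot
#'
#' Fraction of square grid cells of the plot containing at least one point
#' at or above `min_h`, as a percentage.
#'
#' @param clouds A list of [tree_cloud()] objects (plot coordinates).
#' @param plot_side Plot side length in m (square plot at the origin).
#' @param cell Grid cell side in m.
#' @param min_h Minimum height of a point to count as canopy (m).
#' @return Percentage cover in \[0, 100\].
#' @export
percent_cover <- function(clouds, plot_side = 25, cell = 0.5, min_h = 2) {
  if (inherits(clouds, "tree_cloud")) clouds <- list(clouds)
  ncell <- ceiling(plot_side / cell)
  occ <- character(0)
  for (cl in clouds) {
    stopifnot(inherits(cl, "tree_cloud"))
    p <- cl$points
    sel <- p[, "z"] >= min_h
    if (!any(sel)) next
    ix <- floor(p[sel, "x"] / cell); iy <- floor(p[sel, "y"] / cell)
    inb <- ix >= 0 & ix < ncell & iy >= 0 & iy < ncell
    occ <- union(occ, paste(ix[inb], iy[inb]))
  }
  100 * length(occ) / ncell^2
}

#' Extract the full stem trait record of one tree
#'
#' Convenience wrapper running height, crown base, CLR, DBH, canopy area
#' and (optionally) LAI, TDR and branch ratios on one segmented cloud.
#'
#' @param cloud A normalized [tree_cloud()].
#' @param stem_diameters_1m Optional stem inventory for [tdr()].
#' @param branch_table Optional branch table for [branch_ratios()].
#' @param with_lai Logical; run the gap-fraction LAI estimate (slower).
#' @param lai_args List of extra arguments passed to [lai()].
#' @param crown_layer,canopy_layer Layer thicknesses (m) for
#'   [crown_base()] and [canopy_area()].
#' @return One-row data frame with the trait columns of `traits.csv`.
#' @export
extract_traits <- function(cloud, stem_diameters_1m = NULL,
                           branch_table = NULL, with_lai = FALSE,
                           lai_args = list(), crown_layer = 0.25,
                           canopy_layer = 0.5) {
  h <- tree_height(cloud)
  cb <- suppressWarnings(crown_base(cloud, layer = crown_layer))
  d <- dbh(cloud)
  ca <- canopy_area(cloud, crown_base = as.numeric(cb), layer = canopy_layer)
  lai_v <- NA_real_
  if (with_lai) {
    la <- do.call(lai, c(list(cloud = cloud, crown_base = as.numeric(cb)),
                         lai_args))
    lai_v <- la$lai
  }
  tdr_v <- if (!is.null(stem_diameters_1m)) tdr(stem_diameters_1m)
           else tdr(d$stem_diameters)
  br <- if (!is.null(branch_table)) branch_ratios(branch_table)
        else c(sl_fl = NA_real_, sc_fc = NA_real_)
  data.frame(tree_id = cloud$tree_id, plot_id = cloud$plot_id,
             height = h, crown_base = as.numeric(cb),
             clr = as.numeric(cb) / h, dbh = d$dbh, ca = ca, lai = lai_v,
             tdr = tdr_v, sl_fl = unname(br["sl_fl"]),
             sc_fc = unname(br["sc_fc"]), stringsAsFactors = FALSE)
}
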
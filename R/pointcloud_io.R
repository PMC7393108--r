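# Point-cloud containers and IO: plain XYZ text and ASCII PLY, ground
# normalization, and statistical-outlier denoising.

#' Construct a tree point cloud
#'
#' A `tree_cloud` is an n x 3 matrix of coordinates in meters (z up) plus
#' identifiers.  All extraction functions in the package take this container.
#'
#' @param points Numeric matrix or data frame with 3 columns (x, y, z), meters.
#' @param tree_id,plot_id Identifier strings.
#' @param normalized Logical; `TRUE` once heights are ground-normalized
#'   (min z at 0).
#' @return An object of class `tree_cloud`.
#' @export
tree_cloud <- function(points, tree_id = "tree", plot_id = "plot",
                       normalized = FALSE) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3L) stopf("points must have 3 columns, got %d", ncol(pts))
  if (nrow(pts) < 1L) stopf("points must contain at least one point")
  storage.mode(pts) <- "double"
  if (!all(is.finite(pts))) stopf("points contain non-finite coordinates")
  colnames(pts) <- c("x", "y", "z")
  if (isTRUE(normalized) && min(pts[, "z"]) < -1e-9)
    stopf("normalized cloud has min z = %g < 0", min(pts[, "z"]))
  structure(list(points = pts, tree_id = as.character(tree_id),
                 plot_id = as.character(plot_id),
                 normalized = isTRUE(normalized)),
            class = "tree_cloud")
}

#' @export
print.tree_cloud <- function(x, ...) {
  rng <- apply(x$points, 2, range)
  cat(sprintf("<tree_cloud> %s / %s: %d points%s\n", x$plot_id, x$tree_id,
              nrow(x$points), if (x$normalized) " (normalized)" else ""))
  cat(sprintf("  x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f] m\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Read a point cloud from XYZ text or ASCII PLY
#'
#' XYZ dialect: three whitespace-separated decimal numbers per line,
#' `#`-prefixed comment lines skipped, no header.  PLY: ASCII 1.0 only;
#' binary PLY is rejected.  Every input point is kept once, in file order.
#'
#' @param path File path.
#' @param format `"xyz"` or `"ply"`; default guesses from the extension.
#' @inheritParams tree_cloud
#' @return A [tree_cloud()].
#' @export
read_cloud <- function(path, format = c("auto", "xyz", "ply"),
                       tree_id = NULL, plot_id = "plot") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  if (is.null(tree_id)) tree_id <- sub("\\.[^.]*$", "", basename(path))
  pts <- switch(format, xyz = read_xyz(path), ply = read_ply(path))
  tree_cloud(pts, tree_id = tree_id, plot_id = plot_id)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stopf("empty XYZ file: %s", path)
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(lengths(toks) != 3L)
  if (length(bad))
    stopf("XYZ parse error at line %d of %s: expected 3 tokens, got %d",
          idx[bad[1]], path, lengths(toks)[bad[1]])
  m <- matrix(suppressWarnings(as.numeric(unlist(toks))),
              ncol = 3L, byrow = TRUE)
  nab <- which(!stats::complete.cases(m))
  if (length(nab))
    stopf("XYZ parse error at line %d of %s: non-numeric token",
          idx[nab[1]], path)
  m
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || !identical(trimws(lines[1]), "ply"))
    stopf("not a PLY file: %s", path)
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stopf("PLY header of %s has no end_header", path)
  hdr <- trimws(lines[seq_len(hdr_end)])
  fmt <- grep("^format ", hdr, value = TRUE)
  if (!length(fmt) || !grepl("^format\\s+ascii\\s+1\\.0", fmt[1]))
    stopf("only ASCII 1.0 PLY is supported (%s declares '%s')", path,
          if (length(fmt)) fmt[1] else "no format")
  vline <- grep("^element vertex ", hdr)
  if (!length(vline)) stopf("PLY file %s has no vertex element", path)
  nvert <- as.integer(strsplit(hdr[vline[1]], "\\s+")[[1]][3])
  # properties of the vertex element, in declaration order
  after <- hdr[seq(vline[1] + 1L, length(hdr))]
  next_el <- grep("^element ", after)
  stopv <- if (length(next_el)) next_el[1] - 1L else length(after)
  props <- grep("^property ", after[seq_len(stopv)], value = TRUE)
  pnames <- vapply(strsplit(props, "\\s+"), function(t) t[length(t)], "")
  need <- match(c("x", "y", "z"), pnames)
  if (anyNA(need))
    stopf("PLY vertex element of %s lacks x/y/z properties", path)
  body <- lines[seq(hdr_end + 1L, length.out = nvert)]
  if (length(body) < nvert || anyNA(body))
    stopf("PLY file %s truncated: expected %d vertices", path, nvert)
  toks <- strsplit(trimws(body), "\\s+")
  badn <- which(lengths(toks) != length(pnames))
  if (length(badn))
    stopf("PLY parse error at line %d of %s: expected %d values, got %d",
          hdr_end + badn[1], path, length(pnames), lengths(toks)[badn[1]])
  m <- matrix(as.numeric(unlist(toks)), ncol = length(pnames), byrow = TRUE)
  m[, need, drop = FALSE]
}

#' Write a point cloud to XYZ text or ASCII PLY
#'
#' @inheritParams read_cloud
#' @param cloud A [tree_cloud()].
#' @param digits Significant digits written (9 covers float32 exactly).
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "xyz", "ply"),
                        digits = 9L) {
  stopifnot(inherits(cloud, "tree_cloud"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  p <- cloud$points
  body <- sprintf(paste0("%.", digits, "g %.", digits, "g %.", digits, "g"),
                  p[, 1], p[, 2], p[, 3])
  if (format == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(p)),
             "property float32 x", "property float32 y", "property float32 z",
             "end_header")
    writeLines(c(hdr, body), path)
  } else {
    writeLines(body, path)
  }
  invisible(path)
}

#' Normalize heights to the ground
#'
#' Subtracts the ground elevation so that heights are above-ground.  With
#' `method = "global"` (the default, appropriate for a segmented single
#' tree) the ground is the global minimum z.  With `method = "grid"` the
#' cloud is binned into square xy cells and each point is detrended by its
#' cell's minimum z, a grid-minimum terrain model that follows gentle
#' slopes.  Idempotent and equivariant under z-translation.
#'
#' @param cloud A [tree_cloud()].
#' @param method `"global"` or `"grid"`.
#' @param cell Grid cell side in meters (grid method).
#' @return A normalized [tree_cloud()].
#' @export
normalize_ground <- function(cloud, method = c("global", "grid"), cell = 0.5) {
  stopifnot(inherits(cloud, "tree_cloud"))
  method <- match.arg(method)
  p <- cloud$points
  if (method == "global") {
    p[, "z"] <- p[, "z"] - min(p[, "z"])
  } else {
    ix <- floor(p[, "x"] / cell)
    iy <- floor(p[, "y"] / cell)
    key <- paste(ix, iy)
    zmin <- tapply(p[, "z"], key, min)
    p[, "z"] <- p[, "z"] - as.numeric(zmin[key])
  }
  tree_cloud(p, cloud$tree_id, cloud$plot_id, normalized = TRUE)
}

## internal: mean distance to k nearest neighbours, chunked brute force
knn_mean_dist <- function(p, k, chunk = 512L) {
  n <- nrow(p)
  sq <- rowSums(p^2)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    # squared distances from chunk rows to all points
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(p[s:e, , drop = FALSE], p)
    d2[d2 < 0] <- 0
    for (i in seq_len(e - s + 1L)) {
      di <- sort.int(d2[i, ], partial = k + 1L)[2:(k + 1L)]
      out[s + i - 1L] <- mean(sqrt(di))
    }
  }
  out
}

#' Statistical outlier removal
#'
#' Removes points whose mean distance to their `k` nearest neighbours
#' exceeds the cloud-wide mean plus `m` standard deviations of that
#' statistic.  A guard caps removal at 20\% of the cloud (the worst
#' offenders are removed first).
#'
#' @param cloud A [tree_cloud()].
#' @param k Number of neighbours (default 8).
#' @param m Standard-deviation multiplier (default 3).
#' @return A denoised [tree_cloud()].
#' @export
denoise_sor <- function(cloud, k = 8L, m = 3.0) {
  stopifnot(inherits(cloud, "tree_cloud"))
  n <- nrow(cloud$points)
  if (k < 1L) stopf("k must be >= 1")
  if (n <= k) stopf("denoise_sor needs more points (%d) than neighbours k = %d",
                    n, k)
  md <- knn_mean_dist(cloud$points, as.integer(k))
  thr <- mean(md) + m * stats::sd(md)
  bad <- which(md > thr)
  cap <- floor(0.2 * n)
  if (length(bad) > cap)
    bad <- bad[order(md[bad], decreasing = TRUE)][seq_len(cap)]
  keep <- if (length(bad)) cloud$points[-bad, , drop = FALSE] else cloud$points
  tree_cloud(keep, cloud$tree_id, cloud$plot_id, normalized = cloud$normalized)
}
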
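# Trait-trait and trait-environment statistics: Pearson and partial
# correlation with significance stars, standardized PCA with sign
# conventions, centroid-linkage clustering of trait profiles.

sig_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}

cor_t_test <- function(r, df) {
  tstat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = df)
}

#' Two-tailed Pearson correlation
#'
#' Product-moment correlation with p-value from
#' `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` df, and significance stars at
#' the 0.1 / 0.05 / 0.01 levels.
#'
#' @param x,y Numeric vectors (n >= 3, nonzero variance).
#' @return List of class `correlation_result`: `r`, `p`, `n`, `controls`
#'   (empty), `stars`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  n <- length(x)
  if (n < 3L) stopf("need n >= 3, got %d", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance in x or y")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else cor_t_test(r, n - 2L)
  structure(list(r = r, p = p, n = n, controls = character(0),
                 stars = sig_stars(p)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  ctl <- if (length(x$controls))
    sprintf(" | %s", paste(x$controls, collapse = ", ")) else ""
  cat(sprintf("<correlation%s> r = %.4f, p = %.4g, n = %d %s\n",
              ctl, x$r, x$p, x$n, x$stars))
  invisible(x)
}

#' Partial correlation by the residual method
#'
#' Correlation of the residuals of `x` and `y` after ordinary
#' least-squares regression on the control variables (with intercept);
#' p-value on `n - 2 - k` df.  With no controls this reduces exactly to
#' [pearson()].
#'
#' @param x,y Numeric vectors.
#' @param controls Numeric vector, matrix or data frame of control
#'   variables (`NULL` for none).
#' @return A `correlation_result` with the control names recorded.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  n <- length(x)
  if (length(y) != n) stopf("x and y lengths differ")
  if (is.null(controls) || (is.data.frame(controls) && !ncol(controls))) {
    out <- pearson(x, y)
    return(out)
  }
  C <- as.matrix(controls)
  k <- ncol(C)
  if (nrow(C) != n) stopf("controls must have %d rows", n)
  if (n < k + 3L) stopf("need n >= number of controls + 3")
  nm <- colnames(C)
  if (is.null(nm)) nm <- paste0("c", seq_len(k))
  M <- cbind(1, C)
  if (qr(M)$rank < ncol(M)) stopf("rank-deficient control matrix")
  rx <- stats::lm.fit(M, x)$residuals
  ry <- stats::lm.fit(M, y)$residuals
  # a variable explained exactly by the controls leaves numerical dust;
  # its partial correlation is 0 by definition
  degen <- function(res, orig) stats::sd(res) <= 1e-10 * (stats::sd(orig) + 1e-300)
  r <- if (degen(rx, x) || degen(ry, y)) 0 else stats::cor(rx, ry)
  df <- n - 2L - k
  p <- if (abs(r) >= 1) 0 else cor_t_test(r, df)
  structure(list(r = r, p = p, n = n, controls = nm, stars = sig_stars(p)),
            class = "correlation_result")
}

#' Standardized PCA of the trait table
#'
#' LTD and TDR are negated before the analysis (they load opposite to the
#' other hydraulic-axis traits, and flipping keeps the biplot readable);
#' columns are standardized (mean 0, SD 1, `n - 1` denominator); the
#' correlation matrix is eigendecomposed, so explained fractions are
#' eigenvalues over their sum (the number of traits).  Axis signs are
#' fixed so each axis's largest-magnitude loading is positive.
#'
#' @param table Data frame holding the 12 trait columns
#'   ([trait_columns()]), or any all-numeric trait table.
#' @param flip Character vector of columns to negate before the PCA.
#' @return List of class `trait_pca`: `loadings` (traits x axes),
#'   `scores` (rows x axes), `explained_fraction`, `eigenvalues`.
#' @export
pca_traits <- function(table, flip = c("ltd", "tdr")) {
  cols <- if (all(trait_columns() %in% names(table))) trait_columns()
          else names(table)[vapply(table, is.numeric, TRUE)]
  X <- as.matrix(table[, cols, drop = FALSE])
  if (nrow(X) < 3L) stopf("need at least 3 rows")
  fl <- intersect(flip, cols)
  X[, fl] <- -X[, fl]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stopf("constant column(s): %s", paste(cols[sds == 0], collapse = ", "))
  Z <- scale(X)
  R <- stats::cor(X)
  ev <- eigen(R, symmetric = TRUE)
  V <- ev$vectors
  # sign convention: largest-magnitude loading positive on each axis
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- cols
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  scores <- Z %*% V
  structure(list(loadings = V, scores = scores,
                 explained_fraction = ev$values / sum(ev$values),
                 eigenvalues = ev$values),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  ef <- 100 * x$explained_fraction
  cat(sprintf("<trait_pca> %d axes; PC1 %.1f%%, PC2 %.1f%% (two axes %.1f%%)\n",
              length(ef), ef[1], ef[2], ef[1] + ef[2]))
  invisible(x)
}

#' Centroid-linkage clustering of trait profiles
#'
#' Each trait is represented by its standardized profile across plots;
#' agglomeration merges the pair of clusters with the smallest squared
#' Euclidean distance between centroids.  Centroid linkage can produce
#' inversions (a merge lower than an earlier one); these are permitted
#' and flagged.
#'
#' @param table Data frame with trait columns over plots.
#' @param cols Trait columns to cluster (default [trait_columns()] if
#'   present, else all numeric columns).
#' @return An `hclust` object (heights are squared centroid distances)
#'   with attribute `inversions` (logical).
#' @export
cluster_traits <- function(table, cols = NULL) {
  if (is.null(cols))
    cols <- if (all(trait_columns() %in% names(table))) trait_columns()
            else names(table)[vapply(table, is.numeric, TRUE)]
  if (anyDuplicated(cols)) stopf("duplicate trait names")
  if (length(cols) < 2L) stopf("need at least 2 traits")
  X <- t(scale(as.matrix(table[, cols, drop = FALSE])))
  hc <- stats::hclust(stats::dist(X)^2, method = "centroid")
  hc$labels <- cols
  attr(hc, "inversions") <- is.unsorted(hc$height)
  hc
}

#' Environment-trait correlation matrix
#'
#' Two-tailed Pearson correlations between each of the 13 environment
#' variables and each of the 12 plot-mean traits, with significance stars
#' at 0.1 / 0.05 / 0.01 (no multiple-testing correction, matching the
#' raw-star convention of the source analysis style).
#'
#' @param table Plot table holding [trait_columns()] and [env_columns()].
#' @return List of class `env_trait_matrix`: matrices `r`, `p`, `stars`
#'   (environment rows x trait columns) and `n`.
#' @export
env_trait_matrix <- function(table) {
  tc <- trait_columns(); ec <- env_columns()
  miss <- setdiff(c(tc, ec), names(table))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  for (cn in c(tc, ec)) {
    v <- table[[cn]]
    if (stats::sd(v) == 0) stopf("constant column: %s", cn)
  }
  r <- p <- matrix(NA_real_, length(ec), length(tc),
                   dimnames = list(ec, tc))
  for (e in ec) for (t in tc) {
    res <- pearson(table[[e]], table[[t]])
    r[e, t] <- res$r; p[e, t] <- res$p
  }
  st <- matrix(sig_stars(p), nrow(p), ncol(p), dimnames = dimnames(p))
  structure(list(r = r, p = p, stars = st, n = nrow(table)),
            class = "env_trait_matrix")
}

#' @export
print.env_trait_matrix <- function(x, ...) {
  cat(sprintf("<env_trait_matrix> %d environment x %d trait Pearson tests, n = %d\n",
              nrow(x$r), ncol(x$r), x$n))
  m <- matrix(sprintf("%.2f%s", x$r, x$stars), nrow(x$r),
              dimnames = dimnames(x$r))
  print(as.data.frame(m))
  invisible(x)
}
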
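# Leaf morphological traits: SLA, leaf tissue density, and area / main
# vein length from binary leaf-scan masks.

#' Specific leaf area
#'
#' `SLA = LA / leaf dry weight` (cm2/g).
#'
#' @param la Leaf area (cm2, >= 0).
#' @param dry_weight Leaf dry weight (g, > 0).
#' @return SLA in cm2/g.
#' @export
sla <- function(la, dry_weight) {
  if (any(dry_weight <= 0)) stopf("dry_weight must be > 0")
  if (any(la < 0)) stopf("la must be >= 0")
  la / dry_weight
}

#' Leaf tissue density
#'
#' `LTD = leaf dry weight / (LA * leaf thickness)` (g/cm3); thickness in
#' cm (convert caliper mm at ingestion).
#'
#' @param dry_weight Leaf dry weight (g, >= 0).
#' @param la Leaf area (cm2, > 0).
#' @param thickness Leaf thickness (cm, > 0).
#' @return LTD in g/cm3.
#' @export
ltd <- function(dry_weight, la, thickness) {
  if (any(la <= 0) || any(thickness <= 0))
    stopf("la and thickness must be > 0")
  if (any(dry_weight < 0)) stopf("dry_weight must be >= 0")
  dry_weight / (la * thickness)
}

## internal: fill holes of a logical mask by flood-filling the background
## from the borders; anything not reached is foreground
fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  outside <- matrix(FALSE, nr + 2L, nc + 2L)
  # iterative dilation of the border background until it stops growing
  outside[1, ] <- !pad[1, ]; outside[nr + 2L, ] <- !pad[nr + 2L, ]
  outside[, 1] <- outside[, 1] | !pad[, 1]
  outside[, nc + 2L] <- outside[, nc + 2L] | !pad[, nc + 2L]
  repeat {
    grown <- outside
    grown[-1, ] <- grown[-1, ] | outside[-(nr + 2L), ]
    grown[-(nr + 2L), ] <- grown[-(nr + 2L), ] | outside[-1, ]
    grown[, -1] <- grown[, -1] | outside[, -(nc + 2L)]
    grown[, -(nc + 2L)] <- grown[, -(nc + 2L)] | outside[, -1]
    grown <- grown & !pad
    if (identical(grown, outside)) break
    outside <- grown
  }
  !outside[2:(nr + 1L), 2:(nc + 1L)]
}

#' Leaf area from a binary scan mask
#'
#' Holes are filled (the lamina outline counts), then the foreground pixel
#' count is scaled by the squared resolution.
#'
#' @param mask Logical (or 0/1) matrix; `TRUE` = leaf.
#' @param resolution Pixel side length in cm.
#' @return Leaf area in cm2.
#' @export
leaf_area_from_mask <- function(mask, resolution) {
  m <- mask > 0
  if (!any(m)) stopf("empty leaf mask")
  if (resolution <= 0) stopf("resolution must be > 0")
  sum(fill_holes(m)) * resolution^2
}

## internal: Zhang-Suen morphological thinning to a 1-px skeleton
zhang_suen <- function(mask) {
  img <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  img[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask)
  nbrs <- function(img) {
    nr <- nrow(img); nc <- ncol(img)
    sh <- function(dr, dc) img[(2:(nr - 1L)) + dr, (2:(nc - 1L)) + dc]
    list(p2 = sh(-1, 0), p3 = sh(-1, 1), p4 = sh(0, 1), p5 = sh(1, 1),
         p6 = sh(1, 0), p7 = sh(1, -1), p8 = sh(0, -1), p9 = sh(-1, -1))
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- nbrs(img)
      core <- img[2:(nrow(img) - 1L), 2:(ncol(img) - 1L)]
      B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqn <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9,
                   nb$p2)
      A <- Reduce(`+`, lapply(1:8, function(i)
        (seqn[[i]] == 0L) & (seqn[[i + 1L]] == 1L)))
      if (step == 1L) {
        c1 <- nb$p2 * nb$p4 * nb$p6 == 0L
        c2 <- nb$p4 * nb$p6 * nb$p8 == 0L
      } else {
        c1 <- nb$p2 * nb$p4 * nb$p8 == 0L
        c2 <- nb$p2 * nb$p6 * nb$p8 == 0L
      }
      del <- core == 1L & B >= 2L & B <= 6L & A == 1L & c1 & c2
      if (any(del)) {
        core[del] <- 0L
        img[2:(nrow(img) - 1L), 2:(ncol(img) - 1L)] <- core
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[2:(nrow(img) - 1L), 2:(ncol(img) - 1L)] == 1L
}

#' Main vein length from a binary scan mask
#'
#' A surrogate for the main-vein measurement: the mask is hole-filled,
#' thinned to its morphological skeleton (Zhang-Suen), and the length of
#' the longest geodesic path through the skeleton is measured on the
#' 8-connected pixel graph (diagonal steps count sqrt(2) pixels), using
#' the two-sweep farthest-point heuristic.
#'
#' @inheritParams leaf_area_from_mask
#' @return Main vein length in cm.
#' @export
vein_length_from_mask <- function(mask, resolution) {
  m <- fill_holes(mask > 0)
  if (!any(m)) stopf("empty leaf mask")
  if (resolution <= 0) stopf("resolution must be > 0")
  sk <- zhang_suen(m)
  idx <- which(sk, arr.ind = TRUE)
  if (nrow(idx) == 0L) stopf("skeleton is empty")
  if (nrow(idx) == 1L) return(0)
  far <- skeleton_farthest(sk, idx[1, ])
  far2 <- skeleton_farthest(sk, far$pixel)
  far2$dist * resolution
}

## internal: Dijkstra over skeleton pixels (8-connectivity, diagonal
## sqrt(2)); returns the farthest reachable pixel and its distance
skeleton_farthest <- function(sk, start) {
  idx <- which(sk, arr.ind = TRUE)
  key <- paste(idx[, 1], idx[, 2])
  id <- seq_len(nrow(idx))
  names(id) <- key
  dist <- rep(Inf, nrow(idx))
  dist[id[paste(start[1], start[2])]] <- 0
  done <- rep(FALSE, nrow(idx))
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  w <- sqrt(offs$dr^2 + offs$dc^2)
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!length(u) || !is.finite(dist[u])) break
    done[u] <- TRUE
    r <- idx[u, 1]; cc <- idx[u, 2]
    for (k in seq_len(nrow(offs))) {
      nk <- paste(r + offs$dr[k], cc + offs$dc[k])
      v <- id[nk]
      if (!is.na(v) && !done[v] && dist[u] + w[k] < dist[v])
        dist[v] <- dist[u] + w[k]
    }
    if (all(done | !is.finite(dist))) break
  }
  reach <- which(is.finite(dist))
  best <- reach[which.max(dist[reach])]
  list(pixel = idx[best, ], dist = dist[best])
}
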
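# Fixed-radius (distance band) neighbor structure over residential points,
# with row-standardized binary weights. Points with no neighbor inside the
# band are flagged neighborless and excluded from the local statistic.

#' Build distance-band spatial weights
#'
#' Neighbors of point `i` are all other points within `radius_m` meters
#' (boundary inclusive: a pair at exactly the radius is a neighbor).
#' Weights are binary, row-standardized to `1/|N(i)|`, so the spatial lag is
#' the unweighted mean over neighbors. Coincident points are valid
#' neighbors. The kd-tree search is verified against a brute-force pairwise
#' oracle in the package tests.
#'
#' @param points two-column matrix or data frame of planar coordinates in
#'   meters (columns `x_m`, `y_m` if named).
#' @param radius_m band radius in meters (default 1200).
#' @return object of class `spatial_weights`: list with `neighbors` (list of
#'   integer vectors), `neighborless` (logical), `radius_m`, `n`.
#' @export
build_distance_band <- function(points, radius_m = 1200) {
  pts <- as.matrix(if (is.data.frame(points) &&
                       all(c("x_m", "y_m") %in% names(points)))
    points[, c("x_m", "y_m")] else points)
  storage.mode(pts) <- "double"
  if (nrow(pts) < 2) stop("at least 2 points are required")
  if (ncol(pts) != 2) stop("points must have two coordinate columns")
  if (!all(is.finite(pts))) stop("non-finite coordinates in points")
  if (!(radius_m > 0)) stop("radius_m must be positive")

  n <- nrow(pts)
  # adaptive k: grow until every point's neighborhood fits below k
  k <- min(n, 33L)
  repeat {
    res <- RANN::nn2(pts, pts, k = k, searchtype = "radius",
                     radius = radius_m * (1 + 1e-9))
    full <- res$nn.idx[, k] != 0
    if (!any(full) || k == n) break
    k <- min(n, 2L * k)
  }

  r2 <- radius_m^2 * (1 + 1e-12)
  neighbors <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- res$nn.idx[i, ]
    cand <- cand[cand != 0L & cand != i]
    if (length(cand) > 0) {
      d2 <- (pts[cand, 1] - pts[i, 1])^2 + (pts[cand, 2] - pts[i, 2])^2
      cand <- cand[d2 <= r2]
    }
    neighbors[[i]] <- sort(cand)
  }
  structure(list(neighbors = neighbors,
                 neighborless = lengths(neighbors) == 0L,
                 radius_m = radius_m, n = n),
            class = "spatial_weights")
}

#' Export spatial weights as sparse triplets
#'
#' @param w a `spatial_weights` object.
#' @return data frame with columns `i`, `j`, `w` (row-standardized weight
#'   `1/|N(i)|`); neighborless points contribute no rows.
#' @export
as_weight_triplets <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  k <- lengths(w$neighbors)
  data.frame(i = rep(seq_len(w$n), k),
             j = unlist(w$neighbors, use.names = FALSE),
             w = rep(ifelse(k > 0, 1 / k, 0), k))
}

#' @export
print.spatial_weights <- function(x, ...) {
  k <- lengths(x$neighbors)
  cat(sprintf(
    "Distance-band weights: %d points, radius %g m\n", x$n, x$radius_m))
  cat(sprintf("  neighbors per point: min %d, mean %.1f, max %d; %d neighborless\n",
              min(k), mean(k), max(k), sum(x$neighborless)))
  invisible(x)
}
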
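# Local Moran's I over a distance-band neighbor structure, with
# conditional-permutation pseudo p-values, Bonferroni control, and
# Moran-scatterplot quadrant cluster labels.
#
# Conventions (frozen here and exercised by the tests):
#  * the mean and second moment are computed over analyzed (non-neighborless)
#    points only;
#  * the permutation tail is sign-matched: for observed I >= 0 the upper
#    tail is counted, for I < 0 the lower tail, so concordant low-value
#    clusters (positive I driven by jointly low values) are detectable and
#    quadrants then separate High-High from Low-Low;
#  * significance is strict (p < threshold);
#  * labels are point-first: HH = high value among high neighbors, LH = low
#    value among high neighbors, etc.

cluster_levels <- c("NS", "HH", "LL", "LH", "HL", "NEIGHBORLESS")

#' Map palette for cluster labels
#'
#' Color names used on the cluster maps: dark green High-High, dark purple
#' Low-Low, light purple Low-High, light green High-Low, white
#' not-significant.
#' @export
cluster_palette <- c(HH = "dark green", LL = "dark purple",
                     LH = "light purple", HL = "light green",
                     NS = "white", NEIGHBORLESS = "grey")

#' Permutation-inference configuration
#'
#' @param n_permutations number of conditional permutations per point
#'   (default 99,999).
#' @param seed master seed; every point draws from its own substream keyed
#'   by (seed, point index), so results do not depend on evaluation order.
#' @param alpha_overall family-wise alpha for the Bonferroni threshold
#'   (default 0.1).
#' @return list of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 99999L, seed = 1L,
                               alpha_overall = 0.1) {
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1)
    stop("n_permutations must be >= 1")
  if (!(alpha_overall > 0 && alpha_overall < 1))
    stop("alpha_overall must lie in (0, 1)")
  structure(list(n_permutations = n_permutations, seed = as.integer(seed),
                 alpha_overall = alpha_overall),
            class = "permutation_config")
}

# Internal: deviations, second moment, and remapped neighbor lists over the
# analyzed (non-neighborless) subset.
moran_prepare <- function(y, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  if (length(y) != weights$n)
    stop("length(y) must equal the number of points in the weights")
  if (anyNA(y)) stop("y contains missing values")
  analyzed <- which(!weights$neighborless)
  if (length(analyzed) < 2)
    stop("fewer than 2 non-neighborless points")
  ya <- y[analyzed]
  z <- ya - mean(ya)
  m2 <- sum(z^2) / length(z)
  if (m2 <= 0) stop("zero variance among analyzed points: ",
                    "Local Moran statistic undefined")
  remap <- match(seq_len(weights$n), analyzed)
  nbrs <- lapply(weights$neighbors[analyzed],
                 function(nb) as.integer(remap[nb]))
  list(analyzed = analyzed, z = z, m2 = m2, nbrs = nbrs)
}

#' Local Moran statistic
#'
#' For each analyzed point `i`: deviation `z_i = y_i - mean(y)`, spatial lag
#' `lag_i = sum_j w_ij z_j` (the mean deviation over neighbors for
#' row-standardized weights), and `I_i = z_i / m2 * lag_i` with
#' `m2 = sum(z^2) / n`. The mean of the `I_i` equals the global Moran's I
#' under row standardization. Neighborless points get `NA`.
#'
#' @param y numeric analysis variable, one value per point in `weights`.
#' @param weights a [build_distance_band()] object.
#' @return data frame with columns `z`, `lag`, `I` (length = number of
#'   points; `NA` rows for neighborless points).
#' @export
local_moran_statistic <- function(y, weights) {
  prep <- moran_prepare(y, weights)
  lag <- vapply(seq_along(prep$nbrs),
                function(i) mean(prep$z[prep$nbrs[[i]]]), numeric(1))
  out <- data.frame(z = rep(NA_real_, weights$n), lag = NA_real_,
                    I = NA_real_)
  out$z[prep$analyzed] <- prep$z
  out$lag[prep$analyzed] <- lag
  out$I[prep$analyzed] <- prep$z / prep$m2 * lag
  out
}

#' Conditional-permutation pseudo p-values
#'
#' For each analyzed point, `M` conditional permutations hold `y_i` fixed
#' and refill its neighbor slots with values drawn without replacement from
#' the other `n - 1` observed values; the pseudo p-value is
#' `(R + 1) / (M + 1)` with `R` the number of permuted statistics at least
#' as extreme as the observed one, in the tail matching the sign of the
#' observed `I_i`. Fully reproducible from the config seed.
#'
#' @param y numeric analysis variable.
#' @param weights a [build_distance_band()] object.
#' @param config a [permutation_config()].
#' @return numeric vector of pseudo p-values (`NA` for neighborless points).
#' @export
permutation_pvalues <- function(y, weights, config = permutation_config()) {
  stopifnot(inherits(config, "permutation_config"))
  res <- moran_permutation_engine(y, weights, config)
  res$pseudo_p
}

# Internal: full engine output (p-values plus permutation moments, used for
# the closed-form conditional-mean checks).
moran_permutation_engine <- function(y, weights, config) {
  prep <- moran_prepare(y, weights)
  eng <- cond_perm_local_moran(prep$z, prep$nbrs, prep$m2,
                               config$n_permutations,
                               as.double(config$seed))
  expand <- function(v) {
    out <- rep(NA_real_, weights$n)
    out[prep$analyzed] <- v
    out
  }
  data.frame(z = expand(prep$z), lag = expand(eng$lag), I = expand(eng$I),
             pseudo_p = expand(eng$pseudo_p),
             perm_mean = expand(eng$perm_mean),
             perm_sd = expand(eng$perm_sd))
}

#' Bonferroni threshold
#'
#' @param alpha_overall family-wise alpha in (0, 1).
#' @param n_tests number of simultaneous tests.
#' @return per-test significance threshold `alpha_overall / n_tests`.
#' @export
bonferroni_threshold <- function(alpha_overall, n_tests) {
  if (!(alpha_overall > 0 && alpha_overall < 1))
    stop("alpha_overall must lie in (0, 1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha_overall / n_tests
}

#' Classify points into Moran-scatterplot cluster types
#'
#' `NS` when `pseudo_p >= threshold` (strict significance) or when `z` or
#' `lag` is exactly zero at a significant point; otherwise the scatterplot
#' quadrant: HH (`z > 0, lag > 0`), LL (`z < 0, lag < 0`), HL (`z > 0,
#' lag < 0`), LH (`z < 0, lag > 0`). `NA` inputs (neighborless points) map
#' to `NEIGHBORLESS`.
#'
#' @param z,lag,pseudo_p aligned numeric vectors.
#' @param threshold per-test significance threshold.
#' @return factor with levels `NS, HH, LL, LH, HL, NEIGHBORLESS`.
#' @export
classify_clusters <- function(z, lag, pseudo_p, threshold) {
  stopifnot(length(z) == length(lag), length(z) == length(pseudo_p))
  lab <- rep("NS", length(z))
  lab[is.na(z) | is.na(lag) | is.na(pseudo_p)] <- "NEIGHBORLESS"
  sig <- which(lab == "NS" & pseudo_p < threshold & z != 0 & lag != 0)
  lab[sig] <- ifelse(z[sig] > 0,
                     ifelse(lag[sig] > 0, "HH", "HL"),
                     ifelse(lag[sig] > 0, "LH", "LL"))
  factor(lab, levels = cluster_levels)
}

#' Local Moran cluster analysis of one variable
#'
#' Convenience wrapper: statistic, conditional-permutation pseudo p-values,
#' Bonferroni threshold, and quadrant labels in one call.
#'
#' @param y numeric analysis variable, one value per point.
#' @param weights a [build_distance_band()] object.
#' @param config a [permutation_config()].
#' @param n_tests number of tests entering the Bonferroni correction;
#'   defaults to the total number of points (including neighborless ones).
#' @return object of class `local_moran` (data frame with columns `z`,
#'   `lag`, `I`, `pseudo_p`, `label`); attributes `threshold` and
#'   `n_analyzed`.
#' @export
local_moran <- function(y, weights, config = permutation_config(),
                        n_tests = length(y)) {
  res <- moran_permutation_engine(y, weights, config)
  threshold <- bonferroni_threshold(config$alpha_overall, n_tests)
  res$label <- classify_clusters(res$z, res$lag, res$pseudo_p, threshold)
  res$perm_mean <- NULL
  res$perm_sd <- NULL
  attr(res, "threshold") <- threshold
  attr(res, "n_analyzed") <- sum(!weights$neighborless)
  class(res) <- c("local_moran", "data.frame")
  res
}

#' Write Local Moran results to CSV
#'
#' @param result a [local_moran()] result.
#' @param path output CSV path.
#' @param ids optional identifier column.
#' @return `path`, invisibly.
#' @export
write_local_moran_csv <- function(result, path, ids = seq_len(nrow(result))) {
  out <- cbind(data.frame(id = ids), as.data.frame(result))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a Local Moran cluster map as GeoJSON points
#'
#' Each point carries its label, pseudo p-value, and the map color name of
#' its cluster type.
#'
#' @param result a [local_moran()] result.
#' @param points the coordinates the weights were built from.
#' @param path output GeoJSON path.
#' @param ids optional identifier column.
#' @return `path`, invisibly.
#' @export
write_local_moran_geojson <- function(result, points, path,
                                      ids = seq_len(nrow(result))) {
  pts <- as.data.frame(if (is.data.frame(points) &&
                           all(c("x_m", "y_m") %in% names(points)))
    points[, c("x_m", "y_m")] else points)
  names(pts) <- c("x_m", "y_m")
  df <- cbind(pts,
              data.frame(id = ids,
                         label = as.character(result$label),
                         pseudo_p = result$pseudo_p,
                         color = unname(
                           cluster_palette[as.character(result$label)])))
  write_points_geojson(df, path)
}
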
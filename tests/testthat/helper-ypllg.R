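# Shared fixtures and oracles, all built in code.

sample_skewness <- function(x) {
  z <- x - mean(x)
  mean(z^3) / mean(z^2)^1.5
}

# O(n^2) brute-force oracle for the distance-band neighbor structure
# (boundary inclusive), independent of the kd-tree path.
brute_force_neighbors <- function(pts, radius) {
  n <- nrow(pts)
  lapply(seq_len(n), function(i) {
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
    sort(setdiff(which(d2 <= radius^2), i))
  })
}

# Study condition for planted-cluster recovery: two clusters (one high, one
# low) of radius 2.25x the 1200 m lag, 8-year lifespan shift equal to one
# population sd (Gaussian lifespan-deviation noise, sd 6).
recovery_config <- function(seed) {
  synthetic_config(
    n_individuals = 1340, region_extent = c(0, 10050, 0, 10050),
    n_high_clusters = 1, n_low_clusters = 1, cluster_radius_m = 2700,
    cluster_effect_years = 8,
    skew_params = list(mean = 0, sd = 6, median = 0),
    covariate_effects = list(swiss = 0, income_per_1000 = 0,
                             neighborhood_age = 0),
    seed = seed)
}

# Study condition where the spatial structure is entirely covariate-driven:
# no planted clusters, a strong west-to-east income gradient, and a 0.25
# year / 1000 CHF income effect on lifespan.
covariate_config <- function(seed) {
  synthetic_config(
    n_individuals = 600, region_extent = c(0, 8000, 0, 8000),
    n_high_clusters = 0, n_low_clusters = 0,
    skew_params = list(mean = 0, sd = 7.5, median = 0),
    covariate_effects = list(swiss = 0, income_per_1000 = 0.25,
                             neighborhood_age = 0),
    income_gradient = 100000, seed = seed)
}

# Minimal hand-built neighborhood panel: three subsectors on a line at
# x = 0, 1000, 2000 (S002 equidistant from S001 and S003), one year.
tiny_panel <- function(year = 2010, blank = character()) {
  counts <- matrix(0L, nrow = 3, ncol = 21,
                   dimnames = list(NULL, sprintf("c_%d_%d", seq(0, 100, 5),
                                                 seq(5, 105, 5))))
  counts[1, "c_30_35"] <- 10L
  counts[2, "c_40_45"] <- 10L
  counts[3, "c_50_55"] <- 10L
  panel <- cbind(
    data.frame(subsector_id = c("S001", "S002", "S003"), year = year,
               median_income = c(90000, 120000, 150000),
               stringsAsFactors = FALSE),
    as.data.frame(counts))
  panel$centroid_x_m <- c(0, 1000, 2000)
  panel$centroid_y_m <- 0
  for (s in blank) {
    i <- panel$subsector_id == s
    panel$median_income[i] <- NA_real_
    panel[i, grep("^c_", names(panel))] <- NA_integer_
  }
  panel
}

# Minimal record table for the filter-cascade tests.
make_records <- function(n, year = 2012, x = 100, y = 100) {
  if (n == 0) return(make_records(1, year, x[1], y[1])[0, ])
  data.frame(id = sprintf("R%03d", seq_len(n)),
             gender = rep(c("F", "M"), length.out = n),
             nationality = "swiss",
             birth_date = as.Date("1930-05-01") + seq_len(n),
             death_date = as.Date(sprintf("%d-06-15", year)) + seq_len(n),
             x_m = rep_len(x, n), y_m = rep_len(y, n),
             subsector_id = "S001", stringsAsFactors = FALSE)
}
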
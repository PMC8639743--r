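# Synthetic study populations: georeferenced death records with planted
# spatial clusters of long- and short-lived individuals, a cohort life table,
# and a neighborhood (subsector) panel with income and grouped age counts.
# Every downstream stage of the pipeline is testable against the planted
# truth returned by the generator.

#' Configuration of a synthetic study population
#'
#' Defaults emulate the statistical shape of an urban mortality register:
#' a negatively skewed lifespan-deviation distribution (target mean 5.19,
#' sd 20.12, median 9.3 years), 53.3% women, 79.6% nationals, deaths over
#' 2009--2016, and planted circular clusters where expected lifespan is
#' shifted up (high clusters) or down (low clusters).
#'
#' @param n_individuals number of death records to generate.
#' @param region_extent rectangle `c(xmin, xmax, ymin, ymax)` in meters.
#' @param n_high_clusters,n_low_clusters number of planted clusters of long-
#'   respectively short-lived individuals.
#' @param cluster_radius_m radius of each planted cluster, meters.
#' @param cluster_effect_years shift in expected lifespan (years) inside a
#'   planted cluster; added in high clusters, subtracted in low clusters.
#' @param skew_params list `(mean, sd, median)` of the lifespan-deviation
#'   noise in years. `median > mean` requests a left-skewed (negated shifted
#'   log-normal) law; `median == mean` a Gaussian; `sd = 0` a constant.
#' @param frac_women,frac_swiss marginal proportions in `[0, 1]`.
#' @param covariate_effects list with elements `swiss` (years added for
#'   nationals), `income_per_1000` (years per 1000 CHF of neighborhood income,
#'   centred), `neighborhood_age` (years per year of neighborhood median age,
#'   centred). Every contribution is centred, so these shift the spatial and
#'   social structure of lifespans without moving the population mean.
#'   Defaults plant a moderate covariate structure; set all to 0 for purely
#'   spatial effects.
#' @param n_subsectors number of statistical subsectors (neighborhoods).
#' @param year_range inclusive calendar-year interval of deaths.
#' @param seed integer seed; all generator randomness derives from it.
#' @param missing_cell_frac fraction of (subsector, year) panel cells whose
#'   income and age counts are blanked to exercise the nearest-neighborhood
#'   fallback.
#' @param income_base,income_gradient,income_sd shape of the neighborhood
#'   median income surface: base level (CHF/year), total west-to-east linear
#'   gradient (CHF), and between-subsector noise sd (CHF).
#' @param age_base,age_between_sd neighborhood mean-age level and
#'   between-subsector sd (years) used to build the grouped age counts.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_individuals = 2000,
                             region_extent = c(0, 10000, 0, 10000),
                             n_high_clusters = 1,
                             n_low_clusters = 1,
                             cluster_radius_m = 1500,
                             cluster_effect_years = 15,
                             skew_params = list(mean = 5.19, sd = 20.12,
                                                median = 9.3),
                             frac_women = 0.533,
                             frac_swiss = 0.796,
                             covariate_effects = list(swiss = 5,
                                                      income_per_1000 = 0.08,
                                                      neighborhood_age = 0.15),
                             n_subsectors = 100,
                             year_range = c(2009, 2016),
                             seed = 1L,
                             missing_cell_frac = 0,
                             income_base = 128000,
                             income_gradient = 80000,
                             income_sd = 15000,
                             age_base = 42,
                             age_between_sd = 6) {
  stopifnot(length(region_extent) == 4,
            region_extent[2] > region_extent[1],
            region_extent[4] > region_extent[3],
            length(year_range) == 2, year_range[2] >= year_range[1])
  if (n_individuals < 1) stop("n_individuals must be at least 1")
  if (cluster_radius_m <= 0) stop("cluster_radius_m must be positive")
  if (cluster_effect_years < 0) stop("cluster_effect_years must be >= 0")
  if (frac_women < 0 || frac_women > 1) stop("frac_women must lie in [0, 1]")
  if (frac_swiss < 0 || frac_swiss > 1) stop("frac_swiss must lie in [0, 1]")
  if (missing_cell_frac < 0 || missing_cell_frac >= 1)
    stop("missing_cell_frac must lie in [0, 1)")
  if (n_subsectors < 1) stop("n_subsectors must be at least 1")
  sk <- skew_params
  stopifnot(all(c("mean", "sd", "median") %in% names(sk)))
  if (sk$sd < 0) stop("skew_params$sd must be >= 0")
  if (sk$sd > 0 && sk$median < sk$mean)
    stop("skew_params: median < mean would give a right-skewed law; ",
         "this generator only produces left-skewed or symmetric noise")
  ce <- utils::modifyList(list(swiss = 0, income_per_1000 = 0,
                               neighborhood_age = 0), covariate_effects)
  structure(list(n_individuals = as.integer(n_individuals),
                 region_extent = as.numeric(region_extent),
                 n_high_clusters = as.integer(n_high_clusters),
                 n_low_clusters = as.integer(n_low_clusters),
                 cluster_radius_m = cluster_radius_m,
                 cluster_effect_years = cluster_effect_years,
                 skew_params = sk,
                 frac_women = frac_women,
                 frac_swiss = frac_swiss,
                 covariate_effects = ce,
                 n_subsectors = as.integer(n_subsectors),
                 year_range = as.integer(year_range),
                 seed = as.integer(seed),
                 missing_cell_frac = missing_cell_frac,
                 income_base = income_base,
                 income_gradient = income_gradient,
                 income_sd = income_sd,
                 age_base = age_base,
                 age_between_sd = age_between_sd),
            class = "synthetic_config")
}

# Solve (m0, mu, sigma) so that D = m0 - LogNormal(mu, sigma) has the target
# mean, sd, and median. Negating a right-skewed log-normal yields the
# negative skew characteristic of lifespan deviations (a long left tail of
# very premature deaths). median > mean pins down sigma via
#   e^{s/2} sqrt(e^s - 1) / (e^{s/2} - 1) = sd / (median - mean),  s = sigma^2.
solve_left_skew <- function(mean, sd, median) {
  if (sd == 0) return(list(kind = "constant", mean = mean))
  if (median == mean) return(list(kind = "normal", mean = mean, sd = sd))
  ratio <- sd / (median - mean)
  g <- function(s) exp(s / 2) * sqrt(exp(s) - 1) / (exp(s / 2) - 1)
  # g is U-shaped in s = sigma^2 (explodes as s -> 0 and as s -> Inf); take
  # the root on the left branch, i.e. the mildest tail matching the moments
  opt <- stats::optimize(g, c(1e-8, 60))
  if (ratio < opt$objective) {
    stop("skew_params infeasible: sd too small relative to median - mean")
  }
  s <- uniroot(function(s) g(s) - ratio,
               interval = c(1e-8, opt$minimum), tol = 1e-12)$root
  emu <- (median - mean) / (exp(s / 2) - 1)
  list(kind = "lognormal", m0 = median + emu, mu = log(emu), sigma = sqrt(s))
}

# Draw lifespan-deviation noise for the configured skew parameters.
rdev_noise <- function(n, skew_params) {
  par <- solve_left_skew(skew_params$mean, skew_params$sd, skew_params$median)
  switch(par$kind,
         constant = rep(par$mean, n),
         normal = rnorm(n, par$mean, par$sd),
         lognormal = par$m0 - rlnorm(n, par$mu, par$sigma))
}

#' Generate a cohort life table
#'
#' Life expectancy at birth (LEB) for every (birth year, gender) pair, built
#' as a linear cohort trend: `LEB(y, g) = base_leb[g] + annual_gain * (y -
#' min(year_range))`.
#'
#' @param year_range inclusive birth-year interval.
#' @param gender_levels gender categories, default `c("F", "M")`.
#' @param base_leb named numeric, LEB in years at the first birth year for
#'   each gender level (a scalar is recycled).
#' @param annual_gain yearly gain in LEB (years/birth-year), `>= 0`.
#' @return data frame of class `life_table` with columns `birth_year`,
#'   `gender`, `leb_years`.
#' @export
generate_life_table <- function(year_range, gender_levels = c("F", "M"),
                                base_leb = c(F = 74, M = 68),
                                annual_gain = 0.1) {
  if (length(year_range) != 2 || year_range[2] < year_range[1])
    stop("year_range must be a non-empty inclusive interval")
  if (annual_gain < 0) stop("annual_gain must be >= 0")
  if (length(base_leb) == 1) {
    base_leb <- stats::setNames(rep(base_leb, length(gender_levels)),
                                gender_levels)
  }
  if (!all(gender_levels %in% names(base_leb)))
    stop("base_leb must name every gender level")
  years <- seq(year_range[1], year_range[2])
  tab <- expand.grid(birth_year = years, gender = gender_levels,
                     stringsAsFactors = FALSE)
  tab$leb_years <- base_leb[tab$gender] +
    annual_gain * (tab$birth_year - year_range[1])
  rownames(tab) <- NULL
  class(tab) <- c("life_table", "data.frame")
  tab
}

# Subsector centroids are the anchor geometry shared by the panel and the
# population generator; they depend only on the seed.
subsector_centroids <- function(config) {
  set.seed(config$seed)
  ext <- config$region_extent
  data.frame(subsector_id = sprintf("S%03d", seq_len(config$n_subsectors)),
             centroid_x_m = runif(config$n_subsectors, ext[1], ext[2]),
             centroid_y_m = runif(config$n_subsectors, ext[3], ext[4]),
             stringsAsFactors = FALSE)
}

#' Generate a neighborhood-year panel
#'
#' For every (subsector, year): a median household income with a west-to-east
#' linear gradient plus between-subsector noise, and resident-population
#' counts by 5-year age group with a final bin `[100, 105)` (the 105-year cap
#' used for grouped-median computation). A configured fraction of cells is
#' blanked (income and counts set missing) to exercise the
#' nearest-neighborhood fallback downstream.
#'
#' @param config a [synthetic_config()].
#' @return data frame of class `neighborhood_panel` with columns
#'   `subsector_id`, `year`, `median_income`, `c_0_5` ... `c_100_105`,
#'   `centroid_x_m`, `centroid_y_m`. The complete (pre-blanking) income and
#'   neighborhood median age used by the population generator are kept in the
#'   `latent` attribute.
#' @export
generate_neighborhood_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cen <- subsector_centroids(config)
  set.seed(config$seed + 1L)
  ext <- config$region_extent
  years <- seq(config$year_range[1], config$year_range[2])
  ns <- config$n_subsectors

  # subsector-level latent surfaces, constant over years up to small drift
  frac_x <- (cen$centroid_x_m - ext[1]) / (ext[2] - ext[1])
  income_s <- config$income_base +
    config$income_gradient * (frac_x - 0.5) +
    rnorm(ns, 0, config$income_sd)
  income_s <- pmax(income_s, 20000)
  mean_age_s <- rnorm(ns, config$age_base, config$age_between_sd)

  bin_lower <- seq(0, 100, by = 5)
  grid <- expand.grid(subsector_id = cen$subsector_id, year = years,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$subsector_id, grid$year), , drop = FALSE]
  idx <- match(grid$subsector_id, cen$subsector_id)

  grid$median_income <- round(income_s[idx] * exp(rnorm(nrow(grid), 0, 0.02)))
  pop <- stats::rpois(nrow(grid), 800) + 50L
  counts <- t(vapply(seq_len(nrow(grid)), function(i) {
    w <- stats::dnorm(bin_lower + 2.5, mean_age_s[idx[i]], 15)
    as.integer(rmultinom(1, pop[i], w))
  }, integer(length(bin_lower))))
  colnames(counts) <- sprintf("c_%d_%d", bin_lower, bin_lower + 5)
  panel <- cbind(grid, as.data.frame(counts))
  panel$centroid_x_m <- cen$centroid_x_m[idx]
  panel$centroid_y_m <- cen$centroid_y_m[idx]

  latent <- data.frame(subsector_id = grid$subsector_id, year = grid$year,
                       income = income_s[idx],
                       median_age = apply(counts, 1, grouped_median_age),
                       stringsAsFactors = FALSE)

  if (config$missing_cell_frac > 0) {
    blank <- runif(nrow(panel)) < config$missing_cell_frac
    # keep at least one complete cell per year so the fallback stays total
    for (y in years) {
      rows <- which(panel$year == y)
      if (all(blank[rows])) blank[rows[1]] <- FALSE
    }
    panel$median_income[blank] <- NA_real_
    panel[blank, grep("^c_", names(panel))] <- NA_integer_
  }

  rownames(panel) <- NULL
  attr(panel, "latent") <- latent
  class(panel) <- c("neighborhood_panel", "data.frame")
  panel
}

# Rejection-sample planted cluster centers: inside the region inset by the
# cluster radius and pairwise separated by >= 2 radii so high and low
# clusters never overlap.
plant_cluster_centers <- function(config) {
  n_c <- config$n_high_clusters + config$n_low_clusters
  if (n_c == 0) return(NULL)
  ext <- config$region_extent
  r <- config$cluster_radius_m
  if (ext[2] - ext[1] < 2 * r || ext[4] - ext[3] < 2 * r)
    stop("region_extent too small to contain a planted cluster")
  for (try in 1:20000) {
    cx <- runif(n_c, ext[1] + r, ext[2] - r)
    cy <- runif(n_c, ext[3] + r, ext[4] - r)
    d <- as.matrix(stats::dist(cbind(cx, cy)))
    diag(d) <- Inf
    if (all(d >= 2 * r)) {
      return(data.frame(
        cluster = c(seq_len(config$n_high_clusters),
                    -seq_len(config$n_low_clusters))[seq_len(n_c)],
        x = cx, y = cy))
    }
  }
  stop("could not place non-overlapping cluster centers; ",
       "enlarge the region or shrink cluster_radius_m")
}

#' Generate a synthetic population of death records
#'
#' Residential coordinates are uniform over the region; gender and
#' nationality follow the configured proportions; the death date is uniform
#' over the year range. Age at death is assembled as
#' `LEB(birth year, gender) + cluster effect + covariate effects + skewed
#' noise`, resampled when below 0 and capped at 105 years, with the birth
#' year iterated to consistency against the life table.
#'
#' @param config a [synthetic_config()].
#' @param life_table optional [generate_life_table()] output covering every
#'   birth year that can occur; by default a table spanning 1870 to the end
#'   of the death-year range is built (women +6 years over men, 0.12
#'   years/cohort gain, level set so the mean lifespan of a default
#'   population is around 79.4 years).
#' @return list with elements `records` (data frame: `id`, `gender`,
#'   `nationality`, `birth_date`, `death_date`, `x_m`, `y_m`,
#'   `subsector_id`, `age_years`, `leb_years`, `ypllg_true`), `truth`
#'   (per-record planted-cluster membership and effect), `life_table`,
#'   `panel`, and `centers`.
#' @export
generate_population <- function(config, life_table = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_individuals < 1) stop("n_individuals must be at least 1")
  if (is.null(life_table)) {
    life_table <- generate_life_table(
      c(1870L, config$year_range[2]),
      base_leb = c(F = 69.5, M = 63.5), annual_gain = 0.12)
  }
  panel <- generate_neighborhood_panel(config)
  latent <- attr(panel, "latent")
  cen <- unique(panel[, c("subsector_id", "centroid_x_m", "centroid_y_m")])

  set.seed(config$seed + 2L)
  n <- config$n_individuals
  ext <- config$region_extent
  x <- runif(n, ext[1], ext[2])
  y <- runif(n, ext[3], ext[4])
  gender <- ifelse(runif(n) < config$frac_women, "F", "M")
  nationality <- ifelse(runif(n) < config$frac_swiss, "swiss", "non_swiss")

  day0 <- as.Date(sprintf("%d-01-01", config$year_range[1]))
  day1 <- as.Date(sprintf("%d-12-31", config$year_range[2]))
  death_date <- day0 + sample.int(as.integer(day1 - day0) + 1L, n,
                                  replace = TRUE) - 1L
  death_year <- as.integer(format(death_date, "%Y"))

  nn <- RANN::nn2(cen[, c("centroid_x_m", "centroid_y_m")], cbind(x, y), k = 1)
  subsector_id <- cen$subsector_id[nn$nn.idx[, 1]]

  centers <- plant_cluster_centers(config)
  cluster <- integer(n)
  effect <- numeric(n)
  if (!is.null(centers)) {
    for (ci in seq_len(nrow(centers))) {
      d <- sqrt((x - centers$x[ci])^2 + (y - centers$y[ci])^2)
      inside <- d <= config$cluster_radius_m & cluster == 0L
      cluster[inside] <- centers$cluster[ci]
      effect[inside] <- sign(centers$cluster[ci]) * config$cluster_effect_years
    }
  }

  key <- paste(latent$subsector_id, latent$year)
  li <- match(paste(subsector_id, death_year), key)
  # each covariate contribution is centred so the configured noise mean
  # stays the population mean of the lifespan deviation
  ce <- config$covariate_effects
  cov_eff <- ce$swiss * ((nationality == "swiss") - config$frac_swiss) +
    ce$income_per_1000 * (latent$income[li] - mean(latent$income)) / 1000 +
    ce$neighborhood_age * (latent$median_age[li] - mean(latent$median_age))

  dev <- rdev_noise(n, config$skew_params)

  lt_key <- paste(life_table$birth_year, life_table$gender)
  lookup_leb <- function(by, g) {
    i <- match(paste(by, g), lt_key)
    if (anyNA(i)) {
      bad <- which(is.na(i))[1]
      stop(sprintf("life table does not cover birth year %d (%s)",
                   by[bad], g[bad]))
    }
    life_table$leb_years[i]
  }

  # fixed-point iteration: birth year -> LEB -> age -> birth year; the
  # birth year is clamped to the life-table span while iterating (rows with
  # a provisionally negative age are resampled afterwards anyway)
  lt_span <- range(life_table$birth_year)
  assemble_age <- function(dev) {
    by <- pmax(lt_span[1], pmin(lt_span[2], death_year - 80L))
    age <- NULL
    for (iter in 1:12) {
      leb <- lookup_leb(by, gender)
      age <- leb + effect + cov_eff + dev
      by_new <- as.integer(format(death_date - round(age * 365.25), "%Y"))
      by_new <- pmax(lt_span[1], pmin(lt_span[2], by_new))
      if (all(by_new == by)) break
      by <- by_new
    }
    list(age = age, by = by, leb = lookup_leb(by, gender))
  }
  res <- assemble_age(dev)
  for (tries in 1:100) {
    bad <- res$age < 0
    if (!any(bad)) break
    dev[bad] <- rdev_noise(sum(bad), config$skew_params)
    res <- assemble_age(dev)
  }
  if (any(res$age < 0)) stop("could not sample non-negative ages at death")
  # finalize against the birth year actually implied by the (capped) age, so
  # the stored LEB matches a later year-of-birth lookup on the dates
  age <- pmin(res$age, 105)
  by <- as.integer(format(death_date - round(age * 365.25), "%Y"))
  by <- pmax(lt_span[1], pmin(lt_span[2], by))
  leb <- lookup_leb(by, gender)
  age <- pmin(leb + effect + cov_eff + dev, 105)
  birth_date <- death_date - round(age * 365.25)
  # rare year-boundary oscillators: pin the birth date inside the final year
  birth_date <- pmin(pmax(birth_date,
                          as.Date(sprintf("%d-01-01", by))),
                     as.Date(sprintf("%d-12-31", by)))

  records <- data.frame(
    id = sprintf("D%06d", seq_len(n)),
    gender = gender, nationality = nationality,
    birth_date = birth_date, death_date = death_date,
    x_m = x, y_m = y, subsector_id = subsector_id,
    age_years = age, leb_years = leb, ypllg_true = age - leb,
    stringsAsFactors = FALSE)
  truth <- data.frame(id = records$id, cluster = cluster,
                      planted_effect = effect, stringsAsFactors = FALSE)
  list(records = records, truth = truth, life_table = life_table,
       panel = panel, centers = centers)
}

#' Write a synthetic population to plain-text files
#'
#' Emits the death-record, life-table, neighborhood-panel, and truth-label
#' CSVs plus a subsector-centroid GeoJSON into a directory.
#'
#' @param pop result of [generate_population()].
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written.
#' @export
write_synthetic <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(records = file.path(dir, "death_records.csv"),
             life_table = file.path(dir, "life_table.csv"),
             panel = file.path(dir, "neighborhood_panel.csv"),
             truth = file.path(dir, "truth_labels.csv"),
             centroids = file.path(dir, "subsector_centroids.geojson"))
  rec <- pop$records[, c("id", "gender", "nationality", "birth_date",
                         "death_date", "x_m", "y_m", "subsector_id")]
  write.csv(rec, paths["records"], row.names = FALSE)
  write.csv(as.data.frame(pop$life_table), paths["life_table"],
            row.names = FALSE)
  write.csv(as.data.frame(pop$panel), paths["panel"], row.names = FALSE)
  write.csv(pop$truth, paths["truth"], row.names = FALSE)
  cen <- unique(pop$panel[, c("subsector_id", "centroid_x_m", "centroid_y_m")])
  write_points_geojson(cen, paths["centroids"],
                       x = "centroid_x_m", y = "centroid_y_m")
  paths
}
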
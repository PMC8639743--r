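# Neighborhood covariates: median population age from grouped 5-year counts
# (105-year cap) and attachment of (income, median age) to individuals with
# death-year matching and a nearest-neighborhood spatial fallback.

#' Median age from grouped 5-year counts
#'
#' Classical grouped-data median over contiguous equal-width bins
#' `[0,5), ..., [100,105)`: with `N` the total count, find the first bin
#' whose cumulative count reaches `N/2` and interpolate
#' `L + ((N/2 - CF) / f) * h`, where `L` is the bin's lower bound, `CF` the
#' cumulative count below it, `f` its count, and `h = 5` the bin width.
#'
#' @param counts non-negative integer vector of per-bin counts, lowest bin
#'   first.
#' @param bin_width bin width in years (default 5).
#' @return median age in years.
#' @export
grouped_median_age <- function(counts, bin_width = 5) {
  counts <- as.numeric(counts)
  if (anyNA(counts)) return(NA_real_)
  if (any(counts < 0)) stop("age-group counts must be non-negative")
  n <- sum(counts)
  if (n < 1) stop("all age-group counts are zero: median age undefined")
  half <- n / 2
  cum <- cumsum(counts)
  b <- which(cum >= half)[1]
  lower <- (b - 1) * bin_width
  cf <- if (b == 1) 0 else cum[b - 1]
  lower + (half - cf) / counts[b] * bin_width
}

# Derived median age per panel row (NA where counts are blanked).
panel_median_ages <- function(panel) {
  count_cols <- grep("^c_\\d+_\\d+$", names(panel), value = TRUE)
  if (length(count_cols) == 0) stop("panel has no age-count columns")
  apply(panel[, count_cols, drop = FALSE], 1, function(cc) {
    if (anyNA(cc)) NA_real_ else grouped_median_age(cc)
  })
}

#' Attach neighborhood covariates to death records
#'
#' For each record, median household income and neighborhood median
#' population age are taken from the (subsector, death year) panel cell. If
#' that cell is missing a value, the value of the nearest subsector (by
#' centroid Euclidean distance) with data for the same year is used; ties
#' are broken deterministically by the lexicographically smallest subsector
#' id. A `covariate_fallback` flag records whether any fallback fired for
#' the record.
#'
#' @param records death-record data frame with `subsector_id` and
#'   `death_date` columns.
#' @param panel neighborhood panel with columns `subsector_id`, `year`,
#'   `median_income`, age-count columns `c_0_5` ... `c_100_105`, and
#'   centroid coordinates (see [generate_neighborhood_panel()]).
#' @return `records` with `income`, `nbh_median_age`, and
#'   `covariate_fallback` columns appended.
#' @export
attach_covariates <- function(records, panel) {
  stopifnot(all(c("subsector_id", "death_date") %in% names(records)),
            all(c("subsector_id", "year", "median_income",
                  "centroid_x_m", "centroid_y_m") %in% names(panel)))
  panel <- as.data.frame(panel)
  panel$median_age <- panel_median_ages(panel)
  # deterministic donor ranking regardless of panel row order
  panel <- panel[order(panel$year, panel$subsector_id), , drop = FALSE]

  cen <- unique(panel[, c("subsector_id", "centroid_x_m", "centroid_y_m")])
  cen <- cen[!duplicated(cen$subsector_id), , drop = FALSE]

  death_year <- as.integer(format(as.Date(records$death_date), "%Y"))
  key <- paste(panel$subsector_id, panel$year)
  ri <- match(paste(records$subsector_id, death_year), key)

  income <- panel$median_income[ri]
  med_age <- panel$median_age[ri]
  fallback <- logical(nrow(records))

  # income fallback; which.min picks the first minimum, and donors are
  # sorted by subsector id within year, so equidistant ties resolve to the
  # smallest id
  miss <- which(is.na(ri) | is.na(income))
  for (r in miss) {
    yr <- death_year[r]
    donors <- which(panel$year == yr & !is.na(panel$median_income))
    if (length(donors) == 0) {
      stop(sprintf("no subsector has income data for year %d", yr))
    }
    ci <- match(records$subsector_id[r], cen$subsector_id)
    if (is.na(ci)) {
      stop(sprintf("subsector %s has no centroid in the panel",
                   records$subsector_id[r]))
    }
    di <- match(panel$subsector_id[donors], cen$subsector_id)
    d <- sqrt((cen$centroid_x_m[di] - cen$centroid_x_m[ci])^2 +
                (cen$centroid_y_m[di] - cen$centroid_y_m[ci])^2)
    income[r] <- panel$median_income[donors[which.min(d)]]
    fallback[r] <- TRUE
  }

  # median-age fallback
  miss <- which(is.na(ri) | is.na(med_age))
  for (r in miss) {
    yr <- death_year[r]
    donors <- which(panel$year == yr & !is.na(panel$median_age))
    if (length(donors) == 0) {
      stop(sprintf("no subsector has age data for year %d", yr))
    }
    ci <- match(records$subsector_id[r], cen$subsector_id)
    di <- match(panel$subsector_id[donors], cen$subsector_id)
    d <- sqrt((cen$centroid_x_m[di] - cen$centroid_x_m[ci])^2 +
                (cen$centroid_y_m[di] - cen$centroid_y_m[ci])^2)
    med_age[r] <- panel$median_age[donors[which.min(d)]]
    fallback[r] <- TRUE
  }

  records$income <- income
  records$nbh_median_age <- med_age
  records$covariate_fallback <- fallback
  records
}
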
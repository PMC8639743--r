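# Reading death-record tables and applying the exclusion cascade, with an
# auditable step-by-step filter ledger.

record_columns <- c("id", "nationality", "birth_date", "death_date",
                    "x_m", "y_m", "subsector_id")

parse_iso_date <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  ok <- is.na(x) | x == ""
  out[!ok] <- as.Date(x[!ok], format = "%Y-%m-%d", optional = TRUE)
  bad <- which(!ok & is.na(out))
  if (length(bad) > 0) {
    stop(sprintf("unparseable %s at row(s) %s (expected ISO-8601 YYYY-MM-DD)",
                 what, paste(head(bad, 5), collapse = ", ")))
  }
  out
}

#' Load death records from CSV
#'
#' Expected columns: `id`, `gender` (optional), `nationality`, `birth_date`,
#' `death_date`, `x_m`, `y_m`, `subsector_id`, and optionally `name`. When no
#' `gender` column is present, gender is filled from a local name-to-gender
#' lookup (`name`, `gender` columns); names absent from the lookup leave
#' gender missing, to be removed later by the filter cascade.
#'
#' @param path death-record CSV path.
#' @param name_gender_lookup optional data frame (or CSV path) with columns
#'   `name` and `gender`.
#' @return data frame of death records with `Date` columns.
#' @export
load_records <- function(path, name_gender_lookup = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(record_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("death-record file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$birth_date <- parse_iso_date(df$birth_date, "birth_date")
  df$death_date <- parse_iso_date(df$death_date, "death_date")
  if (!"gender" %in% names(df)) {
    df$gender <- NA_character_
    if (!is.null(name_gender_lookup) && "name" %in% names(df)) {
      if (is.character(name_gender_lookup) &&
          length(name_gender_lookup) == 1) {
        name_gender_lookup <- read.csv(name_gender_lookup,
                                       stringsAsFactors = FALSE)
      }
      stopifnot(all(c("name", "gender") %in% names(name_gender_lookup)))
      df$gender <- name_gender_lookup$gender[
        match(df$name, name_gender_lookup$name)]
    }
  }
  df$gender[!is.na(df$gender) & df$gender == ""] <- NA_character_
  df
}

# Boundary-inclusive containment test; records with missing coordinates are
# neither inside nor outside (they fall to the georeferencing step).
points_in_region <- function(x, y, boundary) {
  ok <- !is.na(x) & !is.na(y)
  inside <- rep(NA, length(x))
  if (is.numeric(boundary) && length(boundary) == 4) {
    inside[ok] <- x[ok] >= boundary[1] & x[ok] <= boundary[2] &
      y[ok] >= boundary[3] & y[ok] <= boundary[4]
  } else {
    if (is.character(boundary) && length(boundary) == 1) {
      boundary <- read_polygon_geojson(boundary)
    }
    stopifnot(is.matrix(boundary), ncol(boundary) == 2)
    # sp codes: 0 outside, 1 inside, 2 on edge, 3 on vertex
    inside[ok] <- sp::point.in.polygon(x[ok], y[ok],
                                       boundary[, 1], boundary[, 2]) > 0
  }
  inside
}

new_filter_ledger <- function(steps, n_start) {
  ledger <- data.frame(step = steps$step, n_removed = steps$n_removed,
                       n_remaining = steps$n_remaining,
                       stringsAsFactors = FALSE)
  attr(ledger, "n_start") <- n_start
  class(ledger) <- c("filter_ledger", "data.frame")
  ledger
}

#' Apply the exclusion cascade to death records
#'
#' Steps, in order: (1) keep deaths whose death year falls in `year_range`;
#' (2) remove duplicated entries (identical gender, birth date, death date,
#' and location) and records missing birth date, death date, or nationality;
#' (3) remove records located outside the region boundary; (4) remove
#' records without coordinates (could not be georeferenced); (5) remove
#' records with missing gender. Each step's removed/remaining counts are
#' recorded in a `filter_ledger`.
#'
#' @param records death-record data frame (see [load_records()]).
#' @param year_range inclusive interval of death years to keep.
#' @param region_boundary rectangle `c(xmin, xmax, ymin, ymax)`, a two-column
#'   vertex matrix of a polygon ring, or a path to a GeoJSON Polygon.
#'   Containment is boundary-inclusive.
#' @return list with `records` (the kept rows) and `ledger`
#'   (a `filter_ledger`).
#' @export
filter_records <- function(records, year_range, region_boundary) {
  stopifnot(length(year_range) == 2, year_range[2] >= year_range[1])
  steps <- list(step = character(), n_removed = integer(),
                n_remaining = integer())
  n_start <- nrow(records)
  cur <- records

  drop_step <- function(name, keep) {
    keep[is.na(keep)] <- FALSE
    steps$step <<- c(steps$step, name)
    steps$n_removed <<- c(steps$n_removed, sum(!keep))
    cur <<- cur[keep, , drop = FALSE]
    steps$n_remaining <<- c(steps$n_remaining, nrow(cur))
  }

  # records with no death date cannot be excluded by year; they fall to the
  # missing-fields step
  death_year <- as.integer(format(cur$death_date, "%Y"))
  drop_step("death_year_in_range",
            is.na(death_year) |
              (death_year >= year_range[1] & death_year <= year_range[2]))

  dup_key <- paste(cur$gender, cur$birth_date, cur$death_date,
                   cur$x_m, cur$y_m, sep = "|")
  incomplete <- is.na(cur$birth_date) | is.na(cur$death_date) |
    is.na(cur$nationality) | cur$nationality == ""
  drop_step("duplicates_or_missing_fields",
            !duplicated(dup_key) & !incomplete)

  inside <- points_in_region(cur$x_m, cur$y_m, region_boundary)
  drop_step("outside_region", is.na(inside) | inside)

  drop_step("not_georeferenced", !is.na(cur$x_m) & !is.na(cur$y_m))

  drop_step("missing_gender", !is.na(cur$gender))

  ledger <- new_filter_ledger(steps, n_start)
  rownames(cur) <- NULL
  list(records = cur, ledger = ledger)
}

#' Replay an exclusion cascade from printed step counts
#'
#' Builds a `filter_ledger` from a starting count and per-step removal
#' counts, for auditing published filter accounting without the underlying
#' records.
#'
#' @param n_start number of records before filtering.
#' @param removals named (or unnamed) integer vector of per-step removals.
#' @return a `filter_ledger`.
#' @export
replay_ledger <- function(n_start, removals) {
  steps <- names(removals)
  if (is.null(steps)) steps <- sprintf("step_%d", seq_along(removals))
  remaining <- n_start - cumsum(as.integer(removals))
  ledger <- new_filter_ledger(list(step = steps,
                                   n_removed = as.integer(removals),
                                   n_remaining = as.integer(remaining)),
                              n_start)
  validate_ledger(ledger)
  ledger
}

#' Check the telescoping identity of a filter ledger
#'
#' Each step's remaining count must equal the previous remaining count minus
#' the step's removals, and all counts must be non-negative.
#'
#' @param ledger a `filter_ledger`.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_ledger <- function(ledger) {
  stopifnot(inherits(ledger, "filter_ledger"))
  prev <- c(attr(ledger, "n_start"), head(ledger$n_remaining, -1))
  if (any(ledger$n_removed < 0) || any(ledger$n_remaining < 0))
    stop("ledger counts must be non-negative")
  if (!all(ledger$n_remaining == prev - ledger$n_removed))
    stop("ledger telescoping identity violated")
  invisible(TRUE)
}

#' Retention fraction of a filter ledger
#'
#' @param ledger a `filter_ledger`.
#' @return percentage of the starting records retained after the last step.
#' @export
ledger_retention <- function(ledger) {
  stopifnot(inherits(ledger, "filter_ledger"))
  100 * ledger$n_remaining[nrow(ledger)] / attr(ledger, "n_start")
}

#' Write a filter ledger to CSV and/or JSON
#'
#' @param ledger a `filter_ledger`.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_ledger <- function(ledger, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) write.csv(as.data.frame(ledger), csv_path,
                                    row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(n_start = attr(ledger, "n_start"),
                              steps = as.data.frame(ledger)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv_path, json_path))
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat(sprintf("Filter ledger: %d -> %d records (%.1f%% retained)\n",
              attr(x, "n_start"), x$n_remaining[nrow(x)],
              ledger_retention(x)))
  print(as.data.frame(x), ...)
  invisible(x)
}
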
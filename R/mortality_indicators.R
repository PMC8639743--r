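# Individual-level mortality indicators: cohort life expectancy at birth
# (LEB) attribution, years of potential life lost or gained (YPLLG), and
# years of potential life lost (YPLL) against a fixed cutoff.

#' Age at death in fractional years
#'
#' Exact day difference between the dates divided by 365.25, so a leap-
#' spanning 4-year interval is exactly 4.0 years.
#'
#' @param birth_date,death_date `Date` vectors (recycled to common length).
#' @return numeric vector of ages in years.
#' @export
age_at_death <- function(birth_date, death_date) {
  birth_date <- as.Date(birth_date)
  death_date <- as.Date(death_date)
  days <- as.numeric(death_date - birth_date)
  bad <- which(!is.na(days) & days < 0)
  if (length(bad) > 0) {
    stop(sprintf("death before birth at row(s) %s",
                 paste(head(bad, 5), collapse = ", ")))
  }
  days / 365.25
}

#' Attribute cohort life expectancy at birth
#'
#' Looks up LEB by (birth year, gender) in a life table. There is no
#' interpolation: a missing key is an error naming the key, since the
#' cohort tables this package expects are gap-free over their span.
#'
#' @param birth_year integer vector of birth years.
#' @param gender character vector of gender levels matching the table.
#' @param life_table data frame with columns `birth_year`, `gender`,
#'   `leb_years` (see [generate_life_table()] for the synthetic one).
#' @return numeric vector of LEB in years.
#' @export
attribute_leb <- function(birth_year, gender, life_table) {
  stopifnot(all(c("birth_year", "gender", "leb_years") %in%
                  names(life_table)))
  i <- match(paste(birth_year, gender),
             paste(life_table$birth_year, life_table$gender))
  if (anyNA(i)) {
    bad <- which(is.na(i))[1]
    stop(sprintf("no life-table entry for birth year %s, gender %s",
                 birth_year[bad], gender[bad]))
  }
  life_table$leb_years[i]
}

#' Years of potential life lost or gained (YPLLG)
#'
#' Signed difference between the age at death and the individual's cohort
#' life expectancy at birth: positive values are years of life gained,
#' negative values years lost.
#'
#' @param age_at_death,leb numeric vectors in years.
#' @return signed numeric vector in years.
#' @export
compute_yplg <- function(age_at_death, leb) {
  age_at_death - leb
}

#' Years of potential life lost (YPLL)
#'
#' Years not lived relative to a fixed cutoff age: `max(0, cutoff - age)`.
#' Years lived beyond the cutoff do not count.
#'
#' @param age_at_death numeric vector in years.
#' @param cutoff cutoff age in years (default 75).
#' @return non-negative numeric vector in years.
#' @export
compute_ypll <- function(age_at_death, cutoff = 75) {
  pmax(0, cutoff - age_at_death)
}

#' Attach mortality indicators to death records
#'
#' Adds `age_at_death_years`, `leb_years`, `yplg_years`, and `ypll_years`
#' columns, computed from the record dates and a cohort life table.
#'
#' @param records death-record data frame with `birth_date`, `death_date`,
#'   `gender` columns.
#' @param life_table life table (see [attribute_leb()]).
#' @param cutoff YPLL cutoff age in years.
#' @return `records` with the four indicator columns appended.
#' @export
add_indicators <- function(records, life_table, cutoff = 75) {
  age <- age_at_death(records$birth_date, records$death_date)
  by <- as.integer(format(as.Date(records$birth_date), "%Y"))
  leb <- attribute_leb(by, records$gender, life_table)
  records$age_at_death_years <- age
  records$leb_years <- leb
  records$yplg_years <- compute_yplg(age, leb)
  records$ypll_years <- compute_ypll(age, cutoff)
  records
}
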
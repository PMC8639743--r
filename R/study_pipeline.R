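# Orchestration of the full analysis: repeated random subsets, raw and
# adjusted cluster runs, per-cluster population summaries across subsets,
# Tukey HSD comparisons of cluster-type means, and footprint-reduction
# metrics between the raw and adjusted models.

#' Subset-resampling plan
#'
#' @param k number of random subsets (default 10).
#' @param m subset size, simple random sampling without replacement
#'   (default 10,000).
#' @param seed integer seed; subset `s` draws from its own substream.
#' @return list of class `subset_plan`.
#' @export
subset_plan <- function(k = 10L, m = 10000L, seed = 1L) {
  k <- as.integer(k); m <- as.integer(m)
  if (k < 1) stop("k must be >= 1")
  if (m < 1) stop("m must be >= 1")
  structure(list(k = k, m = m, seed = as.integer(seed)),
            class = "subset_plan")
}

#' Draw random subsets of records
#'
#' Each subset is a simple random sample without replacement of `m`
#' records, drawn independently of the other subsets and reproducible from
#' the plan seed.
#'
#' @param records death-record data frame.
#' @param plan a [subset_plan()].
#' @return list of `k` data frames.
#' @export
draw_subsets <- function(records, plan) {
  stopifnot(inherits(plan, "subset_plan"))
  n <- nrow(records)
  if (plan$m > n) stop("subset size m exceeds the number of records")
  lapply(seq_len(plan$k), function(s) {
    set.seed(plan$seed + 1000L * s)
    idx <- sample.int(n, plan$m)
    out <- records[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Run the cluster model on one subset
#'
#' Builds the distance-band weights on the subset's coordinates, selects
#' the analysis variable (raw YPLLG, or the residuals of a median
#' regression of YPLLG on the nationality indicator, income in 1000 CHF,
#' and neighborhood median age, refitted on this subset), and runs the
#' Local Moran analysis with a Bonferroni threshold of
#' `alpha / nrow(subset)`.
#'
#' @param subset data frame with columns `x_m`, `y_m`, `yplg_years`, and
#'   (for the adjusted variable) `nationality`, `income`, `nbh_median_age`.
#' @param variable `"raw"` or `"adjusted"`.
#' @param radius_m spatial-lag radius in meters (default 1200).
#' @param n_permutations conditional permutations per point.
#' @param alpha family-wise alpha for the Bonferroni correction.
#' @param seed permutation master seed.
#' @return the subset with columns `value` (the analysis variable), `z`,
#'   `lag`, `I`, `pseudo_p`, `label` appended; attribute `fit` carries the
#'   median-regression fit for adjusted runs.
#' @export
run_model <- function(subset, variable = c("raw", "adjusted"),
                      radius_m = 1200, n_permutations = 999L, alpha = 0.1,
                      seed = 1L) {
  variable <- match.arg(variable)
  stopifnot(all(c("x_m", "y_m", "yplg_years") %in% names(subset)))
  fit <- NULL
  if (variable == "raw") {
    value <- subset$yplg_years
  } else {
    stopifnot(all(c("nationality", "income", "nbh_median_age") %in%
                    names(subset)))
    X <- data.frame(swiss = as.numeric(subset$nationality == "swiss"),
                    income_k = subset$income / 1000,
                    nbh_age = subset$nbh_median_age)
    fit <- fit_median_regression(subset$yplg_years, X)
    value <- adjusted_yplg(fit)
  }
  w <- build_distance_band(subset[, c("x_m", "y_m")], radius_m)
  cfg <- permutation_config(n_permutations = n_permutations, seed = seed,
                            alpha_overall = alpha)
  lm_res <- local_moran(value, w, cfg, n_tests = nrow(subset))
  out <- cbind(subset, data.frame(value = value), as.data.frame(lm_res))
  attr(out, "threshold") <- attr(lm_res, "threshold")
  attr(out, "fit") <- fit
  out
}

cluster_characteristics <- c("n", "pct_women", "pct_swiss", "mean_yplg",
                             "mean_ypll", "mean_income", "mean_nbh_age")

# Per-subset, per-label characteristic values for one run_model() output.
subset_label_stats <- function(res) {
  labels <- c("NS", "HH", "LL", "LH", "HL")
  do.call(rbind, lapply(labels, function(lb) {
    rows <- res[!is.na(res$label) & res$label == lb, , drop = FALSE]
    n <- nrow(rows)
    stat <- function(f) if (n > 0) f(rows) else NA_real_
    data.frame(
      label = lb, n = n,
      pct_women = stat(function(r) 100 * mean(r$gender == "F")),
      pct_swiss = stat(function(r) 100 * mean(r$nationality == "swiss")),
      mean_yplg = stat(function(r) mean(r$value)),
      mean_ypll = stat(function(r) mean(r$ypll_years)),
      mean_income = stat(function(r) if ("income" %in% names(r))
        mean(r$income) else NA_real_),
      mean_nbh_age = stat(function(r) if ("nbh_median_age" %in% names(r))
        mean(r$nbh_median_age) else NA_real_),
      stringsAsFactors = FALSE)
  }))
}

#' Summarize cluster characteristics across subsets
#'
#' For each cluster label and characteristic (count, % women, % nationals,
#' mean of the analysis variable, mean YPLL, mean neighborhood income, mean
#' neighborhood median age): the range, mean, and standard deviation across
#' the subsets. A label absent from a subset contributes a zero count and
#' is excluded from that label's mean-characteristic aggregation.
#'
#' @param results list of [run_model()] outputs (one per subset).
#' @return data frame of class `cluster_summary` with columns `label`,
#'   `characteristic`, `min`, `max`, `mean`, `sd` (sd is `NA` for a single
#'   subset); attribute `per_subset` keeps the per-subset table.
#' @export
summarize_clusters <- function(results) {
  per <- do.call(rbind, lapply(seq_along(results), function(s) {
    cbind(subset = s, subset_label_stats(results[[s]]))
  }))
  agg <- do.call(rbind, lapply(split(per, per$label), function(g) {
    do.call(rbind, lapply(cluster_characteristics, function(ch) {
      v <- g[[ch]]
      if (ch != "n") v <- v[!is.na(v)]
      if (length(v) == 0) {
        data.frame(label = g$label[1], characteristic = ch,
                   min = NA_real_, max = NA_real_, mean = NA_real_,
                   sd = NA_real_, stringsAsFactors = FALSE)
      } else {
        data.frame(label = g$label[1], characteristic = ch,
                   min = min(v), max = max(v), mean = mean(v),
                   sd = if (length(v) > 1) sd(v) else NA_real_,
                   stringsAsFactors = FALSE)
      }
    }))
  }))
  rownames(agg) <- NULL
  attr(agg, "per_subset") <- per
  class(agg) <- c("cluster_summary", "data.frame")
  agg
}

#' Tukey HSD comparison of group means
#'
#' All pairwise comparisons of group means under the Tukey--Kramer
#' procedure (studentized-range reference distribution, pooled one-way
#' variance), as implemented by `stats::TukeyHSD`. Groups with fewer than
#' 2 observations are excluded with a warning.
#'
#' @param values numeric observations.
#' @param groups group membership (factor or character).
#' @param conf_level family-wise confidence level (default 0.95).
#' @return data frame with columns `comparison`, `diff`, `lwr`, `upr`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(values, groups, conf_level = 0.95) {
  groups <- as.character(groups)
  keep_levels <- names(which(table(groups) >= 2))
  if (length(keep_levels) < length(unique(groups))) {
    warning("excluding group(s) with fewer than 2 observations: ",
            paste(setdiff(unique(groups), keep_levels), collapse = ", "))
  }
  if (length(keep_levels) < 2) stop("need at least 2 groups with >= 2 observations")
  keep <- groups %in% keep_levels
  g <- factor(groups[keep])
  fit <- aov(values[keep] ~ g)
  th <- TukeyHSD(fit, conf.level = conf_level)$g
  data.frame(comparison = rownames(th), diff = th[, "diff"],
             lwr = th[, "lwr"], upr = th[, "upr"], p_adj = th[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Footprint reduction between raw and adjusted cluster runs
#'
#' Percent change in mean cluster membership, `100 * (n_raw - n_adj) /
#' n_raw`, per concordant cluster type, using mean counts across subsets.
#' Undefined (reported `NA`) when the raw mean count is zero.
#'
#' @param raw_summary,adjusted_summary [summarize_clusters()] outputs for
#'   the raw and adjusted runs.
#' @param labels cluster types to compare (default `LL` and `HH`).
#' @return named numeric vector of percent reductions.
#' @export
footprint_reduction <- function(raw_summary, adjusted_summary,
                                labels = c("LL", "HH")) {
  get_mean_n <- function(s, lb) {
    v <- s$mean[s$label == lb & s$characteristic == "n"]
    if (length(v) == 0) NA_real_ else v
  }
  out <- vapply(labels, function(lb) {
    raw_n <- get_mean_n(raw_summary, lb)
    adj_n <- get_mean_n(adjusted_summary, lb)
    if (is.na(raw_n) || raw_n == 0) return(NA_real_)
    100 * (raw_n - adj_n) / raw_n
  }, numeric(1))
  names(out) <- labels
  out
}

#' Run the full subset-replication study
#'
#' Draws `k` random subsets, runs the cluster model on each for both the
#' raw and the adjusted variable (the median regression is refitted per
#' subset), summarizes cluster characteristics across subsets, and
#' computes the footprint reduction of the concordant cluster types.
#'
#' @param records prepared death records (indicators and covariates
#'   attached).
#' @param plan a [subset_plan()].
#' @param radius_m,n_permutations,alpha,seed passed to [run_model()]; each
#'   subset's permutation seed is derived from `seed` and the subset index.
#' @return list with `raw_results`, `adjusted_results` (lists of per-subset
#'   model outputs), `raw_summary`, `adjusted_summary`, `footprint`, and
#'   `subsets`.
#' @export
run_study <- function(records, plan = subset_plan(),
                      radius_m = 1200, n_permutations = 999L, alpha = 0.1,
                      seed = 1L) {
  subsets <- draw_subsets(records, plan)
  run_all <- function(variable) {
    lapply(seq_along(subsets), function(s) {
      run_model(subsets[[s]], variable, radius_m = radius_m,
                n_permutations = n_permutations, alpha = alpha,
                seed = seed + 7919L * s)
    })
  }
  raw_results <- run_all("raw")
  adjusted_results <- run_all("adjusted")
  raw_summary <- summarize_clusters(raw_results)
  adjusted_summary <- summarize_clusters(adjusted_results)
  list(raw_results = raw_results, adjusted_results = adjusted_results,
       raw_summary = raw_summary, adjusted_summary = adjusted_summary,
       footprint = footprint_reduction(raw_summary, adjusted_summary),
       subsets = subsets)
}
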
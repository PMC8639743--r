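test_that("subset drawing is reproducible, distinct, and bounded", {
  pop <- generate_population(synthetic_config(n_individuals = 250, seed = 51))
  rec <- pop$records

  plan <- subset_plan(k = 3, m = 100, seed = 9)
  s1 <- draw_subsets(rec, plan)
  s2 <- draw_subsets(rec, plan)
  expect_identical(s1, s2)
  expect_true(all(vapply(s1, nrow, integer(1)) == 100))
  for (s in s1) expect_false(any(duplicated(s$id)))
  # subsets are drawn independently, not nested
  expect_false(identical(sort(s1[[1]]$id), sort(s1[[2]]$id)))

  # m = n reproduces the full population as a set
  full <- draw_subsets(rec, subset_plan(k = 2, m = nrow(rec), seed = 1))
  expect_setequal(full[[1]]$id, rec$id)

  expect_error(draw_subsets(rec, subset_plan(k = 1, m = 1000, seed = 1)),
               "exceeds")
})

test_that("zero-effect subsets rarely produce concordant cluster labels", {
  # family-wise guarantee: with Bonferroni alpha = 0.1, a spatially random
  # subset yields any HH/LL label with probability <= ~0.1
  n_bad <- 0
  for (r in 1:10) {
    pop <- generate_population(synthetic_config(
      n_individuals = 100, region_extent = c(0, 4500, 0, 4500),
      n_high_clusters = 0, n_low_clusters = 0,
      skew_params = list(mean = 0, sd = 5, median = 0),
      covariate_effects = list(swiss = 0, income_per_1000 = 0,
                               neighborhood_age = 0),
      seed = 600 + r))
    res <- run_model(add_indicators(pop$records, pop$life_table), "raw",
                     n_permutations = 1999, seed = r)
    n_bad <- n_bad + any(res$label %in% c("HH", "LL"))
  }
  expect_lte(n_bad, 4)  # E[n_bad] <= 1; P(> 4) is negligible
})

test_that("a strongly planted subset is recovered concordantly at the centers", {
  cfg <- synthetic_config(
    n_individuals = 500, region_extent = c(0, 6000, 0, 6000),
    n_high_clusters = 1, n_low_clusters = 0, cluster_radius_m = 2000,
    cluster_effect_years = 16, skew_params = list(mean = 0, sd = 7, median = 0),
    covariate_effects = list(swiss = 0, income_per_1000 = 0,
                             neighborhood_age = 0),
    seed = 61)
  pop <- generate_population(cfg)
  res <- run_model(add_indicators(pop$records, pop$life_table), "raw",
                   n_permutations = 9999, seed = 3)
  core <- sqrt((pop$records$x_m - pop$centers$x)^2 +
                 (pop$records$y_m - pop$centers$y)^2) < 800
  expect_gt(mean(res$label[core] == "HH"), 0.5)
})

test_that("per-subset label counts and the neighborless count add up to the subset size", {
  pop <- generate_population(synthetic_config(n_individuals = 400, seed = 71))
  rec <- attach_covariates(add_indicators(pop$records, pop$life_table),
                           pop$panel)
  plan <- subset_plan(k = 2, m = 200, seed = 5)
  runs <- lapply(draw_subsets(rec, plan), run_model, variable = "raw",
                 n_permutations = 199, seed = 2)
  for (r in runs) {
    expect_identical(length(r$label), 200L)
    expect_identical(sum(table(r$label)), 200L)
  }
  summ <- summarize_clusters(runs)
  per <- attr(summ, "per_subset")
  counts <- tapply(per$n, per$subset, sum)
  neighborless <- vapply(runs, function(r)
    sum(r$label == "NEIGHBORLESS"), integer(1))
  expect_true(all(counts + neighborless == 200))
  # ranges contain means
  ok <- !is.na(summ$mean)
  expect_true(all(summ$min[ok] <= summ$mean[ok] + 1e-12))
  expect_true(all(summ$max[ok] >= summ$mean[ok] - 1e-12))
})

test_that("summaries degrade gracefully for k = 1 and empty labels", {
  pop <- generate_population(synthetic_config(n_individuals = 150, seed = 81))
  rec <- attach_covariates(add_indicators(pop$records, pop$life_table),
                           pop$panel)
  run <- run_model(rec, "raw", n_permutations = 99, seed = 1)
  summ <- summarize_clusters(list(run))
  expect_true(all(is.na(summ$sd)))
  ok <- !is.na(summ$mean)
  expect_identical(summ$min[ok], summ$max[ok])
  # with the permutation floor above the threshold everything is NS
  for (lb in c("HH", "LL", "LH", "HL")) {
    expect_identical(summ$mean[summ$label == lb & summ$characteristic == "n"],
                     0)
  }
})

test_that("Tukey HSD agrees with a direct studentized-range evaluation", {
  set.seed(91)
  g <- rep(c("a", "b", "c"), times = c(20, 25, 30))
  x <- rnorm(75) + c(a = 0, b = 0.8, c = 0.3)[g]
  got <- tukey_hsd(x, g)
  expect_identical(nrow(got), 3L)

  # independent Tukey-Kramer oracle
  ni <- table(g)
  mi <- tapply(x, g, mean)
  mse <- sum((x - mi[g])^2) / (length(x) - 3)
  for (row in seq_len(3)) {
    pair <- strsplit(got$comparison[row], "-")[[1]]
    q <- abs(mi[pair[1]] - mi[pair[2]]) /
      sqrt(mse / 2 * (1 / ni[pair[1]] + 1 / ni[pair[2]]))
    p <- ptukey(q, nmeans = 3, df = length(x) - 3, lower.tail = FALSE)
    expect_equal(got$p_adj[row], unname(p), tolerance = 1e-10)
  }
})

test_that("Tukey HSD handles identical, separated, and undersized groups", {
  x <- c(rep(c(1, 2, 3), 10), rep(c(1, 2, 3), 10))
  g <- rep(c("a", "b"), each = 30)
  got <- tukey_hsd(x, g)
  expect_equal(got$diff, 0)
  expect_gt(got$p_adj, 0.99)

  set.seed(92)
  x <- c(rnorm(50), rnorm(50) + 10)
  g <- rep(c("lo", "hi"), each = 50)
  expect_lt(tukey_hsd(x, g)$p_adj, 0.05)

  expect_warning(got3 <- tukey_hsd(c(x, 5), c(g, "single")), "single")
  expect_identical(nrow(got3), 1L)
  expect_error(suppressWarnings(tukey_hsd(c(1, 2, 3), c("a", "a", "b"))),
               "at least 2 groups")
})

test_that("footprint reduction covers the identical, vanishing, and undefined cases", {
  pop <- generate_population(synthetic_config(n_individuals = 200, seed = 95))
  rec <- attach_covariates(add_indicators(pop$records, pop$life_table),
                           pop$panel)
  run <- run_model(rec, "raw", n_permutations = 99, seed = 1)
  summ <- summarize_clusters(list(run))
  # identical runs: 0% change, but undefined when the raw count is zero
  red <- footprint_reduction(summ, summ)
  expect_true(all(is.na(red)))  # nothing significant at this scale

  fake <- function(n_ll, n_hh) {
    s <- summ
    s$mean[s$label == "LL" & s$characteristic == "n"] <- n_ll
    s$mean[s$label == "HH" & s$characteristic == "n"] <- n_hh
    s
  }
  expect_equal(footprint_reduction(fake(100, 50), fake(100, 50)),
               c(LL = 0, HH = 0))
  expect_equal(footprint_reduction(fake(100, 50), fake(0, 0)),
               c(LL = 100, HH = 100))
  expect_equal(unname(footprint_reduction(fake(779, 1445), fake(375, 752))),
               c(100 * (779 - 375) / 779, 100 * (1445 - 752) / 1445))
})

test_that("the full study pipeline is deterministic end to end", {
  pop <- generate_population(synthetic_config(n_individuals = 350, seed = 97,
                                              missing_cell_frac = 0.1))
  rec <- attach_covariates(add_indicators(pop$records, pop$life_table),
                           pop$panel)
  plan <- subset_plan(k = 2, m = 150, seed = 13)
  s1 <- suppressWarnings(run_study(rec, plan, n_permutations = 199, seed = 17))
  s2 <- suppressWarnings(run_study(rec, plan, n_permutations = 199, seed = 17))
  expect_identical(s1$raw_summary, s2$raw_summary)
  expect_identical(s1$adjusted_summary, s2$adjusted_summary)
  expect_identical(s1$footprint, s2$footprint)
  expect_identical(s1$raw_results, s2$raw_results)
})
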
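std_fields <- function(values_list, method = "percentile_rank", g = NULL) {
  g <- g %||% small_grid(1, length(values_list[[1]]))
  purrr::imap(values_list, function(v, i) {
    standardize_field(raster_field(g, v, name = paste0("dim", i)), method)
  })
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("composite is the cellwise sum of its sub-indicators", {
  set.seed(61)
  g <- small_grid(6, 8)
  fields <- std_fields(purrr::map(1:4, ~ rlnorm(48)), "normal_score", g)
  comp <- composite_indicator(fields)
  expect_equal(
    field_values(comp),
    purrr::reduce(purrr::map(fields, field_values), `+`),
    tolerance = 1e-15
  )
  expect_true(all(field_values(comp) >= 0 & field_values(comp) <= 4))

  # k identical fields scale
  comp2 <- composite_indicator(list(fields[[1]], fields[[1]], fields[[1]]))
  expect_equal(field_values(comp2), 3 * field_values(fields[[1]]))

  expect_error(composite_indicator(fields[1]), "at least 2")
  mixed <- std_fields(purrr::map(1:2, ~ runif(48)), "percentile_rank", g)
  expect_error(composite_indicator(c(fields[1], mixed[1])), "method")
})

test_that("population weighting aggregates composites to blocks", {
  g <- small_grid(2, 2)
  fields <- std_fields(list(c(1, 2, 3, 4), c(4, 3, 2, 1)), g = g)
  comp <- composite_indicator(fields)
  one_block <- zone_map("b1", 1, list(cbind(c(0, 2000, 2000, 0), c(0, 0, 2000, 2000))))

  # uniform population: unweighted mean
  popu <- raster_field(g, rep(5, 4))
  agg <- population_weighted_aggregate(comp, popu, one_block)
  expect_equal(agg$weighted_mean, mean(field_values(comp)))
  expect_false(agg$unweighted_fallback)

  # all population in one cell: that cell's composite
  pop1 <- raster_field(g, c(0, 0, 10, 0))
  agg1 <- population_weighted_aggregate(comp, pop1, one_block)
  expect_equal(agg1$weighted_mean, field_values(comp)[3])

  # explicit weighted mean, population (1, 3) on composites (2, 4)
  gg <- small_grid(1, 2)
  cf <- composite_indicator(std_fields(list(c(0.5, 1), c(0.5, 1)), g = gg))
  cf$value <- c(2, 4)
  aggw <- population_weighted_aggregate(
    cf, raster_field(gg, c(1, 3)),
    zone_map("b", 1, list(cbind(c(0, 2000, 2000, 0), c(0, 0, 1000, 1000))))
  )
  expect_equal(aggw$weighted_mean, 3.5)

  # zero-population block falls back to the unweighted mean, flagged
  agg0 <- population_weighted_aggregate(comp, raster_field(g, rep(0, 4)), one_block)
  expect_true(agg0$unweighted_fallback)
  expect_equal(agg0$weighted_mean, mean(field_values(comp)))

  # bounded by member extremes, permutation-invariant
  set.seed(3)
  gl <- small_grid(4, 5)
  fl <- std_fields(list(runif(20), runif(20)), g = gl)
  cl <- composite_indicator(fl)
  popl <- raster_field(gl, rlnorm(20))
  blocks <- zone_map(
    c("a", "b"), 1:2,
    list(
      cbind(c(0, 2000, 2000, 0), c(0, 0, 4000, 4000)),
      cbind(c(2000, 5000, 5000, 2000), c(0, 0, 4000, 4000))
    )
  )
  aggl <- population_weighted_aggregate(cl, popl, blocks)
  expect_true(all(aggl$weighted_mean >= min(field_values(cl)) &
    aggl$weighted_mean <= max(field_values(cl))))
})

test_that("Spearman matrix matches the brute-force rank-then-Pearson oracle", {
  set.seed(71)
  g <- small_grid(5, 6)
  v1 <- rlnorm(30)
  v2 <- round(rlnorm(30), 1) # with ties
  f1 <- raster_field(g, v1, name = "a")
  f2 <- raster_field(g, v2, name = "b")
  m <- correlation_matrix(list(a = f1, b = f2))
  expect_equal(m["a", "b"], brute_spearman(v1, v2), tolerance = 1e-12)
  expect_equal(m["a", "b"], m["b", "a"])
  expect_equal(diag(m), c(a = 1, b = 1))

  # self and anti-monotone
  expect_equal(
    correlation_matrix(list(x = f1, y = f1))["x", "y"], 1.0
  )
  neg <- raster_field(g, -v1, name = "n")
  expect_equal(correlation_matrix(list(x = f1, n = neg))["x", "n"], -1.0)

  # pairwise-complete over shared valid cells
  v3 <- v1; v3[1:5] <- NA
  f3 <- raster_field(g, v3, name = "c")
  m3 <- correlation_matrix(list(a = f1, c = f3))
  expect_equal(m3["a", "c"], brute_spearman(v1[-(1:5)], v3[-(1:5)]), tolerance = 1e-12)
})

test_that("contribution decomposition above the 90th percentile sums to 100", {
  set.seed(81)
  g <- small_grid(10, 10)
  fields <- std_fields(purrr::map(1:4, ~ rlnorm(100)), "normal_score", g)
  comp <- composite_indicator(fields)
  tab <- contribution_above_percentile(comp, 0.9)
  expect_equal(sum(tab$contribution_pct), 100, tolerance = 1e-9)
  expect_true(all(tab$contribution_pct >= 0))
  expect_equal(attr(tab, "n_cells"), sum(field_values(comp) >
    quantile(field_values(comp), 0.9)))

  # k identical sub-indicators each contribute 100/k
  same <- composite_indicator(list(fields[[1]], fields[[1]], fields[[1]], fields[[1]]))
  tsame <- contribution_above_percentile(same, 0.9)
  expect_equal(tsame$contribution_pct, rep(25, 4))

  # pooled variant also sums to 100
  tp <- contribution_above_percentile(comp, 0.9, pooled = TRUE)
  expect_equal(sum(tp$contribution_pct), 100, tolerance = 1e-9)

  expect_error(contribution_above_percentile(comp, 1.5), "q")
})

test_that("sliding-window slopes flag extremum smoothing", {
  # perfectly linear curve: every slope equals the global slope
  x <- seq(0, 1, length.out = 101)
  sl <- transform_slope(x, 0.3 + 0.4 * x, window = 11)
  expect_equal(
    sl$slope[!is.na(sl$slope)],
    rep(0.4, sum(!is.na(sl$slope))),
    tolerance = 1e-12
  )
  # constant scores give zero slope
  sl0 <- transform_slope(x, rep(0.5, 101), window = 11)
  expect_true(all(sl0$slope[!is.na(sl0$slope)] == 0))
  expect_error(transform_slope(x, 0.3 + 0.4 * x, window = 2001), "window")

  # lognormal raw field: the percentile transform flattens the top decile
  # relative to the normal-score transform
  set.seed(91)
  raw <- rlnorm(1000, 0, 1.3)
  r <- rank_with_ties(raw)
  sp <- transform_slope(raw, percentile_rank_transform(r), window = 51)
  sn <- transform_slope(raw, normal_score_transform(r), window = 51)
  top <- sp$raw > quantile(raw, 0.9)
  expect_lt(
    mean(sp$slope[top], na.rm = TRUE),
    mean(sn$slope[top], na.rm = TRUE)
  )
})

test_that("heteroscedasticity ratio measures the background gap", {
  g <- small_grid(1, 5)
  sf <- standardize_field(
    raster_field(g, c(0, 0, 0, 5, 9)), "percentile_rank",
    zero_background = TRUE
  )
  expect_equal(heteroscedasticity_ratio(sf), 0.3 / 0.7)

  # one background cell among distinct values: Hazen numerators cancel n
  for (n in c(10, 100)) {
    gg <- small_grid(1, n)
    sf1 <- standardize_field(
      raster_field(gg, c(0, seq_len(n - 1))), "percentile_rank",
      zero_background = TRUE
    )
    expect_equal(heteroscedasticity_ratio(sf1), 0.5 / 1.5)
  }

  # percentile ratio follows the closed form k / (2k + 1): the Hazen
  # numerators make it depend on the background count alone
  set.seed(14)
  n <- 2000
  for (fr in c(0.1, 0.4, 0.8)) {
    k <- round(fr * n)
    v <- c(rep(0, k), rlnorm(n - k) + 0.01)
    gg <- build_referent_grid(c(xmin = 0, xmax = n * 10, ymin = 0, ymax = 10), 10)
    r <- heteroscedasticity_ratio(
      standardize_field(raster_field(gg, v), "percentile_rank", zero_background = TRUE)
    )
    expect_equal(r, k / (2 * k + 1), tolerance = 1e-12)
  }

  # under the normal-score transform the ratio shrinks as the background
  # fraction rises (the flattening of the curve), and the gap vanishes
  # (ratio toward 1) along a sequence of growing fields with ever smaller
  # background fractions
  ns_ratio <- function(fr, n) {
    k <- round(fr * n)
    v <- c(rep(0, k), rlnorm(n - k) + 0.01)
    gg <- build_referent_grid(c(xmin = 0, xmax = n * 10, ymin = 0, ymax = 10), 10)
    heteroscedasticity_ratio(
      standardize_field(raster_field(gg, v), "normal_score", zero_background = TRUE)
    )
  }
  falling <- purrr::map_dbl(c(0.1, 0.3, 0.5, 0.7, 0.9), ns_ratio, n = 2000)
  expect_true(all(diff(falling) < 0))
  vanishing <- purrr::map_dbl(
    c(0.2, 0.05, 0.0125),
    function(fr) ns_ratio(fr, round(400 / fr))
  )
  expect_true(all(diff(vanishing) > 0))
  expect_gt(vanishing[3], 0.85)

  sf_nobg <- standardize_field(raster_field(g, c(1, 2, 3, 4, 5)), "percentile_rank")
  expect_error(heteroscedasticity_ratio(sf_nobg), "background")
})

test_that("goodness-of-fit ranking identifies the generating family", {
  set.seed(101)
  for (s in 1:10) {
    x <- rnorm(5000, 3, 2)
    fit <- fit_rank_distribution(x)
    expect_equal(fit$family[1], "normal")
  }
  for (s in 1:5) {
    u <- runif(5000)
    expect_equal(fit_rank_distribution(u)$family[1], "uniform")
  }
  # KS statistic bounded in [0, 1] for arbitrary data/candidates
  y <- rlnorm(200)
  fit <- fit_rank_distribution(y)
  expect_true(all(fit$ks_statistic >= 0 & fit$ks_statistic <= 1))
  expect_equal(glance(fit)$best_family, fit$family[1])
  expect_error(fit_rank_distribution(rnorm(10)), "20")
})
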
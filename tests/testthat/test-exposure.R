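test_that("dose and hazard-quotient arithmetic", {
  expect_equal(average_daily_dose(100, 1e-4, 1, 15), 100 * 1e-4 / 15)
  expect_equal(average_daily_dose(0, 1e-4, 1, 15), 0)
  # linear in concentration
  expect_equal(
    average_daily_dose(200, 1e-4, 1, 15),
    2 * average_daily_dose(100, 1e-4, 1, 15)
  )
  expect_error(average_daily_dose(1, 1e-4, 1, 0), "body_weight")

  expect_equal(hazard_quotient(0.001, 0.001), 1)
  expect_equal(hazard_quotient(0, 0.001), 0)
  expect_equal(hazard_quotient(0.002, 0.001), 2)
  expect_error(hazard_quotient(1, 0), "rfd")
})

test_that("soil indicator sums HQs over pollutants and keeps the worst age class", {
  g <- small_grid(1, 2)
  tox <- default_toxicity_table()
  factors <- default_exposure_factors()
  # concentrations chosen so each pollutant's child HQ is exactly 1:
  # conc = rfd * bw / intake
  conc_cd <- 1e-3 * 15 / 1e-4
  conc_pb <- 3.5e-3 * 15 / 1e-4
  fields <- list(
    cadmium = raster_field(g, rep(conc_cd, 2)),
    lead = raster_field(g, rep(conc_pb, 2))
  )
  out <- soil_concentration_indicator(fields, factors, tox)
  # the child class dominates (higher intake/body-weight ratio)
  expect_equal(field_values(out), c(2, 2))

  # single pollutant reduces to the cellwise HQ of the worst age class
  one <- soil_concentration_indicator(fields["cadmium"], factors, tox)
  expect_equal(field_values(one), c(1, 1))

  # explicit max rule over age classes
  f3 <- exposure_factors(tibble::tibble(
    age_class = c("a", "b", "c"),
    ingestion_rate = c(0.5e-4, 1.2e-4, 0.8e-4),
    frequency = 1, body_weight = 15
  ))
  out3 <- soil_concentration_indicator(fields["cadmium"], f3, tox)
  expect_equal(field_values(out3), c(1.2, 1.2))

  # monotone: raising any concentration never lowers the indicator
  set.seed(8)
  for (rep in 1:5) {
    v <- runif(2, 0, 100)
    base <- soil_concentration_indicator(
      list(cadmium = raster_field(g, v)), factors, tox
    )
    up <- soil_concentration_indicator(
      list(cadmium = raster_field(g, v + c(10, 0))), factors, tox
    )
    expect_true(all(field_values(up) >= field_values(base)))
  }

  expect_error(
    soil_concentration_indicator(
      list(unobtainium = raster_field(g, c(1, 1))), factors, tox
    ),
    "RfD"
  )
})

test_that("air concentration indicator sums concentration/standard ratios", {
  g <- small_grid(1, 1)
  tox <- default_toxicity_table()
  at_standard <- list(
    no2 = raster_field(g, 40), pm10 = raster_field(g, 40)
  )
  expect_equal(field_values(air_concentration_indicator(at_standard, tox)), 2)
  mixed <- list(no2 = raster_field(g, 20), pm10 = raster_field(g, 40))
  expect_equal(field_values(air_concentration_indicator(mixed, tox)), 1.5)
  zeros <- list(no2 = raster_field(g, 0), pm10 = raster_field(g, 0))
  expect_equal(field_values(air_concentration_indicator(zeros, tox)), 0)
  # linear in each pollutant concentration
  f1 <- air_concentration_indicator(list(no2 = raster_field(g, 10)), tox)
  f2 <- air_concentration_indicator(list(no2 = raster_field(g, 30)), tox)
  expect_equal(field_values(f2), 3 * field_values(f1))
  expect_error(
    air_concentration_indicator(list(xyz = raster_field(g, 1)), tox),
    "standard"
  )
})

test_that("emission score min-max scales three components and averages them", {
  tox <- default_toxicity_table()
  g3 <- small_grid(1, 3)
  # three cells of (benzene, pm) emissions engineered by hand so that, with
  # the table's weights (T = b + p; Wc = 10 b + p; Wn = 2 b + 10 p), the
  # min-max scaled components are T = (0, 1/2, 1), Wc = (0, 1, 1/2),
  # Wn = (0, 11/30, 1); the equal-weight average is then
  # (0, 28/45, 5/6).
  b <- c(0, 1 / 3, 0)
  p <- c(0, 2 / 3, 2)
  fields <- list(
    benzene = raster_field(g3, b),
    pm = raster_field(g3, p)
  )
  out <- emission_score(fields, tox)
  expect_equal(field_values(out), c(0, 28 / 45, 5 / 6), tolerance = 1e-12)
  expect_true(all(field_values(out) >= 0 & field_values(out) <= 1))

  # min-max endpoints: an all-zero cell scores 0, the maximal cell 1
  two <- list(benzene = raster_field(small_grid(1, 2), c(0, 5)))
  out2 <- emission_score(two, tox)
  expect_equal(field_values(out2), c(0, 1))

  # degenerate single-cell domain: all three components constant, one
  # warning each
  one <- list(benzene = raster_field(small_grid(1, 1), 3))
  w <- capture_warnings(res <- emission_score(one, tox))
  expect_length(w, 3)
  expect_match(w, "constant", all = TRUE)
  expect_equal(field_values(res), 0)
})

test_that("water exceedance score is the multi-year average count", {
  df <- tibble::tibble(
    zone_id = "u1", year = 1:4, count = c(1, 2, 3, 3)
  )
  expect_equal(water_exceedance_score(df, 4)$score, 2.25)
  expect_equal(
    water_exceedance_score(
      tibble::tibble(zone_id = "u", year = 1:4, count = 0), 4
    )$score, 0
  )
  expect_equal(
    water_exceedance_score(
      tibble::tibble(zone_id = "u", year = 1, count = 4), 1
    )$score, 4
  )
  expect_error(
    water_exceedance_score(tibble::tibble(zone_id = "u", year = 1, count = -1)),
    ">= 0"
  )

  # oracle equivalence: scores from raw concentration tables vs brute force
  set.seed(23)
  zones <- paste0("z", 1:6)
  conc <- expand.grid(
    zone_id = zones, year = 1:4, substance = c("as", "f", "pb"),
    stringsAsFactors = FALSE
  )
  conc$value <- rlnorm(nrow(conc), 0, 1)
  thresholds <- c(as = 1.5, f = 2.0, pb = 3.0)
  conc$exceeds <- conc$value > thresholds[conc$substance]
  counts <- stats::aggregate(exceeds ~ zone_id + year, conc, sum)
  names(counts)[3] <- "count"
  out <- water_exceedance_score(counts, 4)
  for (z in zones) {
    brute <- sum(conc$value[conc$zone_id == z] >
      thresholds[conc$substance[conc$zone_id == z]]) / 4
    expect_equal(out$score[out$zone_id == z], brute)
  }
})

test_that("noise indicator passes Lden through and preserves the mask", {
  g <- small_grid(1, 3)
  f <- raster_field(g, c(68, NA, 55))
  out <- noise_indicator(f)
  expect_equal(field_values(out), c(68, NA, 55))
  expect_equal(is.na(field_values(out)), is.na(field_values(f)))
  expect_error(noise_indicator(raster_field(g, c(-1, 2, 3))), "Lden")
})

test_that("equity combination standardizes both inputs before summing", {
  set.seed(31)
  g <- small_grid(5, 8)
  a <- raster_field(g, runif(40))
  b <- raster_field(g, rlnorm(40))

  for (m in c("normal_score", "percentile_rank")) {
    comb <- combine_equity(a, b, method = m)
    expect_true(all(field_values(comb) >= 0 & field_values(comb) <= 2))
    # identical inputs double the standardized field
    self <- combine_equity(a, a, method = m)
    expect_equal(field_values(self), 2 * field_values(standardize_field(a, m)))
    # equity holds by construction
    sa <- standardize_field(a, m)
    sb <- standardize_field(b, m)
    expect_lt(abs(mean(field_values(sa)) - mean(field_values(sb))), 1e-9)
  }
  g2 <- small_grid(2, 2)
  expect_error(combine_equity(a, raster_field(g2, 1:4)), "grid")
})
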
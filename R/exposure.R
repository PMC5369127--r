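#' Toxicity reference table
#'
#' Per-pollutant reference values used to weight exposure layers: oral
#' reference dose (RfD, mg/kg/day), annual air quality standard (ug/m3),
#' drinking-water threshold (substance units) and dimensionless emission
#' toxicity weights for cancer and non-cancer respiratory effects. Any value
#' may be missing for a pollutant that does not participate in that pathway.
#'
#' @param df Data frame with columns `pollutant`, and any of `rfd`,
#'   `air_standard`, `water_threshold`, `weight_cancer`, `weight_noncancer`.
#' @return A `toxicity_table` tibble.
#' @export
toxicity_table <- function(df) {
  stopifnot(is.data.frame(df), "pollutant" %in% names(df))
  cols <- c("rfd", "air_standard", "water_threshold", "weight_cancer", "weight_noncancer")
  for (cl in cols) if (!cl %in% names(df)) df[[cl]] <- NA_real_
  df <- tibble::as_tibble(df[, c("pollutant", cols)])
  num <- unlist(df[cols])
  if (any(!is.na(num) & num <= 0)) abort("toxicity reference values must be > 0 where present.")
  if (anyDuplicated(df$pollutant)) abort("duplicate pollutant rows in toxicity table.")
  structure(df, class = c("toxicity_table", class(tibble::tibble())))
}

#' Built-in default toxicity table
#'
#' Small reference set for the pollutants used by the synthetic region:
#' cadmium and lead RfDs, NO2 and PM10 annual EU air standards (40 ug/m3),
#' and emission toxicity weights for benzene, benzo(a)pyrene and PM.
#'
#' @return A `toxicity_table`.
#' @export
default_toxicity_table <- function() {
  toxicity_table(tibble::tibble(
    pollutant = c("cadmium", "lead", "no2", "pm10", "benzene", "bap", "pm"),
    rfd = c(1e-3, 3.5e-3, NA, NA, NA, NA, NA),
    air_standard = c(NA, NA, 40, 40, NA, NA, NA),
    water_threshold = c(5, 10, NA, NA, 1, NA, NA),
    weight_cancer = c(NA, NA, NA, NA, 10, 100, 1),
    weight_noncancer = c(NA, NA, NA, NA, 2, 5, 10)
  ))
}

#' Exposure factors by age class
#'
#' Soil ingestion rate (kg/day), exposure frequency (fraction of days in a
#' year) and body weight (kg) per population age class, used in the
#' single-pathway ingestion dose.
#'
#' @param df Data frame with columns `age_class`, `ingestion_rate`,
#'   `frequency`, `body_weight`.
#' @return An `exposure_factors` tibble.
#' @export
exposure_factors <- function(df) {
  stopifnot(
    is.data.frame(df),
    all(c("age_class", "ingestion_rate", "frequency", "body_weight") %in% names(df))
  )
  if (any(df$ingestion_rate <= 0) || any(df$body_weight <= 0) ||
      any(df$frequency <= 0) || any(df$frequency > 1)) {
    abort("exposure factors must be > 0 and frequency in (0, 1].")
  }
  structure(tibble::as_tibble(df), class = c("exposure_factors", class(tibble::tibble())))
}

#' @rdname exposure_factors
#' @export
default_exposure_factors <- function() {
  exposure_factors(tibble::tibble(
    age_class = c("child", "adult"),
    ingestion_rate = c(1e-4, 5e-5), # 100 / 50 mg soil per day
    frequency = c(1, 1),
    body_weight = c(15, 70)
  ))
}

#' Average daily dose for the soil ingestion pathway
#'
#' Single-pathway simplification of a multimedia exposure model:
#' `ADD = conc * intake * frequency / body_weight`, in mg/kg/day. Richer dose
#' models can be substituted upstream, since the hazard-quotient functions
#' accept precomputed ADD values.
#'
#' @param conc Soil concentration, mg/kg (>= 0).
#' @param intake Soil ingestion rate, kg/day (> 0).
#' @param frequency Exposure frequency, fraction of days (> 0, <= 1).
#' @param body_weight Body weight, kg (> 0).
#' @return ADD in mg/kg/day, linear in `conc`.
#' @export
average_daily_dose <- function(conc, intake, frequency, body_weight) {
  if (any(body_weight <= 0)) abort("`body_weight` must be > 0.")
  if (any(intake <= 0) || any(frequency <= 0)) abort("`intake` and `frequency` must be > 0.")
  if (any(conc < 0, na.rm = TRUE)) abort("`conc` must be >= 0.")
  conc * intake * frequency / body_weight
}

#' Hazard quotient
#'
#' Ratio of the average daily dose to the reference dose; HQ > 1 flags
#' potential non-cancer concern.
#'
#' @param add Average daily dose, mg/kg/day.
#' @param rfd Reference dose, mg/kg/day (> 0).
#' @return Dimensionless HQ.
#' @export
hazard_quotient <- function(add, rfd) {
  if (any(rfd <= 0)) abort("`rfd` must be > 0.")
  add / rfd
}

lookup_tox <- function(tox, pollutants, column, what) {
  idx <- match(pollutants, tox$pollutant)
  vals <- tox[[column]][idx]
  missing <- pollutants[is.na(idx) | is.na(vals)]
  if (length(missing)) {
    abort(paste0("missing ", what, " for pollutant(s): ", paste(missing, collapse = ", ")))
  }
  vals
}

#' Topsoil concentration sub-indicator (summed hazard quotients)
#'
#' For each cell and age class, the ingestion-pathway HQs of all pollutants
#' are summed (independence of action); the cell keeps the maximum over age
#' classes, a conservative screening rule. Cells nodata in any input remain
#' nodata.
#'
#' @param conc_fields Named list of `raster_field`s, one per pollutant
#'   (soil concentrations, mg/kg).
#' @param factors An `exposure_factors` table.
#' @param tox A `toxicity_table` with an RfD for every supplied pollutant.
#' @return A `raster_field` of summed HQs (dimensionless).
#' @export
soil_concentration_indicator <- function(conc_fields, factors, tox) {
  stopifnot(length(conc_fields) >= 1, inherits(factors, "exposure_factors"))
  pollutants <- names(conc_fields)
  rfds <- lookup_tox(tox, pollutants, "rfd", "RfD")
  purrr::walk(conc_fields, ~ check_same_grid(.x, conc_fields[[1]]))

  per_age <- purrr::map(seq_len(nrow(factors)), function(a) {
    hq_sum <- 0
    for (k in seq_along(conc_fields)) {
      add <- average_daily_dose(
        field_values(conc_fields[[k]]),
        factors$ingestion_rate[a], factors$frequency[a], factors$body_weight[a]
      )
      hq_sum <- hq_sum + hazard_quotient(add, rfds[k])
    }
    hq_sum
  })
  vmax <- purrr::reduce(per_age, pmax)
  field_with_values(conc_fields[[1]], vmax,
    name = "soil_hq", units = "summed HQ"
  )
}

#' Air concentration sub-indicator
#'
#' Per cell, the sum over pollutants of annual mean concentration divided by
#' its air quality standard.
#'
#' @param conc_fields Named list of `raster_field`s (ug/m3), one per pollutant.
#' @param tox A `toxicity_table` with an `air_standard` for every pollutant.
#' @return A `raster_field` (dimensionless).
#' @export
air_concentration_indicator <- function(conc_fields, tox) {
  stopifnot(length(conc_fields) >= 1)
  stds <- lookup_tox(tox, names(conc_fields), "air_standard", "air quality standard")
  purrr::walk(conc_fields, ~ check_same_grid(.x, conc_fields[[1]]))
  total <- purrr::reduce(
    purrr::map2(conc_fields, stds, ~ field_values(.x) / .y),
    `+`
  )
  field_with_values(conc_fields[[1]], total,
    name = "air_concentration", units = "sum conc/standard"
  )
}

#' Toxicity-weighted emission score
#'
#' Screening score for direct emissions combining three per-cell components:
#' total emissions (sum over pollutants), cancer-toxicity-weighted emissions
#' and respiratory non-cancer-weighted emissions. Each component is min-max
#' scaled to \[0, 1\] over valid cells and the three are averaged (equal
#' weights by default). A degenerate component (min = max) contributes 0
#' everywhere, with a warning.
#'
#' @param emission_fields Named list of `raster_field`s of per-cell emission
#'   totals, one per pollutant.
#' @param tox A `toxicity_table` with `weight_cancer` and `weight_noncancer`
#'   for every pollutant.
#' @param weights Numeric length-3 weights for (total, cancer, non-cancer);
#'   normalized to sum 1.
#' @return A `raster_field` with values in \[0, 1\].
#' @export
emission_score <- function(emission_fields, tox, weights = c(1, 1, 1)) {
  stopifnot(length(emission_fields) >= 1, length(weights) == 3, all(weights >= 0))
  pollutants <- names(emission_fields)
  wc <- lookup_tox(tox, pollutants, "weight_cancer", "cancer toxicity weight")
  wn <- lookup_tox(tox, pollutants, "weight_noncancer", "non-cancer toxicity weight")
  purrr::walk(emission_fields, ~ check_same_grid(.x, emission_fields[[1]]))

  vals <- purrr::map(emission_fields, field_values)
  total <- purrr::reduce(vals, `+`)
  cancer <- purrr::reduce(purrr::map2(vals, wc, `*`), `+`)
  noncancer <- purrr::reduce(purrr::map2(vals, wn, `*`), `+`)

  minmax01 <- function(v, label) {
    rng <- range(v, na.rm = TRUE)
    if (!is.finite(diff(rng)) || diff(rng) == 0) {
      warn(paste0("emission score component '", label, "' is constant; it contributes 0."))
      return(ifelse(is.na(v), NA_real_, 0))
    }
    (v - rng[1]) / diff(rng)
  }
  w <- weights / sum(weights)
  score <- w[1] * minmax01(total, "total") +
    w[2] * minmax01(cancer, "cancer-weighted") +
    w[3] * minmax01(noncancer, "non-cancer-weighted")
  field_with_values(emission_fields[[1]], score,
    name = "emission_score", units = "scaled [0,1]"
  )
}

#' Water threshold-exceedance score
#'
#' Multi-year averaged count of substance threshold exceedances per water
#' distribution unit: `score = sum(annual counts) / n_years`. Concentrations
#' below their thresholds contribute nothing, so most units score 0 and the
#' water dimension is hotspot-only.
#'
#' @param exceedances Data frame with columns `zone_id`, `year`, `count`
#'   (exceedance count per unit and year; a missing unit-year counts as 0).
#' @param n_years Number of years averaged over (default 4).
#' @return A tibble with `zone_id`, `score`.
#' @export
water_exceedance_score <- function(exceedances, n_years = 4) {
  stopifnot(
    is.data.frame(exceedances),
    all(c("zone_id", "count") %in% names(exceedances))
  )
  if (n_years < 1) abort("`n_years` must be >= 1.")
  if (any(exceedances$count < 0)) abort("exceedance counts must be >= 0.")
  exceedances %>%
    group_by(.data$zone_id) %>%
    summarise(score = sum(.data$count) / n_years, .groups = "drop")
}

#' Lden noise sub-indicator
#'
#' Pass-through of the discretized Lden field (day-evening-night weighted
#' annual average sound level, dB(A)). Cells with no noise estimate stay
#' nodata; they are assigned the shared background score during
#' standardization.
#'
#' @param lden_field A `raster_field` of Lden values in dB(A).
#' @return The same field, validated.
#' @export
noise_indicator <- function(lden_field) {
  stopifnot(inherits(lden_field, "raster_field"))
  v <- field_values(lden_field)
  if (any(v < 0, na.rm = TRUE)) abort("Lden values must be >= 0 where valid.")
  field_with_values(lden_field, v, name = "noise_lden", units = "dB(A)")
}

#' Combine two exposure components under the equity principle
#'
#' Standardizes each component with the chosen rank transform (so both enter
#' with equal mean and range) and sums them cellwise, the rule used to build
#' the higher-level air (concentrations + emissions) and soil (proximity +
#' topsoil HQ) indicators. Output values lie in \[0, 2\].
#'
#' @param a,b `raster_field`s on the same grid.
#' @param method `"normal_score"` or `"percentile_rank"`.
#' @param zero_background Length-1 or length-2 logical: treat exact zeros as
#'   background cells in `a` and `b` (hotspot-type layers); default FALSE.
#' @return A `raster_field` of summed standardized scores.
#' @export
combine_equity <- function(a, b, method = c("normal_score", "percentile_rank"),
                           zero_background = FALSE) {
  method <- match.arg(method)
  check_same_grid(a, b)
  zero_background <- rep(zero_background, length.out = 2)
  sa <- standardize_field(a, method = method, zero_background = zero_background[1])
  sb <- standardize_field(b, method = method, zero_background = zero_background[2])
  field_with_values(a, field_values(sa) + field_values(sb),
    name = paste0("combined_", attr(a, "layer_name"), "_", attr(b, "layer_name")),
    units = "summed standardized score"
  )
}
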
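# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force or numerical integration, never by calling the
# implementation they check.

# Monte-Carlo fraction of a grid cell covered by a predicate on points.
mc_cell_fraction <- function(cell, inside, n = 1e5) {
  px <- runif(n, cell$xmin, cell$xmax)
  py <- runif(n, cell$ymin, cell$ymax)
  mean(inside(px, py))
}

# Monte-Carlo mean of a point-evaluated function over a grid cell, ignoring
# NA evaluations (the point-sampling oracle for intensive aggregation and
# zone rasterization).
mc_cell_mean <- function(cell, value_at, n = 1e5) {
  px <- runif(n, cell$xmin, cell$xmax)
  py <- runif(n, cell$ymin, cell$ymax)
  v <- value_at(px, py)
  mean(v, na.rm = TRUE)
}

# Look up source raster values at arbitrary points (NA outside / nodata).
raster_value_at <- function(field) {
  g <- field_grid(field)
  vals <- field_values(field)
  function(px, py) {
    j <- 1L + floor((px - g$x0) / g$cell_size)
    i <- 1L + floor((g$y0 - py) / g$cell_size)
    ok <- i >= 1 & i <= g$n_rows & j >= 1 & j <= g$n_cols
    out <- rep(NA_real_, length(px))
    out[ok] <- vals[(i[ok] - 1L) * g$n_cols + j[ok]]
    out
  }
}

# Brute-force Spearman: explicit average ranks, then the Pearson formula.
brute_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exact expectation of the r-th order statistic of n standard normals, by
# numerical integration of the order-statistic density (log-space to avoid
# overflow at large n).
exact_normal_order_stat <- function(r, n) {
  integrand <- function(x) {
    x * exp(
      log(n) + lchoose(n - 1, r - 1) + dnorm(x, log = TRUE) +
        (r - 1) * pnorm(x, log.p = TRUE) +
        (n - r) * pnorm(x, lower.tail = FALSE, log.p = TRUE)
    )
  }
  integrate(integrand, -Inf, Inf, rel.tol = 1e-10)$value
}

# Brute-force re-ranking oracle for the background/tie rule: sort indices,
# assign background the averaged bottom ranks, others averaged ranks above.
brute_rank_with_background <- function(values, background) {
  background <- background | is.na(values)
  n <- length(values)
  k <- sum(background)
  out <- numeric(n)
  out[background] <- mean(seq_len(k))
  nb <- which(!background)
  v <- values[nb]
  r <- numeric(length(v))
  for (i in seq_along(v)) r[i] <- k + mean(which(sort(v) == v[i]))
  out[nb] <- r
  out
}

sample_excess_kurtosis <- function(x) {
  z <- (x - mean(x)) / sd(x)
  mean(z^4) - 3
}

small_grid <- function(n_rows = 4, n_cols = 5, cell_size = 1000) {
  build_referent_grid(
    c(xmin = 0, xmax = n_cols * cell_size, ymin = 0, ymax = n_rows * cell_size),
    cell_size
  )
}

# a fast, small synthetic-region config for end-to-end tests
test_region_config <- function(seed, ...) {
  region_config(
    n_soil_points = 300, n_sites = 25, n_districts = 15, n_water_units = 12,
    n_census_blocks = 40, seed = seed, ...
  )
}
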
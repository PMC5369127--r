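test_that("surface-ratio aggregation: aligned subcells average and conserve", {
  target <- small_grid(1, 1)
  source_grid <- build_referent_grid(
    c(xmin = 0, xmax = 1000, ymin = 0, ymax = 1000), 500
  )
  src <- raster_field(source_grid, matrix(c(1, 2, 3, 4), 2, byrow = TRUE))

  expect_equal(field_values(aggregate_surface_ratio(src, target, "intensive")), 2.5)
  expect_equal(field_values(aggregate_surface_ratio(src, target, "extensive")), 10)
})

test_that("offset intensive aggregation matches the point-sampling oracle", {
  set.seed(41)
  target <- small_grid(3, 3)
  source_grid <- build_referent_grid(
    c(xmin = -250, xmax = 3250, ymin = -250, ymax = 3250), 500
  )
  src <- raster_field(source_grid, runif(grid_n_cells(source_grid)))
  agg <- aggregate_surface_ratio(src, target, "intensive")
  at <- raster_value_at(src)
  for (idx in c(1, 5, 9)) {
    cell <- cell_bounds(attr(agg, "grid"), agg$row[idx], agg$col[idx])
    expect_equal(field_values(agg)[idx], mc_cell_mean(cell, at), tolerance = 1e-2)
  }
})

test_that("extensive aggregation conserves totals and respects nodata", {
  set.seed(42)
  target <- small_grid(4, 4)
  source_grid <- build_referent_grid(
    c(xmin = 0, xmax = 4000, ymin = 0, ymax = 4000), 250
  )
  v <- runif(grid_n_cells(source_grid), 0, 10)
  v[sample(length(v), 30)] <- NA
  src <- raster_field(source_grid, v)
  agg <- aggregate_surface_ratio(src, target, "extensive")
  expect_equal(sum(field_values(agg), na.rm = TRUE), sum(v, na.rm = TRUE),
    tolerance = 1e-9
  )
  # intensive bounded by source extremes
  agg_i <- aggregate_surface_ratio(src, target, "intensive")
  expect_true(all(field_values(agg_i) >= min(v, na.rm = TRUE) - 1e-12, na.rm = TRUE))
  expect_true(all(field_values(agg_i) <= max(v, na.rm = TRUE) + 1e-12, na.rm = TRUE))
  # a target cell overlapped by no valid source cell is nodata
  v2 <- rep(NA_real_, grid_n_cells(source_grid))
  v2[1] <- 5 # top-left source cell only
  src2 <- raster_field(source_grid, v2)
  agg2 <- aggregate_surface_ratio(src2, target, "intensive")
  expect_equal(sum(!is.na(field_values(agg2))), 1L)
})

test_that("zone rasterization takes overlap-weighted attribute means", {
  g <- small_grid(1, 1)
  # one zone covering the whole cell
  z1 <- zone_map("a", 7, list(cbind(c(-100, 1100, 1100, -100), c(-100, -100, 1100, 1100))))
  expect_equal(field_values(rasterize_zones(z1, g)), 7)

  # 50/50 split between attributes 2 and 4
  z2 <- zone_map(
    c("l", "r"), c(2, 4),
    list(
      cbind(c(0, 500, 500, 0), c(0, 0, 1000, 1000)),
      cbind(c(500, 1000, 1000, 500), c(0, 0, 1000, 1000))
    )
  )
  expect_equal(field_values(rasterize_zones(z2, g)), 3)

  # 30/70 split between 10 and 0, cross-checked by point sampling
  z3 <- zone_map(
    c("l", "r"), c(10, 0),
    list(
      cbind(c(0, 300, 300, 0), c(0, 0, 1000, 1000)),
      cbind(c(300, 1000, 1000, 300), c(0, 0, 1000, 1000))
    )
  )
  expect_equal(field_values(rasterize_zones(z3, g)), 3.0)
  set.seed(7)
  oracle <- mc_cell_mean(
    list(xmin = 0, xmax = 1000, ymin = 0, ymax = 1000),
    function(px, py) ifelse(px < 300, 10, 0)
  )
  expect_equal(field_values(rasterize_zones(z3, g)), oracle, tolerance = 1e-2)

  # uncovered cells are nodata; self-intersecting zones are rejected
  g2 <- small_grid(1, 2)
  out <- rasterize_zones(z2, g2)
  expect_true(is.na(field_values(out)[2]))
  bowtie <- cbind(c(0, 1000, 0, 1000), c(0, 1000, 1000, 0))
  expect_error(zone_map("bad", 1, list(bowtie)), "bad")
})

test_that("buffer partitioning scores cells by summed buffered-area fraction", {
  g <- small_grid(3, 3)
  # one site at the centre cell's centre, 300 m radius
  s <- site_set(1500, 1500)
  f <- buffer_partition(s, 300, g)
  expect_equal(field_values(f, TRUE)[2, 2], pi * 300^2 / 1e6, tolerance = 1e-4)
  set.seed(11)
  oracle <- mc_cell_fraction(
    list(xmin = 1000, xmax = 2000, ymin = 1000, ymax = 2000),
    function(px, py) (px - 1500)^2 + (py - 1500)^2 <= 300^2
  )
  expect_equal(field_values(f, TRUE)[2, 2], oracle, tolerance = 1e-2)
  # cells beyond radius + half-diagonal score exactly 0 (valid, not nodata)
  expect_equal(field_values(f, TRUE)[1, 1], 0)
  expect_false(anyNA(field_values(f)))

  # a cell entirely inside one buffer contributes 1.0
  f2 <- buffer_partition(site_set(1500, 1500), 2000, g)
  expect_equal(field_values(f2, TRUE)[2, 2], 1.0, tolerance = 1e-6)

  # additivity over disjoint site sets
  s1 <- site_set(800, 800)
  s2 <- site_set(2300, 2100)
  both <- buffer_partition(site_set(c(800, 2300), c(800, 2100)), 300, g)
  expect_equal(
    field_values(both),
    field_values(buffer_partition(s1, 300, g)) + field_values(buffer_partition(s2, 300, g))
  )
  expect_error(buffer_partition(s, -1, g), "radius")
})

test_that("IDW interpolation follows the weighted-sum definition", {
  g <- small_grid(1, 1)
  # exact hit returns the sample value
  f <- interpolate_points(data.frame(x = 500, y = 500, value = 42), g, "idw")
  expect_equal(field_values(f), 42)

  # two equidistant samples average
  g2 <- small_grid(1, 3)
  f2 <- interpolate_points(
    data.frame(x = c(500, 2500), y = c(500, 500), value = c(2, 4)), g2, "idw"
  )
  expect_equal(field_values(f2)[2], 3)

  # 20 seeded samples against a brute-force re-implementation
  set.seed(13)
  smp <- data.frame(
    x = runif(20, 0, 5000), y = runif(20, 0, 4000), value = rnorm(20)
  )
  g3 <- small_grid(4, 5)
  f3 <- interpolate_points(smp, g3, "idw", params = list(power = 2))
  cc <- grid_cell_centres(g3)
  for (idx in c(1, 10, 20)) {
    d <- sqrt((smp$x - cc$x[idx])^2 + (smp$y - cc$y[idx])^2)
    w <- d^-2
    expect_equal(field_values(f3)[idx], sum(w * smp$value) / sum(w), tolerance = 1e-12)
  }
  expect_error(interpolate_points(data.frame(x = 1, y = 1, value = 1)[0, ], g, "idw"))
})

test_that("ordinary kriging honours samples and handles duplicates", {
  set.seed(17)
  g <- small_grid(6, 8)
  cc <- grid_cell_centres(g)
  truth <- function(x, y) 10 + 3 * sin(x / 2000) + 2 * cos(y / 1500)
  smp <- data.frame(x = runif(60, 0, 8000), y = runif(60, 0, 6000))
  smp$value <- truth(smp$x, smp$y) + rnorm(60, 0, 0.05)
  f <- interpolate_points(smp, g, "ordinary_kriging")
  est <- field_values(f)
  expect_true(all(is.finite(est)))
  # close to the smooth truth away from edges
  inner <- cc$row %in% 2:5 & cc$col %in% 2:7
  expect_lt(mean(abs(est[inner] - truth(cc$x[inner], cc$y[inner]))), 0.8)

  expect_error(
    interpolate_points(smp[1:5, ], g, "ordinary_kriging"), "at least 10"
  )
  smp_dup <- rbind(smp, smp[1, ])
  expect_warning(interpolate_points(smp_dup, g, "ordinary_kriging"), "duplicate")
})
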
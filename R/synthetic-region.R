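#' Configuration of a synthetic study region
#'
#' Describes every raw layer of a synthetic region with known ground truth:
#' a latent smooth concentration surface per pollutant with injected
#' hotspots, site locations clustered along a linear furrow axis, polygon
#' zones (districts, water-distribution units, census blocks) tiling the
#' extent, a sparse noise corridor raster, per-district emission tables, and
#' a heavy-tailed fine-resolution population raster.
#'
#' @param extent Named bounding box in metres (default 60 km x 40 km, i.e. a
#'   40 x 60 referent grid at 1 km).
#' @param cell_size Referent cell size in metres (default 1000).
#' @param n_soil_points Number of topsoil point samples (default 800).
#' @param n_sites Number of potentially contaminated sites (default 40).
#' @param n_districts,n_water_units,n_census_blocks Zone counts.
#' @param hotspots_per_dimension Injected hotspots per dimension (default 2).
#' @param hotspot_amplitude Hotspot peak height as a multiplier of the
#'   background mean (default 5).
#' @param background_field_params List with `length_scale` (smoothness, m)
#'   and per-pollutant marginal `mean`/`sd` tibbles for `soil` and `air`.
#' @param noise_coverage_fraction Fraction of referent cells carrying a noise
#'   value (default 0.10; the rest are nodata).
#' @param colocate_hotspots Share the first hotspot centre across dimensions
#'   so a multi-stressor hotspot exists (default TRUE).
#' @param seed Integer seed; identical configs and seeds yield identical
#'   regions.
#' @return A validated `region_config` list.
#' @export
region_config <- function(extent = c(xmin = 0, xmax = 60000, ymin = 0, ymax = 40000),
                          cell_size = 1000,
                          n_soil_points = 800,
                          n_sites = 40,
                          n_districts = 30,
                          n_water_units = 25,
                          n_census_blocks = 120,
                          hotspots_per_dimension = 2,
                          hotspot_amplitude = 5,
                          background_field_params = NULL,
                          noise_coverage_fraction = 0.10,
                          colocate_hotspots = TRUE,
                          seed = 1L) {
  extent <- as_extent(extent)
  w <- extent[["xmax"]] - extent[["xmin"]]
  h <- extent[["ymax"]] - extent[["ymin"]]
  if (w < 10 * cell_size || h < 10 * cell_size) {
    abort("extent width and height must be at least 10 cell sizes.")
  }
  counts <- c(
    n_soil_points, n_sites, n_districts, n_water_units, n_census_blocks,
    hotspots_per_dimension
  )
  if (any(counts < 0)) abort("all counts must be >= 0.")
  if (noise_coverage_fraction < 0 || noise_coverage_fraction > 1) {
    abort("`noise_coverage_fraction` must be in [0, 1].")
  }
  if (hotspot_amplitude <= 0) abort("`hotspot_amplitude` must be > 0.")
  if (is.null(background_field_params)) {
    background_field_params <- list(
      length_scale = 5000,
      soil = tibble::tibble(
        pollutant = c("cadmium", "lead"), mean = c(0.4, 30), sd = c(0.12, 8)
      ),
      air = tibble::tibble(
        pollutant = c("no2", "pm10"), mean = c(18, 20), sd = c(4, 4)
      )
    )
  }
  n_cells <- ceiling(w / cell_size) * ceiling(h / cell_size)
  if (n_districts > n_cells || n_water_units > n_cells || n_census_blocks > n_cells) {
    abort("zone counts exceed the number of available cells.")
  }
  structure(
    list(
      extent = extent, cell_size = cell_size,
      n_soil_points = n_soil_points, n_sites = n_sites,
      n_districts = n_districts, n_water_units = n_water_units,
      n_census_blocks = n_census_blocks,
      hotspots_per_dimension = hotspots_per_dimension,
      hotspot_amplitude = hotspot_amplitude,
      background_field_params = background_field_params,
      noise_coverage_fraction = noise_coverage_fraction,
      colocate_hotspots = colocate_hotspots,
      seed = as.integer(seed)
    ),
    class = "region_config"
  )
}

# Gaussian blur of a matrix with edge renormalization; sigma in cells.
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m, along_rows) {
    if (along_rows) m <- t(m)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (d in -r:r) {
      idx <- pmin(pmax(seq_len(n) + d, 1L), n) # replicate edges
      out <- out + k[d + r + 1] * m[idx, , drop = FALSE]
    }
    if (along_rows) t(out) else out
  }
  conv1(conv1(mat, FALSE), TRUE)
}

# Smoothed white noise, standardized to mean 0 sd 1; length_scale in metres.
smooth_noise_surface <- function(n_rows, n_cols, length_scale, cell_size) {
  z <- gaussian_smooth(matrix(rnorm(n_rows * n_cols), n_rows, n_cols),
    sigma = length_scale / cell_size
  )
  (z - mean(z)) / sd(z)
}

# Gaussian bump field evaluated at (x, y) points.
hotspot_bumps <- function(x, y, hotspots) {
  b <- rep(0, length(x))
  for (k in seq_len(nrow(hotspots))) {
    d2 <- (x - hotspots$x[k])^2 + (y - hotspots$y[k])^2
    b <- b + hotspots$amplitude[k] * exp(-d2 / (2 * hotspots$radius[k]^2))
  }
  b
}

# Recursive slice-and-dice partition of the extent into n rectangles that
# exactly tile it (zero-overlap, exact-union polygon layers).
partition_extent <- function(extent, n) {
  rects <- list(list(
    xmin = extent[["xmin"]], xmax = extent[["xmax"]],
    ymin = extent[["ymin"]], ymax = extent[["ymax"]], count = n
  ))
  done <- list()
  while (length(rects)) {
    rc <- rects[[1]]
    rects <- rects[-1]
    if (rc$count <= 1) {
      done[[length(done) + 1]] <- rc
      next
    }
    f <- runif(1, 0.35, 0.65)
    n1 <- max(1L, min(rc$count - 1L, round(rc$count * f)))
    wide <- (rc$xmax - rc$xmin) >= (rc$ymax - rc$ymin)
    if (wide) {
      xm <- rc$xmin + f * (rc$xmax - rc$xmin)
      a <- rc; a$xmax <- xm; a$count <- n1
      b <- rc; b$xmin <- xm; b$count <- rc$count - n1
    } else {
      ym <- rc$ymin + f * (rc$ymax - rc$ymin)
      a <- rc; a$ymax <- ym; a$count <- n1
      b <- rc; b$ymin <- ym; b$count <- rc$count - n1
    }
    rects <- c(rects, list(a, b))
  }
  purrr::map(done, function(rc) {
    cbind(
      c(rc$xmin, rc$xmax, rc$xmax, rc$xmin),
      c(rc$ymin, rc$ymin, rc$ymax, rc$ymax)
    )
  })
}

rects_to_zone_map <- function(rings, prefix) {
  zone_map(
    zone_id = paste0(prefix, seq_along(rings)),
    value = seq_along(rings),
    geometry = rings
  )
}

point_in_rect_ring <- function(ring, x, y) {
  x >= min(ring[, 1]) & x <= max(ring[, 1]) & y >= min(ring[, 2]) & y <= max(ring[, 2])
}

#' Generate a complete synthetic study region
#'
#' Draws every raw input layer of the study design from seeded randomness:
#' topsoil point samples on a latent smooth surface with injected hotspots,
#' sites clustered along a random furrow axis, fine-resolution air
#' concentration rasters, per-district emission totals, zero-inflated
#' per-water-unit exceedance counts over four years, a sparse noise corridor
#' raster covering exactly the configured fraction of cells, a heavy-tailed
#' fine population raster, zone polygon layers that exactly tile the extent,
#' and the ground truth (hotspot locations and latent surfaces) used as the
#' recovery oracle.
#'
#' @param config A `region_config`.
#' @return A `synthetic_region` list: `grid`, `soil_points`, `sites`,
#'   `air_conc`, `emissions`, `water_exceedances`, `noise`, `population`,
#'   `districts`, `water_units`, `census_blocks`, `truth`, `config`.
#' @export
generate_region <- function(config) {
  stopifnot(inherits(config, "region_config"))
  set.seed(config$seed)
  ext <- config$extent
  grid <- build_referent_grid(ext, config$cell_size)
  cc <- grid_cell_centres(grid)
  bfp <- config$background_field_params
  amp_mult <- config$hotspot_amplitude
  nh <- config$hotspots_per_dimension

  cx <- mean(ext[c("xmin", "xmax")]); cy <- mean(ext[c("ymin", "ymax")])
  w <- ext[["xmax"]] - ext[["xmin"]]; h <- ext[["ymax"]] - ext[["ymin"]]

  # furrow axis: a random line through the extent centre
  theta <- runif(1, 0, pi)
  axis_dir <- c(cos(theta), sin(theta))
  half_len <- 0.45 * sqrt(w^2 + h^2)
  axis_point <- function(t) c(cx, cy) + t * half_len * axis_dir

  rand_centre <- function() {
    c(
      runif(1, ext[["xmin"]] + 0.1 * w, ext[["xmax"]] - 0.1 * w),
      runif(1, ext[["ymin"]] + 0.1 * h, ext[["ymax"]] - 0.1 * h)
    )
  }
  shared <- axis_point(runif(1, -0.3, 0.3))
  centres_for <- function() {
    if (nh == 0) return(matrix(numeric(0), ncol = 2))
    first <- if (config$colocate_hotspots) shared else rand_centre()
    extra <- if (nh > 1) t(vapply(seq_len(nh - 1), function(i) rand_centre(), numeric(2)))
             else matrix(numeric(0), ncol = 2)
    rbind(first, extra)
  }
  hotspot_tbl <- function(centres, radius, amplitude) {
    if (nrow(centres) == 0) {
      return(tibble::tibble(
        x = numeric(0), y = numeric(0), radius = numeric(0), amplitude = numeric(0)
      ))
    }
    tibble::tibble(
      x = centres[, 1], y = centres[, 2],
      radius = radius, amplitude = amplitude
    )
  }

  # ---- soil: latent per-pollutant surfaces + point samples --------------
  soil_hot <- hotspot_tbl(centres_for(), radius = 2500,
                          amplitude = amp_mult * mean(bfp$soil$mean))
  soil_latent <- purrr::map(seq_len(nrow(bfp$soil)), function(p) {
    z <- smooth_noise_surface(grid$n_rows, grid$n_cols, bfp$length_scale, grid$cell_size)
    base <- bfp$soil$mean[p] + bfp$soil$sd[p] * as.vector(t(z))
    hs <- soil_hot
    if (nrow(hs)) hs$amplitude <- amp_mult * bfp$soil$mean[p]
    v <- pmax(base + hotspot_bumps(cc$x, cc$y, hs), 0)
    raster_field(grid, v, units = "mg/kg", name = paste0("soil_", bfp$soil$pollutant[p]))
  })
  names(soil_latent) <- bfp$soil$pollutant

  px <- runif(config$n_soil_points, ext[["xmin"]], ext[["xmax"]])
  py <- runif(config$n_soil_points, ext[["ymin"]], ext[["ymax"]])
  pj <- pmin(grid$n_cols, 1L + floor((px - grid$x0) / grid$cell_size))
  pi_ <- pmin(grid$n_rows, 1L + floor((grid$y0 - py) / grid$cell_size))
  cell_idx <- (pi_ - 1L) * grid$n_cols + pj
  soil_points <- purrr::imap_dfr(soil_latent, function(f, nm) {
    tibble::tibble(
      x = px, y = py, pollutant = nm,
      value = field_values(f)[cell_idx] * exp(rnorm(config$n_soil_points, 0, 0.2))
    )
  })

  # ---- sites clustered along the furrow axis ----------------------------
  ts <- runif(config$n_sites, -1, 1)
  off <- rnorm(config$n_sites, 0, 1500)
  sx <- cx + ts * half_len * axis_dir[1] - off * axis_dir[2]
  sy <- cy + ts * half_len * axis_dir[2] + off * axis_dir[1]
  sites <- site_set(
    pmin(pmax(sx, ext[["xmin"]] + 1), ext[["xmax"]] - 1),
    pmin(pmax(sy, ext[["ymin"]] + 1), ext[["ymax"]] - 1)
  )

  # ---- air: fine (500 m) concentration rasters --------------------------
  air_hot <- hotspot_tbl(centres_for(), radius = 3000,
                         amplitude = amp_mult * mean(bfp$air$mean))
  fine_air <- build_referent_grid(ext, config$cell_size / 2)
  fcc <- grid_cell_centres(fine_air)
  air_conc <- purrr::map(seq_len(nrow(bfp$air)), function(p) {
    z <- smooth_noise_surface(fine_air$n_rows, fine_air$n_cols, bfp$length_scale,
                              fine_air$cell_size)
    base <- bfp$air$mean[p] + bfp$air$sd[p] * as.vector(t(z))
    hs <- air_hot
    if (nrow(hs)) hs$amplitude <- amp_mult * bfp$air$mean[p]
    v <- pmax(base + hotspot_bumps(fcc$x, fcc$y, hs), 0)
    raster_field(fine_air, v, units = "ug/m3", name = paste0("air_", bfp$air$pollutant[p]))
  })
  names(air_conc) <- bfp$air$pollutant
  air_latent <- purrr::map(air_conc, aggregate_surface_ratio, target = grid,
                           kind = "intensive")

  # ---- zone layers: exact tilings ---------------------------------------
  districts <- rects_to_zone_map(partition_extent(ext, config$n_districts), "d")
  water_units <- rects_to_zone_map(partition_extent(ext, config$n_water_units), "w")
  census_blocks <- rects_to_zone_map(partition_extent(ext, config$n_census_blocks), "b")

  # ---- per-district emissions (hotspot districts boosted) ---------------
  emis_pollutants <- c("benzene", "bap", "pm")
  emis_base <- c(benzene = 5, bap = 0.5, pm = 50)
  hot_district <- vapply(districts$geometry, function(ring) {
    nrow(air_hot) > 0 && any(point_in_rect_ring(ring, air_hot$x, air_hot$y))
  }, logical(1))
  emissions <- purrr::map_dfr(emis_pollutants, function(p) {
    tibble::tibble(
      zone_id = districts$zone_id,
      pollutant = p,
      emission = rlnorm(nrow(districts), log(emis_base[[p]]), 0.6) *
        ifelse(hot_district, amp_mult, 1)
    )
  })

  # ---- water: zero-inflated exceedance counts over 4 years --------------
  water_hot <- hotspot_tbl(centres_for(), radius = 2000, amplitude = amp_mult)
  hot_unit <- vapply(water_units$geometry, function(ring) {
    nrow(water_hot) > 0 && any(point_in_rect_ring(ring, water_hot$x, water_hot$y))
  }, logical(1))
  water_exceedances <- purrr::map_dfr(1:4, function(yr) {
    active <- hot_unit | (runif(nrow(water_units)) < 0.15)
    tibble::tibble(
      zone_id = water_units$zone_id,
      year = yr,
      count = ifelse(active, rpois(nrow(water_units), ifelse(hot_unit, 2.0, 0.3)) +
                       ifelse(hot_unit, 1L, 0L), 0L)
    )
  })

  # ---- noise: corridor raster with exact coverage -----------------------
  n_cells <- grid_n_cells(grid)
  n_cover <- round(config$noise_coverage_fraction * n_cells)
  n_roads <- 3L
  roads <- purrr::map(seq_len(n_roads), function(r) {
    if (r == 1) {
      # principal road along the furrow axis (through the shared hotspot)
      rbind(axis_point(-1), axis_point(1))
    } else {
      rbind(
        c(runif(1, ext[["xmin"]], ext[["xmax"]]), ext[["ymin"]]),
        c(cx + rnorm(1, 0, w / 6), cy + rnorm(1, 0, h / 6)),
        c(runif(1, ext[["xmin"]], ext[["xmax"]]), ext[["ymax"]])
      )
    }
  })
  d_road <- purrr::reduce(
    purrr::map(roads, ~ dist_to_polyline(cc$x, cc$y, .x)), pmin
  )
  noise_vals <- rep(NA_real_, n_cells)
  noise_hot <- hotspot_tbl(matrix(numeric(0), ncol = 2), 0, 0)
  if (n_cover > 0) {
    thr <- sort(d_road)[n_cover]
    covered <- d_road <= thr
    lden <- 75 - 18 * pmin(d_road[covered] / max(thr, 1), 1)
    if (nh > 0) {
      nh_centres <- t(vapply(
        seq_len(nh),
        function(i) {
          if (i == 1 && config$colocate_hotspots) shared else {
            idx <- sample(which(covered), 1)
            c(cc$x[idx], cc$y[idx])
          }
        },
        numeric(2)
      ))
      noise_hot <- hotspot_tbl(nh_centres, radius = 2000, amplitude = 5)
      lden <- lden + hotspot_bumps(cc$x[covered], cc$y[covered], noise_hot)
    }
    noise_vals[covered] <- pmin(lden, 80)
  }
  noise <- raster_field(grid, noise_vals, units = "dB(A)", name = "lden")

  # ---- population: fine (200 m) heavy-tailed raster ---------------------
  fine_pop <- build_referent_grid(ext, 200)
  pcc <- grid_cell_centres(fine_pop)
  d_axis <- dist_to_polyline(pcc$x, pcc$y, rbind(axis_point(-1), axis_point(1)))
  pop <- rlnorm(grid_n_cells(fine_pop), meanlog = 1.5 + 1.5 * exp(-d_axis / 4000), sdlog = 1)
  population <- raster_field(fine_pop, pop, units = "persons", name = "population")

  # ---- ground truth -----------------------------------------------------
  water_latent <- raster_field(
    grid, hotspot_bumps(cc$x, cc$y, water_hot), name = "water_latent"
  )
  truth <- structure(
    list(
      soil = list(hotspots = soil_hot, latent = soil_latent),
      air = list(hotspots = air_hot, latent = air_latent),
      water = list(hotspots = water_hot, latent = water_latent),
      noise = list(hotspots = noise_hot, latent = noise),
      furrow = list(angle = theta, centre = c(cx, cy), shared_centre = shared)
    ),
    class = "synthetic_truth"
  )

  structure(
    list(
      grid = grid, soil_points = soil_points, sites = sites,
      air_conc = air_conc, emissions = emissions,
      water_exceedances = water_exceedances, noise = noise,
      population = population, districts = districts,
      water_units = water_units, census_blocks = census_blocks,
      truth = truth, config = config
    ),
    class = "synthetic_region"
  )
}

#' @export
print.synthetic_region <- function(x, ...) {
  cat(sprintf(
    "<synthetic_region> grid %s; %d soil points, %d sites, %d districts, %d water units, %d blocks\n",
    format(x$grid), x$config$n_soil_points,
    nrow(x$sites), nrow(x$districts), nrow(x$water_units), nrow(x$census_blocks)
  ))
  invisible(x)
}

#' Heavy- vs light-tailed sub-indicator pair
#'
#' Produces one heavy-right-tailed vector (lognormal, meanlog 0, sdlog 1.5)
#' and one bounded light-tailed vector (Beta(2, 2) scaled to \[0, 10\]) of
#' equal length. Embedding the pair among the sub-indicators reproduces the
#' transform-sensitivity effect: the heavy-tailed dimension contributes more
#' to the composite top decile under the normal-score transform than under
#' the percentile-rank transform.
#'
#' @param n_cells Length of each vector (>= 100).
#' @param seed Integer seed.
#' @return A tibble with columns `heavy` and `light`.
#' @export
generate_tail_contrast_pair <- function(n_cells, seed = 1L) {
  if (n_cells < 100) abort("`n_cells` must be at least 100.")
  set.seed(as.integer(seed))
  tibble::tibble(
    heavy = rlnorm(n_cells, meanlog = 0, sdlog = 1.5),
    light = 10 * rbeta(n_cells, 2, 2)
  )
}
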
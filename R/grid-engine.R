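#' Construct a zone map
#'
#' A zone map is a set of non-overlapping polygons (districts, water
#' distribution units, census blocks), each with a unique identifier and one
#' numeric attribute (an emission total, an exceedance score, a block id, ...).
#'
#' @param zone_id Vector of unique identifiers.
#' @param value Numeric attribute per zone.
#' @param geometry List of two-column (x, y) matrices, one simple ring per
#'   zone, vertices not closed.
#' @return A `zone_map` tibble with columns `zone_id`, `value`, `geometry`.
#' @export
zone_map <- function(zone_id, value, geometry) {
  stopifnot(length(zone_id) == length(value), length(value) == length(geometry))
  if (anyDuplicated(zone_id)) abort("zone identifiers must be unique.")
  bad <- which(!vapply(geometry, poly_is_simple, logical(1)))
  if (length(bad)) {
    abort(paste0(
      "invalid (self-intersecting or degenerate) polygon geometry for zone id(s): ",
      paste(zone_id[bad], collapse = ", ")
    ))
  }
  structure(
    tibble::tibble(zone_id = zone_id, value = as.numeric(value), geometry = geometry),
    class = c("zone_map", class(tibble::tibble()))
  )
}

#' Construct a site set
#'
#' Point locations of potentially contaminated sites.
#'
#' @param x,y Numeric coordinates in metres, or `x` a data frame with columns
#'   `x` and `y`.
#' @return A `site_set` tibble with columns `x`, `y`.
#' @export
site_set <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    stopifnot(all(c("x", "y") %in% names(x)))
    y <- x$y; x <- x$x
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("site coordinates must be finite.")
  structure(
    tibble::tibble(x = as.numeric(x), y = as.numeric(y)),
    class = c("site_set", class(tibble::tibble()))
  )
}

# 1D overlap-length matrix between two sets of consecutive edges.
interval_overlap <- function(lo_a, hi_a, lo_b, hi_b) {
  o <- outer(hi_a, hi_b, pmin) - outer(lo_a, lo_b, pmax)
  o[o < 0] <- 0
  o
}

#' Aggregate a raster onto the referent grid with surface ratios
#'
#' Transfers values between misaligned axis-aligned grids by weighting with
#' exact overlap areas. Intensive quantities (concentrations, Lden) are
#' averaged with overlap-area weights; extensive quantities (emissions,
#' population counts) are split in proportion to the overlapped fraction of
#' each source cell and summed, which conserves the source total over the
#' shared footprint.
#'
#' @param source A `raster_field` on any (typically finer or offset) grid in
#'   the same planar frame.
#' @param target A `referent_grid`.
#' @param kind `"intensive"` or `"extensive"`.
#' @return A `raster_field` on `target`; a target cell is nodata iff no valid
#'   source cell overlaps it.
#' @export
aggregate_surface_ratio <- function(source, target, kind = c("intensive", "extensive")) {
  kind <- match.arg(kind)
  stopifnot(inherits(source, "raster_field"), inherits(target, "referent_grid"))
  sg <- attr(source, "grid")

  sx <- grid_x_edges(sg); sy <- grid_y_edges(sg)
  tx <- grid_x_edges(target); ty <- grid_y_edges(target)

  # columns: left->right increasing x; rows: top->bottom decreasing y
  Wx <- interval_overlap(tx[-length(tx)], tx[-1], sx[-length(sx)], sx[-1])
  Wy <- interval_overlap(
    ty[-1], ty[-length(ty)],
    sy[-1], sy[-length(sy)]
  )

  V <- field_values(source, matrix = TRUE)
  M <- 1 * !is.na(V)
  V0 <- V; V0[is.na(V0)] <- 0

  overlap_valid <- Wy %*% M %*% t(Wx)
  if (kind == "intensive") {
    num <- Wy %*% (V0 * M) %*% t(Wx)
    out <- num / overlap_valid
    out[overlap_valid <= 0] <- NA_real_
  } else {
    src_area <- sg$cell_size^2
    out <- Wy %*% ((V0 * M) / src_area) %*% t(Wx)
    out[overlap_valid <= 0] <- NA_real_
  }
  raster_field(target, out,
    units = attr(source, "units"),
    name = attr(source, "layer_name")
  )
}

# Candidate cell index ranges intersecting a bounding box.
cells_in_bbox <- function(grid, xmin, xmax, ymin, ymax) {
  s <- grid$cell_size
  j0 <- max(1L, 1L + floor((xmin - grid$x0) / s))
  j1 <- min(grid$n_cols, 1L + floor((xmax - grid$x0) / s + 1e-12))
  i0 <- max(1L, 1L + floor((grid$y0 - ymax) / s))
  i1 <- min(grid$n_rows, 1L + floor((grid$y0 - ymin) / s + 1e-12))
  if (j0 > j1 || i0 > i1) return(NULL)
  list(rows = i0:i1, cols = j0:j1)
}

cell_bounds <- function(grid, i, j) {
  s <- grid$cell_size
  list(
    xmin = grid$x0 + (j - 1) * s, xmax = grid$x0 + j * s,
    ymin = grid$y0 - i * s, ymax = grid$y0 - (i - 1) * s
  )
}

#' Rasterize a zone map onto the referent grid
#'
#' Each cell receives the overlap-area-weighted mean of the zone attribute
#' over all zones intersecting it (the surface-ratio rule used to spatialize
#' water distribution-unit scores and district-level data). Cells covered by
#' no zone are nodata.
#'
#' @param zones A `zone_map`.
#' @param grid A `referent_grid` in the same planar frame.
#' @return A `raster_field`.
#' @export
rasterize_zones <- function(zones, grid) {
  stopifnot(inherits(zones, "zone_map"), inherits(grid, "referent_grid"))
  num <- matrix(0, grid$n_rows, grid$n_cols)
  den <- matrix(0, grid$n_rows, grid$n_cols)
  for (k in seq_len(nrow(zones))) {
    ring <- zones$geometry[[k]]
    val <- zones$value[k]
    bb <- cells_in_bbox(grid, min(ring[, 1]), max(ring[, 1]), min(ring[, 2]), max(ring[, 2]))
    if (is.null(bb)) next
    for (i in bb$rows) {
      for (j in bb$cols) {
        cb <- cell_bounds(grid, i, j)
        a <- poly_rect_overlap_area(ring, cb$xmin, cb$xmax, cb$ymin, cb$ymax)
        if (a > 0) {
          num[i, j] <- num[i, j] + a * val
          den[i, j] <- den[i, j] + a
        }
      }
    }
  }
  out <- num / den
  out[den <= grid$cell_size^2 * 1e-12] <- NA_real_
  raster_field(grid, out, name = "zones")
}

#' Buffer-partitioned site proximity density
#'
#' Generates circular buffers of radius `radius_m` around each site and
#' partitions every referent-grid cell into its inside-the-buffer and
#' outside-the-buffer portions. The cell score is the summed buffered area
#' fraction \eqn{\sum_s area(cell \cap disc_s) / area(cell)}: a proximity
#' density proxy in which overlapping buffers from distinct sites accumulate
#' rather than merge. Cells far from all sites score 0 (a valid value, not
#' nodata).
#'
#' @param sites A `site_set` (or data frame with `x`, `y`).
#' @param radius_m Buffer radius in metres (default 300, the working-group
#'   distance).
#' @param grid A `referent_grid`.
#' @return A `raster_field` of dimensionless densities, all values >= 0.
#' @export
buffer_partition <- function(sites, radius_m = 300, grid) {
  if (!inherits(sites, "site_set")) sites <- site_set(sites)
  stopifnot(inherits(grid, "referent_grid"))
  if (!is.numeric(radius_m) || radius_m <= 0) abort("`radius_m` must be > 0.")
  cell_area <- grid$cell_size^2
  out <- matrix(0, grid$n_rows, grid$n_cols)
  for (k in seq_len(nrow(sites))) {
    disc <- disc_polygon(sites$x[k], sites$y[k], radius_m)
    bb <- cells_in_bbox(
      grid,
      min(disc[, 1]), max(disc[, 1]), min(disc[, 2]), max(disc[, 2])
    )
    if (is.null(bb)) next
    for (i in bb$rows) {
      for (j in bb$cols) {
        cb <- cell_bounds(grid, i, j)
        a <- poly_rect_overlap_area(disc, cb$xmin, cb$xmax, cb$ymin, cb$ymax)
        if (a > 0) out[i, j] <- out[i, j] + a / cell_area
      }
    }
  }
  raster_field(grid, out, units = "buffered area fraction", name = "site_proximity")
}

#' Interpolate point samples onto the referent grid
#'
#' Estimates a value at every cell centre from scattered point samples, by
#' inverse-distance weighting or by ordinary kriging with an isotropic
#' exponential variogram fitted by weighted least squares on the empirical
#' variogram (a deliberately simple stand-in for hybrid area-to-point
#' geostatistical methods).
#'
#' @param samples Data frame with columns `x`, `y`, `value`.
#' @param grid A `referent_grid`.
#' @param method `"idw"` or `"ordinary_kriging"`.
#' @param params List of method parameters: `power` (IDW exponent, default 2),
#'   `n_bins` (empirical variogram bins, default 15).
#' @return A `raster_field` (all cells valid).
#' @export
interpolate_points <- function(samples, grid, method = c("idw", "ordinary_kriging"),
                               params = list()) {
  method <- match.arg(method)
  stopifnot(is.data.frame(samples), all(c("x", "y", "value") %in% names(samples)))
  samples <- samples[stats::complete.cases(samples[, c("x", "y", "value")]), ]
  n <- nrow(samples)
  if (n < 1) abort("at least one sample is required.")
  if (method == "ordinary_kriging" && n < 10) {
    abort("ordinary kriging requires at least 10 samples.")
  }

  # duplicate locations break the kriging system; average them, warn
  key <- paste(samples$x, samples$y)
  if (anyDuplicated(key)) {
    if (method == "ordinary_kriging") {
      warn("duplicate sample locations averaged before kriging.")
    }
    samples <- samples %>%
      group_by(.data$x, .data$y) %>%
      summarise(value = mean(.data$value), .groups = "drop")
    n <- nrow(samples)
  }

  cc <- grid_cell_centres(grid)
  D <- sqrt(
    outer(cc$x, samples$x, "-")^2 + outer(cc$y, samples$y, "-")^2
  ) # n_cells x n

  if (method == "idw") {
    p <- params$power %||% 2
    W <- D^(-p)
    est <- (W %*% samples$value) / rowSums(W)
    hit <- D < 1e-9
    if (any(hit)) {
      idx <- which(hit, arr.ind = TRUE)
      est[idx[, 1]] <- samples$value[idx[, 2]]
    }
    return(raster_field(grid, matrix(est, grid$n_rows, byrow = TRUE),
      name = "idw"
    ))
  }

  vg <- fit_exponential_variogram(samples, n_bins = params$n_bins %||% 15)
  Ds <- sqrt(
    outer(samples$x, samples$x, "-")^2 + outer(samples$y, samples$y, "-")^2
  )
  cov_fun <- function(h) vg$psill * exp(-h / vg$range)
  C <- cov_fun(Ds)
  # nugget plus a small ridge keeps the system well conditioned when the
  # fitted range is much larger than the sampled domain
  diag(C) <- vg$psill + vg$nugget + 1e-6 * vg$psill
  K <- rbind(cbind(C, 1), c(rep(1, n), 0))
  rhs <- rbind(t(cov_fun(D)), 1) # (n+1) x n_cells
  w <- solve(K, rhs)
  est <- as.vector(t(w[seq_len(n), , drop = FALSE]) %*% samples$value)
  out <- raster_field(grid, matrix(est, grid$n_rows, byrow = TRUE), name = "kriging")
  attr(out, "variogram") <- vg
  out
}

# WLS fit (Cressie weights N_k / gamma_model^2) of nugget + exponential
# variogram to binned empirical semivariances.
fit_exponential_variogram <- function(samples, n_bins = 15) {
  n <- nrow(samples)
  dx <- outer(samples$x, samples$x, "-")
  dy <- outer(samples$y, samples$y, "-")
  h <- sqrt(dx^2 + dy^2)[lower.tri(dx)]
  g <- (outer(samples$value, samples$value, "-")^2 / 2)[lower.tri(dx)]
  hmax <- max(h) / 2
  keep <- h > 0 & h <= hmax
  h <- h[keep]; g <- g[keep]
  bins <- cut(h, breaks = seq(0, hmax, length.out = n_bins + 1), include.lowest = TRUE)
  emp <- tibble::tibble(h = h, g = g, bin = bins) %>%
    group_by(.data$bin) %>%
    summarise(h = mean(.data$h), gamma = mean(.data$g), n_pairs = dplyr::n(), .groups = "drop") %>%
    filter(.data$n_pairs > 0)

  s2 <- stats::var(samples$value)
  obj <- function(par) {
    nug <- exp(par[1]); psill <- exp(par[2]); rng <- exp(par[3])
    mod <- nug + psill * (1 - exp(-emp$h / rng))
    sum(emp$n_pairs * (emp$gamma / pmax(mod, 1e-12) - 1)^2)
  }
  fit <- stats::optim(
    log(c(max(s2 * 0.1, 1e-8), max(s2, 1e-8), max(emp$h) / 3)),
    obj,
    method = "Nelder-Mead", control = list(maxit = 500)
  )
  # clamp to a sane box: unbounded ranges/sills fit the short lags equally
  # well but make the kriging system numerically singular
  list(
    nugget = min(exp(fit$par[1]), 5 * max(s2, 1e-8)),
    psill = min(exp(fit$par[2]), 10 * max(s2, 1e-8)),
    range = min(exp(fit$par[3]), 3 * hmax),
    empirical = emp
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
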
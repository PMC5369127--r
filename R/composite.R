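#' Composite cumulative-risk indicator
#'
#' Cellwise sum of standardized sub-indicators (all on the same grid and
#' standardized with the same method). Cells that are background in every
#' input stay valid: they carry the sum of the shared background scores.
#'
#' @param fields List of >= 2 `standardized_field`s.
#' @return A `composite_field`: a `raster_field` with values in \[0, k\] for
#'   k sub-indicators, carrying its contributing fields and method.
#' @export
composite_indicator <- function(fields) {
  if (length(fields) < 2) abort("a composite needs at least 2 sub-indicators.")
  methods <- purrr::map_chr(fields, ~ attr(.x, "method"))
  if (length(unique(methods)) != 1) {
    abort("all sub-indicators must use the same standardization method.")
  }
  purrr::walk(fields, ~ check_same_grid(.x, fields[[1]]))
  total <- purrr::reduce(purrr::map(fields, field_values), `+`)
  out <- field_with_values(fields[[1]], total,
    name = paste0("composite_", methods[1]), units = "summed score"
  )
  out$background <- NULL
  attr(out, "method") <- methods[1]
  attr(out, "sub_indicators") <- fields
  class(out) <- c("composite_field", class(out))
  out
}

#' Population-weighted aggregation to census blocks
#'
#' Aggregates the cellwise composite to administrative blocks:
#' each grid cell is assigned to the single block with the largest overlap
#' area, and the block value is the population-weighted mean of its member
#' cells. Blocks whose member cells carry zero total population fall back to
#' the unweighted mean and are flagged.
#'
#' @param composite A `composite_field` (or any `raster_field`).
#' @param population A `raster_field` of population counts on the same grid
#'   (values >= 0; nodata treated as 0 population).
#' @param blocks A `zone_map` of census blocks tiling the grid extent.
#' @return A tibble with one row per block: `zone_id`, `weighted_mean`,
#'   `total_population`, `n_cells`, `unweighted_fallback`.
#' @export
population_weighted_aggregate <- function(composite, population, blocks) {
  stopifnot(inherits(composite, "raster_field"), inherits(blocks, "zone_map"))
  check_same_grid(composite, population)
  grid <- attr(composite, "grid")

  # largest-overlap assignment of each cell to one block
  best_area <- matrix(0, grid$n_rows, grid$n_cols)
  assign_id <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  for (k in seq_len(nrow(blocks))) {
    ring <- blocks$geometry[[k]]
    bb <- cells_in_bbox(grid, min(ring[, 1]), max(ring[, 1]), min(ring[, 2]), max(ring[, 2]))
    if (is.null(bb)) next
    for (i in bb$rows) {
      for (j in bb$cols) {
        cb <- cell_bounds(grid, i, j)
        a <- poly_rect_overlap_area(ring, cb$xmin, cb$xmax, cb$ymin, cb$ymax)
        if (a > best_area[i, j]) {
          best_area[i, j] <- a
          assign_id[i, j] <- k
        }
      }
    }
  }

  df <- tibble::tibble(
    block_index = as.vector(t(assign_id)),
    comp = field_values(composite),
    pop = dplyr::coalesce(field_values(population), 0)
  ) %>% filter(!is.na(.data$block_index), !is.na(.data$comp))

  if (!all(seq_len(nrow(blocks)) %in% df$block_index)) {
    abort("one or more blocks contain no grid cells.")
  }

  df %>%
    group_by(.data$block_index) %>%
    summarise(
      total_population = sum(.data$pop),
      n_cells = dplyr::n(),
      weighted_mean = if (sum(.data$pop) > 0) {
        sum(.data$pop * .data$comp) / sum(.data$pop)
      } else {
        mean(.data$comp)
      },
      unweighted_fallback = sum(.data$pop) == 0,
      .groups = "drop"
    ) %>%
    mutate(zone_id = blocks$zone_id[.data$block_index]) %>%
    select("zone_id", "weighted_mean", "total_population", "n_cells", "unweighted_fallback")
}

#' Spearman correlation matrix between sub-indicators
#'
#' Pairwise Spearman rank correlation (ties averaged) between fields over the
#' cells valid in both members of each pair. A constant field yields `NA`
#' entries, reported as missing.
#'
#' @param fields Named list of `raster_field`s on the same grid.
#' @return A symmetric numeric matrix with unit diagonal.
#' @export
correlation_matrix <- function(fields) {
  stopifnot(length(fields) >= 2)
  purrr::walk(fields, ~ check_same_grid(.x, fields[[1]]))
  nm <- names(fields) %||% purrr::map_chr(fields, ~ attr(.x, "layer_name"))
  vals <- purrr::map(fields, field_values)
  p <- length(fields)
  m <- diag(1, p)
  dimnames(m) <- list(nm, nm)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ok <- !is.na(vals[[i]]) & !is.na(vals[[j]])
      if (sum(ok) < 3) abort("fewer than 3 shared valid cells for a pair.")
      r <- suppressWarnings(cor(vals[[i]][ok], vals[[j]][ok], method = "spearman"))
      m[i, j] <- m[j, i] <- r
    }
  }
  m
}

#' Sub-indicator contributions above a composite percentile
#'
#' Selects the cells whose composite value lies strictly above the empirical
#' `q`-quantile and decomposes the composite there: for each sub-indicator
#' the contribution is the mean over selected cells of its cellwise share,
#' `score / composite * 100`. Shares always sum to 100. A pooled variant
#' (`pooled = TRUE`) instead sums scores over selected cells before dividing.
#'
#' @param composite A `composite_field`.
#' @param q Percentile threshold in (0, 1), default 0.9.
#' @param pooled Use pooled sums rather than averaged cellwise shares.
#' @return A `contribution_table` tibble with `dimension`,
#'   `contribution_pct`.
#' @export
contribution_above_percentile <- function(composite, q = 0.9, pooled = FALSE) {
  stopifnot(inherits(composite, "composite_field"), q > 0, q < 1)
  subs <- attr(composite, "sub_indicators")
  comp <- field_values(composite)
  if (length(comp) <= 1 / (1 - q)) abort("too few cells for this percentile.")
  thr <- as.numeric(quantile(comp, q, na.rm = TRUE, type = 7))
  sel <- which(!is.na(comp) & comp > thr)
  if (!length(sel)) abort("no cells strictly above the threshold.")
  if (any(comp[sel] <= 0)) abort("composite is zero in a selected cell.")

  nm <- purrr::map_chr(subs, ~ attr(.x, "layer_name"))
  contrib <- purrr::map_dbl(subs, function(f) {
    sc <- field_values(f)[sel]
    if (pooled) {
      sum(sc) / sum(comp[sel]) * 100
    } else {
      mean(sc / comp[sel]) * 100
    }
  })
  structure(
    tibble::tibble(dimension = nm, contribution_pct = contrib),
    threshold = thr, q = q, n_cells = length(sel), pooled = pooled,
    class = c("contribution_table", class(tibble::tibble()))
  )
}

#' Sliding-window slope of a transform curve
#'
#' Ordinary least-squares slope of standardized score against raw value
#' within a centred sliding window along the sorted data. A low slope near
#' the maximum flags extremum smoothing by the transform (a loss of contrast
#' among the highest exposures).
#'
#' @param raw Raw sub-indicator values.
#' @param score Standardized scores (same length).
#' @param window Odd window width >= 3.
#' @return A tibble sorted by raw value with `raw`, `score`, `slope` (`NA`
#'   where the window does not fit).
#' @export
transform_slope <- function(raw, score, window = 51) {
  n <- length(raw)
  stopifnot(length(score) == n)
  if (window < 3) abort("`window` must be >= 3.")
  if (window > n) abort("`window` exceeds the number of values.")
  ord <- order(raw)
  x <- raw[ord]; y <- score[ord]
  half <- floor(window / 2)
  slope <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) {
    idx <- (i - half):(i + half)
    xx <- x[idx]; yy <- y[idx]
    sxx <- sum((xx - mean(xx))^2)
    slope[i] <- if (sxx == 0) 0 else sum((xx - mean(xx)) * (yy - mean(yy))) / sxx
  }
  tibble::tibble(raw = x, score = y, slope = slope)
}

#' Heteroscedasticity ratio of a standardized field
#'
#' Ratio between the shared background score and the first (smallest)
#' non-background score. A ratio well below 1 measures the gap the background
#' rule creates between the tied bottom of the distribution and the rest; the
#' gap shrinks (ratio approaches 1) as the background fraction vanishes.
#'
#' @param field A `standardized_field` with at least one background and one
#'   non-background cell.
#' @return A single ratio in (0, 1\].
#' @export
heteroscedasticity_ratio <- function(field) {
  stopifnot(inherits(field, "standardized_field"))
  k <- attr(field, "n_background")
  if (k == 0) abort("field has no background cells.")
  v <- field_values(field)
  bg <- field$background
  if (all(bg)) abort("field has no non-background cells.")
  attr(field, "background_value") / min(v[!bg])
}

#' Rank candidate symmetric distributions by goodness of fit
#'
#' Fits each candidate family (uniform, normal, logistic) by the method of
#' moments and ranks them by the Kolmogorov-Smirnov statistic against the
#' fitted law (the Anderson-Darling statistic is reported alongside). Used to
#' choose the standardization target distribution that least distorts
#' relative distances.
#'
#' @param values Numeric vector, length >= 20.
#' @param candidates Subset of `c("uniform", "normal", "logistic")`.
#' @return A `rank_fit` tibble sorted ascending by KS statistic, with fitted
#'   parameters and both statistics.
#' @export
fit_rank_distribution <- function(values, candidates = c("uniform", "normal", "logistic")) {
  candidates <- match.arg(candidates, several.ok = TRUE)
  values <- values[!is.na(values)]
  if (length(values) < 20) abort("at least 20 values are required.")
  n <- length(values)
  m <- mean(values); s <- sd(values)
  xs <- sort(values)

  cdf_for <- function(family) {
    switch(family,
      normal = function(x) pnorm(x, m, s),
      uniform = {
        a <- m - sqrt(3) * s; b <- m + sqrt(3) * s
        function(x) pmin(1, pmax(0, (x - a) / (b - a)))
      },
      logistic = {
        scale <- s * sqrt(3) / pi
        function(x) plogis(x, m, scale)
      }
    )
  }
  params_for <- function(family) {
    switch(family,
      normal = list(mean = m, sd = s),
      uniform = list(min = m - sqrt(3) * s, max = m + sqrt(3) * s),
      logistic = list(location = m, scale = s * sqrt(3) / pi)
    )
  }

  res <- purrr::map_dfr(candidates, function(fam) {
    Fx <- cdf_for(fam)
    u <- Fx(xs)
    ks <- max(pmax(seq_len(n) / n - u, u - (seq_len(n) - 1) / n))
    uc <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    ad <- -n - mean((2 * seq_len(n) - 1) * (log(uc) + log(1 - rev(uc))))
    tibble::tibble(
      family = fam,
      ks_statistic = ks,
      ad_statistic = ad,
      parameters = list(params_for(fam))
    )
  }) %>% arrange(.data$ks_statistic)
  structure(res, class = c("rank_fit", class(tibble::tibble())))
}

#' @export
glance.rank_fit <- function(x, ...) {
  tibble::tibble(
    best_family = x$family[1],
    best_ks = x$ks_statistic[1],
    n_candidates = nrow(x)
  )
}
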
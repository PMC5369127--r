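#' Flag background cells of a sub-indicator
#'
#' Background cells are those with no possible measurement (nodata) plus, for
#' hotspot-type dimensions, cells whose exposure value is exactly zero (an
#' area with no water exceedance hotspot, no noise estimate, no nearby site).
#' Concentration-type dimensions (air, soil HQ) keep zeros as ordinary low
#' values. All background cells later share a single transformed score, the
#' mean of the first tied ranks.
#'
#' @param field A `raster_field`.
#' @param dimension Dimension label used to pick the rule, e.g. `"water"`.
#' @param zero_background_dimensions Dimensions for which zero counts as
#'   background (default water, noise, proximity).
#' @return The field with an added logical `background` column.
#' @export
flag_background <- function(field, dimension,
                            zero_background_dimensions = c("water", "noise", "proximity")) {
  stopifnot(inherits(field, "raster_field"))
  v <- field_values(field)
  bg <- is.na(v)
  if (dimension %in% zero_background_dimensions) bg <- bg | (!is.na(v) & v == 0)
  out <- field
  out$background <- bg
  out
}

#' Rank cell values with averaged ties and bottom-ranked background
#'
#' Background cells occupy the lowest `k` ranks and each receives their mean,
#' `(k + 1) / 2`; the remaining cells are ranked `k+1 .. n` in increasing
#' value order with tied values given averaged ranks. The rank total is always
#' `n (n + 1) / 2`.
#'
#' @param values Numeric vector (NA allowed only on background positions).
#' @param background Logical vector, TRUE for background cells.
#' @return Numeric vector of fractional ranks in \[1, n\].
#' @export
rank_with_ties <- function(values, background = rep(FALSE, length(values))) {
  n <- length(values)
  if (n < 2) abort("at least 2 cells are required to rank.")
  stopifnot(length(background) == n)
  background <- background | is.na(values)
  k <- sum(background)
  if (k == n) abort("all cells are background; nothing to rank.")
  ranks <- numeric(n)
  ranks[background] <- (k + 1) / 2
  ranks[!background] <- k + rank(values[!background], ties.method = "average")
  ranks
}

#' Percentile-rank transform
#'
#' Maps fractional ranks to plotting-position percentiles
#' `(rank - 0.5) / n` (Hazen), strictly inside (0, 1) and order-preserving.
#'
#' @param ranks Fractional ranks (from [rank_with_ties()]).
#' @param n Total cell count (including background cells).
#' @return Scores in (0, 1).
#' @export
percentile_rank_transform <- function(ranks, n = length(ranks)) {
  if (n == 0) abort("`n` must be positive.")
  (ranks - 0.5) / n
}

#' Normal-score transform
#'
#' Maps fractional ranks to approximate standard-normal order-statistic
#' expectations using the Blom plotting position,
#' `z = qnorm((rank - 0.375) / (n + 0.25))`, then min-max rescales to
#' \[0, 1\] using the normal scores of ranks 1 and n as the anchors, so the
#' standardized field varies between 0 and 1. Anchoring at the rank-grid
#' extremes (rather than at whatever ranks are present) keeps a tied
#' background block strictly above 0 whenever it sits above rank 1, which
#' preserves the gap between background and the first measured cell.
#'
#' @inheritParams percentile_rank_transform
#' @return Scores in \[0, 1\]; rank 1 maps to 0 and rank n to 1.
#' @export
normal_score_transform <- function(ranks, n = length(ranks)) {
  if (length(unique(ranks)) < 2) {
    abort("all ranks tied: normal-score rescaling is undefined.")
  }
  z <- qnorm((ranks - 0.375) / (n + 0.25))
  z_lo <- qnorm((1 - 0.375) / (n + 0.25))
  z_hi <- qnorm((n - 0.375) / (n + 0.25))
  (z - z_lo) / (z_hi - z_lo)
}

#' Standardize a sub-indicator field
#'
#' Full rank-based standardization of a raw sub-indicator: background cells
#' are flagged, all cells ranked with averaged ties (background at the
#' bottom), and the ranks transformed by the chosen method. Background cells
#' receive the shared background score and are valid in the output.
#'
#' @param field A `raster_field` (optionally already carrying a `background`
#'   column from [flag_background()]).
#' @param method `"normal_score"` or `"percentile_rank"`.
#' @param dimension Optional dimension label passed to [flag_background()]
#'   when the field has no `background` column.
#' @param zero_background Logical shortcut overriding the per-dimension rule.
#' @param zero_background_dimensions See [flag_background()].
#' @return A `standardized_field`: a `raster_field` with values in \[0, 1\]
#'   and attributes `method`, `background_value`, `n_background`.
#' @export
standardize_field <- function(field, method = c("normal_score", "percentile_rank"),
                              dimension = NULL, zero_background = NULL,
                              zero_background_dimensions = c("water", "noise", "proximity")) {
  method <- match.arg(method)
  stopifnot(inherits(field, "raster_field"))
  if ("background" %in% names(field)) {
    bg <- field$background
  } else if (!is.null(zero_background)) {
    v <- field_values(field)
    bg <- is.na(v) | (isTRUE(zero_background) & !is.na(v) & v == 0)
  } else if (!is.null(dimension)) {
    bg <- flag_background(field, dimension, zero_background_dimensions)$background
  } else {
    bg <- is.na(field_values(field))
  }
  v <- field_values(field)
  ranks <- rank_with_ties(v, bg)
  n <- length(ranks)
  scores <- switch(method,
    percentile_rank = percentile_rank_transform(ranks, n),
    normal_score = normal_score_transform(ranks, n)
  )
  k <- sum(bg | is.na(v))
  bg_value <- if (k > 0) scores[which(bg | is.na(v))[1]] else NA_real_
  out <- field_with_values(field, scores,
    name = paste0(attr(field, "layer_name"), "_", method),
    units = "standardized score"
  )
  out$background <- bg | is.na(v)
  attr(out, "method") <- method
  attr(out, "background_value") <- bg_value
  attr(out, "n_background") <- k
  class(out) <- c("standardized_field", class(out))
  out
}

#' @export
print.standardized_field <- function(x, ...) {
  cat(sprintf(
    "<standardized_field> method %s, %d background cells (shared score %s)\n",
    attr(x, "method"), attr(x, "n_background"),
    format(attr(x, "background_value"), digits = 4)
  ))
  NextMethod()
}

#' Check the equity constraint across standardized sub-indicators
#'
#' The equity constraint requires every sub-indicator to enter the composite
#' with a similar weight: equal range and, for fields without background
#' inflation, equal mean over the modelling domain. Fields with background
#' cells report how far their mean is pulled from the no-background reference
#' (the heteroscedasticity effect of the tie rule) without failing the check.
#'
#' @param fields List of `standardized_field`s on the same grid.
#' @param tol Numeric tolerance for range and mean agreement (default 1e-9).
#' @return An `equity_report` with per-field statistics and a pass flag; use
#'   [tidy()] / [glance()] to extract them.
#' @export
check_equity <- function(fields, tol = 1e-9) {
  stopifnot(length(fields) >= 2)
  purrr::walk(fields, function(f) {
    stopifnot(inherits(f, "standardized_field"))
    check_same_grid(f, fields[[1]])
  })
  nm <- purrr::map_chr(fields, ~ attr(.x, "layer_name"))
  stats <- purrr::imap_dfr(fields, function(f, i) {
    v <- field_values(f)
    tibble::tibble(
      field = nm[i],
      method = attr(f, "method"),
      mean = mean(v),
      min = min(v),
      max = max(v),
      range = max(v) - min(v),
      n_background = attr(f, "n_background")
    )
  })
  clean <- stats$n_background == 0
  mean_ref <- if (any(clean)) mean(stats$mean[clean]) else mean(stats$mean)
  stats$mean_deviation <- stats$mean - mean_ref

  # background-inflated fields only report their statistics: the tie rule
  # necessarily compresses their range and shifts their mean
  rng <- stats$range[clean]
  range_ok <- length(rng) < 2 || (max(rng) - min(rng)) <= tol
  mean_ok <- !any(clean) || max(abs(stats$mean_deviation[clean])) <= tol
  offenders <- character()
  if (!range_ok) {
    mid <- stats::median(rng)
    bad <- abs(stats$range - mid) == max(abs(rng - mid))
    offenders <- c(offenders, stats$field[clean & bad])
  }
  if (!mean_ok) {
    offenders <- c(offenders, stats$field[clean & abs(stats$mean_deviation) > tol])
  }
  structure(
    list(
      stats = stats, pass = range_ok && mean_ok,
      range_ok = range_ok, mean_ok = mean_ok,
      offenders = unique(offenders), tol = tol
    ),
    class = "equity_report"
  )
}

#' @export
print.equity_report <- function(x, ...) {
  cat(sprintf(
    "<equity_report> %s (tol %g)\n", if (x$pass) "PASS" else "FAIL", x$tol
  ))
  if (!x$pass) cat("  offending field(s):", paste(x$offenders, collapse = ", "), "\n")
  print(x$stats)
  invisible(x)
}

#' @export
tidy.equity_report <- function(x, ...) x$stats

#' @export
glance.equity_report <- function(x, ...) {
  tibble::tibble(
    pass = x$pass, range_ok = x$range_ok, mean_ok = x$mean_ok,
    n_fields = nrow(x$stats), tol = x$tol
  )
}
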
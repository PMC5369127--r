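#' Build a referent grid over an extent
#'
#' The referent grid is the common regular lattice onto which every exposure
#' layer is discretized (1 km cells by default). Cells are indexed row-major
#' from the top-left corner; cell (i, j) covers the half-open square
#' \eqn{[x_0 + (j-1)s, x_0 + js) \times (y_0 - is, y_0 - (i-1)s]} so that
#' shared edges are never counted twice. The grid always covers the extent
#' entirely: if the extent is not an exact multiple of the cell size the last
#' row/column overhangs.
#'
#' @param extent Named numeric vector or list with `xmin`, `xmax`, `ymin`,
#'   `ymax` in metres (a projected, planar frame is assumed).
#' @param cell_size Cell side length in metres (default 1000).
#'
#' @return A `referent_grid` object: a list with `x0`, `y0` (top-left origin),
#'   `cell_size`, `n_rows`, `n_cols`.
#' @examples
#' build_referent_grid(c(xmin = 0, xmax = 10000, ymin = 0, ymax = 6000), 1000)
#' @export
build_referent_grid <- function(extent, cell_size = 1000) {
  extent <- as_extent(extent)
  if (!is.numeric(cell_size) || length(cell_size) != 1 || !is.finite(cell_size) ||
      cell_size <= 0) {
    abort("`cell_size` must be a single positive number (metres).")
  }
  n_cols <- as.integer(ceiling((extent[["xmax"]] - extent[["xmin"]]) / cell_size - 1e-9))
  n_rows <- as.integer(ceiling((extent[["ymax"]] - extent[["ymin"]]) / cell_size - 1e-9))
  structure(
    list(
      x0 = unname(extent[["xmin"]]),
      y0 = unname(extent[["ymax"]]),
      cell_size = cell_size,
      n_rows = n_rows,
      n_cols = n_cols
    ),
    class = "referent_grid"
  )
}

as_extent <- function(extent) {
  extent <- unlist(extent)
  req <- c("xmin", "xmax", "ymin", "ymax")
  if (!all(req %in% names(extent))) {
    abort("`extent` needs named entries xmin, xmax, ymin, ymax.")
  }
  extent <- extent[req]
  if (!all(is.finite(extent)) ||
      extent[["xmax"]] <= extent[["xmin"]] || extent[["ymax"]] <= extent[["ymin"]]) {
    abort("`extent` is degenerate: xmax > xmin and ymax > ymin required.")
  }
  extent
}

#' @export
print.referent_grid <- function(x, ...) {
  cat(sprintf(
    "<referent_grid> %d rows x %d cols, cell %g m, origin (%g, %g) top-left\n",
    x$n_rows, x$n_cols, x$cell_size, x$x0, x$y0
  ))
  invisible(x)
}

#' @export
format.referent_grid <- function(x, ...) {
  sprintf("%dx%d@%gm", x$n_rows, x$n_cols, x$cell_size)
}

#' Number of cells in a referent grid
#'
#' @param grid A `referent_grid`.
#' @return Integer cell count (`n_rows * n_cols`).
#' @export
grid_n_cells <- function(grid) grid$n_rows * grid$n_cols

grid_extent <- function(grid) {
  c(
    xmin = grid$x0, xmax = grid$x0 + grid$n_cols * grid$cell_size,
    ymin = grid$y0 - grid$n_rows * grid$cell_size, ymax = grid$y0
  )
}

# x edges of columns j..j+1 (length n_cols + 1), left to right
grid_x_edges <- function(grid) grid$x0 + (0:grid$n_cols) * grid$cell_size
# y edges of rows, top to bottom (decreasing)
grid_y_edges <- function(grid) grid$y0 - (0:grid$n_rows) * grid$cell_size

grid_same <- function(a, b) {
  isTRUE(all.equal(a$x0, b$x0)) && isTRUE(all.equal(a$y0, b$y0)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Cell centres of a referent grid
#'
#' @param grid A `referent_grid`.
#' @return A tibble with `row`, `col`, `x`, `y` in row-major order (top-left
#'   first).
#' @export
grid_cell_centres <- function(grid) {
  stopifnot(inherits(grid, "referent_grid"))
  s <- grid$cell_size
  tibble::tibble(
    row = rep(seq_len(grid$n_rows), each = grid$n_cols),
    col = rep(seq_len(grid$n_cols), times = grid$n_rows)
  ) %>%
    mutate(
      x = grid$x0 + (.data$col - 0.5) * s,
      y = grid$y0 - (.data$row - 0.5) * s
    )
}

#' Construct a raster field on a referent grid
#'
#' A `raster_field` is a tibble with one row per grid cell (row-major from the
#' top-left) and columns `row`, `col`, `x`, `y` (cell centres) and `value`.
#' `NA` values mark nodata cells ("no measurement possible"); a measured or
#' derived zero exposure is stored as `0`, a distinction that matters for
#' background handling during standardization.
#'
#' @param grid A `referent_grid`.
#' @param values Numeric vector (row-major, length `n_rows * n_cols`) or a
#'   matrix with `n_rows` rows; `NA` = nodata.
#' @param units Free-text units label.
#' @param name Free-text layer name.
#' @return A `raster_field` tibble.
#' @export
raster_field <- function(grid, values, units = "", name = "") {
  stopifnot(inherits(grid, "referent_grid"))
  if (is.matrix(values)) {
    stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
    values <- as.vector(t(values)) # row-major
  }
  if (length(values) != grid_n_cells(grid)) {
    abort("`values` length does not match the grid cell count.")
  }
  if (any(!is.na(values) & !is.finite(values))) {
    abort("raster_field values must be finite wherever not nodata.")
  }
  out <- grid_cell_centres(grid)
  out$value <- as.numeric(values)
  new_raster_field(out, grid, units = units, name = name)
}

new_raster_field <- function(df, grid, units = "", name = "", class = character()) {
  structure(
    df,
    grid = grid, units = units, layer_name = name,
    class = c(class, "raster_field", class(tibble::tibble()))
  )
}

#' @export
print.raster_field <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf(
    "<raster_field '%s'> %s, units '%s', %d valid / %d cells\n",
    attr(x, "layer_name"), format(g), attr(x, "units"),
    sum(!is.na(x$value)), nrow(x)
  ))
  NextMethod()
}

#' Extract the value vector or matrix of a raster field
#'
#' @param field A `raster_field`.
#' @param matrix Return an `n_rows x n_cols` matrix instead of the row-major
#'   vector.
#' @return Numeric vector or matrix; `NA` = nodata.
#' @export
field_values <- function(field, matrix = FALSE) {
  stopifnot(inherits(field, "raster_field"))
  g <- attr(field, "grid")
  v <- field$value
  if (matrix) matrix(v, nrow = g$n_rows, ncol = g$n_cols, byrow = TRUE) else v
}

#' @rdname field_values
#' @export
field_grid <- function(field) attr(field, "grid")

# replace values, keep geometry/metadata
field_with_values <- function(field, values, name = attr(field, "layer_name"),
                              units = attr(field, "units")) {
  raster_field(attr(field, "grid"), values, units = units, name = name)
}

check_same_grid <- function(a, b) {
  if (!grid_same(attr(a, "grid"), attr(b, "grid"))) {
    abort("raster fields are not on the same referent grid.")
  }
  invisible(TRUE)
}
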
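# Planar geometry primitives used by the grid engine.
#
# All coordinates are planar metric (projected CRS assumed upstream); no
# geodesy. Polygons are single rings stored as two-column matrices (x, y),
# not closed (first vertex not repeated). Areas are unsigned.

# Shoelace signed area (positive = counter-clockwise).
poly_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

poly_area <- function(ring) abs(poly_signed_area(ring))

# Sutherland-Hodgman clip of a simple polygon against an axis-aligned
# rectangle. Correct for any simple polygon because the clip region is convex.
clip_poly_rect <- function(ring, xmin, xmax, ymin, ymax) {
  clip_half <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    ins <- inside(pts)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      a <- pts[i, ]; b <- pts[j, ]
      if (ins[i]) {
        out <- rbind(out, a)
        if (!ins[j]) out <- rbind(out, intersect(a, b))
      } else if (ins[j]) {
        out <- rbind(out, intersect(a, b))
      }
    }
    out
  }
  ix <- function(a, b, edge, coord) {
    # intersection of segment a-b with a vertical (coord=1) or horizontal line
    t <- (edge - a[coord]) / (b[coord] - a[coord])
    a + t * (b - a)
  }
  pts <- ring
  pts <- clip_half(pts, function(p) p[, 1] >= xmin, function(a, b) ix(a, b, xmin, 1))
  pts <- clip_half(pts, function(p) p[, 1] <= xmax, function(a, b) ix(a, b, xmax, 1))
  pts <- clip_half(pts, function(p) p[, 2] >= ymin, function(a, b) ix(a, b, ymin, 2))
  pts <- clip_half(pts, function(p) p[, 2] <= ymax, function(a, b) ix(a, b, ymax, 2))
  pts
}

# Area of polygon ∩ axis-aligned rectangle.
poly_rect_overlap_area <- function(ring, xmin, xmax, ymin, ymax) {
  bx <- range(ring[, 1]); by <- range(ring[, 2])
  if (bx[1] >= xmax || bx[2] <= xmin || by[1] >= ymax || by[2] <= ymin) return(0)
  clipped <- clip_poly_rect(ring, xmin, xmax, ymin, ymax)
  if (nrow(clipped) < 3) return(0)
  poly_area(clipped)
}

# Regular polygon approximating a disc, with the radius inflated so the
# polygon area equals pi * r^2 exactly (area-matched disc). With n = 512 the
# boundary deviates from the true circle by < 1e-4 * r.
disc_polygon <- function(cx, cy, r, n = 512L) {
  r_adj <- r * sqrt((2 * pi / n) / sin(2 * pi / n))
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + r_adj * cos(th), cy + r_adj * sin(th))
}

# Segment self-intersection test for polygon validity (O(n^2); rings are
# small). Shared endpoints of adjacent edges do not count.
poly_is_simple <- function(ring) {
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  seg <- function(i) {
    j <- if (i == n) 1L else i + 1L
    list(a = ring[i, ], b = ring[j, ])
  }
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  intersects <- function(p, q) {
    d1 <- cross(p$a, p$b, q$a); d2 <- cross(p$a, p$b, q$b)
    d3 <- cross(q$a, q$b, p$a); d4 <- cross(q$a, q$b, p$b)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (intersects(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

# Distance from points to a polyline (matrix of vertices).
dist_to_polyline <- function(px, py, line) {
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(line) - 1)) {
    ax <- line[i, 1]; ay <- line[i, 2]
    bx <- line[i + 1, 1]; by <- line[i + 1, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
    d <- pmin(d, sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2))
  }
  d
}
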
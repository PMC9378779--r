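# Planar polygon primitives.
#
# Polygons are N x 2 matrices of (x, y) vertices in micrometres, stored as an
# open ring (the closing edge back to the first vertex is implicit). Point
# containment uses the even-odd (crossing-number) rule with half-open edges,
# so a point exactly on a shared boundary is counted by exactly one of two
# abutting regions; which one wins is decided by the caller's region ordering.

#' Area of a simple polygon
#'
#' Shoelace formula; orientation-independent.
#'
#' @param poly numeric matrix with two columns (x, y vertices, micrometres).
#' @return Scalar area in square micrometres.
#' @export
polygon_area <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Even-odd point-in-polygon test
#'
#' Vectorised crossing-number test with half-open edges.
#'
#' @param px,py numeric vectors of point coordinates.
#' @param poly polygon matrix (x, y).
#' @return Logical vector, `TRUE` where the point lies inside.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (y[i] > py) != (y[j] > py)
    if (any(cross)) {
      t <- (py[cross] - y[i]) / (y[j] - y[i])
      xint <- x[i] + t * (x[j] - x[i])
      inside[cross] <- xor(inside[cross], px[cross] < xint)
    }
    j <- i
  }
  inside
}

#' Test whether a polygon is simple (non-self-intersecting)
#'
#' Pairwise segment-intersection check over non-adjacent edges; O(n^2), which
#' is ample for annotation polygons.
#'
#' @param poly polygon matrix (x, y).
#' @return Logical scalar.
#' @export
polygon_is_simple <- function(poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  a <- poly
  b <- poly[c(seq_len(n)[-1], 1L), , drop = FALSE]
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      # skip adjacent edges (they share an endpoint by construction)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_cross(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(p1, p2, p3, p4) {
  orient <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  o1 <- orient(p1, p2, p3); o2 <- orient(p1, p2, p4)
  o3 <- orient(p3, p4, p1); o4 <- orient(p3, p4, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(a, b, c) {
    orient(a, b, c) == 0 &&
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  on_seg(p1, p2, p3) || on_seg(p1, p2, p4) ||
    on_seg(p3, p4, p1) || on_seg(p3, p4, p2)
}

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2 || nrow(poly) < 3) {
    abort("a polygon must be a matrix with >= 3 rows and 2 columns (x, y)")
  }
  storage.mode(poly) <- "double"
  # drop an explicitly closed ring's duplicate last vertex
  if (isTRUE(all(poly[1, ] == poly[nrow(poly), ]))) {
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  poly
}

# Separable Gaussian blur with edge replication (two 1-D passes; avoids an
# FFT for small kernels on large images).
separable_gaussian_blur <- function(m, sigma = 2, half = 4) {
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_blur <- function(x) { # column-wise 1-D convolution, replicated edges
    n <- nrow(x)
    xp <- rbind(x[rep(1L, half), , drop = FALSE], x,
                x[rep(n, half), , drop = FALSE])
    y <- stats::filter(xp, k, sides = 2)
    matrix(y[(half + 1):(half + n), ], n, ncol(x))
  }
  t(pad_blur(t(pad_blur(m))))
}

# Regular n-gon approximations used by the synthetic layout generator.
ellipse_polygon <- function(cx, cy, a, b, angle = 0, n = 64) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x0 <- a * cos(t); y0 <- b * sin(t)
  cbind(cx + x0 * cos(angle) - y0 * sin(angle),
        cy + x0 * sin(angle) + y0 * cos(angle))
}

circle_polygon <- function(cx, cy, r, n = 64) ellipse_polygon(cx, cy, r, r, 0, n)

rect_polygon <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# Assign points to annotation regions. order = "innermost" resolves nesting
# by smallest containing polygon (epithelium before subepithelium before
# parenchyma); order = "file" takes the first containing region in file
# order. Ties fall back to file order in both cases. Returns the region row
# index per point (NA when uncontained).
assign_region_index <- function(px, py, annotation, order = c("innermost", "file")) {
  order <- match.arg(order)
  polys <- annotation$polygon
  if (length(polys) == 0) return(rep(NA_integer_, length(px)))
  areas <- vapply(polys, polygon_area, numeric(1))
  ord <- if (order == "innermost") order(areas, seq_along(polys)) else seq_along(polys)
  out <- rep(NA_integer_, length(px))
  todo <- rep(TRUE, length(px))
  for (k in ord) {
    if (!any(todo)) break
    hit <- todo
    hit[todo] <- point_in_polygon(px[todo], py[todo], polys[[k]])
    out[hit] <- k
    todo <- todo & !hit
  }
  out
}

# Compartment area actually owned by each region once nested regions are
# carved out (a region's polygon area minus the full areas of the maximal
# regions nested directly inside it). Nesting is detected by full vertex
# containment plus strictly smaller area.
region_effective_areas <- function(annotation) {
  polys <- annotation$polygon
  n <- length(polys)
  areas <- vapply(polys, polygon_area, numeric(1))
  if (n == 0) return(numeric(0))
  nested_in <- function(inner, outer) {
    if (areas[inner] >= areas[outer]) return(FALSE)
    all(point_in_polygon(polys[[inner]][, 1], polys[[inner]][, 2], polys[[outer]]))
  }
  eff <- areas
  for (i in seq_len(n)) {
    inside_i <- which(vapply(seq_len(n), function(j) j != i && nested_in(j, i), logical(1)))
    if (length(inside_i) == 0) next
    # only subtract maximal nested regions to avoid double counting
    maximal <- inside_i[vapply(inside_i, function(j) {
      !any(vapply(setdiff(inside_i, j), function(k) nested_in(j, k), logical(1)))
    }, logical(1))]
    eff[i] <- areas[i] - sum(areas[maximal])
  }
  eff
}
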
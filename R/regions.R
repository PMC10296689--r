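# Tissue geometry: tumour-nest polygons, compartment calls, invasive margin.

#' Region geometry for one ROI
#'
#' Holds the tumour-nest polygons and rectangular bounds of a region of
#' interest. The tumour region is the union of the polygons; the tumour/host
#' border is the topological boundary of that union (with disjoint nests,
#' the set of polygon rings). Coordinates are micrometres with the origin at
#' the ROI lower-left corner, y increasing upward.
#'
#' @param roi_id Character scalar identifying the ROI.
#' @param tumour_polygons List of n-by-2 numeric matrices (x, y vertices in
#'   order, ring not closed; at least 3 vertices each). May be empty for an
#'   ROI with no malignant nest.
#' @param roi_bounds Numeric length-4 vector `c(xmin, ymin, xmax, ymax)`.
#' @return An object of class `region_geometry`.
#' @export
region_geometry <- function(roi_id, tumour_polygons = list(),
                            roi_bounds = c(0, 0, 1000, 1000)) {
  if (!is.numeric(roi_bounds) || length(roi_bounds) != 4 ||
      roi_bounds[3] <= roi_bounds[1] || roi_bounds[4] <= roi_bounds[2]) {
    tme_config_error("roi_bounds", "must be c(xmin, ymin, xmax, ymax) with positive extent")
  }
  tumour_polygons <- lapply(tumour_polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 3 || anyNA(p)) {
      tme_config_error("tumour_polygons", "must be n x 2 numeric matrices with n >= 3")
    }
    # drop a duplicated closing vertex
    if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    unname(p)
  })
  structure(list(roi_id = roi_id, tumour_polygons = tumour_polygons,
                 roi_bounds = as.numeric(roi_bounds)),
            class = "region_geometry")
}

#' @export
print.region_geometry <- function(x, ...) {
  cat(sprintf("<region_geometry> ROI %s: %d tumour nest(s), bounds [%g, %g] x [%g, %g] um\n",
              x$roi_id, length(x$tumour_polygons),
              x$roi_bounds[1], x$roi_bounds[3], x$roi_bounds[2], x$roi_bounds[4]))
  invisible(x)
}

#' Invasive-margin configuration
#'
#' @param im_half_width Half-width of the invasive-margin band in
#'   micrometres on each side of the tumour/host border (default 250).
#' @return An object of class `region_config`.
#' @export
region_config <- function(im_half_width = 250) {
  check_number(im_half_width, "im_half_width", lower = 0, strict_lower = TRUE)
  structure(list(im_half_width = im_half_width), class = "region_config")
}

# Even-odd point-in-polygon for a vector of points against one ring.
# Boundary points are not guaranteed a side here; callers wanting the
# closed-region convention combine with a zero-distance test.
points_in_ring <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    spans <- (yi > y) != (yj > y)
    if (any(spans)) {
      xcross <- (xj - xi) * (y - yi) / (yj - yi) + xi
      inside <- xor(inside, spans & (x < xcross))
    }
    j <- i
  }
  inside
}

# Minimal distance from points to the edges of one ring.
dist_to_ring <- function(x, y, poly) {
  n <- nrow(poly)
  best <- rep(Inf, length(x))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    t <- if (len2 > 0) pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / len2)) else 0
    px <- ax + t * vx; py <- ay + t * vy
    best <- pmin(best, sqrt((x - px)^2 + (y - py)^2))
    j <- i
  }
  best
}

check_in_bounds <- function(x, y, geometry) {
  b <- geometry$roi_bounds
  bad <- which(x < b[1] | x > b[3] | y < b[2] | y > b[4] | is.na(x) | is.na(y))
  if (length(bad)) {
    tme_error(sprintf("%d cell(s) outside ROI bounds (first at x=%g, y=%g)",
                      length(bad), x[bad[1]], y[bad[1]]),
              class = "tme_bounds_error")
  }
}

#' Assign tumour/stroma compartment
#'
#' A point is `tumour` iff it lies inside, or on the boundary of, the union
#' of the tumour-nest polygons (closed-region convention: malignant nests
#' include their rim), else `stroma`.
#'
#' @param x,y Numeric coordinate vectors (micrometres).
#' @param geometry A [region_geometry()].
#' @param boundary_eps Numerical tolerance for the on-boundary test, in
#'   micrometres.
#' @return Character vector, `"tumour"` or `"stroma"` per point.
#' @examples
#' disc <- make_disc_polygon(0, 0, 100)
#' g <- region_geometry("r", list(disc), c(-500, -500, 500, 500))
#' assign_compartment(c(0, 200), c(0, 0), g)
#' @export
assign_compartment <- function(x, y, geometry, boundary_eps = 1e-9) {
  check_in_bounds(x, y, geometry)
  inside <- rep(FALSE, length(x))
  for (poly in geometry$tumour_polygons) {
    inside <- inside | points_in_ring(x, y, poly) |
      (dist_to_ring(x, y, poly) <= boundary_eps)
  }
  ifelse(inside, "tumour", "stroma")
}

#' Signed distance to the tumour/host border
#'
#' Unsigned minimal Euclidean distance from each point to the border (the
#' rings of the tumour-nest polygons), negated for points inside the tumour
#' region. Zero on the border itself.
#'
#' @inheritParams assign_compartment
#' @return Numeric vector of signed distances in micrometres (negative in
#'   tumour, positive in stroma).
#' @export
border_distance <- function(x, y, geometry) {
  if (!length(geometry$tumour_polygons)) {
    tme_error(sprintf("ROI %s has an empty tumour border; distance undefined",
                      geometry$roi_id),
              class = "tme_undefined_region_error")
  }
  check_in_bounds(x, y, geometry)
  d <- rep(Inf, length(x))
  inside <- rep(FALSE, length(x))
  for (poly in geometry$tumour_polygons) {
    d <- pmin(d, dist_to_ring(x, y, poly))
    inside <- inside | points_in_ring(x, y, poly)
  }
  ifelse(inside | d <= 1e-9, -d, d)
}

#' Assign invasive-margin labels
#'
#' The invasive margin is the band within `im_half_width` micrometres
#' (inclusive) on each side of the tumour/host border. Points in the band
#' on the tumour side are `IM_T`, on the stroma side `IM_S`, outside the
#' band `NONE`.
#'
#' @inheritParams assign_compartment
#' @param config A [region_config()].
#' @return Character vector in `c("IM_T", "IM_S", "NONE")`.
#' @export
assign_invasive_margin <- function(x, y, geometry, config = region_config()) {
  d <- border_distance(x, y, geometry)
  in_band <- abs(d) <= config$im_half_width
  ifelse(!in_band, "NONE", ifelse(d <= 0, "IM_T", "IM_S"))
}

#' Regular polygon approximating a disc
#'
#' @param cx,cy Centre (micrometres).
#' @param r Radius (micrometres).
#' @param n_vertices Number of vertices (default 64); the first vertex lies
#'   at angle 0, i.e. at `(cx + r, cy)`.
#' @return An n-by-2 vertex matrix usable in [region_geometry()].
#' @export
make_disc_polygon <- function(cx, cy, r, n_vertices = 64) {
  check_number(r, "r", lower = 0, strict_lower = TRUE)
  theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  cbind(cx + r * cos(theta), cy + r * sin(theta))
}

shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Area of a named region within an ROI
#'
#' Areas for `all`, `tumour` and `stroma` are exact (shoelace on the nest
#' polygons, which the generator guarantees disjoint); invasive-margin
#' areas are computed by deterministic grid quadrature over the ROI.
#'
#' @param geometry A [region_geometry()].
#' @param region One of `"ALL"`, `"TUMOUR"`, `"STROMA"`, `"IM_T"`, `"IM_S"`.
#' @param config A [region_config()] (used for the IM regions).
#' @param grid_n Quadrature resolution per axis for the IM regions.
#' @return Area in square millimetres.
#' @export
region_area <- function(geometry, region = c("ALL", "TUMOUR", "STROMA", "IM_T", "IM_S"),
                        config = region_config(), grid_n = 200) {
  region <- match.arg(region)
  region_areas(geometry, config, grid_n)[[region]]
}

# one-pass computation of all region areas (mm^2) for an ROI; the invasive
# margin is quadratured on a single grid classification
region_areas <- function(geometry, config = region_config(), grid_n = 200) {
  b <- geometry$roi_bounds
  um2_to_mm2 <- 1e-6
  total <- (b[3] - b[1]) * (b[4] - b[2])
  tum <- sum(vapply(geometry$tumour_polygons, shoelace_area, numeric(1)))
  out <- c(ALL = total * um2_to_mm2, TUMOUR = tum * um2_to_mm2,
           STROMA = (total - tum) * um2_to_mm2, IM_T = 0, IM_S = 0)
  if (length(geometry$tumour_polygons)) {
    gx <- seq(b[1], b[3], length.out = grid_n + 1)
    gx <- (gx[-1] + gx[-length(gx)]) / 2
    gy <- seq(b[2], b[4], length.out = grid_n + 1)
    gy <- (gy[-1] + gy[-length(gy)]) / 2
    pts <- expand.grid(x = gx, y = gy)
    lab <- assign_invasive_margin(pts$x, pts$y, geometry, config)
    out["IM_T"] <- mean(lab == "IM_T") * total * um2_to_mm2
    out["IM_S"] <- mean(lab == "IM_S") * total * um2_to_mm2
  }
  out
}

#' Annotate a cell table with compartment and invasive-margin labels
#'
#' Applies [assign_compartment()] and [assign_invasive_margin()] per ROI.
#' ROIs whose geometry has no tumour polygon get compartment `stroma` and
#' margin `NONE` throughout. When a cell's ROI has no geometry at all, an
#' existing `compartment` column is kept as given and the invasive margin
#' is left `NONE` with a warning (supports exports without polygons).
#'
#' @param cells Per-cell table with `roi_id`, `x_um`, `y_um`.
#' @param geometries Named list of [region_geometry()] keyed by `roi_id`.
#' @param config A [region_config()].
#' @return `cells` with `compartment` and `im_label` columns.
#' @export
annotate_regions <- function(cells, geometries, config = region_config()) {
  comp <- cells[["compartment"]] %||% rep(NA_character_, nrow(cells))
  im <- rep("NONE", nrow(cells))
  missing_geom <- FALSE
  for (rid in unique(cells$roi_id)) {
    idx <- which(cells$roi_id == rid)
    geom <- geometries[[rid]]
    if (is.null(geom)) {
      missing_geom <- TRUE
      next
    }
    x <- cells$x_um[idx]; y <- cells$y_um[idx]
    if (!length(geom$tumour_polygons)) {
      comp[idx] <- "stroma"
      next
    }
    # one signed-distance pass gives both the compartment and the IM label
    d <- border_distance(x, y, geom)
    comp[idx] <- ifelse(d <= 0, "tumour", "stroma")
    im[idx] <- ifelse(abs(d) > config$im_half_width, "NONE",
                      ifelse(d <= 0, "IM_T", "IM_S"))
  }
  if (missing_geom) {
    if (all(is.na(comp))) {
      tme_error("no geometry and no compartment column: compartments unavailable",
                class = "tme_undefined_region_error")
    }
    warning("some ROIs lack geometry; using supplied compartment labels and skipping invasive-margin analysis for them")
  }
  cells$compartment <- comp
  cells$im_label <- im
  cells
}
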
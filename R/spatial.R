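# Spatial compartments and density estimation.
#
# The tumor is a simple polygon (coordinates in micrometres); the invasive
# margin is a polyline, by default the tumor boundary. The IM compartment is
# the closed Minkowski band of the margin (all points within `halfwidth` of
# it, on both sides); the CT compartment is the tumor polygon minus that
# band. Densities are cell counts divided by compartment area, reported in
# cells/mm^2 (1 mm^2 = 1e6 um^2).
#
# Regions are closed sets: boundary points count as inside. Polygon areas are
# exact (shoelace); band and difference areas are evaluated by midpoint-grid
# quadrature, which is resolution-independent up to a documented grid error.

#' Spatial regions for slide compartments
#'
#' Constructors for the region algebra used to define the center-of-tumor
#' (CT) and invasive-margin (IM) compartments. `region_polygon` wraps a
#' simple polygon; [im_band()] builds the closed band of a polyline;
#' `region_difference` subtracts one region from another.
#'
#' @param coords two-column matrix of vertex coordinates in micrometres
#'   (polygon closed implicitly; last vertex must not repeat the first).
#' @return a `region` object.
#' @export
region_polygon <- function(coords) {
  coords <- as.matrix(coords)
  fail_if(ncol(coords) != 2, "coords must have two columns (x, y in um)")
  fail_if(nrow(coords) < 3, "a polygon needs at least 3 vertices")
  fail_if(any(!is.finite(coords)), "coordinates must be finite")
  structure(list(type = "polygon", coords = coords),
            class = "region")
}

#' Invasive-margin band of a polyline
#'
#' The closed Minkowski band: every point within `halfwidth` micrometres of
#' the margin polyline, on both sides (the peritumoral and the intratumoral
#' side). A closed margin (first vertex repeated, or `closed = TRUE`) yields
#' an annular band.
#'
#' @param margin two-column matrix of polyline vertices (um), at least 2.
#' @param halfwidth band half-width in um, strictly positive. The default of
#'   360 um follows common Immunoscore practice for the margin region.
#' @param closed logical; join the last vertex back to the first.
#' @return a `region` object.
#' @export
im_band <- function(margin, halfwidth = 360, closed = FALSE) {
  margin <- as.matrix(margin)
  fail_if(ncol(margin) != 2, "margin must have two columns (x, y in um)")
  fail_if(nrow(margin) < 2, "margin polyline needs at least 2 vertices")
  fail_if(any(!is.finite(margin)), "coordinates must be finite")
  fail_if(!is.finite(halfwidth) || halfwidth <= 0, "halfwidth must be > 0")
  if (closed && !all(margin[1, ] == margin[nrow(margin), ])) {
    margin <- rbind(margin, margin[1, ])
  }
  structure(list(type = "band", coords = margin, halfwidth = halfwidth),
            class = "region")
}

#' @rdname region_polygon
#' @param a,b regions; the result contains points of `a` not interior to `b`.
#' @export
region_difference <- function(a, b) {
  stopifnot(inherits(a, "region"), inherits(b, "region"))
  structure(list(type = "difference", a = a, b = b), class = "region")
}

#' Center-of-tumor compartment
#'
#' CT = tumor polygon minus the invasive-margin band. Errors when the band
#' swallows the whole tumor (the CT would be empty), which indicates the
#' band half-width is too large for the lesion.
#'
#' @param tumor a polygon `region` (the tumor outline).
#' @param band a band `region` from [im_band()].
#' @return a `region` object whose area has been checked to be positive.
#' @export
ct_region <- function(tumor, band) {
  stopifnot(inherits(tumor, "region"), tumor$type == "polygon",
            inherits(band, "region"))
  ct <- region_difference(tumor, band)
  a <- region_area(ct)
  fail_if(a <= 0,
          "CT region is empty after subtracting the IM band; use a smaller halfwidth")
  ct$area_mm2 <- a
  ct
}

# Bounding box (xmin, xmax, ymin, ymax) of a region, in um.
region_bbox <- function(region) {
  switch(region$type,
    polygon = c(range(region$coords[, 1]), range(region$coords[, 2])),
    band = {
      h <- region$halfwidth
      c(range(region$coords[, 1]) + c(-h, h),
        range(region$coords[, 2]) + c(-h, h))
    },
    difference = region_bbox(region$a)
  )
}

#' Region membership and area
#'
#' `region_contains` tests points against a region (closed convention:
#' boundary points are inside). `region_area` returns the area in mm^2 --
#' exact for polygons, midpoint-grid quadrature for bands and differences.
#'
#' @param region a `region`.
#' @param pts two-column matrix of points (um).
#' @return `region_contains`: logical vector; `region_area`: scalar mm^2.
#' @export
region_contains <- function(region, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (nrow(pts) == 0) return(logical(0))
  switch(region$type,
    polygon = point_in_polygon(pts, region$coords),
    band = dist_to_polyline_le(pts, region$coords, region$halfwidth),
    difference = region_contains(region$a, pts) &
                 !region_contains(region$b, pts)
  )
}

#' @rdname region_contains
#' @param n_grid number of quadrature points along the longer bounding-box
#'   axis (default 1024); grid error scales as perimeter x spacing.
#' @export
region_area <- function(region, n_grid = 1024) {
  if (region$type == "polygon") {
    return(polygon_area_um2(region$coords) / 1e6)
  }
  if (!is.null(region$area_mm2)) return(region$area_mm2)
  bb <- region_bbox(region)
  wx <- bb[2] - bb[1]
  wy <- bb[4] - bb[3]
  sp <- max(wx, wy) / n_grid
  xs <- seq(bb[1] + sp / 2, bb[2], by = sp)
  ys <- seq(bb[3] + sp / 2, bb[4], by = sp)
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  inside <- region_contains(region, grid)
  sum(inside) * sp^2 / 1e6
}

# Shoelace formula, um^2; orientation-independent.
polygon_area_um2 <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Ray-casting point-in-polygon, boundary-inclusive.
point_in_polygon <- function(pts, coords) {
  px <- pts[, 1]; py <- pts[, 2]
  n <- nrow(coords)
  x <- coords[, 1]; y <- coords[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- x[i]; y1 <- y[i]; x2 <- xn[i]; y2 <- yn[i]
    # boundary test: point within numerical tolerance of the segment
    on_edge <- on_edge | point_on_segment(px, py, x1, y1, x2, y2)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses & !is.na(crosses))
  }
  inside | on_edge
}

point_on_segment <- function(px, py, x1, y1, x2, y2, tol = 1e-9) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  if (len2 == 0) return((px - x1)^2 + (py - y1)^2 <= tol^2)
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(1, pmax(0, t))
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2 <= tol^2
}

# TRUE for points within distance h of the polyline. Each segment only
# examines points inside its h-expanded bounding box that are not yet
# claimed, so cost stays near the number of points actually in the band.
dist_to_polyline_le <- function(pts, line, h) {
  px <- pts[, 1]; py <- pts[, 2]
  inside <- rep(FALSE, length(px))
  h2 <- h^2
  for (i in seq_len(nrow(line) - 1)) {
    x1 <- line[i, 1]; y1 <- line[i, 2]
    x2 <- line[i + 1, 1]; y2 <- line[i + 1, 2]
    cand <- which(!inside &
                    px >= min(x1, x2) - h & px <= max(x1, x2) + h &
                    py >= min(y1, y2) - h & py <= max(y1, y2) + h)
    if (length(cand) == 0) next
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx^2 + dy^2
    if (len2 == 0) {
      d2 <- (px[cand] - x1)^2 + (py[cand] - y1)^2
    } else {
      t <- ((px[cand] - x1) * dx + (py[cand] - y1) * dy) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (px[cand] - (x1 + t * dx))^2 + (py[cand] - (y1 + t * dy))^2
    }
    inside[cand[d2 <= h2]] <- TRUE
  }
  inside
}

#' Mean cell density over a region
#'
#' Counts the points falling inside the region (closed convention) and
#' divides by its area; this is the mean density the digital-pathology
#' quantification reports per marker and compartment.
#'
#' @param points two-column matrix of cell coordinates (um); may be empty.
#' @param region a `region` with positive area.
#' @param marker,compartment optional labels carried into the result.
#' @return a `density_measurement` list: `marker`, `compartment`,
#'   `cell_count`, `area_mm2`, `density` (cells/mm^2, exactly
#'   `cell_count / area_mm2`).
#' @export
mean_density <- function(points, region, marker = NA_character_,
                         compartment = NA_character_) {
  area <- region_area(region)
  fail_if(area <= 0, "region has zero area")
  if (is.null(points) || length(points) == 0) {
    count <- 0L
  } else {
    points <- matrix(as.numeric(points), ncol = 2)
    count <- sum(region_contains(region, points))
  }
  structure(list(marker = marker, compartment = compartment,
                 cell_count = as.integer(count), area_mm2 = area,
                 density = count / area),
            class = "density_measurement")
}

#' @export
print.density_measurement <- function(x, ...) {
  cat(sprintf("%s %s: %d cells / %.4f mm^2 = %.1f cells/mm^2\n",
              x$marker %||% "?", x$compartment %||% "?",
              x$cell_count, x$area_mm2, x$density))
  invisible(x)
}

# Uniform points in a region by rejection from its bounding box.
sample_in_region <- function(region, n, area_mm2 = NULL) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  bb <- region_bbox(region)
  bbox_mm2 <- (bb[2] - bb[1]) * (bb[4] - bb[3]) / 1e6
  acc <- (area_mm2 %||% region_area(region)) / bbox_mm2
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) / max(acc, 0.05)) + 16
    cand <- cbind(stats::runif(m, bb[1], bb[2]), stats::runif(m, bb[3], bb[4]))
    out <- rbind(out, cand[region_contains(region, cand), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate a stained slide as marked point patterns
#'
#' Draws CD3+ and CD8+ cell positions as independent homogeneous Poisson
#' point processes over the CT and IM compartments, at the programmed
#' intensity (cells/mm^2) per marker and compartment. This emulates the
#' coordinate-level output of digital image analysis; no pixel-level imaging
#' is modelled, since mean density is resolution-independent.
#'
#' @param tumor polygon `region`: the tumor outline.
#' @param intensities named list `list(CD3 = c(CT =, IM =), CD8 = ...)`, in
#'   cells/mm^2, all nonnegative.
#' @param margin polyline matrix (um); default the tumor boundary (closed).
#' @param halfwidth IM band half-width in um (default 360).
#' @param seed integer seed; identical seeds give identical scenes.
#' @return a `slide_scene` list: `tumor`, `margin`, `halfwidth`, `band`,
#'   `ct` (regions), and `cells`, a data frame with columns `marker`, `x`,
#'   `y` (um). Compartment-of-origin is deliberately not recorded: it is
#'   recovered geometrically by [mean_density()].
#' @examples
#' sq <- region_polygon(cbind(c(0, 4000, 4000, 0), c(0, 0, 4000, 4000)))
#' sc <- simulate_slide(sq, list(CD3 = c(CT = 884, IM = 1409),
#'                               CD8 = c(CT = 358, IM = 535)), seed = 1)
#' mean_density(as.matrix(sc$cells[sc$cells$marker == "CD3", c("x", "y")]),
#'              sc$ct, "CD3", "CT")
#' @export
simulate_slide <- function(tumor, intensities, margin = NULL,
                           halfwidth = 360, seed = NULL) {
  stopifnot(inherits(tumor, "region"), tumor$type == "polygon")
  for (mk in names(intensities)) {
    fail_if(any(intensities[[mk]] < 0), "intensities must be nonnegative")
    fail_if(!all(c("CT", "IM") %in% names(intensities[[mk]])),
            "intensities for %s must name CT and IM", mk)
  }
  if (is.null(margin)) margin <- rbind(tumor$coords, tumor$coords[1, ])
  band <- im_band(margin, halfwidth = halfwidth)
  ct <- ct_region(tumor, band)
  band$area_mm2 <- region_area(band)
  with_seed(seed, {
    cells <- do.call(rbind, lapply(names(intensities), function(mk) {
      pts <- rbind(
        sample_in_region(ct, stats::rpois(1, intensities[[mk]][["CT"]] *
                                               ct$area_mm2), ct$area_mm2),
        sample_in_region(band, stats::rpois(1, intensities[[mk]][["IM"]] *
                                                 band$area_mm2), band$area_mm2))
      if (nrow(pts) == 0) {
        data.frame(marker = character(0), x = numeric(0), y = numeric(0))
      } else {
        data.frame(marker = mk, x = pts[, 1], y = pts[, 2])
      }
    }))
    structure(list(tumor = tumor, margin = margin, halfwidth = halfwidth,
                   band = band, ct = ct, cells = cells),
              class = "slide_scene")
  })
}

#' Quantify a simulated or annotated slide
#'
#' Applies [mean_density()] to every marker x compartment of a slide scene,
#' yielding the four densities a patient record carries.
#'
#' @param scene a `slide_scene` from [simulate_slide()] (or assembled from
#'   annotation files).
#' @return data frame with columns `marker`, `compartment`, `cell_count`,
#'   `area_mm2`, `density`.
#' @export
quantify_slide <- function(scene) {
  stopifnot(inherits(scene, "slide_scene"))
  rows <- list()
  for (mk in unique(scene$cells$marker)) {
    pts <- as.matrix(scene$cells[scene$cells$marker == mk, c("x", "y")])
    for (comp in c("CT", "IM")) {
      reg <- if (comp == "CT") scene$ct else scene$band
      d <- mean_density(pts, reg, marker = mk, compartment = comp)
      rows[[length(rows) + 1]] <- as.data.frame(unclass(d))
    }
  }
  do.call(rbind, rows)
}
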
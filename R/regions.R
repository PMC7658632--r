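# Region-level geometry: effective areas and the invasive-margin band.
#
# Conventions: annotated polygons of one class are pairwise disjoint;
# excluded regions (necrosis, artefacts) lie within the annotated tissue and
# are subtracted before any area or density is computed.  Areas are reported
# in mm^2 (1 mm^2 = 1e6 um^2).

UM2_PER_MM2 <- 1e6

excluded_overlap_area <- function(class_rings, excl_rings) {
  # exact via convex clipping when the excluded outer ring is convex and
  # hole-free, numeric grid integration otherwise
  if (length(excl_rings) == 1L && is_convex_ring(excl_rings[[1L]])) {
    return(polygon_convex_intersection_area(class_rings, excl_rings[[1L]]))
  }
  bb1 <- rings_bbox(class_rings)
  bb2 <- rings_bbox(excl_rings)
  bb <- c(max(bb1[1L], bb2[1L]), max(bb1[2L], bb2[2L]),
          min(bb1[3L], bb2[3L]), min(bb1[4L], bb2[4L]))
  if (bb[1L] >= bb[3L] || bb[2L] >= bb[4L]) return(0)
  res <- max(min(bb[3L] - bb[1L], bb[4L] - bb[2L]) / 400, 0.25)
  grid_area(function(px, py)
    points_in_polygon(px, py, class_rings) &
      points_in_polygon(px, py, excl_rings), bb, res)
}

#' Effective area of a region class
#'
#' Sum of the areas of all polygons of the class (holes subtracted), minus
#' any overlap with excluded regions.
#'
#' @param regions A [region_set()].
#' @param region_class `"tumor"` or `"normal"`.
#' @return Area in mm^2.
#' @export
region_area <- function(regions, region_class = "tumor") {
  polys <- region_polys(regions, region_class)
  if (!length(polys))
    stop("no polygon of class '", region_class, "' in region set")
  excl <- region_polys(regions, "excluded")
  a <- sum(vapply(polys, polygon_area, 0))
  for (e in excl) for (p in polys) a <- a - excluded_overlap_area(p, e)
  if (a <= 0) stop("effective '", region_class, "' area is zero")
  a / UM2_PER_MM2
}

#' Point membership in a region class (excluded regions subtracted)
#'
#' @param regions A [region_set()].
#' @param region_class Region class.
#' @param x,y Point coordinates, micrometres.
#' @return Logical vector.
#' @export
points_in_region <- function(regions, region_class, x, y) {
  polys <- region_polys(regions, region_class)
  inside <- points_in_any_polygon(x, y, polys)
  excl <- region_polys(regions, "excluded")
  if (length(excl)) inside <- inside & !points_in_any_polygon(x, y, excl)
  inside
}

#' Restrict a cell table to a region class
#'
#' @inheritParams points_in_region
#' @param cells A [cell_table()].
#' @return The subset of `cells` inside the class region.
#' @export
clip_cells_to_region <- function(cells, regions, region_class = "tumor") {
  keep <- points_in_region(regions, region_class, cells$x, cells$y)
  cells[keep, , drop = FALSE]
}

#' Derive the invasive-margin band
#'
#' The band straddles the tumor boundary: all points within `half_width` of
#' the boundary (so `half_width` into the tumor and `half_width` into the
#' surrounding tissue, 500 um total at the default), intersected with the
#' annotated tissue (tumor plus normal) and with excluded regions removed.
#' The band is represented implicitly by its distance predicate; its area is
#' integrated on a regular grid at resolution `res` (default
#' `half_width / 50`, i.e. 5 um at the 250 um default).
#'
#' @param regions A [region_set()] with at least one tumor polygon.
#' @param half_width Band half-width in micrometres (> 0).
#' @param res Grid resolution in micrometres for area integration.
#' @return A `margin_band` object with elements `half_width`, `area_mm2` and
#'   a membership predicate usable via [points_in_band()].
#' @export
derive_invasive_margin <- function(regions, half_width = 250,
                                   res = max(half_width / 50, 0.5)) {
  if (half_width <= 0) stop("half_width must be > 0")
  tumor <- region_polys(regions, "tumor")
  if (!length(tumor)) stop("no tumor polygon in region set")
  if (sum(vapply(tumor, polygon_area, 0)) <= 0)
    stop("tumor polygon is degenerate (zero area)")
  tissue <- c(tumor, region_polys(regions, "normal"))
  excl <- region_polys(regions, "excluded")
  boundary_rings <- unlist(tumor, recursive = FALSE)
  band <- structure(list(tumor = tumor, tissue = tissue, excluded = excl,
                         boundary_rings = boundary_rings,
                         half_width = half_width),
                    class = "margin_band")
  bb <- rings_bbox(boundary_rings)
  bb <- bb + c(-1, -1, 1, 1) * half_width
  band$area_mm2 <- grid_area(function(px, py) points_in_band(band, px, py),
                             bb, res) / UM2_PER_MM2
  band
}

#' Band membership test
#'
#' @param band A `margin_band` from [derive_invasive_margin()].
#' @param x,y Coordinates in micrometres.
#' @return Logical vector: within `half_width` of the tumor boundary, inside
#'   annotated tissue, outside excluded regions.
#' @export
points_in_band <- function(band, x, y) {
  ok <- dist_to_rings(x, y, band$boundary_rings) <= band$half_width
  if (any(ok))
    ok[ok] <- points_in_any_polygon(x[ok], y[ok], band$tissue)
  if (length(band$excluded) && any(ok))
    ok[ok] <- !points_in_any_polygon(x[ok], y[ok], band$excluded)
  ok
}

#' @export
print.margin_band <- function(x, ...) {
  cat(sprintf("<margin_band> half-width %g um, area %.4f mm^2\n",
              x$half_width, x$area_mm2))
  invisible(x)
}
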
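# Hexagonal tessellation of the tumor ROI.
#
# Pointy-top hexagons with long (vertex-to-vertex) diagonal `diagonal`,
# i.e. circumradius R = diagonal / 2.  Lattice spacing: sqrt(3) R
# horizontally, 1.5 R vertically, odd rows offset by half a step; the
# Voronoi cell of each lattice center is exactly the pointy-top hexagon, so
# point-to-tile assignment and tile polygons agree by construction.  The
# grid is anchored at the lower-left corner of the ROI bounding box.

hex_vertices <- function(cx, cy, R) {
  ang <- pi / 180 * (90 + 60 * 0:5)
  cbind(cx + R * cos(ang), cy + R * sin(ang))
}

#' Full area of one hexagon tile
#' @param diagonal Long diagonal in micrometres.
#' @return Area in um^2, (3*sqrt(3)/2) * (diagonal/2)^2.
#' @export
hex_full_area <- function(diagonal) 3 * sqrt(3) / 2 * (diagonal / 2)^2

#' Build a hexagonal grid over the tumor ROI
#'
#' Tiles are retained when their intersection with the tumor ROI (excluded
#' regions subtracted) covers at least `min_coverage` of the full hexagon
#' area; the clipped intersection area is stored per tile, and per-tile
#' densities downstream use it, which avoids inflating densities on edge
#' tiles.
#'
#' @param regions A [region_set()] with a tumor polygon.
#' @param diagonal Long hexagon diagonal in micrometres (default 250).
#' @param min_coverage Minimum covered fraction for a tile to be retained.
#' @return A `hex_grid` with a `tiles` data frame (`tile`, `row`, `col`,
#'   `cx`, `cy`, `clipped_area_mm2`) and the lattice parameters.
#' @export
build_hex_grid <- function(regions, diagonal = 250, min_coverage = 0.5) {
  if (diagonal <= 0) stop("diagonal must be > 0")
  tumor <- region_polys(regions, "tumor")
  if (!length(tumor)) stop("no tumor polygon in region set")
  excl <- region_polys(regions, "excluded")
  R <- diagonal / 2
  hs <- sqrt(3) * R
  vs <- 1.5 * R
  bb <- rings_bbox(unlist(tumor, recursive = FALSE))
  x0 <- bb[[1L]]; y0 <- bb[[2L]]
  rows <- seq.int(floor((bb[[2L]] - y0 - R) / vs),
                  ceiling((bb[[4L]] - y0 + R) / vs))
  full <- hex_full_area(diagonal)
  rec <- list()
  for (r in rows) {
    off <- (abs(r) %% 2L) * hs / 2
    cols <- seq.int(floor((bb[[1L]] - x0 - off - hs / 2) / hs),
                    ceiling((bb[[3L]] - x0 - off + hs / 2) / hs))
    for (cc in cols) {
      cx <- x0 + off + cc * hs
      cy <- y0 + r * vs
      hexv <- hex_vertices(cx, cy, R)
      a <- sum(vapply(tumor, polygon_convex_intersection_area, 0,
                      clip = hexv))
      if (a <= 0) next
      for (e in excl)
        a <- a - polygon_convex_intersection_area(e, hexv)
      # small tolerance so tiles at exactly the coverage threshold are
      # retained consistently regardless of coordinate offsets
      if (a / full >= min_coverage - 1e-9)
        rec[[length(rec) + 1L]] <- c(r, cc, cx, cy, a)
    }
  }
  if (!length(rec)) {
    warning("ROI smaller than one retained tile: empty grid")
    tiles <- data.frame(tile = integer(0), row = integer(0),
                        col = integer(0), cx = numeric(0), cy = numeric(0),
                        clipped_area_mm2 = numeric(0))
  } else {
    m <- do.call(rbind, rec)
    o <- order(m[, 1L], m[, 2L])
    m <- m[o, , drop = FALSE]
    tiles <- data.frame(tile = seq_len(nrow(m)), row = as.integer(m[, 1L]),
                        col = as.integer(m[, 2L]), cx = m[, 3L],
                        cy = m[, 4L],
                        clipped_area_mm2 = pmin(m[, 5L], full) / UM2_PER_MM2)
  }
  structure(list(tiles = tiles, diagonal = diagonal, R = R, hs = hs,
                 vs = vs, x0 = x0, y0 = y0,
                 full_area_mm2 = full / UM2_PER_MM2,
                 tile_map = stats::setNames(tiles$tile,
                                            paste(tiles$row, tiles$col))),
            class = "hex_grid")
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf(
    "<hex_grid> %d tiles, diagonal %g um (tile area %.5f mm^2)\n",
    nrow(x$tiles), x$diagonal, x$full_area_mm2))
  invisible(x)
}

#' @export
plot.hex_grid <- function(x, fill = NULL, main = "hex grid", ...) {
  t <- x$tiles
  if (!nrow(t)) return(invisible(x))
  graphics::plot(NA, xlim = range(t$cx) + c(-1, 1) * x$R,
                 ylim = rev(range(t$cy) + c(-1, 1) * x$R),
                 asp = 1, xlab = "x (um)", ylab = "y (um)", main = main, ...)
  cols <- if (is.null(fill)) rep(NA, nrow(t)) else fill
  for (i in seq_len(nrow(t))) {
    v <- hex_vertices(t$cx[i], t$cy[i], x$R)
    graphics::polygon(v[, 1L], v[, 2L], col = cols[i], border = "grey40")
  }
  invisible(x)
}

#' Assign cells to grid tiles
#'
#' Each cell is assigned to the lattice cell whose center is nearest
#' (exact ties broken toward the lower tile index; a tie between a retained
#' and a dropped tile resolves to the retained one).  Cells whose nearest
#' lattice cell was dropped by the coverage rule are not counted anywhere
#' and are reported.
#'
#' @param cells A [cell_table()], already clipped to the tumor ROI.
#' @param grid A [build_hex_grid()] result.
#' @return List with `tile` (integer per cell, `NA` when dropped), `counts`
#'   (tiles x phenotype matrix), `n_dropped` and `dropped_by_phenotype`.
#' @export
assign_cells_to_tiles <- function(cells, grid) {
  n <- nrow(cells)
  N <- nrow(grid$tiles)
  if (n == 0L || N == 0L) {
    counts <- matrix(0L, nrow = N, ncol = length(phenotype_levels()),
                     dimnames = list(NULL, phenotype_levels()))
    return(list(tile = integer(0), counts = counts, n_dropped = 0L,
                dropped_by_phenotype = table(factor(character(0),
                                             phenotype_levels()))))
  }
  x <- cells$x; y <- cells$y
  r0 <- round((y - grid$y0) / grid$vs)
  best_d2 <- rep(Inf, n)
  best_idx <- rep.int(N + 1L, n)  # N+1 encodes a dropped lattice cell
  eps <- 1e-6
  for (dr in -1:1) {
    r <- r0 + dr
    off <- (abs(r) %% 2L) * grid$hs / 2
    c0 <- round((x - grid$x0 - off) / grid$hs)
    for (dc in -1:1) {
      cc <- c0 + dc
      cx <- grid$x0 + off + cc * grid$hs
      cy <- grid$y0 + r * grid$vs
      d2 <- (x - cx)^2 + (y - cy)^2
      idx <- unname(grid$tile_map[paste(r, cc)])
      idx[is.na(idx)] <- N + 1L
      upd <- d2 < best_d2 - eps |
        (abs(d2 - best_d2) <= eps & idx < best_idx)
      best_d2[upd] <- d2[upd]
      best_idx[upd] <- idx[upd]
    }
  }
  tile <- ifelse(best_idx > N, NA_integer_, best_idx)
  ph <- factor(cells$phenotype, levels = phenotype_levels())
  counts_tab <- table(factor(tile, levels = seq_len(N)), ph)
  counts <- matrix(as.integer(counts_tab), nrow = N,
                   dimnames = list(NULL, colnames(counts_tab)))
  dropped <- is.na(tile)
  list(tile = tile, counts = counts, n_dropped = sum(dropped),
       dropped_by_phenotype = table(ph[dropped]))
}

#' Per-tile cell counts for one phenotype
#'
#' `CD8` pools the Ki67-positive and Ki67-negative subsets.
#'
#' @inheritParams assign_cells_to_tiles
#' @param phenotype Label from [phenotype_levels()].
#' @return Integer vector, one count per retained tile.
#' @export
tile_counts <- function(cells, grid, phenotype) {
  sel <- cells_of_type(cells, phenotype)
  asg <- assign_cells_to_tiles(sel, grid)
  as.integer(rowSums(asg$counts))
}

#' Export the grid as GeoJSON for overlay inspection
#'
#' @param grid A `hex_grid`.
#' @param path Output path.
#' @param properties Optional data frame of extra per-tile properties.
#' @export
hex_grid_geojson <- function(grid, path, properties = NULL) {
  t <- grid$tiles
  feats <- lapply(seq_len(nrow(t)), function(i) {
    v <- hex_vertices(t$cx[i], t$cy[i], grid$R)
    v <- rbind(v, v[1L, ])
    props <- list(tile = t$tile[i],
                  clipped_area_mm2 = t$clipped_area_mm2[i])
    if (!is.null(properties))
      props <- c(props, as.list(properties[i, , drop = FALSE]))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(v)),
                           function(k) c(v[k, 1L], v[k, 2L])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
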
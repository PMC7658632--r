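# Distance and overlap metrics.
#
# GAD is the mean distance from each CD8+ T cell in the tumor ROI to its
# nearest myeloid cell.  GAD_norm divides GAD by the expected
# nearest-neighbour distance 0.5 * sqrt(A / n) under complete spatial
# randomness of the n myeloid cells in the tumor area A (Clark-Evans), so
# GAD_norm ~ 1 for randomly placed myeloid cells, > 1 when myeloid cells
# cluster away from T cells, < 1 when the two populations co-localize.
# MTO is the fraction of CD8-hot grid tiles that are also myeloid-hot,
# where "hot" means the tile density strictly exceeds the cohort median
# tumor density of that cell type.

#' Cell density of a phenotype in a region class
#'
#' @param cells A [cell_table()].
#' @param regions A [region_set()].
#' @param region_class Region class, default `"tumor"`.
#' @param phenotype Label from [phenotype_levels()]; `"CD8"` pools the Ki67
#'   subsets.
#' @return Density in cells/mm^2.
#' @export
compute_density <- function(cells, regions, region_class = "tumor",
                            phenotype = "CD8") {
  a <- region_area(regions, region_class)
  sel <- cells_of_type(cells, phenotype)
  inside <- points_in_region(regions, region_class, sel$x, sel$y)
  sum(inside) / a
}

# Mean nearest-neighbour distance from each point of p to the point set q.
# Chunked full distance computation; memory bounded at ~chunk * nrow(q).
nn_mean_dist <- function(px, py, qx, qy, chunk = 512L) {
  n <- length(px)
  total <- 0
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    d2 <- outer(px[i:j], qx, "-")^2 + outer(py[i:j], qy, "-")^2
    total <- total + sum(sqrt(.rowMins(d2)))
    i <- j + 1L
  }
  total / n
}

.rowMins <- function(m) do.call(pmin, as.data.frame(m))

#' Global average distance (GAD) between two point sets
#'
#' Mean over the first point set (CD8+ T cells) of the Euclidean distance to
#' the nearest point of the second set (myeloid cells).  Both sets are
#' expected to be restricted to the tumor ROI already.
#'
#' @param cd8_cells,myeloid_cells Two-column matrices / data frames of x, y
#'   in micrometres (a [cell_table()] works).
#' @return GAD in micrometres, or `NA` when either set is empty.
#' @export
compute_gad <- function(cd8_cells, myeloid_cells) {
  p <- as.matrix(as.data.frame(cd8_cells)[, c("x", "y")])
  q <- as.matrix(as.data.frame(myeloid_cells)[, c("x", "y")])
  if (nrow(p) == 0L || nrow(q) == 0L) return(NA_real_)
  nn_mean_dist(p[, 1L], p[, 2L], q[, 1L], q[, 2L])
}

#' Normalize GAD by the expected random nearest-neighbour distance
#'
#' `GAD_norm = GAD / (0.5 * sqrt(A / n))` with the tumor area `A` converted
#' from mm^2 to um^2, so the ratio is dimensionless.
#'
#' @param gad GAD in micrometres.
#' @param n Number of myeloid cells in the tumor ROI.
#' @param area_mm2 Annotated tumor area in mm^2.
#' @return GAD_norm, or `NA` when `gad` is missing or `n` is 0.
#' @export
normalize_gad <- function(gad, n, area_mm2) {
  if (is.na(gad) || n < 1) return(NA_real_)
  stopifnot(area_mm2 > 0)
  gad / (0.5 * sqrt(area_mm2 * UM2_PER_MM2 / n))
}

#' Per-sample distance result for one myeloid compartment
#'
#' Clips cells to the tumor ROI, computes GAD from CD8+ cells to the given
#' myeloid type, and normalizes by the Clark-Evans expectation.
#'
#' @param cells A [cell_table()].
#' @param regions The sample's [region_set()].
#' @param myeloid_type `"CD11b_CD14"` or `"CD11b_CD15"`.
#' @return One-row data frame: `sample_id`, `myeloid_type`, `gad`, `n`,
#'   `area_mm2`, `gad_norm` (`NA`s when a side is empty).
#' @export
sample_distance <- function(cells, regions, myeloid_type) {
  stopifnot(myeloid_type %in% myeloid_types())
  a <- region_area(regions, "tumor")
  tum <- clip_cells_to_region(cells, regions, "tumor")
  cd8 <- cells_of_type(tum, "CD8")
  mye <- cells_of_type(tum, myeloid_type)
  gad <- compute_gad(cd8, mye)
  data.frame(sample_id = attr(cells, "sample_id"),
             myeloid_type = myeloid_type, gad = gad, n = nrow(mye),
             area_mm2 = a, gad_norm = normalize_gad(gad, nrow(mye), a),
             stringsAsFactors = FALSE)
}

#' Cohort-wide medians used as hot-tile and stratification thresholds
#'
#' Medians are taken over sample-level values (one value per sample, not
#' per tile), skipping samples where the quantity is undefined.
#'
#' @param densities Data frame / matrix of per-sample tumor densities
#'   (cells/mm^2), one column per cell type.
#' @param mto Optional data frame of per-sample MTO values, one column per
#'   myeloid type.
#' @return List with `D` (named vector of median densities) and
#'   `mto_median` (named vector or `NULL`).
#' @export
cohort_thresholds <- function(densities, mto = NULL) {
  med <- function(v, what) {
    v <- v[!is.na(v)]
    if (length(v) < 1L) stop("no defined values for ", what)
    stats::median(v)
  }
  densities <- as.data.frame(densities)
  if (nrow(densities) < 2L) stop("need at least 2 samples for thresholds")
  D <- vapply(names(densities), function(j) med(densities[[j]], j), 0)
  mto_median <- NULL
  if (!is.null(mto)) {
    mto <- as.data.frame(mto)
    mto_median <- vapply(names(mto), function(j) med(mto[[j]], j), 0)
  }
  list(D = D, mto_median = mto_median)
}

#' Label hot tiles
#'
#' A tile is hot for a cell type when its density strictly exceeds the
#' cohort median tumor density of that type; equality is not hot.
#'
#' @param tile_densities Numeric vector of per-tile densities (cells/mm^2).
#' @param threshold The cohort median density for the type.
#' @return Integer 0/1 flags.
#' @export
label_hot_tiles <- function(tile_densities, threshold) {
  as.integer(tile_densities > threshold)
}

#' Myeloid-T-cell overlap score
#'
#' `MTO = sum(h_cd8 * h_myeloid) / sum(h_cd8)`: the fraction of CD8-hot
#' tiles that are also myeloid-hot.  Undefined (`NA`) when no tile is
#' CD8-hot.
#'
#' @param h_cd8,h_myeloid 0/1 hot flags over the same tile set.
#' @return MTO in `[0, 1]`, or `NA`.
#' @export
compute_mto <- function(h_cd8, h_myeloid) {
  if (length(h_cd8) != length(h_myeloid))
    stop("hot-flag vectors cover different tile sets")
  denom <- sum(h_cd8)
  if (denom == 0L) return(NA_real_)
  sum(h_cd8 * h_myeloid) / denom
}

#' Per-sample hot tiles and MTO for one myeloid compartment
#'
#' @param cells Tumor-clipped [cell_table()].
#' @param grid The sample's [build_hex_grid()] result.
#' @param D Named vector of cohort median densities (needs entries `CD8`
#'   and the myeloid type).
#' @param myeloid_type `"CD11b_CD14"` or `"CD11b_CD15"`.
#' @return List with `h_cd8`, `h_myeloid` (per-tile flags), `d_cd8`,
#'   `d_myeloid` (per-tile densities) and `mto`.
#' @export
sample_overlap <- function(cells, grid, D, myeloid_type) {
  stopifnot(myeloid_type %in% myeloid_types(),
            all(c("CD8", myeloid_type) %in% names(D)))
  area <- grid$tiles$clipped_area_mm2
  d_cd8 <- tile_counts(cells, grid, "CD8") / area
  d_mye <- tile_counts(cells, grid, myeloid_type) / area
  h_cd8 <- label_hot_tiles(d_cd8, D[["CD8"]])
  h_mye <- label_hot_tiles(d_mye, D[[myeloid_type]])
  list(h_cd8 = h_cd8, h_myeloid = h_mye, d_cd8 = d_cd8, d_myeloid = d_mye,
       mto = compute_mto(h_cd8, h_mye))
}

#' Four-way stratification by CD8 density and MTO
#'
#' A sample is `high` on an axis when its value strictly exceeds the cohort
#' median (values at the median are `low`).  Categories follow the
#' (CD8 density, MTO) order: low/low = 1, low/high = 2, high/high = 3,
#' high/low = 4.
#'
#' @param cd8_density Tumor CD8 density of the sample (cells/mm^2).
#' @param mto The sample's MTO.
#' @param cd8_median,mto_median Cohort medians.
#' @return List with `category` (1-4, `NA` when MTO undefined),
#'   `cd8_level`, `mto_level`.
#' @export
stratify_sample <- function(cd8_density, mto, cd8_median, mto_median) {
  if (is.na(mto) || is.na(cd8_density))
    return(list(category = NA_integer_, cd8_level = NA_character_,
                mto_level = NA_character_))
  cd8_level <- if (cd8_density > cd8_median) "high" else "low"
  mto_level <- if (mto > mto_median) "high" else "low"
  category <- if (cd8_level == "low") {
    if (mto_level == "low") 1L else 2L
  } else {
    if (mto_level == "high") 3L else 4L
  }
  list(category = category, cd8_level = cd8_level, mto_level = mto_level)
}

#' Cohort-level comparisons and density correlations
#'
#' Two-sided Mann-Whitney tests for each measure between the two levels of
#' `group` (e.g. MSI vs MSS), and a Pearson correlation matrix across the
#' measures.
#'
#' @param measures Data frame of per-sample numeric measures (densities,
#'   GAD_norm, MTO, ...).
#' @param group Optional factor/character of two group labels per sample.
#' @return List with `contrasts` (measure, groups, W, p_value) or `NULL`,
#'   and `correlations` (Pearson matrix, pairwise complete).
#' @export
cohort_statistics <- function(measures, group = NULL) {
  measures <- as.data.frame(measures)
  num <- measures[vapply(measures, is.numeric, TRUE)]
  contrasts <- NULL
  if (!is.null(group)) {
    group <- as.factor(group)
    lev <- levels(droplevels(group))
    if (length(lev) != 2L)
      stop("group must have exactly 2 levels, got ", length(lev))
    rows <- lapply(names(num), function(m) {
      v <- num[[m]]
      ok <- !is.na(v)
      g1 <- v[ok & group == lev[1L]]
      g2 <- v[ok & group == lev[2L]]
      if (length(g1) < 1L || length(g2) < 1L) {
        warning("contrast skipped for ", m, ": empty group")
        return(NULL)
      }
      wt <- stats::wilcox.test(g1, g2, exact = FALSE, correct = FALSE)
      data.frame(measure = m, group1 = lev[1L], group2 = lev[2L],
                 W = unname(wt$statistic), p_value = wt$p.value,
                 stringsAsFactors = FALSE)
    })
    contrasts <- do.call(rbind, rows)
  }
  correlations <- if (ncol(num) >= 2L)
    stats::cor(num, use = "pairwise.complete.obs", method = "pearson")
  else NULL
  list(contrasts = contrasts, correlations = correlations)
}

#' Run the full spatial analysis over a cohort
#'
#' Computes per-sample tumor densities, GAD/GAD_norm for both myeloid
#' compartments, the hexagonal grid with cohort-median hot-tile labelling,
#' MTO, and the four-way stratification.
#'
#' @param cells Named list of [cell_table()]s.
#' @param regions Named list of [region_set()]s (same names).
#' @param config A [run_config()].
#' @param keep_grids Keep per-sample grids and hot maps in the result
#'   (memory permitting).
#' @return A `tme_cohort` object with `densities`, `distances`, `overlap`,
#'   `thresholds` and `warnings` components.
#' @export
analyze_cohort <- function(cells, regions, config = run_config(),
                           keep_grids = FALSE) {
  ids <- names(cells)
  if (is.null(ids) || !all(ids %in% names(regions)))
    stop("cells and regions must be named lists over the same samples")
  types <- c("CD8", "CD8_Ki67pos", "CD8_Ki67neg", "CD11b_CD14",
             "CD11b_CD15", "ARG1", "FOXP3")
  warn <- character(0)

  densities <- do.call(rbind, lapply(ids, function(sid) {
    d <- vapply(types, function(ph)
      compute_density(cells[[sid]], regions[[sid]], "tumor", ph), 0)
    cbind(data.frame(sample_id = sid, stringsAsFactors = FALSE),
          as.data.frame(as.list(d)))
  }))
  densities$ki67_fraction <- ifelse(densities$CD8 > 0,
                                    densities$CD8_Ki67pos / densities$CD8,
                                    NA_real_)

  distances <- do.call(rbind, lapply(ids, function(sid) {
    do.call(rbind, lapply(myeloid_types(), function(mt)
      sample_distance(cells[[sid]], regions[[sid]], mt)))
  }))
  und <- distances$sample_id[is.na(distances$gad)]
  if (length(und))
    warn <- c(warn, paste0("undefined GAD for: ",
                           paste(unique(und), collapse = ", ")))

  D <- cohort_thresholds(densities[, c("CD8", "CD11b_CD14",
                                       "CD11b_CD15")])$D

  grids <- lapply(ids, function(sid)
    build_hex_grid(regions[[sid]], config$hex_diagonal,
                   config$min_tile_coverage))
  names(grids) <- ids

  ov_rows <- list()
  hot_maps <- if (keep_grids) list() else NULL
  for (sid in ids) {
    tum <- clip_cells_to_region(cells[[sid]], regions[[sid]], "tumor")
    for (mt in myeloid_types()) {
      ov <- sample_overlap(tum, grids[[sid]], D, mt)
      ov_rows[[paste(sid, mt)]] <-
        data.frame(sample_id = sid, myeloid_type = mt, mto = ov$mto,
                   n_tiles = nrow(grids[[sid]]$tiles),
                   n_cd8_hot = sum(ov$h_cd8),
                   n_overlap_hot = sum(ov$h_cd8 * ov$h_myeloid),
                   stringsAsFactors = FALSE)
      if (keep_grids) hot_maps[[paste(sid, mt, sep = ".")]] <- ov
    }
  }
  overlap <- do.call(rbind, c(ov_rows, list(make.row.names = FALSE)))
  und_mto <- overlap$sample_id[is.na(overlap$mto)]
  if (length(und_mto))
    warn <- c(warn, paste0("undefined MTO for: ",
                           paste(unique(und_mto), collapse = ", ")))

  mto_wide <- data.frame(
    CD11b_CD14 = overlap$mto[overlap$myeloid_type == "CD11b_CD14"],
    CD11b_CD15 = overlap$mto[overlap$myeloid_type == "CD11b_CD15"])
  thr <- cohort_thresholds(
    densities[, c("CD8", "CD11b_CD14", "CD11b_CD15")], mto_wide)

  cd8_by_sample <- stats::setNames(densities$CD8, densities$sample_id)
  strat <- lapply(seq_len(nrow(overlap)), function(i) {
    stratify_sample(cd8_by_sample[[overlap$sample_id[i]]], overlap$mto[i],
                    thr$D[["CD8"]],
                    thr$mto_median[[overlap$myeloid_type[i]]])
  })
  overlap$category <- vapply(strat, `[[`, 1L, "category")
  overlap$cd8_level <- vapply(strat, `[[`, "", "cd8_level")
  overlap$mto_level <- vapply(strat, `[[`, "", "mto_level")

  structure(list(densities = densities, distances = distances,
                 overlap = overlap, thresholds = thr, config = config,
                 grids = if (keep_grids) grids else NULL,
                 hot_maps = hot_maps, warnings = warn),
            class = "tme_cohort")
}

#' @export
print.tme_cohort <- function(x, ...) {
  cat(sprintf("<tme_cohort> %d samples\n", nrow(x$densities)))
  cat(sprintf("  median tumor densities (cells/mm^2): CD8 %.1f, CD14 %.1f, CD15 %.1f\n",
              x$thresholds$D[["CD8"]], x$thresholds$D[["CD11b_CD14"]],
              x$thresholds$D[["CD11b_CD15"]]))
  if (!is.null(x$thresholds$mto_median))
    cat(sprintf("  median MTO: CD14 %.3f, CD15 %.3f\n",
                x$thresholds$mto_median[["CD11b_CD14"]],
                x$thresholds$mto_median[["CD11b_CD15"]]))
  for (w in x$warnings) cat("  note: ", w, "\n", sep = "")
  invisible(x)
}

#' @export
summary.tme_cohort <- function(object, ...) {
  cat("Per-sample GAD_norm by myeloid compartment:\n")
  print(do.call(rbind, lapply(split(object$distances$gad_norm,
                                    object$distances$myeloid_type),
                              summary)))
  cat("\nStratification (category counts by myeloid compartment):\n")
  print(table(object$overlap$myeloid_type,
              factor(object$overlap$category, levels = 1:4)))
  invisible(object)
}

#' @export
plot.tme_cohort <- function(x, myeloid_type = "CD11b_CD14", ...) {
  ov <- x$overlap[x$overlap$myeloid_type == myeloid_type, ]
  cd8 <- stats::setNames(x$densities$CD8, x$densities$sample_id)[ov$sample_id]
  graphics::plot(cd8, ov$mto, xlab = "tumor CD8 density (cells/mm^2)",
                 ylab = "MTO", pch = 19,
                 col = c("#666666", "#1b9e77", "#d95f02",
                         "#7570b3")[ov$category],
                 main = paste("CD8 density vs MTO,", myeloid_type), ...)
  graphics::abline(v = x$thresholds$D[["CD8"]], lty = 2)
  graphics::abline(h = x$thresholds$mto_median[[myeloid_type]], lty = 2)
  invisible(x)
}
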
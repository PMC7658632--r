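# Domain containers and file I/O.
#
# Cell tables follow the shape of a per-object coordinate export from a
# digital-pathology platform: one row per detected cell with x/y in
# micrometres and a phenotype call from a closed vocabulary.  Regions are
# annotated polygons (tumor / normal / excluded) carried as GeoJSON.

#' Closed phenotype vocabulary
#'
#' The cell phenotypes the pipeline understands: total and
#' proliferation-split cytotoxic T cells (CD8, CD8_Ki67pos, CD8_Ki67neg),
#' monocytic (CD11b_CD14) and granulocytic (CD11b_CD15) myeloid cells,
#' ARG1-positive suppressive myeloid cells, FOXP3 regulatory T cells and
#' Ki67-positive tumor cells.  Unknown labels are rejected at read time;
#' extending the vocabulary is a deliberate code change, not a data option.
#'
#' @return Character vector of valid phenotype labels.
#' @export
phenotype_levels <- function() {
  c("CD8", "CD8_Ki67pos", "CD8_Ki67neg",
    "CD11b_CD14", "CD11b_CD15", "ARG1", "FOXP3", "TUMOR_Ki67pos")
}

#' The two myeloid compartments distance/overlap metrics are computed for
#' @return Character vector `c("CD11b_CD14", "CD11b_CD15")`.
#' @export
myeloid_types <- function() c("CD11b_CD14", "CD11b_CD15")

#' Construct a per-sample cell table
#'
#' @param sample_id Sample identifier (length-1 character).
#' @param x,y Numeric coordinates in micrometres (image frame, y downward).
#' @param phenotype Character vector of phenotype labels; see
#'   [phenotype_levels()].
#' @return A `cell_table`: a data frame with columns `x`, `y`, `phenotype`
#'   and a `sample_id` attribute.
#' @export
cell_table <- function(sample_id, x, y, phenotype) {
  stopifnot(length(sample_id) == 1L)
  x <- as.numeric(x); y <- as.numeric(y)
  phenotype <- as.character(phenotype)
  if (length(x) != length(y) || length(x) != length(phenotype))
    stop("x, y and phenotype must have equal length")
  if (length(x) && !all(is.finite(x) & is.finite(y)))
    stop("cell coordinates must be finite")
  bad <- setdiff(unique(phenotype), phenotype_levels())
  if (length(bad))
    stop("unknown phenotype label(s): ", paste(bad, collapse = ", "))
  out <- data.frame(x = x, y = y, phenotype = phenotype,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- as.character(sample_id)
  class(out) <- c("cell_table", "data.frame")
  out
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> sample %s: %d cells\n",
              attr(x, "sample_id"), nrow(x)))
  if (nrow(x)) print(table(x$phenotype))
  invisible(x)
}

#' Subset a cell table by phenotype
#'
#' `CD8` is treated as the union of `CD8`, `CD8_Ki67pos` and `CD8_Ki67neg`
#' rows so that exports carrying either the total or the Ki67-split labels
#' behave identically.
#'
#' @param cells A `cell_table`.
#' @param phenotype A label from [phenotype_levels()].
#' @return The matching rows of `cells`.
#' @export
cells_of_type <- function(cells, phenotype) {
  labels <- if (identical(phenotype, "CD8"))
    c("CD8", "CD8_Ki67pos", "CD8_Ki67neg") else phenotype
  cells[cells$phenotype %in% labels, , drop = FALSE]
}

#' Construct a region set
#'
#' @param polygons A list; each element is `list(rings = <list of n x 2
#'   matrices, outer ring first, holes after>, region_class = "tumor" |
#'   "normal" | "excluded")`.  Coordinates in micrometres.
#' @param sample_id Optional sample identifier.
#' @return A `region_set` object.
#' @export
region_set <- function(polygons, sample_id = NA_character_) {
  classes <- c("tumor", "normal", "excluded")
  polygons <- lapply(polygons, function(p) {
    if (is.null(p$rings) || is.null(p$region_class))
      stop("each polygon needs 'rings' and 'region_class'")
    if (!p$region_class %in% classes)
      stop("unknown region_class: ", p$region_class)
    p$rings <- lapply(p$rings, as_ring)
    p
  })
  structure(list(polygons = polygons, sample_id = as.character(sample_id)),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cls <- vapply(x$polygons, function(p) p$region_class, "")
  cat(sprintf("<region_set> sample %s: %d polygon(s) [%s]\n",
              x$sample_id, length(x$polygons),
              paste(sprintf("%s: %d", names(table(cls)), table(cls)),
                    collapse = ", ")))
  invisible(x)
}

region_polys <- function(regions, region_class) {
  keep <- vapply(regions$polygons,
                 function(p) p$region_class == region_class, TRUE)
  lapply(regions$polygons[keep], `[[`, "rings")
}

#' Run configuration
#'
#' Bundles the tunable analysis parameters with their defaults: a 250 um
#' hexagon diagonal, a 250 um invasive-margin half-width (500 um total band
#' width), |R| cutoffs of 0.4 / 0.3 for the monocytic / granulocytic distance
#' signatures, and 10,000 permutations.
#'
#' @param hex_diagonal Long (vertex-to-vertex) hexagon diagonal, micrometres.
#' @param margin_half_width Half-width of the invasive-margin band,
#'   micrometres.
#' @param signature_cutoff_cd14,signature_cutoff_cd15 Absolute Spearman R
#'   cutoffs for signature derivation, in (0, 1).
#' @param n_permutations Number of random signatures for the permutation
#'   test.
#' @param min_tile_coverage Fraction of the full hexagon area a tile must
#'   cover inside the tumor ROI to be retained.
#' @param rng_seed Integer seed used by stages that draw random numbers.
#' @return A `run_config` list.
#' @export
run_config <- function(hex_diagonal = 250,
                       margin_half_width = 250,
                       signature_cutoff_cd14 = 0.4,
                       signature_cutoff_cd15 = 0.3,
                       n_permutations = 10000L,
                       min_tile_coverage = 0.5,
                       rng_seed = 1L) {
  stopifnot(hex_diagonal > 0, margin_half_width > 0,
            signature_cutoff_cd14 > 0, signature_cutoff_cd14 < 1,
            signature_cutoff_cd15 > 0, signature_cutoff_cd15 < 1,
            n_permutations >= 1, min_tile_coverage >= 0,
            min_tile_coverage <= 1)
  structure(list(hex_diagonal = hex_diagonal,
                 margin_half_width = margin_half_width,
                 signature_cutoff_cd14 = signature_cutoff_cd14,
                 signature_cutoff_cd15 = signature_cutoff_cd15,
                 n_permutations = as.integer(n_permutations),
                 min_tile_coverage = min_tile_coverage,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' Read a cell CSV
#'
#' Expects columns `sample_id,x_um,y_um,phenotype`.  Rows with an unknown
#' phenotype or non-finite coordinates are an error by default; with
#' `on_invalid = "drop"` they are removed and reported in the
#' `rejected` attribute (a data frame with a `reason` column), so that
#' rows in = rows accepted + rows rejected.
#'
#' @param path CSV file path.
#' @param on_invalid `"error"` or `"drop"`.
#' @return Named list of [cell_table()] objects, one per sample, with a
#'   `rejected` attribute.
#' @export
read_cells <- function(path, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "x_um", "y_um", "phenotype")
  if (!all(need %in% names(df)))
    stop("cell CSV must have columns ", paste(need, collapse = ","))
  x <- suppressWarnings(as.numeric(df$x_um))
  y <- suppressWarnings(as.numeric(df$y_um))
  reason <- rep(NA_character_, nrow(df))
  reason[!(is.finite(x) & is.finite(y))] <- "non-finite coordinate"
  unknown <- !(df$phenotype %in% phenotype_levels())
  reason[unknown & is.na(reason)] <- "unknown phenotype"
  if (anyNA(reason) == FALSE && nrow(df) == 0) reason <- character(0)
  bad <- !is.na(reason)
  if (any(bad) && on_invalid == "error") {
    labs <- unique(df$phenotype[unknown])
    stop(sum(bad), " invalid row(s)",
         if (length(labs)) paste0("; unknown phenotype label(s): ",
                                  paste(labs, collapse = ", ")))
  }
  rejected <- cbind(df[bad, , drop = FALSE], reason = reason[bad])
  ok <- df[!bad, , drop = FALSE]
  okx <- x[!bad]; oky <- y[!bad]
  tables <- lapply(split(seq_len(nrow(ok)), ok$sample_id), function(i) {
    cell_table(ok$sample_id[i[1L]], okx[i], oky[i], ok$phenotype[i])
  })
  attr(tables, "rejected") <- rejected
  tables
}

#' Write cell tables to CSV
#'
#' @param cells A `cell_table` or list of them.
#' @param path Output CSV path.
#' @export
write_cells <- function(cells, path) {
  if (inherits(cells, "cell_table")) cells <- list(cells)
  rows <- do.call(rbind, lapply(cells, function(ct) {
    data.frame(sample_id = attr(ct, "sample_id"),
               x_um = ct$x, y_um = ct$y, phenotype = ct$phenotype,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

geojson_ring_to_matrix <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(pt) as.numeric(pt[1:2])))
  as_ring(m)
}

#' Read region annotations from GeoJSON
#'
#' Expects a FeatureCollection of Polygon / MultiPolygon features with a
#' `region_class` property (`tumor`, `normal`, `excluded`) and an optional
#' `sample_id` property.  Features without `sample_id` are pooled under the
#' id given by `default_sample`.
#'
#' @param path GeoJSON file path.
#' @param default_sample Sample id for features lacking one.
#' @return Named list of [region_set()] objects, one per sample.
#' @export
read_regions <- function(path, default_sample = "sample_1") {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  acc <- list()
  for (fi in seq_along(gj$features)) {
    f <- gj$features[[fi]]
    cls <- f$properties$region_class
    if (is.null(cls))
      stop("feature ", fi, " lacks a region_class property")
    sid <- f$properties$sample_id
    if (is.null(sid)) sid <- default_sample
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("feature ", fi, ": unsupported geometry type ", geom$type))
    for (poly in polys) {
      rings <- tryCatch(lapply(poly, geojson_ring_to_matrix),
                        error = function(e)
                          stop("feature ", fi, ": malformed ring (",
                               conditionMessage(e), ")", call. = FALSE))
      acc[[sid]] <- c(acc[[sid]],
                      list(list(rings = rings, region_class = cls)))
    }
  }
  out <- lapply(names(acc), function(sid) region_set(acc[[sid]], sid))
  names(out) <- names(acc)
  out
}

#' Write region sets to GeoJSON
#'
#' @param regions A `region_set` or named list of them.
#' @param path Output path.
#' @export
write_regions <- function(regions, path) {
  if (inherits(regions, "region_set")) regions <- list(regions)
  feats <- list()
  for (rs in regions) {
    for (p in rs$polygons) {
      coords <- lapply(p$rings, function(r) {
        r <- rbind(r, r[1L, ])  # GeoJSON rings are closed
        lapply(seq_len(nrow(r)), function(i) c(r[i, 1L], r[i, 2L]))
      })
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(region_class = p$region_class,
                          sample_id = rs$sample_id),
        geometry = list(type = "Polygon", coordinates = coords))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a genes x samples expression matrix (TSV, log2 RPKM scale)
#'
#' @param path TSV with first column `gene_id`, one column per sample.
#' @return Numeric matrix, genes in rows (rownames = gene ids).
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "gene_id") stop("first column must be gene_id")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id(s): ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix as TSV
#' @param expr Numeric matrix with gene-id rownames.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and cross-validate all pipeline inputs
#'
#' @param cell_csv_path Cell coordinate CSV (see [read_cells()]).
#' @param regions_geojson_path Region annotation GeoJSON.
#' @param expression_tsv_path Optional expression TSV; `NULL` for a
#'   spatial-only cohort.
#' @return List with `cells`, `regions`, `expression` (or `NULL`) and
#'   `missing_regions` (sample ids present in cells but lacking regions).
#' @export
read_inputs <- function(cell_csv_path, regions_geojson_path,
                        expression_tsv_path = NULL) {
  cells <- read_cells(cell_csv_path)
  regions <- read_regions(regions_geojson_path)
  missing_regions <- setdiff(names(cells), names(regions))
  if (length(missing_regions))
    warning("samples without region annotations: ",
            paste(missing_regions, collapse = ", "))
  expr <- if (!is.null(expression_tsv_path) &&
              nzchar(expression_tsv_path))
    read_expression(expression_tsv_path) else NULL
  list(cells = cells, regions = regions, expression = expr,
       missing_regions = missing_regions)
}
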
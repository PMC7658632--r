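# Single-sample gene-set scoring and distance-derived signatures.
#
# A gene set is scored within each sample by the rank-biserial correlation
# of the set genes against all remaining genes of the matrix:
# r_rb = 2U/(n1*n2) - 1 with U the Mann-Whitney statistic on within-sample
# expression ranks (midranks for ties).  Scores are multiplied by 10 (to a
# [-10, 10] scale comparable to log2 RPKM values) and median-centered per
# signature across samples, so a positive score marks a sample enriched
# relative to at least half the cohort.  Because the statistic only uses
# within-sample ranks, scoring is invariant to any monotone transform of a
# sample's expression values.

expr_ranks <- function(expr) {
  apply(expr, 2L, rank)  # midranks for ties
}

rank_biserial <- function(ranks, idx) {
  n1 <- length(idx)
  n2 <- nrow(ranks) - n1
  U <- colSums(ranks[idx, , drop = FALSE]) - n1 * (n1 + 1) / 2
  2 * U / (n1 * n2) - 1
}

#' Score a gene set in every sample
#'
#' @param expr Genes x samples expression matrix (log2 RPKM scale; any
#'   monotone per-sample transform gives identical scores).
#' @param gene_set Character vector of gene ids.
#' @return A `signature_score` list with per-sample `r_rb` (raw rank
#'   biserial), `scaled` (x10) and `centered` (scaled minus the per-signature
#'   median across samples), plus `n_genes_used`.
#' @export
score_gene_set <- function(expr, gene_set) {
  missing <- setdiff(gene_set, rownames(expr))
  used <- intersect(gene_set, rownames(expr))
  if (!length(used))
    stop("no gene of the set is in the matrix; missing: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  if (nrow(expr) - length(used) < 2L)
    stop("need at least 2 genes outside the set")
  ranks <- attr(expr, "mtospat_ranks")
  if (is.null(ranks)) ranks <- expr_ranks(expr)
  r <- rank_biserial(ranks, match(used, rownames(expr)))
  scaled <- 10 * r
  structure(list(r_rb = r, scaled = scaled,
                 centered = scaled - stats::median(scaled),
                 n_genes_used = length(used), missing_genes = missing),
            class = "signature_score")
}

#' @export
print.signature_score <- function(x, ...) {
  cat(sprintf("<signature_score> %d samples, %d genes used\n",
              length(x$r_rb), x$n_genes_used))
  print(summary(x$centered))
  invisible(x)
}

#' Construct a signed gene signature
#'
#' @param positive,negative Character vectors of gene ids (disjoint).
#' @param name Signature name.
#' @param cutoff The |R| cutoff the signature was derived at (or `NA`).
#' @param source_parameter What the signature tracks, e.g. `"GAD_CD14"`,
#'   `"GAD_CD15"` or `"external"`.
#' @return A `gene_signature` object.
#' @export
gene_signature <- function(positive, negative = character(0),
                           name = "signature", cutoff = NA_real_,
                           source_parameter = "external") {
  positive <- unique(as.character(positive))
  negative <- unique(as.character(negative))
  if (length(intersect(positive, negative)))
    stop("positive and negative sets overlap")
  structure(list(name = name, positive = positive, negative = negative,
                 cutoff = cutoff, source_parameter = source_parameter),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s [%s]: %d positive, %d negative (|R| > %s)\n",
              x$name, x$source_parameter, length(x$positive),
              length(x$negative),
              ifelse(is.na(x$cutoff), "?", format(x$cutoff))))
  invisible(x)
}

#' Score a signed signature
#'
#' Positive-set centered score minus negative-set centered score; a
#' one-sided signature degrades to the single available term (so a
#' negative-only signature scores as minus its set score, preserving sign
#' semantics).
#'
#' @param expr Genes x samples expression matrix.
#' @param sig A [gene_signature()].
#' @return Named numeric vector of per-sample scores.
#' @export
score_signed_signature <- function(expr, sig) {
  has_pos <- length(intersect(sig$positive, rownames(expr))) > 0L
  has_neg <- length(intersect(sig$negative, rownames(expr))) > 0L
  if (!has_pos && !has_neg)
    stop("signature '", sig$name, "' has no gene in the matrix")
  pos <- if (has_pos) score_gene_set(expr, sig$positive)$centered else 0
  neg <- if (has_neg) score_gene_set(expr, sig$negative)$centered else 0
  out <- pos - neg
  names(out) <- colnames(expr)
  out
}

#' Per-gene Spearman correlation with a spatial parameter
#'
#' @param expr Genes x samples expression matrix.
#' @param parameter Named or positional per-sample values (e.g. GAD_norm);
#'   `NA` samples are dropped pairwise.
#' @return Named numeric vector, one Spearman R per gene.
#' @export
correlate_genes_with_parameter <- function(expr, parameter) {
  if (!is.null(names(parameter)))
    parameter <- parameter[colnames(expr)]
  ok <- !is.na(parameter)
  if (sum(ok) < 4L) stop("need at least 4 samples with a defined parameter")
  p <- parameter[ok]
  if (length(unique(p)) == 1L) stop("parameter is constant across samples")
  drop(stats::cor(t(expr[, ok, drop = FALSE]), p, method = "spearman"))
}

#' Derive a distance signature by thresholding per-gene correlations
#'
#' Positive set: genes with `R > cutoff`; negative set: `R < -cutoff`
#' (strict inequalities, so genes exactly at the cutoff are excluded).
#'
#' @param R Named per-gene Spearman correlations.
#' @param cutoff |R| cutoff in (0, 1); the defaults used for the two myeloid
#'   compartments are 0.4 (monocytic) and 0.3 (granulocytic).
#' @param name,source_parameter Passed to [gene_signature()].
#' @return A [gene_signature()]; empty (with a warning) when no gene passes.
#' @export
derive_distance_signature <- function(R, cutoff,
                                      name = "distance_signature",
                                      source_parameter = "external") {
  stopifnot(cutoff > 0, cutoff < 1)
  pos <- names(R)[R > cutoff]
  neg <- names(R)[R < -cutoff]
  if (!length(pos) && !length(neg))
    warning("no gene passes |R| > ", cutoff, "; empty signature")
  gene_signature(pos, neg, name = name, cutoff = cutoff,
                 source_parameter = source_parameter)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Random-signature permutation test
#'
#' Tests whether the Spearman correlation between a distance signature's
#' scores and a signature-or-gene of interest (SGOI) could arise by chance:
#' `n_perm` random signatures with the same positive/negative set sizes are
#' drawn without replacement from the matrix's gene universe, each is scored
#' and correlated with the SGOI, and the p-value is the fraction of random
#' signatures whose absolute correlation strictly exceeds the observed one
#' (no pseudo-count, so p can be exactly 0).
#'
#' @param expr Genes x samples expression matrix.
#' @param distance_sig A [gene_signature()].
#' @param sgoi A gene id present in `expr`, or a [gene_signature()].
#' @param n_perm Number of random signatures (default 10000).
#' @param seed Integer RNG seed; results are bit-for-bit reproducible given
#'   `(seed, n_perm)`.
#' @return A `permutation_result` list: `observed_r`, `p_value`, `n_perm`,
#'   `seed`.
#' @export
permutation_test <- function(expr, distance_sig, sgoi, n_perm = 10000L,
                             seed = 1L) {
  stopifnot(n_perm >= 1)
  sgoi_values <- if (inherits(sgoi, "gene_signature")) {
    score_signed_signature(expr, sgoi)
  } else {
    if (!sgoi %in% rownames(expr))
      stop("SGOI gene '", sgoi, "' not in the matrix")
    expr[sgoi, ]
  }
  ranks <- expr_ranks(expr)
  attr(expr, "mtospat_ranks") <- ranks
  obs <- stats::cor(score_signed_signature(expr, distance_sig),
                    sgoi_values, method = "spearman")
  n_pos <- length(intersect(distance_sig$positive, rownames(expr)))
  n_neg <- length(intersect(distance_sig$negative, rownames(expr)))
  n_tot <- n_pos + n_neg
  if (n_tot == 0L) stop("distance signature has no gene in the matrix")
  sgoi_rank <- rank(sgoi_values)
  rand_r <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(nrow(expr), n_tot)
    sc_pos <- if (n_pos) rank_biserial(ranks, idx[seq_len(n_pos)]) else 0
    sc_neg <- if (n_neg) rank_biserial(ranks, idx[-seq_len(n_pos)]) else 0
    stats::cor(rank(sc_pos - sc_neg), sgoi_rank)
  }, 0))
  structure(list(observed_r = unname(obs),
                 p_value = sum(abs(rand_r) > abs(obs)) / n_perm,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed r = %.3f, p = %.4g (%d permutations, seed %d)\n",
    x$observed_r, x$p_value, x$n_perm, x$seed))
  invisible(x)
}

#' Write a signature as two-column TSV (gene_id, sign)
#' @param sig A [gene_signature()].
#' @param path Output path.
#' @export
write_signature <- function(sig, path) {
  df <- data.frame(
    gene_id = c(sig$positive, sig$negative),
    sign = c(rep("positive", length(sig$positive)),
             rep("negative", length(sig$negative))),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column signature TSV
#' @param path TSV with columns `gene_id`, `sign`.
#' @param ... Passed to [gene_signature()].
#' @return A [gene_signature()].
#' @export
read_signature <- function(path, ...) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_signature(df$gene_id[df$sign == "positive"],
                 df$gene_id[df$sign == "negative"], ...)
}
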
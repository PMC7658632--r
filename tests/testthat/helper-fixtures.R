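# Fixtures built in code: simple region sets, point clouds and expression
# matrices used across the test files.

square_ring <- function(side = 1000, x0 = 0, y0 = 0) {
  cbind(c(x0, x0 + side, x0 + side, x0), c(y0, y0, y0 + side, y0 + side))
}

square_regions <- function(side = 1000, sample_id = "s1") {
  region_set(list(list(rings = list(square_ring(side)),
                       region_class = "tumor")), sample_id)
}

rect_regions <- function(w, h, sample_id = "s1") {
  region_set(list(list(rings = list(cbind(c(0, w, w, 0), c(0, 0, h, h))),
                       region_class = "tumor")), sample_id)
}

circle_ring <- function(r = 1000, cx = 0, cy = 0, n = 128) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

csr_cells <- function(n, w, h, phenotype = "CD8_Ki67neg",
                      sample_id = "s1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cell_table(sample_id, runif(n, 0, w), runif(n, 0, h),
             rep(phenotype, length.out = n))
}

# Expression matrix with known structure: `n_set` signature genes shifted
# upward by `shift` in samples with a high "gradient".
toy_expression <- function(n_genes = 50, n_samples = 12, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 5, 1.5), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  m
}

# Brute-force GAD oracle: explicit loop over the first point set.
gad_oracle <- function(p, q) {
  mean(vapply(seq_len(nrow(p)), function(i)
    min(sqrt((p[i, 1] - q[, 1])^2 + (p[i, 2] - q[, 2])^2)), 0))
}
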
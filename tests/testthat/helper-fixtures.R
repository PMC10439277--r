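# Small in-code fixtures shared across tests.

# Dense integer matrix -> raw count_matrix with default names.
raw_cm <- function(mat, genes = NULL, cells = NULL) {
  genes <- genes %||% sprintf("g%d", seq_len(nrow(mat)))
  cells <- cells %||% sprintf("c%d", seq_len(ncol(mat)))
  count_matrix(mat, genes, cells, layer = "raw")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Dense matrix of lognorm values -> lognorm count_matrix.
lognorm_cm <- function(mat, genes = NULL, cells = NULL) {
  genes <- genes %||% sprintf("g%d", seq_len(nrow(mat)))
  cells <- cells %||% sprintf("c%d", seq_len(ncol(mat)))
  count_matrix(mat, genes, cells, layer = "lognorm")
}

# Read records data.frame for one molecule.
reads_of <- function(alleles, cb = "AAAC", ub = "UMI1", variant = "V1") {
  data.frame(variant_name = variant, cb = cb, ub = ub,
             observed_allele = alleles, stringsAsFactors = FALSE)
}

one_variant <- function(ploidy = "hemizygous") {
  data.frame(name = "V1", chrom = "chrX", pos = 1000L, ref_allele = "C",
             alt_allele = "T", ploidy_mode = ploidy, stringsAsFactors = FALSE)
}

# Random raw matrix with Poisson counts (seeded).
random_raw <- function(n_genes, n_cells, lambda = 2, seed = 1) {
  set.seed(seed)
  raw_cm(matrix(rpois(n_genes * n_cells, lambda), n_genes))
}
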
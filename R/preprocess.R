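#' Quality-control configuration for cell filtering
#'
#' Defaults follow common droplet scRNA-seq practice: cells with fewer than
#' 500 detected genes are treated as low-quality fragments, cells with more
#' than 3,000 as potential doublets, and cells whose mitochondrial read
#' fraction exceeds 10% as damaged. Gene-count bounds are kept inclusive
#' (`[min_genes, max_genes]`); the mitochondrial bound removes cells
#' strictly above `max_mito_frac`.
#'
#' @param min_genes minimum detected genes (inclusive keep bound).
#' @param max_genes maximum detected genes (inclusive keep bound).
#' @param max_mito_frac maximum tolerated mitochondrial fraction.
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_genes = 500L, max_genes = 3000L,
                      max_mito_frac = 0.10, mito_prefix = "MT-") {
  if (min_genes >= max_genes) abort_param("min_genes must be < max_genes")
  if (max_mito_frac < 0 || max_mito_frac > 1) abort_param("max_mito_frac must lie in [0,1]")
  structure(list(min_genes = as.integer(min_genes), max_genes = as.integer(max_genes),
                 max_mito_frac = max_mito_frac, mito_prefix = mito_prefix),
            class = "qc_config")
}

#' Filter cells on detected-gene count and mitochondrial fraction
#'
#' Keeps cells with `min_genes <= n_genes <= max_genes` and mitochondrial
#' fraction `<= max_mito_frac`. The report lists every cell with its
#' metrics, whether it was kept and, if not, the first failing rule
#' (`low_genes`, `high_genes`, `high_mito`).
#'
#' @param m raw-layer `count_matrix`.
#' @param qc a [qc_config()].
#' @return List with elements `matrix` (filtered `count_matrix`) and
#'   `report` (per-cell data.frame: barcode, n_genes, mito_frac, kept,
#'   fail_reason).
#' @export
filter_cells <- function(m, qc = qc_config()) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "raw") abort_usage("filter_cells expects the raw layer")
  cm <- m$counts
  n_genes <- Matrix::colSums(cm > 0)
  mito <- startsWith(m$genes, qc$mito_prefix)
  tot <- Matrix::colSums(cm)
  mito_frac <- ifelse(tot > 0, Matrix::colSums(cm[mito, , drop = FALSE]) / tot, 0)
  fail <- rep(NA_character_, length(n_genes))
  fail[mito_frac > qc$max_mito_frac] <- "high_mito"
  fail[n_genes > qc$max_genes] <- "high_genes"
  fail[n_genes < qc$min_genes] <- "low_genes"
  kept <- is.na(fail)
  report <- data.frame(barcode = m$cells, n_genes = as.integer(n_genes),
                       mito_frac = as.numeric(mito_frac), kept = kept,
                       fail_reason = fail, stringsAsFactors = FALSE)
  if (!any(kept)) warning("all cells removed by QC filtering")
  out <- subset_matrix(m, cells = m$cells[kept])
  list(matrix = out, report = report)
}

#' Library-size log-normalization
#'
#' Each cell's counts are scaled to a common library size (`target`, default
#' 10,000) and log-transformed: `log(1 + c * target / colsum)`. Cells with
#' zero total counts are left all-zero with a warning.
#'
#' @param m raw-layer `count_matrix`.
#' @param target library-size target.
#' @return A lognorm-layer `count_matrix`.
#' @export
normalize_log <- function(m, target = 1e4) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "raw") abort_usage("normalize_log expects the raw layer")
  cs <- Matrix::colSums(m$counts)
  zero <- cs == 0
  if (any(zero)) {
    warning(sprintf("%d cell(s) with zero counts left all-zero", sum(zero)))
  }
  sf <- ifelse(zero, 0, target / cs)
  ln <- m$counts %*% Matrix::Diagonal(x = sf)
  ln@x <- log1p(ln@x)
  out <- count_matrix(ln, m$genes, m$cells, layer = "lognorm",
                      size_factor_target = target)
  out
}

#' Select highly variable genes by binned dispersion z-scores
#'
#' Mean/dispersion procedure on the log-normalized layer: per gene, the
#' mean and dispersion (variance/mean) of `expm1(lognorm)` are computed;
#' genes are cut into `n_bins` equal-width bins of log-mean expression, the
#' log-dispersion is z-scored within each bin, and genes at or above the
#' `dispersion_cutoff` z-score are returned (or the `n_target` genes with
#' the highest z).
#'
#' @param m lognorm-layer `count_matrix`.
#' @param dispersion_cutoff z-score cutoff (default 0.5).
#' @param n_target if given, return this many genes by decreasing z instead
#'   of applying the cutoff.
#' @param n_bins number of mean-expression bins (default 20).
#' @return Character vector of selected gene symbols, ordered by decreasing
#'   dispersion z-score, with the per-gene statistics in attribute `stats`.
#' @export
select_hvg <- function(m, dispersion_cutoff = 0.5, n_target = NULL, n_bins = 20L) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "lognorm") abort_usage("select_hvg expects the lognorm layer")
  ex <- m$counts
  ex@x <- expm1(ex@x)
  mu <- Matrix::rowMeans(ex)
  ex2 <- ex; ex2@x <- ex2@x^2
  n <- ncol(ex)
  v <- (Matrix::rowMeans(ex2) - mu^2) * n / max(1, n - 1)
  expressed <- mu > 0
  if (sum(expressed) < n_bins) {
    abort_param(sprintf("need at least %d expressed genes, have %d", n_bins, sum(expressed)))
  }
  log_mu <- log1p(mu)
  disp <- rep(NA_real_, length(mu))
  disp[expressed] <- log(v[expressed] / mu[expressed] + 1e-12)
  bin <- rep(NA_integer_, length(mu))
  bin[expressed] <- as.integer(cut(log_mu[expressed], breaks = n_bins))
  z <- rep(NA_real_, length(mu))
  for (b in unique(bin[!is.na(bin)])) {
    idx <- which(bin == b)
    mu_b <- mean(disp[idx])
    sd_b <- sd(disp[idx])
    z[idx] <- if (is.na(sd_b) || sd_b == 0) 0 else (disp[idx] - mu_b) / sd_b
  }
  stats <- data.frame(gene = m$genes, mean = mu, dispersion = disp,
                      bin = bin, z = z, stringsAsFactors = FALSE)
  ok <- which(!is.na(z))
  ord <- ok[order(z[ok], decreasing = TRUE)]
  sel <- if (!is.null(n_target)) {
    head(ord, n_target)
  } else {
    ord[z[ord] >= dispersion_cutoff]
  }
  out <- m$genes[sel]
  attr(out, "stats") <- stats
  out
}
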
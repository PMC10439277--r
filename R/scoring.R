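# Per-cell gene-program scores: bin-matched module scores, set-recovery
# AUC scores, cell-cycle phase, composite scores, and score correlation.

# Equal-frequency bins of the per-gene average expression.
expression_bins <- function(avg, n_bins) {
  br <- quantile(avg, probs = seq(0, 1, length.out = n_bins + 1))
  br[1] <- -Inf; br[length(br)] <- Inf
  br <- unique(br)
  as.integer(cut(avg, breaks = br, include.lowest = TRUE))
}

#' Per-cell module score of a gene set
#'
#' The per-cell mean log-normalized expression of the set genes minus the
#' mean of an expression-matched control set: genes are binned into
#' `n_bins` equal-frequency bins of average expression and, for each set
#' gene, `n_ctrl` control genes are sampled (seeded) from its bin; the
#' pooled control genes form the baseline. Scores are therefore centered
#' near zero for sets indistinguishable from their expression-matched
#' background, and positive where the program is active.
#'
#' @param m lognorm-layer `count_matrix`.
#' @param set character vector of gene symbols.
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl control genes drawn per set gene (default 100).
#' @param seed integer seed for control sampling.
#' @return Named numeric vector of per-cell scores (names = barcodes) with
#'   attributes `set_genes` (symbols used) and `ctrl_genes`.
#' @export
module_score <- function(m, set, n_bins = 24L, n_ctrl = 100L, seed = 1L) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "lognorm") abort_usage("module_score expects the lognorm layer")
  set_use <- intersect(unique(set), m$genes)
  if (!length(set_use)) abort_param("gene set has no genes in the matrix")
  if (length(m$genes) < n_bins) abort_param("fewer genes than expression bins")
  avg <- Matrix::rowMeans(m$counts)
  bins <- expression_bins(avg, n_bins)
  names(bins) <- m$genes
  ctrl <- character(0)
  rs <- .make_rng(seed)
  for (g in set_use) {
    pool <- m$genes[bins == bins[[g]]]
    k <- min(n_ctrl, length(pool))
    ctrl <- c(ctrl, pool[.sample_int(rs, length(pool), k)])
  }
  ctrl <- unique(ctrl)
  set_mean <- Matrix::colMeans(m$counts[set_use, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(m$counts[ctrl, , drop = FALSE])
  score <- setNames(as.numeric(set_mean - ctrl_mean), m$cells)
  attr(score, "set_genes") <- set_use
  attr(score, "ctrl_genes") <- ctrl
  score
}

# Local RNG stream so module_score never perturbs the caller's RNG state.
.make_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  env
}

.sample_int <- function(rs, n, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rs$state, globalenv())
  out <- sample.int(n, k)
  rs$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  out
}

#' Per-cell AUC recovery score of a gene set
#'
#' Area under the set-recovery curve within the top-ranked fraction of a
#' cell's genes: genes are ranked by decreasing expression in that cell
#' (ties take the average rank, so the score is deterministic), and the
#' score integrates how early the set genes are recovered within the top
#' `top_frac` of the ranking, normalized so that a cell whose top ranks are
#' exactly the set genes scores 1. Depends on expression only through
#' within-cell ranks, so it is invariant to any strictly monotone
#' per-cell transform.
#'
#' @param m lognorm-layer `count_matrix`.
#' @param set character vector of gene symbols.
#' @param top_frac fraction of the ranking that counts (default 0.05).
#' @return Named numeric vector of per-cell AUC scores in `[0, 1]`.
#' @export
auc_score <- function(m, set, top_frac = 0.05) {
  stopifnot(inherits(m, "count_matrix"))
  set_use <- intersect(unique(set), m$genes)
  if (!length(set_use)) abort_param("gene set has no genes in the matrix")
  n <- length(m$genes)
  k <- floor(top_frac * n)
  if (k < 2) abort_param("top_frac * n_genes must be at least 2")
  mat <- as.matrix(m$counts)
  set_idx <- match(set_use, m$genes)
  s <- length(set_idx)
  denom <- sum(k - seq_len(min(s, k)) + 1)
  score <- apply(mat, 2L, function(x) {
    r <- rank(-x, ties.method = "average")[set_idx]
    sum(pmin(pmax(k - r + 1, 0), k)) / denom
  })
  setNames(pmin(as.numeric(score), 1), m$cells)
}

#' Cell-cycle phase assignment
#'
#' Computes S-phase and G2/M module scores and assigns each cell the phase
#' of its highest score; cells with neither score above zero are labeled
#' G1 (not cycling).
#'
#' @param m lognorm-layer `count_matrix`.
#' @param s_genes,g2m_genes phase marker gene sets.
#' @param seed seed for the module-score control draws.
#' @return data.frame `cb`, `s_score`, `g2m_score`, `phase`.
#' @export
cell_cycle_phase <- function(m, s_genes, g2m_genes, seed = 1L) {
  s <- module_score(m, s_genes, seed = seed)
  g2m <- module_score(m, g2m_genes, seed = seed + 1L)
  phase <- ifelse(pmax(s, g2m) <= 0, "G1", ifelse(s >= g2m, "S", "G2M"))
  data.frame(cb = m$cells, s_score = as.numeric(s),
             g2m_score = as.numeric(g2m), phase = phase,
             stringsAsFactors = FALSE)
}

#' Composite module score over several gene sets
#'
#' Module score of the union of the listed sets — e.g. a composite
#' inflammatory score over the interferon-alpha, interferon-gamma,
#' TNF-alpha-via-NF-kB and inflammatory-response hallmark sets.
#'
#' @param m lognorm-layer `count_matrix`.
#' @param sets list of character vectors.
#' @param mode only `"union"` is defined.
#' @inheritParams module_score
#' @return Named numeric vector of per-cell scores.
#' @export
composite_score <- function(m, sets, mode = "union", n_bins = 24L,
                            n_ctrl = 100L, seed = 1L) {
  mode <- match.arg(mode, "union")
  if (!length(sets)) abort_param("need at least one gene set")
  module_score(m, unique(unlist(sets)), n_bins = n_bins, n_ctrl = n_ctrl,
               seed = seed)
}

#' Pearson correlation between two per-cell scores
#'
#' At `level = "cell"` the scores are paired by barcode; at
#' `level = "donor"` each donor contributes its mean score (per-donor
#' aggregation), mirroring per-patient correlation analyses.
#'
#' @param x,y named numeric score vectors (names = barcodes).
#' @param level `"cell"` or `"donor"`.
#' @param donors named character vector mapping barcode to donor (required
#'   for donor level).
#' @return List `r`, `p`, `n`, `level`; `r` and `p` are `NA` if either
#'   score has zero variance.
#' @export
score_correlation <- function(x, y, level = c("cell", "donor"), donors = NULL) {
  level <- match.arg(level)
  common <- intersect(names(x), names(y))
  x <- x[common]; y <- y[common]
  if (level == "donor") {
    if (is.null(donors)) abort_usage("donor-level correlation needs a donor map")
    d <- donors[common]
    x <- tapply(x, d, mean)
    y <- tapply(y, d, mean)
  }
  if (length(x) < 3L) abort_param("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x), level = level))
  }
  ct <- cor.test(as.numeric(x), as.numeric(y), method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), level = level)
}

#' Ratio of mean scores between two groups
#'
#' Module scores can be negative, so both group means are computed after
#' shifting all scores by `-min(score) + eps`; the ratio of shifted means
#' (group A over group B) is returned with the shift recorded. A ratio of
#' 1 means equal mean program activity.
#'
#' @param score named numeric score vector.
#' @param cells_a,cells_b barcode vectors of the two groups.
#' @param eps positive stabilizer added to the shift (default 1e-9).
#' @return List `ratio`, `shift`, `mean_a`, `mean_b` (shifted means);
#'   `ratio` is `NA` when the shifted B mean is zero.
#' @export
group_score_ratio <- function(score, cells_a, cells_b, eps = 1e-9) {
  if (!length(cells_a) || !length(cells_b)) {
    abort_param("both groups must be nonempty")
  }
  shift <- -min(score) + eps
  a <- mean(score[cells_a]) + shift
  b <- mean(score[cells_b]) + shift
  list(ratio = if (b == 0) NA_real_ else a / b, shift = shift,
       mean_a = a, mean_b = b)
}

#' Center scores on each dataset's control cells
#'
#' Subtracts, within each dataset, the mean score of that dataset's control
#' cells, so that case scores become comparable across datasets with
#' different baselines.
#'
#' @param score named numeric score vector.
#' @param dataset character vector (per cell) naming the dataset.
#' @param is_control logical vector (per cell).
#' @return Named numeric vector of normalized scores.
#' @export
normalized_activity <- function(score, dataset, is_control) {
  stopifnot(length(score) == length(dataset), length(score) == length(is_control))
  out <- score
  for (d in unique(dataset)) {
    idx <- dataset == d
    ctrl <- idx & is_control
    if (!any(ctrl)) abort_param(sprintf("dataset '%s' has no control cells", d))
    out[idx] <- score[idx] - mean(score[ctrl])
  }
  out
}

#' Write per-cell scores
#' @param scores named list of score vectors sharing barcodes.
#' @param path output TSV path.
#' @export
write_scores <- function(scores, path) {
  cb <- names(scores[[1]])
  df <- data.frame(barcode = cb, stringsAsFactors = FALSE)
  for (nm in names(scores)) df[[nm]] <- as.numeric(scores[[nm]][cb])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
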
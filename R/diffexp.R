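# Two-group differential expression and pre-ranked gene-set enrichment.

#' Differential expression between two cell groups
#'
#' Per gene: two-sided Wilcoxon rank-sum test of group A versus group B on
#' the log-normalized layer, log2 fold change of de-logged means
#' (`log2(mean(expm1)+1)` difference), Bonferroni adjustment over tested
#' genes, and the joint significance rule `p < 0.05 & |log2fc| > 0.1`.
#' Genes detected in fewer than `min_frac` of the cells of both groups are
#' not tested.
#'
#' @param m lognorm-layer `count_matrix`.
#' @param cells_a,cells_b barcode vectors of the two groups (>= 3 cells each).
#' @param min_frac minimum detected fraction in at least one group
#'   (default 0.1).
#' @param p_max,lfc_min joint significance thresholds (defaults 0.05, 0.1).
#' @return data.frame `gene`, `log2fc`, `p`, `p_adj`, `significant`,
#'   ordered by increasing p.
#' @export
differential_expression <- function(m, cells_a, cells_b, min_frac = 0.1,
                                    p_max = 0.05, lfc_min = 0.1) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "lognorm") abort_usage("differential_expression expects the lognorm layer")
  if (length(cells_a) < 3L || length(cells_b) < 3L) {
    abort_param("both groups need at least 3 cells")
  }
  sub <- m$counts[, c(cells_a, cells_b), drop = FALSE]
  in_a <- c(rep(TRUE, length(cells_a)), rep(FALSE, length(cells_b)))
  det_a <- Matrix::rowMeans(sub[, in_a, drop = FALSE] > 0)
  det_b <- Matrix::rowMeans(sub[, !in_a, drop = FALSE] > 0)
  test <- det_a >= min_frac | det_b >= min_frac
  if (!any(test)) {
    return(data.frame(gene = character(), log2fc = numeric(), p = numeric(),
                      p_adj = numeric(), significant = logical()))
  }
  mat <- as.matrix(sub[test, , drop = FALSE])
  p <- row_wilcox_p(mat, in_a)
  lfc <- row_log2fc(mat, in_a)
  res <- data.frame(gene = m$genes[test], log2fc = lfc, p = p,
                    p_adj = pmin(1, p * sum(test)),
                    stringsAsFactors = FALSE)
  res$significant <- res$p < p_max & abs(res$log2fc) > lfc_min
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  res
}

# Weighted Kolmogorov-Smirnov running sum over a ranking. Genes must be
# ordered by decreasing statistic. Returns the signed extreme (ES) and the
# running sum itself.
gsea_running_sum <- function(is_hit, stat, weight_p = 1) {
  n <- length(is_hit)
  nh <- sum(is_hit)
  w <- abs(stat)^weight_p
  w[!is_hit] <- 0
  tot <- sum(w)
  inc <- if (tot > 0) w / tot else ifelse(is_hit, 1 / nh, 0)
  dec <- ifelse(is_hit, 0, 1 / (n - nh))
  run <- cumsum(inc - dec)
  i <- which.max(abs(run))
  list(es = run[[i]], at = i, run = run)
}

#' Pre-ranked gene-set enrichment with a permutation null
#'
#' Enrichment score of a gene set along a ranked gene list: the extreme of
#' the weighted Kolmogorov-Smirnov running sum (set genes step the sum up
#' by `|stat|^weight_p`, normalized; other genes step it down uniformly).
#' The null is gene-label permutation: set positions are redrawn uniformly
#' `n_perm` times. The normalized score divides ES by the mean magnitude
#' of same-sign permutation scores, and the p-value is the +1-smoothed
#' fraction of permutations whose |ES| reaches the observed |ES|.
#'
#' @param ranking data.frame with columns `gene` and `stat`; sorted
#'   internally by decreasing stat. Duplicate genes are an error.
#' @param set character vector of gene symbols.
#' @param n_perm number of permutations (default 1000).
#' @param weight_p rank-statistic weight exponent (default 1; 0 gives the
#'   unweighted classic running sum).
#' @param seed RNG seed for the permutations.
#' @return List of class `gsea_result`: `set_size`, `es`, `nes`, `p`,
#'   `leading_edge` (genes), `at` (position of the extreme).
#' @export
gsea_preranked <- function(ranking, set, n_perm = 1000L, weight_p = 1,
                           seed = 1L) {
  if (anyDuplicated(ranking$gene)) abort_format("duplicate genes in ranking")
  ord <- order(ranking$stat, decreasing = TRUE)
  genes <- ranking$gene[ord]
  stat <- ranking$stat[ord]
  is_hit <- genes %in% set
  nh <- sum(is_hit)
  if (nh == 0L) abort_param("gene set has no genes in the ranking")
  if (nh == length(genes)) abort_param("gene set covers the whole ranking")
  obs <- gsea_running_sum(is_hit, stat, weight_p)
  n <- length(genes)
  perm_es <- numeric(n_perm)
  rs <- .make_rng(seed)
  for (b in seq_len(n_perm)) {
    idx <- .sample_int(rs, n, nh)
    hit_b <- logical(n); hit_b[idx] <- TRUE
    perm_es[[b]] <- gsea_running_sum(hit_b, stat, weight_p)$es
  }
  same_sign <- perm_es[sign(perm_es) == sign(obs$es)]
  denom <- if (length(same_sign)) mean(abs(same_sign)) else mean(abs(perm_es))
  nes <- if (denom > 0) obs$es / denom else NA_real_
  p <- (1 + sum(abs(perm_es) >= abs(obs$es))) / (n_perm + 1)
  le <- if (obs$es >= 0) genes[seq_len(obs$at)][is_hit[seq_len(obs$at)]]
        else genes[obs$at:n][is_hit[obs$at:n]]
  structure(list(set_size = nh, es = obs$es, nes = nes, p = p,
                 leading_edge = le, at = obs$at),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> ES = %.3f, NES = %.3f, p = %.4g, %d set genes, %d leading edge\n",
              x$es, x$nes, x$p, x$set_size, length(x$leading_edge)))
  invisible(x)
}
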
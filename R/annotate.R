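# Rank-sum marker detection and Fisher-enrichment cell-type assignment.

# Two-sided Wilcoxon rank-sum p-values for every row of a dense matrix,
# group membership given by a logical vector. Normal approximation with
# tie correction and continuity correction (the standard large-sample
# form; expression data are tie-heavy so exact p-values do not apply).
row_wilcox_p <- function(mat, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  stopifnot(n1 > 0, n2 > 0)
  apply(mat, 1L, function(x) {
    r <- rank(x)
    w <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- table(x)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sig2 <= 0) return(1)
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    2 * stats::pnorm(-abs(z))
  })
}

# log2 fold change on the de-logged scale: log2(mean(expm1)+1) difference.
row_log2fc <- function(mat, in_group) {
  m1 <- rowMeans(expm1(mat[, in_group, drop = FALSE]))
  m2 <- rowMeans(expm1(mat[, !in_group, drop = FALSE]))
  log2(m1 + 1) - log2(m2 + 1)
}

#' Marker genes of one cluster versus all other cells
#'
#' Per gene: two-sided Wilcoxon rank-sum test of the cluster's cells
#' against all remaining cells on the log-normalized layer, log2 fold
#' change of de-logged means, and Bonferroni-adjusted p-values over the
#' tested genes.
#'
#' @param m lognorm-layer `count_matrix`.
#' @param clusters character vector of cluster labels, one per cell.
#' @param cluster the cluster to characterize.
#' @return data.frame `cluster`, `gene`, `log2fc`, `p`, `p_adj`, sorted by
#'   increasing p then decreasing log2fc; `NULL` (with a warning) if the
#'   cluster has fewer than 3 cells.
#' @export
find_markers <- function(m, clusters, cluster) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "lognorm") abort_usage("find_markers expects the lognorm layer")
  if (length(clusters) != length(m$cells)) {
    abort_usage("cluster labels must match the number of cells")
  }
  if (length(unique(clusters)) < 2L) abort_usage("need at least two clusters")
  in_c <- clusters == cluster
  if (sum(in_c) < 3L) {
    warning(sprintf("cluster '%s' has fewer than 3 cells; skipped", cluster))
    return(NULL)
  }
  mat <- as.matrix(m$counts)
  p <- row_wilcox_p(mat, in_c)
  lfc <- row_log2fc(mat, in_c)
  res <- data.frame(cluster = cluster, gene = m$genes, log2fc = lfc, p = p,
                    p_adj = pmin(1, p * length(p)), stringsAsFactors = FALSE)
  res <- res[order(res$p, -res$log2fc), ]
  rownames(res) <- NULL
  res
}

#' Hypergeometric upper-tail enrichment p-value
#'
#' Probability of an overlap at least as large as observed when `n_marker`
#' genes are drawn from a background of `n_background` genes containing
#' `n_signature` signature genes (one-tailed Fisher's exact test).
#'
#' @param overlap observed overlap count.
#' @param n_marker size of the marker list.
#' @param n_signature size of the signature within the background.
#' @param n_background background universe size.
#' @return Upper-tail p-value `P(X >= overlap)`.
#' @export
enrichment_p <- function(overlap, n_marker, n_signature, n_background) {
  phyper(overlap - 1, n_signature, n_background - n_signature, n_marker,
         lower.tail = FALSE)
}

#' Assign cell types to clusters by signature enrichment
#'
#' For each cluster the thresholded marker genes are tested against every
#' signature gene set with a one-tailed Fisher's exact test (hypergeometric
#' upper tail) over the expressed-gene background; the cluster is assigned
#' the signature with the smallest p-value. Ties are broken by larger
#' overlap, then lexicographic signature name, and flagged. Signatures and
#' marker lists are intersected with the background first.
#'
#' @param markers named list of marker data.frames (one per cluster, as
#'   returned by [find_markers()]), or a single data.frame with a `cluster`
#'   column.
#' @param signatures named list of character vectors (e.g. top-250
#'   signature gene lists read from GMT).
#' @param background character vector: the gene universe (typically genes
#'   expressed in more than `min_cells_expressed` cells, see
#'   [expressed_background()]).
#' @param p_adj_max,log2fc_min marker thresholds applied before testing.
#' @return data.frame `cluster`, `assigned_type`, `p_enrich`, `overlap`,
#'   `n_markers`, `n_signature`, `tied` (flag). Clusters with no markers
#'   after thresholding are assigned `"unassigned"`.
#' @export
assign_types <- function(markers, signatures, background,
                         p_adj_max = 0.05, log2fc_min = 0.25) {
  if (is.data.frame(markers)) {
    markers <- split(markers, markers$cluster)
  }
  background <- unique(background)
  sigs <- lapply(signatures, function(s) intersect(unique(s), background))
  out <- lapply(names(markers), function(cl) {
    mk <- markers[[cl]]
    mk <- mk[mk$p_adj < p_adj_max & mk$log2fc > log2fc_min, , drop = FALSE]
    genes <- intersect(mk$gene, background)
    if (!length(genes)) {
      return(data.frame(cluster = cl, assigned_type = "unassigned",
                        p_enrich = NA_real_, overlap = 0L,
                        n_markers = 0L, n_signature = NA_integer_,
                        tied = FALSE, stringsAsFactors = FALSE))
    }
    ov <- vapply(sigs, function(s) length(intersect(genes, s)), integer(1))
    p <- vapply(seq_along(sigs), function(i) {
      enrichment_p(ov[[i]], length(genes), length(sigs[[i]]), length(background))
    }, numeric(1))
    ord <- order(p, -ov, names(sigs))
    best <- ord[[1]]
    tied <- sum(p == p[best] & ov == ov[best]) > 1L
    data.frame(cluster = cl, assigned_type = names(sigs)[best],
               p_enrich = p[best], overlap = ov[[best]],
               n_markers = length(genes), n_signature = length(sigs[[best]]),
               tied = tied, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Background gene universe: genes expressed in more than a minimum number of cells
#'
#' @param m `count_matrix` (either layer; nonzero entries count as expressed).
#' @param min_cells genes detected in more than this many cells are kept
#'   (default 100).
#' @return Character vector of gene symbols.
#' @export
expressed_background <- function(m, min_cells = 100L) {
  stopifnot(inherits(m, "count_matrix"))
  m$genes[Matrix::rowSums(m$counts > 0) > min_cells]
}
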
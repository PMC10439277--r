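# Ligand-receptor interaction scoring between cell types.

#' Housekeeping-normalized expression
#'
#' Per cell, subtracts the mean log-normalized expression of a housekeeping
#' gene set from every gene: `Enorm[g, i] = E[g, i] - mean_hk(E[., i])`.
#' The result is invariant to adding a constant to all genes of a cell.
#'
#' @param m lognorm-layer `count_matrix`.
#' @param housekeeping character vector of housekeeping gene symbols.
#' @return Dense numeric matrix (genes x cells) with attribute `hk_genes`.
#' @export
housekeeping_normalize <- function(m, housekeeping) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "lognorm") abort_usage("housekeeping_normalize expects the lognorm layer")
  hk <- intersect(unique(housekeeping), m$genes)
  if (!length(hk)) abort_param("no housekeeping genes found in the matrix")
  base <- Matrix::colMeans(m$counts[hk, , drop = FALSE])
  en <- sweep(as.matrix(m$counts), 2L, base, `-`)
  attr(en, "hk_genes") <- hk
  en
}

#' Ligand-receptor interaction scores between cell types
#'
#' For every ordered pair of cell types (A, B) and every ligand-receptor
#' pair (L, R): `s = mean_A(Enorm_L) * mean_B(Enorm_R)` — the product of
#' average housekeeping-normalized ligand expression in the sender type and
#' average receptor expression in the receiver type. Significance that
#' `s > 0` is assessed with a one-sided Wilcoxon signed-rank test on the
#' per-sender-cell contributions `Enorm_L[i] * mean_B(Enorm_R)` (a
#' label-permutation alternative is available via `method`).
#'
#' @param en housekeeping-normalized matrix from [housekeeping_normalize()].
#' @param pairs data.frame with columns `ligand`, `receptor`; pairs with a
#'   gene absent from the matrix are skipped and reported in the
#'   `skipped_pairs` attribute.
#' @param type_labels named character vector mapping barcode to cell type.
#' @param types optional subset of types to score (default: all).
#' @param method `"signrank"` or `"permutation"` for the p-value.
#' @param n_perm permutations when `method = "permutation"`.
#' @param seed RNG seed for the permutation test.
#' @return data.frame `ligand`, `receptor`, `type_a`, `type_b`, `s`, `p`.
#' @export
pair_scores <- function(en, pairs, type_labels, types = NULL,
                        method = c("signrank", "permutation"),
                        n_perm = 200L, seed = 1L) {
  method <- match.arg(method)
  cells <- colnames(en)
  type_labels <- type_labels[cells]
  types <- types %||% sort(unique(type_labels))
  for (tp in types) if (!any(type_labels == tp)) abort_param(sprintf("type '%s' has no cells", tp))
  known <- pairs$ligand %in% rownames(en) & pairs$receptor %in% rownames(en)
  skipped <- pairs[!known, , drop = FALSE]
  if (nrow(skipped)) {
    message(sprintf("skipping %d ligand-receptor pair(s) with unknown genes", nrow(skipped)))
  }
  pairs <- pairs[known, , drop = FALSE]
  idx_by_type <- lapply(types, function(tp) which(type_labels == tp))
  names(idx_by_type) <- types
  rs <- .make_rng(seed)
  out <- list()
  for (a in types) for (b in types) {
    ia <- idx_by_type[[a]]; ib <- idx_by_type[[b]]
    for (j in seq_len(nrow(pairs))) {
      L <- pairs$ligand[[j]]; R <- pairs$receptor[[j]]
      lig_a <- en[L, ia]
      mean_r_b <- mean(en[R, ib])
      s <- mean(lig_a) * mean_r_b
      contrib <- lig_a * mean_r_b
      p <- if (method == "signrank") {
        if (all(contrib == 0)) 1
        else suppressWarnings(wilcox.test(contrib, mu = 0, alternative = "greater")$p.value)
      } else {
        pool <- en[L, ]
        perm <- vapply(seq_len(n_perm), function(k) {
          mean(pool[.sample_int(rs, length(pool), length(ia))]) * mean_r_b
        }, numeric(1))
        (1 + sum(perm >= s)) / (n_perm + 1)
      }
      out[[length(out) + 1L]] <- data.frame(
        ligand = L, receptor = R, type_a = a, type_b = b, s = s, p = p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "skipped_pairs") <- skipped
  res
}

#' Per-cell summed interaction scores with a partner population
#'
#' For each focal cell i (e.g. an HSPC), sums over all ligand-receptor
#' pairs the interaction of that single cell with the partner population's
#' mean profile. By default both roles are summed:
#' `s_total(i) = sum_pairs Enorm_L[i] * mean_partner(Enorm_R) +
#' Enorm_R[i] * mean_partner(Enorm_L)`; `direction` restricts the focal
#' cell to the ligand or receptor role.
#'
#' @param en housekeeping-normalized matrix from [housekeeping_normalize()].
#' @param pairs data.frame with `ligand`, `receptor` columns.
#' @param cells barcodes of the focal cells.
#' @param partner_cells barcodes of the partner population (nonempty).
#' @param direction `"both"`, `"ligand"` (focal cell sends only) or
#'   `"receptor"` (focal cell receives only).
#' @return data.frame `cb`, `s_total`.
#' @export
per_cell_scores <- function(en, pairs, cells, partner_cells,
                            direction = c("both", "ligand", "receptor")) {
  direction <- match.arg(direction)
  if (!length(partner_cells)) abort_param("partner population is empty")
  known <- pairs$ligand %in% rownames(en) & pairs$receptor %in% rownames(en)
  pairs <- pairs[known, , drop = FALSE]
  if (!nrow(pairs)) abort_param("no scoreable ligand-receptor pairs")
  partner_mean <- rowMeans(en[, partner_cells, drop = FALSE])
  lig <- en[pairs$ligand, cells, drop = FALSE]
  rec <- en[pairs$receptor, cells, drop = FALSE]
  # ligand role: focal cell's ligand x partner's mean receptor
  lig_term <- colSums(lig * partner_mean[pairs$receptor])
  # receptor role: focal cell's receptor x partner's mean ligand
  rec_term <- colSums(rec * partner_mean[pairs$ligand])
  s_total <- switch(direction,
                    both = lig_term + rec_term,
                    ligand = lig_term,
                    receptor = rec_term)
  data.frame(cb = cells, s_total = as.numeric(s_total),
             stringsAsFactors = FALSE)
}
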
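# Reference projection and windowed pseudotime curves.

#' Project query cells onto a reference by Pearson correlation
#'
#' Each query cell is matched to the reference cell with the highest
#' Pearson correlation over the shared highly-variable genes, and inherits
#' that cell's pseudotime and branch. Ties take the first reference index
#' and are flagged; zero-variance query profiles cannot be correlated and
#' are returned with `NA` matches, flagged.
#'
#' @param query,reference lognorm-layer `count_matrix` objects.
#' @param hvg character vector of highly-variable genes (>= 10 shared with
#'   both matrices).
#' @param reference_meta data.frame with `barcode`, `pseudotime`, `branch`
#'   for the reference cells.
#' @return data.frame `cb`, `ref_cb`, `r`, `pseudotime`, `branch`, `tied`,
#'   `degenerate`.
#' @export
project_to_reference <- function(query, reference, hvg, reference_meta) {
  g <- Reduce(intersect, list(hvg, query$genes, reference$genes))
  if (length(g) < 10L) abort_param("need at least 10 shared highly-variable genes")
  qm <- as.matrix(query$counts[g, , drop = FALSE])
  rm_ <- as.matrix(reference$counts[g, , drop = FALSE])
  q_sd <- apply(qm, 2L, sd)
  r_sd <- apply(rm_, 2L, sd)
  usable_ref <- r_sd > 0
  if (!any(usable_ref)) abort_param("all reference cells are zero-variance on the HVGs")
  cc <- suppressWarnings(cor(qm, rm_[, usable_ref, drop = FALSE]))
  ref_cells <- reference$cells[usable_ref]
  meta_idx <- match(ref_cells, reference_meta$barcode)
  out <- lapply(seq_along(query$cells), function(i) {
    if (q_sd[[i]] == 0) {
      return(data.frame(cb = query$cells[[i]], ref_cb = NA_character_,
                        r = NA_real_, pseudotime = NA_real_,
                        branch = NA_character_, tied = FALSE,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    ri <- cc[i, ]
    best <- which.max(ri)
    tied <- sum(ri == ri[[best]]) > 1L
    mi <- meta_idx[[best]]
    data.frame(cb = query$cells[[i]], ref_cb = ref_cells[[best]],
               r = ri[[best]],
               pseudotime = if (is.na(mi)) NA_real_ else reference_meta$pseudotime[[mi]],
               branch = if (is.na(mi)) NA_character_ else reference_meta$branch[[mi]],
               tied = tied, degenerate = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Equal-width half-open windows on [0,1]; t = 1 falls in the last window.
pseudotime_windows <- function(n_windows) {
  data.frame(t_lo = (seq_len(n_windows) - 1) / n_windows,
             t_hi = seq_len(n_windows) / n_windows)
}

window_index <- function(t, n_windows) {
  pmin(floor(t * n_windows) + 1L, n_windows)
}

window_curve <- function(branch, windows, values, kind, pseudocount = NA_real_,
                         flagged = rep(FALSE, nrow(windows))) {
  structure(data.frame(branch = branch, t_lo = windows$t_lo,
                       t_hi = windows$t_hi, value = values, flagged = flagged,
                       stringsAsFactors = FALSE),
            kind = kind, pseudocount = pseudocount,
            class = c("window_curve", "data.frame"))
}

#' Case/control cell-abundance log2-ratio along pseudotime
#'
#' Pseudotime is cut into equal-width windows; per window the log2 ratio of
#' the within-group cell percentages (case over control) is computed with a
#' pseudocount: `log2((n_case + pc)/(N_case + pc*W)) -
#' log2((n_ctrl + pc)/(N_ctrl + pc*W))`. Percentages are within-group, so
#' unequal group sizes cancel.
#'
#' @param case_t,control_t numeric pseudotimes in `[0,1]` of the two groups
#'   on the branch.
#' @param branch branch label carried into the output.
#' @param n_windows number of windows (default 20).
#' @param pseudocount cells added per window (default 0.5).
#' @return A `window_curve` of kind `abundance_log2_ratio`.
#' @export
abundance_ratio_curve <- function(case_t, control_t, branch = "branch",
                                  n_windows = 20L, pseudocount = 0.5) {
  if (!length(case_t) || !length(control_t)) {
    abort_param("both groups need cells on the branch")
  }
  w <- pseudotime_windows(n_windows)
  nc <- tabulate(window_index(case_t, n_windows), n_windows)
  nk <- tabulate(window_index(control_t, n_windows), n_windows)
  val <- log2((nc + pseudocount) / (length(case_t) + pseudocount * n_windows)) -
         log2((nk + pseudocount) / (length(control_t) + pseudocount * n_windows))
  window_curve(branch, w, val, "abundance_log2_ratio", pseudocount,
               flagged = nc == 0 & nk == 0)
}

#' Lineage-priming score log-ratio along pseudotime
#'
#' Per window, the log (natural by default) of the ratio of mean case
#' lineage scores (e.g. AUC recovery scores) to mean control scores.
#' Windows where either group is absent or has non-positive mean score are
#' reported as `NA`.
#'
#' @param case_scores,control_scores data.frames with columns `t`
#'   (pseudotime) and `score`.
#' @param branch branch label.
#' @param n_windows number of windows (default 20).
#' @param log_base base of the logarithm (default `exp(1)`).
#' @return A `window_curve` of kind `priming_ratio`.
#' @export
priming_ratio_curve <- function(case_scores, control_scores, branch = "branch",
                                n_windows = 20L, log_base = exp(1)) {
  w <- pseudotime_windows(n_windows)
  ci <- window_index(case_scores$t, n_windows)
  ki <- window_index(control_scores$t, n_windows)
  val <- rep(NA_real_, n_windows)
  for (j in seq_len(n_windows)) {
    mc <- mean(case_scores$score[ci == j])
    mk <- mean(control_scores$score[ki == j])
    if (!is.na(mc) && !is.na(mk) && mc > 0 && mk > 0) {
      val[[j]] <- log(mc / mk, base = log_base)
    }
  }
  window_curve(branch, w, val, "priming_ratio")
}

#' Transcription-factor expression ratio along pseudotime
#'
#' Per window, mean case log-normalized expression of one gene divided by
#' the mean control expression (stabilized by `eps` in the denominator);
#' windows without control cells are `NA`.
#'
#' @param case_m,control_m lognorm-layer `count_matrix` objects.
#' @param gene gene symbol (must exist in both matrices).
#' @param case_t,control_t pseudotimes aligned with the matrices' cells.
#' @param branch branch label.
#' @param n_windows number of windows (default 20).
#' @param eps denominator stabilizer (default 1e-9).
#' @return A `window_curve` of kind `tf_ratio`.
#' @export
tf_ratio_curve <- function(case_m, control_m, gene, case_t, control_t,
                           branch = "branch", n_windows = 20L, eps = 1e-9) {
  if (!gene %in% case_m$genes || !gene %in% control_m$genes) {
    abort_param(sprintf("gene '%s' absent from one of the matrices", gene))
  }
  xc <- as.numeric(case_m$counts[gene, ])
  xk <- as.numeric(control_m$counts[gene, ])
  ci <- window_index(case_t, n_windows)
  ki <- window_index(control_t, n_windows)
  w <- pseudotime_windows(n_windows)
  val <- rep(NA_real_, n_windows)
  for (j in seq_len(n_windows)) {
    if (!any(ki == j)) next
    val[[j]] <- mean(xc[ci == j]) / (mean(xk[ki == j]) + eps)
  }
  window_curve(branch, w, val, "tf_ratio", eps)
}

#' Mutant-cell fraction along pseudotime
#'
#' Per window, `log((n_mutant + pc)/(n_genotyped + pc))` where genotyped
#' cells are those labeled mutant or wildtype(-likely). Windows without
#' genotyped cells take the pure-pseudocount value and are flagged.
#'
#' @param calls data.frame from [genotype_matrix()].
#' @param meta data.frame with `barcode`, `pseudotime`, `branch`.
#' @param branch branch to analyze.
#' @param n_windows number of windows (default 20).
#' @param pseudocount cells added per window (default 0.5).
#' @param log_base base of the logarithm (default `exp(1)`).
#' @return A `window_curve` of kind `mutant_fraction`.
#' @export
mutant_fraction_curve <- function(calls, meta, branch, n_windows = 20L,
                                  pseudocount = 0.5, log_base = exp(1)) {
  mm <- meta[!is.na(meta$branch) & meta$branch == branch & !is.na(meta$pseudotime), ]
  joined <- merge(calls, mm, by.x = "cb", by.y = "barcode")
  geno <- joined[joined$label %in% c("mutant", "wildtype", "wildtype_likely"), ]
  wi_all <- window_index(geno$pseudotime, n_windows)
  n_geno <- tabulate(wi_all, n_windows)
  n_mut <- tabulate(wi_all[geno$label == "mutant"], n_windows)
  w <- pseudotime_windows(n_windows)
  val <- log((n_mut + pseudocount) / (n_geno + pseudocount), base = log_base)
  window_curve(branch, w, val, "mutant_fraction", pseudocount,
               flagged = n_geno == 0)
}

#' Write window curves
#' @param curves a `window_curve` or list of them.
#' @param path output TSV path.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "window_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    df <- as.data.frame(cv)
    df$kind <- attr(cv, "kind")
    df
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
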
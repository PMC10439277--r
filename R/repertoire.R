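# Clonotype construction and clonality statistics.

#' Build a clone-size distribution from a clone table
#'
#' Clone keys are CDR3 nucleotide sequences. In `beta_nt` / `heavy_nt`
#' mode cells are keyed on their TRB / IGH chain; cells lacking that chain
#' are excluded and counted. In `paired_nt` mode a cell's key is the sorted
#' pair of its per-locus CDR3 sequences; single-chain cells are keyed on
#' their one chain and flagged. When a cell carries more than one
#' productive chain of a locus, the chain with the most UMIs is used; if no
#' UMI information exists the cell is flagged ambiguous and excluded.
#'
#' @param ct a `clone_table` (see [read_contig_table()]).
#' @param mode `"paired_nt"`, `"beta_nt"` or `"heavy_nt"`.
#' @return A `clone_distribution`: data.frame `clone_id`, `key`, `size`,
#'   `freq` sorted by decreasing size, with attributes `N` (cells kept),
#'   `mode`, `n_excluded`, `single_chain_cells`, `ambiguous_cells`.
#' @export
build_clones <- function(ct, mode = c("beta_nt", "heavy_nt", "paired_nt")) {
  mode <- match.arg(mode)
  if (!nrow(ct)) abort_param("empty clone table")
  df <- as.data.frame(ct)
  ambiguous <- character(0)
  pick_chain <- function(sub) {
    # one record per locus: highest UMI count wins; NA UMIs cannot break ties
    keep <- lapply(split(sub, sub$locus), function(ss) {
      if (nrow(ss) == 1L) return(ss)
      if (nrow(ss) > 2L && all(is.na(ss$umis))) return(NULL)
      if (all(is.na(ss$umis))) return(ss[1L, , drop = FALSE])
      ss[which.max(ss$umis), , drop = FALSE]
    })
    if (any(vapply(keep, is.null, logical(1)))) return(NULL)
    do.call(rbind, keep)
  }
  cells <- split(df, df$cb)
  keys <- character(0); flags <- character(0)
  single_chain <- character(0)
  locus_needed <- switch(mode, beta_nt = "TRB", heavy_nt = "IGH", paired_nt = NA)
  n_excluded <- 0L
  for (cb in names(cells)) {
    sub <- pick_chain(cells[[cb]])
    if (is.null(sub)) { ambiguous <- c(ambiguous, cb); n_excluded <- n_excluded + 1L; next }
    if (mode %in% c("beta_nt", "heavy_nt")) {
      row <- sub[sub$locus == locus_needed, , drop = FALSE]
      if (!nrow(row)) { n_excluded <- n_excluded + 1L; next }
      keys[cb] <- row$cdr3_nt[[1]]
    } else {
      if (nrow(sub) == 1L) single_chain <- c(single_chain, cb)
      keys[cb] <- paste(sort(sub$cdr3_nt), collapse = "|")
    }
  }
  if (!length(keys)) abort_param("no cells left after clone-key construction")
  tab <- sort(table(keys), decreasing = TRUE)
  out <- data.frame(clone_id = sprintf("clone%04d", seq_along(tab)),
                    key = names(tab), size = as.integer(tab),
                    freq = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  structure(out, N = sum(tab), mode = mode, n_excluded = n_excluded,
            single_chain_cells = single_chain, ambiguous_cells = ambiguous,
            class = c("clone_distribution", "data.frame"))
}

#' Construct a clone distribution directly from sizes
#' @param sizes positive integer clone sizes.
#' @param mode clone-key mode tag (default `"beta_nt"`).
#' @return A `clone_distribution`.
#' @export
clone_distribution <- function(sizes, mode = "beta_nt") {
  sizes <- as.integer(sizes)
  if (length(sizes) && any(sizes < 1L)) abort_param("clone sizes must be positive")
  sizes <- sort(sizes, decreasing = TRUE)
  out <- data.frame(clone_id = sprintf("clone%04d", seq_along(sizes)),
                    key = sprintf("key%04d", seq_along(sizes)),
                    size = sizes,
                    freq = if (length(sizes)) sizes / sum(sizes) else numeric(0),
                    stringsAsFactors = FALSE)
  structure(out, N = sum(sizes), mode = mode, n_excluded = 0L,
            single_chain_cells = character(0), ambiguous_cells = character(0),
            class = c("clone_distribution", "data.frame"))
}

#' Shannon entropy of a clone distribution
#'
#' `H = -sum(p_i * log2(p_i))` in bits over clone frequencies; `0 log 0` is
#' taken as 0. Maximal (`log2 K`) for a perfectly even repertoire, 0 for a
#' single clone.
#'
#' @param d a `clone_distribution`.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(d) {
  p <- d$freq[d$freq > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

#' Gini coefficient of clone sizes
#'
#' Inequality of the clone-size distribution: 0 for a perfectly even
#' repertoire, approaching 1 under extreme clonal expansion. The default
#' is the relative-mean-absolute-difference form
#' `G = sum_ij |n_i - n_j| / (2 K^2 nbar)`; `method = "lorenz"` integrates
#' the Lorenz curve by trapezoids (the two agree analytically).
#'
#' @param d a `clone_distribution`.
#' @param method `"pairwise"` or `"lorenz"`.
#' @param small_sample_correction multiply by `K/(K-1)` (off by default).
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini <- function(d, method = c("pairwise", "lorenz"),
                 small_sample_correction = FALSE) {
  method <- match.arg(method)
  n <- as.numeric(d$size)
  k <- length(n)
  if (k <= 1L) return(0)
  g <- if (method == "pairwise") {
    sum(abs(outer(n, n, `-`))) / (2 * k^2 * mean(n))
  } else {
    # Lorenz curve through the K+1 points of cumulative share of sorted sizes;
    # G = 1 - 2 * area under the curve (trapezoidal, exact for the polygon)
    ns <- sort(n)
    cum <- c(0, cumsum(ns)) / sum(ns)
    area <- sum((cum[-1] + cum[-length(cum)]) / 2) / k
    1 - 2 * area
  }
  if (small_sample_correction) g <- g * k / (k - 1)
  g
}

#' Clone expansion classes
#'
#' Partition of clones into the standard reporting classes: singletons,
#' size 2, sizes 3-9, and highly expanded clones of size >= 10.
#'
#' @param d a `clone_distribution`.
#' @return Named integer vector `singleton`, `size_2`, `size_3_9`,
#'   `size_ge10`.
#' @export
expansion_classes <- function(d) {
  n <- d$size
  c(singleton = sum(n == 1L), size_2 = sum(n == 2L),
    size_3_9 = sum(n >= 3L & n <= 9L), size_ge10 = sum(n >= 10L))
}

#' Clone sharing between two repertoires
#'
#' @param d1,d2 `clone_distribution` objects built with the same
#'   clone-key mode.
#' @return List `shared` (keys), `jaccard`.
#' @export
repertoire_overlap <- function(d1, d2) {
  if (!identical(attr(d1, "mode"), attr(d2, "mode"))) {
    abort_usage("clone distributions use different key modes")
  }
  shared <- intersect(d1$key, d2$key)
  uni <- union(d1$key, d2$key)
  list(shared = shared,
       jaccard = if (length(uni)) length(shared) / length(uni) else NA_real_)
}

#' Summarize repertoire diversity
#' @param d a `clone_distribution`.
#' @return One-row data.frame: K, N, H (bits), G, expansion-class counts.
#' @export
diversity_summary <- function(d) {
  cls <- expansion_classes(d)
  data.frame(K = nrow(d), N = attr(d, "N"), H = shannon_entropy(d),
             G = gini(d), t(as.matrix(cls)))
}
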
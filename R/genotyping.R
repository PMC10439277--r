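#' Genotyping configuration
#'
#' @param tau UMI consensus threshold: the modal base must account for at
#'   least this fraction of the reads sharing a molecular barcode, otherwise
#'   the molecule is discarded. Must lie in (0.5, 1] so at most one allele
#'   can reach it.
#' @param strict if `TRUE` the modal fraction must exceed `tau` strictly;
#'   the default keeps the permissive `>= tau` reading.
#' @return A list of class `genotype_config`.
#' @export
genotype_config <- function(tau = 0.75, strict = FALSE) {
  if (tau <= 0.5 || tau > 1) abort_param("tau must lie in (0.5, 1]")
  structure(list(tau = tau, strict = isTRUE(strict)), class = "genotype_config")
}

#' UMI consensus call from the reads of one molecule
#'
#' All reads sharing a (cell barcode, molecular barcode) pair are collapsed
#' to a single consensus base: the most common observed allele is accepted
#' if it accounts for at least `tau` (default 75%) of the reads; otherwise
#' the molecule is discarded. A consensus on a third/unexpected base
#' (`"other"`) can never yield a reportable allele and is also discarded —
#' it still counts in the denominator, so it can veto a ref/alt consensus.
#'
#' @param reads data.frame of read records (columns `cb`, `ub`,
#'   `observed_allele`) all belonging to one molecule.
#' @param cfg a [genotype_config()].
#' @return List of class `umi_consensus`: `cb`, `ub`, `n_reads`, `allele`
#'   (`"ref"`, `"alt"` or `"discarded"`), `top_frac`.
#' @export
consensus_umi <- function(reads, cfg = genotype_config()) {
  if (!nrow(reads)) abort_usage("consensus_umi needs at least one read")
  if (length(unique(reads$cb)) > 1L || length(unique(reads$ub)) > 1L) {
    abort_usage("consensus_umi received reads from more than one (cb, ub) pair")
  }
  n <- nrow(reads)
  counts <- c(ref = sum(reads$observed_allele == "ref"),
              alt = sum(reads$observed_allele == "alt"),
              other = sum(reads$observed_allele == "other"))
  top <- which.max(counts)
  top_frac <- counts[[top]] / n
  pass <- if (cfg$strict) top_frac > cfg$tau else top_frac >= cfg$tau
  allele <- if (pass && names(counts)[top] != "other") names(counts)[top] else "discarded"
  structure(list(cb = reads$cb[[1]], ub = reads$ub[[1]], n_reads = n,
                 allele = allele, top_frac = top_frac),
            class = "umi_consensus")
}

# Vectorized consensus over a read table: one row per (variant, cb, ub).
consensus_table <- function(reads, cfg = genotype_config()) {
  dt <- data.table::as.data.table(reads)
  tau <- cfg$tau; strict <- cfg$strict
  cons <- dt[, {
    n <- .N
    cnt <- c(ref = sum(observed_allele == "ref"),
             alt = sum(observed_allele == "alt"),
             other = sum(observed_allele == "other"))
    top <- which.max(cnt)
    tf <- cnt[[top]] / n
    pass <- if (strict) tf > tau else tf >= tau
    al <- if (pass && names(cnt)[top] != "other") names(cnt)[top] else "discarded"
    list(n_reads = n, allele = al, top_frac = tf)
  }, by = c("variant_name", "cb", "ub")]
  as.data.frame(cons)
}

#' Genotype one cell from its consensus molecules
#'
#' Evidence are the non-discarded consensus UMIs of one cell at one variant.
#' A single mutant molecule suffices to label a cell `mutant` (transcripts
#' cannot acquire the specific substitution by chance at any appreciable
#' rate). With only reference molecules the label is `wildtype` for a
#' hemizygous locus (one expressed allele, so reference transcripts are
#' conclusive) and `wildtype_likely` for a diploid locus (the mutant allele
#' may simply be uncaptured). With no evidence the cell is `unknown`.
#'
#' @param n_alt_umi,n_ref_umi consensus molecule counts for the cell.
#' @param ploidy_mode `"hemizygous"` or `"diploid"`.
#' @return List of class `genotype_call` with `label`, `n_alt_umi`,
#'   `n_ref_umi`.
#' @export
genotype_cell <- function(n_alt_umi, n_ref_umi, ploidy_mode = c("hemizygous", "diploid")) {
  ploidy_mode <- match.arg(ploidy_mode)
  label <- if (n_alt_umi >= 1L) {
    "mutant"
  } else if (n_ref_umi >= 1L) {
    if (ploidy_mode == "hemizygous") "wildtype" else "wildtype_likely"
  } else {
    "unknown"
  }
  structure(list(label = label, n_alt_umi = as.integer(n_alt_umi),
                 n_ref_umi = as.integer(n_ref_umi)),
            class = "genotype_call")
}

#' Genotype all cells at all variants from a read table
#'
#' Groups reads by (variant, cell barcode, molecular barcode), forms UMI
#' consensus calls, and classifies every observed cell at every variant.
#' Cells in `cell_universe` that have no reads for a variant are emitted as
#' `unknown` calls; without a universe only observed cells are reported.
#'
#' @param reads data.frame of read records (`variant_name`, `cb`, `ub`,
#'   `observed_allele`), e.g. from [read_read_table()].
#' @param variants data.frame of variant specs (needs `name` and
#'   `ploidy_mode`), e.g. from [read_variants()].
#' @param cfg a [genotype_config()].
#' @param cell_universe optional character vector of all assayed barcodes.
#' @return data.frame with columns `cb`, `variant_name`, `label`,
#'   `n_alt_umi`, `n_ref_umi`.
#' @export
genotype_matrix <- function(reads, variants, cfg = genotype_config(),
                            cell_universe = NULL) {
  ploidy <- setNames(variants$ploidy_mode, variants$name)
  if (nrow(reads)) {
    cons <- data.table::as.data.table(consensus_table(reads, cfg))
    ev <- cons[, list(n_alt_umi = sum(allele == "alt"),
                      n_ref_umi = sum(allele == "ref")),
               by = c("variant_name", "cb")]
    ev <- as.data.frame(ev)
  } else {
    ev <- data.frame(variant_name = character(), cb = character(),
                     n_alt_umi = integer(), n_ref_umi = integer())
  }
  out <- list()
  for (v in variants$name) {
    sub <- ev[ev$variant_name == v, , drop = FALSE]
    if (!is.null(cell_universe)) {
      missing <- setdiff(cell_universe, sub$cb)
      if (length(missing)) {
        sub <- rbind(sub, data.frame(variant_name = v, cb = missing,
                                     n_alt_umi = 0L, n_ref_umi = 0L))
      }
      sub <- sub[match(cell_universe, sub$cb), , drop = FALSE]
    }
    pm <- ploidy[[v]] %||% "hemizygous"
    wt_label <- if (pm == "hemizygous") "wildtype" else "wildtype_likely"
    label <- ifelse(sub$n_alt_umi >= 1L, "mutant",
                    ifelse(sub$n_ref_umi >= 1L, wt_label, "unknown"))
    out[[v]] <- data.frame(cb = sub$cb, variant_name = v, label = label,
                           n_alt_umi = as.integer(sub$n_alt_umi),
                           n_ref_umi = as.integer(sub$n_ref_umi),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of mutant cells among genotyped cells
#'
#' `n_mutant / (n_mutant + n_wildtype(_likely))` over the given subset;
#' `unknown` cells carry no genotype evidence and are excluded from the
#' denominator. Returns `NA` if no cell in the subset is genotyped.
#'
#' @param calls data.frame from [genotype_matrix()].
#' @param cells optional barcode subset (default: all cells in `calls`).
#' @return Numeric scalar in `[0,1]`, or `NA` if no genotyped cells.
#' @export
mutant_fraction <- function(calls, cells = NULL) {
  if (!is.null(cells)) {
    if (!length(cells)) abort_usage("mutant_fraction requires a nonempty subset")
    calls <- calls[calls$cb %in% cells, , drop = FALSE]
  }
  n_mut <- sum(calls$label == "mutant")
  n_wt <- sum(calls$label %in% c("wildtype", "wildtype_likely"))
  if (n_mut + n_wt == 0L) return(NA_real_)
  n_mut / (n_mut + n_wt)
}

#' Write genotype calls
#' @param calls data.frame from [genotype_matrix()].
#' @param path output TSV path.
#' @export
write_genotypes <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
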
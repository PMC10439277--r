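#' Read gene sets from a GMT file
#'
#' One set per tab-separated line: name, description, then member genes.
#' Duplicate genes within a line are dropped; line order is preserved.
#'
#' @param gmt_path path to the GMT file.
#' @return Named list of character vectors (one per set).
#' @export
read_gene_sets <- function(gmt_path) {
  if (!file.exists(gmt_path)) abort_format(paste("file not found:", gmt_path))
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort_format(sprintf("GMT line %d has %d field(s); need name, description and at least one gene", i, length(f)))
    }
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) abort_format(sprintf("GMT line %d has no genes", i))
    sets[[f[[1]]]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a variant-locus read table
#'
#' The canonical plain-text form of barcode-tagged reads at variant loci:
#' a TSV with columns `variant_name`, `cb` (cell barcode), `ub` (molecular
#' barcode), `observed_allele` in `{ref, alt, other}`. Rows with an empty
#' cell or molecular barcode correspond to reads lacking the CB/UB tags and
#' are dropped; the number dropped is recorded in the `n_dropped` attribute.
#'
#' @param path path to the TSV (with header).
#' @return data.frame of read records with attribute `n_dropped`.
#' @export
read_read_table <- function(path) {
  if (!file.exists(path)) abort_format(paste("file not found:", path))
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("variant_name", "cb", "ub", "observed_allele")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort_format(paste("read table missing column(s):", paste(miss, collapse = ", ")))
  df <- df[, need]
  bad <- !df$observed_allele %in% c("ref", "alt", "other")
  if (any(bad)) {
    abort_format(paste("unknown allele token(s):",
                       paste(unique(df$observed_allele[bad]), collapse = ", ")))
  }
  keep <- nzchar(df$cb) & nzchar(df$ub) & !is.na(df$cb) & !is.na(df$ub)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Write a read table
#' @param reads data.frame as returned by [read_read_table()].
#' @param path output path.
#' @export
write_read_table <- function(reads, path) {
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read variant specifications
#'
#' Minimal VCF-like TSV with header columns `name`, `chrom`, `pos` (1-based),
#' `ref_allele`, `alt_allele`, `ploidy_mode` (`hemizygous` or `diploid`).
#'
#' @param path path to the TSV.
#' @return data.frame of variant specs.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) abort_format(paste("file not found:", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "chrom", "pos", "ref_allele", "alt_allele", "ploidy_mode")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort_format(paste("variant table missing column(s):", paste(miss, collapse = ", ")))
  if (any(df$pos < 1)) abort_format("variant pos must be 1-based (>= 1)")
  if (any(df$ref_allele == df$alt_allele)) abort_format("ref and alt alleles must differ")
  if (!all(df$ploidy_mode %in% c("hemizygous", "diploid"))) {
    abort_format("ploidy_mode must be 'hemizygous' or 'diploid'")
  }
  df
}

#' Read per-cell metadata
#'
#' TSV with header; requires a `barcode` column, and accepts the standard
#' optional columns `donor`, `group` (`case`/`control`), `cluster`,
#' `cell_type`, `pseudotime` (in `[0,1]`), `branch`, `phase`.
#'
#' @param path path to the TSV.
#' @return data.frame keyed by unique barcode.
#' @export
read_cell_meta <- function(path) {
  if (!file.exists(path)) abort_format(paste("file not found:", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"barcode" %in% names(df)) abort_format("cell metadata needs a 'barcode' column")
  if (anyDuplicated(df$barcode)) abort_format("duplicate barcodes in cell metadata")
  if ("pseudotime" %in% names(df)) {
    pt <- df$pseudotime[!is.na(df$pseudotime)]
    if (length(pt) && (min(pt) < 0 || max(pt) > 1)) {
      abort_format("pseudotime must lie in [0,1]")
    }
  }
  df
}

#' Read a V(D)J contig table into a clone table
#'
#' Accepts the 10x `filtered_contig_annotations.csv` dialect (columns
#' `barcode`, `chain`, `cdr3`, `cdr3_nt`, `v_gene`, `j_gene`, `productive`)
#' or the AIRR rearrangement TSV dialect (`cell_id`, `locus`, `junction`,
#' `junction_aa`, `productive`). Only productive contigs are retained;
#' the number of non-productive rows dropped is recorded in the
#' `n_nonproductive` attribute.
#'
#' @param path path to the contig file (CSV for `tenx`, TSV for `airr`).
#' @param dialect `"tenx"` or `"airr"`.
#' @return A `clone_table`: data.frame with columns `cb`, `locus`,
#'   `cdr3_nt`, `cdr3_aa`, `v`, `j`, `umis`.
#' @export
read_contig_table <- function(path, dialect = c("tenx", "airr")) {
  if (!is.character(dialect) || !all(dialect %in% c("tenx", "airr"))) {
    abort_usage("unknown contig dialect; use 'tenx' or 'airr'")
  }
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_format(paste("file not found:", path))
  if (dialect == "tenx") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("barcode", "chain", "cdr3", "cdr3_nt", "v_gene", "j_gene", "productive")
    miss <- setdiff(need, names(df))
    if (length(miss)) abort_format(paste("contig table missing column(s):", paste(miss, collapse = ", ")))
    rec <- data.frame(
      cb = df$barcode, locus = df$chain, cdr3_nt = df$cdr3_nt,
      cdr3_aa = df$cdr3, v = df$v_gene, j = df$j_gene,
      umis = if ("umis" %in% names(df)) df$umis else rep(NA_integer_, nrow(df)),
      productive = df$productive, stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("cell_id", "locus", "junction", "junction_aa", "productive")
    miss <- setdiff(need, names(df))
    if (length(miss)) abort_format(paste("contig table missing column(s):", paste(miss, collapse = ", ")))
    n <- nrow(df)
    rec <- data.frame(
      cb = df$cell_id, locus = df$locus, cdr3_nt = df$junction,
      cdr3_aa = df$junction_aa,
      v = if ("v_call" %in% names(df)) df$v_call else rep(NA_character_, n),
      j = if ("j_call" %in% names(df)) df$j_call else rep(NA_character_, n),
      umis = if ("umi_count" %in% names(df)) df$umi_count else rep(NA_integer_, n),
      productive = df$productive, stringsAsFactors = FALSE)
  }
  prod <- tolower(as.character(rec$productive)) %in% c("true", "t", "1", "yes")
  out <- rec[prod, setdiff(names(rec), "productive"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_nonproductive") <- sum(!prod)
  class(out) <- c("clone_table", "data.frame")
  out
}

#' Construct a clone table from records
#'
#' @param records data.frame with columns `cb`, `locus`, `cdr3_nt`, and
#'   optionally `cdr3_aa`, `v`, `j`, `umis`. All records are assumed
#'   productive.
#' @return A `clone_table`.
#' @export
clone_table <- function(records) {
  need <- c("cb", "locus", "cdr3_nt")
  miss <- setdiff(need, names(records))
  if (length(miss)) abort_format(paste("clone table missing column(s):", paste(miss, collapse = ", ")))
  n <- nrow(records)
  for (col in c("cdr3_aa", "v", "j")) {
    if (!col %in% names(records)) records[[col]] <- rep(NA_character_, n)
  }
  if (!"umis" %in% names(records)) records$umis <- rep(NA_integer_, n)
  out <- records[, c("cb", "locus", "cdr3_nt", "cdr3_aa", "v", "j", "umis")]
  rownames(out) <- NULL
  class(out) <- c("clone_table", "data.frame")
  out
}

#' Write a clone table as an AIRR-style TSV
#' @param ct a `clone_table`.
#' @param path output path.
#' @export
write_contig_table <- function(ct, path) {
  df <- data.frame(cell_id = ct$cb, locus = ct$locus, junction = ct$cdr3_nt,
                   junction_aa = ct$cdr3_aa, v_call = ct$v, j_call = ct$j,
                   umi_count = ct$umis, productive = "TRUE",
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column ligand-receptor pair list
#'
#' @param path TSV with header columns `ligand`, `receptor`.
#' @return data.frame with columns `ligand`, `receptor`.
#' @export
read_lr_pairs <- function(path) {
  if (!file.exists(path)) abort_format(paste("file not found:", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(df))) {
    abort_format("ligand-receptor table needs 'ligand' and 'receptor' columns")
  }
  if (any(!nzchar(df$ligand)) || any(!nzchar(df$receptor))) {
    abort_format("empty gene symbol in ligand-receptor table")
  }
  df[, c("ligand", "receptor")]
}
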
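# End-to-end orchestration: simulate -> preprocess -> genotype -> annotate
# -> score -> differential expression/GSEA -> interactions -> trajectory ->
# clonality, with a manifest recording every output and its content hash.

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed global seed propagated to every stochastic stage.
#' @param sim optional list of [sim_config()] overrides.
#' @param stages character vector of stages to run (default: all).
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, sim = list(),
                       stages = c("simulate", "preprocess", "genotype",
                                  "annotate", "score", "de", "interact",
                                  "trajectory", "clonality")) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 stages = stages),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with fields `out_dir`, `seed`, `sim`, `stages`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_format(paste("config file not found:", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$out_dir)) abort_format("config is missing the 'out_dir' field")
  run_config(out_dir = y$out_dir, seed = y$seed %||% 1L,
             sim = y$sim %||% list(),
             stages = unlist(y$stages) %||% eval(formals(run_config)$stages))
}

.stage_files <- function(manifest, stage, files, params) {
  h <- tools::md5sum(files)
  for (i in seq_along(files)) {
    manifest[[length(manifest) + 1L]] <- list(
      stage = stage, file = unname(files[[i]]), md5 = unname(h[[i]]),
      params = params)
  }
  manifest
}

#' Run the full synthetic pipeline
#'
#' Chains every stage on a synthetic dataset: generation of counts, reads,
#' trajectory and clones; QC and normalization; UMI-consensus genotyping;
#' marker detection and signature assignment; program scores and score
#' correlation; differential expression and pre-ranked GSEA; interaction
#' scores; pseudotime curves; clonality statistics. Every output file is
#' recorded in `manifest.json` with its stage, parameters and MD5 content
#' hash; deterministic stages reproduce their hashes on rerun with the
#' same config and seed.
#'
#' @param cfg a [run_config()] or path to a YAML config.
#' @return Invisibly, the manifest (list of file records).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  manifest <- list()
  say <- function(stage) message(sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"), stage))
  run_stage <- function(stage, body) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    say(stage)
    tryCatch(body(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }
  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  env <- new.env()

  run_stage("simulate", function() {
    sim <- simulate_counts(scfg)
    sim$meta <- simulate_trajectory(sim$meta, scfg, seed = scfg$seed + 1L)
    variant <- data.frame(name = "VAR1", chrom = "chrX", pos = 1000L,
                          ref_allele = "C", alt_allele = "T",
                          ploidy_mode = "hemizygous", stringsAsFactors = FALSE)
    reads <- simulate_reads(sim$meta, variant, scfg, seed = scfg$seed + 2L)
    clones <- simulate_clones(scfg, seed = scfg$seed + 3L)
    env$sim <- sim; env$variant <- variant; env$reads <- reads
    env$clones <- clones
    d <- file.path(cfg$out_dir, "sim")
    paths <- write_count_matrix(sim$matrix, file.path(d, "counts"))
    meta_p <- file.path(d, "cell_meta.tsv")
    write.table(sim$meta, meta_p, sep = "\t", quote = FALSE, row.names = FALSE)
    reads_p <- file.path(d, "reads.tsv")
    write_read_table(reads, reads_p)
    gmt_p <- file.path(d, "programs.gmt")
    write_gene_sets(c(sim$truth$signatures,
                      list(inflammation = sim$truth$inflammation,
                           er_stress = sim$truth$er_stress)), gmt_p)
    contig_p <- file.path(d, "contigs.tsv")
    write_contig_table(clones$table, contig_p)
    manifest <<- .stage_files(manifest, "simulate",
                              c(paths, meta_p, reads_p, gmt_p, contig_p),
                              list(seed = cfg$seed))
  })

  run_stage("preprocess", function() {
    qc <- qc_config(min_genes = 50L, max_genes = 100000L)  # synthetic scale
    fc <- filter_cells(env$sim$matrix, qc)
    env$raw <- fc$matrix
    env$ln <- normalize_log(fc$matrix)
    env$meta <- env$sim$meta[env$sim$meta$barcode %in% env$ln$cells, ]
    p <- file.path(cfg$out_dir, "qc_report.tsv")
    write.table(fc$report, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <<- .stage_files(manifest, "preprocess", p,
                              list(min_genes = qc$min_genes))
  })

  run_stage("genotype", function() {
    calls <- genotype_matrix(read_read_table(file.path(cfg$out_dir, "sim", "reads.tsv")),
                             env$variant, genotype_config(),
                             cell_universe = env$ln$cells)
    env$calls <- calls
    p <- file.path(cfg$out_dir, "genotypes.tsv")
    write_genotypes(calls, p)
    manifest <<- .stage_files(manifest, "genotype", p, list(tau = 0.75))
  })

  run_stage("annotate", function() {
    clusters <- env$meta$true_type  # cluster labels are pipeline inputs
    mk <- lapply(unique(clusters), function(cl) find_markers(env$ln, clusters, cl))
    names(mk) <- unique(clusters)
    bg <- expressed_background(env$ln, min_cells = min(100L, ncol(env$ln$counts) %/% 10L))
    asg <- assign_types(mk, env$sim$truth$signatures, bg)
    env$assignments <- asg
    p <- file.path(cfg$out_dir, "assignments.tsv")
    write.table(asg, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <<- .stage_files(manifest, "annotate", p, list())
  })

  run_stage("score", function() {
    inf <- module_score(env$ln, env$sim$truth$inflammation, seed = cfg$seed)
    er <- module_score(env$ln, env$sim$truth$er_stress, seed = cfg$seed)
    env$inf_score <- inf
    corr <- score_correlation(inf, er)
    env$score_corr <- corr
    p <- file.path(cfg$out_dir, "scores.tsv")
    write_scores(list(inflammation = inf, er_stress = er), p)
    manifest <<- .stage_files(manifest, "score",
                              p, list(r = corr$r, p_value = corr$p))
  })

  run_stage("de", function() {
    mut <- env$calls$cb[env$calls$label == "mutant"]
    wt <- env$calls$cb[env$calls$label %in% c("wildtype", "wildtype_likely")]
    de <- differential_expression(env$ln, mut, wt)
    env$de <- de
    ranking <- data.frame(gene = de$gene, stat = de$log2fc)
    gs <- gsea_preranked(ranking, env$sim$truth$inflammation,
                         n_perm = 500L, seed = cfg$seed)
    env$gsea <- gs
    p1 <- file.path(cfg$out_dir, "de.tsv")
    write.table(de, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    p2 <- file.path(cfg$out_dir, "gsea.tsv")
    write.table(data.frame(set = "inflammation", es = gs$es, nes = gs$nes,
                           p = gs$p), p2, sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest <<- .stage_files(manifest, "de", c(p1, p2), list(n_perm = 500L))
  })

  run_stage("interact", function() {
    # housekeeping stand-in: the 20 most uniformly expressed genes
    det <- Matrix::rowMeans(env$ln$counts > 0)
    hk <- env$ln$genes[order(det, decreasing = TRUE)][1:20]
    en <- housekeeping_normalize(env$ln, hk)
    sig <- env$sim$truth$signatures
    pairs <- data.frame(ligand = sig[[1]][1:5], receptor = sig[[2]][1:5])
    labels <- setNames(env$meta$true_type, env$meta$barcode)
    ps <- pair_scores(en, pairs, labels, types = names(sig)[1:2])
    p <- file.path(cfg$out_dir, "interactions.tsv")
    write.table(ps, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <<- .stage_files(manifest, "interact", p, list(n_hk = 20L))
  })

  run_stage("trajectory", function() {
    meta <- env$meta
    br <- scfg$branches[[1]]
    case_t <- meta$pseudotime[meta$group == "case" & meta$branch == br]
    ctrl_t <- meta$pseudotime[meta$group == "control" & meta$branch == br]
    cv <- abundance_ratio_curve(case_t, ctrl_t, branch = br)
    mf <- mutant_fraction_curve(env$calls, meta, branch = br)
    p <- file.path(cfg$out_dir, "curves.tsv")
    write_curves(list(cv, mf), p)
    manifest <<- .stage_files(manifest, "trajectory", p,
                              list(n_windows = 20L))
  })

  run_stage("clonality", function() {
    ct <- read_contig_table(file.path(cfg$out_dir, "sim", "contigs.tsv"),
                            dialect = "airr")
    d <- build_clones(ct, mode = "beta_nt")
    env$diversity <- diversity_summary(d)
    p <- file.path(cfg$out_dir, "diversity.tsv")
    write.table(env$diversity, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <<- .stage_files(manifest, "clonality", p,
                              list(mode = "beta_nt"))
  })

  say("writing manifest")
  mpath <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
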
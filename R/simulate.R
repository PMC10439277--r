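# Seeded generators for every input the pipeline consumes, with ground
# truth recorded so recovery tests are self-contained.

#' Simulation configuration
#'
#' Defaults describe a small multi-donor case/control cohort with
#' cell-type-structured negative-binomial counts, planted inflammation and
#' ER-stress programs whose per-cell latent activities are correlated, a
#' hemizygous somatic variant carried by a configurable fraction of cells,
#' partial transcript capture with sequencing error at the variant locus,
#' branching pseudotime with lineage-biased case abundance, and power-law
#' clone sizes.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes.
#' @param base_meanlog,base_sdlog lognormal parameters of the per-gene
#'   baseline mean expression; the defaults give deep (roughly 25k UMIs
#'   per cell) libraries dominated by a heavy tail of high expressers.
#' @param n_donors_case,n_donors_control donors per group.
#' @param cells_per_donor cells per donor.
#' @param cell_types type names; cells are assigned uniformly.
#' @param n_signature genes in each cell-type signature program.
#' @param signature_effect log-scale mean shift of signature genes in their
#'   type.
#' @param n_program genes in each of the inflammation and ER-stress
#'   programs.
#' @param program_effect log-scale loading of the per-cell latent activity
#'   on program genes.
#' @param coupling_rho correlation of the inflammation and ER-stress latent
#'   activities.
#' @param mutant_fraction fraction of cells carrying the somatic variant.
#' @param mutant_inflammation_shift added to mutant cells' inflammation
#'   latent activity.
#' @param capture_rate probability a cell's variant transcript yields at
#'   least one UMI.
#' @param umi_mean_extra extra UMIs per captured cell (Poisson mean; total
#'   UMIs = 1 + Poisson).
#' @param reads_per_umi_mean_extra extra reads per UMI (Poisson mean).
#' @param read_error_rate per-read probability of reporting a wrong base.
#' @param empty_ub_rate fraction of reads emitted with an empty molecular
#'   barcode (exercises tag filtering).
#' @param branches branch names for the trajectory.
#' @param branch_beta named list of `c(shape1, shape2)` Beta parameters of
#'   pseudotime per branch.
#' @param case_depletion_branch,case_depletion_from,case_depletion_keep
#'   on this branch, case cells with pseudotime beyond `from` are kept with
#'   probability `keep` (models progressive lineage loss in cases).
#' @param mutant_decline_branch,mutant_decline mutant probability declines
#'   linearly along this branch: `p(t) = mutant_fraction * (1 - decline*t)`.
#' @param clone_k,clone_alpha clone count and power-law exponent
#'   (sizes proportional to `k^-alpha`).
#' @param clone_n_cells cells in a simulated repertoire.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 3000L,
                       base_meanlog = 1, base_sdlog = 1.5,
                       n_donors_case = 4L, n_donors_control = 4L,
                       cells_per_donor = 250L,
                       cell_types = c("HSC", "GMP", "LymP"),
                       n_signature = 40L, signature_effect = 1.0,
                       n_program = 100L, program_effect = 0.6,
                       coupling_rho = 0.6,
                       mutant_fraction = 0.3,
                       mutant_inflammation_shift = 1.0,
                       capture_rate = 0.2,
                       umi_mean_extra = 1.0,
                       reads_per_umi_mean_extra = 3.0,
                       read_error_rate = 0.005,
                       empty_ub_rate = 0.02,
                       branches = c("myeloid", "lymphoid"),
                       branch_beta = list(myeloid = c(2, 2), lymphoid = c(2, 5)),
                       case_depletion_branch = "lymphoid",
                       case_depletion_from = 0.7,
                       case_depletion_keep = 1.0,
                       mutant_decline_branch = NA_character_,
                       mutant_decline = 0,
                       clone_k = 200L, clone_alpha = 2.0,
                       clone_n_cells = 1000L) {
  cfg <- as.list(environment())
  probs <- c(cfg$mutant_fraction, cfg$capture_rate, cfg$read_error_rate,
             cfg$empty_ub_rate, cfg$case_depletion_keep)
  if (any(probs < 0 | probs > 1)) abort_param("probabilities must lie in [0,1]")
  if (abs(cfg$coupling_rho) > 1) abort_param("coupling_rho must lie in [-1,1]")
  structure(cfg, class = "sim_config")
}

#' Simulate a count matrix with planted structure
#'
#' Negative-binomial counts (gene-level lognormal baseline and dispersion)
#' with: per-type signature programs (log-scale mean shift in that type's
#' cells), an inflammation and an ER-stress program driven by per-cell
#' latent activities correlated at `coupling_rho`, and a somatic variant
#' whose mutant cells receive an inflammation shift. Ground truth (type,
#' genotype, latent activities) is recorded in the metadata.
#'
#' @param cfg a [sim_config()].
#' @return List: `matrix` (raw `count_matrix`), `meta` (data.frame with
#'   `barcode`, `donor`, `group`, `true_type`, `true_genotype`,
#'   `latent_inflammation`, `latent_er_stress`), and `truth` (list with the
#'   planted gene sets: `signatures`, `inflammation`, `er_stress`).
#' @export
simulate_counts <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n_donors <- cfg$n_donors_case + cfg$n_donors_control
  n_cells <- n_donors * cfg$cells_per_donor
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  n_planted <- length(cfg$cell_types) * cfg$n_signature + 2L * cfg$n_program
  if (n_planted > cfg$n_genes) {
    abort_param(sprintf("n_genes = %d cannot hold %d planted program genes",
                        cfg$n_genes, n_planted))
  }
  # planted gene programs: disjoint blocks at the head of the gene list
  idx <- 0L
  take <- function(k) { out <- genes[idx + seq_len(k)]; idx <<- idx + k; out }
  signatures <- lapply(cfg$cell_types, function(tp) take(cfg$n_signature))
  names(signatures) <- cfg$cell_types
  inflammation <- take(cfg$n_program)
  er_stress <- take(cfg$n_program)

  donor <- rep(sprintf("D%02d", seq_len(n_donors)), each = cfg$cells_per_donor)
  group <- rep(c(rep("case", cfg$n_donors_case), rep("control", cfg$n_donors_control)),
               each = cfg$cells_per_donor)
  barcode <- sprintf("CELL%05d", seq_len(n_cells))
  true_type <- sample(cfg$cell_types, n_cells, replace = TRUE)
  # mutation is confined to case donors
  true_genotype <- ifelse(group == "case" & runif(n_cells) < cfg$mutant_fraction,
                          "mutant", "wildtype")
  # correlated latent program activities
  z1 <- rnorm(n_cells)
  z2 <- cfg$coupling_rho * z1 + sqrt(max(0, 1 - cfg$coupling_rho^2)) * rnorm(n_cells)
  z1 <- z1 + ifelse(true_genotype == "mutant", cfg$mutant_inflammation_shift, 0)

  base_mu <- exp(rnorm(cfg$n_genes, mean = cfg$base_meanlog,
                       sd = cfg$base_sdlog))                # per-gene baseline
  size <- exp(rnorm(cfg$n_genes, mean = log(2), sd = 0.3))  # NB dispersion
  log_mu <- matrix(log(base_mu), nrow = cfg$n_genes, ncol = n_cells)
  for (tp in cfg$cell_types) {
    gi <- match(signatures[[tp]], genes)
    ci <- which(true_type == tp)
    log_mu[gi, ci] <- log_mu[gi, ci] + cfg$signature_effect
  }
  gi_inf <- match(inflammation, genes)
  gi_er <- match(er_stress, genes)
  log_mu[gi_inf, ] <- log_mu[gi_inf, ] +
    cfg$program_effect * matrix(z1, length(gi_inf), n_cells, byrow = TRUE)
  log_mu[gi_er, ] <- log_mu[gi_er, ] +
    cfg$program_effect * matrix(z2, length(gi_er), n_cells, byrow = TRUE)
  counts <- matrix(rnbinom(length(log_mu), mu = exp(log_mu),
                           size = rep(size, n_cells)),
                   nrow = cfg$n_genes)
  m <- count_matrix(counts, genes, barcode, layer = "raw")
  meta <- data.frame(barcode = barcode, donor = donor, group = group,
                     true_type = true_type, true_genotype = true_genotype,
                     latent_inflammation = z1, latent_er_stress = z2,
                     stringsAsFactors = FALSE)
  list(matrix = m, meta = meta,
       truth = list(signatures = signatures, inflammation = inflammation,
                    er_stress = er_stress))
}

#' Simulate barcode-tagged reads at a variant locus
#'
#' Each cell's variant transcript is captured with probability
#' `capture_rate`; captured cells emit `1 + Poisson(umi_mean_extra)` UMIs,
#' each with `1 + Poisson(reads_per_umi_mean_extra)` reads. For a
#' hemizygous variant mutant cells transcribe only the alt allele; for a
#' diploid variant each UMI of a mutant (heterozygous) cell is alt or ref
#' with probability 1/2. Each read reports a wrong base with probability
#' `read_error_rate` (uniformly one of the two other tokens), and a
#' fraction `empty_ub_rate` of reads carry an empty molecular barcode.
#'
#' @param meta data.frame with `barcode` and `true_genotype` columns.
#' @param variant one-row variant spec (needs `name`, `ploidy_mode`).
#' @param cfg a [sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @return data.frame of read records (`variant_name`, `cb`, `ub`,
#'   `observed_allele`).
#' @export
simulate_reads <- function(meta, variant, cfg = sim_config(), seed = NULL) {
  set.seed(seed %||% cfg$seed)
  n_cells <- nrow(meta)
  captured <- which(runif(n_cells) <= cfg$capture_rate & cfg$capture_rate > 0)
  empty <- data.frame(variant_name = character(), cb = character(),
                      ub = character(), observed_allele = character(),
                      stringsAsFactors = FALSE)
  if (!length(captured)) return(empty)
  n_umi <- 1L + rpois(length(captured), cfg$umi_mean_extra)
  # one row per molecule
  cell_of <- rep(captured, n_umi)
  umi_id <- sequence(n_umi)
  mut <- meta$true_genotype[cell_of] == "mutant"
  umi_allele <- if (variant$ploidy_mode == "hemizygous") {
    ifelse(mut, "alt", "ref")
  } else {
    ifelse(mut & runif(length(cell_of)) < 0.5, "alt", "ref")
  }
  n_reads <- 1L + rpois(length(cell_of), cfg$reads_per_umi_mean_extra)
  # one row per read
  mol_of <- rep(seq_along(cell_of), n_reads)
  obs <- umi_allele[mol_of]
  err <- runif(length(obs)) < cfg$read_error_rate
  if (any(err)) {
    # a wrong base: uniformly one of the two other tokens
    wrong <- cbind(ifelse(obs[err] == "ref", "alt", "ref"),
                   ifelse(obs[err] == "other", "alt", "other"))
    pick <- 1L + (runif(sum(err)) < 0.5)
    obs[err] <- wrong[cbind(seq_len(sum(err)), pick)]
  }
  ub <- sprintf("%s-UMI%03d", meta$barcode[cell_of[mol_of]], umi_id[mol_of])
  ub[runif(length(ub)) < cfg$empty_ub_rate] <- ""
  data.frame(variant_name = variant$name, cb = meta$barcode[cell_of[mol_of]],
             ub = ub, observed_allele = obs, stringsAsFactors = FALSE)
}

#' Simulate branching pseudotime with lineage-biased case abundance
#'
#' Assigns each cell a branch (uniformly) and a Beta-distributed
#' pseudotime; on the configured depletion branch, case cells beyond
#' `case_depletion_from` are kept with probability `case_depletion_keep`
#' (dropped cells are resampled onto the other branches), emulating
#' progressive loss of a lineage in case donors. If configured, the mutant
#' probability declines linearly along a branch:
#' `p(t) = mutant_fraction * (1 - mutant_decline * t)` (case cells only).
#'
#' @param meta data.frame with `barcode` and `group` (case/control).
#' @param cfg a [sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @return `meta` with `branch` and `pseudotime` columns added (and
#'   `true_genotype` overwritten where a mutant decline is configured).
#' @export
simulate_trajectory <- function(meta, cfg = sim_config(), seed = NULL) {
  set.seed(seed %||% cfg$seed)
  n <- nrow(meta)
  draw <- function(k) {
    br <- sample(cfg$branches, k, replace = TRUE)
    t <- vapply(br, function(b) {
      ab <- cfg$branch_beta[[b]]
      rbeta(1L, ab[[1]], ab[[2]])
    }, numeric(1))
    data.frame(branch = br, pseudotime = t, stringsAsFactors = FALSE)
  }
  bt <- draw(n)
  if (!is.na(cfg$case_depletion_branch) && cfg$case_depletion_keep < 1) {
    # accept-reject: each case-cell proposal beyond the depletion point is
    # accepted with probability `keep`, so the case density there is
    # down-weighted by exactly that factor (renormalized)
    reject <- meta$group == "case" &
      bt$branch == cfg$case_depletion_branch &
      bt$pseudotime > cfg$case_depletion_from &
      runif(n) > cfg$case_depletion_keep
    while (any(reject)) {
      idx <- which(reject)
      bt[idx, ] <- draw(length(idx))
      reject[idx] <- bt$branch[idx] == cfg$case_depletion_branch &
        bt$pseudotime[idx] > cfg$case_depletion_from &
        runif(length(idx)) > cfg$case_depletion_keep
    }
  }
  meta$branch <- bt$branch
  meta$pseudotime <- bt$pseudotime
  if (!is.na(cfg$mutant_decline_branch) && cfg$mutant_decline > 0 &&
      "true_genotype" %in% names(meta)) {
    onb <- meta$branch == cfg$mutant_decline_branch & meta$group == "case"
    p <- pmax(0, cfg$mutant_fraction * (1 - cfg$mutant_decline * meta$pseudotime[onb]))
    meta$true_genotype[onb] <- ifelse(runif(sum(onb)) < p, "mutant", "wildtype")
  }
  meta
}

#' Simulate a clone table with power-law clone sizes
#'
#' Clone sizes follow `size_k` proportional to `k^-alpha`; cells are
#' assigned to clones multinomially and each clone receives a random CDR3
#' nucleotide sequence (TRB locus records, one chain per cell).
#'
#' @param cfg a [sim_config()] (uses `clone_n_cells`, `clone_k`,
#'   `clone_alpha`).
#' @param seed optional override of `cfg$seed`.
#' @param locus chain locus for the records (default `"TRB"`).
#' @param shared_keys optional character vector of clone keys to reuse
#'   (models inter-sample sharing); remaining clones get fresh keys.
#' @return List: `table` (a `clone_table`), `truth` (data.frame `key`,
#'   `size`).
#' @export
simulate_clones <- function(cfg = sim_config(), seed = NULL, locus = "TRB",
                            shared_keys = NULL) {
  if (cfg$clone_alpha <= 1) abort_param("clone_alpha must exceed 1")
  if (cfg$clone_k < 1) abort_param("clone_k must be >= 1")
  set.seed(seed %||% cfg$seed)
  w <- seq_len(cfg$clone_k)^(-cfg$clone_alpha)
  assign_ <- sample.int(cfg$clone_k, cfg$clone_n_cells, replace = TRUE,
                        prob = w / sum(w))
  rand_cdr3 <- function(k) {
    vapply(seq_len(k), function(i) {
      paste(sample(c("A", "C", "G", "T"), 30L, replace = TRUE), collapse = "")
    }, character(1))
  }
  keys <- rand_cdr3(cfg$clone_k)
  if (!is.null(shared_keys)) {
    k <- min(length(shared_keys), cfg$clone_k)
    keys[seq_len(k)] <- shared_keys[seq_len(k)]
  }
  cb <- sprintf("TCELL%05d", seq_len(cfg$clone_n_cells))
  tab <- clone_table(data.frame(
    cb = cb, locus = locus, cdr3_nt = keys[assign_],
    cdr3_aa = substr(keys[assign_], 1, 10), v = "TRBV1", j = "TRBJ1",
    umis = 1L, stringsAsFactors = FALSE))
  truth <- as.data.frame(table(factor(assign_, levels = seq_len(cfg$clone_k))))
  list(table = tab,
       truth = data.frame(key = keys, size = as.integer(truth$Freq),
                          stringsAsFactors = FALSE))
}
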
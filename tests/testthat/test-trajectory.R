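ref_with_meta <- function(n_genes = 60, n_cells = 30, seed = 71) {
  m <- normalize_log(random_raw(n_genes, n_cells, lambda = 4, seed = seed))
  meta <- data.frame(barcode = m$cells,
                     pseudotime = seq(0, 1, length.out = n_cells),
                     branch = rep(c("myeloid", "lymphoid"), length.out = n_cells))
  list(m = m, meta = meta)
}

test_that("projection onto an identical reference recovers pseudotime exactly", {
  rf <- ref_with_meta()
  pr <- project_to_reference(rf$m, rf$m, rf$m$genes, rf$meta)
  expect_equal(pr$ref_cb, rf$m$cells)
  expect_equal(pr$r, rep(1, nrow(pr)))
  expect_equal(pr$pseudotime, rf$meta$pseudotime)
  expect_equal(pr$branch, rf$meta$branch)
})

test_that("noisy queries find the correct nearest reference cell", {
  set.seed(72)
  rf <- ref_with_meta(n_genes = 200, n_cells = 40, seed = 72)
  ref_mat <- as.matrix(rf$m$counts)
  correct <- 0; trials <- 200
  for (i in seq_len(trials)) {
    j <- sample(40, 1)
    q <- ref_mat[, j] + rnorm(200, sd = 0.1)
    qm <- lognorm_cm(matrix(pmax(q, 0), ncol = 1), rf$m$genes, "query")
    pr <- project_to_reference(qm, rf$m, rf$m$genes, rf$meta)
    if (pr$ref_cb == rf$m$cells[j]) correct <- correct + 1
  }
  expect_gte(correct / trials, 0.95)
})

test_that("degenerate constant queries are flagged absent", {
  rf <- ref_with_meta()
  qm <- lognorm_cm(matrix(1, nrow(rf$m$counts), 1), rf$m$genes, "flat")
  pr <- project_to_reference(qm, rf$m, rf$m$genes, rf$meta)
  expect_true(pr$degenerate)
  expect_true(is.na(pr$ref_cb))
  expect_error(project_to_reference(qm, rf$m, rf$m$genes[1:3], rf$meta),
               class = "scmosaic_parameter_error")
})

test_that("windows tile [0,1] half-open and curves are deterministic", {
  w <- scmosaic:::pseudotime_windows(20)
  expect_equal(w$t_lo[1], 0)
  expect_equal(w$t_hi[20], 1)
  expect_equal(w$t_lo[-1], w$t_hi[-20])
  set.seed(73)
  a <- runif(500); b <- runif(500)
  c1 <- abundance_ratio_curve(a, b)
  c2 <- abundance_ratio_curve(a, b)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 20L)
})

test_that("matched densities give a flat abundance curve; depletion shows as ~ -1", {
  set.seed(74)
  case_t <- rbeta(10000, 2, 2); ctrl_t <- rbeta(10000, 2, 2)
  cv <- abundance_ratio_curve(case_t, ctrl_t)
  expect_lt(max(abs(cv$value)), 0.3)
  # halve case density beyond t = 0.7 by thinning
  keep <- case_t <= 0.7 | runif(10000) < 0.5
  cv2 <- abundance_ratio_curve(case_t[keep], ctrl_t)
  late <- cv2$value[cv2$t_lo >= 0.7]
  expect_lt(mean(late), -0.6)
  expect_gt(mean(late), -1.4)
})

test_that("abundance curves are invariant to duplicating every case cell", {
  set.seed(75)
  case_t <- runif(300); ctrl_t <- runif(400)
  c1 <- abundance_ratio_curve(case_t, ctrl_t, pseudocount = 0)
  c2 <- abundance_ratio_curve(rep(case_t, 2), ctrl_t, pseudocount = 0)
  expect_equal(c1$value, c2$value, tolerance = 1e-12)
})

test_that("windows empty in both groups take the pseudocount value 0", {
  case_t <- rep(0.01, 50); ctrl_t <- rep(0.01, 50)
  cv <- abundance_ratio_curve(case_t, ctrl_t, n_windows = 10)
  expect_equal(cv$value[10], 0) # same pseudocount mass in both groups
  expect_true(cv$flagged[10])
  expect_error(abundance_ratio_curve(numeric(0), ctrl_t),
               class = "scmosaic_parameter_error")
})

test_that("priming ratio curves track multiplicative score changes", {
  set.seed(76)
  case <- data.frame(t = runif(3000), score = runif(3000, 0.4, 0.6))
  ctrl <- data.frame(t = runif(3000), score = runif(3000, 0.4, 0.6))
  cv <- priming_ratio_curve(case, ctrl)
  expect_lt(max(abs(cv$value), na.rm = TRUE), 0.1)
  case2 <- case
  late <- case2$t >= 0.5
  case2$score[late] <- case2$score[late] * 0.5
  cv2 <- priming_ratio_curve(case2, ctrl)
  expect_equal(mean(cv2$value[cv2$t_lo >= 0.5]), log(0.5), tolerance = 0.1)
  # empty windows are absent
  cv3 <- priming_ratio_curve(case[case$t < 0.5, ], ctrl, n_windows = 4)
  expect_true(all(is.na(cv3$value[3:4])))
})

test_that("transcription-factor ratio curves follow expression ratios", {
  m <- normalize_log(random_raw(30, 200, lambda = 5, seed = 77))
  t_case <- runif(200); t_ctrl <- runif(200)
  cv <- tf_ratio_curve(m, m, "g5", t_case, t_ctrl)
  # identical matrices and pseudotime universes: populated windows at ~1
  expect_true(all(abs(cv$value[!is.na(cv$value)] - 1) < 0.8))
  mat2 <- as.matrix(m$counts); mat2["g5", ] <- mat2["g5", ] * 2
  m2 <- lognorm_cm(mat2, m$genes, m$cells)
  cv2 <- tf_ratio_curve(m2, m, "g5", t_case, t_ctrl)
  expect_equal(median(cv2$value, na.rm = TRUE), 2, tolerance = 0.3)
  expect_error(tf_ratio_curve(m, m, "nope", t_case, t_ctrl),
               class = "scmosaic_parameter_error")
})

test_that("a uniform mutant fraction yields a flat curve at log(0.5)", {
  set.seed(78)
  n <- 4000
  meta <- data.frame(barcode = sprintf("c%d", 1:n), pseudotime = runif(n),
                     branch = "lymphoid")
  calls <- data.frame(cb = meta$barcode, variant_name = "V1",
                      label = rep(c("mutant", "wildtype"), n / 2),
                      n_alt_umi = 0L, n_ref_umi = 0L)
  cv <- mutant_fraction_curve(calls, meta, "lymphoid")
  expect_lt(max(abs(cv$value - log(0.5))), 0.25)
})

test_that("a declining mutant fraction yields a decreasing curve", {
  set.seed(79)
  cfg <- sim_config(seed = 79, mutant_fraction = 0.5,
                    mutant_decline_branch = "lymphoid", mutant_decline = 0.9,
                    branch_beta = list(myeloid = c(2, 2), lymphoid = c(1, 1)),
                    capture_rate = 1, read_error_rate = 0, empty_ub_rate = 0)
  n <- 4000
  meta <- data.frame(barcode = sprintf("c%d", 1:n), group = "case",
                     true_genotype = "wildtype")
  meta <- simulate_trajectory(meta, cfg)
  reads <- simulate_reads(meta, one_variant(), cfg, seed = 80)
  calls <- genotype_matrix(reads, one_variant(), cell_universe = meta$barcode)
  cv <- mutant_fraction_curve(calls, meta, "lymphoid", n_windows = 10)
  ok <- !cv$flagged
  ct <- suppressWarnings(cor.test(cv$t_lo[ok], cv$value[ok], method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("windows without genotyped cells are flagged", {
  meta <- data.frame(barcode = "c1", pseudotime = 0.05, branch = "b")
  calls <- data.frame(cb = "c1", variant_name = "V1", label = "mutant",
                      n_alt_umi = 1L, n_ref_umi = 0L)
  cv <- mutant_fraction_curve(calls, meta, "b", n_windows = 5)
  expect_true(all(cv$flagged[2:5]))
})
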
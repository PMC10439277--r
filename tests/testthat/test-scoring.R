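test_that("module scores of background-like sets center near zero", {
  set.seed(31)
  m <- normalize_log(random_raw(500, 400, lambda = 3, seed = 31))
  null_set <- sample(m$genes, 40)
  sc <- module_score(m, null_set, seed = 4)
  sem <- sd(sc) / sqrt(length(sc))
  expect_lt(abs(mean(sc)), 3 * sem)
})

test_that("a planted program separates active cells decisively", {
  set.seed(32)
  m <- normalize_log(random_raw(500, 300, lambda = 3, seed = 32))
  set <- m$genes[1:30]
  active <- m$cells[1:150]
  mat <- as.matrix(m$counts)
  mat[set, active] <- mat[set, active] + 1 # +1 lognorm unit in half the cells
  m2 <- lognorm_cm(mat, m$genes, m$cells)
  sc <- module_score(m2, set, seed = 4)
  p <- wilcox.test(sc[active], sc[setdiff(m$cells, active)])$p.value
  expect_gt(mean(sc[active]), mean(sc[setdiff(m$cells, active)]))
  expect_lt(p, 1e-6)
})

test_that("module scores are deterministic given the seed", {
  m <- normalize_log(random_raw(300, 100, seed = 33))
  s1 <- module_score(m, m$genes[1:20], seed = 99)
  s2 <- module_score(m, m$genes[1:20], seed = 99)
  expect_identical(s1, s2)
  expect_error(module_score(m, c("nope1", "nope2")), class = "scmosaic_parameter_error")
})

test_that("module score is invariant to a constant added within a fixed bin structure", {
  m <- normalize_log(random_raw(300, 80, seed = 34))
  set <- m$genes[5:25]
  s1 <- module_score(m, set, seed = 7)
  mat <- as.matrix(m$counts) + 0.37 # same shift for every gene of every cell
  m2 <- lognorm_cm(mat, m$genes, m$cells)
  # bins are recomputed from shifted averages but ordering is unchanged
  s2 <- module_score(m2, set, seed = 7)
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-12)
})

test_that("AUC is 1 for a cell expressing only the set genes", {
  n_genes <- 200
  set <- sprintf("g%d", 1:5)
  mat <- matrix(0, n_genes, 2)
  mat[1:5, 1] <- 5           # extreme cell
  mat[, 2] <- seq_len(n_genes) %% 7   # arbitrary other cell
  m <- lognorm_cm(mat)
  auc <- auc_score(m, set, top_frac = 0.05)
  expect_equal(unname(auc[1]), 1)
  expect_true(all(auc >= 0 & auc <= 1))
})

test_that("AUC matches explicit recovery-curve integration, with deterministic ties", {
  n_genes <- 60; k <- 12 # top_frac 0.2
  set.seed(35)
  x <- sample(0:9, n_genes, replace = TRUE)
  m <- lognorm_cm(matrix(x, ncol = 1))
  set <- sprintf("g%d", c(3, 17, 40))
  # oracle: step recovery curve with average-rank ties
  r <- rank(-x, ties.method = "average")[c(3, 17, 40)]
  raw <- sum(pmax(k - r + 1, 0))
  denom <- sum(k - (1:3) + 1)
  expect_equal(unname(auc_score(m, set, top_frac = 0.2)), min(raw / denom, 1))
  # all-zero set genes: deterministic tie value, identical across calls
  x0 <- x; x0[c(3, 17, 40)] <- 0
  m0 <- lognorm_cm(matrix(x0, ncol = 1))
  expect_identical(auc_score(m0, set, top_frac = 0.2),
                   auc_score(m0, set, top_frac = 0.2))
})

test_that("AUC is invariant to strictly monotone transforms of expression", {
  m <- normalize_log(random_raw(300, 40, seed = 36))
  set <- m$genes[10:24]
  a1 <- auc_score(m, set)
  mat <- as.matrix(m$counts)
  m2 <- lognorm_cm(sqrt(mat) + 0.2 * mat, m$genes, m$cells)
  expect_equal(a1, auc_score(m2, set), tolerance = 1e-12)
})

test_that("random expression gives the analytic mean AUC for random ranking", {
  set.seed(37)
  n_genes <- 400; k <- 20; s <- 25
  mat <- matrix(rnorm(n_genes * 300), n_genes) # continuous: no ties
  m <- lognorm_cm(abs(mat))
  set <- sample(m$genes, s)
  auc <- auc_score(m, set, top_frac = 0.05)
  # a uniform random rank contributes E[max(k - r + 1, 0)] = k(k+1)/(2 n)
  expected <- s * k * (k + 1) / (2 * n_genes) / sum(k - seq_len(min(s, k)) + 1)
  expect_equal(mean(auc), expected, tolerance = 0.1)
})

test_that("cell-cycle phases follow the argmax-with-G1-fallback rule", {
  set.seed(38)
  m <- normalize_log(random_raw(300, 60, lambda = 2, seed = 38))
  s_genes <- m$genes[1:20]; g2m_genes <- m$genes[21:40]
  mat <- as.matrix(m$counts)
  mat[s_genes, 1:20] <- mat[s_genes, 1:20] + 2
  mat[g2m_genes, 21:40] <- mat[g2m_genes, 21:40] + 2
  mat[c(s_genes, g2m_genes), 41:60] <- 0
  m2 <- lognorm_cm(mat, m$genes, m$cells)
  ph <- cell_cycle_phase(m2, s_genes, g2m_genes, seed = 5)
  expect_true(mean(ph$phase[1:20] == "S") >= 0.9)
  expect_true(mean(ph$phase[21:40] == "G2M") >= 0.9)
  # zeroed phase genes force scores <= 0 hence G1
  expect_true(all(ph$phase[41:60] == "G1"))
})

test_that("a three-phase synthetic population is recovered at 90%", {
  set.seed(39)
  n <- 300; ng <- 800
  lam <- exp(rnorm(ng, 0.7, 0.9)) # heterogeneous per-gene baselines
  mat <- matrix(rpois(ng * n, rep(lam, n)), ng)
  genes <- sprintf("g%d", seq_len(ng))
  s_genes <- genes[1:25]; g2m_genes <- genes[26:50]
  truth <- sample(c("G1", "S", "G2M"), n, replace = TRUE)
  for (i in 1:25) { # cycle genes: repressed off-phase, induced in phase
    mat[i, ] <- rpois(n, lam[i] * ifelse(truth == "S", 4, 0.25))
    mat[i + 25, ] <- rpois(n, lam[i + 25] * ifelse(truth == "G2M", 4, 0.25))
  }
  ph <- cell_cycle_phase(normalize_log(raw_cm(mat, genes)), s_genes, g2m_genes,
                         seed = 6)
  expect_gt(mean(ph$phase == truth), 0.9)
})

test_that("composite scores reduce to the single-set score and average disjoint sets", {
  m <- normalize_log(random_raw(400, 150, seed = 40))
  one <- composite_score(m, list(m$genes[1:20]), seed = 3)
  expect_equal(one, module_score(m, m$genes[1:20], seed = 3))
  # two disjoint, identically distributed sets: union score ~ mean of both
  a <- m$genes[1:30]; b <- m$genes[31:60]
  u <- composite_score(m, list(a, b), seed = 3)
  avg <- (module_score(m, a, seed = 3) + module_score(m, b, seed = 3)) / 2
  expect_gt(cor(u, avg), 0.8)
  expect_lt(abs(mean(u) - mean(avg)), 0.05)
})

test_that("score correlation is exact on affine pairs and guarded on degenerate input", {
  x <- setNames(rnorm(50), sprintf("c%d", 1:50))
  y <- 2 * x + 1
  expect_equal(score_correlation(x, y)$r, 1)
  z <- setNames(rep(1, 50), names(x))
  expect_true(is.na(score_correlation(x, z)$r))
  expect_error(score_correlation(x[1:2], y[1:2]), class = "scmosaic_parameter_error")
})

test_that("donor-level correlation aggregates per-donor means", {
  set.seed(41)
  donors <- setNames(rep(sprintf("d%d", 1:5), each = 20), sprintf("c%d", 1:100))
  base <- rep(rnorm(5), each = 20)
  x <- setNames(base + rnorm(100, sd = 0.1), names(donors))
  y <- setNames(2 * base + rnorm(100, sd = 0.1), names(donors))
  res <- score_correlation(x, y, level = "donor", donors = donors)
  expect_equal(res$n, 5)
  manual <- cor(tapply(x, donors[names(x)], mean), tapply(y, donors[names(y)], mean))
  expect_equal(res$r, unname(manual))
})

test_that("independent scores show no spurious correlation", {
  set.seed(42)
  hits <- 0
  for (i in 1:10) {
    x <- setNames(rnorm(1000), sprintf("c%d", 1:1000))
    y <- setNames(rnorm(1000), sprintf("c%d", 1:1000))
    res <- score_correlation(x, y)
    if (abs(res$r) < 0.1 && res$p > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("group score ratios handle negative module scores via the recorded shift", {
  sc <- setNames(c(rep(-0.2, 10), rep(-0.2, 10)), sprintf("c%d", 1:20))
  a <- names(sc)[1:10]; b <- names(sc)[11:20]
  expect_equal(group_score_ratio(sc, a, b)$ratio, 1)
  sc2 <- sc; sc2[a] <- sc2[a] + 0.5 # planted program only in A
  expect_gt(group_score_ratio(sc2, a, b)$ratio, 1)
  expect_error(group_score_ratio(sc, character(0), b), class = "scmosaic_parameter_error")
})

test_that("normalized activity centers each dataset on its controls", {
  sc <- c(a1 = 1, a2 = 2, a3 = 3, b1 = 10, b2 = 11, b3 = 12)
  ds <- c("A", "A", "A", "B", "B", "B")
  ctrl <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  out <- normalized_activity(sc, ds, ctrl)
  expect_equal(mean(out[ctrl & ds == "A"]), 0)
  expect_equal(mean(out[ctrl & ds == "B"]), 0)
  # equal case-control gaps align across baselines
  expect_equal(unname(out["a3"]), unname(out["b3"]))
  expect_error(normalized_activity(sc, ds, rep(FALSE, 6)),
               class = "scmosaic_parameter_error")
})
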
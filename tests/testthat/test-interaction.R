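test_that("housekeeping normalization zeroes a gene pinned to the housekeeping mean", {
  mat <- rbind(hk1 = c(1, 2, 3), hk2 = c(3, 2, 1), pinned = c(2, 2, 2),
               other = c(5, 0, 1))
  m <- lognorm_cm(mat, rownames(mat), c("c1", "c2", "c3"))
  en <- housekeeping_normalize(m, c("hk1", "hk2"))
  expect_equal(unname(en["pinned", ]), c(0, 0, 0))
  expect_error(housekeeping_normalize(m, "absent"), class = "scmosaic_parameter_error")
})

test_that("housekeeping normalization cancels per-cell constant shifts", {
  m <- normalize_log(random_raw(50, 20, seed = 61))
  en1 <- housekeeping_normalize(m, m$genes[1:5])
  shifted <- as.matrix(m$counts) + rep(runif(20), each = 50) # per-cell constant
  en2 <- housekeeping_normalize(lognorm_cm(shifted, m$genes, m$cells), m$genes[1:5])
  expect_equal(en1, en2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("pair scores equal the direct mean-product computation", {
  # type A ligand Enorm mean 2, type B receptor Enorm mean 3 -> s = 6
  en <- rbind(L = c(1, 3, 0, 0), R = c(0, 0, 2, 4), X = c(1, 1, 1, 1))
  colnames(en) <- sprintf("c%d", 1:4)
  labels <- setNames(c("A", "A", "B", "B"), colnames(en))
  pairs <- data.frame(ligand = "L", receptor = "R")
  ps <- pair_scores(en, pairs, labels)
  s_ab <- ps$s[ps$type_a == "A" & ps$type_b == "B"]
  expect_equal(s_ab, mean(c(1, 3)) * mean(c(2, 4)))
  # an all-zero ligand scores zero
  en0 <- en; en0["L", ] <- 0
  ps0 <- pair_scores(en0, pairs, labels)
  expect_true(all(ps0$s == 0))
})

test_that("oracle agreement holds on random small matrices", {
  set.seed(62)
  for (i in 1:10) {
    en <- matrix(rnorm(8 * 12), 8, dimnames = list(sprintf("g%d", 1:8), sprintf("c%d", 1:12)))
    labels <- setNames(sample(c("A", "B"), 12, TRUE), colnames(en))
    if (length(unique(labels)) < 2) next
    pairs <- data.frame(ligand = "g1", receptor = "g2")
    ps <- pair_scores(en, pairs, labels)
    for (j in seq_len(nrow(ps))) {
      expect_equal(ps$s[j],
                   mean(en["g1", labels == ps$type_a[j]]) *
                     mean(en["g2", labels == ps$type_b[j]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("role transposition and cell duplication leave scores unchanged", {
  set.seed(63)
  en <- matrix(rnorm(6 * 10), 6, dimnames = list(sprintf("g%d", 1:6), sprintf("c%d", 1:10)))
  labels <- setNames(rep(c("A", "B"), each = 5), colnames(en))
  ps1 <- pair_scores(en, data.frame(ligand = "g1", receptor = "g2"), labels)
  ps2 <- pair_scores(en, data.frame(ligand = "g2", receptor = "g1"), labels)
  expect_equal(ps1$s[ps1$type_a == "A" & ps1$type_b == "B"],
               ps2$s[ps2$type_a == "B" & ps2$type_b == "A"])
  # duplicating every cell of a type leaves the means unchanged
  en_dup <- cbind(en, en[, labels == "B"])
  colnames(en_dup) <- c(colnames(en), sprintf("d%d", 1:5))
  labels_dup <- setNames(c(labels, rep("B", 5)), colnames(en_dup))
  ps3 <- pair_scores(en_dup, data.frame(ligand = "g1", receptor = "g2"), labels_dup)
  expect_equal(ps1$s, ps3$s, tolerance = 1e-12)
})

test_that("a planted complementary pair ranks first and is significant", {
  set.seed(64)
  n <- 80
  mat <- matrix(rpois(60 * n, 3), 60)
  labels <- setNames(rep(c("A", "B"), each = n / 2), sprintf("c%d", 1:n))
  mat[1, labels == "A"] <- rpois(n / 2, 25)  # ligand high in A
  mat[2, labels == "B"] <- rpois(n / 2, 25)  # receptor high in B
  ln <- normalize_log(raw_cm(mat))
  en <- housekeeping_normalize(ln, ln$genes[50:60])
  pairs <- data.frame(ligand = c("g1", sprintf("g%d", 10:14)),
                      receptor = c("g2", sprintf("g%d", 20:24)))
  ps <- pair_scores(en, pairs, labels)
  ab <- ps[ps$type_a == "A" & ps$type_b == "B", ]
  expect_equal(ab$ligand[which.max(ab$s)], "g1")
  expect_lt(ab$p[ab$ligand == "g1"], 0.05)
})

test_that("unknown genes are skipped and reported", {
  en <- matrix(0, 2, 4, dimnames = list(c("a", "b"), sprintf("c%d", 1:4)))
  labels <- setNames(rep(c("A", "B"), 2), colnames(en))
  pairs <- data.frame(ligand = c("a", "zz"), receptor = c("b", "b"))
  expect_message(ps <- pair_scores(en, pairs, labels), "skipping 1")
  expect_equal(nrow(attr(ps, "skipped_pairs")), 1L)
})

test_that("per-cell scores sum both interaction roles", {
  # single pair; focal cell: ligand 1, receptor 0; partner means: receptor 2, ligand 0
  en <- rbind(L = c(1, 0, 0), R = c(0, 2, 2))
  colnames(en) <- c("h1", "p1", "p2")
  pairs <- data.frame(ligand = "L", receptor = "R")
  cs <- per_cell_scores(en, pairs, "h1", c("p1", "p2"))
  expect_equal(cs$s_total, 1 * 2 + 0 * 0)
  # ligand-only direction drops the receptor-role term
  cs_l <- per_cell_scores(en, pairs, "h1", c("p1", "p2"), direction = "ligand")
  expect_equal(cs_l$s_total, 2)
  # an all-zero focal cell scores zero
  en2 <- en; en2[, "h1"] <- 0
  expect_equal(per_cell_scores(en2, pairs, "h1", c("p1", "p2"))$s_total, 0)
  expect_error(per_cell_scores(en, pairs, "h1", character(0)),
               class = "scmosaic_parameter_error")
})

test_that("per-cell interaction scores recover a planted coupling with program activity", {
  set.seed(65)
  n_cells <- 600; n_genes <- 800
  lam <- exp(rnorm(n_genes, 0.8, 1))
  # latent u drives 20 ligand genes in focal cells; v drives an inflammation
  # program; corr(u, v) = 0.5
  u <- rnorm(n_cells)
  v <- 0.5 * u + sqrt(1 - 0.25) * rnorm(n_cells)
  mat <- matrix(rpois(n_genes * n_cells, rep(lam, n_cells)), n_genes)
  lig_idx <- 1:20; inf_idx <- 21:100; rec_idx <- 101:120
  partner_cols <- 401:600
  for (g in lig_idx) mat[g, ] <- rpois(n_cells, lam[g] * exp(0.6 * u))
  for (g in inf_idx) mat[g, ] <- rpois(n_cells, lam[g] * exp(0.6 * v))
  # the partner population expresses the receptors well above baseline
  for (g in rec_idx) mat[g, partner_cols] <- rpois(length(partner_cols), lam[g] * 6)
  genes <- sprintf("g%d", seq_len(n_genes))
  ln <- normalize_log(raw_cm(mat, genes))
  hk <- genes[700:750]
  en <- housekeeping_normalize(ln, hk)
  focal <- ln$cells[1:400]; partner <- ln$cells[401:600]
  pairs <- data.frame(ligand = genes[lig_idx], receptor = genes[101:120])
  cs <- per_cell_scores(en, pairs, focal, partner, direction = "ligand")
  inf_score <- module_score(ln, genes[inf_idx], seed = 9)
  r <- score_correlation(setNames(cs$s_total, cs$cb), inf_score[focal])$r
  expect_gt(r, 0.35)
  expect_lt(r, 0.65)
})

test_that("a null generator keeps the significant-pair fraction near nominal", {
  set.seed(66)
  frac <- replicate(5, {
    en <- matrix(rnorm(40 * 60), 40,
                 dimnames = list(sprintf("g%d", 1:40), sprintf("c%d", 1:60)))
    labels <- setNames(rep(c("A", "B"), each = 30), colnames(en))
    pairs <- data.frame(ligand = sprintf("g%d", 1:10),
                        receptor = sprintf("g%d", 11:20))
    ps <- pair_scores(en, pairs, labels)
    mean(ps$p < 0.05)
  })
  expect_lte(mean(frac), 0.07)
})
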
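design4 <- mission_design()

test_that("library-size normalization scales each sample to the target", {
  m <- tiny_counts()
  n4 <- normalize_library_size(m, scale = 4)
  expect_equal(n4[, "S1"], c(G1 = 10, G2 = 5, G3 = 1) / 16 * 4)
  cpm <- normalize_library_size(m)
  expect_equal(unname(colSums(cpm)), rep(1e6, 3))
  m0 <- cbind(m, S4 = c(0, 0, 0))
  expect_error(normalize_library_size(m0), "S4")
})

test_that("quantifier averaging works on the gene intersection", {
  a <- tiny_counts()
  expect_equal(average_quantifiers(a, a), a, ignore_attr = TRUE)
  b <- rbind(a[1:2, ], G9 = c(2, 2, 2))
  expect_warning(avg <- average_quantifiers(a, b), "dropped")
  expect_setequal(rownames(avg), c("G1", "G2"))
  expect_setequal(attr(avg, "dropped_genes"), c("G3", "G9"))
  expect_equal(avg["G1", "S1"], 10)
  a2 <- a; colnames(a2) <- c("X1", "X2", "X3")
  expect_error(average_quantifiers(a, a2), "sample ids differ")
})

test_that("z-scored rows have mean 0 and sample SD 1 to tolerance", {
  set.seed(4)
  m <- matrix(rpois(200, 50), 20, 10,
              dimnames = list(paste0("G", 1:20), paste0("S", 1:10)))
  z <- zscore_expression(normalize_library_size(m))
  expect_lt(max(abs(rowMeans(z$z))), 1e-9)
  expect_lt(max(abs(apply(z$z, 1, sd) - 1)), 1e-9)
})

test_that("constant genes are set aside and two-point z is +-1/sqrt(2)", {
  m <- matrix(c(5, 5, 2, 8), 2, 2, byrow = TRUE,
              dimnames = list(c("CONST", "VAR"), c("S1", "S2")))
  z <- zscore_expression(m, log_transform = FALSE)
  expect_equal(z$constant_genes, "CONST")
  expect_equal(unname(z$z["VAR", ]), c(-1, 1) / sqrt(2))
  expect_error(zscore_expression(m[, 1, drop = FALSE]), "single-sample")
})

test_that("a singleton pathway's trajectory is the gene's own z series", {
  set.seed(6)
  m <- matrix(rpois(3 * 28, 40), 3, 28,
              dimnames = list(c("A", "B", "C"), design4$sample_id))
  z <- zscore_expression(normalize_library_size(m))
  traj <- pathway_trajectory(z, "A", design4, pathway = "single")
  for (i in seq_len(nrow(traj))) {
    s <- design4$sample_id[design4$time_days == traj$time_days[i]]
    expect_equal(traj$median_z[i], median(z$z["A", s]))
  }
  expect_equal(traj$time_days, sort(unique(design4$time_days)))
  expect_true(all(traj$n_values > 0))
})

test_that("trajectory medians pool gene x subject values per timepoint", {
  z <- structure(list(
    z = matrix(c(0.1, 0.5, 0.9), 3, 1,
               dimnames = list(c("A", "B", "C"), "C001_R+1")),
    constant_genes = character(0)), class = "zmatrix")
  sheet <- data.frame(sample_id = "C001_R+1", subject_id = "C001",
                      timepoint_label = "R+1", time_days = 1,
                      phase = "return")
  traj <- pathway_trajectory(z, c("A", "B", "C"), sheet)
  expect_equal(traj$median_z, 0.5)
  expect_error(pathway_trajectory(z, "ZZZ", sheet, pathway = "gone"),
               "not detected")
})

test_that("co-regulation score follows its definition", {
  set.seed(8)
  m <- matrix(rpois(50 * 28, 60), 50, 28,
              dimnames = list(paste0("G", 1:50), design4$sample_id))
  z <- zscore_expression(normalize_library_size(m))
  # the all-genes set is centered per sample only approximately; a
  # singleton set scores exactly the SD normalization constant n-1
  db <- list(ALL = paste0("G", 1:50), ONE = "G1", TINY = "G2")
  res <- coregulation_test(z, db, n_perm = 100, min_size = 1,
                           max_size = 100, seed = 1)
  one <- res[res$pathway == "ONE", ]
  expect_equal(one$score, ncol(z$z) - 1, tolerance = 1e-9)
  expect_true(all(res$p >= 1 / 101))
  expect_true(all(res$padj >= res$p - 1e-12))
})

test_that("size filters skip pathways and report them", {
  set.seed(9)
  m <- matrix(rpois(30 * 6, 60), 30, 6,
              dimnames = list(paste0("G", 1:30), paste0("S", 1:6)))
  z <- zscore_expression(normalize_library_size(m))
  db <- list(SMALL = "G1", OK = paste0("G", 1:10),
             MISSING = c("X1", "X2"))
  res <- coregulation_test(z, db, n_perm = 100, min_size = 2,
                           max_size = 20, seed = 2)
  expect_equal(res$pathway, "OK")
  skipped <- attr(res, "skipped")
  expect_setequal(skipped$pathway, c("SMALL", "MISSING"))
})

test_that("self-concordance is exact and categories partition genes", {
  set.seed(10)
  m <- matrix(rpois(40 * 4, 80), 40, 4,
              dimnames = list(paste0("G", 1:40), paste0("S", 1:4)))
  dge <- data.frame(gene = rownames(m), log2fc = rnorm(40),
                    padj = runif(40))
  res <- concordance(m, m, dge, dge)
  expect_identical(res$median_r, 1)
  expect_false(any(res$categories %in% c("only_A", "only_B")))
  expect_setequal(res$consensus_degs, dge$gene[dge$padj < 0.05])
})

test_that("consensus DEG rule is the significance intersection", {
  m <- tiny_counts()
  dge_a <- data.frame(gene = c("G1", "G2", "G3"), log2fc = c(1, 2, 3),
                      padj = c(0.01, 0.02, 0.5))
  dge_b <- data.frame(gene = c("G1", "G2", "G3"), log2fc = c(1, 2, 3),
                      padj = c(0.9, 0.001, 0.04))
  res <- concordance(m, m, dge_a, dge_b)
  expect_equal(res$consensus_degs, "G2")
  expect_equal(unname(res$categories), c("only_A", "both", "only_B"))
})

test_that("homolog-group disagreement lowers quantifier concordance", {
  set.seed(12)
  genes <- paste0("G", 1:300)
  m <- matrix(rpois(300 * 28, 100), 300, 28,
              dimnames = list(genes, design4$sample_id))
  groups <- split(genes[1:90], rep(1:30, each = 3))
  dge <- data.frame(gene = genes, log2fc = 0, padj = 1)
  with_g <- simulate_dual_quantifier(m, groups, seed = 3)
  no_g <- simulate_dual_quantifier(m, list(), seed = 3)
  r_with <- concordance(with_g$a, with_g$b, dge, dge)$median_r
  r_no <- concordance(no_g$a, no_g$b, dge, dge)$median_r
  expect_lt(r_with, r_no)
})

test_that("genes-detected uses a strict threshold", {
  m <- matrix(c(10, 11, 0), 3, 1,
              dimnames = list(c("A", "B", "C"), "S1"))
  expect_equal(unname(genes_detected(m)), 1)
  expect_equal(unname(genes_detected(m * 0)), 0)
  expect_equal(unname(genes_detected(m, min_alignments = 0)), 2)
})

test_that("identical groups give zero fold change and p near 1", {
  m <- cbind(tiny_counts(), tiny_counts() + 0)
  colnames(m) <- paste0("S", 1:6)
  res <- simple_de(m, c("S1", "S2"), c("S4", "S5"))
  # S4=S1, S5=S2 by construction
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
  expect_true(all(res$padj >= res$p))
  expect_error(simple_de(m, "S1", c("S2", "S3")), "at least 2")
})

test_that("planted DE genes are recovered by the consensus rule", {
  genes <- paste0("G", 1:300)
  db <- list(DUMMY = genes[1:10])
  de_genes <- genes[101:130]
  truth <- sim_truth(de_genes = setNames(rep(2, 30), de_genes))
  sim <- simulate_counts(300, db, design4, effects = truth,
                         dispersion = 50, gene_ids = genes, seed = 77)
  dual <- simulate_dual_quantifier(sim$counts, noise_sd = 0.02, seed = 78)
  test_s <- design4$sample_id[design4$phase == "return"]
  ref_s <- design4$sample_id[design4$timepoint_label == "L-3"]
  dge_a <- simple_de(dual$a, test_s, ref_s)
  dge_b <- simple_de(dual$b, test_s, ref_s)
  cons <- concordance(dual$a, dual$b, dge_a, dge_b)$consensus_degs
  sensitivity <- length(intersect(cons, de_genes)) / length(de_genes)
  expect_gte(sensitivity, 0.8)
})

test_that("co-regulation calls agree with an independent GESECA route", {
  skip_if_not_installed("fgsea")
  set.seed(16)
  genes <- sprintf("G%04d", 1:600)
  db <- lapply(1:30, function(i) sample(genes, 15))
  names(db) <- sprintf("P%02d", 1:30)
  planted <- names(db)[1:3]
  truth <- sim_truth(disrupted_pathways = setNames(rep(1, 3), planted))
  sim <- simulate_counts(600, db, design4, effects = truth,
                         gene_ids = genes, seed = 4)
  z <- zscore_expression(normalize_library_size(sim$counts))
  res <- coregulation_test(z, db, n_perm = 1000, seed = 5)
  ref <- suppressWarnings(
    fgsea::geseca(db, z$z, minSize = 2, maxSize = 500,
                  center = FALSE, scale = FALSE))
  merged <- merge(res, as.data.frame(ref)[, c("pathway", "pval")],
                  by = "pathway")
  is_planted <- merged$pathway %in% planted
  # both routes call every planted pathway and agree on the null
  expect_true(all(merged$p[is_planted] < 0.01))
  expect_true(all(merged$pval[is_planted] < 0.01))
  expect_lt(max(abs(merged$p - merged$pval)[!is_planted]), 0.1)
})

test_that("BH adjustment agrees with the brute-force step-up oracle", {
  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(3:20, 1))
    expect_equal(p.adjust(p, method = "BH"), bh_oracle(p),
                 tolerance = 1e-12)
  }
})
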
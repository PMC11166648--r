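design4 <- mission_design()

test_that("coverage filter applies per listed sample", {
  cov <- matrix(c(25L, 19L,
                  30L, 20L), 2, 2, byrow = TRUE,
                dimnames = list(NULL, c("A", "B")))
  mod <- matrix(0L, 2, 2, dimnames = list(NULL, c("A", "B")))
  tab <- tiny_meth(cov, mod)
  kept <- filter_coverage(tab, min_cov = 20)
  # coverage exactly 20 is retained (minimum read as >=); 19 removes a site
  expect_equal(kept$sites$site_id, "s02")
  expect_equal(attr(kept, "n_removed"), 1)
  expect_equal(nrow(filter_coverage(tab, min_cov = 1)$sites), 2)
  # the rule can be restricted to a sample subset
  expect_equal(nrow(filter_coverage(tab, min_cov = 20, samples = "A")$sites),
               2)
})

test_that("DRACH check matches canonical examples", {
  expect_true(drach_check("GGACT"))
  expect_false(drach_check("GCACT"))
  expect_true(drach_check("ggacu"))  # case and U/T equivalence
  expect_error(drach_check("GGAC"), "length 5")
  expect_error(drach_check("GGACZ"), "non-ACGTU")
})

test_that("identical group profiles yield zero difference and ns", {
  cov <- matrix(50L, 2, 4, dimnames = list(NULL, paste0("S", 1:4)))
  mod <- matrix(c(20L, 20L, 20L, 20L,
                  5L, 5L, 5L, 5L), 2, 4, byrow = TRUE,
                dimnames = list(NULL, paste0("S", 1:4)))
  tab <- tiny_meth(cov, mod)
  res <- diff_methylation(tab, c("S1", "S2"), c("S3", "S4"),
                          engine = "pooled")
  expect_equal(res$meth_diff, c(0, 0))
  expect_equal(res$direction, c("ns", "ns"))
  expect_true(all(res$q >= res$p - 1e-12))
})

test_that("pooled engine reproduces the 2x2 worked example exactly", {
  cov <- matrix(c(50L, 50L), 1, 2, dimnames = list(NULL, c("T", "R")))
  mod <- matrix(c(30L, 10L), 1, 2, dimnames = list(NULL, c("T", "R")))
  tab <- tiny_meth(cov, mod)
  res <- diff_methylation(tab, "T", "R", engine = "pooled")
  expect_equal(res$meth_diff, 40)
  oracle <- fisher.test(matrix(c(30, 20, 10, 40), 2, byrow = TRUE))$p.value
  expect_equal(res$p, oracle, tolerance = 1e-10)
})

test_that("engine auto falls back to pooled for single-sample groups", {
  cov <- matrix(100L, 1, 3, dimnames = list(NULL, c("A", "B", "C")))
  mod <- matrix(c(60L, 10L, 12L), 1, 3,
                dimnames = list(NULL, c("A", "B", "C")))
  tab <- tiny_meth(cov, mod)
  pooled <- diff_methylation(tab, "A", c("B", "C"), engine = "pooled")
  auto <- diff_methylation(tab, "A", c("B", "C"))
  expect_equal(auto$p, pooled$p)
  expect_error(diff_methylation(tab, character(0), "B"), "nonempty")
  expect_error(diff_methylation(tab, "A", "A"), "overlap")
})

test_that("logistic engine detects a strong shift and stays calibrated", {
  set.seed(20)
  n <- 40
  cov <- matrix(rpois(n * 8, 80) + 10L, n, 8,
                dimnames = list(NULL, paste0("S", 1:8)))
  pi0 <- rep(0.2, n)
  pi1 <- c(0.7, pi0[-1])  # site 1 carries a large effect in the test group
  mod <- cov
  for (j in 1:4) mod[, j] <- rbinom(n, cov[, j], pi1)
  for (j in 5:8) mod[, j] <- rbinom(n, cov[, j], pi0)
  tab <- tiny_meth(cov, mod)
  res <- diff_methylation(tab, paste0("S", 1:4), paste0("S", 5:8),
                          engine = "logistic")
  expect_lt(res$p[1], 1e-6)
  expect_equal(res$direction[1], "hyper")
  expect_lt(mean(res$p[-1] < 0.05), 0.25)
})

test_that("profile classification partitions significant sites by sign", {
  rec <- data.frame(site_id = c("a", "b", "c"),
                    meth_diff = c(15, -10, 5),
                    significant = c(TRUE, TRUE, FALSE),
                    direction = c("hyper", "hypo", "ns"))
  cls <- classify_profile(rec)
  expect_equal(cls$hyper, "a")
  expect_equal(cls$hypo, "b")
  expect_length(intersect(cls$hyper, cls$hypo), 0)
})

test_that("reversal rule reports hyper sites that significantly decrease", {
  flight <- data.frame(site_id = c("a", "b", "c"),
                       gene_id = c("g1", "g2", "g3"),
                       meth_diff = c(30, 25, -20),
                       q = c(0.001, 0.001, 0.001),
                       significant = TRUE,
                       direction = c("hyper", "hyper", "hypo"))
  recovery <- data.frame(site_id = c("a", "b", "c"),
                         gene_id = c("g1", "g2", "g3"),
                         meth_diff = c(-30, -28, 25),
                         q = c(0.005, 0.5, 0.002),
                         significant = c(TRUE, FALSE, TRUE),
                         direction = c("hypo", "ns", "hyper"))
  rep <- reversal_analysis(flight, list("R+45" = recovery))
  expect_equal(rep[["R+45"]]$hyper_reversed$site_id, "a")  # b is ns
  expect_equal(rep[["R+45"]]$hypo_reversed$site_id, "c")
  expect_equal(rep[["R+45"]]$genes_down, "g1")
  expect_error(reversal_analysis(flight, list()), "missing recovery")
})

test_that("pathway methylation density follows the sites-per-gene rule", {
  sig <- data.frame(site_id = sprintf("s%d", 1:9),
                    gene_id = c(rep("g1", 5), rep("g2", 4)),
                    position = 1:9)
  db <- list(P1 = c("g1", "g2"), P2 = c("g3", "g4"), GONE = "zz")
  universe <- c("g1", "g2", "g3", "g4")
  dens <- pathway_meth_density(sig, db, universe)
  expect_equal(dens$density[dens$pathway == "P1"], 4.5)
  expect_equal(dens$density[dens$pathway == "P2"], 0)
  expect_equal(attr(dens, "skipped"), "GONE")
  # undetected pathway genes change neither numerator nor denominator
  db2 <- list(P1 = c("g1", "g2", "undetected"))
  expect_equal(pathway_meth_density(sig, db2, universe)$density, 4.5)
  # transcript collapsing counts one site per (gene, position)
  sig2 <- rbind(sig, data.frame(site_id = "s10", gene_id = "g1",
                                position = 1))
  expect_equal(pathway_meth_density(sig2, db, universe,
                                    collapse_transcripts = TRUE)$density[1],
               4.5)
})

test_that("density/expression correlation handles degenerate inputs", {
  d <- c(P1 = 1, P2 = 2, P3 = 3, P4 = 4)
  res <- density_expression_correlation(d, d)
  expect_equal(res$pearson_r, 1)
  expect_equal(res$spearman_rho, 1)
  expect_warning(res2 <- density_expression_correlation(
    c(P1 = 1, P2 = 1, P3 = 1), d[1:3]), "constant")
  expect_true(is.na(res2$pearson_r))
  rev <- setNames(rev(unname(d)), names(d))
  expect_equal(density_expression_correlation(d, rev)$spearman_rho, -1)
  expect_error(density_expression_correlation(d[1:2], d[1:2]), "fewer than 3")
})

test_that("DEG/methylation overlap is plain set algebra", {
  res <- deg_meth_overlap(c("A", "B", "C"), c("B", "C", "D"))
  expect_setequal(res$overlap, c("B", "C"))
  expect_equal(res$n_overlap, 2)
  expect_equal(deg_meth_overlap(c("A"), c("B"))$n_overlap, 0)
  expect_lte(res$n_overlap, min(res$n_meth, res$n_deg))
})

test_that("planted reversal sites are recovered from simulation", {
  hyper <- site_effects(sprintf("site%05d", 1:10), 40,
                        reversal = c(rep(TRUE, 5), rep(FALSE, 5)))
  truth <- sim_truth(hyper_sites = hyper)
  sim <- simulate_methylation(60, design4, coverage_mean = 100,
                              effects = truth, seed = 51)
  tab <- filter_coverage(sim$table, min_cov = 20)
  ret <- design4$sample_id[design4$phase == "return"]
  pre <- design4$sample_id[design4$phase == "preflight"]
  fp1 <- diff_methylation(tab, ret, pre, engine = "pooled")
  r45 <- diff_methylation(
    tab, design4$sample_id[design4$timepoint_label == "R+45"], ret,
    engine = "pooled")
  rep <- reversal_analysis(fp1, list("R+45" = r45))
  reversed <- rep[["R+45"]]$hyper_reversed$site_id
  planted_rev <- hyper$site_id[hyper$reversal]
  expect_gte(length(intersect(reversed, planted_rev)) /
               length(planted_rev), 0.8)
})
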
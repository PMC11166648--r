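#' Default pipeline configuration
#'
#' A complete, runnable configuration for a simulated end-to-end study:
#' the generator parameters mirror the mission layout (4 subjects, 7
#' timepoints) and the analysis thresholds are the study's conventions
#' (consensus-DEG FDR 0.05, methylation q 0.01, minimum 20x coverage,
#' 400 bp read-length QC).
#'
#' @param outdir output directory for all stage results.
#' @param seed integer seed driving every stochastic stage.
#' @return nested named list, serializable to YAML.
#' @export
default_config <- function(outdir = "pipeline_out", seed = 1) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    simulate = list(
      n_genes = 1200,
      n_pathways = 60,
      pathway_size = 15,
      n_disrupted = 6,
      disrupted_shift = 0.8,
      n_trending = 6,
      trending_slope = 0.01,
      dispersion = 10,
      n_de_genes = 30,
      de_log2fc = 2,
      homolog_groups = 2,
      meth_sites = 300,
      meth_coverage = 50,
      n_hyper = 20,
      n_hypo = 12,
      meth_delta = 35,
      reversal_fraction = 0.5,
      catalog_shared = 60,
      catalog_unique = list("L-92" = 8, "L-3" = 7, "R+1" = 6,
                            "R+82" = 1),
      dropout_rate = 0.05
    ),
    thresholds = list(
      alpha = 0.05,
      q = 0.01,
      min_cov = 20,
      min_avg_read_len = 400,
      n_perm = 200,
      min_size = 5,
      max_size = 500
    )
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Validate a pipeline configuration
#'
#' Violations are data, not errors: the empty character vector means the
#' configuration is runnable.
#'
#' @param config configuration list (see [default_config()]).
#' @return character vector of violations.
#' @export
validate_config <- function(config) {
  v <- character(0)
  th <- config$thresholds
  if (is.null(config$outdir)) v <- c(v, "outdir missing")
  if (is.null(config$seed) || !is.numeric(config$seed)) {
    v <- c(v, "seed missing or non-numeric")
  }
  if (is.null(th)) return(c(v, "thresholds missing"))
  if (!is.null(th$alpha) && (th$alpha <= 0 || th$alpha >= 1)) {
    v <- c(v, "alpha out of range (0,1)")
  }
  if (!is.null(th$q) && (th$q <= 0 || th$q >= 1)) {
    v <- c(v, "q out of range (0,1)")
  }
  if (!is.null(th$min_cov) && th$min_cov < 1) v <- c(v, "min_cov below 1")
  if (!is.null(th$n_perm) && th$n_perm < 100) {
    v <- c(v, "n_perm below minimum 100")
  }
  for (f in c("gmt", "counts_a", "counts_b", "sample_sheet", "meth_table")) {
    p <- config$inputs[[f]]
    if (!is.null(p) && !file.exists(p)) {
      v <- c(v, paste0("input file missing: ", f, " (", p, ")"))
    }
  }
  v
}

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_tsv_atomic <- function(df, path) {
  write_atomic(function(p) {
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

# stable small-integer seeds per stage, derived from the master seed
stage_seed <- function(seed, offset) {
  (as.integer(seed) * 101L + offset * 13L) %% 1000003L
}

#' Run the end-to-end simulated analysis pipeline
#'
#' Simulates a study (counts with planted pathway effects, two quantifier
#' views, methylation sites with planted hyper/hypo/reversal effects, a
#' transcript catalog with planted unique transcripts), then runs every
#' analysis stage in dependency order: normalization, z-scoring,
#' co-regulation testing, dz ranking, dual-quantifier concordance with the
#' consensus-DEG rule, differential methylation (flight and recovery
#' profiles), reversal profiling, pathway methylation density and its
#' correlation with expression variability, DEG-methylation overlap, and
#' per-timepoint unique transcripts. Re-running with an identical
#' configuration and seed reproduces every output byte for byte.
#'
#' @param config configuration list, see [default_config()]; validated
#'   before any compute.
#' @return the run report (also written to `<outdir>/report.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  violations <- validate_config(config)
  if (length(violations) > 0) {
    stop("invalid configuration: ", paste(violations, collapse = "; "))
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$simulate
  th <- config$thresholds
  seed <- as.integer(config$seed)
  # parameter echo omits the output path so identical runs into different
  # directories produce identical reports
  report <- list(parameters = config[setdiff(names(config), "outdir")],
                 stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # -- simulate ------------------------------------------------------------
  design <- mission_design()
  design$avg_read_length_bp <- 600
  res <- stage("simulate", {
    withr::with_seed(stage_seed(seed, 1L), {
      gene_ids <- sprintf("G%05d", seq_len(sim$n_genes))
      db <- lapply(seq_len(sim$n_pathways), function(i) {
        sample(gene_ids, sim$pathway_size)
      })
      names(db) <- sprintf("P%04d", seq_len(sim$n_pathways))
      disrupted <- stats::setNames(rep(sim$disrupted_shift, sim$n_disrupted),
                                   names(db)[seq_len(sim$n_disrupted)])
      trending <- stats::setNames(
        rep(sim$trending_slope, sim$n_trending),
        names(db)[sim$n_disrupted + seq_len(sim$n_trending)])
      null_genes <- setdiff(gene_ids, unlist(db[c(names(disrupted),
                                                  names(trending))]))
      de <- stats::setNames(rep(sim$de_log2fc, sim$n_de_genes),
                            sample(null_genes, sim$n_de_genes))
      hyper <- site_effects(sprintf("site%05d", seq_len(sim$n_hyper)),
                            sim$meth_delta,
                            reversal = seq_len(sim$n_hyper) <=
                              round(sim$n_hyper * sim$reversal_fraction))
      hypo <- site_effects(
        sprintf("site%05d", sim$n_hyper + seq_len(sim$n_hypo)),
        -sim$meth_delta,
        reversal = seq_len(sim$n_hypo) <=
          round(sim$n_hypo * sim$reversal_fraction))
      truth <- sim_truth(disrupted_pathways = disrupted,
                         trending_pathways = trending,
                         hyper_sites = hyper, hypo_sites = hypo,
                         de_genes = de)
      groups <- if (sim$homolog_groups > 0) {
        split(sample(null_genes, 3 * sim$homolog_groups),
              rep(seq_len(sim$homolog_groups), each = 3))
      } else list()
      list(db = db, truth = truth, homolog_groups = groups)
    })
  })
  db <- res$db; truth <- res$truth
  counts_sim <- stage("simulate_counts", {
    simulate_counts(sim$n_genes, db, design, truth,
                    dispersion = sim$dispersion,
                    gene_ids = sprintf("G%05d", seq_len(sim$n_genes)),
                    seed = stage_seed(seed, 2L))
  })
  dual <- stage("simulate_dual_quantifier", {
    simulate_dual_quantifier(counts_sim$counts, res$homolog_groups,
                             seed = stage_seed(seed, 3L))
  })
  meth_sim <- stage("simulate_methylation", {
    simulate_methylation(sim$meth_sites, design,
                         coverage_mean = sim$meth_coverage,
                         effects = truth,
                         gene_pool = unique(unlist(db, use.names = FALSE)),
                         seed = stage_seed(seed, 4L))
  })
  cat_sim <- stage("simulate_catalog", {
    simulate_catalog(design, n_shared = sim$catalog_shared,
                     unique_spec = sim$catalog_unique,
                     dropout_rate = sim$dropout_rate,
                     seed = stage_seed(seed, 5L))
  })
  write_tsv_atomic(design, file.path(outdir, "sample_sheet.tsv"))
  write_atomic(function(p) write_counts(dual$a, p),
               file.path(outdir, "counts_a.tsv"))
  write_atomic(function(p) write_counts(dual$b, p),
               file.path(outdir, "counts_b.tsv"))
  write_atomic(function(p) write_gmt(db, p), file.path(outdir, "sets.gmt"))
  write_atomic(function(p) write_meth_table(meth_sim$table, p),
               file.path(outdir, "meth_sites.tsv"))
  write_atomic(function(p) write_tracking(cat_sim$catalog, p),
               file.path(outdir, "catalog.tracking"))
  report$stages$simulate <- list(
    n_genes = sim$n_genes, n_pathways = length(db),
    n_samples = nrow(design), n_meth_sites = sim$meth_sites,
    n_catalog_transcripts = nrow(cat_sim$catalog$transcripts))

  # -- expression ----------------------------------------------------------
  averaged <- stage("average_quantifiers",
                    suppressWarnings(average_quantifiers(dual$a, dual$b)))
  normed <- stage("normalize", normalize_library_size(averaged))
  zmat <- stage("zscore", zscore_expression(normed))
  coreg <- stage("coregulation", {
    coregulation_test(zmat, db, n_perm = th$n_perm,
                      min_size = th$min_size, max_size = th$max_size,
                      seed = stage_seed(seed, 6L))
  })
  write_tsv_atomic(coreg, file.path(outdir, "coregulation.tsv"))
  n_sig_pathways <- sum(coreg$padj < th$alpha)
  report$stages$coregulation <- list(
    pathways_tested = nrow(coreg), pathways_significant = n_sig_pathways,
    n_perm = th$n_perm)

  dz <- stage("dz", dz_table(zmat, db, design,
                             pathways = coreg$pathway))
  write_tsv_atomic(dz, file.path(outdir, "dz.tsv"))
  report$stages$dz <- list(
    pathways_ranked = nrow(dz),
    top_pathway = dz$pathway[1],
    top_dz = dz$dz[1])

  # -- consensus DEGs ------------------------------------------------------
  test_s <- design$sample_id[design$phase == "return"]
  ref_s <- design$sample_id[design$phase == "preflight"]
  blocks <- stats::setNames(design$subject_id, design$sample_id)
  dge_a <- stage("de_a", simple_de(dual$a, test_s, ref_s, blocks,
                                   source = "quantifier_a"))
  dge_b <- stage("de_b", simple_de(dual$b, test_s, ref_s, blocks,
                                   source = "quantifier_b"))
  conc <- stage("concordance",
                concordance(dual$a, dual$b, dge_a, dge_b,
                            alpha = th$alpha))
  write_tsv_atomic(rbind(dge_a, dge_b), file.path(outdir, "dge.tsv"))
  report$stages$concordance <- list(
    median_r = conc$median_r, log2fc_r = conc$log2fc_r,
    consensus_degs = length(conc$consensus_degs))

  # -- methylation ---------------------------------------------------------
  filtered <- stage("filter_coverage",
                    filter_coverage(meth_sim$table, min_cov = th$min_cov))
  meth_test <- meth_sim$table$sites$site_id  # all sites, pre-filter count
  fp1 <- stage("diffmeth_fp1", {
    diff_methylation(filtered,
                     test_samples = design$sample_id[design$phase == "return"],
                     ref_samples = design$sample_id[design$phase == "preflight"],
                     q_threshold = th$q)
  })
  write_tsv_atomic(fp1, file.path(outdir, "diffmeth_fp1.tsv"))
  flight_sets <- classify_profile(fp1)
  recovery <- list()
  for (day in c("R+45", "R+82")) {
    recovery[[day]] <- stage(paste0("diffmeth_", day), {
      diff_methylation(filtered,
                       test_samples = design$sample_id[design$timepoint_label == day],
                       ref_samples = design$sample_id[design$phase == "return"],
                       q_threshold = th$q)
    })
  }
  rev_report <- stage("reversal", reversal_analysis(fp1, recovery, th$q))
  report$stages$methylation <- list(
    sites_total = length(meth_test),
    sites_tested = nrow(filtered$sites),
    sites_significant = sum(fp1$significant),
    hyper = length(flight_sets$hyper),
    hypo = length(flight_sets$hypo),
    reversed_down_r45 = nrow(rev_report[["R+45"]]$hyper_reversed),
    reversed_up_r45 = nrow(rev_report[["R+45"]]$hypo_reversed))

  dens <- stage("meth_density", {
    pathway_meth_density(fp1[fp1$significant, ], db,
                         gene_universe = unique(filtered$sites$gene_id))
  })
  write_tsv_atomic(dens, file.path(outdir, "meth_density.tsv"))
  corr <- stage("density_correlation",
                tryCatch(density_expression_correlation(dens, coreg),
                         error = function(e) NULL))
  report$stages$meth_density <- list(
    pathways = nrow(dens), max_density = if (nrow(dens)) max(dens$density) else 0,
    pearson_r = if (is.null(corr)) NA else corr$pearson_r)

  overlap <- stage("overlap", {
    deg_meth_overlap(fp1$gene_id[fp1$significant], conc$consensus_degs)
  })
  report$stages$overlap <- list(
    n_overlap = overlap$n_overlap, n_meth = overlap$n_meth,
    n_deg = overlap$n_deg)

  # -- de novo catalog -----------------------------------------------------
  excluded <- stage("qc",
                    suppressMessages(flag_low_quality(design,
                                                      th$min_avg_read_len)))
  win1 <- c("L-92", "L-44", "L-3", "R+1")
  win2 <- c("R+1", "R+45", "R+82", "R+194")
  uniq1 <- stage("unique_window1",
                 unique_transcripts(cat_sim$catalog, win1, excluded))
  uniq2 <- stage("unique_window2",
                 unique_transcripts(cat_sim$catalog, win2, excluded))
  all_unique <- unique(unlist(lapply(c(uniq1$unique_by_timepoint,
                                       uniq2$unique_by_timepoint),
                                     `[[`, "transcript_id")))
  tally <- class_code_tally(all_unique, cat_sim$catalog)
  report$stages$denovo <- list(
    excluded_samples = length(excluded),
    unique_preflight_window = lapply(uniq1$unique_by_timepoint, nrow),
    unique_recovery_window = lapply(uniq2$unique_by_timepoint, nrow),
    class_code_tally = as.list(tally[tally > 0]))

  report_json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 12,
                                  pretty = TRUE, null = "null")
  write_atomic(function(p) writeLines(report_json, p),
               file.path(outdir, "report.json"))
  invisible(report)
}
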
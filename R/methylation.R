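#' Construct a per-site methylation table
#'
#' Holds site annotation (transcript-relative 0-based position, 5-mer
#' context, exon/UTR region) together with per-sample coverage and
#' modified-read counts, as emitted by site-level m6A callers on direct-RNA
#' data.
#'
#' @param sites data.frame: `site_id`, `transcript_id`, `gene_id`,
#'   `position`, `kmer`, `region`.
#' @param coverage,mod_reads integer matrices, sites x samples;
#'   `0 <= mod_reads <= coverage` cell-wise.
#' @return object of class `meth_site_table`.
#' @export
meth_site_table <- function(sites, coverage, mod_reads) {
  stopifnot(is.data.frame(sites),
            all(c("site_id", "transcript_id", "gene_id", "position",
                  "kmer", "region") %in% names(sites)))
  if (anyDuplicated(sites$site_id)) stop("duplicate site_id")
  if (any(nchar(sites$kmer) != 5)) stop("kmer must be length 5")
  stopifnot(is.matrix(coverage), is.matrix(mod_reads),
            all(dim(coverage) == dim(mod_reads)),
            nrow(coverage) == nrow(sites))
  if (any(coverage < 0)) stop("negative coverage")
  if (any(mod_reads < 0) || any(mod_reads > coverage)) {
    stop("mod_reads must satisfy 0 <= mod_reads <= coverage")
  }
  rownames(coverage) <- rownames(mod_reads) <- sites$site_id
  structure(list(sites = sites, coverage = coverage,
                 mod_reads = mod_reads),
            class = "meth_site_table")
}

#' Read / write a methylation site table
#'
#' TSV layout: the six annotation columns followed by `cov_<sample>` and
#' `mod_<sample>` column pairs.
#'
#' @param path file path.
#' @return a [meth_site_table()].
#' @export
read_meth_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  anno <- c("site_id", "transcript_id", "gene_id", "position", "kmer",
            "region")
  missing <- setdiff(anno, names(df))
  if (length(missing) > 0) {
    stop("methylation table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  cov_cols <- grep("^cov_", names(df), value = TRUE)
  mod_cols <- grep("^mod_", names(df), value = TRUE)
  samples <- sub("^cov_", "", cov_cols)
  if (!setequal(samples, sub("^mod_", "", mod_cols))) {
    stop("mismatched cov_/mod_ column pairs")
  }
  coverage <- as.matrix(df[, paste0("cov_", samples), drop = FALSE])
  mod <- as.matrix(df[, paste0("mod_", samples), drop = FALSE])
  colnames(coverage) <- colnames(mod) <- samples
  meth_site_table(df[, anno], coverage, mod)
}

#' @rdname read_meth_table
#' @param table a [meth_site_table()].
#' @export
write_meth_table <- function(table, path) {
  samples <- colnames(table$coverage)
  cov <- table$coverage
  mod <- table$mod_reads
  colnames(cov) <- paste0("cov_", samples)
  colnames(mod) <- paste0("mod_", samples)
  df <- cbind(table$sites, as.data.frame(cov), as.data.frame(mod))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Coverage filter for methylation sites
#'
#' Retains sites with coverage at least `min_cov` in every listed sample —
#' the per-sample rule used before differential testing (minimum 20x by
#' default).
#'
#' @param table a [meth_site_table()].
#' @param min_cov minimum per-sample coverage (>= 1).
#' @param samples sample ids the rule applies to (default: all).
#' @return filtered table; attribute `n_removed` records the removal count.
#' @export
filter_coverage <- function(table, min_cov = 20,
                            samples = colnames(table$coverage)) {
  stopifnot(inherits(table, "meth_site_table"), min_cov >= 1)
  keep <- rowSums(table$coverage[, samples, drop = FALSE] >= min_cov) ==
    length(samples)
  out <- meth_site_table(table$sites[keep, , drop = FALSE],
                         table$coverage[keep, , drop = FALSE],
                         table$mod_reads[keep, , drop = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' DRACH motif check
#'
#' TRUE iff the 5-mer matches D-R-A-C-H with D = A/G/U, R = A/G, H = A/C/U;
#' T and U are equivalent. There are exactly 18 such 5-mers over a
#' T/U-collapsed alphabet.
#'
#' @param kmer character vector of 5-mers over `{A, C, G, T, U}`.
#' @return logical vector.
#' @export
drach_check <- function(kmer) {
  kmer <- toupper(kmer)
  if (any(nchar(kmer) != 5)) stop("kmer must have length 5")
  km <- chartr("U", "T", kmer)
  if (any(grepl("[^ACGT]", km))) stop("kmer contains non-ACGTU characters")
  ch <- function(i) substr(km, i, i)
  ch(1) %in% c("A", "G", "T") &
    ch(2) %in% c("A", "G") &
    ch(3) == "A" &
    ch(4) == "C" &
    ch(5) %in% c("A", "C", "T")
}

# Two-sided Fisher's exact p for the 2x2 table
#   [a, b]   a = modified (test),  b = unmodified (test)
#   [c, d]   c = modified (ref),   d = unmodified (ref)
# Sum of hypergeometric point probabilities <= that of the observed table
# (with the customary (1 + 1e-7) relative guard against floating-point
# ties).
fisher_2x2_p <- function(a, b, c, d) {
  M <- a + c      # total modified
  U <- b + d      # total unmodified
  n1 <- a + b     # test-group coverage
  if (M + U == 0) return(NA_real_)
  lo <- max(0, n1 - U)
  hi <- min(n1, M)
  support <- lo:hi
  dens <- stats::dhyper(support, M, U, n1)
  p_obs <- stats::dhyper(a, M, U, n1)
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}

#' Site-level differential methylation
#'
#' Two engines: `"pooled"` sums (modified, unmodified) reads within each
#' group and applies a two-sided Fisher's exact test on the 2x2 table;
#' `"logistic"` fits a per-sample binomial logistic regression with a group
#' indicator and takes the likelihood-ratio p. `"auto"` (default) uses
#' logistic when both groups have >= 2 samples, else pooled. Percentages
#' are computed from the pooled group counts; q-values are
#' Benjamini-Hochberg across tested sites.
#'
#' @param table a coverage-filtered [meth_site_table()].
#' @param test_samples,ref_samples disjoint, nonempty sample-id vectors.
#' @param q_threshold significance threshold on q (default 0.01).
#' @param engine `"auto"`, `"pooled"`, or `"logistic"`.
#' @return data.frame: `site_id`, `gene_id`, `transcript_id`, `pct_test`,
#'   `pct_ref`, `meth_diff` (percentage points, test - reference), `p`,
#'   `q`, `significant`, `direction` in `{hyper, hypo, ns}`.
#' @export
diff_methylation <- function(table, test_samples, ref_samples,
                             q_threshold = 0.01,
                             engine = c("auto", "pooled", "logistic")) {
  engine <- match.arg(engine)
  stopifnot(inherits(table, "meth_site_table"))
  if (length(test_samples) == 0 || length(ref_samples) == 0) {
    stop("both groups must be nonempty")
  }
  if (length(intersect(test_samples, ref_samples)) > 0) {
    stop("test and reference groups overlap")
  }
  stopifnot(all(c(test_samples, ref_samples) %in% colnames(table$coverage)))
  if (engine == "auto") {
    engine <- if (length(test_samples) >= 2 && length(ref_samples) >= 2) {
      "logistic"
    } else "pooled"
  }
  cov_t <- table$coverage[, test_samples, drop = FALSE]
  cov_r <- table$coverage[, ref_samples, drop = FALSE]
  mod_t <- table$mod_reads[, test_samples, drop = FALSE]
  mod_r <- table$mod_reads[, ref_samples, drop = FALSE]
  ct <- rowSums(cov_t); cr <- rowSums(cov_r)
  mt <- rowSums(mod_t); mr <- rowSums(mod_r)
  pct_test <- ifelse(ct > 0, 100 * mt / ct, NA_real_)
  pct_ref <- ifelse(cr > 0, 100 * mr / cr, NA_real_)

  n_sites <- nrow(table$sites)
  p <- rep(NA_real_, n_sites)
  group <- factor(rep(c("test", "ref"),
                      c(length(test_samples), length(ref_samples))),
                  levels = c("ref", "test"))
  for (i in seq_len(n_sites)) {
    if (ct[i] == 0 || cr[i] == 0) next
    if (engine == "pooled") {
      p[i] <- fisher_2x2_p(mt[i], ct[i] - mt[i], mr[i], cr[i] - mr[i])
    } else {
      mods <- c(mod_t[i, ], mod_r[i, ])
      covs <- c(cov_t[i, ], cov_r[i, ])
      ok <- covs > 0
      fit <- suppressWarnings(
        stats::glm(cbind(mods[ok], covs[ok] - mods[ok]) ~ group[ok],
                   family = stats::binomial()))
      p[i] <- stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                            lower.tail = FALSE)
    }
  }
  q <- rep(NA_real_, n_sites)
  tested <- !is.na(p)
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  meth_diff <- pct_test - pct_ref
  significant <- tested & q < q_threshold
  direction <- ifelse(!significant, "ns",
                      ifelse(meth_diff > 0, "hyper", "hypo"))
  # a significant site with exactly zero difference is not directional
  direction[significant & meth_diff == 0] <- "ns"
  significant[significant & meth_diff == 0] <- FALSE
  data.frame(site_id = table$sites$site_id,
             gene_id = table$sites$gene_id,
             transcript_id = table$sites$transcript_id,
             pct_test = pct_test, pct_ref = pct_ref,
             meth_diff = meth_diff, p = p, q = q,
             significant = significant, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Partition significant sites into hyper- and hypomethylated sets
#'
#' @param records a [diff_methylation()] result from one profile.
#' @return list with character vectors `hyper` and `hypo` (site ids).
#' @export
classify_profile <- function(records) {
  list(hyper = records$site_id[records$direction == "hyper"],
       hypo = records$site_id[records$direction == "hypo"])
}

#' Recovery reversal of flight-induced methylation changes
#'
#' Given the flight profile (return day vs all pre-flight) and one
#' recovery profile per recovery day (that day vs the return day), reports,
#' per day, the sites that were hypermethylated at return and significantly
#' decreased in recovery (q below threshold, negative difference), and
#' symmetrically the hypomethylated sites that significantly increased.
#' Genes are de-duplicated.
#'
#' @param flight_records [diff_methylation()] result for return vs
#'   pre-flight.
#' @param recovery_records_by_day named list (e.g. `R+45`, `R+82`) of
#'   [diff_methylation()] results for recovery day vs return day.
#' @param q_threshold significance threshold (default 0.01).
#' @return object of class `reversal_report`: per day, data.frames
#'   `hyper_reversed` / `hypo_reversed` (`site_id`, `gene_id`,
#'   `meth_diff`, `q`) and gene vectors `genes_down` / `genes_up`.
#' @export
reversal_analysis <- function(flight_records, recovery_records_by_day,
                              q_threshold = 0.01) {
  if (length(recovery_records_by_day) == 0 ||
      is.null(names(recovery_records_by_day))) {
    stop("missing recovery profiles")
  }
  flight <- classify_profile(flight_records)
  out <- lapply(names(recovery_records_by_day), function(day) {
    rec <- recovery_records_by_day[[day]]
    sig <- rec$significant
    down <- rec[sig & rec$meth_diff < 0 & rec$site_id %in% flight$hyper &
                  rec$q < q_threshold,
                c("site_id", "gene_id", "meth_diff", "q")]
    up <- rec[sig & rec$meth_diff > 0 & rec$site_id %in% flight$hypo &
                rec$q < q_threshold,
              c("site_id", "gene_id", "meth_diff", "q")]
    rownames(down) <- rownames(up) <- NULL
    list(hyper_reversed = down, hypo_reversed = up,
         genes_down = unique(down$gene_id), genes_up = unique(up$gene_id))
  })
  names(out) <- names(recovery_records_by_day)
  structure(out, class = "reversal_report")
}

#' Differentially methylated sites per gene, by pathway
#'
#' `density(P) = #significant sites on genes of P / |P intersect
#' gene_universe|`, where the universe is the set of genes detected in the
#' methylation table. Pathways with an empty intersection are skipped and
#' reported in the `skipped` attribute. With `collapse_transcripts`, sites
#' at the same (gene, position) on different transcripts count once.
#'
#' @param sig_sites data.frame of significant sites, carrying `gene_id`
#'   (and `position` if collapsing).
#' @param geneset_db named list of gene sets.
#' @param gene_universe genes detected in the methylation table.
#' @param collapse_transcripts count one site per (gene, position).
#' @return data.frame: `pathway`, `n_sites`, `n_genes`, `density`;
#'   attribute `skipped`.
#' @export
pathway_meth_density <- function(sig_sites, geneset_db, gene_universe,
                                 collapse_transcripts = FALSE) {
  stopifnot(is.data.frame(sig_sites), "gene_id" %in% names(sig_sites))
  if (collapse_transcripts) {
    stopifnot("position" %in% names(sig_sites))
    sig_sites <- sig_sites[!duplicated(paste(sig_sites$gene_id,
                                             sig_sites$position)), ]
  }
  rows <- lapply(names(geneset_db), function(p) {
    genes <- intersect(geneset_db[[p]], gene_universe)
    if (length(genes) == 0) return(NULL)
    n_sites <- sum(sig_sites$gene_id %in% genes)
    data.frame(pathway = p, n_sites = n_sites, n_genes = length(genes),
               density = n_sites / length(genes), stringsAsFactors = FALSE)
  })
  empty <- vapply(rows, is.null, logical(1))
  skipped <- names(geneset_db)[empty]
  out <- if (any(!empty)) do.call(rbind, rows[!empty]) else
    data.frame(pathway = character(), n_sites = integer(),
               n_genes = integer(), density = numeric())
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Correlate methylation density with expressional variability
#'
#' Pearson and Spearman coefficients (with two-sided p-values) between
#' per-pathway methylation density and the co-regulation score, on pathways
#' present in both inputs.
#'
#' @param densities named numeric (pathway -> density) or a
#'   [pathway_meth_density()] data.frame.
#' @param coreg_results named numeric (pathway -> score) or a
#'   [coregulation_test()] data.frame.
#' @return list: `n`, `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p` (Pearson NA with a warning if a vector is constant).
#' @export
density_expression_correlation <- function(densities, coreg_results) {
  if (is.data.frame(densities)) {
    densities <- stats::setNames(densities$density, densities$pathway)
  }
  if (is.data.frame(coreg_results)) {
    coreg_results <- stats::setNames(coreg_results$score,
                                     coreg_results$pathway)
  }
  shared <- intersect(names(densities), names(coreg_results))
  if (length(shared) < 3) stop("fewer than 3 shared pathways")
  x <- densities[shared]
  y <- coreg_results[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; Pearson correlation undefined", call. = FALSE)
    pe <- list(estimate = NA_real_, p.value = NA_real_)
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    pe <- list(estimate = unname(ct$estimate), p.value = ct$p.value)
  }
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(n = length(shared),
       pearson_r = pe$estimate, pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
}

#' Overlap between differentially methylated genes and DEGs
#'
#' @param sig_meth_genes gene ids bearing significant methylation sites.
#' @param deg_genes differentially expressed gene ids.
#' @return list: `overlap`, `only_meth`, `only_deg`, and their sizes.
#' @export
deg_meth_overlap <- function(sig_meth_genes, deg_genes) {
  sig_meth_genes <- unique(sig_meth_genes)
  deg_genes <- unique(deg_genes)
  ov <- intersect(sig_meth_genes, deg_genes)
  list(overlap = ov,
       only_meth = setdiff(sig_meth_genes, deg_genes),
       only_deg = setdiff(deg_genes, sig_meth_genes),
       n_overlap = length(ov),
       n_meth = length(sig_meth_genes),
       n_deg = length(deg_genes))
}
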
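#' Library-size normalization (counts-per-scale)
#'
#' Scales each sample so its column sum equals `scale` — counts-per-million
#' semantics at the default.
#'
#' @param counts gene x sample count matrix.
#' @param scale target column sum (default 1e6, i.e. CPM).
#' @return normalized matrix of the same shape.
#' @export
normalize_library_size <- function(counts, scale = 1e6) {
  validate_counts(counts)
  libs <- colSums(counts)
  zero <- which(libs == 0)
  if (length(zero) > 0) {
    stop("all-zero sample(s): ", paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(counts, 2, libs / scale, "/")
}

#' Average two quantifiers' count matrices
#'
#' Per-gene counts from two quantification pipelines are averaged on the
#' intersection of their gene universes; genes reported by only one
#' quantifier are dropped and listed in the `dropped_genes` attribute (and
#' a warning).
#'
#' @param counts_a,counts_b count matrices with identical sample ids.
#' @return averaged matrix over shared genes, samples in `counts_a` order.
#' @export
average_quantifiers <- function(counts_a, counts_b) {
  validate_counts(counts_a)
  validate_counts(counts_b)
  if (!setequal(colnames(counts_a), colnames(counts_b))) {
    stop("sample ids differ between quantifiers")
  }
  shared <- intersect(rownames(counts_a), rownames(counts_b))
  if (length(shared) == 0) stop("no shared genes between quantifiers")
  dropped <- c(setdiff(rownames(counts_a), shared),
               setdiff(rownames(counts_b), shared))
  if (length(dropped) > 0) {
    warning(length(dropped), " gene(s) reported by only one quantifier; ",
            "dropped", call. = FALSE)
  }
  out <- (counts_a[shared, , drop = FALSE] +
          counts_b[shared, colnames(counts_a), drop = FALSE]) / 2
  attr(out, "dropped_genes") <- dropped
  out
}

#' Gene-wise z-scoring of normalized expression
#'
#' Per gene, z-scores of `log2(value + pseudocount)` (or the raw values)
#' across all samples, using the sample standard deviation (n-1 in the
#' denominator). Genes with zero variance cannot be z-scored and are moved
#' to `constant_genes`.
#'
#' @param norm_counts library-size-normalized matrix.
#' @param log_transform apply `log2(x + pseudocount)` first (default TRUE).
#' @param pseudocount added before the log.
#' @return object of class `zmatrix`: list with `z` (matrix over retained
#'   genes) and `constant_genes` (character).
#' @export
zscore_expression <- function(norm_counts, log_transform = TRUE,
                              pseudocount = 1) {
  stopifnot(is.matrix(norm_counts))
  if (ncol(norm_counts) < 2) {
    stop("z-scores are undefined for a single-sample matrix")
  }
  x <- if (log_transform) log2(norm_counts + pseudocount) else norm_counts
  mu <- rowMeans(x)
  centered <- x - mu
  sds <- sqrt(rowSums(centered^2) / (ncol(x) - 1))
  constant <- rownames(x)[sds == 0]
  keep <- sds > 0
  z <- centered[keep, , drop = FALSE] / sds[keep]
  structure(list(z = z, constant_genes = constant), class = "zmatrix")
}

#' Median pathway z-trajectory
#'
#' For one pathway, the median z-scored expression at each timepoint.
#' Default pooling takes the median over all (member gene x subject) values
#' at the timepoint; `pooling = "by_subject"` first takes each subject's
#' median over member genes, then the median across subjects.
#'
#' @param zmat a [zscore_expression()] result.
#' @param geneset character vector of member gene ids.
#' @param sample_sheet sample sheet data.frame covering the z-matrix's
#'   samples.
#' @param pathway pathway name carried into the output.
#' @param pooling `"pooled"` (default) or `"by_subject"`.
#' @return data.frame of class `pathway_trajectory`: `timepoint_label`,
#'   `time_days`, `median_z`, `n_values`, ordered by day, with a
#'   `pathway` attribute.
#' @export
pathway_trajectory <- function(zmat, geneset, sample_sheet,
                               pathway = "pathway",
                               pooling = c("pooled", "by_subject")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(zmat, "zmatrix"))
  members <- intersect(geneset, rownames(zmat$z))
  if (length(members) == 0) stop("pathway not detected: ", pathway)
  sheet <- sample_sheet[sample_sheet$sample_id %in% colnames(zmat$z), ]
  days <- sort(unique(sheet$time_days))
  rows <- lapply(days, function(d) {
    s <- sheet[sheet$time_days == d, ]
    zsub <- zmat$z[members, s$sample_id, drop = FALSE]
    med <- if (pooling == "pooled") {
      stats::median(as.vector(zsub))
    } else {
      stats::median(apply(zsub, 2, stats::median))
    }
    data.frame(timepoint_label = s$timepoint_label[1], time_days = d,
               median_z = med, n_values = length(zsub),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "pathway") <- pathway
  class(out) <- c("pathway_trajectory", "data.frame")
  out
}

coreg_score <- function(z, members) {
  m <- colMeans(z[members, , drop = FALSE])
  sum(m^2)
}

#' Permutation test for gene-set co-regulation
#'
#' The co-regulation score of a pathway is the squared norm of its mean
#' z-profile: `sum over samples s of m_s^2`, where `m_s` is the mean of
#' member-gene z-scores in sample s. Significance is assessed against
#' uniformly random gene sets of the same size drawn from the detected
#' (z-scored) gene universe; `p = (1 + #{score_perm >= score_obs}) /
#' (n_perm + 1)`, adjusted across pathways by Benjamini-Hochberg.
#'
#' @param zmat a [zscore_expression()] result.
#' @param geneset_db named list of gene-id vectors.
#' @param n_perm number of random sets per pathway (>= 100).
#' @param min_size,max_size size bounds on the pathway after intersection
#'   with the gene universe; pathways outside are skipped and reported in
#'   the `skipped` attribute.
#' @param seed integer seed.
#' @return data.frame: `pathway`, `score`, `p`, `padj`, `n_genes_used`;
#'   attribute `skipped` is a data.frame of skipped pathways with reasons.
#' @export
coregulation_test <- function(zmat, geneset_db, n_perm = 1000,
                              min_size = 5, max_size = 500, seed = 1) {
  stopifnot(inherits(zmat, "zmatrix"), n_perm >= 100)
  z <- zmat$z
  universe <- rownames(z)
  sizes <- vapply(geneset_db, function(g) length(intersect(g, universe)),
                  integer(1))
  in_range <- sizes >= min_size & sizes <= max_size
  skipped <- data.frame(pathway = names(geneset_db)[!in_range],
                        size = sizes[!in_range],
                        reason = ifelse(sizes[!in_range] < min_size,
                                        "below min_size", "above max_size"),
                        stringsAsFactors = FALSE, row.names = NULL)
  tested <- names(geneset_db)[in_range]
  nG <- length(universe)
  withr::with_seed(seed, {
    res <- lapply(tested, function(p) {
      members <- intersect(geneset_db[[p]], universe)
      k <- length(members)
      obs <- coreg_score(z, members)
      idx <- unlist(lapply(seq_len(n_perm),
                           function(i) sample.int(nG, k)),
                    use.names = FALSE)
      sums <- rowsum(z[idx, , drop = FALSE],
                     group = rep(seq_len(n_perm), each = k),
                     reorder = FALSE)
      perm_scores <- rowSums((sums / k)^2)
      pval <- (1 + sum(perm_scores >= obs)) / (n_perm + 1)
      data.frame(pathway = p, score = obs, p = pval, n_genes_used = k,
                 stringsAsFactors = FALSE)
    })
  })
  out <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(pathway = character(), score = numeric(),
               p = numeric(), n_genes_used = integer())
  rownames(out) <- NULL
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("pathway", "score", "p", "padj", "n_genes_used")]
  attr(out, "skipped") <- skipped
  out
}

#' Concordance between two quantification/DGE pipelines
#'
#' Per-sample Pearson correlation of `log2(count + 1)` on the shared gene
#' universe, the Pearson correlation of log2 fold changes between the two
#' DGE tables, per-gene significance categories at `alpha`, and the
#' consensus DEG set: genes significant (adjusted p < alpha) in both
#' pipelines.
#'
#' @param counts_a,counts_b count matrices with identical sample ids.
#' @param dge_a,dge_b data.frames with columns `gene`, `log2fc`, `padj`.
#' @param alpha FDR significance threshold (default 0.05).
#' @return object of class `concordance_result`: list with `per_sample_r`,
#'   `median_r`, `log2fc_r`, `categories` (named character over the shared
#'   DGE universe), and `consensus_degs`.
#' @export
concordance <- function(counts_a, counts_b, dge_a, dge_b, alpha = 0.05) {
  if (!setequal(colnames(counts_a), colnames(counts_b))) {
    stop("sample ids differ between count matrices")
  }
  shared <- intersect(rownames(counts_a), rownames(counts_b))
  if (length(shared) == 0) stop("no shared genes between count matrices")
  a <- log2(counts_a[shared, , drop = FALSE] + 1)
  b <- log2(counts_b[shared, colnames(counts_a), drop = FALSE] + 1)
  per_sample_r <- vapply(seq_len(ncol(a)),
                         function(j) stats::cor(a[, j], b[, j]),
                         numeric(1))
  names(per_sample_r) <- colnames(a)

  genes <- intersect(dge_a$gene, dge_b$gene)
  if (length(genes) == 0) stop("no shared genes between DGE tables")
  ia <- match(genes, dge_a$gene)
  ib <- match(genes, dge_b$gene)
  fa <- dge_a$log2fc[ia]
  fb <- dge_b$log2fc[ib]
  fin <- is.finite(fa) & is.finite(fb)
  log2fc_r <- if (sum(fin) >= 3 && stats::sd(fa[fin]) > 0 &&
                  stats::sd(fb[fin]) > 0) {
    stats::cor(fa[fin], fb[fin])
  } else NA_real_

  sig_a <- !is.na(dge_a$padj[ia]) & dge_a$padj[ia] < alpha
  sig_b <- !is.na(dge_b$padj[ib]) & dge_b$padj[ib] < alpha
  categories <- ifelse(sig_a & sig_b, "both",
                       ifelse(sig_a, "only_A",
                              ifelse(sig_b, "only_B", "neither")))
  names(categories) <- genes
  structure(list(per_sample_r = per_sample_r,
                 median_r = stats::median(per_sample_r),
                 log2fc_r = log2fc_r,
                 categories = categories,
                 consensus_degs = genes[sig_a & sig_b]),
            class = "concordance_result")
}

#' Genes detected per sample
#'
#' A gene counts as detected in a sample when it has strictly more than
#' `min_alignments` assigned reads/alignments.
#'
#' @param counts count matrix.
#' @param min_alignments strict lower bound (default 10).
#' @return named integer vector, one count per sample.
#' @export
genes_detected <- function(counts, min_alignments = 10) {
  colSums(counts > min_alignments)
}

#' Simple two-group differential expression on log2 CPM
#'
#' A self-contained moderated-free test on `log2(CPM + 1)`: the log2 fold
#' change is the mean difference (test minus reference); the p-value is a
#' two-sided paired t-test on subject-blocked differences when every
#' subject contributes exactly one sample to each group, otherwise an
#' unpaired Welch t-test; adjustment is Benjamini-Hochberg.
#'
#' @param counts raw count matrix.
#' @param group_test,group_ref sample-id vectors (>= 2 each).
#' @param subject_blocks optional named character vector, sample_id ->
#'   subject_id, enabling the paired test.
#' @param source label recorded in the `source` column.
#' @return data.frame: `gene`, `log2fc`, `p`, `padj`, `source`.
#' @export
simple_de <- function(counts, group_test, group_ref, subject_blocks = NULL,
                      source = "simple_de") {
  validate_counts(counts)
  if (length(group_test) < 2 || length(group_ref) < 2) {
    stop("each group needs at least 2 samples")
  }
  stopifnot(all(c(group_test, group_ref) %in% colnames(counts)))
  cpm <- log2(normalize_library_size(counts) + 1)
  xt <- cpm[, group_test, drop = FALSE]
  xr <- cpm[, group_ref, drop = FALSE]
  lfc <- rowMeans(xt) - rowMeans(xr)

  paired <- FALSE
  if (!is.null(subject_blocks)) {
    st <- subject_blocks[group_test]
    sr <- subject_blocks[group_ref]
    if (!anyNA(st) && !anyNA(sr) && setequal(st, sr) &&
        !anyDuplicated(st) && !anyDuplicated(sr)) {
      paired <- TRUE
      xr <- xr[, match(st, sr), drop = FALSE]
    }
  }
  if (paired) {
    d <- xt - xr
    n <- ncol(d)
    m <- rowMeans(d)
    s <- sqrt(rowSums((d - m)^2) / (n - 1))
    tt <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(tt), df = n - 1)
    p[s == 0] <- ifelse(m[s == 0] == 0, 1, 0)
  } else {
    n1 <- ncol(xt); n2 <- ncol(xr)
    m1 <- rowMeans(xt); m2 <- rowMeans(xr)
    v1 <- rowSums((xt - m1)^2) / (n1 - 1)
    v2 <- rowSums((xr - m2)^2) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tt), df = df)
    degen <- se2 == 0
    p[degen] <- ifelse((m1 - m2)[degen] == 0, 1, 0)
  }
  data.frame(gene = rownames(counts), log2fc = unname(lfc), p = unname(p),
             padj = stats::p.adjust(p, method = "BH"), source = source,
             stringsAsFactors = FALSE, row.names = NULL)
}
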
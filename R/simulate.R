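#' Ground-truth container for simulated studies
#'
#' Collects the planted effects a simulated study carries, so downstream
#' stages can be scored against known truth: pathways shifted at the return
#' day (R+1), pathways following a pre-flight trend, differentially
#' methylated sites (with a reversal flag for sites that relax back toward
#' baseline in recovery), per-timepoint unique transcripts, and
#' differentially expressed genes.
#'
#' @param disrupted_pathways named numeric; pathway -> R+1 shift in log2
#'   expression units.
#' @param trending_pathways named numeric; pathway -> pre-flight slope in
#'   log2 units/day. Must be disjoint from `disrupted_pathways`.
#' @param hyper_sites data.frame with `site_id`, `delta` (percentage
#'   points, > 0), `reversal` (logical); may be empty.
#' @param hypo_sites like `hyper_sites` with `delta` < 0.
#' @param unique_transcripts named list, timepoint label -> transcript ids.
#' @param de_genes named numeric; gene -> log2 fold change.
#' @return object of class `sim_truth`.
#' @export
sim_truth <- function(disrupted_pathways = numeric(),
                      trending_pathways = numeric(),
                      hyper_sites = empty_site_effects(),
                      hypo_sites = empty_site_effects(),
                      unique_transcripts = list(),
                      de_genes = numeric()) {
  overlap <- intersect(names(disrupted_pathways), names(trending_pathways))
  if (length(overlap) > 0) {
    stop("pathway cannot be both disrupted and trending: ",
         paste(overlap, collapse = ", "))
  }
  for (df in list(hyper_sites, hypo_sites)) {
    stopifnot(is.data.frame(df),
              all(c("site_id", "delta", "reversal") %in% names(df)))
    if (any(abs(df$delta) > 100)) stop("site effect |delta| exceeds 100pp")
  }
  if (nrow(hyper_sites) > 0 && any(hyper_sites$delta <= 0)) {
    stop("hyper_sites must have delta > 0")
  }
  if (nrow(hypo_sites) > 0 && any(hypo_sites$delta >= 0)) {
    stop("hypo_sites must have delta < 0")
  }
  structure(list(disrupted_pathways = disrupted_pathways,
                 trending_pathways = trending_pathways,
                 hyper_sites = hyper_sites,
                 hypo_sites = hypo_sites,
                 unique_transcripts = unique_transcripts,
                 de_genes = de_genes),
            class = "sim_truth")
}

#' @rdname sim_truth
#' @export
empty_site_effects <- function() {
  data.frame(site_id = character(), delta = numeric(), reversal = logical(),
             stringsAsFactors = FALSE)
}

#' @rdname sim_truth
#' @param site_ids character vector of site ids.
#' @param delta effect size in percentage points (recycled).
#' @param reversal logical; does the site relax back toward baseline in
#'   recovery (recycled).
#' @export
site_effects <- function(site_ids, delta, reversal = FALSE) {
  data.frame(site_id = site_ids, delta = delta, reversal = reversal,
             stringsAsFactors = FALSE)
}

# Planted pathway effect, in log2 units, for one (pathway, day) pair.
# Disrupted pathways spike only at the return day. Trending pathways rise
# along slope*t through pre-flight, continue the trend at R+1, then decay
# linearly back to baseline by the final recovery day.
pathway_effect_at <- function(truth, pathway, time_days, last_day = 194) {
  eff <- 0
  s <- truth$disrupted_pathways[pathway]
  if (!is.na(s) && time_days == 1) eff <- eff + unname(s)
  b <- truth$trending_pathways[pathway]
  if (!is.na(b)) {
    if (time_days < 0) {
      eff <- eff + unname(b) * time_days
    } else {
      peak <- unname(b) * 1
      eff <- eff + peak * max(0, (last_day - time_days) / (last_day - 1))
    }
  }
  eff
}

#' Simulate a gene-by-sample count matrix with planted pathway effects
#'
#' Counts are negative-binomial per gene and sample. The log2-scale mean is
#' a per-gene baseline (normal across genes), plus a per-subject random
#' effect, plus the summed planted pathway effects of the gene's pathways at
#' the sample's timepoint. Disrupted pathways add their shift only at the
#' return day (+1); trending pathways add slope x day during pre-flight,
#' continue the trend at return, and decay linearly to baseline by the last
#' recovery day.
#'
#' @param n_genes total gene count; must cover the gene-set database's
#'   union.
#' @param geneset_db named list of gene-id character vectors.
#' @param design a [mission_design()] data.frame.
#' @param effects a [sim_truth()]; every effect pathway must exist in
#'   `geneset_db`.
#' @param dispersion NB size parameter (> 0); large values approach
#'   Poisson.
#' @param base_log2_mean,base_log2_sd normal parameters of the per-gene
#'   baseline log2 mean count.
#' @param subject_sd SD of the per-subject random effect (log2 units).
#' @param gene_ids optional explicit gene universe (length `n_genes`,
#'   covering the database's genes); by default the database's union padded
#'   with `BG...` background ids.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `counts` (matrix) and `truth` (the effects, echoed).
#' @export
simulate_counts <- function(n_genes, geneset_db, design,
                            effects = sim_truth(), dispersion = 10,
                            base_log2_mean = 6, base_log2_sd = 1.5,
                            subject_sd = 0.2, gene_ids = NULL, seed = 1) {
  stopifnot(dispersion > 0, inherits(effects, "sim_truth"))
  eff_paths <- c(names(effects$disrupted_pathways),
                 names(effects$trending_pathways))
  unknown <- setdiff(eff_paths, names(geneset_db))
  if (length(unknown) > 0) {
    stop("effect references unknown gene set(s): ",
         paste(unknown, collapse = ", "))
  }
  db_genes <- unique(unlist(geneset_db, use.names = FALSE))
  if (length(db_genes) > n_genes) {
    stop("n_genes smaller than the gene-set database's gene universe")
  }
  if (is.null(gene_ids)) {
    extra <- n_genes - length(db_genes)
    gene_ids <- c(db_genes,
                  if (extra > 0) sprintf("BG%05d", seq_len(extra)))
  } else {
    stopifnot(length(gene_ids) == n_genes, !anyDuplicated(gene_ids),
              all(db_genes %in% gene_ids))
  }
  subjects <- unique(design$subject_id)
  last_day <- max(design$time_days)

  withr::with_seed(seed, {
    baseline <- stats::rnorm(n_genes, base_log2_mean, base_log2_sd)
    names(baseline) <- gene_ids
    subj_eff <- stats::setNames(stats::rnorm(length(subjects), 0, subject_sd),
                                subjects)
    # per-gene, per-day planted effect (log2 units), summed over pathways
    days <- sort(unique(design$time_days))
    eff_mat <- matrix(0, n_genes, length(days),
                      dimnames = list(gene_ids, as.character(days)))
    for (p in eff_paths) {
      members <- intersect(geneset_db[[p]], gene_ids)
      for (d in days) {
        e <- pathway_effect_at(effects, p, d, last_day)
        if (e != 0) eff_mat[members, as.character(d)] <-
            eff_mat[members, as.character(d)] + e
      }
    }
    de_eff <- rep(0, n_genes)
    names(de_eff) <- gene_ids
    known_de <- intersect(names(effects$de_genes), gene_ids)
    counts <- matrix(0, n_genes, nrow(design),
                     dimnames = list(gene_ids, design$sample_id))
    for (j in seq_len(nrow(design))) {
      d <- design$time_days[j]
      log2mu <- baseline + subj_eff[design$subject_id[j]] +
        eff_mat[, as.character(d)]
      if (d == 1 && length(known_de) > 0) {
        log2mu[known_de] <- log2mu[known_de] + effects$de_genes[known_de]
      }
      counts[, j] <- stats::rnbinom(n_genes, mu = 2^log2mu,
                                    size = dispersion)
    }
    list(counts = validate_counts(counts), truth = effects)
  })
}

#' Caricature two quantifiers' treatment of homologous genes
#'
#' Emulates the downstream signature of multi-mapping read attribution:
#' outside homolog groups the two emitted matrices equal the input up to
#' small multiplicative noise; inside each group quantifier A concentrates
#' the group's per-sample total on one member (winner-take-most) while
#' quantifier B splits it fractionally in proportion to the true counts.
#' Group totals are preserved exactly in both outputs.
#'
#' @param counts input count matrix.
#' @param homolog_groups list of disjoint character vectors (size >= 2) of
#'   gene ids present in `counts`.
#' @param noise_sd SD of the log-normal multiplicative noise applied
#'   outside homolog groups (0 disables noise).
#' @param concentration fraction of a group total the winner receives in
#'   quantifier A.
#' @param seed integer seed.
#' @return list with matrices `a` and `b`.
#' @export
simulate_dual_quantifier <- function(counts, homolog_groups = list(),
                                     noise_sd = 0.05, concentration = 0.9,
                                     seed = 1) {
  validate_counts(counts)
  all_members <- unlist(homolog_groups, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop("homolog groups overlap: ",
         all_members[duplicated(all_members)][1])
  }
  if (length(all_members) > 0 &&
      !all(all_members %in% rownames(counts))) {
    stop("homolog group member absent from count matrix")
  }
  if (any(lengths(homolog_groups) < 2)) stop("homolog groups need size >= 2")
  withr::with_seed(seed, {
    noise <- function() {
      if (noise_sd == 0) return(matrix(1, nrow(counts), ncol(counts)))
      matrix(exp(stats::rnorm(length(counts), 0, noise_sd)),
             nrow(counts))
    }
    a <- counts * noise()
    b <- counts * noise()
    for (grp in homolog_groups) {
      tot <- colSums(counts[grp, , drop = FALSE])
      # A: winner (largest overall count) takes `concentration` of the total
      winner <- grp[which.max(rowSums(counts[grp, , drop = FALSE]))]
      rest <- setdiff(grp, winner)
      a[winner, ] <- tot * concentration
      for (g in rest) a[g, ] <- tot * (1 - concentration) / length(rest)
      # B: proportional split (uniform where the group total is zero)
      prop <- sweep(counts[grp, , drop = FALSE], 2, pmax(tot, 1e-300), "/")
      prop[, tot == 0] <- 1 / length(grp)
      b[grp, ] <- sweep(prop, 2, tot, "*")
    }
    list(a = validate_counts(a), b = validate_counts(b))
  })
}

DRACH_D <- c("A", "G", "T")
DRACH_H <- c("A", "C", "T")

random_kmers <- function(n, drach) {
  if (drach) {
    paste0(sample(DRACH_D, n, replace = TRUE),
           sample(c("A", "G"), n, replace = TRUE),
           "AC",
           sample(DRACH_H, n, replace = TRUE))
  } else {
    # mutate the invariant central A away so the 5-mer can never be DRACH
    paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
           sample(c("A", "C", "G", "T"), n, replace = TRUE),
           sample(c("C", "G", "T"), n, replace = TRUE),
           sample(c("A", "C", "G", "T"), n, replace = TRUE),
           sample(c("A", "C", "G", "T"), n, replace = TRUE))
  }
}

#' Simulate a per-site methylation table with planted effects
#'
#' Per site and sample, coverage is negative-binomial and modified-read
#' counts are binomial with methylation rate pi. Baseline pi is
#' Beta-distributed across sites. Planted effect sites shift pi by
#' delta/100 at the return day; non-reversal effect sites keep the shift
#' through recovery, reversal sites return to baseline at the recovery
#' days. True effect sites carry DRACH 5-mers; a configurable fraction of
#' null sites carries non-DRACH decoy 5-mers. pi is clipped to [0, 1] with
#' a warning naming the site.
#'
#' @param n_sites number of sites.
#' @param design a [mission_design()] data.frame.
#' @param coverage_mean mean NB coverage per site/sample (>= 1).
#' @param effects a [sim_truth()] whose `hyper_sites`/`hypo_sites` site ids
#'   are among `site00001..`.
#' @param coverage_dispersion NB size for coverage.
#' @param baseline_shape length-2 Beta parameters of the baseline rate.
#' @param decoy_fraction fraction of null sites given non-DRACH 5-mers.
#' @param gene_pool optional gene ids sites are placed on (sampled with
#'   replacement); default invents `MG...` ids.
#' @param seed integer seed.
#' @return list with `table` (a [meth_site_table()]) and `truth`.
#' @export
simulate_methylation <- function(n_sites, design, coverage_mean = 50,
                                 effects = sim_truth(),
                                 coverage_dispersion = 10,
                                 baseline_shape = c(2, 8),
                                 decoy_fraction = 0.3, gene_pool = NULL,
                                 seed = 1) {
  stopifnot(coverage_mean >= 1, inherits(effects, "sim_truth"))
  site_ids <- sprintf("site%05d", seq_len(n_sites))
  eff <- rbind(effects$hyper_sites, effects$hypo_sites)
  unknown <- setdiff(eff$site_id, site_ids)
  if (length(unknown) > 0) {
    stop("effect references unknown site(s): ",
         paste(unknown, collapse = ", "))
  }
  withr::with_seed(seed, {
    if (is.null(gene_pool)) {
      gene_pool <- sprintf("MG%04d", seq_len(max(1, ceiling(n_sites / 3))))
    }
    genes <- sample(gene_pool, n_sites, replace = TRUE)
    transcripts <- paste0(genes, ".t1")
    positions <- sample.int(3000, n_sites, replace = TRUE) - 1L
    region <- sample(c("exon", "UTR"), n_sites, replace = TRUE,
                     prob = c(0.7, 0.3))
    is_true <- site_ids %in% eff$site_id
    kmer <- character(n_sites)
    kmer[is_true] <- random_kmers(sum(is_true), drach = TRUE)
    null_idx <- which(!is_true)
    decoy <- null_idx[stats::runif(length(null_idx)) < decoy_fraction]
    keep_drach <- setdiff(null_idx, decoy)
    kmer[decoy] <- random_kmers(length(decoy), drach = FALSE)
    kmer[keep_drach] <- random_kmers(length(keep_drach), drach = TRUE)

    base_pi <- stats::rbeta(n_sites, baseline_shape[1], baseline_shape[2])
    names(base_pi) <- site_ids
    delta <- stats::setNames(rep(0, n_sites), site_ids)
    reversal <- stats::setNames(rep(FALSE, n_sites), site_ids)
    if (nrow(eff) > 0) {
      delta[eff$site_id] <- eff$delta / 100
      reversal[eff$site_id] <- eff$reversal
    }
    n_samp <- nrow(design)
    coverage <- matrix(stats::rnbinom(n_sites * n_samp, mu = coverage_mean,
                                      size = coverage_dispersion),
                       n_sites, n_samp,
                       dimnames = list(site_ids, design$sample_id))
    mod <- matrix(0L, n_sites, n_samp,
                  dimnames = list(site_ids, design$sample_id))
    warned <- character(0)
    for (j in seq_len(n_samp)) {
      d <- design$time_days[j]
      shift <- rep(0, n_sites)
      if (d == 1) {
        shift <- delta
      } else if (d > 1) {
        shift <- ifelse(reversal, 0, delta)
      }
      pi <- base_pi + shift
      out <- pi < 0 | pi > 1
      if (any(out)) warned <- union(warned, site_ids[out])
      pi <- pmin(1, pmax(0, pi))
      mod[, j] <- stats::rbinom(n_sites, coverage[, j], pi)
    }
    if (length(warned) > 0) {
      warning("methylation rate clipped to [0,1] for site(s): ",
              paste(utils::head(warned, 5), collapse = ", "),
              if (length(warned) > 5) ", ...", call. = FALSE)
    }
    sites <- data.frame(site_id = site_ids, transcript_id = transcripts,
                        gene_id = genes, position = positions, kmer = kmer,
                        region = region, stringsAsFactors = FALSE)
    list(table = meth_site_table(sites, coverage, mod), truth = effects)
  })
}

#' Simulate a cross-crew transcript catalog with planted unique transcripts
#'
#' Shared transcripts are present in every sample subject to Bernoulli
#' dropout; planted unique transcripts are present in all subjects at their
#' focal timepoint and absent everywhere else. Class codes are drawn from
#' `class_code_mix`.
#'
#' @param design a [mission_design()] data.frame.
#' @param n_shared number of shared background transcripts.
#' @param unique_spec named list/vector, timepoint label -> count of planted
#'   unique transcripts.
#' @param class_code_mix named numeric of class-code probabilities.
#' @param dropout_rate per-cell dropout probability for shared transcripts.
#' @param seed integer seed.
#' @return list with `catalog` (a [transcript_catalog()]) and `truth`.
#' @export
simulate_catalog <- function(design, n_shared = 50, unique_spec = list(),
                             class_code_mix = c("=" = 0.3, "c" = 0.2,
                                                "j" = 0.2, "u" = 0.3),
                             dropout_rate = 0.1, seed = 1) {
  stopifnot(all(names(class_code_mix) %in% CLASS_CODES),
            dropout_rate >= 0, dropout_rate <= 1)
  bad_tp <- setdiff(names(unique_spec), unique(design$timepoint_label))
  if (length(bad_tp) > 0) {
    stop("unique_spec references timepoint(s) not in the design: ",
         paste(bad_tp, collapse = ", "))
  }
  withr::with_seed(seed, {
    n_unique <- sum(unlist(unique_spec))
    n_total <- n_shared + n_unique
    ids <- sprintf("TCONS%05d", seq_len(n_total))
    codes <- sample(names(class_code_mix), n_total, replace = TRUE,
                    prob = class_code_mix)
    presence <- matrix(FALSE, n_total, nrow(design),
                       dimnames = list(ids, design$sample_id))
    if (n_shared > 0) {
      presence[seq_len(n_shared), ] <-
        stats::runif(n_shared * nrow(design)) >= dropout_rate
    }
    truth_unique <- list()
    k <- n_shared
    for (tp in names(unique_spec)) {
      n_tp <- unique_spec[[tp]]
      if (n_tp == 0) next
      rows <- ids[k + seq_len(n_tp)]
      presence[rows, design$timepoint_label == tp] <- TRUE
      truth_unique[[tp]] <- rows
      k <- k + n_tp
    }
    transcripts <- data.frame(
      transcript_id = ids,
      locus_id = sprintf("XLOC%05d", seq_len(n_total)),
      ref_match = ifelse(codes == "u", NA_character_,
                         sprintf("REF%05d", seq_len(n_total))),
      class_code = codes,
      stringsAsFactors = FALSE
    )
    catalog <- transcript_catalog(transcripts, presence, design)
    truth <- sim_truth(unique_transcripts = truth_unique)
    list(catalog = catalog, truth = truth)
  })
}
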
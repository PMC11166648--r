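# Independent oracles and small fixture builders. Each oracle is coded from
# the definition, on a different route than the implementation it checks.

# least squares through the normal equations via a linear solve
ols_oracle <- function(times, z) {
  X <- cbind(1, times)
  beta <- solve(t(X) %*% X, t(X) %*% z)
  c(intercept = beta[1], slope = beta[2])
}

dz_oracle <- function(times_pre, z_pre, z_obs, t_eval = 1) {
  b <- ols_oracle(times_pre, z_pre)
  unname(z_obs - (b["intercept"] + b["slope"] * t_eval))
}

# DRACH via a single regular expression on the T-collapsed string
drach_oracle <- function(kmer) {
  grepl("^[AGT][AG]AC[ACT]$", chartr("U", "T", toupper(kmer)))
}

# Benjamini-Hochberg step-up, brute force from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    js <- i:n
    adj[o[i]] <- min(1, min(p[o[js]] * n / js))
  }
  adj
}

# per-timepoint unique transcripts by direct enumeration over all
# (transcript, timepoint) pairs
unique_oracle <- function(catalog, window, excluded = character()) {
  samp <- catalog$samples[!(catalog$samples$sample_id %in% excluded), ]
  res <- list()
  for (tp in window) {
    s_tp <- samp[samp$timepoint_label == tp, ]
    uniq <- character(0)
    for (tr in catalog$transcripts$transcript_id) {
      consensus <- TRUE
      for (subj in unique(s_tp$subject_id)) {
        cols <- s_tp$sample_id[s_tp$subject_id == subj]
        if (!any(catalog$presence[tr, cols])) consensus <- FALSE
      }
      if (!consensus) next
      absent_elsewhere <- TRUE
      for (other in setdiff(window, tp)) {
        cols <- samp$sample_id[samp$timepoint_label == other]
        if (length(cols) > 0 && any(catalog$presence[tr, cols])) {
          absent_elsewhere <- FALSE
        }
      }
      if (absent_elsewhere) uniq <- c(uniq, tr)
    }
    res[[tp]] <- sort(uniq)
  }
  res
}

# random small catalog for property tests
random_catalog <- function(n_transcripts, design, p_present = 0.5) {
  ids <- sprintf("T%03d", seq_len(n_transcripts))
  transcripts <- data.frame(
    transcript_id = ids,
    locus_id = sprintf("L%03d", seq_len(n_transcripts)),
    ref_match = NA_character_,
    class_code = sample(CLASS_CODES, n_transcripts, replace = TRUE),
    stringsAsFactors = FALSE
  )
  presence <- matrix(runif(n_transcripts * nrow(design)) < p_present,
                     n_transcripts, nrow(design),
                     dimnames = list(ids, design$sample_id))
  transcript_catalog(transcripts, presence, design)
}

# small deterministic count fixture
tiny_counts <- function() {
  m <- matrix(c(10, 30, 60,
                5, 15, 30,
                1,  1,  2), nrow = 3, byrow = TRUE,
              dimnames = list(c("G1", "G2", "G3"), c("S1", "S2", "S3")))
  m
}

# methylation fixture: n sites x samples with given coverage and rates
tiny_meth <- function(coverage, mod) {
  n <- nrow(coverage)
  sites <- data.frame(site_id = sprintf("s%02d", seq_len(n)),
                      transcript_id = sprintf("t%02d", seq_len(n)),
                      gene_id = sprintf("g%02d", seq_len(n)),
                      position = seq_len(n), kmer = rep("GGACT", n),
                      region = rep("exon", n), stringsAsFactors = FALSE)
  meth_site_table(sites, coverage, mod)
}
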
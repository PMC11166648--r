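#' Fit the pre-flight linear trend of a pathway z-trajectory
#'
#' Ordinary least squares on the pre-flight median z-scores as a time
#' series, by the closed-form normal equations. The intercept is the fitted
#' value at day 0.
#'
#' @param times signed days, all negative, at least 2 distinct values.
#' @param z median z-scores at those days.
#' @return named numeric `c(slope =, intercept =)` (z-units/day, z-units).
#' @export
fit_preflight_trend <- function(times, z) {
  stopifnot(length(times) == length(z))
  if (any(times >= 0)) stop("non-pre-flight time in trend fit: ",
                            times[times >= 0][1])
  if (length(unique(times)) < 2) {
    stop("need at least 2 distinct pre-flight times")
  }
  tm <- mean(times)
  zm <- mean(z)
  slope <- sum((times - tm) * (z - zm)) / sum((times - tm)^2)
  c(slope = slope, intercept = zm - slope * tm)
}

#' dz: deviation of the observed return-day z from the pre-flight trend
#'
#' Fits the pre-flight trend of a pathway trajectory, predicts the z-score
#' at the evaluation day (the return day, +1, by default), and scores the
#' deviation `dz = observed - predicted`. Large positive dz marks a pathway
#' disrupted by flight; dz near zero marks a pathway continuing its
#' pre-flight trend.
#'
#' @param trajectory a [pathway_trajectory()] data.frame; must contain all
#'   pre-flight timepoints of its design and the evaluation day.
#' @param return_day day at which the deviation is evaluated (default +1);
#'   any observed recovery day may be scored against the pre-flight fit.
#' @return one-row data.frame: `pathway`, `slope`, `intercept`,
#'   `z_pred_return`, `z_obs_return`, `dz`.
#' @export
dz_score <- function(trajectory, return_day = 1) {
  stopifnot(is.data.frame(trajectory),
            all(c("time_days", "median_z") %in% names(trajectory)))
  pre <- trajectory[trajectory$time_days < 0, ]
  if (nrow(pre) < 2) stop("missing pre-flight timepoints in trajectory")
  obs_row <- trajectory[trajectory$time_days == return_day, ]
  if (nrow(obs_row) != 1) {
    stop("missing evaluation timepoint (day ", return_day, ") in trajectory")
  }
  fit <- fit_preflight_trend(pre$time_days, pre$median_z)
  z_pred <- unname(fit["intercept"] + fit["slope"] * return_day)
  z_obs <- obs_row$median_z
  data.frame(pathway = attr(trajectory, "pathway") %||% "pathway",
             slope = unname(fit["slope"]),
             intercept = unname(fit["intercept"]),
             z_pred_return = z_pred, z_obs_return = z_obs,
             dz = z_obs - z_pred, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank pathways by dz
#'
#' Descending by signed dz — rank 1 is the pathway most disrupted by
#' flight; the lowest ranks continue their pre-flight trend. Ties are
#' broken lexicographically by pathway name. `absolute = TRUE` ranks by
#' magnitude instead.
#'
#' @param records data.frame of [dz_score()] rows.
#' @param absolute rank by `|dz|` (default FALSE: signed).
#' @return the records, ordered, with a `rank` column `1..n`.
#' @export
rank_by_dz <- function(records, absolute = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  key <- if (absolute) abs(records$dz) else records$dz
  ord <- order(-key, records$pathway)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' dz table for many pathways
#'
#' Convenience wrapper: computes trajectories and dz for every pathway in a
#' result set, then ranks.
#'
#' @param zmat a [zscore_expression()] result.
#' @param geneset_db named list of gene sets.
#' @param sample_sheet sample sheet data.frame.
#' @param pathways pathway names to score (default: all in the database).
#' @param return_day evaluation day (default +1).
#' @param pooling trajectory pooling mode, see [pathway_trajectory()].
#' @return ranked data.frame of dz records.
#' @export
dz_table <- function(zmat, geneset_db, sample_sheet,
                     pathways = names(geneset_db), return_day = 1,
                     pooling = "pooled") {
  rows <- lapply(pathways, function(p) {
    traj <- pathway_trajectory(zmat, geneset_db[[p]], sample_sheet,
                               pathway = p, pooling = pooling)
    dz_score(traj, return_day = return_day)
  })
  rank_by_dz(do.call(rbind, rows))
}
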
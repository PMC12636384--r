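## ---------------------------------------------------------------------------
## biomarkers: per-EGP differential statistics, volcano classes, screening
## ---------------------------------------------------------------------------

#' Per-feature differential statistics (cancer vs healthy)
#'
#' Two-sided Student's t-test with pooled (equal) variance per feature, and
#' the mean-fold ratio MFR = mean(cancer) / mean(healthy) on the normalized
#' levels with zeros (below-detection imputation) included. Features with a
#' zero healthy mean have no defined MFR and are excluded, with their ids
#' recorded in `attr(, "excluded_features")`.
#'
#' @param egp_matrix a [feature_matrix] of normalized levels.
#' @param groups character vector over the matrix columns; values in
#'   `cancer_group` and `healthy_group` define the two arms, other columns
#'   are ignored.
#' @param cancer_group,healthy_group group labels of the two arms.
#' @param cv_intra_pct,cv_inter_pct optional per-feature replicate CVs
#'   carried through for screening.
#' @return data.frame of class `marker_stats`: feature_id, t, p_value, mfr,
#'   log2_mfr, mean_cancer, mean_healthy, cv_intra_pct, cv_inter_pct.
#' @export
egp_stats <- function(egp_matrix, groups, cancer_group = "cancer",
                      healthy_group = "healthy",
                      cv_intra_pct = NULL, cv_inter_pct = NULL) {
  stopifnot(length(groups) == ncol(egp_matrix$values))
  a <- egp_matrix$values[, groups %in% cancer_group, drop = FALSE]
  b <- egp_matrix$values[, groups %in% healthy_group, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2L || n2 < 2L)
    stop_config("need >= 2 samples per group (got %d cancer, %d healthy)",
                n1, n2)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1L, var); v2 <- apply(b, 1L, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, (m1 - m2) / se, NA_real_)
  p <- 2 * pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE)

  ok <- m2 > 0
  nf <- nrow(egp_matrix$values)
  out <- data.frame(
    feature_id = egp_matrix$features$feature_id,
    t = tstat, p_value = p,
    mfr = ifelse(ok, m1 / m2, NA_real_),
    mean_cancer = m1, mean_healthy = m2,
    cv_intra_pct = if (is.null(cv_intra_pct)) rep(NA_real_, nf) else cv_intra_pct,
    cv_inter_pct = if (is.null(cv_inter_pct)) rep(NA_real_, nf) else cv_inter_pct,
    stringsAsFactors = FALSE)
  out$log2_mfr <- log2(out$mfr)
  excluded <- out$feature_id[!ok]
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_features") <- excluded
  class(out) <- c("marker_stats", "data.frame")
  out
}

#' Volcano classification of differential features
#'
#' `up` iff p < `p_thresh` and MFR > `mfr_bound`; `down` iff p < `p_thresh`
#' and MFR < 1/`mfr_bound`; otherwise `ns`. Defaults are the stringent
#' thresholds used for serum EGP profiling: p < 1e-10 and MFR outside
#' [2^-0.5, 2^0.5].
#'
#' @param stats a `marker_stats` data.frame from [egp_stats()].
#' @param p_thresh p-value threshold (strict <).
#' @param mfr_bound fold-ratio band edge (strict > / <).
#' @return factor of labels `up`/`down`/`ns`, one per stats row.
#' @export
volcano_classify <- function(stats, p_thresh = 1e-10, mfr_bound = 2^0.5) {
  sig <- !is.na(stats$p_value) & stats$p_value < p_thresh
  lab <- rep("ns", nrow(stats))
  lab[sig & stats$mfr > mfr_bound] <- "up"
  lab[sig & stats$mfr < 1 / mfr_bound] <- "down"
  factor(lab, levels = c("up", "down", "ns"))
}

#' Candidate biomarker screening
#'
#' A feature passes iff p < `p_max`, the mean fold-change exceeds `fc_min`
#' in either direction (MFR > fc_min or MFR < 1/fc_min), and both intra-
#' and inter-day replicate CVs are <= `cv_max` percent. Missing CVs fail
#' the criterion, with the reason recorded.
#'
#' @param stats a `marker_stats` data.frame carrying `cv_intra_pct` and
#'   `cv_inter_pct`.
#' @param p_max p-value threshold (strict <).
#' @param fc_min fold-change threshold (strict >, direction-agnostic).
#' @param cv_max replicate CV ceiling in percent (inclusive <=).
#' @return the stats rows augmented with `screen_pass` and `fail_reason`
#'   (empty string when passing); attribute `"candidates"` holds the
#'   passing feature ids.
#' @export
screen_biomarkers <- function(stats, p_max = 1e-10, fc_min = 1.5,
                              cv_max = 15) {
  p_ok <- !is.na(stats$p_value) & stats$p_value < p_max
  fc_ok <- !is.na(stats$mfr) & (stats$mfr > fc_min | stats$mfr < 1 / fc_min)
  cvi_ok <- !is.na(stats$cv_intra_pct) & stats$cv_intra_pct <= cv_max
  cvj_ok <- !is.na(stats$cv_inter_pct) & stats$cv_inter_pct <= cv_max
  pass <- p_ok & fc_ok & cvi_ok & cvj_ok
  reason <- character(nrow(stats))
  reason[!p_ok] <- paste0(reason[!p_ok], "p;")
  reason[!fc_ok] <- paste0(reason[!fc_ok], "fold_change;")
  reason[!cvi_ok] <- paste0(reason[!cvi_ok],
                            ifelse(is.na(stats$cv_intra_pct[!cvi_ok]),
                                   "cv_intra_missing;", "cv_intra;"))
  reason[!cvj_ok] <- paste0(reason[!cvj_ok],
                            ifelse(is.na(stats$cv_inter_pct[!cvj_ok]),
                                   "cv_inter_missing;", "cv_inter;"))
  out <- stats
  out$screen_pass <- pass
  out$fail_reason <- reason
  attr(out, "candidates") <- stats$feature_id[pass]
  out
}
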
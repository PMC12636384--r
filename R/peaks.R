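## ---------------------------------------------------------------------------
## peaks: alignment into a feature matrix + three-step EGP selection
## ---------------------------------------------------------------------------

#' Feature matrix container
#'
#' Aligned LC-MS features by samples. `values` holds raw areas after
#' [align_peaks()] and relative levels (ratio to the QC standard) after
#' [normalize_to_qc()]; absent entries are 0.
#'
#' @param features data.frame with columns `feature_id`, `rt`, `mz` (one
#'   row per feature, consensus coordinates).
#' @param values numeric matrix, features x samples; rownames are feature
#'   ids, colnames sample ids.
#' @param provenance optional data.frame mapping (feature_id, sample_id,
#'   peak_id) for each cell's source peak.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(features, values, provenance = NULL) {
  stopifnot(is.data.frame(features), is.matrix(values),
            nrow(features) == nrow(values))
  if (any(values < 0)) stop_config("feature values must be >= 0")
  rownames(values) <- features$feature_id
  structure(list(features = features, values = values,
                 provenance = provenance),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

## normalize the accepted peak-table inputs to one data.table
as_peak_table <- function(tables) {
  if (inherits(tables, "csgsa_peak_tables")) tables <- tables$peaks
  if (is.data.frame(tables)) tables <- list(tables)
  dt <- data.table::rbindlist(lapply(tables, function(t) {
    t <- data.table::as.data.table(t)
    need <- c("sample_id", "rt_min", "mz", "area")
    if (!all(need %in% names(t)))
      stop_config("peak tables need columns: %s", paste(need, collapse = ", "))
    if (!"peak_id" %in% names(t)) t[, peak_id := NA_character_]
    t[, c("sample_id", "rt_min", "mz", "area", "peak_id"), with = FALSE]
  }))
  if (nrow(dt) && any(dt$area <= 0)) stop_config("peak areas must be > 0")
  dt
}

#' Align per-sample peak lists into a feature matrix
#'
#' Greedy seeded clustering: peaks are processed in order of decreasing
#' area; each unclaimed peak opens a feature, which then claims the nearest
#' unclaimed in-tolerance peak from every sample (distance scaled by the
#' tolerances; ties broken by smaller |dm/z| then |dRT|). Consensus
#' coordinates are the area-weighted means of member peaks. Deterministic
#' and invariant to sample order.
#'
#' @param tables a `csgsa_peak_tables`, a long data.frame with columns
#'   sample_id, rt_min, mz, area, or a list of such data.frames.
#' @param tol_mz,tol_rt alignment tolerances (Da, min).
#' @return a [feature_matrix] of raw areas (0 where a sample has no peak).
#' @export
align_peaks <- function(tables, tol_mz = 0.06, tol_rt = 0.3) {
  if (tol_mz <= 0 || tol_rt <= 0)
    stop_config("alignment tolerances must be > 0")
  dt <- as_peak_table(tables)
  samples <- sort(unique(dt$sample_id))
  if (nrow(dt) == 0L)
    return(feature_matrix(
      data.frame(feature_id = character(0), rt = numeric(0),
                 mz = numeric(0), n_members = integer(0)),
      matrix(0, 0, length(samples), dimnames = list(NULL, samples))))

  ## canonical order (mz, rt, sample) makes the greedy pass independent of
  ## input row order; process seeds by descending area
  data.table::setorder(dt, mz, rt_min, sample_id)
  n <- nrow(dt)
  mz <- dt$mz; rt <- dt$rt_min; area <- dt$area; sid <- dt$sample_id
  seed_order <- order(-area, mz, rt)
  claimed <- logical(n)
  feat_of <- integer(n)
  nfeat <- 0L
  for (i in seed_order) {
    if (claimed[i]) next
    nfeat <- nfeat + 1L
    lo <- findInterval(mz[i] - tol_mz, mz) + 1L
    hi <- findInterval(mz[i] + tol_mz, mz)
    cand <- lo:hi
    cand <- cand[!claimed[cand] & abs(rt[cand] - rt[i]) <= tol_rt]
    if (length(cand) > 1L) {
      dmz <- abs(mz[cand] - mz[i]); drt <- abs(rt[cand] - rt[i])
      d <- (dmz / tol_mz)^2 + (drt / tol_rt)^2
      cand <- cand[order(d, dmz, drt)]
      cand <- cand[!duplicated(sid[cand])]   # best per sample
    }
    claimed[cand] <- TRUE
    feat_of[cand] <- nfeat
  }

  g <- data.table::data.table(f = feat_of, mz = mz, rt = rt, area = area,
                              sample_id = sid, peak_id = dt$peak_id,
                              row = seq_len(n))
  cons <- g[, list(rt = sum(rt * area) / sum(area),
                   mz = sum(mz * area) / sum(area),
                   n_members = .N), by = "f"]
  ## stable public ids ordered by consensus coordinates
  data.table::setorder(cons, mz, rt)
  cons[, feature_id := sprintf("F%05d", seq_len(.N))]
  id_of <- setNames(cons$feature_id, as.character(cons$f))

  values <- matrix(0, nrow(cons), length(samples),
                   dimnames = list(cons$feature_id, samples))
  values[cbind(match(id_of[as.character(g$f)], cons$feature_id),
               match(g$sample_id, samples))] <- g$area
  prov <- data.frame(feature_id = id_of[as.character(g$f)],
                     sample_id = g$sample_id, peak_id = g$peak_id,
                     stringsAsFactors = FALSE)
  feature_matrix(
    features = data.frame(feature_id = cons$feature_id, rt = cons$rt,
                          mz = cons$mz, n_members = cons$n_members,
                          stringsAsFactors = FALSE),
    values = values, provenance = prov)
}

#' Coefficient of variation of replicate areas
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation. Fewer than
#' two replicates or a non-positive mean yields `NA` — the undefined-CV
#' signal that makes a feature fail the reproducibility filter.
#'
#' @param replicate_areas numeric vector of replicate peak areas.
#' @return CV in percent, or `NA_real_` if undefined.
#' @export
compute_cv <- function(replicate_areas) {
  x <- replicate_areas[is.finite(replicate_areas)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m <= 0) return(NA_real_)
  100 * sd(x) / m
}

#' Per-feature CVs from QC replicate columns
#'
#' @param matrix a [feature_matrix] whose columns include QC injections.
#' @param replicate_ids column names of the replicate injections.
#' @return numeric vector of CV percent per feature (`NA` when undefined).
#' @export
feature_cvs <- function(matrix, replicate_ids) {
  miss <- setdiff(replicate_ids, colnames(matrix$values))
  if (length(miss))
    stop_config("replicate columns not in matrix: %s",
                paste(miss, collapse = ", "))
  apply(matrix$values[, replicate_ids, drop = FALSE], 1L, compute_cv)
}

#' Signal-to-noise per feature
#'
#' S/N is the median of a feature's observed (non-zero) areas divided by a
#' noise floor: the median area of noise peaks eluting within +-0.5 min of
#' the feature, falling back to the global noise median when no local noise
#' peak exists. When no noise model is given, the floor is estimated as the
#' median area of sparse features (observed in fewer than 5% of samples),
#' which in practice are noise.
#'
#' @param matrix a [feature_matrix].
#' @param noise_peaks optional data.frame of noise peaks with columns
#'   `rt_min` and `area`.
#' @param global_floor optional scalar noise floor overriding estimation.
#' @param rt_window half-width (min) of the local noise window.
#' @return numeric vector of S/N per feature (`NA` if no signal).
#' @export
estimate_snr <- function(matrix, noise_peaks = NULL, global_floor = NULL,
                         rt_window = 0.5) {
  v <- matrix$values
  sig <- apply(v, 1L, function(x) {
    x <- x[x > 0]
    if (!length(x)) NA_real_ else median(x)
  })
  if (is.null(noise_peaks)) {
    if (is.null(global_floor)) {
      frac <- rowMeans(v > 0)
      sparse <- frac < 0.05 & sig > 0
      if (!any(sparse))
        stop_config("no noise model available: supply noise_peaks or global_floor")
      global_floor <- median(sig[sparse])
      message(sprintf("estimate_snr: global noise floor %.3g from %d sparse features",
                      global_floor, sum(sparse)))
    }
    if (global_floor <= 0) stop_config("noise floor must be > 0")
    return(sig / global_floor)
  }
  stopifnot(all(c("rt_min", "area") %in% names(noise_peaks)))
  if (is.null(global_floor)) global_floor <- median(noise_peaks$area)
  if (global_floor <= 0) stop_config("noise floor must be > 0")
  o <- order(noise_peaks$rt_min)
  nrt <- noise_peaks$rt_min[o]; nar <- noise_peaks$area[o]
  floor_at <- vapply(matrix$features$rt, function(r) {
    lo <- findInterval(r - rt_window, nrt) + 1L
    hi <- findInterval(r + rt_window, nrt)
    if (hi < lo) global_floor else median(nar[lo:hi])
  }, numeric(1))
  sig / floor_at
}

#' Flag isotope, adduct and fragment features
#'
#' A feature is flagged relative to any co-eluting (dRT <= `tol_rt_coelute`)
#' more-intense feature: isotope if it sits `+1.00335/z` Da above it for
#' z in 1..3 (within `tol_mz/2`); adduct if it sits at the Na-H (+21.98194)
#' or K-H (+37.95588) offset; fragment if it lies at lower m/z and its
#' per-sample areas correlate with the parent at `r >= frag_cor`.
#' Intensity ranking uses the median of non-zero areas.
#'
#' @param matrix a [feature_matrix] of raw areas.
#' @param tol_mz m/z tolerance; offsets are matched within `tol_mz/2`.
#' @param tol_rt_coelute co-elution window in minutes.
#' @param frag_cor Pearson correlation threshold for the fragment rule.
#' @param sample_ids columns used for the fragment correlation (defaults to
#'   all columns).
#' @return data.frame per feature: `feature_id`, `is_isotope`, `is_adduct`,
#'   `is_fragment`.
#' @export
flag_artifacts <- function(matrix, tol_mz = 0.06, tol_rt_coelute = 0.1,
                           frag_cor = 0.95, sample_ids = NULL) {
  ft <- matrix$features
  nf <- nrow(ft)
  out <- data.frame(feature_id = ft$feature_id,
                    is_isotope = logical(nf), is_adduct = logical(nf),
                    is_fragment = logical(nf), stringsAsFactors = FALSE)
  if (nf < 2L) return(out)
  v <- matrix$values
  if (!is.null(sample_ids)) v <- v[, sample_ids, drop = FALSE]
  inten <- apply(matrix$values, 1L, function(x) {
    x <- x[x > 0]; if (!length(x)) 0 else median(x)
  })
  ## row-standardized values for fast pairwise correlation
  mu <- rowMeans(v)
  s <- sqrt(rowSums((v - mu)^2))
  z <- (v - mu) / ifelse(s > 0, s, 1)

  o <- order(ft$rt)
  rt_s <- ft$rt[o]
  iso_off <- 1.00335 / (1:3)
  add_off <- c(21.98194, 37.95588)
  half <- tol_mz / 2
  for (i in seq_len(nf)) {
    lo <- findInterval(ft$rt[i] - tol_rt_coelute, rt_s) + 1L
    hi <- findInterval(ft$rt[i] + tol_rt_coelute, rt_s)
    if (hi < lo) next
    js <- o[lo:hi]
    js <- js[js != i & inten[js] > inten[i]]
    if (!length(js)) next
    dmz <- ft$mz[i] - ft$mz[js]          # positive if parent below
    if (any(abs(outer(dmz, iso_off, "-")) <= half))
      out$is_isotope[i] <- TRUE
    if (any(abs(outer(dmz, add_off, "-")) <= half))
      out$is_adduct[i] <- TRUE
    frag_parents <- js[ft$mz[js] > ft$mz[i] + 1.5]
    if (length(frag_parents) && s[i] > 0) {
      r <- as.vector(z[frag_parents, , drop = FALSE] %*% z[i, ])
      if (any(r >= frag_cor & s[frag_parents] > 0))
        out$is_fragment[i] <- TRUE
    }
  }
  out
}

#' Assemble the per-feature quality flags
#'
#' Combines replicate CVs, S/N, and artifact bits into the flag table used
#' by [select_egps()]. `pass_egp` is true iff the feature survives all
#' three removal steps: (i) CV > `cv_max` (or undefined CV), (ii)
#' S/N < `snr_min` (or undefined), (iii) isotope/adduct/fragment.
#' Removal conditions are strict inequalities, so CV exactly at `cv_max`
#' or S/N exactly at `snr_min` is retained.
#'
#' @param matrix a [feature_matrix].
#' @param cv_pct,snr numeric vectors per feature (see [feature_cvs()],
#'   [estimate_snr()]).
#' @param artifacts data.frame from [flag_artifacts()].
#' @param cv_max,snr_min filter thresholds.
#' @return data.frame: feature_id, cv_pct, snr, is_isotope, is_adduct,
#'   is_fragment, pass_egp.
#' @export
feature_flags <- function(matrix, cv_pct, snr, artifacts,
                          cv_max = 50, snr_min = 5) {
  stopifnot(length(cv_pct) == nrow(matrix$values),
            length(snr) == nrow(matrix$values),
            nrow(artifacts) == nrow(matrix$values))
  fail_cv <- is.na(cv_pct) | cv_pct > cv_max
  fail_snr <- is.na(snr) | snr < snr_min
  art <- artifacts$is_isotope | artifacts$is_adduct | artifacts$is_fragment
  data.frame(feature_id = matrix$features$feature_id,
             cv_pct = cv_pct, snr = snr,
             is_isotope = artifacts$is_isotope,
             is_adduct = artifacts$is_adduct,
             is_fragment = artifacts$is_fragment,
             pass_egp = !fail_cv & !fail_snr & !art,
             stringsAsFactors = FALSE)
}

#' Apply the three-step EGP selection
#'
#' Retains exactly the features with `pass_egp`, preserving order, and
#' attaches a per-step removal report (attribute `"removal"`): step (i)
#' low reproducibility (CV), step (ii) low reliability (S/N), step (iii)
#' isotope/adduct/fragment ions, each counted on the features surviving the
#' previous steps.
#'
#' @param matrix a [feature_matrix].
#' @param flags data.frame from [feature_flags()] (needs `pass_egp` plus
#'   the per-step columns).
#' @param cv_max,snr_min thresholds used for the report (must match those
#'   used to build `flags`).
#' @return the filtered [feature_matrix]; `attr(, "removal")` is a
#'   data.frame with columns `step`, `removed`.
#' @export
select_egps <- function(matrix, flags, cv_max = 50, snr_min = 5) {
  stopifnot(nrow(flags) == nrow(matrix$values))
  fail_cv <- is.na(flags$cv_pct) | flags$cv_pct > cv_max
  fail_snr <- !fail_cv & (is.na(flags$snr) | flags$snr < snr_min)
  art <- flags$is_isotope | flags$is_adduct | flags$is_fragment
  fail_art <- !fail_cv & !fail_snr & art
  keep <- flags$pass_egp
  out <- feature_matrix(matrix$features[keep, , drop = FALSE],
                        matrix$values[keep, , drop = FALSE],
                        provenance = matrix$provenance)
  attr(out, "removal") <- data.frame(
    step = c("i_cv", "ii_snr", "iii_artifact"),
    removed = c(sum(fail_cv), sum(fail_snr), sum(fail_art)))
  out
}

#' Normalize areas to the QC standard
#'
#' Each sample's area is divided by the mean area of the same feature over
#' the QC replicate injections, giving relative levels. Features whose QC
#' mean is zero (absent from QC) are excluded with a warning; QC columns
#' are dropped from the result. Missing sample entries remain 0.
#'
#' @param matrix a [feature_matrix] of raw areas including QC columns.
#' @param qc_ids column names of the QC injections.
#' @return a [feature_matrix] of relative levels over the non-QC columns;
#'   `attr(, "excluded_features")` lists features dropped for zero QC mean.
#' @export
normalize_to_qc <- function(matrix, qc_ids) {
  miss <- setdiff(qc_ids, colnames(matrix$values))
  if (length(miss))
    stop_config("QC columns not in matrix: %s", paste(miss, collapse = ", "))
  qc_mean <- rowMeans(matrix$values[, qc_ids, drop = FALSE])
  keep <- qc_mean > 0
  if (any(!keep))
    warning(sprintf("%d feature(s) excluded: zero mean in QC standard",
                    sum(!keep)), call. = FALSE)
  sample_ids <- setdiff(colnames(matrix$values), qc_ids)
  vals <- matrix$values[keep, sample_ids, drop = FALSE] / qc_mean[keep]
  out <- feature_matrix(matrix$features[keep, , drop = FALSE], vals,
                        provenance = matrix$provenance)
  attr(out, "excluded_features") <-
    matrix$features$feature_id[!keep]
  out
}

#' Run the full peaks stage
#'
#' Convenience wrapper: align, compute QC-replicate CVs, estimate S/N,
#' flag artifacts, apply the three-step EGP selection, and normalize to the
#' QC standard.
#'
#' @param tables peak tables (see [align_peaks()]).
#' @param qc_ids QC injection sample ids (character vector, or the
#'   `qc_sample_ids` list of a `csgsa_peak_tables`).
#' @param tol_mz,tol_rt alignment tolerances.
#' @param cv_max,snr_min EGP filter thresholds.
#' @param noise_peaks,global_floor noise model for [estimate_snr()].
#' @return list: `egp` (normalized EGP [feature_matrix]), `aligned` (raw
#'   aligned matrix), `flags`, `removal` (per-step report).
#' @export
process_peaks <- function(tables, qc_ids, tol_mz = 0.06, tol_rt = 0.3,
                          cv_max = 50, snr_min = 5,
                          noise_peaks = NULL, global_floor = NULL) {
  if (is.list(qc_ids) && !is.character(qc_ids)) qc_ids <- unlist(qc_ids)
  aligned <- align_peaks(tables, tol_mz = tol_mz, tol_rt = tol_rt)
  sample_ids <- setdiff(colnames(aligned$values), qc_ids)
  cv <- feature_cvs(aligned, qc_ids)
  snr <- estimate_snr(aligned, noise_peaks = noise_peaks,
                      global_floor = global_floor)
  art <- flag_artifacts(aligned, tol_mz = tol_mz, sample_ids = sample_ids)
  flags <- feature_flags(aligned, cv, snr, art,
                         cv_max = cv_max, snr_min = snr_min)
  egp_raw <- select_egps(aligned, flags, cv_max = cv_max, snr_min = snr_min)
  egp <- normalize_to_qc(egp_raw, qc_ids)
  list(egp = egp, aligned = aligned, flags = flags,
       removal = attr(egp_raw, "removal"))
}
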
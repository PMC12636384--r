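## ---------------------------------------------------------------------------
## synthdata: synthetic serum-glycoproteomics cohorts with known ground truth
## ---------------------------------------------------------------------------

#' Tumor-marker panel used throughout the package
#'
#' The nine clinical serum analytes carried by every subject table, in
#' canonical column order.
#' @return character vector of marker names.
#' @export
marker_names <- function() {
  c("CEA", "CA19_9", "CYFRA", "NCC_ST_439", "CA125",
    "PSA", "CA15_3", "AFP", "SCCA")
}

#' Cohort groups
#' @return character vector: healthy plus the three cancer types.
#' @export
group_names <- function() c("healthy", "CRC", "GC", "EC")

## healthy-population log10 medians (native units: ng/mL or U/mL)
.marker_log10_mean <- c(
  CEA = log10(1.5), CA19_9 = log10(8), CYFRA = log10(1.2),
  NCC_ST_439 = log10(2), CA125 = log10(10), PSA = log10(0.8),
  CA15_3 = log10(10), AFP = log10(3), SCCA = log10(0.8)
)

#' Log-scale shift achieving a target single-marker AUC
#'
#' For two equal-variance Gaussians on the log scale, the ROC AUC of the raw
#' marker is `pnorm(delta / (sd * sqrt(2)))`. Inverting gives the mean shift
#' needed for a requested AUC; the simulator calibrates its marker effects
#' with this closed form.
#'
#' @param auc target AUC in `[0.5, 1)`.
#' @param sd common log10 standard deviation of the marker.
#' @return log10 mean shift (same units as `sd`).
#' @export
marker_shift_for_auc <- function(auc, sd) {
  stopifnot(auc >= 0 && auc < 1, sd > 0)
  qnorm(auc) * sd * sqrt(2)
}

default_marker_shifts <- function(sd) {
  m <- matrix(0, nrow = 9, ncol = 3,
              dimnames = list(marker_names(), c("CRC", "GC", "EC")))
  ## calibrated to the single-marker AUCs the panel is expected to show:
  ## CEA and CYFRA respond in CRC, CYFRA in GC, SCCA in EC, CA19-9 weakly
  ## in CRC; AFP/CA125/PSA/CA15-3/NCC-ST-439 carry no signal by default.
  m["CEA",    "CRC"] <- marker_shift_for_auc(0.805, sd)
  m["CYFRA",  "CRC"] <- marker_shift_for_auc(0.834, sd)
  m["CYFRA",  "GC"]  <- marker_shift_for_auc(0.836, sd)
  m["SCCA",   "EC"]  <- marker_shift_for_auc(0.794, sd)
  m["CA19_9", "CRC"] <- marker_shift_for_auc(0.613, sd)
  m
}

default_stage_weights <- function() {
  list(
    CRC = c(I = 76, II = 96, III = 79, IV = 38) / 289,
    GC  = c(I = 73, II = 47, III = 39, IV = 21) / 180,
    EC  = c(I = 5,  II = 18, III = 15, IV = 4)  / 42
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles every tunable of the simulator. Defaults describe a cohort with
#' the demographic structure of a case-control gastrointestinal-cancer study
#' (590 healthy / 296 CRC / 180 GC / 42 EC with the observed stage mix),
#' log-normal tumor markers calibrated to published single-marker AUCs, and
#' a glycopeptide peak layer with isotope/adduct/fragment satellites,
#' below-detection dropout, and coordinate jitter within the alignment
#' tolerances.
#'
#' @param n_per_group named counts for `healthy`, `CRC`, `GC`, `EC`.
#' @param stage_weights named list of stage I-IV proportions per cancer
#'   group; each must sum to 1.
#' @param n_true_egps number of true glycopeptide species planted.
#' @param frac_differential fraction of species carrying group effects.
#' @param effect_log2fc planted log2 fold-change magnitude.
#' @param direction_down_frac named per-group probability that a planted
#'   effect is a reduction; the gastric group defaults to a broad down-shift.
#' @param stage_factors multiplier on effect size per stage I-IV.
#' @param marker_shifts 9 x 3 matrix of per-marker, per-group log10 mean
#'   shifts (rows [marker_names()], columns CRC/GC/EC).
#' @param marker_log10_sd common log10 SD of the markers.
#' @param n_signature number of signature glycopeptide species planted with
#'   a consistent effect in every cancer group (the AT271-FSG / MG70-FSG
#'   analogues).
#' @param signature_auc per-feature AUC the signature species are calibrated
#'   to on the log2 relative-level scale.
#' @param noise_sd multiplicative biological noise, SD on the log2 scale.
#' @param lod detection limit in area units; smaller peaks are dropped.
#' @param jitter_rt_sd,jitter_mz_sd coordinate jitter SDs (min, Da); must be
#'   strictly below half the alignment tolerances (0.3 min, 0.06 Da).
#' @param satellite_rates named probabilities that a species carries an
#'   `isotope`, `adduct`, or `fragment` satellite peak.
#' @param n_noise_per_sample random noise peaks added per injection.
#' @param noise_floor median area of noise peaks.
#' @param qc_cv_intra_pct,qc_cv_inter_pct target CV (%) of intra- and
#'   inter-day QC replicate injections.
#' @param n_qc_replicates named counts `intra`, `inter` of QC injections.
#' @param rt_range,mz_range coordinate ranges (min, Da) species are placed in.
#' @param base_area_log10_mean,base_area_log10_sd log10 distribution of
#'   species base peak areas.
#' @param seed integer RNG seed; all generator functions are deterministic
#'   given the config.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_per_group = c(healthy = 590, CRC = 296,
                                          GC = 180, EC = 42),
                          stage_weights = default_stage_weights(),
                          n_true_egps = 1688,
                          frac_differential = 0.1,
                          effect_log2fc = 1,
                          direction_down_frac = c(CRC = 0.5, GC = 0.8,
                                                  EC = 0.5),
                          stage_factors = c(I = 0.5, II = 1.0,
                                            III = 1.1, IV = 1.2),
                          marker_shifts = NULL,
                          marker_log10_sd = 0.35,
                          n_signature = 2,
                          signature_auc = 0.79,
                          noise_sd = 0.5,
                          lod = 50,
                          jitter_rt_sd = 0.05,
                          jitter_mz_sd = 0.01,
                          satellite_rates = c(isotope = 0.25, adduct = 0.10,
                                              fragment = 0.10),
                          n_noise_per_sample = 150,
                          noise_floor = 100,
                          qc_cv_intra_pct = 8,
                          qc_cv_inter_pct = 10,
                          n_qc_replicates = c(intra = 6, inter = 6),
                          rt_range = c(1, 14),
                          mz_range = c(700, 2500),
                          base_area_log10_mean = 4.5,
                          base_area_log10_sd = 0.5,
                          seed = 1L) {
  if (is.null(marker_shifts)) marker_shifts <- default_marker_shifts(marker_log10_sd)
  cfg <- list(n_per_group = n_per_group, stage_weights = stage_weights,
              n_true_egps = n_true_egps, frac_differential = frac_differential,
              effect_log2fc = effect_log2fc,
              direction_down_frac = direction_down_frac,
              stage_factors = stage_factors, marker_shifts = marker_shifts,
              marker_log10_sd = marker_log10_sd, n_signature = n_signature,
              signature_auc = signature_auc, noise_sd = noise_sd, lod = lod,
              jitter_rt_sd = jitter_rt_sd, jitter_mz_sd = jitter_mz_sd,
              satellite_rates = satellite_rates,
              n_noise_per_sample = n_noise_per_sample,
              noise_floor = noise_floor,
              qc_cv_intra_pct = qc_cv_intra_pct,
              qc_cv_inter_pct = qc_cv_inter_pct,
              n_qc_replicates = n_qc_replicates,
              rt_range = rt_range, mz_range = mz_range,
              base_area_log10_mean = base_area_log10_mean,
              base_area_log10_sd = base_area_log10_sd,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  need <- group_names()
  if (!all(need %in% names(cfg$n_per_group)))
    stop_config("n_per_group must name all of: %s", paste(need, collapse = ", "))
  if (any(cfg$n_per_group < 0) || any(cfg$n_per_group != floor(cfg$n_per_group)))
    stop_config("n_per_group counts must be non-negative integers")
  for (g in c("CRC", "GC", "EC")) {
    w <- cfg$stage_weights[[g]]
    if (is.null(w) || length(w) != 4L)
      stop_config("stage_weights[['%s']] must give 4 stage proportions", g)
    if (abs(sum(w) - 1) > 1e-8)
      stop_config("stage_weights[['%s']] must sum to 1 (got %g)", g, sum(w))
    if (any(w < 0)) stop_config("stage_weights[['%s']] must be non-negative", g)
  }
  assert_fraction(cfg$frac_differential, "frac_differential")
  if (cfg$n_true_egps < 0) stop_config("n_true_egps must be >= 0")
  if (cfg$lod < 0) stop_config("lod must be >= 0")
  ## keep planted peaks recoverable under the default alignment tolerances
  if (cfg$jitter_rt_sd >= 0.3 / 2)
    stop_config("jitter_rt_sd must be < 0.15 min (half the RT tolerance)")
  if (cfg$jitter_mz_sd >= 0.06 / 2)
    stop_config("jitter_mz_sd must be < 0.03 Da (half the m/z tolerance)")
  if (any(cfg$satellite_rates < 0) || any(cfg$satellite_rates > 1))
    stop_config("satellite_rates must be probabilities")
  if (cfg$n_signature > cfg$n_true_egps)
    stop_config("n_signature cannot exceed n_true_egps")
  invisible(cfg)
}

## stage factor lookup tolerant of 'none'
stage_factor_of <- function(stage, factors) {
  f <- rep(0, length(stage))
  hit <- stage %in% names(factors)
  f[hit] <- factors[stage[hit]]
  f
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws subjects (group, stage, nine tumor markers) and the registry of
#' planted glycopeptide species: coordinates, base areas, signature species,
#' differential effects per cancer group, and satellite plans. All
#' randomness is derived from `config$seed`; two calls with the same config
#' return identical results.
#'
#' @param config a [cohort_config()].
#' @return list with `subjects` (data.frame: id, group, stage, nine marker
#'   columns) and `truth` (class `csgsa_truth`; see Details).
#' @details `truth` carries `species` (registry with rt/mz/base area),
#'   `effects` (species x cancer-group log2 fold-change matrix),
#'   `differential` (long form of the non-zero effects),
#'   `signature_ids`, and `satellites` (per-species satellite plan);
#'   `peak_roles` is filled in by [generate_peak_tables()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(child_seed(config$seed, "cohort"))

  groups <- rep(group_names(), times = config$n_per_group[group_names()])
  n <- length(groups)
  stage <- rep("none", n)
  for (g in c("CRC", "GC", "EC")) {
    idx <- which(groups == g)
    if (length(idx))
      stage[idx] <- sample(c("I", "II", "III", "IV"), length(idx),
                           replace = TRUE, prob = config$stage_weights[[g]])
  }
  subjects <- data.frame(
    id = if (n) sprintf("S%04d", seq_len(n)) else character(0),
    group = groups, stage = stage, stringsAsFactors = FALSE
  )
  markers <- generate_marker_panel(subjects, config)
  subjects <- cbind(subjects, as.data.frame(markers))

  truth <- generate_truth(config)
  list(subjects = subjects, truth = truth)
}

#' Draw the nine-marker tumor panel for a subject table
#'
#' Each marker is log-normal on the log10 scale: healthy mean plus the
#' configured per-group shift, common SD `marker_log10_sd`. Uses the current
#' RNG state (callers seed); [generate_cohort()] wraps this with its own
#' deterministic stream.
#'
#' @param subjects data.frame with at least a `group` column.
#' @param config a [cohort_config()].
#' @return numeric matrix, one row per subject, columns [marker_names()].
#' @export
generate_marker_panel <- function(subjects, config) {
  n <- nrow(subjects)
  mk <- marker_names()
  out <- matrix(0, nrow = n, ncol = length(mk), dimnames = list(NULL, mk))
  if (n == 0L) return(out)
  for (m in mk) {
    mu <- rep(.marker_log10_mean[[m]], n)
    for (g in c("CRC", "GC", "EC")) {
      idx <- subjects$group == g
      mu[idx] <- mu[idx] + config$marker_shifts[m, g]
    }
    out[, m] <- 10^(mu + rnorm(n, 0, config$marker_log10_sd))
  }
  out
}

## species registry + effects + satellite plan
generate_truth <- function(config) {
  set.seed(child_seed(config$seed, "truth"))
  ns <- config$n_true_egps
  cancers <- c("CRC", "GC", "EC")

  rt <- runif(ns, config$rt_range[1], config$rt_range[2])
  mz <- runif(ns, config$mz_range[1], config$mz_range[2])
  ## enforce separation > 2x tolerance in at least one coordinate so planted
  ## species are individually recoverable by alignment
  if (ns > 1) {
    for (pass in 1:50) {
      o <- order(mz)
      bad <- integer(0)
      for (k in seq_len(ns - 1)) {
        i <- o[k]
        j <- k + 1L
        while (j <= ns && mz[o[j]] - mz[i] <= 0.12) {
          if (abs(rt[o[j]] - rt[i]) <= 0.6) bad <- c(bad, o[j])
          j <- j + 1L
        }
      }
      bad <- unique(bad)
      if (!length(bad)) break
      rt[bad] <- runif(length(bad), config$rt_range[1], config$rt_range[2])
      mz[bad] <- runif(length(bad), config$mz_range[1], config$mz_range[2])
    }
  }

  species <- data.frame(
    species_id = if (ns) sprintf("EGP%05d", seq_len(ns)) else character(0),
    rt = rt, mz = mz,
    base_area = 10^rnorm(ns, config$base_area_log10_mean,
                         config$base_area_log10_sd),
    is_signature = rep(FALSE, ns),
    stringsAsFactors = FALSE
  )

  effects <- matrix(0, nrow = ns, ncol = 3,
                    dimnames = list(species$species_id, cancers))
  sig_ids <- character(0)
  if (ns > 0 && config$n_signature > 0) {
    sig <- seq_len(min(config$n_signature, ns))
    species$is_signature[sig] <- TRUE
    sig_ids <- species$species_id[sig]
    ## calibrated so the per-feature AUC on log2 levels hits signature_auc;
    ## in a noise-free world any non-zero effect separates perfectly
    fc <- if (config$noise_sd > 0)
      marker_shift_for_auc(config$signature_auc, config$noise_sd) else 1

    effects[sig, ] <- fc
  }
  n_diff <- floor(config$frac_differential * ns)
  diff_idx <- integer(0)
  if (n_diff > 0) {
    pool <- setdiff(seq_len(ns), which(species$is_signature))
    diff_idx <- sort(sample(pool, min(n_diff, length(pool))))
    for (g in cancers) {
      down <- rbinom(length(diff_idx), 1, config$direction_down_frac[[g]]) == 1
      effects[diff_idx, g] <- ifelse(down, -1, 1) * config$effect_log2fc
    }
  }

  nz <- which(effects != 0, arr.ind = TRUE)
  differential <- data.frame(
    species_id = rownames(effects)[nz[, 1]],
    group = cancers[nz[, 2]],
    log2fc = effects[nz],
    direction = ifelse(effects[nz] > 0, "up", "down"),
    stringsAsFactors = FALSE
  )

  ## satellite plan: offsets fixed per species so satellites align across
  ## samples and are detectable by the artifact flags
  sat <- list()
  if (ns > 0) {
    has_iso <- runif(ns) < config$satellite_rates[["isotope"]]
    has_add <- runif(ns) < config$satellite_rates[["adduct"]]
    has_frg <- runif(ns) < config$satellite_rates[["fragment"]]
    iso_z <- sample(1:3, ns, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    add_dm <- sample(c(21.98194, 37.95588), ns, replace = TRUE,
                     prob = c(0.7, 0.3))
    frg_frac <- runif(ns, 0.4, 0.7)
    if (any(has_iso))
      sat$iso <- data.frame(species_id = species$species_id[has_iso],
                            kind = "isotope",
                            d_mz = 1.00335 / iso_z[has_iso],
                            ratio = 0.4, stringsAsFactors = FALSE)
    if (any(has_add))
      sat$add <- data.frame(species_id = species$species_id[has_add],
                            kind = "adduct", d_mz = add_dm[has_add],
                            ratio = 0.25, stringsAsFactors = FALSE)
    if (any(has_frg))
      sat$frg <- data.frame(species_id = species$species_id[has_frg],
                            kind = "fragment",
                            d_mz = (frg_frac[has_frg] - 1) *
                              species$mz[has_frg],
                            ratio = 0.35, stringsAsFactors = FALSE)
  }
  satellites <- if (length(sat)) do.call(rbind, unname(sat)) else
    data.frame(species_id = character(0), kind = character(0),
               d_mz = numeric(0), ratio = numeric(0))

  structure(list(species = species, effects = effects,
                 differential = differential, signature_ids = sig_ids,
                 satellites = satellites, peak_roles = NULL),
            class = "csgsa_truth")
}

## log2-scale relative abundance (ratio to base area) per subject x species
.abundance_log2 <- function(subjects, truth, config, noisy = TRUE) {
  ns <- nrow(truth$species)
  n <- nrow(subjects)
  sf <- stage_factor_of(subjects$stage, config$stage_factors)
  eff <- matrix(0, nrow = ns, ncol = n)
  for (g in c("CRC", "GC", "EC")) {
    idx <- which(subjects$group == g)
    if (length(idx))
      eff[, idx] <- outer(truth$effects[, g], sf[idx])
  }
  if (noisy && config$noise_sd > 0)
    eff <- eff + matrix(rnorm(ns * n, 0, config$noise_sd), ns, n)
  dimnames(eff) <- list(truth$species$species_id, subjects$id)
  eff
}

#' Generate raw peak tables (samples plus QC replicate injections)
#'
#' Emits long-format peak lists: one parent peak per (sample, species) at
#' the registry coordinates with RT/m-z jitter, planned isotope/adduct/
#' fragment satellites tied to each parent's area, per-injection random
#' noise peaks, and below-detection dropout. QC injections (intra- and
#' inter-day) are drawn around the species base areas with the configured
#' replicate CVs.
#'
#' @param cohort output of [generate_cohort()].
#' @param truth the `csgsa_truth` from the same call.
#' @param config the same [cohort_config()].
#' @return object of class `csgsa_peak_tables`: list with `peaks` (a
#'   data.table: sample_id, rt_min, mz, area, peak_id), `qc_sample_ids`
#'   (named list with `intra`, `inter`), and `truth` (the input truth with
#'   `peak_roles` filled: peak_id, sample_id, role, species_id).
#' @export
generate_peak_tables <- function(cohort, truth, config) {
  stopifnot(inherits(config, "cohort_config"), inherits(truth, "csgsa_truth"))
  if (config$lod < 0) stop_config("lod must be >= 0")
  set.seed(child_seed(config$seed, "peaks"))

  subjects <- cohort$subjects
  sp <- truth$species
  ns <- nrow(sp)

  qc_intra <- sprintf("QC_intra_%02d", seq_len(config$n_qc_replicates[["intra"]]))
  qc_inter <- sprintf("QC_inter_%02d", seq_len(config$n_qc_replicates[["inter"]]))

  ## per-injection species areas
  blocks <- list()
  if (ns > 0 && nrow(subjects) > 0) {
    l2 <- .abundance_log2(subjects, truth, config, noisy = TRUE)
    area <- sp$base_area * 2^l2          # ns x n recycled by column
    blocks$sample <- list(ids = subjects$id, area = area)
  }
  cv2sd <- function(cv_pct) sqrt(log(1 + (cv_pct / 100)^2))
  if (ns > 0) {
    if (length(qc_intra)) {
      a <- sp$base_area *
        exp(matrix(rnorm(ns * length(qc_intra), 0,
                         cv2sd(config$qc_cv_intra_pct)),
                   ns, length(qc_intra)))
      blocks$qc_intra <- list(ids = qc_intra, area = a)
    }
    if (length(qc_inter)) {
      a <- sp$base_area *
        exp(matrix(rnorm(ns * length(qc_inter), 0,
                         cv2sd(config$qc_cv_inter_pct)),
                   ns, length(qc_inter)))
      blocks$qc_inter <- list(ids = qc_inter, area = a)
    }
  }

  sat <- truth$satellites
  sat_idx <- match(sat$species_id, sp$species_id)

  out <- vector("list", length(blocks) * 3L + 1L)
  k <- 0L
  for (b in blocks) {
    nb <- length(b$ids)
    ## parent peaks
    par <- data.table::data.table(
      sample_id = rep(b$ids, each = ns),
      species_id = rep(sp$species_id, nb),
      role = "parent",
      rt_min = rep(sp$rt, nb) + rnorm(ns * nb, 0, config$jitter_rt_sd),
      mz = rep(sp$mz, nb) + rnorm(ns * nb, 0, config$jitter_mz_sd),
      area = as.vector(b$area)
    )
    k <- k + 1L; out[[k]] <- par
    if (nrow(sat)) {
      ## satellite area rides on the parent area of the same injection
      parea <- b$area[sat_idx, , drop = FALSE]
      nsat <- nrow(sat)
      satp <- data.table::data.table(
        sample_id = rep(b$ids, each = nsat),
        species_id = rep(sat$species_id, nb),
        role = rep(sat$kind, nb),
        rt_min = rep(sp$rt[sat_idx], nb) +
          rnorm(nsat * nb, 0, config$jitter_rt_sd / 2),
        mz = rep(sp$mz[sat_idx] + sat$d_mz, nb) +
          rnorm(nsat * nb, 0, config$jitter_mz_sd),
        area = as.vector(parea) * rep(sat$ratio, nb) *
          2^rnorm(nsat * nb, 0, 0.05)
      )
      k <- k + 1L; out[[k]] <- satp
    }
    if (config$n_noise_per_sample > 0) {
      nn <- config$n_noise_per_sample * nb
      noi <- data.table::data.table(
        sample_id = rep(b$ids, each = config$n_noise_per_sample),
        species_id = NA_character_,
        role = "noise",
        rt_min = runif(nn, config$rt_range[1], config$rt_range[2]),
        mz = runif(nn, config$mz_range[1], config$mz_range[2]),
        area = exp(rnorm(nn, log(config$noise_floor), 0.5))
      )
      k <- k + 1L; out[[k]] <- noi
    }
  }
  peaks <- data.table::rbindlist(out[seq_len(k)])
  if (nrow(peaks) == 0L)
    peaks <- data.table::data.table(sample_id = character(0),
                                    species_id = character(0),
                                    role = character(0), rt_min = numeric(0),
                                    mz = numeric(0), area = numeric(0))
  peaks <- peaks[peaks$area >= config$lod | peaks$role == "noise", ]
  peaks[, peak_id := if (.N) sprintf("P%07d", seq_len(.N)) else character(0)]

  roles <- peaks[, c("peak_id", "sample_id", "role", "species_id"),
                 with = FALSE]
  truth$peak_roles <- as.data.frame(roles)
  structure(list(
    peaks = peaks[, c("sample_id", "rt_min", "mz", "area", "peak_id"),
                  with = FALSE],
    qc_sample_ids = list(intra = qc_intra, inter = qc_inter),
    truth = truth
  ), class = "csgsa_peak_tables")
}

#' Generate the EGP relative-level matrix directly
#'
#' Shortcut that emits the species-by-sample matrix of relative levels
#' (ratio to the QC standard) without going through peak emission and
#' re-alignment. On satellite-free, noise-free settings the full peaks
#' stage reproduces this matrix exactly; the shortcut keeps classifier
#' benchmarks inside desk-scale budgets.
#'
#' @inheritParams generate_peak_tables
#' @param apply_lod drop (zero out) entries whose implied area falls below
#'   `config$lod`.
#' @return a [feature_matrix] whose feature ids are the species ids.
#' @export
generate_egp_matrix <- function(cohort, truth, config, apply_lod = TRUE) {
  set.seed(child_seed(config$seed, "egpmat"))
  l2 <- .abundance_log2(cohort$subjects, truth, config, noisy = TRUE)
  rel <- 2^l2
  if (apply_lod && config$lod > 0) {
    area <- truth$species$base_area * rel
    rel[area < config$lod] <- 0
  }
  feature_matrix(
    features = data.frame(feature_id = truth$species$species_id,
                          rt = truth$species$rt, mz = truth$species$mz,
                          stringsAsFactors = FALSE),
    values = rel
  )
}

#' Write simulator outputs as plain-text files
#'
#' @param tables a `csgsa_peak_tables`.
#' @param cohort the matching cohort.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (peaks.csv, subjects.csv,
#'   ground_truth.json).
#' @export
write_simulation <- function(tables, cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, c("peaks.csv", "subjects.csv", "ground_truth.json"))
  data.table::fwrite(tables$peaks[, c("sample_id", "rt_min", "mz", "area")],
                     p[1])
  utils::write.csv(cohort$subjects, p[2], row.names = FALSE)
  tr <- tables$truth
  jsonlite::write_json(
    list(species = tr$species, differential = tr$differential,
         signature_ids = tr$signature_ids, satellites = tr$satellites,
         peak_roles = tr$peak_roles,
         qc_sample_ids = tables$qc_sample_ids),
    p[3], dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(p)
}
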
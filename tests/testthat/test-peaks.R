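test_that("compute_cv matches hand-computed values and is scale invariant", {
  expect_equal(compute_cv(c(10, 10, 10)), 0)
  ## sd(c(8,12)) = 2*sqrt(2) = 2.8284, mean 10 -> 28.2843 %
  expect_equal(compute_cv(c(8, 12)), 100 * sd(c(8, 12)) / 10)
  expect_equal(round(compute_cv(c(8, 12)), 2), 28.28)
  expect_true(is.na(compute_cv(c(5))))
  expect_true(is.na(compute_cv(c(0, 0, 0))))
  set.seed(1)
  for (i in 1:5) {
    x <- rlnorm(6, 3, 0.4)
    k <- runif(1, 0.1, 50)
    expect_equal(compute_cv(k * x), compute_cv(x))
  }
})

test_that("align_peaks merges within tolerance and separates beyond it", {
  mk <- function(sid, rt, mz, area = 1000)
    data.frame(sample_id = sid, rt_min = rt, mz = mz, area = area)
  ## identical lists -> one feature per peak, both samples contributing
  tbl <- rbind(mk("A", c(2, 5, 9), c(800, 900.5, 1200.25)),
               mk("B", c(2, 5, 9), c(800, 900.5, 1200.25)))
  fm <- align_peaks(tbl)
  expect_equal(nrow(fm$values), 3L)
  expect_true(all(fm$values > 0))

  ## +0.05 Da, +0.2 min -> same feature
  fm2 <- align_peaks(rbind(mk("A", 5, 900), mk("B", 5.2, 900.05)))
  expect_equal(nrow(fm2$values), 1L)
  ## +0.07 Da -> distinct features
  fm3 <- align_peaks(rbind(mk("A", 5, 900), mk("B", 5, 900.07)))
  expect_equal(nrow(fm3$values), 2L)
  ## RT beyond 0.3 min -> distinct
  fm4 <- align_peaks(rbind(mk("A", 5, 900), mk("B", 5.4, 900)))
  expect_equal(nrow(fm4$values), 2L)

  expect_error(align_peaks(tbl, tol_mz = -1), "tolerance")
  e <- align_peaks(data.frame(sample_id = character(0), rt_min = numeric(0),
                              mz = numeric(0), area = numeric(0)))
  expect_equal(nrow(e$values), 0L)
})

test_that("alignment is invariant to sample and row order", {
  set.seed(42)
  n <- 60
  base <- data.frame(rt = runif(n, 1, 14), mz = runif(n, 700, 2000))
  tabs <- lapply(1:4, function(s) data.frame(
    sample_id = paste0("S", s),
    rt_min = base$rt + rnorm(n, 0, 0.05),
    mz = base$mz + rnorm(n, 0, 0.01),
    area = rlnorm(n, 8, 0.5)))
  all_rows <- do.call(rbind, tabs)
  f1 <- align_peaks(all_rows)
  f2 <- align_peaks(all_rows[sample(nrow(all_rows)), ])
  f3 <- align_peaks(rev(tabs))
  key <- function(f) round(cbind(f$features$rt, f$features$mz), 9)
  expect_equal(key(f1), key(f2))
  expect_equal(key(f1), key(f3))
  expect_equal(f1$values[order(f1$features$mz), colnames(f1$values)],
               f2$values[order(f2$features$mz), colnames(f1$values)])
})

test_that("aligning a table against a relabeled copy adds no features", {
  set.seed(7)
  a <- data.frame(sample_id = "A", rt_min = runif(30, 1, 14),
                  mz = runif(30, 700, 2000), area = rlnorm(30, 8, 0.3))
  solo <- align_peaks(a)
  b <- a; b$sample_id <- "B"
  both <- align_peaks(rbind(a, b))
  expect_equal(nrow(both$values), nrow(solo$values))
})

test_that("simulated species are recovered one feature per species", {
  cfg <- clean_config(n_per_group = c(healthy = 30, CRC = 10, GC = 6,
                                      EC = 4),
                      n_true_egps = 150, seed = 19L)
  ch <- generate_cohort(cfg)
  pt <- generate_peak_tables(ch, ch$truth, cfg)
  fm <- align_peaks(pt)
  hit <- match_registry(fm$features, ch$truth$species)
  expect_gte(mean(!is.na(hit)), 0.99)
  expect_equal(anyDuplicated(hit[!is.na(hit)]), 0L)
})

test_that("estimate_snr follows the median/noise-floor definition", {
  ft <- data.frame(feature_id = c("F1", "F2"), rt = c(5, 9),
                   mz = c(900, 1000))
  vals <- rbind(c(500, 500, 500), c(100, 100, 100))
  fm <- feature_matrix(ft, vals)
  noise <- data.frame(rt_min = c(4.8, 5.1, 9.2), area = c(100, 100, 100))
  snr <- estimate_snr(fm, noise_peaks = noise)
  expect_equal(unname(snr), c(5, 1))
  ## snr exactly 5 survives the strict < 5 filter
  flags <- feature_flags(fm, cv_pct = c(10, 10), snr = snr,
                         artifacts = data.frame(is_isotope = c(FALSE, FALSE),
                                                is_adduct = c(FALSE, FALSE),
                                                is_fragment = c(FALSE, FALSE)))
  expect_true(flags$pass_egp[1])
  expect_false(flags$pass_egp[2])
  ## local floor beats the global one when noise is rt-structured
  noise2 <- data.frame(rt_min = c(5.0, 5.1, 12), area = c(250, 250, 10))
  snr2 <- estimate_snr(fm, noise_peaks = noise2)
  expect_equal(unname(snr2[1]), 2)
})

test_that("flag_artifacts detects constructed satellites and nothing else", {
  ft <- data.frame(
    feature_id = c("parent", "iso", "add", "frag", "lone"),
    rt = c(5, 5.02, 5.01, 4.98, 9),
    mz = c(1200, 1201.00335, 1221.98194, 700, 1500))
  set.seed(3)
  parent <- rlnorm(12, 8, 0.6)
  vals <- rbind(parent, 0.4 * parent, 0.25 * parent,
                0.35 * parent * exp(rnorm(12, 0, 0.01)),
                rlnorm(12, 7, 0.6))
  fm <- feature_matrix(ft, vals)
  fl <- flag_artifacts(fm)
  expect_equal(fl$is_isotope, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(fl$is_adduct, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_true(fl$is_fragment[4])
  expect_false(any(fl$is_isotope[c(1, 5)], fl$is_adduct[c(1, 5)],
                   fl$is_fragment[c(1, 5)]))
})

test_that("satellite-free simulations produce zero artifact flags", {
  cfg <- clean_config(n_true_egps = 80, seed = 23L)
  ch <- generate_cohort(cfg)
  pt <- generate_peak_tables(ch, ch$truth, cfg)
  fm <- align_peaks(pt)
  fl <- flag_artifacts(fm)
  expect_equal(sum(fl$is_isotope | fl$is_adduct | fl$is_fragment), 0L)
})

test_that("simulated satellites are flagged, parents spared", {
  cfg <- small_config(n_true_egps = 200, n_noise_per_sample = 0, seed = 29L)
  ch <- generate_cohort(cfg)
  pt <- generate_peak_tables(ch, ch$truth, cfg)
  fm <- align_peaks(pt)
  fl <- flag_artifacts(fm, sample_ids = ch$subjects$id)
  ## majority role of each feature via provenance
  prov <- merge(fm$provenance, pt$truth$peak_roles[, c("peak_id", "role")],
                by = "peak_id")
  role_of <- tapply(prov$role, prov$feature_id,
                    function(r) names(which.max(table(r))))
  role <- unname(role_of[fm$features$feature_id])
  any_flag <- fl$is_isotope | fl$is_adduct | fl$is_fragment
  is_sat <- role %in% c("isotope", "adduct", "fragment")
  expect_gte(mean(any_flag[is_sat]), 0.95)
  expect_lte(mean(any_flag[role == "parent"]), 0.02)
})

test_that("select_egps applies the three steps with strict boundaries", {
  nf <- 16
  ft <- data.frame(feature_id = sprintf("F%02d", 1:nf), rt = seq_len(nf),
                   mz = 700 + 10 * seq_len(nf))
  fm <- feature_matrix(ft, matrix(1000, nf, 4,
                                  dimnames = list(NULL, paste0("S", 1:4))))
  ## 10 clean parents, 3 isotopes, 2 low snr, 1 high cv
  cv <- c(rep(10, 15), 60)
  snr <- c(rep(20, 13), 4.9, 4.5, 20)
  art <- data.frame(is_isotope = c(rep(FALSE, 10), TRUE, TRUE, TRUE,
                                   rep(FALSE, 3)),
                    is_adduct = FALSE, is_fragment = FALSE)
  flags <- feature_flags(fm, cv, snr, art)
  out <- select_egps(fm, flags)
  expect_equal(nrow(out$values), 10L)
  rem <- attr(out, "removal")
  expect_equal(rem$removed, c(1L, 2L, 3L))
  expect_equal(sum(rem$removed), nf - nrow(out$values))
  expect_true(all(out$features$feature_id %in% ft$feature_id))

  ## boundary semantics: CV exactly 50 retained, snr exactly 5 retained
  fl2 <- feature_flags(fm, rep(50, nf), rep(5, nf),
                       data.frame(is_isotope = rep(FALSE, nf),
                                  is_adduct = FALSE, is_fragment = FALSE))
  expect_true(all(fl2$pass_egp))
  fl3 <- feature_flags(fm, rep(50.0001, nf), rep(5, nf),
                       data.frame(is_isotope = rep(FALSE, nf),
                                  is_adduct = FALSE, is_fragment = FALSE))
  expect_false(any(fl3$pass_egp))
  ## undefined CV fails step (i)
  fl4 <- feature_flags(fm, rep(NA_real_, nf), rep(5, nf),
                       data.frame(is_isotope = rep(FALSE, nf),
                                  is_adduct = FALSE, is_fragment = FALSE))
  expect_false(any(fl4$pass_egp))
})

test_that("normalize_to_qc produces QC ratios with linearity", {
  ft <- data.frame(feature_id = c("F1", "F2"), rt = c(1, 2), mz = c(800, 900))
  vals <- cbind(S1 = c(100, 250), S2 = c(200, 0),
                QC1 = c(100, 100), QC2 = c(100, 100))
  fm <- feature_matrix(ft, vals)
  nm <- normalize_to_qc(fm, c("QC1", "QC2"))
  expect_equal(unname(nm$values[, "S1"]), c(1, 2.5))
  expect_equal(unname(nm$values["F2", "S2"]), 0)   # missing stays zero
  ## doubling one sample's areas doubles its relative levels
  vals2 <- vals; vals2[, "S1"] <- 2 * vals2[, "S1"]
  nm2 <- normalize_to_qc(feature_matrix(ft, vals2), c("QC1", "QC2"))
  expect_equal(nm2$values[, "S1"], 2 * nm$values[, "S1"])
  expect_equal(nm2$values[, "S2"], nm$values[, "S2"])
  ## zero QC mean excludes the feature with a warning
  vals3 <- vals; vals3[2, c("QC1", "QC2")] <- 0
  expect_warning(nm3 <- normalize_to_qc(feature_matrix(ft, vals3),
                                        c("QC1", "QC2")), "zero mean")
  expect_equal(nrow(nm3$values), 1L)
  expect_equal(attr(nm3, "excluded_features"), "F2")
})

test_that("noise-free pipeline is information preserving", {
  ## zero biological noise makes co-regulated species perfectly correlated,
  ## so the fixture must not let two effect-carrying species co-elute or
  ## the fragment rule would (correctly) fire on them; the premise is
  ## asserted below
  cfg <- clean_config(n_per_group = c(healthy = 12, CRC = 6, GC = 4, EC = 2),
                      n_true_egps = 60, noise_sd = 0, n_signature = 0,
                      frac_differential = 0.05,
                      qc_cv_intra_pct = 0, qc_cv_inter_pct = 0,
                      jitter_rt_sd = 0.01, jitter_mz_sd = 0.002, seed = 55L)
  ch <- generate_cohort(cfg)
  eff_rt <- ch$truth$species$rt[ch$truth$species$species_id %in%
                                  ch$truth$differential$species_id]
  expect_gt(min(dist(eff_rt)), 0.1)   # premise: no co-eluting effect pair
  pt <- generate_peak_tables(ch, ch$truth, cfg)
  res <- process_peaks(pt, pt$qc_sample_ids, global_floor = 1)
  truth_mat <- generate_egp_matrix(ch, ch$truth, cfg)
  idx <- match_registry(res$egp$features, ch$truth$species)
  expect_false(any(is.na(idx)))
  got <- res$egp$values[idx, colnames(truth_mat$values)]
  rel_err <- abs(got - truth_mat$values) / pmax(truth_mat$values, 1e-300)
  expect_lt(max(rel_err), 1e-9)
})

test_that("select_egps output is a subset and counts reconcile", {
  cfg <- small_config(n_true_egps = 120, seed = 61L)
  ch <- generate_cohort(cfg)
  pt <- generate_peak_tables(ch, ch$truth, cfg)
  roles <- pt$truth$peak_roles
  np <- merge(as.data.frame(pt$peaks),
              roles[roles$role == "noise", c("peak_id", "role")],
              by = "peak_id")
  res <- process_peaks(pt, pt$qc_sample_ids, noise_peaks = np)
  n_in <- nrow(res$aligned$values)
  n_out_raw <- sum(res$flags$pass_egp)
  expect_equal(sum(res$removal$removed), n_in - n_out_raw)
  expect_true(all(res$egp$features$feature_id %in%
                    res$aligned$features$feature_id))
})
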
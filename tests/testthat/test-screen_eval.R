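test_that("csgsa_score has the closed-form fixed points and the cap", {
  expect_equal(csgsa_score(0), 0)
  expect_equal(csgsa_score(0.99999), 5)
  expect_equal(csgsa_score(1 - 1e-12), 10)   # capped
  expect_equal(csgsa_score(1), 10)
  expect_error(csgsa_score(1.1), "\\[0, 1\\]")
  expect_error(csgsa_score(-0.1), "\\[0, 1\\]")
  ## monotone below the cap
  p <- sort(runif(100, 0, 1 - 1e-11))
  expect_true(all(diff(csgsa_score(p)) >= 0))
})

test_that("confusion_at_cutoff counts with an inclusive boundary", {
  conf <- confusion_at_cutoff(c(10, 10, 0, 0), c(1, 1, 0, 0), cutoff = 5)
  expect_equal(unlist(conf[c("tp", "fp", "fn", "tn")]),
               c(tp = 2L, fp = 0L, fn = 0L, tn = 2L))
  ## score exactly 5 is positive
  conf2 <- confusion_at_cutoff(c(5, 4.999), c(1, 1), cutoff = 5)
  expect_equal(conf2$tp, 1L)
  expect_equal(conf2$fn, 1L)
  expect_error(confusion_table(-1, 0, 0, 0), ">= 0")
})

test_that("sens_spec reproduces the reference observed blocks", {
  obs <- observed_screening_counts()
  got <- t(vapply(seq_len(nrow(obs)), function(i)
    sens_spec(confusion_table(obs$tp[i], obs$fp[i], obs$fn[i], obs$tn[i])),
    numeric(2)))
  expect_equal(round(got[, 1], 1), c(54.3, 61.6, 67.7))
  expect_equal(round(got[, 2], 1), c(99.9, 99.9, 99.9))
  expect_error(sens_spec(confusion_table(0, 1, 0, 1)), "undefined")
})

test_that("prevalence_adjust reproduces every reference adjusted count", {
  obs <- observed_screening_counts()
  expected <- list(
    CRC = list(tp = 134, fp = 112, fn = 113, tn = 99641,
               ppv = 54.5, npv = 99.89),
    GC = list(tp = 61, fp = 112, fn = 38, tn = 99789,
              ppv = 35.3, npv = 99.96),
    EC = list(tp = 14, fp = 112, fn = 7, tn = 99867,
              ppv = 11.1, npv = 99.99))
  for (i in seq_len(nrow(obs))) {
    m <- prevalence_adjust(
      confusion_table(obs$tp[i], obs$fp[i], obs$fn[i], obs$tn[i]),
      obs$prevalence_per_100k[i])
    e <- expected[[obs$cancer_type[i]]]
    expect_equal(m$adjusted$tp, e$tp)
    expect_equal(m$adjusted$fp, e$fp)
    expect_equal(m$adjusted$fn, e$fn)
    expect_equal(m$adjusted$tn, e$tn)
    expect_equal(round(m$ppv, 1), e$ppv)
    expect_equal(round(m$npv, 2), e$npv)
    ## conservation: adjusted table sums to the population
    expect_equal(m$adjusted$tp + m$adjusted$fp + m$adjusted$fn +
                   m$adjusted$tn, 100000)
  }
  ## perfect test -> perfect predictive values at any prevalence
  perf <- prevalence_adjust(confusion_table(50, 0, 0, 50), 21)
  expect_equal(perf$ppv, 100)
  expect_equal(perf$npv, 100)
  expect_error(prevalence_adjust(confusion_table(1, 1, 1, 1), 0), "> 0")
})

test_that("PPV is monotone in prevalence and self-consistent", {
  conf <- confusion_table(324, 2, 202, 1778)
  grid <- c(5, 21, 50, 99, 247, 500, 1000, 5000)
  ppv <- vapply(grid, function(p) prevalence_adjust(conf, p)$ppv, numeric(1))
  expect_true(all(diff(ppv) > 0))
  ## prevalence equal to the observed cancer fraction reproduces the
  ## observed PPV within rounding
  n <- 324 + 2 + 202 + 1778
  prev <- round(100000 * (324 + 202) / n)
  m <- prevalence_adjust(conf, prev)
  obs_ppv <- 100 * 324 / (324 + 2)
  expect_lt(abs(m$ppv - obs_ppv), 0.1)
})

test_that("stagewise_auc orders stages and handles degenerate pools", {
  set.seed(31)
  healthy <- rnorm(300, 0, 1)
  stages <- rep(c("I", "II", "III", "IV"), each = 100)
  ## identical distributions -> AUCs within a narrow band of each other
  sc_null <- rnorm(400, 0, 1)
  res0 <- stagewise_auc(sc_null, stages, healthy)
  expect_lt(max(res0$auc) - min(res0$auc), 0.1)
  ## separated stage I -> AUC 1
  sc <- ifelse(stages == "I", 10, rnorm(200))
  res1 <- stagewise_auc(sc, stages, healthy)
  expect_equal(res1$auc[res1$stage == "I"], 1.0)
  ## empty stage skipped with a message
  res2 <- suppressMessages(stagewise_auc(sc_null[1:150], stages[1:150],
                                         healthy))
  expect_false("IV" %in% res2$stage)
  expect_error(stagewise_auc(1:3, c("I", "I", "I"), numeric(0)), "empty")
})

test_that("stage factors in the simulator yield non-decreasing stage AUCs", {
  aucs <- matrix(NA_real_, 6, 4, dimnames = list(NULL, c("I", "II", "III",
                                                         "IV")))
  for (s in 1:6) {
    cfg <- clean_config(
      n_per_group = c(healthy = 120, CRC = 120, GC = 0, EC = 0),
      n_true_egps = 40, frac_differential = 0.5, n_signature = 0,
      effect_log2fc = 1, noise_sd = 0.5,
      stage_weights = list(CRC = c(I = .25, II = .25, III = .25, IV = .25),
                           GC = default_stage_weights()$GC,
                           EC = default_stage_weights()$EC),
      seed = 900L + s)
    ch <- generate_cohort(cfg)
    egp <- generate_egp_matrix(ch, ch$truth, cfg, apply_lod = FALSE)
    ## simple planted-marker score: mean |log2 level| over differential EGPs
    d <- unique(ch$truth$differential$species_id)
    sc <- colMeans(abs(log2(pmax(egp$values[d, , drop = FALSE], 1e-6))))
    cancer <- ch$subjects$group == "CRC"
    res <- stagewise_auc(sc[cancer], ch$subjects$stage[cancer], sc[!cancer])
    aucs[s, res$stage] <- res$auc
  }
  med <- apply(aucs, 2, median, na.rm = TRUE)
  expect_true(all(diff(med) >= -0.02))   # non-decreasing up to noise
  expect_gt(med[["IV"]], med[["I"]])
})

test_that("two_stage_classify follows the detect-then-type logic", {
  ## perfectly separated clusters -> all per-type accuracies 100
  truth <- c(rep("CRC", 40), rep("GC", 30), rep("EC", 10), rep("healthy", 60))
  scores <- c(rep(10, 80), rep(0, 60))
  pred <- c(rep("CRC", 40), rep("GC", 30), rep("EC", 10), rep("CRC", 60))
  res <- two_stage_classify(scores, truth, pred)
  expect_equal(res$accuracy_pct, c(100, 100, 100))
  ## healthy false negatives never enter stage 2
  expect_equal(sum(res$n_true_entering), 80L)

  ## random type model -> accuracy near chance
  set.seed(41)
  n <- 1500
  truth2 <- sample(c("CRC", "GC", "EC"), n, replace = TRUE)
  res2 <- two_stage_classify(rep(10, n), truth2,
                             sample(c("CRC", "GC", "EC"), n, replace = TRUE))
  expect_true(all(abs(res2$accuracy_pct - 100 / 3) < 5))

  ## probability-matrix input takes the argmax
  pm <- matrix(c(0.7, 0.2, 0.1,
                 0.1, 0.8, 0.1), 2, 3, byrow = TRUE,
               dimnames = list(NULL, c("CRC", "GC", "EC")))
  res3 <- two_stage_classify(c(10, 10), c("CRC", "GC"), pm)
  expect_equal(res3$accuracy_pct[1:2], c(100, 100))

  ## precision denominator option
  res4 <- two_stage_classify(c(10, 10, 10), c("CRC", "CRC", "GC"),
                             c("CRC", "GC", "GC"),
                             denominator = "precision")
  expect_equal(res4$accuracy_pct[res4$type == "GC"], 50)

  ## no stage-1 positives -> empty result with message
  expect_message(res5 <- two_stage_classify(c(0, 0), c("CRC", "GC"),
                                            c("CRC", "GC")), "no stage-1")
  expect_true(all(is.na(res5$accuracy_pct)))
})

test_that("unbalanced cohorts leave the smallest class least accurate", {
  set.seed(47)
  n <- c(CRC = 296, GC = 180, EC = 42)
  truth <- rep(names(n), n)
  x <- matrix(rnorm(sum(n) * 4), sum(n), 4)
  centers <- rbind(CRC = c(1.2, 0, 0, 0), GC = c(0, 1.2, 0, 0),
                   EC = c(0, 0, 1.2, 0))
  x <- x + centers[truth, ]
  fit <- fit_mlp(x, factor(truth), hidden = c(16), epochs = 150)
  pred <- predict(fit, x)
  res <- two_stage_classify(rep(10, sum(n)), truth, pred)
  acc <- setNames(res$accuracy_pct, res$type)
  expect_equal(names(which.min(acc)), "EC")
})

test_that("select_cutoff honors the target-specificity policy", {
  scores <- c(rep(0:9, each = 10), rep(9.5, 10))
  labels <- c(rep(0, 100), rep(1, 10))
  cut <- select_cutoff(scores, labels, target_spec = 95)
  conf <- confusion_at_cutoff(scores, labels, cut)
  expect_gte(100 * conf$tn / (conf$tn + conf$fp), 95)
  ## smallest qualifying cutoff: one step lower fails the target
  conf_lo <- confusion_at_cutoff(scores, labels, cut - 0.1)
  expect_lt(100 * conf_lo$tn / (conf_lo$tn + conf_lo$fp), 95)
})
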
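## ---------------------------------------------------------------------------
## screen_eval: CSGSA score, confusion tables, prevalence-adjusted metrics,
## stagewise ROC and two-stage cancer-type classification
## ---------------------------------------------------------------------------

#' CSGSA score transform
#'
#' `score = min(10, -log10(1 - p))`, a strictly increasing transform of the
#' predicted probability that spreads out values clustering near 1; scores
#' above 10 (p within 1e-10 of 1, including p = 1) are capped at 10. Being
#' monotone, the transform leaves ROC/AUC unchanged.
#'
#' @param p predicted values in `[0, 1]`.
#' @return scores in `[0, 10]`.
#' @export
csgsa_score <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_config("predicted values must lie in [0, 1]")
  pmin(10, -log10(1 - p))
}

#' Confusion table at a score cutoff
#'
#' Samples with `score >= cutoff` are called positive (inclusive boundary).
#'
#' @param scores numeric scores.
#' @param labels binary truth (factor or 0/1; second level / 1 = disease).
#' @param cutoff decision threshold (default 5 on the CSGSA scale).
#' @return object of class `confusion_table`: list with integer counts
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff = 5) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop_config("labels must be binary")
  pos <- scores >= cutoff
  confusion_table(tp = sum(pos & y == 1), fp = sum(pos & y == 0),
                  fn = sum(!pos & y == 1), tn = sum(!pos & y == 0))
}

#' Construct a confusion table from counts
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop_config("confusion counts must be >= 0")
  structure(as.list(counts), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("pred+", "pred-"), c("disease", "healthy")))
  print(m)
  invisible(x)
}

#' Sensitivity and specificity of a confusion table
#'
#' `sensitivity = 100 * tp / (tp + fn)`, `specificity = 100 * tn /
#' (tn + fp)`, both in percent at full precision (round for reporting).
#'
#' @param conf a [confusion_table()].
#' @return named numeric vector `c(sensitivity, specificity)` in percent.
#' @export
sens_spec <- function(conf) {
  stopifnot(inherits(conf, "confusion_table"))
  if (conf$tp + conf$fn == 0 || conf$tn + conf$fp == 0)
    stop_config("sensitivity/specificity undefined: empty truth row")
  c(sensitivity = 100 * conf$tp / (conf$tp + conf$fn),
    specificity = 100 * conf$tn / (conf$tn + conf$fp))
}

#' Project a confusion table onto a screening population
#'
#' Applies the observed sensitivity and specificity to a population of
#' `population` individuals containing `prevalence_per_100k` cases:
#' expected diseased positives are rounded to the nearest integer (half
#' away from zero) and the complements obtained by subtraction, so the
#' adjusted table sums to the population exactly. PPV and NPV are computed
#' on the adjusted table.
#'
#' @param conf observed [confusion_table()].
#' @param prevalence_per_100k cases per `population` individuals.
#' @param population population size (default 100,000).
#' @return object of class `screening_metrics`: list with `sensitivity`,
#'   `specificity` (percent), `prevalence_per_100k`, `adjusted`
#'   (confusion_table on the population), `ppv`, `npv` (percent).
#' @export
prevalence_adjust <- function(conf, prevalence_per_100k,
                              population = 100000) {
  ss <- sens_spec(conf)
  prev <- prevalence_per_100k
  if (prev <= 0) stop_config("prevalence must be > 0")
  if (prev >= population) stop_config("prevalence must be below population")
  sens <- ss[["sensitivity"]] / 100
  spec <- ss[["specificity"]] / 100
  tp <- round_half_up(prev * sens)
  fn <- prev - tp
  fp <- round_half_up((population - prev) * (1 - spec))
  tn <- (population - prev) - fp
  adj <- confusion_table(tp = tp, fp = fp, fn = fn, tn = tn)
  structure(list(
    sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]],
    prevalence_per_100k = prev, population = population, adjusted = adj,
    ppv = 100 * tp / (tp + fp), npv = 100 * tn / (tn + fn)),
    class = "screening_metrics")
}

#' @export
print.screening_metrics <- function(x, ...) {
  cat(sprintf(
    "<screening_metrics> sens %.1f%% spec %.1f%% | prevalence %d/%d\n",
    x$sensitivity, x$specificity, x$prevalence_per_100k, x$population))
  cat(sprintf("  adjusted: tp %d fp %d fn %d tn %d | PPV %.1f%% NPV %.2f%%\n",
              x$adjusted$tp, x$adjusted$fp, x$adjusted$fn, x$adjusted$tn,
              x$ppv, x$npv))
  invisible(x)
}

#' Stagewise ROC against the healthy pool
#'
#' One ROC per tumor stage, comparing that stage's scores with the healthy
#' scores — the stage-I row measures early-detection capability. Stages
#' with no samples are skipped with a message.
#'
#' @param scores scores of the cancer samples.
#' @param stages stage label per cancer sample (I-IV).
#' @param healthy_scores scores of the healthy pool.
#' @param stage_levels stage order for the output.
#' @return data.frame: stage, n_cancer, n_healthy, auc;
#'   `attr(, "curves")` holds the per-stage `roc_result`s.
#' @export
stagewise_auc <- function(scores, stages, healthy_scores,
                          stage_levels = c("I", "II", "III", "IV")) {
  stopifnot(length(scores) == length(stages))
  if (!length(healthy_scores)) stop_config("healthy pool is empty")
  rows <- list(); curves <- list()
  for (s in stage_levels) {
    sc <- scores[stages == s]
    if (!length(sc)) {
      message(sprintf("stagewise_auc: no samples in stage %s; skipped", s))
      next
    }
    r <- roc_auc(c(sc, healthy_scores),
                 c(rep(1L, length(sc)), rep(0L, length(healthy_scores))))
    rows[[s]] <- data.frame(stage = s, n_cancer = length(sc),
                            n_healthy = length(healthy_scores),
                            auc = r$auc, stringsAsFactors = FALSE)
    curves[[s]] <- r
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stage = character(0), n_cancer = integer(0),
               n_healthy = integer(0), auc = numeric(0))
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  out
}

#' Two-stage screening: cancer detection, then cancer-type assignment
#'
#' Stage 1 thresholds the CSGSA score (`score >= cutoff` is positive);
#' stage 2 assigns each stage-1 positive the cancer type with the highest
#' predicted type probability. Per-type accuracy is reported as correct
#' identifications of that type divided by (`denominator = "recall"`,
#' default) the true members of the type entering stage 2, or
#' (`"precision"`) the total predictions made for the type.
#'
#' @param binary_scores CSGSA scores for every sample.
#' @param true_type true label per sample: `"healthy"` or a cancer type.
#' @param type_pred predicted cancer type per sample (character), or a
#'   probability matrix with one column per type (argmax is taken); comes
#'   from a type model trained on cancer-only training samples.
#' @param cutoff stage-1 threshold.
#' @param types cancer-type universe.
#' @param denominator accuracy convention (see above).
#' @return object of class `type_classification`: data.frame with columns
#'   type, n_true_entering, n_predicted, n_correct, accuracy_pct.
#' @export
two_stage_classify <- function(binary_scores, true_type, type_pred,
                               cutoff = 5, types = c("CRC", "GC", "EC"),
                               denominator = c("recall", "precision")) {
  denominator <- match.arg(denominator)
  stopifnot(length(binary_scores) == length(true_type))
  if (is.matrix(type_pred) || is.data.frame(type_pred)) {
    type_pred <- colnames(type_pred)[max.col(as.matrix(type_pred),
                                             ties.method = "first")]
  }
  stopifnot(length(type_pred) == length(true_type))
  pos <- binary_scores >= cutoff
  if (!any(pos)) {
    message("two_stage_classify: no stage-1 positives")
    out <- data.frame(type = types, n_true_entering = 0L, n_predicted = 0L,
                      n_correct = 0L, accuracy_pct = NA_real_)
    class(out) <- c("type_classification", "data.frame")
    return(out)
  }
  tt <- true_type[pos]; pt <- type_pred[pos]
  rows <- lapply(types, function(ty) {
    n_true <- sum(tt == ty)
    n_pred <- sum(pt == ty)
    n_cor <- sum(tt == ty & pt == ty)
    den <- if (denominator == "recall") n_true else n_pred
    data.frame(type = ty, n_true_entering = n_true, n_predicted = n_pred,
               n_correct = n_cor,
               accuracy_pct = if (den > 0) 100 * n_cor / den else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("type_classification", "data.frame")
  out
}

#' Bundled observed screening confusion tables
#'
#' Reference observed-sample confusion counts for the three cancer types
#' (CRC, GC, EC versus healthy) together with the screening prevalences
#' used for population projection. Shipped as plain CSV in `extdata`; used
#' by the acceptance harness to exercise [sens_spec()] and
#' [prevalence_adjust()] end to end.
#'
#' @return data.frame: cancer_type, tp, fp, fn, tn, prevalence_per_100k.
#' @export
observed_screening_counts <- function() {
  path <- system.file("extdata", "screening_observed_counts.csv",
                      package = "csgsa", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Smallest cutoff reaching a target specificity
#'
#' Optional selector for the decision threshold: scans candidate cutoffs
#' over training scores and returns the smallest one whose specificity
#' meets `target_spec` — the "minimize false positives" policy. Falls back
#' to the maximum candidate when none qualifies.
#'
#' @param scores training-sample scores.
#' @param labels binary truth.
#' @param target_spec target specificity in percent.
#' @param grid candidate cutoffs.
#' @return the selected cutoff.
#' @export
select_cutoff <- function(scores, labels, target_spec = 99.9,
                          grid = seq(0, 10, by = 0.1)) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  for (cut in grid) {
    conf <- confusion_at_cutoff(scores, y, cut)
    if (conf$tn + conf$fp == 0) next
    if (100 * conf$tn / (conf$tn + conf$fp) >= target_spec) return(cut)
  }
  max(grid)
}
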
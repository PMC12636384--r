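## ---------------------------------------------------------------------------
## classify: model tiers, PCA reduction, repeated-split evaluation, ROC
## ---------------------------------------------------------------------------

#' Specification of a classification run
#'
#' @param model_id 1 (nine tumor markers), 2 (markers + the two signature
#'   glycopeptides), or 3 (markers + glycopeptides + PCA-reduced EGPs).
#' @param algorithm `"nn"` (feed-forward network, [fit_mlp()]) or `"gbt"`
#'   (gradient-boosted trees, [fit_gbt()]).
#' @param n_components principal components kept from the EGP block
#'   (Model 3 only).
#' @param train_fraction fraction of samples in each training split.
#' @param n_repeats number of independent random splits.
#' @param seed integer seed controlling splits and learner initialization.
#' @param learner_args optional list of extra arguments for the learner.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(model_id, algorithm = c("nn", "gbt"),
                       n_components = 100, train_fraction = 0.7,
                       n_repeats = 10, seed = 1L, learner_args = list()) {
  algorithm <- match.arg(algorithm)
  if (!model_id %in% 1:3) stop_config("model_id must be 1, 2 or 3")
  assert_fraction(train_fraction, "train_fraction", open = TRUE)
  if (n_repeats < 1) stop_config("n_repeats must be >= 1")
  structure(list(model_id = as.integer(model_id), algorithm = algorithm,
                 n_components = as.integer(n_components),
                 train_fraction = train_fraction,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 learner_args = learner_args),
            class = "model_spec")
}

#' Assemble the feature blocks for a model tier
#'
#' Model 1: the nine tumor markers, each entered as `log10(value + eps)`
#' with `eps` the smallest positive observed value of that marker. Model 2
#' adds the two signature glycopeptide levels (untransformed normalized
#' levels). Model 3 additionally routes the EGP matrix to PCA reduction at
#' training time. Column order and names are deterministic.
#'
#' @param model_id model tier (1, 2 or 3).
#' @param marker_table data.frame containing the nine [marker_names()]
#'   columns (rows = samples).
#' @param glyco_levels matrix/data.frame with two columns of signature
#'   glycopeptide levels (required for models 2-3).
#' @param egp_matrix a [feature_matrix] of normalized EGP levels (required
#'   for model 3); its columns must align with the marker rows.
#' @return object of class `model_features`: list with `base` (numeric
#'   matrix, samples x columns), `egp` (samples x features matrix or NULL),
#'   `model_id`.
#' @export
assemble_features <- function(model_id, marker_table, glyco_levels = NULL,
                              egp_matrix = NULL) {
  if (!model_id %in% 1:3) stop_config("model_id must be 1, 2 or 3")
  mk <- marker_names()
  miss <- setdiff(mk, colnames(marker_table))
  if (length(miss))
    stop_config("marker_table is missing marker column(s): %s",
                paste(miss, collapse = ", "))
  m <- as.matrix(marker_table[, mk, drop = FALSE])
  eps <- apply(m, 2L, function(x) {
    pos <- x[x > 0]
    if (length(pos)) min(pos) else 1
  })
  base <- sweep(m, 2L, eps, "+")
  base <- log10(base)
  colnames(base) <- paste0("log10_", mk)

  if (model_id >= 2L) {
    if (is.null(glyco_levels))
      stop_config("model %d needs glyco_levels (signature glycopeptides)",
                  model_id)
    gl <- as.matrix(glyco_levels)
    if (ncol(gl) != 2L)
      stop_config("glyco_levels must have exactly 2 columns")
    if (is.null(colnames(gl))) colnames(gl) <- c("AT271_FSG", "MG70_FSG")
    if (nrow(gl) != nrow(base))
      stop_config("glyco_levels rows (%d) != marker rows (%d)",
                  nrow(gl), nrow(base))
    base <- cbind(base, gl)
  }
  egp <- NULL
  if (model_id == 3L) {
    if (is.null(egp_matrix)) stop_config("model 3 needs egp_matrix")
    egp <- t(egp_matrix$values)
    if (nrow(egp) != nrow(base))
      stop_config("egp_matrix samples (%d) != marker rows (%d)",
                  nrow(egp), nrow(base))
  }
  structure(list(base = base, egp = egp, model_id = as.integer(model_id)),
            class = "model_features")
}

## standardize columns using train statistics; zero-variance columns get
## unit scale so they pass through as constants
.col_standardizer <- function(train) {
  mu <- colMeans(train)
  sdv <- apply(train, 2L, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv,
       apply = function(x) sweep(sweep(x, 2L, mu), 2L, sdv, "/"))
}

#' PCA reduction fitted on the training block only
#'
#' Standardizes the training block (train means/SDs), fits principal
#' components there, and projects both blocks with the training loadings —
#' the honest-evaluation variant that keeps test information out of the
#' reduction. When the training block has fewer informative directions
#' than `n_components`, the actual count is reduced with a warning.
#'
#' @param train_block,test_block numeric matrices (samples x features) on
#'   the raw scale.
#' @param n_components components requested.
#' @return list: `train`, `test` (score matrices), `sdev` (component SDs,
#'   non-increasing), `rotation`, `center`, `scale`, `n_used`.
#' @export
pca_reduce <- function(train_block, test_block, n_components = 100) {
  train_block <- as.matrix(train_block); test_block <- as.matrix(test_block)
  if (nrow(train_block) < 2L) stop_config("pca_reduce needs >= 2 train rows")
  std <- .col_standardizer(train_block)
  ztr <- std$apply(train_block)
  pc <- prcomp(ztr, center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-9)
  n_used <- min(n_components, rank)
  if (n_used < n_components)
    warning(sprintf("rank %d below requested %d components; using %d",
                    rank, n_components, n_used), call. = FALSE)
  rot <- pc$rotation[, seq_len(n_used), drop = FALSE]
  tr <- ztr %*% rot
  te <- std$apply(test_block) %*% rot
  colnames(tr) <- colnames(te) <- sprintf("PC%03d", seq_len(n_used))
  list(train = tr, test = te, sdev = pc$sdev[seq_len(n_used)],
       rotation = rot, center = std$mu, scale = std$sd, n_used = n_used)
}

## builds the learner design matrix for one split, training-fitted only
.split_design <- function(features, train_idx, spec) {
  base <- features$base
  stdb <- .col_standardizer(base[train_idx, , drop = FALSE])
  xtr <- stdb$apply(base[train_idx, , drop = FALSE])
  xte <- stdb$apply(base[-train_idx, , drop = FALSE])
  if (!is.null(features$egp) && features$model_id == 3L) {
    red <- suppressWarnings(
      pca_reduce(features$egp[train_idx, , drop = FALSE],
                 features$egp[-train_idx, , drop = FALSE],
                 n_components = min(spec$n_components,
                                    length(train_idx) - 1L)))
    xtr <- cbind(xtr, red$train)
    xte <- cbind(xte, red$test)
  }
  list(train = xtr, test = xte)
}

#' Repeated stratified 70/30 evaluation with pooled test predictions
#'
#' Draws `n_repeats` independent stratified random splits. Per repeat:
#' standardize the base block on training rows, reduce the EGP block with
#' training-fitted PCA (Model 3), train the learner, and record held-out
#' probabilities. Predictions from all repeats are pooled; the full split
#' bookkeeping is kept so leakage can be audited.
#'
#' @param features a `model_features` from [assemble_features()] (or a
#'   plain matrix used as the base block).
#' @param labels binary labels over the samples (factor or 0/1; the second
#'   level / 1 is the positive class).
#' @param spec a [model_spec()].
#' @return object of class `pooled_predictions`: data.frame with columns
#'   `sample`, `repeat_id`, `y_true`, `p_hat`; `attr(, "splits")` lists
#'   each repeat's training indices.
#' @export
repeated_split_eval <- function(features, labels, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.matrix(features))
    features <- structure(list(base = features, egp = NULL, model_id = 1L),
                          class = "model_features")
  y <- if (is.factor(labels)) labels else factor(labels)
  if (nlevels(y) != 2L) stop_config("labels must have exactly 2 classes")
  n <- nrow(features$base)
  stopifnot(length(y) == n)
  ids <- rownames(features$base) %||% as.character(seq_len(n))
  if (is.null(rownames(features$base))) ids <- as.character(seq_len(n))

  set.seed(child_seed(spec$seed, "splits"))
  splits <- vector("list", spec$n_repeats)
  preds <- vector("list", spec$n_repeats)
  for (r in seq_len(spec$n_repeats)) {
    for (attempt in 1:10) {
      tr <- unlist(lapply(split(seq_len(n), y), function(ix)
        sample(ix, round(spec$train_fraction * length(ix)))),
        use.names = FALSE)
      tr <- sort(tr)
      if (length(unique(y[tr])) == 2L && length(tr) < n) break
      message(sprintf("repeat %d: degenerate split, redrawing", r))
    }
    splits[[r]] <- tr
    des <- .split_design(features, tr, spec)
    fit <- switch(spec$algorithm,
      nn = do.call(fit_mlp, c(list(x = des$train, y = y[tr]),
                              spec$learner_args)),
      gbt = do.call(fit_gbt, c(list(x = des$train, y = y[tr]),
                               spec$learner_args)))
    p <- predict(fit, des$test)
    te <- setdiff(seq_len(n), tr)
    preds[[r]] <- data.frame(sample = ids[te], repeat_id = r,
                             y_true = as.integer(y[te]) - 1L,
                             p_hat = as.numeric(p),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, preds)
  rownames(out) <- NULL
  attr(out, "splits") <- splits
  attr(out, "levels") <- levels(y)
  class(out) <- c("pooled_predictions", "data.frame")
  out
}

#' ROC curve and AUC from pooled predictions
#'
#' Threshold-sweep ROC with tied scores advanced as one simultaneous step;
#' AUC is the trapezoidal area, equal to the Mann-Whitney probability with
#' half-credit for ties.
#'
#' @param pooled a `pooled_predictions`, or a numeric vector of scores
#'   (then `labels` is required).
#' @param labels binary labels when `pooled` is a plain score vector.
#' @return object of class `roc_result`: list with `auc`, `curve`
#'   (data.frame fpr/tpr including the (0,0) and (1,1) endpoints), and
#'   `n_pooled`.
#' @export
roc_auc <- function(pooled, labels = NULL) {
  if (inherits(pooled, "pooled_predictions")) {
    scores <- pooled$p_hat; y <- pooled$y_true
  } else {
    if (is.null(labels)) stop_config("labels required for raw scores")
    scores <- as.numeric(pooled)
    y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  }
  if (length(unique(y)) < 2L)
    stop_config("ROC undefined: pool contains a single class")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  grp_end <- c(which(diff(ss) != 0), length(ss))   # tie groups step together
  tp <- cumsum(ys)[grp_end]
  fp <- cumsum(1 - ys)[grp_end]
  tpr <- c(0, tp / n1); fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr),
                 n_pooled = length(y)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f over %d pooled predictions\n",
              x$auc, x$n_pooled))
  invisible(x)
}
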
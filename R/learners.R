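## ---------------------------------------------------------------------------
## learners: feed-forward neural network and gradient-boosted trees.
## The environment ships no NN/boosting package, so both are implemented
## here behind the single train/predict interface used by classify.
## ---------------------------------------------------------------------------

## --- feed-forward neural network (ReLU hidden layers, softmax output) ------

#' Train a small feed-forward neural network
#'
#' Fully connected net with ReLU hidden layers and a softmax output,
#' trained by full-batch Adam on the cross-entropy loss with L2 weight
#' decay. A stratified validation slice of the training data drives early
#' stopping (best-validation weights are kept). Deterministic given the
#' caller's RNG state.
#'
#' @param x numeric matrix (rows = samples); callers standardize.
#' @param y factor (>= 2 levels) or 0/1 vector of class labels.
#' @param hidden integer sizes of the hidden layers.
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param l2 L2 penalty on weights.
#' @param val_frac fraction of rows held out for early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @return object of class `csgsa_mlp`.
#' @export
fit_mlp <- function(x, y, hidden = c(32, 16), epochs = 300, lr = 0.01,
                    l2 = 1e-4, val_frac = 0.15, patience = 30) {
  x <- as.matrix(x)
  if (!is.factor(y)) y <- factor(y)
  levels_y <- levels(y)
  k <- length(levels_y)
  if (k < 2L) stop_config("fit_mlp needs >= 2 classes")
  n <- nrow(x)
  yi <- as.integer(y)
  Y <- matrix(0, n, k); Y[cbind(seq_len(n), yi)] <- 1

  ## stratified validation slice
  val <- unlist(lapply(split(seq_len(n), yi), function(ix) {
    nv <- floor(length(ix) * val_frac)
    if (nv >= 1L && length(ix) - nv >= 1L) sample(ix, nv) else integer(0)
  }), use.names = FALSE)
  tr <- setdiff(seq_len(n), val)
  if (!length(val)) { val <- tr }   # tiny data: monitor training loss

  sizes <- c(ncol(x), hidden, k)
  L <- length(sizes) - 1L
  W <- lapply(seq_len(L), function(l)
    matrix(rnorm(sizes[l] * sizes[l + 1L], 0, sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1L]))
  b <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1L]))

  forward <- function(X) {
    acts <- vector("list", L + 1L); acts[[1L]] <- X
    for (l in seq_len(L)) {
      z <- acts[[l]] %*% W[[l]]
      z <- sweep(z, 2L, b[[l]], "+")
      acts[[l + 1L]] <- if (l < L) pmax(z, 0) else z
    }
    acts
  }
  softmax <- function(z) {
    z <- z - apply(z, 1L, max)
    e <- exp(z)
    e / rowSums(e)
  }
  xent <- function(P, Yb) -mean(log(pmax(P[Yb == 1], 1e-12)))

  ## Adam state
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  Xtr <- x[tr, , drop = FALSE]; Ytr <- Y[tr, , drop = FALSE]
  Xv <- x[val, , drop = FALSE]; Yv <- Y[val, , drop = FALSE]
  best <- list(loss = Inf, W = W, b = b)
  stall <- 0L
  ntr <- nrow(Xtr)
  for (ep in seq_len(epochs)) {
    acts <- forward(Xtr)
    P <- softmax(acts[[L + 1L]])
    delta <- (P - Ytr) / ntr
    for (l in rev(seq_len(L))) {
      gW <- crossprod(acts[[l]], delta) + l2 * W[[l]]
      gb <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
      }
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
      cor1 <- 1 - b1^ep; cor2 <- 1 - b2^ep
      W[[l]] <- W[[l]] - lr * (mW[[l]] / cor1) / (sqrt(vW[[l]] / cor2) + eps)
      b[[l]] <- b[[l]] - lr * (mb[[l]] / cor1) / (sqrt(vb[[l]] / cor2) + eps)
    }
    Pv <- softmax(forward(Xv)[[L + 1L]])
    vl <- xent(Pv, Yv)
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, W = W, b = b)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  structure(list(W = best$W, b = best$b, sizes = sizes,
                 levels = levels_y), class = "csgsa_mlp")
}

#' Predict class probabilities from a fitted network
#'
#' @param object a `csgsa_mlp`.
#' @param newdata matrix on the training scale.
#' @param ... unused.
#' @return for two classes, the probability of the second level; otherwise
#'   a matrix of class probabilities (columns = levels).
#' @export
predict.csgsa_mlp <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  L <- length(object$W)
  A <- X
  for (l in seq_len(L)) {
    Z <- sweep(A %*% object$W[[l]], 2L, object$b[[l]], "+")
    A <- if (l < L) pmax(Z, 0) else Z
  }
  Z <- A - apply(A, 1L, max)
  P <- exp(Z) / rowSums(exp(Z))
  colnames(P) <- object$levels
  if (length(object$levels) == 2L) P[, 2L] else P
}

## --- gradient-boosted trees -------------------------------------------------

## one regression tree fit to (gradient, hessian) with xgboost-style gain;
## returned as a flat list of nodes
.gbt_tree <- function(x, g, h, idx, depth, max_depth, lambda, min_child) {
  leaf <- function() list(leaf = TRUE, value = -sum(g[idx]) /
                            (sum(h[idx]) + lambda))
  if (depth >= max_depth || length(idx) < 2 * min_child) return(leaf())
  G <- sum(g[idx]); H <- sum(h[idx])
  base <- G^2 / (H + lambda)
  best <- list(gain = 1e-10)
  for (j in seq_len(ncol(x))) {
    xv <- x[idx, j]
    o <- order(xv)
    xs <- xv[o]; gs <- g[idx][o]; hs <- h[idx][o]
    cg <- cumsum(gs); ch <- cumsum(hs)
    nn <- length(xs)
    cand <- which(xs[-nn] < xs[-1])      # split between distinct values
    cand <- cand[cand >= min_child & nn - cand >= min_child]
    if (!length(cand)) next
    gain <- cg[cand]^2 / (ch[cand] + lambda) +
      (G - cg[cand])^2 / (H - ch[cand] + lambda) - base
    w <- which.max(gain)
    if (gain[w] > best$gain)
      best <- list(gain = gain[w], feature = j,
                   threshold = (xs[cand[w]] + xs[cand[w] + 1L]) / 2)
  }
  if (is.null(best$feature)) return(leaf())
  go_left <- x[idx, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = .gbt_tree(x, g, h, idx[go_left], depth + 1L, max_depth,
                        lambda, min_child),
       right = .gbt_tree(x, g, h, idx[!go_left], depth + 1L, max_depth,
                         lambda, min_child))
}

.gbt_tree_predict <- function(node, x) {
  if (node$leaf) return(rep(node$value, nrow(x)))
  out <- numeric(nrow(x))
  left <- x[, node$feature] <= node$threshold
  if (any(left)) out[left] <- .gbt_tree_predict(node$left,
                                                x[left, , drop = FALSE])
  if (any(!left)) out[!left] <- .gbt_tree_predict(node$right,
                                                  x[!left, , drop = FALSE])
  out
}

#' Train gradient-boosted trees (binary logistic loss)
#'
#' Newton boosting over depth-limited regression trees: each round fits a
#' tree to the logistic gradient/hessian and adds its shrunken leaf values
#' to the log-odds. A compact substitute for the usual gradient-boosting
#' libraries with the same loss and split-gain formulation.
#'
#' @param x numeric matrix (rows = samples).
#' @param y factor with 2 levels or 0/1 vector.
#' @param nrounds boosting rounds.
#' @param eta shrinkage.
#' @param max_depth tree depth.
#' @param lambda L2 on leaf values.
#' @param min_child minimum rows per leaf.
#' @param subsample row-subsampling fraction per round.
#' @return object of class `csgsa_gbt`.
#' @export
fit_gbt <- function(x, y, nrounds = 100, eta = 0.1, max_depth = 3,
                    lambda = 1, min_child = 5, subsample = 0.8) {
  x <- as.matrix(x)
  if (!is.factor(y)) y <- factor(y)
  if (nlevels(y) != 2L) stop_config("fit_gbt handles binary labels")
  yb <- as.integer(y) - 1L
  n <- nrow(x)
  f <- rep(qlogis(max(min(mean(yb), 1 - 1e-6), 1e-6)), n)
  trees <- vector("list", nrounds)
  for (r in seq_len(nrounds)) {
    p <- plogis(f)
    g <- p - yb
    h <- pmax(p * (1 - p), 1e-6)
    idx <- if (subsample < 1) sample(n, max(2 * min_child,
                                            floor(subsample * n)))
           else seq_len(n)
    tree <- .gbt_tree(x, g, h, idx, 0L, max_depth, lambda, min_child)
    trees[[r]] <- tree
    f <- f + eta * .gbt_tree_predict(tree, x)
  }
  structure(list(trees = trees, eta = eta, base = f[1] * 0 +
                   qlogis(max(min(mean(yb), 1 - 1e-6), 1e-6)),
                 levels = levels(y)), class = "csgsa_gbt")
}

#' Predict probabilities from boosted trees
#'
#' @param object a `csgsa_gbt`.
#' @param newdata numeric matrix.
#' @param ... unused.
#' @return probability of the second factor level.
#' @export
predict.csgsa_gbt <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  f <- rep(object$base, nrow(X))
  for (tree in object$trees) f <- f + object$eta * .gbt_tree_predict(tree, X)
  plogis(f)
}
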
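# Weighted binary CART with the Gini impurity criterion. Supports random
# feature subsetting per split (mtry) so the same routine backs the single
# decision tree, the bagged random forest, and the boosted stumps.
#
# x: numeric matrix (n x p); y: 0/1; w: non-negative sample weights.

tree_fit <- function(x, y, w = NULL, max_depth = 5L, min_split = 2L,
                     mtry = ncol(x)) {
  n <- nrow(x)
  if (is.null(w)) w <- rep(1 / n, n)
  grow <- function(idx, depth) {
    wi <- w[idx]
    p1 <- sum(wi * y[idx]) / sum(wi)
    if (depth >= max_depth || length(idx) < min_split ||
        p1 <= 0 || p1 >= 1)
      return(list(leaf = TRUE, prob = p1))
    feats <- if (mtry < ncol(x)) sample.int(ncol(x), mtry) else
      seq_len(ncol(x))
    best <- NULL
    for (j in feats) {
      sp <- .best_split(x[idx, j], y[idx], wi)
      if (!is.null(sp) && (is.null(best) || sp$gini < best$gini)) {
        best <- sp; best$j <- j
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, prob = p1))
    left <- idx[x[idx, best$j] <= best$thr]
    right <- idx[x[idx, best$j] > best$thr]
    if (!length(left) || !length(right))
      return(list(leaf = TRUE, prob = p1))
    list(leaf = FALSE, j = best$j, thr = best$thr,
         left = grow(left, depth + 1L), right = grow(right, depth + 1L))
  }
  structure(list(root = grow(seq_len(n), 0L)), class = "phenoENM_tree")
}

# Weighted Gini of the best threshold on one feature, via cumulative sums
# over the sorted values; candidate thresholds are midpoints between
# distinct consecutive values.
.best_split <- function(xj, yj, wj) {
  ord <- order(xj)
  xs <- xj[ord]; ys <- yj[ord]; ws <- wj[ord]
  n <- length(xs)
  if (n < 2L) return(NULL)
  cw <- cumsum(ws)
  cwy <- cumsum(ws * ys)
  W <- cw[n]; WY <- cwy[n]
  cand <- which(diff(xs) > 0)          # split after position i
  if (!length(cand)) return(NULL)
  wl <- cw[cand]; wr <- W - wl
  p1l <- cwy[cand] / wl
  p1r <- (WY - cwy[cand]) / wr
  gini <- wl * 2 * p1l * (1 - p1l) + wr * 2 * p1r * (1 - p1r)
  k <- which.min(gini)
  i <- cand[k]
  list(thr = (xs[i] + xs[i + 1]) / 2, gini = gini[k])
}

tree_predict <- function(tree, x) {
  x <- as.matrix(x)
  out <- numeric(nrow(x))
  walk <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$prob; return() }
    go_left <- x[idx, node$j] <= node$thr
    walk(node$left, idx[go_left])
    walk(node$right, idx[!go_left])
  }
  walk(tree$root, seq_len(nrow(x)))
  out
}

# --- random forest: bagged Gini trees, one random feature per split -----

forest_fit <- function(x, y, n_trees = 100L, max_depth = 5L,
                       min_split = 2L, mtry = 1L) {
  n <- nrow(x)
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- tree_fit(x[idx, , drop = FALSE], y[idx],
                           max_depth = max_depth, min_split = min_split,
                           mtry = mtry)
  }
  structure(list(trees = trees), class = "phenoENM_forest")
}

forest_predict <- function(forest, x) {
  preds <- vapply(forest$trees, tree_predict, numeric(nrow(as.matrix(x))),
                  x = x)
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

# --- AdaBoost, SAMME.R variant on depth-1 stumps ------------------------
#
# Each iteration fits a weighted stump, and sample weights are updated
# with the real-valued (probability-based) exponential-loss rule; the
# final score is the average of the per-stump half-log-odds, mapped to a
# probability with the logistic function.

adaboost_fit <- function(x, y, n_iter = 50L, max_depth = 1L) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  eps <- .Machine$double.eps
  stumps <- vector("list", n_iter)
  used <- 0L
  for (m in seq_len(n_iter)) {
    stump <- tree_fit(x, y, w = w, max_depth = max_depth, min_split = 2L)
    p1 <- pmin(pmax(tree_predict(stump, x), eps), 1 - eps)
    # y coded +1/-1; weight update exp(-(1/2) * ycode * log(p1/p0))
    ycode <- ifelse(y == 1, 1, -1)
    ew <- -0.5 * ycode * (log(p1) - log(1 - p1))
    w <- w * exp(ew)
    if (!all(is.finite(w)) || sum(w) <= 0) break
    w <- w / sum(w)
    used <- m
    stumps[[m]] <- stump
  }
  structure(list(stumps = stumps[seq_len(used)]),
            class = "phenoENM_adaboost")
}

adaboost_predict <- function(model, x) {
  eps <- .Machine$double.eps
  n <- nrow(as.matrix(x))
  h <- numeric(n)
  for (stump in model$stumps) {
    p1 <- pmin(pmax(tree_predict(stump, x), eps), 1 - eps)
    h <- h + 0.5 * (log(p1) - log(1 - p1))
  }
  h <- h / length(model$stumps)
  plogis(2 * h)
}
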
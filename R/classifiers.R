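#' The nine classifier specifications
#'
#' Returns the fixed ensemble members with their hyperparameters:
#' * `GLM` — additive logistic regression on mPPT and mT_min (no
#'   interaction);
#' * `KNC` — k-nearest neighbours, `k = 5`, equal weights, Euclidean
#'   distance;
#' * `GPC` — Gaussian process classifier with RBF kernel
#'   `K(x, x') = alpha^2 exp(-0.5 l^-2 (x - x')^2)`; scale and length
#'   chosen by marginal-likelihood maximization from a (1, 1) start;
#' * `DTC` — decision tree, Gini criterion, max depth 5, minimum 2
#'   samples per group;
#' * `RFC` — random forest of 100 such trees;
#' * `ANN` — one hidden layer of 100 ReLU nodes, gradient training,
#'   regularization `alpha = 1`;
#' * `ABC` — AdaBoost, SAMME.R variant, max 50 iterations, depth-1
#'   stumps;
#' * `NBC` — Gaussian naive Bayes;
#' * `QDA` — quadratic discriminant analysis (per-class covariance).
#'
#' @return named list of `ClassifierSpec` objects.
#' @export
classifier_specs <- function() {
  mk <- function(algorithm, ...) {
    structure(list(algorithm = algorithm, hyperparameters = list(...)),
              class = "ClassifierSpec")
  }
  list(
    GLM = mk("GLM"),
    KNC = mk("KNC", k = 5L),
    GPC = mk("GPC", optimize = TRUE),
    DTC = mk("DTC", max_depth = 5L, min_split = 2L),
    RFC = mk("RFC", n_trees = 100L, max_depth = 5L, min_split = 2L,
             mtry = 1L),
    ANN = mk("ANN", n_hidden = 100L, alpha = 1, max_iter = 400L),
    ABC = mk("ABC", n_iter = 50L, max_depth = 1L),
    NBC = mk("NBC"),
    QDA = mk("QDA"))
}

.env_vars <- c("mPPT", "mT_min")

#' Standardize covariates to zero mean and unit SD
#'
#' Estimates per-variable mean and standard deviation and rescales the
#' covariate columns; the parameters are reused unchanged on hold-out data
#' and on projection grids via [apply_scaler()].
#'
#' @param samples environmental sample data.frame with `mPPT`, `mT_min`.
#' @param variables columns to standardize.
#' @return list with `params` (a `ScalerParams`: `center`, `scale`) and
#'   `data` (standardized samples).
#' @export
standardize <- function(samples, variables = .env_vars) {
  stopifnot(nrow(samples) >= 2)
  center <- vapply(variables, function(v) mean(samples[[v]]), 0)
  scale <- vapply(variables, function(v) sd(samples[[v]]), 0)
  zero <- scale == 0 | !is.finite(scale)
  if (any(zero))
    stop("degenerate input: zero variance in variable(s) ",
         paste(variables[zero], collapse = ", "), call. = FALSE)
  params <- structure(list(center = center, scale = scale,
                           variables = variables),
                      class = "ScalerParams")
  list(params = params, data = apply_scaler(params, samples))
}

#' @rdname standardize
#' @param params a `ScalerParams`.
#' @export
apply_scaler <- function(params, samples) {
  for (v in params$variables)
    samples[[v]] <- (samples[[v]] - params$center[[v]]) / params$scale[[v]]
  samples
}

#' Stratified train/test split
#'
#' Splits the labeled samples into training and test sets, sampling within
#' each label class so the presence/pseudoabsence proportions match the
#' overall data to within one sample.
#'
#' @param samples labeled sample data.frame (`label` in 0/1).
#' @param train_frac fraction of each class assigned to training
#'   (default 0.66).
#' @param seed integer RNG seed.
#' @return list with integer index vectors `train` and `test`
#'   (disjoint, exhaustive).
#' @export
stratified_split <- function(samples, train_frac = 0.66, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  tab <- table(samples$label)
  if (length(tab) < 2 || any(tab < 2))
    stop("split error: need at least 2 samples of each label",
         call. = FALSE)
  withr::with_seed(as.integer(seed), {
    train <- integer(0)
    for (lv in names(tab)) {
      idx <- which(samples$label == as.integer(lv))
      n_tr <- round(train_frac * length(idx))
      n_tr <- max(1L, min(length(idx) - 1L, n_tr))
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(nrow(samples)), train))
  })
}

#' Fit one classifier specification
#'
#' @param spec a `ClassifierSpec` from [classifier_specs()].
#' @param train standardized, labeled sample data.frame.
#' @param seed integer seed for stochastic learners (RFC bootstraps, ANN
#'   initialization); ignored by deterministic ones.
#' @return fitted model object; see [predict_probability()].
#' @export
fit_model <- function(spec, train, seed = 1L) {
  x <- as.matrix(train[, .env_vars])
  y <- train$label
  if (length(unique(y)) < 2)
    stop("both labels must be present in the training data")
  hp <- spec$hyperparameters
  model <- switch(spec$algorithm,
    GLM = glm(label ~ mPPT + mT_min, family = binomial(),
              data = train[, c(.env_vars, "label")]),
    KNC = knn_fit(x, y, k = hp$k),
    GPC = gpc_fit(x, y, optimize = hp$optimize),
    DTC = tree_fit(x, y, max_depth = hp$max_depth,
                   min_split = hp$min_split),
    RFC = withr::with_seed(as.integer(seed),
      forest_fit(x, y, n_trees = hp$n_trees, max_depth = hp$max_depth,
                 min_split = hp$min_split, mtry = hp$mtry)),
    ANN = ann_fit(x, y, n_hidden = hp$n_hidden, alpha = hp$alpha,
                  max_iter = hp$max_iter, seed = seed),
    ABC = adaboost_fit(x, y, n_iter = hp$n_iter,
                       max_depth = hp$max_depth),
    NBC = nbc_fit(x, y),
    QDA = qda_fit(x, y),
    stop("unknown algorithm: ", spec$algorithm))
  structure(list(algorithm = spec$algorithm, fit = model),
            class = "phenoENM_model")
}

# Probability of presence from one fitted model on a standardized matrix.
.model_prob <- function(model, x) {
  p <- switch(model$algorithm,
    GLM = as.vector(predict(model$fit,
      newdata = as.data.frame(x), type = "response")),
    KNC = knn_predict(model$fit, x),
    GPC = gpc_predict(model$fit, x),
    DTC = tree_predict(model$fit, x),
    RFC = forest_predict(model$fit, x),
    ANN = ann_predict(model$fit, x),
    ABC = adaboost_predict(model$fit, x),
    NBC = nbc_predict(model$fit, x),
    QDA = qda_predict(model$fit, x))
  pmin(pmax(p, 0), 1)
}

#' Per-model probabilities and their unweighted ensemble mean
#'
#' Points must already be on the standardized scale (use [apply_scaler()]
#' with the stored parameters); a scale heuristic warns if they do not
#' look standardized.
#'
#' @param models named list of fitted models (from [fit_model()] or a
#'   `FittedEnsemble`'s `$models`).
#' @param points data.frame or matrix with columns `mPPT`, `mT_min`.
#' @return list with `per_model` (matrix, one column per model) and
#'   `ensemble` (unweighted row mean).
#' @export
predict_probability <- function(models, points) {
  if (inherits(models, "FittedEnsemble")) models <- models$models
  x <- as.matrix(as.data.frame(points)[, .env_vars])
  if (!all(is.finite(x))) stop("points must be finite")
  if (nrow(x) > 1 && any(abs(colMeans(x)) > 3 | apply(x, 2, sd) > 10))
    warning("input does not look standardized; apply the stored ",
            "ScalerParams before predicting")
  per_model <- vapply(models, .model_prob, numeric(nrow(x)), x = x)
  if (is.null(dim(per_model))) per_model <- matrix(per_model, nrow = 1,
    dimnames = list(NULL, names(models)))
  list(per_model = per_model, ensemble = rowMeans(per_model))
}

#' Area under the ROC curve
#'
#' Rank-based Mann-Whitney estimate: the probability that a randomly
#' chosen presence is scored above a randomly chosen absence, with ties
#' counted one half.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores numeric scores, higher = more presence-like.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("undefined metric: AUC-ROC requires both labels", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Presentation rounding: half-up (0.005 -> 0.01), not banker's.
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5 + 1e-12) / 10^digits
}

#' Ensemble AUC summary: mean and SD of the nine per-model scores
#'
#' @param per_model_aucs numeric vector of exactly nine AUCs in `[0, 1]`.
#' @return list with `mean`, `sd` (sample SD, n-1 denominator) and their
#'   2-decimal half-up roundings `mean_rounded`, `sd_rounded`.
#' @export
ensemble_auc_summary <- function(per_model_aucs) {
  if (length(per_model_aucs) != 9L)
    stop("arity error: expected exactly nine per-model AUCs, got ",
         length(per_model_aucs), call. = FALSE)
  stopifnot(all(per_model_aucs >= 0 & per_model_aucs <= 1))
  m <- mean(per_model_aucs)
  s <- sd(per_model_aucs)
  list(mean = m, sd = s,
       mean_rounded = round_half_up(m, 2), sd_rounded = round_half_up(s, 2))
}

#' Fit the full nine-classifier ensemble
#'
#' Standardizes the covariates on the complete presence/pseudoabsence
#' table (the scaler is estimated before splitting, deliberately mirroring
#' the conventional workflow), splits 66/33 stratified by label, fits all
#' nine classifiers on the same training set, scores each by AUC-ROC on
#' the same test set, and summarizes the nine scores.
#'
#' @param samples labeled environmental samples (presences and
#'   pseudoabsences).
#' @param seed integer seed controlling the split and the stochastic
#'   learners.
#' @param train_frac training fraction (default 0.66).
#' @param specs classifier specifications (default [classifier_specs()]).
#' @return a `FittedEnsemble`: `models` (named list), `scaler`
#'   (`ScalerParams`), `auc` (named numeric), `ensemble_mean`,
#'   `ensemble_sd`, `split` (train/test indices), `seed`.
#' @export
fit_ensemble <- function(samples, seed = 1L, train_frac = 0.66,
                         specs = classifier_specs()) {
  std <- standardize(samples)
  split <- stratified_split(std$data, train_frac = train_frac, seed = seed)
  train <- std$data[split$train, , drop = FALSE]
  test <- std$data[split$test, , drop = FALSE]
  models <- list()
  for (i in seq_along(specs)) {
    nm <- names(specs)[i]
    models[[nm]] <- fit_model(specs[[i]], train, seed = seed + i)
  }
  pred <- suppressWarnings(predict_probability(models, test))
  aucs <- apply(pred$per_model, 2L, auc_roc, labels = test$label)
  summ <- ensemble_auc_summary(aucs)
  structure(list(models = models, scaler = std$params, auc = aucs,
                 ensemble_mean = summ$mean, ensemble_sd = summ$sd,
                 split = split, seed = as.integer(seed)),
            class = "FittedEnsemble")
}

#' @export
print.FittedEnsemble <- function(x, ...) {
  cat("FittedEnsemble of", length(x$models), "classifiers\n")
  cat("  per-model AUC-ROC:\n")
  for (nm in names(x$auc))
    cat(sprintf("    %-4s %.2f\n", nm, x$auc[[nm]]))
  cat(sprintf("  ensemble: %.2f +/- %.2f\n",
              round_half_up(x$ensemble_mean), round_half_up(x$ensemble_sd)))
  invisible(x)
}
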
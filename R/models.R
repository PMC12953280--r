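# RCB regression models: variance filter -> per-set PCA -> random forest
# for the deep-feature models, plain random forests for the two
# clinical-radiological baselines, and the nonnegative zero-intercept
# stacking ensemble.

#' Low-variance feature filter
#'
#' Keeps exactly the features whose (sample) variance is at least
#' `threshold`; features with variance below 0.0005 are dropped by default.
#' The filter is fitted on training rows only and re-applied unchanged to
#' unseen rows via [apply_variance_filter()].
#'
#' @param X numeric matrix (rows = patients) with column names.
#' @param threshold variance threshold; a feature with variance exactly at
#'   the threshold is kept.
#' @return list with the reduced matrix `X`, the kept column names `keep`
#'   and the `threshold`.
#' @export
variance_filter <- function(X, threshold = 5e-4) {
  if (is.null(dim(X)) || nrow(X) == 0) stop("X must be a non-empty matrix")
  v <- apply(X, 2, var)
  keep <- colnames(X)[v >= threshold]
  if (length(keep) == 0)
    stop("variance filter removed every feature; review the threshold")
  list(X = X[, keep, drop = FALSE], keep = keep, threshold = threshold)
}

#' Re-apply a fitted variance filter to unseen rows
#' @param filter a [variance_filter()] result.
#' @param X matrix with (at least) the fitted columns.
#' @return `X` restricted to the kept features.
#' @export
apply_variance_filter <- function(filter, X) X[, filter$keep, drop = FALSE]

#' Fit the dimensionality reduction: variance filter + per-set PCA
#'
#' For each feature set (pre, post, delta) independently: drop low-variance
#' features, centre, and fit a principal component analysis retaining the
#' smallest number of components reaching `retain` of the variance (capped
#' at `n - 1`). The three reduced blocks are concatenated column-wise in
#' pre/post/delta order. The fitted transform is reusable on unseen rows
#' via `predict()`.
#'
#' @param fs a [build_feature_sets()] result (training rows only).
#' @param variance_threshold threshold for [variance_filter()].
#' @param retain fraction of variance to retain per set, or a fixed
#'   component count (integer >= 1).
#' @return object of class `reduction_spec` with elements `sets` (per-set
#'   filter, centre, rotation, component count) and `X` (reduced training
#'   matrix).
#' @export
fit_reduction <- function(fs, variance_threshold = 5e-4, retain = 0.95) {
  stopifnot(inherits(fs, "feature_set"))
  if (nrow(fs$pre) < 2) stop("need at least 2 training rows to fit PCA")
  sets <- list()
  blocks <- list()
  for (nm in c("pre", "post", "delta")) {
    X <- fs[[nm]]
    flt <- variance_filter(X, variance_threshold)
    pc <- prcomp(flt$X, center = TRUE, scale. = FALSE)
    if (retain >= 1) {
      m <- min(as.integer(retain), ncol(pc$rotation))
    } else {
      cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
      m <- which(cum >= retain)[1]
    }
    m <- min(m, nrow(X) - 1L)
    rot <- pc$rotation[, seq_len(m), drop = FALSE]
    blk <- pc$x[, seq_len(m), drop = FALSE]
    colnames(blk) <- paste0(nm, "_PC", seq_len(m))
    sets[[nm]] <- list(keep = flt$keep, center = pc$center, rotation = rot,
                       n_components = m)
    blocks[[nm]] <- blk
  }
  structure(list(sets = sets, X = do.call(cbind, blocks),
                 variance_threshold = variance_threshold, retain = retain),
            class = "reduction_spec")
}

#' @export
print.reduction_spec <- function(x, ...) {
  m <- vapply(x$sets, `[[`, 1L, "n_components")
  cat(sprintf("<reduction_spec> %d components (%s)\n", sum(m),
              paste(m, collapse = ", ")))
  invisible(x)
}

#' @export
predict.reduction_spec <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "feature_set"))
  blocks <- lapply(c("pre", "post", "delta"), function(nm) {
    s <- object$sets[[nm]]
    X <- newdata[[nm]][, s$keep, drop = FALSE]
    blk <- sweep(X, 2, s$center) %*% s$rotation
    colnames(blk) <- paste0(nm, "_PC", seq_len(s$n_components))
    blk
  })
  do.call(cbind, blocks)
}

#' Random forest training specification
#'
#' @param n_trees candidate tree counts for the grid search.
#' @param max_depth candidate maximum depths (`0` = unlimited).
#' @param cv_folds cross-validation folds for the grid search.
#' @param criterion grid-selection criterion: mean out-of-fold Spearman
#'   correlation with the RCB score (default) or mean squared error.
#' @param seed seed for fold assignment and forest growing.
#' @return object of class `rf_spec`.
#' @export
rf_spec <- function(n_trees = c(50L, 100L, 250L),
                    max_depth = c(2L, 3L, 5L, 0L),
                    cv_folds = 5L, criterion = c("spearman", "mse"),
                    seed = 1L) {
  if (length(n_trees) == 0 || length(max_depth) == 0)
    stop("hyperparameter grid must be non-empty")
  if (cv_folds < 2) stop("cv_folds must be at least 2")
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 cv_folds = as.integer(cv_folds),
                 criterion = match.arg(criterion),
                 seed = as.integer(seed)),
            class = "rf_spec")
}

#' @noRd
fit_ranger <- function(X, y, n_trees, max_depth, seed) {
  df <- as.data.frame(X)
  df$.outcome <- y
  ranger::ranger(dependent.variable.name = ".outcome", data = df,
                 num.trees = n_trees, max.depth = max_depth,
                 seed = seed, num.threads = 1)
}

#' Random forest regression with cross-validated hyperparameter selection
#'
#' Searches the `n_trees` x `max_depth` grid by k-fold cross-validation on
#' the training rows, selects the grid point with the best mean out-of-fold
#' criterion, refits on all rows with the chosen hyperparameters and a
#' fixed seed, and returns the out-of-fold predictions of the winning
#' configuration for training-set evaluation.
#'
#' @param X numeric matrix of predictors (rows = patients).
#' @param y numeric RCB scores.
#' @param spec an [rf_spec()].
#' @return object of class `rcb_rf` with the fitted forest, chosen
#'   hyperparameters, out-of-fold predictions (`oof`) and fold ids.
#' @export
fit_rf_cv <- function(X, y, spec = rf_spec()) {
  if (anyNA(X) || anyNA(y)) stop("NaN/NA in predictors or outcome")
  n <- nrow(X)
  if (n < spec$cv_folds) stop("fewer rows than folds")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(derive_seed(spec$seed, "folds"))
  folds <- sample(rep(seq_len(spec$cv_folds), length.out = n))
  grid <- expand.grid(n_trees = spec$n_trees, max_depth = spec$max_depth)
  scores <- numeric(nrow(grid))
  oof_all <- matrix(NA_real_, n, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    oof <- numeric(n)
    for (f in seq_len(spec$cv_folds)) {
      tr <- folds != f
      fit <- fit_ranger(X[tr, , drop = FALSE], y[tr], grid$n_trees[g],
                        grid$max_depth[g], spec$seed)
      oof[!tr] <- predict(fit,
        as.data.frame(X[!tr, , drop = FALSE]))$predictions
    }
    oof_all[, g] <- oof
    scores[g] <- if (spec$criterion == "spearman") {
      if (sd(oof) == 0 || sd(y) == 0) -Inf
      else cor(oof, y, method = "spearman")
    } else -mean((oof - y)^2)
    }
  best <- which.max(scores)
  final <- fit_ranger(X, y, grid$n_trees[best], grid$max_depth[best],
                      spec$seed)
  structure(list(fit = final,
                 n_trees = grid$n_trees[best],
                 max_depth = grid$max_depth[best],
                 cv_score = scores[best],
                 oof = oof_all[, best], folds = folds,
                 feature_names = colnames(X), spec = spec),
            class = "rcb_rf")
}

#' @export
print.rcb_rf <- function(x, ...) {
  cat(sprintf("<rcb_rf> %d trees, max depth %s, CV %s %.3f\n",
              x$n_trees, if (x$max_depth == 0) "unlimited" else x$max_depth,
              x$spec$criterion, x$cv_score))
  invisible(x)
}

#' @export
predict.rcb_rf <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  predict(object$fit, nd)$predictions
}

#' Clinical-radiological feature matrix
#'
#' Builds the baseline predictors from a clinical table: post-treatment
#' tumor volume (mm^3) and the volume difference relative to baseline
#' (pre minus post, so shrinkage is positive), optionally with a one-hot
#' encoding of the receptor subtype. No PCA or variance filtering is
#' applied to these features.
#'
#' @param clinical data.frame with `pre_volume_mm3`, `post_volume_mm3` and
#'   (if `with_subtype`) `subtype`.
#' @param with_subtype include the subtype one-hot block.
#' @return numeric matrix with 2 or 5 columns.
#' @export
clinical_features <- function(clinical, with_subtype = FALSE) {
  if (any(clinical$pre_volume_mm3 < 0) || any(clinical$post_volume_mm3 < 0))
    stop("volumes must be nonnegative")
  X <- cbind(post_volume_mm3 = clinical$post_volume_mm3,
             delta_volume_mm3 = clinical$pre_volume_mm3 -
               clinical$post_volume_mm3)
  if (with_subtype) {
    if (is.null(clinical$subtype)) stop("subtype column required")
    lev <- c("TN", "ER+/HER2-", "HER2+")
    st <- factor(clinical$subtype, levels = lev)
    if (anyNA(st)) stop("unknown subtype value")
    onehot <- sapply(lev, function(l) as.numeric(st == l))
    colnames(onehot) <- c("subtype_TN", "subtype_ER", "subtype_HER2")
    X <- cbind(X, onehot)
  }
  rownames(X) <- clinical$patient_id
  X
}

#' Train a clinical-radiological baseline model
#'
#' Random forest regression of the RCB score on tumor volume features only
#' (`with_subtype = FALSE`: 2 features) or volume plus one-hot subtype
#' (`with_subtype = TRUE`: 5 features), with the same cross-validated
#' hyperparameter search as the deep-feature models.
#'
#' @param clinical clinical data.frame, see [clinical_features()].
#' @param y numeric RCB scores.
#' @param with_subtype include subtype.
#' @param spec an [rf_spec()].
#' @return an `rcb_rf` model.
#' @export
clinical_model <- function(clinical, y, with_subtype = FALSE,
                           spec = rf_spec()) {
  X <- clinical_features(clinical, with_subtype)
  fit_rf_cv(X, y, spec)
}

#' Fit the nonnegative zero-intercept stacking ensemble
#'
#' Solves the least squares problem `min ||P w - y||` subject to `w >= 0`
#' with no intercept (Lawson-Hanson active set), where the columns of `P`
#' are the base models' predicted RCB scores. Weights of exactly zero mean
#' a base model contributes nothing to the ensemble.
#'
#' @param base_predictions numeric matrix (patients x base models) with
#'   column names identifying the base models.
#' @param y numeric RCB scores.
#' @return object of class `rcb_ensemble` with nonnegative `weights` and
#'   `intercept = 0`.
#' @export
fit_ensemble <- function(base_predictions, y) {
  P <- as.matrix(base_predictions)
  if (anyNA(P) || anyNA(y)) stop("NaN/NA in ensemble inputs")
  if (nrow(P) < 2) stop("need at least 2 patients")
  if (all(P == 0)) stop("degenerate base predictions (all zero)")
  if (is.null(colnames(P))) colnames(P) <- paste0("model", seq_len(ncol(P)))
  w <- pracma::lsqnonneg(P, as.numeric(y))$x
  structure(list(weights = setNames(pmax(w, 0), colnames(P)), intercept = 0),
            class = "rcb_ensemble")
}

#' @export
print.rcb_ensemble <- function(x, ...) {
  cat("<rcb_ensemble> weights (zero intercept):\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' @export
predict.rcb_ensemble <- function(object, newdata, ...) {
  P <- as.matrix(newdata)[, names(object$weights), drop = FALSE]
  as.numeric(P %*% object$weights)
}
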
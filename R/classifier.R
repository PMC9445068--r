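## Bagged decision-tree emotion classifier with balanced
## leave-one-per-category cross-validation and predictor importance.

#' Classifier model specification
#'
#' M1 uses the 8 intrapersonal predictors, M2 the 12 interpersonal ones,
#' M3 all 20; custom predictor lists are allowed.
#'
#' @param name one of \code{"M1"}, \code{"M2"}, \code{"M3"}.
#' @param predictors optional explicit predictor names (subset of
#'   \code{\link{all_features}()}).
#' @param n_trees ensemble size (default 200).
#' @param seed RNG seed controlling bootstrap resampling and tie-breaking.
#' @return Object of class \code{model_spec}.
#' @export
model_spec <- function(name = c("M1", "M2", "M3"), predictors = NULL,
                       n_trees = 200L, seed = 1L) {
  name <- match.arg(name)
  if (is.null(predictors)) {
    predictors <- switch(name, M1 = intrapersonal_features(),
                         M2 = interpersonal_features(), M3 = all_features())
  }
  stopifnot(all(predictors %in% all_features()), n_trees >= 1)
  structure(list(name = name, predictors = predictors,
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "model_spec")
}

prepare_matrix <- function(features, predictors) {
  missing <- setdiff(predictors, names(features))
  if (length(missing))
    stop_dyadkin("feature table lacks predictor(s): %s",
                 paste(missing, collapse = ", "))
  as.matrix(features[, predictors, drop = FALSE])
}

# Training-set median imputation applied to train and test alike.
impute_by_train <- function(train, test = NULL) {
  med <- apply(train, 2, function(v) {
    m <- stats::median(v, na.rm = TRUE)
    if (!is.finite(m)) 0 else m
  })
  fill <- function(m) {
    for (j in seq_len(ncol(m))) m[!is.finite(m[, j]), j] <- med[j]
    m
  }
  list(train = fill(train), test = if (!is.null(test)) fill(test))
}

#' Fit a bagged ensemble of classification trees
#'
#' \code{n_trees} unpruned CART trees, each on a bootstrap resample of the
#' training rows; prediction by majority vote. Per-predictor importance is
#' the impurity decrease summed over splits (node-weighted), summed over
#' trees and normalised to sum 1.
#'
#' @param features feature table (data frame) containing the predictors.
#' @param labels class labels, one per row.
#' @param spec a \code{\link{model_spec}}.
#' @return Object of class \code{bagged_trees} with elements \code{trees},
#'   \code{importance}, \code{classes}, \code{spec}.
#' @export
fit_bagged_trees <- function(features, labels, spec = model_spec("M3")) {
  X <- prepare_matrix(features, spec$predictors)
  if (any(!is.finite(X)))
    stop_dyadkin("missing predictor values; impute before fitting")
  y <- factor(as.character(labels),
              levels = intersect(EMOTIONS, unique(as.character(labels))))
  if (nlevels(y) < 2)
    stop_dyadkin("training data contain a single class")
  n <- nrow(X)
  with_seed(spec$seed, {
    trees <- vector("list", spec$n_trees)
    imp <- stats::setNames(numeric(ncol(X)), colnames(X))
    for (b in seq_len(spec$n_trees)) {
      idx <- sample.int(n, n, replace = TRUE)
      tr <- cart_fit(X[idx, , drop = FALSE], droplevels(y[idx]))
      trees[[b]] <- tr
      imp[tr$vars] <- imp[tr$vars] + tr$importance
    }
    s <- sum(imp)
    structure(list(trees = trees, classes = levels(y),
                   importance = if (s > 0) imp / s else imp,
                   spec = spec),
              class = "bagged_trees")
  })
}

#' @export
predict.bagged_trees <- function(object, newdata, ...) {
  X <- prepare_matrix(as.data.frame(newdata), object$spec$predictors)
  if (any(!is.finite(X)))
    stop_dyadkin("missing predictor values in newdata")
  all_classes <- object$classes
  votes <- matrix(0L, nrow(X), length(all_classes),
                  dimnames = list(NULL, all_classes))
  for (tr in object$trees) {
    pred <- tr$classes[cart_predict(tr, X)]
    for (cl in unique(pred)) votes[pred == cl, cl] <- votes[pred == cl, cl] + 1L
  }
  ## deterministic tie-break: first class (canonical emotion order) among ties
  factor(all_classes[apply(votes, 1, which.max)], levels = all_classes)
}

#' Balanced leave-one-per-category cross-validation
#'
#' Fold k holds out the k-th scene of every class; with 12 scenes per
#' emotion this gives 12 folds of 4 test scenes each, so every scene is
#' tested exactly once and training folds stay balanced. Missing predictor
#' values are imputed with the training fold's medians.
#'
#' @param features feature table; an optional \code{scene_id} column labels
#'   the fold predictions.
#' @param labels class labels, one per row; classes must be balanced.
#' @param spec a \code{\link{model_spec}}.
#' @return Object of class \code{cv_report}: \code{fold_predictions}
#'   (data frame scene_id, fold, truth, predicted), \code{overall_accuracy},
#'   \code{per_class_accuracy}, \code{importance_mean},
#'   \code{importance_std} (across folds), \code{spec}.
#' @export
cross_validate <- function(features, labels, spec = model_spec("M3")) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(unique(tab)) != 1L)
    stop_dyadkin("cross_validate requires equal scene counts per class")
  n_folds <- unname(tab[1])
  classes <- intersect(EMOTIONS, names(tab))
  ids <- features$scene_id %||% sprintf("scene_%03d", seq_along(labels))
  X_all <- prepare_matrix(features, spec$predictors)
  fold_of <- integer(length(labels))
  for (cl in classes) fold_of[labels == cl] <- seq_len(n_folds)
  fold_seeds <- derive_seeds(spec$seed, n_folds)
  preds <- character(length(labels))
  imp <- matrix(NA_real_, n_folds, length(spec$predictors),
                dimnames = list(NULL, spec$predictors))
  for (k in seq_len(n_folds)) {
    test <- which(fold_of == k)
    train <- which(fold_of != k)
    im <- impute_by_train(X_all[train, , drop = FALSE],
                          X_all[test, , drop = FALSE])
    sp_k <- spec
    sp_k$seed <- fold_seeds[k]
    fit <- fit_bagged_trees(as.data.frame(im$train), labels[train], sp_k)
    preds[test] <- as.character(predict(fit, as.data.frame(im$test)))
    imp[k, ] <- fit$importance
  }
  per_class <- vapply(classes, function(cl) {
    mean(preds[labels == cl] == cl)
  }, numeric(1))
  structure(list(
    fold_predictions = data.frame(scene_id = ids, fold = fold_of,
                                  truth = labels, predicted = preds,
                                  stringsAsFactors = FALSE),
    overall_accuracy = mean(preds == labels),
    per_class_accuracy = per_class,
    importance_mean = colMeans(imp),
    importance_std = apply(imp, 2, stats::sd),
    spec = spec), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report %s> overall accuracy %.1f%%\n",
              x$spec$name, 100 * x$overall_accuracy))
  print(round(100 * x$per_class_accuracy, 1))
  invisible(x)
}

#' Compare the M1 / M2 / M3 classifiers
#'
#' @param features feature table.
#' @param labels class labels.
#' @param specs list of \code{\link{model_spec}}s (default M1, M2, M3 with
#'   shared settings).
#' @param n_trees,seed used when \code{specs} is NULL.
#' @return list(reports = named list of \code{cv_report}, table = data frame
#'   of overall and per-class accuracies, ranked by overall accuracy).
#' @export
compare_models <- function(features, labels, specs = NULL,
                           n_trees = 200L, seed = 1L) {
  if (is.null(specs))
    specs <- lapply(c("M1", "M2", "M3"), model_spec,
                    n_trees = n_trees, seed = seed)
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  reports <- lapply(specs, function(s) cross_validate(features, labels, s))
  tab <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    cbind(data.frame(model = nm, overall = r$overall_accuracy),
          as.data.frame(as.list(r$per_class_accuracy)))
  }))
  tab <- tab[order(-tab$overall), ]
  rownames(tab) <- NULL
  list(reports = reports, table = tab)
}
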
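#' Fingerprint feature matrix for a library
#'
#' One fingerprint row per library molecule, in library order.
#'
#' @param library a [mol_library] or character vector of SMILES.
#' @param nbits fingerprint length (see [fingerprint]).
#' @return list with `features` (binary matrix) and `smiles` (row keys).
#' @export
featurize_library <- function(library, nbits = 2048L) {
  smiles <- library_smiles(library)
  if (length(smiles) == 0L) stop("cannot featurize an empty library")
  list(features = fingerprint(smiles, nbits = nbits), smiles = smiles)
}

#' Train a random-forest surrogate for a molecular property
#'
#' Fits an ensemble-of-trees regressor (ranger) on fingerprint features,
#' choosing hyperparameters by k-fold cross-validated grid search scored by
#' mean squared error, then refitting the winning configuration on all
#' data. Deterministic for a fixed seed.
#'
#' @param features binary feature matrix (rows = molecules).
#' @param labels numeric property values, one per row.
#' @param target which property the model predicts (`"gap"` or `"e_s1"`);
#'   bookkeeping only.
#' @param seed integer seed (fold assignment and forest growth).
#' @param folds number of cross-validation folds (default 5).
#' @param grid data.frame of candidate hyperparameters with columns
#'   `num_trees` and `max_depth` (0 = unlimited).
#' @return an object of class `surrogate_model` with fields `fit`,
#'   `target`, `hyperparameters`, `cv_score` (negative CV MSE) and
#'   `fitted_flag`.
#' @export
train_surrogate <- function(features, labels, target = c("gap", "e_s1"),
                            seed = 1L, folds = 5L,
                            grid = expand.grid(num_trees = c(100L, 300L),
                                               max_depth = c(0L, 10L, 20L))) {
  target <- match.arg(target)
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(labels) != n) stop("labels length must match feature rows")
  if (!all(is.finite(labels))) stop("labels must be finite")
  if (n < 20L) stop("need at least 20 labelled examples to train a surrogate")
  if (n < folds) stop("fewer examples (", n, ") than folds (", folds, "); reduce folds")
  colnames(features) <- paste0("b", seq_len(ncol(features)))
  df <- as.data.frame(features)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  cv_mse <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- ranger::ranger(
        x = df[tr, , drop = FALSE], y = labels[tr],
        num.trees = grid$num_trees[g], max.depth = grid$max_depth[g],
        seed = seed + f, num.threads = 1L, verbose = FALSE
      )
      p <- stats::predict(fit, data = df[!tr, , drop = FALSE])$predictions
      mean((p - labels[!tr])^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- which.min(cv_mse)  # ties resolve to the first grid row
  fit <- ranger::ranger(
    x = df, y = labels,
    num.trees = grid$num_trees[best], max.depth = grid$max_depth[best],
    seed = seed, num.threads = 1L, verbose = FALSE
  )
  structure(list(
    fit = fit,
    target = target,
    feature_names = colnames(features),
    hyperparameters = as.list(grid[best, , drop = FALSE]),
    cv_score = -cv_mse[best],
    fitted_flag = TRUE
  ), class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("<surrogate_model> target=%s trees=%d depth=%s cv_mse=%.4g\n",
              x$target, x$hyperparameters$num_trees,
              ifelse(x$hyperparameters$max_depth == 0, "unlimited",
                     x$hyperparameters$max_depth),
              -x$cv_score))
  invisible(x)
}

#' Predict a property for every molecule in a library
#'
#' The entire library is predicted, including molecules that were in the
#' training set: downstream selection uses predicted values uniformly.
#'
#' @param model a fitted [train_surrogate] model.
#' @param library a [mol_library], character vector of SMILES, or a
#'   pre-computed [featurize_library] result.
#' @return named numeric vector of predictions (names = SMILES).
#' @export
predict_library <- function(model, library) {
  if (!inherits(model, "surrogate_model") || !isTRUE(model$fitted_flag)) {
    stop("model is not a fitted surrogate")
  }
  feats <- if (is.list(library) && !inherits(library, "mol_library") &&
               all(c("features", "smiles") %in% names(library))) {
    library
  } else {
    featurize_library(library)
  }
  x <- as.matrix(feats$features)
  colnames(x) <- model$feature_names
  p <- stats::predict(model$fit, data = as.data.frame(x))$predictions
  stats::setNames(p, feats$smiles)
}
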
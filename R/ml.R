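#' Train a gradient-boosted tree classifier
#'
#' Binary logistic boosting with second-order (Newton) leaf weights, exact
#' greedy splits and L2 leaf regularization — the boosted-ensemble learner
#' behind the tf-idf document classifier.
#'
#' @param X numeric feature matrix (dense or `dgCMatrix`).
#' @param y binary 0/1 labels.
#' @param nrounds boosting rounds.
#' @param eta learning rate.
#' @param max_depth maximum tree depth.
#' @param lambda L2 regularization on leaf weights.
#' @param min_child_weight minimum hessian sum per child.
#' @return a `gbt_model`.
#' @export
gbt_train <- function(X, y, nrounds = 50, eta = 0.3, max_depth = 3,
                      lambda = 1, min_child_weight = 1e-3) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  fit <- .gbt_fit_cpp(X, as.numeric(y), as.integer(nrounds), eta,
                      as.integer(max_depth), lambda, min_child_weight)
  structure(list(fit = fit, n_features = ncol(X),
                 params = list(nrounds = nrounds, eta = eta,
                               max_depth = max_depth, lambda = lambda)),
            class = "gbt_model")
}

#' @rdname gbt_train
#' @param object a `gbt_model`.
#' @param newdata feature matrix to score.
#' @param type `"response"` (probabilities) or `"margin"`.
#' @param ... unused.
#' @export
predict.gbt_model <- function(object, newdata, type = "response", ...) {
  m <- .gbt_margin_cpp(object$fit, as.matrix(newdata))
  if (type == "margin") m else 1 / (1 + exp(-m))
}

#' Default hyperparameter grid for the boosted-tree baseline
#'
#' Tree depth 3 or 6, learning rate 0.1 or 0.3, 50 or 200 boosting rounds;
#' overridable by passing any data.frame with columns `max_depth`, `eta`,
#' `nrounds` to [nested_cv_train()].
#'
#' @return data.frame of configurations.
#' @export
default_gbt_grid <- function() {
  expand.grid(max_depth = c(3, 6), eta = c(0.1, 0.3),
              nrounds = c(50, 200))
}

#' Nested stratified cross-validation for the tf-idf + boosted-tree model
#'
#' Per trial: a fresh stratified `n_outer`-fold shuffle of the corpus; for
#' each outer fold a grid search over `grid` is run with stratified
#' `n_inner`-fold CV *inside the outer-training partition only* (the tf-idf
#' vectorizer is also refit on outer-train by default, so the outer test
#' fold can never leak vocabulary into model selection); the winning
#' configuration is refit on outer-train and scored on outer-test with the
#' five report-classification metrics. After all trials, the most
#' frequently selected configuration is refit on the full corpus as the
#' final model.
#'
#' @param texts preprocessed document texts.
#' @param y binary 0/1 labels (any concept vs none).
#' @param grid hyperparameter data.frame (see [default_gbt_grid()]).
#' @param n_outer outer folds (5, as in nested fivefold CV).
#' @param n_inner inner folds for the grid search.
#' @param n_trials repetitions of the whole procedure with different
#'   shuffles.
#' @param seed base RNG seed; trial `t` uses `seed + t`.
#' @param vectorizer `"per_fold"` (leak-free, default) or `"global"` (fit
#'   tf-idf once on the full corpus, for comparison).
#' @param tfidf_opts list of arguments for [fit_tfidf()].
#' @param keep_fold_details store per-fold vocabularies and predictions.
#' @return a `nested_cv_result`: `trial_scores` (per trial x outer fold
#'   metric rows), `chosen` (selected configuration per trial x fold),
#'   `summary` (mean and SD per metric, plus `formatted`), `final_model`
#'   (an `ml_model`), and optionally `fold_details`.
#' @export
nested_cv_train <- function(texts, y, grid = default_gbt_grid(),
                            n_outer = 5, n_trials = 20, seed = 1L,
                            n_inner = 3, vectorizer = c("per_fold", "global"),
                            tfidf_opts = list(), keep_fold_details = FALSE) {
  vectorizer <- match.arg(vectorizer)
  y <- as.integer(y)
  stopifnot(length(texts) == length(y), all(y %in% 0:1))
  if (min(table(y)) < n_outer) {
    stop("each class needs at least n_outer = ", n_outer, " members")
  }
  global_vec <- if (vectorizer == "global") {
    do.call(fit_tfidf, c(list(texts), tfidf_opts))
  } else NULL

  scores <- list(); chosen <- list(); details <- list()
  for (t in seq_len(n_trials)) {
    with_seed(seed + t, {
      fold <- stratified_folds(y, n_outer)
      for (k in seq_len(n_outer)) {
        tr <- which(fold != k); te <- which(fold == k)
        vec <- global_vec %||%
          do.call(fit_tfidf, c(list(texts[tr]), tfidf_opts))
        Xtr <- tfidf_transform(vec, texts[tr])
        Xte <- tfidf_transform(vec, texts[te])
        best <- grid_search_gbt(Xtr, y[tr], grid, n_inner)
        fit <- gbt_train(Xtr, y[tr], nrounds = best$nrounds,
                         eta = best$eta, max_depth = best$max_depth)
        prob <- predict(fit, Xte)
        pred <- as.integer(prob >= 0.5)
        m <- metrics(confusion(y[te], pred), rounding = NULL)
        scores[[length(scores) + 1L]] <-
          data.frame(trial = t, fold = k, as.data.frame(m$raw))
        chosen[[length(chosen) + 1L]] <-
          data.frame(trial = t, fold = k, best)
        if (keep_fold_details) {
          details[[length(details) + 1L]] <- list(
            trial = t, fold = k, vocabulary = names(vec$vocabulary),
            test_idx = te, prob = prob)
        }
      }
    })
  }
  trial_scores <- do.call(rbind, scores)
  chosen <- do.call(rbind, chosen)

  # mean/SD across trials of the per-trial outer-fold means
  per_trial <- aggregate(trial_scores[c("sensitivity", "ppv", "npv", "f1",
                                        "accuracy")],
                         by = list(trial = trial_scores$trial),
                         FUN = mean, na.rm = TRUE)
  mu <- vapply(per_trial[-1], mean, 0, na.rm = TRUE)
  sdev <- vapply(per_trial[-1], sd, 0, na.rm = TRUE)

  cfg_key <- apply(chosen[names(grid)], 1, paste, collapse = "_")
  win <- names(sort(table(cfg_key), decreasing = TRUE))[1]
  best_cfg <- chosen[match(win, cfg_key), names(grid), drop = FALSE]

  final_vec <- global_vec %||% do.call(fit_tfidf, c(list(texts), tfidf_opts))
  Xall <- tfidf_transform(final_vec, texts)
  final_fit <- gbt_train(Xall, y, nrounds = best_cfg$nrounds,
                         eta = best_cfg$eta, max_depth = best_cfg$max_depth)
  final_model <- structure(list(vectorizer = final_vec, fit = final_fit,
                                config = best_cfg, threshold = 0.5,
                                trained = TRUE),
                           class = "ml_model")
  structure(list(
    trial_scores = trial_scores,
    chosen = chosen,
    summary = list(mean = as.list(mu), sd = as.list(sdev),
                   formatted = setNames(mapply(format_mean_sd, mu, sdev),
                                        names(mu))),
    final_model = final_model,
    fold_details = if (keep_fold_details) details else NULL,
    n_outer = n_outer, n_trials = n_trials, seed = seed
  ), class = "nested_cv_result")
}

# Inner-loop grid search: stratified n_inner-fold CV on (X, y); returns the
# grid row with the highest mean accuracy (first row wins ties). Uses the
# ambient RNG state (caller seeds per trial).
grid_search_gbt <- function(X, y, grid, n_inner) {
  fold <- stratified_folds(y, n_inner)
  acc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    hits <- 0L
    for (k in seq_len(n_inner)) {
      tr <- which(fold != k); te <- which(fold == k)
      fit <- gbt_train(X[tr, , drop = FALSE], y[tr],
                       nrounds = grid$nrounds[gi], eta = grid$eta[gi],
                       max_depth = grid$max_depth[gi])
      pred <- as.integer(predict(fit, X[te, , drop = FALSE]) >= 0.5)
      hits <- hits + sum(pred == y[te])
    }
    acc[gi] <- hits / length(y)
  }
  grid[which.max(acc), , drop = FALSE]
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat("<nested_cv_result> ", x$n_trials, " trials x ", x$n_outer,
      " outer folds\n", sep = "")
  for (nm in names(x$summary$formatted)) {
    cat(sprintf("  %-11s %s\n", nm, x$summary$formatted[[nm]]))
  }
  invisible(x)
}

#' Score new documents with the refit tf-idf + boosted-tree model
#'
#' @param object an `ml_model` (from `nested_cv_train()$final_model`).
#' @param newdata character vector of preprocessed texts.
#' @param threshold decision threshold on the probability scale.
#' @param ... unused.
#' @return data.frame with `score` in `[0, 1]` and binary `label`.
#' @export
predict.ml_model <- function(object, newdata, threshold = NULL, ...) {
  if (!isTRUE(object$trained)) stop("model has not been trained")
  thr <- threshold %||% object$threshold
  X <- tfidf_transform(object$vectorizer, newdata)
  score <- predict(object$fit, X)
  data.frame(score = score, label = as.integer(score >= thr))
}
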
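test_that("tf-idf matches a hand-computed arithmetic oracle", {
  set.seed(41)
  texts <- random_texts(20, min_tok = 4, max_tok = 10)
  model <- fit_tfidf(texts, ngram = 1, min_df = 2)
  X <- tfidf_transform(model, texts)
  expect_equal(nrow(X), 20)
  expect_equal(unname(model$vocabulary), seq_along(model$vocabulary))
  expect_true(all(is.finite(model$idf)) && all(model$idf >= 0))

  # independent recomputation, term by term
  toks <- strsplit(texts, " ", fixed = TRUE)
  n <- length(texts)
  for (d in sample(n, 5)) {
    row <- numeric(length(model$vocabulary))
    for (term in names(model$vocabulary)) {
      tf <- sum(toks[[d]] == term)
      df <- sum(vapply(toks, function(tt) term %in% tt, TRUE))
      row[model$vocabulary[[term]]] <- tf * (log((1 + n) / (1 + df)) + 1)
    }
    if (sum(row^2) > 0) row <- row / sqrt(sum(row^2))
    expect_equal(as.numeric(X[d, ]), row, tolerance = 1e-12)
  }
})

test_that("tf-idf transform handles identical, unseen and empty inputs", {
  texts <- c("alpha beta beta", "alpha beta beta", "gamma alpha delta")
  m <- fit_tfidf(texts, ngram = 1, min_df = 1)
  X <- tfidf_transform(m, texts)
  expect_equal(X[1, ], X[2, ])
  # unseen terms contribute nothing
  X2 <- tfidf_transform(m, c("alpha omega", "omega zeta"))
  expect_equal(X2[1, ], tfidf_transform(m, "alpha")[1, ])
  expect_equal(sum(X2[2, ]), 0)
  # single-document corpus: all idf equal, no division error
  m1 <- fit_tfidf("solo doc here", ngram = 1, min_df = 1)
  expect_equal(length(unique(m1$idf)), 1L)
  expect_error(fit_tfidf(character()), "empty")
})

test_that("boosted trees fit a separable problem and a noisy one", {
  sep <- separable_corpus(80, seed = 42)
  X <- tfidf_transform(fit_tfidf(sep$texts, min_df = 1), sep$texts)
  fit <- gbt_train(X, sep$y, nrounds = 20, eta = 0.3, max_depth = 3)
  p <- predict(fit, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(as.integer(p >= 0.5), sep$y)
  # margin type is monotone with response
  mar <- predict(fit, X, type = "margin")
  expect_equal(order(mar), order(p))
})

small_grid <- expand.grid(max_depth = 2, eta = 0.3, nrounds = c(10, 20))

test_that("nested CV is leak-free, stratified and reproducible", {
  sep <- separable_corpus(60, seed = 43)
  res <- nested_cv_train(sep$texts, sep$y, grid = small_grid,
                         n_trials = 2, n_inner = 2, seed = 7,
                         keep_fold_details = TRUE)
  expect_equal(res$summary$mean$accuracy, 1)

  # leak check: plant a token that exists only in one outer-test fold
  texts <- sep$texts
  det <- res$fold_details[[1]]
  texts[det$test_idx] <- paste(texts[det$test_idx], "zzzunique")
  res2 <- nested_cv_train(texts, sep$y, grid = small_grid,
                          n_trials = 1, n_inner = 2, seed = 7,
                          keep_fold_details = TRUE)
  for (d in res2$fold_details) {
    test_has_token <- any(grepl("zzzunique", texts[d$test_idx]))
    train_has_token <- any(grepl("zzzunique", texts[-d$test_idx]))
    if (test_has_token && !train_has_token) {
      expect_false("zzzunique" %in% d$vocabulary)
    }
  }

  # reproducibility
  r1 <- nested_cv_train(sep$texts, sep$y, grid = small_grid,
                        n_trials = 2, n_inner = 2, seed = 11)
  r2 <- nested_cv_train(sep$texts, sep$y, grid = small_grid,
                        n_trials = 2, n_inner = 2, seed = 11)
  expect_identical(r1$trial_scores, r2$trial_scores)
  expect_identical(r1$chosen, r2$chosen)

  # stratification: every outer fold within one document of global ratio
  y <- sep$y
  set.seed(1)
  fold <- radconcept:::stratified_folds(y, 5)
  for (k in 1:5) {
    expect_lt(abs(sum(y[fold == k]) - sum(y) / 5), 1.01)
  }

  # class smaller than fold count
  expect_error(nested_cv_train(sep$texts, c(1, rep(0, 59)),
                               grid = small_grid),
               "at least n_outer")
})

test_that("nested selection does not inherit naive grid-search optimism", {
  # pure-noise labels: the naive protocol (pick the grid config with the
  # best CV score and report that same score) is optimistically biased;
  # the nested outer estimate is not. Paired on identical folds and
  # feature matrices, the average gap (naive - nested) is nonnegative.
  grid <- expand.grid(max_depth = c(1, 2), eta = 0.3, nrounds = c(5, 20))
  cv_acc <- function(X, y, fold, g) {
    hits <- 0
    for (k in sort(unique(fold))) {
      tr <- fold != k
      fit <- gbt_train(X[tr, ], y[tr], nrounds = g$nrounds, eta = g$eta,
                       max_depth = g$max_depth)
      hits <- hits + sum((predict(fit, X[!tr, ]) >= 0.5) == y[!tr])
    }
    hits / length(y)
  }
  set.seed(44)
  gaps <- replicate(12, {
    n <- 80
    texts <- vapply(seq_len(n), function(i)
      paste(sample(letters[1:12], 8, replace = TRUE), collapse = " "), "")
    y <- rep(0:1, each = n / 2)
    X <- tfidf_transform(fit_tfidf(texts, min_df = 1), texts)
    fold <- radconcept:::stratified_folds(y, 5)
    # naive: selection and reporting share the same folds
    naive_acc <- max(vapply(seq_len(nrow(grid)), function(gi)
      cv_acc(X, y, fold, grid[gi, ]), 0))
    # nested: per outer fold, select on inner folds of the training part,
    # then score the held-out fold once
    hits <- 0
    for (k in 1:5) {
      tr <- which(fold != k); te <- which(fold == k)
      inner <- radconcept:::stratified_folds(y[tr], 2)
      best <- which.max(vapply(seq_len(nrow(grid)), function(gi)
        cv_acc(X[tr, ], y[tr], inner, grid[gi, ]), 0))
      g <- grid[best, ]
      fit <- gbt_train(X[tr, ], y[tr], nrounds = g$nrounds, eta = g$eta,
                       max_depth = g$max_depth)
      hits <- hits + sum((predict(fit, X[te, ]) >= 0.5) == y[te])
    }
    naive_acc - hits / n
  })
  # one-sided check: mean gap not significantly below zero
  expect_gte(mean(gaps), -2 * sd(gaps) / sqrt(length(gaps)))
})

test_that("final model predicts deterministically and degrades gracefully", {
  sep <- separable_corpus(60, seed = 45)
  res <- nested_cv_train(sep$texts, sep$y, grid = small_grid,
                         n_trials = 1, n_inner = 2, seed = 3)
  mdl <- res$final_model
  p <- predict(mdl, sep$texts)
  expect_equal(p$label, sep$y)
  expect_true(all(p$score >= 0 & p$score <= 1))

  # duplicating the decisive token does not lower the score
  p1 <- predict(mdl, "malignant lesion")$score
  p2 <- predict(mdl, "malignant lesion malignant malignant")$score
  expect_gte(p2, p1 - 1e-9)

  # empty text scores on all-zero features without failure
  expect_no_error(predict(mdl, ""))

  untrained <- structure(list(trained = FALSE), class = "ml_model")
  expect_error(predict(untrained, "x"), "not been trained")
})
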
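test_that("confusion counts by definition", {
  cc <- confusion(c(1, 1, 0), c(1, 0, 0))
  expect_equal(unclass(cc)[c("tp", "fn", "tn", "fp")],
               list(tp = 1L, fn = 1L, tn = 1L, fp = 0L))

  y <- rbinom(50, 1, 0.5)
  cc2 <- confusion(y, y)
  expect_equal(cc2$fp + cc2$fn, 0L)
  expect_error(confusion(c(1, 0), c(1)), "length")

  # 1,000 random label pairs vs an element-wise tally
  set.seed(31)
  for (rep in 1:5) {
    yt <- sample(0:1, 200, replace = TRUE)
    yp <- sample(0:1, 200, replace = TRUE)
    cc <- confusion(yt, yp)
    tally <- c(tp = 0, fp = 0, fn = 0, tn = 0)
    for (i in seq_along(yt)) {
      k <- if (yt[i] == 1 && yp[i] == 1) "tp"
      else if (yt[i] == 0 && yp[i] == 1) "fp"
      else if (yt[i] == 1 && yp[i] == 0) "fn"
      else "tn"
      tally[k] <- tally[k] + 1
    }
    expect_equal(unlist(unclass(cc)), tally[c("tp", "fp", "fn", "tn")],
                 ignore_attr = TRUE)
    expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 200L)
  }

  # per-concept one-vs-rest
  pc <- confusion_per_concept(c(0, 1, 2, 3, 1), c(0, 1, 2, 0, 2))
  expect_named(pc, c("1", "2", "3"))
  expect_equal(pc[["1"]]$tp, 1L)
  expect_equal(pc[["3"]]$fn, 1L)
})

test_that("metrics match direct formulas and flag undefined values", {
  m <- metrics(confusion(c(rep(1, 10), rep(0, 10)),
                         c(rep(1, 10), rep(0, 10))))
  expect_equal(unlist(m[c("sensitivity", "ppv", "npv", "f1", "accuracy")]),
               rep(1, 5), ignore_attr = TRUE)

  set.seed(32)
  for (rep in 1:500) {
    cc <- structure(as.list(setNames(sample(0:20, 4, replace = TRUE),
                                     c("tp", "fp", "fn", "tn"))),
                    class = "confusion_counts")
    total <- cc$tp + cc$fp + cc$fn + cc$tn
    if (total == 0) {
      expect_error(metrics(cc), "empty")
      next
    }
    m <- metrics(cc, rounding = NULL)
    exp_sens <- if (cc$tp + cc$fn == 0) NA_real_ else cc$tp / (cc$tp + cc$fn)
    exp_ppv <- if (cc$tp + cc$fp == 0) NA_real_ else cc$tp / (cc$tp + cc$fp)
    exp_npv <- if (cc$tn + cc$fn == 0) NA_real_ else cc$tn / (cc$tn + cc$fn)
    expect_equal(m$sensitivity, exp_sens, tolerance = 1e-12)
    expect_equal(m$ppv, exp_ppv, tolerance = 1e-12)
    expect_equal(m$npv, exp_npv, tolerance = 1e-12)
    expect_equal(m$accuracy * total, cc$tp + cc$tn, tolerance = 1e-12)
    # harmonic-mean identity wherever defined
    if (!is.na(m$f1)) {
      expect_equal(m$f1, 2 * m$ppv * m$sensitivity / (m$ppv + m$sensitivity),
                   tolerance = 1e-12)
    }
  }

  # undefined marker, not silent zero
  m0 <- metrics(structure(list(tp = 0, fp = 0, fn = 5, tn = 5),
                          class = "confusion_counts"))
  expect_true(is.na(m0$ppv))
  expect_false(is.na(m0$npv))
})

test_that("rounding is half away from zero at the printed precision", {
  expect_equal(round_half_up(0.905, 2), 0.91)
  expect_equal(round_half_up(0.845, 2), 0.85)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(format_mean_sd(0.7701, 0.0249), "0.77(0.02)")
})

test_that("bootstrap_evaluate is reproducible and well-formatted", {
  set.seed(33)
  y <- rbinom(120, 1, 0.4)
  br <- bootstrap_evaluate(y, y, n_trials = 20, seed = 9)
  expect_equal(br$mean$accuracy, 1)
  expect_equal(br$sd$accuracy, 0)
  expect_equal(br$formatted[["accuracy"]], "1.00(0.00)")
  expect_true(all(grepl("^\\d\\.\\d{2}\\(\\d\\.\\d{2}\\)$", br$formatted)))

  br2 <- bootstrap_evaluate(y, y, n_trials = 20, seed = 9)
  expect_identical(br$trials, br2$trials)

  # undefined trials are excluded with a count
  y1 <- c(1, rep(0, 30))
  p1 <- c(0, rep(0, 30))
  br3 <- bootstrap_evaluate(y1, p1, n_trials = 50, seed = 2)
  expect_true(br3$n_undefined$sensitivity > 0)
  expect_false(is.na(br3$mean$accuracy))

  # callable predictions: resampled classifier application
  pred_fn <- function(idx) y[idx]
  br4 <- bootstrap_evaluate(y, pred_fn, n_trials = 5, seed = 1)
  expect_equal(br4$mean$f1, 1)
})

test_that("roc_auc equals the all-pairs Mann-Whitney statistic", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_error(roc_auc(c(1, 1), c(0.5, 0.6)), "both classes")

  set.seed(34)
  for (rep in 1:200) {
    n <- sample(6:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(c(1, 2, 8), 1))  # induce ties sometimes
    auc <- roc_auc(y, s)
    pos <- which(y == 1); neg <- which(y == 0)
    wins <- 0
    for (i in pos) for (j in neg) {
      wins <- wins + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    }
    expect_equal(auc, wins / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }

  # curve points span (0,0) to (1,1)
  y <- c(0, 1, 0, 1, 1)
  pts <- roc_points(y, c(0.2, 0.7, 0.4, 0.6, 0.9))
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
})

test_that("bootstrap SD shrinks toward the binomial standard error", {
  set.seed(35)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  p <- ifelse(runif(n) < 0.85, y, 1 - y)  # ~85% accurate predictions
  acc <- mean(y == p)
  br <- bootstrap_evaluate(y, p, n_trials = 200, seed = 3)
  se <- sqrt(acc * (1 - acc) / n)
  expect_lt(abs(br$sd$accuracy - se), 0.5 * se)
  expect_lt(abs(br$mean$accuracy - acc), 2 * br$sd$accuracy + 1e-9)
})
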
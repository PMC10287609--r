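#' Confusion counts for a binary or one-vs-rest task
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive_label the label counted as positive; everything else is
#'   negative.
#' @return a `confusion_counts` list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(y_true, y_pred, positive_label = 1L) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred have different lengths (", length(y_true),
         " vs ", length(y_pred), ")")
  }
  t_pos <- y_true == positive_label
  p_pos <- y_pred == positive_label
  structure(list(
    tp = sum(t_pos & p_pos),
    fp = sum(!t_pos & p_pos),
    fn = sum(t_pos & !p_pos),
    tn = sum(!t_pos & !p_pos)
  ), class = "confusion_counts")
}

#' Per-concept one-vs-rest confusion counts
#'
#' @param y_true,y_pred multiclass label vectors (0 = no concept).
#' @param labels the concept labels to tabulate (default: all non-zero
#'   labels present in the truth).
#' @return named list of `confusion_counts`, one per label.
#' @export
confusion_per_concept <- function(y_true, y_pred, labels = NULL) {
  if (is.null(labels)) labels <- sort(setdiff(unique(y_true), 0L))
  setNames(lapply(labels, function(l) confusion(y_true, y_pred, l)),
           as.character(labels))
}

#' The five report-classification metrics
#'
#' Sensitivity `tp/(tp+fn)`, positive predictive value `tp/(tp+fp)`,
#' negative predictive value `tn/(tn+fn)`, accuracy `(tp+tn)/total` and F1
#' (harmonic mean of PPV and sensitivity). A metric whose denominator is
#' zero is *undefined* and reported as `NA` — never silently coerced to 0,
#' so a zero-false-positive evaluation keeps its PPV of exactly 1 while a
#' no-positive-call evaluation shows PPV as undefined.
#'
#' @param c a `confusion_counts`.
#' @param rounding decimal places for the rounded view (`NULL` = none);
#'   full-precision values are always retained in `$raw`.
#' @return a `metric_set` list: `sensitivity`, `ppv`, `npv`, `f1`,
#'   `accuracy` (rounded when requested) and `raw`.
#' @export
metrics <- function(c, rounding = 2) {
  total <- c$tp + c$fp + c$fn + c$tn
  if (total == 0) stop("empty confusion counts: nothing was evaluated")
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- div(c$tp, c$tp + c$fn)
  ppv <- div(c$tp, c$tp + c$fp)
  npv <- div(c$tn, c$tn + c$fn)
  acc <- (c$tp + c$tn) / total
  f1 <- if (is.na(sens) || is.na(ppv) || (sens + ppv) == 0) NA_real_
        else 2 * ppv * sens / (ppv + sens)
  raw <- list(sensitivity = sens, ppv = ppv, npv = npv, f1 = f1,
              accuracy = acc)
  out <- if (is.null(rounding)) raw else lapply(raw, round_half_up, rounding)
  out$raw <- raw
  structure(out, class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "sensitivity %s  ppv %s  f1 %s  npv %s  accuracy %s\n",
    format(x$sensitivity), format(x$ppv), format(x$f1), format(x$npv),
    format(x$accuracy)))
  invisible(x)
}

#' Bootstrap evaluation of a classifier's predictions
#'
#' Resamples report indices with replacement to the original evaluation-set
#' size, `n_trials` times, recomputing all five metrics per trial, and
#' reports the per-metric mean and SD in the `"0.77(0.02)"` style. A trial
#' whose resample lacks a class leaves the affected metrics undefined for
#' that trial; undefined values are excluded from the mean/SD with a
#' logged count.
#'
#' @param y_true gold binary labels of the evaluation set.
#' @param y_pred predicted labels, aligned with `y_true`; alternatively a
#'   function of the resampled index vector returning predictions (for
#'   classifiers re-applied to resampled inputs).
#' @param n_trials number of bootstrap trials.
#' @param seed RNG seed (trial resamples are reproducible).
#' @param positive_label positive class.
#' @return a `bootstrap_result`: `trials` (data.frame of per-trial
#'   metrics), `mean`, `sd`, `formatted`, `n_undefined`.
#' @export
bootstrap_evaluate <- function(y_true, y_pred, n_trials = 20, seed = 1L,
                               positive_label = 1L) {
  n <- length(y_true)
  if (!n) stop("empty evaluation set")
  pred_fn <- if (is.function(y_pred)) y_pred else function(idx) y_pred[idx]
  rows <- with_seed(seed, {
    lapply(seq_len(n_trials), function(t) {
      idx <- sample.int(n, n, replace = TRUE)
      m <- metrics(confusion(y_true[idx], pred_fn(idx), positive_label),
                   rounding = NULL)
      unlist(m$raw)
    })
  })
  trials <- as.data.frame(do.call(rbind, rows))
  mu <- vapply(trials, function(v) mean(v, na.rm = TRUE), 0)
  sdev <- vapply(trials, function(v) sd(v, na.rm = TRUE), 0)
  n_undef <- vapply(trials, function(v) sum(is.na(v)), 0L)
  structure(list(
    n_trials = n_trials,
    trials = trials,
    mean = as.list(mu),
    sd = as.list(sdev),
    formatted = setNames(
      mapply(format_mean_sd, mu, sdev, SIMPLIFY = TRUE),
      names(mu)),
    n_undefined = as.list(n_undef)
  ), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> ", x$n_trials, " trials\n", sep = "")
  for (nm in names(x$formatted)) {
    cat(sprintf("  %-11s %s", nm, x$formatted[[nm]]))
    if (x$n_undefined[[nm]] > 0) {
      cat(sprintf("  [%d undefined trial(s) excluded]",
                  x$n_undefined[[nm]]))
    }
    cat("\n")
  }
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formulation with midranks for tied
#' scores, which is exactly the probability that a random positive scores
#' above a random negative (ties counting one half).
#'
#' @param y_true binary labels (positive = `positive_label`).
#' @param scores real-valued classifier scores.
#' @param positive_label positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores, positive_label = 1L) {
  pos <- y_true == positive_label
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("roc_auc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points for plotting
#'
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `fpr`, `tpr`, sorted for plotting.
#' @export
roc_points <- function(y_true, scores, positive_label = 1L) {
  pos <- y_true == positive_label
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("roc_points needs both classes present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(pos & scores >= t) / n1, 0)
  fpr <- vapply(thr, function(t) sum(!pos & scores >= t) / n0, 0)
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}
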
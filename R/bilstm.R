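#' Encode a corpus as padded integer sequences
#'
#' Builds a frequency-ranked token->index vocabulary from the supplied
#' texts (training texts only — pass the fitted `vocab` back in to encode
#' held-out documents), then maps each document to a fixed-length integer
#' sequence. Index 0 is reserved for padding and index 1 for
#' out-of-vocabulary tokens; in-vocabulary token `j` gets index `j + 1`.
#' Sequences longer than `max_len` are truncated, shorter ones padded at
#' the end.
#'
#' @param texts preprocessed (lowercase) document texts.
#' @param max_len sequence length (must be >= 1).
#' @param vocab_size maximum number of vocabulary tokens.
#' @param vocab existing vocabulary character vector (optional).
#' @return a `sequence_batch`: list with `ids` (n x max_len integer
#'   matrix), `vocab`, `max_len`.
#' @export
encode_corpus <- function(texts, max_len = 200, vocab_size = 2000,
                          vocab = NULL) {
  if (max_len < 1) stop("max_len must be >= 1")
  toks <- tokenize_ws(texts)
  if (is.null(vocab)) {
    tab <- table(unlist(toks))
    ord <- order(-as.numeric(tab), names(tab))
    vocab <- head(names(tab)[ord], vocab_size)
  }
  lut <- setNames(seq_along(vocab) + 1L, vocab)
  ids <- matrix(0L, nrow = length(texts), ncol = max_len)
  for (d in seq_along(toks)) {
    tk <- head(toks[[d]], max_len)
    if (!length(tk)) next
    v <- lut[tk]
    v[is.na(v)] <- 1L
    ids[d, seq_along(v)] <- as.integer(v)
  }
  structure(list(ids = ids, vocab = vocab, max_len = max_len),
            class = "sequence_batch")
}

#' Recover the token sequence from an encoded row
#'
#' @param batch a `sequence_batch`.
#' @param i row index.
#' @return character vector; OOV tokens appear as `"<oov>"`, padding is
#'   dropped.
#' @export
decode_sequence <- function(batch, i) {
  v <- batch$ids[i, ]
  v <- v[v != 0L]
  out <- character(length(v))
  out[v == 1L] <- "<oov>"
  out[v > 1L] <- batch$vocab[v[v > 1L] - 1L]
  out
}

#' Bi-LSTM architecture specification
#'
#' Two fixed architectures are provided. `"simple"` is the 5-layer stack
#' embedding, Bi-LSTM, Bi-LSTM, dense, output. `"dropout"` is the 13-layer
#' stack that interleaves a dropout layer after the embedding, after each
#' Bi-LSTM, and after each of three dense layers. A bidirectional LSTM
#' counts as one layer; the sigmoid output is one layer. The classifier
#' reads the concatenated final hidden states of the top Bi-LSTM (forward
#' direction at the last step, backward direction at the first).
#'
#' @param arch `"simple"` or `"dropout"`.
#' @param embed_dim embedding dimension.
#' @param hidden LSTM hidden size per direction.
#' @param seq_len padded sequence length.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param dropout dropout rate (dropout architecture only).
#' @param vocab_size vocabulary cap for [encode_corpus()].
#' @param seed RNG seed for initialization, splits and shuffling.
#' @return a `bilstm_spec`.
#' @export
bilstm_spec <- function(arch = c("simple", "dropout"), embed_dim = 32,
                        hidden = 16, seq_len = 200, epochs = 8,
                        batch_size = 32, lr = 0.02, dropout = 0.3,
                        vocab_size = 2000, seed = 1L) {
  arch <- match.arg(arch)
  structure(list(arch = arch, embed_dim = embed_dim, hidden = hidden,
                 seq_len = seq_len, epochs = epochs,
                 batch_size = batch_size, lr = lr,
                 dropout = if (arch == "dropout") dropout else 0,
                 vocab_size = vocab_size, seed = seed),
            class = "bilstm_spec")
}

#' Layer listing of a Bi-LSTM architecture
#'
#' @param spec a `bilstm_spec`.
#' @return character vector of layer names (length 5 or 13).
#' @export
bilstm_layers <- function(spec) {
  if (spec$arch == "simple") {
    c("embedding", "bilstm_1", "bilstm_2", "dense", "output")
  } else {
    c("embedding", "dropout_1", "bilstm_1", "dropout_2", "bilstm_2",
      "dropout_3", "dense_1", "dropout_4", "dense_2", "dropout_5",
      "dense_3", "dropout_6", "output")
  }
}

# ---- parameter plumbing -----------------------------------------------

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -s, s), nr, nc)
}

lstm_params <- function(input_dim, H) {
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias starts open
  list(Wx = glorot(input_dim, 4 * H), Wh = glorot(H, 4 * H), b = b)
}

# Flat named list of all trainable matrices/vectors. Embedding row 1 is the
# padding row, kept at zero (its gradient is zeroed after backprop).
bilstm_init_params <- function(spec, n_embed_rows) {
  E <- spec$embed_dim; H <- spec$hidden
  p <- list(emb = glorot(n_embed_rows, E) * 0.5)
  p$emb[1, ] <- 0
  for (nm in c("l1f", "l1b")) p[[nm]] <- lstm_params(E, H)
  for (nm in c("l2f", "l2b")) p[[nm]] <- lstm_params(2 * H, H)
  n_dense <- if (spec$arch == "dropout") 3L else 1L
  dims <- c(2 * H, rep(H, n_dense))
  p$dense <- lapply(seq_len(n_dense), function(i)
    list(W = glorot(dims[i], dims[i + 1]), b = rep(0, dims[i + 1])))
  p$out <- list(W = glorot(H, 1), b = 0)
  p
}

# ---- forward / backward -----------------------------------------------

sigm <- function(x) 1 / (1 + exp(-x))

# Run one LSTM direction over a list of per-timestep input matrices.
lstm_run <- function(xs, p, reverse = FALSE) {
  T_ <- length(xs); B <- nrow(xs[[1]]); H <- nrow(p$Wh)
  ord <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  hs <- vector("list", T_); caches <- vector("list", T_)
  bmat <- matrix(p$b, B, 4 * H, byrow = TRUE)
  for (s in seq_along(ord)) {
    t <- ord[s]
    z <- xs[[t]] %*% p$Wx + h %*% p$Wh + bmat
    i <- sigm(z[, 1:H, drop = FALSE])
    f <- sigm(z[, (H + 1):(2 * H), drop = FALSE])
    o <- sigm(z[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    caches[[s]] <- list(t = t, x = xs[[t]], i = i, f = f, o = o, g = g,
                        c_prev = cc, h_prev = h, tanh_c = tc)
    h <- h_new; cc <- c_new
    hs[[t]] <- h_new
  }
  list(hs = hs, caches = caches, reverse = reverse)
}

# Backward pass of one direction. dhs is a list of upstream gradients per
# timestep (zeros where the timestep output is unused).
lstm_bwd <- function(dhs, run, p) {
  caches <- run$caches
  T_ <- length(caches)
  B <- nrow(caches[[1]]$x); H <- nrow(p$Wh)
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dxs <- vector("list", T_)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (s in rev(seq_len(T_))) {
    cc <- caches[[s]]
    dh <- dh_next
    if (!is.null(dhs[[cc$t]])) dh <- dh + dhs[[cc$t]]
    do_ <- dh * cc$tanh_c
    dc <- dh * cc$o * (1 - cc$tanh_c^2) + dc_next
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    da <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do_ * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dWx <- dWx + crossprod(cc$x, da)
    dWh <- dWh + crossprod(cc$h_prev, da)
    db <- db + colSums(da)
    dxs[[cc$t]] <- da %*% t(p$Wx)
    dh_next <- da %*% t(p$Wh)
  }
  list(Wx = dWx, Wh = dWh, b = db, dxs = dxs)
}

drop_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix(rbinom(nr * nc, 1, 1 - rate) / (1 - rate), nr, nc)
}

apply_mask <- function(x, m) if (is.null(m)) x else x * m

# Full forward pass; with train = TRUE dropout masks are sampled (from the
# ambient RNG) and cached for the backward pass.
bilstm_forward <- function(params, ids, spec, train = FALSE) {
  B <- nrow(ids); T_ <- ncol(ids); H <- spec$hidden
  rate <- if (train) spec$dropout else 0
  xs <- vector("list", T_); mx <- vector("list", T_)
  for (t in seq_len(T_)) {
    x <- params$emb[ids[, t] + 1L, , drop = FALSE]
    mx[t] <- list(drop_mask(B, ncol(x), rate))
    xs[[t]] <- apply_mask(x, mx[[t]])
  }
  r1f <- lstm_run(xs, params$l1f, reverse = FALSE)
  r1b <- lstm_run(xs, params$l1b, reverse = TRUE)
  o1 <- vector("list", T_); mo1 <- vector("list", T_)
  for (t in seq_len(T_)) {
    o <- cbind(r1f$hs[[t]], r1b$hs[[t]])
    mo1[t] <- list(drop_mask(B, 2 * H, rate))
    o1[[t]] <- apply_mask(o, mo1[[t]])
  }
  r2f <- lstm_run(o1, params$l2f, reverse = FALSE)
  r2b <- lstm_run(o1, params$l2b, reverse = TRUE)
  feat <- cbind(r2f$hs[[T_]], r2b$hs[[1]])
  mfeat <- drop_mask(B, 2 * H, rate)
  feat_d <- apply_mask(feat, mfeat)
  acts <- list(); mdense <- list()
  a <- feat_d
  for (i in seq_along(params$dense)) {
    pre <- a %*% params$dense[[i]]$W +
      matrix(params$dense[[i]]$b, B, length(params$dense[[i]]$b),
             byrow = TRUE)
    act <- tanh(pre)
    mdense[i] <- list(drop_mask(B, ncol(act), rate))
    acts[[i]] <- list(input = a, act = act)
    a <- apply_mask(act, mdense[[i]])
  }
  logit <- drop(a %*% params$out$W) + params$out$b
  prob <- sigm(logit)
  list(prob = prob, cache = list(ids = ids, xs = xs, mx = mx, r1f = r1f,
                                 r1b = r1b, o1 = o1, mo1 = mo1, r2f = r2f,
                                 r2b = r2b, feat = feat, mfeat = mfeat,
                                 acts = acts, mdense = mdense,
                                 head_in = a))
}

bilstm_backward <- function(params, fwd, y, spec) {
  cache <- fwd$cache
  B <- nrow(cache$ids); T_ <- ncol(cache$ids); H <- spec$hidden
  grads <- list()
  dlogit <- (fwd$prob - y) / B
  grads$out <- list(W = crossprod(cache$head_in, matrix(dlogit, B, 1)),
                    b = sum(dlogit))
  da <- matrix(dlogit, B, 1) %*% t(params$out$W)
  grads$dense <- vector("list", length(params$dense))
  for (i in rev(seq_along(params$dense))) {
    da <- apply_mask(da, cache$mdense[[i]])
    dpre <- da * (1 - cache$acts[[i]]$act^2)
    grads$dense[[i]] <- list(W = crossprod(cache$acts[[i]]$input, dpre),
                             b = colSums(dpre))
    da <- dpre %*% t(params$dense[[i]]$W)
  }
  dfeat <- apply_mask(da, cache$mfeat)
  zero <- function() matrix(0, B, H)
  dhs2f <- vector("list", T_); dhs2b <- vector("list", T_)
  dhs2f[[T_]] <- dfeat[, 1:H, drop = FALSE]
  dhs2b[[1]] <- dfeat[, (H + 1):(2 * H), drop = FALSE]
  b2f <- lstm_bwd(dhs2f, cache$r2f, params$l2f)
  b2b <- lstm_bwd(dhs2b, cache$r2b, params$l2b)
  grads$l2f <- b2f[c("Wx", "Wh", "b")]
  grads$l2b <- b2b[c("Wx", "Wh", "b")]
  dhs1f <- vector("list", T_); dhs1b <- vector("list", T_)
  for (t in seq_len(T_)) {
    do1 <- b2f$dxs[[t]] + b2b$dxs[[t]]
    do1 <- apply_mask(do1, cache$mo1[[t]])
    dhs1f[[t]] <- do1[, 1:H, drop = FALSE]
    dhs1b[[t]] <- do1[, (H + 1):(2 * H), drop = FALSE]
  }
  b1f <- lstm_bwd(dhs1f, cache$r1f, params$l1f)
  b1b <- lstm_bwd(dhs1b, cache$r1b, params$l1b)
  grads$l1f <- b1f[c("Wx", "Wh", "b")]
  grads$l1b <- b1b[c("Wx", "Wh", "b")]
  demb <- params$emb * 0
  for (t in seq_len(T_)) {
    dx <- apply_mask(b1f$dxs[[t]] + b1b$dxs[[t]], cache$mx[[t]])
    agg <- rowsum(dx, group = cache$ids[, t] + 1L)
    rows <- as.integer(rownames(agg))
    demb[rows, ] <- demb[rows, , drop = FALSE] + agg
  }
  demb[1, ] <- 0  # padding row stays frozen
  grads$emb <- demb
  grads
}

bilstm_loss <- function(prob, y) {
  eps <- 1e-9
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

# loss + full gradient in one call (used by the finite-difference test)
bilstm_loss_grad <- function(params, ids, y, spec) {
  fwd <- bilstm_forward(params, ids, spec, train = FALSE)
  list(loss = bilstm_loss(fwd$prob, y),
       grads = bilstm_backward(params, fwd, y, spec))
}

# ---- flat parameter walking + Adam ------------------------------------

flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    v <- p[[nm]]
    key <- paste0(prefix, nm)
    if (is.list(v) && is.null(names(v))) {
      for (i in seq_along(v)) {
        out <- c(out, flatten_params(v[[i]], paste0(key, i, ".")))
      }
    } else if (is.list(v)) {
      out <- c(out, flatten_params(v, paste0(key, ".")))
    } else {
      out[[key]] <- v
    }
  }
  out
}

unflatten_into <- function(p, flat, prefix = "") {
  for (nm in names(p)) {
    v <- p[[nm]]
    key <- paste0(prefix, nm)
    if (is.list(v) && is.null(names(v))) {
      for (i in seq_along(v)) {
        p[[nm]][[i]] <- unflatten_into(v[[i]], flat, paste0(key, i, "."))
      }
    } else if (is.list(v)) {
      p[[nm]] <- unflatten_into(v, flat, paste0(key, "."))
    } else {
      p[[nm]] <- flat[[key]]
    }
  }
  p
}

adam_step <- function(flat_p, flat_g, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  gn <- sqrt(sum(vapply(flat_g, function(g) sum(g^2), 0)))
  clip <- if (gn > 5) 5 / gn else 1
  for (nm in names(flat_p)) {
    g <- flat_g[[nm]] * clip
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    flat_p[[nm]] <- flat_p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = flat_p, state = state)
}

# ---- training ---------------------------------------------------------

fit_bilstm_core <- function(ids, y, spec, n_embed_rows) {
  params <- bilstm_init_params(spec, n_embed_rows)
  flat <- flatten_params(params)
  state <- list(m = lapply(flat, function(x) x * 0),
                v = lapply(flat, function(x) x * 0))
  n <- nrow(ids)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        acc = numeric())
  step <- 0L
  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    losses <- c(); hits <- 0L
    for (start in seq(1, n, by = spec$batch_size)) {
      bi <- ord[start:min(start + spec$batch_size - 1L, n)]
      fwd <- bilstm_forward(params, ids[bi, , drop = FALSE], spec,
                            train = TRUE)
      grads <- bilstm_backward(params, fwd, y[bi], spec)
      step <- step + 1L
      upd <- adam_step(flatten_params(params), flatten_params(grads),
                       state, spec$lr, step)
      state <- upd$state
      params <- unflatten_into(params, upd$p)
      params$emb[1, ] <- 0
      losses <- c(losses, bilstm_loss(fwd$prob, y[bi]))
      hits <- hits + sum((fwd$prob >= 0.5) == (y[bi] == 1))
    }
    history <- rbind(history, data.frame(epoch = ep, loss = mean(losses),
                                         acc = hits / n))
  }
  list(params = params, history = history)
}

#' Train a Bi-LSTM report classifier with a 70:30 split
#'
#' Stratified 70:30 train/test split (by the spec's seed), vocabulary and
#' model fit on the training partition only, probabilities returned for the
#' held-out partition. Training is exactly reproducible from the seed: the
#' implementation is plain R with no nondeterministic backend.
#'
#' @param texts preprocessed document texts.
#' @param labels binary 0/1 labels.
#' @param spec a [bilstm_spec()].
#' @param train_frac training fraction (default 0.7).
#' @return list with `model` (a `bilstm_model`), `history`, `test_idx`,
#'   `test_scores`, `test_metrics`.
#' @export
train_bilstm <- function(texts, labels, spec, train_frac = 0.7) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("training requires both classes present")
  }
  with_seed(spec$seed, {
    tr <- integer(0)
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      tr <- c(tr, idx[seq_len(max(1L, round(train_frac * length(idx))))])
    }
    tr <- sort(tr)
    te <- setdiff(seq_along(labels), tr)
    if (!length(te)) stop("test partition is empty; lower train_frac")
    if (length(unique(labels[tr])) < 2) stop("degenerate split")
    enc <- encode_corpus(texts[tr], max_len = spec$seq_len,
                         vocab_size = spec$vocab_size)
    fit <- fit_bilstm_core(enc$ids, labels[tr], spec,
                           n_embed_rows = length(enc$vocab) + 2L)
    model <- structure(list(params = fit$params, vocab = enc$vocab,
                            spec = spec, trained = TRUE),
                       class = "bilstm_model")
    test_scores <- predict(model, texts[te])
    m <- metrics(confusion(labels[te], as.integer(test_scores >= 0.5)),
                 rounding = NULL)
    list(model = model, history = fit$history, test_idx = te,
         test_scores = test_scores, test_metrics = m)
  })
}

#' @export
predict.bilstm_model <- function(object, newdata, ...) {
  if (!isTRUE(object$trained)) stop("model has not been trained")
  enc <- encode_corpus(newdata, max_len = object$spec$seq_len,
                       vocab = object$vocab)
  # predict in chunks to bound memory
  n <- nrow(enc$ids)
  out <- numeric(n)
  for (start in seq(1, n, by = 64)) {
    bi <- start:min(start + 63, n)
    out[bi] <- bilstm_forward(object$params, enc$ids[bi, , drop = FALSE],
                              object$spec, train = FALSE)$prob
  }
  out
}

#' Stratified k-fold cross-validation of a Bi-LSTM classifier
#'
#' Each document appears in exactly one test fold; per fold the model is
#' trained from scratch on the remaining folds and scored with the five
#' report-classification metrics; the aggregate is mean (SD) across folds.
#'
#' @param texts preprocessed document texts.
#' @param labels binary 0/1 labels.
#' @param spec a [bilstm_spec()].
#' @param k number of folds (>= 2).
#' @return list with `fold` assignment, `fold_metrics` (data.frame),
#'   `predictions` (per-document out-of-fold scores), `mean`, `sd`,
#'   `formatted`.
#' @export
crossval_bilstm <- function(texts, labels, spec, k = 5) {
  if (k < 2) stop("k must be >= 2")
  labels <- as.integer(labels)
  fold <- with_seed(spec$seed, stratified_folds(labels, k))
  preds <- numeric(length(labels))
  rows <- list()
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    fit <- with_seed(spec$seed + f, {
      enc <- encode_corpus(texts[tr], max_len = spec$seq_len,
                           vocab_size = spec$vocab_size)
      core <- fit_bilstm_core(enc$ids, labels[tr], spec,
                              n_embed_rows = length(enc$vocab) + 2L)
      structure(list(params = core$params, vocab = enc$vocab, spec = spec,
                     trained = TRUE), class = "bilstm_model")
    })
    preds[te] <- predict(fit, texts[te])
    m <- metrics(confusion(labels[te], as.integer(preds[te] >= 0.5)),
                 rounding = NULL)
    rows[[f]] <- data.frame(fold = f, as.data.frame(m$raw))
  }
  fold_metrics <- do.call(rbind, rows)
  mu <- vapply(fold_metrics[-1], mean, 0, na.rm = TRUE)
  sdev <- vapply(fold_metrics[-1], sd, 0, na.rm = TRUE)
  list(fold = fold, fold_metrics = fold_metrics, predictions = preds,
       mean = as.list(mu), sd = as.list(sdev),
       formatted = setNames(mapply(format_mean_sd, mu, sdev), names(mu)))
}
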
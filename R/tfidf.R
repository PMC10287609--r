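#' Fit a tf-idf vectorizer
#'
#' Term frequency-inverse document frequency weighting of a document-term
#' matrix over word n-grams. The variant is the common smoothed one:
#' `idf(t) = ln((1 + n) / (1 + df(t))) + 1` with raw term counts as tf and
#' L2-normalized rows, so a single-document corpus degenerates gracefully
#' (all idf equal) and unseen terms at transform time contribute nothing.
#'
#' @param texts preprocessed (lowercase, space-separated) document texts.
#' @param ngram integer vector of n-gram sizes (default unigrams+bigrams).
#' @param min_df minimum number of documents a term must appear in.
#' @return a `tfidf_model` with `vocabulary` (term -> 1-based column),
#'   `idf`, `ngram`, `min_df`.
#' @export
fit_tfidf <- function(texts, ngram = 1:2, min_df = 2) {
  if (!length(texts)) stop("cannot fit tf-idf on an empty corpus")
  grams <- lapply(tokenize_ws(texts), make_ngrams, ngram = ngram)
  df_counts <- table(unlist(lapply(grams, unique)))
  keep <- names(df_counts)[df_counts >= min_df]
  if (!length(keep)) {
    # degenerate tiny corpus: fall back to df >= 1 so the matrix is usable
    keep <- names(df_counts)
  }
  keep <- sort(keep)
  n <- length(texts)
  df_kept <- as.numeric(df_counts[keep])
  structure(list(
    vocabulary = setNames(seq_along(keep), keep),
    idf = setNames(log((1 + n) / (1 + df_kept)) + 1, keep),
    ngram = ngram,
    min_df = min_df
  ), class = "tfidf_model")
}

make_ngrams <- function(toks, ngram) {
  out <- character(0)
  for (g in ngram) {
    if (length(toks) < g) next
    if (g == 1L) {
      out <- c(out, toks)
    } else {
      m <- length(toks) - g + 1L
      parts <- lapply(seq_len(g) - 1L, function(o) toks[(1 + o):(m + o)])
      out <- c(out, do.call(paste, parts))
    }
  }
  out
}

#' Transform documents into the fitted tf-idf space
#'
#' @param model a `tfidf_model`.
#' @param texts documents to transform.
#' @return a sparse `dgCMatrix`, rows = documents, columns = vocabulary.
#' @export
tfidf_transform <- function(model, texts) {
  stopifnot(inherits(model, "tfidf_model"))
  grams <- lapply(tokenize_ws(texts), make_ngrams, ngram = model$ngram)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (d in seq_along(grams)) {
    cols <- model$vocabulary[grams[[d]]]
    cols <- cols[!is.na(cols)]
    if (!length(cols)) next
    tab <- table(cols)
    j <- as.integer(names(tab))
    w <- as.numeric(tab) * unname(model$idf[j])
    norm <- sqrt(sum(w^2))
    if (norm > 0) w <- w / norm
    ii <- c(ii, rep.int(d, length(j)))
    jj <- c(jj, j)
    xx <- c(xx, w)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(texts), length(model$vocabulary)),
                       dimnames = list(NULL, names(model$vocabulary)))
}
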
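#' The lung-carcinoma concept lexicon
#'
#' A `lexicon` is an ordered set of concept entries, each binding a preferred
#' label and UMLS concept unique identifier (CUI) to a set of lowercase
#' surface phrases ("synonyms") observed in radiology reports: colloquial
#' word orders ("carcinoma lung"), abbreviations ("ca lung", "nsclc"),
#' punctuation-attached variants ("nsclc,") and recurrent misspellings
#' ("sqaumous cell ca lung"). Three concepts are distinguished:
#'
#' * concept 1 — lung carcinoma, CUI `C0684249`
#' * concept 2 — non-small cell lung carcinoma (NSCLC), CUI `C0007131`
#' * concept 3 — small cell lung carcinoma (SCLC), CUI `C0149925`
#'
#' Mapping files are CSV with columns `preferred_label`, `cui`,
#' `concept_index` and a pipe-separated `synonyms` column, so institution-
#' specific dictionaries can be dropped in. A phrase may belong to at most
#' one entry, synonyms are lowercased on load, and a CUI must match
#' `C` + 7 digits.
#'
#' @param path path to a lexicon mapping CSV.
#' @return `load_lexicon()` returns a `lexicon` object: a list with
#'   `entries` (a list of entries, each with `preferred_label`, `cui`,
#'   `concept_index`, `synonyms`) and a free-text `provenance` note.
#' @examples
#' lex <- default_lexicon()
#' lexicon_synonyms(lex, 1)
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 encoding = "UTF-8")
  required <- c("preferred_label", "cui", "concept_index", "synonyms")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("lexicon mapping file is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  entries <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    cui <- trimws(df$cui[i])
    if (!grepl("^C[0-9]{7}$", cui)) {
      stop("malformed CUI '", cui, "' in lexicon row ", i,
           " (expected 'C' followed by 7 digits)")
    }
    syn <- strsplit(df$synonyms[i], "|", fixed = TRUE)[[1]]
    syn <- unique(tolower(trimws(syn)))
    syn <- syn[nzchar(syn)]
    entries[[i]] <- list(
      preferred_label = trimws(df$preferred_label[i]),
      cui = cui,
      concept_index = as.integer(df$concept_index[i]),
      synonyms = syn
    )
  }
  lex <- structure(
    list(entries = entries,
         provenance = paste0("loaded from ", basename(path))),
    class = "lexicon"
  )
  check_phrase_uniqueness(lex)
  lex
}

#' @rdname load_lexicon
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "lung_lexicon.csv",
                           package = "radconcept", mustWork = TRUE))
}

#' @rdname load_lexicon
#' @param lex a `lexicon`.
#' @export
save_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "lexicon"))
  df <- data.frame(
    preferred_label = vapply(lex$entries, `[[`, "", "preferred_label"),
    cui = vapply(lex$entries, `[[`, "", "cui"),
    concept_index = vapply(lex$entries, `[[`, 1L, "concept_index"),
    synonyms = vapply(lex$entries, function(e)
      paste(e$synonyms, collapse = "|"), ""),
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

check_phrase_uniqueness <- function(lex) {
  all_syn <- unlist(lapply(lex$entries, `[[`, "synonyms"))
  dup <- unique(all_syn[duplicated(all_syn)])
  if (length(dup)) {
    owners <- vapply(dup[1], function(p) {
      hit <- vapply(lex$entries, function(e) p %in% e$synonyms, TRUE)
      paste(vapply(lex$entries[hit], `[[`, "", "preferred_label"),
            collapse = "' and '")
    }, "")
    stop("phrase '", dup[1], "' appears in more than one lexicon entry: '",
         owners, "'")
  }
  invisible(TRUE)
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon> ", length(x$entries), " concept entries\n", sep = "")
  for (e in x$entries) {
    cat(sprintf("  [%d] %s (%s): %d synonyms\n", e$concept_index,
                e$preferred_label, e$cui, length(e$synonyms)))
  }
  invisible(x)
}

#' Synonyms of one entry or of the whole lexicon
#'
#' @param lex a `lexicon`.
#' @param concept_index entry selector; `NULL` returns the union over
#'   entries.
#' @return character vector of lowercase phrases.
#' @export
lexicon_synonyms <- function(lex, concept_index = NULL) {
  if (is.null(concept_index)) {
    return(unlist(lapply(lex$entries, `[[`, "synonyms"), use.names = FALSE))
  }
  idx <- vapply(lex$entries, `[[`, 1L, "concept_index")
  unlist(lapply(lex$entries[idx == concept_index], `[[`, "synonyms"),
         use.names = FALSE)
}

#' Add synonym phrases to lexicon entries
#'
#' Customization step: aberrant terms confirmed by expert review are added
#' under the entry whose preferred label they denote. Phrases are lowercased;
#' adding a phrase an entry already owns is a no-op (set semantics); adding a
#' phrase owned by a *different* entry is a conflict. The input lexicon is
#' not modified.
#'
#' @param lex a `lexicon`.
#' @param additions named character vector or list: names are phrases,
#'   values are target preferred labels. A data.frame with columns `phrase`
#'   and `preferred_label` is also accepted.
#' @return a new `lexicon` with the phrases added.
#' @export
add_synonyms <- function(lex, additions) {
  stopifnot(inherits(lex, "lexicon"))
  if (is.data.frame(additions)) {
    phrases <- additions$phrase
    targets <- additions$preferred_label
  } else {
    phrases <- names(additions)
    targets <- unlist(additions, use.names = FALSE)
  }
  if (is.null(phrases) || any(!nzchar(phrases))) {
    stop("additions must map phrase -> preferred_label")
  }
  labels <- vapply(lex$entries, `[[`, "", "preferred_label")
  out <- lex
  for (i in seq_along(phrases)) {
    phrase <- tolower(trimws(phrases[i]))
    j <- match(targets[i], labels)
    if (is.na(j)) stop("unknown preferred_label: '", targets[i], "'")
    owner <- which(vapply(out$entries, function(e) phrase %in% e$synonyms,
                          TRUE))
    if (length(owner) && owner != j) {
      stop("phrase '", phrase, "' already belongs to entry '",
           labels[owner], "'; cannot add it to '", targets[i], "'")
    }
    if (!length(owner)) {
      out$entries[[j]]$synonyms <- c(out$entries[[j]]$synonyms, phrase)
      out$provenance <- paste0(out$provenance, "; +'", phrase, "' -> ",
                               targets[i])
    }
  }
  out
}

#' Propose aberrant candidate phrases for expert review
#'
#' Builds the corpus vocabulary of 1- to 3-grams, keeps those containing an
#' anchor token (disease-root tokens such as "lung" or "ca") that are not
#' already lexicon synonyms, and ranks them by corpus frequency (descending,
#' ties broken lexicographically). Candidates are *proposed only*: accepting
#' them into the lexicon is an expert decision, mirrored by a separate
#' [add_synonyms()] call.
#'
#' @param texts character vector of preprocessed (lowercase) report texts.
#' @param lex a `lexicon`.
#' @param anchors tokens at least one of which must occur in a candidate.
#' @param ngram integer vector of n-gram sizes to enumerate.
#' @return data.frame with columns `phrase` and `freq`, ranked.
#' @export
propose_aberrant_terms <- function(texts, lex,
                                   anchors = c("lung", "ca", "carcinoma",
                                               "nsclc", "sclc"),
                                   ngram = 1:3) {
  if (!length(anchors)) stop("anchors must be non-empty")
  if (!length(texts)) {
    return(data.frame(phrase = character(), freq = integer()))
  }
  known <- lexicon_synonyms(lex)
  counts <- new.env(parent = emptyenv())
  toks_list <- tokenize_ws(texts)
  for (toks in toks_list) {
    for (n in ngram) {
      if (length(toks) < n) next
      for (s in seq_len(length(toks) - n + 1L)) {
        gram_toks <- toks[s:(s + n - 1L)]
        if (!any(gram_toks %in% anchors)) next
        gram <- paste(gram_toks, collapse = " ")
        if (gram %in% known) next
        counts[[gram]] <- (counts[[gram]] %||% 0L) + 1L
      }
    }
  }
  phrases <- ls(counts)
  if (!length(phrases)) {
    return(data.frame(phrase = character(), freq = integer()))
  }
  freq <- vapply(phrases, function(p) counts[[p]], 1L)
  ord <- order(-freq, phrases)
  data.frame(phrase = phrases[ord], freq = unname(freq[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}
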
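# Independent oracles used across the suite. These deliberately avoid the
# package's regex machinery: matching is done by explicit substring
# comparison with manual boundary checks.

# Full phrase table: every lexicon synonym plus the enumeration of the
# generative concept-1 collocations (prefix x head x "lung", and the
# "lung (adeno)carcinoma" forms).
oracle_phrase_table <- function(lex = default_lexicon(),
                                generative = TRUE) {
  rows <- list()
  for (e in lex$entries) {
    for (s in e$synonyms) {
      rows[[length(rows) + 1L]] <- data.frame(
        phrase = s, concept = e$concept_index, cui = e$cui,
        stringsAsFactors = FALSE)
    }
  }
  if (generative) {
    prefixes <- c("", "adeno", "sqaumous cell ", "squamous cell ")
    heads <- c("ca", "ca.", "carcinoma")
    gen <- c(as.vector(outer(prefixes, heads, function(p, h)
               paste0(p, h, " lung"))),
             "lung carcinoma", "lung adenocarcinoma")
    cui1 <- lex$entries[[1]]$cui
    for (g in unique(gen)) {
      rows[[length(rows) + 1L]] <- data.frame(
        phrase = g, concept = 1L, cui = cui1, stringsAsFactors = FALSE)
    }
  }
  unique(do.call(rbind, rows))
}

oracle_is_boundary_before <- function(text, pos) {
  pos == 1L || substr(text, pos - 1L, pos - 1L) == " "
}

oracle_is_boundary_after <- function(text, end) {
  end == nchar(text) ||
    substr(text, end + 1L, end + 1L) %in% c(" ", ".", ",", ";", ")")
}

# All boundary-delimited matches of one phrase in a text (1-based starts).
oracle_phrase_hits <- function(text, phrase) {
  L <- nchar(phrase); n <- nchar(text)
  if (L > n) return(integer(0))
  hits <- integer(0)
  for (pos in seq_len(n - L + 1L)) {
    if (substr(text, pos, pos + L - 1L) == phrase &&
        oracle_is_boundary_before(text, pos) &&
        oracle_is_boundary_after(text, pos + L - 1L)) {
      hits <- c(hits, pos)
    }
  }
  hits
}

# Brute-force analogue of extract_first_concept(): minimal offset, ties to
# the longest surface, then the lowest concept index. Returns NULL or a
# list(concept_index, cui, surface, offset) with 0-based offset.
oracle_first_concept <- function(text, phrases) {
  best <- NULL
  for (r in seq_len(nrow(phrases))) {
    hits <- oracle_phrase_hits(text, phrases$phrase[r])
    if (!length(hits)) next
    off <- min(hits) - 1L
    len <- nchar(phrases$phrase[r])
    if (is.null(best) || off < best$offset ||
        (off == best$offset && len > nchar(best$surface)) ||
        (off == best$offset && len == nchar(best$surface) &&
           phrases$concept[r] < best$concept_index)) {
      best <- list(concept_index = phrases$concept[r],
                   cui = phrases$cui[r],
                   surface = phrases$phrase[r],
                   offset = off)
    }
  }
  best
}

# TRUE when the text contains any phrase of the table as a
# boundary-delimited substring.
oracle_contains_any <- function(text, phrases) {
  for (p in phrases$phrase) {
    if (length(oracle_phrase_hits(text, p))) return(TRUE)
  }
  FALSE
}

# Random lowercase report-like texts over a reduced alphabet, optionally
# with lexicon phrases planted at random positions.
random_texts <- function(n, plant = NULL, min_tok = 3, max_tok = 20) {
  alphabet <- c("mass", "lesion", "seen", "right", "left", "lobe", "lung",
                "ca", "carcinoma", "nsclc", "sclc", "small", "cell",
                "non", "case", "of", "known", "with", "nodal", "pleural",
                "effusion.", "stable,", "adeno")
  vapply(seq_len(n), function(i) {
    k <- sample(min_tok:max_tok, 1)
    toks <- sample(alphabet, k, replace = TRUE)
    if (!is.null(plant)) {
      pos <- sample(k + 1L, 1)
      toks <- append(toks, sample(plant, 1), after = pos - 1L)
    }
    paste(toks, collapse = " ")
  }, "")
}
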
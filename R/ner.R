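#' Compile lexicon phrases into boundary-anchored patterns
#'
#' Every synonym becomes a literal pattern anchored at token boundaries: a
#' match must be preceded by start-of-text or whitespace and followed by
#' end-of-text, whitespace, or one of `.`, `,`, `;`, `)`. The trailing
#' boundary set is what lets `"nsclc,"`-style punctuation-attached mentions
#' match while the `"sclc"` pattern can never fire inside `"nsclc"` (the
#' preceding `n` is not a boundary).
#'
#' With `enable_generative = TRUE` (the default) two morphological templates
#' are added to the concept-1 group so that histology+site collocations not
#' explicitly listed in the dictionary — e.g. "adenoca lung",
#' "squamous cell carcinoma lung" — are still recognized:
#' `(adeno?|<squamous-variant> cell )?(ca|ca.|carcinoma) lung` and
#' `lung (adeno)?carcinoma`.
#'
#' @param lex a `lexicon`.
#' @param enable_generative logical; add the morphological concept-1
#'   templates.
#' @return a `pattern_set`: per-concept lists of perl regexes plus the
#'   CUI binding.
#' @export
compile_patterns <- function(lex, enable_generative = TRUE) {
  stopifnot(inherits(lex, "lexicon"))
  boundary_open <- "(?:^|(?<=\\s))"
  boundary_close <- "(?=$|\\s|[.,;)])"
  groups <- list()
  for (e in lex$entries) {
    pats <- character(0)
    if (!length(e$synonyms)) {
      warning("lexicon entry '", e$preferred_label,
              "' has no synonyms; empty pattern group")
    } else {
      esc <- gsub("([^a-z0-9 ])", "\\\\\\1", e$synonyms, perl = TRUE)
      pats <- paste0(boundary_open, esc, boundary_close)
    }
    key <- as.character(e$concept_index)
    groups[[key]] <- list(
      concept_index = e$concept_index,
      cui = e$cui,
      preferred_label = e$preferred_label,
      patterns = c(groups[[key]]$patterns, pats)
    )
  }
  if (enable_generative && "1" %in% names(groups)) {
    gen <- paste0(
      boundary_open,
      c("(?:(?:adeno|(?:sqaumous|squamous) cell )?(?:ca\\.?|carcinoma)) lung",
        "lung (?:adeno)?carcinoma"),
      boundary_close
    )
    groups[["1"]]$patterns <- c(groups[["1"]]$patterns, gen)
  }
  structure(list(groups = groups, generative = enable_generative),
            class = "pattern_set")
}

#' Find the earliest disease-identification phrase in a report
#'
#' Scans the normalized (lowercase) unified report text with every compiled
#' pattern and returns the match with the minimal character offset across
#' all concepts; ties at equal offset are broken by the longest surface
#' form, then the lowest concept index. Returns `NULL` ("NA" in the results
#' table) when no pattern fires — absence of a match is a value, not an
#' error.
#'
#' @param text one lowercase report text.
#' @param pats a `pattern_set` from [compile_patterns()].
#' @return a `concept_match` list (`concept_index`, `cui`, `surface`,
#'   `offset` 0-based) or `NULL`.
#' @export
extract_first_concept <- function(text, pats) {
  stopifnot(inherits(pats, "pattern_set"), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(NULL)
  best <- NULL
  for (grp in pats$groups) {
    for (p in grp$patterns) {
      m <- regexpr(p, text, perl = TRUE)
      if (m[1] == -1L) next
      off <- as.integer(m[1]) - 1L          # 0-based
      len <- attr(m, "match.length")
      if (is.null(best) ||
          off < best$offset ||
          (off == best$offset && len > nchar(best$surface)) ||
          (off == best$offset && len == nchar(best$surface) &&
             grp$concept_index < best$concept_index)) {
        best <- list(concept_index = grp$concept_index,
                     cui = grp$cui,
                     surface = substr(text, off + 1L, off + len),
                     offset = off)
      }
    }
  }
  if (!is.null(best)) class(best) <- "concept_match"
  best
}

#' Classify one report by its earliest concept mention
#'
#' @param text lowercase unified report text.
#' @param pats a `pattern_set`.
#' @return list with `label` (0 when no concept), `extracted_term` and
#'   `cui` (the string `"NA"` when absent).
#' @export
classify_report <- function(text, pats) {
  m <- extract_first_concept(text, pats)
  if (is.null(m)) {
    list(label = 0L, extracted_term = "NA", cui = "NA")
  } else {
    list(label = m$concept_index, extracted_term = m$surface, cui = m$cui)
  }
}

#' Classify every report in a corpus
#'
#' One output row per input report (order preserved, no cross-record
#' state): `report_key`, `concept_label` 0-3, `extracted_term`, `cui`, and
#' the derived `binary_label` (any concept vs none).
#'
#' @param records a selected `report_corpus` with `unified_text` (or a
#'   plain character vector of texts).
#' @param pats a `pattern_set`.
#' @return data.frame results table.
#' @export
classify_corpus <- function(records, pats) {
  if (is.character(records)) {
    texts <- records
    keys <- sprintf("T%05d", seq_along(texts))
  } else {
    texts <- records$unified_text
    if (is.null(texts)) stop("records lack unified_text; run select_reports()")
    keys <- records$pseudo_id %||% sprintf("T%05d", seq_along(texts))
  }
  rows <- lapply(texts, classify_report, pats = pats)
  data.frame(
    report_key = keys,
    concept_label = vapply(rows, `[[`, 0L, "label"),
    extracted_term = vapply(rows, `[[`, "", "extracted_term"),
    cui = vapply(rows, `[[`, "", "cui"),
    binary_label = as.integer(vapply(rows, `[[`, 0L, "label") > 0L),
    stringsAsFactors = FALSE
  )
}
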
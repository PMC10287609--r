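#' Read a radiology report repository CSV
#'
#' The repository format mirrors a RIS export: one row per report with
#' patient identification columns (`case_number`, `gender`, `name`),
#' `modality`, `report_date`, free-text `findings` and `impression`, and
#' `referred_by`. Optional columns (`dmg`, `gold_concept`, `rule_expected`,
#' `pseudo_id`) are carried through when present. Text fields are preserved
#' byte-for-byte and row order is kept.
#'
#' Rows whose date fails to parse are returned with `report_date = NA` and
#' recorded in the `attr(, "row_errors")` data.frame rather than aborting the
#' read. Rows with both findings and impression blank are flagged
#' (`blank = TRUE`) and excluded later by [select_reports()].
#'
#' @param path CSV path.
#' @param date_format `strptime` format for `report_date`
#'   (default `"%Y-%m-%d"`).
#' @return a `report_corpus` data.frame.
#' @export
read_reports <- function(path, date_format = "%Y-%m-%d") {
  if (!file.exists(path)) stop("report file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 encoding = "UTF-8")
  required <- c("modality", "report_date", "findings", "impression")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("report repository is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("case_number", "gender", "name", "referred_by", "dmg")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  if ("gold_concept" %in% names(df)) {
    df$gold_concept <- as.integer(df$gold_concept)
  }
  if ("rule_expected" %in% names(df)) {
    df$rule_expected <- as.integer(df$rule_expected)
  }
  parsed <- as.Date(df$report_date, format = date_format)
  bad <- which(!is.na(df$report_date) & nzchar(df$report_date) &
                 is.na(parsed))
  row_errors <- data.frame(
    row = bad,
    message = if (length(bad)) {
      paste0("unparseable report_date '", df$report_date[bad], "'")
    } else character(0),
    stringsAsFactors = FALSE
  )
  df$report_date <- parsed
  df$blank <- !nzchar(trimws(df$findings)) & !nzchar(trimws(df$impression))
  out <- structure(df, class = c("report_corpus", "data.frame"))
  attr(out, "row_errors") <- row_errors
  out
}

#' Write a report corpus back to the repository CSV format
#'
#' @param records a `report_corpus` data.frame.
#' @param path output CSV path (UTF-8, header row).
#' @export
write_reports <- function(records, path) {
  df <- as.data.frame(records)
  df$blank <- NULL
  if (inherits(df$report_date, "Date")) {
    df$report_date <- format(df$report_date, "%Y-%m-%d")
  }
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Anonymize a report corpus
#'
#' Strips the patient identification columns (`case_number`, `gender`,
#' `name`), assigns each row a stable `pseudo_id`, and returns the lookup
#' table that reconstructs the mapping. The pseudo-id assignment is a random
#' permutation, deterministic given `seed`, so identifiers cannot be
#' recovered from record order. Duplicate case numbers are mapped to
#' distinct pseudo-ids with a warning.
#'
#' @param records a `report_corpus`.
#' @param seed integer seed for the pseudo-id permutation.
#' @return list with `records` (anonymized corpus) and `lookup`
#'   (data.frame `pseudo_id`, `case_number`, `gender`, `name`).
#' @export
anonymize <- function(records, seed = 1L) {
  n <- nrow(records)
  perm <- with_seed(seed, sample.int(n))
  pseudo <- sprintf("P%05d", perm)
  if (anyDuplicated(records$case_number[!is.na(records$case_number)])) {
    warning("duplicate case_number values: each row still receives a ",
            "distinct pseudo_id")
  }
  lookup <- data.frame(
    pseudo_id = pseudo,
    case_number = records$case_number,
    gender = records$gender,
    name = records$name,
    stringsAsFactors = FALSE
  )
  out <- records
  out$pseudo_id <- pseudo
  out$case_number <- NULL
  out$gender <- NULL
  out$name <- NULL
  list(records = out, lookup = lookup)
}

#' Default clinical stop-word list
#'
#' A compact English function-word list. Negation-bearing tokens (`no`,
#' `not`, `non`) are present here but protected by the default
#' `keep_tokens` of [preprocess()] so that phrases such as
#' "non small cell lung carcinoma" survive preprocessing intact.
#'
#' @return character vector.
#' @export
default_stopwords <- function() {
  c("a", "an", "the", "and", "or", "of", "in", "on", "at", "to", "for",
    "with", "is", "are", "was", "were", "be", "been", "being", "there",
    "this", "that", "these", "those", "it", "its", "as", "by", "from",
    "has", "have", "had", "which", "who", "will", "would", "than", "then",
    "also", "but", "if", "into", "such", "their", "them", "they", "we",
    "our", "no", "not", "non", "both", "any", "all", "same", "so", "s")
}

#' Tokens never removed by stop-word filtering
#'
#' `non`, `no`, `not` guard negated disease names; `small` and `cell` guard
#' the NSCLC/SCLC phrase family.
#'
#' @return character vector.
#' @export
default_keep_tokens <- function() {
  c("non", "no", "not", "small", "cell")
}

#' Lowercase report text and remove reporting-doctor names
#'
#' The cleaning stage of the pipeline: converts text to lowercase, excises
#' every configured doctor-name string (matched case-insensitively as a
#' literal), and leaves everything else untouched. Idempotent.
#'
#' @param text character vector.
#' @param doctor_names character vector of reporting-doctor signature
#'   strings to remove (compared lowercase).
#' @return cleaned character vector.
#' @export
clean_text <- function(text, doctor_names = character()) {
  out <- tolower(text)
  for (nm in doctor_names) {
    nm <- tolower(nm)
    if (nzchar(nm)) out <- gsub(nm, "", out, fixed = TRUE)
  }
  out
}

#' Clean every text field of a corpus
#'
#' Applies [clean_text()] to `findings` and `impression`.
#'
#' @param records a `report_corpus`.
#' @inheritParams clean_text
#' @return the corpus with cleaned text and refreshed `blank` flags.
#' @export
clean_reports <- function(records, doctor_names = character()) {
  records$findings <- clean_text(records$findings, doctor_names)
  records$impression <- clean_text(records$impression, doctor_names)
  records$blank <- !nzchar(trimws(records$findings)) &
    !nzchar(trimws(records$impression))
  records
}

#' Select reports by modality, year range and disease group
#'
#' Filters a cleaned corpus to the requested modalities, calendar-year range
#' and disease-management-group tag, drops blank reports, and attaches the
#' unified text `findings + " " + impression` used by all downstream models.
#' Exclusion counts per filter are recorded in `attr(, "exclusions")`; an
#' empty result is a warning, not an error.
#'
#' @param records a cleaned `report_corpus`.
#' @param modalities character vector of modalities to keep (`NULL` = all).
#' @param year_range length-2 integer vector `(from, to)` inclusive
#'   (`NULL` = all years).
#' @param dmg_tag disease-management-group tag to keep (`NULL` = all).
#' @return the selected corpus with a `unified_text` column.
#' @export
select_reports <- function(records, modalities = NULL, year_range = NULL,
                           dmg_tag = NULL) {
  n0 <- nrow(records)
  excl <- c(blank = 0L, modality = 0L, year = 0L, dmg = 0L)
  keep <- !records$blank
  excl["blank"] <- sum(!keep)
  if (!is.null(modalities)) {
    ok <- records$modality %in% modalities
    excl["modality"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  if (!is.null(year_range)) {
    yr <- as.integer(format(records$report_date, "%Y"))
    ok <- !is.na(yr) & yr >= year_range[1] & yr <= year_range[2]
    excl["year"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  if (!is.null(dmg_tag)) {
    ok <- records$dmg %in% dmg_tag
    excl["dmg"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  out <- records[keep, , drop = FALSE]
  out$unified_text <- squash_ws(paste(out$findings, out$impression))
  if (!nrow(out)) warning("selection returned zero reports")
  attr(out, "exclusions") <- excl
  attr(out, "n_input") <- n0
  out
}

#' Text pre-processing: tokenize, remove stop words, strip special characters
#'
#' Applies exactly three steps in order: (1) whitespace tokenization,
#' (2) stop-word removal — a token is dropped when its alphanumeric core is
#' in `stopwords` unless it is in `keep_tokens`, (3) special-character
#' removal within tokens (everything outside `[a-z0-9]` is deleted; tokens
#' that become empty are dropped). Input must already be cleaned
#' (lowercase); uppercase input is rejected to enforce pipeline order.
#'
#' @param text character vector of cleaned report texts.
#' @param stopwords stop-word list.
#' @param keep_tokens protected tokens never removed.
#' @param strip_punct logical; set `FALSE` to skip step (3), retaining
#'   punctuation-attached token forms such as `"nsclc,"`.
#' @return list with `tokens` (list of character vectors) and `text`
#'   (whitespace-rejoined normalized strings).
#' @export
preprocess <- function(text, stopwords = default_stopwords(),
                       keep_tokens = default_keep_tokens(),
                       strip_punct = TRUE) {
  if (any(grepl("[A-Z]", text))) {
    stop("preprocess() received uppercase input; run clean_text() first")
  }
  toks_list <- tokenize_ws(text)
  toks_list <- lapply(toks_list, function(toks) {
    if (!length(toks)) return(character(0))
    core <- gsub("[^a-z0-9]", "", toks)
    keep <- !(core %in% stopwords) | core %in% keep_tokens
    toks <- toks[keep]
    core <- core[keep]
    if (strip_punct) toks <- core
    toks[nzchar(toks)]
  })
  list(tokens = toks_list,
       text = vapply(toks_list, paste, "", collapse = " "))
}
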
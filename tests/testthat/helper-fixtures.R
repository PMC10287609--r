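# Small programmatic fixtures.

write_lexicon_file <- function(rows, path = tempfile(fileext = ".csv")) {
  df <- do.call(rbind, lapply(rows, as.data.frame,
                              stringsAsFactors = FALSE))
  write.csv(df, path, row.names = FALSE)
  path
}

tiny_lexicon_rows <- function() {
  list(
    list(preferred_label = "Lung carcinoma", cui = "C0684249",
         concept_index = 1,
         synonyms = "ca lung|carcinoma lung|lung carcinoma"),
    list(preferred_label = "Non-small cell lung carcinoma",
         cui = "C0007131", concept_index = 2, synonyms = "nsclc"),
    list(preferred_label = "Small cell lung carcinoma", cui = "C0149925",
         concept_index = 3, synonyms = "sclc")
  )
}

# A linearly separable document corpus: positives carry a decisive token.
separable_corpus <- function(n, seed = 1, decisive = "malignant") {
  set.seed(seed)
  pos <- sample(n, n %/% 2)
  filler <- c("pleural", "effusion", "normal", "study", "liver", "spleen",
              "bone", "stable", "chest", "heart")
  base <- vapply(seq_len(n), function(i)
    paste(sample(filler, 8, replace = TRUE), collapse = " "), "")
  texts <- ifelse(seq_len(n) %in% pos,
                  paste(base, decisive, "lesion"),
                  paste(base, "benign appearance"))
  list(texts = texts, y = as.integer(seq_len(n) %in% pos))
}

# Report repository CSV with the standard columns.
write_reports_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  path
}

sample_reports_df <- function() {
  data.frame(
    case_number = c("T1", "T2", "T3"),
    gender = c("M", "F", "M"),
    name = c("A One", "B Two", "C Three"),
    modality = c("CT", "MR", "PET/CT"),
    report_date = c("2014-05-01", "2015-07-21", "2016-02-11"),
    findings = c("Nodule in right lobe.", "Knee effusion.",
                 "Known case of Ca lung."),
    impression = c("Follow up advised.", "Degenerative.",
                   "Disease as described."),
    referred_by = c("onc", "ortho", "onc"),
    stringsAsFactors = FALSE
  )
}
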
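lex <- default_lexicon()
pats <- compile_patterns(lex)
pats_strict <- compile_patterns(lex, enable_generative = FALSE)

test_that("boundary handling separates sclc from nsclc", {
  # concept-3 patterns never fire inside "nsclc"
  expect_equal(classify_report("nsclc", pats)$label, 2L)
  expect_equal(classify_report("nsclc,", pats)$label, 2L)
  expect_equal(classify_report("patient with nsclc. stable", pats)$label,
               2L)
  expect_equal(classify_report("sclc with nodes", pats)$label, 3L)
  # mid-word occurrences never match
  expect_equal(classify_report("scaling lesion", pats)$label, 0L)
  expect_equal(classify_report("vascalung artifact", pats)$label, 0L)
})

test_that("punctuation-attached variants and generative collocations", {
  expect_equal(classify_report("known adenoca lung primary", pats)$label,
               1L)
  expect_equal(classify_report("adenocarcinoma lung seen", pats)$label, 1L)
  # generative templates extend beyond the listed dictionary
  lex_small <- load_lexicon(write_lexicon_file(tiny_lexicon_rows()))
  p_gen <- compile_patterns(lex_small, enable_generative = TRUE)
  p_str <- compile_patterns(lex_small, enable_generative = FALSE)
  expect_equal(classify_report("squamous cell carcinoma lung", p_gen)$label,
               1L)
  expect_equal(classify_report("adenoca lung", p_str)$label, 0L)
})

test_that("compile_patterns handles degenerate lexicons", {
  rows <- tiny_lexicon_rows()
  rows[[3]]$synonyms <- ""
  lexe <- load_lexicon(write_lexicon_file(rows))
  expect_warning(p <- compile_patterns(lexe), "no synonyms")
  expect_length(p$groups[["3"]]$patterns, 0)
})

test_that("extract_first_concept picks the earliest match", {
  m <- extract_first_concept("known case of ca lung with nodal disease",
                             pats)
  expect_equal(m$concept_index, 1L)
  expect_equal(m$cui, "C0684249")
  expect_equal(m$surface, "ca lung")
  # offset indexes the unified normalized text, 0-based
  txt <- "known case of ca lung with nodal disease"
  expect_equal(substr(txt, m$offset + 1, m$offset + nchar(m$surface)),
               m$surface)

  # interrupted phrasing is a documented miss
  expect_null(extract_first_concept("this is a case of ca left lung",
                                    pats))
  expect_null(extract_first_concept("", pats))
  expect_equal(classify_report("soft tissue mass in left upper lobe",
                               pats)$label, 0L)

  # earliest mention wins across concepts
  expect_equal(
    classify_report("history of nsclc now with ca lung progression",
                    pats)$label, 2L)
})

test_that("matcher is equivalent to the brute-force oracle", {
  phrases <- oracle_phrase_table(lex, generative = TRUE)
  set.seed(21)
  texts <- c(random_texts(250),
             random_texts(250, plant = phrases$phrase))
  for (tx in texts) {
    got <- extract_first_concept(tx, pats)
    want <- oracle_first_concept(tx, phrases)
    if (is.null(want)) {
      expect_null(got, info = tx)
    } else {
      expect_equal(got$offset, want$offset, info = tx)
      expect_equal(got$concept_index, want$concept_index, info = tx)
      expect_equal(got$surface, want$surface, info = tx)
    }
  }
})

test_that("strict matcher matches the oracle without generative phrases", {
  phrases <- oracle_phrase_table(lex, generative = FALSE)
  set.seed(22)
  texts <- random_texts(150, plant = phrases$phrase)
  for (tx in texts) {
    got <- extract_first_concept(tx, pats_strict)
    want <- oracle_first_concept(tx, phrases)
    if (is.null(want)) expect_null(got, info = tx)
    else expect_equal(got$concept_index, want$concept_index, info = tx)
  }
})

test_that("classify_corpus is row-stable and stateless", {
  corp <- clean_reports(generate_corpus(synthetic_spec(n_reports = 40,
                                                       seed = 6)),
                        c("dr. a rao", "dr. s mehta", "dr. p iyer"))
  sel <- select_reports(corp)
  res <- classify_corpus(sel, pats)
  expect_equal(nrow(res), nrow(sel))
  expect_equal(res$binary_label, as.integer(res$concept_label > 0))

  # permuting input permutes output identically
  perm <- sample(nrow(sel))
  res_perm <- classify_corpus(sel[perm, ], pats)
  expect_equal(res_perm$concept_label, res$concept_label[perm])
  expect_equal(res_perm$extracted_term, res$extracted_term[perm])

  # corpus of only negatives -> all NA
  neg <- select_reports(clean_reports(
    generate_corpus(synthetic_spec(n_reports = 30,
                                   class_mix = c(1, 0, 0, 0), seed = 7))))
  res_neg <- classify_corpus(neg, pats)
  expect_true(all(res_neg$concept_label == 0))
  expect_true(all(res_neg$extracted_term == "NA"))
})

test_that("clean injections are always recovered (no FP, no FN)", {
  spec <- synthetic_spec(n_reports = 150, variant_rate = 0.5,
                         hard_negative_rate = 0, seed = 8)
  sel <- select_reports(clean_reports(generate_corpus(spec),
                                      spec$doctor_names))
  res <- classify_corpus(sel, pats)
  cc <- confusion(as.integer(sel$gold_concept > 0), res$binary_label)
  expect_equal(cc$fp, 0)
  expect_equal(cc$fn, 0)
  # per-concept labels are exact on clean injections
  expect_equal(res$concept_label, sel$gold_concept)
})
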
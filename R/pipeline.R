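#' Build or load a pipeline configuration
#'
#' A single declarative configuration drives every stage so a run is fully
#' reproducible from the file plus the recorded seeds. Accepts a YAML or
#' JSON file path, or an R list. Unspecified fields take the defaults
#' below.
#'
#' @param x path to a YAML/JSON config file, or a named list.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x)) {
    x <- if (grepl("\\.json$", x)) {
      jsonlite::read_json(x, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(x)
    }
  }
  defaults <- list(
    reports = NULL,            # input repository CSV; NULL = simulate
    simulate = list(),         # synthetic_spec() overrides
    lexicon = NULL,            # NULL = bundled default
    out_dir = tempfile("radconcept_run_"),
    doctor_names = c("dr. a rao", "dr. s mehta", "dr. p iyer"),
    modalities = c("CT", "PET/CT"),
    year_range = c(2014L, 2016L),
    dmg = NULL,
    generative = TRUE,
    stages = list(anonymize = TRUE, ner = TRUE, ml = FALSE, dl = FALSE,
                  evaluate = TRUE),
    ml = list(n_trials = 3, n_outer = 5, n_inner = 2),
    dl = list(arch = "simple", epochs = 4, seq_len = 60, hidden = 8,
              embed_dim = 16),
    rounding = 2,
    seed = 1L
  )
  cfg <- utils::modifyList(defaults, x)
  structure(cfg, class = "pipeline_config")
}

log_line <- function(log_path, ...) {
  cat(paste0(format(Sys.time(), "%H:%M:%S"), " ", ..., "\n"),
      file = log_path, append = TRUE)
}

#' Run the concept-classification pipeline end to end
#'
#' Executes ingest -> anonymize -> clean -> select -> preprocess ->
#' rule-based NER (optionally ML / DL baselines) -> evaluation, writing
#' every artifact to `out_dir` together with a manifest carrying the config
#' hash and seeds. Re-running with an identical config reproduces the
#' rule-based and ML outputs byte for byte. A stage failure aborts with the
#' stage name; artifacts written so far are retained next to a `FAILED`
#' marker.
#'
#' @param cfg a [pipeline_config()] (or anything it accepts).
#' @return (invisibly) a list of artifact paths and in-memory results.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  cfg <- pipeline_config(unclass(cfg))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  cat("", file = log_path)
  paths <- list(log = log_path)
  stage <- "init"
  result <- tryCatch({
    stage <- "ingest"
    records <- if (is.null(cfg$reports)) {
      spec <- do.call(synthetic_spec, c(cfg$simulate,
                                        if (is.null(cfg$simulate$seed))
                                          list(seed = cfg$seed)))
      log_line(log_path, "ingest: simulated ", spec$n_reports,
               " reports (seed ", spec$seed, ")")
      generate_corpus(spec)
    } else {
      r <- read_reports(cfg$reports)
      log_line(log_path, "ingest: read ", nrow(r), " reports from ",
               cfg$reports, " (", nrow(attr(r, "row_errors")),
               " row errors)")
      r
    }
    n_in <- nrow(records)

    stage <- "anonymize"
    if (isTRUE(cfg$stages$anonymize)) {
      an <- anonymize(records, seed = cfg$seed)
      records <- an$records
      paths$lookup <- file.path(cfg$out_dir, "anonymization_lookup.csv")
      write.csv(an$lookup, paths$lookup, row.names = FALSE,
                fileEncoding = "UTF-8")
      log_line(log_path, "anonymize: stripped identifiers, lookup saved")
    }

    stage <- "clean"
    records <- clean_reports(records, cfg$doctor_names)

    stage <- "select"
    selected <- select_reports(records, modalities = cfg$modalities,
                               year_range = cfg$year_range,
                               dmg_tag = cfg$dmg)
    excl <- attr(selected, "exclusions")
    log_line(log_path, "select: ", nrow(selected), " of ", n_in,
             " reports kept (excluded ",
             paste(names(excl), excl, sep = "=", collapse = ", "), ")")
    stopifnot(nrow(selected) + sum(excl) == n_in)
    paths$corpus <- file.path(cfg$out_dir, "reports_selected.csv")
    write_reports(selected, paths$corpus)

    stage <- "preprocess"
    pp <- preprocess(selected$unified_text)
    selected$normalized_text <- pp$text

    results <- NULL
    if (isTRUE(cfg$stages$ner)) {
      stage <- "ner"
      lex <- if (is.null(cfg$lexicon)) default_lexicon() else
        load_lexicon(cfg$lexicon)
      pats <- compile_patterns(lex, enable_generative = cfg$generative)
      t0 <- proc.time()[["elapsed"]]
      results <- classify_corpus(selected, pats)
      log_line(log_path, "ner: classified ", nrow(results),
               " reports in ",
               sprintf("%.2f", proc.time()[["elapsed"]] - t0), " s")
      paths$results <- file.path(cfg$out_dir, "results_rule.csv")
      write.csv(results, paths$results, row.names = FALSE,
                fileEncoding = "UTF-8")
    }

    ml_res <- NULL
    if (isTRUE(cfg$stages$ml)) {
      stage <- "ml"
      yb <- as.integer(selected$gold_concept > 0)
      ml_res <- do.call(nested_cv_train,
                        c(list(selected$normalized_text, yb,
                               seed = cfg$seed), cfg$ml))
      paths$ml_scores <- file.path(cfg$out_dir, "ml_trial_scores.csv")
      write.csv(ml_res$trial_scores, paths$ml_scores, row.names = FALSE)
      log_line(log_path, "ml: accuracy ",
               ml_res$summary$formatted[["accuracy"]])
    }

    dl_res <- NULL
    if (isTRUE(cfg$stages$dl)) {
      stage <- "dl"
      yb <- as.integer(selected$gold_concept > 0)
      spec_args <- cfg$dl
      spec_args$seed <- spec_args$seed %||% cfg$seed
      dspec <- do.call(bilstm_spec, spec_args)
      dl_res <- train_bilstm(selected$normalized_text, yb, dspec)
      paths$dl_scores <- file.path(cfg$out_dir, "dl_test_scores.csv")
      write.csv(data.frame(index = dl_res$test_idx,
                           score = dl_res$test_scores),
                paths$dl_scores, row.names = FALSE)
      log_line(log_path, "dl: test accuracy ",
               format(dl_res$test_metrics$raw$accuracy))
    }

    eval_res <- NULL
    if (isTRUE(cfg$stages$evaluate) && !is.null(results) &&
        "gold_concept" %in% names(selected)) {
      stage <- "evaluate"
      gold_bin <- as.integer(selected$gold_concept > 0)
      cc <- confusion(gold_bin, results$binary_label)
      eval_res <- list(
        overall = metrics(cc, rounding = cfg$rounding),
        confusion = cc,
        per_concept = lapply(
          confusion_per_concept(selected$gold_concept,
                                results$concept_label),
          metrics, rounding = cfg$rounding)
      )
      paths$metrics <- file.path(cfg$out_dir, "metrics_rule.json")
      jsonlite::write_json(
        list(overall = eval_res$overall$raw,
             confusion = unclass(cc),
             per_concept = lapply(eval_res$per_concept, `[[`, "raw")),
        paths$metrics, auto_unbox = TRUE, digits = NA)
      log_line(log_path, "evaluate: accuracy ",
               format(eval_res$overall$accuracy))
    }

    stage <- "manifest"
    manifest <- list(config = unclass(cfg),
                     config_hash = config_hash(unclass(cfg)),
                     seed = cfg$seed,
                     n_input = n_in, n_selected = nrow(selected),
                     artifacts = paths)
    paths$manifest <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, force = TRUE, null = "null")
    log_line(log_path, "done")
    list(paths = paths, selected = selected, results = results,
         ml = ml_res, dl = dl_res, evaluation = eval_res,
         config_hash = manifest$config_hash)
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}
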
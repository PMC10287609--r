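#' Round half away from zero
#'
#' Report tables print metrics at 2 decimals with conventional half-up
#' rounding (0.905 -> 0.91). Base `round()` rounds half to even, so a small
#' shim is needed.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector; `NA` passes through.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a mean and standard deviation as "0.77(0.02)"
#'
#' @param m mean value.
#' @param s standard deviation.
#' @param digits decimal places for both numbers.
#' @return character scalar.
#' @export
format_mean_sd <- function(m, s, digits = 2) {
  sprintf(paste0("%.", digits, "f(%.", digits, "f)"),
          round_half_up(m, digits), round_half_up(s, digits))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic operations in the package go
# through this so library calls never perturb user seeds.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Whitespace tokenizer on already-lowercased text.
tokenize_ws <- function(text) {
  out <- strsplit(trimws(text), "\\s+")
  lapply(out, function(x) x[nzchar(x)])
}

# Collapse runs of whitespace to single spaces and trim.
squash_ws <- function(text) {
  gsub("\\s+", " ", trimws(text))
}

# Stratified fold assignment: returns an integer vector of fold ids in 1..k
# with class proportions preserved to within one document per fold. Assumes
# the RNG is already seeded by the caller.
stratified_folds <- function(y, k) {
  y <- as.integer(y)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      stop("class ", cls, " has fewer than k = ", k, " members; ",
           "stratified folds are infeasible")
    }
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# md5 of the canonical JSON serialization of an R object (used for config
# hashes in run manifests).
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
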
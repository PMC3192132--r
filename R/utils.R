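DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse complement of character sequences
#'
#' Thin character-vector wrapper used throughout the simulator and matcher;
#' anything outside ACGT (case-insensitive) becomes N.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  cpp_revcomp(as.character(x), rep(TRUE, length(x)))
}

comp_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

stopifnot_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

stopifnot_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != floor(x) ||
      (positive && x <= 0) || (!positive && x < 0))
    stop(sprintf("'%s' must be a %s integer", name,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  invisible(as.integer(x))
}

# Deterministic sub-seeds derived from a master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run expr under a fixed seed without disturbing the caller's RNG stream;
# with seed = NULL the current stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# x / y >= f, decided by cross-multiplication with f held as a rational
# with denominator 1e6, so count-scale boundary cases (10% of 10 reads)
# never fall to floating-point rounding. y == 0 yields FALSE.
frac_ge <- function(x, y, f) {
  as.numeric(x) * 1e6 >= round(f * 1e6) * as.numeric(y) & y > 0
}

substitution_type <- function(genomic_base, rdd_base) {
  paste0(genomic_base, ">", rdd_base)
}
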
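#' @keywords internal
#' @useDynLib minisplice, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Generate random DNA sequences
#'
#' Draws fixed-length sequences uniformly over the alphabet A/C/G/T.
#' Used throughout the synthetic-data module and in tests.
#'
#' @param n Number of sequences.
#' @param len Length of each sequence (single integer, recycled).
#' @return Character vector of `n` sequences.
#' @export
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(l) {
    paste(sample(DNA_BASES, l, replace = TRUE), collapse = "")
  }, character(1))
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Split sequences into per-base character matrices / vectors.
seq_to_bases <- function(x) strsplit(x, "", fixed = TRUE)

is_valid_dna <- function(x) {
  !grepl("[^ACGT]", x)
}

## stopifnot-style check with a formatted message
check_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

## Hamming distance between equal-length strings (vectorised over x)
hamming_dist <- function(x, y) {
  xs <- seq_to_bases(x)
  ys <- seq_to_bases(y)
  mapply(function(a, b) sum(a != b), xs, ys)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

## Deterministic child seeds derived from one user seed. Keeps every
## derived stream independent while staying inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629L)
}

## Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
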
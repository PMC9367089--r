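#' @useDynLib strpileup, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils head read.table write.table
NULL

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain character strings (A/C/G/T/N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_dna <- function(x) {
  is.character(x) && length(x) == 1 && !is.na(x) && grepl("^[ACGTN]*$", x)
}

assert_dna <- function(x, what) {
  if (!is_dna(x)) stop(sprintf("%s must be an uppercase ACGTN string", what), call. = FALSE)
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Parse an extended CIGAR ("=XIDS" ops) into list(op = character,
# len = integer, n = count); a plain list, it sits on hot paths.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar))
    return(list(op = character(0), len = integer(0), n = 0L))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[=XIDSM]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  list(op = ops, len = lens, n = length(ops))
}

cigar_ref_len <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("=", "X", "D", "M")])
}

cigar_read_len <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("=", "X", "I", "S", "M")])
}
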
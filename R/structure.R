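#' Allele structure: run-length description of a repeat allele
#'
#' An ordered list of (motif, count) runs, e.g. the FMR1 allele
#' `(CGG)10AGG(CGG)9AGG(CGG)9`: 10 CGG units, one AGG interruption, and so
#' on.  Adjacent runs with the same motif are merged on construction.
#'
#' @param motifs character vector of DNA motifs.
#' @param counts positive integer vector, same length.
#' @return object of class `AlleleStructure` with a `runs` data.frame.
#' @export
allele_structure <- function(motifs = character(0), counts = integer(0)) {
  if (length(motifs) != length(counts))
    stop("motifs and counts must have equal length", call. = FALSE)
  counts <- as.integer(counts)
  if (any(is.na(counts)) || any(counts < 1))
    stop("run counts must be positive integers", call. = FALSE)
  for (m in motifs) assert_dna(m, "run motif")
  # merge adjacent identical motifs
  if (length(motifs) > 1) {
    keep_m <- character(0); keep_c <- integer(0)
    for (k in seq_along(motifs)) {
      if (length(keep_m) && keep_m[length(keep_m)] == motifs[k])
        keep_c[length(keep_c)] <- keep_c[length(keep_c)] + counts[k]
      else { keep_m <- c(keep_m, motifs[k]); keep_c <- c(keep_c, counts[k]) }
    }
    motifs <- keep_m; counts <- keep_c
  }
  structure(list(runs = data.frame(motif = as.character(motifs), count = counts,
                                   stringsAsFactors = FALSE)),
            class = "AlleleStructure")
}

#' Parse an allele-structure string
#'
#' Accepts the plain form `"(CGG)10AGG(CGG)9AGG(CGG)9"`: parenthesised
#' motifs carry an explicit unit count, bare motifs count as one unit.
#'
#' @param text structure string.
#' @return an [allele_structure()].
#' @export
#' @examples
#' s <- parse_structure_string("(CGG)10AGG(CGG)9AGG(CGG)9")
#' count_repeat_units(s)          # 30
#' interruption_positions(s, "CGG")  # 11 21
parse_structure_string <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text))
    stop("structure must be a single string", call. = FALSE)
  text <- gsub("\\s|_", "", text)
  motifs <- character(0); counts <- integer(0)
  rest <- text
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec("^\\(([ACGT]+)\\)([0-9]+)", rest))[[1]]
    if (length(m) == 3) {
      cnt <- as.integer(m[3])
      if (cnt == 0) stop("zero run count in structure string", call. = FALSE)
      motifs <- c(motifs, m[2]); counts <- c(counts, cnt)
      rest <- substr(rest, nchar(m[1]) + 1, nchar(rest))
      next
    }
    m <- regmatches(rest, regexec("^([ACGT]+)", rest))[[1]]
    if (length(m) == 2) {
      motifs <- c(motifs, m[2]); counts <- c(counts, 1L)
      rest <- substr(rest, nchar(m[1]) + 1, nchar(rest))
      next
    }
    stop(sprintf("cannot parse structure string at '%s'", rest), call. = FALSE)
  }
  allele_structure(motifs, counts)
}

#' Format an allele structure as its canonical string
#'
#' @param x an `AlleleStructure`.
#' @param ... ignored.
#' @return string such as `"(CGG)10AGG(CGG)9"`; runs of count 1 are written
#'   as the bare motif.
#' @export
format.AlleleStructure <- function(x, ...) {
  if (nrow(x$runs) == 0) return("")
  paste0(ifelse(x$runs$count == 1, x$runs$motif,
                sprintf("(%s)%d", x$runs$motif, x$runs$count)),
         collapse = "")
}

#' @export
print.AlleleStructure <- function(x, ...) {
  cat(sprintf("<AlleleStructure %s: %d units>\n", format(x), count_repeat_units(x)))
  invisible(x)
}

#' Total repeat units in an allele structure
#'
#' Each unit of each run counts once: `(CGG)10AGG(CGG)9AGG(CGG)9` has
#' 10+1+9+1+9 = 30 units.
#'
#' @param s an `AlleleStructure`.
#' @return integer unit count.
#' @export
count_repeat_units <- function(s) {
  sum(s$runs$count)
}

#' 1-based unit positions of interruptions
#'
#' Positions, in repeat units, of every unit whose motif differs from the
#' canonical repeat unit — e.g. the two AGGs of
#' `(CGG)10AGG(CGG)9AGG(CGG)9` sit at unit positions 11 and 21.
#'
#' @param s an `AlleleStructure`.
#' @param canonical_motif the locus's repeat unit.
#' @return integer vector (possibly empty) of 1-based unit positions.
#' @export
interruption_positions <- function(s, canonical_motif) {
  if (nrow(s$runs) == 0) return(integer(0))
  ends <- cumsum(s$runs$count)
  starts <- ends - s$runs$count + 1L
  out <- integer(0)
  for (k in seq_len(nrow(s$runs)))
    if (s$runs$motif[k] != canonical_motif)
      out <- c(out, seq.int(starts[k], ends[k]))
  out
}

#' Expand an allele structure to its DNA sequence
#'
#' @param s an `AlleleStructure`.
#' @return DNA text; the concatenation motif x count in run order.
#' @export
expand_structure <- function(s) {
  if (nrow(s$runs) == 0) return("")
  paste0(strrep(s$runs$motif, s$runs$count), collapse = "")
}

#' Compare two allele structures
#'
#' @param a,b `AlleleStructure` objects.
#' @return list with `equal` (flag), `unit_count_delta`
#'   (`count_repeat_units(a) - count_repeat_units(b)`) and `diff`, an
#'   index-aligned run-by-run data.frame.
#' @export
compare_structures <- function(a, b) {
  na <- nrow(a$runs); nb <- nrow(b$runs)
  n <- max(na, nb)
  pad <- function(v, n) c(v, rep(NA, n - length(v)))
  diff <- data.frame(run = seq_len(n),
                     motif_a = pad(a$runs$motif, n), count_a = pad(a$runs$count, n),
                     motif_b = pad(b$runs$motif, n), count_b = pad(b$runs$count, n),
                     stringsAsFactors = FALSE)
  diff$same <- !is.na(diff$motif_a) & !is.na(diff$motif_b) &
    diff$motif_a == diff$motif_b & diff$count_a == diff$count_b
  list(equal = na == nb && all(diff$same),
       unit_count_delta = count_repeat_units(a) - count_repeat_units(b),
       diff = diff)
}
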
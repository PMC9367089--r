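#' Short tandem repeat specification
#'
#' Describes one STR within a locus: its motif, reference interval and
#' ordinal position among the locus's repeats.  Coordinates are 0-based,
#' half-open throughout the package (the BAM-native convention); VCF and
#' other 1-based inputs are converted on ingest.
#'
#' @param str_id text label for the repeat (e.g. `"FMR1"`).
#' @param repeat_unit DNA motif, 1-20 bp, uppercase ACGTN.
#' @param contig reference contig name.
#' @param start,end 0-based half-open reference interval of the repeat.
#' @param index_in_locus 0-based ordinal among the locus's STRs.
#' @return an object of class `StrSpec`.
#' @export
str_spec <- function(str_id, repeat_unit, contig, start, end, index_in_locus = 0L) {
  assert_dna(repeat_unit, "repeat_unit")
  if (nchar(repeat_unit) < 1 || nchar(repeat_unit) > 20)
    stop("repeat_unit must be 1-20 bp", call. = FALSE)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start >= end)
    stop(sprintf("STR '%s': interval start must be < end", str_id), call. = FALSE)
  structure(list(str_id = as.character(str_id), repeat_unit = repeat_unit,
                 contig = as.character(contig), start = start, end = end,
                 index_in_locus = as.integer(index_in_locus)),
            class = "StrSpec")
}

#' Constant (non-repetitive) locus segment
#'
#' @param sequence DNA text; may be empty (a declared empty spacer between
#'   two adjacent STRs).
#' @return an object of class `ConstantSegment`.
#' @export
constant_segment <- function(sequence) {
  assert_dna(sequence, "constant segment sequence")
  structure(list(sequence = sequence), class = "ConstantSegment")
}

is_str_segment <- function(seg) inherits(seg, "StrSpec")

#' Locus specification
#'
#' An ordered alternation of constant segments and STR segments: the
#' sequence graph describing the whole repeat region, flattened to a linear
#' template.  The first and last segments are always constant (the left and
#' right flanks).
#'
#' @param locus_id text label.
#' @param segments ordered list of [constant_segment()] / [str_spec()]
#'   objects.  Must begin and end with a constant segment, and no two STR
#'   segments may be adjacent without a (possibly empty) constant segment
#'   between them.
#' @return an object of class `LocusSpec`.
#' @export
locus_spec <- function(locus_id, segments) {
  if (length(segments) < 3)
    stop("a locus needs at least left flank, one STR, right flank", call. = FALSE)
  if (is_str_segment(segments[[1]]) || is_str_segment(segments[[length(segments)]]))
    stop("first and last locus segments must be constant flanks", call. = FALSE)
  str_idx <- which(vapply(segments, is_str_segment, logical(1)))
  if (length(str_idx) == 0) stop("locus has no STR segment", call. = FALSE)
  for (k in seq_along(str_idx[-1]))
    if (str_idx[k + 1] - str_idx[k] < 2)
      stop("two STR segments are adjacent without a constant segment", call. = FALSE)
  # renumber ordinals 0..n-1 in segment order
  for (k in seq_along(str_idx))
    segments[[str_idx[k]]]$index_in_locus <- k - 1L
  ids <- vapply(segments[str_idx], function(s) s$str_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate str_id within locus", call. = FALSE)
  structure(list(locus_id = as.character(locus_id), segments = segments),
            class = "LocusSpec")
}

#' @export
print.LocusSpec <- function(x, ...) {
  cat(sprintf("<LocusSpec %s: %d segments, %d STR(s)>\n",
              x$locus_id, length(x$segments), length(locus_strs(x))))
  for (seg in x$segments) {
    if (is_str_segment(seg))
      cat(sprintf("  STR %s (%s) %s:%d-%d\n", seg$str_id, seg$repeat_unit,
                  seg$contig, seg$start, seg$end))
    else cat(sprintf("  constant %d bp\n", nchar(seg$sequence)))
  }
  invisible(x)
}

#' Accessors for a LocusSpec
#'
#' `locus_strs()` returns the ordered list of [str_spec()] segments;
#' `left_flank()` / `right_flank()` the flank sequences; `locus_region()`
#' the 0-based reference interval covered by the STRs.
#'
#' @param locus a `LocusSpec`.
#' @return see description.
#' @export
locus_strs <- function(locus) {
  Filter(is_str_segment, locus$segments)
}

#' @rdname locus_strs
#' @export
left_flank <- function(locus) locus$segments[[1]]$sequence

#' @rdname locus_strs
#' @export
right_flank <- function(locus) locus$segments[[length(locus$segments)]]$sequence

#' @rdname locus_strs
#' @export
locus_region <- function(locus) {
  strs <- locus_strs(locus)
  list(contig = strs[[1]]$contig,
       start = min(vapply(strs, function(s) s$start, integer(1))),
       end = max(vapply(strs, function(s) s$end, integer(1))))
}

#' Repeat genotype for one STR
#'
#' Allele sizes in repeat units; one size for haploid loci, two (stored
#' sorted ascending) for diploid.
#'
#' @param str_id the STR this genotype belongs to.
#' @param allele_sizes 1 or 2 non-negative integers (repeat units).
#' @param size_cis optional list of per-allele `c(lo, hi)` confidence
#'   intervals, in the order of the *sorted* allele sizes.
#' @return an object of class `RepeatGenotype`.
#' @export
repeat_genotype <- function(str_id, allele_sizes, size_cis = NULL) {
  allele_sizes <- as.integer(allele_sizes)
  if (!length(allele_sizes) %in% c(1L, 2L) || anyNA(allele_sizes) || any(allele_sizes < 0))
    stop("allele_sizes must be 1 or 2 non-negative integers", call. = FALSE)
  ord <- order(allele_sizes)
  allele_sizes <- allele_sizes[ord]
  if (!is.null(size_cis)) {
    size_cis <- size_cis[ord]
    for (k in seq_along(size_cis)) {
      ci <- size_cis[[k]]
      if (!is.null(ci) && (length(ci) != 2 || ci[1] > allele_sizes[k] || ci[2] < allele_sizes[k]))
        stop("size CI must bracket the point estimate", call. = FALSE)
    }
  }
  structure(list(str_id = as.character(str_id), allele_sizes = allele_sizes,
                 size_cis = size_cis),
            class = "RepeatGenotype")
}

#' A single read record
#'
#' One mate of a read pair, with bases stored in reference orientation (as
#' in SAM).  At least one of `graph_alignment` / `linear_alignment` must be
#' present after loading from a BAM.
#'
#' @param fragment_id read-pair name.
#' @param mate_index 1 or 2.
#' @param bases DNA text, reference orientation.
#' @param strand `"+"` or `"-"`.
#' @param quals optional per-base quality scores.
#' @param graph_alignment optional encoded path through the locus segments
#'   (see [project_graph_alignment()]).
#' @param linear_alignment optional `list(contig, pos, cigar)` with 0-based
#'   `pos`.
#' @return an object of class `ReadRecord`.
#' @export
read_record <- function(fragment_id, mate_index, bases, strand = "+",
                        quals = NULL, graph_alignment = NULL,
                        linear_alignment = NULL) {
  assert_dna(bases, "read bases")
  if (!nzchar(bases)) stop("read bases must be nonempty", call. = FALSE)
  if (!mate_index %in% c(1L, 2L)) stop("mate_index must be 1 or 2", call. = FALSE)
  structure(list(fragment_id = as.character(fragment_id),
                 mate_index = as.integer(mate_index), bases = bases,
                 strand = strand, quals = quals,
                 graph_alignment = graph_alignment,
                 linear_alignment = linear_alignment),
            class = "ReadRecord")
}
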
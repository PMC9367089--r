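#' Alignment scoring scheme
#'
#' Affine-gap scoring used throughout: a length-L gap costs
#' `gap_open + L * gap_extend`; read-end soft clips are free.  Defaults are
#' in the bwa-like range (match +5, mismatch -4, gap open -8, gap extend
#' -2) and are configurable so that equivalence tests can pin them.  `N`
#' in a read or haplotype always scores as a mismatch.
#'
#' @param match positive match score.
#' @param mismatch,gap_open,gap_extend non-positive penalties.
#' @return object of class `ScoringScheme`.
#' @export
scoring_scheme <- function(match = 5L, mismatch = -4L, gap_open = -8L,
                           gap_extend = -2L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (match <= 0) stop("match score must be positive", call. = FALSE)
  if (any(c(mismatch, gap_open, gap_extend) > 0))
    stop("penalties must be <= 0", call. = FALSE)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "ScoringScheme")
}

new_read_alignment <- function(fragment_id, mate_index, hap_index, start,
                               cigar, score, strand = "+", end = NULL) {
  if (is.null(end)) end <- start + cigar_ref_len(cigar)
  structure(list(fragment_id = fragment_id, mate_index = mate_index,
                 hap_index = hap_index, start = start, end = end,
                 cigar = cigar, score = score, strand = strand),
            class = "ReadAlignment")
}

#' Align a read against a haplotype, keeping all score-tied placements
#'
#' Affine-gap alignment of the read to the haplotype with free placement on
#' the haplotype and free soft clipping of read ends.  Every placement
#' achieving the maximum score is returned — for a read lying wholly inside
#' a pure repeat tract this is the full set of U - u + 1 equivalent
#' positions, growing linearly with the repeat length.
#'
#' @param bases read sequence (reference orientation).
#' @param hap a `Haplotype` (or plain DNA text).
#' @param scheme a [scoring_scheme()].
#' @param window optional `c(lo, hi)` 0-based half-open haplotype window to
#'   restrict the alignment to.
#' @param score_only return only the best score (integer)?
#' @param max_placements safety cap on tied placements.
#' @return list of `ReadAlignment` (ordered by start, then end), with the
#'   shared best score in each element; or an integer when `score_only`.
#' @export
align_read <- function(bases, hap, scheme = scoring_scheme(), window = NULL,
                       score_only = FALSE, max_placements = 10000L) {
  if (!is.character(bases) || !nzchar(bases)) stop("empty read", call. = FALSE)
  hseq <- if (inherits(hap, "Haplotype")) hap$sequence else hap
  off <- 0L
  if (!is.null(window)) {
    lo <- max(0L, as.integer(window[1])); hi <- min(nchar(hseq), as.integer(window[2]))
    hseq <- substr(hseq, lo + 1, hi)
    off <- lo
  }
  res <- .cpp_align_read(bases, hseq, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend,
                         score_only = score_only,
                         max_placements = as.integer(max_placements))
  if (score_only) return(res$score)
  if (res$truncated)
    warning("placement enumeration truncated at cap", call. = FALSE)
  lapply(seq_along(res$starts), function(k)
    new_read_alignment(NA_character_, NA_integer_, NA_integer_,
                       res$starts[k] + off, res$cigars[k], res$score,
                       end = res$ends[k] + off))
}

# ---- graph-alignment projection ------------------------------------------

# Tag dialect (pluggable; written by the simulator's graph-tag writer):
# elements separated by ';', each "seg:len" with the FIRST element
# "seg:off:len" carrying the 0-based offset into that segment.  seg indexes
# locus$segments (0-based); len is bp consumed in that segment.
decode_graph_tag <- function(tag) {
  els <- strsplit(tag, ";", fixed = TRUE)[[1]]
  out <- lapply(seq_along(els), function(k) {
    f <- as.integer(strsplit(els[k], ":", fixed = TRUE)[[1]])
    if (k == 1) {
      if (length(f) != 3 || anyNA(f)) stop("malformed graph tag: ", tag, call. = FALSE)
      list(seg = f[1], off = f[2], len = f[3])
    } else {
      if (length(f) != 2 || anyNA(f)) stop("malformed graph tag: ", tag, call. = FALSE)
      list(seg = f[1], off = NA_integer_, len = f[2])
    }
  })
  out
}

encode_graph_tag <- function(path) {
  paste(vapply(seq_along(path), function(k) {
    el <- path[[k]]
    if (k == 1) sprintf("%d:%d:%d", el$seg, el$off, el$len)
    else sprintf("%d:%d", el$seg, el$len)
  }, character(1)), collapse = ";")
}

#' Project a graph alignment onto a haplotype
#'
#' Lays a read's encoded path through the locus segments onto a concrete
#' haplotype's segment map.  Paths anchored in a constant segment have a
#' unique placement; paths lying wholly inside one STR are emitted once per
#' valid unit offset (U - u + 1 placements on a U-unit haplotype).  Scores
#' are recomputed under the active scoring scheme by base comparison.
#'
#' @param rec a [read_record()] with a `graph_alignment` tag.
#' @param hap the `Haplotype` to project onto.
#' @param locus the `LocusSpec` the path indexes into.
#' @param scheme a [scoring_scheme()].
#' @param path optionally, the already-decoded path (internal fast path).
#' @param score_only return only the integer vector of placement scores?
#' @return list of `ReadAlignment` (possibly empty if the path does not fit
#'   this haplotype, e.g. it needs more repeat units than the haplotype has).
#' @export
project_graph_alignment <- function(rec, hap, locus, scheme = scoring_scheme(),
                                    path = NULL, score_only = FALSE) {
  if (is.null(path)) {
    if (is.null(rec$graph_alignment))
      stop("read has no graph alignment", call. = FALSE)
    path <- decode_graph_tag(rec$graph_alignment)
  }
  nseg <- length(locus$segments)
  for (el in path)
    if (el$seg < 0 || el$seg >= nseg)
      stop(sprintf("graph path references segment %d absent from locus", el$seg),
           call. = FALSE)
  sm <- hap$segment_map
  seg_type <- sm$type
  seg_start <- sm$start
  seg_len <- sm$end - sm$start
  read_len <- sum(vapply(path, function(e) e$len, integer(1)))
  if (nchar(rec$bases) != read_len) return(list())  # tag inconsistent with read

  const_k <- which(vapply(path, function(e) seg_type[e$seg + 1] == "constant",
                          logical(1)))
  starts <- integer(0)
  if (length(const_k) > 0) {
    # anchored: the first constant element pins the placement
    k <- const_k[1]
    el <- path[[k]]
    off_in_seg <- if (k == 1) el$off else 0L
    before <- if (k > 1) sum(vapply(path[seq_len(k - 1)], function(e) e$len, integer(1))) else 0L
    starts <- seg_start[el$seg + 1] + off_in_seg - before
  } else {
    # wholly in-repeat: one placement per unit offset that fits
    el <- path[[1]]
    if (length(path) != 1) return(list())  # in-repeat path must be one STR element
    unit_len <- nchar(locus$segments[[el$seg + 1]]$repeat_unit)
    tract_len <- seg_len[el$seg + 1]
    phase <- el$off %% unit_len
    max_start <- tract_len - el$len
    if (max_start < phase) return(list())
    offs <- seq.int(phase, max_start, by = unit_len)
    starts <- seg_start[el$seg + 1] + offs
  }

  out <- list()
  scores <- integer(0)
  rb <- charToRaw(rec$bases)
  rawN <- charToRaw("N")
  for (s in starts) {
    if (s < 0 || s + read_len > nchar(hap$sequence)) next
    # validate the path against this haplotype's segment boundaries
    ok <- TRUE; pos <- s
    for (k in seq_along(path)) {
      el <- path[[k]]
      lo <- seg_start[el$seg + 1]; hi <- lo + seg_len[el$seg + 1]
      if (pos < lo || pos + el$len > hi) { ok <- FALSE; break }
      # interior elements must traverse their whole segment
      if (k > 1 && pos != lo) { ok <- FALSE; break }
      if (k < length(path) && pos + el$len != hi) { ok <- FALSE; break }
      pos <- pos + el$len
    }
    if (!ok) next
    hb <- charToRaw(substr(hap$sequence, s + 1, s + read_len))
    is_match <- rb == hb & rb != rawN & hb != rawN
    score <- sum(is_match) * scheme$match + sum(!is_match) * scheme$mismatch
    if (score_only) { scores <- c(scores, as.integer(score)); next }
    r <- rle(is_match)
    cigar <- paste0(r$lengths, ifelse(r$values, "=", "X"), collapse = "")
    out[[length(out) + 1]] <- new_read_alignment(rec$fragment_id, rec$mate_index,
                                                 NA_integer_, s, cigar,
                                                 as.integer(score), rec$strand,
                                                 end = s + read_len)
  }
  if (score_only) return(scores)
  out
}

# Best placements of one read on one haplotype: graph projection when a tag
# is present and fits, otherwise de-novo alignment.  Returns list(score,
# alignments).
read_placements_on_hap <- function(rec, hap, locus, scheme,
                                   use_graph = TRUE, score_only = FALSE,
                                   path = NULL) {
  if (use_graph && (!is.null(path) || !is.null(rec$graph_alignment))) {
    if (score_only) {
      sc <- tryCatch(project_graph_alignment(rec, hap, locus, scheme, path,
                                             score_only = TRUE),
                     error = function(e) integer(0))
      if (length(sc) > 0) return(list(score = max(sc), alignments = NULL))
    } else {
      alns <- tryCatch(project_graph_alignment(rec, hap, locus, scheme, path),
                       error = function(e) list())
      if (length(alns) > 0) {
        sc <- vapply(alns, function(a) a$score, integer(1))
        best <- max(sc)
        return(list(score = best, alignments = alns[sc == best]))
      }
    }
  }
  if (score_only)
    return(list(score = align_read(rec$bases, hap, scheme, score_only = TRUE),
                alignments = NULL))
  alns <- align_read(rec$bases, hap, scheme)
  alns <- lapply(alns, function(a) {
    a$fragment_id <- rec$fragment_id; a$mate_index <- rec$mate_index
    a$strand <- rec$strand; a
  })
  list(score = if (length(alns)) alns[[1]]$score else 0L, alignments = alns)
}

# Per-read best score against each distinct haplotype sequence, cached.
hap_cache_key <- function(hap) hap$sequence

# decode every read's graph tag once (NULL where absent)
decode_read_paths <- function(reads) {
  lapply(reads, function(r)
    if (is.null(r$graph_alignment)) NULL else decode_graph_tag(r$graph_alignment))
}

#' Cumulative read-alignment score of a haplotype pair
#'
#' Sum over reads of the better of the read's best alignment scores on the
#' two haplotypes.  The pair consistent with the reads accumulates the
#' highest total.
#'
#' @param pair a `HaplotypePair`.
#' @param reads list of [read_record()]s.
#' @param locus the `LocusSpec`.
#' @param scheme a [scoring_scheme()].
#' @param cache optional environment reusing per-haplotype scores across
#'   pairs that share haplotypes.
#' @return the pair with `cumulative_score` set.
#' @export
score_haplotype_pair <- function(pair, reads, locus, scheme = scoring_scheme(),
                                 cache = NULL, paths = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(paths)) paths <- decode_read_paths(reads)
  per_hap_scores <- function(hap) {
    key <- hap_cache_key(hap)
    if (is.null(cache[[key]]))
      cache[[key]] <- vapply(seq_along(reads), function(i)
        read_placements_on_hap(reads[[i]], hap, locus, scheme,
                               score_only = TRUE, path = paths[[i]])$score,
        integer(1))
    cache[[key]]
  }
  s1 <- per_hap_scores(pair$hap1)
  s2 <- if (is.null(pair$hap2)) s1 else per_hap_scores(pair$hap2)
  pair$cumulative_score <- as.integer(sum(pmax(s1, s2)))
  pair
}

#' Select the haplotype pair most consistent with the reads
#'
#' Scores every candidate pair and returns the one with the highest
#' cumulative read-alignment score.  With a single candidate (single-STR or
#' haploid loci) scoring is skipped entirely.  Ties are broken by canonical
#' order (smaller `hap1` sequence, then `phase_id`) and reported via a
#' message.
#'
#' @param candidates list of `HaplotypePair`.
#' @param reads list of [read_record()]s.
#' @param locus the `LocusSpec`.
#' @param scheme a [scoring_scheme()].
#' @return the selected `HaplotypePair`.
#' @export
select_haplotype_pair <- function(candidates, reads, locus,
                                  scheme = scoring_scheme()) {
  if (length(candidates) == 0) stop("no candidate haplotype pairs", call. = FALSE)
  if (length(candidates) == 1) return(candidates[[1]])
  cache <- new.env(parent = emptyenv())
  paths <- decode_read_paths(reads)
  scored <- lapply(candidates, score_haplotype_pair, reads = reads,
                   locus = locus, scheme = scheme, cache = cache, paths = paths)
  sc <- vapply(scored, function(p) p$cumulative_score, integer(1))
  best <- which(sc == max(sc))
  if (length(best) > 1) {
    keys <- vapply(scored[best], function(p)
      paste(p$hap1$sequence, p$phase_id), character(1))
    best <- best[order(keys)]
    message(sprintf("haplotype-pair score tie (%d candidates); canonical pair chosen",
                    length(best)))
  }
  scored[[best[1]]]
}
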
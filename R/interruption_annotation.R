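# Profile of one placed read over haplotype interval [lo, hi): the aligned
# read base per position ("" where unaligned or deleted) plus the reference
# positions at which the read carries an insertion.  A unit column is a
# valid vote only when every base is aligned and no insertion falls
# strictly inside it.
read_repeat_profile <- function(p, lo, hi) {
  chars <- character(hi - lo)
  ins_at <- integer(0)
  ops <- parse_cigar(p$cigar)
  ref <- p$start; rpos <- 0L
  for (k in seq_len(ops$n)) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("=", "X", "M")) {
      a <- max(ref, lo); b <- min(ref + len, hi)
      if (b > a)
        chars[(a - lo + 1):(b - lo)] <-
          strsplit(substr(p$bases, rpos + (a - ref) + 1, rpos + (b - ref)), "")[[1]]
      ref <- ref + len; rpos <- rpos + len
    } else if (op == "D") {
      ref <- ref + len            # deleted positions stay ""
    } else if (op == "I") {
      if (ref > lo && ref < hi) ins_at <- c(ins_at, ref)
      rpos <- rpos + len
    } else if (op == "S") {
      rpos <- rpos + len
    }
  }
  list(chars = chars, ins_at = ins_at)
}

# word voted by a profiled read for column [a, b) relative to interval lo
profile_word <- function(prof, lo, a, b) {
  piece <- prof$chars[(a - lo + 1):(b - lo)]
  if (any(piece == "")) return(NA_character_)
  if (any(prof$ins_at > a & prof$ins_at < b)) return(NA_character_)
  paste0(piece, collapse = "")
}

#' Call a consensus allele structure from the pileup
#'
#' For each repeat-unit column of one allele's repeat tract, reads placed
#' on that haplotype vote with the unit-length word they carry over the
#' column.  The column motif is the canonical repeat unit unless at least
#' `min_frac` of at least `min_depth` covering reads agree on one
#' alternative word (e.g. AGG inside a CGG tract); columns below
#' `min_depth` are reported unresolved.  Runs of identical motifs collapse
#' into an [allele_structure()].
#'
#' Only anchored reads vote: the haplotype assignment must be decided by
#' alignment score (`hap_support == "score"`; moot when the two haplotypes
#' are sequence-identical) and the read must have a single placement on
#' that haplotype.  Reads assigned by fragment-length distance or at
#' random could belong to either allele, and reads with several tied
#' placements (in-repeat reads) carry no reliable column position — either
#' kind of vote would blend or smear the alleles' sequences.
#'
#' @param pileup a `StrPileup`.
#' @param hap_index 1 or 2: which allele to call.
#' @param str_id which STR.
#' @param min_depth minimum covering reads per column (default 5).
#' @param min_frac minimum agreeing fraction for a non-canonical call
#'   (default 0.8).
#' @return list with `structure` (an `AlleleStructure` over the resolved
#'   columns; `NULL` when nothing is resolved), `support` (per-unit
#'   data.frame: unit, motif, depth, agreement, resolved), `complete`
#'   (all columns resolved?) and `unresolved_units`.
#' @export
call_consensus_structure <- function(pileup, hap_index, str_id,
                                     min_depth = 5L, min_frac = 0.8) {
  haps <- pair_haps(pileup$pair)
  if (hap_index > length(haps)) stop("no such haplotype", call. = FALSE)
  hap <- haps[[hap_index]]
  strs <- locus_strs(pileup$locus)
  spec <- NULL
  for (s in strs) if (s$str_id == str_id) spec <- s
  if (is.null(spec)) stop(sprintf("unknown STR '%s'", str_id), call. = FALSE)
  unit <- spec$repeat_unit
  L <- nchar(unit)
  ri <- repeat_interval(hap, str_id)
  U <- hap$str_counts[[str_id]]

  hap_known <- isTRUE(pileup$haps_identical) || length(haps) == 1
  on_hap <- pileup$placed[vapply(pileup$placed, function(p)
    p$hap_index == hap_index &&
      (hap_known || identical(p$hap_support, "score")) &&
      (is.null(p$n_placements) || p$n_placements == 1L), logical(1))]

  # profile each covering read once; columns are then substring lookups
  rs <- ri["start"]; re <- ri["end"]
  on_hap <- Filter(function(p) p$start < re && p$end > rs, on_hap)
  profiles <- lapply(on_hap, read_repeat_profile, lo = rs, hi = re)

  motifs <- character(U); depth <- integer(U); agree <- numeric(U)
  resolved <- logical(U)
  for (u in seq_len(U)) {
    lo <- rs + (u - 1L) * L; hi <- lo + L
    words <- vapply(profiles, profile_word, character(1),
                    lo = rs, a = lo, b = hi)
    words <- words[!is.na(words)]
    depth[u] <- length(words)
    if (depth[u] < min_depth) {
      motifs[u] <- NA_character_; agree[u] <- NA_real_
      next
    }
    tab <- sort(table(words), decreasing = TRUE)
    top <- names(tab)[1]
    frac <- as.numeric(tab[1]) / depth[u]
    if (top != unit && frac >= min_frac) {
      motifs[u] <- top; agree[u] <- frac
    } else {
      motifs[u] <- unit
      agree[u] <- if (unit %in% names(tab)) as.numeric(tab[[unit]]) / depth[u] else 0
    }
    resolved[u] <- TRUE
  }
  support <- data.frame(unit = seq_len(U), motif = motifs, depth = depth,
                        agreement = agree, resolved = resolved,
                        stringsAsFactors = FALSE)
  res_m <- motifs[resolved]
  structure_out <- if (length(res_m) > 0)
    allele_structure(res_m, rep(1L, length(res_m))) else NULL
  list(structure = structure_out, support = support,
       complete = all(resolved) && U > 0 || U == 0,
       unresolved_units = which(!resolved))
}

#' Per-locus structure report
#'
#' Runs [call_consensus_structure()] for every allele and STR of a pileup
#' and returns a JSON-ready report (also used by the `annotate` CLI
#' subcommand).
#'
#' @param pileup a `StrPileup`.
#' @param min_depth,min_frac consensus thresholds.
#' @return list (one entry per hap x STR) with structure text, completeness
#'   and interruption positions.
#' @export
annotate_interruptions <- function(pileup, min_depth = 5L, min_frac = 0.8) {
  haps <- pair_haps(pileup$pair)
  strs <- locus_strs(pileup$locus)
  out <- list()
  for (h in seq_along(haps)) for (s in strs) {
    cc <- call_consensus_structure(pileup, h, s$str_id, min_depth, min_frac)
    key <- sprintf("hap%d.%s", h, s$str_id)
    out[[key]] <- list(
      hap = h, str_id = s$str_id,
      allele_units = haps[[h]]$str_counts[[s$str_id]],
      structure = if (!is.null(cc$structure)) format(cc$structure) else NA,
      complete = cc$complete,
      unresolved_units = cc$unresolved_units,
      interruption_positions = if (cc$complete && !is.null(cc$structure))
        interruption_positions(cc$structure, s$repeat_unit) else integer(0))
  }
  out
}
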
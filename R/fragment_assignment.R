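#' Fragment-length distribution summary
#'
#' @param mean_len,sd_len mean and standard deviation of outermost span,
#'   in bp.
#' @param n_pairs number of qualifying pairs used.
#' @param fallback was the configured default used in place of an estimate?
#' @return object of class `FragmentStats`.
#' @export
fragment_stats <- function(mean_len, sd_len, n_pairs, fallback = FALSE) {
  if (mean_len <= 0) stop("mean fragment length must be positive", call. = FALSE)
  structure(list(mean_len = mean_len, sd_len = sd_len,
                 n_pairs = as.integer(n_pairs), fallback = fallback),
            class = "FragmentStats")
}

aln_in_constant <- function(aln, hap) {
  sm <- hap$segment_map
  consts <- sm[sm$type == "constant", , drop = FALSE]
  any(aln$start >= consts$start & aln$end <= consts$end)
}

#' Estimate fragment-length statistics from flank-mapped pairs
#'
#' Mean and sd of the outermost span over read pairs whose two mates both
#' have a unique placement lying wholly inside constant (non-repeat)
#' segments of the selected haplotypes.  These pairs are immune to repeat
#' placement ambiguity, so their spans estimate the library's fragment
#' length.
#'
#' Placement uniqueness is judged per haplotype: a read lying wholly in a
#' flank shared by both haplotypes places once on each, and still
#' qualifies; a read with several tied placements on one haplotype does
#' not.
#'
#' @param placements named list (fragment_id -> list(mate1, mate2)), each a
#'   list of `ReadAlignment` as produced during pileup generation.
#' @param pair the selected `HaplotypePair`.
#' @param min_flank_pairs minimum qualifying pairs (default 10) before the
#'   configured default is used instead.
#' @param default_mean,default_sd fallback values (default 450 / 100 bp).
#' @return a [fragment_stats()] object.
#' @export
estimate_fragment_stats <- function(placements, pair, min_flank_pairs = 10L,
                                    default_mean = 450, default_sd = 100) {
  haps <- pair_haps(pair)
  spans <- numeric(0)
  for (frag in placements) {
    span <- NA_real_
    for (h in seq_along(haps)) {
      m1 <- Filter(function(a) a$hap_index == h, frag$mate1)
      m2 <- Filter(function(a) a$hap_index == h, frag$mate2)
      if (length(m1) != 1 || length(m2) != 1) next
      a1 <- m1[[1]]; a2 <- m2[[1]]
      hap <- haps[[h]]
      if (!aln_in_constant(a1, hap) || !aln_in_constant(a2, hap)) next
      span <- max(a1$end, a2$end) - min(a1$start, a2$start)
      break   # flanks are shared: the span is the same on either haplotype
    }
    if (!is.na(span)) spans <- c(spans, span)
  }
  if (length(spans) < min_flank_pairs) {
    warning(sprintf(paste("only %d flank pair(s) available for fragment-length",
                          "estimation (< %d); using default mean %g bp"),
                    length(spans), min_flank_pairs, default_mean), call. = FALSE)
    return(fragment_stats(default_mean, default_sd, length(spans), fallback = TRUE))
  }
  s <- if (length(spans) > 1) sd(spans) else 0
  fragment_stats(mean(spans), s, length(spans))
}

#' Enumerate joint placements of a read pair
#'
#' Cartesian product of the two mates' placements per shared haplotype,
#' restricted to proper forward-reverse orientation (forward mate leftmost)
#' and to fragment lengths within `mean + k_sd * sd`.  When both mates lie
#' inside the repeat the raw product grows quadratically with the repeat
#' length; the length gate prunes it.
#'
#' @param placements1,placements2 lists of `ReadAlignment` for mate 1 and
#'   mate 2 (possibly on both haplotypes).
#' @param stats a [fragment_stats()].
#' @param k_sd fragment-length gate width in standard deviations (default 4).
#' @param check_orientation require proper forward-reverse orientation?
#' @return list of candidates, each
#'   `list(aln1, aln2, hap_index, fragment_len, distance)`; empty when no
#'   shared haplotype or nothing passes the gate.
#' @export
enumerate_pair_candidates <- function(placements1, placements2, stats,
                                      k_sd = 4, check_orientation = TRUE) {
  out <- list()
  haps1 <- vapply(placements1, function(a) a$hap_index, integer(1))
  haps2 <- vapply(placements2, function(a) a$hap_index, integer(1))
  gate <- stats$mean_len + k_sd * stats$sd_len
  for (h in intersect(unique(haps1), unique(haps2))) {
    p1 <- placements1[haps1 == h]; p2 <- placements2[haps2 == h]
    for (a1 in p1) for (a2 in p2) {
      if (check_orientation) {
        if (a1$strand == a2$strand) next
        fwd <- if (a1$strand == "+") a1 else a2
        rev <- if (a1$strand == "+") a2 else a1
        if (fwd$start > rev$start) next
      }
      flen <- max(a1$end, a2$end) - min(a1$start, a2$start)
      if (flen > gate) next
      out[[length(out) + 1]] <- list(aln1 = a1, aln2 = a2, hap_index = h,
                                     fragment_len = flen,
                                     distance = abs(flen - stats$mean_len))
    }
  }
  out
}

#' Select one joint placement for a read pair
#'
#' Keeps the candidates whose fragment length is closest to the mean
#' fragment length and picks one of them uniformly at random (using the
#' caller's RNG stream, which the pipeline seeds per locus and consumes in
#' sorted fragment order).  The choice is flagged ambiguous when tied
#' candidates exist on more than one haplotype; such reads are rendered
#' faint.
#'
#' @param candidates non-empty list from [enumerate_pair_candidates()].
#' @return `list(choice, ambiguous, n_tied)`.
#' @export
select_pair_alignment <- function(candidates) {
  if (length(candidates) == 0) stop("no candidates to select from", call. = FALSE)
  d <- vapply(candidates, function(c) c$distance, numeric(1))
  tied <- which(d == min(d))
  pick <- if (length(tied) == 1) tied else tied[sample.int(length(tied), 1)]
  haps <- unique(vapply(candidates[tied], function(c) c$hap_index, integer(1)))
  list(choice = candidates[[pick]], ambiguous = length(haps) > 1,
       n_tied = length(tied))
}
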
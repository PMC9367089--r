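#' Classify a placed read relative to one STR
#'
#' A read *spans* the repeat when its alignment covers the whole repeat
#' interval with at least `min_anchor` bp aligned in each flank; it is
#' *flanking* when it crosses a repeat boundary without spanning;
#' *in_repeat* when contained in the repeat interval; *flank_only*
#' otherwise.
#'
#' @param aln a `ReadAlignment`.
#' @param hap the `Haplotype` it is placed on.
#' @param str_id which STR to classify against.
#' @param min_anchor minimum aligned bp in each flank for a spanning call
#'   (default 5).
#' @return one of `"spanning"`, `"flanking"`, `"in_repeat"`, `"flank_only"`.
#' @export
classify_read <- function(aln, hap, str_id, min_anchor = 5L) {
  ri <- repeat_interval(hap, str_id)
  s <- aln$start; e <- aln$end
  if (s <= ri["start"] - min_anchor && e >= ri["end"] + min_anchor)
    return("spanning")
  crosses_start <- s < ri["start"] && e > ri["start"]
  crosses_end <- s < ri["end"] && e > ri["end"]
  if (crosses_start || crosses_end) return("flanking")
  if (s >= ri["start"] && e <= ri["end"] && ri["end"] > ri["start"])
    return("in_repeat")
  "flank_only"
}

# overall display class across all STRs of the locus
overall_class <- function(classes) {
  for (cl in c("spanning", "flanking", "in_repeat"))
    if (cl %in% classes) return(cl)
  "flank_only"
}

#' Pack placed reads into lanes
#'
#' Greedy interval packing per haplotype: fragments (mate pairs sharing a
#' haplotype) are treated as one interval so mates share a lane; units are
#' sorted by start and each takes the lowest lane whose previous occupant
#' ends at least `gap` bp before it.  First-fit on sorted intervals is
#' optimal for interval graphs, so the lane count equals the maximum
#' overlap depth.
#'
#' @param placed list of placed-read entries (fields `hap_index`, `start`,
#'   `end`, `fragment_id`).
#' @param gap minimum bp between lane neighbours (default 5).
#' @return `placed` with `$lane` filled (0-based).
#' @export
assign_lanes <- function(placed, gap = 5L) {
  if (length(placed) == 0) return(placed)
  hap_of <- vapply(placed, function(p) p$hap_index, integer(1))
  for (h in sort(unique(hap_of))) {
    idx <- which(hap_of == h)
    frag <- vapply(placed[idx], function(p) p$fragment_id, character(1))
    units <- split(idx, frag)
    u_start <- vapply(units, function(ii)
      min(vapply(placed[ii], function(p) p$start, numeric(1))), numeric(1))
    u_end <- vapply(units, function(ii)
      max(vapply(placed[ii], function(p) p$end, numeric(1))), numeric(1))
    ord <- order(u_start, u_end, names(units))
    lane_end <- numeric(0)
    for (u in ord) {
      free <- which(lane_end + gap <= u_start[u])
      lane <- if (length(free)) min(free) else length(lane_end) + 1L
      lane_end[lane] <- u_end[u]
      for (i in units[[u]]) placed[[i]]$lane <- lane - 1L
    }
  }
  placed
}

depth_profile <- function(placed, hap_index, hap_len) {
  depth <- integer(hap_len)
  for (p in placed) {
    if (p$hap_index != hap_index) next
    if (p$end > p$start)
      depth[(p$start + 1):min(p$end, hap_len)] <-
        depth[(p$start + 1):min(p$end, hap_len)] + 1L
  }
  depth
}

#' Quality-control metrics for a haplotype-resolved pileup
#'
#' Computes, per allele (haplotype) and STR: spanning / flanking /
#' in-repeat read counts and repeat-region depth; per allele: flank depth
#' and a depth-evenness score (coefficient of variation of per-position
#' depth over the interior of the haplotype); and the in-repeat indel rate
#' (insertion + deletion events per aligned kb inside repeats).  Boolean
#' flags mirror the visual low-confidence heuristics: `short_allele_weak`
#' (the shorter allele of some STR has <= 1 spanning read),
#' `expansion_weak` (an allele's repeat depth below `expansion_weak_frac`
#' of its flank depth) and `noisy_repeat` (indel rate above
#' `noisy_indel_rate` per kb).
#'
#' @param pileup a `StrPileup` from [generate_pileup()].
#' @param expansion_weak_frac repeat/flank depth ratio threshold
#'   (default 0.3).
#' @param noisy_indel_rate indel events per kb threshold (default 20).
#' @return object of class `PileupMetrics` (list with `per_allele`
#'   data.frame, `per_hap` data.frame, `flags`, `flank_spanning_ratio`).
#' @export
compute_metrics <- function(pileup, expansion_weak_frac = 0.3,
                            noisy_indel_rate = 20) {
  haps <- pair_haps(pileup$pair)
  placed <- pileup$placed
  strs <- locus_strs(pileup$locus)
  read_len <- if (length(placed))
    max(vapply(placed, function(p) cigar_read_len(p$cigar), numeric(1))) else 0

  rows <- list(); hap_rows <- list()
  indel_events <- 0; indel_bases <- 0
  for (h in seq_along(haps)) {
    hap <- haps[[h]]
    hl <- nchar(hap$sequence)
    depth <- depth_profile(placed, h, hl)
    sm <- hap$segment_map
    rep_pos <- logical(hl)
    for (r in which(sm$type == "str"))
      if (sm$end[r] > sm$start[r]) rep_pos[(sm$start[r] + 1):sm$end[r]] <- TRUE
    flank_depth <- if (any(!rep_pos)) mean(depth[!rep_pos]) else 0
    # evenness over the interior (coverage ramps over one read length at
    # each end are geometry, not signal)
    trim <- min(floor(hl / 4), ceiling(read_len))
    interior <- depth[(trim + 1):(hl - trim)]
    cv <- if (mean(interior) > 0) sd(interior) / mean(interior) else NA_real_
    hap_rows[[h]] <- data.frame(hap = h, flank_depth = flank_depth,
                                depth_cv = cv,
                                mean_depth = mean(depth))
    for (s in strs) {
      ri <- repeat_interval(hap, s$str_id)
      cls <- vapply(placed, function(p)
        if (p$hap_index == h) p$classes[[s$str_id]] else "other", character(1))
      rep_depth <- if (ri["end"] > ri["start"])
        mean(depth[(ri["start"] + 1):ri["end"]]) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        hap = h, str_id = s$str_id, allele_units = hap$str_counts[[s$str_id]],
        spanning = sum(cls == "spanning"), flanking = sum(cls == "flanking"),
        in_repeat = sum(cls == "in_repeat"), repeat_depth = rep_depth,
        stringsAsFactors = FALSE)
    }
    # indel ops inside repeats
    for (p in placed) {
      if (p$hap_index != h) next
      ops <- parse_cigar(p$cigar)
      pos <- p$start
      for (k in seq_len(ops$n)) {
        consumes_ref <- ops$op[k] %in% c("=", "X", "D", "M")
        inside <- pos >= 0 && pos < hl && isTRUE(rep_pos[min(pos + 1, hl)])
        if (ops$op[k] %in% c("I", "D") && inside) indel_events <- indel_events + 1
        if (ops$op[k] %in% c("=", "X", "M") && consumes_ref) {
          lo <- pos; hi <- pos + ops$len[k]
          if (hi > lo)
            indel_bases <- indel_bases +
              sum(rep_pos[max(lo + 1, 1):min(hi, hl)])
        }
        if (consumes_ref) pos <- pos + ops$len[k]
      }
    }
  }
  per_allele <- do.call(rbind, rows)
  per_hap <- do.call(rbind, hap_rows)
  indel_rate <- if (indel_bases > 0) 1000 * indel_events / indel_bases else 0

  short_allele_weak <- FALSE
  for (s in strs) {
    sub <- per_allele[per_allele$str_id == s$str_id, , drop = FALSE]
    short <- sub[which.min(sub$allele_units), , drop = FALSE]
    if (nrow(short) && short$spanning <= 1) short_allele_weak <- TRUE
  }
  expansion_weak <- FALSE
  for (h in seq_along(haps)) {
    sub <- per_allele[per_allele$hap == h, , drop = FALSE]
    fd <- per_hap$flank_depth[per_hap$hap == h]
    rd <- sub$repeat_depth[!is.na(sub$repeat_depth)]
    if (length(rd) && fd > 0 && any(rd < expansion_weak_frac * fd))
      expansion_weak <- TRUE
  }
  noisy_repeat <- indel_rate > noisy_indel_rate

  total_flanking <- sum(per_allele$flanking)
  total_spanning <- sum(per_allele$spanning)
  structure(list(per_allele = per_allele, per_hap = per_hap,
                 in_repeat_indel_rate = indel_rate,
                 flank_spanning_ratio = if (total_spanning > 0)
                   total_flanking / total_spanning else Inf,
                 flags = list(short_allele_weak = short_allele_weak,
                              expansion_weak = expansion_weak,
                              noisy_repeat = noisy_repeat)),
            class = "PileupMetrics")
}

#' @export
print.PileupMetrics <- function(x, ...) {
  cat("<PileupMetrics>\n")
  print(x$per_allele, row.names = FALSE)
  cat(sprintf("in-repeat indel rate: %.1f /kb\n", x$in_repeat_indel_rate))
  cat("flags:", paste(names(x$flags)[unlist(x$flags)], collapse = " "),
      if (!any(unlist(x$flags))) "(none)", "\n")
  invisible(x)
}

#' Export metrics as JSON or a one-row TSV
#'
#' @param metrics a `PileupMetrics`.
#' @param locus_id label included in the output.
#' @return JSON text (`metrics_to_json`) or a one-row TSV with header
#'   (`metrics_to_tsv`).
#' @export
metrics_to_json <- function(metrics, locus_id = NA_character_) {
  jsonlite::toJSON(list(locus = locus_id, per_allele = metrics$per_allele,
                        per_hap = metrics$per_hap,
                        in_repeat_indel_rate = metrics$in_repeat_indel_rate,
                        flank_spanning_ratio = metrics$flank_spanning_ratio,
                        flags = metrics$flags),
                   auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
}

#' @rdname metrics_to_json
#' @export
metrics_to_tsv <- function(metrics, locus_id = NA_character_) {
  pa <- metrics$per_allele
  flat <- list(locus = locus_id)
  for (r in seq_len(nrow(pa))) {
    key <- sprintf("h%d_%s", pa$hap[r], pa$str_id[r])
    flat[[paste0(key, "_units")]] <- pa$allele_units[r]
    flat[[paste0(key, "_spanning")]] <- pa$spanning[r]
    flat[[paste0(key, "_flanking")]] <- pa$flanking[r]
    flat[[paste0(key, "_in_repeat")]] <- pa$in_repeat[r]
  }
  flat$in_repeat_indel_rate <- metrics$in_repeat_indel_rate
  flat$flank_spanning_ratio <- metrics$flank_spanning_ratio
  for (f in names(metrics$flags)) flat[[f]] <- metrics$flags[[f]]
  df <- as.data.frame(flat, stringsAsFactors = FALSE)
  paste(paste(names(df), collapse = "\t"),
        paste(vapply(df[1, ], as.character, character(1)), collapse = "\t"),
        sep = "\n")
}
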
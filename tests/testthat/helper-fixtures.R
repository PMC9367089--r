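# Shared fixture builders.  Everything is generated in code; no data files.

rand_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# single-STR locus with given flank length; coordinates on a synthetic
# contig laid out so that haplotype position == contig position
make_locus <- function(unit = "CGG", ref_units = 20L, flank = 500L,
                       contig = "sim", locus_id = "L1", str_id = "STR1") {
  locus_spec(locus_id, list(
    constant_segment(rand_dna(flank)),
    str_spec(str_id, unit, contig, flank, flank + ref_units * nchar(unit)),
    constant_segment(rand_dna(flank))))
}

# two-STR locus (CAG spacer CCG), HD-like geometry
make_two_str_locus <- function(flank = 400L, spacer = 20L, contig = "sim",
                               locus_id = "L2") {
  locus_spec(locus_id, list(
    constant_segment(rand_dna(flank)),
    str_spec("STR_A", "CAG", contig, flank, flank + 30L),
    constant_segment(rand_dna(spacer)),
    str_spec("STR_B", "CCG", contig, flank + 30L + spacer,
             flank + 30L + spacer + 21L),
    constant_segment(rand_dna(flank))))
}

make_truth_pair <- function(locus, counts1, counts2, structures1 = NULL,
                            structures2 = NULL) {
  h1 <- build_haplotype(locus, counts1, structures1)
  h2 <- build_haplotype(locus, counts2, structures2)
  strpileup:::new_haplotype_pair(h1, h2, "truth")
}

# minimal hand-built pileup for metric/render unit tests
make_manual_pileup <- function(locus, pair, placed) {
  haps <- strpileup:::pair_haps(pair)
  strs <- locus_strs(locus)
  for (i in seq_along(placed)) {
    p <- placed[[i]]
    cls <- lapply(strs, function(s)
      classify_read(structure(list(start = p$start, end = p$end),
                              class = "ReadAlignment"),
                    haps[[p$hap_index]], s$str_id))
    names(cls) <- vapply(strs, function(s) s$str_id, character(1))
    placed[[i]]$classes <- cls
    placed[[i]]$class <- strpileup:::overall_class(unlist(cls))
    if (is.null(placed[[i]]$faint)) placed[[i]]$faint <- FALSE
    if (is.null(placed[[i]]$hap_support)) placed[[i]]$hap_support <- "score"
  }
  placed <- assign_lanes(placed)
  pu <- structure(list(locus = locus, pair = pair, placed = placed,
                       fragment_stats = fragment_stats(450, 100, 50),
                       counters = c(), haps_identical = FALSE, seed = 1L),
                  class = "StrPileup")
  pu$metrics <- compute_metrics(pu)
  pu
}

manual_read <- function(fragment_id, mate, hap, start, cigar, bases,
                        strand = "+", score = 0L) {
  list(fragment_id = fragment_id, mate_index = mate, hap_index = hap,
       start = start, end = start + strpileup:::cigar_ref_len(cigar),
       cigar = cigar, score = score, strand = strand, bases = bases,
       faint = FALSE, hap_support = "score", lane = NA_integer_)
}

# Independent affine-gap local-alignment score oracle: plain-loop Gotoh
# with a zero floor, free read-end clipping implicit in locality.
oracle_local_score <- function(read, hap, scheme) {
  m <- nchar(read); n <- nchar(hap)
  rb <- strsplit(read, "")[[1]]; hb <- strsplit(hap, "")[[1]]
  NEG <- -1e9
  Hprev <- rep(0, n + 1); Eprev <- NULL
  Fprev <- rep(NEG, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    Hcur <- rep(0, n + 1); Fcur <- rep(NEG, n + 1); Ecur <- rep(NEG, n + 1)
    for (j in seq_len(n)) {
      s <- if (rb[i] == "N" || hb[j] == "N") scheme$mismatch
      else if (rb[i] == hb[j]) scheme$match else scheme$mismatch
      Ecur[j + 1] <- max(Hcur[j] + scheme$gap_open + scheme$gap_extend,
                         Ecur[j] + scheme$gap_extend)
      Fcur[j + 1] <- max(Hprev[j + 1] + scheme$gap_open + scheme$gap_extend,
                         Fprev[j + 1] + scheme$gap_extend)
      Hcur[j + 1] <- max(0, Hprev[j] + s, Ecur[j + 1], Fcur[j + 1])
      if (Hcur[j + 1] > best) best <- Hcur[j + 1]
    }
    Hprev <- Hcur; Fprev <- Fcur
  }
  best
}

# brute-force count of perfect (ungapped, mismatch-free) placements
sliding_exact_placements <- function(read, hap) {
  m <- nchar(read); n <- nchar(hap)
  if (m > n) return(integer(0))
  hits <- integer(0)
  for (s in 0:(n - m))
    if (substr(hap, s + 1, s + m) == read) hits <- c(hits, s)
  hits
}

# exhaustive haplotype-pair enumeration oracle: all 2^n ordered allele
# assignments, deduplicated as unordered sequence pairs
oracle_enumerate_pairs <- function(locus, genotypes) {
  ids <- vapply(locus_strs(locus), function(s) s$str_id, character(1))
  n <- length(ids)
  seen <- character(0)
  for (mask in 0:(2^n - 1)) {
    bits <- bitwAnd(bitwShiftR(mask, seq_len(n) - 1), 1L) + 1L
    c1 <- vapply(seq_len(n), function(k)
      genotypes[[ids[k]]]$allele_sizes[bits[k]], integer(1))
    c2 <- vapply(seq_len(n), function(k)
      genotypes[[ids[k]]]$allele_sizes[3L - bits[k]], integer(1))
    names(c1) <- ids; names(c2) <- ids
    s1 <- build_haplotype(locus, c1)$sequence
    s2 <- build_haplotype(locus, c2)$sequence
    seen <- union(seen, paste(sort(c(s1, s2)), collapse = "|"))
  }
  seen
}
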
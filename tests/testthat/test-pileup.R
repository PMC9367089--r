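test_that("read classification partitions cleanly by repeat overlap", {
  set.seed(30)
  locus <- make_locus(unit = "CAG", ref_units = 10, flank = 200)
  hap <- build_haplotype(locus, c(STR1 = 10L))  # repeat [200, 230)
  aln <- function(s, e) structure(list(start = s, end = e), class = "ReadAlignment")

  expect_equal(classify_read(aln(190, 240), hap, "STR1"), "spanning")
  expect_equal(classify_read(aln(195, 215), hap, "STR1"), "flanking")
  expect_equal(classify_read(aln(215, 245), hap, "STR1"), "flanking")
  expect_equal(classify_read(aln(203, 227), hap, "STR1"), "in_repeat")
  expect_equal(classify_read(aln(10, 150), hap, "STR1"), "flank_only")
  # anchors shorter than min_anchor demote spanning to flanking
  expect_equal(classify_read(aln(198, 232), hap, "STR1"), "flanking")
  expect_equal(classify_read(aln(195, 235), hap, "STR1", min_anchor = 5L), "spanning")
  expect_error(classify_read(aln(0, 10), hap, "NOPE"), "unknown")

  # the partition is exhaustive and exclusive over random intervals
  hap600 <- build_haplotype(locus, c(STR1 = 200L))  # long expansion
  for (i in 1:50) {
    s <- sample(0:900, 1); e <- s + sample(20:150, 1)
    cls <- classify_read(aln(s, e), hap600, "STR1")
    expect_true(cls %in% c("spanning", "flanking", "in_repeat", "flank_only"))
  }
  # a read wholly inside a 600 bp expansion is in_repeat
  expect_equal(classify_read(aln(300, 440), hap600, "STR1"), "in_repeat")
})

test_that("lane packing is greedy, gap-aware, and matches the depth oracle", {
  mk <- function(fid, s, e, hap = 1L)
    list(fragment_id = fid, hap_index = hap, start = s, end = e,
         lane = NA_integer_)
  # two non-overlapping reads share lane 0
  p <- assign_lanes(list(mk("a", 0, 100), mk("b", 200, 300)), gap = 5)
  expect_equal(vapply(p, function(x) x$lane, integer(1)), c(0L, 0L))

  # three mutually overlapping reads need lanes 0,1,2
  p3 <- assign_lanes(list(mk("a", 0, 100), mk("b", 50, 150), mk("c", 80, 180)))
  expect_setequal(vapply(p3, function(x) x$lane, integer(1)), 0:2)

  # mates share a lane
  pm <- assign_lanes(list(mk("a", 0, 100), mk("a", 300, 400),
                          mk("b", 50, 150)))
  lanes <- vapply(pm, function(x) x$lane, integer(1))
  expect_equal(lanes[1], lanes[2])
  expect_true(lanes[3] != lanes[1])

  # 100 random single reads: lane count equals max gap-extended overlap
  set.seed(31)
  reads <- lapply(1:100, function(i) {
    s <- sample(0:2000, 1)
    mk(sprintf("r%03d", i), s, s + sample(50:200, 1))
  })
  packed <- assign_lanes(reads, gap = 5)
  lanes_used <- max(vapply(packed, function(x) x$lane, integer(1))) + 1L
  # oracle: max overlap depth of [start, end + gap) intervals
  ev <- sort(unique(unlist(lapply(reads, function(r) c(r$start, r$end + 5)))))
  depth <- vapply(ev, function(t)
    sum(vapply(reads, function(r) r$start <= t && t < r$end + 5, logical(1))),
    integer(1))
  expect_equal(lanes_used, max(depth))
  # no overlapping lane-mates anywhere
  for (l in 0:(lanes_used - 1)) {
    inl <- Filter(function(x) x$lane == l, packed)
    ivs <- do.call(rbind, lapply(inl, function(x) c(x$start, x$end)))
    ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
    if (nrow(ivs) > 1)
      expect_true(all(ivs[-1, 1] >= ivs[-nrow(ivs), 2] + 5))
  }
})

test_that("metrics flag weak short alleles, thin expansions and noisy repeats", {
  set.seed(32)
  locus <- make_locus(unit = "CAG", ref_units = 10, flank = 200)
  pair <- make_truth_pair(locus, c(STR1 = 10L), c(STR1 = 120L))
  haps <- strpileup:::pair_haps(pair)
  short_h <- which(vapply(haps, function(h) h$str_counts[["STR1"]] == 10L,
                          logical(1)))
  long_h <- 3L - short_h
  ri_s <- repeat_interval(haps[[short_h]], "STR1")
  ri_l <- repeat_interval(haps[[long_h]], "STR1")

  base_reads <- function() {
    out <- list()
    for (i in 1:12) {   # spanning reads on the short allele
      s <- ri_s["start"] - 60 + i * 4
      out[[length(out) + 1]] <- manual_read(sprintf("s%02d", i), 1L, short_h,
                                            s, "120=", rand_dna(120))
    }
    for (i in 1:25) {   # flanking + in-repeat coverage on the expansion
      s <- ri_l["start"] - 60 + i * 16
      out[[length(out) + 1]] <- manual_read(sprintf("l%02d", i), 1L, long_h,
                                            s, "120=", rand_dna(120))
    }
    out
  }
  pu <- make_manual_pileup(locus, pair, base_reads())
  m <- pu$metrics
  expect_false(m$flags$short_allele_weak)
  expect_false(m$flags$noisy_repeat)
  sub <- m$per_allele[m$per_allele$hap == short_h, ]
  expect_gte(sub$spanning, 10)

  # exactly one spanning read on the short allele
  one_span <- Filter(function(p) !(p$hap_index == short_h), base_reads())
  one_span[[length(one_span) + 1]] <- manual_read("s01", 1L, short_h,
                                                  ri_s["start"] - 30, "100=",
                                                  rand_dna(100))
  m2 <- make_manual_pileup(locus, pair, one_span)$metrics
  expect_true(m2$flags$short_allele_weak)

  # expansion supported only by in-repeat reads carrying 3 indels each
  noisy <- Filter(function(p)
    !(p$hap_index == long_h && p$start >= ri_l["start"] - 50), base_reads())
  for (i in 1:10) {
    s <- ri_l["start"] + 20 + i * 10
    noisy[[length(noisy) + 1]] <- manual_read(sprintf("n%02d", i), 1L, long_h,
                                              s, "20=1D20=1I20=1D39=",
                                              rand_dna(100))
  }
  m3 <- make_manual_pileup(locus, pair, noisy)$metrics
  expect_true(m3$flags$noisy_repeat)
  expect_gt(m3$in_repeat_indel_rate, 20)

  # starve the expansion of in-repeat coverage -> expansion_weak
  thin <- Filter(function(p) {
    !(p$hap_index == long_h && p$start >= ri_l["start"] - 50)
  }, base_reads())
  for (i in 1:8)   # flank coverage on the long hap, away from the repeat
    thin[[length(thin) + 1]] <- manual_read(sprintf("f%02d", i), 1L, long_h,
                                            10 + i * 8, "100=", rand_dna(100))
  m4 <- make_manual_pileup(locus, pair, thin)$metrics
  expect_true(m4$flags$expansion_weak)
})

test_that("metrics are invariant to read input order", {
  set.seed(33)
  locus <- make_locus(ref_units = 15, flank = 450)
  pair <- make_truth_pair(locus, c(STR1 = 15L), c(STR1 = 25L))
  cfg <- sim_config(pair, coverage = 15, read_len = 100, frag_mean = 300,
                    frag_sd = 40, base_error = 0.002, seed = 8)
  sim <- simulate_read_pairs(cfg)
  genos <- list(STR1 = repeat_genotype("STR1", c(15L, 25L)))
  pu1 <- generate_pileup(locus, genos, sim$reads, seed = 4)
  perm <- sample(length(sim$reads))
  pu2 <- generate_pileup(locus, genos, sim$reads[perm], seed = 4)
  expect_equal(pu1$metrics$per_allele, pu2$metrics$per_allele)
  expect_equal(pu1$metrics$flags, pu2$metrics$flags)
})

test_that("metrics export to JSON and one-row TSV", {
  set.seed(34)
  locus <- make_locus(unit = "CAG", ref_units = 10, flank = 200)
  pair <- make_truth_pair(locus, c(STR1 = 10L), c(STR1 = 12L))
  pu <- make_manual_pileup(locus, pair, list(
    manual_read("a", 1L, 1L, 150, "120=", rand_dna(120)),
    manual_read("b", 1L, 2L, 160, "120=", rand_dna(120))))
  js <- jsonlite::fromJSON(metrics_to_json(pu$metrics, "L1"))
  expect_equal(js$locus, "L1")
  expect_false(js$flags$noisy_repeat)
  tsv <- strsplit(metrics_to_tsv(pu$metrics, "L1"), "\n")[[1]]
  expect_length(tsv, 2)
  expect_equal(length(strsplit(tsv[1], "\t")[[1]]),
               length(strsplit(tsv[2], "\t")[[1]]))
})
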
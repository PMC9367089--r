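make_aln <- function(hap, start, len, strand = "+", frag = "f", mate = 1L) {
  strpileup:::new_read_alignment(frag, mate, hap, as.integer(start),
                                 sprintf("%d=", len), len * 5L, strand)
}

test_that("fragment stats come from uniquely placed flank pairs", {
  set.seed(20)
  locus <- make_locus(ref_units = 20, flank = 600)
  pair <- make_truth_pair(locus, c(STR1 = 20L), c(STR1 = 20L))

  # 50 pairs with span exactly 400, wholly in the left flank
  placements <- list()
  for (i in 1:50) {
    fid <- sprintf("f%03d", i)
    placements[[fid]] <- list(
      mate1 = list(make_aln(1L, 10 + i, 100, "+", fid, 1L)),
      mate2 = list(make_aln(1L, 10 + i + 300, 100, "-", fid, 2L)))
  }
  st <- estimate_fragment_stats(placements, pair)
  expect_equal(st$mean_len, 400)
  expect_equal(st$sd_len, 0)
  expect_equal(st$n_pairs, 50L)
  expect_false(st$fallback)

  # a mate overlapping the repeat does not qualify
  fid <- "fbad"
  placements[[fid]] <- list(
    mate1 = list(make_aln(1L, 550, 100, "+", fid, 1L)),  # crosses repeat start
    mate2 = list(make_aln(1L, 900, 100, "-", fid, 2L)))
  expect_equal(estimate_fragment_stats(placements, pair)$n_pairs, 50L)

  # too few pairs: loud fallback to the configured default
  expect_warning(
    st0 <- estimate_fragment_stats(placements[1:3], pair),
    "default")
  expect_true(st0$fallback)
  expect_equal(st0$mean_len, 450)
})

test_that("estimated mean tracks the simulated distribution", {
  set.seed(21)
  locus <- make_locus(ref_units = 10, flank = 900)
  pair <- make_truth_pair(locus, c(STR1 = 10L), c(STR1 = 12L))
  cfg <- sim_config(pair, coverage = 40, read_len = 100, frag_mean = 450,
                    frag_sd = 100, base_error = 0, seed = 9)
  sim <- simulate_read_pairs(cfg)
  genos <- list(STR1 = repeat_genotype("STR1", c(10L, 12L)))
  pu <- generate_pileup(locus, genos, sim$reads, seed = 1)
  expect_gt(pu$fragment_stats$n_pairs, 100)
  # sampling-error bound at this n
  expect_lt(abs(pu$fragment_stats$mean_len - 450), 15)
})

test_that("joint placements follow the product law and the length gate", {
  st <- fragment_stats(450, 100, 50)
  one1 <- list(make_aln(1L, 100, 100, "+", "f", 1L))
  one2 <- list(make_aln(1L, 400, 100, "-", "f", 2L))
  expect_length(enumerate_pair_candidates(one1, one2, st), 1)

  # 11 x 11 in-repeat placements: <= 121 candidates before the gate
  p1 <- lapply(seq(0, 30, 3), function(s) make_aln(1L, 100 + s, 30, "+", "f", 1L))
  p2 <- lapply(seq(0, 30, 3), function(s) make_aln(1L, 300 + s, 30, "-", "f", 2L))
  cands <- enumerate_pair_candidates(p1, p2, fragment_stats(260, 1000, 50),
                                     check_orientation = FALSE)
  expect_length(cands, 121)
  # with a tight gate only close-to-mean spans survive
  gated <- enumerate_pair_candidates(p1, p2, fragment_stats(230, 1, 50),
                                     check_orientation = FALSE)
  expect_true(all(vapply(gated, function(c) c$fragment_len <= 234, logical(1))))
  expect_lt(length(gated), 121)

  # no shared haplotype -> empty
  other <- list(make_aln(2L, 400, 100, "-", "f", 2L))
  expect_length(enumerate_pair_candidates(one1, other, st), 0)

  # discordant orientation dropped
  same <- list(make_aln(1L, 400, 100, "+", "f", 2L))
  expect_length(enumerate_pair_candidates(one1, same, st), 0)
})

test_that("flank-anchored pairs across a repeat report allele-dependent spans", {
  set.seed(22)
  locus <- make_locus(unit = "CAG", ref_units = 10, flank = 300)
  h_short <- build_haplotype(locus, c(STR1 = 10L))
  h_long <- build_haplotype(locus, c(STR1 = 40L))
  st <- fragment_stats(450, 150, 50)
  for (h in list(list(1L, h_short, 10L), list(1L, h_long, 40L))) {
    hap <- h[[2]]
    ri <- repeat_interval(hap, "STR1")
    a1 <- make_aln(1L, ri["start"] - 120, 100, "+", "f", 1L)
    a2 <- make_aln(1L, ri["end"] + 20, 100, "-", "f", 2L)
    cands <- enumerate_pair_candidates(list(a1), list(a2), st)
    expect_length(cands, 1)
    expect_equal(cands[[1]]$fragment_len, 240 + 3 * h[[3]])
  }
})

test_that("selection is argmin-by-distance, deterministic, and splits ties 50/50", {
  c1 <- list(aln1 = make_aln(1L, 0, 10), aln2 = make_aln(1L, 50, 10),
             hap_index = 1L, fragment_len = 60, distance = 5)
  c2 <- list(aln1 = make_aln(1L, 0, 10), aln2 = make_aln(1L, 60, 10),
             hap_index = 1L, fragment_len = 70, distance = 12)
  sel <- select_pair_alignment(list(c1, c2))
  expect_equal(sel$choice$distance, 5)
  expect_false(sel$ambiguous)
  expect_equal(sel$n_tied, 1L)

  sel1 <- select_pair_alignment(list(c2))
  expect_false(sel1$ambiguous)

  # 4 tied candidates, 2 per haplotype: uniform over ties, ambiguous
  tied <- lapply(c(1L, 1L, 2L, 2L), function(h)
    list(aln1 = make_aln(h, 0, 10), aln2 = make_aln(h, 50, 10),
         hap_index = h, fragment_len = 60, distance = 3))
  draws <- vapply(1:4000, function(i) {
    set.seed(i)
    s <- select_pair_alignment(tied)
    expect_true(s$ambiguous)
    s$choice$hap_index
  }, integer(1))
  expect_lt(abs(mean(draws == 1L) - 0.5), 0.03)

  # determinism: same seed, same choice
  pick <- function(seed) { set.seed(seed); select_pair_alignment(tied)$choice$aln2$start }
  expect_identical(pick(7), pick(7))
})

test_that("homozygous loci get even coverage and no duplicated fragments", {
  set.seed(23)
  locus <- make_locus(unit = "CAG", ref_units = 20, flank = 600)
  truth <- make_truth_pair(locus, c(STR1 = 60L), c(STR1 = 60L))
  cfg <- sim_config(truth, coverage = 30, read_len = 120, frag_mean = 400,
                    frag_sd = 60, base_error = 0, seed = 19)
  sim <- simulate_read_pairs(cfg)
  genos <- list(STR1 = repeat_genotype("STR1", c(60L, 60L)))
  pu <- generate_pileup(locus, genos, sim$reads, seed = 8)

  # every placed fragment sits on exactly one haplotype, both mates together
  frag_hap <- tapply(vapply(pu$placed, function(p) p$hap_index, integer(1)),
                     vapply(pu$placed, function(p) p$fragment_id, character(1)),
                     function(h) length(unique(h)))
  expect_true(all(frag_hap == 1))
  tab <- table(vapply(pu$placed, function(p)
    paste(p$fragment_id, p$mate_index, p$hap_index), character(1)))
  expect_true(all(tab == 1))

  # identical alleles: the random tie-break spreads fragments ~50/50 and
  # per-position depth on each haplotype is even (binomial-noise CV)
  n_hap <- table(vapply(pu$placed, function(p) p$hap_index, integer(1)))
  expect_lt(abs(n_hap[[1]] / sum(n_hap) - 0.5), 0.07)
  for (h in 1:2) {
    depth <- strpileup:::depth_profile(pu$placed, h,
                                       nchar(strpileup:::pair_haps(pu$pair)[[h]]$sequence))
    interior <- depth[200:(length(depth) - 200)]
    expect_gt(mean(interior), 8)
    expect_lt(sd(interior) / mean(interior), 0.45)
  }
})
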
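test_that("align_read matches the independent affine-gap DP oracle", {
  set.seed(10)
  scheme <- scoring_scheme()
  for (i in 1:120) {
    n <- sample(30:200, 1)
    hap <- rand_dna(n)
    m <- sample(8:min(50, n), 1)
    kind <- sample(1:3, 1)
    read <- if (kind == 1) {
      rand_dna(m)                       # unrelated
    } else {
      s <- sample(0:(n - m), 1)
      r <- substr(hap, s + 1, s + m)    # substring, possibly mutated
      if (kind == 3) {
        ch <- strsplit(r, "")[[1]]
        for (p in sample(m, sample(1:3, 1)))
          ch[p] <- sample(c("A", "C", "G", "T"), 1)
        if (m > 12) ch <- ch[-sample(3:(m - 3), 1)]   # deletion in read
        r <- paste0(ch, collapse = "")
      }
      r
    }
    got <- align_read(read, hap, scheme, score_only = TRUE)
    expect_identical(got, as.integer(oracle_local_score(read, hap, scheme)))
  }
})

test_that("alignment scores equal recomputation from their ops", {
  set.seed(11)
  scheme <- scoring_scheme()
  hap <- paste0(rand_dna(40), strrep("CAG", 15), rand_dna(40))
  for (i in 1:20) {
    s <- sample(0:(nchar(hap) - 30), 1)
    read <- substr(hap, s + 1, s + 30)
    ch <- strsplit(read, "")[[1]]
    ch[sample(30, 1)] <- sample(c("A", "C", "G", "T"), 1)
    read <- paste0(ch, collapse = "")
    for (a in align_read(read, hap, scheme)) {
      ops <- strpileup:::parse_cigar(a$cigar)
      sc <- 0L
      for (k in seq_len(ops$n)) {
        sc <- sc + switch(ops$op[k],
          "=" = scheme$match * ops$len[k],
          "X" = scheme$mismatch * ops$len[k],
          "I" = scheme$gap_open + scheme$gap_extend * ops$len[k],
          "D" = scheme$gap_open + scheme$gap_extend * ops$len[k],
          "S" = 0L)
      }
      expect_equal(a$score, sc)
      expect_equal(sum(ops$len[ops$op %in% c("=", "X", "I", "S")]), nchar(read))
      expect_lte(a$end, nchar(hap))
    }
  }
})

test_that("placement sets follow the repeat geometry laws", {
  set.seed(12)
  scheme <- scoring_scheme()
  flank_l <- rand_dna(20); flank_r <- rand_dna(20)

  # a unique flank substring aligns at exactly one position
  hap <- paste0(flank_l, strrep("CAG", 20), flank_r)
  read <- substr(hap, 3, 18)
  expect_length(align_read(read, hap, scheme), 1)

  # in-repeat read: placements match a sliding-window brute force and grow
  # linearly with the repeat length (U - u + 1 unit offsets)
  for (U in c(10, 20, 35)) {
    hap_u <- paste0(flank_l, strrep("CAG", U), flank_r)
    read_u <- strrep("CAG", 7)
    placements <- align_read(read_u, hap_u, scheme)
    expected <- sliding_exact_placements(read_u, hap_u)
    expect_equal(vapply(placements, function(a) a$start, integer(1)), expected)
    expect_length(placements, U - 7 + 1)
    expect_true(all(vapply(placements, function(a) a$score == 21L * scheme$match,
                           logical(1))))
  }

  # one interior mismatch: score (L-1)*match + mismatch at the true position
  hap <- paste0(flank_l, strrep("CAG", 20), flank_r)
  read <- substr(hap, 11, 40)
  ch <- strsplit(read, "")[[1]]; ch[15] <- if (ch[15] == "A") "T" else "A"
  read <- paste0(ch, collapse = "")
  best <- align_read(read, hap, scheme, score_only = TRUE)
  expect_equal(best, 29L * scheme$match + scheme$mismatch)
  expect_identical(best, as.integer(oracle_local_score(read, hap, scheme)))

  expect_error(align_read("", hap, scheme), "empty")
})

test_that("graph alignments project onto haplotypes with correct multiplicity", {
  set.seed(13)
  locus <- make_locus(unit = "CGG", flank = 500)
  hap30 <- build_haplotype(locus, c(STR1 = 30L))
  hap8 <- build_haplotype(locus, c(STR1 = 8L))
  scheme <- scoring_scheme()

  # flank-anchored path: left flank 30 bp + 5 units -> unique placement
  bases <- substr(hap30$sequence, 471, 471 + 44)
  rec <- read_record("f1", 1L, bases, graph_alignment = "0:470:30;1:15")
  pl <- project_graph_alignment(rec, hap30, locus, scheme)
  expect_length(pl, 1)
  expect_equal(pl[[1]]$start, 470L)
  expect_equal(pl[[1]]$score, 45L * scheme$match)

  # wholly in-repeat path of 10 units: U - u + 1 = 21 placements
  rec2 <- read_record("f2", 1L, strrep("CGG", 10), graph_alignment = "1:0:30")
  pl2 <- project_graph_alignment(rec2, hap30, locus, scheme)
  expect_length(pl2, 21)
  expect_equal(vapply(pl2, function(a) a$start, integer(1)),
               seq(500L, 560L, by = 3L))

  # same path on an 8-unit haplotype: incompatible -> empty
  expect_length(project_graph_alignment(rec2, hap8, locus, scheme), 0)

  # unknown segment -> error
  rec3 <- read_record("f3", 1L, "CGG", graph_alignment = "9:0:3")
  expect_error(project_graph_alignment(rec3, hap30, locus, scheme), "absent")
})

test_that("pair scoring is order/swap invariant and selects the best pair", {
  set.seed(14)
  locus <- make_two_str_locus(flank = 400)
  genos <- list(STR_A = repeat_genotype("STR_A", c(6L, 10L)),
                STR_B = repeat_genotype("STR_B", c(3L, 7L)))
  cands <- enumerate_haplotype_pairs(locus, genos)
  expect_length(cands, 2)
  truth <- cands[[1]]
  cfg <- sim_config(truth, coverage = 10, read_len = 100, frag_mean = 300,
                    frag_sd = 40, base_error = 0, seed = 21)
  sim <- simulate_read_pairs(cfg)

  scored <- lapply(cands, score_haplotype_pair, reads = sim$reads, locus = locus)
  sc <- vapply(scored, function(p) p$cumulative_score, integer(1))
  expect_gt(sc[1], sc[2])  # true phase wins

  # error-free reads from the true pair: cumulative score = total bases x match
  total_bases <- sum(vapply(sim$reads, function(r) nchar(r$bases), numeric(1)))
  expect_equal(sc[1], as.integer(total_bases * scoring_scheme()$match))

  # invariant to read order
  perm <- sample(length(sim$reads))
  re <- score_haplotype_pair(cands[[1]], sim$reads[perm], locus)
  expect_equal(re$cumulative_score, sc[1])

  # invariant to hap1/hap2 swap
  swapped <- cands[[1]]
  tmp <- swapped$hap1; swapped$hap1 <- swapped$hap2; swapped$hap2 <- tmp
  expect_equal(score_haplotype_pair(swapped, sim$reads, locus)$cumulative_score,
               sc[1])

  sel <- select_haplotype_pair(cands, sim$reads, locus)
  expect_equal(sel$phase_id, truth$phase_id)

  # single candidate: returned unscored
  single <- select_haplotype_pair(cands[1], sim$reads, locus)
  expect_true(is.na(single$cumulative_score))
})

test_that("tied pair scores resolve canonically with a message", {
  set.seed(15)
  # palindromic genotype situation: reads wholly in flanks can't phase
  locus <- make_two_str_locus(flank = 400)
  genos <- list(STR_A = repeat_genotype("STR_A", c(6L, 10L)),
                STR_B = repeat_genotype("STR_B", c(3L, 7L)))
  cands <- enumerate_haplotype_pairs(locus, genos)
  # one flank-only read: scores tie across pairings
  reads <- list(read_record("f1", 1L, substr(left_flank(locus), 11, 90)))
  expect_message(sel <- select_haplotype_pair(cands, reads, locus), "tie")
  keys <- vapply(cands, function(p) paste(p$hap1$sequence, p$phase_id),
                 character(1))
  expect_equal(paste(sel$hap1$sequence, sel$phase_id), sort(keys)[1])
})
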
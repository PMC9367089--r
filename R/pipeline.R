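#' Generate a haplotype-resolved STR pileup
#'
#' The full method: enumerate candidate haplotype pairs from the repeat
#' genotypes, select the pair with the highest cumulative read-alignment
#' score, find every score-tied placement of each read on the selected
#' haplotypes, estimate the fragment-length distribution from flank-mapped
#' pairs, keep each read pair's joint placements closest to the mean
#' fragment length, and pick one per pair at random for visualisation.
#'
#' @param locus a `LocusSpec`.
#' @param genotypes named list of [repeat_genotype()] per STR.
#' @param reads list of [read_record()]s (mates joined by `fragment_id`).
#' @param scheme a [scoring_scheme()].
#' @param seed integer seed for the per-locus RNG used in tie-breaking
#'   (default 42); fragments are processed in sorted `fragment_id` order so
#'   identical inputs and seed give byte-identical output.
#' @param use_graph honour graph-alignment tags when present (default TRUE);
#'   otherwise reads are realigned de novo.
#' @param min_flank_pairs,default_frag_mean,default_frag_sd fragment-length
#'   estimation controls (see [estimate_fragment_stats()]).
#' @param k_sd fragment-length gate width (default 4 sd).
#' @param min_anchor spanning-read anchor length in bp (default 5).
#' @param lane_gap minimum bp between lane neighbours (default 5).
#' @param max_pairings cap on enumerated pairings (default 64).
#' @return an object of class `StrPileup`: list with `locus`, `genotypes`,
#'   `pair` (selected `HaplotypePair`), `placed` (placed, classified,
#'   lane-assigned reads), `fragment_stats`, `counters` (dropped-read
#'   bookkeeping) and `metrics`.
#' @export
generate_pileup <- function(locus, genotypes, reads, scheme = scoring_scheme(),
                            seed = 42L, use_graph = TRUE,
                            min_flank_pairs = 10L, default_frag_mean = 450,
                            default_frag_sd = 100, k_sd = 4, min_anchor = 5L,
                            lane_gap = 5L, max_pairings = 64L) {
  candidates <- enumerate_haplotype_pairs(locus, genotypes, max_pairings)
  pair <- select_haplotype_pair(candidates, reads, locus, scheme)
  haps <- pair_haps(pair)

  # all top-scoring placements of every read on the selected haplotypes,
  # filtered to the global maximum across haplotypes
  paths <- decode_read_paths(reads)
  same_haps <- length(haps) == 2 && haps[[1]]$sequence == haps[[2]]$sequence
  per_read <- lapply(seq_along(reads), function(i) {
    rec <- reads[[i]]
    res <- vector("list", length(haps))
    for (h in seq_along(haps)) {
      r <- if (h == 2 && same_haps) res[[1]]
      else read_placements_on_hap(rec, haps[[h]], locus, scheme,
                                  use_graph = use_graph, path = paths[[i]])
      r$alignments <- lapply(r$alignments, function(a) { a$hap_index <- h; a })
      res[[h]] <- r
    }
    best <- max(vapply(res, function(r) r$score, integer(1)))
    alns <- do.call(c, lapply(res, function(r)
      if (r$score == best) r$alignments else list()))
    list(rec = rec, alignments = alns, score = best)
  })

  frag_ids <- vapply(reads, function(r) r$fragment_id, character(1))
  mates <- vapply(reads, function(r) r$mate_index, integer(1))
  counters <- c(orphan = 0L, unalignable = 0L, no_shared_hap = 0L,
                discordant_or_gated = 0L)

  placements <- list()
  for (fid in sort(unique(frag_ids))) {
    idx <- which(frag_ids == fid)
    m1 <- idx[mates[idx] == 1L]; m2 <- idx[mates[idx] == 2L]
    if (length(m1) != 1 || length(m2) != 1) {
      counters["orphan"] <- counters["orphan"] + 1L
      next
    }
    placements[[fid]] <- list(mate1 = per_read[[m1]]$alignments,
                              mate2 = per_read[[m2]]$alignments)
  }

  stats <- estimate_fragment_stats(placements, pair, min_flank_pairs,
                                   default_frag_mean, default_frag_sd)

  placed <- list()
  assignments <- list()
  with_seed(seed, {
    for (fid in sort(names(placements))) {
      pl <- placements[[fid]]
      if (length(pl$mate1) == 0 || length(pl$mate2) == 0) {
        counters["unalignable"] <- counters["unalignable"] + 1L
        next
      }
      cands <- enumerate_pair_candidates(pl$mate1, pl$mate2, stats, k_sd)
      if (length(cands) == 0) {
        h1 <- unique(vapply(pl$mate1, function(a) a$hap_index, integer(1)))
        h2 <- unique(vapply(pl$mate2, function(a) a$hap_index, integer(1)))
        key <- if (length(intersect(h1, h2)) == 0) "no_shared_hap"
        else "discordant_or_gated"
        counters[key] <- counters[key] + 1L
        next
      }
      sel <- select_pair_alignment(cands)
      assignments[[fid]] <- sel
      # how was the haplotype decided?  "score": alignment score alone
      # confined the candidates to one haplotype; "fragment": several
      # haplotypes were possible and fragment-length distance decided;
      # "random": the distance was tied across haplotypes too (rendered
      # faint).
      cand_haps <- unique(vapply(cands, function(c) c$hap_index, integer(1)))
      support <- if (length(cand_haps) == 1) "score"
      else if (sel$ambiguous) "random" else "fragment"
      for (a in list(sel$choice$aln1, sel$choice$aln2)) {
        rec_i <- idx_for(fid, a$mate_index, frag_ids, mates)
        mate_pl <- if (a$mate_index == 1L) pl$mate1 else pl$mate2
        n_on_hap <- sum(vapply(mate_pl, function(x)
          x$hap_index == a$hap_index, logical(1)))
        placed[[length(placed) + 1]] <- list(
          fragment_id = fid, mate_index = a$mate_index,
          hap_index = a$hap_index, start = a$start, end = a$end,
          cigar = a$cigar, score = a$score, strand = a$strand,
          bases = reads[[rec_i]]$bases, faint = sel$ambiguous,
          hap_support = support, n_placements = n_on_hap,
          lane = NA_integer_)
      }
    }
  })

  strs <- locus_strs(locus)
  for (i in seq_along(placed)) {
    p <- placed[[i]]
    aln <- structure(list(start = p$start, end = p$end), class = "ReadAlignment")
    cls <- lapply(strs, function(s)
      classify_read(aln, haps[[p$hap_index]], s$str_id, min_anchor))
    names(cls) <- vapply(strs, function(s) s$str_id, character(1))
    placed[[i]]$classes <- cls
    placed[[i]]$class <- overall_class(unlist(cls))
  }
  placed <- assign_lanes(placed, lane_gap)

  haps_identical <- length(haps) == 2 && haps[[1]]$sequence == haps[[2]]$sequence
  pileup <- structure(list(locus = locus, genotypes = genotypes, pair = pair,
                           placed = placed, fragment_stats = stats,
                           assignments = assignments, counters = counters,
                           haps_identical = haps_identical,
                           seed = seed, scheme = scheme),
                      class = "StrPileup")
  pileup$metrics <- compute_metrics(pileup)
  pileup
}

idx_for <- function(fid, mate, frag_ids, mates) {
  which(frag_ids == fid & mates == mate)[1]
}

#' @export
print.StrPileup <- function(x, ...) {
  cat(sprintf("<StrPileup %s: %d placed reads on %d haplotype(s)>\n",
              x$locus$locus_id, length(x$placed), length(pair_haps(x$pair))))
  cat(sprintf("  fragment length: mean %.1f sd %.1f (n = %d%s)\n",
              x$fragment_stats$mean_len, x$fragment_stats$sd_len,
              x$fragment_stats$n_pairs,
              if (x$fragment_stats$fallback) ", fallback" else ""))
  drops <- x$counters[x$counters > 0]
  if (length(drops))
    cat("  dropped:", paste(sprintf("%s=%d", names(drops), drops), collapse = " "), "\n")
  invisible(x)
}

#' Run the pipeline from files
#'
#' File-based front end used by the command-line interface: reads a locus
#' catalog (JSON) or wrapper TSV, genotypes (VCF, unless the TSV carries
#' them), and an indexed BAM, and produces the pileup.
#'
#' @param bam path to an indexed BAM of reads over the locus.
#' @param catalog path to a catalog JSON (with `vcf`), or `NULL` when
#'   `wrapper_tsv` is used.
#' @param vcf path to an ExpansionHunter-style VCF (catalog path only).
#' @param wrapper_tsv path to the 5-column wrapper TSV (self-sufficient:
#'   carries coordinates, units and genotypes).
#' @param locus_id which catalog locus to plot; defaults to the first.
#' @param reference optional reference source (FASTA path, named sequences
#'   or lookup function) for flanks when not inline.
#' @param flank_len flank length when extracting from a reference.
#' @param ... passed to [generate_pileup()].
#' @return a `StrPileup`.
#' @export
run_locus <- function(bam, catalog = NULL, vcf = NULL, wrapper_tsv = NULL,
                      locus_id = NULL, reference = NULL, flank_len = 1000L,
                      ...) {
  if (!is.null(wrapper_tsv)) {
    if (is.null(reference))
      stop("the wrapper path needs a reference for flank sequence", call. = FALSE)
    w <- parse_wrapper_tsv(wrapper_tsv, reference, flank_len, locus_id)
    locus <- w$locus; genotypes <- w$genotypes
  } else {
    if (is.null(catalog) || is.null(vcf))
      stop("need either a wrapper TSV or a catalog + VCF", call. = FALSE)
    loci <- parse_locus_catalog(catalog, reference, flank_len)
    ids <- vapply(loci, function(l) l$locus_id, character(1))
    if (is.null(locus_id)) locus_id <- ids[1]
    if (!locus_id %in% ids)
      stop(sprintf("locus '%s' not in catalog; available: %s", locus_id,
                   paste(ids, collapse = ", ")), call. = FALSE)
    locus <- loci[[match(locus_id, ids)]]
    genotypes <- parse_genotypes_vcf(vcf, locus)
  }
  reads <- load_reads(bam, locus)
  generate_pileup(locus, genotypes, reads, ...)
}
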
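#' Simulation configuration
#'
#' Parameters for the paired-end read simulator.  Defaults emulate a
#' PCR-free short-read library: 150 bp reads, fragment lengths
#' Normal(450, 100) bp, 30-fold per-haplotype coverage, 0.2% uniform base
#' substitution error.
#'
#' @param truth a `HaplotypePair` giving the two source haplotypes (build
#'   with interruption structures via [build_haplotype()] to simulate
#'   interrupted alleles).
#' @param coverage per-haplotype fold coverage.
#' @param read_len read length in bp.
#' @param frag_mean,frag_sd fragment-length distribution (bp).
#' @param base_error per-base substitution probability in `[0, 0.1)`.
#' @param seed RNG seed.
#' @return object of class `SimConfig`.
#' @export
sim_config <- function(truth, coverage = 30, read_len = 150, frag_mean = 450,
                       frag_sd = 100, base_error = 0.002, seed = 42L) {
  if (base_error < 0 || base_error >= 0.1)
    stop("base_error must be in [0, 0.1)", call. = FALSE)
  if (read_len >= frag_mean)
    stop("read_len must be below frag_mean", call. = FALSE)
  if (coverage <= 0) stop("coverage must be positive", call. = FALSE)
  for (hap in pair_haps(truth))
    if (nchar(hap$sequence) < frag_mean + 4 * frag_sd)
      stop(sprintf(paste("haplotype (%d bp) shorter than frag_mean + 4*frag_sd",
                         "(%g bp); use longer flanks"),
                   nchar(hap$sequence), frag_mean + 4 * frag_sd), call. = FALSE)
  structure(list(truth = truth, coverage = coverage,
                 read_len = as.integer(read_len), frag_mean = frag_mean,
                 frag_sd = frag_sd, base_error = base_error,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

apply_base_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  lens <- nchar(seqs)
  hits <- runif(sum(lens)) < rate
  if (!any(hits)) return(seqs)
  offsets <- cumsum(c(0, lens[-length(lens)]))
  idx <- which(hits)
  read_of <- findInterval(idx - 1, offsets)
  pos_in <- idx - offsets[read_of]
  for (k in seq_along(idx)) {
    r <- read_of[k]; p <- pos_in[k]
    cur <- substr(seqs[r], p, p)
    alt <- setdiff(bases, cur)
    substr(seqs[r], p, p) <- alt[sample.int(length(alt), 1)]
  }
  seqs
}

# graph path of a perfect read [start, start+len) on a haplotype
graph_path_for <- function(hap, start, len) {
  sm <- hap$segment_map
  path <- list()
  pos <- start; remaining <- len
  while (remaining > 0) {
    r <- findInterval(pos, sm$start)
    while (sm$end[r] <= pos && r < nrow(sm)) r <- r + 1  # skip empty segments
    take <- min(sm$end[r] - pos, remaining)
    el <- list(seg = sm$segment[r], off = pos - sm$start[r], len = take)
    path[[length(path) + 1]] <- el
    pos <- pos + take; remaining <- remaining - take
  }
  encode_graph_tag(path)
}

#' Simulate paired-end reads from a known haplotype pair
#'
#' Fragments are drawn uniformly along each haplotype with lengths
#' Normal(frag_mean, frag_sd) truncated below at `read_len`; the two mates
#' are the fragment's ends, one per strand (which mate is forward is random
#' per fragment, as in real libraries).  Bases are stored in reference
#' orientation; substitution errors are applied at `base_error`.  Each read
#' carries a graph-alignment tag describing its true path through the
#' locus segments, so both the projection path and the de-novo realignment
#' path can be exercised.  Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `reads` (list of [read_record()]) and `truth`
#'   (data.frame: fragment_id, hap, start, frag_len, mate1_forward).
#' @export
simulate_read_pairs <- function(cfg) {
  truth_haps <- pair_haps(cfg$truth)
  rl <- cfg$read_len
  hap_v <- integer(0); start_v <- integer(0); flen_v <- integer(0)
  m1fwd_v <- logical(0)
  with_seed(cfg$seed, {
    for (h in seq_along(truth_haps)) {
      L <- nchar(truth_haps[[h]]$sequence)
      n_frag <- max(1L, round(cfg$coverage * L / (2 * rl)))
      flens <- pmin(pmax(round(rnorm(n_frag, cfg$frag_mean, cfg$frag_sd)), rl), L)
      starts <- floor(runif(n_frag) * (L - flens + 1))
      hap_v <- c(hap_v, rep(h, n_frag))
      start_v <- c(start_v, as.integer(starts))
      flen_v <- c(flen_v, as.integer(flens))
      m1fwd_v <- c(m1fwd_v, runif(n_frag) < 0.5)
    }
    n <- length(hap_v)
    fid_v <- sprintf("frag%06d", seq_len(n))
    hseq <- vapply(truth_haps, function(h) h$sequence, character(1))[hap_v]
    left_start <- start_v
    right_start <- start_v + flen_v - rl
    left <- substring(hseq, left_start + 1, left_start + rl)
    right <- substring(hseq, right_start + 1, right_start + rl)
    seqs <- apply_base_errors(c(left, right), cfg$base_error)
    left <- seqs[seq_len(n)]; right <- seqs[n + seq_len(n)]

    reads <- vector("list", 2L * n)
    for (i in seq_len(n)) {
      hap <- truth_haps[[hap_v[i]]]
      # mate 1 is the forward-strand (left) read half the time
      if (m1fwd_v[i]) {
        m1 <- list(bases = left[i], strand = "+", start = left_start[i])
        m2 <- list(bases = right[i], strand = "-", start = right_start[i])
      } else {
        m1 <- list(bases = right[i], strand = "-", start = right_start[i])
        m2 <- list(bases = left[i], strand = "+", start = left_start[i])
      }
      for (m in 1:2) {
        r <- if (m == 1) m1 else m2
        reads[[2L * (i - 1L) + m]] <- read_record(
          fid_v[i], m, r$bases, strand = r$strand,
          graph_alignment = graph_path_for(hap, r$start, rl),
          linear_alignment = list(contig = "sim", pos = r$start,
                                  cigar = sprintf("%dM", rl)))
      }
    }
    truth <- data.frame(fragment_id = fid_v, hap = hap_v, start = start_v,
                        frag_len = flen_v, mate1_forward = m1fwd_v,
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth, truth_pair = cfg$truth)
  })
}

sam_flag <- function(mate, strand, mate_strand) {
  f <- 1L + 2L + if (mate == 1L) 64L else 128L
  if (strand == "-") f <- f + 16L
  if (mate_strand == "-") f <- f + 32L
  f
}

#' Write a complete simulated fixture to disk
#'
#' Emits everything the pipeline consumes: an indexed BAM of the reads
#' (placed on a synthetic contig, with graph-alignment `XG` tags), an
#' ExpansionHunter-style VCF of the genotypes, a catalog JSON with inline
#' flanks, the 5-column wrapper TSV, and a truth TSV.
#'
#' @param sim output of [simulate_read_pairs()].
#' @param locus the `LocusSpec` the haplotypes were built from.
#' @param genotypes named list of [repeat_genotype()].
#' @param out_dir output directory (created if needed).
#' @param contig synthetic contig name recorded in the BAM; defaults to the
#'   locus's reference contig so that [load_reads()] can fetch by the
#'   catalog coordinates.
#' @return named character vector of the five file paths.
#' @export
write_fixture <- function(sim, locus, genotypes, out_dir,
                          contig = locus_region(locus)$contig) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (file.access(out_dir, 2) != 0)
    stop("output directory not writable: ", out_dir, call. = FALSE)
  reg <- locus_region(locus)
  # map haplotype coordinates into the reference frame: hap position 0
  # corresponds to reference (locus start - left flank length), and repeat
  # intervals are squeezed/stretched onto their reference intervals the way
  # a linear aligner would place reads around a non-reference allele length
  origin <- reg$start - nchar(left_flank(locus))
  contig_len <- reg$end + nchar(right_flank(locus)) + 10000L
  strs <- locus_strs(locus)
  hap_to_ref <- function(hap, pos) {
    sm <- hap$segment_map
    r <- findInterval(pos, sm$start)
    r <- max(1L, min(r, nrow(sm)))
    if (sm$type[r] == "constant") {
      # reference offset of this constant segment = its hap start shifted
      # by the preceding repeats' reference lengths
      shift <- 0L
      for (s in strs) {
        ri <- sm[sm$type == "str" & sm$str_id == s$str_id, ]
        if (ri$start < sm$start[r])
          shift <- shift + (ri$end - ri$start) - (s$end - s$start)
      }
      pos - shift
    } else {
      s <- strs[[which(vapply(strs, function(x)
        identical(x$str_id, sm$str_id[r]), logical(1)))]]
      ref_len <- s$end - s$start
      (s$start - origin) + min(pos - sm$start[r], max(ref_len - 1L, 0L))
    }
  }

  sam <- file.path(out_dir, "reads.sam")
  con <- file(sam, "w")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len)), con)
  reads <- sim$reads
  if (length(reads) > 0) {
    truth <- sim$truth
    if (is.null(sim$truth_pair))
      stop("fixture writing needs the simulation's truth pair", call. = FALSE)
    haps <- pair_haps(sim$truth_pair)
    meta <- do.call(rbind, lapply(reads, function(r) {
      h <- truth$hap[match(r$fragment_id, truth$fragment_id)]
      data.frame(fid = r$fragment_id, mate = r$mate_index,
                 pos = hap_to_ref(haps[[h]], r$linear_alignment$pos),
                 stringsAsFactors = FALSE)
    }))
    ord <- order(meta$pos, meta$fid, meta$mate)
    for (i in ord) {
      r <- reads[[i]]
      j <- which(meta$fid == meta$fid[i] & meta$mate != meta$mate[i])[1]
      mate_rec <- reads[[j]]
      flag <- sam_flag(r$mate_index, r$strand, mate_rec$strand)
      tlen_row <- truth[truth$fragment_id == r$fragment_id, ]
      tlen <- tlen_row$frag_len * (if (meta$pos[i] <= meta$pos[j]) 1 else -1)
      writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*\tXG:Z:%s",
                         r$fragment_id, flag, contig,
                         meta$pos[i] + origin + 1L,
                         r$linear_alignment$cigar,
                         meta$pos[j] + origin + 1L,
                         tlen, r$bases, r$graph_alignment), con)
    }
  }
  close(con)
  bam <- suppressMessages(
    Rsamtools::asBam(sam, file.path(out_dir, "reads"), overwrite = TRUE,
                     indexDestination = TRUE))

  strs <- locus_strs(locus)
  vcf <- file.path(out_dir, "genotypes.vcf")
  vcf_lines <- c("##fileformat=VCFv4.2",
                 "##INFO=<ID=REPID,Number=1,Type=String,Description=\"Repeat id\">",
                 "##INFO=<ID=RU,Number=1,Type=String,Description=\"Repeat unit\">",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 "##FORMAT=<ID=REPCN,Number=1,Type=String,Description=\"Repeat counts\">",
                 sprintf("##contig=<ID=%s,length=%d>", contig, contig_len),
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE")
  for (s in strs) {
    g <- genotypes[[s$str_id]]
    cn <- paste(g$allele_sizes, collapse = "/")
    gt <- if (length(g$allele_sizes) == 2) "1/2" else "1"
    vcf_lines <- c(vcf_lines, sprintf(
      "%s\t%d\t%s\tN\t<STR>\t.\tPASS\tREPID=%s;RU=%s\tGT:REPCN\t%s:%s",
      s$contig, s$start + 1L, s$str_id, s$str_id, s$repeat_unit, gt, cn))
  }
  writeLines(vcf_lines, vcf)

  catalog <- file.path(out_dir, "catalog.json")
  writeLines(write_locus_catalog(locus), catalog)

  tsv <- file.path(out_dir, "wrapper.tsv")
  writeLines(vapply(strs, function(s) {
    g <- genotypes[[s$str_id]]
    sprintf("%s\t%d\t%d\t%s\t%s", s$contig, s$start, s$end, s$repeat_unit,
            paste(g$allele_sizes, collapse = "/"))
  }, character(1)), tsv)

  truth_path <- file.path(out_dir, "truth.tsv")
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)

  c(bam = bam, vcf = vcf, catalog = catalog, wrapper = tsv, truth = truth_path)
}
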
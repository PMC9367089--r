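#' Build one concrete haplotype sequence from allele sizes
#'
#' Realises a haplotype from a locus template and one allele size per STR:
#' left flank + alternating constant segments and repeat expansions + right
#' flank.  Each STR expands to `repeat_unit` x count unless an
#' [allele_structure()] override (carrying interruptions) is supplied; an
#' override must total exactly the stated unit count.
#'
#' @param locus a `LocusSpec`.
#' @param counts integer vector of per-STR allele sizes, named by `str_id`
#'   or in locus STR order.
#' @param structures optional named list (`str_id` -> `AlleleStructure`)
#'   of per-STR structure overrides.
#' @return object of class `Haplotype` with fields `sequence`,
#'   `str_counts`, `segment_map` (0-based half-open intervals tiling the
#'   sequence) and `structures`.
#' @export
build_haplotype <- function(locus, counts, structures = NULL) {
  strs <- locus_strs(locus)
  ids <- vapply(strs, function(s) s$str_id, character(1))
  if (is.null(names(counts))) {
    if (length(counts) != length(ids))
      stop("counts must cover every STR of the locus", call. = FALSE)
    names(counts) <- ids
  }
  if (!all(ids %in% names(counts)))
    stop("counts must cover every STR of the locus", call. = FALSE)
  counts <- as.integer(counts[ids])
  names(counts) <- ids
  if (anyNA(counts) || any(counts < 0))
    stop("allele sizes must be non-negative integers", call. = FALSE)

  pieces <- character(0)
  seg_rows <- list()
  pos <- 0L
  for (k in seq_along(locus$segments)) {
    seg <- locus$segments[[k]]
    if (is_str_segment(seg)) {
      cnt <- counts[[seg$str_id]]
      st <- structures[[seg$str_id]]
      if (!is.null(st)) {
        if (count_repeat_units(st) != cnt)
          stop(sprintf("structure for STR '%s' totals %d units but count is %d",
                       seg$str_id, count_repeat_units(st), cnt), call. = FALSE)
        seq_k <- expand_structure(st)
      } else {
        seq_k <- strrep(seg$repeat_unit, cnt)
      }
      type <- "str"; sid <- seg$str_id
    } else {
      seq_k <- seg$sequence
      type <- "constant"; sid <- NA_character_
    }
    len <- nchar(seq_k)
    seg_rows[[k]] <- data.frame(segment = k - 1L, type = type, str_id = sid,
                                start = pos, end = pos + len,
                                stringsAsFactors = FALSE)
    pieces <- c(pieces, seq_k)
    pos <- pos + len
  }
  structure(list(sequence = paste0(pieces, collapse = ""),
                 str_counts = counts,
                 segment_map = do.call(rbind, seg_rows),
                 structures = structures),
            class = "Haplotype")
}

#' @export
print.Haplotype <- function(x, ...) {
  cat(sprintf("<Haplotype %d bp; %s>\n", nchar(x$sequence),
              paste(sprintf("%s=%d", names(x$str_counts), x$str_counts),
                    collapse = ", ")))
  invisible(x)
}

# 0-based half-open repeat interval of one STR on a haplotype
repeat_interval <- function(hap, str_id) {
  row <- hap$segment_map[hap$segment_map$type == "str" &
                           hap$segment_map$str_id == str_id, , drop = FALSE]
  if (nrow(row) != 1) stop(sprintf("unknown STR '%s' on haplotype", str_id), call. = FALSE)
  c(start = row$start, end = row$end)
}

new_haplotype_pair <- function(hap1, hap2, phase_id) {
  # canonical unordered pair: hap1 is the lexicographically smaller sequence
  if (!is.null(hap2) && hap2$sequence < hap1$sequence) {
    tmp <- hap1; hap1 <- hap2; hap2 <- tmp
  }
  structure(list(hap1 = hap1, hap2 = hap2, cumulative_score = NA_integer_,
                 phase_id = phase_id),
            class = "HaplotypePair")
}

#' @export
print.HaplotypePair <- function(x, ...) {
  cat(sprintf("<HaplotypePair %s%s>\n", x$phase_id,
              if (is.na(x$cumulative_score)) "" else
                sprintf(", score %d", x$cumulative_score)))
  invisible(x)
}

pair_haps <- function(pair) {
  if (is.null(pair$hap2)) list(pair$hap1) else list(pair$hap1, pair$hap2)
}

#' Enumerate candidate diploid haplotype pairs
#'
#' From per-STR repeat genotypes, constructs every distinct unordered pair
#' of haplotype sequences consistent with all genotypes.  With k
#' heterozygous STRs there are 2^(k-1) pairings for k >= 1 (a region with
#' two heterozygous STRs yields four possible haplotypes and two possible
#' pairings), and a single pairing when every STR is homozygous.  Haploid
#' loci yield one single-haplotype "pair" with `hap2 = NULL`.
#'
#' @param locus a `LocusSpec`.
#' @param genotypes named list of [repeat_genotype()], one per STR.
#' @param max_pairings cap on the number of pairings (default 64); exceeding
#'   it is an error advising a locus split.
#' @return list of `HaplotypePair` objects, deterministically ordered.
#' @export
enumerate_haplotype_pairs <- function(locus, genotypes, max_pairings = 64L) {
  strs <- locus_strs(locus)
  ids <- vapply(strs, function(s) s$str_id, character(1))
  missing <- setdiff(ids, names(genotypes))
  if (length(missing))
    stop("missing genotype for STR(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ploidy <- vapply(ids, function(i) length(genotypes[[i]]$allele_sizes), integer(1))
  if (length(unique(ploidy)) != 1)
    stop("ploidy must be uniform across STRs at a locus", call. = FALSE)

  if (ploidy[1] == 1L) {
    counts <- vapply(ids, function(i) genotypes[[i]]$allele_sizes[1], integer(1))
    hap <- build_haplotype(locus, counts)
    return(list(new_haplotype_pair(hap, NULL,
                                   paste(sprintf("%s:%d", ids, counts), collapse = ";"))))
  }

  het <- vapply(ids, function(i) {
    a <- genotypes[[i]]$allele_sizes; a[1] != a[2]
  }, logical(1))
  k <- sum(het)
  n_pairings <- if (k >= 1) 2^(k - 1) else 1
  if (n_pairings > max_pairings)
    stop(sprintf(paste("locus has %d heterozygous STRs (%d pairings, cap %d);",
                       "consider splitting the locus"),
                 k, n_pairings, max_pairings), call. = FALSE)

  # ordered assignments: for each STR choose which allele goes to hap1
  choice_list <- lapply(ids, function(i) if (het[[i]]) c(1L, 2L) else 1L)
  names(choice_list) <- ids
  grid <- expand.grid(choice_list, KEEP.OUT.ATTRS = FALSE)
  hap_cache <- new.env(parent = emptyenv())
  get_hap <- function(counts) {
    key <- paste(counts, collapse = ",")
    if (is.null(hap_cache[[key]])) hap_cache[[key]] <- build_haplotype(locus, counts)
    hap_cache[[key]]
  }
  pairs <- list(); seen <- character(0)
  for (r in seq_len(nrow(grid))) {
    c1 <- vapply(ids, function(i) genotypes[[i]]$allele_sizes[grid[r, i]], integer(1))
    c2 <- vapply(ids, function(i) genotypes[[i]]$allele_sizes[3L - grid[r, i]], integer(1))
    # the two orderings of an all-homozygous STR coincide; 3 - 1 = 2 only
    # matters for het STRs, and hom STRs have grid column fixed at 1 -> use
    # the same allele for both haplotypes.
    c2[!het] <- c1[!het]
    h1 <- get_hap(c1); h2 <- get_hap(c2)
    key <- paste(sort(c(h1$sequence, h2$sequence)), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    phase <- paste(sprintf("%s:%d|%d", ids, c1, c2), collapse = ";")
    pairs[[length(pairs) + 1]] <- new_haplotype_pair(h1, h2, phase)
  }
  pairs
}
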
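#' Build a reference sequence lookup
#'
#' Normalises the different ways flank/spacer sequence can be supplied into
#' a single accessor `function(contig, start, end)` over 0-based half-open
#' coordinates.
#'
#' @param x a function `(contig, start, end) -> DNA text`, a named character
#'   vector of full contig sequences, or a path to a FASTA file.
#' @return a lookup function.
#' @export
as_reference_lookup <- function(x) {
  if (is.function(x)) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    seqs <- Biostrings::readDNAStringSet(x)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    x <- setNames(as.character(seqs), names(seqs))
  }
  if (is.character(x) && !is.null(names(x))) {
    contigs <- x
    return(function(contig, start, end) {
      if (!contig %in% names(contigs))
        stop(sprintf("contig '%s' not in reference", contig), call. = FALSE)
      full <- contigs[[contig]]
      if (start < 0 || end > nchar(full))
        stop(sprintf("region %s:%d-%d outside contig (len %d)",
                     contig, start, end, nchar(full)), call. = FALSE)
      substr(full, start + 1, end)
    })
  }
  stop("reference_lookup must be a function, named character vector or FASTA path",
       call. = FALSE)
}

parse_region <- function(txt) {
  m <- regmatches(txt, regexec("^([^:]+):([0-9]+)-([0-9]+)$", txt))[[1]]
  if (length(m) != 4) stop(sprintf("malformed reference region '%s'", txt), call. = FALSE)
  list(contig = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Parse a locus catalog (JSON)
#'
#' The catalog follows ExpansionHunter variant-catalog conventions: a JSON
#' array of locus entries, each with a `LocusId` and a list of `Strs`
#' (`StrId`, `RepeatUnit`, `ReferenceRegion` as `"contig:start-end"`,
#' 0-based half-open).  Flanking and inter-repeat sequence comes either
#' inline (`LeftFlank`, `RightFlank`, `Spacers`) or from `reference_lookup`.
#'
#' @param catalog_text JSON text (or a file path to it).
#' @param reference_lookup optional sequence provider (see
#'   [as_reference_lookup()]); required when flanks are not inline.
#' @param flank_len flank length in bp extracted from the reference when
#'   flanks are not inline (default 1000).
#' @return list of [locus_spec()] objects.
#' @export
parse_locus_catalog <- function(catalog_text, reference_lookup = NULL,
                                flank_len = 1000L) {
  if (length(catalog_text) == 1 && !grepl("[\\[{]", catalog_text) &&
      file.exists(catalog_text))
    catalog_text <- paste(readLines(catalog_text, warn = FALSE), collapse = "\n")
  entries <- tryCatch(
    jsonlite::fromJSON(catalog_text, simplifyVector = FALSE),
    error = function(e) stop("malformed catalog JSON: ", conditionMessage(e),
                             call. = FALSE))
  if (!is.null(names(entries))) entries <- list(entries)  # single object
  if (!is.null(reference_lookup)) reference_lookup <- as_reference_lookup(reference_lookup)

  lapply(entries, function(entry) {
    lid <- entry$LocusId
    if (is.null(lid)) stop("catalog entry missing LocusId", call. = FALSE)
    strs_raw <- entry$Strs
    if (is.null(strs_raw) || length(strs_raw) == 0)
      stop(sprintf("catalog entry '%s' has no Strs", lid), call. = FALSE)
    strs <- lapply(strs_raw, function(s) {
      if (is.null(s$RepeatUnit) || is.null(s$ReferenceRegion))
        stop(sprintf("catalog entry '%s': every STR needs a RepeatUnit and ReferenceRegion", lid),
             call. = FALSE)
      reg <- parse_region(s$ReferenceRegion)
      str_spec(if (is.null(s$StrId)) lid else s$StrId, s$RepeatUnit,
               reg$contig, reg$start, reg$end)
    })
    ord <- order(vapply(strs, function(s) s$start, integer(1)))
    strs <- strs[ord]
    for (k in seq_along(strs)[-1])
      if (strs[[k]]$start < strs[[k - 1]]$end)
        stop(sprintf("catalog entry '%s': STR intervals overlap (%s, %s)",
                     lid, strs[[k - 1]]$str_id, strs[[k]]$str_id), call. = FALSE)

    n <- length(strs)
    if (!is.null(entry$LeftFlank) && !is.null(entry$RightFlank)) {
      lf <- entry$LeftFlank; rf <- entry$RightFlank
      spacers <- vapply(entry$Spacers %||% list(), as.character, character(1))
      if (length(spacers) != n - 1)
        stop(sprintf("catalog entry '%s': expected %d spacer(s), got %d",
                     lid, n - 1, length(spacers)), call. = FALSE)
    } else if (!is.null(reference_lookup)) {
      contig <- strs[[1]]$contig
      lf <- reference_lookup(contig, max(0L, strs[[1]]$start - flank_len),
                             strs[[1]]$start)
      rf <- reference_lookup(contig, strs[[n]]$end, strs[[n]]$end + flank_len)
      spacers <- if (n > 1)
        vapply(seq_len(n - 1), function(k)
          reference_lookup(contig, strs[[k]]$end, strs[[k + 1]]$start),
          character(1))
      else character(0)
    } else {
      stop(sprintf("catalog entry '%s': no inline flanks and no reference_lookup", lid),
           call. = FALSE)
    }

    segments <- list(constant_segment(lf))
    for (k in seq_len(n)) {
      segments <- c(segments, list(strs[[k]]))
      if (k < n) segments <- c(segments, list(constant_segment(spacers[k])))
    }
    segments <- c(segments, list(constant_segment(rf)))
    locus_spec(lid, segments)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise loci back to catalog JSON
#'
#' Inverse of [parse_locus_catalog()] (with inline flanks); parsing the
#' output yields an identical `LocusSpec`.
#'
#' @param loci list of `LocusSpec` objects (or a single one).
#' @return JSON text.
#' @export
write_locus_catalog <- function(loci) {
  if (inherits(loci, "LocusSpec")) loci <- list(loci)
  entries <- lapply(loci, function(locus) {
    strs <- locus_strs(locus)
    consts <- Filter(Negate(is_str_segment), locus$segments)
    spacers <- if (length(consts) > 2)
      lapply(consts[2:(length(consts) - 1)], function(s) s$sequence)
    else list()
    list(LocusId = locus$locus_id,
         Strs = lapply(strs, function(s)
           list(StrId = s$str_id, RepeatUnit = s$repeat_unit,
                ReferenceRegion = sprintf("%s:%d-%d", s$contig, s$start, s$end))),
         LeftFlank = left_flank(locus), RightFlank = right_flank(locus),
         Spacers = spacers)
  })
  jsonlite::toJSON(entries, auto_unbox = TRUE, pretty = TRUE)
}

parse_genotype_token <- function(txt, str_id) {
  parts <- strsplit(trimws(txt), "/", fixed = TRUE)[[1]]
  sizes <- suppressWarnings(as.integer(parts))
  if (length(sizes) < 1 || length(sizes) > 2 || anyNA(sizes))
    stop(sprintf("STR '%s': cannot parse genotype '%s' (expected e.g. 30/46)",
                 str_id, txt), call. = FALSE)
  sizes
}

#' Parse repeat genotypes from an ExpansionHunter-style VCF
#'
#' Pulls per-STR repeat-count genotypes (`REPCN`, e.g. `"30/46"`) and
#' optional per-allele confidence intervals (`REPCI`, e.g. `"28-32/44-48"`)
#' from VCF records.  Records are matched to the locus's STRs by the
#' `REPID`/`VARID` INFO field when present, otherwise by position.
#'
#' @param vcf_text VCF text or a path to a VCF file.
#' @param locus a `LocusSpec`; every STR of the locus must have a record.
#' @return named list of [repeat_genotype()], one per STR.
#' @export
parse_genotypes_vcf <- function(vcf_text, locus) {
  path <- vcf_text
  if (length(vcf_text) == 1 && grepl("\n", vcf_text)) {
    path <- tempfile(fileext = ".vcf")
    writeLines(strsplit(vcf_text, "\n")[[1]], path)
    on.exit(unlink(path))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2)
    stop("VCF has no sample column", call. = FALSE)
  fmt <- strsplit(gt[, 1], ":", fixed = TRUE)
  smp <- strsplit(gt[, 2], ":", fixed = TRUE)
  get_field <- function(i, key) {
    k <- match(key, fmt[[i]])
    if (is.na(k) || k > length(smp[[i]])) NA_character_ else smp[[i]][k]
  }
  repid <- sub(".*(?:REPID|VARID)=([^;]+).*", "\\1", fix$INFO)
  repid[!grepl("REPID=|VARID=", fix$INFO)] <- NA

  out <- list()
  for (s in locus_strs(locus)) {
    i <- which(!is.na(repid) & repid == s$str_id)
    if (length(i) == 0)
      i <- which(fix$CHROM == s$contig & as.integer(fix$POS) == s$start + 1L)
    if (length(i) == 0)
      stop(sprintf("no VCF record for STR '%s'", s$str_id), call. = FALSE)
    i <- i[1]
    cn <- get_field(i, "REPCN")
    if (is.na(cn))
      stop(sprintf("record for STR '%s' lacks a REPCN field", s$str_id), call. = FALSE)
    sizes <- parse_genotype_token(cn, s$str_id)
    cis <- NULL
    ci_txt <- get_field(i, "REPCI")
    if (!is.na(ci_txt) && ci_txt != ".") {
      ci_parts <- strsplit(ci_txt, "/", fixed = TRUE)[[1]]
      if (length(ci_parts) == length(sizes)) {
        cis <- lapply(ci_parts, function(p) {
          lohi <- suppressWarnings(as.integer(strsplit(p, "-", fixed = TRUE)[[1]]))
          if (length(lohi) == 2 && !anyNA(lohi)) lohi else NULL
        })
      }
    }
    out[[s$str_id]] <- repeat_genotype(s$str_id, sizes, cis)
  }
  out
}

#' Parse the tab-separated wrapper input
#'
#' The wrapper path accepts a plain linear-reference BAM plus a 5-column TSV
#' giving, for each STR of one locus: contig, 0-based start, end, repeat
#' unit and genotype (`"30/46"` or haploid `"30"`).  A header line and `#`
#' comments are ignored.
#'
#' @param tsv_text TSV text or a path.
#' @param reference_lookup optional sequence provider; when given, a full
#'   `LocusSpec` (with flanks from the reference) is also returned.
#' @param flank_len flank length for reference extraction (default 1000).
#' @param locus_id label for the assembled locus; default derived from the
#'   first row's coordinates.
#' @return list with `strs` (list of `StrSpec`), `genotypes` (named list of
#'   `RepeatGenotype`) and `locus` (a `LocusSpec`, or `NULL` without a
#'   reference).
#' @export
parse_wrapper_tsv <- function(tsv_text, reference_lookup = NULL,
                              flank_len = 1000L, locus_id = NULL) {
  lines <- if (length(tsv_text) == 1 && grepl("\n|\t", tsv_text))
    strsplit(tsv_text, "\n")[[1]] else readLines(tsv_text, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) && grepl("^(contig|chrom|chr)\\b", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  if (length(lines) == 0) stop("wrapper TSV has no data rows", call. = FALSE)

  strs <- list(); genos <- list()
  for (r in seq_along(lines)) {
    f <- strsplit(lines[r], "\t", fixed = TRUE)[[1]]
    if (length(f) == 1) f <- strsplit(trimws(lines[r]), "\\s+")[[1]]
    if (length(f) != 5)
      stop(sprintf("wrapper TSV row %d: expected 5 columns, got %d", r, length(f)),
           call. = FALSE)
    start <- suppressWarnings(as.integer(f[2])); end <- suppressWarnings(as.integer(f[3]))
    if (anyNA(c(start, end)))
      stop(sprintf("wrapper TSV row %d: non-integer coordinates", r), call. = FALSE)
    sid <- sprintf("%s_%d", f[1], start)
    s <- tryCatch(str_spec(sid, f[4], f[1], start, end),
                  error = function(e)
                    stop(sprintf("wrapper TSV row %d: %s", r, conditionMessage(e)),
                         call. = FALSE))
    strs[[length(strs) + 1]] <- s
    genos[[sid]] <- repeat_genotype(sid, parse_genotype_token(f[5], sid))
  }
  ord <- order(vapply(strs, function(s) s$start, integer(1)))
  strs <- strs[ord]
  ploidy <- vapply(genos, function(g) length(g$allele_sizes), integer(1))
  if (length(unique(ploidy)) > 1)
    stop("wrapper TSV mixes haploid and diploid genotypes at one locus", call. = FALSE)

  locus <- NULL
  if (!is.null(reference_lookup)) {
    if (is.null(locus_id))
      locus_id <- sprintf("%s_%d", strs[[1]]$contig, strs[[1]]$start)
    entry <- list(LocusId = locus_id,
                  Strs = lapply(strs, function(s)
                    list(StrId = s$str_id, RepeatUnit = s$repeat_unit,
                         ReferenceRegion = sprintf("%s:%d-%d", s$contig, s$start, s$end))))
    locus <- parse_locus_catalog(jsonlite::toJSON(list(entry), auto_unbox = TRUE),
                                 reference_lookup, flank_len)[[1]]
  }
  list(strs = strs, genotypes = genos, locus = locus)
}

#' Load reads overlapping a locus from an indexed BAM
#'
#' Fetches read pairs overlapping the locus's reference span plus a margin,
#' joins mates by read name, and decodes the graph-alignment tag (`XG`)
#' when present.  Orphan mates are kept but counted (attribute `orphans`)
#' and are excluded from pairing and fragment-length statistics downstream.
#'
#' @param bam_path path to an indexed BAM.
#' @param locus a `LocusSpec`.
#' @param fetch_margin bp added on each side of the locus span (default:
#'   left flank length).
#' @return list of [read_record()]s, with attributes `orphans` (count) and
#'   `n_fragments`.
#' @export
load_reads <- function(bam_path, locus, fetch_margin = NULL) {
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path, call. = FALSE)
  if (is.null(fetch_margin)) fetch_margin <- nchar(left_flank(locus))
  reg <- locus_region(locus)
  which <- GenomicRanges::GRanges(reg$contig,
                                  IRanges::IRanges(max(1L, reg$start + 1L - fetch_margin),
                                                   reg$end + fetch_margin))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "seq", "qual"),
    tag = "XG", which = which)
  res <- tryCatch(Rsamtools::scanBam(bam_path, param = param)[[1]],
                  error = function(e) stop("cannot read BAM: ", conditionMessage(e),
                                           call. = FALSE))
  n <- length(res$qname)
  recs <- vector("list", n)
  xg <- res$tag$XG
  if (is.null(xg)) xg <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    flag <- res$flag[i]
    mate <- if (bitwAnd(flag, 64L) > 0) 1L else 2L
    lin <- if (!is.na(res$pos[i]))
      list(contig = as.character(res$rname[i]), pos = res$pos[i] - 1L,
           cigar = res$cigar[i])
    else NULL
    recs[[i]] <- read_record(res$qname[i], mate, as.character(res$seq[i]),
                             strand = if (bitwAnd(flag, 16L) > 0) "-" else "+",
                             quals = as.character(res$qual[i]),
                             graph_alignment = if (!is.na(xg[i])) xg[i] else NULL,
                             linear_alignment = lin)
  }
  tab <- table(vapply(recs, function(r) r$fragment_id, character(1)))
  orphans <- sum(tab != 2)
  if (orphans > 0)
    warning(sprintf("%d fragment(s) with unpaired mates; excluded from pairing stages",
                    orphans), call. = FALSE)
  ord <- order(vapply(recs, function(r) r$fragment_id, character(1)),
               vapply(recs, function(r) r$mate_index, integer(1)))
  recs <- recs[ord]
  attr(recs, "orphans") <- orphans
  attr(recs, "n_fragments") <- length(tab)
  recs
}
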
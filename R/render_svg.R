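#' Rendering options for pileup SVGs
#'
#' @param px_per_bp horizontal scale (default 2 px/bp).
#' @param lane_height_px lane height (default 10 px).
#' @param colors named list of fill colours: `flank`, `repeat_palette`
#'   (recycled per STR index), `read`, `mismatch` (named A/C/G/T/N) and
#'   `indel`.
#' @param faint_opacity opacity for ambiguously assigned reads, in (0, 1).
#' @param show_allele_labels draw per-STR allele-length labels
#'   (e.g. "30 x CGG")?
#' @param max_width_px repeats longer than this at `px_per_bp` are drawn
#'   compressed (piecewise-linear x-map) and annotated with the scale.
#' @return object of class `RenderOptions`.
#' @export
render_options <- function(px_per_bp = 2, lane_height_px = 10,
                           colors = NULL, faint_opacity = 0.4,
                           show_allele_labels = TRUE, max_width_px = 1600) {
  if (px_per_bp <= 0) stop("px_per_bp must be positive", call. = FALSE)
  if (faint_opacity <= 0 || faint_opacity >= 1)
    stop("faint_opacity must be in (0, 1)", call. = FALSE)
  defaults <- list(flank = "#b8b8b8",
                   repeat_palette = c("#4a7fb5", "#7fb54a", "#b54a7f"),
                   read = "#d9e4f0",
                   mismatch = c(A = "#2ca02c", C = "#1f77b4", G = "#ff7f0e",
                                T = "#d62728", N = "#7f7f7f"),
                   indel = "#555555")
  if (!is.null(colors)) defaults[names(colors)] <- colors
  structure(list(px_per_bp = px_per_bp, lane_height_px = lane_height_px,
                 colors = defaults, faint_opacity = faint_opacity,
                 show_allele_labels = show_allele_labels,
                 max_width_px = max_width_px),
            class = "RenderOptions")
}

# piecewise-linear bp -> px map compressing long repeat intervals
make_xmap <- function(hap, opts) {
  sm <- hap$segment_map
  scale <- rep(opts$px_per_bp, nrow(sm))
  for (r in which(sm$type == "str")) {
    w <- (sm$end[r] - sm$start[r]) * opts$px_per_bp
    if (w > opts$max_width_px)
      scale[r] <- opts$max_width_px / (sm$end[r] - sm$start[r])
  }
  seg_px <- (sm$end - sm$start) * scale
  px0 <- cumsum(c(0, seg_px))[seq_len(nrow(sm))]
  compressed <- any(scale < opts$px_per_bp)
  list(map = function(bp) {
    bp <- pmax(0, pmin(bp, sm$end[nrow(sm)]))
    r <- findInterval(bp, sm$start, rightmost.closed = FALSE)
    r <- pmax(1, pmin(r, nrow(sm)))
    px0[r] + (bp - sm$start[r]) * scale[r]
  }, total_px = sum(seg_px), compressed = compressed)
}

svg_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fmt_px <- function(x) formatC(x, format = "f", digits = 2, drop0trailing = TRUE)

#' Render a haplotype-resolved pileup as SVG
#'
#' Draws one track per haplotype: a flank/repeat backbone with per-STR
#' allele-length labels ("30 x CGG"), then the placed reads in their lanes.
#' Mismatched positions are drawn as small rectangles in the base's colour,
#' deletions as a thin connector line across the gap, insertions as caret
#' marks, and ambiguously assigned reads at `faint_opacity`.  Output is a
#' deterministic function of the pileup and options.
#'
#' @param pileup a `StrPileup`.
#' @param opts a [render_options()].
#' @return SVG 1.1 document text (well-formed XML).
#' @export
render_svg <- function(pileup, opts = render_options()) {
  haps <- pair_haps(pileup$pair)
  placed <- pileup$placed
  lane_h <- opts$lane_height_px
  read_h <- lane_h - 2
  pad <- 20
  label_h <- if (opts$show_allele_labels) 16 else 0
  track_h <- 12

  xmaps <- lapply(haps, make_xmap, opts = opts)
  width <- max(vapply(xmaps, function(x) x$total_px, numeric(1))) + 2 * pad

  body <- character(0)
  y <- pad
  for (h in seq_along(haps)) {
    hap <- haps[[h]]
    xm <- xmaps[[h]]
    mp <- xm$map
    sm <- hap$segment_map
    body <- c(body, sprintf('<g class="track" id="hap%d">', h))
    # allele labels
    if (opts$show_allele_labels) {
      strs <- locus_strs(pileup$locus)
      for (s in strs) {
        ri <- repeat_interval(hap, s$str_id)
        cx <- (mp(ri["start"]) + mp(ri["end"])) / 2 + pad
        lab <- sprintf("%d × %s", hap$str_counts[[s$str_id]], s$repeat_unit)
        body <- c(body, sprintf(
          '<text class="allele-label" x="%s" y="%s" font-size="11" text-anchor="middle" font-family="sans-serif">%s</text>',
          fmt_px(cx), fmt_px(y + 11), svg_esc(lab)))
      }
      y <- y + label_h
    }
    # backbone: flank segments grey, repeat intervals coloured per STR index
    for (r in seq_len(nrow(sm))) {
      if (sm$end[r] == sm$start[r]) next
      col <- if (sm$type[r] == "str") {
        pal <- opts$colors$repeat_palette
        idx <- which(sm$type == "str" & sm$start <= sm$start[r])
        pal[(length(idx) - 1) %% length(pal) + 1]
      } else opts$colors$flank
      body <- c(body, sprintf(
        '<rect class="backbone %s" x="%s" y="%s" width="%s" height="%d" fill="%s"/>',
        sm$type[r], fmt_px(mp(sm$start[r]) + pad), fmt_px(y),
        fmt_px(mp(sm$end[r]) - mp(sm$start[r])), track_h, col))
    }
    if (xm$compressed)
      body <- c(body, sprintf(
        '<text class="scale-note" x="%s" y="%s" font-size="9" font-family="sans-serif">repeat compressed to fit</text>',
        fmt_px(pad), fmt_px(y + track_h + 10)))
    y <- y + track_h + 6

    hp <- placed[vapply(placed, function(p) p$hap_index == h, logical(1))]
    if (length(hp) == 0) {
      body <- c(body, sprintf(
        '<text class="empty-banner" x="%s" y="%s" font-size="11" font-family="sans-serif">no reads placed</text>',
        fmt_px(pad), fmt_px(y + 11)))
      y <- y + lane_h
    } else {
      nlanes <- max(vapply(hp, function(p) p$lane, integer(1))) + 1
      for (p in hp) {
        ry <- y + p$lane * lane_h
        op_attr <- if (p$faint) sprintf(' opacity="%s"', fmt_px(opts$faint_opacity)) else ""
        grp <- sprintf('<g class="read %s%s"%s>', p$class,
                       if (p$faint) " faint" else "", op_attr)
        body <- c(body, grp)
        # walk ops, drawing body pieces and glyphs
        ops <- parse_cigar(p$cigar)
        ref <- p$start; rpos <- 0
        for (k in seq_len(ops$n)) {
          op <- ops$op[k]; len <- ops$len[k]
          if (op %in% c("=", "X", "M")) {
            body <- c(body, sprintf(
              '<rect class="read-body" x="%s" y="%s" width="%s" height="%d" fill="%s"/>',
              fmt_px(mp(ref) + pad), fmt_px(ry),
              fmt_px(mp(ref + len) - mp(ref)), read_h, opts$colors$read))
            if (op == "X") {
              for (o in seq_len(len)) {
                base <- substr(p$bases, rpos + o, rpos + o)
                col <- opts$colors$mismatch[[base]] %||% opts$colors$mismatch[["N"]]
                body <- c(body, sprintf(
                  '<rect class="mismatch base-%s" x="%s" y="%s" width="%s" height="%d" fill="%s"/>',
                  base, fmt_px(mp(ref + o - 1) + pad), fmt_px(ry),
                  fmt_px(max(mp(ref + o) - mp(ref + o - 1), 1)), read_h, col))
              }
            }
            ref <- ref + len; rpos <- rpos + len
          } else if (op == "D") {
            body <- c(body, sprintf(
              '<line class="deletion" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1.5"/>',
              fmt_px(mp(ref) + pad), fmt_px(ry + read_h / 2),
              fmt_px(mp(ref + len) + pad), fmt_px(ry + read_h / 2),
              opts$colors$indel))
            ref <- ref + len
          } else if (op == "I") {
            x <- mp(ref) + pad
            body <- c(body, sprintf(
              '<path class="insertion" d="M %s %s l 3 -4 l 3 4 z" fill="%s"/>',
              fmt_px(x - 3), fmt_px(ry + read_h), opts$colors$indel))
            rpos <- rpos + len
          } else if (op == "S") {
            rpos <- rpos + len
          }
        }
        body <- c(body, "</g>")
      }
      y <- y + nlanes * lane_h
    }
    body <- c(body, "</g>")
    y <- y + pad
  }

  height <- y
  paste(c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                         'width="%s" height="%s" viewBox="0 0 %s %s">'),
                  fmt_px(width), fmt_px(height), fmt_px(width), fmt_px(height)),
          sprintf('<title>%s</title>', svg_esc(pileup$locus$locus_id)),
          body, "</svg>"),
        collapse = "\n")
}
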
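#' Fill color for a pNeg/pS ratio
#'
#' Monotone continuous scale: green at 0 (strong purifying selection),
#' grey at 1, orange at 1.5, red beyond (saturating at 3). Undefined
#' ratios map to light grey.
#'
#' @param ratio Numeric vector of pNeg/pS values (NA/Inf allowed).
#' @return Character vector of `#rrggbb` colors.
#' @export
ratioColor <- function(ratio) {
  anchors_x <- c(0, 1, 1.5, 3)
  anchors_c <- rbind(c(44, 160, 44),    # green
                     c(158, 158, 158),  # grey
                     c(255, 127, 14),   # orange
                     c(255, 40, 40))    # red
  vapply(ratio, function(r) {
    if (is.na(r)) return("#cccccc")
    r <- min(max(r, 0), 3)
    j <- findInterval(r, anchors_x, all.inside = TRUE)
    t <- (r - anchors_x[j]) / (anchors_x[j + 1] - anchors_x[j])
    rgbv <- round(anchors_c[j, ] + t * (anchors_c[j + 1, ] - anchors_c[j, ]))
    sprintf("#%02x%02x%02x", rgbv[1], rgbv[2], rgbv[3])
  }, character(1))
}

#' Render the multi-track SVG genome report
#'
#' Draws, top to bottom: one lane per external gene-prediction source, the
#' plus- and minus-strand ORF lanes colored by pNeg/pS ([ratioColor()]),
#' the coverage profile, and the six windowed substitution bar charts
#' (SYN / POS / NEG+STOP per strand). Mirror-discarded ORFs are outlined in
#' red; ORFs with a suspect start carry a red square at their 5' end.
#' Circular genomes are drawn linearized at position 1, with wrapping ORFs
#' split into two segments joined by a dashed connector. Output is
#' deterministic: identical inputs give byte-identical SVG.
#'
#' @param result A [MicrodivResult-class].
#' @param path Output path for the SVG document.
#' @param external_features Optional data.frame from [readGeneFeatures()].
#' @param width Drawing width in pixels (default 1000).
#' @return The path, invisibly.
#' @export
renderReport <- function(result, path, external_features = NULL,
                         width = 1000) {
  genome <- result@genome
  L <- length(genome)
  stats <- result@stats
  windows <- result@windows
  coverage <- result@coverage
  margin <- 60
  xw <- width - 2 * margin
  xpos <- function(p) margin + (p - 1) / max(L - 1, 1) * xw
  el <- character(0)
  add <- function(...) el[[length(el) + 1L]] <<- sprintf(...)
  y <- 30
  laneH <- 26
  add('<text x="%g" y="%g" font-size="13" font-family="sans-serif">%s (%d nt, %s)</text>',
      margin, y - 12, genomeId(genome), L,
      if (isCircular(genome)) "circular" else "linear")

  # external prediction lanes
  if (!is.null(external_features) && nrow(external_features)) {
    for (src in unique(external_features$source)) {
      fs <- external_features[external_features$source == src, ,
                              drop = FALSE]
      add('<text x="4" y="%g" font-size="10" font-family="sans-serif">%s</text>',
          y + 12, src)
      for (k in seq_len(nrow(fs))) {
        add('<rect id="feat_%s_%d" x="%.2f" y="%g" width="%.2f" height="10" fill="#7f9fc4" stroke="#2a4d7f"/>',
            gsub("[^A-Za-z0-9_]", "_", src), k, xpos(fs$start[k]),
            y + if (fs$strand[k] == "+") 0 else 12,
            max(xpos(fs$end[k]) - xpos(fs$start[k]), 1))
      }
      y <- y + laneH + 6
    }
  }

  # ORF lanes, plus then minus
  for (s in c("+", "-")) {
    add('<text x="4" y="%g" font-size="10" font-family="sans-serif">ORFs %s</text>',
        y + 12, s)
    rows <- which(stats$strand == s)
    for (i in rows) {
      fill <- ratioColor(stats$pneg_ps[i])
      mirror <- .hasFlag(stats$flags[i], "mirror_discarded")
      stroke <- if (mirror) "#ff0000" else "#333333"
      sw <- if (mirror) 2 else 0.5
      yy <- y + stats$frame[i] * 5
      segs <- if (stats$wraps[i])
        list(c(stats$start[i], L), c(1, stats$end[i]))
      else list(c(stats$start[i], stats$end[i]))
      add('<g id="orf_%s">', stats$orf_id[i])
      for (sg in segs)
        add('<rect x="%.2f" y="%g" width="%.2f" height="8" fill="%s" stroke="%s" stroke-width="%g"/>',
            xpos(sg[1]), yy, max(xpos(sg[2]) - xpos(sg[1]), 1), fill,
            stroke, sw)
      if (length(segs) == 2L)
        add('<line x1="%.2f" y1="%g" x2="%.2f" y2="%g" stroke="%s" stroke-width="0.5" stroke-dasharray="3,3"/>',
            xpos(L), y + stats$frame[i] * 5 + 4, xpos(1),
            y + stats$frame[i] * 5 + 4, stroke)
      if (.hasFlag(stats$flags[i], "suspect_start")) {
        p5 <- if (s == "+") stats$start[i] else stats$end[i]
        add('<rect id="startmark_%s" x="%.2f" y="%g" width="6" height="6" fill="#ff0000"/>',
            stats$orf_id[i], xpos(p5) - 3, yy - 5)
      }
      add('</g>')
    }
    y <- y + 3 * 5 + 18
  }

  # coverage
  covH <- 50
  add('<text x="4" y="%g" font-size="10" font-family="sans-serif">coverage</text>',
      y + 12)
  if (length(coverage)) {
    cmax <- max(coverage, 1)
    pts <- paste(sprintf("%.2f,%.2f", xpos(seq_len(L)),
                         y + covH - coverage / cmax * covH),
                 collapse = " ")
    add('<polyline id="coverage" points="%s" fill="none" stroke="#444444" stroke-width="0.8"/>',
        pts)
    add('<text x="%g" y="%g" font-size="9" font-family="sans-serif">max %g</text>',
        margin + xw + 4, y + 10, cmax)
  } else {
    add('<line id="coverage" x1="%g" y1="%g" x2="%g" y2="%g" stroke="#bbbbbb" stroke-width="0.8"/>',
        margin, y + covH, margin + xw, y + covH)
  }
  y <- y + covH + 14

  # six bar charts: 3 groups per strand
  barH <- 34
  groupCol <- c(SYN = "#2ca02c", POS = "#9467bd", NEGSTOP = "#d62728")
  if (nrow(windows)) {
    wmax <- max(windows$count, 1)
    for (s in c("+", "-")) for (g in c("SYN", "POS", "NEGSTOP")) {
      add('<text x="4" y="%g" font-size="9" font-family="sans-serif">%s %s</text>',
          y + 10, s, if (g == "NEGSTOP") "NEG+STOP" else g)
      ws <- windows[windows$strand == s & windows$group == g &
                      windows$count > 0, , drop = FALSE]
      for (k in seq_len(nrow(ws))) {
        h <- ws$count[k] / wmax * barH
        add('<rect id="bar_%s_%s_%d" x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="%s"/>',
            if (s == "+") "plus" else "minus", g, ws$window[k],
            xpos(ws$start[k]), y + barH - h,
            max(xpos(ws$end[k]) - xpos(ws$start[k]), 0.8), h, groupCol[[g]])
      }
      add('<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="#999999" stroke-width="0.5"/>',
          margin, y + barH, margin + xw, y + barH)
      y <- y + barH + 14
    }
  }

  height <- y + 20
  doc <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%g" height="%g">',
                   width, height),
           el, "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(doc, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
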
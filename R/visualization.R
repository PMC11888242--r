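# Minimal SVG emitter. Figures are built as explicit SVG elements so that
# glyph counts, colors and opacities are machine-checkable attributes.

svg_doc <- function(width, height) {
  structure(list(
    head = sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%g" height="%g" viewBox="0 0 %g %g">',
      width, height, width, height),
    body = character()), class = "gator_svg")
}

svg_add <- function(doc, ...) {
  doc$body <- c(doc$body, ...)
  doc
}

svg_el <- function(tag, ..., text = NULL) {
  at <- list(...)
  at <- at[!vapply(at, is.null, TRUE)]
  attrs <- paste(sprintf('%s="%s"', gsub("_", "-", names(at)),
                         vapply(at, as.character, "")), collapse = " ")
  if (is.null(text)) sprintf("<%s %s/>", tag, attrs)
  else sprintf("<%s %s>%s</%s>", tag, attrs, xml_escape(text), tag)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_write <- function(doc, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(c(doc$head, doc$body, "</svg>"), path)
  invisible(path)
}

# Arrow polygon for a gene glyph in track coordinates.
gene_arrow_points <- function(x1, x2, y, h, strand) {
  head_len <- min(0.3 * (x2 - x1), h)
  if (strand >= 0) {
    xs <- c(x1, x2 - head_len, x2 - head_len, x2, x2 - head_len,
            x2 - head_len, x1)
    ys <- c(y - h / 2, y - h / 2, y - h, y, y + h, y + h / 2, y + h / 2)
  } else {
    xs <- c(x2, x1 + head_len, x1 + head_len, x1, x1 + head_len,
            x1 + head_len, x2)
    ys <- c(y - h / 2, y - h / 2, y - h, y, y + h, y + h / 2, y + h / 2)
  }
  paste(sprintf("%.2f,%.2f", xs, ys), collapse = " ")
}

#' Default figure colors
#'
#' Required genes purple, optional orange, all other genes green; contig-edge
#' genes get a red outline.
#' @return named character vector of hex colors.
#' @export
gator_colors <- function() {
  c(required = "#800080", optional = "#FFA500", None = "#008000",
    edge = "#FF0000", outline = "#333333")
}

#' Per-gene conservation of a focal window
#'
#' Fraction of windows (rows of the presence-absence matrix, focal row
#' included) in which each focal gene is present.
#'
#' @param focal the focal `gator_window`.
#' @param presence presence-absence matrix from [presence_absence()].
#' @return named numeric vector in [0, 1] over focal genes.
#' @export
conservation_profile <- function(focal, presence) {
  stopifnot(identical(colnames(presence), focal$genes$gene_id))
  colMeans(presence)
}

#' Draw the conservation diagram of one window
#'
#' Gene arrows are colored by query role (purple required, orange optional,
#' green other) with fill opacity equal to the gene's conservation fraction
#' (0 = fully transparent, 1 = fully opaque). Contig-edge genes are outlined
#' red. The figure carries the window name, query labels on anchored genes,
#' the genomic length and a scale bar. Each gene glyph is a
#' `<polygon class="gene">` with `data-gene` and `data-conservation`
#' attributes.
#'
#' @param window annotated `gator_window`.
#' @param profile conservation vector ([conservation_profile()]).
#' @param out SVG output path.
#' @param width figure width in px.
#' @return `out`, invisibly.
#' @export
draw_conservation <- function(window, profile, out, width = 900) {
  g <- window$genes
  stopifnot(length(profile) == nrow(g))
  cols <- gator_colors()
  pad <- 40; track_y <- 70; h <- 12
  span <- c(window$span_start, window$span_end)
  sc <- (width - 2 * pad) / max(1, diff(span))
  px <- function(bp) pad + (bp - span[1]) * sc
  doc <- svg_doc(width, 140)
  doc <- svg_add(doc, svg_el("text", x = pad, y = 20, class = "track-name",
                             font_size = 12, text = window$window_id))
  doc <- svg_add(doc, svg_el("line", x1 = px(span[1]), y1 = track_y,
                             x2 = px(span[2]), y2 = track_y,
                             stroke = "#999999", stroke_width = 1))
  for (i in seq_len(nrow(g))) {
    role <- if (is.null(g$gator_query)) "None" else g$gator_query[i]
    stroke <- if (isTRUE(g$contig_edge[i])) cols[["edge"]] else cols[["outline"]]
    doc <- svg_add(doc, svg_el(
      "polygon", class = "gene",
      points = gene_arrow_points(px(g$start[i]), px(g$end[i]), track_y, h,
                                 g$strand[i]),
      fill = cols[[role]], fill_opacity = sprintf("%.4f", profile[i]),
      stroke = stroke, stroke_width = 1,
      data_gene = g$gene_id[i],
      data_conservation = sprintf("%.4f", profile[i])))
    if (!is.null(g$gator_hit) && !is.na(g$gator_hit[i]))
      doc <- svg_add(doc, svg_el("text", x = px((g$start[i] + g$end[i]) / 2),
                                 y = track_y - 20, class = "query-label",
                                 font_size = 9, text_anchor = "middle",
                                 text = g$gator_hit[i]))
  }
  bar_bp <- signif(diff(span) / 5, 1)
  doc <- svg_add(doc,
    svg_el("line", x1 = pad, y1 = 120, x2 = pad + bar_bp * sc, y2 = 120,
           stroke = "#000000", stroke_width = 2, class = "scale-bar"),
    svg_el("text", x = pad, y = 135, font_size = 10, class = "scale-label",
           text = sprintf("%g kb of %g kb", bar_bp / 1000,
                          diff(span) / 1000)))
  svg_write(doc, out)
}

#' Draw the GFS-sorted focal neighborhood figure
#'
#' The focal window is the top track; the remaining windows follow in
#' descending GFS order. Query labels appear only on the focal track.
#' Homology rails (`<polygon class="rail">`) connect aligned amino-acid
#' ranges, scaled into the gene glyphs; for modular (NRPS/PKS) focal genes
#' only the highest-bit-score hit per target window is railed, for
#' non-modular genes all passing hits are drawn.
#'
#' @param focal the focal `gator_window`.
#' @param windows all windows (the focal may be included; it is drawn once,
#'   on top).
#' @param gfs_column named scores of each window against the focal.
#' @param hits gene-vs-gene hit table with alignment coordinates.
#' @param out SVG output path.
#' @param width figure width in px.
#' @return `out`, invisibly.
#' @export
draw_neighborhood <- function(focal, windows, gfs_column, hits, out,
                              width = 900) {
  cols <- gator_colors()
  ids <- vapply(windows, `[[`, "", "window_id")
  others <- windows[ids != focal$window_id]
  oid <- vapply(others, `[[`, "", "window_id")
  ord <- order(-gfs_column[oid], oid)
  tracks <- c(list(focal), others[ord])
  pad <- 40; row_h <- 60; h <- 10
  height <- 40 + row_h * length(tracks)
  doc <- svg_doc(width, height)
  geom <- list()   # per track: gene_id -> c(x1, x2, y)
  for (t in seq_along(tracks)) {
    w <- tracks[[t]]
    y <- 40 + row_h * (t - 1) + 20
    sc <- (width - 2 * pad) / max(1, window_length(w))
    px <- function(bp) pad + (bp - w$span_start) * sc
    label <- if (t == 1) sprintf("%s (focal)", w$window_id) else
      sprintf("%s  GFS=%.3f", w$window_id, gfs_column[w$window_id])
    doc <- svg_add(doc,
      svg_el("text", x = pad, y = y - 22, class = "track-name",
             font_size = 10, text = label),
      svg_el("line", x1 = pad, y1 = y, x2 = width - pad, y2 = y,
             stroke = "#999999", stroke_width = 1))
    gg <- w$genes
    gm <- matrix(NA_real_, nrow(gg), 3,
                 dimnames = list(gg$gene_id, c("x1", "x2", "y")))
    for (i in seq_len(nrow(gg))) {
      role <- if (is.null(gg$gator_query)) "None" else gg$gator_query[i]
      gm[i, ] <- c(px(gg$start[i]), px(gg$end[i]), y)
      doc <- svg_add(doc, svg_el(
        "polygon", class = "gene",
        points = gene_arrow_points(px(gg$start[i]), px(gg$end[i]), y, h,
                                   gg$strand[i]),
        fill = cols[[role]], fill_opacity = "1",
        stroke = if (isTRUE(gg$contig_edge[i])) cols[["edge"]] else cols[["outline"]],
        stroke_width = 1, data_gene = gg$gene_id[i]))
      if (t == 1 && !is.null(gg$gator_hit) && !is.na(gg$gator_hit[i]))
        doc <- svg_add(doc, svg_el("text",
                                   x = (px(gg$start[i]) + px(gg$end[i])) / 2,
                                   y = y - 12, class = "query-label",
                                   font_size = 8, text_anchor = "middle",
                                   text = gg$gator_hit[i]))
    }
    geom[[w$window_id]] <- gm
  }
  doc <- add_rails(doc, focal, tracks, geom, hits, h)
  svg_write(doc, out)
}

add_rails <- function(doc, focal, tracks, geom, hits, h) {
  if (!nrow(hits)) return(doc)
  fg <- focal$genes
  modular <- if (is.null(fg$gator_nrps)) rep(FALSE, nrow(fg)) else
    fg$gator_nrps | fg$gator_pks
  fh <- hits[hits$query_id %in% fg$gene_id, , drop = FALSE]
  for (t in seq_along(tracks)[-1]) {
    w <- tracks[[t]]
    th <- fh[fh$subject_id %in% w$genes$gene_id, , drop = FALSE]
    if (!nrow(th)) next
    for (gi in seq_len(nrow(fg))) {
      gh <- th[th$query_id == fg$gene_id[gi], , drop = FALSE]
      if (!nrow(gh)) next
      if (modular[gi]) gh <- gh[which.max(gh$bit_score), , drop = FALSE]
      for (k in seq_len(nrow(gh))) {
        doc <- svg_add(doc, rail_polygon(
          geom[[focal$window_id]], geom[[w$window_id]], fg, w$genes,
          gh[k, ], h))
      }
    }
  }
  doc
}

rail_polygon <- function(gsrc, gtgt, src_genes, tgt_genes, hit, h) {
  qlen <- nchar(src_genes$protein_seq[src_genes$gene_id == hit$query_id])
  slen <- nchar(tgt_genes$protein_seq[tgt_genes$gene_id == hit$subject_id])
  a <- gsrc[hit$query_id, ]; b <- gtgt[hit$subject_id, ]
  frac <- function(gxy, p, len) gxy[["x1"]] +
    (gxy[["x2"]] - gxy[["x1"]]) * min(1, p / max(1, len))
  xs <- c(frac(a, hit$q_start - 1, qlen), frac(a, hit$q_end, qlen),
          frac(b, hit$s_end, slen), frac(b, hit$s_start - 1, slen))
  ys <- c(a[["y"]] + h, a[["y"]] + h, b[["y"]] - h, b[["y"]] - h)
  svg_el("polygon", class = "rail",
         points = paste(sprintf("%.2f,%.2f", xs, ys), collapse = " "),
         fill = "#888888",
         fill_opacity = sprintf("%.3f", 0.15 + 0.6 * hit$pct_identity / 100),
         stroke = "none",
         data_identity = sprintf("%.1f", hit$pct_identity))
}

#' Draw the clustered GFS heatmap with dendrogram
#'
#' Rows and columns are permuted by the clustering leaf order; cells are
#' `<rect class="cell">` with a linear white-to-blue fill over [0, 1] and a
#' `data-gfs` attribute. The row dendrogram is drawn from the merge tree.
#'
#' @param matrix GFS matrix.
#' @param order `gator_cluster` from [cluster_gfs()].
#' @param out SVG output path.
#' @param cell px size of one heatmap cell.
#' @return `out`, invisibly.
#' @export
draw_heatmap <- function(matrix, order, out, cell = 18) {
  m <- unclass(matrix)
  leaf <- order$order
  m <- m[leaf, leaf, drop = FALSE]
  n <- nrow(m)
  dend_w <- 80; pad <- 140
  width <- dend_w + pad + n * cell + 20
  height <- 40 + n * cell + pad
  doc <- svg_doc(width, height)
  ramp <- grDevices::colorRamp(c("#FFFFFF", "#08306B"))
  x0 <- dend_w + pad; y0 <- 40
  for (i in seq_len(n)) for (j in seq_len(n)) {
    rgbv <- ramp(max(0, min(1, m[i, j])))
    doc <- svg_add(doc, svg_el(
      "rect", class = "cell", x = x0 + (j - 1) * cell, y = y0 + (i - 1) * cell,
      width = cell, height = cell,
      fill = grDevices::rgb(rgbv[1], rgbv[2], rgbv[3], maxColorValue = 255),
      data_gfs = sprintf("%.4f", m[i, j])))
  }
  for (i in seq_len(n)) {
    doc <- svg_add(doc,
      svg_el("text", x = x0 - 4, y = y0 + (i - 0.35) * cell,
             font_size = 8, text_anchor = "end", class = "row-label",
             text = leaf[i]),
      svg_el("text", x = x0 + (i - 0.5) * cell, y = y0 + n * cell + 10,
             font_size = 8, class = "col-label",
             transform = sprintf("rotate(90 %g %g)", x0 + (i - 0.5) * cell,
                                 y0 + n * cell + 10),
             text = leaf[i]))
  }
  if (!is.null(order$hclust)) doc <- dendro_lines(doc, order$hclust, x0 = 5,
                                                  w = dend_w - 10, y0 = y0,
                                                  cell = cell)
  svg_write(doc, out)
}

# Draw an hclust tree to the left of the heatmap rows.
dendro_lines <- function(doc, hc, x0, w, y0, cell) {
  n <- length(hc$order)
  leaf_y <- stats::setNames(y0 + (match(seq_len(n), hc$order) - 0.5) * cell,
                            seq_len(n))
  maxh <- max(hc$height)
  hx <- function(height) x0 + w * (1 - height / max(maxh, .Machine$double.eps))
  pos <- matrix(NA_real_, nrow(hc$merge), 2)  # y, x of each internal node
  node_y <- function(k) if (k < 0) leaf_y[[as.character(-k)]] else pos[k, 1]
  node_x <- function(k) if (k < 0) x0 + w else pos[k, 2]
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    ya <- node_y(a); yb <- node_y(b); xm <- hx(hc$height[i])
    doc <- svg_add(doc,
      svg_el("line", class = "dendro", x1 = node_x(a), y1 = ya, x2 = xm,
             y2 = ya, stroke = "#000000", stroke_width = 1),
      svg_el("line", class = "dendro", x1 = node_x(b), y1 = yb, x2 = xm,
             y2 = yb, stroke = "#000000", stroke_width = 1),
      svg_el("line", class = "dendro", x1 = xm, y1 = ya, x2 = xm, y2 = yb,
             stroke = "#000000", stroke_width = 1))
    pos[i, ] <- c((ya + yb) / 2, xm)
  }
  doc
}
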
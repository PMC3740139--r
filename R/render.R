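# Render planning and drawing.
#
# A render plan resolves every annotation to its leaf coordinate and fixes
# the z-order: backbone first, then annotations in non-increasing scale
# order (large shapes drawn first so they never hide smaller ones; ties keep
# document order), then remainder name labels, then the legend. Drawing a
# plan is deterministic; the PostScript and SVG writers emit byte-identical
# output for identical plans.

# Regular n-gon circumscribed by the scale-diameter circle, one vertex up
# (y grows downward everywhere in this package).
polygon_vertices <- function(cx, cy, scale, n) {
  a <- -pi / 2 + 2 * pi * (seq_len(n) - 1) / n
  r <- scale / 2
  list(x = cx + r * cos(a), y = cy + r * sin(a))
}

# Width estimate for Helvetica-like text: 0.6 em per glyph. The PostScript
# writer re-measures with the interpreter's own stringwidth; this estimate
# drives SVG boxes and legend flow.
est_text_width <- function(payload, scale) {
  0.6 * scale * nchar(payload, type = "chars")
}

#' Position legend elements
#'
#' Flows legend items left-to-right from an anchor point: drawables advance
#' the cursor by their width, \code{space} inserts a gap, \code{next-line}
#' starts a new baseline below the current line. When the legend is boxed a
#' rectangle enclosing every element with uniform padding is computed.
#'
#' @param items legend item list from a \code{\link{kr_document}}.
#' @param anchor \code{c(x, y)} top-left of the legend block, points.
#' @param boxed draw an enclosing box.
#' @param padding box padding and inter-element gap basis, points.
#' @return List with \code{elements} (positioned drawables carrying
#'   \code{cx}, \code{cy} centers and extents) and \code{box}
#'   (\code{c(x0, y0, x1, y1)} or \code{NULL}).
#' @export
layout_legend <- function(items, anchor = c(40, 40), boxed = FALSE, padding = 5) {
  elements <- list()
  if (length(items)) {
    # split into lines at next-line markers
    line_of <- cumsum(vapply(items, function(i) identical(i$type, "next-line"),
                             logical(1)))
    keep <- !vapply(items, function(i) identical(i$type, "next-line"), logical(1))
    lines <- split(items[keep], line_of[keep])
    y_top <- anchor[2]
    for (ln in lines) {
      scales <- vapply(ln, function(i) if (identical(i$type, "drawable"))
        i$scale else NA_integer_, integer(1))
      line_h <- if (all(is.na(scales))) 12 else 1.3 * max(scales, na.rm = TRUE)
      cy <- y_top + line_h / 2
      x <- anchor[1]
      last_scale <- 10L
      for (it in ln) {
        if (identical(it$type, "space")) { x <- x + 0.4 * last_scale; next }
        w <- if (it$kind %in% TEXT_KINDS) est_text_width(it$payload, it$scale)
             else it$scale
        el <- it
        el$cx <- x + w / 2
        el$cy <- cy
        el$x0 <- x; el$x1 <- x + w
        el$y0 <- cy - max(it$scale, 1) / 2
        el$y1 <- cy + max(it$scale, 1) / 2
        elements[[length(elements) + 1L]] <- el
        x <- x + w + 0.2 * it$scale
        last_scale <- it$scale
      }
      y_top <- y_top + line_h
    }
  }
  box <- NULL
  if (boxed && length(elements)) {
    box <- c(min(vapply(elements, `[[`, numeric(1), "x0")) - padding,
             min(vapply(elements, `[[`, numeric(1), "y0")) - padding,
             max(vapply(elements, `[[`, numeric(1), "x1")) + padding,
             max(vapply(elements, `[[`, numeric(1), "y1")) + padding)
  }
  list(elements = elements, box = box)
}

#' Build a render plan
#'
#' Resolves every annotation target to its template coordinate, orders
#' annotations by non-increasing scale (stable in document order so ties
#' keep their relative order), attaches remainder name labels (black,
#' scale 10) for every template leaf without an annotation when the
#' document requests it, and positions the legend last.
#'
#' @param doc a \code{\link{kr_document}}.
#' @param template a \code{\link{tree_template}}.
#' @param legend_anchor \code{c(x, y)} for the legend block; default is
#'   near the bottom-left of the canvas.
#' @return A \code{render_plan}.
#' @export
plan_render <- function(doc, template, legend_anchor = NULL) {
  stopifnot(inherits(doc, "kr_document"), inherits(template, "tree_template"))
  anns <- doc$annotations
  if (length(anns)) {
    targets <- vapply(anns, `[[`, character(1), "target")
    pos <- leaf_coords(template, targets)
    missing <- unique(pos$leaf[is.na(pos$x)])
    if (length(missing))
      kv_render_error(sprintf("no template coordinate for kinase(s): %s",
                              paste(missing, collapse = ", ")))
    df <- data.frame(
      target = targets,
      kind = vapply(anns, `[[`, character(1), "kind"),
      n_sides = vapply(anns, `[[`, integer(1), "n_sides"),
      payload = vapply(anns, `[[`, character(1), "payload"),
      r = vapply(anns, function(a) a$color[1], numeric(1)),
      g = vapply(anns, function(a) a$color[2], numeric(1)),
      b = vapply(anns, function(a) a$color[3], numeric(1)),
      scale = vapply(anns, `[[`, integer(1), "scale"),
      boxed = vapply(anns, `[[`, logical(1), "boxed"),
      underlined = vapply(anns, `[[`, logical(1), "underlined"),
      x = pos$x, y = pos$y, stringsAsFactors = FALSE)
    df <- df[order(-df$scale), , drop = FALSE]  # stable: ties keep doc order
    rownames(df) <- NULL
  } else {
    df <- data.frame(target = character(0), kind = character(0),
                     n_sides = integer(0), payload = character(0),
                     r = numeric(0), g = numeric(0), b = numeric(0),
                     scale = integer(0), boxed = logical(0),
                     underlined = logical(0), x = numeric(0), y = numeric(0),
                     stringsAsFactors = FALSE)
  }
  remainder <- NULL
  if (doc$remainder && nrow(template$coords)) {
    annotated <- unique(tolower(df$target))
    rem <- template$coords[!(tolower(template$coords$leaf) %in% annotated), ,
                           drop = FALSE]
    rownames(rem) <- NULL
    remainder <- rem
  }
  anchor <- legend_anchor %||% c(40, max(40, template$canvas[2] - 160))
  legend <- layout_legend(doc$legend, anchor = anchor, boxed = doc$legend_boxed)
  structure(list(canvas = template$canvas, backbone = template$edges,
                 annotations = df, remainder = remainder, legend = legend),
            class = "render_plan")
}

#' @export
print.render_plan <- function(x, ...) {
  cat(sprintf("<render_plan> %g x %g pt, %d annotation(s), %d remainder label(s), %d legend element(s)\n",
              x$canvas[1], x$canvas[2], nrow(x$annotations),
              if (is.null(x$remainder)) 0L else nrow(x$remainder),
              length(x$legend$elements)))
  invisible(x)
}

hex_color <- function(r, g, b) {
  sprintf("#%02X%02X%02X", round(255 * r), round(255 * g), round(255 * b))
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

svg_shape <- function(kind, cx, cy, scale, n_sides, col) {
  style <- switch(kind,
    circle = , polygon =
      sprintf('fill="none" stroke="%s" stroke-width="0.75"', col),
    `circle-filled` = , `polygon-filled` =
      sprintf('fill="%s" stroke="none"', col),
    `circle-lined` = , `polygon-lined` =
      sprintf('fill="%s" stroke="#000000" stroke-width="0.75"', col))
  if (startsWith(kind, "circle")) {
    sprintf('<circle cx="%s" cy="%s" r="%s" %s/>',
            fmt_num(cx), fmt_num(cy), fmt_num(scale / 2), style)
  } else {
    v <- polygon_vertices(cx, cy, scale, n_sides)
    pts <- paste(sprintf("%s,%s", fmt_num(round(v$x, 4)), fmt_num(round(v$y, 4))),
                 collapse = " ")
    sprintf('<polygon points="%s" %s/>', pts, style)
  }
}

svg_text <- function(cx, cy, payload, scale, col, boxed, underlined) {
  out <- sprintf(
    '<text x="%s" y="%s" font-family="Helvetica, Arial, sans-serif" font-size="%s" fill="%s" text-anchor="middle">%s</text>',
    fmt_num(cx), fmt_num(round(cy + 0.36 * scale, 4)), fmt_num(scale), col,
    xml_escape(payload))
  w <- est_text_width(payload, scale)
  if (underlined)
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="0.75"/>',
      fmt_num(round(cx - w / 2, 4)), fmt_num(round(cy + 0.5 * scale, 4)),
      fmt_num(round(cx + w / 2, 4)), fmt_num(round(cy + 0.5 * scale, 4)), col))
  if (boxed)
    out <- c(out, sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="none" stroke="%s" stroke-width="0.75"/>',
      fmt_num(round(cx - w / 2 - 2, 4)), fmt_num(round(cy - 0.5 * scale - 2, 4)),
      fmt_num(round(w + 4, 4)), fmt_num(round(scale + 4, 4)), col))
  out
}

emit_svg <- function(plan) {
  W <- plan$canvas[1]; H <- plan$canvas[2]
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%spt" height="%spt" viewBox="0 0 %s %s">',
                   fmt_num(W), fmt_num(H), fmt_num(W), fmt_num(H)))
  if (!is.null(plan$backbone) && nrow(plan$backbone)) {
    bb <- plan$backbone
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#999999" stroke-width="0.5"/>',
      fmt_num(round(bb$x1, 4)), fmt_num(round(bb$y1, 4)),
      fmt_num(round(bb$x2, 4)), fmt_num(round(bb$y2, 4))))
  }
  a <- plan$annotations
  for (i in seq_len(nrow(a))) {
    col <- hex_color(a$r[i], a$g[i], a$b[i])
    out <- c(out, if (a$kind[i] %in% TEXT_KINDS)
      svg_text(a$x[i], a$y[i], a$payload[i], a$scale[i], col,
               a$boxed[i], a$underlined[i])
      else svg_shape(a$kind[i], a$x[i], a$y[i], a$scale[i], a$n_sides[i], col))
  }
  if (!is.null(plan$remainder) && nrow(plan$remainder)) {
    rm <- plan$remainder
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-family="Helvetica, Arial, sans-serif" font-size="10" fill="#000000" text-anchor="middle">%s</text>',
      fmt_num(rm$x), fmt_num(round(rm$y + 3.6, 4)), xml_escape(rm$leaf)))
  }
  for (el in plan$legend$elements) {
    col <- hex_color(el$color[1], el$color[2], el$color[3])
    out <- c(out, if (el$kind %in% TEXT_KINDS)
      svg_text(el$cx, el$cy, el$payload, el$scale, col,
               isTRUE(el$boxed), isTRUE(el$underlined))
      else svg_shape(el$kind, el$cx, el$cy, el$scale, el$n_sides, col))
  }
  if (!is.null(plan$legend$box)) {
    bx <- plan$legend$box
    out <- c(out, sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#000000" stroke-width="0.75"/>',
      fmt_num(round(bx[1], 4)), fmt_num(round(bx[2], 4)),
      fmt_num(round(bx[3] - bx[1], 4)), fmt_num(round(bx[4] - bx[2], 4))))
  }
  c(out, "</svg>")
}

ps_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("(", "\\(", s, fixed = TRUE)
  gsub(")", "\\)", s, fixed = TRUE)
}

ps_rgb <- function(r, g, b) paste(fmt_num(c(r, g, b)), collapse = " ")

ps_shape <- function(kind, cx, cy, scale, n_sides, col, H) {
  y <- H - cy
  path <- if (startsWith(kind, "circle")) {
    sprintf("newpath %s %s %s 0 360 arc closepath",
            fmt_num(round(cx, 4)), fmt_num(round(y, 4)), fmt_num(scale / 2))
  } else {
    v <- polygon_vertices(cx, cy, scale, n_sides)
    vy <- H - v$y
    paste("newpath",
          sprintf("%s %s moveto", fmt_num(round(v$x[1], 4)), fmt_num(round(vy[1], 4))),
          paste(sprintf("%s %s lineto", fmt_num(round(v$x[-1], 4)),
                        fmt_num(round(vy[-1], 4))), collapse = " "),
          "closepath")
  }
  suffix <- sub("^(circle|polygon)", "", kind)
  finish <- if (suffix == "-filled") {
    sprintf("%s setrgbcolor fill", col)
  } else if (suffix == "-lined") {
    sprintf("gsave %s setrgbcolor fill grestore 0 0 0 setrgbcolor 0.75 setlinewidth stroke", col)
  } else {
    sprintf("%s setrgbcolor 0.75 setlinewidth stroke", col)
  }
  paste(path, finish)
}

ps_text <- function(cx, cy, payload, scale, col, boxed, underlined, H) {
  y <- H - cy
  txt <- ps_escape(enc2utf8(payload))
  out <- c(
    sprintf("/Helvetica findfont %d scalefont setfont %s setrgbcolor", scale, col),
    sprintf("(%s) stringwidth pop /tw exch def", txt),
    sprintf("%s tw 2 div sub %s moveto (%s) show",
            fmt_num(round(cx, 4)), fmt_num(round(y - 0.36 * scale, 4)), txt))
  if (underlined)
    out <- c(out, sprintf(
      "newpath %s tw 2 div sub %s moveto tw 0 rlineto 0.75 setlinewidth stroke",
      fmt_num(round(cx, 4)), fmt_num(round(y - 0.5 * scale, 4))))
  if (boxed)
    out <- c(out, sprintf(
      "newpath %s tw 2 div sub 2 sub %s moveto tw 4 add 0 rlineto 0 %s rlineto tw 4 add neg 0 rlineto closepath 0.75 setlinewidth stroke",
      fmt_num(round(cx, 4)), fmt_num(round(y - 0.5 * scale - 2, 4)),
      fmt_num(scale + 4)))
  out
}

emit_ps <- function(plan) {
  W <- plan$canvas[1]; H <- plan$canvas[2]
  out <- c("%!PS-Adobe-3.0 EPSF-3.0",
           sprintf("%%%%BoundingBox: 0 0 %d %d", ceiling(W), ceiling(H)),
           "%%Pages: 1", "%%EndComments", "%%Page: 1 1")
  if (!is.null(plan$backbone) && nrow(plan$backbone)) {
    bb <- plan$backbone
    out <- c(out, "0.6 0.6 0.6 setrgbcolor 0.5 setlinewidth",
             sprintf("newpath %s %s moveto %s %s lineto stroke",
                     fmt_num(round(bb$x1, 4)), fmt_num(round(H - bb$y1, 4)),
                     fmt_num(round(bb$x2, 4)), fmt_num(round(H - bb$y2, 4))))
  }
  a <- plan$annotations
  for (i in seq_len(nrow(a))) {
    col <- ps_rgb(a$r[i], a$g[i], a$b[i])
    out <- c(out, if (a$kind[i] %in% TEXT_KINDS)
      ps_text(a$x[i], a$y[i], a$payload[i], a$scale[i], col,
              a$boxed[i], a$underlined[i], H)
      else ps_shape(a$kind[i], a$x[i], a$y[i], a$scale[i], a$n_sides[i], col, H))
  }
  if (!is.null(plan$remainder) && nrow(plan$remainder)) {
    rm <- plan$remainder
    out <- c(out, "/Helvetica findfont 10 scalefont setfont 0 0 0 setrgbcolor",
             sprintf("(%s) stringwidth pop /tw exch def %s tw 2 div sub %s moveto (%s) show",
                     ps_escape(rm$leaf), fmt_num(rm$x),
                     fmt_num(round(H - rm$y - 3.6, 4)), ps_escape(rm$leaf)))
  }
  for (el in plan$legend$elements) {
    col <- ps_rgb(el$color[1], el$color[2], el$color[3])
    out <- c(out, if (el$kind %in% TEXT_KINDS) {
      # legend text is left-anchored at its slot; shift the centering back
      ps_text(el$cx, el$cy, el$payload, el$scale, col,
              isTRUE(el$boxed), isTRUE(el$underlined), H)
    } else {
      ps_shape(el$kind, el$cx, el$cy, el$scale, el$n_sides, col, H)
    })
  }
  if (!is.null(plan$legend$box)) {
    bx <- plan$legend$box
    out <- c(out, sprintf(
      "newpath %s %s moveto %s 0 rlineto 0 %s rlineto %s neg 0 rlineto closepath 0 0 0 setrgbcolor 0.75 setlinewidth stroke",
      fmt_num(round(bx[1], 4)), fmt_num(round(H - bx[4], 4)),
      fmt_num(round(bx[3] - bx[1], 4)), fmt_num(round(bx[4] - bx[2], 4)),
      fmt_num(round(bx[3] - bx[1], 4))))
  }
  c(out, "showpage", "%%EOF")
}

draw_device <- function(plan, path, format, dpi = 300) {
  W <- plan$canvas[1]; H <- plan$canvas[2]
  win <- W / 72; hin <- H / 72
  switch(format,
    pdf = grDevices::pdf(path, width = win, height = hin, useDingbats = FALSE),
    png = grDevices::png(path, width = win, height = hin, units = "in", res = dpi),
    jpg = , jpeg = grDevices::jpeg(path, width = win, height = hin,
                                   units = "in", res = dpi, quality = 95),
    tiff = grDevices::tiff(path, width = win, height = hin, units = "in",
                           res = dpi))
  on.exit(grDevices::dev.off())
  graphics::par(mar = rep(0, 4), xaxs = "i", yaxs = "i", ps = 10)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, W), ylim = c(H, 0))
  if (!is.null(plan$backbone) && nrow(plan$backbone)) {
    bb <- plan$backbone
    graphics::segments(bb$x1, bb$y1, bb$x2, bb$y2, col = "grey60", lwd = 0.5)
  }
  draw_one <- function(kind, cx, cy, scale, n_sides, col, payload,
                       boxed, underlined) {
    if (kind %in% TEXT_KINDS) {
      graphics::text(cx, cy, payload, col = col, cex = scale / 10)
      w <- est_text_width(payload, scale)
      if (underlined)
        graphics::segments(cx - w / 2, cy + 0.5 * scale,
                           cx + w / 2, cy + 0.5 * scale, col = col, lwd = 0.75)
      if (boxed)
        graphics::rect(cx - w / 2 - 2, cy - 0.5 * scale - 2,
                       cx + w / 2 + 2, cy + 0.5 * scale + 2,
                       border = col, lwd = 0.75)
    } else if (startsWith(kind, "circle")) {
      bg <- if (kind == "circle") NA else col
      fg <- switch(kind, circle = col, `circle-filled` = NA,
                   `circle-lined` = "black")
      graphics::symbols(cx, cy, circles = scale / 2, inches = FALSE,
                        add = TRUE, fg = fg, bg = bg, lwd = 0.75)
    } else {
      v <- polygon_vertices(cx, cy, scale, n_sides)
      bg <- if (kind == "polygon") NA else col
      fg <- switch(kind, polygon = col, `polygon-filled` = NA,
                   `polygon-lined` = "black")
      graphics::polygon(v$x, v$y, border = fg, col = bg, lwd = 0.75)
    }
  }
  a <- plan$annotations
  for (i in seq_len(nrow(a)))
    draw_one(a$kind[i], a$x[i], a$y[i], a$scale[i], a$n_sides[i],
             grDevices::rgb(a$r[i], a$g[i], a$b[i]), a$payload[i],
             a$boxed[i], a$underlined[i])
  if (!is.null(plan$remainder) && nrow(plan$remainder))
    graphics::text(plan$remainder$x, plan$remainder$y, plan$remainder$leaf,
                   col = "black", cex = 1)
  for (el in plan$legend$elements)
    draw_one(el$kind, el$cx, el$cy, el$scale, el$n_sides,
             grDevices::rgb(el$color[1], el$color[2], el$color[3]),
             el$payload, isTRUE(el$boxed), isTRUE(el$underlined))
  if (!is.null(plan$legend$box)) {
    bx <- plan$legend$box
    graphics::rect(bx[1], bx[2], bx[3], bx[4], border = "black", lwd = 0.75)
  }
  invisible(path)
}

RENDER_FORMATS <- c("ps", "postscript", "svg", "pdf", "png", "jpg", "jpeg", "tiff")

#' Draw a render plan to an image file
#'
#' PostScript and SVG are written by the package's own deterministic vector
#' writers (identical plans give byte-identical files); PDF, PNG, JPG and
#' TIFF replay the plan onto the corresponding graphics device, rasterizing
#' at \code{dpi} where applicable.
#'
#' @param plan a \code{\link{plan_render}} result.
#' @param path output file path.
#' @param format one of \code{"ps"}, \code{"postscript"}, \code{"svg"},
#'   \code{"pdf"}, \code{"png"}, \code{"jpg"}, \code{"jpeg"}, \code{"tiff"};
#'   default is taken from the file extension.
#' @param dpi raster resolution for PNG/JPG/TIFF.
#' @return The path, invisibly.
#' @export
render_kinome <- function(plan, path, format = NULL, dpi = 300) {
  stopifnot(inherits(plan, "render_plan"))
  format <- tolower(format %||% tools::file_ext(path))
  if (!format %in% RENDER_FORMATS)
    kv_error(sprintf("unsupported output format '%s' (supported: %s)",
                     format, paste(RENDER_FORMATS, collapse = ", ")),
             "kv_format_error")
  if (format %in% c("ps", "postscript")) {
    atomic_write_lines(emit_ps(plan), path)
  } else if (format == "svg") {
    atomic_write_lines(emit_svg(plan), path)
  } else {
    draw_device(plan, path, format, dpi = dpi)
  }
  invisible(path)
}
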
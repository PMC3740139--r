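# The KR annotation language: one command per line, stateful color/scale,
# an optional legend program and a remainder flag.
#
# Grammar (one command per line):
#   at <name> | color <r g b | name> | scale <int> | text <string> |
#   circle | circle-filled | circle-lined |
#   polygon <n> | polygon-filled <n> | polygon-lined <n> |
#   boxed | underlined | remainder |
#   legend | space | next-line | legendBox
#
# Color and scale persist until redefined (defaults: black, 10), across
# annotations and into the legend section. Blank lines are ignored;
# "#"-prefixed lines are comments (an extension, the original language has
# no comment syntax).

KR_COLORS <- list(
  black   = c(0, 0, 0),
  red     = c(1, 0, 0),
  green   = c(0, 0.67, 0),
  blue    = c(0, 0, 1),
  yellow  = c(1, 1, 0),
  magenta = c(1, 0, 1),
  cyan    = c(0, 1, 1),
  orange  = c(1, 0.65, 0),
  pink    = c(1, 0.75, 0.8),
  grey    = c(0.5, 0.5, 0.5))

TEXT_KINDS  <- c("text")
SHAPE_KINDS <- c("circle", "circle-filled", "circle-lined",
                 "polygon", "polygon-filled", "polygon-lined")
MAX_TEXT_GLYPHS <- 25L

#' Create one annotation
#'
#' Low-level constructor used by the parser and by programmatic document
#' builders (e.g. the binding-profile encoder).
#'
#' @param target leaf name the annotation is centered on.
#' @param kind one of \code{"text"}, \code{"circle"}, \code{"circle-filled"},
#'   \code{"circle-lined"}, \code{"polygon"}, \code{"polygon-filled"},
#'   \code{"polygon-lined"}.
#' @param color RGB triple, each component in \code{[0, 1]}.
#' @param scale positive integer; shape bounding-circle diameter or text
#'   font size, in points.
#' @param n_sides polygon side count (\code{>= 3}); polygon kinds only.
#' @param payload text string (at most 25 glyphs after symbol expansion);
#'   text kind only.
#' @param boxed,underlined text decorations; text kind only.
#' @return A \code{kr_annotation} list.
#' @export
kr_annotation <- function(target, kind, color = c(0, 0, 0), scale = 10L,
                          n_sides = NA_integer_, payload = NA_character_,
                          boxed = FALSE, underlined = FALSE) {
  target <- normalize_tilde(target)
  if (!is.character(target) || length(target) != 1L || !nzchar(target))
    kv_validation_error("annotation target must be a non-empty string")
  if (!kind %in% c(TEXT_KINDS, SHAPE_KINDS))
    kv_validation_error(sprintf("unknown annotation kind '%s'", kind))
  color <- as.numeric(color)
  if (length(color) != 3L || anyNA(color) || any(color < 0 | color > 1))
    kv_validation_error("color must be an RGB triple with components in [0, 1]")
  if (length(scale) != 1L || is.na(scale) || scale != as.integer(scale) || scale <= 0)
    kv_validation_error("scale must be a positive integer")
  scale <- as.integer(scale)
  is_poly <- startsWith(kind, "polygon")
  if (is_poly) {
    if (is.na(n_sides) || n_sides != as.integer(n_sides) || n_sides < 3L)
      kv_validation_error("polygon annotations need an integer n_sides >= 3")
    n_sides <- as.integer(n_sides)
  } else {
    n_sides <- NA_integer_
  }
  is_text <- kind %in% TEXT_KINDS
  if (is_text) {
    if (is.na(payload))
      kv_validation_error("text annotations need a payload")
    if (nchar(payload, type = "chars") > MAX_TEXT_GLYPHS)
      kv_validation_error(sprintf("text payload exceeds %d glyphs", MAX_TEXT_GLYPHS))
  } else {
    payload <- NA_character_
    if (isTRUE(boxed) || isTRUE(underlined))
      kv_validation_error("boxed/underlined apply to text annotations only")
  }
  structure(list(target = target, kind = kind, n_sides = n_sides,
                 payload = payload, color = color, scale = scale,
                 boxed = isTRUE(boxed), underlined = isTRUE(underlined)),
            class = "kr_annotation")
}

legend_drawable <- function(kind, color, scale, n_sides = NA_integer_,
                            payload = NA_character_, boxed = FALSE,
                            underlined = FALSE) {
  is_poly <- startsWith(kind, "polygon")
  list(type = "drawable", kind = kind,
       n_sides = if (is_poly) as.integer(n_sides) else NA_integer_,
       payload = if (kind %in% TEXT_KINDS) payload else NA_character_,
       color = as.numeric(color), scale = as.integer(scale),
       boxed = isTRUE(boxed), underlined = isTRUE(underlined))
}

#' Create a KR document
#'
#' @param annotations list of \code{\link{kr_annotation}} objects.
#' @param legend list of legend items (drawables, spaces, line breaks) as
#'   produced by the parser.
#' @param legend_boxed draw a box around the whole legend.
#' @param remainder label every non-annotated leaf with its name (black,
#'   scale 10).
#' @return A \code{kr_document}.
#' @export
kr_document <- function(annotations = list(), legend = list(),
                        legend_boxed = FALSE, remainder = FALSE) {
  stopifnot(all(vapply(annotations, inherits, logical(1), "kr_annotation")))
  structure(list(annotations = annotations, legend = legend,
                 legend_boxed = isTRUE(legend_boxed),
                 remainder = isTRUE(remainder)),
            class = "kr_document")
}

#' @export
print.kr_document <- function(x, ...) {
  cat(sprintf("<kr_document> %d annotation(s), %d legend item(s)%s%s\n",
              length(x$annotations), length(x$legend),
              if (x$legend_boxed) ", boxed legend" else "",
              if (x$remainder) ", remainder" else ""))
  for (a in utils::head(x$annotations, 10)) {
    cat(sprintf("  at %-12s %s%s scale %d color (%s)\n", a$target, a$kind,
                if (!is.na(a$n_sides)) paste0(" ", a$n_sides)
                else if (!is.na(a$payload)) sprintf(" \"%s\"", a$payload)
                else "",
                a$scale, paste(fmt_num(a$color), collapse = ", ")))
  }
  if (length(x$annotations) > 10)
    cat(sprintf("  ... and %d more\n", length(x$annotations) - 10))
  invisible(x)
}

parse_color_arg <- function(arg, lineno) {
  arg <- trimws2(arg)
  if (arg %in% names(KR_COLORS)) return(KR_COLORS[[arg]])
  parts <- strsplit(arg, "[[:space:]]+")[[1]]
  vals <- suppressWarnings(as.numeric(parts))
  if (length(vals) != 3L || anyNA(vals))
    kv_parse_error(sprintf(
      "color expects three RGB values in [0, 1] or a predefined name, got '%s'", arg),
      line = lineno)
  if (any(vals < 0 | vals > 1))
    kv_parse_error("RGB components must lie in [0, 1]", line = lineno)
  vals
}

parse_int_arg <- function(arg, what, lineno, min = 1L) {
  arg <- trimws2(arg)
  if (!grepl("^[0-9]+$", arg))
    kv_parse_error(sprintf("%s expects an integer, got '%s'", what, arg),
                   line = lineno)
  v <- as.integer(arg)
  if (v < min)
    kv_parse_error(sprintf("%s must be >= %d, got %d", what, min, v),
                   line = lineno)
  v
}

#' Parse KR annotation source
#'
#' Parses KR-syntax text into a \code{\link{kr_document}}. Color (default
#' black) and scale (default 10) are stateful: they persist across
#' annotations and into the legend until redefined. \code{at} opens a new
#' annotation context; each drawable command (\code{text}, \code{circle*},
#' \code{polygon*}) emits one annotation with the current state;
#' \code{boxed}/\code{underlined} decorate the text emitted on the
#' immediately preceding line; \code{legend} switches to legend mode;
#' \code{remainder} requests name labels on all non-annotated leaves.
#' Special-symbol codes in text payloads are expanded (see
#' \code{\link{expand_symbols}}). Errors carry the offending line number.
#'
#' @param text KR source: one string (with embedded newlines) or a character
#'   vector of lines.
#' @return A \code{kr_document}.
#' @examples
#' doc <- parse_kr(c("at PINK1", "color 1 0 1", "scale 30", "polygon-filled 3"))
#' doc$annotations[[1]]$scale
#' @export
parse_kr <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  mode <- "annot"
  target <- NULL
  color <- KR_COLORS$black
  scale <- 10L
  annotations <- list()
  legend <- list()
  legend_boxed <- FALSE
  remainder <- FALSE
  last_text <- NULL   # c(where, index) of a text drawable emitted on the previous line
  prev_decor <- NA_character_

  for (i in seq_along(lines)) {
    raw <- trimws2(normalize_tilde(lines[[i]]))
    if (!nzchar(raw) || startsWith(raw, "#")) next
    sp <- regexpr("[[:space:]]", raw)
    cmd <- if (sp == -1L) raw else substr(raw, 1L, sp - 1L)
    arg <- if (sp == -1L) "" else trimws2(substr(raw, sp + 1L, nchar(raw)))
    new_last_text <- NULL

    if (legend_boxed && mode == "legend")
      kv_parse_error("legendBox must be the last line of the legend", line = i)

    emit_shape <- function(kind, n_sides = NA_integer_) {
      if (mode == "annot") {
        if (is.null(target))
          kv_parse_error(sprintf("'%s' before any 'at' command", kind), line = i)
        annotations[[length(annotations) + 1L]] <<- kr_annotation(
          target, kind, color = color, scale = scale, n_sides = n_sides)
      } else {
        legend[[length(legend) + 1L]] <<- legend_drawable(
          kind, color, scale, n_sides = n_sides)
      }
    }

    switch(cmd,
      "at" = {
        if (mode == "legend")
          kv_parse_error("'at' is not allowed inside the legend", line = i)
        if (!nzchar(arg)) kv_parse_error("'at' needs a kinase name", line = i)
        target <- arg
      },
      "color" = { color <- parse_color_arg(arg, i) },
      "scale" = { scale <- parse_int_arg(arg, "scale", i, min = 1L) },
      "text" = {
        payload <- expand_symbols(arg)
        if (mode == "annot") {
          if (is.null(target))
            kv_parse_error("'text' before any 'at' command", line = i)
          if (nchar(payload, type = "chars") > MAX_TEXT_GLYPHS)
            kv_parse_error(sprintf("text payload exceeds %d glyphs after symbol expansion",
                                   MAX_TEXT_GLYPHS), line = i)
          annotations[[length(annotations) + 1L]] <- kr_annotation(
            target, "text", color = color, scale = scale, payload = payload)
          new_last_text <- c("annot", length(annotations))
        } else {
          legend[[length(legend) + 1L]] <- legend_drawable(
            "text", color, scale, payload = payload)
          new_last_text <- c("legend", length(legend))
        }
      },
      "kinase-name" = {
        if (mode == "legend")
          kv_parse_error("'kinase-name' is not allowed inside the legend", line = i)
        if (is.null(target))
          kv_parse_error("'kinase-name' before any 'at' command", line = i)
        annotations[[length(annotations) + 1L]] <- kr_annotation(
          target, "text", color = color, scale = scale, payload = target)
        new_last_text <- c("annot", length(annotations))
      },
      "circle" = emit_shape("circle"),
      "circle-filled" = emit_shape("circle-filled"),
      "circle-lined" = emit_shape("circle-lined"),
      "polygon" = emit_shape("polygon", parse_int_arg(arg, "polygon sides", i, min = 3L)),
      "polygon-filled" = emit_shape("polygon-filled",
                                    parse_int_arg(arg, "polygon sides", i, min = 3L)),
      "polygon-lined" = emit_shape("polygon-lined",
                                   parse_int_arg(arg, "polygon sides", i, min = 3L)),
      "boxed" = ,
      "underlined" = {
        if (is.null(last_text))
          kv_parse_error(sprintf(
            "'%s' must immediately follow a text annotation line", cmd), line = i)
        field <- if (cmd == "boxed") "boxed" else "underlined"
        if (last_text[[1]] == "annot") {
          annotations[[as.integer(last_text[[2]])]][[field]] <- TRUE
        } else {
          legend[[as.integer(last_text[[2]])]][[field]] <- TRUE
        }
        new_last_text <- last_text  # allow "boxed" then "underlined"
      },
      "remainder" = {
        if (mode == "legend")
          kv_parse_error("'remainder' is not allowed inside the legend", line = i)
        remainder <- TRUE
      },
      "legend" = {
        if (mode == "legend")
          kv_parse_error("duplicate 'legend' command", line = i)
        mode <- "legend"
      },
      "space" = {
        if (mode != "legend")
          kv_parse_error("'space' is only allowed inside the legend", line = i)
        legend[[length(legend) + 1L]] <- list(type = "space")
      },
      "next-line" = {
        if (mode != "legend")
          kv_parse_error("'next-line' is only allowed inside the legend", line = i)
        legend[[length(legend) + 1L]] <- list(type = "next-line")
      },
      "legendBox" = {
        if (mode != "legend")
          kv_parse_error("'legendBox' is only allowed inside the legend", line = i)
        legend_boxed <- TRUE
      },
      kv_parse_error(sprintf("unknown command '%s'", cmd), line = i)
    )
    last_text <- new_last_text
  }
  kr_document(annotations, legend, legend_boxed, remainder)
}

#' Read a KR file
#'
#' @param path path to a UTF-8 KR-syntax file.
#' @return A \code{kr_document}.
#' @export
read_kr <- function(path) {
  if (!file.exists(path)) kv_input_error(sprintf("KR file not found: %s", path))
  parse_kr(readLines(path, encoding = "UTF-8", warn = FALSE))
}

fmt_num <- function(x) {
  vapply(x, function(v) format(v, digits = 15, scientific = FALSE, trim = TRUE),
         character(1))
}

emit_state <- function(out, color, scale, cur) {
  if (!identical(cur$color, color))
    out <- c(out, paste("color", paste(fmt_num(color), collapse = " ")))
  if (cur$scale != scale) out <- c(out, paste("scale", scale))
  out
}

drawable_line <- function(d) {
  switch(d$kind,
    text = paste("text", d$payload),
    circle = "circle", `circle-filled` = "circle-filled",
    `circle-lined` = "circle-lined",
    polygon = paste("polygon", d$n_sides),
    `polygon-filled` = paste("polygon-filled", d$n_sides),
    `polygon-lined` = paste("polygon-lined", d$n_sides))
}

#' Serialize a KR document to source text
#'
#' Emits minimal KR syntax: \code{color} and \code{scale} commands appear
#' only where the stateful value changes, and \code{at} only where the
#' target changes. Parsing the emitted text reproduces the document exactly.
#'
#' @param doc a \code{\link{kr_document}}.
#' @return Character vector of KR source lines.
#' @export
serialize_kr <- function(doc) {
  stopifnot(inherits(doc, "kr_document"))
  out <- character(0)
  cur <- list(color = KR_COLORS$black, scale = 10L, target = NULL)
  for (a in doc$annotations) {
    if (is.null(cur$target) || !identical(cur$target, a$target)) {
      out <- c(out, paste("at", a$target))
      cur$target <- a$target
    }
    out <- emit_state(out, a$color, a$scale, cur)
    cur$color <- a$color; cur$scale <- a$scale
    out <- c(out, drawable_line(a))
    if (a$boxed) out <- c(out, "boxed")
    if (a$underlined) out <- c(out, "underlined")
  }
  if (doc$remainder) out <- c(out, "remainder")
  if (length(doc$legend) || doc$legend_boxed) {
    out <- c(out, "legend")
    for (it in doc$legend) {
      if (it$type == "space") { out <- c(out, "space"); next }
      if (it$type == "next-line") { out <- c(out, "next-line"); next }
      out <- emit_state(out, it$color, it$scale, cur)
      cur$color <- it$color; cur$scale <- it$scale
      out <- c(out, drawable_line(it))
      if (isTRUE(it$boxed)) out <- c(out, "boxed")
      if (isTRUE(it$underlined)) out <- c(out, "underlined")
    }
    if (doc$legend_boxed) out <- c(out, "legendBox")
  }
  out
}

#' Write a KR document to a file
#'
#' @param doc a \code{\link{kr_document}}.
#' @param path output path; written atomically.
#' @return The path, invisibly.
#' @export
write_kr <- function(doc, path) {
  atomic_write_lines(serialize_kr(doc), path)
}

#' Check document targets against a registry
#'
#' Produces one diagnostic per annotation whose target is not a registry
#' entry name (matched case-insensitively). Diagnostics are data, not
#' conditions, so batch workflows can degrade gracefully.
#'
#' @param doc a \code{\link{kr_document}}.
#' @param registry a \code{\link{kinase_registry}}.
#' @param severity \code{"warning"} (default) or \code{"error"}; recorded on
#'   each diagnostic.
#' @return Data frame with columns \code{annotation} (index), \code{target},
#'   \code{severity}, \code{message}; zero rows when all targets resolve.
#' @export
validate_kr <- function(doc, registry, severity = c("warning", "error")) {
  stopifnot(inherits(doc, "kr_document"), inherits(registry, "kinase_registry"))
  severity <- match.arg(severity)
  known <- tolower(leaf_names(registry, include_atypical = TRUE))
  targets <- vapply(doc$annotations, `[[`, character(1), "target")
  bad <- which(!(tolower(targets) %in% known))
  data.frame(annotation = bad,
             target = targets[bad],
             severity = rep(severity, length(bad)),
             message = sprintf("unknown kinase '%s'", targets[bad]),
             stringsAsFactors = FALSE)
}
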
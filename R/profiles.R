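# Inhibitor binding profiles: tab-separated affinity matrices (Kd, IC50 or
# any measure where lower means stronger) turned into annotated-tree
# documents. Cell semantics: a positive number is a measured affinity, "-"
# marks a tested combination with no observed effect, "NA" marks an
# untested combination. An optional threshold (in table units) reclassifies
# every value at or above it as no-effect.

#' Construct a binding table
#'
#' @param values numeric kinase x inhibitor matrix; \code{NA} for untested
#'   cells or cells without effect (see \code{status}).
#' @param status character matrix of the same shape with entries
#'   \code{"binder"}, \code{"no_effect"}, \code{"na"}.
#' @param kinase_ids row identifiers (Manning name, UniProt ID or IPI).
#' @param inhibitors ordered column names.
#' @param units \code{"nM"} or \code{"uM"}.
#' @param threshold optional no-effect threshold in table units.
#' @return A \code{binding_table}.
#' @export
binding_table <- function(values, status, kinase_ids, inhibitors,
                          units = c("nM", "uM"), threshold = NULL) {
  units <- normalize_units(units[1])
  if (!is.matrix(values) || nrow(values) != length(kinase_ids) ||
      ncol(values) != length(inhibitors))
    kv_validation_error("values must be a |kinases| x |inhibitors| matrix")
  stopifnot(identical(dim(values), dim(status)))
  if (any(values[status == "binder"] <= 0, na.rm = TRUE))
    kv_validation_error("affinity values must be positive")
  if (!is.null(threshold)) {
    threshold <- as.numeric(threshold)
    if (is.na(threshold) || threshold <= 0)
      kv_validation_error("threshold must be a positive number")
    reclass <- status == "binder" & values >= threshold
    status[reclass] <- "no_effect"
    values[reclass] <- NA_real_
  }
  dimnames(values) <- dimnames(status) <- list(kinase_ids, inhibitors)
  structure(list(values = values, status = status,
                 kinase_ids = as.character(kinase_ids),
                 inhibitors = as.character(inhibitors),
                 units = units, threshold = threshold),
            class = "binding_table")
}

normalize_units <- function(u) {
  u <- trimws2(as.character(u))
  if (u %in% c("uM", "µM", "um", "µM")) return("uM")
  if (tolower(u) == "nm") return("nM")
  kv_validation_error(sprintf("units must be nM or uM, got '%s'", u))
}

#' @export
print.binding_table <- function(x, ...) {
  cat(sprintf("<binding_table> %d kinase(s) x %d inhibitor(s), units %s%s\n",
              length(x$kinase_ids), length(x$inhibitors), x$units,
              if (!is.null(x$threshold))
                sprintf(", no-effect threshold %g %s", x$threshold, x$units)
              else ""))
  cat(sprintf("  binders %d, no-effect %d, untested %d\n",
              sum(x$status == "binder"), sum(x$status == "no_effect"),
              sum(x$status == "na")))
  invisible(x)
}

#' Read a tab-separated affinity matrix
#'
#' First row: inhibitor names; first column: kinase identifiers (Manning
#' name, UniProt ID or IPI). Cells: positive numbers (affinity in
#' \code{units}), \code{"-"} (tested, no effect), \code{"NA"} (untested).
#' With a threshold, values at or above it are reclassified as no-effect.
#'
#' @param path path to the TSV file.
#' @param units \code{"nM"} or \code{"uM"}; required to label legends.
#' @param threshold optional no-effect threshold in table units.
#' @return A \code{\link{binding_table}}.
#' @export
read_binding_table <- function(path, units = c("nM", "uM"), threshold = NULL) {
  if (!file.exists(path)) kv_input_error(sprintf("affinity file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws2(lines))]
  if (length(lines) < 1L) kv_format_error("affinity file is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws2(parts[[1]])
  inhibitors <- header[-1]
  inhibitors <- inhibitors[nzchar(inhibitors)]
  if (!length(inhibitors)) kv_format_error("no inhibitor columns in header row")
  rows <- parts[-1]
  kinase_ids <- character(length(rows))
  values <- matrix(NA_real_, length(rows), length(inhibitors))
  status <- matrix("na", length(rows), length(inhibitors))
  for (i in seq_along(rows)) {
    row <- trimws2(rows[[i]])
    if (length(row) != length(inhibitors) + 1L)
      kv_format_error(sprintf("row %d has %d cells, expected %d",
                              i + 1L, length(row), length(inhibitors) + 1L))
    kinase_ids[i] <- normalize_tilde(row[1])
    for (j in seq_along(inhibitors)) {
      cell <- row[j + 1L]
      if (cell == "-") { status[i, j] <- "no_effect"; next }
      if (toupper(cell) == "NA" || cell == "") next
      v <- suppressWarnings(as.numeric(cell))
      if (is.na(v))
        kv_format_error(sprintf(
          "non-numeric cell '%s' at row %d, column %s (use '-' for no effect, 'NA' for untested)",
          cell, i + 1L, inhibitors[j]))
      if (v <= 0)
        kv_format_error(sprintf("non-positive affinity %g at row %d, column %s",
                                v, i + 1L, inhibitors[j]))
      values[i, j] <- v
      status[i, j] <- "binder"
    }
  }
  if (any(duplicated(kinase_ids)))
    kv_validation_error("duplicate kinase identifiers in affinity table")
  binding_table(values, status, kinase_ids, inhibitors, units = units,
                threshold = threshold)
}

#' Radius-encoding and styling options for binding profiles
#'
#' Affinities span orders of magnitude, so circle size is log-encoded:
#' \code{scale = s_min + (s_max - s_min) * (log10(vc) - log10(v)) /
#' (log10(vc) - log10(vf))}, clamped to \code{[s_min, s_max]}, where
#' \code{vc} is the no-effect threshold (or the column maximum) and
#' \code{vf} the column minimum. Lower values (stronger binding) therefore
#' give strictly larger circles.
#'
#' @param s_min,s_max smallest/largest binder circle diameter, points.
#' @param no_effect_circles draw small grey circles for tested-but-no-effect
#'   cells (automatically disabled on combination plots with more than one
#'   inhibitor).
#' @param no_effect_scale diameter of the grey no-effect circles, points.
#' @param color RGB triple for single-inhibitor plots.
#' @return A \code{profile_style} list.
#' @export
profile_style <- function(s_min = 6, s_max = 36, no_effect_circles = TRUE,
                          no_effect_scale = 4, color = c(1, 0, 0)) {
  if (s_min <= 0 || s_max < s_min)
    kv_validation_error("need 0 < s_min <= s_max")
  structure(list(s_min = as.integer(round(s_min)),
                 s_max = as.integer(round(s_max)),
                 no_effect_circles = isTRUE(no_effect_circles),
                 no_effect_scale = as.integer(round(no_effect_scale)),
                 color = as.numeric(color)),
            class = "profile_style")
}

# Map affinity values of one inhibitor column to integer circle diameters.
profile_scales <- function(v, style, threshold = NULL) {
  if (!length(v)) return(integer(0))
  vc <- threshold %||% max(v)
  vf <- min(v)
  if (!is.finite(log10(vf)) || vc <= vf) {
    s <- rep(style$s_max, length(v))
  } else {
    s <- style$s_min + (style$s_max - style$s_min) *
      (log10(vc) - log10(v)) / (log10(vc) - log10(vf))
  }
  as.integer(round(pmin(style$s_max, pmax(style$s_min, s))))
}

resolve_table_ids <- function(ids, registry) {
  if (is.null(registry)) return(ids)
  out <- vapply(ids, function(id) {
    for (f in c("name", "uniprot", "ipi")) {
      hit <- resolve_kinase(registry, id, fields = f)
      if (nrow(hit)) return(hit$name[1])
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(out))
    warning(sprintf("skipping unresolved kinase identifier(s): %s",
                    paste(ids[is.na(out)], collapse = ", ")), call. = FALSE)
  out
}

units_label <- function(units) if (units == "uM") "µM" else "nM"

profile_legend <- function(entries, units, threshold, style, show_no_effect) {
  items <- list()
  for (k in seq_len(nrow(entries))) {
    if (k > 1) items[[length(items) + 1L]] <- list(type = "next-line")
    items[[length(items) + 1L]] <- legend_drawable(
      "circle-filled", color = as.numeric(entries[k, c("r", "g", "b")]),
      scale = 10L)
    items[[length(items) + 1L]] <- list(type = "space")
    items[[length(items) + 1L]] <- legend_drawable(
      "text", color = KR_COLORS$black, scale = 10L,
      payload = sprintf("%s, affinity in %s", entries$name[k], units_label(units)))
  }
  items[[length(items) + 1L]] <- list(type = "next-line")
  items[[length(items) + 1L]] <- legend_drawable(
    "text", color = KR_COLORS$black, scale = 10L,
    payload = "bigger circle = stronger binding")
  if (show_no_effect) {
    items[[length(items) + 1L]] <- list(type = "next-line")
    items[[length(items) + 1L]] <- legend_drawable(
      "circle-filled", color = KR_COLORS$grey, scale = style$no_effect_scale)
    items[[length(items) + 1L]] <- list(type = "space")
    payload <- if (is.null(threshold)) "tested, no effect"
      else sprintf("no effect (>= %s %s)", fmt_num(threshold), units_label(units))
    items[[length(items) + 1L]] <- legend_drawable(
      "text", color = KR_COLORS$black, scale = 10L, payload = payload)
  }
  items
}

encode_columns <- function(table, cols, colors, style, registry) {
  leaves <- resolve_table_ids(table$kinase_ids, registry)
  show_no_effect <- style$no_effect_circles && length(cols) == 1L
  anns <- list()
  for (ci in seq_along(cols)) {
    j <- cols[ci]
    col_rgb <- colors[[ci]]
    binder <- table$status[, j] == "binder" & !is.na(leaves)
    v <- table$values[binder, j]
    scales <- profile_scales(v, style, table$threshold)
    tg <- leaves[binder]
    for (k in seq_along(tg))
      anns[[length(anns) + 1L]] <- kr_annotation(
        tg[k], "circle-filled", color = col_rgb, scale = scales[k])
    if (show_no_effect) {
      ne <- table$status[, j] == "no_effect" & !is.na(leaves)
      for (t in leaves[ne])
        anns[[length(anns) + 1L]] <- kr_annotation(
          t, "circle-filled", color = KR_COLORS$grey,
          scale = style$no_effect_scale)
    }
  }
  entries <- data.frame(name = table$inhibitors[cols],
                        r = vapply(colors, `[`, numeric(1), 1),
                        g = vapply(colors, `[`, numeric(1), 2),
                        b = vapply(colors, `[`, numeric(1), 3),
                        stringsAsFactors = FALSE)
  legend <- profile_legend(entries, table$units, table$threshold, style,
                           show_no_effect)
  kr_document(anns, legend = legend, legend_boxed = TRUE)
}

#' Encode one inhibitor's binding profile as a KR document
#'
#' Binders become filled circles whose diameter decreases log-linearly with
#' the affinity value (lower Kd / stronger binding = bigger circle, see
#' \code{\link{profile_style}}); tested combinations with no effect become
#' small grey circles; untested (\code{NA}) cells produce no annotation. An
#' auto-generated boxed legend states the inhibitor, the units and the size
#' encoding. The result is an ordinary \code{\link{kr_document}} that can be
#' serialized, re-parsed and further edited.
#'
#' @param table a \code{\link{binding_table}}.
#' @param inhibitor inhibitor (column) name.
#' @param style a \code{\link{profile_style}}.
#' @param registry optional \code{\link{kinase_registry}} used to resolve
#'   row identifiers (name, then UniProt, then IPI; first hit wins,
#'   unresolved rows are reported and skipped). Without a registry, row
#'   identifiers are used as leaf names directly.
#' @return A \code{kr_document}.
#' @export
encode_profile <- function(table, inhibitor, style = profile_style(),
                           registry = NULL) {
  stopifnot(inherits(table, "binding_table"), inherits(style, "profile_style"))
  j <- match(inhibitor, table$inhibitors)
  if (is.na(j))
    kv_input_error(sprintf("unknown inhibitor '%s'", inhibitor))
  encode_columns(table, j, list(style$color), style, registry)
}

PROFILE_COLOR_CYCLE <- c("red", "blue", "green", "orange", "magenta", "cyan")
MAX_PER_PLOT <- 6L

#' Partition inhibitors into combination plots
#'
#' Splits the inhibitor columns, in their input order, into consecutive
#' groups of at most \code{per_plot} (maximum 6) and encodes one KR
#' document per group. Within a group each inhibitor gets a distinct color
#' from a fixed six-color cycle. When a group holds more than one
#' inhibitor, grey no-effect circles are disabled.
#'
#' @param table a \code{\link{binding_table}}.
#' @param per_plot inhibitors per plot, between 1 and 6.
#' @param style a \code{\link{profile_style}}.
#' @param registry optional registry for identifier resolution.
#' @return Named list of \code{kr_document}s, one per group, named by the
#'   inhibitors it covers.
#' @export
combination_plots <- function(table, per_plot = 1L, style = profile_style(),
                              registry = NULL) {
  stopifnot(inherits(table, "binding_table"))
  if (length(per_plot) != 1L || is.na(per_plot) ||
      per_plot != as.integer(per_plot) || per_plot < 1L || per_plot > MAX_PER_PLOT)
    kv_validation_error(sprintf("per_plot must be an integer between 1 and %d",
                                MAX_PER_PLOT))
  per_plot <- as.integer(per_plot)
  n <- length(table$inhibitors)
  groups <- split(seq_len(n), ceiling(seq_len(n) / per_plot))
  docs <- lapply(groups, function(cols) {
    colors <- lapply(PROFILE_COLOR_CYCLE[seq_along(cols)],
                     function(nm) KR_COLORS[[nm]])
    if (length(cols) == 1L && per_plot == 1L) colors <- list(style$color)
    encode_columns(table, cols, colors, style, registry)
  })
  names(docs) <- vapply(groups, function(cols)
    paste(table$inhibitors[cols], collapse = "_"), character(1))
  docs
}
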
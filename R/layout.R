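# Leaf coordinates for the kinome tree: coordinate-template files and a
# deterministic schematic layout generated from the group/family/subfamily
# classification. Coordinate convention: origin at the TOP-LEFT of the
# canvas, y increases downward, units are points (1/72 inch).
#
# Template 1 carries only the typical-kinase tree; template 2 additionally
# places the atypical kinases in a small detached sub-tree anchored at the
# bottom left, and its coordinate set is a superset of template 1's.

#' Construct a tree coordinate template
#'
#' @param coords data frame with columns \code{leaf}, \code{x}, \code{y}
#'   (points, top-left origin, y down).
#' @param canvas numeric \code{c(width, height)} in points.
#' @param template_id 1 (typical kinases only) or 2 (typical + atypical
#'   sub-tree).
#' @param edges optional data frame of backbone segments with columns
#'   \code{x1}, \code{y1}, \code{x2}, \code{y2}.
#' @return A \code{tree_template}.
#' @export
tree_template <- function(coords, canvas, template_id = 1L, edges = NULL) {
  canvas <- as.numeric(canvas)
  if (length(canvas) != 2L || anyNA(canvas) || any(canvas <= 0))
    kv_validation_error("canvas must be positive c(width, height)")
  coords <- as.data.frame(coords, stringsAsFactors = FALSE)
  if (!nrow(coords)) {
    coords <- data.frame(leaf = character(0), x = numeric(0), y = numeric(0))
  } else {
    if (!all(c("leaf", "x", "y") %in% names(coords)))
      kv_format_error("coords needs columns leaf, x, y")
    coords <- coords[c("leaf", "x", "y")]
    coords$leaf <- normalize_tilde(as.character(coords$leaf))
    coords$x <- as.numeric(coords$x); coords$y <- as.numeric(coords$y)
    dup <- coords$leaf[duplicated(coords$leaf)]
    if (length(dup))
      kv_validation_error(sprintf("duplicate leaf coordinates: %s",
                                  paste(unique(dup), collapse = ", ")))
    out_of_canvas <- coords$x < 0 | coords$x > canvas[1] |
                     coords$y < 0 | coords$y > canvas[2] |
                     is.na(coords$x) | is.na(coords$y)
    if (any(out_of_canvas))
      kv_validation_error(sprintf("coordinates outside the %g x %g canvas: %s",
                                  canvas[1], canvas[2],
                                  paste(coords$leaf[out_of_canvas], collapse = ", ")))
  }
  if (!template_id %in% c(1L, 2L))
    kv_validation_error("template_id must be 1 or 2")
  rownames(coords) <- NULL
  structure(list(coords = coords, canvas = canvas,
                 template_id = as.integer(template_id), edges = edges),
            class = "tree_template")
}

#' @export
print.tree_template <- function(x, ...) {
  cat(sprintf("<tree_template> id %d, %g x %g pt canvas, %d leaf coordinate(s), %d backbone segment(s)\n",
              x$template_id, x$canvas[1], x$canvas[2], nrow(x$coords),
              if (is.null(x$edges)) 0L else nrow(x$edges)))
  invisible(x)
}

#' Look up leaf coordinates (case-insensitive)
#'
#' @param template a \code{tree_template}.
#' @param leaves character vector of leaf names.
#' @return Data frame of \code{leaf}, \code{x}, \code{y} rows (NA for
#'   missing leaves), one per query, in query order.
#' @export
leaf_coords <- function(template, leaves) {
  stopifnot(inherits(template, "tree_template"))
  leaves <- normalize_tilde(leaves)
  idx <- match(tolower(leaves), tolower(template$coords$leaf))
  data.frame(leaf = leaves,
             x = template$coords$x[idx],
             y = template$coords$y[idx],
             stringsAsFactors = FALSE)
}

#' Read a coordinate-template file
#'
#' Format: UTF-8 TSV whose first line is
#' \code{#canvas<TAB>width<TAB>height<TAB>template_id}, followed by
#' \code{leaf<TAB>x<TAB>y} rows. Coordinates outside the canvas and
#' duplicate leaves are rejected.
#'
#' @param path path to the template file.
#' @return A \code{tree_template}.
#' @export
read_template <- function(path) {
  if (!file.exists(path)) kv_input_error(sprintf("template file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws2(lines))]
  if (!length(lines) || !startsWith(lines[1], "#canvas"))
    kv_format_error("template file must start with a '#canvas' header line")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 4L)
    kv_format_error("'#canvas' header needs width, height and template_id fields")
  canvas <- suppressWarnings(as.numeric(hdr[2:3]))
  template_id <- suppressWarnings(as.integer(hdr[4]))
  if (anyNA(canvas) || is.na(template_id))
    kv_format_error("malformed '#canvas' header")
  body <- lines[-1]
  coords <- if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) < 3L))
      kv_format_error("template rows must be leaf<TAB>x<TAB>y")
    data.frame(leaf = vapply(parts, `[[`, character(1), 1),
               x = suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2))),
               y = suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3))),
               stringsAsFactors = FALSE)
  } else {
    data.frame(leaf = character(0), x = numeric(0), y = numeric(0))
  }
  tree_template(coords, canvas, template_id)
}

#' Write a coordinate template to a file
#'
#' Inverse of \code{\link{read_template}} on coordinate content.
#'
#' @param template a \code{tree_template}.
#' @param path output path; written atomically.
#' @return The path, invisibly.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "tree_template"))
  hdr <- paste("#canvas", fmt_num(template$canvas[1]), fmt_num(template$canvas[2]),
               template$template_id, sep = "\t")
  rows <- if (nrow(template$coords))
    paste(template$coords$leaf, fmt_num(template$coords$x),
          fmt_num(template$coords$y), sep = "\t")
  else character(0)
  atomic_write_lines(c(hdr, rows), path)
}

#' Generate a schematic kinome layout
#'
#' Builds a deterministic, seed-free schematic dendrogram layout from the
#' registry classification: leaves are ordered by group, then family, then
#' subfamily, then name, so all leaves of one group are contiguous (and
#' families contiguous within groups). Branch lengths are uniform; the
#' original tree's sequence-similarity branch geometry is not reproduced
#' (users with a captured coordinate file can supply it via
#' \code{\link{read_template}}). For template 2, atypical entries are placed
#' in a detached sub-tree block anchored at the bottom left.
#'
#' @param registry a non-empty \code{\link{kinase_registry}}.
#' @param style \code{"rectangular"} (leaves in a right-hand column) or
#'   \code{"radial"} (leaves on a circle).
#' @param canvas \code{c(width, height)} in points.
#' @param template_id 1 or 2; atypical entries get coordinates only for 2.
#' @param min_spacing minimum distance between adjacent leaves, points.
#' @param margin canvas margin in points.
#' @return A \code{tree_template} with backbone edges.
#' @export
generate_layout <- function(registry, style = c("rectangular", "radial"),
                            canvas = c(900, 1250), template_id = 1L,
                            min_spacing = 1, margin = 40) {
  stopifnot(inherits(registry, "kinase_registry"))
  style <- match.arg(style)
  canvas <- as.numeric(canvas)
  e <- registry$entries
  if (!nrow(e)) kv_validation_error("registry is empty")
  typ <- e[!e$is_atypical, , drop = FALSE]
  ord <- order(typ$group, typ$family, typ$subfamily, typ$name, method = "radix")
  typ <- typ[ord, , drop = FALSE]
  n <- nrow(typ)
  edges <- NULL

  if (style == "rectangular") {
    usable <- canvas[2] - 2 * margin
    if (n > 1 && usable / (n - 1) < min_spacing)
      kv_error(sprintf("canvas too small: %d leaves need >= %g pt of height",
                       n, (n - 1) * min_spacing + 2 * margin), "kv_layout_error")
    y <- if (n == 1) canvas[2] / 2 else margin + usable * (seq_len(n) - 1) / (n - 1)
    x <- rep(canvas[1] - margin, n)
    coords <- data.frame(leaf = typ$name, x = x, y = y, stringsAsFactors = FALSE)
    # backbone: root -> one node per group -> leaves
    root <- c(margin, canvas[2] / 2)
    grp_x <- margin + (canvas[1] - 2 * margin) * 0.45
    edges <- do.call(rbind, lapply(unique(typ$group), function(g) {
      idx <- which(typ$group == g)
      gy <- mean(y[idx])
      rbind(data.frame(x1 = root[1], y1 = root[2], x2 = grp_x, y2 = gy),
            data.frame(x1 = grp_x, y1 = y[idx], x2 = x[idx], y2 = y[idx]))
    }))
  } else {
    cx <- canvas[1] / 2; cy <- canvas[2] / 2
    r <- min(canvas) / 2 - margin
    if (r <= 0) kv_error("canvas too small for the margin", "kv_layout_error")
    theta <- -pi / 2 + 2 * pi * (seq_len(n) - 1) / n
    if (n > 1) {
      chord <- 2 * r * sin(pi / n)
      if (chord < min_spacing)
        kv_error(sprintf("canvas too small: %d leaves on radius %g give %.2f pt spacing",
                         n, r, chord), "kv_layout_error")
    }
    x <- cx + r * cos(theta)
    y <- cy + r * sin(theta)
    coords <- data.frame(leaf = typ$name, x = x, y = y, stringsAsFactors = FALSE)
    edges <- data.frame(x1 = cx, y1 = cy, x2 = cx + 0.85 * r * cos(theta),
                        y2 = cy + 0.85 * r * sin(theta))
  }

  if (template_id == 2L) {
    atyp <- e[e$is_atypical, , drop = FALSE]
    if (nrow(atyp)) {
      atyp <- atyp[order(atyp$name, method = "radix"), , drop = FALSE]
      m <- nrow(atyp)
      block_h <- max(min_spacing * (m - 1), min(120, canvas[2] / 6))
      ay <- canvas[2] - margin - block_h +
        (if (m == 1) block_h / 2 else block_h * (seq_len(m) - 1) / (m - 1))
      ax <- rep(margin + 60, m)
      coords <- rbind(coords,
                      data.frame(leaf = atyp$name, x = ax, y = ay,
                                 stringsAsFactors = FALSE))
      edges <- rbind(edges,
                     data.frame(x1 = margin, y1 = canvas[2] - margin - block_h / 2,
                                x2 = ax, y2 = ay))
    }
  }
  # 6-decimal grid (sub-micron at 72 dpi) so written templates re-read exactly
  coords$x <- round(coords$x, 6); coords$y <- round(coords$y, 6)
  tree_template(coords, canvas, template_id, edges = edges)
}

#' Choose the template required by a document
#'
#' Returns 2 whenever any annotation targets an atypical registry entry
#' (those only appear on the extended template); otherwise the user's
#' preference (default 1).
#'
#' @param doc a \code{\link{kr_document}}.
#' @param registry a \code{\link{kinase_registry}}.
#' @param preferred template id to use when no atypical kinase is annotated.
#' @return 1 or 2.
#' @export
select_template <- function(doc, registry, preferred = 1L) {
  stopifnot(inherits(doc, "kr_document"), inherits(registry, "kinase_registry"))
  atyp <- tolower(registry$entries$name[registry$entries$is_atypical])
  targets <- tolower(vapply(doc$annotations, `[[`, character(1), "target"))
  if (length(targets) && any(targets %in% atyp)) 2L else as.integer(preferred)
}
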
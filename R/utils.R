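# Shared internal helpers: error classes, seeded RNG scoping, atomic writes.

kv_error <- function(msg, class, call = NULL, ...) {
  stop(structure(
    class = c(class, "kinomeviz_error", "error", "condition"),
    list(message = msg, call = call, ...)
  ))
}

kv_format_error <- function(msg, ...) kv_error(msg, "kv_format_error", ...)
kv_validation_error <- function(msg, ...) kv_error(msg, "kv_validation_error", ...)
kv_parse_error <- function(msg, line = NA_integer_, ...) {
  if (!is.na(line)) msg <- sprintf("line %d: %s", line, msg)
  kv_error(msg, "kv_parse_error", line = line, ...)
}
kv_render_error <- function(msg, ...) kv_error(msg, "kv_render_error", ...)
kv_input_error <- function(msg, ...) kv_error(msg, "kv_input_error", ...)

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# All file outputs go through temp-file + rename so partial writes never land.
atomic_write_lines <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "wb")
  writeLines(lines, con, sep = "\n", useBytes = FALSE)
  close(con)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

trimws2 <- function(x) trimws(x, which = "both")

# The paper prints the second-catalytic-domain tag with a tilde operator
# glyph; normalize it (and the plain ASCII form) to "~b".
normalize_tilde <- function(x) {
  gsub("∼", "~", x, fixed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

is_protein_sequence <- function(s, allow_extended = TRUE) {
  if (is.na(s)) return(FALSE)
  if (!nzchar(s)) return(TRUE)
  extra <- if (allow_extended) "BJOUXZ*" else ""
  grepl(sprintf("^[%s%s]+$", "ACDEFGHIKLMNPQRSTVWY", extra), toupper(s))
}
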
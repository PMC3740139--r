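# KR language: parsing, stateful color/scale semantics, symbol expansion,
# serialization round trips and target validation.

test_that("the three-kinase worked example parses to the printed attributes", {
  doc <- parse_kr(EX1_SOURCE)
  expect_length(doc$annotations, 3)
  a <- doc$annotations
  expect_identical(a[[1]]$target, "PINK1")
  expect_identical(a[[1]]$kind, "polygon-filled")
  expect_identical(a[[1]]$n_sides, 3L)
  expect_identical(a[[1]]$color, c(1, 0, 1))
  expect_identical(a[[1]]$scale, 30L)
  expect_identical(a[[2]]$target, "MPSK1")
  expect_identical(a[[2]]$kind, "circle-lined")
  expect_identical(a[[2]]$color, c(0.92, 0.08, 0.08))
  expect_identical(a[[2]]$scale, 20L)
  expect_identical(a[[3]]$target, "BIKE")
  expect_identical(a[[3]]$kind, "text")
  expect_identical(a[[3]]$payload, "BIKE")
  expect_identical(a[[3]]$color, c(0, 0.67, 0))
  expect_identical(a[[3]]$scale, 10L)
})

test_that("color and scale default to black/10 and persist until redefined", {
  doc <- parse_kr(c("at PINK1", "circle"))
  expect_identical(doc$annotations[[1]]$scale, 10L)
  expect_identical(doc$annotations[[1]]$color, c(0, 0, 0))

  doc <- parse_kr(c("at A", "scale 20", "circle", "at B", "circle"))
  expect_identical(vapply(doc$annotations, `[[`, integer(1), "scale"),
                   c(20L, 20L))

  # property: each annotation carries the latest preceding color/scale
  set.seed(7)
  for (rep in 1:20) {
    lines <- character(0)
    expected <- list()
    col <- c(0, 0, 0); sc <- 10L
    lines <- c(lines, "at X")
    for (k in 1:10) {
      r <- runif(1)
      if (r < 0.3) { sc <- sample(1:50, 1); lines <- c(lines, paste("scale", sc)) }
      else if (r < 0.6) { col <- round(runif(3), 2)
                          lines <- c(lines, paste("color", paste(col, collapse = " "))) }
      else { lines <- c(lines, "circle")
             expected[[length(expected) + 1]] <- list(color = col, scale = sc) }
    }
    doc <- parse_kr(lines)
    expect_length(doc$annotations, length(expected))
    for (i in seq_along(expected)) {
      expect_identical(doc$annotations[[i]]$color, expected[[i]]$color)
      expect_identical(doc$annotations[[i]]$scale, as.integer(expected[[i]]$scale))
    }
  }
})

test_that("predefined color names map to their RGB triples", {
  doc <- parse_kr(c("at A", "color orange", "circle", "color green", "circle"))
  expect_identical(doc$annotations[[1]]$color, c(1, 0.65, 0))
  expect_identical(doc$annotations[[2]]$color, c(0, 0.67, 0))
})

test_that("malformed input fails with the offending line number", {
  err <- expect_error(parse_kr(c("at A", "circle", "wiggle")),
                      class = "kv_parse_error")
  expect_match(conditionMessage(err), "line 3")
  expect_error(parse_kr("circle"), class = "kv_parse_error")
  expect_error(parse_kr(c("at A", "color 1 0 2", "circle")),
               class = "kv_parse_error")
  expect_error(parse_kr(c("at A", "color 0.5 0.5", "circle")),
               class = "kv_parse_error")
  expect_error(parse_kr(c("at A", "polygon 2")), class = "kv_parse_error")
  expect_error(parse_kr(c("at A", "scale 12.5", "circle")),
               class = "kv_parse_error")
  expect_error(parse_kr(c("at A", "boxed")), class = "kv_parse_error")
  expect_error(parse_kr(c("at A", "circle", "boxed")), class = "kv_parse_error")
  expect_error(parse_kr(c("at A", paste("text", strrep("x", 26)))),
               class = "kv_parse_error")
  # 25 glyphs are fine, also when symbol codes expand to single glyphs
  ok <- parse_kr(c("at A", paste("text", strrep("x", 25))))
  expect_identical(nchar(ok$annotations[[1]]$payload), 25L)
  ok2 <- parse_kr(c("at A", paste0("text [alpha]", strrep("x", 24))))
  expect_identical(nchar(ok2$annotations[[1]]$payload, type = "chars"), 25L)
})

test_that("boxed/underlined decorate the immediately preceding text line", {
  doc <- parse_kr(c("at A", "text hi", "boxed", "underlined"))
  expect_true(doc$annotations[[1]]$boxed)
  expect_true(doc$annotations[[1]]$underlined)
  # a drawable in between breaks adjacency
  expect_error(parse_kr(c("at A", "text hi", "circle", "boxed")),
               class = "kv_parse_error")
})

test_that("symbol codes expand to glyphs and expansion is idempotent", {
  expect_identical(expand_symbols("[alpha]"), "α")
  expect_identical(expand_symbols("IC[lesserequal]50"), "IC≤50")
  expect_identical(expand_symbols("plain"), "plain")
  expect_identical(expand_symbols("[Delta][delta]"), "Δδ")
  # every code in the table maps to a distinct single glyph
  tab <- kinomeviz:::KR_SYMBOLS
  expect_length(tab, 43)
  expect_identical(anyDuplicated(unname(tab)), 0L)
  for (code in names(tab))
    expect_identical(expand_symbols(sprintf("[%s]", code)), unname(tab[code]))
  # idempotent on its own output
  once <- expand_symbols("a[alpha]b[heart]c")
  expect_identical(expand_symbols(once), once)
  # unknown codes warn and stay verbatim
  expect_warning(out <- expand_symbols("x[notacode]y"), "notacode")
  expect_identical(out, "x[notacode]y")
})

test_that("legend programs parse into flat item sequences", {
  doc <- parse_kr(c(EX1_SOURCE, EX2_LEGEND_SOURCE))
  expect_length(doc$annotations, 3)
  expect_true(doc$legend_boxed)
  types <- vapply(doc$legend, `[[`, character(1), "type")
  expect_identical(sum(types == "next-line"), 2L)
  # three lines: shape+text, shape+text, text
  kinds <- vapply(doc$legend, function(i)
    if (i$type == "drawable") i$kind else i$type, character(1))
  expect_identical(kinds,
    c("polygon-filled", "space", "text", "next-line",
      "circle-lined", "space", "text", "next-line", "text"))
  # state set before the legend flows into it
  first_shape <- doc$legend[[1]]
  expect_identical(first_shape$scale, 20L)
  expect_identical(first_shape$color, c(1, 0, 1))
  # legend text is not subject to the 25-glyph annotation limit
  expect_identical(doc$legend[[3]]$payload,
                   "PINK1 is annotated with a pink triangle")
  # legendBox must be terminal, legend commands must stay in the legend
  expect_error(parse_kr(c("legend", "legendBox", "circle")),
               class = "kv_parse_error")
  expect_error(parse_kr(c("at A", "space")), class = "kv_parse_error")
  expect_error(parse_kr(c("legend", "at A")), class = "kv_parse_error")
})

test_that("serialization emits minimal state commands and re-parses exactly", {
  doc <- parse_kr(c(EX1_SOURCE, "remainder", EX2_LEGEND_SOURCE))
  txt <- serialize_kr(doc)
  expect_identical(parse_kr(txt), doc)
  # repeated state is not re-emitted
  doc2 <- parse_kr(c("at A", "scale 20", "circle", "at B", "scale 20", "circle"))
  expect_identical(sum(startsWith(serialize_kr(doc2), "scale")), 1L)
  expect_identical(serialize_kr(kr_document()), character(0))
})

test_that("parse/serialize round trip is the identity on random documents", {
  set.seed(123)
  for (i in 1:120) {
    doc <- random_doc()
    expect_identical(parse_kr(serialize_kr(doc)), doc)
  }
})

test_that("target validation reports one diagnostic per unknown kinase", {
  reg <- tiny_registry()
  ok <- parse_kr(c("at PINK1", "circle"))
  expect_identical(nrow(validate_kr(ok, reg)), 0L)
  bad <- parse_kr(c("at NOT_A_KINASE", "circle"))
  d <- validate_kr(bad, reg)
  expect_identical(nrow(d), 1L)
  expect_identical(d$target, "NOT_A_KINASE")
  mixed <- parse_kr(c(
    "at Abl", "circle", "at Nope1", "circle", "at Src", "circle",
    "at BIKE", "circle", "at Nope2", "circle", "at MPSK1", "circle",
    "at pink1", "circle"))
  expect_identical(nrow(validate_kr(mixed, reg)), 2L)
  expect_identical(validate_kr(mixed, reg, severity = "error")$severity,
                   rep("error", 2))
})
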
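# Render planning (z-order, remainder labels, legend placement) and the
# deterministic vector writers.

make_template <- function(reg = tiny_registry(), id = 2L) {
  generate_layout(reg, template_id = id, canvas = c(500, 700))
}

test_that("annotations are planned in non-increasing scale order, ties stable", {
  tpl <- make_template()
  doc <- parse_kr(EX1_SOURCE)
  plan <- plan_render(doc, tpl)
  expect_identical(plan$annotations$target, c("PINK1", "MPSK1", "BIKE"))
  expect_true(all(diff(plan$annotations$scale) <= 0))

  tie <- parse_kr(c("at Abl", "scale 15", "circle", "at Src", "circle",
                    "at BIKE", "scale 40", "circle"))
  p2 <- plan_render(tie, tpl)
  expect_identical(p2$annotations$target, c("BIKE", "Abl", "Src"))

  # property: z-order invariant over random plans
  set.seed(5)
  for (i in 1:30) {
    doc <- random_doc(n_annotations = sample(1:12, 1), with_legend = FALSE)
    p <- plan_render(doc, tpl)
    expect_true(all(diff(p$annotations$scale) <= 0))
    expect_identical(nrow(p$annotations), length(doc$annotations))
  }
})

test_that("every annotation is centered at its leaf coordinate", {
  tpl <- make_template()
  doc <- parse_kr(c("at PINK1", "scale 24", "circle", "at mpsk1", "circle"))
  plan <- plan_render(doc, tpl)
  for (i in seq_len(nrow(plan$annotations))) {
    pos <- leaf_coords(tpl, plan$annotations$target[i])
    expect_identical(plan$annotations$x[i], pos$x)
    expect_identical(plan$annotations$y[i], pos$y)
  }
  expect_error(plan_render(parse_kr(c("at Missing", "circle")), tpl),
               class = "kv_render_error")
  err <- tryCatch(plan_render(parse_kr(c("at Missing", "circle")), tpl),
                  error = identity)
  expect_match(conditionMessage(err), "Missing")
})

test_that("remainder labels cover exactly the non-annotated leaves", {
  tpl <- make_template()
  n_leaves <- nrow(tpl$coords)
  doc <- parse_kr(c(EX1_SOURCE, "remainder"))
  plan <- plan_render(doc, tpl)
  expect_identical(nrow(plan$remainder), n_leaves - 3L)
  expect_false(any(tolower(plan$remainder$leaf) %in%
                     tolower(plan$annotations$target)))
  # without remainder no labels are planned
  expect_null(plan_render(parse_kr(EX1_SOURCE), tpl)$remainder)
})

test_that("legend elements flow in lines and the box encloses them", {
  doc <- parse_kr(c(EX1_SOURCE, EX2_LEGEND_SOURCE))
  lay <- layout_legend(doc$legend, anchor = c(50, 60), boxed = doc$legend_boxed)
  expect_length(lay$elements, 5)  # 2 shapes + 3 texts; spaces/breaks consume none
  ys <- sort(unique(vapply(lay$elements, `[[`, numeric(1), "cy")))
  expect_length(ys, 3)  # three legend lines
  expect_false(is.null(lay$box))
  for (el in lay$elements) {
    expect_gte(el$x0, lay$box[1]); expect_lte(el$x1, lay$box[3])
    expect_gte(el$y0, lay$box[2]); expect_lte(el$y1, lay$box[4])
  }
  empty <- layout_legend(list(), boxed = TRUE)
  expect_length(empty$elements, 0)
  expect_null(empty$box)
})

test_that("vector output is byte-identical across renders and formats write", {
  tpl <- make_template()
  doc <- parse_kr(c(EX1_SOURCE, "remainder", EX2_LEGEND_SOURCE))
  plan <- plan_render(doc, tpl)
  for (fmt in c("svg", "ps")) {
    f1 <- withr::local_tempfile(fileext = paste0(".", fmt))
    f2 <- withr::local_tempfile(fileext = paste0(".", fmt))
    render_kinome(plan, f1); render_kinome(plan, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)), info = fmt)
  }
  for (fmt in c("pdf", "png", "jpg", "tiff")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    render_kinome(plan, f, dpi = 72)
    expect_gt(file.size(f), 0, label = fmt)
  }
  expect_error(render_kinome(plan, tempfile(), format = "bmp"),
               class = "kv_format_error")
})

test_that("drawn circles sit exactly on the leaf with scale as diameter", {
  tpl <- make_template()
  doc <- parse_kr(c("at PINK1", "scale 24", "color 0.92 0.08 0.08",
                    "circle-lined"))
  plan <- plan_render(doc, tpl)
  f <- withr::local_tempfile(fileext = ".svg")
  render_kinome(plan, f)
  svg <- readLines(f)
  circ <- grep("<circle", svg, value = TRUE)
  expect_length(circ, 1)
  pos <- leaf_coords(tpl, "PINK1")
  expect_match(circ, sprintf('cx="%s"', format(pos$x, digits = 15)), fixed = TRUE)
  expect_match(circ, sprintf('cy="%s"', format(pos$y, digits = 15)), fixed = TRUE)
  expect_match(circ, 'r="12"', fixed = TRUE)
  # color-filled with black outline
  expect_match(circ, 'stroke="#000000"', fixed = TRUE)
  expect_match(circ, 'fill="#EB1414"', fixed = TRUE)

  # square = 4-sided polygon, one vertex up
  sq <- plan_render(parse_kr(c("at PINK1", "scale 20", "polygon-filled 4")), tpl)
  fsq <- withr::local_tempfile(fileext = ".svg")
  render_kinome(sq, fsq)
  pts <- regmatches(readLines(fsq), regexpr('points="[^"]*"', readLines(fsq)))
  pts <- pts[nzchar(pts)]
  v <- do.call(rbind, strsplit(strsplit(gsub('points="|"', "", pts[1]), " ")[[1]], ","))
  v <- apply(v, 2, as.numeric)
  expect_identical(nrow(v), 4L)
  # vertices lie on the circumscribed circle of diameter 20
  r <- sqrt((v[, 1] - pos$x)^2 + (v[, 2] - pos$y)^2)
  expect_true(all(abs(r - 10) < 1e-3))
  expect_true(any(abs(v[, 2] - (pos$y - 10)) < 1e-3))  # one vertex points up
})

test_that("an empty document renders a backbone-only image", {
  tpl <- make_template()
  plan <- plan_render(kr_document(), tpl)
  f <- withr::local_tempfile(fileext = ".svg")
  render_kinome(plan, f)
  svg <- readLines(f)
  expect_false(any(grepl("<circle|<polygon|<text", svg)))
  expect_true(any(grepl("<line", svg)))
})
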
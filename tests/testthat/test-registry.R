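# Registry loading, leaf-set arithmetic, identifier resolution, batch lists
# and the synthetic-registry generator.

test_that("registry construction enforces its invariants", {
  reg <- tiny_registry()
  expect_s3_class(reg, "kinase_registry")
  expect_length(reg, 8)
  expect_identical(reg$entries$is_second_domain,
                   endsWith(reg$entries$name, "~b"))

  dup <- as.data.frame(reg)
  dup$name[2] <- "Abl"
  expect_error(kinase_registry(dup), class = "kv_validation_error")

  bad <- as.data.frame(reg)
  bad$full_sequence[1] <- "MGQ123"
  expect_error(kinase_registry(bad), class = "kv_validation_error")

  # tilde-operator glyph from typeset text normalizes to ASCII "~b"
  glyph <- kinase_registry(data.frame(name = "JAK1∼b"))
  expect_identical(glyph$entries$name, "JAK1~b")
  expect_true(glyph$entries$is_second_domain)
})

test_that("registry files round-trip and reject malformed input", {
  reg <- tiny_registry()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_registry(reg, path)
  back <- read_registry(path)
  expect_identical(as.data.frame(back), as.data.frame(reg))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("name", "group", "family"), collapse = "\t"), empty)
  expect_length(read_registry(empty), 0)

  noname <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("group\tfamily", "TK\tAbl"), noname)
  expect_error(read_registry(noname), class = "kv_format_error")

  dups <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tgroup\tfamily", "Abl\tTK\tAbl", "Abl\tTK\tAbl"), dups)
  expect_error(read_registry(dups), class = "kv_validation_error")
})

test_that("leaf-set arithmetic removes atypicals and doubles dual-domain kinases", {
  expect_identical(build_leaf_set(c("JAK1"), dual_domain = c("JAK1")),
                   c("JAK1", "JAK1~b"))
  expect_identical(build_leaf_set(character()), character())
  expect_error(build_leaf_set(c("A", "B"), atypical_absent = "A",
                              dual_domain = "A"),
               class = "kv_validation_error")
  expect_error(build_leaf_set(c("A"), atypical_absent = "Z"),
               class = "kv_validation_error")

  # |leaves| = |genes| - |atypical| + |dual| over random valid inputs
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    genes <- sprintf("G%03d", seq_len(n))
    atyp <- sample(genes, sample(0:3, 1))
    dual <- sample(setdiff(genes, atyp), sample(0:4, 1))
    leaves <- build_leaf_set(genes, atyp, dual)
    expect_length(leaves, n - length(atyp) + length(dual))
    expect_false(anyDuplicated(leaves) > 0)
  }
})

test_that("the full-scale leaf arithmetic yields 523 leaves with 13 second domains", {
  reg <- simulate_registry(518, 8, 13, seed = 7)
  genes <- reg$entries$name[!reg$entries$is_second_domain]
  expect_length(genes, 518)
  leaves <- build_leaf_set(genes, ATYPICAL_ABSENT, DUAL_DOMAIN)
  expect_length(leaves, 523)
  expect_identical(sort(leaves), sort(leaf_names(reg)))
  expect_identical(sum(reg$entries$is_second_domain), 13L)
  expect_identical(sum(reg$entries$is_atypical & reg$entries$is_second_domain), 0L)
})

test_that("resolution matches queries the way a search box would", {
  reg <- tiny_registry()
  # exact, case-insensitive Manning name
  expect_identical(resolve_kinase(reg, "abl", "name")$name, "Abl")
  expect_identical(resolve_kinase(reg, "JAK1~B", "name")$name, "JAK1~b")
  # name queries also reach the full protein name and synonyms
  expect_identical(
    resolve_kinase(reg, "Serine/threonine-protein kinase PINK1, mitochondrial",
                   "name")$name, "PINK1")
  expect_identical(resolve_kinase(reg, "PARK6", "name")$name, "PINK1")
  # name matching is exact, not substring
  expect_identical(nrow(resolve_kinase(reg, "JAK", "uniprot")), 0L)
  # classification fields are exact
  expect_identical(resolve_kinase(reg, "tk", "group")$name,
                   c("Abl", "Src", "JAK1", "JAK1~b"))
  expect_identical(resolve_kinase(reg, "P00519", "uniprot")$name, "Abl")
  # no match is an empty result, not an error
  expect_identical(nrow(resolve_kinase(reg, "NOT_A_KINASE", "name")), 0L)
  expect_error(resolve_kinase(reg, "", "name"), class = "kv_input_error")
})

test_that("resolution agrees with a brute-force linear scan", {
  reg <- simulate_registry(120, 4, 6, seed = 11)
  fields_pool <- c("name", "synonym", "full_name", "uniprot", "ipi",
                   "group", "family", "subfamily")
  e <- as.data.frame(reg)
  set.seed(99)
  queries <- c(sample(e$name, 10), sample(e$uniprot_id, 5),
               sample(e$group, 3), "SYN_KIN001", "nonexistent-kinase")
  for (q in queries) {
    fields <- sample(fields_pool, sample(1:4, 1))
    got <- resolve_kinase(reg, q, fields)$name
    expect_identical(got, oracle_resolve(reg, q, fields),
                     info = sprintf("query '%s' fields %s", q,
                                    paste(fields, collapse = ",")))
  }
})

test_that("batch lists split on commas, semicolons and newlines", {
  expect_identical(parse_batch_list("Abl;Src,PINK1\nBIKE"),
                   c("Abl", "Src", "PINK1", "BIKE"))
  expect_identical(parse_batch_list(""), character(0))
  expect_identical(parse_batch_list(" Abl ,, Src "), c("Abl", "Src"))
  expect_identical(parse_batch_list("one\r\ntwo;\n;three"),
                   c("one", "two", "three"))
})

test_that("the synthetic registry is deterministic and honors its counts", {
  a <- simulate_registry(10, 0, 0, seed = 1)
  b <- simulate_registry(10, 0, 0, seed = 1)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a),
                         as.data.frame(simulate_registry(10, 0, 0, seed = 2))))
  expect_error(simulate_registry(5, 3, 3, seed = 1),
               class = "kv_validation_error")

  full <- simulate_registry(518, 8, 13, seed = 1)
  expect_length(leaf_names(full), 523)
  expect_true(all(ATYPICAL_ABSENT %in% full$entries$name))
  expect_true(all(paste0(DUAL_DOMAIN, "~b") %in% full$entries$name))
  expect_identical(full$entries$domain_sequence[full$entries$is_atypical],
                   rep("", 8))
})
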
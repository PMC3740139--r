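# Shared fixtures: a tiny deterministic registry, a random-document
# generator for round-trip properties, and independent oracles (linear-scan
# identifier resolution, affine-gap Smith-Waterman DP).

tiny_registry <- function() {
  kinase_registry(data.frame(
    name = c("Abl", "Src", "PINK1", "MPSK1", "BIKE", "JAK1", "JAK1~b", "BCR"),
    synonyms = c("ABL1|c-ABL", "SRC1", "PARK6", "STK16", "BMP2K",
                 "Janus kinase 1", "", ""),
    full_name = c("Tyrosine-protein kinase ABL1",
                  "Proto-oncogene tyrosine-protein kinase Src",
                  "Serine/threonine-protein kinase PINK1, mitochondrial",
                  "Serine/threonine-protein kinase 16",
                  "BMP-2-inducible protein kinase",
                  "Tyrosine-protein kinase JAK1",
                  "Tyrosine-protein kinase JAK1 domain 2",
                  "Breakpoint cluster region protein"),
    uniprot_id = c("P00519", "P12931", "Q9BXM7", "O75716", "Q9NSY1",
                   "P23458", "P23458b", "P11274"),
    ipi = sprintf("IPI%08d", 1:8),
    group = c("TK", "TK", "Other", "Other", "Other", "TK", "TK", "Atypical"),
    family = c("Abl", "Src", "PINK1", "NAK", "NAK", "JakA", "JakB", "BCR"),
    subfamily = "",
    full_sequence = c("MGQQPGKVLGDQRRPSLPALHFIKGA", "MGSNKSKPKDASQRRRSLEPAENVHG",
                      "MAVRQALGRGLQLGRALLLRFTPKPA", "MGHALCVCSRGTVIIDNKRYLFIQKL",
                      "MKKFSRMPKSEGGSGGGAAGGGAGGA", "MQYLNIKEDCNAMAFCAKMRSSKKTE",
                      "MQYLNIKEDCNAMAFCAKMRSSKKTV", "MVDPVGFAEAWKAQFPDSEPPRMELR"),
    domain_sequence = c("GQQPGKVLGD", "GSNKSKPKDA", "AVRQALGRGL", "GHALCVCSRG",
                        "KKFSRMPKSE", "QYLNIKEDCN", "YLNIKEDCNA", ""),
    is_atypical = c(rep(FALSE, 7), TRUE),
    stringsAsFactors = FALSE))
}

EX1_SOURCE <- c(
  "at PINK1", "color 1 0 1", "scale 30", "polygon-filled 3",
  "at MPSK1", "color 0.92 0.08 0.08", "scale 20", "circle-lined",
  "at BIKE", "color 0 0.67 0", "scale 10", "text BIKE")

EX2_LEGEND_SOURCE <- c(
  "legend", "scale 20", "color 1 0 1", "polygon-filled 3", "space",
  "text PINK1 is annotated with a pink triangle", "next-line",
  "color 0.92 0.08 0.08", "circle-lined", "space",
  "text MPSK1 is annotated with a red circle", "next-line",
  "color 0 0.67 0", "text BIKE is annotated in green", "legendBox")

# Random valid document built programmatically (colors on a 0.01 grid so
# that text serialization is lossless).
random_doc <- function(n_annotations = NULL, targets = NULL, with_legend = TRUE) {
  targets <- targets %||% c("Abl", "Src", "PINK1", "MPSK1", "BIKE", "JAK1~b")
  n <- n_annotations %||% sample(0:8, 1)
  rand_color <- function() round(runif(3), 2)
  rand_payload <- function() {
    chars <- c(LETTERS, letters, 0:9, "α", "β", "≤", "-", "_")
    paste(sample(chars, sample(1:25, 1), replace = TRUE), collapse = "")
  }
  anns <- lapply(seq_len(n), function(i) {
    kind <- sample(c(kinomeviz:::TEXT_KINDS, kinomeviz:::SHAPE_KINDS), 1)
    is_text <- kind == "text"
    kr_annotation(
      target = sample(targets, 1), kind = kind,
      color = rand_color(), scale = sample(1:40, 1),
      n_sides = if (startsWith(kind, "polygon")) sample(3:8, 1) else NA_integer_,
      payload = if (is_text) rand_payload() else NA_character_,
      boxed = is_text && runif(1) < 0.3,
      underlined = is_text && runif(1) < 0.3)
  })
  legend <- list()
  legend_boxed <- FALSE
  if (with_legend && runif(1) < 0.6) {
    m <- sample(1:6, 1)
    legend <- lapply(seq_len(m), function(i) {
      p <- runif(1)
      if (p < 0.2) list(type = "space")
      else if (p < 0.4) list(type = "next-line")
      else {
        kind <- sample(c("text", "circle-filled", "polygon", "circle-lined"), 1)
        kinomeviz:::legend_drawable(
          kind, color = rand_color(), scale = sample(1:30, 1),
          n_sides = if (startsWith(kind, "polygon")) sample(3:6, 1) else NA_integer_,
          payload = if (kind == "text") rand_payload() else NA_character_)
      }
    })
    legend_boxed <- runif(1) < 0.5
  }
  kr_document(anns, legend = legend, legend_boxed = legend_boxed,
              remainder = runif(1) < 0.3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracle: brute-force resolution by scanning every entry/field.
oracle_resolve <- function(registry, query, fields) {
  e <- as.data.frame(registry)
  q <- tolower(trimws(query))
  keep <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    syns <- tolower(trimws(strsplit(e$synonyms[i], "|", fixed = TRUE)[[1]]))
    syns <- syns[nzchar(syns)]
    syn_match <- any(vapply(syns, function(s) grepl(q, s, fixed = TRUE), logical(1)))
    full_match <- nzchar(e$full_name[i]) && grepl(q, tolower(e$full_name[i]), fixed = TRUE)
    for (f in fields) {
      ok <- switch(f,
        name = tolower(e$name[i]) == q || full_match || syn_match,
        synonym = syn_match,
        full_name = full_match,
        uniprot = tolower(e$uniprot_id[i]) == q,
        ipi = tolower(e$ipi[i]) == q,
        group = tolower(e$group[i]) == q,
        family = tolower(e$family[i]) == q,
        subfamily = tolower(e$subfamily[i]) == q)
      if (ok) { keep[i] <- TRUE; break }
    }
  }
  e$name[keep]
}

# Independent oracle: affine-gap local alignment score by explicit Gotoh DP
# (a gap of length L costs open + L * extend).
oracle_sw_score <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (horizontal)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend, F[i - 1, j] - gap_extend)
      diag <- H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]]
      H[i, j] <- max(0, diag, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_protein <- function(len) {
  paste(sample(kinomeviz:::AA_LETTERS, len, replace = TRUE), collapse = "")
}
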
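# Kinase leaf registry: loading, validation, leaf-set arithmetic, identifier
# resolution, batch lists, and a deterministic synthetic-registry generator.
#
# The human kinome comprises 518 protein kinases. Eight atypical kinases are
# absent from the classic tree and 13 kinases carry two distinct catalytic
# domains, each domain being its own leaf (the second tagged "~b"), so the
# canonical typical-tree leaf set has 518 - 8 + 13 = 523 names. Registries may
# additionally carry the atypical entries (flagged), which are placeable only
# on the extended template that includes the atypical sub-tree.

#' Atypical kinases absent from the typical kinome tree
#'
#' The eight atypical protein kinases that are not drawn on the classic
#' human kinome tree and, when present in a registry, are flagged
#' \code{is_atypical} and only placeable on template 2.
#' @format Character vector of eight Manning names.
#' @export
ATYPICAL_ABSENT <- c("BCR", "FASTK", "G11", "H11", "TAF1", "TAF1L", "A6", "A6r")

#' Kinases with two distinct catalytic domains
#'
#' The thirteen human kinases carrying two distinct catalytic domains; each
#' contributes two leaves to the tree, the second tagged with the
#' \code{"~b"} suffix.
#' @format Character vector of thirteen Manning names.
#' @export
DUAL_DOMAIN <- c("JAK1", "JAK2", "JAK3", "MSK1", "MSK2", "RSK1", "RSK2",
                 "RSK3", "Tyk2", "GCN2", "RSK4", "SPEG", "Obscn")

REGISTRY_COLUMNS <- c("name", "synonyms", "full_name", "uniprot_id", "ipi",
                      "group", "family", "subfamily", "full_sequence",
                      "domain_sequence", "is_atypical")

#' Construct a kinase registry
#'
#' Builds a validated registry from a data frame of kinase entries. One row
#' per tree leaf (or flagged atypical entry); names must be unique, second
#' catalytic domains must carry the \code{"~b"} suffix, and sequences may only
#' contain amino-acid letters (or be empty, as for atypical kinase domains).
#'
#' @param entries data frame with columns \code{name}, \code{synonyms}
#'   (\code{"|"}-separated), \code{full_name}, \code{uniprot_id}, \code{ipi},
#'   \code{group}, \code{family}, \code{subfamily}, \code{full_sequence},
#'   \code{domain_sequence}, \code{is_atypical}. Missing columns are filled
#'   with empty strings / \code{FALSE}.
#' @return An object of class \code{kinase_registry}.
#' @export
kinase_registry <- function(entries) {
  if (!is.data.frame(entries)) kv_format_error("entries must be a data frame")
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (nrow(entries) > 0 && !"name" %in% names(entries))
    kv_format_error("registry is missing required column 'name'")
  for (col in REGISTRY_COLUMNS) {
    if (!col %in% names(entries)) {
      entries[[col]] <- if (col == "is_atypical") logical(nrow(entries))
                        else character(nrow(entries))
    }
  }
  entries <- entries[REGISTRY_COLUMNS]
  if (nrow(entries) > 0) {
    entries$name <- normalize_tilde(as.character(entries$name))
    for (col in setdiff(REGISTRY_COLUMNS, c("name", "is_atypical"))) {
      v <- as.character(entries[[col]])
      v[is.na(v)] <- ""
      entries[[col]] <- v
    }
    entries$is_atypical <- as.logical(entries$is_atypical) %in% TRUE
  }
  entries$is_second_domain <- endsWith(entries$name, "~b")

  if (any(!nzchar(entries$name)))
    kv_validation_error("registry entries must have non-empty names")
  dup <- entries$name[duplicated(entries$name)]
  if (length(dup))
    kv_validation_error(sprintf("duplicate leaf name(s): %s",
                                paste(unique(dup), collapse = ", ")))
  bad_seq <- !vapply(entries$full_sequence, is_protein_sequence, logical(1)) |
             !vapply(entries$domain_sequence, is_protein_sequence, logical(1))
  if (any(bad_seq))
    kv_validation_error(sprintf(
      "invalid amino-acid letters in sequence(s) of: %s",
      paste(entries$name[bad_seq], collapse = ", ")))
  if (any(entries$is_atypical & entries$is_second_domain))
    kv_validation_error("an entry cannot be both atypical and a second catalytic domain")

  rownames(entries) <- NULL
  structure(list(entries = entries), class = "kinase_registry")
}

#' @export
length.kinase_registry <- function(x) nrow(x$entries)

#' @export
as.data.frame.kinase_registry <- function(x, ...) x$entries

#' @export
print.kinase_registry <- function(x, ...) {
  e <- x$entries
  cat(sprintf("<kinase_registry> %d entries (%d atypical, %d second-domain), %d leaves on the typical tree\n",
              nrow(e), sum(e$is_atypical), sum(e$is_second_domain),
              sum(!e$is_atypical)))
  if (nrow(e)) {
    grp <- sort(table(e$group[nzchar(e$group)]), decreasing = TRUE)
    if (length(grp))
      cat("  groups:", paste(sprintf("%s(%d)", names(grp), grp), collapse = " "), "\n")
  }
  invisible(x)
}

#' Leaf names of a registry
#'
#' @param registry a \code{kinase_registry}.
#' @param include_atypical if \code{FALSE} (default) atypical entries are
#'   excluded, giving the typical-tree leaf set (523 names for a full-scale
#'   registry).
#' @return Character vector of leaf names in registry order.
#' @export
leaf_names <- function(registry, include_atypical = FALSE) {
  stopifnot(inherits(registry, "kinase_registry"))
  e <- registry$entries
  if (include_atypical) e$name else e$name[!e$is_atypical]
}

#' Read a registry from a tab-separated file
#'
#' Expects a UTF-8 TSV with a header row naming at least \code{name},
#' \code{group} and \code{family}; synonyms are packed in one column
#' separated by \code{"|"}.
#'
#' @param path path to the TSV file.
#' @return A \code{kinase_registry}.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) kv_input_error(sprintf("registry file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  required <- c("name", "group", "family")
  missing <- setdiff(required, names(df))
  if (length(missing))
    kv_format_error(sprintf("registry file is missing required column(s): %s",
                            paste(missing, collapse = ", ")))
  if ("is_atypical" %in% names(df))
    df$is_atypical <- toupper(trimws2(df$is_atypical)) %in% c("TRUE", "T", "1", "YES")
  kinase_registry(df)
}

#' Write a registry to a tab-separated file
#'
#' Inverse of \code{\link{read_registry}}: reading the written file
#' reproduces the entry content exactly.
#'
#' @param registry a \code{kinase_registry}.
#' @param path output path; written atomically.
#' @return The path, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "kinase_registry"))
  e <- registry$entries[REGISTRY_COLUMNS]
  e$is_atypical <- ifelse(e$is_atypical, "TRUE", "FALSE")
  lines <- c(paste(REGISTRY_COLUMNS, collapse = "\t"),
             do.call(paste, c(unname(as.list(e)), sep = "\t")))
  atomic_write_lines(lines, path)
}

#' Build the tree leaf set from gene lists
#'
#' Applies the leaf-set arithmetic of the kinome tree: genes flagged as
#' absent atypical kinases are removed and every dual-catalytic-domain gene
#' contributes a second \code{"~b"}-suffixed leaf, so
#' \code{|leaves| = |genes| - |atypical| + |dual|}. With the 518 human
#' kinases, the 8 absent atypicals and the 13 dual-domain kinases this yields
#' the canonical 523 leaves.
#'
#' @param gene_names character vector of gene symbols.
#' @param atypical_absent subset of \code{gene_names} to drop.
#' @param dual_domain subset of \code{gene_names} gaining a second leaf.
#' @return Character vector of leaf names.
#' @export
build_leaf_set <- function(gene_names, atypical_absent = character(),
                           dual_domain = character()) {
  gene_names <- normalize_tilde(as.character(gene_names))
  atypical_absent <- as.character(atypical_absent)
  dual_domain <- as.character(dual_domain)
  if (length(intersect(atypical_absent, dual_domain)))
    kv_validation_error("atypical_absent and dual_domain lists overlap")
  if (length(setdiff(atypical_absent, gene_names)))
    kv_validation_error("atypical_absent contains genes not in gene_names")
  if (length(setdiff(dual_domain, gene_names)))
    kv_validation_error("dual_domain contains genes not in gene_names")
  leaves <- character(0)
  for (g in gene_names) {
    if (g %in% atypical_absent) next
    leaves <- c(leaves, g)
    if (g %in% dual_domain) leaves <- c(leaves, paste0(g, "~b"))
  }
  leaves
}

#' Resolve a query string to registry entries
#'
#' Case-insensitive search over a chosen set of identifier fields. The
#' \code{"name"} field matches the Manning name exactly and additionally the
#' full protein name and synonym list by substring, mirroring search-box
#' behaviour; \code{"uniprot"} and \code{"ipi"} match exactly;
#' \code{"group"}, \code{"family"} and \code{"subfamily"} match the
#' classification labels exactly. No match is an empty result, not an error.
#'
#' @param registry a \code{kinase_registry}.
#' @param query non-empty query string.
#' @param fields subset of \code{c("name", "synonym", "full_name", "uniprot",
#'   "ipi", "group", "family", "subfamily")}.
#' @return The matching entries as a data frame, in registry order.
#' @export
resolve_kinase <- function(registry, query, fields = "name") {
  stopifnot(inherits(registry, "kinase_registry"))
  query <- normalize_tilde(trimws2(query))
  if (!nzchar(query)) kv_input_error("query must be non-empty")
  allowed <- c("name", "synonym", "full_name", "uniprot", "ipi",
               "group", "family", "subfamily")
  fields <- match.arg(fields, allowed, several.ok = TRUE)
  e <- registry$entries
  if (!nrow(e)) return(e)
  q <- tolower(query)
  hit <- logical(nrow(e))
  substr_hit <- function(col) {
    nzchar(col) & grepl(q, tolower(col), fixed = TRUE)
  }
  syn_hit <- function() {
    vapply(strsplit(e$synonyms, "|", fixed = TRUE), function(s) {
      s <- tolower(trimws2(s))
      any(nzchar(s) & (s == q | grepl(q, s, fixed = TRUE)))
    }, logical(1))
  }
  for (f in fields) {
    hit <- hit | switch(f,
      name      = tolower(e$name) == q | substr_hit(e$full_name) | syn_hit(),
      synonym   = syn_hit(),
      full_name = substr_hit(e$full_name),
      uniprot   = tolower(e$uniprot_id) == q,
      ipi       = tolower(e$ipi) == q,
      group     = tolower(e$group) == q,
      family    = tolower(e$family) == q,
      subfamily = tolower(e$subfamily) == q)
  }
  out <- e[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split a batch identifier list
#'
#' Batch uploads accept identifiers separated by commas, semicolons or
#' newlines; tokens are whitespace-trimmed, empty tokens dropped, order
#' preserved.
#'
#' @param text raw list text.
#' @return Character vector of identifier tokens.
#' @export
parse_batch_list <- function(text) {
  if (length(text) == 0) return(character(0))
  text <- paste(text, collapse = "\n")
  toks <- trimws2(strsplit(text, "[,;\r\n]")[[1]])
  toks <- toks[nzchar(toks)]
  normalize_tilde(toks)
}

random_aa <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(AA_LETTERS, len, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate a deterministic synthetic registry
#'
#' Emulates a full-scale registry for testing and demonstration: gene symbols
#' with random amino-acid sequences, the real eight absent-atypical and
#' thirteen dual-domain kinase names included whenever the counts permit, and
#' a \code{"~b"} second-domain entry per dual-domain gene. With the defaults
#' (518 genes, 8 atypical, 13 dual) the typical-tree leaf set has 523 names.
#' Atypical entries are kept in the registry, flagged, with empty kinase
#' domain sequences.
#'
#' @param n_genes number of gene symbols.
#' @param n_atypical number of genes flagged atypical (absent from the
#'   typical tree).
#' @param n_dual number of genes with a second catalytic domain.
#' @param seed integer seed; identical seeds give identical registries.
#' @param seq_length length of the simulated full protein sequences.
#' @return A \code{kinase_registry} with \code{n_genes + n_dual} entries.
#' @export
simulate_registry <- function(n_genes = 518, n_atypical = 8, n_dual = 13,
                              seed = 1, seq_length = 80) {
  if (n_atypical + n_dual > n_genes)
    kv_validation_error("n_atypical + n_dual must not exceed n_genes")
  if (n_genes < 0 || n_atypical < 0 || n_dual < 0)
    kv_validation_error("counts must be non-negative")
  with_seed(seed, {
    atyp <- c(ATYPICAL_ABSENT, sprintf("ATYP%03d", seq_len(max(0, n_atypical - 8))))
    atyp <- atyp[seq_len(n_atypical)]
    dual <- c(DUAL_DOMAIN, sprintf("DUAL%03d", seq_len(max(0, n_dual - 13))))
    dual <- dual[seq_len(n_dual)]
    n_plain <- n_genes - n_atypical - n_dual
    # lead with familiar typical-kinase names so worked examples resolve
    known <- c("PINK1", "MPSK1", "BIKE", "Abl", "Src", "EGFR", "BRAF",
               "CDK2", "Fyn", "Lck")
    plain <- c(known, sprintf("KIN%03d", seq_len(max(0, n_plain - length(known)))))
    plain <- plain[seq_len(n_plain)]
    genes <- c(plain, dual, atyp)
    groups <- c("TK", "TKL", "STE", "CK1", "AGC", "CAMK", "CMGC", "Other")
    if (n_genes == 0) {
      return(kinase_registry(data.frame(name = character(0))))
    }
    grp <- groups[1 + (seq_along(genes) - 1) %% length(groups)]
    grp[genes %in% atyp] <- "Atypical"
    fam <- paste0(grp, "-fam", 1 + (seq_along(genes) - 1) %/% length(groups) %% 4)
    rows <- data.frame(
      name = genes,
      synonyms = paste0("SYN_", genes, "|ALT_", toupper(genes)),
      full_name = paste("Synthetic protein kinase", genes),
      uniprot_id = sprintf("P%05d", seq_along(genes)),
      ipi = sprintf("IPI%08d", seq_along(genes)),
      group = grp, family = fam,
      subfamily = ifelse(seq_along(genes) %% 2 == 0, paste0(fam, "a"), ""),
      full_sequence = random_aa(length(genes), seq_length),
      is_atypical = genes %in% atyp,
      stringsAsFactors = FALSE)
    rows$domain_sequence <- ifelse(
      rows$is_atypical, "",
      substr(rows$full_sequence, 1, max(1, seq_length %/% 2)))
    second <- rows[rows$name %in% dual, , drop = FALSE]
    if (nrow(second)) {
      second$name <- paste0(second$name, "~b")
      second$synonyms <- ""
      second$domain_sequence <- substr(second$full_sequence,
                                       max(1, seq_length %/% 2), seq_length)
      rows <- rbind(rows, second)
    }
    kinase_registry(rows)
  })
}
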
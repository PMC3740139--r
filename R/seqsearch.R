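# Identify registry kinases from a protein query by Smith-Waterman local
# alignment against the stored full sequences (BLOSUM62, gap open 11,
# gap extend 1 -- standard protein defaults). Hits are ranked by a
# Karlin-Altschul E-value approximation computed over the total registry
# residue count; exact reproduction of a particular search program's
# statistics is a non-goal, the contract is ranking fidelity.

# Gapped BLOSUM62 (11, 1) Karlin-Altschul constants.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Search a registry by protein sequence
#'
#' Aligns the query locally against the full protein sequence of every
#' registry entry (so matches outside the kinase domain are found) and
#' returns the best hits sorted by ascending E-value, ties broken by
#' descending alignment score. Percent identity and percent similarity
#' (identities plus positive-scoring substitutions) are computed over the
#' aligned region including gap positions, so identity never exceeds
#' similarity.
#'
#' @param query protein sequence: a plain string or a
#'   \code{Biostrings::AAString}. Use \code{\link{read_fasta_queries}} for
#'   FASTA input.
#' @param registry a \code{\link{kinase_registry}} whose entries carry
#'   sequences.
#' @param max_hits maximum number of hits returned.
#' @param use_domain align against kinase-domain sequences instead of full
#'   sequences; entries with an empty domain sequence are skipped.
#' @return Data frame of class \code{kinome_hits} with columns \code{name},
#'   \code{score}, \code{bit_score}, \code{e_value}, \code{pct_identity},
#'   \code{pct_similarity}.
#' @export
search_sequence <- function(query, registry, max_hits = 10L,
                            use_domain = FALSE) {
  stopifnot(inherits(registry, "kinase_registry"))
  query <- toupper(trimws2(as.character(query)))
  if (!nzchar(query)) kv_input_error("query sequence is empty")
  if (!is_protein_sequence(query, allow_extended = FALSE))
    kv_input_error("query contains non-amino-acid letters")
  e <- registry$entries
  seqs <- if (use_domain) e$domain_sequence else e$full_sequence
  keep <- nzchar(seqs)
  if (!any(keep)) kv_input_error("registry carries no sequences to search")
  subjects <- Biostrings::AAStringSet(seqs[keep])
  names(subjects) <- e$name[keep]
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    pattern = subjects, subject = Biostrings::AAString(query),
    type = "local", substitutionMatrix = BLOSUM62,
    gapOpening = 11, gapExtension = 1)
  scores <- Biostrings::score(aln)
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  stats <- vapply(seq_along(pa), function(i) {
    pc <- strsplit(pa[i], "")[[1]]; sc <- strsplit(sa[i], "")[[1]]
    len <- length(pc)
    if (!len) return(c(0, 0))
    aligned <- pc != "-" & sc != "-"
    ident <- sum(aligned & pc == sc)
    pos <- ident
    mism <- which(aligned & pc != sc)
    if (length(mism))
      pos <- pos + sum(BLOSUM62[cbind(pc[mism], sc[mism])] > 0)
    c(100 * ident / len, 100 * pos / len)
  }, numeric(2))
  db_residues <- sum(nchar(seqs[keep]))
  bit <- (KA_LAMBDA * scores - log(KA_K)) / log(2)
  evalue <- nchar(query) * db_residues * 2^(-bit)
  hits <- data.frame(name = names(subjects),
                     score = scores,
                     bit_score = bit,
                     e_value = evalue,
                     pct_identity = stats[1, ],
                     pct_similarity = stats[2, ],
                     stringsAsFactors = FALSE)
  ord <- order(hits$e_value, -hits$score, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  hits <- utils::head(hits, max_hits)
  rownames(hits) <- NULL
  class(hits) <- c("kinome_hits", "data.frame")
  hits
}

#' @export
print.kinome_hits <- function(x, ...) {
  cat(sprintf("<kinome_hits> %d hit(s)\n", nrow(x)))
  y <- as.data.frame(x)
  y$e_value <- signif(y$e_value, 3)
  y$bit_score <- round(y$bit_score, 1)
  y$pct_identity <- round(y$pct_identity, 1)
  y$pct_similarity <- round(y$pct_similarity, 1)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Read protein queries from a FASTA file
#'
#' @param path FASTA file; each record is searched independently.
#' @return Named character vector of sequences.
#' @export
read_fasta_queries <- function(path) {
  if (!file.exists(path)) kv_input_error(sprintf("FASTA file not found: %s", path))
  s <- Biostrings::readAAStringSet(path)
  if (!length(s)) kv_input_error("FASTA file contains no records")
  stats::setNames(as.character(s), names(s))
}
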
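# Deterministic synthetic affinity matrices for demonstrations and tests.

#' Generate a synthetic affinity table
#'
#' Draws a kinase x inhibitor matrix emulating a selectivity panel: a subset
#' of cells are binders with log-uniform affinities, a subset are tested
#' with no effect ("-"), and the rest are untested ("NA"). Deterministic
#' for a fixed seed.
#'
#' @param registry a \code{\link{kinase_registry}}; rows are drawn from its
#'   typical-tree leaves.
#' @param n_kinases number of kinase rows.
#' @param n_inhibitors number of inhibitor columns.
#' @param seed integer seed.
#' @param units \code{"nM"} or \code{"uM"}.
#' @param affinity_range \code{c(low, high)} of drawn affinities, in table
#'   units; values are log-uniform in this range.
#' @param p_binder,p_no_effect cell probabilities (the remainder is
#'   untested).
#' @param threshold optional no-effect threshold stored on the table.
#' @return A \code{\link{binding_table}}.
#' @export
simulate_binding_table <- function(registry, n_kinases = 10, n_inhibitors = 14,
                                   seed = 1, units = "uM",
                                   affinity_range = c(0.001, 10),
                                   p_binder = 0.35, p_no_effect = 0.35,
                                   threshold = NULL) {
  stopifnot(inherits(registry, "kinase_registry"))
  leaves <- leaf_names(registry)
  if (n_kinases > length(leaves))
    kv_validation_error("n_kinases exceeds the registry's leaf count")
  with_seed(seed, {
    kin <- sample(leaves, n_kinases)
    inh <- sprintf("Inhib%02d", seq_len(n_inhibitors))
    u <- matrix(stats::runif(n_kinases * n_inhibitors), n_kinases)
    status <- matrix("na", n_kinases, n_inhibitors)
    status[u < p_binder] <- "binder"
    status[u >= p_binder & u < p_binder + p_no_effect] <- "no_effect"
    lo <- log10(affinity_range[1]); hi <- log10(affinity_range[2])
    values <- matrix(NA_real_, n_kinases, n_inhibitors)
    nb <- sum(status == "binder")
    values[status == "binder"] <- 10^stats::runif(nb, lo, hi)
    binding_table(values, status, kin, inh, units = units, threshold = threshold)
  })
}

#' Write a binding table to a tab-separated file
#'
#' Inverse of \code{\link{read_binding_table}} on cell content; binder
#' values are written as plain numbers, no-effect cells as \code{"-"} and
#' untested cells as \code{"NA"}.
#'
#' @param table a \code{\link{binding_table}}.
#' @param path output path; written atomically.
#' @return The path, invisibly.
#' @export
write_binding_table <- function(table, path) {
  stopifnot(inherits(table, "binding_table"))
  cells <- matrix("NA", length(table$kinase_ids), length(table$inhibitors))
  cells[table$status == "no_effect"] <- "-"
  b <- table$status == "binder"
  cells[b] <- fmt_num(signif(table$values[b], 6))
  lines <- c(paste(c("kinase", table$inhibitors), collapse = "\t"),
             vapply(seq_along(table$kinase_ids), function(i)
               paste(c(table$kinase_ids[i], cells[i, ]), collapse = "\t"),
               character(1)))
  atomic_write_lines(lines, path)
}
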
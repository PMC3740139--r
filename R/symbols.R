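# Bracketed special-symbol codes usable inside text annotations, e.g.
# "[alpha]" -> "α". Codes are case-sensitive; unknown codes are left
# verbatim with a warning.

KR_SYMBOLS <- c(
  alpha = "α", beta = "β", chi = "χ", delta = "δ",
  Delta = "Δ", epsilon = "ε", phi = "φ", gamma = "γ",
  Gamma = "Γ", eta = "η", iota = "ι", lambda = "λ",
  kappa = "κ", mu = "μ", nu = "ν", pi = "π",
  Pi = "Π", rho = "ρ", theta = "θ", Theta = "Θ",
  theta1 = "ϑ", omega = "ω", Omega = "Ω", sigma = "σ",
  Sigma = "Σ", sigma1 = "ς", upsilon = "υ", tau = "τ",
  xi = "ξ", psi = "ψ", Psi = "Ψ", zeta = "ζ",
  intersection = "⋂", union = "⋃", angle = "∠",
  equivalence = "≡", plusminus = "±", lesserequal = "≤",
  greaterequal = "≥", diamond = "⧫", heart = "♥",
  spade = "♠", club = "♣")

#' Expand bracketed special-symbol codes
#'
#' Replaces every recognized \code{[code]} occurrence in a string by its
#' Unicode glyph (Greek letters, set operators, comparison signs, card
#' suits). Text outside brackets is left unchanged and expansion is
#' idempotent on its own output. Unrecognized codes trigger a warning and
#' are left verbatim.
#'
#' @param s character vector to expand.
#' @return Character vector with codes replaced by glyphs.
#' @examples
#' expand_symbols("[alpha]-kinase")   # "α-kinase"
#' expand_symbols("IC[lesserequal]50")
#' @export
expand_symbols <- function(s) {
  vapply(s, function(one) {
    if (is.na(one) || !grepl("[", one, fixed = TRUE)) return(one)
    m <- gregexpr("\\[([A-Za-z0-9]+)\\]", one)[[1]]
    if (m[1] == -1L) return(one)
    codes <- regmatches(one, list(m))[[1]]
    bare <- substr(codes, 2, nchar(codes) - 1L)
    unknown <- unique(bare[!bare %in% names(KR_SYMBOLS)])
    if (length(unknown))
      warning(sprintf("unrecognized symbol code(s) left verbatim: %s",
                      paste0("[", unknown, "]", collapse = ", ")),
              call. = FALSE)
    repl <- ifelse(bare %in% names(KR_SYMBOLS), KR_SYMBOLS[bare], codes)
    regmatches(one, list(m)) <- list(repl)
    one
  }, character(1), USE.NAMES = FALSE)
}
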
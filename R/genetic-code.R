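#' The standard genetic code as a tibble
#'
#' Returns the 64-codon table of the standard nuclear genetic code with the
#' synonymous-family structure needed by every index: the amino acid each
#' codon encodes and the family degeneracy \eqn{n_i} (number of synonymous
#' codons for that amino acid; 1 for Met and Trp, up to 6 for Leu/Ser/Arg,
#' 3 for the stop "family").
#'
#' Stop codons are carried as a family labelled `"Stop"` (`aa == "*"`) so
#' that corpus-level tables cover all 64 codons; whether stops enter a given
#' index is decided downstream, not here.
#'
#' @param code_id Genetic code label. Only `"standard"` is currently
#'   supported.
#' @return A tibble with one row per codon and columns `codon`, `aa`
#'   (single-letter, `"*"` for stop), `amino_acid` (full name), and
#'   `family_size`.
#' @examples
#' gc_tab <- genetic_code()
#' dplyr::count(gc_tab, amino_acid, family_size)
#' @export
genetic_code <- function(code_id = "standard") {
  if (!identical(code_id, "standard")) {
    stop("only the standard genetic code is supported, got: ", code_id)
  }
  code <- Biostrings::GENETIC_CODE
  tbl <- tibble::tibble(
    codon = names(code),
    aa = unname(code)
  )
  tbl$amino_acid <- aa_name(tbl$aa)
  fam <- table(tbl$aa)
  tbl$family_size <- as.integer(fam[tbl$aa])
  tbl[order(tbl$amino_acid, tbl$codon), ]
}

# single-letter -> full amino-acid name ("*" -> "Stop")
aa_name <- function(aa) {
  lookup <- c(
    A = "Alanine", R = "Arginine", N = "Asparagine", D = "Aspartate",
    C = "Cysteine", Q = "Glutamine", E = "Glutamate", G = "Glycine",
    H = "Histidine", I = "Isoleucine", L = "Leucine", K = "Lysine",
    M = "Methionine", F = "Phenylalanine", P = "Proline", S = "Serine",
    T = "Threonine", W = "Tryptophan", Y = "Tyrosine", V = "Valine",
    `*` = "Stop"
  )
  unname(lookup[aa])
}

#' All 64 codons in a fixed order
#'
#' @return Character vector of the 64 codons, ordered as in
#'   [genetic_code()] (by amino-acid name, then codon).
#' @export
all_codons <- function() genetic_code()$codon

# amino acids whose codons are conventionally excluded from CAI:
# single-codon families carry no choice, stops are not translated
cai_default_exclusions <- function() c("Methionine", "Tryptophan", "Stop")
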
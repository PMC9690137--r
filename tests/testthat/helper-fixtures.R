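# build a validated sequence tibble from named nucleotide strings; the
# start/stop checks default off so arbitrary in-frame fixtures can be used
make_seqs <- function(..., require_start = FALSE, require_stop = FALSE) {
  s <- c(...)
  validate_cds(
    tibble::tibble(
      id = names(s),
      accession = NA_character_,
      sequence = unname(s),
      length_bp = nchar(s),
      is_validated = FALSE
    ),
    require_start = require_start, require_stop = require_stop
  )
}

# 64-row codon count tibble from a named count vector (unlisted codons 0)
make_counts <- function(counts, source_id = "g1") {
  code <- genetic_code()
  n <- integer(nrow(code))
  names(n) <- code$codon
  n[names(counts)] <- as.integer(counts)
  tibble::tibble(
    source_id = source_id,
    codon = code$codon,
    amino_acid = code$amino_acid,
    aa = code$aa,
    family_size = code$family_size,
    count = unname(n)
  )
}

# counts table from an explicit codon vector (e.g. iid positional draws)
make_counts_from_codons <- function(codons, source_id = "g1") {
  make_counts(table(codons), source_id = source_id)
}

# write a FASTA string to a temp file
write_tmp_fasta <- function(lines) {
  fa <- tempfile(fileext = ".fa")
  writeLines(lines, fa)
  fa
}

# small synthetic spec used across tests
tiny_spec <- function(seed = 11, ...) {
  synthetic_spec(
    n_sequences = 5, length_range = c(300, 600), seed = seed, ...
  )
}

# uniform codon preferences over every sense family
uniform_prefs <- function() {
  code <- genetic_code()
  sense <- code[code$aa != "*", ]
  dplyr::bind_rows(lapply(split(sense, sense$amino_acid), function(fam) {
    tibble::tibble(codon = fam$codon, pref = 1 / nrow(fam))
  }))
}

# preferences concentrated on one codon per family (prob `w` on the first
# codon alphabetically, rest shared)
skewed_prefs <- function(w = 0.85) {
  code <- genetic_code()
  sense <- code[code$aa != "*", ]
  dplyr::bind_rows(lapply(split(sense, sense$amino_acid), function(fam) {
    k <- nrow(fam)
    p <- if (k == 1) 1 else c(w, rep((1 - w) / (k - 1), k - 1))
    tibble::tibble(codon = sort(fam$codon), pref = p)
  }))
}
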
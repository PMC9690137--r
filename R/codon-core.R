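#' Count codons in validated coding sequences
#'
#' Counts non-overlapping in-frame triplets for each sequence.  All 64
#' codons appear in the output (zero counts included) so downstream tables
#' always cover the full code; stop codons are counted here and excluded,
#' where appropriate, at the index level.
#'
#' @param seqs A validated sequence tibble ([validate_cds()] /
#'   [qc_corpus()]).  Sequences must be flagged validated and in frame.
#' @return A long tibble with columns `source_id`, `codon`, `amino_acid`,
#'   `aa`, `family_size`, `count`; 64 rows per sequence, and
#'   `sum(count) == length_bp / 3` per sequence.
#' @examples
#' seqs <- validate_cds(tibble::tibble(
#'   id = "s1", accession = NA_character_, sequence = "ATGTTTTAA",
#'   length_bp = 9L, is_validated = FALSE
#' ))
#' count_codons(seqs)
#' @export
count_codons <- function(seqs) {
  if (!all(seqs$is_validated)) {
    stop("count_codons() requires validated sequences; run validate_cds() ",
         "or qc_corpus() first (offenders: ",
         paste(utils::head(seqs$id[!seqs$is_validated], 3), collapse = ", "),
         ")")
  }
  if (any(nchar(seqs$sequence) %% 3L != 0L)) {
    stop("count_codons(): sequence length not a multiple of 3")
  }
  code <- genetic_code()
  per_seq <- lapply(seq_len(nrow(seqs)), function(i) {
    s <- seqs$sequence[i]
    starts <- seq.int(1L, nchar(s) - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    tab <- table(factor(codons, levels = code$codon))
    tibble::tibble(
      source_id = seqs$id[i],
      codon = code$codon,
      count = as.integer(tab)
    )
  })
  out <- dplyr::bind_rows(per_seq)
  dplyr::left_join(
    out, code[, c("codon", "amino_acid", "aa", "family_size")],
    by = "codon"
  )[, c("source_id", "codon", "amino_acid", "aa", "family_size", "count")] |>
    tibble::as_tibble()
}

#' Pool codon count tables into one corpus-level table
#'
#' Codon-wise sum over sources; the pool's total equals the sum of member
#' totals.
#'
#' @param counts A codon count tibble (any number of `source_id`s).
#' @param pool_id Label for the pooled table.
#' @return A 64-row codon count tibble with `source_id = pool_id`.
#' @export
pool_counts <- function(counts, pool_id = "pooled") {
  if (nrow(counts) == 0L) stop("pool_counts(): empty input")
  counts |>
    dplyr::group_by(
      .data$codon, .data$amino_acid, .data$aa, .data$family_size
    ) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(source_id = pool_id, .before = 1) |>
    dplyr::arrange(.data$amino_acid, .data$codon)
}

#' GC content of each sequence
#'
#' Percentage of G+C bases, computed at full precision; report layers round
#' to 2 decimals for display.  Works on any nucleotide record (full mRNA or
#' extracted CDS), so composition can be reported on the full record even
#' when indices use the ORF.
#'
#' @param seqs A sequence tibble.
#' @return A tibble with `id`, `length_bp`, `gc_percent`.
#' @examples
#' gc_content(tibble::tibble(
#'   id = "x", accession = NA, sequence = "ATGC", length_bp = 4L,
#'   is_validated = FALSE
#' ))
#' @export
gc_content <- function(seqs) {
  n <- nchar(seqs$sequence)
  if (any(n == 0L)) {
    stop("gc_content(): empty sequence: ",
         paste(seqs$id[n == 0L], collapse = ", "))
  }
  gc <- nchar(gsub("[^GCgc]", "", seqs$sequence))
  tibble::tibble(
    id = seqs$id,
    length_bp = n,
    gc_percent = 100 * gc / n
  )
}

#' Positional base frequencies of counted codons
#'
#' For each codon position (1, 2, 3) and base, the proportion of counted
#' codons carrying that base at that position — the normalised positional
#' frequencies that form the independence baseline of RCBS.
#'
#' @param counts A codon count tibble; computed separately per `source_id`.
#' @return A tibble with `source_id`, `position`, `base`, `freq`; the four
#'   frequencies at each position sum to 1.
#' @export
positional_base_frequencies <- function(counts) {
  totals <- tapply(counts$count, counts$source_id, sum)
  if (any(totals == 0)) {
    stop("positional_base_frequencies(): all-zero counts for: ",
         paste(names(totals)[totals == 0], collapse = ", "))
  }
  bases <- c("A", "C", "G", "T")
  per_source <- lapply(split(counts, counts$source_id), function(d) {
    total <- sum(d$count)
    freq <- vapply(1:3, function(pos) {
      at <- factor(substr(d$codon, pos, pos), levels = bases)
      as.numeric(tapply(d$count, at, sum, default = 0L)) / total
    }, numeric(4))
    tibble::tibble(
      source_id = d$source_id[1],
      position = rep(1:3, each = 4L),
      base = rep(bases, 3L),
      freq = as.vector(freq)
    )
  })
  dplyr::bind_rows(per_source)
}
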
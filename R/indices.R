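#' Relative-adaptiveness weights from a reference count table
#'
#' Computes the CAI weight table \eqn{w_i = f_i / f_{aa,max}}: within each
#' synonymous family, each codon's reference count divided by the family's
#' maximum count, so every used family has at least one codon with
#' \eqn{w = 1} (ties all get 1).  Families entirely unused in the reference
#' get `NA` weights (undefined).  Zero-count codons inside a used family
#' receive the pseudo-weight `pseudo_count / max count` so the log-space
#' geometric mean of CAI stays defined; the floor is configurable.
#'
#' @param reference_counts A codon count tibble for a single source
#'   (typically [pool_counts()] of the analysis corpus).
#' @param pseudo_count Numerator of the pseudo-weight assigned to
#'   zero-count codons in used families (default 0.5).
#' @return A tibble with `codon`, `amino_acid`, `aa`, `family_size`,
#'   `count`, `w`; the reference label is kept in the
#'   `"reference_label"` attribute.
#' @examples
#' seqs <- validate_cds(tibble::tibble(
#'   id = "r", accession = NA, sequence = "ATGTTTTTTTTCAAATAA",
#'   length_bp = 18L, is_validated = FALSE
#' ))
#' reference_weights(count_codons(seqs))
#' @export
reference_weights <- function(reference_counts, pseudo_count = 0.5) {
  if (length(unique(reference_counts$source_id)) != 1L) {
    stop("reference_weights() expects counts for a single source; ",
         "pool_counts() the corpus first")
  }
  if (sum(reference_counts$count) == 0L) {
    stop("reference_weights(): empty reference (all counts zero)")
  }
  out <- reference_counts |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(
      fam_max = max(.data$count),
      w = dplyr::case_when(
        .data$fam_max == 0L ~ NA_real_,
        .data$count > 0L ~ .data$count / .data$fam_max,
        TRUE ~ pseudo_count / .data$fam_max
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(
      "codon", "amino_acid", "aa", "family_size", "count", "w"
    )
  attr(out, "reference_label") <- reference_counts$source_id[1]
  out
}

#' Codon adaptation index
#'
#' CAI of each gene: the geometric mean of the reference relative-
#' adaptiveness weights over the gene's codon occurrences,
#' \eqn{\mathrm{CAI} = (\prod_i w_i)^{1/N}}, computed in log space as
#' \eqn{\exp(\sum_c n_c \log w_c / N)} to avoid underflow on long genes.
#' By convention the single-codon families (Met, Trp) and stop codons carry
#' no synonymous choice and are excluded from the mean; the exclusion set
#' is configurable.
#'
#' @param gene_counts A codon count tibble (one or more `source_id`s).
#' @param weights A weight table from [reference_weights()].
#' @param exclude Amino-acid names excluded from the geometric mean
#'   (default Methionine, Tryptophan, Stop).
#' @return A tibble with `source_id`, `cai`, `n_codons` (occurrences
#'   entering the mean); `cai` is in (0, 1], and equals 1 exactly when
#'   every included codon is family-maximal under the reference.
#' @export
cai <- function(gene_counts, weights,
                exclude = cai_default_exclusions()) {
  joined <- dplyr::left_join(
    gene_counts, weights[, c("codon", "w")], by = "codon"
  ) |>
    dplyr::filter(
      .data$count > 0L,
      !(.data$amino_acid %in% exclude),
      !is.na(.data$w)
    )
  out <- joined |>
    dplyr::group_by(source_id = .data$source_id) |>
    dplyr::summarise(
      cai = exp(sum(.data$count * log(.data$w)) / sum(.data$count)),
      n_codons = sum(.data$count),
      .groups = "drop"
    )
  missing <- setdiff(unique(gene_counts$source_id), out$source_id)
  if (length(missing) > 0L) {
    stop("cai(): no codons with defined weights for: ",
         paste(missing, collapse = ", "))
  }
  out
}

#' Relative synonymous codon usage
#'
#' Two conventions are provided.  The `"fraction"` variant is the within-
#' family fraction \eqn{X_{ij} / \sum_j X_{ij}}: values in a used family
#' sum to 1, the neutral point is \eqn{1/n_i}, and 0.5 is the equal-usage
#' threshold for two-fold families.  The `"classical"` variant multiplies
#' by the family size \eqn{n_i}, so equal usage gives 1 for every codon
#' and values above 1 mark over-represented codons.  Families with zero
#' usage in a gene get value 0 for all members and are flagged unused.
#'
#' @param gene_counts A codon count tibble (per-`source_id`).
#' @param variant `"fraction"` (within-family fraction, default) or `"classical"`.
#' @return A tibble with `source_id`, `codon`, `amino_acid`, `aa`,
#'   `family_size`, `count`, `family_used`, `rscu`.
#' @examples
#' seqs <- validate_cds(tibble::tibble(
#'   id = "g", accession = NA, sequence = "ATGTTTTTTTTCTAA",
#'   length_bp = 15L, is_validated = FALSE
#' ))
#' cc <- count_codons(seqs)
#' subset(rscu(cc), count > 0)
#' subset(rscu(cc, variant = "classical"), count > 0)
#' @export
rscu <- function(gene_counts, variant = c("fraction", "classical")) {
  variant <- match.arg(variant)
  gene_counts |>
    dplyr::group_by(.data$source_id, .data$aa) |>
    dplyr::mutate(
      fam_total = sum(.data$count),
      family_used = .data$fam_total > 0L,
      rscu = dplyr::if_else(
        .data$family_used,
        .data$count / .data$fam_total *
          (if (variant == "classical") .data$family_size else 1L),
        0
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(
      "source_id", "codon", "amino_acid", "aa", "family_size", "count",
      "family_used", "rscu"
    )
}

#' Relative codon bias strength
#'
#' For each counted codon xyz, the ratio of its observed frequency to the
#' product of its three positional base frequencies in the same gene:
#' \eqn{\mathrm{RCBS}_{xyz} = f_{xyz} / (f_1(x) f_2(y) f_3(z))}, where
#' \eqn{f_{xyz}} is the codon's proportion of total codons.  Under
#' positional independence RCBS is 1; values above 1 mark codons used more
#' often than their base composition predicts.  Codons with zero count get
#' value 0.
#'
#' @param gene_counts A codon count tibble (per-`source_id`).
#' @return A tibble with `source_id`, `codon`, `amino_acid`, `aa`,
#'   `family_size`, `count`, `rcbs`.
#' @seealso [mrcbs()], [gene_scores()] for the gene-level geometric mean.
#' @export
rcbs <- function(gene_counts) {
  pos <- positional_base_frequencies(gene_counts)
  pos_wide <- tidyr::pivot_wider(
    pos,
    names_from = c("position", "base"), values_from = "freq",
    names_glue = "f{position}_{base}"
  )
  out <- gene_counts |>
    dplyr::group_by(.data$source_id) |>
    dplyr::mutate(f_xyz = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::left_join(pos_wide, by = "source_id")
  f1 <- as.matrix(out[, paste0("f1_", c("A", "C", "G", "T"))])
  f2 <- as.matrix(out[, paste0("f2_", c("A", "C", "G", "T"))])
  f3 <- as.matrix(out[, paste0("f3_", c("A", "C", "G", "T"))])
  idx <- function(pos_mat, chars) {
    pos_mat[cbind(seq_along(chars), match(chars, c("A", "C", "G", "T")))]
  }
  d <- idx(f1, substr(out$codon, 1, 1)) *
    idx(f2, substr(out$codon, 2, 2)) *
    idx(f3, substr(out$codon, 3, 3))
  out$rcbs <- ifelse(out$count > 0L, out$f_xyz / d, 0)
  out[, c("source_id", "codon", "amino_acid", "aa", "family_size",
          "count", "rcbs")]
}

#' Modified relative codon bias strength
#'
#' RCBS normalised by the maximum RCBS within each codon's synonymous
#' family: \eqn{\mathrm{MRCBS}_{xyz} = \mathrm{RCBS}_{xyz} /
#' \mathrm{RCBS}_{aa,max}}.  Per-codon values lie in [0, 1] and at least
#' one codon per used family attains 1 (ties all get 1); a gene-level
#' summary score is available from [gene_scores()].
#'
#' @param gene_counts A codon count tibble (per-`source_id`).
#' @return A tibble like [rcbs()]'s with additional column `mrcbs`.
#' @export
mrcbs <- function(gene_counts) {
  rcbs(gene_counts) |>
    dplyr::group_by(.data$source_id, .data$aa) |>
    dplyr::mutate(
      fam_max = max(.data$rcbs),
      mrcbs = dplyr::if_else(.data$fam_max > 0, .data$rcbs / .data$fam_max, 0)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"fam_max")
}

# geometric mean of per-codon values over counted occurrences, log space
geo_mean_score <- function(tbl, value_col) {
  tbl |>
    dplyr::filter(.data$count > 0L, .data[[value_col]] > 0) |>
    dplyr::group_by(source_id = .data$source_id) |>
    dplyr::summarise(
      score = exp(
        sum(.data$count * log(.data[[value_col]])) / sum(.data$count)
      ),
      .groups = "drop"
    )
}

#' Gene-level bias scores: CAI, RCBS and MRCBS per sequence
#'
#' Gene-level RCBS and MRCBS are the geometric means of the per-codon
#' values over all counted codon occurrences, computed in log space; an
#' unrooted product would vanish for genes of realistic length, while the
#' 1/N root keeps the score on the per-codon scale (MRCBS in (0, 1]).
#' CAI is included when a reference weight table is supplied.
#'
#' @param gene_counts A codon count tibble (per-`source_id`).
#' @param weights Optional [reference_weights()] table; adds a `cai`
#'   column.
#' @param exclude Amino acids excluded from CAI (see [cai()]).
#' @return A tibble with `source_id`, optional `cai`, `rcbs_gene`,
#'   `mrcbs_gene`.
#' @export
gene_scores <- function(gene_counts, weights = NULL,
                        exclude = cai_default_exclusions()) {
  m <- mrcbs(gene_counts)
  out <- dplyr::full_join(
    dplyr::rename(geo_mean_score(m, "rcbs"), rcbs_gene = "score"),
    dplyr::rename(geo_mean_score(m, "mrcbs"), mrcbs_gene = "score"),
    by = "source_id"
  )
  if (!is.null(weights)) {
    out <- dplyr::left_join(
      cai(gene_counts, weights, exclude = exclude)[, c("source_id", "cai")],
      out,
      by = "source_id"
    )
  }
  out
}

#' Classify amino acids into high/low predicted expression
#'
#' Averages MRCBS per amino acid (over codons and, when several sequences
#' are present, over sequences) and labels amino acids whose mean exceeds
#' the threshold as high predicted expression, strictly: a mean exactly at
#' the threshold is low.  The default threshold 0.62 is the conventional
#' operating point for this index.
#'
#' @param mrcbs_tbl A per-codon MRCBS tibble from [mrcbs()].
#' @param threshold Classification threshold in [0, 1] (default 0.62).
#' @param exclude Amino-acid names left out of the classification
#'   (default none; stop codons are always dropped).
#' @return A tibble with `amino_acid`, `mean_mrcbs`, `expression`
#'   (`"high"`/`"low"`).
#' @export
classify_expression <- function(mrcbs_tbl, threshold = 0.62,
                                exclude = character(0)) {
  stopifnot(threshold >= 0, threshold <= 1)
  mrcbs_tbl |>
    dplyr::filter(
      .data$amino_acid != "Stop",
      !(.data$amino_acid %in% exclude),
      .data$count > 0L
    ) |>
    dplyr::group_by(amino_acid = .data$amino_acid) |>
    dplyr::summarise(mean_mrcbs = mean(.data$mrcbs), .groups = "drop") |>
    dplyr::mutate(
      expression = dplyr::if_else(
        .data$mean_mrcbs > threshold, "high", "low"
      )
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_mrcbs))
}

#' Per-amino-acid summary of an index (mean and sd)
#'
#' The bar-chart-shaped summary of an index across a corpus: mean and
#' standard deviation per amino acid over all (sequence, codon) values,
#' conventionally excluding the single-codon families Met and Trp whose
#' values carry no synonymous signal.
#'
#' @param index_tbl A per-codon index tibble (e.g. [rscu()], [mrcbs()]).
#' @param value_col Name of the value column to summarise.
#' @param exclude Amino acids to drop (default Met, Trp and Stop).
#' @param used_only Summarise only codons with `count > 0` (default TRUE).
#' @return A tibble with `amino_acid`, `mean`, `sd`, `n`.
#' @export
amino_acid_summary <- function(index_tbl, value_col,
                               exclude = c("Methionine", "Tryptophan",
                                           "Stop"),
                               used_only = TRUE) {
  tbl <- dplyr::filter(index_tbl, !(.data$amino_acid %in% exclude))
  if (used_only) tbl <- dplyr::filter(tbl, .data$count > 0L)
  tbl |>
    dplyr::group_by(amino_acid = .data$amino_acid) |>
    dplyr::summarise(
      mean = mean(.data[[value_col]]),
      sd = stats::sd(.data[[value_col]]),
      n = dplyr::n(),
      .groups = "drop"
    )
}
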
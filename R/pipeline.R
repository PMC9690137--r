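#' Run the full codon-usage analysis pipeline
#'
#' End-to-end analysis of a FASTA corpus: QC (validation, deduplication,
#' optional ORF extraction), codon counting, the four bias indices (CAI
#' against a reference weight table, RSCU, RCBS, MRCBS), per-amino-acid
#' summaries, fixed-effects ANOVA of the MRCBS table, a per-codon
#' z-screen, correlation PCA across the three per-codon indices, and the
#' high/low expression classification.  Deterministic given inputs and
#' settings: no randomness is involved.
#'
#' Composition (GC%, length) is always reported on the full input record;
#' with `cds_only = TRUE` the indices are computed on the longest
#' extracted ORF of each record instead of the record itself, which is the
#' appropriate route for mRNA inputs with UTRs.
#'
#' The CAI reference defaults to the pooled codon counts of the analysis
#' corpus itself — self-contained and reproducible; supply `reference` (a
#' FASTA path) to use an external reference gene set.
#'
#' @param fasta Path to a FASTA file, or a sequence tibble (as from
#'   [read_fasta()] or [generate_corpus()]`$sequences`).
#' @param rscu_variant `"fraction"` (within-family fraction) or
#'   `"classical"`; see [rscu()].
#' @param reference `NULL` (pooled input corpus), a FASTA path, or a
#'   pooled codon count tibble.
#' @param cai_exclude Amino acids excluded from CAI (see [cai()]).
#' @param mrcbs_threshold Expression classification threshold (default
#'   0.62).
#' @param alpha z-screen significance level (default 0.05).
#' @param cds_only Extract and analyse the longest ORF per record.
#' @param require_start,require_stop QC flags passed to [qc_corpus()].
#' @param out_dir Optional directory; when set, every stage output is
#'   written as TSV/JSON with a `manifest.json`.
#' @param verbose Narrate stage boundaries and record counts.
#' @return A `codon_report` list: `per_sequence`, `per_codon`,
#'   `amino_acid_summary` (per index), `anova`, `z_screen`, `pca`,
#'   `classification`, `qc_report`, `settings`.
#' @examples
#' corpus <- generate_corpus(synthetic_spec(n_sequences = 4,
#'                                          length_range = c(300, 900),
#'                                          seed = 7))
#' rep <- run_analysis(corpus$sequences)
#' rep$per_sequence
#' @export
run_analysis <- function(fasta,
                         rscu_variant = c("fraction", "classical"),
                         reference = NULL,
                         cai_exclude = cai_default_exclusions(),
                         mrcbs_threshold = 0.62,
                         alpha = 0.05,
                         cds_only = FALSE,
                         require_start = TRUE,
                         require_stop = TRUE,
                         out_dir = NULL,
                         verbose = FALSE) {
  rscu_variant <- match.arg(rscu_variant)
  say <- function(...) if (verbose) message("[codonbias] ", ...)

  seqs <- if (is.character(fasta)) read_fasta(fasta) else
    tibble::as_tibble(fasta)
  say("input: ", nrow(seqs), " record(s)")
  record_stats <- gc_content(seqs)

  analysis_seqs <- if (cds_only) {
    say("extracting longest ORFs")
    extract_orf(seqs)
  } else {
    seqs
  }
  qc <- qc_corpus(analysis_seqs, require_start, require_stop)
  if (nrow(qc$sequences) == 0L) {
    stop("run_analysis() [qc]: zero sequences survive validation; ",
         "reasons: ", paste(unique(qc$report$rejected$reason),
                            collapse = "; "))
  }
  say("qc: ", length(qc$report$passed), " passed, ",
      nrow(qc$report$rejected), " rejected, ",
      length(qc$report$duplicates_removed), " duplicate(s) removed")

  counts <- count_codons(qc$sequences)

  ref_counts <- if (is.null(reference)) {
    pool_counts(counts, pool_id = "input-corpus-pool")
  } else if (is.character(reference)) {
    ref_qc <- qc_corpus(read_fasta(reference), require_start, require_stop)
    pool_counts(count_codons(ref_qc$sequences),
                pool_id = paste0("reference:", basename(reference)))
  } else {
    reference
  }
  weights <- reference_weights(ref_counts)
  say("CAI reference: ", attr(weights, "reference_label"))

  r <- rscu(counts, variant = rscu_variant)
  m <- mrcbs(counts)
  per_codon <- r |>
    dplyr::left_join(
      rcbs(counts)[, c("source_id", "codon", "rcbs")],
      by = c("source_id", "codon")
    ) |>
    dplyr::left_join(
      m[, c("source_id", "codon", "mrcbs")],
      by = c("source_id", "codon")
    )

  scores <- gene_scores(counts, weights, exclude = cai_exclude)
  per_sequence <- qc$sequences[, c("id", "accession")] |>
    dplyr::left_join(dplyr::rename(scores, id = "source_id"), by = "id") |>
    dplyr::left_join(record_stats, by = "id") |>
    dplyr::select("id", "accession", "cai", "rcbs_gene", "mrcbs_gene",
                  "gc_percent", "length_bp")

  aa_sum <- list(
    rscu = amino_acid_summary(r, "rscu"),
    mrcbs = amino_acid_summary(m, "mrcbs")
  )

  long <- tibble::tibble(
    sequence_id = m$source_id,
    amino_acid = m$amino_acid,
    codon = m$codon,
    value = m$mrcbs
  )
  if (length(unique(long$sequence_id)) >= 2L) {
    say("ANOVA on the MRCBS long table (", nrow(long), " rows)")
    anova <- anova_report(long)
  } else {
    say("ANOVA skipped: fewer than 2 sequences")
    anova <- NULL
  }

  codon_means <- m |>
    dplyr::group_by(codon = .data$codon) |>
    dplyr::summarise(value = mean(.data$mrcbs), .groups = "drop")
  z <- codon_z_screen(codon_means, alpha = alpha)

  wide <- per_codon[, c("source_id", "codon", "rscu", "rcbs", "mrcbs")]
  pca <- pca_indices(wide, cols = c("rscu", "mrcbs", "rcbs"))

  classification <- classify_expression(m, threshold = mrcbs_threshold)

  report <- structure(
    list(
      per_sequence = per_sequence,
      per_codon = per_codon,
      amino_acid_summary = aa_sum,
      anova = anova,
      z_screen = z,
      pca = pca,
      classification = classification,
      qc_report = qc$report,
      settings = list(
        rscu_variant = rscu_variant,
        reference = attr(weights, "reference_label"),
        cai_exclude = cai_exclude,
        mrcbs_threshold = mrcbs_threshold,
        alpha = alpha,
        cds_only = cds_only,
        require_start = require_start,
        require_stop = require_stop
      )
    ),
    class = "codon_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir, verbose = verbose)
  report
}

# two two-way fixed-effects fits; the combined table presents each factor
# at its full k-1 degrees of freedom (codon determines amino acid, so a
# single three-factor fit cannot)
anova_report <- function(long) {
  seq_aa <- anova_fixed(long, c("sequence", "amino_acid"))
  seq_codon <- anova_fixed(long, c("sequence", "codon"))
  combined <- dplyr::bind_rows(
    dplyr::mutate(
      seq_aa$table[seq_aa$table$term != "Residuals", ],
      source = c("Sequences", "Amino acids")
    ),
    dplyr::mutate(
      seq_codon$table[seq_codon$table$term == "codon", ],
      source = "Codons"
    )
  )[, c("source", "df", "sumsq", "meansq", "statistic", "p.value")]
  list(
    sequence_amino_acid = seq_aa,
    sequence_codon = seq_codon,
    combined = combined
  )
}

#' @export
print.codon_report <- function(x, ...) {
  cat("Codon-usage analysis report\n")
  cat("  sequences:", nrow(x$per_sequence), "\n")
  cat("  CAI range: [",
      sprintf("%.2f", min(x$per_sequence$cai)), ", ",
      sprintf("%.2f", max(x$per_sequence$cai)), "]\n", sep = "")
  cat("  GC% range: [",
      sprintf("%.2f", min(x$per_sequence$gc_percent)), ", ",
      sprintf("%.2f", max(x$per_sequence$gc_percent)), "]\n", sep = "")
  high <- x$classification$amino_acid[x$classification$expression == "high"]
  cat("  high-expression amino acids (MRCBS > ",
      x$settings$mrcbs_threshold, "): ",
      paste(high, collapse = ", "), "\n", sep = "")
  cat("  z-screen: ", sum(x$z_screen$significant), " codon(s) at alpha = ",
      x$settings$alpha, "\n", sep = "")
  cat("  PCA eigenvalues: ",
      paste(sprintf("%.2f", x$pca$eigenvalues), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Write every stage output of a report to disk
#'
#' Serialises the report as TSV/JSON files under `out_dir` with a
#' `manifest.json` listing files and settings.  Numbers are written at
#' full precision; the per-sequence table mirrors the usual corpus summary
#' (id, accession, CAI, gene scores, GC% and length).
#'
#' @param report A `codon_report` from [run_analysis()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Narrate files written.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(report$per_sequence, p("per_sequence.tsv"))
  readr::write_tsv(report$per_codon, p("per_codon.tsv"))
  readr::write_tsv(report$amino_acid_summary$rscu,
                   p("amino_acid_summary_rscu.tsv"))
  readr::write_tsv(report$amino_acid_summary$mrcbs,
                   p("amino_acid_summary_mrcbs.tsv"))
  if (!is.null(report$anova)) {
    readr::write_tsv(report$anova$combined, p("anova_combined.tsv"))
    jsonlite::write_json(
      list(
        sequence_amino_acid = report$anova$sequence_amino_acid$table,
        sequence_codon = report$anova$sequence_codon$table,
        combined = report$anova$combined
      ),
      p("anova.json"), auto_unbox = TRUE, digits = NA
    )
  }
  readr::write_tsv(report$z_screen, p("z_screen.tsv"))
  jsonlite::write_json(
    list(
      eigenvalues = report$pca$eigenvalues,
      proportion = report$pca$proportion,
      loadings = as.data.frame(report$pca$loadings)
    ),
    p("pca.json"), auto_unbox = TRUE, digits = NA
  )
  readr::write_tsv(report$classification, p("classification.tsv"))
  write_validation_report(report$qc_report,
                          json_path = p("validation_report.json"),
                          tsv_path = p("validation_report.tsv"))
  files <- c(
    "per_sequence.tsv", "per_codon.tsv", "amino_acid_summary_rscu.tsv",
    "amino_acid_summary_mrcbs.tsv",
    if (!is.null(report$anova)) c("anova_combined.tsv", "anova.json"),
    "z_screen.tsv", "pca.json", "classification.tsv",
    "validation_report.json", "validation_report.tsv"
  )
  jsonlite::write_json(
    list(files = files, settings = report$settings),
    p("manifest.json"), auto_unbox = TRUE
  )
  if (verbose) message("[codonbias] wrote ", length(files) + 1,
                       " files to ", out_dir)
  invisible(out_dir)
}
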
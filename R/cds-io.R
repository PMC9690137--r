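#' Read nucleotide sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble of unvalidated sequences, one row per
#' record, preserving file order.  The header token before the first
#' whitespace becomes the `id`; sequences are uppercased and RNA `U` is
#' mapped to `T`.  Ids that look like versioned NCBI accessions (e.g.
#' `NM_001247047.2`) are copied into the `accession` column.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `accession`, `sequence`,
#'   `length_bp`, `is_validated` (all `FALSE` on read).
#' @seealso [validate_cds()], [write_fasta()]
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 demo", "ATGTTTTAA"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    stop("format error: ", path, " contains no FASTA records")
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("format error in ", path, ": line ", first,
         " is not a FASTA header: ", substr(lines[first], 1, 40))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("format error: ", path, " contains no FASTA records")
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- chartr("u", "t", chartr("U", "T", toupper(as.character(set))))
  as_cds_tbl(ids, seqs)
}

as_cds_tbl <- function(ids, seqs, accession = NULL) {
  if (is.null(accession)) {
    accession <- ifelse(
      grepl("^[A-Z]{2}_[0-9]+\\.[0-9]+$", ids), ids, NA_character_
    )
  }
  tibble::tibble(
    id = ids,
    accession = accession,
    sequence = unname(seqs),
    length_bp = nchar(seqs),
    is_validated = FALSE
  )
}

#' Write sequences to a FASTA file
#'
#' @param seqs A sequence tibble (as from [read_fasta()]).
#' @param path Output path.
#' @param width Line width for wrapped sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(stats::setNames(seqs$sequence, seqs$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Validate coding sequences
#'
#' Applies the coding-sequence QC rules: the sequence must contain only
#' A/C/G/T (ambiguity codes such as N are rejected rather than skipped,
#' because every downstream index assumes unambiguous codons), its length
#' must be a positive multiple of 3, the first codon must be the ATG start
#' and the last codon one of the TAA/TAG/TGA stops.  The start/stop checks
#' can be disabled individually for inputs that are full mRNA records with
#' UTRs (see [extract_orf()] for the CDS-only route).
#'
#' @param seqs A sequence tibble (as from [read_fasta()]).
#' @param require_start,require_stop Enable the start/stop codon checks.
#' @return The input tibble with `is_validated` set and a `reason` column
#'   (`NA` for sequences that pass; otherwise one of `"non-ACGT symbol"`,
#'   `"length not multiple of 3"`, `"missing START"`, `"missing STOP"`).
#' @examples
#' seqs <- tibble::tibble(
#'   id = c("ok", "bad"), accession = NA_character_,
#'   sequence = c("ATGTTTTAA", "ATGTTN"), length_bp = c(9L, 6L),
#'   is_validated = FALSE
#' )
#' validate_cds(seqs)
#' @export
validate_cds <- function(seqs, require_start = TRUE, require_stop = TRUE) {
  reason <- rep(NA_character_, nrow(seqs))
  s <- seqs$sequence
  n <- nchar(s)
  bad_symbol <- grepl("[^ACGT]", s) | n == 0L
  off_frame <- !bad_symbol & (n %% 3L != 0L)
  first_codon <- substr(s, 1L, 3L)
  last_codon <- substr(s, n - 2L, n)
  no_start <- require_start & !bad_symbol & !off_frame & first_codon != "ATG"
  no_stop <- require_stop & !bad_symbol & !off_frame &
    !(last_codon %in% c("TAA", "TAG", "TGA"))
  reason[no_stop] <- "missing STOP"
  reason[no_start] <- "missing START"
  reason[off_frame] <- "length not multiple of 3"
  reason[bad_symbol] <- "non-ACGT symbol"
  out <- seqs
  out$is_validated <- is.na(reason)
  out$reason <- reason
  out
}

#' Remove exact-sequence duplicates
#'
#' A duplicate is an identical nucleotide string (not an identical id); the
#' first occurrence is kept.  Idempotent.
#'
#' @param seqs A sequence tibble.
#' @return The deduplicated tibble, with the ids of removed records in the
#'   `"duplicates_removed"` attribute.
#' @export
deduplicate <- function(seqs) {
  dup <- duplicated(seqs$sequence)
  out <- seqs[!dup, ]
  attr(out, "duplicates_removed") <- seqs$id[dup]
  out
}

#' Validate and deduplicate a corpus, with an accounting report
#'
#' Runs [validate_cds()] then [deduplicate()] on the survivors and returns
#' both the clean corpus and a `validation_report` whose three buckets
#' (passed, rejected, duplicates removed) partition the input exactly.
#'
#' @inheritParams validate_cds
#' @return A list with `sequences` (clean tibble) and `report`
#'   (`validation_report`: `input_count`, `passed`, `rejected` tibble of
#'   id/reason, `duplicates_removed`).
#' @export
qc_corpus <- function(seqs, require_start = TRUE, require_stop = TRUE) {
  checked <- validate_cds(seqs, require_start, require_stop)
  ok <- checked[checked$is_validated, setdiff(names(checked), "reason")]
  rejected <- tibble::tibble(
    id = checked$id[!checked$is_validated],
    reason = checked$reason[!checked$is_validated]
  )
  clean <- deduplicate(ok)
  report <- structure(
    list(
      input_count = nrow(seqs),
      passed = clean$id,
      rejected = rejected,
      duplicates_removed = attr(clean, "duplicates_removed")
    ),
    class = "validation_report"
  )
  stopifnot(
    report$input_count ==
      length(report$passed) + nrow(report$rejected) +
      length(report$duplicates_removed)
  )
  list(sequences = clean, report = report)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report:", x$input_count, "input sequence(s)\n")
  cat("  passed:            ", length(x$passed), "\n")
  cat("  rejected:          ", nrow(x$rejected), "\n")
  cat("  duplicates removed:", length(x$duplicates_removed), "\n")
  invisible(x)
}

#' Serialise a validation report
#'
#' @param report A `validation_report` from [qc_corpus()].
#' @param json_path,tsv_path Optional output paths; the TSV has two columns
#'   (id, disposition).
#' @return A tibble of (id, disposition), invisibly if written.
#' @export
write_validation_report <- function(report, json_path = NULL,
                                    tsv_path = NULL) {
  tsv <- tibble::tibble(
    id = c(report$passed, report$rejected$id, report$duplicates_removed),
    disposition = c(
      rep("passed", length(report$passed)),
      if (nrow(report$rejected) > 0L) {
        paste0("rejected: ", report$rejected$reason)
      } else {
        character(0)
      },
      rep("duplicate", length(report$duplicates_removed))
    )
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE)
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(tsv, tsv_path)
  }
  if (is.null(json_path) && is.null(tsv_path)) tsv else invisible(tsv)
}

#' Extract the longest open reading frame from each record
#'
#' Scans the forward strand in frames 0, 1 and 2 for ATG-to-stop open
#' reading frames (stop included) and returns the longest per record.
#' Intended for full mRNA records with UTRs, where composition statistics
#' are reported on the full record but codon indices are only meaningful on
#' the CDS.  Coordinates are 0-based half-open.
#'
#' @param seqs A sequence tibble.
#' @return A tibble with the ORF as `sequence` plus `orf_start`, `orf_end`
#'   (0-based half-open on the input record) and `record_length_bp`; rows
#'   with no ORF are dropped.
#' @export
extract_orf <- function(seqs) {
  rows <- lapply(seq_len(nrow(seqs)), function(i) {
    orf <- longest_orf(seqs$sequence[i])
    if (is.null(orf)) return(NULL)
    tibble::tibble(
      id = seqs$id[i],
      accession = seqs$accession[i],
      sequence = orf$seq,
      length_bp = nchar(orf$seq),
      is_validated = FALSE,
      orf_start = orf$start,
      orf_end = orf$end,
      record_length_bp = nchar(seqs$sequence[i])
    )
  })
  dplyr::bind_rows(rows)
}

longest_orf <- function(seq) {
  n <- nchar(seq)
  best <- NULL
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0L) next
    codons <- substring(seq, starts, starts + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% stops
    open_from <- NA_integer_
    for (k in seq_along(codons)) {
      if (is.na(open_from) && is_start[k]) open_from <- k
      if (!is.na(open_from) && is_stop[k]) {
        len <- (k - open_from + 1L) * 3L
        if (is.null(best) || len > best$len) {
          best <- list(
            len = len,
            start = starts[open_from] - 1L,
            end = starts[k] + 2L,
            seq = substr(seq, starts[open_from], starts[k] + 2L)
          )
        }
        open_from <- NA_integer_
      }
    }
  }
  best
}

#' Download NCBI nucleotide records (optional convenience, needs network)
#'
#' Fetches versioned accessions from NCBI efetch into a FASTA file.  This
#' helper is a convenience for reproducing analyses on public transcripts;
#' it requires internet access and is never used by the test suite, which
#' runs entirely on synthetic sequences from [generate_corpus()].
#'
#' @param accessions Character vector of versioned accessions.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
fetch_accessions <- function(accessions, path) {
  url <- paste0(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
    "?db=nuccore&rettype=fasta&retmode=text&id=",
    paste(accessions, collapse = ",")
  )
  utils::download.file(url, path, quiet = TRUE)
  invisible(path)
}
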
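# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# expected GC% of one body codon under (aa_composition, preferences)
expected_body_gc <- function(prefs, aa_composition) {
  gc_per_codon <- nchar(gsub("[^GC]", "", prefs$codon)) / 3
  per_aa <- tapply(prefs$pref * gc_per_codon, prefs$amino_acid, sum)
  100 * sum(aa_composition[names(per_aa)] * per_aa)
}

# deterministic per-(sequence, attempt) sub-seed below 2^31
derive_seed <- function(seed, index, attempt = 0L) {
  as.integer(
    (as.numeric(seed) * 2654435761 + index * 1000003 + attempt * 7919) %%
      2147483647
  )
}

#' Specification for a synthetic coding-sequence corpus
#'
#' Defines the ground truth for a simulated corpus of clean open reading
#' frames: every sequence is `ATG` + i.i.d. body codons + one stop codon.
#' Body amino acids are drawn from `aa_composition` and the codon within
#' each family from `codon_preferences`, so the generating within-family
#' fractions are known exactly and index estimators can be checked for
#' recovery.  Stop codons never occur in the body (clean ORFs by
#' construction); the terminal stop is drawn from `stop_preferences`.
#'
#' The defaults emulate a small plant heat-shock-protein transcript set:
#' 19 sequences of 800–4000 nt with GC% in the 33–45 band, with
#' per-family preferences drawn once from a flat Dirichlet using `seed`.
#'
#' @param n_sequences Number of sequences (default 19).
#' @param length_range Total length bounds in nt, inclusive; both must be
#'   positive multiples of 3 (default `c(801, 3999)`).
#' @param aa_composition Named probability vector over the 20 amino acids
#'   (full names); default uniform.  Must sum to 1.
#' @param codon_preferences Either `NULL` (Dirichlet(1)-sampled per family
#'   from `seed`) or a tibble with columns `codon` and `pref` covering the
#'   61 sense codons, `pref` summing to 1 within each family.
#' @param stop_preferences Named probabilities over TAA/TAG/TGA (default
#'   uniform).
#' @param target_gc_band Length-2 numeric `(low%, high%)` or `NULL` to
#'   disable GC rejection sampling (default `c(33, 45)`).
#' @param seed Integer seed; the corpus is byte-identical for a fixed
#'   seed.
#' @return A `synthetic_spec` object.
#' @examples
#' spec <- synthetic_spec(n_sequences = 3, length_range = c(300, 600),
#'                        seed = 42)
#' corpus <- generate_corpus(spec)
#' corpus$sequences$length_bp
#' @export
synthetic_spec <- function(n_sequences = 19L,
                           length_range = c(801L, 3999L),
                           aa_composition = NULL,
                           codon_preferences = NULL,
                           stop_preferences = c(TAA = 1, TAG = 1, TGA = 1) / 3,
                           target_gc_band = c(33, 45),
                           seed = 1L) {
  code <- genetic_code()
  sense <- code[code$aa != "*", ]
  aa_names <- sort(unique(sense$amino_acid))
  if (is.null(aa_composition)) {
    aa_composition <- stats::setNames(
      rep(1 / length(aa_names), length(aa_names)), aa_names
    )
  }
  if (!setequal(names(aa_composition), aa_names)) {
    stop("aa_composition must be named by the 20 amino acids")
  }
  if (abs(sum(aa_composition) - 1) > 1e-12) {
    stop("aa_composition must sum to 1")
  }
  if (length(length_range) != 2L || any(length_range <= 0) ||
      any(length_range %% 3 != 0) || length_range[1] > length_range[2]) {
    stop("length_range must be two positive multiples of 3, min <= max")
  }
  if (is.null(codon_preferences)) {
    # Dirichlet(1)-sampled family preferences; when a GC band is requested
    # the draw is repeated until the implied expected body GC sits in the
    # band's central region, so per-sequence rejection converges quickly
    # while the drawn preferences stay the exact ground truth
    draw_prefs <- function(attempt) {
      with_seed(derive_seed(seed, 0L, attempt), {
        dplyr::bind_rows(lapply(
          split(sense, sense$amino_acid),
          function(fam) {
            g <- stats::rgamma(nrow(fam), shape = 1)
            tibble::tibble(
              codon = fam$codon, amino_acid = fam$amino_acid,
              pref = g / sum(g)
            )
          }
        ))
      })
    }
    codon_preferences <- draw_prefs(0L)
    if (!is.null(target_gc_band)) {
      width <- target_gc_band[2] - target_gc_band[1]
      lo <- target_gc_band[1] + 0.2 * width
      hi <- target_gc_band[2] - 0.2 * width
      for (attempt in seq_len(1000L)) {
        egc <- expected_body_gc(codon_preferences, aa_composition)
        if (egc >= lo && egc <= hi) break
        codon_preferences <- draw_prefs(attempt)
      }
    }
  } else {
    codon_preferences <- dplyr::left_join(
      codon_preferences[, c("codon", "pref")],
      sense[, c("codon", "amino_acid")],
      by = "codon"
    )
    if (any(is.na(codon_preferences$amino_acid)) ||
        nrow(codon_preferences) != nrow(sense)) {
      stop("codon_preferences must cover exactly the 61 sense codons")
    }
    fam_sums <- tapply(codon_preferences$pref, codon_preferences$amino_acid,
                       sum)
    if (any(abs(fam_sums - 1) > 1e-12)) {
      stop("codon_preferences must sum to 1 within each family (off: ",
           paste(names(fam_sums)[abs(fam_sums - 1) > 1e-12], collapse = ", "),
           ")")
    }
  }
  if (abs(sum(stop_preferences) - 1) > 1e-12 ||
      !setequal(names(stop_preferences), c("TAA", "TAG", "TGA"))) {
    stop("stop_preferences must be named TAA/TAG/TGA and sum to 1")
  }
  if (!is.null(target_gc_band) &&
      (length(target_gc_band) != 2L ||
       target_gc_band[1] >= target_gc_band[2])) {
    stop("target_gc_band must be (low, high) with low < high, or NULL")
  }
  structure(
    list(
      n_sequences = as.integer(n_sequences),
      length_range = as.integer(length_range),
      aa_composition = aa_composition[aa_names],
      codon_preferences = codon_preferences,
      stop_preferences = stop_preferences,
      target_gc_band = target_gc_band,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate one synthetic coding sequence
#'
#' Deterministic given `(spec$seed, index, attempt)`.  Returns both the
#' sequence and the generation ledger — the exact tally of every codon
#' drawn — which downstream counting must reproduce exactly.
#'
#' @param spec A [synthetic_spec()].
#' @param index Sequence index within the corpus (drives the sub-seed and
#'   the id `syn<index>`).
#' @param attempt Rejection-sampling attempt number (internal; changes the
#'   sub-seed).
#' @return A list with `sequence` (one-row tibble) and `ledger` (64-row
#'   codon count tibble).
#' @export
generate_cds <- function(spec, index, attempt = 0L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  code <- genetic_code()
  prefs <- spec$codon_preferences
  with_seed(derive_seed(spec$seed, index, attempt), {
    lens <- seq.int(spec$length_range[1], spec$length_range[2], by = 3L)
    len <- if (length(lens) == 1L) lens else sample(lens, 1L)
    n_body <- len %/% 3L - 2L
    if (n_body < 1L) stop("length_range too short for ATG + body + STOP")
    aa_draw <- sample(names(spec$aa_composition), n_body, replace = TRUE,
                      prob = spec$aa_composition)
    body <- character(n_body)
    for (fam in unique(aa_draw)) {
      at <- which(aa_draw == fam)
      p <- prefs[prefs$amino_acid == fam, ]
      body[at] <- if (nrow(p) == 1L) p$codon else {
        sample(p$codon, length(at), replace = TRUE, prob = p$pref)
      }
    }
    stop_codon <- sample(names(spec$stop_preferences), 1L,
                         prob = spec$stop_preferences)
    codons <- c("ATG", body, stop_codon)
    seq <- paste(codons, collapse = "")
    id <- sprintf("syn%02d", index)
    tab <- table(factor(codons, levels = code$codon))
    ledger <- tibble::tibble(
      source_id = id,
      codon = code$codon,
      amino_acid = code$amino_acid,
      aa = code$aa,
      family_size = code$family_size,
      count = as.integer(tab)
    )
    list(
      sequence = tibble::tibble(
        id = id, accession = NA_character_, sequence = seq,
        length_bp = nchar(seq), is_validated = FALSE
      ),
      ledger = ledger
    )
  })
}

#' Generate a synthetic corpus with ground truth
#'
#' Draws `spec$n_sequences` sequences; when `spec$target_gc_band` is set,
#' each sequence is rejection-sampled (fresh sub-seed per attempt, cap
#' 1000) until its GC% falls inside the band, so the generating codon
#' preferences remain the exact ground truth.  All sequences are validated
#' before return.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_corpus` list: `sequences` (validated tibble),
#'   `ledger` (long codon-count tibble, one 64-row block per sequence),
#'   `preferences` (the generating within-family fractions), `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  band <- spec$target_gc_band
  seqs <- vector("list", spec$n_sequences)
  ledgers <- vector("list", spec$n_sequences)
  for (i in seq_len(spec$n_sequences)) {
    found <- FALSE
    for (attempt in 0:999) {
      cand <- generate_cds(spec, i, attempt)
      if (is.null(band)) {
        found <- TRUE
      } else {
        gc <- gc_content(cand$sequence)$gc_percent
        found <- gc >= band[1] && gc <= band[2]
      }
      if (found) break
    }
    if (!found) {
      stop("generate_corpus(): could not reach GC band (", band[1], ", ",
           band[2], ")% for sequence ", i, " in 1000 attempts; the codon ",
           "preferences imply a GC content incompatible with the band")
    }
    seqs[[i]] <- cand$sequence
    ledgers[[i]] <- cand$ledger
  }
  sequences <- validate_cds(dplyr::bind_rows(seqs))
  stopifnot(all(sequences$is_validated))
  structure(
    list(
      sequences = sequences[, setdiff(names(sequences), "reason")],
      ledger = dplyr::bind_rows(ledgers),
      preferences = spec$codon_preferences,
      spec = spec
    ),
    class = "synthetic_corpus"
  )
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("Synthetic corpus:", nrow(x$sequences), "coding sequences,",
      "lengths", min(x$sequences$length_bp), "-",
      max(x$sequences$length_bp), "nt, seed", x$spec$seed, "\n")
  invisible(x)
}

#' Write a synthetic corpus to FASTA plus a ground-truth JSON
#'
#' @param corpus A `synthetic_corpus` from [generate_corpus()].
#' @param fasta_path Output FASTA path.
#' @param truth_path Optional JSON path for the ground truth (spec echo,
#'   generating preferences, per-sequence codon totals).
#' @return `fasta_path`, invisibly.
#' @export
write_corpus <- function(corpus, fasta_path, truth_path = NULL) {
  write_fasta(corpus$sequences, fasta_path)
  if (!is.null(truth_path)) {
    truth <- list(
      n_sequences = nrow(corpus$sequences),
      seed = corpus$spec$seed,
      length_range = corpus$spec$length_range,
      target_gc_band = corpus$spec$target_gc_band,
      aa_composition = as.list(corpus$spec$aa_composition),
      preferences = corpus$preferences,
      ledger_totals = tapply(
        corpus$ledger$count, corpus$ledger$source_id, sum
      )
    )
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(fasta_path)
}
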
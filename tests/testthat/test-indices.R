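test_that("reference weights: family maxima get 1, others their ratio", {
  rw <- reference_weights(make_counts(c(
    TTT = 3, TTC = 1,          # Phe, 2-fold
    ATG = 5,                   # Met, single
    GGA = 2, GGC = 2           # Gly tie (GGG/GGT zero, pseudo)
  ), "ref"))
  w <- stats::setNames(rw$w, rw$codon)
  expect_equal(w[["TTT"]], 1)
  expect_equal(w[["TTC"]], 1 / 3)
  expect_equal(w[["ATG"]], 1)
  expect_equal(w[["GGA"]], 1)
  expect_equal(w[["GGC"]], 1)
  # zero-count codons in a used family get the pseudo-weight floor
  expect_equal(w[["GGG"]], 0.5 / 2)
  # unused families are undefined
  expect_true(is.na(w[["AAA"]]))
  expect_error(reference_weights(make_counts(c(ATG = 0))), "empty")
})

test_that("CAI point cases: all-maximal gene gives 1, constant w gives w", {
  ref <- reference_weights(make_counts(
    c(TTT = 4, TTC = 1, AAA = 2, AAG = 1), "ref"
  ))
  # gene uses only the family-maximal codons
  g_max <- make_counts(c(TTT = 7, AAA = 3), "gmax")
  expect_equal(cai(g_max, ref)$cai, 1)
  # 10 repeats of a codon with w = 0.25
  g_const <- make_counts(c(TTC = 10), "gconst")
  expect_equal(cai(g_const, ref)$cai, 0.25)
  # a gene consisting only of excluded codons errors
  g_met <- make_counts(c(ATG = 4), "gmet")
  expect_error(cai(g_met, ref), "no codons")
})

test_that("CAI matches the product-then-root oracle on random genes", {
  spec <- tiny_spec(seed = 17)
  corpus <- generate_corpus(spec)
  counts <- count_codons(corpus$sequences)
  ref <- reference_weights(pool_counts(counts))
  fast <- cai(counts, ref)
  for (sid in unique(counts$source_id)) {
    d <- dplyr::left_join(
      counts[counts$source_id == sid, ],
      ref[, c("codon", "w")], by = "codon"
    )
    d <- d[d$count > 0 & !(d$amino_acid %in%
                             c("Methionine", "Tryptophan", "Stop")), ]
    slow <- prod(rep(d$w, d$count))^(1 / sum(d$count))
    expect_equal(fast$cai[fast$source_id == sid], slow,
                 tolerance = 1e-10)
  }
})

test_that("RSCU fraction variant: family fractions summing to 1", {
  v <- rscu(make_counts(c(TTT = 3, TTC = 1)))
  r <- stats::setNames(v$rscu, v$codon)
  expect_equal(r[["TTT"]], 0.75)
  expect_equal(r[["TTC"]], 0.25)
  # equal 2-fold usage sits exactly at the 0.5 threshold
  v2 <- rscu(make_counts(c(AAA = 5, AAG = 5)))
  expect_equal(v2$rscu[v2$codon %in% c("AAA", "AAG")], c(0.5, 0.5))
  # equal 4-fold usage gives 0.25 each
  v4 <- rscu(make_counts(c(GGA = 2, GGC = 2, GGG = 2, GGT = 2)))
  expect_equal(v4$rscu[v4$aa == "G"], rep(0.25, 4))
  # unused families are 0 and flagged
  expect_true(all(v$rscu[!v$family_used] == 0))
})

test_that("classical RSCU is the fraction variant scaled by family size", {
  cc <- make_counts(c(TTT = 3, TTC = 1, GGA = 1, GGC = 1, GGG = 1,
                      GGT = 1))
  p <- rscu(cc, "fraction")
  cl <- rscu(cc, "classical")
  expect_equal(cl$rscu, p$rscu * p$family_size)
  r <- stats::setNames(cl$rscu, cl$codon)
  expect_equal(r[["TTT"]], 1.5)
  expect_equal(r[["TTC"]], 0.5)
  expect_equal(unname(r[c("GGA", "GGC", "GGG", "GGT")]), rep(1, 4))
})

test_that("RSCU family sums: 1 for fraction variant, family size for classical", {
  corpus <- generate_corpus(tiny_spec(seed = 3))
  counts <- count_codons(corpus$sequences)
  for (variant in c("fraction", "classical")) {
    v <- rscu(counts, variant)
    sums <- v |>
      dplyr::filter(.data$family_used) |>
      dplyr::group_by(.data$source_id, .data$aa, .data$family_size) |>
      dplyr::summarise(s = sum(.data$rscu), .groups = "drop")
    target <- if (variant == "fraction") 1 else sums$family_size
    expect_true(all(abs(sums$s - target) < 1e-12))
  }
})

test_that("RCBS point cases", {
  # two codons AAA/TTT: f = 0.5, positional products 0.125 -> 4.0
  v <- rcbs(make_counts(c(AAA = 1, TTT = 1)))
  expect_equal(v$rcbs[v$codon == "AAA"], 4)
  expect_equal(v$rcbs[v$codon == "TTT"], 4)
  # a gene of a single codon type has RCBS exactly 1
  v1 <- rcbs(make_counts(c(ATG = 12)))
  expect_equal(v1$rcbs[v1$codon == "ATG"], 1)
  # zero-count codons get 0
  expect_true(all(v$rcbs[v$count == 0] == 0))
})

test_that("MRCBS is family-normalised into [0, 1] with a 1 per used family", {
  corpus <- generate_corpus(tiny_spec(seed = 13))
  counts <- count_codons(corpus$sequences)
  m <- mrcbs(counts)
  expect_true(all(m$mrcbs >= 0 & m$mrcbs <= 1 + 1e-12))
  fam_max <- m |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$source_id, .data$aa) |>
    dplyr::summarise(mx = max(.data$mrcbs), .groups = "drop")
  expect_true(all(abs(fam_max$mx - 1) < 1e-12))
  # single-codon families score 1 when used
  expect_true(all(
    m$mrcbs[m$amino_acid == "Methionine" & m$count > 0] == 1
  ))
})

test_that("gene-level MRCBS matches the product-then-root oracle", {
  corpus <- generate_corpus(tiny_spec(seed = 19))
  counts <- count_codons(corpus$sequences)
  m <- mrcbs(counts)
  scores <- gene_scores(counts)
  for (sid in unique(counts$source_id)) {
    d <- m[m$source_id == sid & m$count > 0, ]
    slow <- prod(rep(d$mrcbs, d$count))^(1 / sum(d$count))
    expect_equal(scores$mrcbs_gene[scores$source_id == sid], slow,
                 tolerance = 1e-10)
    expect_gt(scores$mrcbs_gene[scores$source_id == sid], 0)
    expect_lte(scores$mrcbs_gene[scores$source_id == sid], 1)
  }
})

test_that("all indices and weights are invariant under count scaling", {
  base <- make_counts(c(
    TTT = 3, TTC = 1, AAA = 4, AAG = 2, GGA = 1, GGC = 5, ATG = 2,
    TAA = 1
  ))
  scaled <- dplyr::mutate(base, count = count * 7L)
  expect_equal(rscu(base)$rscu, rscu(scaled)$rscu)
  expect_equal(rscu(base, "classical")$rscu,
               rscu(scaled, "classical")$rscu)
  expect_equal(rcbs(base)$rcbs, rcbs(scaled)$rcbs)
  expect_equal(mrcbs(base)$mrcbs, mrcbs(scaled)$mrcbs)
  # weights of observed codons are scale-free; only the pseudo-weight
  # floor for unobserved codons shrinks with reference depth
  wb <- reference_weights(base)
  ws <- reference_weights(scaled)
  expect_equal(wb$w[wb$count > 0], ws$w[ws$count > 0])
})

test_that("expression classification is strict at the threshold", {
  m <- mrcbs(make_counts(c(TTT = 6, TTC = 2, ATG = 3)))
  # engineered table: force known means via direct values
  tbl <- tibble::tibble(
    amino_acid = c("Phenylalanine", "Methionine"),
    aa = c("F", "M"), codon = c("TTT", "ATG"),
    count = c(1L, 1L), mrcbs = c(0.62, 1.0)
  )
  out <- classify_expression(tbl)
  expect_equal(
    out$expression[out$amino_acid == "Phenylalanine"], "low"
  )
  expect_equal(out$expression[out$amino_acid == "Methionine"], "high")
  # all values 1 -> all high
  all_one <- dplyr::mutate(m[m$count > 0, ], mrcbs = 1)
  expect_true(all(classify_expression(all_one)$expression == "high"))
})

test_that("a family engineered to be maximally biased classifies high", {
  # Asn usage concentrated on AAT across a corpus
  prefs <- uniform_prefs()
  prefs$pref[prefs$codon == "AAT"] <- 1
  prefs$pref[prefs$codon == "AAC"] <- 0
  spec <- synthetic_spec(
    n_sequences = 6, length_range = c(600, 900),
    codon_preferences = prefs, seed = 23
  )
  corpus <- generate_corpus(spec)
  m <- mrcbs(count_codons(corpus$sequences))
  out <- classify_expression(m)
  expect_equal(
    out$expression[out$amino_acid == "Asparagine"], "high"
  )
})

test_that("amino-acid summaries exclude Met and Trp by default", {
  corpus <- generate_corpus(tiny_spec(seed = 29))
  r <- rscu(count_codons(corpus$sequences))
  s <- amino_acid_summary(r, "rscu")
  expect_false(any(s$amino_acid %in%
                     c("Methionine", "Tryptophan", "Stop")))
  expect_true(all(c("mean", "sd", "n") %in% names(s)))
})
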
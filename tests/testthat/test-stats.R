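# sums of squares by definition for a balanced two-factor additive design
ss_by_definition <- function(d, factor_col) {
  grand <- mean(d$value)
  means <- tapply(d$value, d[[factor_col]], mean)
  n_per <- table(d[[factor_col]])
  sum(n_per * (means - grand)^2)
}

test_that("sequential SS matches the by-definition oracle on balanced noiseless data", {
  a_eff <- c(a1 = 0, a2 = 1.5, a3 = -0.5)
  b_eff <- c(b1 = 0.2, b2 = -0.2)
  d <- expand.grid(sequence_id = names(a_eff), codon = names(b_eff),
                   rep = 1:3, stringsAsFactors = FALSE)
  d$value <- a_eff[d$sequence_id] + b_eff[d$codon]
  fit <- anova_fixed(d, c("sequence", "codon"))
  tab <- tidy(fit)
  expect_equal(tab$df[tab$term == "sequence_id"], 2L)
  expect_equal(tab$df[tab$term == "codon"], 1L)
  expect_equal(tab$sumsq[tab$term == "sequence_id"],
               ss_by_definition(d, "sequence_id"))
  expect_equal(tab$sumsq[tab$term == "codon"],
               ss_by_definition(d, "codon"))
  # additive noiseless data: residual SS is zero
  expect_equal(tab$sumsq[tab$term == "Residuals"], 0, tolerance = 1e-20)
})

test_that("balanced designs give order-invariant sequential SS and conserve total SS", {
  set.seed(7)
  d <- expand.grid(sequence_id = paste0("s", 1:4),
                   codon = paste0("c", 1:5), stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d))
  f1 <- tidy(anova_fixed(d, c("sequence", "codon")))
  f2 <- tidy(anova_fixed(d, c("codon", "sequence")))
  expect_equal(
    f1$sumsq[f1$term == "codon"], f2$sumsq[f2$term == "codon"],
    tolerance = 1e-10
  )
  expect_equal(
    f1$sumsq[f1$term == "sequence_id"],
    f2$sumsq[f2$term == "sequence_id"],
    tolerance = 1e-10
  )
  total <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(f1$sumsq), total, tolerance = 1e-8 * total)
})

test_that("a full 64-codon design yields the conventional df rows", {
  corpus <- generate_corpus(
    synthetic_spec(n_sequences = 19, length_range = c(300, 600),
                   seed = 41)
  )
  m <- mrcbs(count_codons(corpus$sequences))
  long <- tibble::tibble(
    sequence_id = m$source_id, amino_acid = m$amino_acid,
    codon = m$codon, value = m$mrcbs
  )
  f_codon <- tidy(anova_fixed(long, c("sequence", "codon")))
  expect_equal(f_codon$df[f_codon$term == "sequence_id"], 18L)
  expect_equal(f_codon$df[f_codon$term == "codon"], 63L)
  f_aa <- tidy(anova_fixed(long, c("sequence", "amino_acid")))
  expect_equal(f_aa$df[f_aa$term == "amino_acid"], 20L)
  expect_true(all(f_codon$meansq[1:2] ==
                    f_codon$sumsq[1:2] / f_codon$df[1:2]))
  # codon determines amino acid: the three-factor model is aliased
  expect_warning(
    anova_fixed(long, c("sequence", "amino_acid", "codon")),
    "aliased"
  )
})

test_that("anova_fixed rejects degenerate designs", {
  d <- data.frame(
    sequence_id = c("a", "a", "b"), codon = c("x", "y", "x"),
    value = rnorm(3)
  )
  expect_error(anova_fixed(d, c("sequence", "codon")), "saturated")
  d1 <- d
  d1$codon <- "x"
  expect_error(anova_fixed(d1, c("sequence", "codon")),
               "fewer than 2 levels")
  # all-equal values: zero SS everywhere
  d2 <- expand.grid(sequence_id = c("a", "b"), codon = c("x", "y"),
                    rep = 1:2, stringsAsFactors = FALSE)
  d2$value <- 1
  tab <- tidy(anova_fixed(d2, c("sequence", "codon")))
  expect_lt(max(tab$sumsq), 1e-20)
})

test_that("z-screen: point cases and affine invariance", {
  vals <- tibble::tibble(
    codon = c("AAA", "AAC", "AAG", "AAT", "ACA"),
    value = c(1, 1, 1, 1, 5)
  )
  z <- codon_z_screen(vals)
  expect_equal(z$codon[which.max(abs(z$z))], "ACA")
  # a value exactly at the mean
  sym <- tibble::tibble(
    codon = c("AAA", "AAC", "AAG"), value = c(-1, 0, 1)
  )
  zs <- codon_z_screen(sym)
  expect_equal(zs$z[zs$codon == "AAC"], 0)
  expect_equal(zs$p.value[zs$codon == "AAC"], 1)
  # symmetric pair equidistant from the mean
  expect_equal(abs(zs$z[1]), abs(zs$z[3]))
  # affine transformation leaves flags unchanged
  z2 <- codon_z_screen(dplyr::mutate(vals, value = 3 * value - 10))
  expect_equal(z$significant, z2$significant)
  expect_equal(z$z, z2$z, tolerance = 1e-12)
  # degenerate inputs
  expect_error(codon_z_screen(vals[1:2, ]), "at least 3")
  expect_error(
    codon_z_screen(dplyr::mutate(vals, value = 2)), "zero variance"
  )
})

test_that("normality summary: arithmetic and degenerate cases", {
  out <- normality_summary(c(-1, 1))
  expect_equal(out$mean, 0)
  expect_equal(out$sd, sqrt(2))
  cst <- normality_summary(rep(3, 10))
  expect_equal(cst$sd, 0)
  expect_equal(cst$within_1sd, 1)
  expect_equal(cst$within_2sd, 1)
  expect_error(normality_summary(1), "at least 2")
})

test_that("PCA: degenerate, independent and conservation cases", {
  # three identical columns: all correlation, eigenvalues (3, 0, 0)
  set.seed(2)
  v <- rnorm(100)
  ident <- data.frame(a = v, b = v, c = v)
  p <- pca_indices(ident)
  expect_equal(p$eigenvalues, c(3, 0, 0), tolerance = 1e-8)
  expect_equal(sum(p$proportion), 1)

  # independent columns: eigenvalues near 1 (Monte-Carlo oracle)
  set.seed(3)
  ind <- data.frame(a = rnorm(10000), b = rnorm(10000), c = rnorm(10000))
  pi_ <- pca_indices(ind)
  expect_true(all(abs(pi_$eigenvalues - 1) < 0.1))

  # trace conservation on arbitrary data
  set.seed(4)
  arb <- data.frame(
    a = rnorm(50), b = rnorm(50) + seq_len(50) / 10, c = runif(50)
  )
  pa <- pca_indices(arb)
  expect_equal(sum(pa$eigenvalues), 3, tolerance = 1e-8)

  const <- data.frame(a = rnorm(10), b = rep(1, 10))
  expect_error(pca_indices(const), "constant column.*b")
})

test_that("PCA agrees with the prcomp oracle and respects the sign convention", {
  set.seed(6)
  d <- data.frame(
    x = rnorm(200), y = rnorm(200), z = rnorm(200)
  )
  d$y <- d$y + 0.8 * d$x
  p <- pca_indices(d)
  o <- prcomp(d, scale. = TRUE)
  expect_equal(p$eigenvalues, unname(o$sdev^2), tolerance = 1e-8)
  # loadings agree up to sign; our convention fixes the dominant one positive
  for (j in 1:3) {
    expect_equal(unname(abs(p$loadings[, j])),
                 unname(abs(o$rotation[, j])), tolerance = 1e-8)
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
  # scores reproduce the standardized data through the loadings
  expect_equal(unname(p$scores %*% t(p$loadings)),
               unname(scale(as.matrix(d))), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("tidy/glance/autoplot methods work on fitted objects", {
  set.seed(8)
  d <- expand.grid(sequence_id = paste0("s", 1:3),
                   codon = paste0("c", 1:4), stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d))
  fit <- anova_fixed(d, c("sequence", "codon"))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n, 12)
  p <- pca_indices(data.frame(a = rnorm(30), b = rnorm(30)))
  expect_s3_class(tidy(p), "tbl_df")
  expect_equal(glance(p)$k, 2)
  expect_s3_class(autoplot(p), "ggplot")
})
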
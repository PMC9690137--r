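#' Fixed-effects ANOVA with sequential sums of squares
#'
#' Fits the additive fixed-effects model `value ~ factor1 + factor2 + ...`
#' on a long index table and returns the sequential (Type I, fit-order)
#' ANOVA table, the convention of classical general-linear-model ANOVA
#' output.  Factors may be any ordered subset of
#' `c("sequence", "amino_acid", "codon")` (or literal column names).
#'
#' Note that in a full 64-codon design the codon factor determines the
#' amino acid, so a model containing `amino_acid` before `codon` can only
#' attribute the between-family variation to `amino_acid`; the codon row
#' then carries the remaining within-family degrees of freedom and a
#' warning is issued.  The conventional presentation of all three sources
#' at full degrees of freedom comes from two separate two-way fits (see
#' [run_analysis()]).
#'
#' @param table A long tibble with a numeric `value` column plus the
#'   factor columns.
#' @param factors Ordered character vector of factor names; `"sequence"`
#'   is an alias for `sequence_id`.
#' @param value_col Name of the response column (default `"value"`).
#' @return A `codon_anova` object; its `table` element is a tibble with
#'   `term`, `df`, `sumsq`, `meansq`, `statistic`, `p.value` (Residuals
#'   row included).  [generics::tidy()] and [generics::glance()] methods
#'   are provided.
#' @export
anova_fixed <- function(table,
                        factors = c("sequence", "codon"),
                        value_col = "value") {
  cols <- dplyr::recode(factors, sequence = "sequence_id")
  missing_cols <- setdiff(c(cols, value_col), names(table))
  if (length(missing_cols) > 0L) {
    stop("anova_fixed(): missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dat <- data.frame(
    value = table[[value_col]],
    lapply(table[cols], factor),
    check.names = FALSE
  )
  nlev <- vapply(dat[cols], nlevels, integer(1))
  if (any(nlev < 2L)) {
    stop("anova_fixed(): factor(s) with fewer than 2 levels: ",
         paste(cols[nlev < 2L], collapse = ", "))
  }
  form <- stats::as.formula(paste("value ~", paste(cols, collapse = " + ")))
  fit <- stats::aov(form, data = dat)
  if (stats::df.residual(fit) <= 0L) {
    stop("anova_fixed(): saturated design (zero residual degrees of ",
         "freedom) for factors: ", paste(cols, collapse = " + "))
  }
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  tab <- tibble::tibble(
    term = terms,
    df = as.integer(sm[["Df"]]),
    sumsq = sm[["Sum Sq"]],
    meansq = sm[["Mean Sq"]],
    statistic = sm[["F value"]],
    p.value = sm[["Pr(>F)"]]
  )
  full_df <- nlev - 1L
  got_df <- tab$df[match(cols, tab$term)]
  reduced <- which(got_df < full_df)
  if (length(reduced) > 0L) {
    warning("anova_fixed(): aliased factor(s) entered with reduced ",
            "degrees of freedom: ",
            paste0(cols[reduced], " (", got_df[reduced], " of ",
                   full_df[reduced], ")", collapse = ", "))
  }
  structure(
    list(table = tab, fit = fit, factors = cols),
    class = "codon_anova"
  )
}

#' @export
print.codon_anova <- function(x, ...) {
  cat("Fixed-effects ANOVA (sequential SS): value ~",
      paste(x$factors, collapse = " + "), "\n")
  print(x$table)
  invisible(x)
}

#' @rdname anova_fixed
#' @param x A `codon_anova` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.codon_anova <- function(x, ...) x$table

#' @rdname anova_fixed
#' @exportS3Method generics::glance
#' @export
glance.codon_anova <- function(x, ...) {
  resid <- x$table[x$table$term == "Residuals", ]
  tibble::tibble(
    df.residual = resid$df,
    ms.residual = resid$meansq,
    ss.total = sum(x$table$sumsq),
    n = length(stats::fitted(x$fit))
  )
}

#' Per-codon z-screen of an index
#'
#' Standardises each codon's value against the across-codon mean and
#' standard deviation, and flags codons whose two-sided normal p-value
#' falls below `alpha` — a screen for codons whose index value is
#' atypical among the 64.
#'
#' @param values A tibble with a `codon` column and one value per codon.
#' @param value_col Name of the value column.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with `codon`, the value, `z`, `p.value`,
#'   `significant`.
#' @export
codon_z_screen <- function(values, value_col = "value", alpha = 0.05) {
  v <- values[[value_col]]
  if (length(v) < 3L) stop("codon_z_screen(): need at least 3 values")
  if (anyDuplicated(values$codon)) {
    stop("codon_z_screen(): duplicate codon rows; aggregate first")
  }
  s <- stats::sd(v)
  if (s == 0) stop("codon_z_screen(): zero variance across codons")
  z <- (v - mean(v)) / s
  tibble::tibble(
    codon = values$codon,
    value = v,
    z = z,
    p.value = 2 * stats::pnorm(-abs(z)),
    significant = 2 * stats::pnorm(-abs(z)) < alpha
  )
}

#' Empirical normality summary
#'
#' Sample mean, sample standard deviation (denominator n − 1) and the
#' empirical coverage of mean ± 1·sd and mean ± 2·sd — the descriptive
#' check against the 68–95 rule of the normal distribution.  A constant
#' input is degenerate (sd 0) and reported with coverage 1.
#'
#' @param values Numeric vector (length ≥ 2).
#' @return A one-row tibble: `n`, `mean`, `sd`, `within_1sd`,
#'   `within_2sd`.
#' @export
normality_summary <- function(values) {
  if (length(values) < 2L) {
    stop("normality_summary(): need at least 2 values")
  }
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) {
    return(tibble::tibble(
      n = length(values), mean = m, sd = 0,
      within_1sd = 1, within_2sd = 1
    ))
  }
  tibble::tibble(
    n = length(values),
    mean = m,
    sd = s,
    within_1sd = mean(abs(values - m) <= s),
    within_2sd = mean(abs(values - m) <= 2 * s)
  )
}

#' Correlation-matrix PCA across codon-usage indices
#'
#' Standardises each index column and eigen-decomposes the correlation
#' matrix, so eigenvalues sum to the number of indices and the proportion
#' of variance of each component is eigenvalue / k.  Rows are typically
#' the (sequence, codon) observations of the long index table.  Sign
#' convention: within each component the largest-magnitude loading is made
#' positive.
#'
#' @param data A data frame; `cols` selects the index columns.
#' @param cols Character vector of numeric columns to use (default: all
#'   numeric columns).
#' @return A `codon_pca` object with `eigenvalues` (descending),
#'   `proportion`, `loadings` (variables × components), `scores`, `n`.
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()]
#'   methods are provided.
#' @export
pca_indices <- function(data, cols = NULL) {
  if (is.null(cols)) {
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  x <- as.matrix(data[, cols, drop = FALSE])
  if (nrow(x) < 3L) stop("pca_indices(): need at least 3 rows")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("pca_indices(): constant column(s): ",
         paste(cols[sds == 0], collapse = ", "))
  }
  z <- scale(x)
  eig <- eigen(stats::cor(x), symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  # sign convention: dominant loading positive per component
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(cols, paste0("PC", seq_along(vals)))
  structure(
    list(
      eigenvalues = vals,
      proportion = vals / length(vals),
      loadings = vecs,
      scores = z %*% vecs,
      n = nrow(x),
      variables = cols
    ),
    class = "codon_pca"
  )
}

#' @export
print.codon_pca <- function(x, ...) {
  cat("Correlation-matrix PCA of", length(x$variables), "indices,",
      x$n, "observations\n")
  print(tidy.codon_pca(x))
  invisible(x)
}

#' @rdname pca_indices
#' @param x A `codon_pca` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.codon_pca <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    proportion = x$proportion,
    cumulative = cumsum(x$proportion)
  )
}

#' @rdname pca_indices
#' @exportS3Method generics::glance
#' @export
glance.codon_pca <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    k = length(x$variables),
    n.above.1 = sum(x$eigenvalues > 1),
    prop.pc1 = x$proportion[1]
  )
}
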
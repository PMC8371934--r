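#' Summarize the mapping population's phenotypes
#'
#' Per colorimeter index: range, mean and standard deviation; pairwise
#' Pearson correlations with two-sided p-values; and a Shapiro-Wilk
#' normality statistic per index. A constant column yields NA
#' correlations for its pairs and is flagged rather than raising an
#' error.
#'
#' @param pheno phenotype data frame with an `id` column.
#' @param traits trait columns to summarize (default: all numeric
#'   columns except `id`).
#' @return list of class `pheno_summary`: `summary` data frame (trait,
#'   n, min, max, mean, sd), `correlation` and `correlation_p` matrices,
#'   `normality` data frame (trait, W, p), `constant` (flagged traits).
#' @export
summarize_phenotypes <- function(pheno, traits = NULL) {
  num <- vapply(pheno, is.numeric, TRUE)
  traits <- traits %||% setdiff(names(pheno)[num], "id")
  X <- as.matrix(pheno[, traits, drop = FALSE])
  if (nrow(X) < 3) stop("need at least 3 individuals")
  summ <- data.frame(
    trait = traits,
    n = colSums(!is.na(X)),
    min = apply(X, 2, min, na.rm = TRUE),
    max = apply(X, 2, max, na.rm = TRUE),
    mean = colMeans(X, na.rm = TRUE),
    sd = apply(X, 2, sd, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  k <- length(traits)
  cmat <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  pmat <- cmat
  diag(cmat) <- 1
  constant <- traits[summ$sd == 0 | is.na(summ$sd)]
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    if (traits[i] %in% constant || traits[j] %in% constant) next
    ct <- cor.test(X[, i], X[, j], method = "pearson")
    cmat[i, j] <- cmat[j, i] <- unname(ct$estimate)
    pmat[i, j] <- pmat[j, i] <- ct$p.value
  }
  norm <- do.call(rbind, lapply(traits, function(t) {
    x <- X[, t]; x <- x[!is.na(x)]
    if (t %in% constant || length(x) < 3 || length(x) > 5000)
      return(data.frame(trait = t, W = NA_real_, p = NA_real_))
    sw <- shapiro.test(x)
    data.frame(trait = t, W = unname(sw$statistic), p = sw$p.value,
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ, correlation = cmat,
                 correlation_p = pmat, normality = norm,
                 constant = constant), class = "pheno_summary")
}

#' @export
print.pheno_summary <- function(x, ...) {
  cat("Phenotype summary:\n")
  print(x$summary, digits = 4)
  cat("\nPearson correlations:\n")
  print(round(x$correlation, 3))
  cat("\nNormality (Shapiro-Wilk):\n")
  print(x$normality, digits = 4)
  invisible(x)
}
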
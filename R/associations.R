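# Cross-feature correlation structure across a population, cross-rate
# coupling across pathways, development-vs-aging rate coupling, and
# anterior-posterior gradient fits. Pearson correlations throughout, with
# Benjamini-Hochberg FDR masks per matrix and pairwise deletion of missing
# values (cortical features are undefined for mid-brain pathways).

#' Benjamini-Hochberg rejection mask
#'
#' Step-up procedure: reject the m' smallest p-values where
#' `m' = max{i : p_(i) <= i q / m}`, with m the number of finite p-values
#' (NaN/NA entries are excluded from the family and never rejected).
#'
#' @param pvalues numeric vector of p-values in [0, 1] (NA/NaN allowed).
#' @param q false discovery rate.
#' @return logical rejection mask, FALSE at non-finite entries.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  stopifnot(q > 0, q < 1)
  finite <- is.finite(pvalues)
  if (any(pvalues[finite] < 0 | pvalues[finite] > 1))
    stop("p-values must lie in [0, 1]")
  mask <- rep(FALSE, length(pvalues))
  if (any(finite))
    mask[finite] <- stats::p.adjust(pvalues[finite], method = "BH") <= q
  mask
}

cor_test_p <- function(r, n, n_controls = 0) {
  df <- n - 2 - n_controls
  ifelse(df > 0 & abs(r) < 1,
         2 * stats::pt(-abs(r) * sqrt(df / (1 - r^2)), df),
         ifelse(df > 0, 0, NA_real_))
}

pairwise_cor_matrix <- function(M, min_n = 3, n_controls = 0) {
  p <- ncol(M)
  r <- matrix(NA_real_, p, p, dimnames = list(colnames(M), colnames(M)))
  pv <- r
  n_pair <- matrix(0L, p, p, dimnames = dimnames(r))
  diag(r) <- 1
  diag(pv) <- 0
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ok <- is.finite(M[, i]) & is.finite(M[, j])
      n <- sum(ok)
      n_pair[i, j] <- n_pair[j, i] <- n
      if (n < min_n) next
      if (stats::sd(M[ok, i]) == 0 || stats::sd(M[ok, j]) == 0) next
      rij <- stats::cor(M[ok, i], M[ok, j])
      r[i, j] <- r[j, i] <- rij
      pv[i, j] <- pv[j, i] <- cor_test_p(rij, n, n_controls)
    }
  }
  list(r = r, p = pv, n = n_pair)
}

mask_from_p <- function(pv, q) {
  ut <- upper.tri(pv)
  mask <- matrix(FALSE, nrow(pv), ncol(pv), dimnames = dimnames(pv))
  mask[ut] <- bh_fdr(pv[ut], q)
  mask | t(mask)
}

#' Cross-feature correlation matrix for one pathway (or pooled)
#'
#' Pearson correlation between every pair of feature columns over sessions.
#' In partial mode both features are first residualized on the controls
#' (age and sex by default), and the t-test degrees of freedom are reduced
#' accordingly. Significance is a BH-FDR mask over all pairs in the matrix.
#'
#' @param table feature-table rows for one pathway (and optionally one
#'   cohort), or pooled sessions.
#' @param features feature columns; default all feature columns present.
#' @param method `"pearson"` or `"partial"`.
#' @param controls covariates to remove in partial mode.
#' @param fdr_q FDR level for the significance mask.
#' @param min_n minimum complete observations per pair.
#' @return object of class `association_result`: `r`, `p`, `significant`
#'   matrices plus `n`, `method`, `fdr_q`.
#' @export
feature_correlations <- function(table, features = NULL,
                                 method = c("pearson", "partial"),
                                 controls = c("age", "sex"), fdr_q = 0.05,
                                 min_n = 4) {
  method <- match.arg(method)
  if (is.null(features)) features <- feature_columns(table)
  if (length(features) < 2) stop("need at least two features")
  M <- as.matrix(table[, features, drop = FALSE])
  n_controls <- 0
  if (method == "partial") {
    Z <- cbind(1, age = table$age,
               if ("sex" %in% controls) as.numeric(table$sex == "F"))
    n_controls <- ncol(Z) - 1
    for (j in seq_len(ncol(M))) {
      ok <- is.finite(M[, j]) & stats::complete.cases(Z)
      if (sum(ok) > ncol(Z))
        M[ok, j] <- stats::lm.fit(Z[ok, , drop = FALSE], M[ok, j])$residuals
    }
  }
  pc <- pairwise_cor_matrix(M, min_n = max(min_n, n_controls + 3),
                            n_controls = n_controls)
  zero_var <- apply(M, 2, function(v) stats::sd(v[is.finite(v)]) == 0)
  if (any(zero_var))
    warning("zero-variance features: ", paste(features[zero_var], collapse = ", "))
  structure(list(r = pc$r, p = pc$p, significant = mask_from_p(pc$p, fdr_q),
                 n = pc$n, method = method,
                 controls = if (method == "partial") controls else character(0),
                 fdr_q = fdr_q),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> %s, %d features, %d significant pairs (q = %g)\n",
              x$method, ncol(x$r), sum(x$significant[upper.tri(x$significant)]),
              x$fdr_q))
  invisible(x)
}

#' Correlate per-pathway rates between features within one cohort
#'
#' Each column of `rates` is a feature's per-pathway difference (or
#' percent difference) per year; rows are pathways. Pairwise Pearson
#' correlation over pathways with pairwise NaN deletion; pairs with fewer
#' than 3 complete pathways stay NA. BH-FDR mask over the matrix.
#'
#' @param rates pathways x features numeric matrix.
#' @param fdr_q FDR level.
#' @return an `association_result`.
#' @export
rate_coupling <- function(rates, fdr_q = 0.05) {
  rates <- as.matrix(rates)
  if (is.null(colnames(rates)))
    colnames(rates) <- paste0("feature", seq_len(ncol(rates)))
  pc <- pairwise_cor_matrix(rates, min_n = 3)
  structure(list(r = pc$r, p = pc$p, significant = mask_from_p(pc$p, fdr_q),
                 n = pc$n, method = "pearson", controls = character(0),
                 fdr_q = fdr_q),
            class = "association_result")
}

#' Development-vs-aging rate coupling for one feature
#'
#' Pearson correlation, across pathways, of a feature's per-pathway rate
#' in the development cohort against the same feature's rate in aging
#' (the gain-predicts-loss test). Pathway order must match; NaN pathways
#' are dropped pairwise.
#'
#' @param rates_dev,rates_aging numeric vectors, one entry per pathway.
#' @return list with `r`, `p` (two-sided) and `n_pathways`.
#' @export
dev_aging_coupling <- function(rates_dev, rates_aging) {
  if (length(rates_dev) != length(rates_aging))
    stop("rate vectors must share the same pathway ordering and length")
  ok <- is.finite(rates_dev) & is.finite(rates_aging)
  if (sum(ok) < 3) stop("fewer than 3 complete pathways")
  r <- stats::cor(rates_dev[ok], rates_aging[ok])
  list(r = r, p = cor_test_p(r, sum(ok)), n_pathways = sum(ok))
}

#' Anterior-posterior gradient of per-pathway rates
#'
#' Least-squares fits of `rate ~ y` and `rate ~ y + y^2` against each
#' pathway's anterior-posterior coordinate (MNI y, mm), with the p-value
#' of the highest-order term of each fit.
#'
#' @param rates per-pathway rate vector.
#' @param coords per-pathway anterior-posterior coordinates (mm).
#' @return list with `linear` (slope, p), `quadratic` (coefficients, p)
#'   and `n`.
#' @export
ap_gradient <- function(rates, coords) {
  ok <- is.finite(rates) & is.finite(coords)
  rates <- rates[ok]; coords <- coords[ok]
  if (length(rates) < 3) stop("need at least 3 pathways with finite values")
  if (stats::sd(coords) == 0) stop("anterior-posterior coordinates are collinear")
  lin <- stats::lm(rates ~ coords)
  lin_p <- summary(lin)$coefficients["coords", "Pr(>|t|)"]
  out <- list(linear = list(slope = unname(stats::coef(lin)["coords"]), p = lin_p),
              quadratic = NULL, n = length(rates))
  if (length(rates) >= 4 && length(unique(coords)) >= 3) {
    quad <- stats::lm(rates ~ coords + I(coords^2))
    out$quadratic <- list(
      coefficients = unname(stats::coef(quad)),
      coef2 = unname(stats::coef(quad)["I(coords^2)"]),
      p = summary(quad)$coefficients["I(coords^2)", "Pr(>|t|)"])
  }
  out
}

#' Tidy long format for an association matrix
#'
#' @param assoc an `association_result`.
#' @return data.frame with `feature1`, `feature2`, `r`, `p`, `n`,
#'   `significant` (upper triangle only).
#' @export
association_table <- function(assoc) {
  ut <- which(upper.tri(assoc$r), arr.ind = TRUE)
  data.frame(feature1 = rownames(assoc$r)[ut[, 1]],
             feature2 = colnames(assoc$r)[ut[, 2]],
             r = assoc$r[ut], p = assoc$p[ut], n = assoc$n[ut],
             significant = assoc$significant[ut],
             stringsAsFactors = FALSE)
}
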
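## Step 1-2 machinery: descriptives / reliability and the three IRT
## assumption screens (unidimensionality, local independence,
## monotonicity via scalability).

# population variance (divide by n); stated convention for Cronbach alpha
# so that small hand-worked examples match exactly
pvar <- function(z) mean((z - mean(z))^2)

#' Item descriptives and internal consistency
#'
#' Per-item category counts, means and standard deviations, alpha-if-item
#' -deleted, and item-rest correlations (each item against the sum of the
#' remaining items), plus the overall Cronbach alpha and total-score mean
#' and SD.
#'
#' Cronbach alpha uses the population-variance convention (divide by n):
#' `alpha = K/(K-1) * (1 - sum(var_i)/var_total)`. Printed item SDs are
#' sample SDs (divide by n-1), the usual descriptive convention.
#'
#' @param x a [response_matrix()].
#' @return An object of class `grm_descriptives`: list with `items`
#'   (data.frame), `cronbach_alpha`, `total_mean`, `total_sd`,
#'   `n_persons`.
#' @export
descriptives <- function(x) {
  stopifnot(inherits(x, "response_matrix"))
  Y <- x$responses
  if (nrow(Y) < 2 || ncol(Y) < 2)
    stop("descriptives require at least 2 persons and 2 items")
  K <- ncol(Y)
  total <- rowSums(Y)
  if (pvar(total) == 0)
    stop("total score has zero variance: Cronbach alpha is undefined")
  m <- x$n_categories - 1L
  counts <- t(apply(Y, 2, function(col) tabulate(col + 1L, nbins = m + 1L)))
  alpha_total <- cronbach(Y)
  aid <- vapply(seq_len(K), function(j) {
    rest <- Y[, -j, drop = FALSE]
    if (pvar(rowSums(rest)) == 0) NA_real_ else cronbach(rest)
  }, numeric(1))
  irc <- vapply(seq_len(K), function(j) {
    rest <- total - Y[, j]
    if (pvar(Y[, j]) == 0 || pvar(rest) == 0) NA_real_
    else cor(Y[, j], rest)
  }, numeric(1))
  items <- data.frame(item = seq_len(K), counts,
                      mean = colMeans(Y), sd = apply(Y, 2, sd),
                      alpha_if_deleted = aid, item_rest_r = irc)
  names(items)[2:(m + 2L)] <- paste0("n", 0:m)
  rownames(items) <- NULL
  structure(list(items = items, cronbach_alpha = alpha_total,
                 total_mean = mean(total), total_sd = sd(total),
                 n_persons = nrow(Y)),
            class = "grm_descriptives")
}

cronbach <- function(Y) {
  K <- ncol(Y)
  (K / (K - 1)) * (1 - sum(apply(Y, 2, pvar)) / pvar(rowSums(Y)))
}

#' @export
print.grm_descriptives <- function(x, ...) {
  cat(sprintf("n = %d; Cronbach alpha = %.3f; total mean (SD) = %.2f (%.2f)\n",
              x$n_persons, x$cronbach_alpha, x$total_mean, x$total_sd))
  print(x$items, digits = 3)
  invisible(x)
}

#' Principal components unidimensionality screen
#'
#' Eigen-decomposition of the Pearson correlation matrix of the raw item
#' scores. Reports the proportion of variance carried by the first
#' component (`lambda_1 / K`), the first-to-second eigenvalue ratio, and
#' the two conventional pass flags: first component at least 20% of the
#' variance, and ratio at least 4.
#'
#' @param x a [response_matrix()].
#' @return list with `eigenvalues`, `prop_var_first`,
#'   `ratio_first_second`, `pass_20pct`, `pass_ratio4`.
#' @export
pca_screen <- function(x) {
  stopifnot(inherits(x, "response_matrix"))
  Y <- x$responses
  v <- apply(Y, 2, pvar)
  if (any(v == 0))
    stop("constant item(s) prevent correlation: ",
         paste(which(v == 0), collapse = ", "))
  ev <- sort(eigen(cor(Y), symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  list(eigenvalues = ev, prop_var_first = ev[1] / ncol(Y),
       ratio_first_second = ev[1] / ev[2],
       pass_20pct = ev[1] / ncol(Y) >= 0.20,
       pass_ratio4 = ev[1] / ev[2] >= 4)
}

#' One-factor confirmatory factor analysis
#'
#' Maximum-likelihood single-factor fit to the Pearson correlation matrix
#' of the raw item scores, with the standard fit indices. The model
#' chi-square is `(n - 1) * F_ML` where `F_ML` is the ML discrepancy at
#' the solution (no Bartlett correction; the same convention is applied
#' to the independence baseline, so the incremental indices are
#' internally consistent). RMSEA confidence limits come from
#' noncentrality inversion; SRMR is the root mean square of the residual
#' correlations over the lower triangle including the diagonal (the
#' diagonal residuals are zero by the unit-variance parameterisation, so
#' including them only rescales).
#'
#' @param x a [response_matrix()], or a correlation matrix (in which
#'   case `n` must be supplied) — the latter form mirrors
#'   `factanal(covmat = )` and is convenient for constructed examples.
#' @param n number of observations when `x` is a correlation matrix.
#' @return list with `loadings`, `uniquenesses`, `chi2`, `df`, `CFI`,
#'   `TLI`, `RMSEA`, `RMSEA_90CI`, `SRMR`, `residuals` (residual
#'   correlation matrix), `heywood` (TRUE if any uniqueness hit its lower
#'   bound), `n`.
#' @export
cfa_one_factor <- function(x, n = NULL) {
  if (inherits(x, "response_matrix")) {
    n <- x$n_persons
    R <- cor(x$responses)
  } else {
    R <- as.matrix(x)
    if (is.null(n)) stop("n must be supplied with a correlation matrix")
  }
  p <- ncol(R)
  if (n <= p) stop("one-factor CFA requires more persons than items")
  fa <- factanal(covmat = R, factors = 1, n.obs = n, rotation = "none")
  lambda <- as.vector(fa$loadings)
  psi <- fa$uniquenesses
  Sigma <- tcrossprod(lambda) + diag(psi)
  fml <- ml_discrepancy(R, Sigma)
  chi2 <- (n - 1) * fml
  df <- p * (p - 3) / 2
  # independence baseline: Sigma0 = I, F0 = -log det R
  chi2_0 <- (n - 1) * ml_discrepancy(R, diag(p))
  df0 <- p * (p - 1) / 2
  cfi <- 1 - max(chi2 - df, 0) / max(chi2 - df, chi2_0 - df0, 0)
  if (!is.finite(cfi)) cfi <- 1
  tli_raw <- ((chi2_0 / df0) - (chi2 / df)) / ((chi2_0 / df0) - 1)
  tli <- min(tli_raw, 1)
  rmsea <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  ci <- rmsea_ci(chi2, df, n)
  resid <- R - Sigma
  lower <- resid[lower.tri(resid, diag = TRUE)]
  srmr <- sqrt(mean(lower^2))
  list(loadings = lambda, uniquenesses = psi, chi2 = chi2, df = df,
       CFI = cfi, TLI = tli, RMSEA = rmsea, RMSEA_90CI = ci, SRMR = srmr,
       residuals = resid, heywood = any(psi <= 0.005 + 1e-12), n = n)
}

ml_discrepancy <- function(S, Sigma) {
  p <- ncol(S)
  as.numeric(determinant(Sigma)$modulus - determinant(S)$modulus +
               sum(diag(solve(Sigma, S))) - p)
}

# 90% CI for RMSEA by inverting the noncentral chi-square distribution
rmsea_ci <- function(chi2, df, n) {
  bound <- function(q) {
    if (pchisq(chi2, df, ncp = 0) < q) return(0)
    hi <- max(chi2 * 2, df * 5, 100)
    while (pchisq(chi2, df, ncp = hi) > q && hi < 1e8) hi <- hi * 2
    uniroot(function(l) pchisq(chi2, df, ncp = l) - q, c(0, hi))$root
  }
  lam_lo <- bound(0.95)  # lower RMSEA limit uses the upper tail prob
  lam_hi <- bound(0.05)
  c(lower = sqrt(lam_lo / (df * (n - 1))),
    upper = sqrt(lam_hi / (df * (n - 1))))
}

#' Flag residual correlations as local-independence violations
#'
#' All off-diagonal pairs of the residual correlation matrix whose
#' absolute value exceeds the threshold (0.2 by convention) are listed;
#' an empty result is a pass.
#'
#' @param residuals square symmetric residual correlation matrix.
#' @param threshold flagging threshold (default 0.2).
#' @return data.frame with columns `item_i`, `item_j`, `residual_r`.
#' @export
local_independence_flags <- function(residuals, threshold = 0.2) {
  residuals <- as.matrix(residuals)
  if (nrow(residuals) != ncol(residuals) ||
      max(abs(residuals - t(residuals))) > 1e-8)
    stop("residuals must be a square symmetric matrix")
  idx <- which(abs(residuals) > threshold & lower.tri(residuals),
               arr.ind = TRUE)
  data.frame(item_i = idx[, 2], item_j = idx[, 1],
             residual_r = residuals[idx])
}

#' Mokken scalability coefficients
#'
#' Loevinger's H: for each item pair, `H_ij = cov(X_i, X_j) /
#' covmax(X_i, X_j)` where `covmax` is the covariance of the comonotonic
#' coupling of the two observed marginals (the maximal covariance
#' attainable given the marginals). Item coefficients pool numerators and
#' denominators over the other items; the overall H pools all pairs.
#' Items with `H_j` below the threshold (0.3 by convention) are flagged
#' as weakly scalable / possibly nonmonotone.
#'
#' @param x a [response_matrix()].
#' @param threshold item flagging threshold (default 0.3).
#' @return list with `H_pairs` (matrix), `H_item` (vector), `H_overall`,
#'   `flagged` (item indices with `H_j < threshold`), `excluded`
#'   (zero-variance items, dropped with a warning).
#' @export
mokken_scalability <- function(x, threshold = 0.3) {
  stopifnot(inherits(x, "response_matrix"))
  Y <- x$responses
  if (ncol(Y) < 2) stop("scalability requires at least 2 items")
  v <- apply(Y, 2, pvar)
  excluded <- which(v == 0)
  if (length(excluded)) {
    warning("zero-variance item(s) excluded from scalability: ",
            paste(excluded, collapse = ", "))
    Y <- Y[, -excluded, drop = FALSE]
  }
  K <- ncol(Y)
  cv <- matrix(NA_real_, K, K)
  cvmax <- matrix(NA_real_, K, K)
  sorted <- apply(Y, 2, sort)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    cv[i, j] <- cv[j, i] <- mean(Y[, i] * Y[, j]) -
      mean(Y[, i]) * mean(Y[, j])
    cvmax[i, j] <- cvmax[j, i] <- mean(sorted[, i] * sorted[, j]) -
      mean(Y[, i]) * mean(Y[, j])
  }
  H_pairs <- cv / cvmax
  H_item <- vapply(seq_len(K), function(j)
    sum(cv[j, -j]) / sum(cvmax[j, -j]), numeric(1))
  H_overall <- sum(cv[upper.tri(cv)]) / sum(cvmax[upper.tri(cvmax)])
  kept <- setdiff(seq_len(x$n_items), excluded)
  names(H_item) <- kept
  list(H_pairs = H_pairs, H_item = H_item, H_overall = H_overall,
       flagged = kept[H_item < threshold], excluded = excluded)
}

#' Full assumption report (step 2)
#'
#' Bundles the PCA screen, the one-factor CFA with local-independence
#' flags on its residuals, and Mokken scalability into one report.
#'
#' @param x a [response_matrix()].
#' @param residual_threshold local-independence flag level (default 0.2).
#' @param scalability_threshold Mokken flag level (default 0.3).
#' @return list with components `pca`, `cfa`, `local_independence`,
#'   `scalability`.
#' @export
assumption_report <- function(x, residual_threshold = 0.2,
                              scalability_threshold = 0.3) {
  pca <- pca_screen(x)
  cfa <- cfa_one_factor(x)
  li <- local_independence_flags(cfa$residuals, residual_threshold)
  mok <- mokken_scalability(x, scalability_threshold)
  list(pca = pca, cfa = cfa, local_independence = li, scalability = mok)
}
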
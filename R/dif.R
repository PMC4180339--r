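## Step 4: differential item functioning by nested cumulative-logit
## (proportional odds) models, flagged at alpha = .01, with McFadden
## pseudo R-squared effect sizes banded at .13 / .26.

#' Fit a cumulative-logit (proportional odds) model
#'
#' Model: `logit P(Y <= k) = zeta_k - x' beta` with ordered intercepts
#' `zeta_1 < ... < zeta_m` for categories `0..m`. Fitted by
#' Newton-Raphson with analytic gradient and Hessian and step-halving,
#' to gradient max-norm below `1e-8`. If the Hessian turns singular or
#' the fit diverges (separation), the fit is retried with a small ridge
#' penalty on `beta` and a warning.
#'
#' @param y integer responses in `0..m`.
#' @param X design matrix (persons x predictors), no intercept column;
#'   may have zero columns for the intercept-only model.
#' @param max_iter Newton iteration cap (default 100).
#' @param ridge ridge constant used on fallback (default 1e-4).
#' @return list with `zeta`, `beta`, `log_likelihood`, `converged`,
#'   `n_iterations`, `ridged`.
#' @export
fit_cumulative_logit <- function(y, X = NULL, max_iter = 100,
                                 ridge = 1e-4) {
  y <- as.integer(y)
  m <- max(y)
  if (m < 1) stop("y must have at least 2 observed categories")
  if (is.null(X)) X <- matrix(numeric(0), length(y), 0)
  X <- as.matrix(X)
  if (ncol(X) > 0 && qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient")
  fit <- po_newton(y, X, m, max_iter, lambda = 0)
  if (!fit$converged || !is.finite(fit$log_likelihood)) {
    warning("cumulative-logit fit unstable (possible separation); ",
            "refitting with ridge penalty")
    fit <- po_newton(y, X, m, max_iter, lambda = ridge)
    fit$ridged <- TRUE
  } else fit$ridged <- FALSE
  fit
}

po_newton <- function(y, X, m, max_iter, lambda) {
  n <- length(y); p <- ncol(X)
  counts <- tabulate(y + 1L, nbins = m + 1L)
  cumprop <- pmin(pmax(cumsum(counts)[1:m] / n, 1 / (2 * n)),
                  1 - 1 / (2 * n))
  theta <- c(qlogis(cumprop), rep(0, p))     # (zeta, beta)
  ll <- po_loglik(theta, y, X, m) - ridge_pen(theta, m, p, lambda)
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    gh <- po_grad_hess(theta, y, X, m)
    g <- gh$grad; H <- gh$hess
    if (lambda > 0 && p > 0) {
      bi <- (m + 1):(m + p)
      g[bi] <- g[bi] - 2 * lambda * theta[bi]
      H[cbind(bi, bi)] <- H[cbind(bi, bi)] - 2 * lambda
    }
    if (max(abs(g)) < 1e-8) { converged <- TRUE; break }
    step <- tryCatch(solve(-H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    # step-halving: keep intercepts ordered and log-likelihood finite
    ok <- FALSE
    for (h in 0:30) {
      cand <- theta + step / 2^h
      if (m > 1 && any(diff(cand[1:m]) <= 0)) next
      ll_new <- po_loglik(cand, y, X, m) - ridge_pen(cand, m, p, lambda)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) {
        theta <- cand; ll <- ll_new; ok <- TRUE; break
      }
    }
    if (!ok) break
  }
  list(zeta = theta[seq_len(m)],
       beta = if (p > 0) theta[(m + 1):(m + p)] else numeric(0),
       log_likelihood = po_loglik(theta, y, X, m),
       converged = converged, n_iterations = it)
}

ridge_pen <- function(th, m, p, lambda)
  if (lambda > 0 && p > 0) lambda * sum(th[(m + 1):(m + p)]^2) else 0

po_cumprobs <- function(theta, X, m) {
  eta <- if (ncol(X) > 0) drop(X %*% theta[(m + 1):(m + ncol(X))])
  else rep(0, nrow(X))
  vapply(seq_len(m), function(k) plogis(theta[k] - eta),
         numeric(nrow(X)))
}

po_loglik <- function(theta, y, X, m) {
  gam <- cbind(0, po_cumprobs(theta, X, m), 1)     # n x (m+2)
  idx <- seq_along(y)
  pr <- gam[cbind(idx, y + 2L)] - gam[cbind(idx, y + 1L)]
  if (any(pr <= 0)) return(-Inf)
  sum(log(pr))
}

po_grad_hess <- function(theta, y, X, m) {
  n <- length(y); p <- ncol(X); d <- m + p
  gam <- cbind(0, po_cumprobs(theta, X, m), 1)
  idx <- seq_along(y)
  gU <- gam[cbind(idx, y + 2L)]   # gamma_{y}
  gL <- gam[cbind(idx, y + 1L)]   # gamma_{y-1}
  D <- pmax(gU - gL, 1e-300)
  sU <- gU * (1 - gU); sU[y == m] <- 0        # sigma' at upper cut (0 at top)
  sL <- gL * (1 - gL); sL[y == 0] <- 0
  cU <- sU * (1 - 2 * gU); cU[y == m] <- 0    # sigma'' at upper cut
  cL <- sL * (1 - 2 * gL); cL[y == 0] <- 0
  # rows of U / V: gradients of the upper / lower cut linear predictors
  # wrt (zeta, beta); the upper cut for response y is zeta_{y+1} (exists
  # when y < m), the lower cut is zeta_{y} (exists when y > 0)
  U <- matrix(0, n, d); V <- matrix(0, n, d)
  has_up <- y < m; has_lo <- y > 0
  U[cbind(which(has_up), y[has_up] + 1L)] <- 1
  V[cbind(which(has_lo), y[has_lo])] <- 1
  if (p > 0) {
    U[, (m + 1):d] <- -X
    V[, (m + 1):d] <- -X
  }
  a <- sU / D; b <- sL / D
  G <- U * a - V * b                           # per-person gradient rows
  grad <- colSums(G)
  H <- crossprod(U, U * (cU / D)) - crossprod(V, V * (cL / D)) -
    crossprod(G)
  list(grad = grad, hess = H)
}

# McFadden pseudo R-squared of a fitted model against the intercept-only
# null log-likelihood
mcfadden_r2 <- function(ll_model, ll_null) 1 - ll_model / ll_null

#' DIF test for a single item against a binary group
#'
#' Nested cumulative-logit models with the latent-trait estimate as the
#' matching variable: M1 `y ~ theta`, M2 `y ~ theta + group`, M3
#' `y ~ theta + group + theta:group`. The total DIF statistic is the
#' 2-df likelihood ratio of M3 against M1; the effect size is the
#' McFadden pseudo R-squared difference between M3 and M1, banded as
#' negligible (< .13), moderate (.13-.26) or large (>= .26).
#'
#' @param y item responses `0..m`.
#' @param theta_hat matching variable (EAP scores from the pooled fit).
#' @param group binary group membership (factor, logical, or two-level
#'   vector).
#' @param alpha flagging level (default 0.01).
#' @return one-row data.frame: `lr_chi2_total`, `df`, `p_value`,
#'   `lr_uniform`, `lr_nonuniform`, `delta_mcfadden_r2`, `flag`,
#'   `effect_band`, `underpowered`.
#' @export
dif_test_item <- function(y, theta_hat, group, alpha = 0.01) {
  g <- as.integer(factor(group)) - 1L
  if (length(unique(g)) != 2L) stop("group must be binary")
  underpowered <- min(table(g)) < 10
  m1 <- fit_cumulative_logit(y, cbind(theta = theta_hat))
  m2 <- fit_cumulative_logit(y, cbind(theta = theta_hat, group = g))
  m3 <- fit_cumulative_logit(y, cbind(theta = theta_hat, group = g,
                                      txg = theta_hat * g))
  m0 <- fit_cumulative_logit(y, NULL)
  lr_total <- max(2 * (m3$log_likelihood - m1$log_likelihood), 0)
  lr_unif <- max(2 * (m2$log_likelihood - m1$log_likelihood), 0)
  lr_nonunif <- max(2 * (m3$log_likelihood - m2$log_likelihood), 0)
  p <- pchisq(lr_total, df = 2, lower.tail = FALSE)
  dr2 <- max(mcfadden_r2(m3$log_likelihood, m0$log_likelihood) -
               mcfadden_r2(m1$log_likelihood, m0$log_likelihood), 0)
  band <- if (dr2 < 0.13) "negligible" else if (dr2 < 0.26) "moderate"
  else "large"
  data.frame(lr_chi2_total = lr_total, df = 2, p_value = p,
             lr_uniform = lr_unif, lr_nonuniform = lr_nonunif,
             delta_mcfadden_r2 = dr2, flag = p < alpha,
             effect_band = band, underpowered = underpowered)
}

#' Screen every item against every covariate for DIF
#'
#' Runs [dif_test_item()] for each bank item crossed with each available
#' binary covariate. Covariates with fewer than two observed levels are
#' skipped with a warning. Flags use the configured alpha (default .01);
#' flagged items whose pseudo R-squared difference stays below .13 are
#' annotated as negligible.
#'
#' @param x a [response_matrix()] carrying covariates.
#' @param fit a `grm_fit` or [item_bank()] providing the matching
#'   parameters (EAP scores are computed from it, pooled, once).
#' @param covariates covariate names to test (default: all present).
#' @param alpha flagging level (default 0.01).
#' @return An object of class `dif_result`: data.frame with one row per
#'   item x covariate, plus attributes `n_flagged` and `alpha`.
#' @export
dif_screen <- function(x, fit, covariates = NULL, alpha = 0.01) {
  stopifnot(inherits(x, "response_matrix"))
  bank <- if (inherits(fit, "grm_fit")) fit$bank else fit
  if (is.null(x$covariates) || ncol(x$covariates) == 0)
    stop("response matrix carries no covariates")
  if (is.null(covariates)) covariates <- names(x$covariates)
  th <- eap_scores(bank, x)$theta
  rows <- list()
  for (cv in covariates) {
    if (!cv %in% names(x$covariates)) {
      warning("covariate not present, skipped: ", cv)
      next
    }
    gvals <- x$covariates[[cv]]
    keep <- !is.na(gvals)
    if (cv == "age_band")  # only the two printed bands enter the test
      keep <- keep & gvals %in% .covariate_levels$age_band
    if (length(unique(gvals[keep])) != 2L) {
      warning("covariate without two observed levels, skipped: ", cv)
      next
    }
    for (j in seq_len(x$n_items)) {
      res <- dif_test_item(x$responses[keep, j], th[keep], gvals[keep],
                           alpha = alpha)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(item = bank$id[j], covariate = cv), res)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_flagged") <- sum(out$flag)
  attr(out, "alpha") <- alpha
  class(out) <- c("dif_result", class(out))
  out
}

#' @export
print.dif_result <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  cat(sprintf("DIF screen: %d tests, %d flagged at alpha = %g\n",
              nrow(y), sum(y$flag), attr(x, "alpha") %||% 0.01))
  flagged <- y[y$flag, c("item", "covariate", "p_value",
                         "delta_mcfadden_r2", "effect_band")]
  if (nrow(flagged)) print(flagged, digits = 3) else cat("no flags\n")
  invisible(x)
}
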
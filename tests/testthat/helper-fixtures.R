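# shared builders and independent oracles used across the suite

bss_bank <- function() default_item_bank()

# a tiny 2-item, 3-category bank with thresholds mirrored around 0, so a
# complementary response pattern has EAP exactly 0 by symmetry
symmetric_bank <- function() {
  item_bank(1:2, c("lo", "hi"), c(1.7, 1.7),
            rbind(c(-1.2, -0.4), c(0.4, 1.2)))
}

# standard-normal latent trait: the identified scale MML assumes
normal_mixture <- data.frame(weight = 1, mean = 0, sd = 1)

# --- independent oracles -------------------------------------------------

# closed-form GRM category probabilities built from first principles
# (explicit exp/(1+exp)), kept separate from the package's plogis path
oracle_grm_probs <- function(alpha, betas, theta) {
  ps <- c(1, sapply(betas, function(b) {
    e <- exp(alpha * (theta - b)); e / (1 + e)
  }), 0)
  ps[-length(ps)] - ps[-1]
}

# dense-grid posterior mean oracle for EAP (Riemann sum over 1e5 points;
# probabilities built from explicit exp ratios, not the package path)
oracle_eap <- function(bank, pattern, n_grid = 1e5, lim = 4.5) {
  grid <- seq(-lim, lim, length.out = n_grid)
  lp <- dnorm(grid, log = TRUE)
  ids <- as.integer(names(pattern))
  for (j in seq_along(ids)) {
    i <- match(ids[j], bank$id)
    a <- bank$alpha[i]
    ps <- cbind(1, sapply(bank$betas[i, ], function(b) {
      e <- exp(a * (grid - b)); e / (1 + e)
    }), 0)
    lp <- lp + log(ps[, pattern[j] + 1L] - ps[, pattern[j] + 2L])
  }
  w <- exp(lp - max(lp)); w <- w / sum(w)
  sum(w * grid)
}

# build a response matrix whose single-item category counts are exact
matrix_from_counts <- function(counts_list) {
  cols <- lapply(counts_list, function(cnt)
    rep(seq_along(cnt) - 1L, times = cnt))
  response_matrix(do.call(cbind, cols),
                  n_categories = max(lengths(counts_list)))
}

# brute-force proportional-odds log-likelihood, maximised by optim from
# several starts; independent of the package's Newton path
oracle_polr <- function(y, X) {
  m <- max(y)
  p <- ncol(X)
  nll <- function(par) {
    zeta <- cumsum(c(par[1], exp(par[2:m])))
    if (m == 1) zeta <- par[1]
    beta <- if (p > 0) par[(m + 1):(m + p)] else numeric(0)
    eta <- if (p > 0) drop(X %*% beta) else rep(0, length(y))
    gam <- cbind(0, sapply(zeta, function(z) 1 / (1 + exp(-(z - eta)))), 1)
    pr <- gam[cbind(seq_along(y), y + 2L)] - gam[cbind(seq_along(y), y + 1L)]
    if (any(pr <= 0)) return(1e10)
    -sum(log(pr))
  }
  best <- NULL
  for (s in list(rep(0, m + p), c(seq(-1, 1, length.out = m), rep(0.5, p)))) {
    op <- optim(s, nll, method = "BFGS",
                control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || op$value < best$value) best <- op
  }
  zeta <- if (m == 1) best$par[1] else cumsum(c(best$par[1],
                                                exp(best$par[2:m])))
  list(zeta = zeta,
       beta = if (p > 0) best$par[(m + 1):(m + p)] else numeric(0),
       log_likelihood = -best$value)
}

# exhaustive enumeration of all 2-way tables with the observed margins,
# returning the maximal covariance (population convention) — the Mokken
# covmax oracle
oracle_covmax <- function(xi, xj) {
  n <- length(xi)
  mi <- tabulate(xi + 1L, nbins = max(xi) + 1L)
  mj <- tabulate(xj + 1L, nbins = max(xj) + 1L)
  vals_i <- seq_along(mi) - 1L
  vals_j <- seq_along(mj) - 1L
  best <- -Inf
  recurse <- function(tab, row, rem_col) {
    if (row > length(mi)) {
      exy <- sum(outer(vals_i, vals_j) * tab) / n
      best <<- max(best, exy)
      return()
    }
    fill_row <- function(cells, col, rem) {
      if (col == length(mj)) {
        if (rem <= rem_col[col]) {
          t2 <- tab; t2[row, ] <- c(cells, rem)
          recurse(t2, row + 1L, rem_col - t2[row, ])
        }
        return()
      }
      for (v in 0:min(rem, rem_col[col]))
        fill_row(c(cells, v), col + 1L, rem - v)
    }
    fill_row(integer(0), 1L, mi[row])
  }
  recurse(matrix(0L, length(mi), length(mj)), 1L, mj)
  best - mean(xi) * mean(xj)
}
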
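# step 1-2: descriptives, reliability, PCA/CFA screens, local
# independence, Mokken scalability

test_that("item means recomputed from published category counts", {
  # items 1, 7 and 11 of the printed descriptives table (n = 505)
  counts <- list(item1 = c(242, 195, 68),
                 item7 = c(310, 160, 35),
                 item11 = c(223, 47, 235))
  x <- matrix_from_counts(counts)
  d <- descriptives(x)
  expect_equal(round(d$items$mean, 2), c(0.66, 0.46, 1.02))
  expect_equal(unname(as.matrix(d$items[, c("n0", "n1", "n2")])),
               unname(do.call(rbind, counts)))
  expect_equal(sum(d$items$n0[1] + d$items$n1[1] + d$items$n2[1]), 505)
})

test_that("Cronbach alpha: closed forms and invariances", {
  # two identical items -> alpha exactly 1
  set.seed(4)
  y <- sample(0:2, 50, replace = TRUE)
  x <- response_matrix(cbind(y, y), n_categories = 3)
  expect_equal(descriptives(x)$cronbach_alpha, 1)

  # 4-person x 3-item toy: hand-computed population-variance formula
  Y <- rbind(c(0, 1, 2), c(1, 1, 1), c(2, 0, 1), c(2, 2, 2))
  pv <- function(z) mean((z - mean(z))^2)
  hand <- (3 / 2) * (1 - sum(apply(Y, 2, pv)) / pv(rowSums(Y)))
  x <- response_matrix(Y, n_categories = 3)
  expect_equal(descriptives(x)$cronbach_alpha, hand)

  # invariant to item order
  xp <- response_matrix(Y[, c(3, 1, 2)], n_categories = 3)
  expect_equal(descriptives(xp)$cronbach_alpha, hand)

  # two parallel items: alpha approaches the Spearman-Brown closed form
  # (exact only under exactly equal item variances, hence the tolerance)
  coh <- generate_cohort(cohort_spec(n_persons = 4000, seed = 8))
  y2 <- coh$matrix$responses[, c(4, 4)]
  y2[, 2] <- simulate_responses(bss_bank(), coh$thetas,
                                seed = 81)$responses[, 4]
  x2 <- response_matrix(y2, n_categories = 3)
  r <- cor(y2[, 1], y2[, 2])
  expect_equal(descriptives(x2)$cronbach_alpha, 2 * r / (1 + r),
               tolerance = 1e-4)

  # degenerate: zero total variance is an explicit error
  expect_error(descriptives(response_matrix(matrix(1L, 5, 3),
                                            n_categories = 3)),
               "undefined")
})

test_that("PCA screen: eigen structure and pass rules", {
  set.seed(10)
  # independent items: ratio near 1, no pass on the ratio rule
  Y <- matrix(sample(0:2, 4000 * 10, replace = TRUE), 4000, 10)
  p <- pca_screen(response_matrix(Y, n_categories = 3))
  expect_lt(p$ratio_first_second, 1.5)
  expect_false(p$pass_ratio4)
  expect_equal(sum(p$eigenvalues), 10, tolerance = 1e-8)

  # single-factor synthetic cohort passes the 20% rule
  coh <- generate_cohort(cohort_spec(n_persons = 5000, seed = 12))
  ps <- pca_screen(coh$matrix)
  expect_true(ps$pass_20pct)
  expect_true(ps$pass_ratio4)

  # near rank-1 data: first component dominates
  set.seed(11)
  base <- sample(0:2, 500, replace = TRUE)
  Yr <- sapply(1:6, function(j) {
    flip <- runif(500) < 0.02
    ifelse(flip, sample(0:2, 500, replace = TRUE), base)
  })
  pr <- pca_screen(response_matrix(Yr, n_categories = 3))
  expect_gt(pr$prop_var_first, 0.9)

  expect_error(pca_screen(response_matrix(cbind(base, 1L),
                                          n_categories = 3)),
               "constant")
})

test_that("one-factor CFA: saturating construction and optimizer oracle", {
  # a correlation matrix built exactly as lambda lambda' + Psi fits
  # perfectly
  lambda <- c(0.8, 0.7, 0.6, 0.5, 0.4)
  R <- tcrossprod(lambda) + diag(1 - lambda^2)
  sat <- cfa_one_factor(R, n = 800)
  expect_equal(abs(sat$loadings), lambda, tolerance = 1e-4)
  expect_lt(sat$chi2, 1e-4)
  expect_equal(sat$CFI, 1)
  expect_lt(sat$SRMR, 1e-6)

  # package CFA on GRM cohort data: loadings match a direct numerical
  # minimisation of the ML discrepancy
  coh <- generate_cohort(cohort_spec(n_persons = 1500, seed = 14,
                                     bank = bss_bank()))
  x5 <- response_matrix(coh$matrix$responses[, 1:5], n_categories = 3)
  fit <- cfa_one_factor(x5)
  R5 <- cor(x5$responses)
  disc <- function(par) {
    l <- par[1:5]; psi <- exp(par[6:10])
    S <- tcrossprod(l) + diag(psi)
    as.numeric(determinant(S)$modulus - determinant(R5)$modulus +
                 sum(diag(solve(S, R5))) - 5)
  }
  op <- optim(c(rep(0.5, 5), rep(log(0.5), 5)), disc, method = "BFGS",
              control = list(maxit = 5000, reltol = 1e-15))
  expect_equal(abs(fit$loadings), abs(op$par[1:5]), tolerance = 1e-3)

  expect_true(fit$CFI <= 1 && fit$TLI <= 1)
  expect_gte(fit$RMSEA, 0)
  expect_true(fit$RMSEA_90CI[1] <= fit$RMSEA_90CI[2])
})

test_that("local independence flags exactly the violating pairs", {
  R <- diag(4) * 0
  expect_equal(nrow(local_independence_flags(R)), 0L)
  R[2, 3] <- R[3, 2] <- 0.25
  fl <- local_independence_flags(R)
  expect_equal(nrow(fl), 1L)
  expect_equal(c(fl$item_i, fl$item_j), c(2, 3))
  expect_equal(fl$residual_r, 0.25)
  # threshold is strict
  R[2, 3] <- R[3, 2] <- 0.2
  expect_equal(nrow(local_independence_flags(R)), 0L)
  expect_error(local_independence_flags(matrix(1:6, 2, 3)), "square")
})

test_that("single-factor cohorts rarely violate local independence", {
  # scaled-down replicate study: 25 seeded cohorts of n = 2000
  clean <- vapply(1:25, function(s) {
    coh <- generate_cohort(cohort_spec(n_persons = 2000, seed = 100 + s))
    cfa <- cfa_one_factor(coh$matrix)
    nrow(local_independence_flags(cfa$residuals)) == 0
  }, logical(1))
  expect_gte(mean(clean), 0.9)
})

test_that("Mokken scalability: Guttman, independence, and cross-table oracle", {
  # perfect Guttman-ordered polytomous data -> H = 1 everywhere
  Y <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0),
             c(2, 2, 1), c(2, 2, 2))
  mok <- mokken_scalability(response_matrix(Y, n_categories = 3))
  expect_equal(unname(mok$H_item), rep(1, 3), tolerance = 1e-12)
  expect_equal(mok$H_overall, 1, tolerance = 1e-12)
  expect_length(mok$flagged, 0)

  # independent items: H near 0, all flagged
  set.seed(15)
  Yi <- matrix(sample(0:2, 3000 * 4, replace = TRUE), ncol = 4)
  mi <- mokken_scalability(response_matrix(Yi, n_categories = 3))
  expect_true(all(abs(mi$H_item) < 0.15))
  expect_setequal(mi$flagged, 1:4)

  # 3-item toy: pairwise H equals cov / enumerated maximal covariance
  set.seed(16)
  Yt <- matrix(sample(0:2, 8 * 3, replace = TRUE, prob = c(3, 2, 1)),
               8, 3)
  mt <- mokken_scalability(response_matrix(Yt, n_categories = 3))
  for (i in 1:2) for (j in (i + 1):3) {
    cv <- mean(Yt[, i] * Yt[, j]) - mean(Yt[, i]) * mean(Yt[, j])
    expect_equal(mt$H_pairs[i, j], cv / oracle_covmax(Yt[, i], Yt[, j]),
                 tolerance = 1e-12)
  }

  # zero-variance item excluded with a warning
  expect_warning(mokken_scalability(response_matrix(cbind(Yt, 0L),
                                                    n_categories = 3)),
                 "excluded")
})
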
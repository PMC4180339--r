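# graded response model: probabilities, information, calibration, scoring

test_that("category probabilities: closed form, normalization, midpoints", {
  b <- bss_bank()
  # P(category 0) at theta = -2 for item 7 rounds to 1.00
  p <- category_probabilities(b, -2, items = 7)[1, 1, ]
  expect_equal(round(unname(p[1]), 2), 1)
  # normalization holds to machine precision at arbitrary thetas
  for (th in c(-3.7, 0, 0.37, 1.5, 4.2)) {
    probs <- category_probabilities(b, th)
    expect_equal(unname(rowSums(probs[1, , ])), rep(1, 19),
                 tolerance = 1e-15)
  }
  # logistic midpoint: P*(>=1) = 0.5 exactly at theta = beta1
  for (j in c(1, 7, 18)) {
    pj <- category_probabilities(b, b$betas[j, 1], items = j)[1, 1, ]
    expect_equal(unname(pj[2] + pj[3]), 0.5, tolerance = 1e-12)
  }
  # item 7 at theta = 1.5 against the first-principles closed form
  p15 <- category_probabilities(b, 1.5, items = 7)[1, 1, ]
  expect_equal(unname(p15), oracle_grm_probs(4.117, c(0.171, 1.243), 1.5),
               tolerance = 1e-12)
  # saturation at infinite theta
  pinf <- category_probabilities(b, c(-Inf, Inf), items = 4)
  expect_equal(unname(pinf[1, 1, ]), c(1, 0, 0))
  expect_equal(unname(pinf[2, 1, ]), c(0, 0, 1))
})

test_that("boundary curves are monotone in k and in theta", {
  b <- bss_bank()
  grid <- seq(-4, 4, 0.25)
  p <- category_probabilities(b, grid)
  for (j in 1:19) {
    pge1 <- p[, j, 2] + p[, j, 3]   # P*(>=1)
    pge2 <- p[, j, 3]               # P*(>=2)
    expect_true(all(pge1 > pge2))
    expect_true(all(diff(pge1) > 0) && all(diff(pge2) > 0))
    # expected score strictly increasing in theta
    esc <- p[, j, 2] + 2 * p[, j, 3]
    expect_true(all(diff(esc) > 0))
  }
})

test_that("item information: argmax, nonnegativity, curvature oracle", {
  b <- bss_bank()
  info0 <- item_information(b, 0)[1, ]
  expect_equal(unname(which.max(info0)), 4L)   # the CAT entry item
  expect_true(all(item_information(b, seq(-4, 4, 0.5)) >= 0))

  # I(theta) equals the negative expected second derivative of the
  # log-likelihood, by central finite differences
  h <- 1e-4
  for (j in c(4, 11, 18)) {
    for (th in c(-0.5, 0, 1.2)) {
      pr <- function(t) category_probabilities(b, t, items = j)[1, 1, ]
      d2 <- (log(pr(th + h)) - 2 * log(pr(th)) + log(pr(th - h))) / h^2
      oracle <- -sum(pr(th) * d2)
      expect_equal(unname(item_information(b, th, items = j)[1, 1]),
                   oracle, tolerance = 1e-4)
    }
  }
  # information vanishes in the tails
  expect_lt(max(item_information(b, 20)), 1e-6)
})

test_that("test information is additive and right-peaked", {
  b <- bss_bank()
  th <- c(-1, 0.5)
  expect_equal(test_information(b, th, subset = 7),
               unname(item_information(b, th, items = 7)[, 1]))
  expect_equal(test_information(b, th),
               rowSums(item_information(b, th)))
  # grid search: the full-bank curve peaks at positive theta
  grid <- seq(-3, 3, length.out = 121)
  curve <- test_information(b, grid)
  expect_gt(grid[which.max(curve)], 0)
  expect_warning(ti <- test_information(b, 0, subset = integer(0)),
                 "empty")
  expect_equal(ti, 0)
})

test_that("M-step gradient matches numerical differentiation", {
  skip_if_not_installed("numDeriv")
  set.seed(20)
  nodes <- seq(-3, 3, length.out = 11)
  r <- matrix(rexp(11 * 3), 11, 3)
  par <- c(log(2.1), -0.3, log(0.9))
  g_num <- numDeriv::grad(grmcat:::item_mstep_obj, par, r = r,
                          nodes = nodes)
  g_ana <- grmcat:::item_mstep_grad(par, r, nodes)
  expect_equal(g_ana, g_num, tolerance = 1e-6)
})

test_that("MML-EM recovers generating parameters (single cohort)", {
  b <- bss_bank()
  coh <- generate_cohort(cohort_spec(n_persons = 2000,
                                     theta_mixture = normal_mixture,
                                     seed = 21))
  fit <- fit_grm(coh$matrix)
  expect_true(fit$converged)
  expect_lt(mean(abs(fit$bank$alpha - b$alpha)), 0.35)
  expect_lt(mean(abs(fit$bank$betas - b$betas)), 0.15)
  expect_true(all(apply(fit$bank$betas, 1, diff) > 0))
  expect_true(all(is.finite(fit$se_alpha)))
  # a noise item (responses carry no trait signal) calibrates to tiny alpha
  Yn <- coh$matrix$responses
  set.seed(22)
  Yn[, 11] <- sample(0:2, 2000, replace = TRUE)
  fitn <- fit_grm(response_matrix(Yn, n_categories = 3), tol = 1e-5)
  expect_lt(fitn$bank$alpha[11], 0.3)
  # degenerate item is an explicit error
  Yd <- coh$matrix$responses
  Yd[, 3] <- 0L
  expect_error(fit_grm(response_matrix(Yd, n_categories = 3)), "collapse")
})

test_that("EAP matches the dense-grid posterior-mean oracle", {
  b <- bss_bank()
  set.seed(24)
  for (rep in 1:20) {
    k <- sample(1:6, 1)
    ids <- sort(sample(b$id, k))
    pattern <- setNames(sample(0:2, k, replace = TRUE), ids)
    est <- estimate_theta(b, pattern)
    expect_equal(est$theta, oracle_eap(b, pattern), tolerance = 1e-3)
  }
})

test_that("EAP symmetry, shift direction, and MLE boundary handling", {
  sb <- symmetric_bank()
  est <- estimate_theta(sb, setNames(c(0L, 2L), 1:2))
  expect_equal(est$theta, 0, tolerance = 1e-10)
  # a single top response on the entry item pushes the posterior above 0
  b <- bss_bank()
  est2 <- estimate_theta(b, setNames(2L, 4))
  expect_gt(est2$theta, 0)
  # EAP se shrinks as informative items are added
  est3 <- estimate_theta(b, setNames(c(2L, 2L, 2L), c(4, 7, 15)))
  expect_lt(est3$se, est2$se)
  # MLE flags all-minimum patterns as boundary
  mle <- estimate_theta(b, setNames(c(0L, 0L), c(4, 7)), method = "MLE")
  expect_true(mle$boundary)
  # interior MLE has positive finite se
  mle2 <- estimate_theta(b, setNames(c(1L, 2L, 0L), c(4, 7, 1)),
                         method = "MLE")
  expect_false(mle2$boundary)
  expect_gt(mle2$se, 0)
  expect_error(estimate_theta(b, setNames(integer(0), character(0))),
               "at least one")
})

test_that("cohort EAP scoring agrees with per-person estimation", {
  b <- bss_bank()
  coh <- generate_cohort(cohort_spec(n_persons = 30, seed = 25))
  sc <- eap_scores(b, coh$matrix)
  for (i in c(1, 13, 30)) {
    ref <- estimate_theta(b, setNames(coh$matrix$responses[i, ], b$id))
    expect_equal(sc$theta[i], ref$theta, tolerance = 1e-10)
    expect_equal(sc$se[i], ref$se, tolerance = 1e-10)
  }
})

test_that("mean theta by response category separates well-behaved items", {
  b <- bss_bank()
  coh <- generate_cohort(cohort_spec(n_persons = 1500, seed = 26))
  tab <- mean_theta_by_response(coh$matrix, b)
  # item 7 (high alpha, wide thresholds): increasing means, no overlap
  t7 <- tab[tab$item == 7, ]
  expect_true(all(diff(t7$mean_theta) > 0))
  expect_false(t7$overlap_flag[1])
  # an item whose responses ignore the trait (the misfit pattern the
  # diagnostic exists to catch) must show overlapping category intervals
  Yj <- coh$matrix$responses
  set.seed(261)
  Yj[, 11] <- sample(0:2, 1500, replace = TRUE)
  tabj <- mean_theta_by_response(response_matrix(Yj, n_categories = 3), b)
  expect_true(tabj$overlap_flag[tabj$item == 11][1])
  # empty category reported as missing
  Y <- coh$matrix$responses
  Y[, 5] <- 0L
  tab2 <- mean_theta_by_response(response_matrix(Y, n_categories = 3), b)
  t5 <- tab2[tab2$item == 5, ]
  expect_true(all(is.na(t5$mean_theta[t5$category > 0])))
  expect_equal(t5$n[t5$category > 0], c(0L, 0L))
})
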
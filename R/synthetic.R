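#' Specify a synthetic cohort
#'
#' Describes the generative world for a synthetic respondent cohort: a
#' Gaussian-mixture latent trait, a GRM item bank driving the ordinal
#' responses, independent binary covariates, and (optionally) injected
#' uniform differential item functioning.
#'
#' The default trait mixture, `0.2 N(-2.2, 0.4^2) + 0.8 N(0.6, 1^2)`,
#' emulates a right-heavy clinical severity distribution with a
#' substantial floor group: under the default 19-item bank roughly a
#' fifth of simulated respondents produce a total score of 0.
#'
#' @param n_persons cohort size (default 505).
#' @param theta_mixture data.frame/list with columns `weight`, `mean`,
#'   `sd`; weights must sum to 1, sds positive.
#' @param bank an [item_bank()] (default [default_item_bank()]).
#' @param covariate_probs named list giving, per covariate, the
#'   probability of its first level. Defaults to 50/50 for `gender`
#'   (female/male), `age_band` (18-49/50-69), `education` (low/high),
#'   `mode` (computer/paper).
#' @param dif optional list `list(item_id =, covariate =, beta_shift =)`:
#'   before response generation, the focal group's thresholds for that
#'   item are all shifted by `beta_shift` (uniform DIF). The focal group
#'   is the *second* level of the covariate.
#' @param seed integer seed; mandatory (the whole cohort is a
#'   deterministic function of the spec).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_persons = 505,
                        theta_mixture = data.frame(
                          weight = c(0.2, 0.8),
                          mean = c(-2.2, 0.6),
                          sd = c(0.4, 1.0)),
                        bank = default_item_bank(),
                        covariate_probs = list(gender = 0.5, age_band = 0.5,
                                               education = 0.5, mode = 0.5),
                        dif = NULL, seed) {
  if (missing(seed) || !is.finite(seed))
    stop("seed is mandatory for cohort generation")
  theta_mixture <- as.data.frame(theta_mixture)
  if (abs(sum(theta_mixture$weight) - 1) > 1e-8)
    stop("mixture weights must sum to 1")
  if (any(theta_mixture$sd <= 0)) stop("mixture sds must be positive")
  if (n_persons < 1) stop("n_persons must be >= 1")
  stopifnot(inherits(bank, "item_bank"))
  if (!is.null(dif)) {
    if (!all(c("item_id", "covariate", "beta_shift") %in% names(dif)))
      stop("dif must name item_id, covariate and beta_shift")
    if (!dif$item_id %in% bank$id)
      stop("dif target item not in bank: ", dif$item_id)
    if (!dif$covariate %in% names(covariate_probs))
      stop("dif covariate unknown: ", dif$covariate)
  }
  structure(list(n_persons = as.integer(n_persons),
                 theta_mixture = theta_mixture, bank = bank,
                 covariate_probs = covariate_probs, dif = dif,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

.covariate_levels <- list(gender = c("female", "male"),
                          age_band = c("18-49", "50-69"),
                          education = c("low", "high"),
                          mode = c("computer", "paper"))

#' Draw latent trait values from a cohort spec's mixture
#'
#' @param spec a [cohort_spec()].
#' @return numeric vector of length `spec$n_persons`; reproducible under
#'   the spec's seed.
#' @export
sample_thetas <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  draw_mixture(spec$n_persons, spec$theta_mixture)
}

draw_mixture <- function(n, mix) {
  comp <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
  rnorm(n, mean = mix$mean[comp], sd = mix$sd[comp])
}

#' Simulate GRM-consistent responses at given trait values
#'
#' Each cell is drawn from the item's category distribution at the
#' person's theta (see [category_probabilities()]).
#'
#' @param bank an [item_bank()].
#' @param thetas numeric vector of latent trait values.
#' @param seed optional seed (set it for reproducibility when calling
#'   directly; [generate_cohort()] manages seeding itself).
#' @return A [response_matrix()] of dimension `length(thetas) x` bank
#'   size.
#' @export
simulate_responses <- function(bank, thetas, seed = NULL) {
  stopifnot(inherits(bank, "item_bank"))
  if (!is.null(seed)) set.seed(seed)
  draw_grm_responses(bank$alpha, bank$betas, thetas, bank$n_categories)
}

# workhorse: inverse-CDF sampling on the boundary curves; alphas/betas may
# be person-specific via the `shift` matrix (used for DIF injection)
draw_grm_responses <- function(alpha, betas, thetas, n_categories,
                               shift = NULL) {
  n <- length(thetas); K <- length(alpha); m <- n_categories - 1L
  Y <- matrix(0L, n, K)
  for (j in seq_len(K)) {
    b <- matrix(betas[j, ], n, m, byrow = TRUE)
    if (!is.null(shift)) b <- b + shift[, j]
    u <- runif(n)
    # response = number of boundary curves exceeded
    y <- integer(n)
    for (k in seq_len(m)) {
      pk <- plogis(alpha[j] * (thetas - b[, k]))
      y <- y + as.integer(u < pk)
    }
    Y[, j] <- y
  }
  colnames(Y) <- paste0("item_", seq_len(K))
  response_matrix(Y, n_categories = n_categories)
}

#' Generate a complete synthetic cohort
#'
#' Draws latent traits from the spec's mixture, covariates independently
#' of theta (so differential item functioning screens are clean under the
#' null), and GRM-consistent responses. If the spec injects DIF, the
#' focal group's thresholds for the target item are shifted by
#' `beta_shift` before response generation. True thetas are retained for
#' recovery checks.
#'
#' @param spec a [cohort_spec()].
#' @return list with `matrix` (a [response_matrix()] carrying the
#'   covariates), `thetas` (true latent traits), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_persons
  thetas <- draw_mixture(n, spec$theta_mixture)
  covs <- lapply(names(spec$covariate_probs), function(nm) {
    lv <- .covariate_levels[[nm]] %||% c(paste0(nm, "_a"), paste0(nm, "_b"))
    ifelse(runif(n) < spec$covariate_probs[[nm]], lv[1], lv[2])
  })
  names(covs) <- names(spec$covariate_probs)
  covariates <- as.data.frame(covs, stringsAsFactors = FALSE,
                              check.names = FALSE)
  shift <- NULL
  bank <- spec$bank
  if (!is.null(spec$dif)) {
    lv <- .covariate_levels[[spec$dif$covariate]]
    focal <- covariates[[spec$dif$covariate]] == lv[2]
    shift <- matrix(0, n, bank$n_items)
    shift[focal, match(spec$dif$item_id, bank$id)] <- spec$dif$beta_shift
  }
  rm_ <- draw_grm_responses(bank$alpha, bank$betas, thetas,
                            bank$n_categories, shift = shift)
  out <- response_matrix(rm_$responses, covariates = covariates,
                         n_categories = bank$n_categories)
  list(matrix = out, thetas = thetas, spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
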
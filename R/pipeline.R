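## End-to-end orchestration of the five analysis steps, driven by a
## single config. Every screening threshold has a named key defaulting
## to the conventional printed value.

#' Pipeline configuration
#'
#' @param seed integer seed, mandatory for any stochastic step.
#' @param estimator trait estimator (`"EAP"` or `"MLE"`).
#' @param quadrature list `n_nodes` / `range` for calibration and
#'   scoring grids.
#' @param cat a [cat_config()].
#' @param dif_alpha DIF flagging level (default .01).
#' @param flags named list of screening thresholds:
#'   `alpha_min` (reliability floor, .8), `pca_prop` (.20),
#'   `pca_ratio` (4), `residual_r` (.2), `scalability_h` (.3),
#'   `effect_negligible` (.13), `effect_moderate` (.26).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            estimator = c("EAP", "MLE"),
                            quadrature = list(n_nodes = 41,
                                              range = c(-4.5, 4.5)),
                            cat = cat_config(),
                            dif_alpha = 0.01,
                            flags = list(alpha_min = 0.8, pca_prop = 0.20,
                                         pca_ratio = 4, residual_r = 0.2,
                                         scalability_h = 0.3,
                                         effect_negligible = 0.13,
                                         effect_moderate = 0.26)) {
  if (missing(seed) || !is.finite(seed)) stop("seed is mandatory")
  estimator <- match.arg(estimator)
  stopifnot(all(vapply(flags, is.finite, logical(1))))
  structure(list(seed = as.integer(seed), estimator = estimator,
                 quadrature = quadrature, cat = cat,
                 dif_alpha = dif_alpha, flags = flags),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror [pipeline_config()] and [cat_config()]:
#' `seed`, `estimator`, `quadrature: {n_nodes, range}`,
#' `cat: {entry_theta, cutoff_theta, confidence, min_items, max_items}`,
#' `dif_alpha`, `flags: {...}`. Missing keys fall back to defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed")
  cc <- do.call(cat_config, c(cfg$cat %||% list(),
                              if (!is.null(cfg$estimator))
                                list(estimator = cfg$estimator)))
  args <- list(seed = cfg$seed, cat = cc)
  for (k in c("estimator", "quadrature", "dif_alpha"))
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  if (!is.null(cfg$flags)) {
    defaults <- formals(pipeline_config)$flags |> eval()
    defaults[names(cfg$flags)] <- cfg$flags
    args$flags <- defaults
  }
  do.call(pipeline_config, args)
}

#' Run the five-step pipeline
#'
#' Executes, in order: (1) descriptives and reliability, (2) assumption
#' screens, (3) GRM calibration and category-level diagnostics, (4) DIF
#' screening over the available covariates (skipped with a notice when
#' none are present), (5) the CAT stopping-rule comparison. Deterministic
#' given config and data.
#'
#' @param config a [pipeline_config()].
#' @param x a [response_matrix()] (e.g. loaded via
#'   [load_response_matrix()] or generated by [generate_cohort()]).
#' @param bank an [item_bank()]; default [default_item_bank()]. Used for
#'   validation and as the CAT bank when `calibrate = FALSE`.
#' @param calibrate if `TRUE` (default) steps 3-5 use parameters
#'   re-estimated from the data; if `FALSE` they use `bank` as-is.
#' @return An object of class `pipeline_report`: list of per-step
#'   sections plus a `provenance` block (seed, config, package version).
#' @export
run_pipeline <- function(config, x, bank = default_item_bank(),
                         calibrate = TRUE) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(x, "response_matrix"))
  sections <- list()
  sections$validation <- validate_dataset(x, bank)
  sections$descriptives <- descriptives(x)
  sections$assumptions <- assumption_report(
    x, residual_threshold = config$flags$residual_r,
    scalability_threshold = config$flags$scalability_h)
  fit <- if (calibrate) fit_grm(x, n_quad = config$quadrature$n_nodes)
  else NULL
  score_bank <- if (calibrate) fit$bank else bank
  sections$grm <- list(fit = fit, bank = score_bank,
                       mean_theta = mean_theta_by_response(x, score_bank))
  if (!is.null(x$covariates) && ncol(x$covariates) > 0) {
    sections$dif <- dif_screen(x, score_bank, alpha = config$dif_alpha)
  } else {
    sections$dif <- NULL
    sections$dif_skipped <- "no covariates present; DIF step skipped"
  }
  sections$cat <- compare_stopping_rules(score_bank, x, base = config$cat)
  sections$provenance <- list(
    seed = config$seed, estimator = config$estimator,
    dif_alpha = config$dif_alpha, flags = config$flags,
    package_version = as.character(utils::packageVersion("grmcat")))
  class(sections) <- "pipeline_report"
  sections
}

#' Render a pipeline report
#'
#' `"json"` renders a machine-readable document (parse it back with
#' `jsonlite::fromJSON`); `"markdown"` renders human-readable tables
#' mirroring the conventional layouts (per-item descriptives; a
#' stopping-rule comparison with min/max items, mean (SD) administered
#' and low/elevated counts).
#'
#' @param report a `pipeline_report`.
#' @param format `"json"` or `"markdown"`.
#' @param path optional output file; when `NULL` the rendering is
#'   returned as a character string.
#' @return the rendering, invisibly if written to `path`.
#' @export
render_report <- function(report, format = c("json", "markdown"),
                          path = NULL) {
  format <- match.arg(format,
                      choices = c("json", "markdown"),
                      several.ok = FALSE)
  out <- if (format == "json") render_json(report) else render_md(report)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

render_json <- function(report) {
  strip <- function(z) {
    if (is.data.frame(z)) return(as.data.frame(z))
    if (inherits(z, "pipeline_report") || is.list(z))
      return(lapply(unclass(z), strip))
    if (is.matrix(z)) return(as.data.frame(z))
    z
  }
  safe <- strip(report)
  safe$grm$fit$bank <- if (!is.null(report$grm[["fit"]]))
    as.data.frame(report$grm$fit$bank)
  safe$grm$bank <- as.data.frame(report$grm$bank)
  if (!is.null(report[["dif"]])) safe$dif <- as.data.frame(report[["dif"]])
  jsonlite::toJSON(safe, dataframe = "rows", digits = 10,
                   auto_unbox = TRUE, na = "null", force = TRUE)
}

md_table <- function(df, digits = 3) {
  fmt <- function(v) if (is.numeric(v)) format(round(v, digits),
                                               trim = TRUE) else as.character(v)
  body <- apply(as.data.frame(lapply(df, fmt)), 1, paste, collapse = " | ")
  c(paste("|", paste(names(df), collapse = " | "), "|"),
    paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
    paste("|", body, "|"))
}

render_md <- function(report) {
  ln <- c("# Psychometric pipeline report", "")
  d <- report$descriptives
  if (!is.null(d)) {
    ln <- c(ln, "## Step 1: descriptives",
            sprintf("n = %d; Cronbach alpha = %.3f; total mean (SD) = %.2f (%.2f)",
                    d$n_persons, d$cronbach_alpha, d$total_mean, d$total_sd),
            "", md_table(d$items), "")
  }
  a <- report$assumptions
  if (!is.null(a)) {
    ln <- c(ln, "## Step 2: assumption screens",
            sprintf("PCA: first component %.1f%% of variance (ratio %.1f); pass 20%%: %s; pass ratio 4: %s",
                    100 * a$pca$prop_var_first, a$pca$ratio_first_second,
                    a$pca$pass_20pct, a$pca$pass_ratio4),
            sprintf("CFA: chi2(%d) = %.1f, CFI %.3f, TLI %.3f, RMSEA %.3f (90%% CI %.3f-%.3f), SRMR %.3f",
                    a$cfa$df, a$cfa$chi2, a$cfa$CFI, a$cfa$TLI, a$cfa$RMSEA,
                    a$cfa$RMSEA_90CI[1], a$cfa$RMSEA_90CI[2], a$cfa$SRMR),
            sprintf("local independence: %d flagged pair(s); scalability: overall H %.2f, %d item(s) flagged",
                    nrow(a$local_independence), a$scalability$H_overall,
                    length(a$scalability$flagged)), "")
  }
  if (!is.null(report$grm)) {
    ln <- c(ln, "## Step 3: graded response model",
            md_table(as.data.frame(report$grm$bank)), "")
  }
  if (!is.null(report[["dif"]])) {
    ln <- c(ln, "## Step 4: differential item functioning",
            sprintf("%d of %d tests flagged", sum(report$dif$flag),
                    nrow(report$dif)), "")
  } else if (!is.null(report$dif_skipped)) {
    ln <- c(ln, "## Step 4: differential item functioning",
            report$dif_skipped, "")
  }
  if (!is.null(report$cat)) {
    cat_tab <- report$cat
    cat_tab$`mean (SD)` <- sprintf("%.1f (%.1f)", cat_tab$mean_items,
                                   cat_tab$sd_items)
    ln <- c(ln, "## Step 5: computer adaptive testing",
            md_table(cat_tab[, c("min_items", "max_items", "mean (SD)",
                                 "n_low", "n_elevated", "agreement")]),
            "")
  }
  paste(ln, collapse = "\n")
}
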
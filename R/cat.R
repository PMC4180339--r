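## Step 5: post-hoc computer adaptive testing. Items are "administered"
## by replaying the responses already recorded on the full instrument;
## selection is maximum Fisher information at the current trait estimate,
## stopping by a confidence-interval classification rule against a fixed
## trait cut-off plus an item-count cap.

#' CAT configuration
#'
#' @param entry_theta trait value at which the first item is selected
#'   (default 0, the conventional entry level).
#' @param estimator `"EAP"` (default) or `"MLE"` trait estimator used
#'   between administrations.
#' @param cutoff_theta classification cut-off on the trait scale
#'   (default -1, the elevated-risk bound corresponding to a raw total
#'   above 2 on the default 19-item bank).
#' @param confidence confidence level for the classification interval
#'   (default 0.99, i.e. z = 2.5758).
#' @param min_items minimum administered before a classification stop
#'   (default 3).
#' @param max_items administration cap (default 6).
#' @return An object of class `cat_config`.
#' @export
cat_config <- function(entry_theta = 0, estimator = c("EAP", "MLE"),
                       cutoff_theta = -1, confidence = 0.99,
                       min_items = 3, max_items = 6) {
  estimator <- match.arg(estimator)
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must be strictly between 0 and 1")
  if (min_items < 1 || max_items < min_items)
    stop("need 1 <= min_items <= max_items")
  structure(list(entry_theta = entry_theta, estimator = estimator,
                 cutoff_theta = cutoff_theta, confidence = confidence,
                 min_items = as.integer(min_items),
                 max_items = as.integer(max_items)),
            class = "cat_config")
}

#' Select the next item by maximum Fisher information
#'
#' Argmax of [item_information()] at the current trait estimate over the
#' unadministered items; ties break to the lowest item id.
#'
#' @param bank an [item_bank()].
#' @param administered integer ids already used (may be empty).
#' @param theta_current current trait estimate.
#' @return a single item id.
#' @export
select_next_item <- function(bank, administered, theta_current) {
  remaining <- setdiff(bank$id, administered)
  if (length(remaining) == 0L) stop("no unadministered items remain")
  info <- item_information(bank, theta_current, items = remaining)[1, ]
  remaining[which.max(info)]   # which.max takes the first (lowest id) on ties
}

#' Classification stopping rule
#'
#' The interval `theta +- z * se` (z the two-sided normal quantile at the
#' configured confidence) triggers a `"classified"` stop when it lies
#' entirely on one side of the cut-off and at least `min_items` have been
#' administered; the cap triggers `"max_items"`; an empty remainder
#' triggers `"bank_exhausted"`.
#'
#' @param estimate list with `theta` and `se` (as from
#'   [estimate_theta()]).
#' @param config a [cat_config()].
#' @param n_administered,n_remaining administration state.
#' @return list `stop` (logical) and `reason` (`NA` when continuing).
#' @export
check_stopping <- function(estimate, config, n_administered, n_remaining) {
  z <- qnorm(1 - (1 - config$confidence) / 2)
  lo <- estimate$theta - z * estimate$se
  hi <- estimate$theta + z * estimate$se
  clear <- lo > config$cutoff_theta || hi < config$cutoff_theta
  if (clear && n_administered >= config$min_items)
    return(list(stop = TRUE, reason = "classified"))
  if (n_administered >= config$max_items)
    return(list(stop = TRUE, reason = "max_items"))
  if (n_remaining == 0L)
    return(list(stop = TRUE, reason = "bank_exhausted"))
  list(stop = FALSE, reason = NA_character_)
}

#' Post-hoc CAT for one person
#'
#' Replays one complete recorded response vector through the adaptive
#' algorithm: select the most informative unadministered item at the
#' current estimate, "administer" it by reading off the recorded
#' response, re-estimate the trait, and test the stopping rule. Fully
#' deterministic given the configuration.
#'
#' @param bank an [item_bank()].
#' @param responses complete integer vector over the bank (in bank id
#'   order).
#' @param config a [cat_config()].
#' @return An object of class `cat_result`: list with `administered`,
#'   `responses`, `theta_trajectory` (data.frame theta/se per step),
#'   `theta`, `se`, `stop_reason`, `classification` (`"elevated"` if the
#'   final estimate exceeds the cut-off, else `"low"`).
#' @export
run_cat_post_hoc <- function(bank, responses, config = cat_config()) {
  stopifnot(inherits(bank, "item_bank"), inherits(config, "cat_config"))
  if (length(responses) != bank$n_items || any(is.na(responses)))
    stop("a complete response vector over the bank is required")
  administered <- integer(0)
  traj <- list()
  th <- config$entry_theta
  est <- NULL
  repeat {
    nxt <- select_next_item(bank, administered, th)
    administered <- c(administered, nxt)
    pattern <- setNames(responses[match(administered, bank$id)],
                        administered)
    est <- estimate_theta(bank, pattern, method = config$estimator)
    if (config$estimator == "MLE" && est$boundary)
      est <- estimate_theta(bank, pattern, method = "EAP")
    th <- est$theta
    traj[[length(traj) + 1L]] <- c(theta = est$theta, se = est$se)
    st <- check_stopping(est, config, length(administered),
                         bank$n_items - length(administered))
    if (st$stop) { reason <- st$reason; break }
  }
  structure(list(
    administered = administered,
    responses = unname(responses[match(administered, bank$id)]),
    theta_trajectory = as.data.frame(do.call(rbind, traj)),
    theta = est$theta, se = est$se, stop_reason = reason,
    classification = if (est$theta > config$cutoff_theta) "elevated"
    else "low"),
    class = "cat_result")
}

#' @export
print.cat_result <- function(x, ...) {
  cat(sprintf("CAT: %d items [%s], theta %.2f (se %.2f), stop: %s, %s risk\n",
              length(x$administered),
              paste(x$administered, collapse = ","),
              x$theta, x$se, x$stop_reason, x$classification))
  invisible(x)
}

#' Cohort-level CAT simulation
#'
#' Runs [run_cat_post_hoc()] for every person and summarises: mean and SD
#' of items administered, low/elevated classification counts, and
#' agreement with the full-test classification (EAP over all items
#' against the same cut-off).
#'
#' @param bank an [item_bank()]; @param x a [response_matrix()].
#' @param config a [cat_config()].
#' @return An object of class `cat_summary`: list with `n_persons`,
#'   `mean_items`, `sd_items`, `n_low`, `n_elevated`,
#'   `agreement_with_full_test`, `results` (per-person list), and
#'   `full_test` (data.frame of full-test theta and classification).
#' @export
simulate_cohort_cat <- function(bank, x, config = cat_config()) {
  stopifnot(inherits(x, "response_matrix"))
  full <- eap_scores(bank, x)
  full_class <- ifelse(full$theta > config$cutoff_theta, "elevated", "low")
  results <- vector("list", x$n_persons)
  n_items <- integer(x$n_persons)
  cls <- character(x$n_persons)
  for (i in seq_len(x$n_persons)) {
    r <- run_cat_post_hoc(bank, x$responses[i, ], config)
    results[[i]] <- r
    n_items[i] <- length(r$administered)
    cls[i] <- r$classification
  }
  structure(list(
    n_persons = x$n_persons,
    mean_items = mean(n_items), sd_items = sd(n_items),
    n_low = sum(cls == "low"), n_elevated = sum(cls == "elevated"),
    agreement_with_full_test = mean(cls == full_class),
    items_administered = n_items,
    classifications = cls,
    full_test = data.frame(theta = full$theta, se = full$se,
                           classification = full_class),
    results = results, config = config),
    class = "cat_summary")
}

#' @export
print.cat_summary <- function(x, ...) {
  cat(sprintf(
    "CAT simulation, n = %d: %.1f (SD %.1f) items; low %d / elevated %d; agreement with full test %.1f%%\n",
    x$n_persons, x$mean_items, x$sd_items, x$n_low, x$n_elevated,
    100 * x$agreement_with_full_test))
  invisible(x)
}

#' Compare stopping rules on one cohort
#'
#' Reproduces the standard three-row comparison: full administration
#' (min = max = bank size), the confidence-interval rule with the full
#' bank available (min 3, max 19 for the default bank), and the capped
#' rule (min 3, max 6).
#'
#' @param bank an [item_bank()]; @param x a [response_matrix()].
#' @param base a [cat_config()] supplying estimator, cut-off and
#'   confidence shared by all rows.
#' @param rules list of `c(min_items, max_items)` pairs; default the
#'   three canonical rows.
#' @return data.frame with columns `min_items`, `max_items`,
#'   `mean_items`, `sd_items`, `n_low`, `n_elevated`, `agreement`.
#' @export
compare_stopping_rules <- function(bank, x, base = cat_config(),
                                   rules = NULL) {
  K <- bank$n_items
  if (is.null(rules))
    rules <- list(c(K, K), c(3, K), c(3, 6))
  rows <- lapply(rules, function(r) {
    cfg <- cat_config(entry_theta = base$entry_theta,
                      estimator = base$estimator,
                      cutoff_theta = base$cutoff_theta,
                      confidence = base$confidence,
                      min_items = r[1], max_items = r[2])
    s <- simulate_cohort_cat(bank, x, cfg)
    data.frame(min_items = r[1], max_items = r[2],
               mean_items = s$mean_items, sd_items = s$sd_items,
               n_low = s$n_low, n_elevated = s$n_elevated,
               agreement = s$agreement_with_full_test)
  })
  do.call(rbind, rows)
}

#' Enumerate the CAT decision tree
#'
#' Breadth-first enumeration of every possible response path under the
#' adaptive algorithm, to a given depth: each node names the item to
#' administer, each outgoing edge a response category leading either to a
#' child node or to a terminal classification. The tree is the complete
#' "paper form" of the adaptive algorithm.
#'
#' @param bank an [item_bank()]; @param config a [cat_config()].
#' @param max_depth maximum tree depth (must be >= 1 and <= the config's
#'   `max_items`).
#' @return nested list: node = `list(item =, edges = list(<one per
#'   category>))`; each edge is `list(response =, child = <node>)` or
#'   `list(response =, classification =, theta =)`.
#' @export
export_decision_tree <- function(bank, config = cat_config(),
                                 max_depth = config$max_items) {
  if (max_depth < 1) stop("max_depth must be at least 1")
  max_depth <- min(max_depth, config$max_items)
  m <- bank$n_categories - 1L
  grow <- function(administered, pattern, theta, depth) {
    item <- select_next_item(bank, administered, theta)
    edges <- lapply(0:m, function(resp) {
      pat <- c(pattern, setNames(resp, item))
      est <- estimate_theta(bank, pat, method = config$estimator)
      if (config$estimator == "MLE" && est$boundary)
        est <- estimate_theta(bank, pat, method = "EAP")
      cls <- if (est$theta > config$cutoff_theta) "elevated" else "low"
      n_adm <- length(pat)
      st <- check_stopping(est, config, n_adm, bank$n_items - n_adm)
      if ((st$stop && st$reason == "classified") || depth >= max_depth)
        list(response = resp, classification = cls,
             theta = round(est$theta, 3),
             terminal_reason = if (st$stop && st$reason == "classified")
               "classified" else "depth")
      else
        list(response = resp,
             child = grow(c(administered, item), pat, est$theta,
                          depth + 1L))
    })
    list(item = item, edges = edges)
  }
  grow(integer(0), setNames(integer(0), character(0)),
       config$entry_theta, 1L)
}

#' Render a decision tree in DOT (graphviz) format
#'
#' @param tree a tree from [export_decision_tree()].
#' @return a single character string of DOT source.
#' @export
decision_tree_dot <- function(tree) {
  lines <- c("digraph cat {", "  node [shape=box];")
  counter <- new.env(); counter$i <- 0L
  nid <- function() { counter$i <- counter$i + 1L
    sprintf("n%d", counter$i) }
  walk <- function(node) {
    id <- nid()
    lines <<- c(lines, sprintf("  %s [label=\"item %d\"];", id, node$item))
    for (e in node$edges) {
      if (!is.null(e$classification)) {
        tid <- nid()
        lines <<- c(lines,
          sprintf("  %s [shape=ellipse,label=\"%s risk\"];", tid,
                  e$classification),
          sprintf("  %s -> %s [label=\"%d\"];", id, tid, e$response))
      } else {
        cid <- walk(e$child)
        lines <<- c(lines, sprintf("  %s -> %s [label=\"%d\"];", id, cid,
                                   e$response))
      }
    }
    id
  }
  walk(tree)
  paste(c(lines, "}"), collapse = "\n")
}
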
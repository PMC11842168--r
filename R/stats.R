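#' Binomial GLM for migration success
#'
#' Fits a logit-link binomial GLM on per-path success outcomes from a
#' simulation grid and reports coefficients, log-likelihood, and odds ratios
#' `exp(beta)` with Wald confidence intervals. Per-path binary fitting is
#' likelihood-equivalent to fitting aggregated cell proportions.
#'
#' Complete separation (some term perfectly predicting success) is flagged
#' and the odds-ratio intervals are suppressed rather than reported at
#' absurd magnitudes.
#'
#' @param records Data.frame of per-path records with a logical/0-1 `success`
#'   column (e.g. `run_grid(...)$records`).
#' @param formula Model formula on `success` (default: basin, step length,
#'   turning-angle SD, and all interactions).
#' @param ci_level Confidence level for odds-ratio intervals; default 0.95.
#'   `0.975` is available to mirror reports quoting 97.5% intervals.
#' @return An object of class `glm_fit`: the `stats::glm` fit, `logLik`,
#'   `coefficients`, an `odds_ratios` table, and a `separation` flag.
#' @export
fit_success_glm <- function(records,
                            formula = success ~ basin * step_length * turn_sd,
                            ci_level = 0.95) {
  stopifnot(is.data.frame(records), "success" %in% names(records) ||
              all(all.vars(formula)[1] %in% names(records)),
            ci_level > 0, ci_level < 1)
  resp <- all.vars(formula)[1]
  y <- records[[resp]]
  if (!all(y %in% c(0, 1, TRUE, FALSE)))
    stop("response must be binary per path", call. = FALSE)
  fit <- stats::glm(formula, family = stats::binomial(), data = records)
  co <- summary(fit)$coefficients
  separated <- !fit$converged || any(abs(co[, "Estimate"]) > 15)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  or <- data.frame(
    term = rownames(co),
    estimate = co[, "Estimate"],
    se = co[, "Std. Error"],
    odds_ratio = exp(co[, "Estimate"]),
    ci_lower = if (separated) NA_real_ else exp(co[, "Estimate"] - z * co[, "Std. Error"]),
    ci_upper = if (separated) NA_real_ else exp(co[, "Estimate"] + z * co[, "Std. Error"]),
    row.names = NULL
  )
  structure(list(fit = fit, formula = formula,
                 logLik = as.numeric(stats::logLik(fit)),
                 df = attr(stats::logLik(fit), "df"),
                 coefficients = co, odds_ratios = or,
                 ci_level = ci_level, separation = separated),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %s | logLik %.2f (df %d)%s\n",
              deparse(x$formula), x$logLik, x$df,
              if (x$separation) " [separation flagged]" else ""))
  print(x$odds_ratios, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test between nested binomial GLMs
#'
#' `statistic = 2 (LL_full - LL_nested)` referred to a chi-squared
#' distribution with df equal to the parameter-count difference.
#'
#' @param nested,full `glm_fit` objects; the nested model's terms must be a
#'   subset of the full model's.
#' @return A `test_result` with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(nested, full) {
  stopifnot(inherits(nested, "glm_fit"), inherits(full, "glm_fit"))
  t_n <- attr(stats::terms(nested$fit), "term.labels")
  t_f <- attr(stats::terms(full$fit), "term.labels")
  if (!all(t_n %in% t_f))
    stop("models are not nested (nested terms must be a subset of full terms)",
         call. = FALSE)
  stat <- 2 * (full$logLik - nested$logLik)
  df <- full$df - nested$df
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  test_result("likelihood ratio", max(stat, 0), df, p,
              groups = c(deparse(nested$formula), deparse(full$formula)))
}

#' Chi-squared tail probability for a likelihood-ratio statistic
#'
#' @param statistic 2 x delta log-likelihood.
#' @param df Degrees of freedom.
#' @return Upper-tail p value.
#' @export
lrt_pvalue <- function(statistic, df) {
  stats::pchisq(statistic, df, lower.tail = FALSE)
}

test_result <- function(method, statistic, df, p_value, adjusted_p = NA_real_,
                        groups = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(method = method, statistic = as.numeric(statistic),
                 df = df, p_value = p_value, adjusted_p = adjusted_p,
                 groups = groups),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic %.4g, df %s, p %.4g%s\n",
              x$method, x$statistic, paste(x$df, collapse = ","), x$p_value,
              if (!is.na(x$adjusted_p)) sprintf(" (adjusted %.4g)", x$adjusted_p) else ""))
  invisible(x)
}

#' Chi-squared comparison of success frequencies between groups
#'
#' Pearson chi-squared test (no continuity correction by default, matching
#' multi-group usage) on a groups x (success, failure) count table.
#'
#' @param counts Matrix with one row per group and two columns
#'   (successes, failures), or a data.frame with columns `group`, `success`,
#'   `failure`.
#' @param correct Apply the Yates continuity correction (2x2 only).
#' @return A `test_result`.
#' @export
chisq_success <- function(counts, correct = FALSE) {
  if (is.data.frame(counts)) {
    m <- as.matrix(counts[, c("success", "failure")])
    rownames(m) <- counts$group
    counts <- m
  }
  counts <- as.matrix(counts)
  if (nrow(counts) < 2)
    stop("need at least two groups", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: a group or outcome has zero total", call. = FALSE)
  ct <- stats::chisq.test(counts, correct = correct)
  test_result("Pearson chi-squared", unname(ct$statistic),
              unname(ct$parameter), ct$p.value,
              groups = rownames(counts))
}

#' Kruskal-Wallis with Dunn's post hoc test and Holm-Bonferroni correction
#'
#' Nonparametric multi-group comparison for passage times: a tie-corrected
#' Kruskal-Wallis rank-sum test, followed by pairwise Dunn Z statistics on
#' the shared ranks, with Holm-Bonferroni adjusted p values.
#'
#' @param x Numeric response (e.g. passage days).
#' @param g Grouping factor/vector, same length; every group non-empty.
#' @return A list with `kruskal` (a `test_result`) and `pairwise` (a
#'   data.frame: `group1`, `group2`, `z`, `p_value`, `adjusted_p`).
#' @export
kruskal_dunn <- function(x, g) {
  g <- factor(g)
  stopifnot(length(x) == length(g))
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(g) == 0)) stop("every group must be non-empty", call. = FALSE)
  kw <- stats::kruskal.test(x, g)
  res_kw <- test_result("Kruskal-Wallis", unname(kw$statistic),
                        unname(kw$parameter), kw$p.value,
                        groups = levels(g))
  # Dunn's test on the pooled ranks with tie correction
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    sigma <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z[i] <- (rbar[[a]] - rbar[[b]]) / sigma
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  adj <- stats::p.adjust(p, method = "holm")
  list(kruskal = res_kw,
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             z = z, p_value = p, adjusted_p = adj))
}

#' Backward model selection by likelihood-ratio tests
#'
#' Starting from the full interaction model, repeatedly drops the least
#' significant droppable term (highest LRT p value above `alpha`, respecting
#' marginality) and stops when no further term can be removed without
#' significantly worsening the fit.
#'
#' @param records Per-path records (see [fit_success_glm()]).
#' @param formula Starting (full) model formula.
#' @param alpha Significance level for retaining a term (default 0.05).
#' @param ci_level Passed to [fit_success_glm()].
#' @return A list: `fit` (the selected `glm_fit`) and `steps` (a data.frame
#'   of the terms dropped with their LRT statistics).
#' @export
select_success_glm <- function(records,
                               formula = success ~ basin * step_length * turn_sd,
                               alpha = 0.05, ci_level = 0.95) {
  current <- fit_success_glm(records, formula, ci_level)
  steps <- list()
  repeat {
    dr <- stats::drop1(current$fit, test = "LRT")
    cand <- dr[-1, , drop = FALSE]
    if (!nrow(cand)) break
    worst <- rownames(cand)[which.max(cand$`Pr(>Chi)`)]
    p <- max(cand$`Pr(>Chi)`, na.rm = TRUE)
    if (is.na(p) || p <= alpha) break
    new_formula <- stats::update(stats::formula(current$fit),
                                 paste("~ . -", worst))
    steps[[length(steps) + 1L]] <- data.frame(
      dropped = worst, statistic = cand[worst, "LRT"],
      df = cand[worst, "Df"], p_value = cand[worst, "Pr(>Chi)"])
    current <- fit_success_glm(records, new_formula, ci_level)
  }
  list(fit = current,
       steps = if (length(steps)) do.call(rbind, steps) else
         data.frame(dropped = character(), statistic = numeric(),
                    df = numeric(), p_value = numeric()))
}

#' Compare simulated grid cells with telemetry outcomes for one lake
#'
#' For each simulation cell of a lake: a two-sided exact binomial test of the
#' cell's success count against the empirical success proportion, a flag for
#' whether the empirical rate lies inside the cell's 95% (Clopper-Pearson)
#' binomial interval, and the analogous interval check for mean passage time
#' (empirical mean inside the cell's t-based interval for the mean).
#'
#' @param grid A `lakewalk_grid` containing the lake's cells.
#' @param records Telemetry records for that lake (e.g. [lake_telemetry()]).
#' @param lake Lake name; defaults to the single lake present in `records`.
#' @param conf_level Interval level (default 0.95).
#' @return A data.frame with one row per cell: the cell labels, simulated and
#'   empirical rates, `p_value` of the exact test, `rate_within_ci`, and
#'   `passage_within_ci`.
#' @export
compare_to_telemetry <- function(grid, records, lake = NULL,
                                 conf_level = 0.95) {
  stopifnot(inherits(grid, "lakewalk_grid"), is.data.frame(records))
  if (!nrow(records)) stop("no telemetry records supplied", call. = FALSE)
  lake <- lake %||% unique(records$lake)
  if (length(lake) != 1)
    stop("records must come from a single lake", call. = FALSE)
  cells <- grid$cells[grid$cells$basin == lake, , drop = FALSE]
  if (!nrow(cells))
    stop(sprintf("grid contains no cells for lake '%s'", lake), call. = FALSE)
  emp_rate <- mean(records$success)
  emp_passage <- if (any(records$success))
    mean(records$passage_days[records$success]) else NA_real_
  out <- cells[, c("basin", "step_length", "turn_sd", "n_sims", "n_success",
                   "success_rate")]
  out$empirical_rate <- 100 * emp_rate
  out$p_value <- NA_real_
  out$rate_within_ci <- NA
  out$passage_within_ci <- NA
  for (i in seq_len(nrow(cells))) {
    bt <- stats::binom.test(cells$n_success[i], cells$n_sims[i], p = emp_rate,
                            conf.level = conf_level)
    out$p_value[i] <- bt$p.value
    out$rate_within_ci[i] <- emp_rate >= bt$conf.int[1] & emp_rate <= bt$conf.int[2]
    m <- cells$mean_passage_days[i]
    s <- cells$se_passage_days[i]
    nok <- cells$n_success[i] >= 2 && is.finite(s) && !is.na(emp_passage)
    if (nok) {
      tq <- stats::qt(1 - (1 - conf_level) / 2, cells$n_success[i] - 1)
      out$passage_within_ci[i] <- emp_passage >= m - tq * s &
        emp_passage <= m + tq * s
    }
  }
  rownames(out) <- NULL
  out
}
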
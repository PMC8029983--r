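## Survival stratification: product-limit estimation, k-group log-rank,
## Cox proportional hazards (Efron ties) and the mutation-by-expression
## four-subgroup analysis. The numerical machinery is survival::survfit /
## survdiff / coxph; this module fixes the contracts (tie handling, median
## split rule, reporting) used throughout the pipeline.

#' Kaplan-Meier product-limit estimate
#'
#' Right-censoring-aware survival curve with at-risk and event counts at
#' each observed time. The estimate is 1 before the first event and drops
#' only at event times.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 event, 0 censored).
#' @return data.frame of class `km_estimate`: time, n_risk, n_event,
#'   n_censor, surv.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 0, 1))
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (any(times < 0)) stop("negative follow-up time")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_estimate", "data.frame")
  out
}

#' k-group log-rank test
#'
#' Observed-minus-expected chi-square statistic over the pooled event
#' times, df = k - 1.
#'
#' @param times,events As in [km_estimate()].
#' @param groups Group label per subject, k >= 2 non-empty groups.
#' @return List: statistic, df, p, n (per-group sizes).
#' @export
logrank <- function(times, events, groups) {
  g <- as.factor(as.character(groups))
  if (nlevels(g) < 2) stop("log-rank needs >= 2 groups")
  if (any(table(g) == 0)) stop("empty group")
  if (length(unique(paste(times, events))) == 1L ||
      sum(events) == 0)
    return(list(statistic = 0, df = nlevels(g) - 1L, p = 1,
                n = table(g)))
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE), n = table(g))
}

#' Cox proportional-hazards fit (Efron ties)
#'
#' Maximizes the Efron-tied partial likelihood and reports per-covariate
#' log hazard ratios, Wald tests and 95% confidence intervals. Constant
#' covariates are rejected; non-convergence or monotone likelihood
#' (complete separation) is surfaced as a warning with `converged = FALSE`
#' rather than silently returned.
#'
#' @param covariates Numeric matrix/data.frame, one column per covariate.
#' @param times,events As in [km_estimate()]; at least one event required.
#' @return data.frame (one row per covariate): term, loghr, hr, se, z, p,
#'   lower, upper; attributes `loglik`, `ties` ("efron"), `converged`.
#' @export
cox_fit <- function(covariates, times, events) {
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (sum(events) < 1) stop("no events")
  const <- apply(x, 2, function(v) length(unique(v)) == 1L)
  if (any(const))
    stop("constant covariate(s): ",
         paste(colnames(x)[const], collapse = ", "))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ x, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|Loglik", conditionMessage(w))) {
        converged <<- FALSE
        warning("Cox fit did not converge cleanly: ", conditionMessage(w),
                call. = FALSE)
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)$coefficients
  out <- data.frame(term = colnames(x), loghr = sm[, "coef"],
                    hr = sm[, "exp(coef)"], se = sm[, "se(coef)"],
                    z = sm[, "z"], p = sm[, "Pr(>|z|)"],
                    lower = exp(sm[, "coef"] - 1.96 * sm[, "se(coef)"]),
                    upper = exp(sm[, "coef"] + 1.96 * sm[, "se(coef)"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "loglik") <- fit$loglik[2]
  attr(out, "ties") <- "efron"
  attr(out, "converged") <- converged
  out
}

#' Median dichotomization of expression
#'
#' Splits samples at the median: `low` = values at or below the median,
#' `high` = values above it. Constant vectors cannot be split.
#'
#' @param x Numeric vector, n >= 2, not all equal.
#' @return Factor with levels low, high, aligned to `x`.
#' @export
median_dichotomize <- function(x) {
  if (length(x) < 2) stop("need at least 2 values")
  if (length(unique(x)) == 1L) stop("all values identical; cannot split")
  factor(ifelse(x <= median(x), "low", "high"), levels = c("low", "high"))
}

#' Mutation-by-expression four-subgroup survival stratification
#'
#' Splits samples into \{mut, wt\} x \{high, low\} by mutation status and
#' the median expression split, then reports the overall four-group
#' log-rank test, the two within-stratum two-group tests (expression
#' effect within wild-type and within mutant carriers), and a
#' pooled-variance t-test comparing expression between mutant and
#' wild-type samples. Tests whose subgroups are empty are skipped with a
#' warning.
#'
#' @param mut_status Binary (0/1 or logical) mutation status per sample.
#' @param expression Numeric expression per sample.
#' @param times,events Survival endpoint per sample.
#' @return List: groups (factor mut/wt x high/low), sizes, overall,
#'   wt_logrank, mut_logrank, expr_ttest (each NULL when skipped).
#' @export
mutation_expression_strata <- function(mut_status, expression, times,
                                       events) {
  mut <- as.logical(mut_status)
  n <- length(mut)
  stopifnot(length(expression) == n, length(times) == n,
            length(events) == n)
  split <- median_dichotomize(expression)
  groups <- factor(paste(ifelse(mut, "mut", "wt"), split, sep = "/"),
                   levels = c("mut/high", "mut/low", "wt/high", "wt/low"))
  sizes <- table(groups)
  out <- list(groups = groups, sizes = sizes, overall = NULL,
              wt_logrank = NULL, mut_logrank = NULL, expr_ttest = NULL)
  if (all(sizes > 0)) {
    out$overall <- logrank(times, events, groups)
  } else warning("empty subgroup(s): ",
                 paste(names(sizes)[sizes == 0], collapse = ", "),
                 "; overall test skipped")
  for (stratum in c("wt", "mut")) {
    idx <- if (stratum == "wt") !mut else mut
    if (length(unique(split[idx])) == 2L) {
      out[[paste0(stratum, "_logrank")]] <-
        logrank(times[idx], events[idx], split[idx])
    } else warning("stratum ", stratum,
                   " lacks both expression subgroups; test skipped")
  }
  if (any(mut) && any(!mut) && sum(mut) >= 2 && sum(!mut) >= 2) {
    tt <- t.test(expression[mut], expression[!mut], var.equal = TRUE)
    out$expr_ttest <- list(statistic = unname(tt$statistic),
                           p = tt$p.value,
                           mean_mut = mean(expression[mut]),
                           mean_wt = mean(expression[!mut]))
  } else warning("mutant/wild-type expression comparison skipped")
  out
}
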
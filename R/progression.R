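## Progression analyses: metastasis-group differential expression and
## stage-wise trend testing (one-way ANOVA with Tukey-Kramer post-hoc
## pairwise comparisons plus a pooled early-vs-late contrast).

#' Partition tumor samples by metastasis status
#'
#' Metastatic = lymph-node metastasis or distant metastasis (N+ or M+);
#' non-metastatic = neither (N0 and M0); samples with NX/MX or missing
#' status are excluded. The three sets partition the tumor samples.
#'
#' @param sheet Sample-sheet data.frame with `n_status`/`m_status`
#'   columns (see [read_sample_sheet()]).
#' @return List of sample-id vectors: metastatic, non_metastatic,
#'   excluded.
#' @export
split_metastasis <- function(sheet) {
  if (!any(c("n_status", "m_status") %in% names(sheet)))
    stop("sheet has neither n_status nor m_status")
  tum <- sheet[sheet$group == "tumor", , drop = FALSE]
  n <- if ("n_status" %in% names(tum)) tum$n_status else rep(NA, nrow(tum))
  m <- if ("m_status" %in% names(tum)) tum$m_status else rep(NA, nrow(tum))
  met <- (!is.na(n) & n == "N+") | (!is.na(m) & m == "M+")
  non <- !met & !is.na(n) & n == "N0" & !is.na(m) & m == "M0"
  list(metastatic = tum$sample_id[met],
       non_metastatic = tum$sample_id[non],
       excluded = tum$sample_id[!met & !non])
}

#' Metastatic vs non-metastatic differential expression
#'
#' Pooled-variance t-test per gene between the metastatic and
#' non-metastatic tumor samples on log expression, BH-adjusted, with a
#' +/-1/0 call column at FDR < alpha. Comparisons with a group below the
#' minimum size are skipped with a warning (returning NULL), mirroring the
#' exclusion of cohorts with too few metastatic samples.
#'
#' @param logexpr Log-scale gene x sample matrix covering tumor samples.
#' @param groups Output of [split_metastasis()].
#' @param min_group Minimum samples per group (default 10).
#' @param alpha FDR threshold for the call column (default 0.05).
#' @return DE data.frame (gene, statistic, p, fdr, direction, call) or
#'   NULL when skipped.
#' @export
metastasis_de <- function(logexpr, groups, min_group = 10, alpha = 0.05) {
  met <- intersect(groups$metastatic, colnames(logexpr))
  non <- intersect(groups$non_metastatic, colnames(logexpr))
  if (length(met) < min_group || length(non) < min_group) {
    warning(sprintf(
      "metastasis comparison skipped: group sizes %d/%d below minimum %d",
      length(met), length(non), min_group))
    return(NULL)
  }
  mat <- logexpr[, c(met, non), drop = FALSE]
  lab <- factor(rep(c("metastatic", "non_metastatic"),
                    c(length(met), length(non))),
                levels = c("metastatic", "non_metastatic"))
  de <- array_ttest_de(mat, lab)
  de$call <- ifelse(!is.na(de$fdr) & de$fdr < alpha, de$direction, 0)
  de
}

#' Stage-wise expression comparison (ANOVA + Tukey, early vs late)
#'
#' One-way fixed-effects ANOVA of expression across tumor stages,
#' Tukey-Kramer adjusted pairwise comparisons (studentized range, unequal
#' n), and a pooled early (I-II) versus late (III-IV) two-sample Student's
#' t-test. Stages with fewer than 2 samples are dropped with a warning.
#'
#' @param values Numeric expression vector (one gene) over tumor samples.
#' @param stages Stage labels (I, II, III, IV) aligned to `values`.
#' @return List: `anova` (F, df1, df2, p), `tukey` (data.frame pair,
#'   diff, p_adj), `early_late` (t, df, p; NULL when a side is missing),
#'   `n` (per-stage sizes).
#' @export
stage_anova_tukey <- function(values, stages) {
  stage <- factor(as.character(stages), levels = c("I", "II", "III", "IV"))
  keep <- !is.na(values) & !is.na(stage)
  values <- values[keep]; stage <- droplevels(stage[keep])
  sizes <- table(stage)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("stage(s) with < 2 samples dropped: ",
            paste(small, collapse = ", "))
    keep <- !(as.character(stage) %in% small)
    values <- values[keep]; stage <- droplevels(stage[keep])
    sizes <- table(stage)
  }
  if (nlevels(stage) < 2) stop("need >= 2 stages with >= 2 samples")
  fit <- aov(values ~ stage)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$stage
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE,
                      row.names = NULL)
  early <- values[stage %in% c("I", "II")]
  late <- values[stage %in% c("III", "IV")]
  early_late <- if (length(early) >= 2 && length(late) >= 2) {
    tt <- t.test(late, early, var.equal = TRUE)
    list(statistic = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value)
  } else NULL
  list(anova = list(F = an[1, "F value"], df1 = an[1, "Df"],
                    df2 = an[2, "Df"], p = an[1, "Pr(>F)"]),
       tukey = tukey, early_late = early_late, n = sizes)
}
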
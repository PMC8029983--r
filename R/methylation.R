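## CpG-site filtering/imputation and the all-sites-consistent gene-level
## differential-methylation call: a gene is hyper/hypo-methylated only when
## every one of its CpG sites is significantly shifted in the same
## direction; genes with significant sites in both directions are excluded
## from downstream analysis.

#' Filter and impute a CpG beta-value matrix
#'
#' Drops CpG sites that are missing in at least half of the samples
#' (all-missing sites trigger a warning) and replaces each remaining
#' missing entry with the site's minimum observed beta value. After
#' imputation no missing values remain and all betas stay in \[0, 1\].
#'
#' @param beta CpG x sample matrix of beta values in \[0, 1\] with NAs
#'   marking missing entries.
#' @param map Optional CpG-to-gene map (data.frame cpg, gene), filtered to
#'   the retained sites.
#' @return List with `beta` (imputed matrix), `map` (filtered, or NULL)
#'   and `dropped` (removed CpG ids).
#' @export
filter_impute_cpgs <- function(beta, map = NULL) {
  if (is.null(rownames(beta))) stop("beta matrix needs CpG rownames")
  na_frac <- rowMeans(is.na(beta))
  if (any(na_frac == 1))
    warning("site(s) missing in all samples dropped: ",
            paste(rownames(beta)[na_frac == 1], collapse = ", "))
  keep <- na_frac < 0.5
  dropped <- rownames(beta)[!keep]
  beta <- beta[keep, , drop = FALSE]
  has_na <- which(rowSums(is.na(beta)) > 0)
  for (i in has_na) {
    row <- beta[i, ]
    beta[i, is.na(row)] <- min(row, na.rm = TRUE)
  }
  if (!is.null(map)) map <- map[map$cpg %in% rownames(beta), , drop = FALSE]
  list(beta = beta, map = map, dropped = dropped)
}

#' Per-site Wilcoxon rank-sum differential methylation
#'
#' Two-sided Wilcoxon rank-sum test per CpG site between tumor and normal
#' samples (exact for small tie-free samples, normal approximation with
#' tie correction otherwise), BH adjustment across sites, and direction
#' from the sign of (tumor median - normal median). Sites constant across
#' all samples get p = 1 and no direction.
#'
#' @param beta Imputed CpG x sample beta matrix (no NAs).
#' @param groups Two-level factor/character aligned to columns.
#' @return data.frame: cpg, p, fdr, direction (+1 hyper / -1 hypo / 0).
#' @export
cpg_wilcoxon <- function(beta, groups) {
  if (anyNA(beta)) stop("beta matrix must be imputed first")
  g <- .two_level_groups(groups, ncol(beta))
  i1 <- g == levels(g)[1]; i2 <- g == levels(g)[2]
  res <- t(vapply(seq_len(nrow(beta)), function(i) {
    x <- beta[i, i1]; y <- beta[i, i2]
    if (length(unique(c(x, y))) == 1L) return(c(1, 0))
    p <- suppressWarnings(wilcox.test(x, y)$p.value)
    c(p, sign(median(x) - median(y)))
  }, numeric(2)))
  data.frame(cpg = rownames(beta), p = res[, 1],
             fdr = bh_adjust(res[, 1]), direction = res[, 2],
             stringsAsFactors = FALSE)
}

#' Gene-level methylation consistency call
#'
#' Applies the all-sites rule: a gene is called hypermethylated (+1) when
#' every mapped CpG site is significant and shifted up, hypomethylated
#' (-1) when every site is significant and shifted down, `excluded` when
#' significant sites disagree in direction, and `none` otherwise. With
#' `require_all = FALSE` the call is made from significant sites only
#' (at least one required), relaxing the literal rule.
#'
#' @param site_calls Output of [cpg_wilcoxon()].
#' @param map CpG-to-gene map (data.frame cpg, gene); every site must map
#'   to exactly one gene.
#' @param alpha FDR threshold for site significance (default 0.05).
#' @param require_all Require every site significant for a directional
#'   call (default TRUE, the literal rule).
#' @return data.frame: gene, call in \{hyper, hypo, excluded, none\}, and
#'   the numeric encoding `code` (+1, -1, NA, 0).
#' @export
gene_methylation_status <- function(site_calls, map, alpha = 0.05,
                                    require_all = TRUE) {
  unmapped <- setdiff(site_calls$cpg, map$cpg)
  if (length(unmapped))
    stop("unmapped CpG site(s): ", paste(head(unmapped, 5), collapse = ", "))
  if (anyDuplicated(map$cpg))
    stop("CpG site(s) mapped to multiple genes")
  m <- merge(site_calls, map, by = "cpg")
  calls <- vapply(split(m, m$gene), function(d) {
    sig <- d$fdr < alpha & d$direction != 0
    if (any(sig & d$direction > 0) && any(sig & d$direction < 0))
      return("excluded")
    if (!any(sig)) return("none")
    if (require_all && !all(sig)) return("none")
    if (all(d$direction[sig] > 0)) "hyper" else "hypo"
  }, character(1))
  data.frame(gene = names(calls), call = unname(calls),
             code = unname(c(hyper = 1, hypo = -1, excluded = NA,
                             none = 0)[calls]),
             stringsAsFactors = FALSE, row.names = NULL)
}
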
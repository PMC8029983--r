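## Two-platform differential expression and the integrated status score S.
## The array route is a pooled-variance (classic Student) t-test per gene;
## the count route is a conditional negative-binomial exact test with a
## method-of-moments common dispersion on library-equalized counts. Each
## platform's call is mapped to a signed status (+/-1 significant,
## +/-0.5 not) and the two statuses are combined by a sign-gated sum:
## S = s_array + s_seq when the platforms agree in direction, 0 otherwise,
## so S lives in {-2, -1.5, -1, 0, 1, 1.5, 2}.

STATUS_ALPHABET <- c(-1, -0.5, 0.5, 1)

.two_level_groups <- function(groups, n) {
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  if (length(g) != n) stop("one group label per sample is required")
  if (all(c("tumor", "normal") %in% levels(g)))
    g <- factor(g, levels = c("tumor", "normal"))
  if (min(table(g)) < 2L) stop("each group needs at least 2 samples")
  g
}

#' Per-gene pooled-variance t-test on log expression
#'
#' Classic (equal-variance) Student's t per gene between the two groups;
#' the statistic is first-level minus second-level means (tumor minus
#' normal when those labels are used), two-sided p, and BH adjustment
#' across all genes in the matrix. Genes with zero variance in both groups
#' and equal means get an undefined direction and are excluded from
#' adjustment.
#'
#' @param logexpr Log-scale gene x sample matrix of finite values.
#' @param groups Two-level factor/character aligned to columns.
#' @return data.frame with columns gene, statistic (t), p, fdr,
#'   direction (+1/-1, NA when undefined).
#' @export
array_ttest_de <- function(logexpr, groups) {
  g <- .two_level_groups(groups, ncol(logexpr))
  i1 <- g == levels(g)[1]; i2 <- g == levels(g)[2]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(logexpr[, i1, drop = FALSE])
  m2 <- rowMeans(logexpr[, i2, drop = FALSE])
  v1 <- apply(logexpr[, i1, drop = FALSE], 1, var)
  v2 <- apply(logexpr[, i2, drop = FALSE], 1, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  df <- n1 + n2 - 2
  p <- 2 * pt(-abs(tt), df)
  degenerate <- se == 0 & m1 == m2
  tt[degenerate] <- NA_real_
  p[degenerate] <- NA_real_
  p[se == 0 & m1 != m2] <- 0
  tt[se == 0 & m1 != m2] <- sign(m1 - m2)[se == 0 & m1 != m2] * Inf
  res <- data.frame(gene = rownames(logexpr), statistic = tt, p = p,
                    fdr = bh_adjust(p), direction = sign(tt),
                    stringsAsFactors = FALSE)
  res$direction[!is.na(res$direction) & res$direction == 0] <- NA
  rownames(res) <- NULL
  res
}

## Method-of-moments common dispersion on library-equalized counts:
## for each gene and group, phi contribution = (var - mean) / mean^2;
## the common value is the across-cell mean, floored at 0.
.common_dispersion <- function(pseudo, g) {
  contrib <- c()
  for (lev in levels(g)) {
    m <- rowMeans(pseudo[, g == lev, drop = FALSE])
    v <- apply(pseudo[, g == lev, drop = FALSE], 1, var)
    ok <- m > 0
    contrib <- c(contrib, ((v - m) / m^2)[ok])
  }
  max(0, mean(contrib, na.rm = TRUE))
}

## Two-sided conditional exact NB p-value for a split (ya, y - ya) of the
## gene total y between nA and nB samples sharing dispersion phi. The
## conditional pmf is proportional to the product of two NB pmfs with a
## common probability parameter (which cancels), and is log-concave, so
## evaluation is restricted to the region within ~60 log units of the
## mode; the two-sided p sums all outcomes no more probable than the
## observed one.
.nb_exact_p <- function(ya, y, nA, nB, phi) {
  if (y == 0) return(NA_real_)
  lpmf <- function(a) {
    if (phi <= 1e-12) dbinom(a, y, nA / (nA + nB), log = TRUE)
    else dnbinom(a, size = nA / phi, prob = 0.5, log = TRUE) +
      dnbinom(y - a, size = nB / phi, prob = 0.5, log = TRUE)
  }
  mode_a <- round(y * nA / (nA + nB))
  lmode <- lpmf(mode_a)
  widen <- function(a, step_dir) {
    a_cur <- mode_a; step <- 16L
    repeat {
      a_next <- a_cur + step_dir * step
      a_next <- max(0L, min(y, a_next))
      if (a_next == a_cur || lpmf(a_next) < lmode - 60) {
        if (a_next != a_cur) a_cur <- a_next
        break
      }
      a_cur <- a_next
      step <- step * 2L
    }
    a_cur
  }
  lo <- min(widen(mode_a, -1L), ya)
  hi <- max(widen(mode_a, +1L), ya)
  a <- lo:hi
  lg <- lpmf(a)
  lz <- max(lg) + log(sum(exp(lg - max(lg))))
  lobs <- lpmf(ya)
  min(1, sum(exp(lg[lg <= lobs + 1e-10] - lz)))
}

#' Conditional negative-binomial exact test for count data
#'
#' Library sizes are equalized by scaling every sample's counts to the
#' geometric mean of the effective (TMM-scaled) library sizes and
#' rounding; a common Gamma-Poisson dispersion (variance mu + phi mu^2) is
#' estimated by the method of moments across genes; each gene's tumor
#' total is then tested against its grand total with a two-sided
#' conditional exact NB test (the dispersion-zero limit is the exact
#' binomial split test). Fold changes are log2 ratios of normalized group
#' means with a pseudocount. BH adjustment runs across all testable genes;
#' all-zero genes are reported with NA p.
#'
#' @param counts Non-negative integer gene x sample matrix.
#' @param factors [tmm_factors()] for the samples, or `NULL` for raw
#'   library sizes.
#' @param groups Two-level factor/character aligned to columns.
#' @param dispersion Optional fixed dispersion phi, overriding the
#'   method-of-moments estimate.
#' @param prior Pseudocount for the log2 fold change (default 0.5).
#' @return data.frame with columns gene, statistic (log2 fold change,
#'   first level vs second), p, fdr, direction, plus a `dispersion`
#'   attribute.
#' @export
count_nb_de <- function(counts, factors = NULL, groups,
                        dispersion = NULL, prior = 0.5) {
  g <- .two_level_groups(groups, ncol(counts))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  eff <- if (is.null(factors)) colSums(counts)
  else factors$eff_lib_size[colnames(counts)]
  lstar <- exp(mean(log(eff)))
  pseudo <- round(sweep(counts, 2, lstar / eff, "*"))
  phi <- if (is.null(dispersion)) .common_dispersion(pseudo, g)
  else dispersion
  i1 <- g == levels(g)[1]; i2 <- g == levels(g)[2]
  n1 <- sum(i1); n2 <- sum(i2)
  y1 <- rowSums(pseudo[, i1, drop = FALSE])
  y2 <- rowSums(pseudo[, i2, drop = FALSE])
  lfc <- log2((y1 / n1 + prior) / (y2 / n2 + prior))
  p <- vapply(seq_len(nrow(counts)), function(i)
    .nb_exact_p(y1[i], y1[i] + y2[i], n1, n2, phi), numeric(1))
  res <- data.frame(gene = rownames(counts), statistic = lfc, p = p,
                    fdr = bh_adjust(p), direction = sign(lfc),
                    stringsAsFactors = FALSE)
  res$direction[!is.na(res$direction) & res$direction == 0] <- NA
  attr(res, "dispersion") <- phi
  attr(res, "skipped") <- res$gene[is.na(p)]
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the inputs and applies the BH step-up procedure (monotone in
#' rank, capped at 1). NAs are carried through.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Per-platform signed differential-expression status
#'
#' Maps each gene's FDR and direction to a platform status: +/-1 for a
#' significant call (FDR < alpha) in that direction, +/-0.5 for a
#' non-significant trend. Genes whose direction is undefined (statistic
#' exactly zero or untestable) get NA and are excluded from integration.
#'
#' @param de A DE result data.frame with `fdr` and `direction` columns, or
#'   a numeric FDR vector paired with `direction`.
#' @param direction Direction vector when `de` is a bare FDR vector.
#' @param alpha Significance threshold on FDR (default 0.05).
#' @return Numeric vector of statuses in \{-1, -0.5, 0.5, 1\} (NA where
#'   undefined).
#' @export
assign_platform_status <- function(de, direction = NULL, alpha = 0.05) {
  if (is.data.frame(de)) {
    fdr <- de$fdr; direction <- de$direction
  } else fdr <- de
  if (length(fdr) != length(direction))
    stop("fdr and direction lengths differ")
  s <- ifelse(fdr < alpha, 1, 0.5) * direction
  s[is.na(direction) | direction == 0] <- NA
  s
}

#' Integrated cross-platform status S
#'
#' Sign-gated sum of the two platform statuses: when the microarray and
#' RNA-seq directions agree, S = s_array + s_seq; when they disagree,
#' S = 0. A significantly overexpressed gene on one platform with a
#' non-significant same-direction trend on the other therefore scores 1.5;
#' a direction conflict scores 0 regardless of significance.
#'
#' @param s_array,s_seq Platform statuses in \{-1, -0.5, 0.5, 1\}
#'   (vectorized; NA propagates).
#' @return S in \{-2, -1.5, -1, 0, 1, 1.5, 2\}.
#' @examples
#' integrate_status(0.5, 1)   # 1.5
#' integrate_status(-0.5, 1)  # 0
#' @export
integrate_status <- function(s_array, s_seq) {
  chk <- function(s, nm) {
    if (any(!is.na(s) & !s %in% STATUS_ALPHABET))
      stop(nm, " outside the status alphabet {-1, -0.5, 0.5, 1}")
  }
  chk(s_array, "s_array"); chk(s_seq, "s_seq")
  ifelse(is.na(s_array) | is.na(s_seq), NA_real_,
         ifelse(sign(s_array) == sign(s_seq), s_array + s_seq, 0))
}

#' Two-platform status table
#'
#' Joins array and RNA-seq DE results by gene, assigns platform statuses
#' at the given FDR threshold and integrates them into S.
#'
#' @param array_de DE result from [array_ttest_de()].
#' @param seq_de DE result from [count_nb_de()].
#' @param alpha FDR threshold (default 0.05).
#' @param genes Optional subset of genes to report (e.g. the melatonergic
#'   panel); defaults to the genes shared by both results.
#' @return data.frame: gene, s_array, s_seq, S.
#' @export
status_table <- function(array_de, seq_de, alpha = 0.05, genes = NULL) {
  shared <- intersect(array_de$gene, seq_de$gene)
  if (is.null(genes)) genes <- shared
  missing <- setdiff(genes, shared)
  if (length(missing))
    stop("gene(s) absent from a platform: ", paste(missing, collapse = ", "))
  a <- array_de[match(genes, array_de$gene), ]
  s <- seq_de[match(genes, seq_de$gene), ]
  s_array <- assign_platform_status(a, alpha = alpha)
  s_seq <- assign_platform_status(s, alpha = alpha)
  data.frame(gene = genes, s_array = s_array, s_seq = s_seq,
             S = integrate_status(s_array, s_seq),
             stringsAsFactors = FALSE)
}
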
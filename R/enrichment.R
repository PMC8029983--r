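## Anchor-gene correlation screening, hypergeometric pathway enrichment
## with cross-dataset intersection, and the miRNA target-consensus and
## differential-expression analyses.

#' Pearson correlation screen against an anchor gene
#'
#' Correlates every other gene with the anchor across samples; p-values
#' come from the t-transform t = r * sqrt((n - 2) / (1 - r^2)),
#' two-sided. Genes with correlation p below `alpha` (raw, unadjusted)
#' form the positive (r > 0) and negative (r < 0) correlate sets.
#' Zero-variance genes are excluded and reported.
#'
#' @param anchor Gene symbol present in `logexpr`.
#' @param logexpr Log-scale gene x sample matrix, n >= 3 samples.
#' @param alpha Raw-p selection threshold (default 0.05).
#' @return List: `result` (data.frame gene, r, p), `positive`,
#'   `negative` (gene vectors), `excluded` (zero-variance genes).
#' @export
pearson_screen <- function(anchor, logexpr, alpha = 0.05) {
  if (!anchor %in% rownames(logexpr)) stop("anchor not in matrix: ", anchor)
  n <- ncol(logexpr)
  if (n < 3) stop("need >= 3 samples")
  x <- logexpr[anchor, ]
  others <- setdiff(rownames(logexpr), anchor)
  sds <- apply(logexpr[others, , drop = FALSE], 1, sd)
  excluded <- others[sds == 0]
  others <- others[sds > 0]
  r <- as.numeric(cor(x, t(logexpr[others, , drop = FALSE])))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  p[abs(r) >= 1] <- 0
  res <- data.frame(gene = others, r = r, p = p, stringsAsFactors = FALSE)
  list(result = res,
       positive = res$gene[res$r > 0 & res$p < alpha],
       negative = res$gene[res$r < 0 & res$p < alpha],
       excluded = excluded)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail overlap test per set: with universe size N, set size K
#' (after intersecting each set with the universe), query size n and
#' overlap k, p = P(X >= k) for X ~ Hypergeometric(N, K, n); BH across
#' sets.
#'
#' @param query Gene vector (intersected with the universe; must overlap
#'   it).
#' @param sets Named list of gene vectors ([read_gmt()]).
#' @param universe Background gene vector.
#' @return data.frame: pathway, k, K, n, N, p, fdr.
#' @export
hypergeom_enrich <- function(query, sets, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stop("empty universe")
  query <- intersect(unique(query), universe)
  n <- length(query)
  if (n == 0) stop("query has no genes in the universe")
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(sets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Pathways significant in every dataset
#'
#' Intersects per-dataset significant pathway name vectors (typically the
#' FDR < 0.05 rows of [hypergeom_enrich()] results), run separately for
#' positive and negative correlate sets.
#'
#' @param pathway_lists List (>= 2) of character vectors.
#' @return Character vector of pathways present in every list.
#' @export
common_pathways <- function(pathway_lists) {
  if (length(pathway_lists) < 2) stop("need >= 2 datasets")
  Reduce(intersect, pathway_lists)
}

#' Consensus of miRNA target-prediction lists
#'
#' Keeps miRNAs supported by at least `min_support` of the named
#' prediction lists (duplicates within a list count once).
#'
#' @param lists Named list of miRNA character vectors.
#' @param min_support Minimum number of supporting lists (default 2).
#' @return List: `consensus` (miRNA vector), `membership` (data.frame
#'   mirna, one logical column per list, n_lists).
#' @export
mirna_consensus <- function(lists, min_support = 2) {
  if (min_support > length(lists))
    stop("min_support exceeds the number of lists")
  lists <- lapply(lists, unique)
  all_m <- sort(unique(unlist(lists)))
  mem <- vapply(lists, function(l) all_m %in% l,
                logical(length(all_m)))
  mem <- matrix(mem, nrow = length(all_m),
                dimnames = list(NULL, names(lists)))
  n_lists <- rowSums(mem)
  membership <- data.frame(mirna = all_m, mem, n_lists = n_lists,
                           stringsAsFactors = FALSE)
  list(consensus = all_m[n_lists >= min_support], membership = membership)
}

#' Differential expression of consensus miRNAs
#'
#' TMM-normalizes the miRNA count matrix, restricts to the given miRNAs,
#' runs the pooled-variance t-test on log2-CPM between tumor and normal
#' samples, and reports the over/under split among FDR-significant
#' miRNAs.
#'
#' @param counts miRNA x sample count matrix.
#' @param groups Two-level factor/character aligned to columns.
#' @param mirnas miRNAs to test (default all rows).
#' @param alpha FDR threshold (default 0.05).
#' @return List: `de` (DE data.frame), `over`, `under` (miRNA vectors
#'   significant up/down in the first group).
#' @export
mirna_de <- function(counts, groups, mirnas = rownames(counts),
                     alpha = 0.05) {
  mirnas <- intersect(mirnas, rownames(counts))
  if (!length(mirnas)) stop("no requested miRNAs in the matrix")
  nf <- tmm_factors(counts)
  lc <- log_cpm(counts, nf)[mirnas, , drop = FALSE]
  de <- array_ttest_de(lc, groups)
  sig <- !is.na(de$fdr) & de$fdr < alpha
  list(de = de,
       over = de$gene[sig & de$direction > 0],
       under = de$gene[sig & de$direction < 0])
}
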
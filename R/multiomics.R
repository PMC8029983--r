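## Mutation and copy-number frequency summaries, and the annotation that a
## genomic or epigenetic alteration is consistent in direction with the
## gene's integrated expression status S.

#' Mutation and copy-number alteration frequencies
#'
#' Per-gene percentages over a defined sample universe: mutation frequency
#' counts each sample once if it carries at least one (non-synonymous)
#' mutation of the gene; amplification frequency is the percentage of
#' positive discrete CNV calls (reported with sign +), deletion frequency
#' the percentage of negative calls (reported with sign -).
#'
#' @param mutations Mutation table (data.frame gene, sample, ...), already
#'   filtered to the classes of interest.
#' @param cnv Gene x sample discrete call matrix in \{-2..2\}, or NULL.
#' @param samples Character vector: the profiled sample universe.
#' @param genes Genes to summarise; defaults to the union of genes seen in
#'   the two layers.
#' @return data.frame gene, mut_freq, amp_freq, del_freq (percent), with
#'   attributes `mean_mut_freq` (across genes) and `n_samples`.
#' @examples
#' mt <- data.frame(gene = "CALM1", sample = c("s1", "s2"),
#'                  classification = "Missense_Mutation")
#' alteration_frequencies(mt, cnv = NULL, samples = paste0("s", 1:40))
#' @export
alteration_frequencies <- function(mutations, cnv = NULL, samples,
                                   genes = NULL) {
  n <- length(unique(samples))
  if (n == 0) stop("empty sample universe")
  if (is.null(genes))
    genes <- sort(unique(c(mutations$gene, rownames(cnv))))
  mut_freq <- vapply(genes, function(g) {
    hit <- unique(mutations$sample[mutations$gene == g])
    100 * length(intersect(hit, samples)) / n
  }, numeric(1))
  if (!is.null(cnv)) {
    cs <- intersect(colnames(cnv), samples)
    amp <- del <- setNames(rep(NA_real_, length(genes)), genes)
    gg <- intersect(genes, rownames(cnv))
    amp[gg] <- 100 * rowMeans(cnv[gg, cs, drop = FALSE] > 0)
    del[gg] <- -100 * rowMeans(cnv[gg, cs, drop = FALSE] < 0)
  } else amp <- del <- setNames(rep(NA_real_, length(genes)), genes)
  out <- data.frame(gene = genes, mut_freq = unname(mut_freq),
                    amp_freq = unname(amp), del_freq = unname(del),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "mean_mut_freq") <- mean(out$mut_freq)
  attr(out, "n_samples") <- n
  out
}

#' Consistency of genomic/epigenetic alterations with expression status
#'
#' CNV layer: a gene's dominant copy-number direction is amplification or
#' deletion, whichever has the higher frequency (ties give no dominant
#' direction and no flag); the alteration is consistent when that
#' direction matches the sign of S, its frequency reaches `min_cnv_freq`
#' percent, and S is nonzero. Methylation layer: hypermethylation (+1) is
#' consistent with underexpression (S < 0), hypomethylation (-1) with
#' overexpression (S > 0). Flags are emitted only where both an
#' expression status and an alteration direction exist.
#'
#' @param status Status table (data.frame gene, S), e.g. [status_table()].
#' @param summary Output of [alteration_frequencies()].
#' @param gene_meth Optional gene-level methylation calls
#'   ([gene_methylation_status()]).
#' @param min_cnv_freq Minimum dominant CNV frequency (percent) for a CNV
#'   flag (default 10).
#' @return data.frame gene, layer ("cnv"/"methylation"), direction,
#'   frequency (CNV only), consistent (logical).
#' @export
consistency_annotation <- function(status, summary, gene_meth = NULL,
                                   min_cnv_freq = 10) {
  rows <- list()
  s_of <- setNames(status$S, status$gene)
  for (i in seq_len(nrow(summary))) {
    g <- summary$gene[i]
    S <- s_of[g]
    if (is.na(S) || S == 0) next
    ampf <- summary$amp_freq[i]; delf <- abs(summary$del_freq[i])
    if (!is.na(ampf) && !is.na(delf) && ampf != delf) {
      dom <- if (ampf > delf) 1 else -1
      domf <- max(ampf, delf)
      if (domf >= min_cnv_freq)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, layer = "cnv",
          direction = if (dom > 0) "amplification" else "deletion",
          frequency = domf * dom, consistent = sign(dom) == sign(S),
          stringsAsFactors = FALSE)
    }
  }
  if (!is.null(gene_meth)) {
    for (i in seq_len(nrow(gene_meth))) {
      g <- gene_meth$gene[i]
      code <- gene_meth$code[i]
      S <- s_of[g]
      if (is.na(S) || S == 0 || is.na(code) || code == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, layer = "methylation",
        direction = if (code > 0) "hyper" else "hypo",
        frequency = NA_real_,
        consistent = (code > 0 && S < 0) || (code < 0 && S > 0),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(), layer = character(),
                      direction = character(), frequency = numeric(),
                      consistent = logical(), stringsAsFactors = FALSE))
  do.call(rbind, c(rows, make.row.names = FALSE))
}
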
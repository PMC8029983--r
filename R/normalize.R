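## Between-sample normalization for count matrices and per-batch location
## adjustment for log expression. TMM factors are delegated to
## edgeR::calcNormFactors (trimmed mean of M-values; 30% trim on M, 5% on
## A, reference = sample whose 75th count percentile is closest to the
## mean), wrapped so the rest of the pipeline carries explicit effective
## library sizes.

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes per-sample TMM scaling factors against a reference sample.
#' Genes with a zero count in either the sample or the reference are
#' excluded from the trimmed mean; factors are rescaled so their geometric
#' mean is 1. The reference defaults to the sample whose 75th percentile of
#' scaled counts is closest to the across-sample mean.
#'
#' @param counts Non-negative integer gene x sample matrix, >= 2 samples.
#' @param ref Reference sample name, or `NULL` for automatic choice.
#' @return An object of class `norm_factors`: list with `factors` (named,
#'   geometric mean 1), `ref`, `lib_size` and `eff_lib_size`
#'   (`lib_size * factors`).
#' @examples
#' m <- matrix(rpois(40, 50), 10, 4,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' tmm_factors(m)$factors
#' @export
tmm_factors <- function(counts, ref = NULL) {
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("all-zero sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  f75 <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
  ref_name <- if (is.null(ref)) colnames(counts)[which.min(abs(f75 - mean(f75)))]
  else {
    if (!ref %in% colnames(counts)) stop("unknown reference sample: ", ref)
    ref
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              refColumn = match(ref_name, colnames(counts)))
  f <- f / exp(mean(log(f)))
  structure(list(factors = setNames(as.numeric(f), colnames(counts)),
                 ref = ref_name, lib_size = lib,
                 eff_lib_size = lib * as.numeric(f)),
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat("TMM normalization factors (reference:", x$ref, ")\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' Log2 counts-per-million
#'
#' `log2((count + prior) / (effective library size + 2 * prior) * 1e6)`,
#' using TMM effective library sizes when factors are supplied.
#'
#' @param counts Non-negative count matrix.
#' @param factors A [tmm_factors()] object aligned to the samples, or
#'   `NULL` to use raw library sizes.
#' @param prior Pseudocount (default 0.5) keeping zeros finite.
#' @return Matrix of log2-CPM values.
#' @export
log_cpm <- function(counts, factors = NULL, prior = 0.5) {
  lib <- if (is.null(factors)) colSums(counts)
  else {
    if (!identical(sort(names(factors$factors)), sort(colnames(counts))))
      stop("factors and counts cover different sample sets")
    factors$eff_lib_size[colnames(counts)]
  }
  t(log2(t(counts + prior) / (lib + 2 * prior) * 1e6))
}

#' Per-batch location adjustment on log expression
#'
#' Equalizes per-gene batch means while preserving each gene's grand mean:
#' within every batch the batch mean is subtracted and the grand mean
#' added back. Within-batch variances are untouched. Batches with a single
#' sample are passed through with a warning.
#'
#' @param logexpr Log-scale gene x sample matrix.
#' @param batch Batch label per sample (length `ncol(logexpr)`).
#' @return Adjusted matrix of the same shape.
#' @export
batch_adjust <- function(logexpr, batch) {
  if (length(batch) != ncol(logexpr))
    stop("one batch label per sample is required")
  batch <- as.factor(batch)
  if (nlevels(batch) == 1L) return(logexpr)
  sizes <- table(batch)
  single <- names(sizes)[sizes == 1L]
  if (length(single))
    warning("batch(es) with a single sample passed through unadjusted: ",
            paste(single, collapse = ", "))
  grand <- rowMeans(logexpr)
  out <- logexpr
  for (b in setdiff(levels(batch), single)) {
    idx <- which(batch == b)
    bm <- rowMeans(logexpr[, idx, drop = FALSE])
    out[, idx] <- logexpr[, idx] - bm + grand
  }
  out
}
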
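## Readers and writers for the plain-text table formats the pipeline touches.
## All matrices travel as TSV: first column the gene/CpG identifier, header
## row of sample ids. gzip-compressed files are accepted transparently
## (read.delim/gzfile handle the magic bytes).

NONSYN_CLASSES <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Splice_Site", "Translation_Start_Site")

SILENT_CLASSES <- c("Silent", "Synonymous", "synonymous_variant",
                    "3'UTR", "5'UTR", "Intron", "IGR", "RNA", "5'Flank",
                    "3'Flank")

#' Read a gene-by-sample matrix from TSV
#'
#' Reads a tab-separated matrix whose first column holds gene (or CpG, or
#' miRNA) identifiers and whose header row holds sample ids. The `kind`
#' argument switches on validation: `"counts"` must be non-negative
#' integers, `"beta"` must lie in \[0, 1\] (the literal string `NA` marks a
#' missing beta value), `"array"` and `"mirna"` only require numeric cells.
#'
#' @param path Path to a TSV file (optionally gzip-compressed).
#' @param kind One of `"array"`, `"counts"`, `"beta"`, `"mirna"`.
#' @return Numeric matrix with identifier rownames and sample colnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_matrix(matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3),
#'                                                c("s1", "s2"))), tf)
#' read_matrix(tf, kind = "counts")
#' @export
read_matrix <- function(path, kind = c("array", "counts", "beta", "mirna")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = "NA")
  if (ncol(df) < 2L) stop("matrix TSV needs an identifier column plus >=1 sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  non_num <- !vapply(body, is.numeric, logical(1))
  if (any(non_num))
    stop("non-numeric cells in column(s): ",
         paste(names(body)[non_num], collapse = ", "))
  mat <- as.matrix(body)
  rownames(mat) <- ids
  if (kind == "counts") {
    if (anyNA(mat)) stop("counts matrix contains missing values")
    if (any(mat < 0) || any(mat != round(mat)))
      stop("counts must be non-negative integers")
  } else if (kind == "beta") {
    rng <- range(mat, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stop("beta values outside [0, 1]: range ",
           paste(signif(rng, 4), collapse = " .. "))
  } else if (anyNA(mat)) {
    stop(kind, " matrix contains missing values")
  }
  mat
}

#' Write a matrix (or data.frame) as TSV
#'
#' Inverse of [read_matrix()]: identifiers go in a first column named
#' `id`, samples in the header. Round-trips losslessly through
#' [read_matrix()] for full-precision numeric matrices.
#'
#' @param x Matrix with rownames, or a data.frame.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (is.matrix(x)) {
    df <- data.frame(id = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
  } else df <- x
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Plain tab-separated export used for all pipeline result tables.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a minimal mutation table
#'
#' Expects a MAF-minimal three-column TSV with columns `gene`, `sample`
#' and `classification` (a variant-classification string). With
#' `nonsyn_only = TRUE` (the default, matching the study design of keeping
#' only protein-altering events), silent/synonymous/non-coding classes are
#' removed.
#'
#' @param path Path to the TSV.
#' @param nonsyn_only Drop non-protein-altering classes?
#' @return data.frame with columns gene, sample, classification.
#' @export
read_mutations <- function(path, nonsyn_only = TRUE) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene", "sample", "classification")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("mutation table missing required column(s): ",
         paste(miss, collapse = ", "))
  df <- df[, need, drop = FALSE]
  if (nonsyn_only) df <- df[!(df$classification %in% SILENT_CLASSES), ,
                            drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read GISTIC-style thresholded copy-number calls
#'
#' Gene-by-sample TSV of discrete calls in \{-2, -1, 0, 1, 2\}
#' (deep loss .. high amplification).
#'
#' @param path Path to the TSV.
#' @return Integer matrix of discrete calls.
#' @export
read_cnv_calls <- function(path) {
  mat <- suppressWarnings(read_matrix(path, kind = "array"))
  if (!all(mat %in% -2:2))
    stop("CNV calls must be in {-2,-1,0,1,2}")
  storage.mode(mat) <- "integer"
  mat
}

#' Read a GMT gene-set collection
#'
#' Broad-dialect GMT: one set per line, tab-separated fields
#' `name  description  gene1 gene2 ...`. Gene symbols are de-duplicated
#' within each set.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (one per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(which(short), collapse = ", "))
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene-set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  empty <- lengths(sets) == 0L
  if (any(empty)) stop("empty gene set(s): ", paste(nms[empty], collapse = ", "))
  names(sets) <- nms
  sets
}

#' Read a clinical sample sheet
#'
#' TSV with one row per sample. Required columns: `sample_id`, `group`
#' (`tumor`/`normal`). Recognised optional columns: `batch`, `stage`
#' (I..IV), `n_status` (N0/N+/NX), `m_status` (M0/M+/MX), per-endpoint
#' `<endpoint>_time`/`<endpoint>_event` pairs (e.g. `os_time`, `os_event`),
#' `afp`, `tumor_size`, `tnm`, and `mut_<GENE>` binary mutation-status
#' columns.
#'
#' @param path Path to the TSV.
#' @return data.frame, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate a clinical sample sheet
#'
#' Checks the closed vocabularies and time/event pairing invariants and
#' returns the sheet unchanged.
#'
#' @param df Sample-sheet data.frame.
#' @return The validated data.frame.
#' @export
validate_sample_sheet <- function(df) {
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id values")
  if (!all(df$group %in% c("tumor", "normal")))
    stop("group must be 'tumor' or 'normal'")
  if ("stage" %in% names(df) &&
      !all(is.na(df$stage) | df$stage %in% c("I", "II", "III", "IV")))
    stop("stage must be one of I, II, III, IV")
  if ("n_status" %in% names(df) &&
      !all(is.na(df$n_status) | df$n_status %in% c("N0", "N+", "NX")))
    stop("n_status must be one of N0, N+, NX")
  if ("m_status" %in% names(df) &&
      !all(is.na(df$m_status) | df$m_status %in% c("M0", "M+", "MX")))
    stop("m_status must be one of M0, M+, MX")
  time_cols <- grep("_time$", names(df), value = TRUE)
  for (tc in time_cols) {
    ec <- sub("_time$", "_event", tc)
    if (!ec %in% names(df))
      stop("time column ", tc, " has no matching ", ec)
    has_t <- !is.na(df[[tc]])
    if (any(df[[tc]][has_t] < 0)) stop(tc, " contains negative times")
    if (!all(df[[ec]][has_t] %in% c(0, 1)))
      stop(ec, " must be 0/1 wherever ", tc, " is present")
    if (any(!is.na(df[[ec]]) & !has_t))
      stop(ec, " present without ", tc)
  }
  df
}
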
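## Seeded synthetic multi-omics cohort generator. Every planted effect is
## recorded in a truth table so downstream recovery tests consume truth
## rather than re-deriving it. Full-cohort generation is a pure function of
## (config, seed): each generator reseeds from config$seed plus a fixed
## per-layer offset.

SEED_OFFSETS <- c(expression = 1L, methylation = 2L, clinical = 3L,
                  genomic = 4L, mirna = 5L)

#' Build a synthetic-cohort configuration
#'
#' Returns the full configuration for the cohort generator, with defaults
#' chosen to emulate paired tumor/normal profiling on both expression
#' platforms, 450K-style multi-CpG methylation with missingness, sparse
#' non-synonymous mutation (panel-wide mean rate 0.68%), discrete
#' copy-number calls, proportional-hazards survival with uniform censoring,
#' stage/metastasis labels and miRNA-target anticorrelation. Any default can
#' be overridden by name.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A list of class `cohort_config`.
#' @section Key fields:
#' \describe{
#'   \item{n_tumor, n_normal}{samples per group (30/30)}
#'   \item{n_genes}{genes in the expression matrices (2000); the first 12
#'     are named after the melatonergic panel}
#'   \item{de_fraction, effect_size}{fraction of genes with a planted
#'     log2 shift and its magnitude (0.1, 2)}
#'   \item{discordant_fraction}{fraction of planted genes whose RNA-seq
#'     direction is flipped relative to the array (0.05)}
#'   \item{array_sd}{log2-scale Gaussian noise on the array platform (1)}
#'   \item{nb_dispersion, libsize_range}{Gamma-Poisson dispersion phi
#'     (variance mu + phi mu^2; 0.1) and the log-uniform library-size range
#'     (5e5..1.5e6)}
#'   \item{cpg_per_gene, meth_shift, meth_sd, meth_na_rate}{CpG sites per
#'     gene (2..5), planted logit-scale shift (1), logit noise sd (0.5),
#'     missing-entry rate (0.05)}
#'   \item{meth_de_fraction, meth_mixed_fraction}{fraction of genes with a
#'     planted shift (0.1) and fraction of those with mixed-direction CpGs
#'     (0.2)}
#'   \item{mutation_rate}{per-gene per-sample mutation probability, scalar
#'     or named by gene (0.0068, the panel-wide mean rate being emulated)}
#'   \item{cnv_del_prob, cnv_amp_prob}{per-sample deletion/amplification
#'     call probabilities, scalar or named (0.1, 0.05)}
#'   \item{surv_shape, surv_scale}{Weibull baseline (1.5, 1500 days)}
#'   \item{hr_genes}{named log-hazard-ratio per standardized expression
#'     unit for prognostic genes (default none)}
#'   \item{censor_rate}{target fraction censored under independent uniform
#'     censoring (0.3)}
#'   \item{stage_probs}{stage I..IV distribution (0.3, 0.3, 0.25, 0.15)}
#'   \item{stage_trend_genes, stage_trend_strength}{genes whose expression
#'     trends monotonically with stage, and the latent trend weight (none, 1)}
#'   \item{n_mirna, n_consensus_mirna, n_regulatory_mirna}{miRNA universe
#'     (200), consensus (>=2-list) truth size (60), planted regulators (10)}
#'   \item{anticor_strength, mirna_shift}{latent target-miRNA
#'     anticorrelation (0.8) and tumor log2 overexpression of regulators (1)}
#'   \item{seed}{integer seed; same config + seed gives an identical cohort}
#' }
#' @examples
#' cfg <- cohort_config(n_tumor = 10, n_normal = 10, n_genes = 50, seed = 1)
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_tumor = 30L, n_normal = 30L, n_genes = 2000L,
    de_fraction = 0.1, effect_size = 2, discordant_fraction = 0.05,
    array_sd = 1,
    nb_dispersion = 0.1, libsize_range = c(5e5, 1.5e6),
    cpg_per_gene = c(2L, 5L), meth_shift = 1, meth_sd = 0.5,
    meth_na_rate = 0.05, meth_de_fraction = 0.1, meth_mixed_fraction = 0.2,
    mutation_rate = 0.0068, cnv_del_prob = 0.1, cnv_amp_prob = 0.05,
    surv_shape = 1.5, surv_scale = 1500, hr_genes = numeric(0),
    censor_rate = 0.3,
    stage_probs = c(0.3, 0.3, 0.25, 0.15),
    stage_trend_genes = character(0), stage_trend_strength = 1,
    afp_cutoff = 20,
    n_mirna = 200L, n_consensus_mirna = 60L, n_regulatory_mirna = 10L,
    anticor_strength = 0.8, mirna_shift = 1,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown cohort_config field(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_tumor >= 1, cfg$n_normal >= 1, cfg$n_genes >= 1)
  fracs <- c(cfg$de_fraction, cfg$discordant_fraction, cfg$meth_na_rate,
             cfg$meth_de_fraction, cfg$meth_mixed_fraction,
             cfg$mutation_rate, cfg$cnv_del_prob, cfg$cnv_amp_prob,
             cfg$censor_rate)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions/probabilities must lie in [0, 1]")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (any(cfg$libsize_range <= 0) || diff(cfg$libsize_range) < 0)
    stop("libsize_range must be an increasing positive pair")
  if (abs(sum(cfg$stage_probs) - 1) > 1e-8 || length(cfg$stage_probs) != 4)
    stop("stage_probs must be 4 probabilities summing to 1")
  structure(cfg, class = "cohort_config")
}

.gene_names <- function(n) {
  panel <- unname(melatonergic_genes())
  k <- min(length(panel), n)
  c(panel[seq_len(k)],
    if (n > k) sprintf("g%04d", seq_len(n - k) + k))
}

.sample_names <- function(cfg) {
  list(tumor = sprintf("T%03d", seq_len(cfg$n_tumor)),
       normal = sprintf("N%03d", seq_len(cfg$n_normal)))
}

.group_factor <- function(cfg) {
  factor(rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal)),
         levels = c("tumor", "normal"))
}

#' Simulate paired microarray and RNA-seq expression with planted effects
#'
#' Microarray values are Gaussian on the log2 scale around per-gene
#' baselines shifted by +/- effect/2 per group; RNA-seq counts are
#' Gamma-Poisson (negative binomial with variance mu + phi mu^2) around
#' per-gene relative abundances times log-uniform library sizes, shifted by
#' the same log2 effect. A configurable fraction of planted genes is
#' discordant: the count-platform direction is flipped.
#'
#' @param config A [cohort_config()].
#' @return List with `array` (log2 matrix), `counts` (integer matrix),
#'   `groups` (factor aligned to columns) and `truth` (data.frame: gene,
#'   planted, dir_array, dir_seq, effect).
#' @export
simulate_expression_pair <- function(config) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed + SEED_OFFSETS[["expression"]])
  genes <- .gene_names(cfg$n_genes)
  sn <- .sample_names(cfg)
  groups <- .group_factor(cfg)

  n_de <- round(cfg$de_fraction * cfg$n_genes)
  planted <- rep(FALSE, cfg$n_genes)
  planted[sample.int(cfg$n_genes, n_de)] <- TRUE
  dir_array <- ifelse(planted, sample(c(-1, 1), cfg$n_genes, replace = TRUE), 0)
  dir_seq <- dir_array
  idx_p <- which(planted)
  n_disc <- round(cfg$discordant_fraction * n_de)
  if (n_disc > 0) {
    disc <- sample(idx_p, n_disc)
    dir_seq[disc] <- -dir_seq[disc]
  }
  eff <- ifelse(planted, cfg$effect_size, 0)

  base <- runif(cfg$n_genes, 4, 12)
  shift_a <- outer(dir_array * eff / 2,
                   ifelse(groups == "tumor", 1, -1))
  arr <- matrix(rnorm(cfg$n_genes * length(groups),
                      mean = base + shift_a, sd = cfg$array_sd),
                nrow = cfg$n_genes,
                dimnames = list(genes, c(sn$tumor, sn$normal)))

  lib <- exp(runif(length(groups), log(cfg$libsize_range[1]),
                   log(cfg$libsize_range[2])))
  w <- 2^base / sum(2^base)
  shift_s <- outer(dir_seq * eff / 2, ifelse(groups == "tumor", 1, -1))
  mu <- (w %o% lib) * 2^shift_s
  n <- length(mu)
  cnt <- if (cfg$nb_dispersion > 0)
    rnbinom(n, size = 1 / cfg$nb_dispersion, mu = mu)
  else rpois(n, mu)
  counts <- matrix(cnt, nrow = cfg$n_genes,
                   dimnames = dimnames(arr))
  storage.mode(counts) <- "integer"

  list(array = arr, counts = counts, groups = groups,
       truth = data.frame(gene = genes, planted = planted,
                          dir_array = dir_array, dir_seq = dir_seq,
                          effect = eff, stringsAsFactors = FALSE))
}

#' Simulate a 450K-style beta-value matrix with a CpG-to-gene map
#'
#' Beta values are inverse-logit transforms of Gaussians around per-site
#' baselines. Planted genes shift all their CpG sites by `meth_shift` on
#' the logit scale in one direction; a configurable fraction of planted
#' genes instead receives mixed-direction sites (half up, half down).
#' A missingness mask is applied at `meth_na_rate`.
#'
#' @param config A [cohort_config()].
#' @return List with `beta` (CpG x sample matrix, NAs where masked),
#'   `map` (data.frame cpg, gene), `groups`, and `truth` (gene-level:
#'   hyper / hypo / mixed / none).
#' @export
simulate_methylation <- function(config) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed + SEED_OFFSETS[["methylation"]])
  genes <- .gene_names(cfg$n_genes)
  sn <- .sample_names(cfg)
  groups <- .group_factor(cfg)
  ns <- length(groups)

  n_sites <- sample(seq(cfg$cpg_per_gene[1], cfg$cpg_per_gene[2]),
                    cfg$n_genes, replace = TRUE)
  map <- data.frame(
    cpg = sprintf("cg%07d", seq_len(sum(n_sites))),
    gene = rep(genes, n_sites), stringsAsFactors = FALSE)

  n_de <- round(cfg$meth_de_fraction * cfg$n_genes)
  truth <- rep("none", cfg$n_genes)
  idx <- sample.int(cfg$n_genes, n_de)
  dirs <- sample(c("hyper", "hypo"), n_de, replace = TRUE)
  truth[idx] <- dirs
  n_mixed <- round(cfg$meth_mixed_fraction * n_de)
  if (n_mixed > 0) {
    mixable <- idx[n_sites[idx] >= 2]
    mixed <- head(sample(mixable), n_mixed)
    truth[mixed] <- "mixed"
  }
  names(truth) <- genes

  base <- rnorm(nrow(map), 0, 1.5)
  site_dir <- numeric(nrow(map))
  for (g in which(truth != "none")) {
    rows <- which(map$gene == genes[g])
    site_dir[rows] <- switch(truth[g],
      hyper = 1, hypo = -1,
      mixed = {
        half <- seq_len(ceiling(length(rows) / 2))
        d <- rep(-1, length(rows)); d[half] <- 1; d
      })
  }
  shift <- outer(site_dir * cfg$meth_shift,
                 ifelse(groups == "tumor", 1, 0))
  beta <- plogis(matrix(rnorm(nrow(map) * ns, base + shift, cfg$meth_sd),
                        nrow = nrow(map)))
  dimnames(beta) <- list(map$cpg, c(sn$tumor, sn$normal))
  if (cfg$meth_na_rate > 0)
    beta[runif(length(beta)) < cfg$meth_na_rate] <- NA

  list(beta = beta, map = map, groups = groups,
       truth = data.frame(gene = genes, meth_truth = unname(truth),
                          stringsAsFactors = FALSE))
}

#' Simulate a clinical sample sheet with proportional-hazards survival
#'
#' Tumor event times follow a Weibull proportional-hazards model with
#' linear predictor `sum(beta_g * standardized expression of gene g)` over
#' the genes named in `config$hr_genes`; censoring is independent
#' Uniform(0, b) with b solved so the expected censored fraction matches
#' `censor_rate`. Stage labels follow `stage_probs`, optionally with a
#' monotone expression-stage trend for `stage_trend_genes`; nodal and
#' distant metastasis probabilities increase with stage. AFP, tumor size
#' and ordinal TNM covariates are drawn for tumor samples.
#'
#' @param config A [cohort_config()].
#' @param expression Log-scale gene x sample matrix containing the tumor
#'   samples (used for hazard and stage-trend effects).
#' @return A sample-sheet data.frame (one row per expression column) with
#'   `os_time`/`os_event` for tumor samples.
#' @export
simulate_clinical_survival <- function(config, expression) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed + SEED_OFFSETS[["clinical"]])
  sn <- .sample_names(cfg)
  tumor <- sn$tumor
  if (!all(tumor %in% colnames(expression)))
    stop("expression matrix lacks the cohort's tumor samples")
  nt <- length(tumor)

  lp <- numeric(nt)
  for (g in names(cfg$hr_genes)) {
    if (!g %in% rownames(expression))
      stop("hr_genes entry not in expression matrix: ", g)
    x <- expression[g, tumor]
    lp <- lp + cfg$hr_genes[[g]] * as.numeric(scale(x))
  }
  u <- runif(nt)
  t_event <- cfg$surv_scale * (-log(u) / exp(lp))^(1 / cfg$surv_shape)

  r <- cfg$censor_rate
  if (r >= 1) {
    warning("censor_rate >= 1: all samples censored at time 0")
    time <- rep(0, nt); event <- rep(0L, nt)
  } else if (r <= 0) {
    time <- t_event; event <- rep(1L, nt)
  } else {
    cens_frac <- function(b) mean(pmin(t_event, b)) / b - r
    b <- uniroot(cens_frac, lower = min(t_event) * 1e-6,
                 upper = max(t_event) * 1e6, tol = 1e-8)$root
    cens <- runif(nt, 0, b)
    event <- as.integer(t_event <= cens)
    time <- pmin(t_event, cens)
    if (all(event == 0)) warning("all simulated samples are censored")
  }

  cum <- cumsum(cfg$stage_probs)
  if (length(cfg$stage_trend_genes)) {
    zs <- scale(t(expression[cfg$stage_trend_genes, tumor, drop = FALSE]))
    latent <- rowMeans(zs) * cfg$stage_trend_strength + rnorm(nt)
    stage_idx <- as.integer(cut(rank(latent, ties.method = "first") / nt,
                                breaks = c(0, cum), include.lowest = TRUE))
  } else {
    stage_idx <- sample.int(4L, nt, replace = TRUE, prob = cfg$stage_probs)
  }
  stage <- c("I", "II", "III", "IV")[stage_idx]
  p_n <- c(0.10, 0.25, 0.50, 0.70)[stage_idx]
  p_m <- c(0.02, 0.05, 0.15, 0.50)[stage_idx]
  n_status <- ifelse(runif(nt) < 0.03, "NX",
                     ifelse(runif(nt) < p_n, "N+", "N0"))
  m_status <- ifelse(runif(nt) < 0.03, "MX",
                     ifelse(runif(nt) < p_m, "M+", "M0"))

  tum <- data.frame(
    sample_id = tumor, group = "tumor", stage = stage,
    n_status = n_status, m_status = m_status,
    os_time = round(time, 2), os_event = event,
    afp = round(exp(rnorm(nt, log(30), 1.5)), 1),
    tumor_size = round(pmax(0.3, rnorm(nt, 4, 1.5)), 1),
    tnm = stage_idx, stringsAsFactors = FALSE)
  nor <- data.frame(
    sample_id = sn$normal, group = "normal", stage = NA_character_,
    n_status = NA_character_, m_status = NA_character_,
    os_time = NA_real_, os_event = NA_integer_,
    afp = NA_real_, tumor_size = NA_real_, tnm = NA_integer_,
    stringsAsFactors = FALSE)
  validate_sample_sheet(rbind(tum, nor))
}

#' Simulate sparse non-synonymous mutations and discrete copy-number calls
#'
#' Per-gene, per-tumor-sample Bernoulli mutation at `mutation_rate`
#' (scalar or named by gene), with a random protein-altering variant
#' classification per event; discrete copy-number calls at
#' `cnv_del_prob`/`cnv_amp_prob` per sample (80% single, 20% double
#' gain/loss).
#'
#' @param config A [cohort_config()].
#' @param genes Genes to simulate alterations for; defaults to the
#'   melatonergic panel.
#' @return List with `mutations` (gene/sample/classification data.frame),
#'   `cnv` (gene x sample integer matrix) and `samples` (tumor sample ids).
#' @export
simulate_genomic_alterations <- function(config,
                                         genes = unname(melatonergic_genes())) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed + SEED_OFFSETS[["genomic"]])
  tumor <- .sample_names(cfg)$tumor
  nt <- length(tumor)
  rate <- .per_gene(cfg$mutation_rate, genes)
  pdel <- .per_gene(cfg$cnv_del_prob, genes)
  pamp <- .per_gene(cfg$cnv_amp_prob, genes)

  rows <- list()
  for (g in genes) {
    hit <- which(runif(nt) < rate[[g]])
    if (length(hit))
      rows[[g]] <- data.frame(
        gene = g, sample = tumor[hit],
        classification = sample(NONSYN_CLASSES, length(hit), replace = TRUE),
        stringsAsFactors = FALSE)
  }
  mutations <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(gene = character(), sample = character(),
                  classification = character(), stringsAsFactors = FALSE)

  cnv <- matrix(0L, length(genes), nt, dimnames = list(genes, tumor))
  for (g in genes) {
    u <- runif(nt)
    del <- u < pdel[[g]]
    amp <- !del & u < pdel[[g]] + pamp[[g]]
    mag <- ifelse(runif(nt) < 0.2, 2L, 1L)
    cnv[g, del] <- -mag[del]
    cnv[g, amp] <- mag[amp]
  }
  list(mutations = mutations, cnv = cnv, samples = tumor)
}

.per_gene <- function(x, genes) {
  if (is.null(names(x))) return(setNames(rep(x[[1]], length(genes)), genes))
  out <- setNames(rep(0, length(genes)), genes)
  out[intersect(names(x), genes)] <- x[intersect(names(x), genes)]
  out
}

#' Simulate miRNA counts and three target-prediction lists
#'
#' Builds a miRNA count matrix over the cohort samples plus three named
#' target-prediction lists. Consensus-truth miRNAs are placed in at least
#' two lists; other listed miRNAs in exactly one. Planted regulatory
#' miRNAs (a subset of the consensus set) are overexpressed in tumor
#' samples by `mirna_shift` log2 units and anticorrelated with the target
#' gene at latent strength `anticor_strength`.
#'
#' @param config A [cohort_config()].
#' @param target Optional numeric vector (log-scale target-gene expression,
#'   named by sample) driving the anticorrelation; a latent Gaussian is
#'   used when absent.
#' @return List with `counts` (miRNA x sample integer matrix), `lists`
#'   (named list of three character vectors) and `truth` (data.frame:
#'   mirna, n_lists, consensus, regulatory).
#' @export
simulate_mirna_targets <- function(config, target = NULL) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed + SEED_OFFSETS[["mirna"]])
  sn <- .sample_names(cfg)
  samples <- c(sn$tumor, sn$normal)
  groups <- .group_factor(cfg)
  ns <- length(samples)
  mirnas <- sprintf("hsa-mir-%04d", seq_len(cfg$n_mirna))

  n_cons <- min(cfg$n_consensus_mirna, cfg$n_mirna)
  consensus <- mirnas[seq_len(n_cons)]
  others <- setdiff(mirnas, consensus)
  lists <- list(miRTarBase = character(), miRDB = character(),
                Targetscan = character())
  for (m in consensus) {
    k <- sample(2:3, 1)
    for (l in sample(names(lists), k)) lists[[l]] <- c(lists[[l]], m)
  }
  single <- others[runif(length(others)) < 0.5]
  for (m in single) {
    l <- sample(names(lists), 1)
    lists[[l]] <- c(lists[[l]], m)
  }

  if (is.null(target)) target <- setNames(rnorm(ns), samples)
  ## centre the target within each group so a differentially expressed
  ## target cannot cancel the planted tumor overexpression of regulators
  zt <- as.numeric(target[samples])
  for (lev in levels(groups))
    zt[groups == lev] <- zt[groups == lev] - mean(zt[groups == lev])
  zt <- zt / max(sd(zt), .Machine$double.eps)
  n_reg <- min(cfg$n_regulatory_mirna, n_cons)
  regulatory <- consensus[seq_len(n_reg)]
  rho <- cfg$anticor_strength

  z <- matrix(rnorm(cfg$n_mirna * ns), cfg$n_mirna)
  for (i in seq_len(n_reg))
    z[i, ] <- -rho * zt + sqrt(1 - rho^2) * z[i, ] +
      cfg$mirna_shift * (groups == "tumor")
  mu <- 2^(8 + z)
  counts <- matrix(rnbinom(length(mu), size = 20, mu = mu),
                   nrow = cfg$n_mirna, dimnames = list(mirnas, samples))
  storage.mode(counts) <- "integer"

  n_lists <- vapply(mirnas, function(m)
    sum(vapply(lists, function(l) m %in% l, logical(1))), integer(1))
  list(counts = counts, lists = lists, groups = groups,
       truth = data.frame(mirna = mirnas, n_lists = unname(n_lists),
                          consensus = mirnas %in% consensus,
                          regulatory = mirnas %in% regulatory,
                          stringsAsFactors = FALSE))
}

#' Generate a complete synthetic multi-omics cohort
#'
#' Runs every layer generator under the shared configuration seed and
#' returns the assembled cohort. The miRNA layer's anticorrelation target
#' is the first gene named in `hr_genes`, else the first panel gene.
#'
#' @param config A [cohort_config()].
#' @return List with elements `expression` (array/counts/groups/truth),
#'   `methylation`, `clinical`, `genomic`, `mirna` and the `config`.
#' @examples
#' co <- simulate_cohort(cohort_config(n_tumor = 6, n_normal = 6,
#'                                     n_genes = 40, seed = 7))
#' dim(co$expression$counts)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  cfg <- validate_cohort_config(config)
  expr <- simulate_expression_pair(cfg)
  meth <- simulate_methylation(cfg)
  clin <- simulate_clinical_survival(cfg, expr$array)
  geno <- simulate_genomic_alterations(cfg)
  anchor <- if (length(cfg$hr_genes)) names(cfg$hr_genes)[1]
  else rownames(expr$array)[1]
  mirna <- simulate_mirna_targets(cfg, target = expr$array[anchor, ])
  list(expression = expr, methylation = meth, clinical = clin,
       genomic = geno, mirna = mirna, config = cfg)
}

#' Write a simulated cohort to a directory of plain-text files
#'
#' Emits the same TSV formats the readers in this package consume:
#' `array.tsv`, `counts.tsv`, `beta.tsv`, `cpg_map.tsv`, `mutations.tsv`,
#' `cnv.tsv`, `samples.tsv`, `mirna_counts.tsv`, one `targets_<db>.txt`
#' per prediction list, and the truth tables.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_matrix(round(cohort$expression$array, 6), p("array.tsv"))
  write_matrix(cohort$expression$counts, p("counts.tsv"))
  write_matrix(round(cohort$methylation$beta, 6), p("beta.tsv"))
  write_table_tsv(cohort$methylation$map, p("cpg_map.tsv"))
  write_table_tsv(cohort$genomic$mutations, p("mutations.tsv"))
  write_matrix(cohort$genomic$cnv, p("cnv.tsv"))
  write_table_tsv(cohort$clinical, p("samples.tsv"))
  write_matrix(cohort$mirna$counts, p("mirna_counts.tsv"))
  for (db in names(cohort$mirna$lists))
    writeLines(cohort$mirna$lists[[db]], p(sprintf("targets_%s.txt", db)))
  write_table_tsv(cohort$expression$truth, p("truth_expression.tsv"))
  write_table_tsv(cohort$methylation$truth, p("truth_methylation.tsv"))
  write_table_tsv(cohort$mirna$truth, p("truth_mirna.tsv"))
  invisible(dir)
}
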
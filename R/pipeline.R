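## End-to-end driver: reads a YAML/JSON config (or an equivalent list)
## naming either a simulate: block or inputs: file paths, runs the enabled
## stages, and writes one TSV per result plus a manifest recording
## versions, seed and parameters. Identical config + seed reproduces
## byte-identical result tables.

PIPELINE_STAGES <- c("de_status", "methylation", "multiomics", "survival",
                     "progression", "enrichment", "mirna")

PIPELINE_PARAMS <- list(alpha = 0.05, min_cnv_freq = 10, min_group = 10,
                        anchor_gene = "RORA", afp_cutoff = 20,
                        n_gene_sets = 50, mirna_min_support = 2)

#' Run the multi-omics integration pipeline
#'
#' Drives every enabled stage over a simulated cohort (config `simulate:`
#' block, merged into [cohort_config()]) or over files named in an
#' `inputs:` block, writing result tables and a manifest to `out`.
#' Stages: `de_status` (TMM, two-platform DE, status table),
#' `methylation` (site filter/impute, Wilcoxon, gene calls),
#' `multiomics` (alteration frequencies + consistency flags),
#' `survival` (per-gene univariate/multivariate Cox and median-split
#' log-rank), `progression` (metastasis DE, stage ANOVA/Tukey),
#' `enrichment` (anchor correlation screen + hypergeometric pathways) and
#' `mirna` (target-list consensus + DE). Unknown config keys are
#' rejected by name.
#'
#' @param config Path to a YAML/JSON config file, or an equivalent list.
#'   Recognised top-level keys: `simulate`, `inputs`, `stages`, `params`.
#' @param seed Integer seed governing all randomness (overrides any seed
#'   in the simulate block).
#' @param out Output directory.
#' @return Invisibly, a list of the in-memory stage results.
#' @examples
#' \donttest{
#' res <- run_pipeline(list(simulate = list(n_tumor = 12, n_normal = 12,
#'                                          n_genes = 60),
#'                          stages = "de_status"),
#'                     seed = 1, out = tempfile())
#' head(res$status)
#' }
#' @export
run_pipeline <- function(config, seed = 1L, out = "results") {
  cfg <- if (is.character(config)) {
    if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                       simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else config
  unknown <- setdiff(names(cfg), c("simulate", "inputs", "stages", "params"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  stages <- if (is.null(cfg$stages)) PIPELINE_STAGES else unlist(cfg$stages)
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  params <- PIPELINE_PARAMS
  if (!is.null(cfg$params)) {
    badp <- setdiff(names(cfg$params), names(params))
    if (length(badp))
      stop("unknown params key(s): ", paste(badp, collapse = ", "))
    params <- modifyList(params, cfg$params)
  }
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config needs a 'simulate' or 'inputs' block")

  set.seed(seed)
  data <- if (!is.null(cfg$simulate)) {
    sim_cfg <- do.call(cohort_config,
                       modifyList(cfg$simulate, list(seed = as.integer(seed))))
    .cohort_as_data(simulate_cohort(sim_cfg))
  } else .load_inputs(cfg$inputs)

  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  panel <- intersect(unname(melatonergic_genes()), rownames(data$array))
  if (!length(panel)) panel <- rownames(data$array)

  nf <- NULL; lcpm <- NULL
  if (!is.null(data$counts)) {
    nf <- tmm_factors(data$counts)
    lcpm <- log_cpm(data$counts, nf)
    if (!is.null(data$batch)) lcpm <- batch_adjust(lcpm, data$batch)
  }

  if ("de_status" %in% stages) {
    de_a <- array_ttest_de(data$array, data$groups)
    de_s <- count_nb_de(data$counts, nf, data$groups)
    res$de_array <- de_a; res$de_seq <- de_s
    res$status <- status_table(de_a, de_s, alpha = params$alpha,
                               genes = panel)
    write_table_tsv(res$status, file.path(out, "status_table.tsv"))
  }

  if ("methylation" %in% stages && !is.null(data$beta)) {
    fi <- filter_impute_cpgs(data$beta, data$cpg_map)
    sites <- cpg_wilcoxon(fi$beta, data$meth_groups)
    res$meth_sites <- sites
    res$meth_genes <- gene_methylation_status(sites, fi$map,
                                              alpha = params$alpha)
    write_table_tsv(res$meth_genes, file.path(out, "methylation_calls.tsv"))
  }

  if ("multiomics" %in% stages && !is.null(data$mutations)) {
    summ <- alteration_frequencies(data$mutations, data$cnv,
                                   samples = data$alteration_samples,
                                   genes = panel)
    res$alterations <- summ
    write_table_tsv(summ, file.path(out, "alteration_frequencies.tsv"))
    if (!is.null(res$status)) {
      meth <- if (!is.null(res$meth_genes))
        res$meth_genes[res$meth_genes$gene %in% panel, ] else NULL
      res$consistency <- consistency_annotation(
        res$status, summ, gene_meth = meth,
        min_cnv_freq = params$min_cnv_freq)
      write_table_tsv(res$consistency, file.path(out, "consistency.tsv"))
    }
  }

  if ("survival" %in% stages && !is.null(data$clinical) &&
      "os_time" %in% names(data$clinical)) {
    res$survival <- .survival_stage(lcpm, data$clinical, panel, params)
    write_table_tsv(res$survival, file.path(out, "survival_report.tsv"))
  }

  if ("progression" %in% stages && !is.null(data$clinical)) {
    groups <- split_metastasis(data$clinical)
    md <- withCallingHandlers(
      metastasis_de(lcpm[panel, , drop = FALSE], groups,
                    min_group = params$min_group, alpha = params$alpha),
      warning = function(w) invokeRestart("muffleWarning"))
    res$metastasis <- md
    if (!is.null(md))
      write_table_tsv(md, file.path(out, "metastasis_de.tsv"))
    res$stage_comparison <- .stage_stage(lcpm, data$clinical, panel)
    write_table_tsv(res$stage_comparison,
                    file.path(out, "stage_comparison.tsv"))
  }

  if ("enrichment" %in% stages) {
    tum <- data$clinical$sample_id[data$clinical$group == "tumor"]
    tum <- intersect(tum, colnames(lcpm))
    anchor <- params$anchor_gene
    if (!anchor %in% rownames(lcpm)) anchor <- panel[1]
    screen <- pearson_screen(anchor, lcpm[, tum, drop = FALSE],
                             alpha = params$alpha)
    res$screen <- screen
    sets <- if (!is.null(data$gene_sets)) data$gene_sets
    else .simulate_gene_sets(rownames(lcpm), params$n_gene_sets)
    universe <- intersect(rownames(lcpm), unique(unlist(sets)))
    for (side in c("positive", "negative")) {
      q <- intersect(screen[[side]], universe)
      if (length(q)) {
        enr <- hypergeom_enrich(q, sets, universe)
        res[[paste0("enrich_", side)]] <- enr
        write_table_tsv(enr, file.path(out,
                                       sprintf("enrichment_%s.tsv", side)))
      }
    }
  }

  if ("mirna" %in% stages && !is.null(data$mirna_counts)) {
    cons <- mirna_consensus(data$target_lists,
                            min_support = params$mirna_min_support)
    res$mirna_consensus <- cons
    write_table_tsv(cons$membership, file.path(out, "mirna_consensus.tsv"))
    if (length(cons$consensus)) {
      res$mirna_de <- mirna_de(data$mirna_counts, data$mirna_groups,
                               mirnas = cons$consensus,
                               alpha = params$alpha)
      write_table_tsv(res$mirna_de$de, file.path(out, "mirna_de.tsv"))
    }
  }

  manifest <- list(
    package = "melatomics",
    version = as.character(utils::packageVersion("melatomics")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = as.integer(seed), stages = stages, params = params,
    normalization_order = "TMM on raw counts, then per-batch location adjustment of log-CPM",
    site_significance = "BH FDR < alpha for CpG site calls",
    nb_dispersion_estimate = if (!is.null(res$de_seq))
      attr(res$de_seq, "dispersion") else NULL)
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(res)
}

.cohort_as_data <- function(co) {
  list(array = co$expression$array, counts = co$expression$counts,
       groups = co$expression$groups, batch = NULL,
       beta = co$methylation$beta, cpg_map = co$methylation$map,
       meth_groups = co$methylation$groups,
       mutations = co$genomic$mutations, cnv = co$genomic$cnv,
       alteration_samples = co$genomic$samples,
       clinical = co$clinical,
       mirna_counts = co$mirna$counts, mirna_groups = co$mirna$groups,
       target_lists = co$mirna$lists, gene_sets = NULL,
       truth = list(expression = co$expression$truth,
                    methylation = co$methylation$truth,
                    mirna = co$mirna$truth))
}

.load_inputs <- function(inputs) {
  known <- c("array", "counts", "beta", "cpg_map", "mutations", "cnv",
             "samples", "mirna_counts", "target_lists", "gmt", "batch")
  bad <- setdiff(names(inputs), known)
  if (length(bad)) stop("unknown inputs key(s): ", paste(bad, collapse = ", "))
  g <- function(k, f) if (!is.null(inputs[[k]])) f(inputs[[k]])
  clinical <- g("samples", read_sample_sheet)
  groups <- if (!is.null(clinical)) {
    factor(clinical$group, levels = c("tumor", "normal"))
  }
  arr <- g("array", function(p) read_matrix(p, "array"))
  cnt <- g("counts", function(p) read_matrix(p, "counts"))
  align <- function(m) {
    if (is.null(m) || is.null(clinical)) return(groups)
    factor(clinical$group[match(colnames(m), clinical$sample_id)],
           levels = c("tumor", "normal"))
  }
  beta <- g("beta", function(p) read_matrix(p, "beta"))
  lists <- if (!is.null(inputs$target_lists))
    lapply(inputs$target_lists, readLines)
  mirna <- g("mirna_counts", function(p) read_matrix(p, "mirna"))
  list(array = arr, counts = cnt, groups = align(cnt), batch = NULL,
       beta = beta,
       cpg_map = g("cpg_map", function(p)
         read.delim(p, stringsAsFactors = FALSE)),
       meth_groups = align(beta),
       mutations = g("mutations", read_mutations),
       cnv = g("cnv", read_cnv_calls),
       alteration_samples = if (!is.null(clinical))
         clinical$sample_id[clinical$group == "tumor"],
       clinical = clinical, mirna_counts = mirna,
       mirna_groups = align(mirna), target_lists = lists,
       gene_sets = g("gmt", read_gmt), truth = NULL)
}

.survival_stage <- function(lcpm, clinical, panel, params) {
  cl <- clinical[clinical$group == "tumor" & !is.na(clinical$os_time), ,
                 drop = FALSE]
  cl <- cl[cl$sample_id %in% colnames(lcpm), , drop = FALSE]
  rows <- lapply(panel, function(g) {
    x <- lcpm[g, cl$sample_id]
    row <- data.frame(gene = g, hr = NA_real_, lower = NA_real_,
                      upper = NA_real_, p = NA_real_, adj_hr = NA_real_,
                      adj_p = NA_real_, logrank_p = NA_real_,
                      n_low = NA_integer_, n_high = NA_integer_,
                      stringsAsFactors = FALSE)
    if (length(unique(x)) < 2L) return(row)
    uni <- cox_fit(matrix(as.numeric(scale(x)), ncol = 1,
                          dimnames = list(NULL, g)),
                   cl$os_time, cl$os_event)
    row$hr <- uni$hr; row$lower <- uni$lower; row$upper <- uni$upper
    row$p <- uni$p
    covs <- data.frame(expr = as.numeric(scale(x)),
                       afp_high = as.numeric(cl$afp > params$afp_cutoff),
                       size = cl$tumor_size, tnm = cl$tnm)
    covs <- covs[, vapply(covs, function(v)
      length(unique(v[!is.na(v)])) > 1L, logical(1)), drop = FALSE]
    ok <- complete.cases(covs)
    if ("expr" %in% names(covs) && ncol(covs) > 1 && sum(ok) > 5) {
      multi <- cox_fit(as.matrix(covs[ok, ]), cl$os_time[ok],
                       cl$os_event[ok])
      row$adj_hr <- multi$hr[multi$term == "expr"]
      row$adj_p <- multi$p[multi$term == "expr"]
    }
    split <- median_dichotomize(x)
    row$n_low <- sum(split == "low"); row$n_high <- sum(split == "high")
    row$logrank_p <- logrank(cl$os_time, cl$os_event, split)$p
    row
  })
  do.call(rbind, rows)
}

.stage_stage <- function(lcpm, clinical, panel) {
  cl <- clinical[clinical$group == "tumor" & !is.na(clinical$stage), ,
                 drop = FALSE]
  cl <- cl[cl$sample_id %in% colnames(lcpm), , drop = FALSE]
  rows <- lapply(panel, function(g) {
    sc <- tryCatch(
      suppressWarnings(stage_anova_tukey(lcpm[g, cl$sample_id], cl$stage)),
      error = function(e) NULL)
    if (is.null(sc))
      return(data.frame(gene = g, F = NA_real_, anova_p = NA_real_,
                        early_late_p = NA_real_, stringsAsFactors = FALSE))
    data.frame(gene = g, F = sc$anova$F, anova_p = sc$anova$p,
               early_late_p = if (is.null(sc$early_late)) NA_real_
               else sc$early_late$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Random gene sets over the matrix genes; used only when no GMT is
## supplied (simulate-backed runs), so the enrichment stage is exercised
## mechanically.
.simulate_gene_sets <- function(genes, n_sets) {
  sizes <- sample(10:min(50, max(10, length(genes) %/% 2)), n_sets,
                  replace = TRUE)
  sets <- lapply(sizes, function(k) sample(genes, min(k, length(genes))))
  names(sets) <- sprintf("pathway_%03d", seq_len(n_sets))
  sets
}
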
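# End-to-end orchestration of the synthetic analysis: simulate -> score ->
# differential expression -> consensus signatures -> enrichment -> CNV ->
# survival -> association statistics, with one master seed, per-stage derived
# seeds, and a machine-readable run report with file checksums.

#' Validate a pipeline configuration
#'
#' @param config A list (or path to a YAML file) with a mandatory integer
#'   `seed` and optional elements: `panel` (overrides for [panel_config()]),
#'   `gsea` (`n_perm`), `cnv` (`window`, `clip`), `survival` (`n_patients`,
#'   `hazard_beta`, `censor_rate`).
#' @return The validated configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path", call. = FALSE)
  if (is.null(config$seed)) {
    stop("config is missing the mandatory `seed` (an integer); every run is seeded",
         call. = FALSE)
  }
  assert_scalar_number(config$seed, "seed", lower = 0, upper = 2^31 - 1)
  config$panel <- config$panel %||% list()
  config$gsea <- config$gsea %||% list()
  config$cnv <- config$cnv %||% list()
  config$survival <- config$survival %||% list()
  config
}

#' Run the full synthetic analysis pipeline
#'
#' Executes every stage in dependency order, writing TSV outputs and a
#' `report.json` that lists the stage DAG, per-stage seeds, output files and
#' their MD5 checksums. Rerunning with an identical configuration reproduces
#' identical checksums.
#'
#' @param config See [validate_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, the run report list.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stats::setNames(vapply(1:8, derive_seed, integer(1), master = config$seed),
                           c("simulate", "score", "de", "consensus", "gsea",
                             "cnv", "survival", "association"))
  stages <- list()
  outputs <- character(0)
  emit <- function(name, obj, stage, inputs) {
    path <- file.path(out_dir, name)
    utils::write.table(format(obj, digits = 12), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, path)
    stages[[stage]]$outputs <<- c(stages[[stage]]$outputs %||% character(0), name)
    stages[[stage]]$inputs <<- unique(c(stages[[stage]]$inputs %||% character(0), inputs))
    path
  }

  # -- simulate ---------------------------------------------------------------
  pcfg <- do.call(panel_config, utils::modifyList(list(seed = seeds[["simulate"]]),
                                                  config$panel))
  sim <- simulate_panel(pcfg)
  ds <- sim$dataset
  truth <- sim$truth
  emit("cells.tsv", ds$cell_meta, "simulate", character(0))
  emit("genes.tsv", ds$gene_meta, "simulate", character(0))
  emit("truth_de_genes.tsv",
       data.frame(gene = names(truth$de_effects), log2fc = truth$de_effects),
       "simulate", character(0))

  plate_cells <- ds$cell_meta$cell_id[ds$cell_meta$platform == "plate"]
  droplet_cells <- ds$cell_meta$cell_id[ds$cell_meta$platform == "droplet"]

  # -- score ------------------------------------------------------------------
  scores <- compute_emp(ds, truth$epithelial_genes, truth$mesenchymal_genes,
                        seed = seeds[["score"]])
  emit("emp_scores.tsv", scores, "score", "cells.tsv")
  comp <- state_composition(scores, ds$cell_meta, "tumor_model")
  emit("state_composition.tsv", comp, "score", "emp_scores.tsv")

  # -- differential expression ------------------------------------------------
  de <- run_de(ds, "tissue", "metastasis", "primary",
               covariate_keys = "tumor_model", cells = plate_cells)
  emit("de_tissue.tsv", as.data.frame(de), "de", "cells.tsv")

  # -- consensus --------------------------------------------------------------
  pm <- per_model_de(ds, cells = plate_cells)
  shared <- shared_upregulated(pm$results, direction = "up", min_models = 2,
                               within_groups = truth$potential)
  shared_tab <- do.call(rbind, lapply(shared, function(s) {
    if (length(s$genes) == 0L) return(NULL)
    data.frame(group = s$label, gene = s$genes,
               n_support = vapply(s$support, length, integer(1)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(shared_tab)) {
    shared_tab <- data.frame(group = character(), gene = character(),
                             n_support = integer())
  }
  emit("shared_metastasis_genes.tsv", shared_tab, "consensus", "de_tissue.tsv")

  sm_plate <- state_marker_de(ds, scores, cells = plate_cells)
  sm_droplet <- state_marker_de(ds, scores, cells = droplet_cells)
  up_plate <- lapply(sm_plate, significant_genes, direction = "up")
  up_droplet <- lapply(sm_droplet, significant_genes, direction = "up")
  common <- intersect(names(up_plate), names(up_droplet))
  xp <- cross_platform_intersect(up_plate[common], up_droplet[common],
                                 platform_names = c("plate", "droplet"))
  xp_tab <- do.call(rbind, lapply(xp, function(s) {
    if (length(s$genes) == 0L) return(NULL)
    data.frame(state = s$label, gene = s$genes, stringsAsFactors = FALSE)
  }))
  if (is.null(xp_tab)) xp_tab <- data.frame(state = character(), gene = character())
  emit("state_markers_cross_platform.tsv", xp_tab, "consensus", "emp_scores.tsv")

  # -- enrichment -------------------------------------------------------------
  ranking <- rank_from_de(de)
  sets <- list(epithelial_program = truth$epithelial_genes,
               mesenchymal_program = truth$mesenchymal_genes,
               intermediate_program = truth$intermediate_markers,
               metastasis_up = names(truth$de_effects)[truth$de_effects > 0],
               metastasis_down = names(truth$de_effects)[truth$de_effects < 0])
  gsea <- preranked_gsea(ranking, sets,
                         n_perm = config$gsea$n_perm %||% 500L,
                         seed = seeds[["gsea"]])
  emit("gsea.tsv", as.data.frame(gsea), "gsea", "de_tissue.tsv")

  # -- CNV --------------------------------------------------------------------
  prof <- infer_profiles(ds, window = config$cnv$window %||% 51L,
                         clip = config$cnv$clip %||% 3.0)
  cnv_cmp <- compare_compartments(prof, ds$cell_meta)
  emit("cnv_compartments.tsv", cnv_cmp, "cnv", "cells.tsv")

  # -- survival ---------------------------------------------------------------
  surv_sim <- simulate_survival(
    n_patients = config$survival$n_patients %||% 400L,
    hazard_beta = config$survival$hazard_beta %||% 1.0,
    signature_genes = truth$intermediate_markers,
    censor_rate = config$survival$censor_rate %||% 0.3,
    seed = seeds[["survival"]])
  strat <- stratify_by_signature(surv_sim$cohort, truth$intermediate_markers)
  surv_tab <- data.frame(analysis = "overall", chi2 = strat$logrank$chi2,
                         df = strat$logrank$df, p = strat$logrank$p,
                         stringsAsFactors = FALSE)
  by_sub <- tryCatch(
    subtype_stratified(surv_sim$cohort, truth$intermediate_markers),
    error = function(e) NULL)
  if (!is.null(by_sub)) {
    surv_tab <- rbind(surv_tab, do.call(rbind, lapply(names(by_sub), function(s) {
      data.frame(analysis = s, chi2 = by_sub[[s]]$logrank$chi2,
                 df = by_sub[[s]]$logrank$df, p = by_sub[[s]]$logrank$p,
                 stringsAsFactors = FALSE)
    })))
  }
  emit("survival.tsv", surv_tab, "survival", character(0))

  # -- associations -----------------------------------------------------------
  plate_ds <- subset_cells(ds, plate_cells)
  plate_scores <- scores[scores$cell_id %in% plate_cells, , drop = FALSE]
  pot <- potential_correlation(plate_scores, plate_ds$cell_meta)
  paired <- paired_emp_correlation(plate_scores, plate_ds$cell_meta, "tissue")
  pc <- pca_cells(plate_ds, n_components = 5)
  sep <- pc_separation(pc$coords, plate_ds$cell_meta, axis = 2, group_key = "tissue")
  assoc <- data.frame(
    statistic = c("potential_r", "paired_tissue_r2", "pc2_separation_p"),
    value = c(pot$r, paired$r_squared, sep$p), stringsAsFactors = FALSE)
  emit("associations.tsv", assoc, "association", "emp_scores.tsv")

  # -- report -----------------------------------------------------------------
  checksums <- tools::md5sum(outputs)
  report <- list(
    seed = config$seed,
    stage_seeds = as.list(seeds),
    stages = lapply(names(stages), function(s) {
      list(name = s, inputs = stages[[s]]$inputs, outputs = stages[[s]]$outputs)
    }),
    checksums = as.list(stats::setNames(unname(checksums), basename(outputs)))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

#' Subset an expression dataset by cell ids
#'
#' @param dataset An `ExpressionDataset`.
#' @param cells Character vector of cell ids to keep.
#' @return The subset `ExpressionDataset` (normalized layer recomputed).
#' @export
subset_cells <- function(dataset, cells) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  keep <- dataset$cell_meta$cell_id %in% cells
  if (!any(keep)) stop("no cell matches the subset", call. = FALSE)
  expression_dataset(dataset$counts[keep, , drop = FALSE],
                     dataset$cell_meta[keep, , drop = FALSE],
                     dataset$gene_meta, scale = dataset$scale)
}
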
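# Multi-level consensus signatures: per-model DE, sharing within metastatic
# potential groups, group-vs-rest DE on primary tumors, cross-platform
# intersection, EMP-state markers, and peak-profile validation.

#' Primary-vs-metastasis DE per tumor model
#'
#' Runs the hurdle contrast within each model separately (no covariate needed
#' for a within-model contrast). Models with fewer than `min_met_cells`
#' metastatic cells are excluded and reported.
#'
#' @param dataset An `ExpressionDataset` with tissue labels.
#' @param min_met_cells Minimum metastatic cells per model (default 10).
#' @param min_cells Per-group minimum for [run_de()].
#' @param cells Optional cell subset.
#' @return List with `results` (named list of `de_result`, metastasis vs
#'   primary) and `excluded` (model names).
#' @export
per_model_de <- function(dataset, min_met_cells = 10L, min_cells = 3L, cells = NULL) {
  meta <- dataset$cell_meta
  if (!is.null(cells)) meta <- meta[meta$cell_id %in% cells, , drop = FALSE]
  results <- list()
  excluded <- character(0)
  for (m in unique(meta$tumor_model)) {
    mm <- meta[meta$tumor_model == m, , drop = FALSE]
    n_met <- sum(mm$tissue == "metastasis")
    if (n_met < min_met_cells) {
      excluded <- c(excluded, m)
      next
    }
    results[[m]] <- run_de(dataset, "tissue", "metastasis", "primary",
                           min_cells = min_cells, cells = mm$cell_id)
  }
  if (length(results) == 0L) stop("no model passed the metastatic-cell filter", call. = FALSE)
  list(results = results, excluded = excluded)
}

#' Genes shared across models, optionally within potential groups
#'
#' Thresholds every model's DE table with [significant_genes()] and admits a
#' gene to a group's consensus signature when it is significant in the stated
#' direction in at least `min_models` models of that group. Also tallies the
#' sharing histogram (how many genes are exclusive to one model, shared by
#' two, ...).
#'
#' @param de_by_model Named list of `de_result` tables.
#' @param direction `"up"` or `"down"`.
#' @param min_models Sharing threshold (default 2).
#' @param within_groups Optional named character vector mapping model name to
#'   group label; `NULL` treats all models as one group `"all"`.
#' @param lfc,alpha,use_adj Thresholds passed to [significant_genes()].
#' @return List of `consensus_signature` objects, one per group: `label`,
#'   `genes`, `support` (gene -> supporting models), `histogram` (sharing
#'   tally over the group's models).
#' @export
shared_upregulated <- function(de_by_model, direction = "up", min_models = 2L,
                               within_groups = NULL, lfc = 0.5, alpha = 0.05,
                               use_adj = FALSE) {
  models <- names(de_by_model)
  if (is.null(within_groups)) {
    within_groups <- stats::setNames(rep("all", length(models)), models)
  }
  unknown <- setdiff(models, names(within_groups))
  if (length(unknown)) {
    stop(sprintf("models without a group label: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  gene_sets <- lapply(de_by_model, significant_genes, direction = direction,
                      lfc = lfc, alpha = alpha, use_adj = use_adj)
  out <- list()
  for (grp in unique(within_groups[models])) {
    grp_models <- models[within_groups[models] == grp]
    tally <- table(unlist(gene_sets[grp_models], use.names = FALSE))
    genes <- sort(names(tally)[tally >= min_models])
    support <- lapply(stats::setNames(genes, genes), function(g) {
      grp_models[vapply(gene_sets[grp_models], function(s) g %in% s, logical(1))]
    })
    hist_tab <- if (length(tally)) table(factor(as.integer(tally),
                                                levels = seq_along(grp_models))) else
      table(factor(integer(0), levels = seq_along(grp_models)))
    out[[grp]] <- structure(list(label = grp, genes = genes, support = support,
                                 histogram = hist_tab,
                                 n_models = length(grp_models),
                                 min_models = min_models),
                            class = "consensus_signature")
  }
  out
}

#' Per-tumor DE against the other metastatic-potential groups
#'
#' Using primary-tumor cells only, contrasts each tumor's cells against the
#' pooled primary cells of all tumors belonging to *other* potential groups,
#' then applies the sharing rule within each group.
#'
#' @param dataset An `ExpressionDataset` (only `tissue == "primary"` cells are
#'   used).
#' @param min_models Sharing threshold within a potential group (default 2).
#' @param min_cells Passed to [run_de()].
#' @param lfc,alpha,use_adj Significance thresholds.
#' @return List with `de` (named per-tumor `de_result`) and `signatures`
#'   (consensus per potential group, upregulated direction).
#' @export
potential_group_de <- function(dataset, min_models = 2L, min_cells = 3L,
                               lfc = 0.5, alpha = 0.05, use_adj = FALSE) {
  meta <- dataset$cell_meta[dataset$cell_meta$tissue == "primary", , drop = FALSE]
  groups <- unique(meta$metastatic_potential)
  if (length(groups) < 2L) {
    stop("need >= 2 metastatic potential groups among primary tumors", call. = FALSE)
  }
  de <- list()
  model_group <- character(0)
  for (m in unique(meta$tumor_model)) {
    grp <- meta$metastatic_potential[meta$tumor_model == m][1]
    other <- meta[meta$metastatic_potential != grp, , drop = FALSE]
    own <- meta[meta$tumor_model == m, , drop = FALSE]
    cells <- c(own$cell_id, other$cell_id)
    # contrast: this tumor vs pooled other-group tumors
    sub <- dataset
    sub$cell_meta$is_target <- ifelse(sub$cell_meta$tumor_model == m, "target", "rest")
    de[[m]] <- run_de(sub, "is_target", "target", "rest",
                      min_cells = min_cells, cells = cells)
    model_group[m] <- grp
  }
  sigs <- shared_upregulated(de, direction = "up", min_models = min_models,
                             within_groups = model_group,
                             lfc = lfc, alpha = alpha, use_adj = use_adj)
  list(de = de, signatures = sigs)
}

#' Intersect consensus signatures across two platforms
#'
#' @param signatures_platform1,signatures_platform2 Named lists of
#'   `consensus_signature` objects (or plain character vectors) with matching
#'   labels.
#' @param platform_names Length-2 character vector naming the platforms.
#' @return Named list of `consensus_signature` objects holding the per-label
#'   set intersections, with platform provenance recorded.
#' @export
cross_platform_intersect <- function(signatures_platform1, signatures_platform2,
                                     platform_names = c("platform1", "platform2")) {
  l1 <- names(signatures_platform1); l2 <- names(signatures_platform2)
  unmatched <- c(setdiff(l1, l2), setdiff(l2, l1))
  if (length(unmatched)) {
    stop(sprintf("labels present on one platform only: %s",
                 paste(unique(unmatched), collapse = ", ")), call. = FALSE)
  }
  out <- list()
  for (lab in l1) {
    g1 <- sig_genes(signatures_platform1[[lab]])
    g2 <- sig_genes(signatures_platform2[[lab]])
    genes <- sort(intersect(g1, g2))
    if (length(genes) == 0L) {
      warning(sprintf("empty cross-platform intersection for label '%s'", lab),
              call. = FALSE)
    }
    out[[lab]] <- structure(list(
      label = lab, genes = genes,
      support = lapply(stats::setNames(genes, genes), function(g) platform_names),
      platforms = stats::setNames(rep(list(platform_names), length(genes)), genes)),
      class = "consensus_signature")
  }
  out
}

sig_genes <- function(x) {
  if (inherits(x, "consensus_signature")) x$genes else as.character(x)
}

#' One-vs-rest DE for each EMP state
#'
#' @param dataset An `ExpressionDataset`.
#' @param score_table An `emp_score_table` for the same cells.
#' @param min_cells Minimum cells for a state to be tested (states below are
#'   skipped with a warning).
#' @param cells Optional cell subset.
#' @return Named list of `de_result` tables (state vs rest). Errors if fewer
#'   than two states are populated.
#' @export
state_marker_de <- function(dataset, score_table, min_cells = 3L, cells = NULL) {
  sub <- dataset
  st <- score_table$state[match(sub$cell_meta$cell_id, score_table$cell_id)]
  sub$cell_meta$emp_state <- st
  keep <- !is.na(st)
  use_cells <- sub$cell_meta$cell_id[keep]
  if (!is.null(cells)) use_cells <- intersect(use_cells, cells)
  present <- table(sub$cell_meta$emp_state[sub$cell_meta$cell_id %in% use_cells])
  populated <- names(present)[present >= min_cells]
  if (sum(present > 0) < 2L) {
    stop("need >= 2 populated EMP states for one-vs-rest DE", call. = FALSE)
  }
  skipped_states <- setdiff(names(present)[present > 0], populated)
  if (length(skipped_states)) {
    warning(sprintf("state(s) below min_cells skipped: %s",
                    paste(skipped_states, collapse = ", ")), call. = FALSE)
  }
  out <- list()
  for (st_i in populated) {
    sub$cell_meta$is_state <- ifelse(sub$cell_meta$emp_state == st_i, "state", "rest")
    out[[st_i]] <- run_de(sub, "is_state", "state", "rest",
                          min_cells = min_cells, cells = use_cells)
  }
  out
}

#' Expression profile of a gene along the EMP axis
#'
#' Orders cells by increasing EMP score, smooths the expression of expressing
#' cells with a centered running mean, and reports whether the smoothed
#' maximum falls strictly inside the intermediate band (a flat curve or a
#' maximum at either end of the curve is "not peaked").
#'
#' @param dataset An `ExpressionDataset`.
#' @param gene Gene symbol.
#' @param score_table An `emp_score_table`.
#' @param smoothing_span Fraction of expressing cells per smoothing window
#'   (default 0.3).
#' @param low,high Intermediate band thresholds.
#' @return List with `cells` (data.frame: `cell_id`, `emp`, `expr`, `state`),
#'   `smoothed` (data.frame over expressing cells: `emp`, `fit`),
#'   `positive_fraction` (per-state fraction of expressing cells), and
#'   `peaks_in_intermediate` (logical; `NA` when the gene is expressed
#'   nowhere).
#' @export
peak_profile <- function(dataset, gene, score_table, smoothing_span = 0.3,
                         low = -0.2, high = 0.2) {
  if (!gene %in% colnames(dataset$normalized)) {
    stop(sprintf("gene '%s' not in dataset", gene), call. = FALSE)
  }
  emp <- score_table$emp[match(rownames(dataset$normalized), score_table$cell_id)]
  ok <- !is.na(emp)
  expr <- dataset$normalized[ok, gene]
  emp <- emp[ok]
  state <- score_table$state[match(rownames(dataset$normalized)[ok], score_table$cell_id)]
  ord <- order(emp)
  cells <- data.frame(cell_id = rownames(dataset$normalized)[ok][ord],
                      emp = emp[ord], expr = expr[ord], state = state[ord],
                      stringsAsFactors = FALSE)
  pos_frac <- vapply(split(cells$expr > 0, factor(cells$state, levels = EMP_STATES)),
                     function(v) if (length(v)) mean(v) else NA_real_, numeric(1))
  expressing <- cells[cells$expr > 0, , drop = FALSE]
  if (nrow(expressing) == 0L) {
    warning(sprintf("gene '%s' expressed nowhere; peak flag undefined", gene),
            call. = FALSE)
    return(list(cells = cells, smoothed = NULL, positive_fraction = pos_frac,
                peaks_in_intermediate = NA))
  }
  window <- max(5L, round(smoothing_span * nrow(expressing)))
  fit <- running_mean(expressing$expr, window = window)
  smoothed <- data.frame(emp = expressing$emp, fit = fit)
  # trust the maximum only where the smoother has full window support; the
  # truncated edges average few cells and are dominated by single-cell noise
  h <- (window - 1L) %/% 2L
  n_fit <- length(fit)
  interior <- if (n_fit > 2L * h + 1L) seq(h + 1L, n_fit - h) else seq_len(n_fit)
  i_max <- interior[which.max(fit[interior])]
  flat <- diff(range(fit[interior])) < 1e-12
  boundary <- i_max == interior[1] || i_max == interior[length(interior)]
  peaked <- !flat && !boundary &&
    smoothed$emp[i_max] >= low && smoothed$emp[i_max] <= high
  list(cells = cells, smoothed = smoothed, positive_fraction = pos_frac,
       peaks_in_intermediate = peaked)
}

# centered running mean with symmetric truncation at the ends
running_mean <- function(x, window) {
  n <- length(x)
  h <- max(0L, (as.integer(window) - 1L) %/% 2L)
  cs <- cumsum(c(0, x))
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1L, n - i)
    (cs[i + k + 1] - cs[i - k]) / (2 * k + 1)
  }, numeric(1))
}
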
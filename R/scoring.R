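# Gene-set scoring with bin-matched control genes, the combined EMP score,
# three-state classification, state composition, and TF expression summaries.

#' Score cells for a gene signature with bin-matched controls
#'
#' For every signature gene present in the dataset, control genes are drawn
#' from the gene's expression-abundance bin (equal-frequency bins over gene
#' mean normalized expression). The per-cell score is the mean normalized
#' expression over signature genes minus the mean over the pooled control
#' genes, which centers scores near zero. When a bin holds no more than
#' `n_ctrl` genes the whole bin is used (the draw is then deterministic).
#'
#' @param dataset An `ExpressionDataset`.
#' @param signature Character vector of gene symbols.
#' @param n_bins Number of abundance bins (default 25; capped at the gene count).
#' @param n_ctrl Control genes drawn per signature gene (default 50).
#' @param seed Seed for the control draw.
#' @return Numeric per-cell score named by cell id. Signature genes absent
#'   from the dataset are dropped and reported via attribute `"dropped"`.
#' @export
score_gene_set <- function(dataset, signature, n_bins = 25L, n_ctrl = 50L, seed = 1L) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  signature <- unique(signature)
  present <- intersect(signature, colnames(dataset$normalized))
  if (length(present) == 0L) {
    stop("no signature gene present in the dataset", call. = FALSE)
  }
  expr <- dataset$normalized
  gene_means <- colMeans(expr)
  n_genes <- length(gene_means)
  n_bins <- max(1L, min(as.integer(n_bins), n_genes))
  # equal-frequency bins over mean expression
  rk <- rank(gene_means, ties.method = "first")
  bin <- ceiling(rk / (n_genes / n_bins))
  names(bin) <- names(gene_means)

  ctrl_pool <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      members <- names(bin)[bin == bin[[g]]]
      if (length(members) <= n_ctrl) members else sample(members, n_ctrl)
    }), use.names = FALSE)
  })
  score <- rowMeans(expr[, present, drop = FALSE]) -
    rowMeans(expr[, ctrl_pool, drop = FALSE])
  attr(score, "dropped") <- setdiff(signature, present)
  score
}

#' Compute the combined EMP score table
#'
#' EMP = mesenchymal score - epithelial score; positive values indicate a more
#' mesenchymal than epithelial transcriptional state. Cells are classified
#' into three states by [classify_state()].
#'
#' @param dataset An `ExpressionDataset`.
#' @param epi_signature,mes_signature Character vectors of epithelial and
#'   mesenchymal marker symbols.
#' @param low,high State thresholds (defaults -0.2 / 0.2).
#' @param n_bins,n_ctrl,seed Passed to [score_gene_set()].
#' @return `data.frame` (class `emp_score_table`) with columns `cell_id`,
#'   `epi_score`, `mes_score`, `emp`, `state`.
#' @export
compute_emp <- function(dataset, epi_signature, mes_signature,
                        low = -0.2, high = 0.2,
                        n_bins = 25L, n_ctrl = 50L, seed = 1L) {
  epi <- score_gene_set(dataset, epi_signature, n_bins, n_ctrl, seed)
  mes <- score_gene_set(dataset, mes_signature, n_bins, n_ctrl, seed)
  emp <- mes - epi
  out <- data.frame(cell_id = rownames(dataset$normalized),
                    epi_score = as.numeric(epi),
                    mes_score = as.numeric(mes),
                    emp = as.numeric(emp),
                    state = classify_state(emp, low, high),
                    stringsAsFactors = FALSE)
  class(out) <- c("emp_score_table", "data.frame")
  out
}

EMP_STATES <- c("epithelial-like", "intermediate", "mesenchymal-like")

#' Classify EMP scores into three states
#'
#' Epithelial-like below `low`, mesenchymal-like above `high`, intermediate in
#' the closed band `[low, high]` (boundary values are intermediate).
#'
#' @param emp Numeric EMP scores (finite).
#' @param low,high Band thresholds, `low < high`.
#' @return Character vector over `epithelial-like` / `intermediate` /
#'   `mesenchymal-like`.
#' @export
classify_state <- function(emp, low = -0.2, high = 0.2) {
  if (low >= high) stop("state thresholds require low < high", call. = FALSE)
  if (any(!is.finite(emp))) stop("EMP scores must be finite", call. = FALSE)
  ifelse(emp < low, EMP_STATES[1], ifelse(emp > high, EMP_STATES[3], EMP_STATES[2]))
}

#' EMP state composition per cell group
#'
#' @param score_table An `emp_score_table`.
#' @param cell_meta Cell annotation table with `cell_id`.
#' @param group_key Column of `cell_meta` to group by.
#' @return `data.frame` with one row per (group, state): counts and
#'   proportions summing to one within each group.
#' @export
state_composition <- function(score_table, cell_meta, group_key) {
  if (!group_key %in% names(cell_meta)) {
    stop(sprintf("unknown group key '%s'", group_key), call. = FALSE)
  }
  grp <- cell_meta[[group_key]][match(score_table$cell_id, cell_meta$cell_id)]
  if (any(is.na(grp))) stop("cells in score table missing from cell_meta", call. = FALSE)
  tab <- table(group = grp, state = factor(score_table$state, levels = EMP_STATES))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c(group_key, "state", "n")
  totals <- stats::ave(out$n, out[[group_key]], FUN = sum)
  out$prop <- ifelse(totals > 0, out$n / totals, NA_real_)
  out
}

#' Transcription-factor expression summaries by EMP state
#'
#' For each TF and EMP state: the fraction of cells with detected expression
#' (normalized > 0) and the mean normalized expression among those expressing
#' cells (NA when no cell expresses the TF in that state).
#'
#' @param dataset An `ExpressionDataset`.
#' @param tf_genes Character vector of TF symbols; absent genes are skipped
#'   and reported via attribute `"skipped"`.
#' @param score_table An `emp_score_table` over the same cells.
#' @return `data.frame` with columns `gene`, `state`, `n_cells`,
#'   `frac_expressing`, `mean_expressing`.
#' @export
tf_summary <- function(dataset, tf_genes, score_table) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  present <- intersect(unique(tf_genes), colnames(dataset$normalized))
  skipped <- setdiff(unique(tf_genes), present)
  state <- score_table$state[match(rownames(dataset$normalized), score_table$cell_id)]
  rows <- list()
  for (g in present) {
    v <- dataset$normalized[, g]
    for (st in EMP_STATES) {
      in_state <- !is.na(state) & state == st
      if (!any(in_state)) next
      vv <- v[in_state]
      expressing <- vv > 0
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, state = st, n_cells = sum(in_state),
        frac_expressing = mean(expressing),
        mean_expressing = if (any(expressing)) mean(vv[expressing]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), state = character(), n_cells = integer(),
               frac_expressing = numeric(), mean_expressing = numeric())
  attr(out, "skipped") <- skipped
  out
}
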
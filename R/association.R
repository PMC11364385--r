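# Cross-cutting association statistics: PCA of cells, EMP-vs-PC correlations,
# EMP vs metastatic potential, paired compartment/platform EMP correlations,
# and PC-axis separation between tissues.

#' Principal components of the normalized expression
#'
#' PCA of the centered normalized matrix restricted to the top
#' dispersion-ranked genes (variance / mean of normalized expression). A
#' deterministic sign convention makes repeated runs identical: the gene with
#' the largest absolute loading on each component gets a positive loading.
#'
#' @param dataset An `ExpressionDataset`.
#' @param n_components Number of components (default 5).
#' @param scope `"global"` (one PCA over all cells) or `"per_tumor"`
#'   (independent PCA within each tumor model; coordinates are then only
#'   comparable within a model).
#' @param n_top_genes Number of variable genes (default 2000, capped at the
#'   available non-constant genes).
#' @return List with `coords` (cells x PCs), `var_explained` (global scope
#'   only), `scope`.
#' @export
pca_cells <- function(dataset, n_components = 5L, scope = c("global", "per_tumor"),
                      n_top_genes = 2000L) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  scope <- match.arg(scope)
  if (scope == "global") {
    res <- pca_matrix(dataset$normalized, n_components, n_top_genes)
    return(list(coords = res$coords, var_explained = res$var_explained, scope = scope))
  }
  meta <- dataset$cell_meta
  coords <- matrix(NA_real_, nrow(dataset$normalized), n_components,
                   dimnames = list(rownames(dataset$normalized),
                                   paste0("PC", seq_len(n_components))))
  for (m in unique(meta$tumor_model)) {
    cells <- meta$cell_id[meta$tumor_model == m]
    if (length(cells) <= n_components) next
    res <- pca_matrix(dataset$normalized[cells, , drop = FALSE],
                      n_components, n_top_genes)
    coords[cells, ] <- res$coords
  }
  list(coords = coords, var_explained = NULL, scope = scope)
}

pca_matrix <- function(expr, n_components, n_top_genes) {
  if (nrow(expr) <= n_components) {
    stop("fewer cells than requested components", call. = FALSE)
  }
  v <- apply(expr, 2, stats::var)
  m <- colMeans(expr)
  keep <- v > 0
  if (sum(keep) < n_components) stop("not enough non-constant genes", call. = FALSE)
  disp <- ifelse(m[keep] > 0, v[keep] / m[keep], v[keep])
  top <- names(sort(disp, decreasing = TRUE))[seq_len(min(n_top_genes, sum(keep)))]
  pr <- stats::prcomp(expr[, top, drop = FALSE], center = TRUE, scale. = FALSE,
                      rank. = n_components)
  k <- ncol(pr$x)
  for (j in seq_len(k)) {
    lead <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[lead, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  colnames(pr$x) <- paste0("PC", seq_len(k))
  list(coords = pr$x,
       var_explained = pr$sdev[seq_len(k)]^2 / sum(pr$sdev^2))
}

#' Per-tumor correlation of the EMP score with principal components
#'
#' @param score_table An `emp_score_table`.
#' @param pc_coords Matrix of PC coordinates (cells x PCs; per-tumor scope is
#'   the intended input).
#' @param cell_meta Cell annotations with `cell_id` and the grouping column.
#' @param group_key Grouping column (default `"tumor_model"`).
#' @return `data.frame`: one row per (tumor, PC) with the Pearson `r`
#'   (NA when the EMP score is constant within a tumor); tumors with fewer
#'   than 3 cells are skipped.
#' @export
emp_pc_correlation <- function(score_table, pc_coords, cell_meta,
                               group_key = "tumor_model") {
  emp <- score_table$emp[match(rownames(pc_coords), score_table$cell_id)]
  grp <- cell_meta[[group_key]][match(rownames(pc_coords), cell_meta$cell_id)]
  rows <- list()
  for (m in unique(grp)) {
    sel <- which(grp == m & !is.na(emp) & !is.na(pc_coords[, 1]))
    if (length(sel) < 3L) next
    for (j in seq_len(ncol(pc_coords))) {
      e <- emp[sel]
      r <- if (stats::sd(e) == 0) NA_real_ else stats::cor(e, pc_coords[sel, j])
      rows[[length(rows) + 1L]] <- data.frame(
        tumor = m, pc = colnames(pc_coords)[j] %||% paste0("PC", j), r = r,
        n = length(sel), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Correlation of per-tumor mean EMP with metastatic potential
#'
#' Encodes the ordinal potential levels numerically (default low/moderate/
#' high -> 1/2/3) and reports the Pearson correlation over tumors (one point
#' per tumor).
#'
#' @param score_table An `emp_score_table`.
#' @param cell_meta Cell annotations (`cell_id`, `tumor_model`,
#'   `metastatic_potential`).
#' @param encoding Named numeric encoding of the levels.
#' @return List with `r`, `r_squared`, `per_tumor` (mean EMP and encoded
#'   potential per tumor).
#' @export
potential_correlation <- function(score_table, cell_meta,
                                  encoding = c(low = 1, moderate = 2, high = 3)) {
  meta <- cell_meta[match(score_table$cell_id, cell_meta$cell_id), , drop = FALSE]
  mean_emp <- tapply(score_table$emp, meta$tumor_model, mean)
  pot <- tapply(meta$metastatic_potential, meta$tumor_model, function(v) v[1])
  enc <- encoding[pot]
  if (any(is.na(enc))) {
    stop(sprintf("potential level(s) missing from encoding: %s",
                 paste(unique(pot[is.na(enc)]), collapse = ", ")), call. = FALSE)
  }
  if (length(unique(enc)) < 2L) stop("all tumors share one potential level", call. = FALSE)
  if (length(mean_emp) < 3L) stop("need >= 3 tumors", call. = FALSE)
  r <- stats::cor(as.numeric(mean_emp), as.numeric(enc))
  list(r = r, r_squared = r^2,
       per_tumor = data.frame(tumor = names(mean_emp),
                              mean_emp = as.numeric(mean_emp),
                              potential = as.character(pot),
                              encoded = as.numeric(enc),
                              stringsAsFactors = FALSE))
}

#' Paired per-model EMP correlation between two compartments
#'
#' One point per tumor model: the mean EMP score in each of the two levels of
#' `pair_key` (e.g. primary vs metastasis tissue, or plate vs droplet
#' platform). Reports Pearson r, R-squared, and the least-squares line with
#' 95% confidence intervals.
#'
#' @param score_table An `emp_score_table`.
#' @param cell_meta Cell annotations.
#' @param pair_key Column with exactly two levels pairing the compartments.
#' @return List with `pairs` (per-model means), `r`, `r_squared`, `slope`,
#'   `intercept`, `conf_int` (95% CI on slope and intercept).
#' @export
paired_emp_correlation <- function(score_table, cell_meta, pair_key = "tissue") {
  meta <- cell_meta[match(score_table$cell_id, cell_meta$cell_id), , drop = FALSE]
  levels_ <- sort(unique(meta[[pair_key]]))
  if (length(levels_) != 2L) {
    stop(sprintf("pair key '%s' must have exactly 2 levels", pair_key), call. = FALSE)
  }
  key <- interaction(meta$tumor_model, meta[[pair_key]], drop = TRUE)
  means <- tapply(score_table$emp, key, mean)
  models <- unique(meta$tumor_model)
  x <- means[paste(models, levels_[1], sep = ".")]
  y <- means[paste(models, levels_[2], sep = ".")]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  r <- stats::cor(x, y)
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit)
  list(pairs = data.frame(model = models[ok], x = x, y = y,
                          stringsAsFactors = FALSE),
       levels = levels_, r = r, r_squared = r^2,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       conf_int = ci)
}

#' Separation of two cell groups along a principal component
#'
#' @param pc_coords Matrix of PC coordinates.
#' @param cell_meta Cell annotations.
#' @param axis Component index (default 2).
#' @param group_key Two-level grouping column (default `"tissue"`).
#' @return List with `summaries` (per-group n/mean/median along the axis) and
#'   `p` (two-sided Wilcoxon on the coordinates).
#' @export
pc_separation <- function(pc_coords, cell_meta, axis = 2L, group_key = "tissue") {
  if (axis > ncol(pc_coords)) {
    stop(sprintf("axis %d beyond the %d computed PCs", axis, ncol(pc_coords)),
         call. = FALSE)
  }
  grp <- cell_meta[[group_key]][match(rownames(pc_coords), cell_meta$cell_id)]
  v <- pc_coords[, axis]
  ok <- !is.na(v) & !is.na(grp)
  v <- v[ok]; grp <- grp[ok]
  levels_ <- unique(grp)
  if (length(levels_) != 2L || any(table(grp) == 0L)) {
    stop("need exactly 2 non-empty groups", call. = FALSE)
  }
  summaries <- do.call(rbind, lapply(levels_, function(l) {
    data.frame(group = l, n = sum(grp == l), mean = mean(v[grp == l]),
               median = stats::median(v[grp == l]), stringsAsFactors = FALSE)
  }))
  list(summaries = summaries,
       p = wilcoxon_test(v[grp == levels_[1]], v[grp == levels_[2]]))
}
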
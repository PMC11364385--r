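# Expression-based relative copy-number profiles: genomic ordering, reference
# centering, clipping, chromosome-bounded moving-average smoothing, and
# primary-vs-metastasis profile correlation.

#' Infer windowed CNV profiles from expression
#'
#' Steps: (1) center each gene's normalized expression by the reference mean
#' (all cells by default; tumor-only data has no normal reference); (2) clip
#' to `+/- clip`; (3) moving average of length `window` along each chromosome
#' in genomic order, with the window truncated symmetrically at chromosome
#' ends so smoothing never crosses a chromosome boundary; (4) median-center
#' each cell's profile. Genes without coordinates are dropped and reported.
#'
#' @param dataset An `ExpressionDataset` whose `gene_meta` carries
#'   `chromosome` and `start`.
#' @param window Odd moving-average window (genes; default 101).
#' @param clip Symmetric clipping bound on centered expression (default 3).
#' @param reference Optional named per-gene reference means; default is the
#'   mean over all cells.
#' @return Object of class `cnv_profile`: `profile` (cells x ordered genes),
#'   `gene_meta` (ordered), `dropped` (genes without coordinates).
#' @export
infer_profiles <- function(dataset, window = 101L, clip = 3.0, reference = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  assert_scalar_number(clip, "clip", lower = 1e-8)
  gm <- dataset$gene_meta
  mappable <- !is.na(gm$start) & gm$chromosome != SENTINEL
  if (!any(mappable)) stop("no gene has genomic coordinates", call. = FALSE)
  dropped <- gm$symbol[!mappable]
  gm <- gm[mappable, , drop = FALSE]
  ord <- chromosome_order(gm$chromosome)
  gm <- gm[ord, , drop = FALSE]
  within <- order(match(gm$chromosome, unique(gm$chromosome)), gm$start)
  gm <- gm[within, , drop = FALSE]

  expr <- dataset$normalized[, gm$symbol, drop = FALSE]
  ref <- if (is.null(reference)) colMeans(expr) else {
    if (!all(gm$symbol %in% names(reference))) {
      stop("reference must cover every mappable gene", call. = FALSE)
    }
    reference[gm$symbol]
  }
  centered <- sweep(expr, 2, ref)
  centered[centered > clip] <- clip
  centered[centered < -clip] <- -clip

  smoothed <- centered
  h <- (window - 1L) %/% 2L
  for (chr in unique(gm$chromosome)) {
    cols <- which(gm$chromosome == chr)
    block <- centered[, cols, drop = FALSE]
    sm <- t(apply(block, 1, running_mean, window = window))
    if (length(cols) == 1L) sm <- matrix(block, ncol = 1L)
    smoothed[, cols] <- sm
  }
  smoothed <- smoothed - apply(smoothed, 1, stats::median)

  structure(list(profile = smoothed, gene_meta = gm, dropped = dropped,
                 window = window, clip = clip),
            class = "cnv_profile")
}

#' Correlate CNV profiles between tissue compartments per model
#'
#' Pseudobulks the smoothed profile (mean over cells) per model and tissue,
#' then reports the Pearson correlation and its square between the primary
#' and metastasis profiles of each model. Models lacking either compartment
#' are skipped and reported.
#'
#' @param profile A `cnv_profile`.
#' @param cell_meta Cell annotations with `cell_id` plus the grouping columns.
#' @param model_key,tissue_key Column names (defaults `tumor_model`,
#'   `tissue`).
#' @return `data.frame` with `model`, `r`, `r_squared`, `n_primary`,
#'   `n_metastasis`; skipped models via attribute `"skipped"`.
#' @export
compare_compartments <- function(profile, cell_meta, model_key = "tumor_model",
                                 tissue_key = "tissue") {
  stopifnot(inherits(profile, "cnv_profile"))
  meta <- cell_meta[match(rownames(profile$profile), cell_meta$cell_id), , drop = FALSE]
  rows <- list(); skipped <- character(0)
  for (m in unique(meta[[model_key]])) {
    sel <- meta[[model_key]] == m
    pri <- sel & meta[[tissue_key]] == "primary"
    met <- sel & meta[[tissue_key]] == "metastasis"
    if (!any(pri) || !any(met)) { skipped <- c(skipped, m); next }
    v1 <- colMeans(profile$profile[pri, , drop = FALSE])
    v2 <- colMeans(profile$profile[met, , drop = FALSE])
    r <- stats::cor(v1, v2)
    rows[[length(rows) + 1L]] <- data.frame(
      model = m, r = r, r_squared = r^2,
      n_primary = sum(pri), n_metastasis = sum(met), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(model = character(), r = numeric(), r_squared = numeric(),
               n_primary = integer(), n_metastasis = integer())
  attr(out, "skipped") <- skipped
  out
}
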
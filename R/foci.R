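# Histology-derived metastasis quantification: foci size classes, burden
# summaries, and the low/moderate/high metastatic-potential call.

FOCUS_CLASSES <- c("micro", "intermediate", "macro")

#' Classify a metastatic focus by cell count
#'
#' Micrometastasis below 10 cells, intermediate focus at 10-100 cells
#' (inclusive), macrometastasis above 100 cells.
#'
#' @param cell_count Integer cell count(s), >= 1.
#' @return Character vector over `micro` / `intermediate` / `macro`.
#' @export
classify_focus <- function(cell_count) {
  if (any(cell_count < 1)) stop("focus cell count must be >= 1", call. = FALSE)
  ifelse(cell_count < 10, "micro", ifelse(cell_count <= 100, "intermediate", "macro"))
}

#' Summarize metastatic foci in a tissue section
#'
#' @param foci `data.frame` with columns `cell_count` and `area` (mm^2); may
#'   have zero rows.
#' @param tissue_area Total tissue area in mm^2 (> 0).
#' @return List (class `foci_summary`): `n_foci`, `class_counts`,
#'   `foci_per_mm2`, `burden` (total focus area / tissue area),
#'   `tissue_area`.
#' @export
summarize_foci <- function(foci, tissue_area) {
  assert_scalar_number(tissue_area, "tissue_area", lower = 1e-12)
  if (nrow(foci) > 0 && sum(foci$area) > tissue_area) {
    stop("total focus area exceeds tissue area", call. = FALSE)
  }
  classes <- if (nrow(foci) > 0) classify_focus(foci$cell_count) else character(0)
  counts <- table(factor(classes, levels = FOCUS_CLASSES))
  structure(list(
    n_foci = nrow(foci),
    class_counts = counts,
    foci_per_mm2 = nrow(foci) / tissue_area,
    burden = if (nrow(foci) > 0) sum(foci$area) / tissue_area else 0,
    tissue_area = tissue_area
  ), class = "foci_summary")
}

#' Call the metastatic potential of a model from its foci summary
#'
#' Explicit, configurable thresholds standing in for the qualitative
#' histology judgment: `low` when the foci density is below `tau_low` and no
#' macrometastasis is present; `high` when at least `kappa_macro`
#' macrometastases are present or the density reaches `tau_high`; `moderate`
#' otherwise. The rule that fired is reported.
#'
#' @param summary A `foci_summary`.
#' @param tau_low Density (foci/mm^2) below which a macro-free section is
#'   `low` (default 0.05).
#' @param tau_high Density at or above which the call is `high` (default 0.5).
#' @param kappa_macro Macro count at or above which the call is `high`
#'   (default 3).
#' @return List with `call` (`low`/`moderate`/`high`) and `rule`.
#' @export
call_potential <- function(summary, tau_low = 0.05, tau_high = 0.5, kappa_macro = 3L) {
  stopifnot(inherits(summary, "foci_summary"))
  n_macro <- as.integer(summary$class_counts["macro"])
  dens <- summary$foci_per_mm2
  if (n_macro >= kappa_macro || dens >= tau_high) {
    return(list(call = "high",
                rule = if (n_macro >= kappa_macro) "macro_count" else "density_high"))
  }
  if (dens < tau_low && n_macro == 0L) {
    return(list(call = "low", rule = "low_density_no_macro"))
  }
  list(call = "moderate", rule = "residual")
}
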
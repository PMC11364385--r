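# Preranked gene-set enrichment: weighted Kolmogorov-Smirnov enrichment score
# with a size-matched random-set permutation null, sign-aware NES and FDR.

#' Weighted KS enrichment score of a gene set on a ranking
#'
#' Walking down the ranking, hits increment the running sum proportionally to
#' `|stat|^weight` (normalized over hits) and misses decrement it by
#' `1 / (N - N_hits)`. The enrichment score is the maximum deviation from
#' zero; the leading edge contains the hits up to (or from, for negative ES)
#' the extremum.
#'
#' @param ranked_genes Character vector of unique gene symbols, best first.
#' @param ranking_stat Numeric statistic aligned with `ranked_genes`.
#' @param gene_set Character vector of gene symbols.
#' @param weight Exponent on `|stat|` (0 gives the classic KS statistic).
#' @return List with `es`, `running` (the running sum), `leading_edge`.
#' @export
enrichment_score <- function(ranked_genes, ranking_stat, gene_set, weight = 1) {
  if (anyDuplicated(ranked_genes)) stop("ranking has duplicate genes", call. = FALSE)
  hits <- ranked_genes %in% gene_set
  n <- length(ranked_genes)
  n_hits <- sum(hits)
  if (n_hits == 0L) stop("gene set does not intersect the ranking", call. = FALSE)
  if (n_hits == n) stop("gene set covers the whole ranking (degenerate)", call. = FALSE)
  w <- abs(ranking_stat)^weight
  w_hit <- w * hits
  sw <- sum(w_hit)
  inc <- if (sw > 0) w_hit / sw else hits / n_hits
  running <- cumsum(ifelse(hits, inc, -1 / (n - n_hits)))
  i_max <- which.max(abs(running))
  es <- running[i_max]
  leading_edge <- if (es >= 0) {
    ranked_genes[seq_len(i_max)][hits[seq_len(i_max)]]
  } else {
    ranked_genes[i_max:n][hits[i_max:n]]
  }
  list(es = es, running = running, leading_edge = leading_edge)
}

#' Preranked GSEA over a collection of gene sets
#'
#' The null distribution for each set is generated by drawing size-matched
#' random gene sets from the ranking (`n_perm` draws). NES is the observed ES
#' divided by the mean |null ES| of matching sign; the p-value uses the
#' standard +1 correction `(1 + #extreme) / (1 + n_perm)` counting same-sign
#' nulls at least as extreme; FDR follows the sign-stratified null-NES method.
#'
#' @param ranking `data.frame` with columns `gene`, `stat` (best first) as
#'   produced by [rank_from_de()].
#' @param gene_sets Named list of character vectors.
#' @param n_perm Number of permutations (>= 100).
#' @param weight Enrichment weight.
#' @param seed Seed for the permutation draw.
#' @param min_size Minimum set size after intersection with the ranking; sets
#'   below are skipped and reported via attribute `"skipped"`.
#' @return `data.frame` (class `gsea_result`) with `set`, `size`, `es`,
#'   `nes`, `p`, `fdr`, `leading_edge` (comma-separated).
#' @export
preranked_gsea <- function(ranking, gene_sets, n_perm = 1000L, weight = 1,
                           seed = 1L, min_size = 5L) {
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  genes <- ranking$gene
  stat <- ranking$stat
  n <- length(genes)
  keep <- vapply(gene_sets, function(s) sum(genes %in% s), integer(1))
  skipped <- names(gene_sets)[keep < min_size | keep >= n]
  sets <- gene_sets[setdiff(names(gene_sets), skipped)]
  if (length(sets) == 0L) stop("no gene set of sufficient size", call. = FALSE)

  obs <- lapply(sets, function(s) enrichment_score(genes, stat, s, weight))
  es_obs <- vapply(obs, `[[`, numeric(1), "es")
  sizes <- vapply(sets, function(s) sum(genes %in% s), integer(1))

  null_by_size <- with_seed(seed, {
    out <- list()
    for (sz in unique(sizes)) {
      out[[as.character(sz)]] <- vapply(seq_len(n_perm), function(b) {
        es_from_indices(sample.int(n, sz), stat, n, weight)
      }, numeric(1))
    }
    out
  })

  nes <- p <- numeric(length(sets))
  for (i in seq_along(sets)) {
    null_es <- null_by_size[[as.character(sizes[i])]]
    same <- if (es_obs[i] >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    denom <- mean(abs(same))
    nes[i] <- if (is.finite(denom) && denom > 0) es_obs[i] / denom else NA_real_
    extreme <- sum(abs(same) >= abs(es_obs[i]))
    p[i] <- (1 + extreme) / (1 + n_perm)
  }

  # sign-stratified FDR on NES
  null_nes <- unlist(lapply(seq_along(sets), function(i) {
    null_es <- null_by_size[[as.character(sizes[i])]]
    pos <- null_es[null_es >= 0]; neg <- null_es[null_es < 0]
    c(if (length(pos)) pos / mean(pos) else numeric(0),
      if (length(neg)) -neg / mean(-neg) * -1 else numeric(0))
  }), use.names = FALSE)
  fdr <- vapply(seq_along(sets), function(i) {
    if (!is.finite(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num <- mean(null_nes[null_nes >= 0] >= nes[i])
      den <- mean(nes[nes >= 0 & is.finite(nes)] >= nes[i])
    } else {
      num <- mean(null_nes[null_nes < 0] <= nes[i])
      den <- mean(nes[nes < 0 & is.finite(nes)] <= nes[i])
    }
    if (!is.finite(den) || den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))

  out <- data.frame(
    set = names(sets), size = sizes, es = es_obs, nes = nes, p = p, fdr = fdr,
    leading_edge = vapply(obs, function(o) paste(o$leading_edge, collapse = ","),
                          character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "skipped") <- skipped
  class(out) <- c("gsea_result", "data.frame")
  out
}

# ES from hit positions only (O(n_hits)); equals the running-sum definition.
es_from_indices <- function(idx, stat, n, weight) {
  idx <- sort(idx)
  nh <- length(idx)
  w <- abs(stat[idx])^weight
  sw <- sum(w)
  gains <- if (sw > 0) cumsum(w) / sw else seq_len(nh) / nh
  miss_step <- 1 / (n - nh)
  # running sum immediately after each hit, and immediately before each hit
  after <- gains - (idx - seq_len(nh)) * miss_step
  before <- c(0, gains[-nh]) - (idx - seq_len(nh)) * miss_step
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Ranking from a DE result
#'
#' @param de A `de_result`.
#' @param stat `"log2fc"` (default) or `"signed_logp"`
#'   (`sign(log2fc) * -log10(p_hurdle)`).
#' @return `data.frame` with `gene`, `stat`, sorted descending; ties broken
#'   by gene symbol for determinism.
#' @export
rank_from_de <- function(de, stat = c("log2fc", "signed_logp")) {
  stat <- match.arg(stat)
  if (nrow(de) == 0L) stop("empty DE table", call. = FALSE)
  s <- switch(stat,
              log2fc = de$log2fc,
              signed_logp = sign(de$log2fc) * -log10(pmax(de$p_hurdle, 1e-300)))
  if (any(!is.finite(s))) stop("non-finite ranking statistic", call. = FALSE)
  ord <- order(-s, de$gene)
  data.frame(gene = de$gene[ord], stat = s[ord], stringsAsFactors = FALSE)
}
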
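# Seeded synthetic data: a multi-tumor, two-platform single-cell panel with a
# latent EMP axis and planted ground truth (tissue DE genes, intermediate-state
# markers, CNV segments), plus survival cohorts and histology foci draws.

#' Configuration for the synthetic tumor panel
#'
#' Defaults emulate a scaled-down panel of patient-derived xenograft models
#' profiled with a deep plate-based and a shallow droplet-based protocol:
#' ten tumor models split 4/3/3 across low/moderate/high metastatic potential,
#' a per-cell latent EMP axis `t in [0,1]` whose Beta law skews toward the
#' epithelial end for low-potential models and the mesenchymal end for
#' high-potential models, monotone epithelial/mesenchymal gene programs,
#' intermediate markers peaking at `t = 0.5`, planted primary-vs-metastasis
#' DE genes, and per-model CNV segments shared by both tissues.
#'
#' Program slopes are calibrated so that, after bin-matched control scoring,
#' the combined EMP score crosses +/-0.2 near `t = 0.35` and `t = 0.65`; the
#' intermediate-marker bump width (`intermediate_sigma = 0.15`) then roughly
#' matches the scored intermediate band.
#'
#' @param n_models Number of tumor models.
#' @param potential_counts Named integer vector: models per metastatic
#'   potential class (must sum to `n_models`).
#' @param cells_per_model_per_tissue Cells per model per tissue per platform.
#' @param n_genes Total genes.
#' @param n_epithelial,n_mesenchymal,n_intermediate,n_tissue_de Sizes of the
#'   planted gene blocks (remaining genes are background).
#' @param cnv_segment_genes Genes per planted CNV segment (one segment per model).
#' @param cnv_fold_changes Candidate segment fold changes (> 0).
#' @param beta_params Named list of `c(a, b)` Beta parameters per potential.
#' @param tissue_log2fc Planted metastasis-vs-primary log2 effect.
#' @param nb_dispersion Negative-binomial dispersion (variance = mu + dispersion * mu^2).
#' @param intermediate_sigma Width of the Gaussian bump at `t = 0.5`.
#' @param model_offset_sdlog Log-sd of per-model lognormal gene offsets
#'   (inter-model heterogeneity / batch structure).
#' @param platforms List of per-platform profiles: `lib_mean`, `lib_sdlog`,
#'   `dropout` (extra zero-inflation probability).
#' @param n_chromosomes Chromosomes in the synthetic genome.
#' @param seed Mandatory integer seed; all simulation is seeded by contract.
#' @return A validated `panel_config` list.
#' @export
panel_config <- function(n_models = 10L,
                         potential_counts = c(low = 4L, moderate = 3L, high = 3L),
                         cells_per_model_per_tissue = 50L,
                         n_genes = 500L,
                         n_epithelial = 75L,
                         n_mesenchymal = 75L,
                         n_intermediate = 30L,
                         n_tissue_de = 40L,
                         cnv_segment_genes = 60L,
                         cnv_fold_changes = c(0.5, 2),
                         beta_params = list(low = c(2, 5), moderate = c(3.5, 3.5),
                                            high = c(5, 2)),
                         tissue_log2fc = 1.0,
                         nb_dispersion = 0.4,
                         intermediate_sigma = 0.15,
                         model_offset_sdlog = 0.25,
                         platforms = list(
                           plate = list(lib_mean = 2e4, lib_sdlog = 0.3, dropout = 0),
                           droplet = list(lib_mean = 5e3, lib_sdlog = 0.3, dropout = 0.15)),
                         n_chromosomes = 5L,
                         seed = NULL) {
  if (is.null(seed)) stop("panel_config requires a `seed`; all simulation is seeded", call. = FALSE)
  cfg <- as.list(environment())
  if (sum(potential_counts) != n_models) {
    stop("potential_counts must sum to n_models", call. = FALSE)
  }
  if (!all(names(potential_counts) %in% names(beta_params))) {
    stop("beta_params must cover every potential class", call. = FALSE)
  }
  blocks <- n_epithelial + n_mesenchymal + n_intermediate + n_tissue_de
  if (blocks > n_genes) stop("gene block sizes exceed n_genes", call. = FALSE)
  if (cnv_segment_genes > n_genes %/% n_chromosomes) {
    stop("cnv_segment_genes larger than a chromosome", call. = FALSE)
  }
  assert_scalar_number(nb_dispersion, "nb_dispersion", lower = 1e-8)
  assert_scalar_number(intermediate_sigma, "intermediate_sigma", lower = 1e-4)
  if (any(cnv_fold_changes <= 0)) stop("cnv fold changes must be > 0", call. = FALSE)
  for (p in cfg$platforms) {
    if (p$dropout < 0 || p$dropout > 1) stop("dropout must be in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "panel_config")
}

#' Simulate the multi-tumor two-platform panel
#'
#' For cell `i` of model `m`, the latent EMP coordinate is
#' `t_i ~ Beta(a_m, b_m)` with `(a_m, b_m)` set by the model's metastatic
#' potential. Gene-wise mean expression multiplies a lognormal baseline by a
#' program factor: epithelial genes decrease in `t`, mesenchymal genes
#' increase, intermediate markers follow a Gaussian bump at `t = 0.5`, and
#' background genes are flat. Planted tissue DE genes gain `2^(+/-log2fc)` in
#' metastatic cells; CNV-segment genes gain the segment fold in that model's
#' cells (both tissues); per-model lognormal offsets add inter-model
#' heterogeneity. Counts are negative binomial on platform-specific library
#' sizes; droplet cells receive extra dropout zeros. The same ground truth
#' drives both platform renderings.
#'
#' @param config A [panel_config()].
#' @return List with `dataset` (an `ExpressionDataset` holding both platforms)
#'   and `truth` (class `synthetic_truth`): `latent_t` (named per cell),
#'   `de_effects` (named signed log2 effects), `intermediate_markers`,
#'   `epithelial_genes`, `mesenchymal_genes`, `cnv_segments` (per-model
#'   chromosome/index-range/fold), and the block assignment.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  with_seed(config$seed, simulate_panel_impl(config))
}

simulate_panel_impl <- function(cfg) {
  G <- cfg$n_genes
  symbols <- sprintf("G%04d", seq_len(G))
  per_chr <- ceiling(G / cfg$n_chromosomes)
  chrom <- as.character(rep(seq_len(cfg$n_chromosomes), each = per_chr, length.out = G))
  start <- unlist(lapply(split(seq_len(G), chrom), seq_along), use.names = FALSE)
  start <- integer(G)
  for (c in unique(chrom)) start[chrom == c] <- seq_len(sum(chrom == c)) * 100000L
  gene_meta <- data.frame(symbol = symbols, chromosome = chrom, start = start,
                          stringsAsFactors = FALSE)

  # scatter the planted blocks across the genome
  idx <- sample.int(G)
  n_e <- cfg$n_epithelial; n_m <- cfg$n_mesenchymal
  n_i <- cfg$n_intermediate; n_d <- cfg$n_tissue_de
  epi <- sort(idx[seq_len(n_e)])
  mes <- sort(idx[n_e + seq_len(n_m)])
  int <- sort(idx[n_e + n_m + seq_len(n_i)])
  de  <- sort(idx[n_e + n_m + n_i + seq_len(n_d)])
  de_sign <- rep(c(1, -1), length.out = n_d)
  de_effects <- stats::setNames(de_sign * cfg$tissue_log2fc, symbols[de])

  base <- stats::rlnorm(G, meanlog = 0, sdlog = 0.5)

  models <- sprintf("M%02d", seq_len(cfg$n_models))
  potential <- rep(names(cfg$potential_counts), times = cfg$potential_counts)

  offsets <- vapply(models, function(m) stats::rlnorm(G, 0, cfg$model_offset_sdlog),
                    numeric(G))

  cnv_segments <- list()
  for (mi in seq_along(models)) {
    ch <- as.character(sample.int(cfg$n_chromosomes, 1))
    on_chr <- which(chrom == ch)
    max_start <- length(on_chr) - cfg$cnv_segment_genes + 1L
    s <- sample.int(max_start, 1)
    genes_in <- on_chr[s:(s + cfg$cnv_segment_genes - 1L)]
    fold <- sample(cfg$cnv_fold_changes, 1)
    cnv_segments[[models[mi]]] <- list(chromosome = ch, gene_index = genes_in,
                                       genes = symbols[genes_in], fold = fold)
  }

  sig2 <- 2 * cfg$intermediate_sigma^2
  n_per <- cfg$cells_per_model_per_tissue
  cell_rows <- list()
  count_rows <- list()
  latent <- numeric(0)
  cell_counter <- 0L

  for (pf in names(cfg$platforms)) {
    prof <- cfg$platforms[[pf]]
    for (mi in seq_along(models)) {
      m <- models[mi]
      ab <- cfg$beta_params[[potential[mi]]]
      for (ts in c("primary", "metastasis")) {
        t_i <- stats::rbeta(n_per, ab[1], ab[2])
        ids <- sprintf("%s_%s_%s_%04d", pf, m, substr(ts, 1, 3),
                       cell_counter + seq_len(n_per))
        cell_counter <- cell_counter + n_per
        lib <- stats::rlnorm(n_per, meanlog = log(prof$lib_mean), sdlog = prof$lib_sdlog)

        # program factors: cells x genes
        fac <- matrix(1, n_per, G)
        fac[, epi] <- 1.3 - 0.6 * t_i
        fac[, mes] <- 0.7 + 0.6 * t_i
        fac[, int] <- 0.2 + 5.8 * exp(-(t_i - 0.5)^2 / sig2)
        if (ts == "metastasis") {
          fac[, de] <- fac[, de] * matrix(2^(de_sign * cfg$tissue_log2fc),
                                          n_per, n_d, byrow = TRUE)
        }
        seg <- cnv_segments[[m]]
        fac[, seg$gene_index] <- fac[, seg$gene_index] * seg$fold

        mu <- fac * matrix(base * offsets[, mi], n_per, G, byrow = TRUE)
        mu <- mu / rowSums(mu) * lib
        cnt <- matrix(stats::rnbinom(n_per * G, mu = as.vector(mu),
                                     size = 1 / cfg$nb_dispersion), n_per, G)
        if (prof$dropout > 0) {
          keep <- matrix(stats::rbinom(n_per * G, 1, 1 - prof$dropout), n_per, G)
          cnt <- cnt * keep
        }
        rownames(cnt) <- ids
        count_rows[[length(count_rows) + 1L]] <- cnt
        cell_rows[[length(cell_rows) + 1L]] <- data.frame(
          cell_id = ids, tumor_model = m, tissue = ts, platform = pf,
          metastatic_potential = potential[mi], stringsAsFactors = FALSE)
        latent <- c(latent, stats::setNames(t_i, ids))
      }
    }
  }

  counts <- do.call(rbind, count_rows)
  cell_meta <- do.call(rbind, cell_rows)
  # guard against empty cells (possible at extreme dropout): give one count
  zero_cells <- rowSums(counts) == 0
  if (any(zero_cells)) counts[zero_cells, 1] <- 1

  dataset <- expression_dataset(counts, cell_meta, gene_meta)
  truth <- structure(list(
    latent_t = latent,
    de_effects = de_effects,
    intermediate_markers = symbols[int],
    epithelial_genes = symbols[epi],
    mesenchymal_genes = symbols[mes],
    background_genes = symbols[-c(epi, mes, int, de)],
    cnv_segments = cnv_segments,
    potential = stats::setNames(potential, models),
    config = cfg
  ), class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}

#' Simulate a survival cohort with a signature-linked hazard
#'
#' Each patient carries a latent score `s ~ Normal(0, 1)` expressed on the
#' signature genes (`expr = s + noise`); event times are exponential with
#' rate `lambda0 * exp(hazard_beta * s)`; censoring is independent uniform on
#' `[0, c_max]` with `c_max` calibrated so the expected censoring fraction at
#' `hazard_beta = 0` equals `censor_rate`.
#'
#' @param n_patients Number of patients (>= 2).
#' @param hazard_beta Log-hazard coefficient of the latent score.
#' @param signature_genes Character vector of signature gene names.
#' @param censor_rate Expected censoring fraction in `[0, 1)`; 0 disables
#'   censoring.
#' @param seed Integer seed.
#' @param n_noise_genes Unlinked genes added to the expression table.
#' @param baseline_hazard Baseline exponential rate (default: median survival
#'   24 months).
#' @param subtype_probs Named multinomial probabilities for subtype labels.
#' @return List with `cohort` (data.frame: `time`, `event`, `subtype`, one
#'   column per gene) and `truth` (latent scores and `hazard_beta`).
#' @export
simulate_survival <- function(n_patients, hazard_beta, signature_genes,
                              censor_rate = 0.3, seed = NULL,
                              n_noise_genes = 20L,
                              baseline_hazard = log(2) / 24,
                              subtype_probs = c(LumA = 0.35, LumB = 0.2,
                                                Her2 = 0.15, Basal = 0.3)) {
  if (n_patients < 2) stop("n_patients must be >= 2", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("censor_rate must be in [0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    s <- stats::rnorm(n_patients)
    expr <- vapply(signature_genes, function(g) s + stats::rnorm(n_patients, sd = 0.5),
                   numeric(n_patients))
    noise <- vapply(seq_len(n_noise_genes), function(k) stats::rnorm(n_patients),
                    numeric(n_patients))
    colnames(noise) <- sprintf("NOISE%03d", seq_len(n_noise_genes))
    t_event <- stats::rexp(n_patients, rate = baseline_hazard * exp(hazard_beta * s))
    if (censor_rate > 0) {
      cmax <- uniform_censor_bound(baseline_hazard, censor_rate)
      c_time <- stats::runif(n_patients, 0, cmax)
      time <- pmin(t_event, c_time)
      event <- as.integer(t_event <= c_time)
    } else {
      time <- t_event
      event <- rep(1L, n_patients)
    }
    subtype <- sample(names(subtype_probs), n_patients, replace = TRUE,
                      prob = subtype_probs)
    cohort <- data.frame(time = time, event = event, subtype = subtype,
                         stringsAsFactors = FALSE)
    cohort <- cbind(cohort, as.data.frame(expr), as.data.frame(noise))
    truth <- structure(list(score = s, hazard_beta = hazard_beta,
                            signature_genes = signature_genes),
                       class = "synthetic_truth")
    list(cohort = validate_cohort(cohort), truth = truth)
  })
}

# P(C < T) for T ~ Exp(lambda), C ~ U(0, c) is (1 - exp(-lambda c)) / (lambda c),
# decreasing in c from 1 to 0.
uniform_censor_bound <- function(lambda, rate) {
  f <- function(c) (1 - exp(-lambda * c)) / (lambda * c) - rate
  stats::uniroot(f, c(1e-8, 1e8), tol = 1e-10)$root
}

#' Simulate metastatic foci sizes
#'
#' Draws focus cell counts from a discrete size distribution for use by the
#' histology quantification rules; focus areas are proportional to cell count.
#'
#' @param n_foci Number of foci.
#' @param size_distribution `data.frame` with columns `size` (cells, >= 1) and
#'   `prob`, or a numeric vector of sizes sampled uniformly.
#' @param seed Integer seed.
#' @param area_per_cell Area per tumor cell in mm^2.
#' @param tissue_area Total tissue area in mm^2.
#' @return List with `foci` (data.frame `cell_count`, `area`) and `tissue_area`.
#' @export
simulate_foci <- function(n_foci, size_distribution, seed = NULL,
                          area_per_cell = 5e-4, tissue_area = 50) {
  if (is.numeric(size_distribution)) {
    size_distribution <- data.frame(size = size_distribution,
                                    prob = rep(1 / length(size_distribution),
                                               length(size_distribution)))
  }
  if (any(size_distribution$size < 1)) stop("focus sizes must be >= 1", call. = FALSE)
  if (any(size_distribution$prob < 0)) stop("probabilities must be >= 0", call. = FALSE)
  with_seed(seed, {
    sizes <- if (n_foci > 0) {
      idx <- sample.int(nrow(size_distribution), n_foci, replace = TRUE,
                        prob = size_distribution$prob)
      size_distribution$size[idx]
    } else numeric(0)
    list(foci = data.frame(cell_count = as.integer(round(sizes)),
                           area = sizes * area_per_cell),
         tissue_area = tissue_area)
  })
}
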
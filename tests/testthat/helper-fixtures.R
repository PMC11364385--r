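# Shared fixtures, built in code. Heavy objects are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A tiny deterministic dataset: counts chosen by hand.
tiny_dataset <- function() {
  counts <- matrix(c(4, 0, 1, 0,
                     0, 1, 2, 3,
                     5, 2, 0, 1),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
  cell_meta <- data.frame(cell_id = paste0("c", 1:3),
                          tumor_model = c("A", "A", "B"),
                          tissue = c("primary", "metastasis", "primary"),
                          stringsAsFactors = FALSE)
  gene_meta <- data.frame(symbol = paste0("g", 1:4),
                          chromosome = c("1", "1", "2", "2"),
                          start = c(100L, 200L, 100L, 200L),
                          stringsAsFactors = FALSE)
  expression_dataset(counts, cell_meta, gene_meta)
}

# Default study-condition panel, shared by recovery tests.
default_panel <- function() {
  cached("default_panel", simulate_panel(panel_config(seed = 42)))
}

default_scores <- function() {
  cached("default_scores", {
    sim <- default_panel()
    compute_emp(sim$dataset, sim$truth$epithelial_genes,
                sim$truth$mesenchymal_genes, seed = 7)
  })
}

# A small panel for cheaper unit-level recovery checks.
small_panel <- function() {
  cached("small_panel", simulate_panel(panel_config(
    n_models = 4L, potential_counts = c(low = 2L, moderate = 1L, high = 1L),
    cells_per_model_per_tissue = 30L, n_genes = 200L,
    n_epithelial = 30L, n_mesenchymal = 30L, n_intermediate = 15L,
    n_tissue_de = 15L, cnv_segment_genes = 30L, seed = 314)))
}

plate_cells_of <- function(sim) {
  sim$dataset$cell_meta$cell_id[sim$dataset$cell_meta$platform == "plate"]
}

droplet_cells_of <- function(sim) {
  sim$dataset$cell_meta$cell_id[sim$dataset$cell_meta$platform == "droplet"]
}

# Brute-force Pearson correlation by the textbook formula.
pearson_loop <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

# Brute-force running-sum GSEA enrichment score.
es_brute <- function(ranked, stat, set, weight) {
  n <- length(ranked)
  hits <- ranked %in% set
  w <- abs(stat)^weight
  sw <- sum(w[hits])
  run <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- cur + if (hits[i]) {
      if (sw > 0) w[i] / sw else 1 / sum(hits)
    } else -1 / (n - sum(hits))
    run[i] <- cur
  }
  run[which.max(abs(run))]
}
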
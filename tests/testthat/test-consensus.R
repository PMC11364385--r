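# Sharing/intersection logic, per-model DE with the metastatic-cell filter,
# state markers, and peak profiles.

# Build a fake de_result from explicit gene effects.
fake_de <- function(up = character(0), down = character(0),
                    null = character(0)) {
  genes <- c(up, down, null)
  tab <- data.frame(gene = genes,
                    log2fc = c(rep(1, length(up)), rep(-1, length(down)),
                               rep(0, length(null))),
                    p_discrete = 0.5, p_continuous = 0.5,
                    p_hurdle = c(rep(0.001, length(up) + length(down)),
                                 rep(0.9, length(null))),
                    frac_expr_A = 0.5, frac_expr_B = 0.5,
                    n_A = 50L, n_B = 50L, stringsAsFactors = FALSE)
  tab$adj_p <- p.adjust(tab$p_hurdle, "BH")
  tab$direction <- sign(tab$log2fc)
  class(tab) <- c("de_result", "data.frame")
  tab
}

test_that("sharing rule admits genes significant in >= min_models models", {
  de <- list(m1 = fake_de(up = c("A", "B")),
             m2 = fake_de(up = c("B", "C")),
             m3 = fake_de(up = "D"))
  sig2 <- shared_upregulated(de, min_models = 2)
  expect_equal(sig2$all$genes, "B")
  expect_equal(sig2$all$support$B, c("m1", "m2"))
  sig1 <- shared_upregulated(de, min_models = 1)
  expect_equal(sig1$all$genes, sort(c("A", "B", "C", "D")))
  # histogram equals brute-force tally: A,C,D seen once; B twice
  expect_equal(as.integer(sig1$all$histogram), c(3L, 1L, 0L))
})

test_that("sharing is grouped and monotone in min_models", {
  de <- list(m1 = fake_de(up = c("A", "B")), m2 = fake_de(up = c("A", "C")),
             m3 = fake_de(up = c("A", "B")), m4 = fake_de(up = "B"))
  groups <- c(m1 = "low", m2 = "low", m3 = "high", m4 = "high")
  sig <- shared_upregulated(de, min_models = 2, within_groups = groups)
  expect_equal(sig$low$genes, "A")
  expect_equal(sig$high$genes, "B")
  for (k in 1:4) {
    s_k <- shared_upregulated(de, min_models = k, within_groups = groups)
    s_k1 <- shared_upregulated(de, min_models = k + 1, within_groups = groups)
    for (g in names(s_k1)) expect_true(all(s_k1[[g]]$genes %in% s_k[[g]]$genes))
  }
  expect_error(shared_upregulated(de, within_groups = c(m1 = "low")),
               "without a group label")
})

test_that("cross-platform intersection equals brute-force set membership", {
  s1 <- list(low = c("A", "B"), high = c("X", "Y", "Z"))
  s2 <- list(low = c("B", "C"), high = c("Q"))
  expect_warning(xp <- cross_platform_intersect(s1, s2), "empty")
  expect_equal(xp$low$genes, "B")
  expect_equal(xp$high$genes, character(0))
  # brute-force membership scan
  brute <- character(0)
  for (g in s1$low) if (g %in% s2$low) brute <- c(brute, g)
  expect_equal(xp$low$genes, sort(brute))
  expect_error(cross_platform_intersect(list(a = "X"), list(b = "X")),
               "one platform only")
})

test_that("per-model DE applies the <10 metastatic-cell exclusion at the boundary", {
  sim <- small_panel()
  ds <- sim$dataset
  meta <- ds$cell_meta[ds$cell_meta$platform == "plate", ]
  # trim metastatic cells: M01 -> 9 (excluded), M02 -> 10 (included)
  keep <- meta$cell_id
  for (trim in list(c("M01", 9), c("M02", 10))) {
    met <- meta$cell_id[meta$tumor_model == trim[1] & meta$tissue == "metastasis"]
    keep <- setdiff(keep, met[-seq_len(as.integer(trim[2]))])
  }
  pm <- per_model_de(ds, min_met_cells = 10, cells = keep)
  expect_true("M01" %in% pm$excluded)
  expect_true("M02" %in% names(pm$results))
  expect_false("M01" %in% names(pm$results))
})

test_that("per-model DE recovers planted tissue genes within models", {
  sim <- default_panel()
  pm <- per_model_de(sim$dataset, cells = plate_cells_of(sim))
  shared <- shared_upregulated(pm$results, direction = "up", min_models = 2,
                               within_groups = sim$truth$potential)
  found <- unique(unlist(lapply(shared, function(s) s$genes)))
  planted_up <- names(sim$truth$de_effects)[sim$truth$de_effects > 0]
  expect_gt(mean(planted_up %in% found), 0.8)
})

test_that("potential-group DE contrasts each tumor against other groups", {
  sim <- small_panel()
  ds <- sim$dataset
  res <- potential_group_de(ds, min_cells = 3)
  expect_setequal(names(res$de), unique(ds$cell_meta$tumor_model))
  # group labels carried through to signatures
  expect_true(all(names(res$signatures) %in%
                  unique(ds$cell_meta$metastatic_potential)))
  # single-group input errors
  low_models <- names(sim$truth$potential)[sim$truth$potential == "low"]
  low_cells <- ds$cell_meta$cell_id[ds$cell_meta$tumor_model %in% low_models]
  expect_error(potential_group_de(subset_cells(ds, low_cells)), ">= 2")
})

test_that("state-marker DE requires two populated states", {
  sim <- small_panel()
  ds <- sim$dataset
  sc <- compute_emp(ds, sim$truth$epithelial_genes, sim$truth$mesenchymal_genes,
                    seed = 5)
  one_state <- sc
  one_state$state <- "intermediate"
  expect_error(state_marker_de(ds, one_state), ">= 2 populated")
})

test_that("planted bump markers dominate the intermediate one-vs-rest list", {
  sim <- default_panel()
  sc <- default_scores()
  sm <- state_marker_de(sim$dataset, sc, cells = plate_cells_of(sim))
  up_int <- significant_genes(sm$intermediate, direction = "up")
  expect_gt(mean(sim$truth$intermediate_markers %in% up_int), 0.8)
  # the gentle epithelial program slope keeps fold changes near the significance
  # threshold, so only partial recall is expected; the list should still be
  # enriched for true program genes
  up_epi <- significant_genes(sm$`epithelial-like`, direction = "up")
  expect_gt(mean(sim$truth$epithelial_genes %in% up_epi), 0.3)
  expect_gt(mean(up_epi %in% sim$truth$epithelial_genes), 0.5)
})

test_that("peak profiles flag bump markers but not monotone or constant genes", {
  sim <- default_panel()
  sc <- default_scores()
  flags <- vapply(sim$truth$intermediate_markers[1:10], function(g) {
    isTRUE(peak_profile(sim$dataset, g, sc)$peaks_in_intermediate)
  }, logical(1))
  expect_gt(mean(flags), 0.5)
  pp_mes <- peak_profile(sim$dataset, sim$truth$mesenchymal_genes[1], sc)
  expect_false(pp_mes$peaks_in_intermediate)

  # constant gene: flat smoothed curve -> not peaked by the tie rule
  counts <- matrix(3, 30, 4, dimnames = list(paste0("c", 1:30), paste0("g", 1:4)))
  ds <- expression_dataset(counts)
  st <- data.frame(cell_id = paste0("c", 1:30), epi_score = 0, mes_score = 0,
                   emp = seq(-1, 1, length.out = 30),
                   state = classify_state(seq(-1, 1, length.out = 30)),
                   stringsAsFactors = FALSE)
  pp <- peak_profile(ds, "g1", st)
  expect_false(pp$peaks_in_intermediate)
  # a never-expressed gene leaves the flag undefined
  counts[, "g2"] <- 0
  ds2 <- expression_dataset(counts)
  expect_warning(pp2 <- peak_profile(ds2, "g2", st), "expressed nowhere")
  expect_true(is.na(pp2$peaks_in_intermediate))
})
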
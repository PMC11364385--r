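# Gene-set scoring, EMP combination, state classification, composition,
# and TF summaries.

test_that("constant matrix and all-gene signatures score exactly zero", {
  counts <- matrix(5, 4, 8, dimnames = list(paste0("c", 1:4), paste0("g", 1:8)))
  ds <- expression_dataset(counts)
  s <- score_gene_set(ds, c("g1", "g2"), n_bins = 2, n_ctrl = 50, seed = 1)
  expect_true(all(abs(s) < 1e-12))
  sim <- small_panel()
  s_all <- score_gene_set(sim$dataset, colnames(sim$dataset$normalized),
                          n_bins = 1, n_ctrl = 1e6, seed = 1)
  expect_true(all(abs(s_all) < 1e-12))
})

test_that("score equals set mean minus bin-control mean on a hand-computable toy", {
  # 10 genes with strictly increasing means -> 2 bins of 5; n_ctrl >= bin size
  # makes the control pool the whole bin, so the score is fully deterministic.
  set.seed(99)
  counts <- matrix(rpois(4 * 10, lambda = rep(seq(2, 40, length.out = 10), each = 4)),
                   4, 10, dimnames = list(paste0("c", 1:4), paste0("g", 1:10)))
  counts[1, ] <- counts[1, ] + 1  # avoid zero library edge
  ds <- expression_dataset(counts)
  means <- colMeans(ds$normalized)
  bin <- ceiling(rank(means, ties.method = "first") / 5)
  sig <- names(sort(means, decreasing = TRUE))[1]  # one gene, top bin
  ctrl_genes <- names(bin)[bin == bin[[sig]]]
  expected <- ds$normalized[, sig] - rowMeans(ds$normalized[, ctrl_genes])
  got <- score_gene_set(ds, sig, n_bins = 2, n_ctrl = 50, seed = 1)
  expect_equal(as.numeric(got), as.numeric(expected))
  att <- attr(score_gene_set(ds, c(sig, "ABSENT"), n_bins = 2, n_ctrl = 50, seed = 1),
              "dropped")
  expect_equal(att, "ABSENT")
})

test_that("scoring errors when no signature gene is present", {
  ds <- tiny_dataset()
  expect_error(score_gene_set(ds, c("nope1", "nope2")), "no signature gene")
})

test_that("EMP is antisymmetric under signature swap and order-invariant", {
  sim <- small_panel()
  ds <- sim$dataset; tr <- sim$truth
  e1 <- compute_emp(ds, tr$epithelial_genes, tr$mesenchymal_genes, seed = 5)
  e2 <- compute_emp(ds, tr$mesenchymal_genes, tr$epithelial_genes, seed = 5)
  expect_equal(e1$emp, -e2$emp)
  # cell order invariance
  perm <- rev(seq_len(nrow(ds$counts)))
  ds_perm <- expression_dataset(as.matrix(ds$counts)[perm, ],
                                ds$cell_meta[perm, ], ds$gene_meta)
  e3 <- compute_emp(ds_perm, tr$epithelial_genes, tr$mesenchymal_genes, seed = 5)
  expect_equal(e3$emp[match(e1$cell_id, e3$cell_id)], e1$emp)
})

test_that("random gene-set scores on shuffled data center near zero", {
  sim <- small_panel()
  ds <- sim$dataset
  set.seed(31)
  shuffled <- ds$normalized[sample(nrow(ds$normalized)), ]
  rownames(shuffled) <- rownames(ds$normalized)
  ds_shuf <- ds; ds_shuf$normalized <- shuffled
  means <- vapply(1:30, function(k) {
    genes <- sample(colnames(ds$normalized), 15)
    mean(score_gene_set(ds_shuf, genes, seed = k))
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se + 1e-3)
})

test_that("state classification follows the fixed thresholds exactly", {
  expect_equal(classify_state(c(-0.5, 0, 0.2, 0.2000001)),
               c("epithelial-like", "intermediate", "intermediate",
                 "mesenchymal-like"))
  expect_equal(classify_state(-0.2), "intermediate")  # closed band
  expect_error(classify_state(0, low = 0.2, high = -0.2), "low < high")
  expect_error(classify_state(NaN), "finite")
})

test_that("classification partitions the line for arbitrary thresholds", {
  set.seed(8)
  for (rep in 1:20) {
    th <- sort(rnorm(2))
    x <- rnorm(50)
    st <- classify_state(x, th[1], th[2])
    manual <- ifelse(x < th[1], "epithelial-like",
                     ifelse(x > th[2], "mesenchymal-like", "intermediate"))
    expect_identical(st, manual)
  }
})

test_that("state composition matches a brute-force tally", {
  st <- data.frame(cell_id = paste0("c", 1:6),
                   epi_score = 0, mes_score = 0,
                   emp = c(-1, 0, 1, 0.1, -0.3, 0.6),
                   state = classify_state(c(-1, 0, 1, 0.1, -0.3, 0.6)),
                   stringsAsFactors = FALSE)
  meta <- data.frame(cell_id = paste0("c", 1:6),
                     grp = c("a", "a", "a", "b", "b", "b"),
                     stringsAsFactors = FALSE)
  comp <- state_composition(st, meta, "grp")
  expect_equal(sum(comp$prop[comp$grp == "a"]), 1)
  one_third <- comp$prop[comp$grp == "a"]
  expect_equal(sort(one_third), rep(1 / 3, 3))
  # brute force per (group, state)
  for (i in seq_len(nrow(comp))) {
    n <- 0
    for (j in 1:6) {
      if (meta$grp[j] == comp$grp[i] && st$state[j] == comp$state[i]) n <- n + 1
    }
    expect_equal(comp$n[i], n)
  }
  expect_error(state_composition(st, meta, "nope"), "unknown group key")
})

test_that("TF summaries report fractions and conditional means by state", {
  counts <- matrix(c(0, 0, 0,    # TF1 never expressed
                     2, 2, 2,    # TF2 always expressed
                     1, 0, 3,
                     4, 4, 4),
                   nrow = 3, dimnames = list(paste0("c", 1:3),
                                             c("TF1", "TF2", "g3", "g4")))
  ds <- expression_dataset(counts)
  st <- data.frame(cell_id = paste0("c", 1:3), epi_score = 0, mes_score = 0,
                   emp = c(-1, 0, 1),
                   state = classify_state(c(-1, 0, 1)), stringsAsFactors = FALSE)
  out <- tf_summary(ds, c("TF1", "TF2", "MISSING"), st)
  expect_equal(attr(out, "skipped"), "MISSING")
  tf1 <- out[out$gene == "TF1", ]
  expect_true(all(tf1$frac_expressing == 0))
  expect_true(all(is.na(tf1$mean_expressing)))
  tf2 <- out[out$gene == "TF2", ]
  expect_true(all(tf2$frac_expressing == 1))
  expect_equal(tf2$mean_expressing,
               as.numeric(ds$normalized[match(c("c1", "c2", "c3"),
                                              rownames(ds$normalized)), "TF2"]))
})

test_that("a mesenchymal-program TF has increasing expressing fraction across states", {
  sim <- default_panel()
  sc <- default_scores()
  tf <- sim$truth$mesenchymal_genes[1:5]
  out <- tf_summary(sim$dataset, tf, sc)
  agg <- tapply(out$frac_expressing, out$state, mean)
  expect_lt(agg[["epithelial-like"]], agg[["intermediate"]])
  expect_lt(agg[["intermediate"]], agg[["mesenchymal-like"]])
})

test_that("EMP score recovers the latent axis on the default panel", {
  sim <- default_panel()
  sc <- default_scores()
  plate <- plate_cells_of(sim)
  scp <- sc[sc$cell_id %in% plate, ]
  rho <- cor(sim$truth$latent_t[scp$cell_id], scp$emp, method = "spearman")
  expect_gt(rho, 0.8)
})
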
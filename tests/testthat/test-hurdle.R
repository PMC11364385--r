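# The two-part hurdle model, its likelihood-ratio test, the DE driver, and
# the simple two-group tests.

test_that("hurdle log-likelihoods match a brute-force grid optimizer", {
  # 6 cells, intercept + one covariate
  y <- c(0, 0, 1.2, 0, 2.5, 3.1)
  x <- c(-1, -0.5, 0, 0.5, 1, 1.5)
  X <- cbind(intercept = 1, x = x)
  fit <- fit_hurdle(y, X, ridge = 1e-3)

  # grid over logistic coefficients, penalized objective
  z <- as.numeric(y > 0)
  obj <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(z * eta - log1p(exp(eta))) - 1e-3 / 2 * (b0^2 + b1^2)
  }
  coarse <- seq(-6, 6, by = 0.05)
  vals <- outer(coarse, coarse, Vectorize(obj))
  top <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  fine0 <- seq(coarse[top[1]] - 0.06, coarse[top[1]] + 0.06, by = 0.001)
  fine1 <- seq(coarse[top[2]] - 0.06, coarse[top[2]] + 0.06, by = 0.001)
  best <- max(outer(fine0, fine1, Vectorize(obj)))
  expect_equal(fit$discrete$loglik_pen, best, tolerance = 1e-4)

  # continuous component: closed-form OLS loglik equals reported value
  pos <- y > 0
  f <- lm.fit(X[pos, , drop = FALSE], y[pos])
  s2 <- sum(f$residuals^2) / sum(pos)
  ll <- -sum(pos) / 2 * (log(2 * pi * s2) + 1)
  expect_equal(fit$continuous$loglik, ll, tolerance = 1e-8)
})

test_that("degenerate responses are handled by the penalty", {
  X <- matrix(1, 5, 1, dimnames = list(NULL, "i"))
  f0 <- fit_hurdle(rep(0, 5), X)
  expect_true(is.finite(f0$discrete$loglik_pen))
  expect_null(f0$continuous)
  # half-expressing with intercept only: shrunk logit of 0.5 = 0
  f5 <- fit_hurdle(c(0, 0, 0, 1, 2, 3), matrix(1, 6, 1, dimnames = list(NULL, "i")))
  expect_equal(unname(f5$discrete$coef), 0, tolerance = 1e-6)
})

test_that("rank-deficient designs name the collinear column", {
  X <- cbind(intercept = 1, a = c(1, 2, 3, 4), dup = c(1, 2, 3, 4))
  expect_error(fit_hurdle(c(0, 1, 2, 0), X), "dup")
})

test_that("identical designs are rejected by the LRT", {
  X <- cbind(intercept = rep(1, 4), x = c(0, 1, 0, 1))
  expect_error(hurdle_lrt(c(0, 1, 2, 0), X, X), "identical designs")
})

test_that("LRT statistic is non-negative and detects a planted shift", {
  set.seed(4)
  n <- 200
  grp <- rep(0:1, each = n / 2)
  X_full <- cbind(intercept = 1, grp = grp)
  X_red <- X_full[, "intercept", drop = FALSE]
  # null genes: statistic >= 0 always
  for (k in 1:20) {
    y <- rbinom(n, 1, 0.6) * rlnorm(n, 1, 0.4)
    lrt <- hurdle_lrt(y, X_full, X_red)
    expect_gte(lrt$chi2, 0)
    expect_true(lrt$p >= 0 && lrt$p <= 1)
  }
  # a shift in both detection and positive mean has high power
  hits <- vapply(1:25, function(k) {
    y0 <- rbinom(n / 2, 1, 0.5) * rlnorm(n / 2, 0.5, 0.5)
    y1 <- rbinom(n / 2, 1, 0.8) * rlnorm(n / 2, 1.5, 0.5)
    hurdle_lrt(c(y0, y1), X_full, X_red)$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("exchanging groups negates log2fc and keeps p-values", {
  sim <- small_panel()
  ds <- sim$dataset
  cells <- plate_cells_of(sim)
  de1 <- run_de(ds, "tissue", "metastasis", "primary", cells = cells)
  de2 <- run_de(ds, "tissue", "primary", "metastasis", cells = cells)
  ord <- match(de1$gene, de2$gene)
  expect_equal(de1$log2fc, -de2$log2fc[ord])
  expect_equal(de1$p_hurdle, de2$p_hurdle[ord], tolerance = 1e-8)
  expect_equal(de1$frac_expr_A, de2$frac_expr_B[ord])
})

test_that("BH adjustment equals the brute-force step-up definition", {
  sim <- small_panel()
  de <- run_de(sim$dataset, "tissue", "metastasis", "primary",
               cells = plate_cells_of(sim))
  p <- de$p_hurdle
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    running_min <- min(running_min, p[ord[i]] * m / i)
    adj[ord[i]] <- min(1, running_min)
  }
  expect_equal(de$adj_p, adj)
  expect_true(all(de$adj_p >= de$p_hurdle - 1e-12))
})

test_that("identical groups give p near 1 and zero log2fc", {
  counts <- matrix(rep(c(0, 3, 5, 0, 2, 4), 4), 6, 4,
                   dimnames = list(paste0("c", 1:6), paste0("g", 1:4)))
  counts[, 4] <- 1  # keep libraries positive
  meta <- data.frame(cell_id = paste0("c", 1:6),
                     tissue = rep(c("primary", "metastasis"), 3),
                     stringsAsFactors = FALSE)
  # groups have identical value multisets per gene
  counts[meta$tissue == "primary", 1:3] <- counts[meta$tissue == "metastasis", 1:3]
  ds <- expression_dataset(counts, meta)
  de <- run_de(ds, "tissue", "metastasis", "primary", min_cells = 3)
  expect_equal(de$log2fc, rep(0, nrow(de)))
  expect_true(all(de$p_hurdle > 0.9))
})

test_that("aliased covariates and empty groups are rejected", {
  sim <- small_panel()
  ds <- sim$dataset
  one_model <- ds$cell_meta$cell_id[ds$cell_meta$tumor_model == "M01"]
  # within one model, tumor_model is constant -> aliased with the intercept
  expect_error(run_de(ds, "tissue", "metastasis", "primary",
                      covariate_keys = "tumor_model", cells = one_model),
               "collinear|aliased|rank")
  expect_error(run_de(ds, "tissue", "metastasis", "nonexistent"), "empty")
})

test_that("permuted labels yield approximately no discoveries", {
  sim <- small_panel()
  ds <- sim$dataset
  set.seed(77)
  meta <- ds$cell_meta
  plate <- meta$platform == "plate"
  meta$tissue[plate] <- sample(meta$tissue[plate])
  ds_perm <- ds; ds_perm$cell_meta <- meta
  de <- run_de(ds_perm, "tissue", "metastasis", "primary",
               cells = meta$cell_id[plate])
  expect_lte(sum(de$adj_p < 0.05), 2)
})

test_that("Wilcoxon p equals full enumeration on (1,2) vs (3,4)", {
  # all C(4,2) = 6 rank assignments; W = 0 is one of 6 at each tail
  combs <- combn(4, 2)
  ranks <- rank(c(1, 2, 3, 4))
  W_obs <- sum(ranks[1:2]) - 2 * 3 / 2
  count_extreme <- 0
  for (j in seq_len(ncol(combs))) {
    W <- sum(ranks[combs[, j]]) - 2 * 3 / 2
    mid <- 2 * 2 / 2
    if (abs(W - mid) >= abs(W_obs - mid)) count_extreme <- count_extreme + 1
  }
  expect_equal(count_extreme / ncol(combs), 1 / 3)
  expect_equal(wilcoxon_test(c(1, 2), c(3, 4)), 1 / 3)
})

test_that("Wilcoxon degenerate and identical-sample behavior", {
  expect_warning(p <- wilcoxon_test(c(2, 2), c(2, 2)), "tied")
  expect_equal(p, 1)
  expect_equal(suppressWarnings(wilcoxon_test(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_error(wilcoxon_test(numeric(0), 1), "empty")
})

test_that("Fisher exact p equals hypergeometric enumeration on [[2,0],[0,2]]", {
  # margins (2,2)x(2,2): P(X = k) = C(2,k) C(2,2-k) / C(4,2), k = 0,1,2
  probs <- sapply(0:2, function(k) choose(2, k) * choose(2, 2 - k) / choose(4, 2))
  p_two_sided <- sum(probs[probs <= probs[3] + 1e-12])  # observed k = 2
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2)), p_two_sided)
  expect_equal(p_two_sided, 1 / 3)
  expect_error(fisher_exact(matrix(c(1.5, 0, 0, 2), 2)), "integer")
})
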
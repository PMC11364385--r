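# Two-part hurdle differential expression: a ridge-penalized logistic model
# for detection (y > 0) and a Gaussian model for expression conditional on
# detection, combined in a likelihood-ratio test. Plus thin wrappers for the
# simple two-group Wilcoxon and Fisher tests.

#' Fit the two-part hurdle model
#'
#' The discrete component models detection `1{y > 0}` with a logistic
#' regression fit by penalized maximum likelihood (ridge penalty `ridge` on
#' all coefficients, which keeps estimates finite under complete separation).
#' The continuous component is ordinary least squares on the expressing cells
#' with a Gaussian log-likelihood; it is marked absent when fewer than two
#' cells express the gene or the design loses rank on the expressing subset.
#'
#' @param y Numeric vector of normalized expression.
#' @param X Design matrix with intercept; must be full rank.
#' @param ridge Ridge penalty on logistic coefficients (default 1e-3).
#' @return List with `discrete` (coefficients, penalized and unpenalized
#'   log-likelihoods) and `continuous` (`NULL` when absent; otherwise
#'   coefficients, `sigma`, log-likelihood, `n`).
#' @export
fit_hurdle <- function(y, X, ridge = 1e-3) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank-deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  z <- as.numeric(y > 0)
  disc <- logistic_ridge(z, X, ridge)

  pos <- y > 0
  cont <- NULL
  if (sum(pos) >= 2L) {
    Xp <- X[pos, , drop = FALSE]
    if (qr(Xp)$rank == ncol(Xp)) {
      fit <- stats::lm.fit(Xp, y[pos])
      n <- sum(pos)
      rss <- sum(fit$residuals^2)
      sigma2 <- max(rss / n, 1e-12)  # MLE variance; floored for exact fits
      ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
      cont <- list(coef = fit$coefficients, sigma = sqrt(sigma2), loglik = ll, n = n)
    }
  }
  list(discrete = disc, continuous = cont)
}

# Newton-Raphson ridge-penalized logistic regression. Objective:
# sum(z * eta - log(1 + exp(eta))) - ridge/2 * ||beta||^2.
logistic_ridge <- function(z, X, ridge = 1e-3, max_iter = 100L, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  obj_old <- -Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, z - mu)) - ridge * beta
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + ridge
    step <- solve(H, grad)
    # halving line search on the penalized objective
    obj <- logistic_obj(z, X, beta, ridge)
    for (h in 0:20) {
      cand <- beta + step / 2^h
      obj_new <- logistic_obj(z, X, cand, ridge)
      if (obj_new >= obj - 1e-12) { beta <- cand; obj <- obj_new; break }
    }
    if (abs(obj - obj_old) < tol) break
    obj_old <- obj
  }
  eta <- drop(X %*% beta)
  ll_unpen <- sum(z * eta - log1p(exp(pmin(eta, 700))))
  list(coef = stats::setNames(beta, colnames(X)),
       loglik_pen = logistic_obj(z, X, beta, ridge),
       loglik = ll_unpen)
}

logistic_obj <- function(z, X, beta, ridge) {
  eta <- drop(X %*% beta)
  sum(z * eta - log1p(exp(pmin(eta, 700)))) - ridge / 2 * sum(beta^2)
}

#' Hurdle likelihood-ratio test
#'
#' Compares nested designs for both hurdle components. The statistic is
#' `2 * (l_full - l_reduced)` summed over the components (the penalized
#' objective for the logistic part — both designs share the penalty, so the
#' statistic is non-negative — and the Gaussian log-likelihood for the
#' continuous part). Components absent from the fit contribute zero statistic
#' and zero degrees of freedom; the degrees of freedom are the columns dropped
#' from each fitted component.
#'
#' @param y Normalized expression vector.
#' @param X_full,X_reduced Nested design matrices (reduced columns must be a
#'   strict subset of full columns).
#' @param ridge Shared logistic ridge penalty.
#' @return List with `chi2`, `df`, `p`, and per-component statistics
#'   (`p_discrete`, `p_continuous`).
#' @export
hurdle_lrt <- function(y, X_full, X_reduced, ridge = 1e-3) {
  X_full <- as.matrix(X_full); X_reduced <- as.matrix(X_reduced)
  cn_f <- colnames(X_full); cn_r <- colnames(X_reduced)
  if (is.null(cn_f) || is.null(cn_r)) stop("design matrices need column names", call. = FALSE)
  if (!all(cn_r %in% cn_f)) {
    stop("reduced design columns must be a subset of the full design", call. = FALSE)
  }
  if (ncol(X_full) == ncol(X_reduced)) {
    stop("identical designs: no term is dropped", call. = FALSE)
  }
  f_full <- fit_hurdle(y, X_full, ridge)
  f_red <- fit_hurdle(y, X_reduced, ridge)

  d_drop <- ncol(X_full) - ncol(X_reduced)
  stat_d <- max(0, 2 * (f_full$discrete$loglik_pen - f_red$discrete$loglik_pen))
  df_d <- d_drop
  p_d <- stats::pchisq(stat_d, df_d, lower.tail = FALSE)

  if (!is.null(f_full$continuous) && !is.null(f_red$continuous)) {
    stat_c <- max(0, 2 * (f_full$continuous$loglik - f_red$continuous$loglik))
    df_c <- d_drop
    p_c <- stats::pchisq(stat_c, df_c, lower.tail = FALSE)
  } else {
    stat_c <- 0; df_c <- 0L; p_c <- NA_real_
  }
  chi2 <- stat_d + stat_c
  df <- df_d + df_c
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       p_discrete = p_d, p_continuous = p_c,
       stat_discrete = stat_d, stat_continuous = stat_c)
}

#' Hurdle differential expression between two cell groups
#'
#' For every gene expressed in at least `min_cells` cells, tests the contrast
#' term with [hurdle_lrt()], keeping the covariates in both designs. The
#' log2 fold change is the difference in group means of the normalized layer
#' (group A minus group B). P-values are adjusted with Benjamini-Hochberg
#' across tested genes.
#'
#' @param dataset An `ExpressionDataset`.
#' @param contrast_key `cell_meta` column defining the contrast.
#' @param group_A,group_B Levels of `contrast_key` to compare (A vs B).
#' @param covariate_keys Optional `cell_meta` columns kept in both designs.
#' @param min_cells Minimum cells per group and minimum expressing cells per
#'   gene (default 3).
#' @param cells Optional character vector restricting the analysis to a cell
#'   subset.
#' @param ridge Logistic ridge penalty.
#' @return `data.frame` (class `de_result`) with per-gene `log2fc`,
#'   `p_discrete`, `p_continuous`, `p_hurdle`, `adj_p`, `frac_expr_A`,
#'   `frac_expr_B`, `n_A`, `n_B`, `direction`. Skipped genes are reported via
#'   attribute `"skipped"`.
#' @export
run_de <- function(dataset, contrast_key, group_A, group_B,
                   covariate_keys = NULL, min_cells = 3L, cells = NULL,
                   ridge = 1e-3) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  meta <- dataset$cell_meta
  if (!is.null(cells)) meta <- meta[meta$cell_id %in% cells, , drop = FALSE]
  if (!contrast_key %in% names(meta)) {
    stop(sprintf("unknown contrast key '%s'", contrast_key), call. = FALSE)
  }
  in_A <- meta[[contrast_key]] == group_A
  in_B <- meta[[contrast_key]] == group_B
  n_A <- sum(in_A); n_B <- sum(in_B)
  if (n_A == 0L || n_B == 0L) stop("empty contrast group", call. = FALSE)
  if (n_A < min_cells || n_B < min_cells) {
    stop(sprintf("groups need >= %d cells (have %d and %d)", min_cells, n_A, n_B),
         call. = FALSE)
  }
  meta <- meta[in_A | in_B, , drop = FALSE]
  # symmetric +/-0.5 coding keeps the ridge-penalized fit exactly invariant
  # under exchanging the two groups
  contrast <- ifelse(meta[[contrast_key]] == group_A, 0.5, -0.5)

  df <- data.frame(.contrast = contrast)
  if (!is.null(covariate_keys)) {
    for (k in covariate_keys) {
      if (!k %in% names(meta)) stop(sprintf("unknown covariate '%s'", k), call. = FALSE)
      v <- meta[[k]]
      if (!is.numeric(v) && length(unique(v)) < 2L) {
        stop(sprintf("covariate '%s' is constant on the contrast cells (aliased)", k),
             call. = FALSE)
      }
      df[[k]] <- if (is.numeric(v)) v else factor(v)
    }
  }
  X_full <- stats::model.matrix(~ ., data = df)
  X_reduced <- X_full[, setdiff(colnames(X_full), ".contrast"), drop = FALSE]
  if (qr(X_full)$rank < ncol(X_full)) {
    stop("contrast is confounded with a covariate (aliased design)", call. = FALSE)
  }

  expr <- dataset$normalized[meta$cell_id, , drop = FALSE]
  idx_A <- contrast > 0
  n_expr <- colSums(expr > 0)
  test_genes <- colnames(expr)[n_expr >= min_cells]
  skipped <- setdiff(colnames(expr), test_genes)

  res <- lapply(test_genes, function(g) {
    y <- expr[, g]
    lrt <- hurdle_lrt(y, X_full, X_reduced, ridge = ridge)
    c(log2fc = mean(y[idx_A]) - mean(y[!idx_A]),
      p_discrete = lrt$p_discrete,
      p_continuous = lrt$p_continuous,
      p_hurdle = lrt$p,
      frac_expr_A = mean(y[idx_A] > 0),
      frac_expr_B = mean(y[!idx_A] > 0))
  })
  tab <- as.data.frame(do.call(rbind, res))
  tab <- cbind(data.frame(gene = test_genes, stringsAsFactors = FALSE), tab)
  tab$adj_p <- stats::p.adjust(tab$p_hurdle, method = "BH")
  tab$n_A <- n_A
  tab$n_B <- n_B
  tab$direction <- sign(tab$log2fc)
  rownames(tab) <- NULL
  attr(tab, "skipped") <- skipped
  attr(tab, "contrast") <- c(A = group_A, B = group_B)
  class(tab) <- c("de_result", "data.frame")
  tab
}

#' Select significant genes from a DE table
#'
#' Mirrors the conventional volcano thresholds: `|log2FC| > lfc` and
#' `p < alpha` (raw p by default; set `use_adj = TRUE` for BH-adjusted).
#'
#' @param de A `de_result`.
#' @param direction `"up"` (log2fc > 0), `"down"`, or `"both"`.
#' @param lfc Fold-change threshold (default 0.5).
#' @param alpha P-value threshold (default 0.05).
#' @param use_adj Use `adj_p` instead of raw `p_hurdle`.
#' @return Character vector of gene symbols.
#' @export
significant_genes <- function(de, direction = c("both", "up", "down"),
                              lfc = 0.5, alpha = 0.05, use_adj = FALSE) {
  direction <- match.arg(direction)
  p <- if (use_adj) de$adj_p else de$p_hurdle
  keep <- abs(de$log2fc) > lfc & p < alpha
  keep <- keep & switch(direction,
                        both = TRUE,
                        up = de$log2fc > 0,
                        down = de$log2fc < 0)
  de$gene[keep & !is.na(keep)]
}

#' Two-sided unpaired Wilcoxon rank-sum test
#'
#' Exact enumeration for small untied samples (n + m <= 20), normal
#' approximation with tie correction otherwise; a fully tied degenerate input
#' returns p = 1 with a warning.
#'
#' @param x,y Non-empty numeric samples.
#' @return Two-sided p-value.
#' @export
wilcoxon_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample", call. = FALSE)
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied; Wilcoxon p set to 1", call. = FALSE)
    return(1)
  }
  exact <- (length(x) + length(y) <= 20L) && !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = FALSE)$p.value
  )
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value from the hypergeometric distribution.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("expected a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be non-negative integers", call. = FALSE)
  }
  stats::fisher.test(tab)$p.value
}
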
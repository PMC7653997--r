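# Independent oracles used to cross-check the package implementations.
# They deliberately use dense, loop-based linear algebra rather than the
# rotated/vectorized paths in the package.

# Per-variant regression with known residual variance: dense normal
# equations for y = a + b x + e, e ~ N(0, sigma_e2).
ols_oracle <- function(y, x, sigma_e2) {
  X <- unname(cbind(1, x))
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, y)
  list(beta = unname(beta[2, 1]), se = unname(sqrt(sigma_e2 * XtXi[2, 2])))
}

# Brute-force 1-D grid search over h2 of the restricted log-likelihood of
# y = 1 mu + u + e, u ~ N(0, K sigma_u2), with the common scale profiled
# out; everything computed with dense solves and determinants.
reml_grid_oracle <- function(y, K) {
  n <- length(y)
  ll_at <- function(h2) {
    H <- h2 * K + (1 - h2) * diag(n)
    Hi <- solve(H)
    ldH <- as.numeric(determinant(H, logarithm = TRUE)$modulus)
    xhx <- sum(Hi)
    beta <- sum(Hi %*% y) / xhx
    r <- y - beta
    sigma2 <- drop(t(r) %*% Hi %*% r) / (n - 1)
    -0.5 * ((n - 1) * (log(2 * pi) + log(sigma2) + 1) + ldH + log(xhx))
  }
  # coarse pass over (0, 1), then a fine pass around the coarse maximum
  coarse <- seq(0.001, 0.999, by = 0.001)
  ll <- vapply(coarse, ll_at, numeric(1))
  best <- coarse[which.max(ll)]
  fine <- seq(max(1e-6, best - 0.001), min(1 - 1e-6, best + 0.001), by = 1e-5)
  llf <- vapply(fine, ll_at, numeric(1))
  list(h2 = fine[which.max(llf)], loglik = max(llf))
}

# Exhaustive, rule-by-rule AWM construction: key-SNP inclusion at
# P <= p_threshold, trait retention at |r| >= r_threshold over the key
# rows, secondary recruitment with >= min_other retained non-key traits,
# then per-gene max-trait-count / min-cumulated-P / position selection.
# Plain loops throughout.
awm_oracle <- function(results, key, p_thr, r_thr, min_other, gene_map = NULL) {
  traits <- names(results)
  nvar <- nrow(results[[1]])
  key_rows <- c()
  for (i in seq_len(nvar))
    if (results[[key]]$p[i] <= p_thr) key_rows <- c(key_rows, i)
  if (length(key_rows) == 0)
    return(list(rows = integer(0), traits = key, selection = NULL))
  retained <- key
  for (tr in setdiff(traits, key)) {
    zk <- results[[key]]$z[key_rows]
    zt <- results[[tr]]$z[key_rows]
    if (length(key_rows) >= 2 && sd(zk) > 0 && sd(zt) > 0 &&
        abs(cor(zk, zt)) >= r_thr)
      retained <- c(retained, tr)
  }
  sec_rows <- c()
  for (i in setdiff(seq_len(nvar), key_rows)) {
    cnt <- 0
    for (tr in setdiff(retained, key))
      if (results[[tr]]$p[i] <= p_thr) cnt <- cnt + 1
    if (cnt >= min_other) sec_rows <- c(sec_rows, i)
  }
  rows <- sort(c(key_rows, sec_rows))
  selection <- NULL
  if (!is.null(gene_map)) {
    per_gene <- list()
    for (i in rows) {
      gene <- gene_map[i]
      if (is.na(gene)) next
      n_assoc <- 0
      cum_p <- 0
      for (tr in retained) if (results[[tr]]$p[i] <= p_thr) {
        n_assoc <- n_assoc + 1
        cum_p <- cum_p + results[[tr]]$p[i]
      }
      cand <- list(row = i, n_assoc = n_assoc, cum_p = cum_p,
                   pos = results[[key]]$pos[i])
      best <- per_gene[[gene]]
      if (is.null(best) ||
          cand$n_assoc > best$n_assoc ||
          (cand$n_assoc == best$n_assoc && cand$cum_p < best$cum_p) ||
          (cand$n_assoc == best$n_assoc && cand$cum_p == best$cum_p &&
           cand$pos < best$pos))
        per_gene[[gene]] <- cand
    }
    selection <- data.frame(
      gene_id = names(per_gene),
      variant_id = vapply(per_gene, function(b) results[[key]]$variant_id[b$row], character(1)),
      n_traits_associated = vapply(per_gene, function(b) b$n_assoc, numeric(1)),
      cum_p = vapply(per_gene, function(b) b$cum_p, numeric(1)),
      stringsAsFactors = FALSE
    )
    selection <- selection[order(selection$gene_id), ]
    rownames(selection) <- NULL
  }
  list(rows = rows, traits = retained, selection = selection)
}
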
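# Independent brute-force oracles and fixture builders used across the suite.

# Scree elbow by exhaustive evaluation of second forward differences.
scree_oracle <- function(ev) {
  best_j <- 1L
  best_a <- -Inf
  for (j in seq_len(length(ev) - 2)) {
    a <- ev[j] - 2 * ev[j + 1] + ev[j + 2]
    if (a > best_a + 1e-15) {
      best_a <- a
      best_j <- j
    }
  }
  best_j
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign patterns.
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_null <- as.matrix(signs) %*% r
  pl <- mean(v_null <= v_obs)
  pg <- mean(v_null >= v_obs)
  min(1, 2 * min(pl, pg))
}

# Minimal extraction_model stand-in with hand-set loadings, for testing the
# assignment rules in isolation from any fitted backend.
toy_model <- function(loadings, eigenvalues = NULL) {
  p <- nrow(loadings)
  m <- ncol(loadings)
  feat <- rownames(loadings) %||% paste0("f", seq_len(p))
  rownames(loadings) <- feat
  colnames(loadings) <- paste0("C", seq_len(m))
  ev <- eigenvalues %||% rev(seq_len(m))
  structure(
    list(
      method = "pca",
      rotation = sweep(loadings, 2, sqrt(pmax(ev, 1e-12)), "/"),
      eigenvalues = ev,
      loadings = loadings,
      explained_variance = ev / sum(ev),
      feature_names = feat
    ),
    class = "extraction_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct re-implementation of the beta membership + max-loading assignment
# rule with plain loops (enumeration oracle for assign_features).
assignment_oracle <- function(loadings, beta, transform = "zscore") {
  t_mat <- switch(transform,
    zscore = apply(abs(loadings), 2, function(v) (v - mean(v)) / sd(v)),
    abs = abs(loadings)
  )
  phi <- pnorm(t_mat)
  out <- list()
  for (i in seq_len(nrow(loadings))) {
    comps <- which(phi[i, ] >= beta)
    if (length(comps) == 0) next
    best <- comps[order(-abs(loadings[i, comps]), comps)][1]
    out[[length(out) + 1]] <- data.frame(
      feature = rownames(loadings)[i], component = best,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# Exactly equicorrelated standardized data: z_i = sqrt(rho) g + sqrt(1-rho) e_i
# with g and e_i exactly orthonormal columns, so every sample correlation is
# exactly rho and the item-total correlation has the closed form
# sqrt((1 + (k-1) rho) / k).
equicorrelated_data <- function(n, k, rho, seed = 1) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(cbind(1, matrix(rnorm(n * (k + 1)), n, k + 1))))
  })
  # drop the intercept column: the rest are exactly mean-zero and orthogonal
  q <- q[, -1, drop = FALSE] * sqrt(n)
  g <- q[, 1]
  z <- sqrt(rho) * g + sqrt(1 - rho) * q[, -1, drop = FALSE]
  colnames(z) <- paste0("z", seq_len(k))
  as.data.frame(z)
}
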
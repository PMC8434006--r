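test_that("Kaiser criterion counts eigenvalues strictly above 1", {
  expect_identical(kaiser_select(c(2.5, 1.2, 0.8, 0.5)), 2L)
  expect_identical(kaiser_select(c(1.0, 0.9)), 0L)
  expect_error(kaiser_select(numeric(0)), "empty")
  # on uncorrelated data the count fluctuates around p/2: a known instability
  set.seed(30)
  m <- fit_pca(as.data.frame(matrix(rnorm(2000 * 10), 2000)))
  expect_true(kaiser_select(m) >= 3 && kaiser_select(m) <= 7)
})

test_that("scree elbow sits at the maximum acceleration, ties to smaller M", {
  expect_identical(scree_select(c(3.0, 1.5, 0.4, 0.35, 0.3)), 2L)
  expect_identical(scree_select(c(4, 3, 2, 1)), 1L)
  expect_identical(scree_select(c(10, 1, 0.9, 0.8)), 1L)
  expect_error(scree_select(c(2, 1)), "at least 3")
  set.seed(31)
  for (i in 1:50) {
    ev <- sort(rexp(sample(3:12, 1)) * 3, decreasing = TRUE)
    expect_identical(scree_select(ev), scree_oracle(ev))
  }
})

test_that("fused criterion is the intersection of Kaiser and scree", {
  # K = 2 and SP = 2 agree
  expect_identical(fused_select(c(3.0, 1.5, 0.4, 0.35, 0.3)), 2L)
  # K = 3 but the elbow sits after component 2: the fusion takes the minimum
  ev <- c(4, 3.5, 1.01, 0.3, 0.2)
  expect_identical(kaiser_select(ev), 3L)
  expect_identical(scree_select(ev), 2L)
  expect_identical(fused_select(ev), 2L)
  expect_warning(m0 <- fused_select(c(0.9, 0.8, 0.7)), "no components")
  expect_identical(m0, 0L)
})

test_that("beta matches the closed form on exactly equicorrelated scales", {
  for (k in c(2L, 5L, 10L, 40L)) {
    for (rho in c(0, 0.2, 0.5, 0.8)) {
      z <- equicorrelated_data(n = 200, k = k, rho = rho, seed = k + round(100 * rho))
      b <- compute_beta(z)
      r_dot_expected <- sqrt((1 + (k - 1) * rho) / k)
      rr <- rho * r_dot_expected
      expect_equal(b$r_bar, rho, tolerance = 1e-10)
      expect_equal(b$r_dot_mean, r_dot_expected, tolerance = 1e-10)
      expect_equal(b$beta_global, k * rr / (1 + (k - 1) * rr), tolerance = 1e-10)
    }
  }
  # limits: zero inter-item correlation and a perfect scale
  expect_equal(compute_beta(equicorrelated_data(100, 5, 0))$beta_global, 0,
    tolerance = 1e-10
  )
  x <- rnorm(50)
  perfect <- data.frame(a = x, b = x, c = x)
  expect_equal(compute_beta(perfect)$beta_global, 1, tolerance = 1e-12)
  # single feature degenerates to the item-total correlation (= 1)
  expect_equal(compute_beta(data.frame(a = rnorm(20)))$beta_global, 1)
  expect_error(compute_beta(data.frame(a = rnorm(10), b = rep(1, 10))), "zero-variance")
  expect_error(compute_beta(data.frame(a = 1:2)), "at least 3")
})

test_that("beta is monotone in the correlation level and in scale size", {
  rhos <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  betas <- vapply(rhos, function(r) {
    compute_beta(equicorrelated_data(150, 8, r, seed = 5))$beta_global
  }, numeric(1))
  expect_true(all(diff(betas) > 0))
  ks <- c(3L, 6L, 12L, 24L)
  betas_k <- vapply(ks, function(k) {
    compute_beta(equicorrelated_data(150, k, 0.4, seed = 6))$beta_global
  }, numeric(1))
  expect_true(all(diff(betas_k) > 0))
})

test_that("feature assignment matches the enumeration oracle", {
  set.seed(33)
  for (i in 1:25) {
    p <- sample(5:12, 1)
    m <- sample(2:4, 1)
    ld <- matrix(runif(p * m, -1, 1), p, m,
      dimnames = list(paste0("f", 1:p), NULL)
    )
    model <- toy_model(ld)
    beta <- runif(1, 0.3, 0.9)
    want <- assignment_oracle(ld, beta)
    if (is.null(want)) {
      expect_error(assign_features(model, beta, m_max = m), "empty selection")
      next
    }
    got <- assign_features(model, beta, m_max = m)
    expect_identical(
      as.data.frame(got$assignment[
        order(got$assignment$feature), c("feature", "component")
      ]),
      want[order(want$feature), ],
      ignore_attr = TRUE,
      info = paste("instance", i)
    )
  }
})

test_that("assignment respects the beta limits and the partition invariants", {
  ld <- rbind(
    f1 = c(0.9, 0.1), f2 = c(0.8, 0.3), f3 = c(0.2, 0.95), f4 = c(-0.1, 0.7)
  )
  model <- toy_model(ld)
  all_in <- assign_features(model, 0, m_max = 2)
  expect_identical(sort(all_in$retained_features), paste0("f", 1:4))
  expect_identical(all_in$M_retained, 2L)
  expect_error(assign_features(model, 1, m_max = 2), "empty selection")
  # partition: each feature maps to exactly one component, no empty component
  expect_false(any(duplicated(all_in$assignment$feature)))
  expect_setequal(unique(all_in$assignment$component), all_in$retained_components)
})

test_that("raising beta never adds a feature (linear rule monotonicity)", {
  set.seed(34)
  for (i in 1:10) {
    ld <- matrix(runif(10 * 3, -1, 1), 10, 3,
      dimnames = list(paste0("f", 1:10), NULL)
    )
    model <- toy_model(ld)
    kept <- lapply(c(0.2, 0.5, 0.7, 0.85), function(b) {
      tryCatch(assign_features(model, b, 3)$retained_features,
        error = function(e) character(0)
      )
    })
    for (j in seq_len(length(kept) - 1)) {
      expect_true(all(kept[[j + 1]] %in% kept[[j]]))
    }
  }
})

test_that("multi-assignment resolves by max |loading| with index tie-break", {
  cand <- tibble::tibble(
    feature = c("f1", "f1", "f2", "f2"),
    component = c(1L, 2L, 1L, 2L),
    loading = c(0.8, 0.5, 0.6, -0.6)
  )
  res <- resolve_multiassignment(cand)
  expect_identical(res$component[res$feature == "f1"], 1L)
  expect_identical(res$component[res$feature == "f2"], 1L) # exact tie -> lower index
  set.seed(35)
  for (i in 1:10) {
    p <- 20
    ld <- matrix(runif(p * 3, -1, 1), p, 3)
    cand <- tibble::tibble(
      feature = rep(paste0("f", sprintf("%02d", 1:p)), 3),
      component = rep(1:3, each = p),
      loading = as.vector(ld)
    )
    res <- resolve_multiassignment(cand)
    want <- apply(abs(ld), 1, which.max)
    expect_identical(
      res$component[order(res$feature)],
      as.integer(want)
    )
  }
})

test_that("the margin SVM selection degenerates to the linear rule at delta = 0", {
  set.seed(36)
  for (i in 1:100) {
    p <- sample(6:15, 1)
    m <- sample(2:4, 1)
    ld <- matrix(runif(p * m, -1, 1), p, m,
      dimnames = list(paste0("f", 1:p), NULL)
    )
    model <- toy_model(ld)
    beta <- runif(1, 0.3, 0.9)
    lin <- assign_features(model, beta, m)
    svm <- svm_margin_select(model, beta, m, margin_delta = 0)
    expect_identical(lin$assignment[c("feature", "component")],
      svm$assignment[c("feature", "component")],
      info = paste("instance", i)
    )
    expect_identical(lin$M_retained, svm$M_retained)
  }
})

test_that("the margin SVM resolves ambiguous features by descriptor proximity", {
  # Under the abs transform, Phi(|loading|) gives 0.95 for the planted keeps,
  # 0.54 for the drops, and 0.90 for the in-margin features; with beta = 0.9
  # and delta = 0.02 the mids are ambiguous but lie next to the keep cluster
  # in descriptor space, so the kernel SVM should keep at least 90% of them.
  set.seed(37)
  ld <- cbind(
    c(seq(1.48, 1.9, length.out = 12), seq(0.05, 0.30, length.out = 12),
      rep(1.31, 8)),
    runif(32, 0.02, 0.05)
  )
  rownames(ld) <- paste0("f", sprintf("%02d", 1:32))
  sel <- svm_margin_select(
    toy_model(ld), 0.90,
    m_max = 2, margin_delta = 0.02, loading_transform = "abs"
  )
  expect_identical(sel$diagnostics$n_in_margin, 8L)
  mid <- paste0("f", 25:32)
  expect_gte(mean(mid %in% sel$retained_features), 0.9)
  # none of the planted drops sneak in
  expect_false(any(paste0("f", 13:24) %in% sel$retained_features))

  # a one-class teaching sample falls back to the linear rule with a warning
  ld1 <- cbind(c(rep(2, 4), rep(1.30, 2)), rep(0.03, 6))
  rownames(ld1) <- paste0("f", 1:6)
  expect_warning(
    one <- svm_margin_select(toy_model(ld1), 0.90, 2, margin_delta = 0.05,
                             loading_transform = "abs"),
    "one-class"
  )
  expect_identical(sort(one$retained_features), paste0("f", 1:6))
})

test_that("the pipeline reproduces the 2-feature Kaiser toy and is deterministic", {
  set.seed(38)
  g <- rnorm(500)
  df <- data.frame(
    x = g + rnorm(500, sd = 0.23), y = g + rnorm(500, sd = 0.23),
    risk_class = sample(c("no", "low"), 500, TRUE)
  )
  fit <- run_selection_pipeline(df, method = "pca", criterion = "k")
  expect_identical(fit$selection$M_retained, 1L)
  expect_identical(kaiser_select(fit$model), 1L)

  ds <- generate_dataset(generator_config(n_samples = 800, seed = 40))
  a <- run_selection_pipeline(ds, "pca", "beta", seed = 3)
  b <- run_selection_pipeline(ds, "pca", "beta", seed = 3)
  expect_identical(a$selection$assignment, b$selection$assignment)
  expect_identical(a$model$eigenvalues, b$model$eigenvalues)
})

test_that("beta retains fewer features than the classical criteria", {
  ds <- generate_dataset(generator_config(n_samples = 2000, seed = 41))
  n_of <- function(crit) {
    length(run_selection_pipeline(ds, "pca", crit)$selection$retained_features)
  }
  n_beta <- n_of("beta")
  n_ksp <- n_of("ksp")
  n_sp <- n_of("sp")
  n_k <- n_of("k")
  expect_lt(n_beta, n_ksp)
  expect_lte(n_ksp, n_sp)
  expect_lte(n_sp, n_k)
})
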
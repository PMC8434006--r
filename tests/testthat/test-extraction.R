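principal_angle_deg <- function(u, v) {
  qu <- qr.Q(qr(u))
  qv <- qr.Q(qr(v))
  s <- svd(crossprod(qu, qv))$d
  acos(min(1, min(s))) * 180 / pi
}

test_that("standardize uses the population-SD convention", {
  out <- standardize(data.frame(a = c(2, 4, 6)))
  expect_equal(out$a, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  z <- data.frame(b = c(-1, 0, 1) * sqrt(3 / 2))
  expect_equal(standardize(z)$b, z$b, tolerance = 1e-12)
  expect_error(standardize(data.frame(a = 1:3, bad = rep(2, 3))), "bad")
})

test_that("PCA matches the 2x2 closed form and correlation-trace identity", {
  set.seed(42)
  g <- rnorm(400)
  df <- data.frame(x = g + rnorm(400, sd = 0.4), y = g + rnorm(400, sd = 0.4))
  m <- fit_pca(df)
  z <- as.matrix(standardize(df))
  r <- (crossprod(z) / nrow(z))[1, 2]
  expect_equal(m$eigenvalues, c(1 + abs(r), 1 - abs(r)), tolerance = 1e-10)
  expect_equal(sum(m$eigenvalues), 2, tolerance = 1e-10)

  ds <- generate_dataset(generator_config(n_samples = 400, seed = 8))
  m2 <- fit_pca(ds)
  expect_equal(sum(m2$eigenvalues), 63, tolerance = 1e-6)
  # deterministic sign convention: largest-magnitude entry positive
  for (j in 1:5) {
    expect_gt(m2$rotation[which.max(abs(m2$rotation[, j])), j], 0)
  }
})

test_that("PCA on uncorrelated features keeps all eigenvalues near 1", {
  set.seed(7)
  df <- as.data.frame(matrix(rnorm(4000 * 5), 4000))
  m <- fit_pca(df)
  expect_true(all(m$eigenvalues > 0.85 & m$eigenvalues < 1.15))
  expect_error(fit_pca(data.frame(a = c(1, NA, 3), b = 1:3 + 0.5)), "non-finite")
})

test_that("projection with all components inverts within 1e-8", {
  set.seed(1)
  df <- as.data.frame(matrix(rnorm(200 * 6), 200))
  m <- fit_pca(df)
  z <- as.matrix(standardize(df))
  sc <- as.matrix(transform_scores(df, m))
  expect_lt(max(abs(sc %*% t(m$rotation) - z)), 1e-8)
})

test_that("selection-restricted projection zeroes dropped features", {
  set.seed(3)
  df <- as.data.frame(matrix(rnorm(50 * 4), 50, dimnames = list(NULL, letters[1:4])))
  m <- fit_pca(df)
  sel <- structure(
    list(
      criterion = "beta", M_retained = 2L, retained_components = c(1L, 2L),
      retained_features = c("a", "c")
    ),
    class = "selection_result"
  )
  sc <- as.matrix(transform_scores(df, m, sel))
  z <- as.matrix(standardize(df))
  z[, c("b", "d")] <- 0
  expect_equal(sc, z %*% m$rotation[, 1:2], tolerance = 1e-10, ignore_attr = TRUE)

  empty <- sel
  empty$retained_features <- character(0)
  expect_error(transform_scores(df, m, empty), "empty selection")
  bad <- sel
  bad$retained_components <- 9L
  expect_error(transform_scores(df, m, bad), "components absent")
})

test_that("centroid-class PCA rotates the leading axis onto the centroid direction", {
  set.seed(10)
  n <- 1200
  cl <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * 6), n, 6)
  x[, 1] <- x[, 1] + ifelse(cl == "a", 1.5, -1.5) # delta = 3 on e1
  df <- as.data.frame(x)
  df$risk_class <- cl
  m <- fit_ccpca(df)
  expect_gt(abs(m$rotation[1, 1]), 0.99)
})

test_that("centroid-class PCA equals PCA exactly when centroids coincide", {
  set.seed(11)
  base <- as.data.frame(matrix(rnorm(80 * 5), 80))
  doubled <- rbind(base, base)
  doubled$risk_class <- rep(c("a", "b"), each = 80)
  m_cc <- fit_ccpca(doubled)
  m_pca <- fit_pca(doubled[-6])
  expect_equal(m_cc$rotation, m_pca$rotation, tolerance = 1e-6)
  expect_equal(m_cc$eigenvalues, m_pca$eigenvalues, tolerance = 1e-6)
  expect_equal(m_cc$loadings, m_pca$loadings, tolerance = 1e-6)

  single <- base
  single$risk_class <- "a"
  expect_warning(m_one <- fit_ccpca(single), "single class")
  expect_equal(m_one$rotation, fit_pca(base)$rotation, tolerance = 1e-9)
})

test_that("three separated class centroids put their plane in the top-2 axes", {
  set.seed(12)
  n <- 1800
  cl <- rep(c("a", "b", "c"), each = n / 3)
  mu <- rbind(a = c(4, 0), b = c(0, 4), c = c(-4, -4) / sqrt(2))
  x <- matrix(rnorm(n * 8), n, 8)
  x[, 1:2] <- x[, 1:2] + mu[cl, ]
  df <- as.data.frame(x)
  df$risk_class <- cl
  m <- fit_ccpca(df)
  plane <- rbind(diag(2), matrix(0, 6, 2))
  expect_lt(principal_angle_deg(m$rotation[, 1:2], plane), 5)
})

test_that("stochastic-gradient PCA converges to the exact eigenspace", {
  set.seed(13)
  f <- matrix(rnorm(700 * 3), 700, 3)
  load <- matrix(runif(20 * 3, -1, 1), 20, 3)
  df <- as.data.frame(f %*% t(load) + matrix(rnorm(700 * 20, sd = 0.5), 700))
  g1 <- fit_gpca(df, n_components = 3, seed = 99)
  g2 <- fit_gpca(df, n_components = 3, seed = 99)
  expect_identical(g1$rotation, g2$rotation)
  exact <- fit_pca(df)
  expect_lt(principal_angle_deg(g1$rotation, exact$rotation[, 1:3]), 2)
  expect_equal(g1$eigenvalues, exact$eigenvalues[1:3], tolerance = 0.05)
})

test_that("stochastic-gradient PCA captures rank-1 structure in one component", {
  set.seed(14)
  v <- rnorm(200)
  df <- as.data.frame(outer(v, runif(5, 0.5, 1)) +
    matrix(rnorm(200 * 5, sd = 0.05), 200))
  g <- fit_gpca(df, n_components = 2, seed = 1)
  expect_gt(g$explained_variance[1], 0.99)
})

test_that("linear-kernel KPCA reproduces PCA scores up to sign", {
  set.seed(15)
  df <- as.data.frame(matrix(rnorm(120 * 6), 120))
  kp <- fit_kpca(df, kernel = "linear")
  pc <- fit_pca(df)
  sc_k <- as.matrix(transform_scores(df, kp))
  sc_p <- as.matrix(transform_scores(df, pc))[, seq_len(ncol(sc_k))]
  for (j in seq_len(ncol(sc_k))) {
    expect_lt(min(
      max(abs(sc_k[, j] - sc_p[, j])),
      max(abs(sc_k[, j] + sc_p[, j]))
    ), 1e-6)
  }
  expect_equal(kp$eigenvalues, pc$eigenvalues[seq_along(kp$eigenvalues)],
    tolerance = 1e-6
  )
})

test_that("KPCA treats duplicate rows identically and projects new data consistently", {
  set.seed(16)
  df <- as.data.frame(matrix(rnorm(60 * 4), 60))
  df[31:60, ] <- df[1:30, ]
  kp <- fit_kpca(df, kernel = "rbf")
  expect_equal(kp$scores[1:30, ], kp$scores[31:60, ], tolerance = 1e-8)
  reproj <- as.matrix(transform_scores(df, kp))
  expect_equal(unname(reproj), unname(kp$scores), tolerance = 1e-6)
})

test_that("RBF pseudo-loadings separate radius-structured classes better than PCA", {
  set.seed(17)
  n <- 300
  r <- c(runif(n / 2, 0.8, 1.2), runif(n / 2, 2.3, 2.7))
  th <- runif(n, 0, 2 * pi)
  df <- data.frame(x = r * cos(th), y = r * sin(th))
  cl <- rep(c(1, 2), each = n / 2)
  gap <- function(scores) {
    max(vapply(seq_len(ncol(scores)), function(j) {
      abs(mean(scores[cl == 1, j]) - mean(scores[cl == 2, j])) / sd(scores[, j])
    }, numeric(1)))
  }
  kp <- fit_kpca(df, kernel = "rbf", kernel_params = list(gamma = 1),
                 n_components = 3)
  pc <- fit_pca(df)
  expect_gt(gap(as.matrix(kp$scores)), 3 * gap(as.matrix(transform_scores(df, pc))))
})

test_that("KPCA agrees with an independent kernel-PCA implementation", {
  set.seed(18)
  x <- matrix(rnorm(80 * 5), 80, 5)
  z <- scale(x)[, ] * sqrt(80 / 79) # population-SD standardization
  kp <- fit_kpca(as.data.frame(x), kernel = "rbf", kernel_params = list(gamma = 0.2))
  ref <- kernlab::kpca(z, kernel = "rbfdot", kpar = list(sigma = 0.2), features = 3)
  for (j in 1:3) {
    expect_gt(abs(cor(kp$scores[, j], kernlab::rotated(ref)[, j])), 0.999)
  }
})
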
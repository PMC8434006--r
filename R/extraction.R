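#' Standardize feature columns
#'
#' Centers each feature to mean 0 and scales to SD 1 under the population-SD
#' convention (`sqrt(mean((x - mean(x))^2))`), the normalization step that
#' precedes every extraction backend. A `risk_class` column, if present, is
#' carried through unchanged.
#'
#' @param data Data frame of numeric features, optionally with a
#'   `risk_class` column, or a `hazard_dataset`.
#' @return A tibble of the same shape with standardized feature columns.
#' @examples
#' standardize(data.frame(a = c(2, 4, 6)))
#' @export
standardize <- function(data) {
  if (inherits(data, "hazard_dataset")) data <- data$data
  parts <- as_feature_matrix(data)
  z <- scale_pop(parts$x)
  out <- tibble::as_tibble(as.data.frame(z))
  if (!is.null(parts$labels)) {
    out <- dplyr::bind_cols(tibble::tibble(risk_class = parts$labels), out)
  }
  out
}

new_extraction_model <- function(method, rotation, eigenvalues, center, scale,
                                 feature_names, extra = list()) {
  p <- length(feature_names)
  colnames(rotation) <- paste0("C", seq_len(ncol(rotation)))
  rownames(rotation) <- feature_names
  loadings <- sweep(rotation, 2, sqrt(pmax(eigenvalues, 0)), "*")
  structure(
    c(
      list(
        method = method,
        rotation = rotation,
        eigenvalues = eigenvalues,
        loadings = loadings,
        explained_variance = eigenvalues / sum_total_variance(eigenvalues, extra, p),
        center = center,
        scale = scale,
        feature_names = feature_names
      ),
      extra
    ),
    class = "extraction_model"
  )
}

sum_total_variance <- function(eigenvalues, extra, p) {
  if (!is.null(extra$total_variance)) extra$total_variance else p
}

#' @export
print.extraction_model <- function(x, ...) {
  cat(
    "<extraction_model> method=", x$method, ", ",
    length(x$eigenvalues), " components over ",
    length(x$feature_names), " features\n",
    sep = ""
  )
  ev <- head(x$explained_variance, 8)
  cat(
    "explained variance: ",
    paste(sprintf("%.3f", ev), collapse = " "),
    if (length(x$explained_variance) > 8) " ...",
    "\n",
    sep = ""
  )
  invisible(x)
}

check_finite <- function(x) {
  if (!all(is.finite(x))) abort("non-finite values in input data")
  invisible(x)
}

prep_z <- function(data) {
  if (inherits(data, "hazard_dataset")) data <- data$data
  parts <- as_feature_matrix(data)
  check_finite(parts$x)
  m <- colMeans(parts$x)
  xc <- sweep(parts$x, 2, m)
  s <- sqrt(colMeans(xc^2))
  if (any(s == 0)) {
    abort(paste0(
      "zero-variance column: ",
      paste(parts$feature_names[s == 0], collapse = ", ")
    ))
  }
  list(
    z = sweep(xc, 2, s, "/"),
    center = m, scale = s,
    labels = parts$labels,
    feature_names = parts$feature_names
  )
}

# Deterministic sign convention: the largest-magnitude entry of each
# eigenvector is positive; ties on magnitude resolved by the first such entry.
fix_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}

#' Fit exact principal component analysis
#'
#' Eigendecomposition of the correlation matrix of the (internally
#' standardized) data. Components are ordered by non-increasing eigenvalue;
#' each eigenvector's largest-magnitude entry is made positive so the
#' decomposition is deterministic. Loadings are `eigenvector * sqrt(lambda)`,
#' i.e. feature-component correlations on standardized data.
#'
#' @param data Data frame of numeric features (a `risk_class` column is
#'   ignored), or a `hazard_dataset`.
#' @return An `extraction_model`.
#' @examples
#' m <- fit_pca(as.data.frame(matrix(rnorm(200), 50)))
#' m$eigenvalues
#' @export
fit_pca <- function(data) {
  pz <- prep_z(data)
  cmat <- crossprod(pz$z) / nrow(pz$z)
  eg <- eigen(cmat, symmetric = TRUE)
  new_extraction_model(
    "pca",
    rotation = fix_signs(eg$vectors),
    eigenvalues = pmax(eg$values, 0),
    center = pz$center, scale = pz$scale,
    feature_names = pz$feature_names
  )
}

#' Fit centroid-class PCA
#'
#' Supervised variant in which the component rotation is guided by the class
#' centroids: axes are the eigenvectors of `B + gamma * C`, where `B` is the
#' class-size-weighted between-centroid scatter of the standardized data,
#' `C` the correlation matrix, and `gamma` a small mixing weight. Reported
#' eigenvalues are on the correlation-matrix scale (the decomposition is
#' computed as `B/gamma + C`, which has the same eigenvectors), so with
#' coincident centroids (`B = 0`) the model is identical to [fit_pca()],
#' while a strong centroid scatter promotes the centroid-separating axis to
#' the leading component. Loadings are the feature-score correlations
#' `C w / sqrt(w'Cw)` and explained variance is the data variance each axis
#' carries (mixed-scatter eigenvectors are not `C`-eigenvectors).
#'
#' @inheritParams fit_pca
#' @param labels Class label per row; taken from a `risk_class` column or a
#'   `hazard_dataset` when omitted.
#' @param gamma Mixing weight on the correlation matrix.
#' @return An `extraction_model`.
#' @export
fit_ccpca <- function(data, labels = NULL, gamma = 0.1) {
  pz <- prep_z(data)
  labels <- labels %||% pz$labels
  if (is.null(labels)) abort("fit_ccpca() needs class labels")
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) {
    warn("single class present; centroid scatter is zero, falling back to PCA")
    out <- fit_pca(data)
    out$method <- "ccpca"
    out$gamma <- gamma
    return(out)
  }
  z <- pz$z
  n <- nrow(z)
  cmat <- crossprod(z) / n
  bmat <- matrix(0, ncol(z), ncol(z))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    m <- colMeans(z[idx, , drop = FALSE])
    bmat <- bmat + (length(idx) / n) * tcrossprod(m)
  }
  # Axes are the eigenvectors of B + gamma C; dividing through by gamma puts
  # the reported eigenvalues on the correlation-matrix scale, so with
  # coincident centroids (B = 0) the model equals fit_pca() exactly, while a
  # strong between-centroid scatter promotes the centroid-separating axis to
  # the leading component.
  eg <- eigen(bmat / gamma + cmat, symmetric = TRUE)
  v <- fix_signs(eg$vectors)
  # mixed-scatter eigenvectors are not C-eigenvectors, so loadings are
  # computed as feature-score correlations and explained variance as the
  # data variance each axis carries
  cv <- cmat %*% v
  var_axis <- pmax(colSums(cv * v), 0)
  out <- new_extraction_model(
    "ccpca",
    rotation = v,
    eigenvalues = pmax(eg$values, 0),
    center = pz$center, scale = pz$scale,
    feature_names = pz$feature_names,
    extra = list(gamma = gamma)
  )
  out$loadings <- sweep(cv, 2, sqrt(pmax(var_axis, 1e-12)), "/")
  dimnames(out$loadings) <- dimnames(out$rotation)
  out$explained_variance <- var_axis / ncol(z)
  out
}

#' Fit PCA by stochastic-gradient (Oja) ascent with deflation
#'
#' Estimates the leading components one at a time by seeded minibatch
#' stochastic-gradient ascent on the Rayleigh quotient (Oja's rule) with a
#' decaying learning rate and a fixed epoch budget, deflating the data after
#' each component. Converged components agree with the exact
#' eigendecomposition; a warning with diagnostics is raised when the update
#' has not stabilized within the epoch budget.
#'
#' @inheritParams fit_pca
#' @param n_components Number of components to estimate.
#' @param seed Integer seed for the minibatch stream and initialization.
#' @param epochs Epoch budget per component.
#' @param batch_size Minibatch size.
#' @param lr0,lr_decay Initial learning rate and per-epoch decay of the
#'   schedule `lr0 / (1 + lr_decay * epoch)`.
#' @param tol Convergence tolerance on `1 - |<w_t, w_{t-1}>|` between epochs.
#' @return An `extraction_model` with `n_components` components.
#' @export
fit_gpca <- function(data, n_components = NULL, seed = 1L, epochs = 120L,
                     batch_size = 32L, lr0 = 0.5, lr_decay = 2,
                     tol = 1e-4) {
  pz <- prep_z(data)
  z <- pz$z
  p <- ncol(z)
  n <- nrow(z)
  k <- min(n_components %||% min(p, 15L), p)
  withr::with_seed(seed, {
    w_all <- matrix(0, p, k)
    lam <- numeric(k)
    zd <- z
    for (m in seq_len(k)) {
      w <- rnorm(p)
      w <- w / sqrt(sum(w^2))
      converged <- FALSE
      for (e in seq_len(epochs)) {
        w_prev <- w
        lr <- lr0 / (1 + lr_decay * (e - 1))
        idx <- sample.int(n)
        starts <- seq(1, n, by = batch_size)
        for (s in starts) {
          rows <- idx[s:min(s + batch_size - 1, n)]
          zb <- zd[rows, , drop = FALSE]
          g <- crossprod(zb, zb %*% w) / length(rows)
          w <- w + lr * g
          w <- w / sqrt(sum(w^2))
        }
        if (1 - abs(sum(w * w_prev)) < tol) {
          converged <- TRUE
          break
        }
      }
      if (!converged) {
        warn(sprintf(
          "gpca component %d not converged after %d epochs (last delta %.2e)",
          m, epochs, 1 - abs(sum(w * w_prev))
        ))
      }
      sc <- zd %*% w
      lam[m] <- mean(sc^2)
      w_all[, m] <- w
      zd <- zd - sc %*% t(w)
    }
    # eigenvalues against the undeflated data, population convention
    lam_full <- colMeans((z %*% w_all)^2)
    ord <- order(lam_full, decreasing = TRUE)
    new_extraction_model(
      "gpca",
      rotation = fix_signs(w_all[, ord, drop = FALSE]),
      eigenvalues = pmax(lam_full[ord], 0),
      center = pz$center, scale = pz$scale,
      feature_names = pz$feature_names,
      extra = list(seed = seed)
    )
  })
}

kernel_fun <- function(kernel, params) {
  gamma <- params$gamma
  degree <- params$degree %||% 3
  coef0 <- params$coef0 %||% 1
  switch(kernel,
    linear = function(a, b) tcrossprod(a, b),
    rbf = function(a, b) {
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      exp(-gamma * pmax(d2, 0))
    },
    poly = function(a, b) (gamma * tcrossprod(a, b) + coef0)^degree,
    sigmoid = function(a, b) tanh(gamma * tcrossprod(a, b) + coef0),
    abort(paste0("unknown kernel: ", kernel))
  )
}

#' Fit kernel PCA with feature-score pseudo-loadings
#'
#' Eigendecomposition of the doubly centered kernel matrix. Reported
#' eigenvalues are the variances of the component scores (population
#' convention), so with the linear kernel the model coincides with
#' [fit_pca()] scores up to the shared sign convention. Because kernel
#' components have no native feature loadings, pseudo-loadings are defined
#' as the Pearson correlations between each original feature and each
#' component score; these feed the reliability-thresholded assignment rule
#' exactly like linear loadings.
#'
#' @inheritParams fit_pca
#' @param kernel One of `"linear"`, `"rbf"`, `"poly"`, `"sigmoid"`.
#' @param kernel_params Optional list with `gamma` (default `1/ncol`),
#'   `degree` (3) and `coef0` (1).
#' @param n_components Number of components to keep (default all with
#'   positive eigenvalue, capped at `min(n, p)` for the linear kernel).
#' @return An `extraction_model`; negative numerical kernel eigenvalues are
#'   clipped at zero with a warning.
#' @export
fit_kpca <- function(data, kernel = c("rbf", "linear", "poly", "sigmoid"),
                     kernel_params = list(), n_components = NULL) {
  kernel <- match.arg(kernel)
  pz <- prep_z(data)
  z <- pz$z
  n <- nrow(z)
  p <- ncol(z)
  kernel_params$gamma <- kernel_params$gamma %||% (1 / p)
  kf <- kernel_fun(kernel, kernel_params)
  kmat <- kf(z, z)
  ones <- matrix(1 / n, n, n)
  kc <- kmat - ones %*% kmat - kmat %*% ones + ones %*% kmat %*% ones
  eg <- eigen(kc, symmetric = TRUE)
  vals <- eg$values
  if (any(vals < -1e-8 * max(abs(vals)))) {
    warn("kernel matrix numerically non-PSD; negative eigenvalues clipped at 0")
  }
  vals <- pmax(vals, 0)
  kmax <- if (kernel == "linear") min(n - 1L, p) else n - 1L
  keep <- which(vals > max(vals) * 1e-12)
  keep <- keep[seq_len(min(length(keep), n_components %||% kmax, kmax))]
  vals <- vals[keep]
  alpha <- eg$vectors[, keep, drop = FALSE]
  # score for component m: kc %*% alpha_m / sqrt(lambda_m); unit norm scores
  scores <- kc %*% sweep(alpha, 2, sqrt(vals), "/")
  lam <- vals / n # variance of scores, population convention
  scores_sc <- sweep(scores, 2, sqrt(n * lam), "/") * sqrt(n) # sd-1 scores
  pseudo <- suppressWarnings(cor(z, scores_sc))
  # sign convention on pseudo-loadings mirrors the eigenvector rule
  for (j in seq_len(ncol(pseudo))) {
    i <- which.max(abs(pseudo[, j]))
    if (pseudo[i, j] < 0) {
      pseudo[, j] <- -pseudo[, j]
      alpha[, j] <- -alpha[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(pseudo) <- paste0("C", seq_along(keep))
  rownames(pseudo) <- pz$feature_names
  total_var <- sum(diag(kc)) / n
  out <- new_extraction_model(
    "kpca",
    rotation = pseudo, # placeholder shape; overwritten below
    eigenvalues = lam,
    center = pz$center, scale = pz$scale,
    feature_names = pz$feature_names,
    extra = list(
      kernel = kernel, kernel_params = kernel_params,
      alpha = alpha, train_z = z, kmat_colmeans = colMeans(kmat),
      kmat_mean = mean(kmat), total_variance = total_var
    )
  )
  # kernel components have no eigenvector in feature space: rotation is not
  # defined, loadings are the feature-score correlations
  out$rotation <- NULL
  out$loadings <- pseudo
  out$scores <- scores
  out
}

#' Fit an extraction backend by name
#'
#' Thin dispatcher over [fit_pca()], [fit_ccpca()], [fit_gpca()] and
#' [fit_kpca()].
#'
#' @inheritParams fit_pca
#' @param method Backend name.
#' @param labels Class labels (ccpca only).
#' @param seed Seed (gpca only).
#' @param kernel,kernel_params Kernel settings (kpca only).
#' @param ... Passed on to the backend.
#' @return An `extraction_model`.
#' @export
fit_extraction <- function(data, method = c("pca", "ccpca", "gpca", "kpca"),
                           labels = NULL, seed = 1L, kernel = "rbf",
                           kernel_params = list(), ...) {
  method <- match.arg(method)
  switch(method,
    pca = fit_pca(data),
    ccpca = fit_ccpca(data, labels = labels, ...),
    gpca = fit_gpca(data, seed = seed, ...),
    kpca = fit_kpca(data, kernel = kernel, kernel_params = kernel_params, ...)
  )
}

#' Project data onto retained components
#'
#' Computes component scores for new data under a fitted extraction model,
#' optionally restricted by a selection: only retained components are
#' returned, and features outside the retained set are zeroed (after
#' centering/scaling with the training parameters) before projection.
#'
#' @param data Data frame of features (a `risk_class` column is ignored) or a
#'   `hazard_dataset`.
#' @param model An `extraction_model`.
#' @param selection Optional `selection_result` fitted on this model.
#' @return A tibble of scores, one column per retained component.
#' @export
transform_scores <- function(data, model, selection = NULL) {
  if (inherits(data, "hazard_dataset")) data <- data$data
  parts <- as_feature_matrix(data)
  if (!identical(parts$feature_names, model$feature_names)) {
    abort("feature columns do not match the fitted model")
  }
  z <- sweep(sweep(parts$x, 2, model$center), 2, model$scale, "/")
  comps <- seq_along(model$eigenvalues)
  if (!is.null(selection)) {
    if (length(selection$retained_features) == 0) {
      abort("empty selection: no retained features")
    }
    comps <- selection$retained_components
    if (max(comps) > length(model$eigenvalues)) {
      abort("selection refers to components absent from the model")
    }
    drop_idx <- !model$feature_names %in% selection$retained_features
    z[, drop_idx] <- 0
  }
  scores <- if (model$method == "kpca") {
    kpca_project(z, model)[, comps, drop = FALSE]
  } else {
    z %*% model$rotation[, comps, drop = FALSE]
  }
  colnames(scores) <- paste0("C", comps)
  tibble::as_tibble(as.data.frame(scores))
}

kpca_project <- function(znew, model) {
  kf <- kernel_fun(model$kernel, model$kernel_params)
  kx <- kf(znew, model$train_z)
  n <- nrow(model$train_z)
  kc <- sweep(kx, 2, model$kmat_colmeans) -
    matrix(rowMeans(kx), nrow(kx), n) + model$kmat_mean
  lam_n <- model$eigenvalues * n
  kc %*% sweep(model$alpha, 2, sqrt(lam_n), "/")
}

#' @export
predict.extraction_model <- function(object, newdata, selection = NULL, ...) {
  transform_scores(newdata, object, selection = selection)
}
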
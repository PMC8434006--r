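#' Kaiser criterion for the number of components
#'
#' Retains the components of a correlation-matrix eigendecomposition whose
#' eigenvalue strictly exceeds 1.
#'
#' @param eigenvalues Non-increasing eigenvalues (or an `extraction_model`).
#' @return Integer count of retained components.
#' @examples
#' kaiser_select(c(2.5, 1.2, 0.8, 0.5))
#' @export
kaiser_select <- function(eigenvalues) {
  ev <- as_eigenvalues(eigenvalues)
  if (length(ev) == 0) abort("empty eigenvalue vector")
  sum(ev > 1)
}

as_eigenvalues <- function(x) {
  if (inherits(x, "extraction_model")) x$eigenvalues else as.numeric(x)
}

#' Scree (elbow) criterion for the number of components
#'
#' Formalizes the visual scree-plot rule as the point of maximum acceleration
#' of the eigenvalue curve: with second forward differences
#' `a_j = lambda_j - 2 lambda_{j+1} + lambda_{j+2}`, the retained count is
#' the smallest `j` maximizing `a_j` (the component just before the elbow).
#'
#' @inheritParams kaiser_select
#' @return Integer count of retained components.
#' @examples
#' scree_select(c(3, 1.5, 0.4, 0.35, 0.3))
#' @export
scree_select <- function(eigenvalues) {
  ev <- as_eigenvalues(eigenvalues)
  if (length(ev) < 3) abort("scree_select() needs at least 3 eigenvalues")
  acc <- ev[seq_len(length(ev) - 2)] -
    2 * ev[seq(2, length(ev) - 1)] +
    ev[seq(3, length(ev))]
  which.max(acc) # ties resolved to the smaller index by which.max
}

#' Fused Kaiser + scree criterion
#'
#' A component must satisfy both rules: the retained count is the minimum of
#' [kaiser_select()] and [scree_select()]. Degenerates to 0 (with a warning)
#' when no eigenvalue exceeds 1.
#'
#' @inheritParams kaiser_select
#' @return Integer count of retained components.
#' @export
fused_select <- function(eigenvalues) {
  m <- min(kaiser_select(eigenvalues), scree_select(eigenvalues))
  if (m == 0) warn("fused criterion retains no components (all eigenvalues <= 1)")
  m
}

#' Cronbach-type beta reliability of a feature scale
#'
#' Treats a set of standardized features as items of one scale and computes
#' `beta = k * rb * rd / (1 + (k - 1) * rb * rd)`, where `k` is the number of
#' items, `rb` the mean absolute pairwise Pearson correlation, and `rd` the
#' mean absolute item-total correlation (each feature against the row sum of
#' all features). Absolute values keep sign-mixed items from cancelling. With
#' a single feature `rb` is taken as 1 and beta reduces to `rd`. Per-feature
#' variants `beta_i` substitute feature `i`'s own item-total correlation.
#'
#' @param data Data frame or matrix of numeric features (>= 3 rows); a
#'   `risk_class` column is ignored.
#' @return A list of class `beta_result` with `k`, `r_bar`, `r_dot`
#'   (per-feature, named), `r_dot_mean`, `beta_global`, `beta_per_feature`.
#' @examples
#' z <- as.data.frame(matrix(rnorm(300), 100))
#' compute_beta(z)$beta_global
#' @export
compute_beta <- function(data) {
  if (inherits(data, "hazard_dataset")) data <- data$data
  parts <- as_feature_matrix(data)
  x <- parts$x
  if (nrow(x) < 3) abort("compute_beta() needs at least 3 samples")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0(
      "zero-variance feature: ",
      paste(parts$feature_names[sds == 0], collapse = ", ")
    ))
  }
  k <- ncol(x)
  if (k == 1L) {
    r_bar <- 1
    r_dot <- stats::setNames(1, parts$feature_names)
  } else {
    cm <- abs(cor(x))
    r_bar <- mean(cm[upper.tri(cm)])
    total <- rowSums(x)
    r_dot <- abs(drop(cor(x, total)))
    names(r_dot) <- parts$feature_names
  }
  r_dot_mean <- mean(r_dot)
  beta_closed <- function(rr) k * rr / (1 + (k - 1) * rr)
  structure(
    list(
      k = k,
      r_bar = r_bar,
      r_dot = r_dot,
      r_dot_mean = r_dot_mean,
      beta_global = beta_closed(r_bar * r_dot_mean),
      beta_per_feature = beta_closed(r_bar * r_dot)
    ),
    class = "beta_result"
  )
}

#' @export
print.beta_result <- function(x, ...) {
  cat(sprintf(
    "<beta_result> k=%d  r_bar=%.4f  r_dot=%.4f  beta=%.4f\n",
    x$k, x$r_bar, x$r_dot_mean, x$beta_global
  ))
  invisible(x)
}

# Loading transform feeding the membership rule Phi(t) >= beta.
# zscore: within-component z-score of |loading| (default; beta acts as a
#   quantile-like threshold on each component's loading profile);
# abs: |loading| itself; raw: the eigenvector entry (the literal reading).
loading_transform_matrix <- function(model, m_max,
                                     transform = c("zscore", "abs", "raw")) {
  transform <- match.arg(transform)
  ld <- model$loadings[, seq_len(m_max), drop = FALSE]
  t_mat <- switch(transform,
    zscore = apply(abs(ld), 2, function(v) {
      s <- sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }),
    abs = abs(ld),
    raw = {
      if (is.null(model$rotation)) {
        abort("raw transform needs eigenvectors; not defined for kpca models")
      }
      model$rotation[, seq_len(m_max), drop = FALSE]
    }
  )
  t_mat <- matrix(t_mat, nrow = nrow(ld), dimnames = dimnames(ld))
  t_mat
}

#' Resolve features passing the membership rule for several components
#'
#' The component with the maximal absolute loading wins; exact ties go to the
#' lower component index.
#'
#' @param candidates Tibble with columns `feature`, `component`, `loading`
#'   (one row per passing feature-component pair).
#' @return Tibble with one row per feature: `feature`, `component`, `loading`.
#' @export
resolve_multiassignment <- function(candidates) {
  candidates |>
    dplyr::group_by(.data$feature) |>
    dplyr::arrange(dplyr::desc(abs(.data$loading)), .data$component,
      .by_group = TRUE
    ) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$component, .data$feature)
}

new_selection_result <- function(criterion, assignment, m_max, diagnostics) {
  retained_components <- sort(unique(assignment$component))
  structure(
    list(
      criterion = criterion,
      M_retained = length(retained_components),
      retained_components = retained_components,
      assignment = assignment,
      retained_features = assignment$feature,
      m_max = m_max,
      diagnostics = diagnostics
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> criterion=%s  M=%d  features=%d/%d\n",
    x$criterion, x$M_retained, length(x$retained_features),
    nrow(x$diagnostics$phi %||% x$assignment)
  ))
  invisible(x)
}

#' Assign features to components by the beta-thresholded membership rule
#'
#' A feature belongs to component `m` when `Phi(t_{m,i}) >= beta`, with `Phi`
#' the standard normal distribution function and `t` the configured loading
#' transform. Features passing for several components are resolved by
#' [resolve_multiassignment()]; components left with no member are pruned,
#' and the retained count `M` is the number of surviving components.
#'
#' @param model An `extraction_model`.
#' @param beta A `beta_result` from [compute_beta()], or a single numeric
#'   threshold in \[0, 1\].
#' @param m_max Number of candidate components the rule is applied to.
#' @param loading_transform `"zscore"` (default), `"abs"` or `"raw"`; see
#'   Details of [run_selection_pipeline()].
#' @param beta_ref Use the global beta (default) or each feature's own
#'   `beta_i` as its threshold.
#' @return A `selection_result`.
#' @export
assign_features <- function(model, beta, m_max = NULL,
                            loading_transform = c("zscore", "abs", "raw"),
                            beta_ref = c("global", "per_feature")) {
  loading_transform <- match.arg(loading_transform)
  beta_ref <- match.arg(beta_ref)
  m_max <- m_max %||% length(model$eigenvalues)
  if (m_max < 1) abort("m_max must be >= 1")
  thr <- beta_thresholds(beta, model$feature_names, beta_ref)
  t_mat <- loading_transform_matrix(model, m_max, loading_transform)
  phi <- pnorm(t_mat)
  pass <- phi >= thr # thr recycles over rows (features)
  if (!any(pass)) {
    abort("empty selection: no feature reaches the beta threshold")
  }
  ld <- model$loadings[, seq_len(m_max), drop = FALSE]
  idx <- which(pass, arr.ind = TRUE)
  candidates <- tibble::tibble(
    feature = model$feature_names[idx[, 1]],
    component = as.integer(idx[, 2]),
    loading = ld[idx]
  )
  assignment <- resolve_multiassignment(candidates)
  new_selection_result(
    criterion = "beta",
    assignment = assignment,
    m_max = m_max,
    diagnostics = list(
      beta = thr, phi = phi, transform = loading_transform,
      n_candidates = nrow(candidates)
    )
  )
}

beta_thresholds <- function(beta, feature_names, beta_ref) {
  if (inherits(beta, "beta_result")) {
    if (beta_ref == "global") beta$beta_global else beta$beta_per_feature
  } else {
    if (length(beta) != 1 || beta < 0 || beta > 1) {
      abort("`beta` must be a beta_result or a single value in [0, 1]")
    }
    as.numeric(beta)
  }
}

#' Beta selection with a kernel-SVM margin for ambiguous features
#'
#' Extends [assign_features()] for nonlinearly separated feature spaces. Each
#' feature gets a descriptor `(Phi(t_{1,i}), ..., Phi(t_{M,i}), beta_i)`.
#' Features whose best membership value clears the threshold by at least
#' `margin_delta` are labeled keep (+1), those at least `margin_delta` below
#' are labeled drop (-1); this margin-exterior labeling forms the teaching
#' sample on which a kernel SVM is trained, and the in-margin features are
#' classified by the SVM. Kept features are then assigned to components by
#' [resolve_multiassignment()]. With `margin_delta = 0` the result is
#' identical to the linear rule. A one-class teaching sample falls back to
#' the linear rule with a warning; an empty kept set is an error.
#'
#' @inheritParams assign_features
#' @param margin_delta Half-width of the ambiguity margin around beta.
#' @param kernel SVM kernel (`e1071::svm` naming).
#' @param seed Seed for the SVM fit.
#' @return A `selection_result` with margin diagnostics.
#' @export
svm_margin_select <- function(model, beta, m_max = NULL, margin_delta = 0.05,
                              kernel = "radial", seed = 1L,
                              loading_transform = c("zscore", "abs", "raw"),
                              beta_ref = c("global", "per_feature")) {
  loading_transform <- match.arg(loading_transform)
  beta_ref <- match.arg(beta_ref)
  if (margin_delta < 0) abort("`margin_delta` must be >= 0")
  m_max <- m_max %||% length(model$eigenvalues)
  thr <- beta_thresholds(beta, model$feature_names, beta_ref)
  t_mat <- loading_transform_matrix(model, m_max, loading_transform)
  phi <- pnorm(t_mat)
  beta_i <- if (inherits(beta, "beta_result")) {
    beta$beta_per_feature[model$feature_names]
  } else {
    rep(as.numeric(beta), length(model$feature_names))
  }
  descriptors <- cbind(phi, beta_i = beta_i)
  best <- apply(phi, 1, max)
  lab <- rep(NA_integer_, length(best))
  lab[best >= thr + margin_delta] <- 1L
  lab[best <= thr - margin_delta] <- -1L
  in_margin <- is.na(lab)
  fallback <- FALSE
  if (any(in_margin)) {
    teach <- which(!is.na(lab))
    if (length(unique(lab[teach])) < 2L) {
      warn("one-class teaching sample; falling back to the linear beta rule")
      fallback <- TRUE
      lab[in_margin] <- ifelse(best[in_margin] >= thr, 1L, -1L)
    } else {
      fit <- withr::with_seed(seed, e1071::svm(
        x = descriptors[teach, , drop = FALSE],
        y = factor(lab[teach], levels = c(-1L, 1L)),
        kernel = kernel, scale = FALSE
      ))
      pred <- predict(fit, descriptors[in_margin, , drop = FALSE])
      lab[in_margin] <- as.integer(as.character(pred))
    }
  }
  keep <- lab == 1L
  if (!any(keep)) abort("empty selection: the margin SVM kept no features")
  ld <- model$loadings[, seq_len(m_max), drop = FALSE]
  pass <- phi >= thr
  candidates <- purrr::map_dfr(which(keep), function(i) {
    comps <- which(pass[i, ])
    if (length(comps) == 0) comps <- which.max(abs(ld[i, ]))
    tibble::tibble(
      feature = model$feature_names[i],
      component = as.integer(comps),
      loading = ld[i, comps]
    )
  })
  assignment <- resolve_multiassignment(candidates)
  new_selection_result(
    criterion = "beta_svm",
    assignment = assignment,
    m_max = m_max,
    diagnostics = list(
      beta = thr, phi = phi, transform = loading_transform,
      margin_delta = margin_delta, n_in_margin = sum(in_margin),
      teaching_labels = lab, svm_fallback = fallback,
      descriptors = descriptors,
      label_construction = "margin-exterior labeling (package construction)"
    )
  )
}

# Classical criteria retain features by the conventional salient-loading
# cutoff over the retained components; assignment by max |loading|.
classical_assignment <- function(model, m, criterion, salient_cutoff = 0.5) {
  if (m == 0) {
    return(new_selection_result(
      criterion = criterion,
      assignment = tibble::tibble(
        feature = character(), component = integer(), loading = numeric()
      ),
      m_max = 0L,
      diagnostics = list(salient_cutoff = salient_cutoff)
    ))
  }
  ld <- model$loadings[, seq_len(m), drop = FALSE]
  idx <- which(abs(ld) >= salient_cutoff, arr.ind = TRUE)
  candidates <- tibble::tibble(
    feature = model$feature_names[idx[, 1]],
    component = as.integer(idx[, 2]),
    loading = ld[idx]
  )
  assignment <- resolve_multiassignment(candidates)
  new_selection_result(
    criterion = criterion,
    assignment = assignment,
    m_max = m,
    diagnostics = list(salient_cutoff = salient_cutoff, M_rule = m)
  )
}

#' Run the full component/feature-selection pipeline
#'
#' Standardizes the data, fits the requested extraction backend, initializes
#' the candidate component count `M_max` as the smallest number of components
#' reaching `var_target` cumulative explained variance, and applies the
#' chosen criterion:
#' \describe{
#'   \item{k, sp, ksp}{Kaiser, scree, or their fusion pick `M`; features are
#'     retained by the salient-loading cutoff (default `|loading| >= 0.5`)
#'     over those components.}
#'   \item{beta}{The reliability threshold of [compute_beta()] applied
#'     through [assign_features()] over the `M_max` candidates.}
#'   \item{beta_svm}{As `beta`, with the kernel-SVM margin of
#'     [svm_margin_select()].}
#' }
#'
#' The default loading transform maps each component's absolute loadings to
#' within-component z-scores before `Phi`, so the reliability threshold acts
#' as a quantile-like cut on each component's loading profile; `"abs"` and
#' `"raw"` expose the literal readings (raw unit-norm eigenvector entries
#' rarely exceed 0.4, so the literal rule retains nothing at realistic beta).
#'
#' @param data Data frame with a `risk_class` column (needed for ccpca), or a
#'   `hazard_dataset`.
#' @param method Extraction backend.
#' @param criterion One of `"k"`, `"sp"`, `"ksp"`, `"beta"`, `"beta_svm"`.
#' @param var_target Cumulative explained-variance horizon defining `M_max`.
#' @param salient_cutoff Loading cutoff for the classical criteria.
#' @param margin_delta,kernel Margin settings for `beta_svm`.
#' @param loading_transform,beta_ref See [assign_features()].
#' @param seed Seed for stochastic backends and the margin SVM.
#' @param gamma ccpca mixing weight.
#' @param kernel_params kpca kernel parameters.
#' @param verbose Log stage counts with `message()`.
#' @return A list of class `selection_pipeline` with `model`
#'   (`extraction_model`), `selection` (`selection_result`), `beta`
#'   (`beta_result` or `NULL`), and `log` (stage counts).
#' @examples
#' ds <- generate_dataset(generator_config(n_samples = 600, seed = 3))
#' fit <- run_selection_pipeline(ds, method = "pca", criterion = "beta")
#' fit$selection$M_retained
#' @export
run_selection_pipeline <- function(data,
                                   method = c("pca", "ccpca", "gpca", "kpca"),
                                   criterion = c("beta", "k", "sp", "ksp", "beta_svm"),
                                   var_target = 0.745,
                                   salient_cutoff = 0.5,
                                   margin_delta = 0.05,
                                   kernel = "rbf",
                                   loading_transform = "zscore",
                                   beta_ref = "global",
                                   seed = 1L,
                                   gamma = 0.1,
                                   kernel_params = list(),
                                   verbose = FALSE) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  if (inherits(data, "hazard_dataset")) data <- data$data
  parts <- as_feature_matrix(data)
  say <- function(...) if (verbose) message(sprintf(...))
  say("input: %d samples x %d features", nrow(parts$x), ncol(parts$x))

  model <- switch(method,
    pca = fit_pca(data),
    ccpca = fit_ccpca(data, gamma = gamma),
    gpca = fit_gpca(data, seed = derive_seed(seed, "gpca")),
    kpca = fit_kpca(data, kernel = if (kernel == "rbf") "rbf" else kernel,
      kernel_params = kernel_params
    )
  )
  cum <- cumsum(model$explained_variance)
  m_max <- max(1L, which(cum >= min(var_target, max(cum)))[1])
  say(
    "backend %s: %d components, M_max=%d (%.1f%% variance)",
    method, length(model$eigenvalues), m_max, 100 * cum[m_max]
  )

  beta <- NULL
  selection <- switch(criterion,
    k = classical_assignment(
      model, min(kaiser_select(model), m_max), "k", salient_cutoff
    ),
    sp = classical_assignment(
      model, min(scree_select(model), m_max), "sp", salient_cutoff
    ),
    ksp = classical_assignment(
      model, min(fused_select(model), m_max), "ksp", salient_cutoff
    ),
    beta = {
      beta <- compute_beta(tibble::as_tibble(as.data.frame(standardize(data))))
      assign_features(model, beta, m_max,
        loading_transform = loading_transform, beta_ref = beta_ref
      )
    },
    beta_svm = {
      beta <- compute_beta(tibble::as_tibble(as.data.frame(standardize(data))))
      svm_margin_select(model, beta, m_max,
        margin_delta = margin_delta,
        kernel = if (kernel == "rbf") "radial" else kernel,
        seed = derive_seed(seed, "svm"),
        loading_transform = loading_transform, beta_ref = beta_ref
      )
    }
  )
  say(
    "criterion %s: M=%d, %d features retained",
    criterion, selection$M_retained, length(selection$retained_features)
  )
  structure(
    list(
      model = model,
      selection = selection,
      beta = beta,
      log = list(
        n_samples = nrow(parts$x), n_features = ncol(parts$x),
        m_max = m_max, cum_variance_at_m_max = cum[m_max],
        M_retained = selection$M_retained,
        n_retained = length(selection$retained_features)
      )
    ),
    class = "selection_pipeline"
  )
}

#' @export
print.selection_pipeline <- function(x, ...) {
  cat(sprintf(
    "<selection_pipeline> %s + %s: M=%d, %d/%d features\n",
    x$model$method, x$selection$criterion, x$selection$M_retained,
    x$log$n_retained, x$log$n_features
  ))
  invisible(x)
}
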
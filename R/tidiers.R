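#' Tidy an extraction model into a long loadings table
#'
#' @param x An `extraction_model`.
#' @param ... Unused.
#' @return Tibble with `component`, `feature`, `loading`, `eigenvalue`,
#'   `explained_variance`.
#' @export
tidy.extraction_model <- function(x, ...) {
  ld <- x$loadings
  tibble::tibble(
    component = rep(seq_len(ncol(ld)), each = nrow(ld)),
    feature = rep(rownames(ld), ncol(ld)),
    loading = as.vector(ld),
    eigenvalue = rep(x$eigenvalues, each = nrow(ld)),
    explained_variance = rep(x$explained_variance, each = nrow(ld))
  )
}

#' @rdname tidy.extraction_model
#' @export
glance.extraction_model <- function(x, ...) {
  cum <- cumsum(x$explained_variance)
  tibble::tibble(
    method = x$method,
    n_features = length(x$feature_names),
    n_components = length(x$eigenvalues),
    lambda_max = x$eigenvalues[1],
    var_top4 = cum[min(4, length(cum))]
  )
}

#' Tidy a beta reliability result
#'
#' @param x A `beta_result`.
#' @param ... Unused.
#' @return Per-feature tibble with `feature`, `r_dot`, `beta_i`.
#' @export
tidy.beta_result <- function(x, ...) {
  tibble::tibble(
    feature = names(x$r_dot),
    r_dot = unname(x$r_dot),
    beta_i = unname(x$beta_per_feature)
  )
}

#' @rdname tidy.beta_result
#' @export
glance.beta_result <- function(x, ...) {
  tibble::tibble(
    k = x$k, r_bar = x$r_bar, r_dot = x$r_dot_mean, beta = x$beta_global
  )
}

#' Tidy a selection result into the feature-component assignment
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return Tibble with `feature`, `component`, `loading`.
#' @export
tidy.selection_result <- function(x, ...) {
  x$assignment
}

#' @rdname tidy.selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(
    criterion = x$criterion,
    M_retained = x$M_retained,
    n_retained = length(x$retained_features),
    m_max = x$m_max
  )
}

#' @export
tidy.selection_pipeline <- function(x, ...) tidy(x$selection)

#' @export
glance.selection_pipeline <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$selection),
    tibble::tibble(
      method = x$model$method,
      beta = if (!is.null(x$beta)) x$beta$beta_global else NA_real_,
      cum_variance = x$log$cum_variance_at_m_max
    )
  )
}

#' Tidy a benchmark report into per-fold rows
#'
#' @param x A `benchmark_report`.
#' @param ... Unused.
#' @return The long per-fold tibble.
#' @export
tidy.benchmark_report <- function(x, ...) {
  x$folds
}

#' @rdname tidy.benchmark_report
#' @export
glance.benchmark_report <- function(x, ...) {
  best <- x$folds |>
    dplyr::group_by(.data$method, .data$classifier) |>
    dplyr::summarise(bac = mean(.data$bac), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$bac))
  tibble::tibble(
    n_methods = length(x$method_order),
    n_classifiers = length(x$classifier_order),
    best_method = best$method[1],
    best_classifier = best$classifier[1],
    best_bac = best$bac[1]
  )
}
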
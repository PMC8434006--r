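#' Scree plot of an extraction model
#'
#' Eigenvalue against component rank, with the Kaiser reference line at 1.
#'
#' @param object An `extraction_model`.
#' @param n_components Number of leading components shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.extraction_model <- function(object, n_components = 20L, ...) {
  k <- min(n_components, length(object$eigenvalues))
  df <- tibble::tibble(component = seq_len(k), eigenvalue = object$eigenvalues[seq_len(k)])
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      title = paste0("Scree plot (", object$method, ")"),
      x = "component", y = "eigenvalue"
    ) +
    ggplot2::theme_minimal()
}

#' Membership-value map of a selection result
#'
#' Heatmap of the membership values `Phi(t)` per feature and candidate
#' component, with the retained feature-component assignments outlined.
#'
#' @param object A `selection_result` carrying `Phi` diagnostics.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.selection_result <- function(object, ...) {
  phi <- object$diagnostics$phi
  if (is.null(phi)) {
    df <- object$assignment
    return(
      ggplot2::ggplot(df, ggplot2::aes(
        x = factor(.data$component), y = abs(.data$loading)
      )) +
        ggplot2::geom_point() +
        ggplot2::labs(x = "component", y = "|loading|") +
        ggplot2::theme_minimal()
    )
  }
  long <- tibble::tibble(
    feature = rep(rownames(phi), ncol(phi)),
    component = rep(seq_len(ncol(phi)), each = nrow(phi)),
    phi = as.vector(phi)
  )
  assigned <- dplyr::mutate(object$assignment, assigned = TRUE)
  long <- dplyr::left_join(
    long, assigned[c("feature", "component", "assigned")],
    by = c("feature", "component")
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$component),
    y = factor(.data$feature, levels = rev(rownames(phi))),
    fill = .data$phi
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(
      data = dplyr::filter(long, isTRUE(.data$assigned) | .data$assigned %in% TRUE),
      fill = NA, colour = "black", linewidth = 0.4
    ) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(
      x = "component", y = NULL, fill = "Phi(t)",
      title = sprintf(
        "Membership values (criterion %s, beta threshold on fill scale)",
        object$criterion
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' @export
autoplot.selection_pipeline <- function(object, ...) {
  autoplot(object$selection, ...)
}

#' Mean balanced accuracy by method and classifier
#'
#' @param object A `benchmark_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.benchmark_report <- function(object, ...) {
  df <- object$folds |>
    dplyr::group_by(.data$method, .data$classifier) |>
    dplyr::summarise(bac = mean(.data$bac), .groups = "drop") |>
    dplyr::mutate(method = factor(.data$method, levels = object$method_order))
  ggplot2::ggplot(df, ggplot2::aes(
    .data$method, .data$bac,
    group = .data$classifier, colour = .data$classifier
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "balanced accuracy") +
    ggplot2::theme_minimal()
}

#' First two principal-component scores of a hazard dataset
#'
#' @param object A `hazard_dataset`.
#' @param max_points Subsample cap for plotting.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hazard_dataset <- function(object, max_points = 2000L, ...) {
  model <- fit_pca(object)
  sc <- transform_scores(object, model)
  df <- dplyr::bind_cols(
    tibble::tibble(risk_class = object$data$risk_class),
    sc[, 1:2]
  )
  if (nrow(df) > max_points) {
    df <- df[seq(1, nrow(df), length.out = max_points), ]
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$C1, .data$C2, colour = .data$risk_class)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "risk") +
    ggplot2::theme_minimal()
}
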
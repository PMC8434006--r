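#' Mixture exposure index for co-occurring substances
#'
#' For a mixture of `r` substances, the default (`"printed"`) rule is the
#' ratio of sums `sum(Ps_r) / sum(NDS_r)`: total shift-weighted exposure over
#' the total of the substances' permissible limits (TLV/NDS). The
#' `"conventional"` rule is the additive occupational-hygiene form
#' `sum(Ps_r / NDS_r)`, the sum of per-substance limit fractions.
#'
#' @param records Data frame with one row per substance and numeric columns
#'   `Ps` (shift-weighted exposure index) and `NDS` (permissible limit,
#'   mg/m3). Optional columns `Pch` and `Pp` (instantaneous and ceiling
#'   indices) are used only by `exposure_assessment()`; measurement metadata
#'   such as `Cw` (weighted mean shift concentration) and `GGw` (upper
#'   confidence bound of the weighted mean, both mg/m3) may be carried along
#'   and are ignored by the index computations.
#' @param rule `"printed"` or `"conventional"`.
#' @return A single numeric index.
#' @examples
#' mixture_exposure_index(data.frame(Ps = c(1, 1), NDS = c(2, 2)))
#' @export
mixture_exposure_index <- function(records, rule = c("printed", "conventional")) {
  rule <- match.arg(rule)
  records <- as.data.frame(records)
  if (nrow(records) == 0) abort("`records` must contain at least one substance")
  for (col in c("Ps", "NDS")) {
    if (!col %in% names(records) || !is.numeric(records[[col]])) {
      abort(paste0("`records` must have a numeric `", col, "` column"))
    }
  }
  if (any(records$NDS <= 0)) abort("all `NDS` limits must be positive")
  if (any(records$Ps < 0)) abort("`Ps` indices must be non-negative")
  switch(rule,
    printed = sum(records$Ps) / sum(records$NDS),
    conventional = sum(records$Ps / records$NDS)
  )
}

#' Map an exposure index to a risk level
#'
#' Applies a strictly increasing two-threshold ladder: indices up to the
#' first threshold are `low`, up to the second `medium`, above it `high`.
#' Boundary values belong to the lower band. The default ladder (0.5, 1.0)
#' follows the standard occupational-hygiene convention for exposure indices
#' relative to the permissible limit.
#'
#' @param index Numeric exposure index (vectorized).
#' @param thresholds Strictly increasing numeric vector of length 2.
#' @return Factor with levels `low`, `medium`, `high`.
#' @examples
#' risk_level(c(0.5, 0.75, 1.01))
#' @export
risk_level <- function(index, thresholds = c(0.5, 1.0)) {
  if (length(thresholds) != 2 || diff(thresholds) <= 0) {
    abort("`thresholds` must be two strictly increasing values")
  }
  out <- dplyr::case_when(
    index <= thresholds[1] ~ "low",
    index <= thresholds[2] ~ "medium",
    TRUE ~ "high"
  )
  factor(out, levels = c("low", "medium", "high"))
}

#' Combined exposure assessment over all three index families
#'
#' Computes the mixture index over the shift-weighted `Ps` values and, when
#' `use_all_indices = TRUE`, also over the instantaneous (`Pch`) and ceiling
#' (`Pp`) columns where present, taking the maximum as the governing index.
#' The three-index combination rule is a package construction: the source
#' risk-estimation ladder only gestures at how the instantaneous and ceiling
#' indices enter the final call, so the combination is configurable and
#' flagged in the output.
#'
#' @inheritParams mixture_exposure_index
#' @param thresholds Risk ladder passed to [risk_level()].
#' @param use_all_indices Also consider `Pch`/`Pp` columns via a max rule.
#' @return A one-row tibble with the index, the governing index family, the
#'   risk level, and a `construction` note.
#' @export
exposure_assessment <- function(records, rule = c("printed", "conventional"),
                                thresholds = c(0.5, 1.0),
                                use_all_indices = FALSE) {
  rule <- match.arg(rule)
  idx <- c(Ps = mixture_exposure_index(records, rule))
  if (use_all_indices) {
    for (col in c("Pch", "Pp")) {
      if (col %in% names(records) && any(!is.na(records[[col]]))) {
        rec <- records[!is.na(records[[col]]), ]
        rec$Ps <- rec[[col]]
        idx[col] <- mixture_exposure_index(rec, rule)
      }
    }
  }
  governing <- names(idx)[which.max(idx)]
  tibble::tibble(
    index = max(idx),
    governing = governing,
    risk = risk_level(max(idx), thresholds),
    rule = rule,
    construction = if (use_all_indices) {
      "max over Ps/Pch/Pp mixture indices (package construction)"
    } else {
      "Ps mixture index"
    }
  )
}
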
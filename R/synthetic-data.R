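#' Configuration for the synthetic chemical-hazard generator
#'
#' Builds the parameter set for [generate_dataset()]. Defaults emulate the
#' printed structure of a 40,000-record, 63-feature occupational
#' chemical-hazard sensor dataset: three feature groups (toxic,
#' physicochemical, network security), four imbalanced risk classes, a
#' low-dimensional latent-factor structure in which about four components
#' carry about 80% of the variance, and a planted informative subspace of
#' 18 features (6/7/5 per group) that alone carries the class-centroid
#' separation.
#'
#' @param n_samples Number of records.
#' @param group_sizes Named integer vector of features per group, in order
#'   toxic, physicochemical, network_security.
#' @param class_fractions Proportions of the low/medium/high risk classes;
#'   the no-risk class takes the remainder. Must sum to less than 1.
#' @param informative_per_group Number of class-informative features per
#'   group; these are the only features with nonzero class-centroid
#'   displacement.
#' @param n_latent_factors Number of common latent factors.
#' @param centroid_separation Euclidean norm (in pre-standardization feature
#'   units, i.e. within-class total-SD units) of the centroid displacement
#'   between adjacent risk levels. Risk levels are ordinal: no = 0, low = 1,
#'   medium = 2, high = 3 times this displacement.
#' @param noise_sd Multiplier on each feature's residual (uniqueness) SD;
#'   1 keeps total pre-standardization variance at 1.
#' @param nonlinear_fraction Fraction of features generated as a monotone
#'   nonlinear transform (signed square or exponential) of their dominant
#'   latent factor instead of the linear map. Drawn from the
#'   non-informative features so the planted class signal stays linear.
#' @param centroid_alignment In \[0, 1\]: how strongly the class-displacement
#'   direction aligns with the informative features' hazard-factor response
#'   (1 = fully along it, 0 = a random direction in the informative
#'   subspace).
#' @param hazard_loading_share,secondary_hazard_share Shares of each
#'   informative feature's communality carried by the primary and secondary
#'   hazard-response factors (the last two latent factors, loaded only by
#'   informative features); the remainder loads the dense "process" factors
#'   shared by all features. The secondary response is deliberately weak: it
#'   forms a minor trailing component that eigenvalue-ranking criteria tend
#'   to discard.
#' @param n_distractors Number of non-informative "distractor" channels that
#'   co-load the hazard-intensity factor (shared process-intensity variance)
#'   while carrying zero class displacement.
#' @param distractor_loading_share Communality share a distractor channel
#'   puts on the hazard factor; kept moderate so distractors load the hazard
#'   component weakly relative to the informative channels.
#' @param informative_communality,other_communality Length-2 ranges of the
#'   per-feature communality (variance share carried by the latent factors)
#'   for informative and non-informative features.
#' @param cyber_counts If `TRUE`, network-security features are generated as
#'   log-scale counts (rounded exponentials) and then normal-scored, mimicking
#'   count-valued telemetry such as lost packets or failed logins.
#' @param seed Integer seed; fully determines the output.
#'
#' @return A list of class `generator_config`.
#' @seealso [generate_dataset()]
#' @export
generator_config <- function(n_samples = 40000L,
                             group_sizes = c(
                               toxic = 18L, physicochemical = 28L,
                               network_security = 17L
                             ),
                             class_fractions = c(
                               low = 0.121, medium = 0.04, high = 0.035
                             ),
                             informative_per_group = c(
                               toxic = 6L, physicochemical = 7L,
                               network_security = 5L
                             ),
                             n_latent_factors = 5L,
                             centroid_separation = 5,
                             noise_sd = 1,
                             nonlinear_fraction = 0.15,
                             centroid_alignment = 0.95,
                             hazard_loading_share = 0.45,
                             secondary_hazard_share = 0.15,
                             n_distractors = 0L,
                             distractor_loading_share = 0.35,
                             informative_communality = c(0.88, 0.96),
                             other_communality = c(0.55, 0.80),
                             cyber_counts = TRUE,
                             seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    group_sizes = group_sizes,
    class_fractions = class_fractions,
    informative_per_group = informative_per_group,
    n_latent_factors = as.integer(n_latent_factors),
    centroid_separation = centroid_separation,
    noise_sd = noise_sd,
    nonlinear_fraction = nonlinear_fraction,
    centroid_alignment = centroid_alignment,
    hazard_loading_share = hazard_loading_share,
    secondary_hazard_share = secondary_hazard_share,
    n_distractors = as.integer(n_distractors),
    distractor_loading_share = distractor_loading_share,
    informative_communality = informative_communality,
    other_communality = other_communality,
    cyber_counts = isTRUE(cyber_counts),
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (length(cfg$group_sizes) != 3L || any(cfg$group_sizes < 1L)) {
    abort("`group_sizes` must give a positive size for each of the three groups")
  }
  if (sum(cfg$class_fractions) >= 1) {
    abort("`class_fractions` must sum to less than 1 (no-risk takes the remainder)")
  }
  if (any(cfg$class_fractions <= 0)) {
    abort("`class_fractions` must all be positive")
  }
  if (length(cfg$informative_per_group) != 3L ||
      any(cfg$informative_per_group > cfg$group_sizes)) {
    abort("`informative_per_group` must be <= `group_sizes` elementwise")
  }
  if (cfg$n_latent_factors < 1L) abort("`n_latent_factors` must be >= 1")
  if (cfg$nonlinear_fraction < 0 || cfg$nonlinear_fraction >= 1) {
    abort("`nonlinear_fraction` must be in [0, 1)")
  }
  if (cfg$centroid_alignment < 0 || cfg$centroid_alignment > 1) {
    abort("`centroid_alignment` must be in [0, 1]")
  }
  if (cfg$hazard_loading_share < 0 || cfg$secondary_hazard_share < 0 ||
      cfg$hazard_loading_share + cfg$secondary_hazard_share >= 1) {
    abort("hazard loading shares must be non-negative and sum below 1")
  }
  if (cfg$n_distractors < 0 ||
      cfg$n_distractors > sum(cfg$group_sizes) - sum(cfg$informative_per_group)) {
    abort("`n_distractors` must fit among the non-informative features")
  }
  if (cfg$distractor_loading_share < 0 || cfg$distractor_loading_share >= 1) {
    abort("`distractor_loading_share` must be in [0, 1)")
  }
  counts <- class_counts(cfg$n_samples, cfg$class_fractions)
  if (any(counts == 0L)) {
    abort("`n_samples` is too small to realize every risk class")
  }
  invisible(cfg)
}

risk_classes <- c("no", "low", "medium", "high")

# Largest-remainder allocation of n among the four risk classes; exact counts
# beat expected counts for testability. Ties go to the earlier class.
class_counts <- function(n, class_fractions) {
  frac <- c(no = 1 - sum(class_fractions), class_fractions)
  names(frac) <- risk_classes
  exact <- frac * n
  counts <- floor(exact)
  left <- n - sum(counts)
  if (left > 0) {
    rem <- exact - counts
    top <- order(rem, decreasing = TRUE)[seq_len(left)]
    counts[top] <- counts[top] + 1
  }
  stats::setNames(as.integer(counts), risk_classes)
}

cyber_feature_names <- c(
  "packets_lost", "incorrect_logins", "incorrect_sensor_responses",
  "email_spam", "network_traffic"
)

make_feature_names <- function(group_sizes) {
  n_net <- group_sizes[[3]]
  net <- c(
    head(cyber_feature_names, min(5L, n_net)),
    if (n_net > 5L) sprintf("net_%02d", 6:n_net)
  )
  c(
    sprintf("tox_%02d", seq_len(group_sizes[[1]])),
    sprintf("phc_%02d", seq_len(group_sizes[[2]])),
    net
  )
}

#' Generate a seeded synthetic chemical-hazard dataset
#'
#' Draws a sample-by-feature table from a planted latent-factor model. Each
#' record is `x = Lambda f + mu_class + eps` with standard-normal latent
#' factors `f`, a factor-loading matrix `Lambda` of dense unit directions
#' scaled by per-feature communalities, a class-centroid displacement
#' `mu_class` supported only on the informative features, and independent
#' residual noise. A configurable minority of features replaces the linear
#' map with a monotone nonlinearity of the dominant factor, network-security
#' features can be generated as normal-scored log-scale counts, and all
#' columns are standardized (mean 0, SD 1, population convention) on output.
#' Class counts are allocated exactly by largest-remainder rounding.
#'
#' @param config A [generator_config()].
#'
#' @return A list of class `hazard_dataset` with elements
#'   \describe{
#'     \item{data}{tibble: `risk_class` factor plus one numeric column per feature.}
#'     \item{feature_groups}{tibble with columns `feature`, `group`.}
#'     \item{truth}{ground truth: `loading_matrix`, `informative_set`,
#'       `class_centroids` (per-class feature-space displacement),
#'       `nonlinear_features`, `latent_scores`, `class_levels`.}
#'     \item{config}{the echoed configuration.}
#'   }
#' @examples
#' ds <- generate_dataset(generator_config(n_samples = 400, seed = 7))
#' table(ds$data$risk_class)
#' @export
generate_dataset <- function(config = generator_config()) {
  validate_generator_config(config)
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  n <- cfg$n_samples
  p <- sum(cfg$group_sizes)
  q <- cfg$n_latent_factors
  feat <- make_feature_names(cfg$group_sizes)
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)

  counts <- class_counts(n, cfg$class_fractions)
  labels <- sample(rep(risk_classes, counts))
  labels <- factor(labels, levels = risk_classes)
  level <- as.integer(labels) - 1L # ordinal risk level 0..3

  # informative features: seeded draw per group; the named cyber telemetry
  # channels come first in the network group so they are informative by default
  group_idx <- split(seq_len(p), factor(groups, levels = names(cfg$group_sizes)))
  informative <- integer(0)
  for (g in seq_along(group_idx)) {
    k <- cfg$informative_per_group[[g]]
    idx <- group_idx[[g]]
    if (g == 3L) {
      pick <- idx[seq_len(k)]
    } else {
      pick <- sort(sample(idx, k))
    }
    informative <- c(informative, pick)
  }

  # per-feature communality: informative channels are the most strongly
  # factor-driven ones
  h <- numeric(p)
  h[informative] <- runif(
    length(informative),
    cfg$informative_communality[1], cfg$informative_communality[2]
  )
  h[-informative] <- runif(
    p - length(informative),
    cfg$other_communality[1], cfg$other_communality[2]
  )

  # factor structure: the last two factors are hazard-response factors
  # (primary and secondary), loaded only by the informative features; the
  # remaining "process" factors are loaded densely by every feature (random
  # unit directions scaled by sqrt(communality))
  n_hz <- min(2L, q - 1L) # hazard factors actually available
  q_proc <- max(1L, q - n_hz)
  i_h1 <- if (n_hz >= 1L) q_proc + 1L else 0L
  i_h2 <- if (n_hz >= 2L) q_proc + 2L else 0L
  dirs <- matrix(rnorm(p * q_proc), p, q_proc)
  dirs <- dirs / sqrt(pmax(rowSums(dirs^2), 1e-12))
  lambda <- matrix(0, p, q)
  lambda[, seq_len(q_proc)] <- dirs * sqrt(h)
  s1 <- if (n_hz >= 1L) cfg$hazard_loading_share else 0
  s2 <- if (n_hz >= 2L) cfg$secondary_hazard_share else 0
  distractors <- integer(0)
  if (n_hz >= 1L) {
    lambda[informative, seq_len(q_proc)] <-
      dirs[informative, , drop = FALSE] * sqrt((1 - s1 - s2) * h[informative])
    lambda[informative, i_h1] <-
      sample(c(-1, 1), length(informative), TRUE) * sqrt(s1 * h[informative])
    if (n_hz >= 2L) {
      lambda[informative, i_h2] <-
        sample(c(-1, 1), length(informative), TRUE) * sqrt(s2 * h[informative])
    }
    # distractor channels: co-load the primary hazard factor (shared
    # process-intensity variance) but receive no class displacement; the
    # weakly-loading channels a discrimination-aware criterion should reject
    n_d <- min(cfg$n_distractors, p - length(informative))
    if (n_d > 0) {
      distractors <- sort(sample(setdiff(seq_len(p), informative), n_d))
      d_s <- cfg$distractor_loading_share
      d_sign <- sample(c(-1, 1), n_d, replace = TRUE)
      lambda[distractors, seq_len(q_proc)] <-
        dirs[distractors, , drop = FALSE] * sqrt((1 - d_s) * h[distractors])
      lambda[distractors, i_h1] <- d_sign * sqrt(d_s * h[distractors])
    }
  }
  rownames(lambda) <- feat

  # class displacement: unit vector supported on the informative set;
  # `centroid_alignment` is the share of squared displacement lying along the
  # channels' primary hazard response, the rest along the secondary response
  # (noise-tempered like the primary, so it offers no shortcut direction)
  u <- numeric(p)
  if (n_hz >= 1L) {
    c1 <- lambda[informative, i_h1]
    c1 <- c1 / sqrt(sum(c1^2))
    c2 <- if (n_hz >= 2L) lambda[informative, i_h2] else rnorm(length(informative))
    c2 <- c2 - sum(c2 * c1) * c1
    c2 <- c2 / sqrt(sum(c2^2))
    a <- cfg$centroid_alignment
    u_inf <- sqrt(a) * c1 + sqrt(1 - a) * c2
  } else {
    r <- rnorm(q)
    u_inf <- drop(lambda[informative, , drop = FALSE] %*% (r / sqrt(sum(r^2))))
  }
  u[informative] <- u_inf / sqrt(sum(u_inf^2))

  f <- matrix(rnorm(n * q), n, q)
  resid_sd <- cfg$noise_sd * sqrt(pmax(0, 1 - h))
  x <- f %*% t(lambda) +
    tcrossprod(level * cfg$centroid_separation, u) +
    matrix(rnorm(n * p), n, p) * rep(resid_sd, each = n)

  # monotone nonlinear features, drawn from the non-informative set
  n_nl <- round(cfg$nonlinear_fraction * p)
  nonlinear <- integer(0)
  if (n_nl > 0) {
    pool <- setdiff(seq_len(p), c(informative, distractors))
    nonlinear <- sort(sample(pool, min(n_nl, length(pool))))
    for (j in seq_along(nonlinear)) {
      i <- nonlinear[j]
      dom <- which.max(abs(lambda[i, ]))
      fd <- f[, dom]
      g <- if (j %% 2L == 1L) {
        fd * abs(fd) / sqrt(3) # signed square, unit variance
      } else {
        (exp(fd) - exp(0.5)) / sqrt(exp(2) - exp(1))
      }
      x[, i] <- sqrt(h[i]) * g + rnorm(n) * resid_sd[i]
    }
  }

  # network telemetry as normal-scored log-scale counts
  if (cfg$cyber_counts) {
    for (i in group_idx[[3]]) {
      cnt <- round(exp(5 + 1.2 * x[, i]))
      x[, i] <- qnorm((rank(cnt, ties.method = "average") - 0.5) / n)
    }
  }

  m_col <- colMeans(x)
  x <- sweep(x, 2, m_col)
  s_col <- sqrt(colMeans(x^2))
  if (any(s_col == 0)) abort("degenerate zero-variance feature generated")
  x <- sweep(x, 2, s_col, "/")
  colnames(x) <- feat

  data <- tibble::as_tibble(as.data.frame(x))
  data <- dplyr::bind_cols(tibble::tibble(risk_class = labels), data)

  # ground truth in output units: the generated columns are standardized, so
  # loading rows and centroids are rescaled by the realized column SDs
  centroids <- outer(0:3 * cfg$centroid_separation, u / s_col)
  rownames(centroids) <- risk_classes
  colnames(centroids) <- feat

  truth <- list(
    loading_matrix = lambda / s_col,
    informative_set = feat[informative],
    class_centroids = centroids,
    nonlinear_features = feat[nonlinear],
    distractor_set = feat[distractors],
    latent_scores = f,
    class_levels = stats::setNames(0:3, risk_classes)
  )

  structure(
    list(
      data = data,
      feature_groups = tibble::tibble(feature = feat, group = groups),
      truth = truth,
      config = cfg
    ),
    class = "hazard_dataset"
  )
}

# column standardization, population-SD convention
scale_pop <- function(x) {
  m <- colMeans(x)
  x <- sweep(x, 2, m)
  s <- sqrt(colMeans(x^2))
  if (any(s == 0)) {
    abort(paste0(
      "zero-variance column: ",
      paste(colnames(x)[s == 0], collapse = ", ")
    ))
  }
  sweep(x, 2, s, "/")
}

#' @export
print.hazard_dataset <- function(x, ...) {
  cat(
    "<hazard_dataset> ", nrow(x$data), " samples x ",
    nrow(x$feature_groups), " features\n",
    sep = ""
  )
  print(table(x$data$risk_class))
  invisible(x)
}

#' Write / read a hazard dataset as CSV plus JSON sidecar
#'
#' `write_dataset()` writes the sample table to `path` as a headered CSV with
#' a `risk_class` column, and a JSON sidecar (same path, `.json` extension)
#' holding the feature-group map, the generator configuration echo and the
#' ground truth (latent scores excluded). `read_dataset()` reads both back;
#' without a sidecar, feature groups are inferred from the naming convention.
#' The CSV round-trip is lossless: values are written with full
#' round-trip precision.
#'
#' @param dataset A `hazard_dataset` (or any data frame with a `risk_class`
#'   column for `write_dataset`).
#' @param path CSV file path.
#' @param sidecar Write/read the JSON sidecar?
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a `hazard_dataset`.
#' @export
write_dataset <- function(dataset, path, sidecar = TRUE) {
  if (inherits(dataset, "hazard_dataset")) {
    data <- dataset$data
    meta <- list(
      feature_groups = dataset$feature_groups,
      config = unclass(dataset$config),
      truth = truth_for_sidecar(dataset$truth)
    )
  } else {
    data <- tibble::as_tibble(dataset)
    meta <- NULL
  }
  if (!"risk_class" %in% names(data)) {
    abort("dataset must contain a `risk_class` column")
  }
  readr::write_csv(data, path, progress = FALSE)
  if (sidecar && !is.null(meta)) {
    jsonlite::write_json(
      meta, sidecar_path(path),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(path)
}

truth_for_sidecar <- function(truth) {
  if (is.null(truth)) return(NULL)
  list(
    loading_matrix = truth$loading_matrix,
    informative_set = truth$informative_set,
    class_centroids = truth$class_centroids,
    nonlinear_features = truth$nonlinear_features,
    class_levels = truth$class_levels
  )
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, sidecar = TRUE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (file.size(path) == 0) abort(paste0("parse error: ", path, " is empty"))
  # read through strtod (exact double parsing) so a write -> read -> write
  # cycle is byte-identical; validation reports the offending row and column
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  header <- names(raw)
  if (!"risk_class" %in% header) {
    abort("parse error: malformed header, no `risk_class` column")
  }
  feat <- setdiff(header, "risk_class")
  num <- vector("list", length(feat))
  names(num) <- feat
  for (col in feat) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf(
        "parse error: non-numeric cell at row %d, column %s (%d problem cells)",
        bad[1], col, length(bad)
      ))
    }
    num[[col]] <- v
  }
  bad <- which(!raw$risk_class %in% risk_classes)
  if (length(bad) > 0) {
    abort(sprintf(
      "parse error: unknown class label '%s' at row %d of column risk_class",
      raw$risk_class[bad[1]], bad[1]
    ))
  }
  data <- dplyr::bind_cols(
    tibble::tibble(risk_class = factor(raw$risk_class, levels = risk_classes)),
    tibble::as_tibble(num)
  )[header]

  meta <- NULL
  sp <- sidecar_path(path)
  if (sidecar && file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  }
  groups <- if (!is.null(meta$feature_groups)) {
    tibble::as_tibble(meta$feature_groups)
  } else {
    tibble::tibble(feature = feat, group = infer_groups(feat))
  }
  truth <- NULL
  if (!is.null(meta$truth)) {
    truth <- meta$truth
    truth$loading_matrix <- as.matrix(truth$loading_matrix)
    rownames(truth$loading_matrix) <- feat
    truth$class_centroids <- as.matrix(truth$class_centroids)
    rownames(truth$class_centroids) <- risk_classes
    truth$class_levels <- unlist(truth$class_levels)
  }
  structure(
    list(
      data = data,
      feature_groups = groups,
      truth = truth,
      config = meta$config
    ),
    class = "hazard_dataset"
  )
}

infer_groups <- function(feat) {
  dplyr::case_when(
    startsWith(feat, "tox_") ~ "toxic",
    startsWith(feat, "phc_") ~ "physicochemical",
    startsWith(feat, "net_") | feat %in% cyber_feature_names ~
      "network_security",
    TRUE ~ "unknown"
  )
}
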
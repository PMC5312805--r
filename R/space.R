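#' Define a syllable representational space
#'
#' Syllable categories live in a two-dimensional representational space whose
#' x-axis carries auditory features and whose y-axis carries visual features
#' (arbitrary "space units"). Each category is summarised by a prototype
#' location, a shared isotropic category covariance (exemplars of a syllable
#' scatter around the prototype), and a prior probability.
#'
#' When the labels are exactly `"ba"`, `"da"`, `"ga"` the canonical ordering
#' constraints are enforced: "da" lies strictly between "ba" and "ga" on both
#' axes, closer to "ba" on the auditory x-axis and closer to "ga" on the
#' visual y-axis. This encodes the pairwise confusability structure of the
#' three syllables.
#'
#' @param prototypes Data frame with columns `label`, `x`, `y`: one row per
#'   syllable category, giving its prototype location.
#' @param category_sd Standard deviation of the category distribution along
#'   each axis (space units). The category covariance is
#'   `diag(category_sd^2, 2)`: zero covariance, equal variances.
#' @param priors Optional numeric vector of prior category probabilities in
#'   label order; defaults to uniform. Must be nonnegative and sum to 1.
#'
#' @return An object of class `cims_space`: a list with elements `labels`,
#'   `prototypes` (tibble), `category_sd`, `category_cov` (2x2 matrix) and
#'   `priors` (named numeric).
#' @examples
#' sp <- syllable_space(
#'   data.frame(label = c("ba", "da", "ga"),
#'              x = c(0, 0.33, 1), y = c(0, 0.67, 1)),
#'   category_sd = 0.12
#' )
#' sp
#' @export
syllable_space <- function(prototypes, category_sd = 0.1, priors = NULL) {
  prototypes <- as_tibble(prototypes)
  req <- c("label", "x", "y")
  if (!all(req %in% names(prototypes))) {
    abort(paste0("`prototypes` must have columns ",
                 paste(req, collapse = ", ")),
          class = "cims_validation_error")
  }
  prototypes <- prototypes[, req]
  prototypes$label <- as.character(prototypes$label)
  labels <- prototypes$label
  if (length(labels) < 1L || anyDuplicated(labels) > 0L) {
    abort("at least 1 unique syllable label is required",
          class = "cims_validation_error")
  }
  if (!all(is.finite(prototypes$x)) || !all(is.finite(prototypes$y))) {
    abort("prototype coordinates must be finite",
          class = "cims_validation_error")
  }
  if (!is.numeric(category_sd) || length(category_sd) != 1L ||
      !is.finite(category_sd) || category_sd <= 0) {
    abort("`category_sd` must be a single positive number",
          class = "cims_validation_error")
  }
  if (is.null(priors)) priors <- rep(1 / length(labels), length(labels))
  if (length(priors) != length(labels) || any(priors < 0) ||
      abs(sum(priors) - 1) > 1e-8) {
    abort("`priors` must be nonnegative, one per label, and sum to 1",
          class = "cims_validation_error")
  }
  priors <- stats::setNames(as.numeric(priors), labels)

  space <- structure(
    list(labels = labels,
         prototypes = prototypes,
         category_sd = as.numeric(category_sd),
         category_cov = diag(category_sd^2, 2L),
         priors = priors),
    class = "cims_space")
  check_canonical_ordering(space)
  space
}

# "da" intermediate on both axes, nearer "ba" auditorily, nearer "ga" visually
check_canonical_ordering <- function(space) {
  if (!setequal(space$labels, c("ba", "da", "ga"))) return(invisible(space))
  p <- prototype_matrix(space)
  ba <- p["ba", ]; da <- p["da", ]; ga <- p["ga", ]
  between <- function(v, a, b) v > min(a, b) && v < max(a, b)
  ok <- between(da[1], ba[1], ga[1]) && between(da[2], ba[2], ga[2]) &&
    abs(da[1] - ba[1]) < abs(da[1] - ga[1]) &&
    abs(da[2] - ga[2]) < abs(da[2] - ba[2])
  if (!ok) {
    abort(paste0("invalid prototype layout: 'da' must lie strictly between ",
                 "'ba' and 'ga' on both axes, closer to 'ba' on the auditory ",
                 "x-axis and closer to 'ga' on the visual y-axis"),
          class = "cims_validation_error")
  }
  invisible(space)
}

#' @export
print.cims_space <- function(x, ...) {
  cat("<cims_space> ", length(x$labels), " syllable categories\n", sep = "")
  print(x$prototypes)
  cat("category_sd:", format(x$category_sd), "(space units)\n")
  cat("priors:", paste(sprintf("%s=%.3g", names(x$priors), x$priors),
                       collapse = ", "), "\n")
  invisible(x)
}

prototype_matrix <- function(space) {
  m <- as.matrix(space$prototypes[, c("x", "y")])
  rownames(m) <- space$labels
  m
}

prototype_of <- function(space, label) {
  if (!label %in% space$labels) {
    abort(paste0("unknown syllable label '", label, "'; space has: ",
                 paste(space$labels, collapse = ", ")),
          class = "cims_lookup_error")
  }
  as.numeric(prototype_matrix(space)[label, ])
}

#' Define the sensory-noise model
#'
#' Each modality encodes a stimulus with independent bivariate Gaussian noise.
#' A unisensory cue is more precise along its own feature axis: the standard
#' deviation along the *other* axis is inflated by the `anisotropy` factor
#' (default 1.5). With `sigma_a == sigma_v` the two noise covariances are
#' axis-swapped rotations of one another.
#'
#' @param sigma_a Noise SD of the auditory channel along the auditory x-axis
#'   (space units).
#' @param sigma_v Noise SD of the visual channel along the visual y-axis
#'   (space units).
#' @param anisotropy Cross-axis SD multiplier, `>= 1`.
#' @return An object of class `cims_noise`.
#' @seealso [noise_covariances()]
#' @export
noise_model <- function(sigma_a, sigma_v, anisotropy = 1.5) {
  for (nm in c("sigma_a", "sigma_v")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(paste0("`", nm, "` must be a single positive number"),
            class = "cims_validation_error")
    }
  }
  if (!is.numeric(anisotropy) || length(anisotropy) != 1L ||
      !is.finite(anisotropy) || anisotropy < 1) {
    abort("`anisotropy` must be a single number >= 1",
          class = "cims_validation_error")
  }
  structure(list(sigma_a = as.numeric(sigma_a),
                 sigma_v = as.numeric(sigma_v),
                 anisotropy = as.numeric(anisotropy)),
            class = "cims_noise")
}

#' @export
print.cims_noise <- function(x, ...) {
  cat(sprintf("<cims_noise> sigma_a=%.4g sigma_v=%.4g anisotropy=%.3g\n",
              x$sigma_a, x$sigma_v, x$anisotropy))
  invisible(x)
}

#' Sensory-noise covariance matrices
#'
#' Builds the 2x2 encoding covariances: the auditory channel has variance
#' `sigma_a^2` along the auditory x-axis and `(anisotropy * sigma_a)^2` along
#' the visual y-axis; the visual channel is the axis-swapped analogue.
#'
#' @param noise A [noise_model()].
#' @return A list with 2x2 matrices `sigma_a_cov` and `sigma_v_cov`.
#' @examples
#' noise_covariances(noise_model(1, 1, 1.5))
#' @export
noise_covariances <- function(noise) {
  stopifnot(inherits(noise, "cims_noise"))
  k <- noise$anisotropy
  list(
    sigma_a_cov = diag(c(noise$sigma_a^2, (k * noise$sigma_a)^2)),
    sigma_v_cov = diag(c((k * noise$sigma_v)^2, noise$sigma_v^2))
  )
}

#' Assemble a full model configuration
#'
#' Bundles everything one simulation run needs: the representational space,
#' the sensory-noise model, the prior probability of a common cause, the
#' number of Monte-Carlo trials per stimulus, the combination strategy, and
#' the RNG seed.
#'
#' @param space A [syllable_space()].
#' @param noise A [noise_model()].
#' @param prior_common Prior probability `P(C = 1)` that the auditory and
#'   visual cues share a common cause, in `[0, 1]`. `1` forces fusion (the
#'   non-causal-inference baseline); `0.5` expresses no prior bias.
#' @param n_trials Default Monte-Carlo trials per stimulus (`>= 1`).
#' @param strategy How the fused (`C = 1`) and auditory-only (`C = 2`)
#'   representations are combined: `"averaging"` (posterior-weighted average,
#'   the default model), `"selection"` (winner-take-all) or `"matching"`
#'   (probability matching).
#' @param c2_eval How the separate-cause likelihood is evaluated: `"fused"`
#'   (default; density of the inflated-precision fusion statistic) or
#'   `"joint"` (product of the two unisensory cue densities), provided for
#'   sensitivity analysis.
#' @param seed Integer RNG seed.
#' @param meta Optional named list of free-form metadata (e.g. calibration
#'   provenance), carried through config files untouched.
#' @return An object of class `cims_config`.
#' @export
model_config <- function(space, noise, prior_common = 0.5,
                         n_trials = 10000L,
                         strategy = c("averaging", "selection", "matching"),
                         c2_eval = c("fused", "joint"),
                         seed = 1L, meta = list()) {
  if (!inherits(space, "cims_space")) {
    abort("`space` must be a cims_space", class = "cims_validation_error")
  }
  if (!inherits(noise, "cims_noise")) {
    abort("`noise` must be a cims_noise", class = "cims_validation_error")
  }
  if (!is.numeric(prior_common) || length(prior_common) != 1L ||
      is.na(prior_common) || prior_common < 0 || prior_common > 1) {
    abort("`prior_common` must be a probability in [0, 1]",
          class = "cims_validation_error")
  }
  if (!is.numeric(n_trials) || length(n_trials) != 1L ||
      is.na(n_trials) || n_trials < 1) {
    abort("`n_trials` must be >= 1", class = "cims_validation_error")
  }
  strategy <- match.arg(strategy)
  c2_eval <- match.arg(c2_eval)
  structure(
    list(space = space, noise = noise,
         prior_common = as.numeric(prior_common),
         n_trials = as.integer(n_trials),
         strategy = strategy, c2_eval = c2_eval,
         seed = as.integer(seed), meta = meta),
    class = "cims_config")
}

#' @export
print.cims_config <- function(x, ...) {
  cat("<cims_config>\n")
  print(x$space)
  print(x$noise)
  cat(sprintf("prior_common=%.3g  n_trials=%d  strategy=%s  c2_eval=%s  seed=%d\n",
              x$prior_common, x$n_trials, x$strategy, x$c2_eval, x$seed))
  if (isTRUE(x$meta$calibrated)) cat("calibrated defaults (see $meta)\n")
  invisible(x)
}

check_stimulus <- function(space, auditory, visual) {
  for (lab in c(auditory, visual)) prototype_of(space, lab)
  invisible(NULL)
}

#' All audiovisual pairings of the space's labels
#'
#' @param space A [syllable_space()].
#' @return A tibble with columns `auditory`, `visual`, `congruent` and the
#'   stable `grid_index` used to derive per-stimulus random sub-streams.
#' @export
stimulus_grid <- function(space) {
  g <- tidyr::expand_grid(auditory = space$labels, visual = space$labels)
  g$congruent <- g$auditory == g$visual
  g$grid_index <- seq_len(nrow(g))
  g
}

#' The shipped default representational space
#'
#' The calibrated default layout: gauge fixed at ba = (0, 0), ga = (1, 1),
#' with the "da" prototype, category SD and noise SDs fitted to the packaged
#' behavioral confusion proportions (see [behavioral_fixture()] and
#' [cims_calibrate()]).
#'
#' @return A `cims_space`.
#' @export
default_space <- function() default_config()$space

#' The shipped default model configuration
#'
#' Reads the packaged calibrated configuration (prototype geometry, category
#' SD, sensory-noise SDs fitted to behavioral confusion proportions;
#' `prior_common = 0.5`, 10,000 trials per stimulus, model averaging).
#' Calibration provenance is recorded in `$meta`.
#'
#' @return A `cims_config`.
#' @export
default_config <- function() {
  path <- system.file("extdata", "default-config.yaml",
                      package = "cimspeech", mustWork = TRUE)
  read_config(path)
}
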
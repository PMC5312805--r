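# Synthetic multi-subject behavioral datasets with the design of the source
# experiment: 60 subjects x 9 audiovisual stimuli x 10 repetitions, 3AFC.
# Individual differences enter as subject-level log-normal multipliers on
# the two sensory-noise SDs and an optional subject-level causal prior.

#' Specify between-subject variability
#'
#' Subject-level parameters are drawn once per subject and then held fixed
#' across that subject's trials (a repeated-measures design). Noise SDs get
#' independent log-normal multipliers `exp(N(0, sigma_sdlog^2))` (median 1);
#' the subject's causal prior is `plogis(qlogis(prior_common) + N(0,
#' prior_sdlog^2))`, fixed at the base value when `prior_sdlog = 0`.
#'
#' @param sigma_sdlog SD of the log noise-multipliers (`>= 0`; 0 = no
#'   between-subject noise variability).
#' @param prior_sdlog SD of the subject prior on the logit scale (`>= 0`).
#' @return A list of class `cims_variability`.
#' @export
variability_spec <- function(sigma_sdlog = 0.15, prior_sdlog = 0) {
  for (nm in c("sigma_sdlog", "prior_sdlog")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      abort(paste0("`", nm, "` must be a single nonnegative number"),
            class = "cims_validation_error")
    }
  }
  structure(list(sigma_sdlog = sigma_sdlog, prior_sdlog = prior_sdlog),
            class = "cims_variability")
}

#' Generate a synthetic multi-subject behavioral dataset
#'
#' For each subject the base configuration is perturbed per
#' [variability_spec()], then every design stimulus is simulated for
#' `trials_per_stimulus` trials and the percept counts recorded. Fully
#' reproducible for a given seed.
#'
#' @param config Base [model_config()] (the generating "ground truth").
#' @param n_subjects Number of subjects (`>= 1`; the emulated design uses 60).
#' @param trials_per_stimulus Repetitions per stimulus per subject
#'   (the emulated design uses 10).
#' @param variability A [variability_spec()].
#' @param stimuli Optional design tibble (`auditory`, `visual`); defaults to
#'   all pairings.
#' @param seed Integer seed.
#' @param mode Model variant generating the responses (default `"cims"`).
#' @return A tibble of class `cims_behavior` with columns `subject_id`,
#'   `stimulus_auditory`, `stimulus_visual`, `response`, `count`, plus
#'   attributes `subjects` (the true subject-level parameters, for recovery
#'   tests) and `trials_per_stimulus`.
#' @export
simulate_subjects <- function(config, n_subjects = 60L,
                              trials_per_stimulus = 10L,
                              variability = variability_spec(),
                              stimuli = NULL, seed = config$seed,
                              mode = "cims") {
  if (!inherits(variability, "cims_variability")) {
    abort("`variability` must come from variability_spec()",
          class = "cims_validation_error")
  }
  if (n_subjects < 1L || trials_per_stimulus < 1L) {
    abort("`n_subjects` and `trials_per_stimulus` must be >= 1",
          class = "cims_validation_error")
  }
  if (is.null(stimuli)) stimuli <- stimulus_grid(config$space)
  stimuli <- as_tibble(stimuli)

  set.seed(seed)
  subjects <- tibble(
    subject_id = sprintf("S%03d", seq_len(n_subjects)),
    mult_a = exp(rnorm(n_subjects, 0, variability$sigma_sdlog)),
    mult_v = exp(rnorm(n_subjects, 0, variability$sigma_sdlog)),
    prior_common = plogis(qlogis(pmin(pmax(config$prior_common, 1e-12),
                                      1 - 1e-12)) +
                          rnorm(n_subjects, 0, variability$prior_sdlog)))
  subject_seeds <- sample.int(2147483646L, n_subjects)

  rows <- purrr::pmap(subjects, function(subject_id, mult_a, mult_v,
                                          prior_common) {
    i <- match(subject_id, subjects$subject_id)
    subj_cfg <- model_config(
      config$space,
      noise_model(config$noise$sigma_a * mult_a,
                  config$noise$sigma_v * mult_v,
                  anisotropy = config$noise$anisotropy),
      prior_common = prior_common,
      n_trials = trials_per_stimulus,
      strategy = config$strategy, c2_eval = config$c2_eval,
      seed = subject_seeds[i])
    cm <- simulate_grid(subj_cfg, mode = mode, stimuli = stimuli,
                        n_trials = trials_per_stimulus,
                        seed = subject_seeds[i])
    dplyr::mutate(as_tibble(cm)[, c("stimulus_auditory", "stimulus_visual",
                                    "response", "count")],
                  subject_id = subject_id, .before = 1L)
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
            subjects = subjects,
            trials_per_stimulus = as.integer(trials_per_stimulus),
            class = c("cims_behavior", class(out)))
}

#' True subject-level parameters of a synthetic dataset
#'
#' @param dataset A `cims_behavior` from [simulate_subjects()].
#' @return Tibble with `subject_id`, `mult_a`, `mult_v`, `prior_common`.
#' @export
subject_parameters <- function(dataset) attr(dataset, "subjects")

#' Pool a behavioral dataset across subjects
#'
#' Sums counts over subjects per stimulus x response cell and recomputes
#' proportions, yielding an aggregate confusion matrix.
#'
#' @param dataset A `cims_behavior` (or any tibble with `subject_id`,
#'   `stimulus_auditory`, `stimulus_visual`, `response`, `count`).
#' @return A `cims_confusion` tibble.
#' @export
aggregate_behavior <- function(dataset) {
  tbl <- as_tibble(dataset)
  agg <- dplyr::summarise(
    dplyr::group_by(tbl, .data$stimulus_auditory, .data$stimulus_visual,
                    .data$response),
    count = sum(.data$count), .groups = "drop_last")
  agg <- dplyr::mutate(agg, n_trials = sum(.data$count),
                       proportion = .data$count / .data$n_trials)
  agg <- dplyr::ungroup(agg)
  new_confusion(agg[, c("stimulus_auditory", "stimulus_visual", "response",
                        "count", "proportion", "n_trials")],
                meta = list(mode = "behavior",
                            n_subjects = length(unique(tbl$subject_id))))
}

#' Read and write behavioral dataset CSV files
#'
#' Columns: `subject_id, stimulus_auditory, stimulus_visual, response,
#' count`. The companion file written by `write_behavior()` (same path with
#' suffix `"-subjects"`) stores the true subject-level parameters when they
#' are available, for parameter-recovery workflows.
#'
#' @param dataset A `cims_behavior`.
#' @param path CSV path.
#' @return `read_behavior()` returns a `cims_behavior`; `write_behavior()`
#'   returns `path` invisibly.
#' @export
write_behavior <- function(dataset, path) {
  write.csv(as_tibble(dataset)[, c("subject_id", "stimulus_auditory",
                                   "stimulus_visual", "response", "count")],
            path, row.names = FALSE)
  subj <- subject_parameters(dataset)
  if (!is.null(subj)) {
    write.csv(subj, sub("(\\.[^.]*)?$", "-subjects\\1", path, perl = TRUE),
              row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  tbl <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  req <- c("subject_id", "stimulus_auditory", "stimulus_visual",
           "response", "count")
  if (!all(req %in% names(tbl))) {
    abort(paste0("behavior CSV must have columns: ",
                 paste(req, collapse = ", ")),
          class = "cims_parse_error")
  }
  subj_path <- sub("(\\.[^.]*)?$", "-subjects\\1", path, perl = TRUE)
  subj <- if (file.exists(subj_path)) {
    as_tibble(read.csv(subj_path, stringsAsFactors = FALSE))
  }
  structure(tbl, subjects = subj,
            class = c("cims_behavior", class(tbl)))
}
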
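# Monte-Carlo simulation over stimuli: percept tallies and confusion
# matrices. A confusion matrix is a tidy tibble (class cims_confusion) with
# one row per stimulus x response cell.

new_confusion <- function(tbl, meta = list()) {
  tbl <- as_tibble(tbl)
  structure(tbl, meta = meta,
            class = c("cims_confusion", class(tbl)))
}

#' Metadata attached to a confusion matrix
#'
#' @param x A `cims_confusion`.
#' @return A named list (mode, seed, n_trials, config hash) or an empty list.
#' @export
confusion_meta <- function(x) attr(x, "meta") %||% list()

# Stable per-stimulus sub-seed: master seed plus an offset proportional to
# the stimulus's position in the full label grid, so adding stimuli to a run
# never perturbs existing rows. Kept well below .Machine$integer.max.
stimulus_subseed <- function(seed, index) {
  as.integer((as.numeric(seed) + 1009 * as.numeric(index)) %% 2147483647)
}

grid_index_of <- function(space, auditory, visual) {
  l <- length(space$labels)
  (match(auditory, space$labels) - 1L) * l + match(visual, space$labels)
}

#' Simulate many trials of one audiovisual stimulus
#'
#' Runs `n_trials` independent model trials of the stimulus and tallies the
#' percepts. Reproducible: the same `(config, seed)` always yields the same
#' tallies.
#'
#' @param config A [model_config()].
#' @param auditory,visual Syllable labels of the stimulus components.
#' @param mode `"cims"` (causal inference) or `"non_cims"` (forced fusion).
#' @param n_trials Trials to simulate (default from the config).
#' @param seed RNG seed for this run (default from the config).
#' @param zero_noise If `TRUE`, encode without sensory noise (degenerate
#'   check: every congruent stimulus is then perceived veridically).
#' @param details If `TRUE`, return the trial-level tibble (coordinates,
#'   decision variable, posterior, percept) instead of tallies.
#' @return A `cims_confusion` tibble with columns `stimulus_auditory`,
#'   `stimulus_visual`, `response`, `count`, `proportion`, `n_trials`
#'   (or the trial-level tibble when `details = TRUE`).
#' @export
simulate_stimulus <- function(config, auditory, visual,
                              mode = c("cims", "non_cims"),
                              n_trials = config$n_trials,
                              seed = config$seed,
                              zero_noise = FALSE, details = FALSE) {
  mode <- match.arg(mode)
  if (n_trials < 1) abort("`n_trials` must be >= 1",
                          class = "cims_validation_error")
  set.seed(seed)
  res <- run_trials_engine(auditory, visual, config, mode, n = n_trials,
                           zero_noise = zero_noise)
  if (details) {
    return(tibble(
      trial = seq_len(n_trials),
      x_a_x = res$x_a[, 1L], x_a_y = res$x_a[, 2L],
      x_v_x = res$x_v[, 1L], x_v_y = res$x_v[, 2L],
      x_av_x = res$x_av[, 1L], x_av_y = res$x_av[, 2L],
      x_final_x = res$x_final[, 1L], x_final_y = res$x_final[, 2L],
      d = res$d, p_common = res$p_common, percept = res$percept))
  }
  counts <- vapply(config$space$labels,
                   function(lab) sum(res$percept == lab), integer(1))
  new_confusion(
    tibble(stimulus_auditory = auditory, stimulus_visual = visual,
           response = config$space$labels,
           count = as.integer(counts),
           proportion = as.integer(counts) / n_trials,
           n_trials = as.integer(n_trials)),
    meta = list(mode = mode, seed = as.integer(seed),
                n_trials = as.integer(n_trials),
                config_hash = rlang::hash(config[c("space", "noise",
                                                   "prior_common",
                                                   "strategy", "c2_eval")])))
}

#' Simulate a full stimulus grid into a confusion matrix
#'
#' Runs [simulate_stimulus()] for each stimulus (default: all pairings of the
#' space's labels) with an independent random sub-stream per stimulus derived
#' from the master seed and the stimulus's grid index, and binds the results
#' into one confusion matrix.
#'
#' @inheritParams simulate_stimulus
#' @param stimuli Optional tibble/data frame with columns `auditory`,
#'   `visual` selecting stimuli; defaults to [stimulus_grid()] of the space.
#' @return A `cims_confusion` tibble; every stimulus row-group sums to 1.
#' @examples
#' \donttest{
#' cm <- simulate_grid(default_config(), mode = "cims", n_trials = 500)
#' dplyr::filter(cm, stimulus_auditory == "ba", stimulus_visual == "ga")
#' }
#' @export
simulate_grid <- function(config, mode = c("cims", "non_cims"),
                          stimuli = NULL, n_trials = config$n_trials,
                          seed = config$seed, zero_noise = FALSE) {
  mode <- match.arg(mode)
  if (is.null(stimuli)) stimuli <- stimulus_grid(config$space)
  stimuli <- as_tibble(stimuli)
  rows <- purrr::map2(stimuli$auditory, stimuli$visual, function(a, v) {
    idx <- grid_index_of(config$space, a, v)
    simulate_stimulus(config, a, v, mode = mode, n_trials = n_trials,
                      seed = stimulus_subseed(seed, idx),
                      zero_noise = zero_noise)
  })
  new_confusion(
    dplyr::bind_rows(rows),
    meta = list(mode = mode, seed = as.integer(seed),
                n_trials = as.integer(n_trials),
                config_hash = rlang::hash(config[c("space", "noise",
                                                   "prior_common",
                                                   "strategy", "c2_eval")])))
}

#' Mean posterior probability of a common cause, per stimulus
#'
#' A signature of the causal-inference step: congruent stimuli should carry a
#' strictly higher mean `p_common` than every incongruent stimulus.
#'
#' @inheritParams simulate_grid
#' @return A tibble with `auditory`, `visual`, `congruent`, `mean_p_common`.
#' @export
p_common_by_stimulus <- function(config, stimuli = NULL,
                                 n_trials = config$n_trials,
                                 seed = config$seed) {
  if (is.null(stimuli)) stimuli <- stimulus_grid(config$space)
  stimuli <- as_tibble(stimuli)
  mp <- purrr::map2_dbl(stimuli$auditory, stimuli$visual, function(a, v) {
    idx <- grid_index_of(config$space, a, v)
    det <- simulate_stimulus(config, a, v, mode = "cims",
                             n_trials = n_trials,
                             seed = stimulus_subseed(seed, idx),
                             details = TRUE)
    mean(det$p_common)
  })
  tibble(auditory = stimuli$auditory, visual = stimuli$visual,
         congruent = stimuli$auditory == stimuli$visual,
         mean_p_common = mp)
}

#' Read and write confusion-matrix CSV files
#'
#' Columns: `stimulus_auditory, stimulus_visual, response, proportion, count,
#' n_trials`; one header line; UTF-8; rows in grid order then label order.
#' Missing cells (behavioral data the source study never reported) are
#' empty fields.
#'
#' @param x A `cims_confusion` (or compatible tibble).
#' @param path File path.
#' @return `read_confusion()` returns a `cims_confusion` tibble;
#'   `write_confusion()` returns `path` invisibly.
#' @export
write_confusion <- function(x, path) {
  cols <- c("stimulus_auditory", "stimulus_visual", "response",
            "proportion", "count", "n_trials")
  out <- as_tibble(x)
  for (cc in setdiff(cols, names(out))) out[[cc]] <- NA
  write.csv(out[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_confusion
#' @export
read_confusion <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "cims_io_error")
  }
  tbl <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("stimulus_auditory", "stimulus_visual", "response", "proportion")
  if (!all(req %in% names(tbl))) {
    abort(paste0("confusion CSV must have columns: ",
                 paste(req, collapse = ", ")),
          class = "cims_parse_error")
  }
  new_confusion(tbl)
}

#' @export
print.cims_confusion <- function(x, ...) {
  meta <- confusion_meta(x)
  if (length(meta)) {
    cat(sprintf("<cims_confusion> mode=%s seed=%s n_trials=%s\n",
                meta$mode %||% "?", meta$seed %||% "?",
                meta$n_trials %||% "?"))
  } else {
    cat("<cims_confusion>\n")
  }
  NextMethod()
}

# wide stimulus x response proportion view, used by plots and checks
confusion_wide <- function(x) {
  tidyr::pivot_wider(
    as_tibble(x)[, c("stimulus_auditory", "stimulus_visual",
                     "response", "proportion")],
    names_from = "response", values_from = "proportion")
}
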
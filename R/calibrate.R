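# Calibration of the free parameters that were never published: the "da"
# prototype location (gauge fixed at ba = (0,0), ga = (1,1)), the category
# SD, and the two sensory-noise SDs. A coarse grid search is followed by
# Nelder-Mead refinement from the best grid point; the objective simulates
# the model with a fixed evaluation seed so the optimizer sees a
# deterministic surface.

#' Behavioral confusion proportions shipped with the package
#'
#' The response proportions reported in the source behavioral study
#' (60 subjects, 9 audiovisual stimuli, 10 repetitions, 3AFC): the McGurk
#' stimulus AbaVga (57% "ba", 40% "da"), the inverse-McGurk stimulus AgaVba
#' (96% "ga", 2% "da"), and congruent stimuli at the reported 97% mean
#' accuracy. Cells never reported numerically are missing (`NA`) rather
#' than guessed. The behavioral "da/tha" response option is mapped to
#' category "da".
#'
#' @param path Path to a behavioral confusion CSV; defaults to the packaged
#'   fixture.
#' @return A `cims_confusion` tibble with `NA` proportions for unreported
#'   cells.
#' @export
behavioral_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "behavior-reported.csv",
                        package = "cimspeech", mustWork = TRUE)
  }
  read_confusion(path)
}

#' Calibration loss: model vs behavioral proportions
#'
#' Root-mean-square difference between model-predicted and observed response
#' proportions over all non-missing cells of the behavioral matrix. The
#' model prediction is simulated only for the stimuli present in the
#' behavioral data, with a fixed evaluation seed so repeated evaluations are
#' identical.
#'
#' @param config Candidate [model_config()].
#' @param behavior A `cims_confusion` of observed proportions (missing cells
#'   as `NA`).
#' @param mode Model variant to score, `"cims"` or `"non_cims"`.
#' @param n_trials Trials per stimulus used inside the objective.
#' @param eval_seed Fixed seed for the objective's simulations.
#' @return A single nonnegative number.
#' @export
cims_loss <- function(config, behavior, mode = "cims", n_trials = 2000L,
                      eval_seed = 20260101L) {
  beh <- as_tibble(behavior)
  bad_stim <- setdiff(unique(c(beh$stimulus_auditory, beh$stimulus_visual)),
                      config$space$labels)
  bad_resp <- setdiff(unique(beh$response), config$space$labels)
  if (length(bad_stim) || length(bad_resp)) {
    abort(paste0("behavior labels not in the model space: ",
                 paste(unique(c(bad_stim, bad_resp)), collapse = ", ")),
          class = "cims_alignment_error")
  }
  stimuli <- dplyr::distinct(beh, auditory = .data$stimulus_auditory,
                             visual = .data$stimulus_visual)
  pred <- simulate_grid(config, mode = mode, stimuli = stimuli,
                        n_trials = n_trials, seed = eval_seed)
  j <- dplyr::inner_join(
    beh[, c("stimulus_auditory", "stimulus_visual", "response", "proportion")],
    dplyr::rename(as_tibble(pred)[, c("stimulus_auditory", "stimulus_visual",
                                      "response", "proportion")],
                  model = "proportion"),
    by = c("stimulus_auditory", "stimulus_visual", "response"))
  j <- dplyr::filter(j, !is.na(.data$proportion))
  if (nrow(j) == 0L) {
    abort("no overlapping non-missing cells between model and behavior",
          class = "cims_alignment_error")
  }
  sqrt(mean((j$model - j$proportion)^2))
}

#' Baseline-signature constraint used by the default calibration
#'
#' The forced-fusion baseline of the source model family predicts the fused
#' "da" percept on more than 99% of trials for both the McGurk (AbaVga) and
#' inverse-McGurk (AgaVba) stimuli. Because the calibrated parameters are
#' shared between the causal-inference model and this baseline, candidates
#' that lose this signature are rejected during calibration.
#'
#' @return A tibble with columns `auditory`, `visual`, `response`, `floor`.
#' @export
default_baseline_floor <- function() {
  tibble(auditory = c("ba", "ga"), visual = c("ga", "ba"),
         response = "da", floor = 0.99)
}

#' Default calibration search bounds
#'
#' Box bounds for the five free parameters, honouring the layout invariants:
#' the "da" prototype auditory coordinate `d_x` in (0, 0.5), visual
#' coordinate `d_y` in (0.5, 1) (gauge ba = (0,0), ga = (1,1)), plus positive
#' category and sensory-noise SDs.
#'
#' @return A tibble with columns `param`, `lower`, `upper`, `n_grid`.
#' @export
default_search_bounds <- function() {
  tibble(
    param = c("d_x", "d_y", "category_sd", "sigma_a", "sigma_v"),
    lower = c(0.15, 0.55, 0.04, 0.04, 0.04),
    upper = c(0.45, 0.85, 0.22, 0.28, 0.28),
    n_grid = c(4L, 4L, 4L, 4L, 4L)
  )
}

# Build a candidate config from a named parameter vector.
config_from_params <- function(par, template = NULL) {
  space <- syllable_space(
    tibble(label = c("ba", "da", "ga"),
           x = c(0, par[["d_x"]], 1),
           y = c(0, par[["d_y"]], 1)),
    category_sd = par[["category_sd"]])
  noise <- noise_model(par[["sigma_a"]], par[["sigma_v"]],
                       anisotropy = template$noise$anisotropy %||% 1.5)
  model_config(space, noise,
               prior_common = template$prior_common %||% 0.5,
               n_trials = template$n_trials %||% 10000L,
               strategy = template$strategy %||% "averaging",
               c2_eval = template$c2_eval %||% "fused",
               seed = template$seed %||% 1L)
}

#' Calibrate the model's free parameters to behavioral data
#'
#' Coarse grid search over `(d_x, d_y, category_sd, sigma_a, sigma_v)` within
#' `bounds`, followed by Nelder-Mead refinement from the best grid point
#' (with out-of-bounds proposals penalized). The objective is [cims_loss()]
#' with a fixed evaluation seed derived from `seed`, so the whole procedure
#' is deterministic given its inputs.
#'
#' Sparse behavioral matrices (the packaged fixture reports only seven cells)
#' under-identify the five parameters: an unconstrained fit can reach a
#' slightly lower RMSE in a regime where the forced-fusion baseline no longer
#' produces the fused percept on essentially every incongruent trial — a
#' defining, printed property of the model family the parameters are shared
#' with. `baseline_floor` therefore constrains the search (as a penalty) to
#' configurations whose `non_cims` variant still meets stated minimum
#' response proportions; set it to `NULL` for an unconstrained fit.
#'
#' @param behavior Behavioral `cims_confusion` (missing cells allowed).
#' @param bounds Search box, as from [default_search_bounds()]. Collapsed
#'   bounds (`lower == upper` everywhere) evaluate that single point.
#' @param seed Integer seed; fixes the objective's evaluation seed.
#' @param mode Model variant fitted (default `"cims"`).
#' @param n_trials_eval Trials per stimulus inside the objective.
#' @param refine Run the local refinement stage?
#' @param template Optional `cims_config` supplying the non-searched settings
#'   (prior, strategy, anisotropy, ...).
#' @param maxit Refinement iteration cap.
#' @param baseline_floor Optional tibble with columns `auditory`, `visual`,
#'   `response`, `floor`: minimum forced-fusion (`non_cims`) response
#'   proportions a candidate must retain. Defaults to
#'   [default_baseline_floor()] (fused "da" percepts on at least 99% of
#'   trials for both incongruent syllable types); `NULL` disables it.
#' @return A `cims_calibration`: `fitted_config`, `loss` (the pure RMSE of
#'   the fitted config), `trace` (tibble of every evaluation, penalized
#'   objective), `constraints_report`. [tidy()] returns the trace,
#'   [glance()] a one-row summary.
#' @export
cims_calibrate <- function(behavior, bounds = default_search_bounds(),
                           seed = 1L, mode = "cims", n_trials_eval = 2000L,
                           refine = TRUE, template = NULL, maxit = 150L,
                           baseline_floor = default_baseline_floor()) {
  bounds <- as_tibble(bounds)
  need <- c("d_x", "d_y", "category_sd", "sigma_a", "sigma_v")
  if (!setequal(bounds$param, need)) {
    abort(paste0("`bounds` must cover exactly: ", paste(need, collapse = ", ")),
          class = "cims_config_error")
  }
  if (any(bounds$lower > bounds$upper)) {
    abort("empty feasible set: some lower bound exceeds its upper bound",
          class = "cims_config_error")
  }
  bounds <- bounds[match(need, bounds$param), ]
  eval_seed <- stimulus_subseed(seed, 97L)

  grid_pts <- purrr::pmap(bounds, function(param, lower, upper, n_grid) {
    if (lower == upper) lower else seq(lower, upper, length.out = max(2L, n_grid))
  })
  names(grid_pts) <- bounds$param
  grid <- do.call(tidyr::expand_grid, grid_pts)

  baseline_shortfall <- function(config) {
    if (is.null(baseline_floor)) return(0)
    bf <- as_tibble(baseline_floor)
    short <- purrr::pmap_dbl(bf, function(auditory, visual, response, floor) {
      cm <- simulate_stimulus(config, auditory, visual, mode = "non_cims",
                              n_trials = n_trials_eval,
                              seed = stimulus_subseed(
                                eval_seed,
                                grid_index_of(config$space, auditory, visual)))
      max(0, floor - cm$proportion[cm$response == response])
    })
    sum(short)
  }

  objective <- function(par) {
    config <- config_from_params(par, template)
    cims_loss(config, behavior, mode = mode,
              n_trials = n_trials_eval, eval_seed = eval_seed) +
      10 * baseline_shortfall(config)
  }

  grid_loss <- purrr::pmap_dbl(grid, function(...) objective(c(...)))
  trace <- dplyr::mutate(grid, loss = grid_loss, stage = "grid")
  best_i <- which.min(grid_loss)
  best_par <- unlist(grid[best_i, need])
  best_loss <- grid_loss[best_i]

  do_refine <- refine && any(bounds$lower < bounds$upper)
  if (do_refine) {
    lo <- stats::setNames(bounds$lower, bounds$param)
    hi <- stats::setNames(bounds$upper, bounds$param)
    refine_rows <- list()
    penalized <- function(p) {
      p <- stats::setNames(p, need)
      if (any(p < lo) || any(p > hi)) {
        return(1 + sum(pmax(lo - p, 0) + pmax(p - hi, 0)))
      }
      val <- objective(p)
      refine_rows[[length(refine_rows) + 1L]] <<-
        c(as.list(p), list(loss = val, stage = "refine"))
      val
    }
    # multi-start: Nelder-Mead from the best few grid points, best result
    # kept; never worse than the grid optimum by construction
    starts <- utils::head(order(grid_loss), 3L)
    for (si in starts) {
      opt <- optim(unlist(grid[si, need]), penalized,
                   method = "Nelder-Mead",
                   control = list(maxit = maxit,
                                  parscale = pmax(hi - lo, 1e-6)))
      if (opt$value <= best_loss) {
        best_par <- stats::setNames(opt$par, need)
        best_loss <- opt$value
      }
    }
    trace <- dplyr::bind_rows(trace, dplyr::bind_rows(refine_rows))
  }

  fitted <- config_from_params(best_par, template)
  fitted_shortfall <- baseline_shortfall(fitted)
  fitted_rmse <- cims_loss(fitted, behavior, mode = mode,
                           n_trials = n_trials_eval, eval_seed = eval_seed)
  active <- tibble(
    param = need,
    at_lower = abs(best_par - bounds$lower) <= 1e-6,
    at_upper = abs(best_par - bounds$upper) <= 1e-6)
  structure(
    list(fitted_config = fitted, loss = fitted_rmse,
         baseline_shortfall = fitted_shortfall,
         params = tibble(param = need, value = as.numeric(best_par)),
         trace = as_tibble(trace),
         constraints_report = active,
         eval_seed = eval_seed, mode = mode,
         n_trials_eval = as.integer(n_trials_eval)),
    class = "cims_calibration")
}

#' @export
print.cims_calibration <- function(x, ...) {
  cat(sprintf("<cims_calibration> loss (RMSE) = %.5f over %d evaluations\n",
              x$loss, nrow(x$trace)))
  print(x$params)
  invisible(x)
}

#' @rdname cims_calibrate
#' @param x A `cims_calibration`.
#' @param ... Unused.
#' @method tidy cims_calibration
#' @export
tidy.cims_calibration <- function(x, ...) x$trace

#' @rdname cims_calibrate
#' @method glance cims_calibration
#' @export
glance.cims_calibration <- function(x, ...) {
  out <- tidyr::pivot_wider(x$params, names_from = "param",
                            values_from = "value")
  dplyr::mutate(out, loss = x$loss, n_evaluations = nrow(x$trace),
                mode = x$mode)
}
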
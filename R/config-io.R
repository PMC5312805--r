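#' Read and write model configurations
#'
#' Configurations are stored as human-readable YAML with three required
#' sections — `space` (labels, prototypes, category_sd, priors), `noise`
#' (sigma_a, sigma_v, anisotropy) and `model` (prior_common, n_trials,
#' strategy, c2_eval, seed) — plus an optional free-form `meta` section.
#' All lengths are in space units. Unknown sections or keys are rejected
#' rather than ignored, so a typo cannot silently fall back to a default.
#' `write_config()` then `read_config()` round-trips losslessly.
#'
#' @param path Path to a YAML configuration file.
#' @return `read_config()` returns a validated [model_config()];
#'   `write_config()` returns `path` invisibly.
#' @examples
#' cfg <- default_config()
#' p <- tempfile(fileext = ".yaml")
#' write_config(cfg, p)
#' cfg2 <- read_config(p)
#' identical(cfg$space$labels, cfg2$space$labels)
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "cims_io_error")
  }
  raw <- yaml::read_yaml(path)
  check_keys(raw, required = c("space", "noise", "model"),
             optional = "meta", where = "top level")
  check_keys(raw$space, required = c("labels", "prototypes", "category_sd"),
             optional = "priors", where = "section `space`")
  check_keys(raw$noise, required = c("sigma_a", "sigma_v"),
             optional = "anisotropy", where = "section `noise`")
  check_keys(raw$model, required = character(),
             optional = c("prior_common", "n_trials", "strategy",
                          "c2_eval", "seed"),
             where = "section `model`")

  labels <- as.character(raw$space$labels)
  protos <- raw$space$prototypes
  if (!all(labels %in% names(protos))) {
    abort(paste0("section `space`: field `prototypes` is missing entries for: ",
                 paste(setdiff(labels, names(protos)), collapse = ", ")),
          class = "cims_parse_error")
  }
  if (any(lengths(protos[labels]) != 2L)) {
    abort("section `space`: each prototype must be a length-2 [x, y] pair",
          class = "cims_parse_error")
  }
  proto_tbl <- tibble(
    label = labels,
    x = unname(purrr::map_dbl(protos[labels], 1)),
    y = unname(purrr::map_dbl(protos[labels], 2))
  )
  space <- syllable_space(proto_tbl,
                          category_sd = raw$space$category_sd,
                          priors = raw$space$priors)
  noise <- noise_model(sigma_a = raw$noise$sigma_a,
                       sigma_v = raw$noise$sigma_v,
                       anisotropy = raw$noise$anisotropy %||% 1.5)
  m <- raw$model %||% list()
  model_config(space, noise,
               prior_common = m$prior_common %||% 0.5,
               n_trials = m$n_trials %||% 10000L,
               strategy = m$strategy %||% "averaging",
               c2_eval = m$c2_eval %||% "fused",
               seed = m$seed %||% 1L,
               meta = raw$meta %||% list())
}

#' @param config A [model_config()] to serialize.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cims_config"))
  protos <- purrr::map(config$space$labels, function(lab) {
    as.numeric(prototype_of(config$space, lab))
  })
  names(protos) <- config$space$labels
  out <- list(
    space = list(labels = config$space$labels,
                 prototypes = protos,
                 category_sd = config$space$category_sd,
                 priors = as.numeric(config$space$priors)),
    noise = list(sigma_a = config$noise$sigma_a,
                 sigma_v = config$noise$sigma_v,
                 anisotropy = config$noise$anisotropy),
    model = list(prior_common = config$prior_common,
                 n_trials = config$n_trials,
                 strategy = config$strategy,
                 c2_eval = config$c2_eval,
                 seed = config$seed)
  )
  if (length(config$meta)) out$meta <- config$meta
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

check_keys <- function(x, required, optional, where) {
  if (!is.list(x)) {
    abort(paste0(where, ": expected a mapping"), class = "cims_parse_error")
  }
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(paste0(where, ": missing required field(s): ",
                 paste(missing, collapse = ", ")),
          class = "cims_parse_error")
  }
  unknown <- setdiff(names(x), c(required, optional))
  if (length(unknown)) {
    abort(paste0(where, ": unknown field(s): ",
                 paste(unknown, collapse = ", ")),
          class = "cims_parse_error")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
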
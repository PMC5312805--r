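# Single-trial machinery of the causal-inference observer:
# noisy encoding -> reliability-weighted fusion -> causal-structure
# likelihoods -> posterior over structures -> combined representation ->
# categorization. All densities are bivariate Gaussians evaluated in
# log-space; the forced-fusion baseline is the prior_common = 1 special case.

# log N2(x; mu, Sigma) for n x 2 matrix x, general SPD 2x2 Sigma.
dmvn2_log <- function(x, mu, sigma) {
  x <- as_xy_matrix(x)
  p <- inv2(sigma)
  ld <- log(det2(sigma))
  dx <- x[, 1L] - mu[1L]
  dy <- x[, 2L] - mu[2L]
  q <- p[1L, 1L] * dx^2 + 2 * p[1L, 2L] * dx * dy + p[2L, 2L] * dy^2
  -log(2 * pi) - 0.5 * ld - 0.5 * q
}

det2 <- function(s) s[1L, 1L] * s[2L, 2L] - s[1L, 2L] * s[2L, 1L]

inv2 <- function(s) {
  d <- det2(s)
  if (!is.finite(d) || d <= 0) {
    abort(paste0("covariance matrix is singular or not positive-definite ",
                 "(determinant = ", format(d), ")"),
          class = "cims_numeric_error")
  }
  matrix(c(s[2L, 2L], -s[2L, 1L], -s[1L, 2L], s[1L, 1L]), 2L, 2L) / d
}

as_xy_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
}

# rowwise log-sum-exp over the columns of a matrix
row_logsumexp <- function(lm) {
  m <- do.call(pmax, c(as.data.frame(lm), list(na.rm = FALSE)))
  out <- m + log(rowSums(exp(lm - m)))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Encode one or more trials of an audiovisual stimulus
#'
#' Draws the noisy internal representations of the auditory and visual cue:
#' `x_a ~ N(prototype(auditory), Sigma_A)` and
#' `x_v ~ N(prototype(visual), Sigma_V)`, independently across modalities and
#' trials. With `zero_noise = TRUE` the cues sit exactly on their prototypes
#' (the noiseless limit); the covariances used downstream for fusion and
#' likelihoods are unchanged.
#'
#' @param auditory,visual Syllable labels present in `config$space`.
#' @param config A [model_config()].
#' @param n Number of trials to encode.
#' @param zero_noise If `TRUE`, skip the noise draws.
#' @return A list with `x_a` and `x_v`, each an `n x 2` matrix.
#' @export
encode_trials <- function(auditory, visual, config, n = 1L,
                          zero_noise = FALSE) {
  check_stimulus(config$space, auditory, visual)
  covs <- noise_covariances(config$noise)
  pa <- prototype_of(config$space, auditory)
  pv <- prototype_of(config$space, visual)
  if (zero_noise) {
    return(list(x_a = matrix(pa, n, 2L, byrow = TRUE),
                x_v = matrix(pv, n, 2L, byrow = TRUE)))
  }
  # draw order is fixed: all auditory deviates first, then all visual
  x_a <- matrix(rnorm(2L * n), n, 2L) %*% chol(covs$sigma_a_cov)
  x_v <- matrix(rnorm(2L * n), n, 2L) %*% chol(covs$sigma_v_cov)
  list(x_a = sweep(x_a, 2L, pa, "+"), x_v = sweep(x_v, 2L, pv, "+"))
}

#' Reliability-weighted fusion of the two cues
#'
#' The common-cause (`C = 1`) representation combines the cues by their
#' precisions: `Sigma_AV = (Sigma_A^-1 + Sigma_V^-1)^-1` and
#' `X_AV = Sigma_AV (Sigma_A^-1 X_A + Sigma_V^-1 X_V)`.
#'
#' @param x_a,x_v Encoded cues: length-2 vectors or `n x 2` matrices.
#' @param sigma_a_cov,sigma_v_cov 2x2 symmetric positive-definite noise
#'   covariances.
#' @return A list with `x_av` (`n x 2`) and the 2x2 `sigma_av`.
#' @examples
#' fuse(c(0, 0), c(1, 1), diag(c(1, 2.25)), diag(c(2.25, 1)))
#' @export
fuse <- function(x_a, x_v, sigma_a_cov, sigma_v_cov) {
  x_a <- as_xy_matrix(x_a); x_v <- as_xy_matrix(x_v)
  pa <- inv2(sigma_a_cov); pv <- inv2(sigma_v_cov)
  sigma_av <- inv2(pa + pv)
  x_av <- (x_a %*% pa + x_v %*% pv) %*% sigma_av
  list(x_av = x_av, sigma_av = sigma_av)
}

#' Likelihood of the cues under a common cause
#'
#' For each syllable category the fused representation is scored against the
#' prototype with covariance `Sigma_i + Sigma_AV` (category scatter plus
#' fusion noise: the exact marginal of `X_AV` when a single exemplar of that
#' category drives both cues). Terms are combined weighted by the category
#' priors. Everything is computed in log-space.
#'
#' @param x_av Fused representation(s), `n x 2`.
#' @param sigma_av 2x2 fused covariance from [fuse()].
#' @param space A [syllable_space()].
#' @return A list: `log_lik` (length n, log of the prior-weighted sum) and
#'   `log_per_syllable` (`n x L` matrix of per-category log densities).
#' @export
likelihood_common <- function(x_av, sigma_av, space) {
  x_av <- as_xy_matrix(x_av)
  protos <- prototype_matrix(space)
  ld <- vapply(space$labels, function(lab) {
    dmvn2_log(x_av, protos[lab, ], space$category_cov + sigma_av)
  }, numeric(nrow(x_av)))
  ld <- matrix(ld, nrow = nrow(x_av),
               dimnames = list(NULL, space$labels))
  lp <- sweep(ld, 2L, log(space$priors), "+")
  list(log_lik = row_logsumexp(lp), log_per_syllable = ld)
}

#' Likelihood of the cues under separate causes
#'
#' Every ordered incongruent category pair (`S_i` driving the auditory cue,
#' `S_j` the visual cue, `i != j`) is a separate-cause hypothesis. The noise
#' covariances are inflated by the category covariance
#' (`Sigma_A' = Sigma_A + Sigma_i`, `Sigma_V' = Sigma_V + Sigma_j`), the cues
#' are fused with the inflated precisions
#' (`Sigma_C2 = (Sigma_A'^-1 + Sigma_V'^-1)^-1`,
#' `mu_C2 = Sigma_C2 (Sigma_A'^-1 X_A + Sigma_V'^-1 X_V)`), and `mu_C2` is
#' scored against the identically fused prototype pair with covariance
#' `Sigma_C2` — the exact marginal of the inflated fusion statistic under
#' that hypothesis. Pair priors are equal (`1 / (L^2 - L)`).
#'
#' With `c2_eval = "joint"` the hypothesis is instead scored as the product
#' of the two unisensory cue densities
#' `N2(X_A; mu_i, Sigma_A') * N2(X_V; mu_j, Sigma_V')` (sensitivity check).
#'
#' @param x_a,x_v Encoded cues, `n x 2`.
#' @param noise A [noise_model()].
#' @param space A [syllable_space()].
#' @param c2_eval `"fused"` (default) or `"joint"`.
#' @return A list: `log_lik` (length n), `log_per_pair` (`n x P`), and
#'   `pairs` (tibble of the ordered incongruent pairs).
#' @export
likelihood_separate <- function(x_a, x_v, noise, space,
                                c2_eval = c("fused", "joint")) {
  c2_eval <- match.arg(c2_eval)
  if (length(space$labels) < 2L) {
    abort("separate-cause likelihood needs at least 2 labels",
          class = "cims_config_error")
  }
  x_a <- as_xy_matrix(x_a); x_v <- as_xy_matrix(x_v)
  covs <- noise_covariances(noise)
  # equal category covariances: the inflated matrices are pair-independent
  sa_inf <- covs$sigma_a_cov + space$category_cov
  sv_inf <- covs$sigma_v_cov + space$category_cov
  pairs <- dplyr::filter(
    tidyr::expand_grid(aud_cause = space$labels, vis_cause = space$labels),
    .data$aud_cause != .data$vis_cause)
  protos <- prototype_matrix(space)

  if (c2_eval == "fused") {
    fz <- fuse(x_a, x_v, sa_inf, sv_inf)
    lp <- purrr::map2(pairs$aud_cause, pairs$vis_cause, function(i, j) {
      mu <- fuse(protos[i, ], protos[j, ], sa_inf, sv_inf)$x_av
      dmvn2_log(fz$x_av, as.numeric(mu), fz$sigma_av)
    })
  } else {
    lp <- purrr::map2(pairs$aud_cause, pairs$vis_cause, function(i, j) {
      dmvn2_log(x_a, protos[i, ], sa_inf) + dmvn2_log(x_v, protos[j, ], sv_inf)
    })
  }
  lm <- matrix(unlist(lp), nrow = nrow(x_a),
               dimnames = list(NULL, paste0("A", pairs$aud_cause,
                                            "V", pairs$vis_cause)))
  list(log_lik = row_logsumexp(lm + log(1 / nrow(pairs))),
       log_per_pair = lm, pairs = pairs)
}

#' Posterior probability of a common cause
#'
#' The decision variable is the log posterior ratio
#' `d = log(lik_c1 / lik_c2) + log(prior / (1 - prior))`, mapped through the
#' logistic function: `p_common = 1 / (1 + exp(-d))`. A prior of exactly 0 or
#' 1 short-circuits to `p_common = 0` or `1` without evaluating `d` (the
#' forced-fusion baseline is `prior_common = 1`).
#'
#' @param lik_c1,lik_c2 Likelihoods of the two causal structures (vectors).
#'   Interpreted as log-likelihoods when `log_input = TRUE`.
#' @param prior_common Prior probability of a common cause, in `[0, 1]`.
#' @param log_input Are `lik_c1`/`lik_c2` already on the log scale?
#' @return A list with `d` (log posterior ratio) and `p_common`.
#' @examples
#' posterior_common(3, 1, 0.5)   # likelihood ratio 3 -> p_common = 0.75
#' @export
posterior_common <- function(lik_c1, lik_c2, prior_common,
                             log_input = FALSE) {
  if (!is.numeric(prior_common) || length(prior_common) != 1L ||
      is.na(prior_common) || prior_common < 0 || prior_common > 1) {
    abort("`prior_common` must be in [0, 1]",
          class = "cims_validation_error")
  }
  n <- max(length(lik_c1), length(lik_c2))
  if (prior_common %in% c(0, 1)) {
    return(list(d = rep(if (prior_common == 1) Inf else -Inf, n),
                p_common = rep(prior_common, n)))
  }
  if (log_input) {
    ll1 <- lik_c1; ll2 <- lik_c2
  } else {
    if (any(lik_c1 < 0) || any(lik_c2 < 0)) {
      abort("likelihoods must be nonnegative",
            class = "cims_validation_error")
    }
    ll1 <- log(lik_c1); ll2 <- log(lik_c2)
  }
  if (any(is.infinite(ll1) & is.infinite(ll2) & ll1 < 0 & ll2 < 0)) {
    abort("both causal-structure likelihoods underflowed to zero",
          class = "cims_degenerate_error")
  }
  d <- ll1 - ll2 + qlogis(prior_common)
  list(d = d, p_common = plogis(d))
}

#' Combine the common- and separate-cause representations
#'
#' Under `"averaging"` (the model's default strategy) the final
#' representation is the posterior-weighted average
#' `p_common * X_AV + (1 - p_common) * X_A`, computed per trial. Under
#' `"selection"` the more probable candidate is taken outright (`X_AV` on
#' ties); under `"matching"` `X_AV` is chosen with probability `p_common`
#' using the trial's random stream.
#'
#' @param x_av,x_a Candidate representations, `n x 2`.
#' @param p_common Posterior probability of a common cause, length n.
#' @param strategy `"averaging"`, `"selection"` or `"matching"`.
#' @param u Optional uniform deviates for `"matching"` (drawn if missing).
#' @return An `n x 2` matrix of final representations.
#' @export
combine_representations <- function(x_av, x_a, p_common,
                                    strategy = c("averaging", "selection",
                                                 "matching"),
                                    u = NULL) {
  strategy <- match.arg(strategy)
  x_av <- as_xy_matrix(x_av); x_a <- as_xy_matrix(x_a)
  if (any(p_common < 0 | p_common > 1)) {
    abort("`p_common` must lie in [0, 1]", class = "cims_validation_error")
  }
  w <- switch(strategy,
    averaging = p_common,
    selection = as.numeric(p_common >= 0.5),
    matching = {
      if (is.null(u)) u <- runif(nrow(x_av))
      as.numeric(u < p_common)
    })
  w * x_av + (1 - w) * x_a
}

#' Categorize a representation into a syllable percept
#'
#' Returns the category whose prototype is most likely to have generated the
#' representation: argmax over labels of the bivariate Gaussian density at
#' the prototype with covariance `Sigma_i + Sigma_AV`. With equal category
#' covariances and priors this induces linear decision boundaries. Exact ties
#' are broken deterministically by label order.
#'
#' @param x_final Representation(s) to categorize, `n x 2`.
#' @param sigma_av 2x2 fused covariance.
#' @param space A [syllable_space()].
#' @return Character vector of percept labels.
#' @export
categorize <- function(x_final, sigma_av, space) {
  x_final <- as_xy_matrix(x_final)
  protos <- prototype_matrix(space)
  ld <- vapply(space$labels, function(lab) {
    dmvn2_log(x_final, protos[lab, ], space$category_cov + sigma_av)
  }, numeric(nrow(x_final)))
  ld <- matrix(ld, nrow = nrow(x_final))
  space$labels[max.col(ld, ties.method = "first")]
}

# Vectorized engine: n trials of one stimulus under one mode. Assumes the
# RNG has been seeded by the caller. Stream order: auditory deviates, visual
# deviates, then (matching strategy only) the n combination uniforms.
run_trials_engine <- function(auditory, visual, config,
                              mode = c("cims", "non_cims"), n,
                              zero_noise = FALSE) {
  mode <- match.arg(mode)
  enc <- encode_trials(auditory, visual, config, n = n,
                       zero_noise = zero_noise)
  covs <- noise_covariances(config$noise)
  fz <- fuse(enc$x_a, enc$x_v, covs$sigma_a_cov, covs$sigma_v_cov)
  if (mode == "non_cims" || config$prior_common == 1) {
    d <- rep(Inf, n); p_common <- rep(1, n)
    if (mode == "non_cims") { d <- rep(NA_real_, n); p_common <- rep(NA_real_, n) }
    x_final <- fz$x_av
  } else if (config$prior_common == 0) {
    d <- rep(-Inf, n); p_common <- rep(0, n)
    x_final <- enc$x_a
  } else {
    lc1 <- likelihood_common(fz$x_av, fz$sigma_av, config$space)
    lc2 <- likelihood_separate(enc$x_a, enc$x_v, config$noise, config$space,
                               c2_eval = config$c2_eval)
    post <- posterior_common(lc1$log_lik, lc2$log_lik, config$prior_common,
                             log_input = TRUE)
    d <- post$d; p_common <- post$p_common
    u <- if (config$strategy == "matching") runif(n) else NULL
    x_final <- combine_representations(fz$x_av, enc$x_a, p_common,
                                       strategy = config$strategy, u = u)
  }
  list(x_a = enc$x_a, x_v = enc$x_v, x_av = fz$x_av, sigma_av = fz$sigma_av,
       d = d, p_common = p_common, x_final = x_final,
       percept = categorize(x_final, fz$sigma_av, config$space))
}

#' Run a single model trial
#'
#' Composes one full trial — encode, fuse, causal-structure likelihoods,
#' posterior, combination, categorization — and returns every intermediate
#' quantity. In `mode = "non_cims"` the fused representation is taken as
#' final without causal inference (equivalently, `prior_common = 1`).
#'
#' @inheritParams encode_trials
#' @param mode `"cims"` or `"non_cims"`.
#' @param seed Optional seed set before the trial's draws (defaults to the
#'   config seed).
#' @return A list of class `cims_trial` with fields `x_a`, `x_v`, `x_av`,
#'   `sigma_av`, `d`, `p_common`, `x_final`, `percept`.
#' @export
run_trial <- function(auditory, visual, config, mode = c("cims", "non_cims"),
                      seed = config$seed, zero_noise = FALSE) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  res <- run_trials_engine(auditory, visual, config, mode, n = 1L,
                           zero_noise = zero_noise)
  out <- list(x_a = as.numeric(res$x_a), x_v = as.numeric(res$x_v),
              x_av = as.numeric(res$x_av), sigma_av = res$sigma_av,
              d = res$d, p_common = res$p_common,
              x_final = as.numeric(res$x_final), percept = res$percept)
  class(out) <- "cims_trial"
  out
}

#' @export
print.cims_trial <- function(x, ...) {
  cat("<cims_trial> percept:", x$percept, "\n")
  cat(sprintf("  x_a = (%.4g, %.4g)  x_v = (%.4g, %.4g)\n",
              x$x_a[1], x$x_a[2], x$x_v[1], x$x_v[2]))
  cat(sprintf("  x_av = (%.4g, %.4g)  x_final = (%.4g, %.4g)\n",
              x$x_av[1], x$x_av[2], x$x_final[1], x$x_final[2]))
  cat(sprintf("  d = %.4g  p_common = %.4g\n", x$d, x$p_common))
  invisible(x)
}
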
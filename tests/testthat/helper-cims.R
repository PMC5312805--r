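# Shared fixtures: a hand-written space/config (independent of the shipped
# calibrated defaults) and density oracles that avoid the package's own
# log-density code path.

make_test_space <- function(category_sd = 0.1) {
  syllable_space(
    tibble::tibble(label = c("ba", "da", "ga"),
                   x = c(0, 0.35, 1),
                   y = c(0, 0.65, 1)),
    category_sd = category_sd)
}

make_test_config <- function(space = make_test_space(),
                             sigma_a = 0.15, sigma_v = 0.15, ...) {
  model_config(space, noise_model(sigma_a, sigma_v), ...)
}

# bivariate normal density via independent 1-D dnorm factors (diagonal
# covariances only, which covers every default-model covariance)
oracle_dnorm2 <- function(x, mu, sigma) {
  x <- matrix(x, ncol = 2L)
  stopifnot(abs(sigma[1, 2]) < 1e-15, abs(sigma[2, 1]) < 1e-15)
  stats::dnorm(x[, 1], mu[1], sqrt(sigma[1, 1])) *
    stats::dnorm(x[, 2], mu[2], sqrt(sigma[2, 2]))
}

# brute-force categorization: per-label density comparison, first-label ties
oracle_categorize <- function(x, sigma_av, space) {
  x <- matrix(x, ncol = 2L)
  protos <- as.matrix(space$prototypes[, c("x", "y")])
  dens <- sapply(seq_along(space$labels), function(i) {
    oracle_dnorm2(x, protos[i, ], space$category_cov + sigma_av)
  })
  dens <- matrix(dens, nrow = nrow(x))
  space$labels[apply(dens, 1L, which.max)]
}

proportions_of <- function(cm, response) {
  cm$proportion[cm$response == response]
}
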
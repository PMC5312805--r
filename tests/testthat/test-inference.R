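test_that("fusion matches the closed-form precision-weighted combination", {
  sa <- diag(c(1, 2.25))
  sv <- diag(c(2.25, 1))
  fz <- fuse(c(0, 0), c(1, 1), sa, sv)
  # hand computation: precision diag(13/9, 13/9), weights 9/13 and 4/13
  expect_equal(as.numeric(fz$x_av), c(4 / 13, 9 / 13), tolerance = 1e-12)
  expect_equal(fz$sigma_av, diag(c(9 / 13, 9 / 13)), tolerance = 1e-12)

  # equal reliabilities: midpoint
  fz2 <- fuse(c(0, 2), c(4, 0), diag(2), diag(2))
  expect_equal(as.numeric(fz2$x_av), c(2, 1))

  # an unreliable visual cue is ignored
  fz3 <- fuse(c(0, 0), c(1, 1), diag(2), diag(2) * 1e6)
  expect_equal(as.numeric(fz3$x_av), c(0, 0), tolerance = 1e-4)

  # solving the linear system directly agrees with the closed form
  x_a <- c(0.2, -0.4); x_v <- c(1.1, 0.6)
  sa2 <- matrix(c(0.04, 0.01, 0.01, 0.09), 2)
  sv2 <- matrix(c(0.16, -0.02, -0.02, 0.05), 2)
  fz4 <- fuse(x_a, x_v, sa2, sv2)
  direct <- solve(solve(sa2) + solve(sv2),
                  solve(sa2, x_a) + solve(sv2, x_v))
  expect_equal(as.numeric(fz4$x_av), as.numeric(direct), tolerance = 1e-12)

  expect_error(fuse(c(0, 0), c(1, 1), matrix(0, 2, 2), diag(2)),
               class = "cims_numeric_error")
})

test_that("encoding draws follow the stated Gaussian distributions", {
  cfg <- make_test_config()
  set.seed(11)
  enc <- encode_trials("ba", "ga", cfg, n = 100000)
  covs <- noise_covariances(cfg$noise)
  se <- sqrt(diag(covs$sigma_a_cov) / 1e5)
  expect_true(all(abs(colMeans(enc$x_a) - c(0, 0)) < 3 * se))
  se_v <- sqrt(diag(covs$sigma_v_cov) / 1e5)
  expect_true(all(abs(colMeans(enc$x_v) - c(1, 1)) < 3 * se_v))
  expect_equal(stats::cov(enc$x_a), covs$sigma_a_cov, tolerance = 0.02)
  expect_equal(stats::cov(enc$x_v), covs$sigma_v_cov, tolerance = 0.02)
  # anisotropy: auditory cue is tighter along the auditory x-axis
  expect_lt(stats::sd(enc$x_a[, 1]), stats::sd(enc$x_a[, 2]))
  expect_gt(stats::sd(enc$x_v[, 1]), stats::sd(enc$x_v[, 2]))

  z <- encode_trials("ba", "ga", cfg, n = 3, zero_noise = TRUE)
  expect_equal(z$x_a, matrix(0, 3, 2))
  expect_equal(z$x_v, matrix(1, 3, 2))
})

test_that("common-cause likelihood matches a brute-force density oracle", {
  cfg <- make_test_config()
  covs <- noise_covariances(cfg$noise)
  sigma_av <- fuse(c(0, 0), c(0, 0), covs$sigma_a_cov,
                   covs$sigma_v_cov)$sigma_av
  sp <- cfg$space
  pts <- rbind(c(0.45, 0.55), c(0, 0), c(1, 1), c(0.35, 0.65), c(-0.2, 1.4))
  lc <- likelihood_common(pts, sigma_av, sp)
  protos <- as.matrix(sp$prototypes[, c("x", "y")])
  brute <- rowSums(sapply(1:3, function(i) {
    sp$priors[i] * oracle_dnorm2(pts, protos[i, ], sp$category_cov + sigma_av)
  }))
  expect_equal(exp(lc$log_lik), brute, tolerance = 1e-10)

  # at a prototype, that syllable's term dominates
  at_da <- likelihood_common(c(0.35, 0.65), sigma_av, sp)
  expect_identical(unname(which.max(at_da$log_per_syllable[1, ])), 2L)

  # a single-category space reduces to that category's density
  solo <- syllable_space(tibble::tibble(label = "da", x = 0.35, y = 0.65),
                         category_sd = 0.1)
  lc1 <- likelihood_common(c(0.2, 0.2), sigma_av, solo)
  expect_equal(exp(lc1$log_lik),
               oracle_dnorm2(c(0.2, 0.2), c(0.35, 0.65),
                             solo$category_cov + sigma_av),
               tolerance = 1e-12)
})

test_that("separate-cause likelihood behaves as the causal geometry demands", {
  cfg <- make_test_config()
  covs <- noise_covariances(cfg$noise)
  sp <- cfg$space

  # congruent cues on one prototype favour a common cause
  on_ba <- list(x_a = c(0, 0), x_v = c(0, 0))
  fz <- fuse(on_ba$x_a, on_ba$x_v, covs$sigma_a_cov, covs$sigma_v_cov)
  l1 <- likelihood_common(fz$x_av, fz$sigma_av, sp)$log_lik
  l2 <- likelihood_separate(on_ba$x_a, on_ba$x_v, cfg$noise, sp)$log_lik
  expect_gt(l1, l2)

  # cues on two distant prototypes favour separate causes: auditory on
  # "ga", visual on "ba" fuses into the empty corner of the space
  apart <- list(x_a = c(1, 1), x_v = c(0, 0))
  fz2 <- fuse(apart$x_a, apart$x_v, covs$sigma_a_cov, covs$sigma_v_cov)
  l1b <- likelihood_common(fz2$x_av, fz2$sigma_av, sp)$log_lik
  l2b <- likelihood_separate(apart$x_a, apart$x_v, cfg$noise, sp)$log_lik
  expect_gt(l2b, l1b)

  ls <- likelihood_separate(rbind(c(0.3, 0.4)), rbind(c(0.6, 0.2)),
                            cfg$noise, sp)
  expect_identical(ncol(ls$log_per_pair), 6L)   # ordered incongruent pairs
  expect_identical(nrow(ls$pairs), 6L)

  # joint-cue evaluation is a distinct, valid scoring rule
  lj <- likelihood_separate(rbind(c(0.3, 0.4)), rbind(c(0.6, 0.2)),
                            cfg$noise, sp, c2_eval = "joint")
  expect_true(is.finite(lj$log_lik))
  expect_false(isTRUE(all.equal(ls$log_lik, lj$log_lik)))

  solo <- syllable_space(tibble::tibble(label = "da", x = 0.35, y = 0.65),
                         category_sd = 0.1)
  expect_error(likelihood_separate(c(0, 0), c(1, 1), cfg$noise, solo),
               class = "cims_config_error")
})

test_that("log-space and direct-space likelihoods agree off the underflow regime", {
  skip_if_not_installed("mvtnorm")
  cfg <- make_test_config()
  covs <- noise_covariances(cfg$noise)
  sp <- cfg$space
  set.seed(21)
  enc <- encode_trials("ba", "ga", cfg, n = 50)
  fz <- fuse(enc$x_a, enc$x_v, covs$sigma_a_cov, covs$sigma_v_cov)
  lc <- likelihood_common(fz$x_av, fz$sigma_av, sp)
  protos <- as.matrix(sp$prototypes[, c("x", "y")])
  direct <- rowSums(sapply(1:3, function(i) {
    sp$priors[i] * mvtnorm::dmvnorm(fz$x_av, protos[i, ],
                                    sp$category_cov + fz$sigma_av)
  }))
  expect_equal(exp(lc$log_lik), direct, tolerance = 1e-10)

  ls <- likelihood_separate(enc$x_a, enc$x_v, cfg$noise, sp)
  sa_inf <- covs$sigma_a_cov + sp$category_cov
  sv_inf <- covs$sigma_v_cov + sp$category_cov
  fzi <- fuse(enc$x_a, enc$x_v, sa_inf, sv_inf)
  direct2 <- rowMeans(sapply(seq_len(nrow(ls$pairs)), function(k) {
    mu <- fuse(protos[match(ls$pairs$aud_cause[k], sp$labels), ],
               protos[match(ls$pairs$vis_cause[k], sp$labels), ],
               sa_inf, sv_inf)$x_av
    mvtnorm::dmvnorm(fzi$x_av, as.numeric(mu), fzi$sigma_av)
  }))
  expect_equal(exp(ls$log_lik), direct2, tolerance = 1e-10)
})

test_that("the causal posterior follows the logistic of the log posterior ratio", {
  eq <- posterior_common(0.2, 0.2, 0.5)
  expect_equal(eq$d, 0)
  expect_equal(eq$p_common, 0.5)

  lr3 <- posterior_common(0.3, 0.1, 0.5)
  expect_equal(lr3$d, log(3), tolerance = 1e-12)
  expect_equal(lr3$p_common, 0.75, tolerance = 1e-12)

  expect_equal(posterior_common(1e-300, 1, 1)$p_common, 1)
  expect_equal(posterior_common(1, 1e-300, 0)$p_common, 0)

  # prior shifts the ratio additively on the log scale
  sh <- posterior_common(0.1, 0.1, 0.8)
  expect_equal(sh$d, log(0.8 / 0.2), tolerance = 1e-12)

  expect_error(posterior_common(0, 0, 0.5), class = "cims_degenerate_error")
  expect_error(posterior_common(-1, 1, 0.5), class = "cims_validation_error")
  expect_error(posterior_common(-Inf, -Inf, 0.5, log_input = TRUE),
               class = "cims_degenerate_error")
})

test_that("strategy combination is a convex or selective mix of X_AV and X_A", {
  x_av <- rbind(c(1, 1), c(2, 0))
  x_a <- rbind(c(0, 0), c(0, 2))
  expect_equal(combine_representations(x_av, x_a, c(1, 1)), x_av)
  expect_equal(combine_representations(x_av, x_a, c(0, 0)), x_a)
  expect_equal(combine_representations(x_av, x_a, c(0.5, 0.5)),
               (x_av + x_a) / 2)
  # selection: hard threshold at 0.5, ties go to the fused candidate
  expect_equal(combine_representations(x_av, x_a, c(0.5, 0.49),
                                       strategy = "selection"),
               rbind(x_av[1, ], x_a[2, ]))
  # matching consumes the provided uniforms
  expect_equal(combine_representations(x_av, x_a, c(0.7, 0.7),
                                       strategy = "matching", u = c(0.6, 0.9)),
               rbind(x_av[1, ], x_a[2, ]))
  expect_error(combine_representations(x_av, x_a, c(1.2, 0)),
               class = "cims_validation_error")
})

test_that("categorization matches the brute-force density comparison", {
  cfg <- make_test_config()
  covs <- noise_covariances(cfg$noise)
  sigma_av <- fuse(c(0, 0), c(0, 0), covs$sigma_a_cov,
                   covs$sigma_v_cov)$sigma_av
  sp <- cfg$space

  expect_identical(categorize(c(0.35, 0.65), sigma_av, sp), "da")
  # exact tie between "ba" and "da": first label in order wins
  midpoint <- c(0.35 / 2, 0.65 / 2)
  expect_identical(categorize(midpoint, sigma_av, sp), "ba")

  grid <- as.matrix(expand.grid(x = seq(-0.3, 1.3, length.out = 20),
                                y = seq(-0.3, 1.3, length.out = 20)))
  expect_identical(categorize(grid, sigma_av, sp),
                   oracle_categorize(grid, sigma_av, sp))
})

test_that("a full trial composes the stages coherently", {
  cfg <- make_test_config()

  # noiseless congruent stimulus is perceived veridically
  tr <- run_trial("ba", "ba", cfg, mode = "cims", zero_noise = TRUE)
  expect_identical(tr$percept, "ba")
  expect_equal(tr$x_av, c(0, 0))

  # forced-fusion equivalence at the single-trial level
  cfg1 <- make_test_config(prior_common = 1)
  t_ff <- run_trial("ba", "ga", cfg1, mode = "cims", seed = 7)
  t_nc <- run_trial("ba", "ga", cfg, mode = "non_cims", seed = 7)
  expect_identical(t_ff$x_a, t_nc$x_a)
  expect_identical(t_ff$x_final, t_nc$x_final)
  expect_identical(t_ff$percept, t_nc$percept)
  expect_equal(t_ff$p_common, 1)

  # averaging keeps the final representation between X_AV and X_A
  for (s in 1:20) {
    tr2 <- run_trial("ba", "ga", cfg, mode = "cims", seed = s)
    lo <- pmin(tr2$x_av, tr2$x_a) - 1e-12
    hi <- pmax(tr2$x_av, tr2$x_a) + 1e-12
    expect_true(all(tr2$x_final >= lo & tr2$x_final <= hi))
    expect_equal(tr2$p_common, stats::plogis(tr2$d))
  }
})
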
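test_that("synthetic datasets respect the experimental design and the seed", {
  cfg <- make_test_config()
  ds <- simulate_subjects(cfg, n_subjects = 6, trials_per_stimulus = 10,
                          seed = 42)
  per <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(ds), subject_id, stimulus_auditory,
                    stimulus_visual),
    n = sum(count), .groups = "drop")
  expect_true(all(per$n == 10L))
  expect_identical(nrow(per), 6L * 9L)

  subj <- subject_parameters(ds)
  expect_identical(nrow(subj), 6L)
  expect_true(all(subj$mult_a > 0 & subj$mult_v > 0))

  ds2 <- simulate_subjects(cfg, n_subjects = 6, trials_per_stimulus = 10,
                           seed = 42)
  expect_identical(tibble::as_tibble(ds), tibble::as_tibble(ds2))
  expect_identical(subject_parameters(ds), subject_parameters(ds2))

  expect_error(simulate_subjects(cfg, variability = list(sigma_sdlog = 1)),
               class = "cims_validation_error")
  expect_error(variability_spec(sigma_sdlog = -0.1),
               class = "cims_validation_error")
})

test_that("aggregation pools counts exactly", {
  cfg <- make_test_config()
  ds1 <- simulate_subjects(cfg, n_subjects = 1, trials_per_stimulus = 10,
                           seed = 9)
  agg1 <- aggregate_behavior(ds1)
  own <- dplyr::arrange(tibble::as_tibble(ds1), stimulus_auditory,
                        stimulus_visual, response)
  agg_s <- dplyr::arrange(tibble::as_tibble(agg1), stimulus_auditory,
                          stimulus_visual, response)
  expect_identical(agg_s$count, as.integer(own$count))
  expect_equal(agg_s$proportion, own$count / 10)

  # duplicating a subject leaves the pooled proportions unchanged
  twin <- dplyr::mutate(tibble::as_tibble(ds1), subject_id = "S999")
  agg2 <- aggregate_behavior(dplyr::bind_rows(tibble::as_tibble(ds1), twin))
  agg2_s <- dplyr::arrange(tibble::as_tibble(agg2), stimulus_auditory,
                           stimulus_visual, response)
  expect_equal(agg2_s$proportion, agg_s$proportion)
  expect_true(all(agg2_s$n_trials == 20L))

  rows <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(agg1), stimulus_auditory,
                    stimulus_visual),
    p = sum(proportion), .groups = "drop")
  expect_true(all(abs(rows$p - 1) < 1e-9))
})

test_that("a zero-variability cohort converges to the base-config predictions", {
  cfg <- make_test_config()
  ds <- simulate_subjects(cfg, n_subjects = 60, trials_per_stimulus = 10,
                          variability = variability_spec(0, 0), seed = 314)
  agg <- aggregate_behavior(ds)
  ref <- simulate_grid(cfg, mode = "cims", n_trials = 20000, seed = 2718)
  j <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(agg)[, c(1:3, 5)], obs = "proportion"),
    dplyr::rename(tibble::as_tibble(ref)[, c(1, 2, 3, 5)],
                  pred = "proportion"),
    by = c("stimulus_auditory", "stimulus_visual", "response"))
  se <- sqrt(pmax(j$pred * (1 - j$pred), 1e-12) / 600)
  expect_true(all(abs(j$obs - j$pred) <= pmax(4 * se, 0.02)))
})

test_that("between-subject spread in McGurk susceptibility tracks the variability spec", {
  cfg <- make_test_config()
  mcgurk <- tibble::tibble(auditory = "ba", visual = "ga")
  spreads <- c(0.02, 0.2, 0.6)
  v <- vapply(spreads, function(sdlog) {
    ds <- simulate_subjects(cfg, n_subjects = 40, trials_per_stimulus = 10,
                            variability = variability_spec(sdlog, 0),
                            stimuli = mcgurk, seed = 77)
    rates <- dplyr::filter(tibble::as_tibble(ds), response == "da")$count / 10
    stats::var(rates)
  }, numeric(1))
  expect_identical(order(v), 1:3)   # rank correlation 1 with the spread grid
})

test_that("behavioral CSV files round-trip with their subject companion", {
  cfg <- make_test_config()
  ds <- simulate_subjects(cfg, n_subjects = 3, trials_per_stimulus = 5,
                          seed = 8)
  p <- file.path(withr::local_tempdir(), "synth.csv")
  write_behavior(ds, p)
  expect_true(file.exists(sub("\\.csv$", "-subjects.csv", p)))
  back <- read_behavior(p)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ds),
               ignore_attr = TRUE)
  expect_equal(subject_parameters(back)$mult_a,
               subject_parameters(ds)$mult_a, tolerance = 1e-12)
})
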
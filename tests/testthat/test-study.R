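test_that("configuration validation catches bad inputs", {
  expect_error(study_config(tests = data.frame(test = "banana",
                                               variant = "standard")),
               "unknown test")
  expect_error(study_config(tests = data.frame(test = "chisq",
                                               variant = "tb")),
               "no TB variant")
  expect_error(study_config(alpha = 1.5), "alpha")
  expect_error(type1_experiment(study_config(
    distributions = list(vm = circ_dist("vonmises", kappa = 1)))),
    "uniform")
  expect_error(power_experiment(study_config()), "non-uniform")
})

test_that("precomputed null distributions are deterministic and size-checked", {
  a <- null_statistics("rao", n = 13, n_reps = 200, variant = "tb",
                       kappa = 1000, seed = 51, grouping_m = 36)
  b <- null_statistics("rao", n = 13, n_reps = 200, variant = "tb",
                       kappa = 1000, seed = 51, grouping_m = 36)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_identical(attr(a, "grouping_m"), 36L)
  expect_error(tb_test(random_angles(20), "rao", null_stats = a), "n = 13")
})

test_that("shared and per-dataset nulls give compatible rejection rates", {
  base <- list(tests = data.frame(test = "rao", variant = "tb"),
               sample_sizes = 10, n_datasets = 200, n_reps = 500, seed = 52)
  shared <- type1_experiment(do.call(study_config, c(base, share_null = TRUE)))
  fresh <- type1_experiment(do.call(study_config, c(base, share_null = FALSE)))
  se <- sqrt(2 * 0.05 * 0.95 / 200)
  expect_lt(abs(shared$rejection_rate - fresh$rejection_rate), 3 * se)
})

test_that("rejection rates are exact fractions of the dataset count", {
  cfg <- study_config(tests = data.frame(test = c("rayleigh", "chisq"),
                                         variant = "standard"),
                      sample_sizes = c(5, 10), n_datasets = 150,
                      n_reps = 100, seed = 53)
  res <- type1_experiment(cfg)
  ok <- !is.na(res$rejection_rate)
  expect_equal(res$rejection_rate[ok] * 150,
               round(res$rejection_rate[ok] * 150), tolerance = 1e-9)
  # chi-squared is not applicable at n = 5
  expect_true(is.na(res$rejection_rate[res$test == "chisq" & res$n == 5]))
  # ... nor on continuous data
  cont <- type1_experiment(study_config(
    tests = data.frame(test = "chisq", variant = "standard"),
    sample_sizes = 10, grouping = NULL, n_datasets = 50, n_reps = 50,
    seed = 54))
  expect_true(is.na(cont$rejection_rate))
})

test_that("power grows with sample size", {
  cfg <- study_config(tests = data.frame(test = "rayleigh",
                                         variant = "standard"),
                      sample_sizes = c(10, 25, 50), grouping = NULL,
                      distributions = list(vm = circ_dist("vonmises",
                                                          kappa = 1)),
                      n_datasets = 500, n_reps = 200, seed = 55)
  res <- power_experiment(cfg)
  res <- res[order(res$n), ]
  se <- sqrt(2 * 0.25 / 500)
  expect_true(all(diff(res$rejection_rate) > -3 * se))
  # and clearly exceeds the nominal level at n = 50
  expect_gt(res$rejection_rate[res$n == 50], 0.5)
})

test_that("standard and TB variants agree on continuous data at small n", {
  cfg <- study_config(tests = data.frame(test = c("rao", "rao"),
                                         variant = c("standard", "tb")),
                      sample_sizes = 10, grouping = NULL,
                      n_datasets = 1000, n_reps = 1000, seed = 56)
  res <- type1_experiment(cfg)
  se <- sqrt(2 * 0.05 * 0.95 / 1000)
  expect_lt(abs(diff(res$rejection_rate)), 3 * se + 0.01)
})

test_that("a study rerun under the same seed is identical, and the CSV too", {
  cfg <- study_config(tests = data.frame(test = "gini", variant = "tb"),
                      sample_sizes = c(5, 10), n_datasets = 100,
                      n_reps = 100, seed = 57)
  r1 <- type1_experiment(cfg)
  r2 <- type1_experiment(cfg)
  expect_identical(r1, r2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_study_csv(r1, f1); write_study_csv(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("YAML study configs round-trip into runnable experiments", {
  skip_if_not_installed("yaml")
  f <- tempfile(fileext = ".yaml")
  writeLines(c("sample_sizes: [5, 10]",
               "n_datasets: 50", "n_reps: 50", "seed: 58",
               "tests:", "  - {test: rao, variant: tb}",
               "distributions: [uniform]"), f)
  cfg <- read_study_config(f)
  expect_s3_class(cfg, "study_config")
  res <- type1_experiment(cfg)
  expect_identical(nrow(res), 2L)
  writeLines("distributions: [nope]", f)
  expect_error(read_study_config(f), "unknown distribution")
})
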
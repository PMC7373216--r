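test_that("Monte-Carlo p-value follows the (N_e + 1)/(N_R + 1) rule", {
  # coincident points maximize the Rao statistic: no null sample exceeds it
  res <- monte_carlo_pvalue(rep(1, 10), "rao", n_reps = 99, seed = 1)
  expect_identical(res$n_exceed, 0L)
  expect_equal(res$p.value, 1 / 100)

  # equally spaced points minimize it: every null sample exceeds it
  res2 <- monte_carlo_pvalue(2 * pi * (0:9) / 10, "rao", n_reps = 99, seed = 1)
  expect_identical(res2$n_exceed, 99L)
  expect_equal(res2$p.value, 1)

  # the rule holds against a precomputed null, and p >= 1/(N_R + 1)
  null <- null_statistics("gini", n = 13, n_reps = 500, seed = 2)
  res3 <- monte_carlo_pvalue(pigeon_radians(), "gini", null_stats = null)
  expect_equal(res3$p.value, (res3$n_exceed + 1) / 501)
  expect_gte(res3$p.value, 1 / 501)
  expect_lte(res3$p.value, 1)
})

test_that("precomputed nulls are rejected on any mismatch", {
  null <- null_statistics("gini", n = 13, n_reps = 100, seed = 3)
  expect_error(monte_carlo_pvalue(random_angles(20), "gini",
                                  null_stats = null), "n = 13")
  expect_error(monte_carlo_pvalue(pigeon_radians(), "rao",
                                  null_stats = null), "statistic")
  expect_error(tb_test(pigeon_radians(), "gini", null_stats = null),
               "variant")
  expect_error(monte_carlo_pvalue(pigeon_radians(), "banana", n_reps = 10),
               "arg")
})

test_that("results are reproducible under a seed", {
  x <- pigeon_radians()
  a <- monte_carlo_pvalue(x, "hr", n_reps = 300, seed = 7)
  b <- monte_carlo_pvalue(x, "hr", n_reps = 300, seed = 7)
  expect_identical(a$p.value, b$p.value)
  expect_identical(a$n_exceed, b$n_exceed)

  ta <- tb_test(x, "rao", n_reps = 300, kappa = 1000, seed = 8)
  tb <- tb_test(x, "rao", n_reps = 300, kappa = 1000, seed = 8)
  expect_identical(ta$p.value, tb$p.value)
  expect_identical(unname(ta$statistic), unname(tb$statistic))
})

test_that("perturbation is tiny for large kappa, breaks ties, and wraps", {
  x <- rep(350 * pi / 180, 3)
  set.seed(9)
  y <- circ_perturb(x, kappa = 1000)
  expect_length(unique(as.numeric(y)), 3L)
  expect_true(all(abs(as.numeric(y) - x) < 0.1 |
                    abs(abs(as.numeric(y) - x) - 2 * pi) < 0.1))

  z <- random_angles(200)
  w <- as.numeric(circ_perturb(z, kappa = 1e8, seed = 10))
  d <- pmin(abs(w - z), 2 * pi - abs(w - z))
  expect_lt(max(d), 0.001)

  edge <- as.numeric(circ_perturb(rep(2 * pi - 1e-6, 50), kappa = 1000,
                                  seed = 11))
  expect_true(all(edge >= 0 & edge < 2 * pi))

  expect_error(circ_perturb(z, kappa = -1), "kappa")
})

test_that("TB p-value approaches the standard one as perturbation and grouping vanish", {
  set.seed(12)
  x <- random_angles(20)  # continuous, untied
  std <- monte_carlo_pvalue(x, "rao", n_reps = 2000, seed = 13)
  tb <- tb_test(x, "rao", n_reps = 2000, kappa = 1e8, seed = 14, m = 1e6)
  tol <- 3 * sqrt(2 * std$p.value * (1 - std$p.value) / 2000)
  expect_lt(abs(tb$p.value - std$p.value), tol + 0.01)
})

test_that("closed-form Rayleigh p-value behaves at the extremes", {
  # symmetric grid: no directionality
  grid <- 2 * pi * (0:35) / 36
  expect_gt(rayleigh_test(grid)$p.value, 0.99)
  # perfect concentration at n = 50
  res <- rayleigh_test(rep(0.3, 50))
  expect_lt(res$p.value, 1e-15)
  expect_gt(res$p.value, 0)
  expect_error(rayleigh_test(1.0), "at least two")
})

test_that("chi-squared test gives p = 1 for uniform counts and matches the tail", {
  x <- 2 * pi * (0:11) / 12
  res <- chisq_uniformity_test(x, m = 12)
  expect_equal(res$p.value, 1)

  y <- c(rep(0, 5), rep(pi / 2, 1), rep(3 * pi / 2, 2))
  res2 <- chisq_uniformity_test(y, m = 4)
  expect_equal(res2$p.value,
               stats::pchisq(unname(res2$statistic), df = 3,
                             lower.tail = FALSE))
  expect_error(chisq_uniformity_test(c(0, 1), m = 4), "n > 5")
})

test_that("table bounds reproduce the classical range statements", {
  pg <- pigeon_radians()
  kb <- kuiper_pvalue_bounds(pg)
  expect_equal(unname(kb["lower"]), 0.15)   # "p > 0.15"
  wb <- watson_pvalue_bounds(pg)
  expect_equal(unname(wb["lower"]), 0.10)   # "p > 0.1"
  # strongly clustered data are significant at the smallest tabled level
  clustered <- rvonmises(30, mu = 1, kappa = 20, seed = 15)
  expect_equal(unname(kuiper_pvalue_bounds(clustered)["upper"]), 0.01)
})

test_that("Monte-Carlo p-values are valid (super-uniform) under the null", {
  # data drawn from the exact null pipeline used inside the engine
  set.seed(16)
  null <- null_statistics("rao", n = 8, n_reps = 999)
  X <- matrix(random_angles(8 * 2000), nrow = 8)
  obs <- circtb:::batch_statistic(X, "rao")
  ne <- 999 - findInterval(obs, null, left.open = TRUE)
  p <- (ne + 1) / 1000
  expect_lt(mean(p <= 0.05), 0.05 + 0.015)
})

test_that("the auto variant picks TB exactly when ties or grouping are present", {
  tied <- circ_sample(pigeon_bearings)
  res <- circ_uniformity_test(tied, "rao", variant = "auto", n_reps = 200,
                              seed = 17)
  expect_identical(res$variant, "tb")

  set.seed(18)
  cont <- circ_sample(random_angles(15), units = "radians")
  res2 <- circ_uniformity_test(cont, "rao", variant = "auto", n_reps = 200,
                               seed = 19)
  expect_identical(res2$variant, "standard")

  expect_error(circ_uniformity_test(tied, "chisq", variant = "tb", m = 72),
               "no TB variant")
})
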
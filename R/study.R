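#' Default test battery for the simulation study
#'
#' All six circular tests in both standard and tie-breaking variants, plus
#' the standard chi-squared baseline (which has no TB variant).
#'
#' @return data.frame with columns `test` and `variant`.
#' @export
default_tests <- function() {
  circ <- c("rayleigh", "kuiper", "watson", "rao", "gini", "hr")
  rbind(data.frame(test = circ, variant = "standard"),
        data.frame(test = circ, variant = "tb"),
        data.frame(test = "chisq", variant = "standard"))
}

#' Configuration for a type-I-error / power study
#'
#' Bundles and validates every knob of the simulation harness. Defaults are
#' desk-scale (2,000 datasets and 2,000 Monte-Carlo replicates per cell
#' rather than the full-scale 10,000/10,000), with the nominal level 0.05,
#' grouping to 36 values (10-degree rounding) and tie-breaking
#' concentration kappa = 1000.
#'
#' @param tests data.frame with columns `test`, `variant` (see
#'   [default_tests()]).
#' @param sample_sizes integer vector of sample sizes per cell.
#' @param grouping `NULL` for continuous data, or an integer m: each
#'   generated angle is rounded to the nearest of m evenly spaced values
#'   (after generation, emulating measurement rounding).
#' @param distributions named list of [circ_dist()] objects.
#' @param n_datasets datasets simulated per cell.
#' @param n_reps Monte-Carlo replicates \eqn{N_R} per null distribution.
#' @param alpha nominal test level.
#' @param kappa tie-breaking perturbation concentration.
#' @param seed master seed; per-cell seeds are derived from it by hashing
#'   the cell coordinates, so any single cell can be reproduced alone.
#' @param share_null reuse one Monte-Carlo null distribution for every
#'   dataset of a cell (valid because all of a cell's datasets share an
#'   identical null pipeline); set `FALSE` to draw a fresh null per dataset
#'   at roughly `n_datasets`-fold cost.
#' @return a list of class `study_config`.
#' @export
study_config <- function(tests = default_tests(),
                         sample_sizes = c(5, 10, 15, 25, 50),
                         grouping = 36,
                         distributions = list(uniform = circ_dist("uniform")),
                         n_datasets = 2000, n_reps = 2000, alpha = 0.05,
                         kappa = 1000, seed = 1, share_null = TRUE) {
  stopifnot(is.data.frame(tests), all(c("test", "variant") %in% names(tests)),
            nrow(tests) >= 1L)
  bad <- !tests$test %in% c(circ_stat_names, "chisq")
  if (any(bad)) stop("unknown test(s): ", paste(tests$test[bad], collapse = ", "))
  if (any(!tests$variant %in% c("standard", "tb")))
    stop("variant must be 'standard' or 'tb'")
  if (any(tests$test == "chisq" & tests$variant == "tb"))
    stop("the chi-squared test has no TB variant")
  stopifnot(length(sample_sizes) >= 1L, all(sample_sizes >= 2))
  if (!is.null(grouping)) stopifnot(grouping >= 2)
  stopifnot(is.list(distributions), length(distributions) >= 1L,
            !is.null(names(distributions)),
            all(vapply(distributions, inherits, TRUE, "circ_dist")))
  stopifnot(n_datasets >= 1, n_reps >= 1, alpha > 0, alpha < 1, kappa > 0)
  structure(list(tests = tests, sample_sizes = as.integer(sample_sizes),
                 grouping = if (is.null(grouping)) NULL else as.integer(grouping),
                 distributions = distributions,
                 n_datasets = as.integer(n_datasets),
                 n_reps = as.integer(n_reps), alpha = alpha, kappa = kappa,
                 seed = as.integer(seed), share_null = isTRUE(share_null)),
            class = "study_config")
}

# deterministic per-cell seed: polynomial hash of the cell label folded
# with the master seed, kept inside the 32-bit integer range
cell_seed <- function(master, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 1000000007
  as.integer((abs(master) + h) %% (.Machine$integer.max - 1L) + 1L)
}

#' Type-I error experiment
#'
#' Rejection rate of each configured (test, variant) pair at the nominal
#' level when the data truly are uniform: for every cell (test, variant,
#' sample size), `n_datasets` uniform samples are generated, grouped if
#' configured, tested, and the fraction of p-values below `alpha` is
#' recorded. A well-behaved test should stay at `alpha`; spacing-based
#' standard tests on grouped data do not.
#'
#' @param config a [study_config()] whose distributions are all uniform
#'   (the default).
#' @return data.frame with one row per cell: `test`, `variant`,
#'   `distribution`, `n`, `grouping_m`, `rejection_rate`, `n_datasets`,
#'   `seed`.
#' @export
type1_experiment <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  if (!all(vapply(config$distributions, function(d) d$family, "") == "uniform"))
    stop("type1_experiment requires all distributions to be uniform")
  run_study(config)
}

#' Power experiment
#'
#' As [type1_experiment()], but sampling from the configured non-uniform
#' alternatives; the rejection rate is then the power of the test against
#' that alternative at the given sample size. Grouping, when configured, is
#' applied to each continuously generated sample by rounding, mirroring how
#' rounded field data arise.
#'
#' @param config a [study_config()] with at least one non-uniform
#'   distribution.
#' @return data.frame as in [type1_experiment()].
#' @export
power_experiment <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (all(vapply(config$distributions, function(d) d$family, "") == "uniform"))
    stop("power_experiment requires at least one non-uniform distribution")
  run_study(config)
}

run_study <- function(config) {
  rows <- list()
  for (dname in names(config$distributions)) {
    for (n in config$sample_sizes) {
      for (i in seq_len(nrow(config$tests))) {
        test <- config$tests$test[i]
        variant <- config$tests$variant[i]
        rate <- run_cell(test, variant, config$distributions[[dname]],
                         dname, n, config)
        rows[[length(rows) + 1L]] <- data.frame(
          test = test, variant = variant, distribution = dname, n = n,
          grouping_m = if (is.null(config$grouping)) NA_integer_
                       else config$grouping,
          rejection_rate = rate, n_datasets = config$n_datasets,
          seed = config$seed)
      }
    }
  }
  do.call(rbind, rows)
}

# rejection rate for one study cell; NA when the test is inapplicable
# (chi-squared needs grouped data with n > 5)
run_cell <- function(test, variant, dist, dist_name, n, config) {
  m <- config$grouping
  if (test == "chisq" && (is.null(m) || n <= 5L)) return(NA_real_)
  seed <- cell_seed(config$seed,
                    paste(test, variant, dist_name, n,
                          if (is.null(m)) 0L else m, sep = "|"))
  set.seed(seed)
  nd <- config$n_datasets
  X <- matrix(as.numeric(rcirc(n * nd, dist)), nrow = n)
  if (!is.null(m))
    X <- (floor(X * m / (2 * pi) + 0.5 + 1e-9) %% m) * (2 * pi / m)
  p <- cell_pvalues(X, test, variant, config)
  mean(p < config$alpha)
}

cell_pvalues <- function(X, test, variant, config) {
  n <- nrow(X)
  if (test == "chisq") {
    m <- config$grouping
    idx <- floor(X * m / (2 * pi) + 0.5 + 1e-9) %% m
    x2 <- apply(idx, 2L, function(v) {
      counts <- tabulate(v + 1L, nbins = m)
      sum((counts - n / m)^2 / (n / m))
    })
    return(stats::pchisq(x2, df = m - 1, lower.tail = FALSE))
  }
  if (test == "rayleigh" && variant == "standard") {
    rbar <- batch_statistic(X, "rayleigh")
    return(vapply(rbar, rayleigh_pvalue_approx, 0, n = n))
  }
  if (variant == "tb") {
    eps <- rvonmises(length(X), mu = 0, kappa = config$kappa)
    eps <- ifelse(eps > pi, eps - 2 * pi, eps)
    X <- (X + eps) %% (2 * pi)
  }
  obs <- batch_statistic(X, test)
  nr <- config$n_reps
  # the TB null assumes the configured grouping resolution (36 bins when
  # the data are continuous), mirroring the data-generating pipeline
  m_null <- if (is.null(config$grouping)) 36L else config$grouping
  draw_null <- function() {
    null_statistics(test, n, nr, variant = variant, kappa = config$kappa,
                    grouping_m = m_null)
  }
  if (config$share_null) {
    null <- draw_null()
    ne <- length(null) - findInterval(obs, null, left.open = TRUE)
    (ne + 1) / (nr + 1)
  } else {
    vapply(seq_along(obs), function(j) {
      (count_exceed(draw_null(), obs[j]) + 1) / (nr + 1)
    }, 0)
  }
}

#' Write a study result table to CSV
#'
#' @param result data.frame from [type1_experiment()] or
#'   [power_experiment()].
#' @param file output path.
#' @export
write_study_csv <- function(result, file) {
  utils::write.csv(result, file, row.names = FALSE)
  invisible(file)
}

#' Read a study configuration from a YAML file
#'
#' The file may set any of the scalar [study_config()] fields
#' (`sample_sizes`, `grouping`, `n_datasets`, `n_reps`, `alpha`, `kappa`,
#' `seed`, `share_null`), a `tests` list of `test`/`variant` pairs, and a
#' `distributions` list of names from the built-in panel
#' ([study_distributions()], plus `uniform`).
#'
#' @param file path to a YAML config.
#' @return a [study_config()].
#' @export
read_study_config <- function(file) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  raw <- yaml::read_yaml(file)
  args <- list()
  for (f in c("sample_sizes", "grouping", "n_datasets", "n_reps", "alpha",
              "kappa", "seed", "share_null"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  if (!is.null(raw$tests)) {
    args$tests <- do.call(rbind, lapply(raw$tests, function(t)
      data.frame(test = t$test, variant = t$variant)))
  }
  if (!is.null(raw$distributions)) {
    panel <- c(list(uniform = circ_dist("uniform")), study_distributions())
    unknown <- setdiff(unlist(raw$distributions), names(panel))
    if (length(unknown) > 0L)
      stop("unknown distribution(s) in config: ",
           paste(unknown, collapse = ", "))
    args$distributions <- panel[unlist(raw$distributions)]
  }
  do.call(study_config, args)
}
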
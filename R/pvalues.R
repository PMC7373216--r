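#' Von Mises random deviates
#'
#' Draws from the von Mises distribution by the Best-Fisher rejection
#' algorithm (exact; wrapped-Cauchy envelope). Used both as an alternative
#' distribution in power studies and, with large `kappa`, as the
#' tie-breaking perturbation noise.
#'
#' @param n number of deviates.
#' @param mu mean direction (radians).
#' @param kappa concentration parameter, > 0.
#' @param seed optional integer; if given, `set.seed(seed)` is called first.
#' @return numeric vector of n angles in \eqn{[0, 2\pi)}.
#' @export
rvonmises <- function(n, mu = 0, kappa, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be > 0")
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    todo <- n - length(out)
    k <- max(ceiling(todo * 1.6), 16L)
    u1 <- stats::runif(k); u2 <- stats::runif(k); u3 <- stats::runif(k)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    out <- c(out, th)
  }
  wrap_angle(mu + out[seq_len(n)])
}

#' Tie-breaking perturbation
#'
#' Adds an independent von Mises(0, kappa) perturbation to every angle and
#' wraps the result back into \eqn{[0, 2\pi)}. With the default
#' `kappa = 1000` the noise has circular SD of about 1.8 degrees, small
#' relative to typical grouping resolutions (10 degrees), so tied values
#' become distinct while the ordering of distinct grouped values is
#' essentially never disturbed. kappa should be chosen so that almost all
#' perturbations are below the data's rounding granularity.
#'
#' @param x a [circ_sample()] or numeric vector of radians.
#' @param kappa perturbation concentration, > 0; larger means smaller noise.
#' @param seed optional integer seed.
#' @return a `circ_sample` of perturbed angles (grouping metadata dropped:
#'   the output is continuous).
#' @export
circ_perturb <- function(x, kappa = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as_circ_sample(x)
  eps <- rvonmises(length(x), mu = 0, kappa = kappa)
  # noise is drawn on [0, 2pi); recentre to (-pi, pi] before adding
  eps <- ifelse(eps > pi, eps - 2 * pi, eps)
  structure(wrap_angle(as.numeric(x) + eps), class = "circ_sample",
            units_original = attr(x, "units_original"), grouping_m = NULL)
}

#' Precompute a Monte-Carlo null distribution of a statistic
#'
#' Draws `n_reps` samples of size `n` from the continuous circular uniform
#' distribution, optionally applies the tie-breaking perturbation to each
#' (for the TB variant), and evaluates the chosen statistic. The returned
#' sorted vector can be passed as `null_stats` to [monte_carlo_pvalue()] or
#' [tb_test()] and reused across many datasets of the same size — the key
#' acceleration of the simulation study, valid because every dataset in a
#' study cell shares an identical null pipeline.
#'
#' @param statistic one of `"rayleigh"`, `"kuiper"`, `"watson"`, `"rao"`,
#'   `"gini"`, `"hr"`.
#' @param n sample size the null is computed for.
#' @param n_reps number of null replicates \eqn{N_R}.
#' @param variant `"standard"` (plain uniform nulls) or `"tb"` (each null
#'   sample grouped to `grouping_m` values and then perturbed with von
#'   Mises(0, kappa) noise before evaluation, mirroring the pipeline that
#'   produced grouped observed data).
#' @param kappa perturbation concentration for the TB variant.
#' @param seed optional integer seed.
#' @param grouping_m grouping resolution of the TB null pipeline (default
#'   36, i.e. 10-degree rounding). The TB tests assume this resolution even
#'   for continuous data, which makes them exact on data grouped to
#'   `grouping_m` and mildly conservative on continuous data.
#' @return sorted numeric vector of `n_reps` statistic values, with
#'   attributes `statistic`, `n`, `variant`, `kappa`, `grouping_m`.
#' @export
null_statistics <- function(statistic, n, n_reps,
                            variant = c("standard", "tb"),
                            kappa = 1000, seed = NULL, grouping_m = 36) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_reps >= 1L, n >= 1L)
  statistic <- match.arg(statistic, circ_stat_names)
  X <- matrix(stats::runif(n * n_reps, 0, 2 * pi), nrow = n)
  if (variant == "tb") {
    grouping_m <- as.integer(grouping_m)
    stopifnot(grouping_m >= 2L)
    X <- (floor(X * grouping_m / (2 * pi) + 0.5 + 1e-9) %% grouping_m) *
      (2 * pi / grouping_m)
    eps <- rvonmises(n * n_reps, mu = 0, kappa = kappa)
    eps <- ifelse(eps > pi, eps - 2 * pi, eps)
    X <- (X + eps) %% (2 * pi)
  }
  structure(sort(batch_statistic(X, statistic)),
            statistic = statistic, n = as.integer(n),
            variant = variant, kappa = if (variant == "tb") kappa else NULL,
            grouping_m = if (variant == "tb") grouping_m else NULL)
}

# spacing- and CDF-based statistics are undefined for a single point
check_min_n <- function(statistic, n) {
  if (statistic %in% c("rao", "gini", "kuiper", "watson") && n < 2L)
    stop("need at least two points")
  invisible(NULL)
}

# number of null values >= obs, for a sorted null vector; ties count
count_exceed <- function(null_sorted, obs) {
  length(null_sorted) - findInterval(obs, null_sorted, left.open = TRUE)
}

check_null_stats <- function(null_stats, statistic, n, variant) {
  if (!identical(attr(null_stats, "statistic"), statistic))
    stop("null_stats were computed for statistic '",
         attr(null_stats, "statistic"), "', not '", statistic, "'")
  if (!identical(as.integer(attr(null_stats, "n")), as.integer(n)))
    stop("null_stats were computed for n = ", attr(null_stats, "n"),
         ", not n = ", n)
  if (!identical(attr(null_stats, "variant"), variant))
    stop("null_stats were computed for the '", attr(null_stats, "variant"),
         "' variant, not '", variant, "'")
  invisible(null_stats)
}

new_circ_test <- function(statistic_name, value, n, p, method_label,
                          method_type, variant, n_reps = 0L, n_exceed = NA_integer_,
                          seed = NULL, kappa = NULL, p_bounds = NULL) {
  stat <- c(value)
  names(stat) <- switch(statistic_name,
                        rayleigh = "Rbar", kuiper = "Vn", watson = "U2",
                        rao = "U", gini = "Gn", hr = "V", chisq = "X2")
  structure(list(statistic = stat, p.value = p,
                 method = method_label,
                 data.name = sprintf("%d angles", n),
                 alternative = "non-uniform distribution around the circle",
                 test = statistic_name, n = n,
                 p.method = method_type, variant = variant,
                 n_reps = as.integer(n_reps), n_exceed = as.integer(n_exceed),
                 seed = seed, kappa = kappa, p_bounds = p_bounds),
            class = c("circ_test", "htest"))
}

#' @export
print.circ_test <- function(x, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  cat(sprintf("data:  %s\n", x$data.name))
  cat(sprintf("%s = %.6g, p-value = %.4g\n",
              names(x$statistic), x$statistic, x$p.value))
  if (x$p.method == "monte_carlo")
    cat(sprintf("variant: %s; N_R = %d, N_e = %d%s%s\n", x$variant, x$n_reps,
                x$n_exceed,
                if (!is.null(x$kappa)) sprintf(", kappa = %g", x$kappa) else "",
                if (!is.null(x$seed)) sprintf(", seed = %d", x$seed) else ""))
  if (!is.null(x$p_bounds))
    cat(sprintf("table bound: %s\n", format_p_bounds(x$p_bounds)))
  cat(sprintf("alternative hypothesis: %s\n", x$alternative))
  invisible(x)
}

#' Monte-Carlo p-value for a uniformity statistic
#'
#' The simulation p-value used for every statistic without a usable
#' closed-form null: draw \eqn{N_R} samples of the same size from the
#' continuous circular uniform, count the number \eqn{N_e} whose statistic
#' is equal to or greater than the observed one, and report
#' \eqn{p = (N_e + 1) / (N_R + 1)}. The +1 correction makes the p-value
#' valid (never below \eqn{1/(N_R+1)}) and is the standard permutation
#' p-value construction.
#'
#' @param x a [circ_sample()] or numeric vector of radians.
#' @param statistic one of `"rayleigh"`, `"kuiper"`, `"watson"`, `"rao"`,
#'   `"gini"`, `"hr"`.
#' @param n_reps number of null replicates \eqn{N_R} (default 10,000).
#' @param seed optional integer seed.
#' @param null_stats optional precomputed null distribution from
#'   [null_statistics()] (must match statistic, n, and the standard
#'   variant); when supplied no null sampling is done.
#' @return an object of class `circ_test` (inherits `htest`).
#' @examples
#' monte_carlo_pvalue(circ_sample(pigeon_bearings), "gini",
#'                    n_reps = 500, seed = 1)
#' @export
monte_carlo_pvalue <- function(x, statistic, n_reps = 10000, seed = NULL,
                               null_stats = NULL) {
  statistic <- match.arg(statistic, circ_stat_names)
  x <- as_circ_sample(x)
  n <- length(x)
  check_min_n(statistic, n)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(null_stats)) {
    null_stats <- null_statistics(statistic, n, n_reps, variant = "standard")
  } else {
    check_null_stats(null_stats, statistic, n, "standard")
    n_reps <- length(null_stats)
  }
  obs <- statistic_fun(statistic)(x)
  ne <- count_exceed(null_stats, obs)
  new_circ_test(statistic, obs, n, (ne + 1) / (n_reps + 1),
                sprintf("%s test of circular uniformity (Monte-Carlo)",
                        stat_label(statistic)),
                "monte_carlo", "standard", n_reps, ne, seed)
}

#' Tie-breaking (TB) test
#'
#' The tie-breaking variant of a Monte-Carlo uniformity test for grouped or
#' rounded data: the observed sample is perturbed once with small von
#' Mises(0, kappa) noise, and each of the \eqn{N_R} null samples is drawn
#' uniform, grouped to the data's grouping resolution, and perturbed the
#' same way before its statistic is evaluated, so that the null mirrors the
#' pipeline that produced the observed data;
#' \eqn{p = (N_e + 1)/(N_R + 1)} as in [monte_carlo_pvalue()]. Breaking the
#' ties restores type-I error control for spacing-based tests on grouped
#' data, at negligible power cost.
#'
#' @inheritParams monte_carlo_pvalue
#' @param kappa perturbation concentration (default 1000; see
#'   [circ_perturb()]).
#' @param m grouping resolution applied to the null samples; defaults to
#'   the sample's own `grouping_m` if recorded, else 36 (10-degree
#'   rounding, the most common field resolution).
#' @param null_stats optional precomputed TB null from [null_statistics()]
#'   with `variant = "tb"`.
#' @return an object of class `circ_test`.
#' @examples
#' tb_test(circ_sample(pigeon_bearings), "rao", n_reps = 500, seed = 1)
#' @export
tb_test <- function(x, statistic, n_reps = 10000, kappa = 1000, seed = NULL,
                    m = NULL, null_stats = NULL) {
  statistic <- match.arg(statistic, circ_stat_names)
  if (kappa <= 0) stop("kappa must be > 0")
  x <- as_circ_sample(x)
  n <- length(x)
  check_min_n(statistic, n)
  if (is.null(m)) m <- attr(x, "grouping_m")
  if (is.null(m)) m <- 36L
  if (!is.null(seed)) set.seed(seed)
  xp <- circ_perturb(x, kappa = kappa)
  if (is.null(null_stats)) {
    null_stats <- null_statistics(statistic, n, n_reps, variant = "tb",
                                  kappa = kappa, grouping_m = m)
  } else {
    check_null_stats(null_stats, statistic, n, "tb")
    n_reps <- length(null_stats)
  }
  obs <- statistic_fun(statistic)(xp)
  ne <- count_exceed(null_stats, obs)
  new_circ_test(statistic, obs, n, (ne + 1) / (n_reps + 1),
                sprintf("%s test of circular uniformity (tie-breaking, Monte-Carlo)",
                        stat_label(statistic)),
                "monte_carlo", "tb", n_reps, ne, seed, kappa)
}

#' Closed-form Rayleigh test
#'
#' The Rayleigh test with its standard second-order series approximation to
#' the p-value: with \eqn{S = n\bar{R}^2},
#' \deqn{p \approx e^{-S}\left[1 + \frac{2S - S^2}{4n}
#'   - \frac{24S - 132S^2 + 76S^3 - 9S^4}{288 n^2}\right],}
#' clamped into \eqn{(0, 1]}. This is the de-facto standard implementation
#' of the test and needs no simulation; the Rayleigh test is also the one
#' standard test whose type-I error is unaffected by grouping.
#'
#' @param x a [circ_sample()] or numeric vector of radians, \eqn{n \ge 2}.
#' @return an object of class `circ_test`.
#' @examples
#' rayleigh_test(circ_sample(pigeon_bearings))
#' @export
rayleigh_test <- function(x) {
  x <- as_circ_sample(x)
  n <- length(x)
  if (n < 2L) stop("need at least two points")
  rbar <- rayleigh_statistic(x)
  p <- rayleigh_pvalue_approx(rbar, n)
  new_circ_test("rayleigh", rbar, n, p,
                "Rayleigh test of circular uniformity", "closed_form",
                "standard")
}

# series approximation for P(n*Rbar^2 >= S) under uniformity
rayleigh_pvalue_approx <- function(rbar, n) {
  S <- n * rbar^2
  p <- exp(-S) * (1 + (2 * S - S^2) / (4 * n) -
                    (24 * S - 132 * S^2 + 76 * S^3 - 9 * S^4) / (288 * n^2))
  min(max(p, .Machine$double.xmin), 1)
}

#' Chi-squared test of uniformity on binned directions
#'
#' Pearson goodness-of-fit test of equal expected counts \eqn{n/m} across
#' the m grouping bins, with \eqn{m - 1} degrees of freedom and no
#' continuity correction — the natural non-circular baseline for grouped
#' directional data. Only applied to samples with \eqn{n > 5}.
#'
#' @param x a [circ_sample()] or numeric vector of radians.
#' @param m number of bins; defaults to the sample's grouping resolution.
#' @return an object of class `circ_test`.
#' @export
chisq_uniformity_test <- function(x, m = NULL) {
  x <- as_circ_sample(x)
  if (is.null(m)) m <- attr(x, "grouping_m")
  if (is.null(m)) stop("chi-squared test needs a bin count m")
  x2 <- chisq_statistic(x, m)
  p <- stats::pchisq(x2, df = m - 1, lower.tail = FALSE)
  new_circ_test("chisq", x2, length(x), p,
                sprintf("Chi-squared test of uniformity over %d bins", m),
                "closed_form", "standard")
}

stat_label <- function(name) {
  switch(name, rayleigh = "Rayleigh", kuiper = "Kuiper", watson = "Watson",
         rao = "Rao spacing", gini = "Gini", hr = "Hermans-Rasson",
         chisq = "Chi-squared")
}

# Classical upper percentage points (Stephens' modified statistics) used
# only for optional table-bound reporting, mirroring how the Kuiper and
# Watson tests are traditionally reported as p-value ranges.
kuiper_table <- c("0.15" = 1.537, "0.10" = 1.620, "0.05" = 1.747,
                  "0.025" = 1.862, "0.01" = 2.001)
watson_table <- c("0.10" = 0.152, "0.05" = 0.187, "0.025" = 0.221,
                  "0.01" = 0.267)

table_p_bounds <- function(modified_stat, table) {
  levels <- as.numeric(names(table))
  below <- modified_stat < table        # not significant at that level
  upper <- if (all(below)) 1 else min(levels[!below])
  lower <- if (all(!below)) 0 else max(levels[below])
  c(lower = lower, upper = upper)
}

format_p_bounds <- function(b) {
  if (b["lower"] <= 0) sprintf("p < %g", b["upper"])
  else if (b["upper"] >= 1) sprintf("p > %g", b["lower"])
  else sprintf("%g > p > %g", b["upper"], b["lower"])
}

#' Table-bound p-value ranges for the Kuiper and Watson tests
#'
#' The classical way these tests are reported: the observed statistic is
#' modified per Stephens and compared against tabulated upper percentage
#' points, yielding a range such as "p > 0.15" rather than a point value.
#' Provided for parity with traditional software output; Monte-Carlo
#' p-values are the package default.
#'
#' @param x a [circ_sample()] or numeric vector of radians.
#' @return named numeric `c(lower, upper)` bounding the p-value.
#' @export
kuiper_pvalue_bounds <- function(x) {
  n <- length(as_circ_sample(x))
  v <- kuiper_statistic(x)
  table_p_bounds(v * (1 + 0.155 / sqrt(n) + 0.24 / n), kuiper_table)
}

#' @rdname kuiper_pvalue_bounds
#' @export
watson_pvalue_bounds <- function(x) {
  n <- length(as_circ_sample(x))
  u2 <- watson_statistic(x)
  table_p_bounds((u2 - 0.1 / n + 0.1 / n^2) * (1 + 0.8 / n), watson_table)
}

#' Test circular uniformity (main entry point)
#'
#' Runs one of the seven uniformity tests in its standard or tie-breaking
#' (TB) variant. `variant = "auto"` selects TB whenever the sample contains
#' tied values or carries a grouping resolution, since those are exactly the
#' situations in which the standard Monte-Carlo tests lose type-I error
#' control; it selects the standard variant otherwise. The Rayleigh test is
#' closed-form in its standard variant and Monte-Carlo in its TB variant;
#' chi-squared is always closed-form (and has no TB variant: binning is
#' unaffected by sub-bin perturbations).
#'
#' @param x a [circ_sample()] or numeric vector of radians.
#' @param test one of `"rayleigh"`, `"kuiper"`, `"watson"`, `"rao"`,
#'   `"gini"`, `"hr"`, `"chisq"`.
#' @param variant `"auto"`, `"standard"` or `"tb"`.
#' @param n_reps Monte-Carlo replicates \eqn{N_R} (default 10,000).
#' @param kappa TB perturbation concentration (default 1000).
#' @param m bin count for `"chisq"`; defaults to the sample's grouping
#'   resolution.
#' @param seed optional integer seed for the Monte-Carlo draws.
#' @param null_stats optional precomputed null from [null_statistics()].
#' @return an object of class `circ_test`.
#' @examples
#' x <- circ_sample(pigeon_bearings)
#' circ_uniformity_test(x, "rayleigh")
#' circ_uniformity_test(x, "hr", variant = "tb", n_reps = 1000, seed = 1)
#' @export
circ_uniformity_test <- function(x,
                                 test = c("rayleigh", "kuiper", "watson",
                                          "rao", "gini", "hr", "chisq"),
                                 variant = c("auto", "standard", "tb"),
                                 n_reps = 10000, kappa = 1000, m = NULL,
                                 seed = NULL, null_stats = NULL) {
  test <- match.arg(test)
  variant <- match.arg(variant)
  x <- as_circ_sample(x)
  if (variant == "auto") {
    grouped <- anyDuplicated(as.numeric(x)) > 0L ||
      !is.null(attr(x, "grouping_m")) || !is.null(m)
    variant <- if (grouped && test != "chisq") "tb" else "standard"
  }
  if (test == "chisq") {
    if (variant == "tb") stop("the chi-squared test has no TB variant")
    return(chisq_uniformity_test(x, m = m))
  }
  if (test == "rayleigh" && variant == "standard") return(rayleigh_test(x))
  if (variant == "tb")
    tb_test(x, test, n_reps = n_reps, kappa = kappa, seed = seed, m = m,
            null_stats = null_stats)
  else
    monte_carlo_pvalue(x, test, n_reps = n_reps, seed = seed,
                       null_stats = null_stats)
}
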
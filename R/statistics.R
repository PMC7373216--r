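#' Test statistics for circular uniformity
#'
#' Pure statistic computations, separated from p-value machinery. Each
#' function takes a [circ_sample()] (or numeric radians) and returns a
#' single number. All of the circular statistics are rotation-invariant and
#' are deterministic functions of the sample.
#'
#' @name circ_statistics
#' @param x a [circ_sample()] or numeric vector of radians.
NULL

#' @describeIn circ_statistics Mean resultant length
#'   \eqn{\bar{R} = |\sum_i e^{i\phi_i}|/n \in [0,1]}, the core of the
#'   Rayleigh test: 0 for balanced or symmetric samples, 1 when all angles
#'   coincide.
#' @export
rayleigh_statistic <- function(x) {
  x <- as.numeric(as_circ_sample(x))
  sqrt(mean(cos(x))^2 + mean(sin(x))^2)
}

#' @describeIn circ_statistics Rao spacing statistic
#'   \eqn{U = \frac{1}{2}\sum_i |T_i - 2\pi/n|}, the total deviation of the
#'   arc lengths \eqn{T_i} from their uniform expectation \eqn{2\pi/n};
#'   0 iff the points are exactly equally spaced. Requires \eqn{n \ge 2}.
#' @export
rao_statistic <- function(x) {
  sp <- circ_spacings(x)
  0.5 * sum(abs(sp - 2 * pi / length(sp)))
}

#' @describeIn circ_statistics Gini spacing statistic
#'   \eqn{G_n = \frac{2}{n(n-1)} \sum_{i<j} \frac{1}{2} |nT_i - nT_j|}, the
#'   Gini mean difference of the scaled spacings; 0 iff all spacings are
#'   equal. Computed via the O(n log n) sorted-spacings identity
#'   \eqn{G_n = \frac{1}{n-1}\sum_k (2k - n - 1) T_{(k)}}, which is
#'   algebraically equal to the double sum.
#' @export
gini_statistic <- function(x) {
  sp <- sort(circ_spacings(x))
  n <- length(sp)
  sum((2 * seq_len(n) - n - 1) * sp) / (n - 1)
}

#' @describeIn circ_statistics Hermans-Rasson statistic
#'   \eqn{V = \frac{1}{n}\sum_i\sum_j (||\phi_i-\phi_j| - \pi| - \pi/2
#'   - 2.895(|\sin(\phi_i-\phi_j)| - 2/\pi))}, over all pairs including
#'   \eqn{i = j} (each diagonal term contributes
#'   \eqn{\pi/2 + 2.895 \cdot 2/\pi}). Powerful against multimodal
#'   alternatives. Defined for \eqn{n \ge 1}.
#' @export
hr_statistic <- function(x) {
  x <- as.numeric(as_circ_sample(x))
  n <- length(x)
  d <- outer(x, x, "-")
  sum(abs(abs(d) - pi) - pi / 2 - 2.895 * (abs(sin(d)) - 2 / pi)) / n
}

#' @describeIn circ_statistics Kuiper statistic
#'   \eqn{V_n = \sqrt{n}(D^+ + D^-)} computed from \eqn{u_i = \phi_{(i)} /
#'   (2\pi)}; the \eqn{\sqrt{n}} factor makes classical critical-value
#'   tables applicable. Rotation-invariant, unlike the Kolmogorov-Smirnov
#'   statistic it modifies. Requires \eqn{n \ge 2}.
#' @export
kuiper_statistic <- function(x) {
  x <- as.numeric(as_circ_sample(x))
  n <- length(x)
  if (n < 2L) stop("need at least two points")
  u <- sort(x) / (2 * pi)
  i <- seq_len(n)
  sqrt(n) * (max(i / n - u) + max(u - (i - 1) / n))
}

#' @describeIn circ_statistics Watson statistic
#'   \eqn{U^2 = \sum_i (u_i - (2i-1)/(2n))^2 - n(\bar{u} - 1/2)^2 +
#'   1/(12n)}, the rotation-invariant Cramer-von Mises variant. Its minimum,
#'   attained by an equally spaced sample, is \eqn{1/(12n)}. Requires
#'   \eqn{n \ge 2}.
#' @export
watson_statistic <- function(x) {
  x <- as.numeric(as_circ_sample(x))
  n <- length(x)
  if (n < 2L) stop("need at least two points")
  u <- sort(x) / (2 * pi)
  i <- seq_len(n)
  sum((u - (2 * i - 1) / (2 * n))^2) - n * (mean(u) - 0.5)^2 + 1 / (12 * n)
}

#' @describeIn circ_statistics Pearson chi-squared statistic on m bins:
#'   angles are assigned to their nearest of `m` evenly spaced values and
#'   \eqn{X^2 = \sum_k (O_k - n/m)^2 / (n/m)} is computed over all m bins,
#'   empty bins included (df = m - 1). Following the usual small-sample
#'   caution for this test, it refuses samples with \eqn{n \le 5}.
#' @param m number of bins (grouping resolution).
#' @export
chisq_statistic <- function(x, m) {
  x <- as_circ_sample(x)
  n <- length(x)
  if (n <= 5L) stop("chi-squared requires n > 5")
  m <- as.integer(m)
  if (is.na(m) || m < 2L) stop("m must be an integer >= 2")
  idx <- floor(as.numeric(x) * m / (2 * pi) + 0.5 + 1e-9) %% m
  counts <- tabulate(idx + 1L, nbins = m)
  expected <- n / m
  sum((counts - expected)^2 / expected)
}

# registry mapping statistic names to their functions (chisq excluded: it
# needs the extra bin argument and is never evaluated by simulation)
circ_stat_names <- c("rayleigh", "kuiper", "watson", "rao", "gini", "hr")

statistic_fun <- function(name) {
  switch(name,
         rayleigh = rayleigh_statistic,
         kuiper   = kuiper_statistic,
         watson   = watson_statistic,
         rao      = rao_statistic,
         gini     = gini_statistic,
         hr       = hr_statistic,
         stop("unknown statistic '", name, "'; expected one of: ",
              paste(circ_stat_names, collapse = ", ")))
}

#' Compute a named uniformity statistic
#'
#' Dispatcher over the individual statistic functions; see
#' [circ_statistics].
#'
#' @param x a [circ_sample()] or numeric vector of radians.
#' @param statistic one of `"rayleigh"`, `"kuiper"`, `"watson"`, `"rao"`,
#'   `"gini"`, `"hr"`, `"chisq"`.
#' @param m bin count, required for `"chisq"` only.
#' @return the statistic value (single numeric).
#' @export
circ_statistic <- function(x, statistic, m = NULL) {
  if (identical(statistic, "chisq")) {
    if (is.null(m)) m <- attr(as_circ_sample(x), "grouping_m")
    if (is.null(m)) stop("chisq statistic needs a bin count m")
    return(chisq_statistic(x, m))
  }
  statistic_fun(statistic)(x)
}

# Vectorized statistic evaluation over the columns of an n x B matrix of
# angles (radians). Used by the Monte-Carlo engine and the simulation
# study, where hundreds of thousands of statistic evaluations are needed.
batch_statistic <- function(X, statistic) {
  n <- nrow(X)
  switch(statistic,
    rayleigh = sqrt(colMeans(cos(X))^2 + colMeans(sin(X))^2),
    rao = {
      S <- column_spacings(X)
      0.5 * colSums(abs(S - 2 * pi / n))
    },
    gini = {
      S <- apply(column_spacings(X), 2L, sort)
      colSums((2 * seq_len(n) - n - 1) * S) / (n - 1)
    },
    kuiper = {
      U <- apply(X, 2L, sort) / (2 * pi)
      i <- seq_len(n)
      sqrt(n) * (apply(i / n - U, 2L, max) + apply(U - (i - 1) / n, 2L, max))
    },
    watson = {
      U <- apply(X, 2L, sort) / (2 * pi)
      i <- seq_len(n)
      colSums((U - (2 * i - 1) / (2 * n))^2) -
        n * (colMeans(U) - 0.5)^2 + 1 / (12 * n)
    },
    hr = apply(X, 2L, hr_statistic),
    stop("unknown statistic '", statistic, "'"))
}

column_spacings <- function(X) {
  S <- apply(X, 2L, sort)
  rbind(diff(S), 2 * pi - S[nrow(S), ] + S[1L, ])
}
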
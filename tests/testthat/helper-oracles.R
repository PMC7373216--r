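# Brute-force oracle implementations of the test statistics, coded
# directly from their defining formulas with explicit loops, independent of
# the package's vectorized implementations.

oracle_spacings <- function(x) {
  s <- sort(x %% (2 * pi))
  n <- length(s)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- if (i < n) s[i + 1] - s[i] else 2 * pi - s[n] + s[1]
  }
  out
}

oracle_rao <- function(x) {
  sp <- oracle_spacings(x)
  n <- length(sp)
  total <- 0
  for (i in seq_len(n)) total <- total + abs(sp[i] - 2 * pi / n)
  0.5 * total
}

oracle_gini <- function(x) {
  sp <- oracle_spacings(x)
  n <- length(sp)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + 0.5 * abs(n * sp[i] - n * sp[j])
    }
  }
  (2 / (n * (n - 1))) * total
}

oracle_hr <- function(x) {
  n <- length(x)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- x[i] - x[j]
      total <- total + abs(abs(d) - pi) - pi / 2 -
        2.895 * (abs(sin(d)) - 2 / pi)
    }
  }
  total / n
}

oracle_kuiper <- function(x) {
  n <- length(x)
  u <- sort((x %% (2 * pi)) / (2 * pi))
  dplus <- -Inf
  dminus <- -Inf
  for (i in seq_len(n)) {
    dplus <- max(dplus, i / n - u[i])
    dminus <- max(dminus, u[i] - (i - 1) / n)
  }
  sqrt(n) * (dplus + dminus)
}

oracle_watson <- function(x) {
  n <- length(x)
  u <- sort((x %% (2 * pi)) / (2 * pi))
  total <- 0
  for (i in seq_len(n)) total <- total + (u[i] - (2 * i - 1) / (2 * n))^2
  total - n * (mean(u) - 0.5)^2 + 1 / (12 * n)
}

random_angles <- function(n) stats::runif(n, 0, 2 * pi)

pigeon_radians <- function() as.numeric(circ_sample(pigeon_bearings))

# 3 binomial standard errors around a Monte-Carlo estimate of p
three_se <- function(p, n_reps) 3 * sqrt(p * (1 - p) / n_reps)
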
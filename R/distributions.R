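#' Specify a circular distribution
#'
#' Constructs a validated distribution specification for use with
#' [rcirc()]. Supported families and their parameters:
#'
#' * `uniform` — no parameters.
#' * `vonmises` — `mu` (mean direction, radians), `kappa` (> 0).
#' * `skewnormal` — `dispersion` (> 0), `skewness`; a linear Azzalini
#'   skew-normal with location 0, wrapped onto the circle.
#' * `cardioid` — `rho` in \eqn{[0, 0.5)}, `mu`; density
#'   \eqn{(1 + 2\rho\cos(\theta - \mu))/(2\pi)}; resultant length `rho`.
#' * `katojones` — `r` in \eqn{[0, 1)}, `kappa`, `mu`, `nu`; a Möbius
#'   transformation of a von Mises variate.
#' * `triangular` — `rho` in \eqn{[0, 4/\pi^2]}; symmetric triangular
#'   density peaked at 0, resultant length `rho`.
#' * `wrappedcauchy` — `rho` in \eqn{(0, 1)}, `mu`; resultant length `rho`.
#' * `wrappednormal` — `rho` in \eqn{(0, 1)} (resultant length,
#'   \eqn{\sigma = \sqrt{-2\log\rho}}), `mu`.
#' * `wrappedstable` — `scale`, `index` (stability \eqn{\alpha} in (0, 2]),
#'   `skewness` (\eqn{\beta} in \eqn{[-1, 1]}); Chambers-Mallows-Stuck
#'   construction, 1-parameterization, wrapped mod \eqn{2\pi}.
#' * `mixture` — `components` (list of `circ_dist`), `weights`
#'   (non-negative, summing to 1).
#'
#' @param family family name (see above).
#' @param ... family parameters.
#' @return an object of class `circ_dist`: `list(family, params)`.
#' @examples
#' circ_dist("vonmises", mu = 0, kappa = 1)
#' circ_dist("wrappedcauchy", rho = 0.7)
#' @export
circ_dist <- function(family, ...) {
  params <- list(...)
  known <- c("uniform", "vonmises", "skewnormal", "cardioid", "katojones",
             "triangular", "wrappedcauchy", "wrappednormal", "wrappedstable",
             "mixture")
  if (!family %in% known)
    stop("unknown distribution family '", family, "'; supported: ",
         paste(known, collapse = ", "))
  defaults <- switch(family,
    uniform       = list(),
    vonmises      = list(mu = 0, kappa = 1),
    skewnormal    = list(dispersion = 1, skewness = 0),
    cardioid      = list(mu = 0, rho = 0.3),
    katojones     = list(mu = 0, nu = 0, r = 0.7, kappa = 2.3),
    triangular    = list(rho = 0.3),
    wrappedcauchy = list(mu = 0, rho = 0.7),
    wrappednormal = list(mu = 0, rho = 0.7),
    wrappedstable = list(scale = 1, index = 0.3, skewness = 1),
    mixture       = list(components = list(), weights = numeric()))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown parameter(s) for family '", family, "': ",
         paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  params <- defaults
  validate_dist_params(family, params)
  structure(list(family = family, params = params), class = "circ_dist")
}

validate_dist_params <- function(family, p) {
  chk <- function(cond, msg) if (!cond) stop(family, ": ", msg)
  switch(family,
    vonmises      = chk(p$kappa > 0, "kappa must be > 0"),
    skewnormal    = chk(p$dispersion > 0, "dispersion must be > 0"),
    cardioid      = chk(p$rho >= 0 && p$rho < 0.5, "rho must be in [0, 0.5)"),
    katojones     = chk(p$r >= 0 && p$r < 1 && p$kappa >= 0,
                        "need 0 <= r < 1 and kappa >= 0"),
    triangular    = chk(p$rho >= 0 && p$rho <= 4 / pi^2,
                        "rho must be in [0, 4/pi^2]"),
    wrappedcauchy = chk(p$rho > 0 && p$rho < 1, "rho must be in (0, 1)"),
    wrappednormal = chk(p$rho > 0 && p$rho < 1, "rho must be in (0, 1)"),
    wrappedstable = chk(p$scale > 0 && p$index > 0 && p$index <= 2 &&
                          abs(p$skewness) <= 1,
                        "need scale > 0, 0 < index <= 2, |skewness| <= 1"),
    mixture       = {
      chk(length(p$components) >= 1L &&
            all(vapply(p$components, inherits, TRUE, "circ_dist")),
          "components must be a non-empty list of circ_dist objects")
      chk(length(p$weights) == length(p$components) && all(p$weights >= 0) &&
            abs(sum(p$weights) - 1) < 1e-9,
          "weights must be non-negative, match components, and sum to 1")
    },
    invisible(NULL))
  invisible(NULL)
}

#' Mixture of circular distributions
#'
#' Convenience wrapper building a `mixture` [circ_dist()]: each draw picks a
#' component with the given probability and then samples from it. Used for
#' the multimodal von Mises alternatives in the power study.
#'
#' @param components list of [circ_dist()] objects.
#' @param weights mixing proportions, non-negative and summing to 1.
#' @return a `circ_dist` of family `"mixture"`.
#' @examples
#' circ_mixture(list(circ_dist("vonmises", mu = 0, kappa = 5),
#'                   circ_dist("vonmises", mu = pi, kappa = 5)),
#'              weights = c(0.5, 0.5))
#' @export
circ_mixture <- function(components, weights) {
  circ_dist("mixture", components = components, weights = weights)
}

#' Draw a random circular sample
#'
#' Seeded sampling from any [circ_dist()] specification. All draws are
#' wrapped into \eqn{[0, 2\pi)} and are deterministic given `seed`.
#'
#' @param n number of draws, \eqn{\ge 1}.
#' @param dist a [circ_dist()]; defaults to the circular uniform.
#' @param seed optional integer seed.
#' @return a [circ_sample()] of n angles.
#' @examples
#' rcirc(5, circ_dist("vonmises", kappa = 1), seed = 1)
#' @export
rcirc <- function(n, dist = circ_dist("uniform"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(dist, "circ_dist"), n >= 1L)
  p <- dist$params
  theta <- switch(dist$family,
    uniform       = stats::runif(n, 0, 2 * pi),
    vonmises      = rvonmises(n, mu = p$mu, kappa = p$kappa),
    skewnormal    = rwrapped_skewnormal(n, p$dispersion, p$skewness),
    cardioid      = rcardioid(n, p$mu, p$rho),
    katojones     = rkatojones(n, p$mu, p$nu, p$r, p$kappa),
    triangular    = rtriangular_circ(n, p$rho),
    wrappedcauchy = (p$mu + stats::rcauchy(n, 0, -log(p$rho))) %% (2 * pi),
    wrappednormal = (p$mu + stats::rnorm(n, 0, sqrt(-2 * log(p$rho)))) %% (2 * pi),
    wrappedstable = rwrapped_stable(n, p$scale, p$index, p$skewness),
    mixture       = {
      k <- sample.int(length(p$components), n, replace = TRUE,
                      prob = p$weights)
      out <- numeric(n)
      for (j in seq_along(p$components)) {
        idx <- which(k == j)
        if (length(idx) > 0L)
          out[idx] <- as.numeric(rcirc(length(idx), p$components[[j]]))
      }
      out
    })
  circ_sample(wrap_angle(theta), units = "radians")
}

# Azzalini representation: Z = delta|U0| + sqrt(1-delta^2) U1 is skew-normal
# with shape alpha; scaled by the dispersion and wrapped.
rwrapped_skewnormal <- function(n, dispersion, skewness) {
  delta <- skewness / sqrt(1 + skewness^2)
  u0 <- stats::rnorm(n); u1 <- stats::rnorm(n)
  (dispersion * (delta * abs(u0) + sqrt(1 - delta^2) * u1)) %% (2 * pi)
}

# rejection from the uniform envelope; density max is (1 + 2 rho)/(2 pi)
rcardioid <- function(n, mu, rho) {
  if (rho == 0) return(stats::runif(n, 0, 2 * pi))
  out <- numeric(0)
  while (length(out) < n) {
    k <- max(ceiling((n - length(out)) * (1 + 2 * rho) * 1.1), 16L)
    th <- stats::runif(k, 0, 2 * pi)
    u <- stats::runif(k)
    ok <- u <= (1 + 2 * rho * cos(th - mu)) / (1 + 2 * rho)
    out <- c(out, th[ok])
  }
  out[seq_len(n)]
}

# Möbius transformation of a von Mises(0, kappa) variate: with
# zeta = e^{i theta}, the output angle is mu + Arg((zeta + r e^{i nu}) /
# (r e^{-i nu} zeta + 1)). r = 0 recovers the von Mises itself.
rkatojones <- function(n, mu, nu, r, kappa) {
  theta <- if (kappa > 0) rvonmises(n, mu = 0, kappa = kappa)
           else stats::runif(n, 0, 2 * pi)
  zeta <- exp(1i * theta)
  w <- (zeta + r * exp(1i * nu)) / (r * exp(-1i * nu) * zeta + 1)
  (mu + Arg(w)) %% (2 * pi)
}

# symmetric triangular density f(t) = (4 - pi^2 rho)/(8 pi) + (rho/4)|pi - t|
# on [0, 2pi), mode at 0, resultant length rho; sampled by analytic
# inversion of the piecewise-quadratic CDF.
rtriangular_circ <- function(n, rho) {
  if (rho == 0) return(stats::runif(n, 0, 2 * pi))
  a <- (4 - pi^2 * rho) / (8 * pi)
  b <- a + rho * pi / 4
  u <- stats::runif(n)
  lower <- u <= 0.5
  uu <- ifelse(lower, u, 1 - u)
  # solve (rho/8) t^2 - b t + uu = 0 for the small root
  t <- (b - sqrt(b^2 - rho * uu / 2)) / (rho / 4)
  ifelse(lower, t, 2 * pi - t) %% (2 * pi)
}

# Chambers-Mallows-Stuck alpha-stable generator (1-parameterization,
# location 0), wrapped mod 2pi.
rwrapped_stable <- function(n, scale, index, skewness) {
  u <- stats::runif(n, -pi / 2, pi / 2)
  w <- stats::rexp(n)
  a <- index
  if (abs(a - 1) < 1e-12) {
    x <- (2 / pi) * ((pi / 2 + skewness * u) * tan(u) -
                       skewness * log((pi / 2 * w * cos(u)) /
                                        (pi / 2 + skewness * u)))
  } else {
    b0 <- atan(skewness * tan(pi * a / 2)) / a
    s0 <- (1 + skewness^2 * tan(pi * a / 2)^2)^(1 / (2 * a))
    x <- s0 * sin(a * (u + b0)) / cos(u)^(1 / a) *
      (cos(u - a * (u + b0)) / w)^((1 - a) / a)
  }
  (scale * x) %% (2 * pi)
}

#' The alternative-distribution panel of the simulation study
#'
#' The 12 non-uniform circular distributions against which power is
#' measured, with their study parameters: von Mises (\eqn{\kappa = 1}),
#' wrapped skew normal (dispersion 1, skewness 30), symmetric and
#' asymmetric bimodal von Mises mixtures (\eqn{\kappa = 5}, modes at
#' 0°/180° and 0°/120°), symmetric and asymmetric trimodal mixtures
#' (\eqn{\kappa = 10}, modes at 0°/120°/240° and 0°/90°/200°), cardioid
#' (\eqn{\rho = 0.3}), Kato-Jones (r = 0.7, \eqn{\kappa = 2.3}),
#' triangular (\eqn{\rho = 0.3}), wrapped Cauchy (\eqn{\rho = 0.7}),
#' wrapped normal (\eqn{\rho = 0.7}) and wrapped stable (scale 1, index
#' 0.3, skewness 1).
#'
#' @return named list of [circ_dist()] objects.
#' @export
study_distributions <- function() {
  vm <- function(mu_deg, kappa)
    circ_dist("vonmises", mu = mu_deg * pi / 180, kappa = kappa)
  list(
    vonmises      = circ_dist("vonmises", mu = 0, kappa = 1),
    skewnormal    = circ_dist("skewnormal", dispersion = 1, skewness = 30),
    bimodal_sym   = circ_mixture(list(vm(0, 5), vm(180, 5)), c(0.5, 0.5)),
    bimodal_asym  = circ_mixture(list(vm(0, 5), vm(120, 5)), c(0.5, 0.5)),
    trimodal_sym  = circ_mixture(list(vm(0, 10), vm(120, 10), vm(240, 10)),
                                 c(1, 1, 1) / 3),
    trimodal_asym = circ_mixture(list(vm(0, 10), vm(90, 10), vm(200, 10)),
                                 c(1, 1, 1) / 3),
    cardioid      = circ_dist("cardioid", rho = 0.3),
    katojones     = circ_dist("katojones", r = 0.7, kappa = 2.3),
    triangular    = circ_dist("triangular", rho = 0.3),
    wrappedcauchy = circ_dist("wrappedcauchy", rho = 0.7),
    wrappedstable = circ_dist("wrappedstable", scale = 1, index = 0.3,
                              skewness = 1),
    wrappednormal = circ_dist("wrappednormal", rho = 0.7)
  )
}
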
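#' Distribution law specifications
#'
#' Several simulator parameters (per-gene baselines, effect sizes, NB
#' dispersions, library sizes, XCI skewing coefficients) are specified as
#' small "law" objects rather than hard-coded distributions, so study
#' conditions can be varied without touching the generators. A law is a
#' list with a `dist` element and the distribution's parameters.
#'
#' Supported laws:
#' \describe{
#'   \item{`point`}{`value`: degenerate law, always returns `value`.}
#'   \item{`uniform`}{`min`, `max`.}
#'   \item{`normal`}{`mean`, `sd`.}
#'   \item{`lognormal`}{`meanlog`, `sdlog`.}
#'   \item{`gamma`}{`shape`, `rate`.}
#'   \item{`exponential`}{`rate`, optional `max` (rejection-truncated).}
#' }
#'
#' @param dist Distribution name.
#' @param ... Distribution parameters (see above).
#' @return A `sim_law` object.
#' @examples
#' law("uniform", min = 0.1, max = 0.5)
#' draw_law(law("point", value = 2), 3)
#' @export
law <- function(dist = c("point", "uniform", "normal", "lognormal",
                         "gamma", "exponential"), ...) {
  dist <- match.arg(dist)
  structure(c(list(dist = dist), list(...)), class = "sim_law")
}

#' Draw from a distribution law
#'
#' @param x A `sim_law` object (a plain list with the same fields is
#'   accepted).
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_law <- function(x, n) {
  if (!is.list(x) || is.null(x$dist))
    stop("'x' must be a law specification; see ?law")
  n <- as.integer(n)
  switch(x$dist,
    point = rep(x$value, n),
    uniform = stats::runif(n, x$min, x$max),
    normal = stats::rnorm(n, x$mean, x$sd),
    lognormal = stats::rlnorm(n, x$meanlog, x$sdlog),
    gamma = stats::rgamma(n, shape = x$shape, rate = x$rate),
    exponential = {
      out <- stats::rexp(n, x$rate)
      if (!is.null(x$max)) {
        bad <- which(out > x$max)
        while (length(bad)) {
          out[bad] <- stats::rexp(length(bad), x$rate)
          bad <- bad[out[bad] > x$max]
        }
      }
      out
    },
    stop("unknown law: ", x$dist)
  )
}
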
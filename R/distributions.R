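# Univariate prior-distribution helpers shared by the prior machinery and
# the MCMC sampler. A distribution is a list(family, ...parameters...);
# supported families: "lognormal" (meanlog, sdlog), "uniform" (min, max),
# "gamma" (shape, rate), "fixed" (value).

#' Specify a univariate prior distribution
#'
#' @param family one of `"lognormal"` (`meanlog`, `sdlog`), `"uniform"`
#'   (`min`, `max`), `"gamma"` (`shape`, `rate`) or `"fixed"` (`value`).
#' @param ... the named parameters of the family.
#' @return a list describing the distribution, used in [prior_spec].
#' @export
dist_spec <- function(family, ...) {
  pars <- list(...)
  ok <- switch(family,
    lognormal = all(c("meanlog", "sdlog") %in% names(pars)),
    uniform = all(c("min", "max") %in% names(pars)),
    gamma = all(c("shape", "rate") %in% names(pars)),
    fixed = "value" %in% names(pars),
    FALSE)
  if (!isTRUE(ok)) stop("unknown or incomplete distribution: ", family)
  c(list(family = family), pars)
}

#' Draw from a prior distribution specification
#'
#' @param dist a distribution from [dist_spec].
#' @param n number of draws.
#' @return numeric vector of draws.
#' @export
dist_draw <- function(dist, n = 1) {
  switch(dist$family,
    lognormal = rlnorm(n, dist$meanlog, dist$sdlog),
    uniform = runif(n, dist$min, dist$max),
    gamma = rgamma(n, shape = dist$shape, rate = dist$rate),
    fixed = rep(dist$value, n),
    stop("unknown family ", dist$family))
}

dist_logdens <- function(dist, x) {
  switch(dist$family,
    lognormal = dlnorm(x, dist$meanlog, dist$sdlog, log = TRUE),
    uniform = dunif(x, dist$min, dist$max, log = TRUE),
    gamma = dgamma(x, shape = dist$shape, rate = dist$rate, log = TRUE),
    fixed = ifelse(x == dist$value, 0, -Inf),
    stop("unknown family ", dist$family))
}

dist_median <- function(dist) {
  switch(dist$family,
    lognormal = qlnorm(0.5, dist$meanlog, dist$sdlog),
    uniform = (dist$min + dist$max) / 2,
    gamma = qgamma(0.5, shape = dist$shape, rate = dist$rate),
    fixed = dist$value,
    stop("unknown family ", dist$family))
}

dist_support <- function(dist) {
  switch(dist$family,
    lognormal = c(0, Inf),
    uniform = c(dist$min, dist$max),
    gamma = c(0, Inf),
    fixed = c(dist$value, dist$value))
}
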
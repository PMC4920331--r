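#' FBD process parameters
#'
#' Container for the parametrization of the fossilized birth-death process
#' used throughout the package: the origin time `T` of the process before
#' the present, the net diversification rate `d` (speciation minus
#' extinction), the turnover `r` (extinction/speciation) and the fossil
#' sampling proportion `s` (sampling rate over extinction plus sampling
#' rate). The extant-species sampling probability is fixed at 1.
#'
#' @param origin_T origin of the process, Myr before present (> 0).
#' @param d net diversification rate per Myr (> 0).
#' @param r turnover, in `[0, 1)`.
#' @param s fossil sampling proportion, in `[0, 1)`.
#' @return an object of class `fbd_params`.
#' @examples
#' p <- fbd_params(origin_T = 40, d = 0.05, r = 0.5, s = 0.2)
#' to_canonical_rates(p)
#' @export
fbd_params <- function(origin_T, d, r, s) {
  stopifnot(is.numeric(origin_T), is.numeric(d), is.numeric(r), is.numeric(s))
  if (origin_T <= 0) stop("origin_T must be > 0")
  if (d <= 0) stop("net diversification rate d must be > 0")
  if (r < 0 || r >= 1) stop("turnover r must lie in [0, 1)")
  if (s < 0 || s >= 1) stop("sampling proportion s must lie in [0, 1)")
  structure(list(origin_T = origin_T, d = d, r = r, s = s),
            class = "fbd_params")
}

#' @export
print.fbd_params <- function(x, ...) {
  rates <- to_canonical_rates(x)
  cat("Fossilized birth-death parameters\n")
  cat(sprintf("  origin T : %.4g Myr\n", x$origin_T))
  cat(sprintf("  d = %.4g /Myr, r = %.4g, s = %.4g\n", x$d, x$r, x$s))
  cat(sprintf("  lambda = %.4g, mu = %.4g, psi = %.4g\n",
              rates[["lambda"]], rates[["mu"]], rates[["psi"]]))
  invisible(x)
}

#' Canonical birth-death-sampling rates
#'
#' Converts the (d, r, s) parametrization to the canonical rates:
#' speciation `lambda = d/(1-r)`, extinction `mu = r d/(1-r)` and fossil
#' sampling rate `psi = s mu/(1-s)`.
#'
#' @param params an [fbd_params] object.
#' @return named numeric vector `c(lambda, mu, psi)`.
#' @export
to_canonical_rates <- function(params) {
  stopifnot(inherits(params, "fbd_params"))
  lambda <- params$d / (1 - params$r)
  mu <- params$r * params$d / (1 - params$r)
  psi <- params$s * mu / (1 - params$s)
  c(lambda = lambda, mu = mu, psi = psi)
}

#' Sampling proportion from canonical rates
#'
#' Inverse of the `psi` transformation: `s = psi/(mu + psi)`. Returns 0
#' when both rates are 0.
#'
#' @param mu extinction rate per Myr.
#' @param psi fossil sampling rate per Myr.
#' @return the sampling proportion `s` in `[0, 1]`.
#' @export
sampling_proportion <- function(mu, psi) {
  stopifnot(mu >= 0, psi >= 0)
  if (mu + psi == 0) return(0)
  psi / (mu + psi)
}
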
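# The fossilized birth-death process: Kendall birth-death transition
# probabilities, the analytic density of fossil sampling times given
# survival of the process, and its integrals over age intervals.

#' Extinction probability of a linear birth-death process
#'
#' Probability that a single lineage leaves no surviving descendant after
#' time `t`, for net diversification `d` and turnover `r` (Kendall's
#' `p_0`): `p0(t) = r (1 - exp(-d t)) / (1 - r exp(-d t))`.
#'
#' @param t elapsed time (Myr), `>= 0`; vectorized.
#' @param d net diversification rate (> 0).
#' @param r turnover in `[0, 1)`.
#' @return extinction probabilities in `[0, 1)`.
#' @export
extinction_prob_p0 <- function(t, d, r) {
  if (any(t < 0)) stop("t must be >= 0")
  stopifnot(d > 0, r >= 0, r < 1)
  e <- exp(-d * t)
  r * (1 - e) / (1 - r * e)
}

# Geometric parameter of the surviving-lineage count distribution.
bd_eta <- function(t, d, r) {
  e <- exp(-d * t)
  (1 - e) / (1 - r * e)
}

#' Surviving-lineage count probabilities of a birth-death process
#'
#' Probability that a single lineage has exactly `k` surviving descendant
#' lineages after time `t`: `p_0` as in [extinction_prob_p0], and for
#' `k >= 1` a geometric law `p_k = (1 - p0)(1 - eta) eta^(k-1)` with
#' `eta = (1 - exp(-d t))/(1 - r exp(-d t))`.
#'
#' @param k number of surviving lineages, non-negative integer(s).
#' @param t elapsed time (Myr), `>= 0`.
#' @param d net diversification rate (> 0).
#' @param r turnover in `[0, 1)`.
#' @return probabilities; `k` and `t` recycle against each other.
#' @export
lineage_count_prob_pk <- function(k, t, d, r) {
  if (any(k < 0) || any(k != floor(k))) stop("k must be a non-negative integer")
  if (any(t < 0)) stop("t must be >= 0")
  stopifnot(d > 0, r >= 0, r < 1)
  n <- max(length(k), length(t))
  k <- rep_len(k, n); t <- rep_len(t, n)
  p0 <- extinction_prob_p0(t, d, r)
  eta <- bd_eta(t, d, r)
  out <- numeric(n)
  z <- k == 0
  out[z] <- p0[z]
  # at t = 0 the process is still a single lineage
  out[!z] <- (1 - p0[!z]) * (1 - eta[!z]) * eta[!z]^(k[!z] - 1)
  t0 <- t == 0
  out[t0] <- as.numeric(k[t0] == 1)
  out
}

#' Density of fossil sampling times under the FBD process
#'
#' Probability density (up to normalization over `[0, T]`) of sampling a
#' fossil at age `t` before present, given that the process started at the
#' origin `T` and does not go extinct: the probability of `k` lineages at
#' age `t` is weighted by the per-lineage sampling rate (`k psi`) and by
#' the probability that at least one of the `k` lineages survives to the
#' present, summed over `k >= 1` and conditioned on survival from the
#' origin.
#'
#' `mode = "sum"` evaluates the k-sum directly, truncating once the tail
#' bound drops below `tail_tol`; `mode = "closed"` evaluates the
#' geometric-series closed form
#' `psi (1-p0(T-t)) (1-eta(T-t)) [ (1-eta(T-t))^-2 - p0(t) (1 - eta(T-t) p0(t))^-2 ] / (1-p0(T))`.
#' Both agree to near machine precision; the closed form is the default.
#'
#' @param t fossil age(s), Myr before present, in `[0, T]`.
#' @param params an [fbd_params] object.
#' @param mode `"closed"` (default) or `"sum"`.
#' @param tail_tol truncation bound for the k-sum tail.
#' @param max_terms hard cap on summed terms.
#' @return sampling intensity at each `t` (units 1/Myr).
#' @export
sampling_time_density <- function(t, params, mode = c("closed", "sum"),
                                  tail_tol = 1e-12, max_terms = 1e6) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "fbd_params"))
  T <- params$origin_T; d <- params$d; r <- params$r
  if (any(t < 0 | t > T)) stop("t must lie in [0, origin_T]")
  rates <- to_canonical_rates(params)
  psi <- rates[["psi"]]
  if (psi == 0) return(numeric(length(t)) + 0)
  z <- extinction_prob_p0(t, d, r)
  tau <- T - t
  h <- bd_eta(tau, d, r)
  a <- 1 - extinction_prob_p0(tau, d, r)
  b <- 1 - h
  cond <- 1 - extinction_prob_p0(T, d, r)
  if (mode == "closed") {
    # factored form: a/b = a (exp(d tau) - r)/(1 - r) stays well defined
    # when b = 1 - eta underflows for large d (T - t); the density then
    # overflows to Inf cleanly instead of producing 0 * Inf
    one_over_b <- (exp(d * tau) - r) / (1 - r)
    return(psi * a * (one_over_b - b * z / (1 - h * z)^2) / cond)
  }
  vapply(seq_along(t), function(i) {
    tot <- 0
    k <- 1
    repeat {
      term <- k * psi * a[i] * b[i] * h[i]^(k - 1) * (1 - z[i]^k)
      tot <- tot + term
      # remaining tail of sum_k k q h^(k-1) is bounded by a geometric-in-k
      # envelope once h^k dominates; stop when the next term is tiny
      if ((term < tail_tol && k > 1) || k >= max_terms) break
      k <- k + 1
    }
    tot / cond
  }, numeric(1))
}

# Integral of the (unnormalized) sampling-time density over [l, u].
# Falls back to composite Simpson on a grid refined toward the present
# when adaptive quadrature stumbles over near-singular parameter draws
# (very large psi or origin times concentrate the density at 0).
.density_integral <- function(l, u, params, rel.tol = 1e-10) {
  if (u <= l) return(0)
  val <- tryCatch(
    integrate(function(x) sampling_time_density(x, params),
              lower = l, upper = u, rel.tol = rel.tol,
              subdivisions = 400L)$value,
    error = function(e) NA_real_)
  if (is.finite(val)) return(val)
  # geometric refinement toward l, Simpson per panel
  edges <- l + (u - l) * (seq(0, 1, length.out = 401))^3
  mids <- (edges[-1] + edges[-401]) / 2
  f_e <- sampling_time_density(edges, params)
  f_m <- sampling_time_density(mids, params)
  sum((edges[-1] - edges[-401]) / 6 * (f_e[-401] + 4 * f_m + f_e[-1]))
}

#' Probability that a fossil sampling time falls in an age interval
#'
#' Normalizes the FBD sampling-time density over `[0, T]` and integrates
#' it over `[l, u]` by adaptive quadrature, giving the probability that a
#' single fossil's age lies in the interval for fixed process parameters.
#'
#' @param l,u interval bounds, Myr before present, `0 <= l <= u <= T`.
#' @param params an [fbd_params] object.
#' @return a probability in `[0, 1]`.
#' @export
normalized_age_probability <- function(l, u, params) {
  stopifnot(inherits(params, "fbd_params"))
  if (l > u) stop("l must be <= u")
  if (l < 0 || u > params$origin_T) stop("interval must lie within [0, origin_T]")
  if (l == u) return(0)
  total <- .density_integral(0, params$origin_T, params)
  if (!is.finite(total)) {
    # astronomically growing trees: the lineage count scales as
    # exp(d (T - t)), so the normalized age density collapses to a
    # truncated exponential with rate d
    T <- params$origin_T; d <- params$d
    return((exp(-d * l) - exp(-d * u)) / (1 - exp(-d * T)))
  }
  if (total == 0) return(0)
  min(1, .density_integral(l, u, params) / total)
}
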
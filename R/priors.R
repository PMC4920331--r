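# Prior specifications for the FBD and morphological-clock parameters,
# including the implicit prior constructions on the origin time T (via the
# number of present-day species N) and on the sampling proportion s (via
# the fossil sampling rate psi).

#' Prior specification for an FBD tip-dating analysis
#'
#' Bundles one univariate prior per model parameter plus flags selecting
#' the implicit-prior constructions. With `implicit_T = TRUE`, the prior
#' on the origin is induced by `N ~ Uniform(N_min, N_max)` on the number of
#' present-day species together with the expectation `N = exp(d T)`, giving
#' `T = log(N)/d`. With `implicit_s = TRUE`, the prior is placed on the
#' fossil sampling rate `psi` and `s = psi/(mu + psi)` is derived.
#'
#' @param d,r priors on net diversification and turnover (see
#'   [dist_spec] families: `lognormal`, `uniform`, `gamma`, `fixed`).
#' @param s_or_psi prior on `s` (when `implicit_s = FALSE`) or on `psi`.
#' @param T_or_N prior on `T` (when `implicit_T = FALSE`) or on `N`.
#' @param mu_clock,S,alpha priors on the mean morphological clock rate
#'   (changes per Myr), the relaxed-clock log standard deviation, and the
#'   gamma shape for among-character rate variation.
#' @param implicit_s,implicit_T logical flags, see Details.
#' @return an object of class `prior_spec`.
#' @seealso [prior_preset] for the named presets.
#' @export
prior_spec <- function(d, r, s_or_psi, T_or_N,
                       mu_clock = dist_spec("lognormal", meanlog = -5.5, sdlog = 2),
                       S = dist_spec("gamma", shape = 0.5396, rate = 0.3819),
                       alpha = dist_spec("uniform", min = 0, max = 10),
                       implicit_s = FALSE, implicit_T = FALSE) {
  spec <- list(d = d, r = r, s_or_psi = s_or_psi, T_or_N = T_or_N,
               mu_clock = mu_clock, S = S, alpha = alpha,
               implicit_s = implicit_s, implicit_T = implicit_T)
  for (nm in c("d", "r", "s_or_psi", "T_or_N", "mu_clock", "S", "alpha"))
    if (is.null(spec[[nm]]$family)) stop("missing prior for ", nm)
  if (!implicit_s) {
    sup <- dist_support(spec$s_or_psi)
    if (sup[1] < 0 || sup[2] > 1) stop("prior on s must have support within [0, 1]")
  }
  structure(spec, class = "prior_spec")
}

#' Named prior presets
#'
#' `"implicit_2016"`: d ~ lognormal(-3.5, 0.5), r ~ Uniform(0, 1), the
#' implicit prior on `s` via psi ~ lognormal(-2, 1), and the implicit
#' prior on `T` via N ~ Uniform(1, 100) present-day species. This is the
#' prior designed so that old sampling times keep non-negligible weight,
#' making Bayes-factor tests of age ranges meaningful.
#'
#' `"gavryushkina_2014"`: the earlier standard parametrization with
#' T ~ Uniform(0, 120) Myr, d ~ lognormal(-3.5, 1.5), r ~ Uniform(0, 1)
#' and s ~ Uniform(0, 1), under which almost all prior sampling-time mass
#' lies close to the present.
#'
#' @param name `"implicit_2016"` or `"gavryushkina_2014"`.
#' @return a [prior_spec].
#' @export
prior_preset <- function(name = c("implicit_2016", "gavryushkina_2014")) {
  name <- match.arg(name)
  switch(name,
    implicit_2016 = prior_spec(
      d = dist_spec("lognormal", meanlog = -3.5, sdlog = 0.5),
      r = dist_spec("uniform", min = 0, max = 1),
      s_or_psi = dist_spec("lognormal", meanlog = -2, sdlog = 1),
      T_or_N = dist_spec("uniform", min = 1, max = 100),
      implicit_s = TRUE, implicit_T = TRUE),
    gavryushkina_2014 = prior_spec(
      d = dist_spec("lognormal", meanlog = -3.5, sdlog = 1.5),
      r = dist_spec("uniform", min = 0, max = 1),
      s_or_psi = dist_spec("uniform", min = 0, max = 1),
      T_or_N = dist_spec("uniform", min = 0, max = 120),
      implicit_s = FALSE, implicit_T = FALSE))
}

#' Draw FBD parameters from a prior specification
#'
#' Draws `(d, r)` from their priors; then either `s` directly or `psi`
#' followed by `s = psi/(mu + psi)` with `mu = r d/(1 - r)`; then either
#' `T` directly or `N` followed by `T = log(N)/d`. Draws with `T <= 0`
#' (possible only at the degenerate boundary `N = 1`) or outside the
#' parameter space are rejected and redrawn.
#'
#' @param spec a [prior_spec].
#' @param n number of draws.
#' @return a list of [fbd_params] (a single object when `n = 1`).
#' @export
implicit_prior_draw <- function(spec, n = 1) {
  stopifnot(inherits(spec, "prior_spec"))
  draw1 <- function() {
    for (i in 1:1000) {
      d <- dist_draw(spec$d); r <- dist_draw(spec$r)
      if (d <= 0 || r < 0 || r >= 1) next
      mu <- r * d / (1 - r)
      if (spec$implicit_s) {
        psi <- dist_draw(spec$s_or_psi)
        s <- sampling_proportion(mu, psi)
      } else {
        s <- dist_draw(spec$s_or_psi)
      }
      if (s < 0 || s >= 1) next
      if (spec$implicit_T) {
        N <- dist_draw(spec$T_or_N)
        if (N < 1) next
        T <- log(N) / d
      } else {
        T <- dist_draw(spec$T_or_N)
      }
      if (T <= 0) next
      return(fbd_params(origin_T = T, d = d, r = r, s = s))
    }
    stop("could not draw valid FBD parameters from the prior")
  }
  out <- replicate(n, draw1(), simplify = FALSE)
  if (n == 1) out[[1]] else out
}

#' Marginal (prior-predictive) fossil sampling-time density
#'
#' Monte-Carlo average over prior draws of the FBD sampling-time density
#' evaluated on a grid of ages. With `normalize = "per_draw"` (default)
#' each draw's density is normalized over its own `[0, T]` before
#' averaging, so the curve is the prior density of the age of one given
#' fossil; draws contribute 0 beyond their own origin. With
#' `normalize = "pooled"` raw intensities are averaged and the pooled
#' curve is normalized at the end, weighting draws by their expected
#' fossil counts.
#'
#' @param spec a [prior_spec].
#' @param t_grid ages (Myr) at which to evaluate the curve.
#' @param n_draws number of prior draws.
#' @param normalize `"per_draw"` or `"pooled"`.
#' @return data.frame with columns `age_Myr`, `density` and `mc_se`
#'   (Monte-Carlo standard error of the curve).
#' @export
marginal_sampling_density <- function(spec, t_grid, n_draws = 1000,
                                      normalize = c("per_draw", "pooled")) {
  normalize <- match.arg(normalize)
  stopifnot(n_draws >= 1, all(t_grid >= 0))
  acc <- matrix(0, nrow = n_draws, ncol = length(t_grid))
  for (i in seq_len(n_draws)) {
    p <- implicit_prior_draw(spec)
    inside <- t_grid <= p$origin_T
    if (!any(inside)) next
    f <- sampling_time_density(t_grid[inside], p)
    if (normalize == "per_draw") {
      tot <- .density_integral(0, p$origin_T, p, rel.tol = 1e-8)
      if (!is.finite(tot) || !all(is.finite(f))) {
        # see normalized_age_probability: truncated-exponential limit
        f <- p$d * exp(-p$d * t_grid[inside]) /
          (1 - exp(-p$d * p$origin_T))
      } else if (tot > 0) {
        f <- f / tot
      }
    }
    acc[i, inside] <- f
  }
  if (normalize == "pooled") {
    # raw intensities can overflow for rare explosive draws whose mass
    # sits entirely at the present; such draws are dropped from the pool
    bad <- !apply(acc, 1, function(x) all(is.finite(x)))
    if (any(bad)) {
      warning(sum(bad), " overflowing draw(s) dropped from the pooled curve")
      acc <- acc[!bad, , drop = FALSE]
    }
  }
  est <- colMeans(acc)
  se <- apply(acc, 2, sd) / sqrt(n_draws)
  if (normalize == "pooled") {
    # normalize the pooled curve by trapezoidal mass on the grid
    w <- sum(diff(t_grid) * (est[-1] + est[-length(est)]) / 2)
    if (w > 0) { est <- est / w; se <- se / w }
  }
  data.frame(age_Myr = t_grid, density = est, mc_se = se)
}

#' Export a density curve as tab-separated values
#'
#' Writes a two-column (plus Monte-Carlo standard error, if present) TSV
#' of a density curve as produced by [marginal_sampling_density].
#'
#' @param curve data.frame with columns `age_Myr` and `density`.
#' @param path output file path.
#' @param header_comment optional comment lines (prefixed `#`).
#' @return `path`, invisibly.
#' @export
write_density_curve <- function(curve, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(curve, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
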
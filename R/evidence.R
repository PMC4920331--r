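# Bayes-factor evidence for stratigraphic age ranges and the per-fossil
# and per-dataset summary statistics of the tip-dating reports.

#' Posterior probability that the focal age lies in a range
#'
#' Fraction of post-burn-in sampled focal ages inside `[l, u]`.
#'
#' @param run an `fbd_mcmc` object (from [run_mcmc]) or a numeric vector
#'   of age samples.
#' @param l,u range bounds in Myr.
#' @return a probability.
#' @export
posterior_prob_age_range <- function(run, l, u) {
  samples <- if (inherits(run, "fbd_mcmc")) .post_burnin(run)$focal_age
             else run
  if (length(samples) < 1 || all(is.na(samples)))
    stop("no focal-age samples in the trace")
  mean(samples >= l & samples <= u)
}

#' Prior probability of an age range under the FBD process
#'
#' Monte-Carlo average, over draws from the parameter priors, of the
#' normalized sampling-time probability of `[l, u]`; each draw's density
#' is normalized over its own `[0, T]`, and draws whose origin lies below
#' `l` contribute 0.
#'
#' @param l,u range bounds in Myr.
#' @param priors a [prior_spec].
#' @param n_draws number of prior draws.
#' @return list with `prob` and its Monte-Carlo standard error `mc_se`.
#' @export
prior_prob_age_range <- function(l, u, priors, n_draws = 1000) {
  stopifnot(l <= u, n_draws >= 1)
  vals <- vapply(seq_len(n_draws), function(i) {
    p <- implicit_prior_draw(priors)
    if (p$origin_T <= l) return(0)
    normalized_age_probability(l, min(u, p$origin_T), p)
  }, numeric(1))
  list(prob = mean(vals), mc_se = sd(vals) / sqrt(n_draws))
}

#' Bayes factor for an age-range hypothesis
#'
#' Evidence for the hypothesis that the fossil's age lies inside the range
#' (H1) against it lying outside (H2), as the ratio of posterior to prior
#' odds: `BF = [p/(1-p)] / [q/(1-q)]`. Probabilities of exactly 0 or 1 are
#' clamped to the finite-sample boundary `1/(2 n)` (or its complement) and
#' flagged.
#'
#' @param post_p posterior probability of the range.
#' @param prior_p prior probability of the range.
#' @param n_samples number of samples behind `post_p`, used for clamping.
#' @return list with `bf`, `log_bf` (natural log), and `clamped`.
#' @export
bayes_factor <- function(post_p, prior_p, n_samples = 1000) {
  stopifnot(post_p >= 0, post_p <= 1, prior_p >= 0, prior_p <= 1)
  eps <- 1 / (2 * n_samples)
  clamped <- FALSE
  if (post_p <= 0 || post_p >= 1) {
    post_p <- min(max(post_p, eps), 1 - eps)
    clamped <- TRUE
  }
  if (prior_p <= 0 || prior_p >= 1) {
    prior_p <- min(max(prior_p, eps), 1 - eps)
    clamped <- TRUE
  }
  bf <- (post_p / (1 - post_p)) / (prior_p / (1 - prior_p))
  list(bf = bf, log_bf = log(bf), clamped = clamped)
}

#' Classify Bayes-factor support for an age range
#'
#' Natural-log Bayes-factor categories: strong evidence against the range
#' below -3, negative evidence below 0, positive evidence at or above 0,
#' and strong support above +3.
#'
#' @param log_bf natural-log Bayes factor.
#' @return one of `"strong_against"`, `"negative"`, `"positive"`,
#'   `"strong_for"`.
#' @export
classify_support <- function(log_bf) {
  stopifnot(is.finite(log_bf))
  if (log_bf < -3) "strong_against"
  else if (log_bf < 0) "negative"
  else if (log_bf > 3) "strong_for"
  else "positive"
}

#' Highest posterior density interval
#'
#' Shortest interval containing `ceiling(mass * n)` of the sorted samples.
#'
#' @param samples numeric vector (`>= 100` values).
#' @param mass interval mass (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  n <- length(samples)
  if (n < 100) stop("need at least 100 samples for an HPD interval")
  x <- sort(samples)
  m <- ceiling(mass * n)
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1])
}

#' Effective sample size of an autocorrelated trace
#'
#' `n / (1 + 2 sum rho_k)` with the autocorrelation sum truncated at the
#' first non-positive adjacent pair (initial positive sequence rule).
#' Constant series are flagged degenerate and reported as `n`.
#'
#' @param samples numeric vector (`>= 100` values).
#' @return effective sample size; attribute `degenerate` when constant.
#' @export
ess <- function(samples) {
  n <- length(samples)
  if (n < 100) stop("need at least 100 samples for an ESS estimate")
  v <- var(samples)
  if (v == 0) return(structure(as.numeric(n), degenerate = TRUE))
  x <- samples - mean(samples)
  maxlag <- min(n - 2, 2000)
  rho <- numeric(maxlag)
  denom <- sum(x^2)
  for (k in seq_len(maxlag)) {
    rho[k] <- sum(x[1:(n - k)] * x[(k + 1):n]) / denom
  }
  s <- 0
  k <- 1
  while (k + 1 <= maxlag) {
    pair <- rho[k] + rho[k + 1]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  n / (1 + 2 * s)
}

#' Error of a phylogenetic age estimate against a geological range
#'
#' The error is the absolute difference between the phylogenetic median
#' and the geological mid-point (in Myr); the relative error divides it by
#' the geological mid-point.
#'
#' @param phylo_median phylogenetic point estimate (Myr).
#' @param lower,upper geological range bounds (Myr).
#' @return list with `error`, `relative_error` (NA with a flag when the
#'   geological mid-point is 0) and `geo_median`.
#' @export
error_metrics <- function(phylo_median, lower, upper) {
  geo <- (lower + upper) / 2
  err <- abs(phylo_median - geo)
  rel <- if (geo > 0) err / geo else NA_real_
  list(error = err, relative_error = rel, geo_median = geo,
       relative_undefined = geo <= 0)
}

#' Relative standard deviation of a posterior sample
#'
#' Standard deviation of the marginal posterior divided by its median.
#'
#' @param samples numeric vector.
#' @return the RSD; `NA` with a flag when the median is 0.
#' @export
rsd <- function(samples) {
  m <- median(samples)
  if (m == 0) return(structure(NA_real_, undefined = TRUE))
  sd(samples) / m
}

#' Precision of a posterior sample
#'
#' Reciprocal of the marginal posterior variance.
#'
#' @param samples numeric vector.
#' @return `1/var(samples)`; `Inf` with a flag for constant samples.
#' @export
precision <- function(samples) {
  v <- var(samples)
  if (v == 0) return(structure(Inf, degenerate = TRUE))
  1 / v
}

#' Dataset-level summary of fossil age estimates
#'
#' R-squared (squared Pearson correlation) between the phylogenetic
#' medians and the geological mid-points, medians of the error, relative
#' error and RSD columns, and the fossils whose geological mid-point falls
#' outside the phylogenetic 95% HPD.
#'
#' @param report a data.frame as returned by [leave_one_out_report].
#' @return list with `r_squared`, `median_error`, `median_relative_error`,
#'   `median_rsd`, `n_outside_hpd`, `outside_hpd` (taxa).
#' @export
dataset_summary <- function(report) {
  stopifnot(nrow(report) >= 2)
  geo_mid <- (report$geo_lower + report$geo_upper) / 2
  r2 <- suppressWarnings(stats::cor(report$phylo_age, geo_mid))^2
  outside <- report$taxon[geo_mid < report$hpd_lower |
                          geo_mid > report$hpd_upper]
  list(r_squared = r2,
       median_error = median(report$error),
       median_relative_error = median(report$relative_error, na.rm = TRUE),
       median_rsd = median(report$rsd),
       n_outside_hpd = length(outside),
       outside_hpd = outside)
}

#' Leave-one-out fossil age report
#'
#' For each fossil in turn, releases its stratigraphic constraint to the
#' FBD prior, estimates its age, and assembles the per-fossil report row:
#' posterior probability of the range, Bayes factor, phylogenetic age with
#' 95% HPD, error against the geological mid-point and ESS. The prior
#' range probability for the Bayes factor is computed once per fossil from
#' the analytic sampling-time density averaged over prior draws.
#'
#' @inheritParams run_mcmc
#' @param prior_draws Monte-Carlo draws for the prior range probability.
#' @param fossils optional subset of fossil taxa to process.
#' @return data.frame (one row per fossil) with columns `taxon`, `post`,
#'   `bf`, `log_bf`, `phylo_age`, `hpd_lower`, `hpd_upper`, `error`,
#'   `relative_error`, `rsd`, `precision`, `ess`, `geo_lower`,
#'   `geo_upper`, `failed`.
#' @export
leave_one_out_report <- function(tree, data, constraints, priors,
                                 config = mcmc_config(), seed = NULL,
                                 prior_draws = 500, fossils = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fossils))
    fossils <- tree$tip_label[tree$is_fossil]
  rows <- vector("list", length(fossils))
  for (i in seq_along(fossils)) {
    f <- fossils[i]
    ci <- match(f, constraints$taxon)
    l <- constraints$lower[ci]; u <- constraints$upper[ci]
    row <- data.frame(taxon = f, post = NA_real_, bf = NA_real_,
                      log_bf = NA_real_, phylo_age = NA_real_,
                      hpd_lower = NA_real_, hpd_upper = NA_real_,
                      error = NA_real_, relative_error = NA_real_,
                      rsd = NA_real_, precision = NA_real_, ess = NA_real_,
                      geo_lower = l, geo_upper = u, failed = FALSE,
                      stringsAsFactors = FALSE)
    est <- tryCatch(
      estimate_focal_fossil_age(tree, data, constraints, priors, f, config),
      error = function(e) e)
    if (inherits(est, "error")) {
      row$failed <- TRUE
      warning("fossil ", f, " failed: ", conditionMessage(est))
      rows[[i]] <- row
      next
    }
    pr <- prior_prob_age_range(l, u, priors, n_draws = prior_draws)
    post_p <- posterior_prob_age_range(est$samples, l, u)
    bf <- bayes_factor(post_p, pr$prob, n_samples = length(est$samples))
    em <- error_metrics(est$median, l, u)
    row$post <- post_p; row$bf <- bf$bf; row$log_bf <- bf$log_bf
    row$phylo_age <- est$median
    row$hpd_lower <- est$hpd[1]; row$hpd_upper <- est$hpd[2]
    row$error <- em$error; row$relative_error <- em$relative_error
    row$rsd <- rsd(est$samples); row$precision <- precision(est$samples)
    row$ess <- est$ess
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}
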
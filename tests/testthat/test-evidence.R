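# Bayes factors, support categories, and the posterior summary metrics.

test_that("posterior range probability is a simple sample fraction", {
  set.seed(501)
  x <- runif(1e5)
  expect_equal(posterior_prob_age_range(x, -1, 2), 1)
  expect_equal(posterior_prob_age_range(x, 0.3, 0.3), 0,
               tolerance = 1e-4)
  p <- posterior_prob_age_range(x, 0.2, 0.5)
  expect_lt(abs(p - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5))
  expect_error(posterior_prob_age_range(numeric(0), 0, 1), "samples")
})

test_that("prior range probability collapses for point-mass priors", {
  p <- fbd_params(40, 0.05, 0.5, 0.2)
  pr <- prior_prob_age_range(10, 20, fixed_priors(p), n_draws = 5)
  expect_equal(pr$prob, normalized_age_probability(10, 20, p),
               tolerance = 1e-8)
  full <- prior_prob_age_range(0, 1e6, fixed_priors(p), n_draws = 5)
  expect_equal(full$prob, 1, tolerance = 1e-7)
})

test_that("prior range probability sums to one over a partition", {
  set.seed(502)
  spec <- study_prior()
  cuts <- c(0, 5, 15, 40, 1e4)
  set.seed(77)
  parts <- vapply(seq_len(length(cuts) - 1), function(i) {
    set.seed(77)   # same prior draws for every interval
    prior_prob_age_range(cuts[i], cuts[i + 1], spec, n_draws = 120)$prob
  }, 1)
  expect_equal(sum(parts), 1, tolerance = 1e-6)
})

test_that("Bayes factor follows the odds-ratio arithmetic", {
  expect_equal(bayes_factor(0.5, 0.5)$bf, 1)
  expect_equal(bayes_factor(0.5, 0.5)$log_bf, 0)
  expect_equal(bayes_factor(0.75, 0.5)$bf, 3)
  for (p in c(0.05, 0.3, 0.9)) expect_equal(bayes_factor(p, p)$bf, 1)
  # clamping at the finite-sample boundary
  cl <- bayes_factor(0, 0.4, n_samples = 1000)
  expect_true(cl$clamped)
  expect_true(is.finite(cl$log_bf))
  expect_equal(cl$bf,
               ((1 / 2000) / (1 - 1 / 2000)) / (0.4 / 0.6))
})

test_that("support classification uses the natural-log thresholds", {
  expect_equal(classify_support(-3.4), "strong_against")
  expect_equal(classify_support(-0.5), "negative")
  expect_equal(classify_support(0), "positive")
  expect_equal(classify_support(2.9), "positive")
  expect_equal(classify_support(3.5), "strong_for")
  expect_error(classify_support(Inf), "finite")
})

test_that("HPD intervals match analytic widths", {
  set.seed(503)
  u <- runif(1e5)
  h <- hpd_interval(u, 0.95)
  expect_lt(abs(diff(h) - 0.95), 0.02)
  z <- rnorm(1e5)
  hz <- hpd_interval(z, 0.95)
  expect_lt(abs(hz[1] + 1.96), 0.05)
  expect_lt(abs(hz[2] - 1.96), 0.05)
  expect_equal(diff(hpd_interval(rep(3.3, 200), 0.95)), 0,
               ignore_attr = TRUE)
  expect_error(hpd_interval(1:10), "100")
})

test_that("ESS behaves for iid, AR(1) and duplicated samples", {
  set.seed(504)
  x <- rnorm(1e4)
  expect_true(ess(x) / 1e4 > 0.8 && ess(x) / 1e4 < 1.2)
  # AR(1) with phi = 0.9: ESS/n ~ (1-phi)/(1+phi)
  phi <- 0.9
  ar <- as.numeric(arima.sim(list(ar = phi), 1e5))
  ratio <- ess(ar) / 1e5
  expect_lt(abs(ratio / ((1 - phi) / (1 + phi)) - 1), 0.5)
  # duplicating every sample roughly halves ESS/n
  dup <- rep(x, each = 2)
  expect_lt(ess(dup) / length(dup), 0.75 * ess(x) / length(x))
  # constant series flagged degenerate
  const <- ess(rep(1, 200))
  expect_true(attr(const, "degenerate"))
})

test_that("error metrics reproduce the reported example pairs", {
  # S. muizoni-style pair: phylogenetic 5.2 vs geological median 9.1
  em <- error_metrics(5.2, 9.1 - 1, 9.1 + 1)
  expect_equal(em$error, 3.9)
  expect_equal(em$relative_error, 3.9 / 9.1, tolerance = 1e-6)
  # P. antarcticus-style pair: 29.9 vs 22
  em2 <- error_metrics(29.9, 22 - 2, 22 + 2)
  expect_equal(em2$error, 7.9)
  expect_equal(error_metrics(7, 6, 8)$error, 0)
  expect_true(error_metrics(1, 0, 0)$relative_undefined)
})

test_that("RSD and precision follow their definitions", {
  expect_equal(rsd(c(1, 2, 3)), 0.5)
  expect_equal(rsd(rep(4, 10)), 0)
  x <- rlnorm(500)
  expect_equal(rsd(3 * x), rsd(x))
  set.seed(505)
  u <- runif(1e5)
  expect_lt(abs(precision(u) - 12), 0.6)
  expect_equal(precision(u + 100), precision(u))
  expect_true(is.infinite(precision(rep(2, 10))))
})

test_that("dataset summary computes R-squared like a spreadsheet", {
  set.seed(506)
  n <- 30
  geo_mid <- runif(n, 5, 50)
  phylo <- geo_mid + rnorm(n, 0, 3)
  report <- data.frame(taxon = paste0("f", 1:n), phylo_age = phylo,
                       geo_lower = geo_mid - 2, geo_upper = geo_mid + 2,
                       error = abs(phylo - geo_mid),
                       relative_error = abs(phylo - geo_mid) / geo_mid,
                       rsd = runif(n, 0.05, 0.2),
                       hpd_lower = phylo - 5, hpd_upper = phylo + 5)
  s <- dataset_summary(report)
  # independent recomputation of the squared Pearson correlation
  r2 <- (sum((phylo - mean(phylo)) * (geo_mid - mean(geo_mid))) /
           sqrt(sum((phylo - mean(phylo))^2) *
                  sum((geo_mid - mean(geo_mid))^2)))^2
  expect_equal(s$r_squared, r2, tolerance = 1e-10)
  # permutation invariance
  perm <- sample(n)
  s2 <- dataset_summary(report[perm, ])
  expect_equal(s2$r_squared, s$r_squared)
  # perfect agreement
  report$phylo_age <- geo_mid
  report$error <- 0; report$relative_error <- 0
  report$hpd_lower <- geo_mid - 1; report$hpd_upper <- geo_mid + 1
  s3 <- dataset_summary(report)
  expect_equal(s3$r_squared, 1)
  expect_equal(s3$median_error, 0)
  expect_equal(s3$n_outside_hpd, 0)
})

test_that("leave-one-out reports one row per fossil, deterministically", {
  set.seed(507)
  p <- fbd_params(15, 0.1, 0.5, 0.5)
  tr <- simulate_fbd_tree(p)
  while (sum(tr$is_fossil) < 2 || length(tr$tip_label) > 12)
    tr <- simulate_fbd_tree(p)
  cm <- simulate_characters(tr, 30, state_counts = 2,
                            clock = list(kind = "strict", mu = 0.02))
  ranges <- make_age_ranges(tr, 2)
  cfg <- mcmc_config(chain_length = 1e4, thin = 50)
  rep1 <- leave_one_out_report(tr, cm, ranges, study_prior(), cfg,
                               seed = 3, prior_draws = 40)
  expect_equal(nrow(rep1), sum(tr$is_fossil))
  expect_false(any(rep1$failed))
  expect_true(all(rep1$hpd_lower <= rep1$phylo_age &
                    rep1$phylo_age <= rep1$hpd_upper))
  expect_true(all(is.finite(rep1$log_bf)))
  rep2 <- leave_one_out_report(tr, cm, ranges, study_prior(), cfg,
                               seed = 3, prior_draws = 40)
  expect_identical(rep1, rep2)
})
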
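# FBD tree density and the Metropolis-Hastings sampler.

test_that("FBD density reduces to the conditioned birth-death density", {
  set.seed(401)
  # with psi = 0 and extant-only trees, the density must equal the
  # classic birth-death form with q = p1 computed independently
  p <- fbd_params(20, 0.1, 0.4, 0)
  for (rep in 1:20) {
    tr <- simulate_fbd_tree(p)
    n <- length(tr$tip_label)
    if (n < 2) next
    d <- p$d; r <- p$r
    p1 <- function(t) {
      (1 - extinction_prob_p0(t, d, r)) * (1 - fbdage:::bd_eta(t, d, r))
    }
    lambda <- to_canonical_rates(p)[["lambda"]]
    internals <- (n + 1):(2 * n - 1)
    oracle <- log(p1(20)) - log(1 - extinction_prob_p0(20, d, r)) +
      sum(log(2 * lambda) + log(p1(tr$age[internals])))
    expect_equal(fbd_tree_log_density(tr, p), oracle, tolerance = 1e-8)
  }
})

test_that("support violations return -Inf", {
  tr <- two_tip_tree(fossil_age = 4, root_age = 5, origin_T = 10)
  expect_equal(fbd_tree_log_density(tr, fbd_params(4.5, 0.1, 0.5, 0.3)),
               -Inf)   # origin below the root
  tr2 <- tr; tr2$age[2] <- 12
  expect_equal(fbd_tree_log_density(tr2, fbd_params(10, 0.1, 0.5, 0.3)),
               -Inf)   # fossil older than the origin
  # fossils present but no sampling rate
  expect_equal(fbd_tree_log_density(tr, fbd_params(10, 0.1, 0.5, 0)), -Inf)
})

test_that("R and C++ density implementations agree on random states", {
  set.seed(402)
  p <- fbd_params(20, 0.08, 0.5, 0.5)
  rates <- to_canonical_rates(p)
  for (rep in 1:30) {
    tr <- simulate_fbd_tree(p)
    n <- length(tr$tip_label)
    if (n < 2) next
    sa <- is_sampled_ancestor(tr)
    a <- fbd_tree_log_density(tr, p)
    b <- fbdage:::fbd_tree_logdens_cpp(tr$edge, tr$age, n, tr$is_fossil,
                                       sa, tr$origin_T, rates[["lambda"]],
                                       rates[["mu"]], rates[["psi"]],
                                       p$d, p$r)
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("log posterior decomposes and enforces the range indicator", {
  set.seed(403)
  p <- fbd_params(20, 0.08, 0.5, 0.5)
  tr <- simulate_fbd_tree(p)
  while (sum(tr$is_fossil) < 1) tr <- simulate_fbd_tree(p)
  cm <- simulate_characters(tr, 10, state_counts = 2,
                            clock = list(kind = "strict", mu = 0.02))
  ranges <- make_age_ranges(tr, 2)
  clock <- list(kind = "strict", mu = 0.02)
  lp <- log_posterior(tr, p, clock, cm, ranges, fixed_priors(p))
  expect_true(is.finite(lp$log_posterior))
  expect_equal(lp$log_posterior,
               lp$log_likelihood + lp$log_tree_prior + lp$log_param_prior)
  # pushing a fossil outside its range kills the posterior
  ranges2 <- ranges
  ranges2$upper[1] <- ranges2$lower[1] <-
    tr$age[match(ranges2$taxon[1], tr$tip_label)] / 2
  lp2 <- log_posterior(tr, p, clock, cm, ranges2, fixed_priors(p))
  expect_equal(lp2$log_posterior, -Inf)
  # without characters, posterior differences are prior-only differences
  lp3 <- log_posterior(tr, p, clock, NULL, ranges, fixed_priors(p))
  expect_equal(lp3$log_likelihood, 0)
})

test_that("log posterior is finite across random valid states", {
  set.seed(404)
  p <- fbd_params(25, 0.06, 0.5, 0.5)
  tr <- simulate_fbd_tree(p)
  while (sum(tr$is_fossil) < 2) tr <- simulate_fbd_tree(p)
  cm <- simulate_characters(tr, 30, state_counts = rep(2:3, 15),
                            clock = list(kind = "strict", mu = 0.02))
  ranges <- make_age_ranges(tr, 2)
  for (i in 1:50) {
    pp <- fbd_params(tr$origin_T * runif(1, 1, 1.5), runif(1, 0.02, 0.2),
                     runif(1, 0.05, 0.9), runif(1, 0.05, 0.9))
    mu <- runif(1, 0.005, 0.1)
    lp <- log_posterior(tr, pp, list(kind = "strict", mu = mu),
                        cm, ranges, fixed_priors(pp, mu_clock = mu))
    expect_true(is.finite(lp$log_posterior))
  }
})

test_that("identical seeds give identical chains", {
  set.seed(405)
  p <- fbd_params(20, 0.08, 0.5, 0.5)
  tr <- simulate_fbd_tree(p)
  while (sum(tr$is_fossil) < 1 || length(tr$tip_label) < 4)
    tr <- simulate_fbd_tree(p)
  cm <- simulate_characters(tr, 20, state_counts = 2,
                            clock = list(kind = "strict", mu = 0.02))
  ranges <- make_age_ranges(tr, 2)
  cfg <- mcmc_config(chain_length = 5000, thin = 50)
  run1 <- run_mcmc(tr, cm, ranges, study_prior(), cfg, seed = 99)
  run2 <- run_mcmc(tr, cm, ranges, study_prior(), cfg, seed = 99)
  expect_identical(run1$trace, run2$trace)
  run3 <- run_mcmc(tr, cm, ranges, study_prior(), cfg, seed = 100)
  expect_false(identical(run3$trace$posterior, run1$trace$posterior))
})

test_that("tuned scale moves land in a sane acceptance band", {
  set.seed(406)
  fx <- fixture_preset("penguin_like", n_chars = 60)
  cfg <- mcmc_config(chain_length = 4e4, thin = 100)
  run <- run_mcmc(fx$tree, fx$matrix, fx$ranges, study_prior(), cfg,
                  seed = 11)
  acc <- run$acceptance
  scale_moves <- c("scale_d", "scale_spsi", "scale_T", "scale_mu")
  for (mv in scale_moves) {
    row <- acc[acc$move == mv, ]
    if (row$proposed > 200) {
      rate <- row$accepted / row$proposed
      expect_gt(rate, 0.1)
      expect_lt(rate, 0.6)
    }
  }
})

test_that("focal estimation requires a fossil taxon", {
  set.seed(407)
  p <- fbd_params(20, 0.08, 0.5, 0.5)
  tr <- simulate_fbd_tree(p)
  while (sum(tr$is_fossil) < 1) tr <- simulate_fbd_tree(p)
  ranges <- make_age_ranges(tr, 2)
  expect_error(run_mcmc(tr, NULL, ranges, study_prior(),
                        mcmc_config(chain_length = 1000, thin = 10),
                        focal = "extant_1"),
               "fossil")
})

test_that("zero characters reduce the focal posterior to its prior", {
  set.seed(408)
  p <- fbd_params(15, 0.1, 0.5, 0.5)
  tr <- simulate_fbd_tree(p)
  while (sum(tr$is_fossil) < 2 || length(tr$tip_label) > 12 ||
         length(tr$tip_label) < 5)
    tr <- simulate_fbd_tree(p)
  ranges <- make_age_ranges(tr, 2)
  focal <- ranges$taxon[1]
  cfg <- mcmc_config(chain_length = 2e5, thin = 100,
                     sample_prior_only = TRUE)
  prior_run <- run_mcmc(tr, NULL, ranges, fixed_priors(p), cfg,
                        focal = focal, seed = 1)
  # a zero-character data matrix must sample the same distribution
  cm0 <- simulate_characters(tr, 1, state_counts = 2,
                             clock = list(kind = "strict", mu = 0.02))
  cm0$data[] <- "?"
  data_run <- run_mcmc(tr, cm0, ranges, fixed_priors(p),
                       mcmc_config(chain_length = 2e5, thin = 100),
                       focal = focal, seed = 2)
  a <- fbdage:::.post_burnin(prior_run)$focal_age
  b <- fbdage:::.post_burnin(data_run)$focal_age
  expect_gt(suppressWarnings(ks.test(a, b))$p.value, 0.01)
})
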
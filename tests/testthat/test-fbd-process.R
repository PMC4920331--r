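# The FBD process: parameter maps, Kendall probabilities, the analytic
# fossil sampling-time density and the implicit prior machinery.

test_that("canonical rate transformation and its inverse", {
  p <- fbd_params(40, 1, 0, 0)
  expect_equal(unname(to_canonical_rates(p)), c(1, 0, 0))
  p2 <- fbd_params(40, 0.05, 0.5, 0.3)
  rates <- to_canonical_rates(p2)
  expect_equal(unname(rates[["lambda"]]), 0.1)
  expect_equal(unname(rates[["mu"]]), 0.05)
  expect_equal(rates[["lambda"]] - rates[["mu"]], 0.05,
               ignore_attr = TRUE)
  expect_equal(rates[["mu"]] / rates[["lambda"]], 0.5, ignore_attr = TRUE)
  # s = psi/(mu+psi) round-trips; mu = psi implies s = 1/2
  expect_equal(sampling_proportion(rates[["mu"]], rates[["psi"]]), p2$s)
  expect_equal(sampling_proportion(0.2, 0.2), 0.5)
  expect_error(fbd_params(40, 0.05, 1, 0.3), "turnover")
  expect_error(fbd_params(40, 0.05, 0.5, 1), "sampling")
  expect_error(fbd_params(-1, 0.05, 0.5, 0.3), "origin_T")
})

test_that("extinction probability p0 has the right limits and shape", {
  expect_equal(extinction_prob_p0(0, 0.1, 0.5), 0)
  expect_equal(extinction_prob_p0(c(1, 5, 100), 0.1, 0), rep(0, 3))
  # nondecreasing in t, tending to r
  t <- seq(0, 400, length.out = 300)
  v <- extinction_prob_p0(t, 0.05, 0.6)
  expect_true(all(diff(v) >= 0))
  expect_lt(abs(v[300] - 0.6), 1e-6)
  expect_true(all(v >= 0 & v < 1))
  expect_error(extinction_prob_p0(-1, 0.1, 0.5), ">= 0")
})

test_that("lineage-count probabilities normalize and start at identity", {
  expect_equal(lineage_count_prob_pk(1, 0, 0.1, 0.5), 1)
  expect_equal(lineage_count_prob_pk(c(0, 2, 3), 0, 0.1, 0.5), c(0, 0, 0))
  for (dr in list(c(0.05, 0.2), c(0.1, 0.5), c(0.25, 0.8))) {
    tot <- sum(lineage_count_prob_pk(0:1e5, 20, dr[1], dr[2]))
    expect_lt(abs(tot - 1), 1e-8)
  }
  expect_error(lineage_count_prob_pk(-1, 1, 0.1, 0.5), "non-negative")
})

test_that("Kendall probabilities match forward simulation on a grid", {
  set.seed(101)
  nsim <- 1200
  for (d in c(0.05, 0.1, 0.2)) {
    for (r in c(0.2, 0.5, 0.8)) {
      for (t in c(5, 10, 20)) {
        counts <- sim_lineage_count(d, r, t, nsim)
        # p0 within 3 Monte-Carlo standard errors
        p0 <- extinction_prob_p0(t, d, r)
        se0 <- sqrt(p0 * (1 - p0) / nsim)
        expect_lt(abs(mean(counts == 0) - p0), 3 * se0 + 1e-12)
        # p_k for small k within 3 SEs
        for (k in 1:2) {
          pk <- lineage_count_prob_pk(k, t, d, r)
          sek <- sqrt(pk * (1 - pk) / nsim)
          expect_lt(abs(mean(counts == k) - pk), 3 * sek + 1e-12)
        }
      }
    }
  }
})

test_that("closed-form sampling density equals the truncated sum", {
  p <- fbd_params(40, 0.05, 0.5, 0.2)
  ts <- seq(0.01, 39.99, length.out = 100)
  a <- sampling_time_density(ts, p, mode = "closed")
  b <- sampling_time_density(ts, p, mode = "sum")
  expect_lt(max(abs(a / b - 1)), 1e-8)
  # no sampling, no density
  p0 <- fbd_params(40, 0.05, 0.5, 0)
  expect_equal(sampling_time_density(ts, p0), rep(0, length(ts)))
  expect_error(sampling_time_density(41, p), "origin_T")
})

test_that("normalized age probability is a proper interval probability", {
  p <- fbd_params(40, 0.05, 0.5, 0.2)
  expect_equal(normalized_age_probability(0, 40, p), 1)
  expect_equal(normalized_age_probability(7, 7, p), 0)
  expect_error(normalized_age_probability(8, 7, p), "l must be <= u")
  # monotone in u and additive over disjoint intervals
  u <- c(5, 10, 20, 30, 40)
  v <- vapply(u, function(x) normalized_age_probability(0, x, p), 1)
  expect_true(all(diff(v) > 0))
  expect_equal(normalized_age_probability(0, 10, p) +
                 normalized_age_probability(10, 25, p),
               normalized_age_probability(0, 25, p), tolerance = 1e-7)
})

test_that("fraction of simulated fossil ages in a range matches quadrature", {
  set.seed(102)
  p <- fbd_params(40, 0.05, 0.5, 0.2)
  ages <- numeric(0)
  for (i in 1:1500) {
    tr <- simulate_fbd_tree(p)
    ages <- c(ages, tr$age[which(tr$is_fossil)])
  }
  emp <- mean(ages >= 10 & ages <= 20)
  thy <- normalized_age_probability(10, 20, p)
  se <- sqrt(thy * (1 - thy) / length(ages))
  # pooled ages are weakly dependent within trees; allow a margin on the
  # binomial standard error
  expect_lt(abs(emp - thy), 5 * se)
})

test_that("implicit prior draws respect the constructions", {
  set.seed(103)
  spec <- prior_preset("implicit_2016")
  draws <- implicit_prior_draw(spec, n = 200)
  for (p in draws) {
    expect_true(p$origin_T > 0 && p$d > 0 && p$r >= 0 && p$r < 1 &&
                  p$s >= 0 && p$s < 1)
    # s back-transforms to a psi inside the lognormal support
    rates <- to_canonical_rates(p)
    expect_equal(sampling_proportion(rates[["mu"]], rates[["psi"]]), p$s,
                 tolerance = 1e-12)
    # T = log(N)/d with N in [1, 100]
    N <- exp(p$d * p$origin_T)
    expect_true(N >= 1 - 1e-9 && N <= 100 + 1e-9)
  }
  # direct arithmetic: N = 100, d = 0.05
  expect_equal(log(100) / 0.05, 92.10, tolerance = 1e-3)
})

test_that("marginal sampling density reduces to the fixed-parameter case", {
  p <- fbd_params(40, 0.05, 0.5, 0.2)
  spec <- fixed_priors(p)
  grid <- seq(0.5, 39.5, length.out = 30)
  curve <- marginal_sampling_density(spec, grid, n_draws = 3)
  dens <- sampling_time_density(grid, p)
  dens <- dens / fbdage:::.density_integral(0, 40, p)
  expect_equal(curve$density, dens, tolerance = 1e-6)
  expect_true(all(curve$mc_se < 1e-12))
})

test_that("old prior puts far less mass on old sampling times", {
  set.seed(104)
  grid <- seq(0, 80, length.out = 41)
  # prior-predictive curves pool raw sampling intensities across draws;
  # rare huge-tree draws dominate the earlier standard prior and push
  # essentially all mass to the present, while the implicit prior keeps
  # non-negligible weight on old ages
  new <- marginal_sampling_density(prior_preset("implicit_2016"), grid,
                                   n_draws = 250, normalize = "pooled")
  old <- marginal_sampling_density(prior_preset("gavryushkina_2014"), grid,
                                   n_draws = 250, normalize = "pooled")
  mass_old_tail <- function(cv)
    sum(cv$density[cv$age_Myr > 40]) / sum(cv$density)
  expect_gt(mass_old_tail(new), 100 * mass_old_tail(old))
  expect_gt(mass_old_tail(new), 0.05)
})

test_that("Monte-Carlo standard error shrinks with draw count", {
  set.seed(105)
  grid <- c(5, 20)
  small <- marginal_sampling_density(prior_preset("implicit_2016"), grid,
                                     n_draws = 200)
  large <- marginal_sampling_density(prior_preset("implicit_2016"), grid,
                                     n_draws = 800)
  # fourfold draws should roughly halve the standard error
  expect_lt(mean(large$mc_se / small$mc_se), 0.8)
})
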
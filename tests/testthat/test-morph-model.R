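# Lewis-Mk machinery: partitioning, transition probabilities, rate
# heterogeneity, relaxed-clock rates and the pruning likelihood.

test_that("characters partition by observed state count", {
  data <- rbind(a = c("0", "0", "2", "?"),
                b = c("1", "0", "1", "?"),
                c = c("0", "0", "0", "?"))
  cm <- character_matrix(data, k = c(2, 2, 3, 2))
  parts <- partition_by_state_count(cm)
  expect_named(parts, c("k2", "k3"))
  expect_equal(attr(parts$k2, "chars"), c(1, 2, 4))
  expect_equal(attr(parts$k3, "chars"), 3)
  # constant and all-missing characters resolve to the binary partition
  expect_true(all(parts$k2$k == 2))
})

test_that("penguin-like fixture yields at most six partitions", {
  set.seed(301)
  fx <- fixture_preset("penguin_like")
  parts <- partition_by_state_count(fx$matrix)
  expect_lte(length(parts), 6)
})

test_that("Mk transition matrix matches its limits and the generator", {
  expect_equal(mk_transition_matrix(3, 0.1, 0), diag(3))
  expect_equal(mk_transition_matrix(4, 0.1, 1e6),
               matrix(0.25, 4, 4), tolerance = 1e-12)
  P <- mk_transition_matrix(3, 0.02, 10)
  expect_equal(rowSums(P), rep(1, 3))
  # generic matrix exponential of the normalized generator
  Q <- matrix(0.02 / 2, 3, 3); diag(Q) <- -0.02
  expect_lt(max(abs(P - as.matrix(Matrix::expm(Q * 10)))), 1e-10)
})

test_that("discrete gamma categories are mean-one and match quadrature", {
  expect_equal(discrete_gamma_rates(0.7, 1), 1)
  for (alpha in c(0.2, 0.5, 1, 3)) {
    for (ncat in c(2, 4, 8)) {
      rates <- discrete_gamma_rates(alpha, ncat)
      expect_equal(mean(rates), 1, tolerance = 1e-10)
      expect_true(all(diff(rates) >= 0))
    }
  }
  # numeric quantile-integration oracle at alpha = 0.5, 4 categories
  alpha <- 0.5
  bounds <- qgamma(seq(0, 1, 0.25), alpha, alpha)
  oracle <- vapply(1:4, function(i) {
    lo <- bounds[i]; hi <- if (i == 4) Inf else bounds[i + 1]
    4 * integrate(function(x) x * dgamma(x, alpha, alpha), lo, hi,
                  rel.tol = 1e-10)$value
  }, 1)
  expect_equal(discrete_gamma_rates(0.5, 4), oracle, tolerance = 1e-6)
})

test_that("UCLN branch rates have real-space mean mu", {
  expect_equal(ucln_branch_rates(0.02, 0, c(0.1, 0.5, 0.9)), rep(0.02, 3))
  set.seed(302)
  q <- runif(1e5)
  rates <- ucln_branch_rates(0.02, 0.8, q)
  expect_lt(abs(mean(rates) / 0.02 - 1), 0.02)
  # lognormal identity: the median sits at mu exp(-S^2/2)
  expect_equal(ucln_branch_rates(0.02, 0.8, 0.5), 0.02 * exp(-0.8^2 / 2))
})

test_that("pruning handles the degenerate and trivial cases", {
  tr <- two_tip_tree(fossil_age = 4, root_age = 4, origin_T = 10)
  # zero-duration tree, one binary character, both tips in state 0:
  # only the uniform root draw remains
  tr0 <- tr; tr0$age <- c(4, 4, 4)
  tr0$is_fossil <- c(TRUE, TRUE)
  cm <- character_matrix(rbind(extant_1 = "0", fossil_1 = "0"), k = 2)
  cm$taxa <- c("extant_1", "fossil_1")
  ll <- tree_log_likelihood(tr0, cm, clock = list(kind = "strict", mu = 0.1))
  expect_equal(ll, log(0.5), tolerance = 1e-12)
  # an all-missing character contributes exactly zero
  cm2 <- character_matrix(rbind(extant_1 = c("0", "?"),
                                fossil_1 = c("0", "?")), k = 2)
  ll2 <- tree_log_likelihood(tr0, cm2, clock = list(kind = "strict", mu = 0.1))
  expect_equal(ll2, ll)
})

test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(303)
  maxdiff <- 0
  for (rep in 1:100) {
    tr <- rand_small_tree(force_sa = rep %% 2 == 0)
    cm <- simulate_characters(tr, 4, state_counts = sample(2:3, 4, TRUE),
                              clock = list(kind = "strict", mu = 0.05))
    cm$data[sample(length(cm$data), 2)] <- "?"
    cm <- character_matrix(cm$data, k = cm$k)
    ll <- tree_log_likelihood(tr, cm, clock = list(kind = "strict", mu = 0.05))
    oracle <- brute_loglik(tr, cm, 0.05)
    maxdiff <- max(maxdiff, abs(ll - oracle))
  }
  expect_lt(maxdiff, 1e-8)
})

test_that("likelihood is invariant to character and taxon order", {
  set.seed(304)
  tr <- simulate_fbd_tree(fbd_params(20, 0.1, 0.5, 0.5))
  while (length(tr$tip_label) < 5) tr <- simulate_fbd_tree(fbd_params(20, 0.1, 0.5, 0.5))
  cm <- simulate_characters(tr, 20, state_counts = rep(2:3, 10),
                            clock = list(kind = "strict", mu = 0.03))
  clock <- list(kind = "strict", mu = 0.03)
  base <- tree_log_likelihood(tr, cm, clock = clock)
  perm <- sample(ncol(cm$data))
  cmp <- subset_characters(cm, perm)
  expect_equal(tree_log_likelihood(tr, cmp, clock = clock), base)
  rperm <- sample(nrow(cm$data))
  cmr <- character_matrix(cm$data[rperm, , drop = FALSE], k = cm$k)
  expect_equal(tree_log_likelihood(tr, cmr, clock = clock), base)
})

test_that("rate-time confounding and the strict-UCLN collapse hold", {
  set.seed(305)
  tr <- simulate_fbd_tree(fbd_params(20, 0.1, 0.5, 0.5))
  cm <- simulate_characters(tr, 15, state_counts = 2,
                            clock = list(kind = "strict", mu = 0.03))
  base <- tree_log_likelihood(tr, cm, clock = list(kind = "strict", mu = 0.03))
  # scaling durations by c and dividing the rate by c changes nothing
  tr2 <- tr; tr2$age <- tr$age * 3; tr2$origin_T <- tr$origin_T * 3
  expect_equal(tree_log_likelihood(tr2, cm,
                                   clock = list(kind = "strict", mu = 0.01)),
               base, tolerance = 1e-10)
  # UCLN with S = 0 is the strict clock
  expect_equal(tree_log_likelihood(tr, cm,
                                   clock = list(kind = "ucln", mu = 0.03,
                                                S = 0)),
               base)
})

test_that("taxon mismatches are labeled errors", {
  tr <- two_tip_tree()
  cm <- character_matrix(rbind(extant_1 = "0", zebra = "1"), k = 2)
  expect_error(tree_log_likelihood(tr, cm), "zebra")
})

test_that("the variable-characters correction increases the likelihood", {
  set.seed(306)
  tr <- simulate_fbd_tree(fbd_params(20, 0.1, 0.5, 0.5))
  cm <- simulate_characters(tr, 10, state_counts = 2,
                            clock = list(kind = "strict", mu = 0.03))
  # keep only variable characters, as the correction assumes
  keep <- which(apply(cm$data, 2, function(x) length(unique(x))) > 1)
  if (length(keep) >= 2) {
    cmv <- subset_characters(cm, keep)
    plain <- tree_log_likelihood(tr, cmv, mk_model_config(),
                                 clock = list(kind = "strict", mu = 0.03))
    mkv <- tree_log_likelihood(tr, cmv,
                               mk_model_config(ascertainment = "variable"),
                               clock = list(kind = "strict", mu = 0.03))
    expect_gt(mkv, plain)
  }
})
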
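# Shared helpers: small reference trees, fixed-parameter priors, the
# brute-force likelihood oracle and the reduced study prior used by the
# calibration experiments.

# two-tip reference tree: one extant, one fossil, origin above
two_tip_tree <- function(fossil_age = 4, root_age = 5, origin_T = 10) {
  sampled_tree(edge = rbind(c(3L, 1L), c(3L, 2L)),
               age = c(0, fossil_age, root_age),
               tip_label = c("extant_1", "fossil_1"),
               is_fossil = c(FALSE, TRUE), origin_T = origin_T)
}

# point-mass priors fixing the FBD parameters (prior-only chains)
fixed_priors <- function(params, mu_clock = 0.02) {
  prior_spec(
    d = dist_spec("fixed", value = params$d),
    r = dist_spec("fixed", value = params$r),
    s_or_psi = dist_spec("fixed", value = params$s),
    T_or_N = dist_spec("fixed", value = params$origin_T),
    mu_clock = dist_spec("fixed", value = mu_clock))
}

# reduced penguin-like study prior for the calibration experiments:
# moderate diversification and fossil sampling, origin via the implicit
# construction, targeting trees of roughly 30 taxa
study_prior <- function() {
  prior_spec(
    d = dist_spec("lognormal", meanlog = log(0.06), sdlog = 0.25),
    r = dist_spec("uniform", min = 0.3, max = 0.7),
    s_or_psi = dist_spec("lognormal", meanlog = log(0.10), sdlog = 0.4),
    T_or_N = dist_spec("uniform", min = 5, max = 25),
    mu_clock = dist_spec("lognormal", meanlog = log(0.018), sdlog = 0.3),
    implicit_s = TRUE, implicit_T = TRUE)
}

# draw one study replicate from the prior: parameters, tree (within a
# workable size range), characters, ranges, and a random focal fossil
sim_study_replicate <- function(n_chars = 100, min_tips = 10,
                                max_tips = 45, half_width = 2.5) {
  pr <- study_prior()
  repeat {
    params <- implicit_prior_draw(pr)
    if (params$origin_T > 100) next
    tree <- tryCatch(simulate_fbd_tree(params), error = function(e) NULL)
    if (is.null(tree)) next
    n <- length(tree$tip_label)
    nf <- sum(tree$is_fossil)
    if (n < min_tips || n > max_tips || nf < 2) next
    mu <- dist_draw(pr$mu_clock)
    cm <- simulate_characters(tree, n_chars,
                              state_counts = rep(c(2L, 3L), length.out = n_chars),
                              clock = list(kind = "strict", mu = mu))
    ranges <- make_age_ranges(tree, half_width = half_width)
    foss <- which(tree$is_fossil)
    focal <- tree$tip_label[sample(foss, 1)]
    return(list(params = params, tree = tree, matrix = cm, ranges = ranges,
                focal = focal,
                truth = tree$age[match(focal, tree$tip_label)],
                priors = pr))
  }
}

# brute-force Lewis-Mk likelihood by enumeration over interior states
brute_loglik <- function(tree, cm, mu) {
  n <- length(tree$tip_label)
  bits <- matrix(0L, n, ncol(cm$data))
  bits[match(cm$taxa, tree$tip_label), ] <- fbdage:::.cm_bitmask(cm)
  internals <- (n + 1):(2 * n - 1)
  ll <- 0
  for (j in seq_len(ncol(bits))) {
    k <- cm$k[j]
    grid <- as.matrix(expand.grid(rep(list(0:(k - 1)), length(internals))))
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      st <- grid[g, ]
      pr <- 1 / k
      for (e in seq_len(nrow(tree$edge))) {
        pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        P <- mk_transition_matrix(k, mu, tree$age[pa] - tree$age[ch])
        sp <- st[match(pa, internals)]
        if (ch <= n) {
          allowed <- which(bitwAnd(bits[ch, j],
                                   bitwShiftL(1L, 0:(k - 1))) > 0)
          pr <- pr * sum(P[sp + 1, allowed])
        } else {
          pr <- pr * P[sp + 1, st[match(ch, internals)] + 1]
        }
      }
      tot <- tot + pr
    }
    ll <- ll + log(tot)
  }
  ll
}

# random small tree (3-5 tips) containing fossils, with one fossil
# converted to a sampled ancestor where the attachment allows it
rand_small_tree <- function(force_sa = TRUE) {
  p <- fbd_params(origin_T = 15, d = 0.1, r = 0.5, s = 0.6)
  repeat {
    tr <- simulate_fbd_tree(p)
    n <- length(tr$tip_label)
    if (n < 3 || n > 5 || sum(tr$is_fossil) < 1) next
    if (force_sa && !any(is_sampled_ancestor(tr))) {
      parent <- fbdage:::.tree_parents(tr)
      foss <- which(tr$is_fossil)
      done <- FALSE
      for (f in foss) {
        cand <- tr$age[parent[f]]
        if (cand < tr$origin_T && cand > 0) {
          tr$age[f] <- cand
          done <- TRUE
          break
        }
      }
      if (!done) next
    }
    return(tr)
  }
}

# single-lineage birth-death survival/lineage-count simulation (Gillespie
# on counts), the independent oracle for the Kendall probabilities
sim_lineage_count <- function(d, r, t, nsim) {
  lam <- d / (1 - r); mu <- r * d / (1 - r)
  vapply(seq_len(nsim), function(i) {
    k <- 1; tt <- 0
    repeat {
      if (k == 0) return(0L)
      tt <- tt + rexp(1, k * (lam + mu))
      if (tt > t) return(as.integer(k))
      k <- k + if (runif(1) < lam / (lam + mu)) 1L else -1L
    }
  }, integer(1))
}
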
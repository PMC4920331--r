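# MCMC inference of fossil ages, divergence times, clock and FBD
# parameters on a fixed sampled-ancestor topology, and the focal-fossil
# age-estimation procedure.

#' Log density of a sampled-ancestor tree under the FBD process
#'
#' The fossilized birth-death density of a tree with extant samples (all
#' sampled, rho = 1), fossil tip samples and sampled ancestors,
#' conditioned on survival of the process from the origin to the present:
#' `q(T)/(1 - p0_bd(T))` for the origin segment, `lambda q(x)` per
#' bifurcation, `psi p0(y)/q(y)` per fossil tip and `psi` per sampled
#' ancestor, where `q` and `p0` are the birth-death-sampling auxiliary
#' functions and `p0_bd` the plain birth-death extinction probability.
#'
#' @param tree a [sampled_tree].
#' @param params an [fbd_params] with `origin_T >= ` the root age.
#' @return the log density; `-Inf` for states outside the support (e.g.
#'   a fossil age above the origin).
#' @export
fbd_tree_log_density <- function(tree, params) {
  stopifnot(inherits(tree, "sampled_tree"), inherits(params, "fbd_params"))
  rates <- to_canonical_rates(params)
  lambda <- rates[["lambda"]]; mu <- rates[["mu"]]; psi <- rates[["psi"]]
  T <- params$origin_T; d <- params$d; r <- params$r
  n <- length(tree$tip_label)
  root <- n + 1L
  if (n < 2) stop("tree must have at least two tips")
  if (T < tree$age[root]) return(-Inf)
  foss <- which(tree$is_fossil)
  if (any(tree$age[foss] >= T) || any(tree$age[foss] <= 0)) return(-Inf)
  if (length(foss) > 0 && psi == 0) return(-Inf)
  # birth-death-sampling constants (rho = 1)
  c1 <- sqrt((lambda - mu - psi)^2 + 4 * lambda * psi)
  c2 <- (lambda + mu + psi) / c1
  log_q <- function(t) {
    e <- exp(-c1 * t)
    log(4) - c1 * t - 2 * log(e * (1 - c2) + (1 + c2))
  }
  p0_full <- function(t) {
    e <- exp(-c1 * t)
    frac <- (e * (1 - c2) - (1 + c2)) / (e * (1 - c2) + (1 + c2))
    (lambda + mu + psi + c1 * frac) / (2 * lambda)
  }
  sa <- is_sampled_ancestor(tree)
  parent <- .tree_parents(tree)
  # internal nodes hosting a sampled ancestor contribute no speciation
  sa_nodes <- unique(parent[which(sa)])
  internals <- (n + 1L):(2L * n - 1L)
  bif <- setdiff(internals, sa_nodes)
  lp <- log_q(T) - log(1 - extinction_prob_p0(T, d, r))
  # labeled-tree convention: each bifurcation contributes 2*lambda (the
  # two orientations of its children map to the same labeled topology)
  lp <- lp + length(bif) * log(2 * lambda) + sum(log_q(tree$age[bif]))
  tipfoss <- foss[!sa[foss]]
  if (length(tipfoss) > 0) {
    p0y <- p0_full(tree$age[tipfoss])
    if (any(p0y <= 0)) return(-Inf)
    lp <- lp + length(tipfoss) * log(psi) +
      sum(log(p0y)) - sum(log_q(tree$age[tipfoss]))
  }
  if (any(sa)) lp <- lp + sum(sa) * log(psi)
  unname(lp)
}

#' MCMC chain settings
#'
#' @param chain_length number of proposal steps.
#' @param thin record every `thin`-th state.
#' @param burnin_frac fraction of the chain treated as burn-in (proposal
#'   step sizes adapt during burn-in and are frozen afterwards; summaries
#'   discard it).
#' @param clock `"strict"` or `"ucln"` (UCLN samples one lognormal rate
#'   multiplier per branch).
#' @param use_gamma sample a gamma shape for among-character rate
#'   variation.
#' @param gamma_ncat discrete gamma category count.
#' @param sample_prior_only drop the character likelihood (prior-only
#'   chain).
#' @param use_tree_prior include the FBD tree density and the age moves;
#'   disabling both this and the likelihood leaves a chain targeting the
#'   parameter priors alone (a detailed-balance smoke test).
#' @return a list of class `mcmc_config`.
#' @export
mcmc_config <- function(chain_length = 2e5, thin = 200, burnin_frac = 0.25,
                        clock = c("strict", "ucln"), use_gamma = FALSE,
                        gamma_ncat = 4, sample_prior_only = FALSE,
                        use_tree_prior = TRUE) {
  clock <- match.arg(clock)
  stopifnot(chain_length >= thin, thin > 0,
            burnin_frac >= 0, burnin_frac <= 0.9)
  structure(list(chain_length = chain_length, thin = thin,
                 burnin_frac = burnin_frac, clock = clock,
                 use_gamma = use_gamma, gamma_ncat = gamma_ncat,
                 sample_prior_only = sample_prior_only,
                 use_tree_prior = use_tree_prior),
            class = "mcmc_config")
}

# prior coding for the kernel: family code + two parameters per row,
# rows (d, r, s_or_psi, mu_clock, S, alpha, T)
.encode_priors <- function(priors) {
  fam_code <- c(lognormal = 0L, uniform = 1L, gamma = 2L, fixed = 3L)
  enc <- function(dist) {
    code <- fam_code[[dist$family]]
    pars <- switch(dist$family,
      lognormal = c(dist$meanlog, dist$sdlog),
      uniform = c(dist$min, dist$max),
      gamma = c(dist$shape, dist$rate),
      fixed = c(dist$value, 0))
    list(code, pars)
  }
  slots <- list(priors$d, priors$r, priors$s_or_psi, priors$mu_clock,
                priors$S, priors$alpha,
                if (priors$implicit_T) dist_spec("fixed", value = 0) else
                  priors$T_or_N)
  fam <- integer(7); par <- matrix(0, 7, 2)
  for (i in seq_along(slots)) {
    e <- enc(slots[[i]])
    fam[i] <- e[[1]]; par[i, ] <- e[[2]]
  }
  list(fam = fam, par = par)
}

# initial parameter values consistent with the priors and the tree
.init_state <- function(tree, priors, config) {
  root_age <- tree$age[length(tree$tip_label) + 1L]
  d <- dist_median(priors$d)
  if (priors$implicit_T) {
    # keep the implicit origin-support bound log(Nmax)/d above the root
    hi <- log(priors$T_or_N$max)
    if (hi / d < root_age * 1.05) d <- hi / (root_age * 1.1)
    T <- max(root_age * 1.02, min(log(50) / d, hi / d))
  } else {
    T <- max(root_age * 1.02, dist_median(priors$T_or_N))
    sup <- dist_support(priors$T_or_N)
    if (T > sup[2]) T <- (root_age + sup[2]) / 2
    if (T <= root_age) stop("prior support for T excludes the root age")
  }
  r <- min(dist_median(priors$r), 0.95)
  spsi <- dist_median(priors$s_or_psi)
  if (!priors$implicit_s) spsi <- min(spsi, 0.95)
  list(d = d, r = r, spsi = spsi, T = T,
       mu = dist_median(priors$mu_clock),
       S = max(dist_median(priors$S), 1e-3),
       alpha = max(dist_median(priors$alpha), 0.1))
}

#' Run the Metropolis-Hastings sampler
#'
#' Samples fossil ages, divergence times, the sampled-ancestor
#' configuration, FBD parameters and clock parameters at fixed topology.
#' Moves: scale moves on d, psi-or-s, T, the clock mean, S and the gamma
#' shape; a reflected slide on r; uniform-window moves on node and fossil
#' ages within their bounds; a reversible-jump toggle between fossil-tip
#' and sampled-ancestor attachment (the zero-length boundary atom is
#' treated explicitly in the acceptance ratio); and a global scale move on
#' all internal ages and the origin.
#'
#' Non-focal fossil ages are constrained to their stratigraphic ranges;
#' the focal fossil's range is replaced by `[0, T]` (conditioned on the
#' current origin). Chains are deterministic given the R random seed.
#'
#' @param tree a [sampled_tree] providing the fixed reference topology and
#'   initial ages.
#' @param data a [character_matrix], or `NULL` for a characters-free run.
#' @param constraints data.frame (taxon, lower, upper) of stratigraphic
#'   ranges for the fossils; extant taxa may be omitted.
#' @param priors a [prior_spec].
#' @param config an [mcmc_config].
#' @param focal optional taxon id of the focal fossil whose range is
#'   released to `[0, T]`.
#' @param seed optional integer; when given, `set.seed(seed)` is called.
#' @return a list of class `fbd_mcmc` with elements `trace` (data.frame,
#'   one row per recorded state), `acceptance` (per-move proposal and
#'   acceptance counts), `final` (final ages and sampled-ancestor flags)
#'   and `config`.
#' @export
run_mcmc <- function(tree, data = NULL, constraints = NULL,
                     priors = prior_preset("implicit_2016"),
                     config = mcmc_config(), focal = NULL, seed = NULL) {
  stopifnot(inherits(tree, "sampled_tree"), inherits(priors, "prior_spec"),
            inherits(config, "mcmc_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip_label)
  if (n < 2) stop("inference requires at least two tips")
  foss <- which(tree$is_fossil)

  lower <- numeric(n); upper <- numeric(n)
  if (length(foss) > 0) {
    if (is.null(constraints)) stop("fossil taxa need age constraints")
    idx <- match(tree$tip_label[foss], constraints$taxon)
    if (anyNA(idx))
      stop("missing age constraints for: ",
           paste(tree$tip_label[foss][is.na(idx)], collapse = ", "))
    lower[foss] <- constraints$lower[idx]
    upper[foss] <- constraints$upper[idx]
  }
  focal_i <- -1L
  if (!is.null(focal)) {
    focal_i <- match(focal, tree$tip_label)
    if (is.na(focal_i) || !tree$is_fossil[focal_i])
      stop("focal taxon must be a fossil tip: ", focal)
    focal_i <- focal_i - 1L   # 0-based for the kernel
  }

  # initial ages: reference-tree ages, with non-sampled-ancestor fossils
  # nudged to their range mid-points where the attachment allows it
  age <- tree$age
  sa <- is_sampled_ancestor(tree)
  parent <- .tree_parents(tree)
  for (f in foss) {
    if (sa[f] || (f - 1L) == focal_i) next
    mid <- (lower[f] + upper[f]) / 2
    cap <- age[parent[f]]
    cand <- min(max(mid, lower[f]), upper[f], cap * 0.999)
    if (cand > 0 && cand >= lower[f] && cand <= upper[f]) age[f] <- cand
    if (age[f] < lower[f] || age[f] > upper[f])
      stop("initial age for ", tree$tip_label[f],
           " incompatible with its range")
  }

  init <- .init_state(tree, priors, config)
  pc <- .encode_priors(priors)
  if (!is.null(data)) {
    stopifnot(inherits(data, "character_matrix"))
    midx <- match(data$taxa, tree$tip_label)
    if (anyNA(midx)) stop("matrix taxa missing from the tree")
    bits <- matrix(0L, n, ncol(data$data))
    bits[midx, ] <- .cm_bitmask(data)
    kvec <- data$k
  } else {
    bits <- matrix(0L, n, 0)
    kvec <- integer(0)
  }
  nnode <- 2L * n - 1L
  mult0 <- rep(1, nnode)
  Nmin <- if (priors$implicit_T) priors$T_or_N$min else 1
  Nmax <- if (priors$implicit_T) priors$T_or_N$max else 100

  res <- fbd_mcmc_cpp(tree$edge, age, n, tree$is_fossil, sa, focal_i,
                      lower, upper, init$T,
                      bits, as.integer(kvec),
                      c(init$d, init$r, init$spsi, init$mu, init$S,
                        init$alpha),
                      mult0, pc$fam, pc$par,
                      priors$implicit_s, priors$implicit_T, Nmin, Nmax,
                      if (config$clock == "ucln") 1L else 0L,
                      config$use_gamma, config$gamma_ncat,
                      config$use_tree_prior,
                      !config$sample_prior_only,
                      config$chain_length, config$thin, config$burnin_frac)

  trace <- as.data.frame(res$trace)
  names(trace) <- c("iter", "posterior", "likelihood", "prior", "d", "r",
                    "s", "psi", "origin_T", "mu_clock", "S", "alpha",
                    "focal_age", "root_age", "n_sa")
  move_names <- c("scale_d", "slide_r", "scale_spsi", "scale_T", "scale_mu",
                  "scale_S", "slide_alpha", "node_age", "fossil_age",
                  "sa_toggle", "tree_scale", "ucln_mult")
  acc <- data.frame(move = move_names, proposed = res$n_proposed,
                    accepted = res$n_accepted)
  out <- list(trace = trace, acceptance = acc,
              final = list(age = res$final_age, sa = res$final_sa),
              config = config, seed = seed,
              focal = if (focal_i >= 0) tree$tip_label[focal_i + 1L] else NULL)
  class(out) <- "fbd_mcmc"
  out
}

#' @export
print.fbd_mcmc <- function(x, ...) {
  cat(sprintf("FBD MCMC run: %d recorded states (chain length %g)\n",
              nrow(x$trace), x$config$chain_length))
  if (!is.null(x$focal)) cat("  focal fossil:", x$focal, "\n")
  acc <- x$acceptance
  acc <- acc[acc$proposed > 0, ]
  cat(sprintf("  acceptance: %s\n",
              paste(sprintf("%s %.2f", acc$move, acc$accepted / acc$proposed),
                    collapse = ", ")))
  invisible(x)
}

# post-burn-in rows of a trace
.post_burnin <- function(run) {
  trace <- run$trace
  cut <- run$config$burnin_frac * run$config$chain_length
  trace[trace$iter > cut, , drop = FALSE]
}

#' Joint log posterior of a model state
#'
#' Sum of the Lewis-Mk log-likelihood, the FBD tree log density, the
#' parameter log priors and the stratigraphic-range indicator (`-Inf`
#' when any non-focal fossil age leaves its range). The components are
#' returned separately alongside the total.
#'
#' @param tree a [sampled_tree] carrying the state's node and fossil ages.
#' @param params an [fbd_params].
#' @param clock clock model (see [tree_log_likelihood]).
#' @param data a [character_matrix] or `NULL` (likelihood 0).
#' @param constraints stratigraphic ranges (taxon, lower, upper).
#' @param priors a [prior_spec].
#' @param model an [mk_model_config].
#' @param focal optional focal taxon id exempted from its range.
#' @return list with `log_likelihood`, `log_tree_prior`, `log_param_prior`,
#'   `log_posterior`.
#' @export
log_posterior <- function(tree, params, clock, data = NULL,
                          constraints = NULL,
                          priors = prior_preset("implicit_2016"),
                          model = mk_model_config(), focal = NULL) {
  ll <- if (is.null(data)) 0 else
    tree_log_likelihood(tree, data, model, clock)
  lt <- fbd_tree_log_density(tree, params)
  lp <- 0
  lp <- lp + dist_logdens(priors$d, params$d)
  lp <- lp + dist_logdens(priors$r, params$r)
  rates <- to_canonical_rates(params)
  if (priors$implicit_s) {
    lp <- lp + dist_logdens(priors$s_or_psi, rates[["psi"]])
  } else {
    lp <- lp + dist_logdens(priors$s_or_psi, params$s)
  }
  if (priors$implicit_T) {
    d <- params$d
    lo <- log(max(priors$T_or_N$min, 1)) / d
    hi <- log(priors$T_or_N$max) / d
    lp <- lp + if (params$origin_T < lo || params$origin_T > hi) -Inf else
      log(d) + d * params$origin_T - log(priors$T_or_N$max - priors$T_or_N$min)
  } else {
    lp <- lp + dist_logdens(priors$T_or_N, params$origin_T)
  }
  lp <- lp + dist_logdens(priors$mu_clock, clock$mu)
  # range indicator
  if (!is.null(constraints)) {
    foss <- which(tree$is_fossil)
    for (f in foss) {
      taxon <- tree$tip_label[f]
      if (!is.null(focal) && taxon == focal) next
      i <- match(taxon, constraints$taxon)
      if (is.na(i)) stop("no age constraint for fossil ", taxon)
      if (tree$age[f] < constraints$lower[i] ||
          tree$age[f] > constraints$upper[i]) lp <- -Inf
    }
  }
  list(log_likelihood = ll, log_tree_prior = lt, log_param_prior = lp,
       log_posterior = ll + lt + lp)
}

#' Phylogenetic estimate of a focal fossil's age
#'
#' Runs the sampler with the focal fossil's stratigraphic constraint
#' replaced by the FBD prior (range `[0, T]`) and summarizes the marginal
#' posterior of its age.
#'
#' @inheritParams run_mcmc
#' @param focal taxon id of the focal fossil.
#' @return a list of class `fossil_age_estimate` with the posterior
#'   `median`, `hpd` (95% interval), `sd`, `ess`, the focal age `samples`
#'   (post burn-in) and the full `run`.
#' @export
estimate_focal_fossil_age <- function(tree, data, constraints, priors,
                                      focal, config = mcmc_config(),
                                      seed = NULL) {
  run <- run_mcmc(tree, data, constraints, priors, config, focal = focal,
                  seed = seed)
  post <- .post_burnin(run)
  samples <- post$focal_age
  est <- list(taxon = focal,
              median = median(samples),
              hpd = hpd_interval(samples, 0.95),
              sd = sd(samples),
              ess = ess(samples),
              samples = samples,
              run = run)
  class(est) <- "fossil_age_estimate"
  est
}

#' @export
print.fossil_age_estimate <- function(x, ...) {
  cat(sprintf("%s: phylogenetic age %.2f Myr (95%% HPD %.2f-%.2f), ESS %.0f\n",
              x$taxon, x$median, x$hpd[1], x$hpd[2], x$ess))
  invisible(x)
}
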
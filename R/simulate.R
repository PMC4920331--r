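# Forward simulation of the fossilized birth-death process and of
# Lewis-Mk character evolution; the synthetic-data source for all tests.

# Simulate the complete (unsampled) birth-death genealogy from the origin.
# Lineages are edges: each row has a birth age, an end age (0 if it
# reaches the present), a parent lineage and up to two children.
.sim_bd_lineages <- function(lambda, mu, origin_T, lineage_cap = 1e5) {
  birth <- origin_T; end <- NA_real_; parent <- 0L; alive <- FALSE
  child1 <- 0L; child2 <- 0L
  stack <- 1L
  total <- lambda + mu
  while (length(stack) > 0) {
    i <- stack[length(stack)]; stack <- stack[-length(stack)]
    t <- birth[i]
    dt <- if (total > 0) rexp(1, total) else Inf
    t2 <- t - dt
    if (t2 <= 0) {
      end[i] <- 0; alive[i] <- TRUE
    } else if (runif(1) < lambda / total) {
      end[i] <- t2
      j <- length(birth) + 1L
      birth[j:(j + 1)] <- t2; end[j:(j + 1)] <- NA_real_
      parent[j:(j + 1)] <- i; alive[j:(j + 1)] <- FALSE
      child1[j:(j + 1)] <- 0L; child2[j:(j + 1)] <- 0L
      child1[i] <- j; child2[i] <- j + 1L
      stack <- c(stack, j, j + 1L)
      if (length(birth) > lineage_cap)
        stop("birth-death simulation exceeded the lineage cap (explosion)")
    } else {
      end[i] <- t2; alive[i] <- FALSE
    }
  }
  list(birth = birth, end = end, parent = parent, alive = alive,
       child1 = child1, child2 = child2)
}

#' Simulate a tree under the fossilized birth-death process
#'
#' Forward birth-death simulation with rates `lambda`, `mu` from the
#' origin to the present, Poisson fossilization at rate `psi` along every
#' lineage (surviving or extinct), and pruning to the sampled taxa: all
#' extant lineages plus every fossilization event. Fossils on lineages
#' with sampled descendants become sampled ancestors (zero-length
#' branches).
#'
#' @param params an [fbd_params] object.
#' @param condition_on_survival if `TRUE` (default), rejection-sample
#'   until at least one lineage survives to the present.
#' @param lineage_cap abort threshold for explosive parameter draws.
#' @return a [sampled_tree], or `NULL` when the process dies without
#'   leaving any sample and `condition_on_survival = FALSE`. A tree with a
#'   single sample is returned as a degenerate one-tip tree.
#' @export
simulate_fbd_tree <- function(params, condition_on_survival = TRUE,
                              lineage_cap = 1e5) {
  stopifnot(inherits(params, "fbd_params"))
  rates <- to_canonical_rates(params)
  repeat {
    lin <- .sim_bd_lineages(rates[["lambda"]], rates[["mu"]],
                            params$origin_T, lineage_cap)
    if (condition_on_survival && !any(lin$alive)) next
    tree <- .build_sampled_tree(lin, rates[["psi"]], params$origin_T)
    if (!condition_on_survival || !is.null(tree)) return(tree)
  }
}

# Prune the complete genealogy to sampled nodes. Returns NULL if nothing
# was sampled. Fossil events are drawn here (Poisson along each lineage).
.build_sampled_tree <- function(lin, psi, origin_T) {
  nlin <- length(lin$birth)
  fossils <- vector("list", nlin)
  if (psi > 0) {
    for (i in seq_len(nlin)) {
      dur <- lin$birth[i] - lin$end[i]
      nf <- rpois(1, psi * dur)
      if (nf > 0) fossils[[i]] <- sort(runif(nf, lin$end[i], lin$birth[i]))
    }
  }
  # nested structure: tip = list(age, fossil); node = list(age, l, r)
  subtree <- function(i) {
    base <- NULL
    if (lin$alive[i]) {
      base <- list(tip = TRUE, age = 0, fossil = FALSE)
    } else if (lin$child1[i] > 0) {
      b1 <- subtree(lin$child1[i])
      b2 <- subtree(lin$child2[i])
      if (!is.null(b1) && !is.null(b2)) {
        base <- list(tip = FALSE, age = lin$end[i], l = b1, r = b2)
      } else if (!is.null(b1)) base <- b1 else base <- b2
    }
    for (y in fossils[[i]]) {     # ascending age: youngest first
      ftip <- list(tip = TRUE, age = y, fossil = TRUE)
      if (is.null(base)) base <- ftip
      else base <- list(tip = FALSE, age = y, l = base, r = ftip)
    }
    base
  }
  root <- subtree(1L)
  if (is.null(root)) return(NULL)
  # flatten: count tips, then assign indices (tips 1..n in preorder,
  # internals n+1.. with the root first)
  count_tips <- function(nd) if (nd$tip) 1L else
    count_tips(nd$l) + count_tips(nd$r)
  n <- count_tips(root)
  if (n == 1) {
    return(structure(list(edge = matrix(integer(0), 0, 2),
                          age = root$age, tip_label = if (root$fossil)
                            "fossil_1" else "extant_1",
                          is_fossil = root$fossil, origin_T = origin_T),
                     class = "sampled_tree"))
  }
  age <- numeric(2 * n - 1)
  is_fossil <- logical(n)
  edge <- matrix(0L, 2 * n - 2, 2)
  env <- new.env()
  env$tip_i <- 0L; env$int_i <- n; env$edge_i <- 0L
  assign_ids <- function(nd) {
    if (nd$tip) {
      env$tip_i <- env$tip_i + 1L
      id <- env$tip_i
      age[id] <<- nd$age; is_fossil[id] <<- nd$fossil
      return(id)
    }
    env$int_i <- env$int_i + 1L
    id <- env$int_i
    age[id] <<- nd$age
    for (ch in list(nd$l, nd$r)) {
      cid <- assign_ids(ch)
      env$edge_i <- env$edge_i + 1L
      edge[env$edge_i, ] <<- c(id, cid)
    }
    id
  }
  assign_ids(root)
  nf <- cumsum(is_fossil); ne <- cumsum(!is_fossil)
  tip_label <- ifelse(is_fossil, paste0("fossil_", nf), paste0("extant_", ne))
  sampled_tree(edge = edge, age = age, tip_label = tip_label,
               is_fossil = is_fossil, origin_T = origin_T)
}

#' Simulate discrete characters under the Lewis-Mk model
#'
#' Each character evolves independently along the tree under the k-state
#' symmetric Markov process, with the root state drawn uniformly. The
#' expected number of changes per Myr on a branch is the branch rate times
#' the character's site-rate multiplier; the Mk generator is normalized so
#' that the rate is the expected change rate at stationarity.
#'
#' @param tree a [sampled_tree].
#' @param n_chars number of characters.
#' @param state_counts integer vector of state counts `k >= 2`, recycled
#'   to `n_chars`.
#' @param clock list with `kind` (`"strict"` or `"ucln"`), `mu` (mean rate
#'   in changes per Myr) and, for `"ucln"`, `S` (log standard deviation);
#'   UCLN branch rates are independent lognormals with real-space mean `mu`.
#' @param gamma_alpha optional gamma shape; site-rate multipliers are
#'   drawn from `Gamma(alpha, alpha)` (mean 1). `NULL` for equal rates.
#' @param missing_rate per-taxon probability that an entry is replaced by
#'   the missing code `"?"`; scalar or vector over tips.
#' @return a [character_matrix].
#' @export
simulate_characters <- function(tree, n_chars, state_counts = 2,
                                clock = list(kind = "strict", mu = 0.02),
                                gamma_alpha = NULL, missing_rate = 0) {
  stopifnot(inherits(tree, "sampled_tree"), n_chars >= 1)
  k <- rep_len(as.integer(state_counts), n_chars)
  if (any(k < 2)) stop("all state counts must be >= 2")
  n <- length(tree$tip_label)
  nn <- length(tree$age)
  nedge <- nrow(tree$edge)
  rate_branch <- switch(clock$kind,
    strict = rep(clock$mu, nedge),
    ucln = clock$mu * rlnorm(nedge, -clock$S^2 / 2, clock$S),
    stop("unknown clock kind ", clock$kind))
  rate_site <- if (is.null(gamma_alpha)) rep(1, n_chars) else
    rgamma(n_chars, shape = gamma_alpha, rate = gamma_alpha)
  states <- matrix(0L, nn, n_chars)
  root <- if (n >= 2) n + 1L else 1L
  states[root, ] <- vapply(k, function(ki) sample.int(ki, 1) - 1L, integer(1))
  if (nedge > 0) {
    # preorder: parents before children (root-first index assignment
    # guarantees edges sorted by parent do this; sort to be safe)
    ord <- order(tree$edge[, 1])
    for (e in ord) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      dur <- tree$age[par] - tree$age[ch]
      m <- dur * rate_branch[e] * rate_site
      p_same <- 1 / k + (k - 1) / k * exp(-k / (k - 1) * m)
      same <- runif(n_chars) < p_same
      shift <- vapply(k, function(ki) sample.int(ki - 1L, 1), integer(1))
      states[ch, ] <- ifelse(same, states[par, ],
                             (states[par, ] + shift) %% k)
    }
  }
  tip_states <- matrix(as.character(states[seq_len(n), , drop = FALSE]),
                       n, n_chars)
  missing_rate <- rep_len(missing_rate, n)
  for (i in seq_len(n)) {
    if (missing_rate[i] > 0) {
      miss <- runif(n_chars) < missing_rate[i]
      tip_states[i, miss] <- "?"
    }
  }
  rownames(tip_states) <- tree$tip_label
  character_matrix(tip_states, k = k)
}

#' Stratigraphic age ranges around true fossil ages
#'
#' Builds an interval for each fossil tip that contains its true age:
#' `[c - hw, c + hw]` clipped at 0, where `hw` is the half width (absolute
#' Myr, or a fraction of the true age when `relative = TRUE`) and the
#' centre `c` is the true age, optionally jittered uniformly within
#' `hw` so that the interval mid-point need not equal the true age.
#'
#' @param tree a [sampled_tree].
#' @param half_width interval half width (`>= 0`).
#' @param relative interpret `half_width` as a fraction of the true age.
#' @param jitter jitter the interval centre uniformly in
#'   `[-half_width, half_width]` around the true age.
#' @return data.frame with columns `taxon`, `lower`, `upper` (class
#'   `age_constraints`); every interval contains the true age.
#' @export
make_age_ranges <- function(tree, half_width, relative = FALSE,
                            jitter = FALSE) {
  stopifnot(half_width >= 0)
  foss <- which(tree$is_fossil)
  ages <- tree$age[foss]
  hw <- if (relative) half_width * ages else rep(half_width, length(foss))
  centre <- ages
  if (jitter) centre <- ages + runif(length(foss), -hw, hw)
  out <- data.frame(taxon = tree$tip_label[foss],
                    lower = pmax(0, centre - hw),
                    upper = centre + hw,
                    stringsAsFactors = FALSE)
  class(out) <- c("age_constraints", "data.frame")
  out
}

# state-count mixes emulating the empirical matrices: most characters
# binary or three-state, a thin tail up to k = 7 (penguin-like, 202
# characters, > 95% with k <= 3) or k = 5 (canid-like, 122 characters)
.preset_state_counts <- function(name) {
  switch(name,
    penguin_like = rep(c(2L, 3L, 4L, 5L, 6L, 7L), c(110, 84, 4, 2, 1, 1)),
    canid_like = rep(c(2L, 3L, 4L, 5L), c(70, 40, 8, 4)))
}

.preset_config <- function(name) {
  switch(name,
    # targets: ~19 extant + ~36 fossil taxa; clock per the penguin
    # strict-clock rate estimate (~1.8e-2 changes/Myr)
    penguin_like = list(
      params = fbd_params(origin_T = 60, d = 0.042, r = 0.55, s = 0.62),
      clock = list(kind = "strict", mu = 0.018),
      extant_target = 19, fossil_target = 36, extant_exact = FALSE,
      half_width = 2.5),
    # targets: exactly 9 extant, ~116 fossil taxa; faster clock
    canid_like = list(
      params = fbd_params(origin_T = 38, d = 0.042, r = 0.65, s = 0.90),
      clock = list(kind = "strict", mu = 0.0283),
      extant_target = 9, fossil_target = 116, extant_exact = TRUE,
      half_width = 1.5))
}

#' Simulated datasets emulating the empirical study systems
#'
#' Draws an FBD tree, an Mk character matrix and stratigraphic age ranges
#' with dimensions emulating the two empirical datasets: `"penguin_like"`
#' (~55 taxa, 202 characters, > 95% of characters with fewer than four
#' states, k up to 7) and `"canid_like"` (~125 taxa with exactly 9 extant,
#' 122 characters, k up to 5). FBD parameters are calibrated so that
#' simulated taxon counts hit the targets; trees are redrawn until both
#' counts fall within +/-20% of target (extant exactly 9 for
#' `"canid_like"`).
#'
#' @param name `"penguin_like"` or `"canid_like"`.
#' @param n_chars optionally override the number of characters (scaled
#'   presets for faster experiments).
#' @param max_tries rejection cap for the taxon-count targets.
#' @return list with elements `tree`, `matrix`, `ranges`, `params`,
#'   `clock`.
#' @export
fixture_preset <- function(name = c("penguin_like", "canid_like"),
                           n_chars = NULL, max_tries = 1000) {
  name <- match.arg(name)
  cfg <- .preset_config(name)
  ks <- .preset_state_counts(name)
  if (!is.null(n_chars)) ks <- rep_len(ks, n_chars)
  lo_f <- ceiling(cfg$fossil_target * 0.8)
  hi_f <- floor(cfg$fossil_target * 1.2)
  for (i in seq_len(max_tries)) {
    tree <- simulate_fbd_tree(cfg$params)
    n_ext <- sum(!tree$is_fossil); n_fos <- sum(tree$is_fossil)
    ok_ext <- if (cfg$extant_exact) n_ext == cfg$extant_target else
      abs(n_ext - cfg$extant_target) <= 0.2 * cfg$extant_target
    if (ok_ext && n_fos >= lo_f && n_fos <= hi_f) {
      mat <- simulate_characters(tree, n_chars = length(ks),
                                 state_counts = ks, clock = cfg$clock)
      ranges <- make_age_ranges(tree, half_width = cfg$half_width)
      return(list(tree = tree, matrix = mat, ranges = ranges,
                  params = cfg$params, clock = cfg$clock))
    }
  }
  stop("could not hit the preset taxon-count targets in ", max_tries,
       " tries")
}
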
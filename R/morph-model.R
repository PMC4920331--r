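# Lewis-Mk likelihood machinery: state-count partitioning, transition
# probabilities, discrete-gamma rate heterogeneity, relaxed-clock branch
# rates and the pruning likelihood on sampled-ancestor time trees.

#' Partition characters by observed state count
#'
#' Groups characters by the number of distinct states observed across the
#' sampled taxa; partition `i` holds the characters with `i + 1` observed
#' states. Characters that are constant or entirely missing are assigned
#' the minimal state space (`k = 2`) rather than dropped. Character order
#' is preserved within partitions.
#'
#' @param matrix a [character_matrix].
#' @return named list of [character_matrix] objects (`"k2"`, `"k3"`, ...),
#'   each with an attribute `chars` giving the original column indices.
#' @export
partition_by_state_count <- function(matrix) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (ncol(matrix$data) == 0) stop("empty character matrix")
  obs <- pmax(observed_state_counts(matrix), 2L)
  out <- list()
  for (kk in sort(unique(obs))) {
    idx <- which(obs == kk)
    sub <- subset_characters(matrix, idx)
    sub$k <- rep(as.integer(kk), length(idx))
    attr(sub, "chars") <- idx
    out[[paste0("k", kk)]] <- sub
  }
  out
}

#' Lewis-Mk transition probability matrix
#'
#' The k-state symmetric Markov process with generator normalized so that
#' `rate` is the expected number of state changes per unit time at
#' stationarity: `P_ii(t) = 1/k + (k-1)/k exp(-k/(k-1) rate t)`, all
#' off-diagonal entries equal.
#'
#' @param k number of states (`>= 2`).
#' @param rate expected changes per unit time (`>= 0`).
#' @param t elapsed time (`>= 0`).
#' @return a `k x k` stochastic matrix.
#' @export
mk_transition_matrix <- function(k, rate, t) {
  stopifnot(k >= 2, rate >= 0, t >= 0)
  e <- exp(-k / (k - 1) * rate * t)
  p_same <- 1 / k + (k - 1) / k * e
  p_diff <- 1 / k - 1 / k * e
  P <- matrix(p_diff, k, k)
  diag(P) <- p_same
  P
}

#' Discrete-gamma site-rate multipliers
#'
#' Mean-one rate multipliers from `ncat` equal-probability categories of
#' the `Gamma(alpha, alpha)` distribution, each category represented by
#' its mean.
#'
#' @param alpha gamma shape (> 0).
#' @param ncat number of categories (`>= 1`).
#' @return nondecreasing numeric vector of length `ncat` with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, ncat = 4) {
  stopifnot(alpha > 0, ncat >= 1)
  if (ncat == 1) return(1)
  bounds <- qgamma(seq(0, 1, length.out = ncat + 1), shape = alpha,
                   rate = alpha)
  # E[X | a < X <= b] for Gamma(alpha, alpha) via the shape+1 identity
  cum <- pgamma(bounds, shape = alpha + 1, rate = alpha)
  ncat * diff(cum)
}

#' Uncorrelated-lognormal relaxed-clock branch rates
#'
#' Branch rates are lognormal quantiles parameterized so that the
#' real-space mean of the rate distribution is `mu` and the log standard
#' deviation is `S`; `S = 0` collapses to the strict clock.
#'
#' @param mu mean rate (changes per Myr, > 0).
#' @param S log standard deviation (`>= 0`).
#' @param quantiles per-branch quantiles in (0, 1).
#' @return numeric vector of branch rates.
#' @export
ucln_branch_rates <- function(mu, S, quantiles) {
  stopifnot(mu > 0, S >= 0, all(quantiles > 0 & quantiles < 1))
  if (S == 0) return(rep(mu, length(quantiles)))
  qlnorm(quantiles, meanlog = log(mu) - S^2 / 2, sdlog = S)
}

#' Mk model configuration
#'
#' @param partition `"single"` or `"by_state_count"` (likelihoods are
#'   summed over partitions in log space; partitioning by state count is
#'   implied by the per-character state counts and recorded here for the
#'   reporting layer).
#' @param gamma_alpha gamma shape for among-character rate variation, or
#'   `NULL` for equal rates.
#' @param gamma_ncat number of discrete gamma categories.
#' @param ascertainment `"none"` or `"variable"` (Lewis's Mkv correction,
#'   conditioning on characters being variable).
#' @return an object of class `mk_model_config`.
#' @export
mk_model_config <- function(partition = c("single", "by_state_count"),
                            gamma_alpha = NULL, gamma_ncat = 4,
                            ascertainment = c("none", "variable")) {
  partition <- match.arg(partition)
  ascertainment <- match.arg(ascertainment)
  if (!is.null(gamma_alpha)) stopifnot(gamma_alpha > 0)
  stopifnot(gamma_ncat >= 1)
  structure(list(partition = partition, gamma_alpha = gamma_alpha,
                 gamma_ncat = gamma_ncat, ascertainment = ascertainment),
            class = "mk_model_config")
}

# resolve per-edge rates from a clock model
.edge_rates <- function(clock, nedge) {
  if (clock$kind == "strict") return(rep(clock$mu, nedge))
  if (clock$kind == "ucln") {
    if (!is.null(clock$rates)) {
      stopifnot(length(clock$rates) == nedge)
      return(clock$rates)
    }
    if (isTRUE(clock$S == 0)) return(rep(clock$mu, nedge))
    stop("ucln clock needs explicit per-branch rates (or S = 0)")
  }
  stop("unknown clock kind ", clock$kind)
}

#' Lewis-Mk log-likelihood of a character matrix on a time tree
#'
#' Felsenstein pruning over every character with uniform root state
#' frequencies `1/k`. Missing entries contribute an all-ones partial
#' likelihood; polymorphic cells are ambiguity over the listed states;
#' sampled ancestors sit on zero-length terminal branches and contribute
#' their observed state directly. Gamma rate categories are averaged with
#' equal weight, and per-character log-likelihoods (partitions) are summed
#' in log space. With `ascertainment = "variable"` each character's
#' likelihood is divided by the probability of being variable.
#'
#' @param tree a [sampled_tree] whose tips cover the matrix taxa.
#' @param matrix a [character_matrix].
#' @param model an [mk_model_config].
#' @param clock clock model: list with `kind` (`"strict"`/`"ucln"`), `mu`,
#'   and for `"ucln"` either `S = 0` or explicit per-branch `rates`.
#' @return the log-likelihood (scalar).
#' @export
tree_log_likelihood <- function(tree, matrix, model = mk_model_config(),
                                clock = list(kind = "strict", mu = 0.02)) {
  stopifnot(inherits(tree, "sampled_tree"),
            inherits(matrix, "character_matrix"))
  idx <- match(matrix$taxa, tree$tip_label)
  if (anyNA(idx))
    stop("taxa missing from the tree: ",
         paste(matrix$taxa[is.na(idx)], collapse = ", "))
  n <- length(tree$tip_label)
  if (length(idx) != n)
    stop("tree tips not covered by the matrix: ",
         paste(setdiff(tree$tip_label, matrix$taxa), collapse = ", "))
  bits <- matrix(0L, n, ncol(matrix$data))
  bits[idx, ] <- .cm_bitmask(matrix)
  nedge <- nrow(tree$edge)
  rates <- .edge_rates(clock, nedge)
  grates <- if (is.null(model$gamma_alpha)) 1 else
    discrete_gamma_rates(model$gamma_alpha, model$gamma_ncat)
  ll <- mk_loglik_cpp(tree$edge, tree$age, n, bits, matrix$k,
                      rates, grates,
                      model$ascertainment == "variable")
  if (!is.finite(ll)) {
    perchar <- vapply(seq_len(ncol(matrix$data)), function(j)
      mk_loglik_cpp(tree$edge, tree$age, n, bits[, j, drop = FALSE],
                    matrix$k[j], rates, grates,
                    model$ascertainment == "variable"), numeric(1))
    stop("non-finite log-likelihood at character(s) ",
         paste(which(!is.finite(perchar)), collapse = ", "))
  }
  ll
}
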
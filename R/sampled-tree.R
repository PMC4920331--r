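# Sampled-ancestor time-tree container. Tips are numbered 1..n, internal
# nodes (n+1)..(2n-1) with the root at n+1 (ape edge-matrix convention).
# Every fossil is represented as a tip; a sampled ancestor is a fossil tip
# attached by a zero-length branch, i.e. its age equals its parent's age.

#' Construct a sampled-ancestor time tree
#'
#' @param edge two-column integer matrix of (parent, child) node indices.
#' @param age numeric vector of node ages in Myr before present, tips
#'   first; extant tips have age 0, fossil tips positive ages.
#' @param tip_label character vector of tip names.
#' @param is_fossil logical vector over tips.
#' @param origin_T origin of the FBD process, `>=` the root age.
#' @return an object of class `sampled_tree`.
#' @export
sampled_tree <- function(edge, age, tip_label, is_fossil, origin_T) {
  tr <- structure(list(edge = edge, age = age, tip_label = tip_label,
                       is_fossil = is_fossil, origin_T = origin_T),
                  class = "sampled_tree")
  validate_sampled_tree(tr)
  tr
}

#' Validate the invariants of a sampled tree
#'
#' Checks that extant tips sit at age 0, fossil ages lie in
#' `(0, origin_T)`, every parent is at least as old as its child (strictly
#' older except for zero-length sampled-ancestor attachments), and the
#' origin is at least as old as the root.
#'
#' @param tree a [sampled_tree].
#' @param tol age comparison tolerance.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_sampled_tree <- function(tree, tol = 1e-9) {
  n <- length(tree$tip_label)
  stopifnot(length(tree$is_fossil) == n)
  if (anyDuplicated(tree$tip_label)) stop("duplicate tip labels")
  if (n >= 2) {
    stopifnot(nrow(tree$edge) == 2 * n - 2,
              length(tree$age) == 2 * n - 1)
  }
  extant <- which(!tree$is_fossil)
  if (any(abs(tree$age[extant]) > tol)) stop("extant tips must have age 0")
  foss <- which(tree$is_fossil)
  if (any(tree$age[foss] <= 0) || any(tree$age[foss] >= tree$origin_T))
    stop("fossil tip ages must lie in (0, origin_T)")
  if (nrow(tree$edge) > 0) {
    dur <- tree$age[tree$edge[, 1]] - tree$age[tree$edge[, 2]]
    if (any(dur < -tol)) stop("parent ages must be >= child ages")
    # zero-length terminal branches are only legal for fossils (sampled
    # ancestors); zero-length internal branches are degenerate
    zero <- which(dur <= tol)
    bad <- zero[!(tree$edge[zero, 2] %in% foss)]
    if (length(bad) > 0) stop("zero-length branch to a non-fossil node")
  }
  root <- n + 1L
  if (n >= 2 && tree$origin_T < tree$age[root] - tol)
    stop("origin_T must be >= root age")
  invisible(TRUE)
}

#' Identify sampled ancestors
#'
#' A fossil tip is a sampled ancestor when it is attached by a zero-length
#' branch, i.e. its age equals its parent's age.
#'
#' @param tree a [sampled_tree].
#' @param tol age comparison tolerance.
#' @return logical vector over tips.
#' @export
is_sampled_ancestor <- function(tree, tol = 1e-9) {
  n <- length(tree$tip_label)
  out <- logical(n)
  if (nrow(tree$edge) == 0) return(out)
  parent <- integer(2 * n - 1)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  tips <- seq_len(n)
  has_par <- parent[tips] != 0
  out[has_par] <- tree$is_fossil[has_par] &
    abs(tree$age[parent[tips[has_par]]] - tree$age[tips[has_par]]) <= tol
  out
}

#' Convert a sampled tree to an ape "phylo" object
#'
#' Branch lengths are age differences; sampled ancestors become
#' zero-length terminal branches. The origin segment above the root is
#' stored in `root.edge`.
#'
#' @param x a [sampled_tree].
#' @param ... unused.
#' @return an object of class `phylo`.
#' @export
as.phylo.sampled_tree <- function(x, ...) {
  n <- length(x$tip_label)
  phy <- list(edge = x$edge,
              edge.length = x$age[x$edge[, 1]] - x$age[x$edge[, 2]],
              tip.label = x$tip_label,
              Nnode = n - 1L,
              root.edge = x$origin_T - x$age[n + 1L])
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy
}

#' @export
print.sampled_tree <- function(x, ...) {
  n <- length(x$tip_label)
  sa <- sum(is_sampled_ancestor(x))
  cat(sprintf(
    "Sampled-ancestor time tree: %d tips (%d extant, %d fossil, %d sampled ancestors)\n",
    n, sum(!x$is_fossil), sum(x$is_fossil), sa))
  if (n >= 2)
    cat(sprintf("  root age %.3f Myr, origin %.3f Myr\n",
                x$age[n + 1L], x$origin_T))
  invisible(x)
}

# parent index lookup (0 for the root)
.tree_parents <- function(tree) {
  nn <- length(tree$age)
  parent <- integer(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

#' Write a sampled tree in Newick format
#'
#' Ages are encoded in branch lengths; sampled ancestors appear as
#' zero-length terminal branches and the origin segment as the root edge.
#'
#' @param tree a [sampled_tree].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sampled_tree_newick <- function(tree, path) {
  ape::write.tree(as.phylo.sampled_tree(tree), file = path)
  invisible(path)
}
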
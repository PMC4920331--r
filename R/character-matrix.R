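# Discrete morphological character matrix. Cells are symbol strings:
# "0".."9" for states, "?" for missing, "{02}" for polymorphic/ambiguous
# observations (ambiguity over the listed states).

#' Construct a character matrix
#'
#' @param data character matrix (taxa x characters) of symbols; row names
#'   are taxon ids.
#' @param k optional integer vector of declared state counts per
#'   character; defaults to the observed distinct-state count (at least
#'   one more than the largest observed code), with constant or
#'   all-missing characters assigned `k = 2`.
#' @return an object of class `character_matrix` with fields `taxa`,
#'   `data` and `k`.
#' @export
character_matrix <- function(data, k = NULL) {
  stopifnot(is.matrix(data), is.character(data))
  taxa <- rownames(data)
  if (is.null(taxa)) stop("data must have taxon row names")
  if (anyDuplicated(taxa)) stop("duplicate taxon ids")
  obs <- apply(data, 2, function(col) length(.observed_states(col)))
  if (is.null(k)) {
    # the state space must cover the largest observed code, which can
    # exceed the distinct-state count when codes are sparse (e.g. {0, 2})
    maxcode <- apply(data, 2, function(col) {
      st <- .observed_states(col)
      if (length(st) == 0) -1L else max(st)
    })
    k <- pmax(obs, maxcode + 1L, 2L)
  } else {
    k <- rep_len(as.integer(k), ncol(data))
    if (any(k < 2)) stop("declared state counts must be >= 2")
  }
  # every observed state code must fit the declared state space
  for (j in seq_len(ncol(data))) {
    st <- .observed_states(data[, j])
    if (length(st) > 0 && max(st) >= k[j])
      stop("character ", j, " has observed state ", max(st),
           " >= declared k = ", k[j])
  }
  structure(list(taxa = taxa, data = data, k = as.integer(k)),
            class = "character_matrix")
}

# distinct observed state codes in one character column (integer vector);
# polymorphic sets contribute their listed states, "?" contributes none
.observed_states <- function(col) {
  states <- integer(0)
  for (cell in col) {
    if (cell == "?" || cell == "-") next
    states <- c(states, .cell_states(cell))
  }
  sort(unique(states))
}

.cell_states <- function(cell) {
  if (grepl("^[{(]", cell)) {
    digits <- strsplit(gsub("[{}()]", "", cell), "")[[1]]
    as.integer(digits)
  } else {
    as.integer(cell)
  }
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("Character matrix: %d taxa x %d characters (k in %d..%d)\n",
              length(x$taxa), ncol(x$data), min(x$k), max(x$k)))
  miss <- mean(x$data == "?")
  cat(sprintf("  missing entries: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Observed distinct-state counts per character
#'
#' @param matrix a [character_matrix].
#' @return integer vector of observed state counts (0 for all-missing).
#' @export
observed_state_counts <- function(matrix) {
  stopifnot(inherits(matrix, "character_matrix"))
  unname(apply(matrix$data, 2, function(col) length(.observed_states(col))))
}

#' Count non-ambiguous characters per taxon
#'
#' Number of characters in which a taxon is coded with a single
#' unambiguous state (not missing, not polymorphic).
#'
#' @param matrix a [character_matrix].
#' @return named integer vector over taxa.
#' @export
nonambiguous_counts <- function(matrix) {
  stopifnot(inherits(matrix, "character_matrix"))
  out <- apply(matrix$data, 1, function(row)
    sum(grepl("^[0-9]$", row)))
  names(out) <- matrix$taxa
  out
}

# bitmask encoding used by the pruning likelihood: bit j set iff state j
# is compatible with the observation; "?" is compatible with everything
.cm_bitmask <- function(matrix) {
  n <- length(matrix$taxa); m <- ncol(matrix$data)
  out <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    full <- bitwShiftL(1L, matrix$k[j]) - 1L
    for (i in seq_len(n)) {
      cell <- matrix$data[i, j]
      if (cell == "?" || cell == "-") {
        out[i, j] <- full
      } else {
        bits <- 0L
        for (s in .cell_states(cell)) bits <- bitwOr(bits, bitwShiftL(1L, s))
        out[i, j] <- bits
      }
    }
  }
  out
}

#' Subset a character matrix by character index
#'
#' @param matrix a [character_matrix].
#' @param chars integer vector of character columns to keep.
#' @return a [character_matrix].
#' @export
subset_characters <- function(matrix, chars) {
  stopifnot(inherits(matrix, "character_matrix"))
  character_matrix(matrix$data[, chars, drop = FALSE], k = matrix$k[chars])
}
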
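# Readers and writers: NEXUS standard character matrices, stratigraphic
# age-range tables, and BEAST-style tab-separated trace logs.

#' Read a NEXUS standard-datatype character matrix
#'
#' Parses a NEXUS DATA/CHARACTERS block (datatype standard, symbols
#' 0-9, missing `?`), with polymorphic cells (`{01}` or `(01)`) kept as
#' ambiguity over the listed states. State counts are the observed
#' distinct-state counts (constant or all-missing characters resolve to
#' `k = 2`).
#'
#' @param path NEXUS file path.
#' @return a [character_matrix].
#' @export
read_nexus_standard <- function(path) {
  raw <- tryCatch(ape::read.nexus.data(path), error = function(e)
    stop("malformed NEXUS file ", path, ": ", conditionMessage(e)))
  if (anyDuplicated(names(raw)))
    stop("duplicate taxa in ", path, ": ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
  norm_cell <- function(cell) {
    if (cell %in% c("?", "-", "N", "n")) return("?")
    if (grepl("/", cell, fixed = TRUE)) {
      st <- strsplit(cell, "/", fixed = TRUE)[[1]]
      return(paste0("{", paste(sort(st), collapse = ""), "}"))
    }
    cell
  }
  data <- t(vapply(raw, function(row) vapply(row, norm_cell, character(1)),
                   character(length(raw[[1]]))))
  dimnames(data) <- list(names(raw), NULL)
  character_matrix(data)
}

#' Write a character matrix as NEXUS standard data
#'
#' @param matrix a [character_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nexus_standard <- function(matrix, path) {
  stopifnot(inherits(matrix, "character_matrix"))
  n <- length(matrix$taxa); m <- ncol(matrix$data)
  symbols <- paste(0:max(matrix$k - 1), collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", n, m),
               sprintf("FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
                       symbols),
               "MATRIX"), con)
  pad <- max(nchar(matrix$taxa)) + 2
  for (i in seq_len(n)) {
    writeLines(paste0(formatC(matrix$taxa[i], width = -pad),
                      paste(matrix$data[i, ], collapse = "")), con)
  }
  writeLines(c(";", "END;"), con)
  invisible(path)
}

#' Read stratigraphic age ranges
#'
#' Tab-separated table with columns `taxon`, `lower`, `upper` (ages in
#' Myr before present). Extant taxa may be omitted (treated as age 0).
#'
#' @param path TSV file path.
#' @return data.frame of class `age_constraints`.
#' @export
read_age_ranges <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("taxon", "lower", "upper")
  if (!all(need %in% names(tab)))
    stop("age-range table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$taxon))
    stop("duplicate taxon rows: ",
         paste(unique(tab$taxon[duplicated(tab$taxon)]), collapse = ", "))
  bad <- tab$taxon[tab$lower > tab$upper]
  if (length(bad) > 0)
    stop("lower > upper for: ", paste(bad, collapse = ", "))
  if (any(tab$lower < 0)) stop("negative ages in ", path)
  out <- tab[, need]
  class(out) <- c("age_constraints", "data.frame")
  out
}

#' Write stratigraphic age ranges
#'
#' @param ranges data.frame with columns `taxon`, `lower`, `upper`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_age_ranges <- function(ranges, path) {
  utils::write.table(ranges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# small provenance hash of an R object (polynomial rolling hash over its
# deparsed form)
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write an MCMC trace as a tab-separated log
#'
#' BEAST-style log dialect: comment lines carrying the seed and a config
#' hash, then a header row and one row per recorded state, at 17
#' significant digits for lossless round-tripping.
#'
#' @param run an `fbd_mcmc` object or a plain trace data.frame.
#' @param path output path.
#' @param seed seed to record (taken from the run when available).
#' @return `path`, invisibly.
#' @export
write_trace <- function(run, path, seed = NULL) {
  if (inherits(run, "fbd_mcmc")) {
    trace <- run$trace
    if (is.null(seed)) seed <- run$seed
    hash <- .config_hash(run$config)
  } else {
    trace <- run
    hash <- .config_hash(names(trace))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seed=%s", if (is.null(seed)) "NA" else seed),
               sprintf("# config_hash=%s", hash)), con)
  writeLines(paste(names(trace), collapse = "\t"), con)
  if (nrow(trace) > 0) {
    rows <- apply(trace, 1, function(x)
      paste(ifelse(is.na(x), "NA", sprintf("%.17g", x)), collapse = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a tab-separated trace log
#'
#' @param path trace file written by [write_trace].
#' @return data.frame with attributes `seed` and `config_hash`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 1) stop("trace file has no header row")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rows <- body[-1]
  if (length(rows) > 0) {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) != length(header))
    if (length(bad) > 0)
      stop("ragged trace row(s): ", paste(utils::head(bad, 5), collapse = ", "))
    mat <- do.call(rbind, lapply(parts, function(p)
      suppressWarnings(as.numeric(p))))
    bad2 <- which(vapply(seq_along(parts), function(i)
      anyNA(mat[i, ]) && !all(parts[[i]][is.na(mat[i, ])] == "NA"),
      logical(1)))
    if (length(bad2) > 0)
      stop("non-numeric trace row(s): ",
           paste(utils::head(bad2, 5), collapse = ", "))
    trace <- as.data.frame(mat)
  } else {
    trace <- as.data.frame(matrix(numeric(0), 0, length(header)))
  }
  names(trace) <- header
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(m) > 0) sub(paste0("^# ", key, "="), "", m[1]) else NA_character_
  }
  attr(trace, "seed") <- get_meta("seed")
  attr(trace, "config_hash") <- get_meta("config_hash")
  trace
}

#' Write a leave-one-out report as TSV
#'
#' Columns mirror the per-fossil report schema (posterior range
#' probability, Bayes factor on the natural-log scale, phylogenetic age
#' with 95% HPD, error, ESS).
#'
#' @param report data.frame from [leave_one_out_report].
#' @param path output path.
#' @param seed seed to record in the header comment.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fossil age report; log_bf uses natural logarithms",
               sprintf("# seed=%s", if (is.null(seed)) "NA" else seed)), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
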
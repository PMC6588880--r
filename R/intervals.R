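#' Residue intervals
#'
#' Intervals are 1-based, closed on both ends (PDB residue-numbering
#' convention) and represented as an integer matrix with columns `start`
#' and `end`, sorted by start. A zero-row matrix is the empty interval set.
#'
#' @param start,end integer vectors of equal length; `start[i] <= end[i]`.
#' @return an interval matrix.
#' @examples
#' residue_intervals(c(1, 40), c(20, 90))
#' @export
residue_intervals <- function(start = integer(), end = integer()) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(end))
    stop("start and end must have equal length")
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval bounds must not be NA")
  if (any(start < 1L)) stop("intervals are 1-based: start >= 1")
  if (any(end < start)) stop("interval end must be >= start")
  m <- cbind(start = start, end = end)
  m[order(m[, "start"], m[, "end"]), , drop = FALSE]
}

iv_empty <- function() residue_intervals()

#' Parse and deparse "start-end" interval lists
#'
#' The TSV dialects used by the hit and chain tables encode interval lists
#' as comma-separated `"start-end"` pairs, e.g. `"1-120,150-200"`. An empty
#' string (or `"."`) is the empty set.
#'
#' @param s a single string.
#' @return `parse_intervals`: an interval matrix; `deparse_intervals`: a string.
#' @export
parse_intervals <- function(s) {
  if (is.na(s) || !nzchar(s) || identical(s, ".")) return(iv_empty())
  parts <- strsplit(trimws(s), ",", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  se <- regmatches(parts, regexec("^\\s*(\\d+)-(\\d+)\\s*$", parts))
  bad <- vapply(se, length, 1L) != 3L
  if (any(bad))
    stop("malformed interval token(s): ", paste(parts[bad], collapse = ", "))
  residue_intervals(vapply(se, function(x) as.integer(x[2]), 1L),
                    vapply(se, function(x) as.integer(x[3]), 1L))
}

#' @rdname parse_intervals
#' @param iv an interval matrix.
#' @export
deparse_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(".")
  paste(sprintf("%d-%d", iv[, "start"], iv[, "end"]), collapse = ",")
}

## expand intervals to the sorted set of residue indices they cover
iv_residues <- function(iv) {
  if (nrow(iv) == 0L) return(integer())
  sort(unique(unlist(lapply(seq_len(nrow(iv)),
                            function(i) seq.int(iv[i, "start"], iv[i, "end"])))))
}

## collapse a sorted set of residue indices back to maximal runs
iv_from_residues <- function(res) {
  res <- sort(unique(as.integer(res)))
  if (length(res) == 0L) return(iv_empty())
  brk <- which(diff(res) > 1L)
  starts <- res[c(1L, brk + 1L)]
  ends <- res[c(brk, length(res))]
  residue_intervals(starts, ends)
}

iv_total_length <- function(iv) length(iv_residues(iv))

iv_overlaps <- function(iv) {
  ## TRUE when any pair of intervals in the (sorted) set overlaps
  if (nrow(iv) < 2L) return(FALSE)
  any(iv[-1L, "start"] <= iv[-nrow(iv), "end"])
}
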
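#' Alignment evidence for one reference domain
#'
#' One piece of evidence mapping a reference domain onto one or more query
#' intervals (discontinuous domains are allowed), as produced by any
#' sequence search tool and read from the hit TSV.
#'
#' @param ref_domain_id reference domain identifier.
#' @param intervals interval matrix of query residue ranges
#'   (see [residue_intervals()]); must be non-overlapping.
#' @param ref_length residue length of the reference domain.
#' @param ref_coverage fraction of the reference covered by the alignment,
#'   in `[0, 1]`.
#' @param score non-negative alignment score; higher is better.
#' @return an object of class `"alignment_hit"`.
#' @export
alignment_hit <- function(ref_domain_id, intervals, ref_length,
                          ref_coverage, score) {
  if (!is.matrix(intervals)) intervals <- parse_intervals(intervals)
  if (nrow(intervals) < 1L) stop("a hit needs at least one query interval")
  if (iv_overlaps(intervals)) stop("query intervals of a hit must not overlap")
  ref_coverage <- as.numeric(ref_coverage)
  if (is.na(ref_coverage) || ref_coverage < 0 || ref_coverage > 1)
    stop("ref_coverage must be in [0, 1]")
  score <- as.numeric(score)
  if (is.na(score) || score < 0) stop("score must be non-negative")
  structure(list(ref_domain_id = as.character(ref_domain_id),
                 intervals = intervals,
                 ref_length = as.integer(ref_length),
                 ref_coverage = ref_coverage,
                 score = score),
            class = "alignment_hit")
}

hit_length <- function(hit) iv_total_length(hit$intervals)

#' Per-chain metadata record
#'
#' @param chain_id chain identifier.
#' @param length residue count of the chain.
#' @param unknown_runs interval matrix (or `"start-end"` string) of runs of
#'   unknown/unresolved residues, excluded from the classifiable denominator.
#' @param tm_runs interval matrix (or string) of annotated transmembrane
#'   segments; must be sorted and non-overlapping.
#' @param method experimental method, one of `"XRAY"`, `"EM"`, `"NMR"`,
#'   `"OTHER"`.
#' @param synthetic `TRUE` for synthetic constructs with no evolutionary
#'   history.
#' @return an object of class `"chain_record"`.
#' @export
chain_record <- function(chain_id, length,
                         unknown_runs = iv_empty(),
                         tm_runs = iv_empty(),
                         method = c("XRAY", "EM", "NMR", "OTHER"),
                         synthetic = FALSE) {
  method <- match.arg(method)
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("chain length must be >= 1")
  if (!is.matrix(unknown_runs)) unknown_runs <- parse_intervals(unknown_runs)
  if (!is.matrix(tm_runs)) tm_runs <- parse_intervals(tm_runs)
  for (iv in list(unknown_runs, tm_runs)) {
    if (nrow(iv) && (min(iv[, "start"]) < 1L || max(iv[, "end"]) > length))
      stop("annotation interval outside [1, length] for chain ", chain_id)
  }
  if (iv_overlaps(tm_runs)) stop("tm_runs must be pairwise non-overlapping")
  structure(list(chain_id = as.character(chain_id),
                 length = length,
                 unknown_mask = iv_residues(unknown_runs),
                 tm_annotations = tm_runs,
                 method = method,
                 synthetic = isTRUE(synthetic)),
            class = "chain_record")
}

#' @export
print.chain_record <- function(x, ...) {
  cat(sprintf("chain %s: %d residues, method %s%s\n", x$chain_id, x$length,
              x$method, if (x$synthetic) ", synthetic construct" else ""))
  if (length(x$unknown_mask))
    cat("  unknown residues:", deparse_intervals(iv_from_residues(x$unknown_mask)), "\n")
  if (nrow(x$tm_annotations))
    cat("  TM segments:", deparse_intervals(x$tm_annotations), "\n")
  invisible(x)
}
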
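#' Filter alignment hits by length and reference coverage
#'
#' Hits shorter than `min_domain_len` or covering too little of their
#' reference domain are not usable as domain evidence. Coverage is tiered:
#' below `min_ref_coverage` a hit is dropped outright; between
#' `min_ref_coverage` and `fragment_coverage` it is rejected but retained
#' as evidence that the chain carries a fragment of a known domain.
#'
#' @param hits list of [alignment_hit()] objects.
#' @param config a [tm_config()] list.
#' @return list with elements `kept` (usable hits), `rejected` (retained
#'   rejects) and `reject_reason` (character vector parallel to `rejected`,
#'   values `"FRAGMENT"` or `"TOO_SHORT"`).
#' @export
filter_hits <- function(hits, config = tm_config()) {
  kept <- list(); rejected <- list(); reasons <- character()
  for (h in hits) {
    stopifnot(inherits(h, "alignment_hit"))
    if (h$ref_coverage < config$min_ref_coverage) next  # dropped outright
    if (h$ref_coverage < config$fragment_coverage) {
      rejected[[length(rejected) + 1L]] <- h
      reasons <- c(reasons, "FRAGMENT")
    } else if (hit_length(h) < config$min_domain_len) {
      rejected[[length(rejected) + 1L]] <- h
      reasons <- c(reasons, "TOO_SHORT")
    } else {
      kept[[length(kept) + 1L]] <- h
    }
  }
  list(kept = kept, rejected = rejected, reject_reason = reasons)
}

## deterministic priority: score desc, total length desc, id lexicographic
hit_order <- function(hits) {
  sc <- vapply(hits, `[[`, numeric(1), "score")
  ln <- vapply(hits, hit_length, integer(1))
  id <- vapply(hits, `[[`, character(1), "ref_domain_id")
  order(-sc, -ln, id, method = "radix")
}

#' Resolve overlaps among filtered hits into domain assignments
#'
#' Greedy selection in a fully deterministic priority order (score
#' descending, then total length descending, then reference id
#' lexicographic). An incoming hit is accepted when its residue overlap
#' with already-accepted residues is at most `overlap_tol_residues` *and*
#' at most `overlap_tol_frac` of its own length; the overlapping residues
#' are trimmed from the incoming (lower-priority) hit. Otherwise the hit is
#' rejected, and if its score is at least `conflict_score_ratio` times the
#' score of an accepted hit it overlaps beyond tolerance, the chain has
#' comparable competing parses and `conflict_flag` is raised.
#'
#' @inheritParams filter_hits
#' @return list with `assignments` (list of `domain_assignment` objects:
#'   `ref_domain_id`, `intervals`, `source_hit`, `trimmed_residues`) and
#'   `conflict_flag`.
#' @export
resolve_overlaps <- function(hits, config = tm_config()) {
  assignments <- list()
  conflict <- FALSE
  if (length(hits) == 0L)
    return(list(assignments = assignments, conflict_flag = conflict))
  taken <- integer()          # residues already assigned
  acc_res <- list()           # per accepted hit: its original residue set
  acc_score <- numeric()
  for (h in hits[hit_order(hits)]) {
    res <- iv_residues(h$intervals)
    ov <- intersect(res, taken)
    if (length(ov) <= config$overlap_tol_residues &&
        length(ov) <= config$overlap_tol_frac * length(res)) {
      keep <- setdiff(res, ov)
      assignments[[length(assignments) + 1L]] <- structure(
        list(ref_domain_id = h$ref_domain_id,
             intervals = iv_from_residues(keep),
             source_hit = h,
             trimmed_residues = length(ov)),
        class = "domain_assignment")
      taken <- c(taken, keep)
      acc_res[[length(acc_res) + 1L]] <- res
      acc_score <- c(acc_score, h$score)
    } else {
      for (k in seq_along(acc_res)) {
        if (length(intersect(res, acc_res[[k]])) > config$overlap_tol_residues &&
            h$score >= config$conflict_score_ratio * acc_score[k]) {
          conflict <- TRUE
          break
        }
      }
    }
  }
  list(assignments = assignments, conflict_flag = conflict)
}

#' Coverage of a chain by its domain assignments
#'
#' The covered fraction is computed over classifiable residues only:
#' assigned (non-masked) residues divided by `length - |unknown_mask|`.
#' A chain whose classifiable denominator is zero is defined as fully
#' covered. Gaps are maximal runs of residues that are neither assigned
#' nor masked.
#'
#' @param assignments list of `domain_assignment` objects.
#' @param chain a [chain_record()].
#' @return list with `covered_frac` and `gaps` (interval matrix).
#' @export
compute_coverage <- function(assignments, chain) {
  assigned <- integer()
  for (a in assignments) {
    res <- iv_residues(a$intervals)
    if (length(res) && max(res) > chain$length)
      stop("assignment exceeds chain length for chain ", chain$chain_id)
    assigned <- c(assigned, res)
  }
  assigned <- unique(assigned)
  mask <- chain$unknown_mask
  denom <- chain$length - length(mask)
  covered_frac <- if (denom == 0L) 1.0 else length(setdiff(assigned, mask)) / denom
  free <- setdiff(seq_len(chain$length), union(assigned, mask))
  list(covered_frac = covered_frac, gaps = iv_from_residues(free))
}

#' Decide the curation outcome for a chain
#'
#' A parse is auto-accepted when the chain is (nearly) completely covered,
#' no unassigned gap reaches `gap_max`, and there is no comparable
#' competing parse. Otherwise the chain is flagged with reasons:
#' `INCONSISTENT_BOUNDARIES` when competing parses exist, `NOVEL_REGION`
#' when coverage fails on a chain with evolutionary history, and
#' `UNASSIGNABLE` when the failure is attributable to synthetic or
#' masked content alone.
#'
#' @param chain a [chain_record()].
#' @param assignments accepted assignments from [resolve_overlaps()].
#' @param covered_frac,gaps from [compute_coverage()].
#' @param conflict_flag from [resolve_overlaps()].
#' @param config a [tm_config()] list.
#' @return an object of class `"partition_result"`.
#' @export
decide_outcome <- function(chain, assignments, covered_frac, gaps,
                           conflict_flag, config = tm_config()) {
  cover_ok <- covered_frac >= config$min_cover_frac
  gap_ok <- nrow(gaps) == 0L ||
    all(gaps[, "end"] - gaps[, "start"] + 1L < config$gap_max)
  reasons <- character()
  if (conflict_flag) reasons <- c(reasons, "INCONSISTENT_BOUNDARIES")
  if (!cover_ok || !gap_ok) {
    reasons <- c(reasons,
                 if (chain$synthetic) "UNASSIGNABLE" else "NOVEL_REGION")
  }
  outcome <- if (cover_ok && gap_ok && !conflict_flag) "AUTO_ACCEPTED" else "FLAGGED"
  if (outcome == "FLAGGED" && length(reasons) == 0L)
    reasons <- "UNASSIGNABLE"   # failure explained by masked content only
  structure(list(chain_id = chain$chain_id,
                 assignments = assignments,
                 gaps = gaps,
                 covered_frac = covered_frac,
                 conflict_flag = conflict_flag,
                 outcome = outcome,
                 reasons = sort(unique(reasons)),
                 architecture_tags = character()),
            class = "partition_result")
}

#' Tag the architecture of a partitioned chain
#'
#' Adds classification tags: `PEPTIDE` (short chain, nothing assigned),
#' `SYNTHETIC` (synthetic construct), `FRAGMENT` (the only evidence was
#' fragment-rejected hits), `SINGLE_DOMAIN` / `MULTI_DOMAIN` (mutually
#' exclusive, by assignment count) and `TM_CONTAINING` (the chain carries
#' at least one annotated transmembrane segment).
#'
#' @param result a `partition_result`.
#' @param chain the matching [chain_record()].
#' @param rejected_reasons reasons of retained rejected hits, from
#'   [filter_hits()].
#' @param config a [tm_config()] list.
#' @return the `partition_result` with `architecture_tags` filled in.
#' @export
classify_architecture <- function(result, chain, rejected_reasons = character(),
                                  config = tm_config()) {
  n <- length(result$assignments)
  tags <- character()
  if (chain$length < config$peptide_max_len && n == 0L) tags <- c(tags, "PEPTIDE")
  if (chain$synthetic) tags <- c(tags, "SYNTHETIC")
  if (n == 0L && length(rejected_reasons) > 0L &&
      all(rejected_reasons == "FRAGMENT")) tags <- c(tags, "FRAGMENT")
  if (n == 1L) tags <- c(tags, "SINGLE_DOMAIN")
  if (n >= 2L) tags <- c(tags, "MULTI_DOMAIN")
  if (nrow(chain$tm_annotations) > 0L) tags <- c(tags, "TM_CONTAINING")
  result$architecture_tags <- sort(unique(tags))
  result$method <- chain$method
  result
}

#' Partition one chain from its alignment evidence
#'
#' Runs the whole triage pipeline: [filter_hits()], [resolve_overlaps()],
#' [compute_coverage()], [decide_outcome()] and [classify_architecture()].
#' Identical inputs always produce identical output; there is no randomness
#' anywhere in the pipeline.
#'
#' @param chain a [chain_record()].
#' @param hits list of [alignment_hit()] objects for the chain.
#' @param config a [tm_config()] list.
#' @return a `partition_result`.
#' @examples
#' ch <- chain_record("A", 200)
#' h <- list(alignment_hit("d1", "1-100", 100, 0.95, 80),
#'           alignment_hit("d2", "101-200", 100, 0.95, 70))
#' partition_chain(ch, h)
#' @export
partition_chain <- function(chain, hits, config = tm_config()) {
  flt <- filter_hits(hits, config)
  res <- resolve_overlaps(flt$kept, config)
  cov <- compute_coverage(res$assignments, chain)
  out <- decide_outcome(chain, res$assignments, cov$covered_frac, cov$gaps,
                        res$conflict_flag, config)
  classify_architecture(out, chain, flt$reject_reason, config)
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("chain %s: %s (coverage %.3f)\n", x$chain_id, x$outcome,
              x$covered_frac))
  for (a in x$assignments)
    cat(sprintf("  %-12s %s%s\n", a$ref_domain_id, deparse_intervals(a$intervals),
                if (a$trimmed_residues) sprintf("  (trimmed %d)", a$trimmed_residues) else ""))
  if (nrow(x$gaps)) cat("  gaps:", deparse_intervals(x$gaps), "\n")
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = ", "), "\n")
  if (length(x$architecture_tags))
    cat("  tags:", paste(x$architecture_tags, collapse = ", "), "\n")
  invisible(x)
}
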
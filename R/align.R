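## pair score between segment i of A and j of B:
## orientation agreement (+1 same, -1 opposite, 0 if either UNDEFINED)
## weighted by w_or, plus length similarity 1 - |lA-lB|/max(lA,lB)
## weighted by w_len.
pair_score_matrix <- function(lenA, orA, lenB, orB, config) {
  n <- length(lenA); m <- length(lenB)
  s <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    ot <- if (orA[i] == "UNDEFINED" || orB[j] == "UNDEFINED") 0
          else if (orA[i] == orB[j]) 1 else -1
    lt <- 1 - abs(lenA[i] - lenB[j]) / max(lenA[i], lenB[j])
    s[i, j] <- config$w_or * ot + config$w_len * lt
  }
  s
}

## affine cost of an internal run of k gapped segments
gap_cost <- function(k, config) {
  ifelse(k <= 0L, 0, config$g_open + config$g_ext * (k - 1L))
}

## Exact semi-global DP over "last matched pair": P[i,j] is the best score
## of any alignment whose final matched pair is (i, j). End gaps are free,
## internal gaps affine. Profiles hold <= ~15 segments, so the O(n^2 m^2)
## predecessor scan is negligible and keeps the affine cost exact.
## Deterministic tie-breaking: higher score, then fewer internal gapped
## segments, then predecessor preference (larger i'+j', smaller |i'-j'|,
## larger i') which places unavoidable gaps leftmost and keeps the pair
## set transpose-symmetric except in doubly degenerate ties.
align_core <- function(lenA, orA, lenB, orB, config) {
  n <- length(lenA); m <- length(lenB)
  s <- pair_score_matrix(lenA, orA, lenB, orB, config)
  P <- matrix(-Inf, n, m); G <- matrix(0L, n, m)
  PI <- matrix(0L, n, m); PJ <- matrix(0L, n, m)
  eps <- 1e-9
  gpv <- vapply(0:max(n, m), gap_cost, numeric(1), config = config)
  ## among equal-score candidates prefer fewest internal gaps, then the
  ## rightmost predecessor (which places unavoidable gaps leftmost), with
  ## |i-j| before i to keep A/B-transpose symmetry
  pick <- function(cand, g) {
    order(g, -(cand[, 1L] + cand[, 2L]), abs(cand[, 1L] - cand[, 2L]),
          -cand[, 1L])[1L]
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    base <- 0; bg <- 0L; bi <- 0L; bj <- 0L  # fresh start: leading gaps free
    if (i > 1L && j > 1L) {
      ip <- seq_len(i - 1L); jp <- seq_len(j - 1L)
      ## gpv[i - ip] is the affine cost of the i - ip - 1 skipped segments
      val <- P[ip, jp, drop = FALSE] - outer(gpv[i - ip], gpv[j - jp], `+`)
      mv <- max(val)
      if (mv > eps) {   # a zero-value predecessor loses to a fresh start
        cand <- which(val > mv - eps, arr.ind = TRUE)
        g <- G[cand] + (i - cand[, 1L] - 1L) + (j - cand[, 2L] - 1L)
        k <- pick(cand, g)
        bi <- cand[k, 1L]; bj <- cand[k, 2L]
        base <- val[bi, bj]; bg <- g[k]
      }
    }
    P[i, j] <- base + s[i, j]
    G[i, j] <- bg; PI[i, j] <- bi; PJ[i, j] <- bj
  }
  ## best end pair (trailing gaps free); the empty alignment scores 0 and
  ## wins when no pairing is strictly positive
  escore <- max(P)
  pairs <- matrix(integer(), 0L, 2L, dimnames = list(NULL, c("a", "b")))
  if (escore <= eps) return(list(pairs = pairs, score = 0))
  cand <- which(P > escore - eps, arr.ind = TRUE)
  k <- pick(cand, G[cand])
  i <- cand[k, 1L]; j <- cand[k, 2L]
  escore <- P[i, j]
  while (i > 0L) {
    pairs <- rbind(c(i, j), pairs)
    ip <- PI[i, j]; jp <- PJ[i, j]
    i <- ip; j <- jp
  }
  colnames(pairs) <- c("a", "b")
  list(pairs = pairs, score = escore)
}

topology_alignment <- function(pairs, n, m, score, offset = 0L,
                               handedness_identity = NA_real_) {
  structure(list(pairs = pairs,
                 gaps_A = setdiff(seq_len(n), pairs[, "a"]),
                 gaps_B = setdiff(seq_len(m), pairs[, "b"]),
                 score = score,
                 permutation_offset = as.integer(offset),
                 handedness_identity = handedness_identity),
            class = "topology_alignment")
}

#' Align two TM profiles at segment level
#'
#' Semi-global dynamic programming over the two ordered segment sequences:
#' end gaps are free (extra terminal segments cost nothing), internal gaps
#' carry an affine penalty, and each matched pair is scored by orientation
#' agreement and length similarity. Geometry enters only through
#' per-segment orientation and length; this is a topology comparison, not
#' a 3D superposition. Output is deterministic: ties are broken toward
#' fewer internal gaps, then leftmost gap placement.
#'
#' @param A,B [tm_profile()] objects.
#' @param config a [tm_config()] (uses `w_or`, `w_len`, `g_open`, `g_ext`).
#' @return an object of class `"topology_alignment"`: matched `pairs`
#'   (matrix with columns `a`, `b`, strictly increasing in both), unmatched
#'   `gaps_A` / `gaps_B`, `score`, `permutation_offset` (0 here) and
#'   `handedness_identity` (fraction of matched-core triplet labels equal,
#'   `NA` when fewer than 3 core pairs).
#' @export
align_profiles <- function(A, B, config = tm_config()) {
  res <- align_core(segment_lengths(A), segment_orientations(A),
                    segment_lengths(B), segment_orientations(B), config)
  aln <- topology_alignment(res$pairs, n_segments(A), n_segments(B), res$score)
  aln$handedness_identity <- core_handedness_identity(aln, A, B, config)
  aln
}

core_handedness_identity <- function(aln, A, B, config) {
  if (nrow(aln$pairs) < 3L) return(NA_real_)
  coreA <- vapply(A$segments, function(s) isTRUE(s$is_core), logical(1))
  coreB <- vapply(B$segments, function(s) isTRUE(s$is_core), logical(1))
  keep <- coreA[aln$pairs[, "a"]] & coreB[aln$pairs[, "b"]]
  if (sum(keep) < 3L) return(NA_real_)
  sub <- aln; sub$pairs <- aln$pairs[keep, , drop = FALSE]
  tryCatch(compare_handedness(sub, A, B, config), error = function(e) NA_real_)
}

#' Handedness agreement over the matched segments of an alignment
#'
#' Computes the triplet handedness string over each profile's matched
#' segments, taken in alignment order, and returns the fraction of
#' positions with equal labels. Positions where either label is `X`
#' (degenerate geometry) are excluded from the denominator.
#'
#' @param aln a `topology_alignment` with at least 3 matched pairs.
#' @param A,B the aligned [tm_profile()] objects.
#' @param config a [tm_config()].
#' @return fraction in `[0, 1]`.
#' @export
compare_handedness <- function(aln, A, B, config = tm_config()) {
  if (nrow(aln$pairs) < 3L)
    stop("handedness comparison needs at least 3 matched pairs")
  labs <- function(profile, idx) {
    cents <- lapply(profile$segments[idx], `[[`, "centroid")
    vapply(seq_len(length(cents) - 2L), function(i) {
      triplet_handedness(cents[[i]], cents[[i + 1L]], cents[[i + 2L]],
                         profile$frame, config)
    }, character(1))
  }
  la <- labs(A, aln$pairs[, "a"])
  lb <- labs(B, aln$pairs[, "b"])
  use <- la != "X" & lb != "X"
  if (!any(use))
    stop("all matched triplets are degenerate (X); handedness identity undefined")
  mean(la[use] == lb[use])
}

#' Rotate the segment order of a profile
#'
#' Cyclic rotation by `k`: the profile's segment list becomes
#' `(k+1, ..., n, 1, ..., k)`. Each segment keeps its own geometry,
#' orientation and flags (a genuine circular permutation preserves each
#' segment's membrane-crossing direction); residue intervals are
#' renumbered to keep the new order a valid chain order.
#'
#' @param profile a [tm_profile()].
#' @param k rotation offset, `0 <= k < n_segments`.
#' @return a rotated [tm_profile()].
#' @export
rotate_profile <- function(profile, k) {
  n <- n_segments(profile)
  k <- as.integer(k) %% n
  if (k == 0L) return(profile)
  ord <- c(seq.int(k + 1L, n), seq_len(k))
  segs <- profile$segments[ord]
  pos <- 1L
  for (i in seq_along(segs)) {        # renumber intervals to chain order
    len <- segs[[i]]$interval[1L, "end"] - segs[[i]]$interval[1L, "start"]
    segs[[i]]$interval <- residue_intervals(pos, pos + len)
    pos <- pos + len + 5L
  }
  tm_profile(segs, profile$frame,
             label = sprintf("%s(rot%d)", profile$label, k))
}

#' Detect circular permutation between two TM profiles
#'
#' Aligns `A` against every cyclic rotation of `B`'s segment order and
#' keeps the best-scoring alignment. The unrotated alignment wins unless
#' some rotation beats it by more than `cp_margin`, so unrelated profiles
#' report offset 0. The reported `permutation_offset` is the rotation of
#' `A`'s segment order that produces `B`'s: `detect` on `A` versus
#' `rotate_profile(A, k)` reports `k`.
#'
#' @param A,B [tm_profile()] objects.
#' @param config a [tm_config()] (adds `cp_margin`).
#' @return a `topology_alignment` whose `pairs[, "b"]` are original
#'   (unrotated) B segment indices, monotone after undoing the rotation.
#' @export
detect_circular_permutation <- function(A, B, config = tm_config()) {
  n <- n_segments(A); m <- n_segments(B)
  lenA <- segment_lengths(A); orA <- segment_orientations(A)
  lenB <- segment_lengths(B); orB <- segment_orientations(B)
  best <- NULL; best_r <- 0L
  for (r in 0:(m - 1L)) {
    ord <- if (r == 0L) seq_len(m) else c(seq.int(r + 1L, m), seq_len(r))
    res <- align_core(lenA, orA, lenB[ord], orB[ord], config)
    if (r == 0L) {
      base <- res; best <- res; best_r <- 0L
    } else if (res$score > best$score + (if (best_r == 0L) config$cp_margin else 1e-9)) {
      best <- res; best_r <- r
    }
  }
  pairs <- best$pairs
  if (best_r > 0L && nrow(pairs)) {
    ord <- c(seq.int(best_r + 1L, m), seq_len(best_r))
    pairs[, "b"] <- ord[pairs[, "b"]]
  }
  offset <- if (best_r == 0L) 0L else (m - best_r) %% m
  aln <- topology_alignment(pairs, n, m, best$score, offset)
  aln$handedness_identity <- core_handedness_identity(aln, A, B, config)
  aln
}

#' @export
print.topology_alignment <- function(x, ...) {
  cat(sprintf("topology alignment: %d matched pairs, score %.3f\n",
              nrow(x$pairs), x$score))
  if (nrow(x$pairs))
    cat("  pairs:", paste(sprintf("%d-%d", x$pairs[, "a"], x$pairs[, "b"]),
                          collapse = " "), "\n")
  if (length(x$gaps_A)) cat("  unmatched in A:", paste(x$gaps_A, collapse = ","), "\n")
  if (length(x$gaps_B)) cat("  unmatched in B:", paste(x$gaps_B, collapse = ","), "\n")
  if (x$permutation_offset)
    cat("  circular permutation offset:", x$permutation_offset, "\n")
  if (!is.na(x$handedness_identity))
    cat(sprintf("  matched-core handedness identity: %.2f\n", x$handedness_identity))
  invisible(x)
}
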
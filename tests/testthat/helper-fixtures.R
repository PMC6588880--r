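# Shared fixtures and independent oracles for the test suite.

## ---- independent chirality oracle -----------------------------------------
## Signed area of the projected triangle, computed in an explicit
## orthonormal basis of the membrane plane (a different code path from the
## package's cross-product rule): shoelace formula on 2D coordinates.
oracle_turn_label <- function(c1, c2, c3, normal = c(0, 0, 1), tol = 0.05) {
  n <- normal / sqrt(sum(normal^2))
  e <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- e - sum(e * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],    # v = n x u, so (u, v, n) right-handed
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  p <- lapply(list(c1, c2, c3), function(p) c(sum(p * u), sum(p * v)))
  area2 <- (p[[2]][1] - p[[1]][1]) * (p[[3]][2] - p[[1]][2]) -
           (p[[3]][1] - p[[1]][1]) * (p[[2]][2] - p[[1]][2])
  d1 <- sqrt(sum((p[[2]] - p[[1]])^2)); d2 <- sqrt(sum((p[[3]] - p[[2]])^2))
  s <- area2 / (d1 * d2)
  ## positive signed area = counterclockwise from the +normal side = L
  if (s > tol) "L" else if (s < -tol) "R" else "X"
}

## ---- brute-force alignment oracle -----------------------------------------
## Enumerates every monotone pair set between sequences of lengths n and m,
## scores it with free end gaps and affine internal gaps, and returns the
## maximum score. Exponential; use only for n, m <= 5.
oracle_align_score <- function(lenA, orA, lenB, orB, cfg) {
  n <- length(lenA); m <- length(lenB)
  pair_s <- function(i, j) {
    ot <- if (orA[i] == "UNDEFINED" || orB[j] == "UNDEFINED") 0
          else if (orA[i] == orB[j]) 1 else -1
    cfg$w_or * ot + cfg$w_len * (1 - abs(lenA[i] - lenB[j]) / max(lenA[i], lenB[j]))
  }
  gp <- function(k) if (k <= 0) 0 else cfg$g_open + cfg$g_ext * (k - 1)
  best <- 0  # empty alignment
  score_set <- function(pairs) {
    if (nrow(pairs) == 0L) return(0)
    sc <- sum(mapply(pair_s, pairs[, 1], pairs[, 2]))
    if (nrow(pairs) > 1L) {
      da <- diff(pairs[, 1]) - 1L
      db <- diff(pairs[, 2]) - 1L
      sc <- sc - sum(vapply(da, gp, 0)) - sum(vapply(db, gp, 0))
    }
    sc
  }
  recurse <- function(i0, j0, pairs) {
    best <<- max(best, score_set(pairs))
    if (i0 > n || j0 > m) return(invisible())
    for (i in i0:n) for (j in j0:m)
      recurse(i + 1L, j + 1L, rbind(pairs, c(i, j)))
  }
  recurse(1L, 1L, matrix(integer(), 0L, 2L))
  best
}

## ---- profile builders ------------------------------------------------------
## Direct tm_profile construction from per-segment descriptors, bypassing
## coordinates (the DP only sees lengths, orientations, centroids).
mk_profile <- function(lengths, orientations, angles = NULL, radius = 12,
                       is_core = TRUE, label = "fix") {
  n <- length(lengths)
  if (is.null(angles)) angles <- seq(0, by = 40, length.out = n)
  is_core <- rep_len(is_core, n)
  th <- angles * pi / 180
  pos <- 1L
  segs <- vector("list", n)
  for (i in seq_len(n)) {
    ax <- switch(orientations[i], UP = c(0, 0, 1), DOWN = c(0, 0, -1),
                 UNDEFINED = c(1, 0, 0))
    segs[[i]] <- list(interval = residue_intervals(pos, pos + lengths[i] - 1L),
                      axis = ax,
                      centroid = c(radius * cos(th[i]), radius * sin(th[i]), 0),
                      orientation = orientations[i],
                      is_core = is_core[i], is_coupling_helix = FALSE)
    pos <- pos + lengths[i] + 5L
  }
  tm_profile(segs, membrane_frame(), label)
}

## profile with explicit 2D centroids (for handedness-comparison tests)
mk_profile_xy <- function(centroids_xy, lengths = 20L,
                          orientations = NULL, label = "fix") {
  n <- nrow(centroids_xy)
  lengths <- rep_len(as.integer(lengths), n)
  if (is.null(orientations))
    orientations <- rep(c("UP", "DOWN"), length.out = n)
  pos <- 1L
  segs <- vector("list", n)
  for (i in seq_len(n)) {
    ax <- if (orientations[i] == "UP") c(0, 0, 1) else c(0, 0, -1)
    segs[[i]] <- list(interval = residue_intervals(pos, pos + lengths[i] - 1L),
                      axis = ax,
                      centroid = c(centroids_xy[i, 1], centroids_xy[i, 2], 0),
                      orientation = orientations[i],
                      is_core = TRUE, is_coupling_helix = FALSE)
    pos <- pos + lengths[i] + 5L
  }
  tm_profile(segs, membrane_frame(), label)
}

## the six-segment reference core used by the alignment fixtures: the
## RRLL centroid arrangement with distinctive segment lengths
core6_lengths <- c(30L, 20L, 28L, 18L, 26L, 22L)

make_core6_bundle <- function(noise_sigma = 0, seed = 1L) {
  spec <- bundle_preset("rrll")
  spec$helix_length <- core6_lengths
  spec$noise_sigma <- noise_sigma
  spec$seed <- seed
  do.call(make_helix_bundle, spec)
}

make_core6_profile <- function() {
  b <- make_core6_bundle()
  build_profile(b$coords, b$tm_ranges, b$frame, label = "core6")
}

## seven segments: one extra N-terminal TM segment before the same core
make_extra_nterm_bundle <- function() {
  b <- do.call(make_helix_bundle, list(
    n_segments = 7L, ring_radius = 12,
    helix_length = c(20L, core6_lengths),
    angular_order = c(210, 150, 90, 30, 330, 0, 60),
    orientation_pattern = "DUDUDUD"))
  b$tm_ranges$is_core <- c(FALSE, rep(TRUE, 6L))
  b
}

## eight segments: two extra (tilted, non-spanning) segments inserted
## between core segments 1 and 2
make_inserted_pair_bundle <- function() {
  b <- do.call(make_helix_bundle, list(
    n_segments = 8L, ring_radius = 12,
    helix_length = c(30L, 15L, 15L, 20L, 28L, 18L, 26L, 22L),
    angular_order = c(150, 200, 250, 90, 30, 330, 0, 60),
    orientation_pattern = "UTTDUDUD"))
  b$tm_ranges$is_core <- c(TRUE, FALSE, FALSE, rep(TRUE, 5L))
  b
}

profile_of_bundle <- function(b, label = "bundle") {
  build_profile(b$coords, b$tm_ranges, b$frame, label = label)
}

## a random rigid rotation matrix (uniform via QR of Gaussian matrix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## outcome records of prescribed composition for summary tests: builds
## minimal partition results through the package constructors
mk_outcome_record <- function(chain_id, n_domains = 1L, method = "XRAY",
                              tm = FALSE, special = FALSE, gap = FALSE) {
  len <- 100L * max(1L, n_domains) + if (gap) 80L else 0L
  chain <- chain_record(chain_id, len,
                        tm_runs = if (tm) residue_intervals(5L, 25L) else iv_empty(),
                        method = method, synthetic = special)
  hits <- lapply(seq_len(n_domains), function(i)
    alignment_hit(sprintf("d%s.%d", chain_id, i),
                  residue_intervals((i - 1L) * 100L + 1L, i * 100L),
                  100L, 0.95, 50))
  partition_chain(chain, hits)
}
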
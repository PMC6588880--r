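## analytic chirality of three plane points (signed-area turn sense);
## this is the rule the generator uses to derive truth labels
plane_turn_label <- function(p1, p2, p3, degeneracy_tol = 0.05,
                             convention = "clockwise_R") {
  d1 <- p2 - p1; d2 <- p3 - p2
  z <- d1[1] * d2[2] - d1[2] * d2[1]
  s <- z / (sqrt(sum(d1^2)) * sqrt(sum(d2^2)))
  lab <- if (s > degeneracy_tol) "L" else if (s < -degeneracy_tol) "R" else "X"
  if (convention == "clockwise_L") lab <- chartr("RL", "LR", lab)
  lab
}

#' Preset helix-bundle arrangements
#'
#' Named centroid arrangements with known truth:
#' `"rrll"` — six helices whose consecutive triplets are right-handed,
#' right-handed, left-handed, left-handed (the arrangement of the
#' CAAX-protease / APH-1 six-segment core); `"rr"` — four helices with
#' both triplets right-handed (the MacB-like four-segment ABC transporter
#' core); `"l3"` — three helices on a counterclockwise circle (one
#' left-handed triplet).
#'
#' @param name preset name.
#' @return a list of [make_helix_bundle()] arguments.
#' @export
bundle_preset <- function(name = c("rrll", "rr", "l3")) {
  name <- match.arg(name)
  switch(name,
    rrll = list(n_segments = 6L, angular_order = c(150, 90, 30, 330, 0, 60),
                orientation_pattern = "UDUDUD", ring_radius = 12),
    rr   = list(n_segments = 4L, angular_order = c(135, 90, 45, 0),
                orientation_pattern = "UDUD", ring_radius = 12),
    l3   = list(n_segments = 3L, angular_order = c(0, 120, 240),
                orientation_pattern = "UDU", ring_radius = 12))
}

#' Generate an ideal helix bundle with known topology truth
#'
#' Builds canonical C-alpha alpha-helices (right-handed, 1.5 A rise and
#' 100 degrees twist per residue, 2.3 A helical radius) along the +z or -z
#' direction, with helix centroids placed in the membrane plane at the
#' prescribed ring angles. The truth handedness string is derived
#' analytically from the centroid arrangement by the signed-area rule, so
#' with zero noise the geometry pipeline must reproduce it exactly.
#'
#' @param n_segments number of helices.
#' @param ring_radius centroid ring radius in Angstrom.
#' @param helix_length residues per helix; a scalar or one value per helix.
#' @param rise_per_residue,twist_per_residue,helix_radius ideal-helix
#'   parameters (defaults 1.5 A, 100 degrees, 2.3 A).
#' @param angular_order plane angles (degrees) of the helix centroids, in
#'   chain order; must be distinct.
#' @param orientation_pattern string over `{U, D, T}`, one letter per
#'   helix: `U` runs N-to-C along +z, `D` along -z, and `T` is a strongly
#'   tilted helix (70 degrees off the normal) that does not span the
#'   bilayer and therefore classifies as `UNDEFINED` orientation — useful
#'   for modelling inserted helical hairpins.
#' @param noise_sigma isotropic Gaussian coordinate noise (A).
#' @param seed RNG seed for the noise (ignored at `noise_sigma = 0`).
#' @param loop_gap unmodelled residues between consecutive segments
#'   (default 5); only TM residues get coordinates.
#' @return list with `coords` (data frame `resno`, `x`, `y`, `z`),
#'   `tm_ranges` (data frame `seg_index`, `start`, `end`, `is_core`,
#'   `is_coupling`), `frame` (the +z [membrane_frame()]) and `truth`
#'   (list: `orientations`, `handedness`).
#' @examples
#' b <- do.call(make_helix_bundle, bundle_preset("rrll"))
#' b$truth$handedness
#' @export
make_helix_bundle <- function(n_segments,
                              ring_radius = 12,
                              helix_length = 22L,
                              rise_per_residue = 1.5,
                              twist_per_residue = 100,
                              helix_radius = 2.3,
                              angular_order,
                              orientation_pattern,
                              noise_sigma = 0,
                              seed = 1L,
                              loop_gap = 5L) {
  n <- as.integer(n_segments)
  if (length(angular_order) != n) stop("angular_order must have one angle per segment")
  if (anyDuplicated(angular_order %% 360)) stop("angular positions must be distinct")
  pat <- strsplit(orientation_pattern, "")[[1]]
  if (length(pat) != n || !all(pat %in% c("U", "D", "T")))
    stop("orientation_pattern must be a string over {U, D, T}, one per segment")
  th <- angular_order * pi / 180
  cx <- ring_radius * cos(th); cy <- ring_radius * sin(th)
  dmin <- min(stats::dist(cbind(cx, cy)))
  if (dmin < 2 * helix_radius)
    stop(sprintf("helices overlap: centroid spacing %.2f A < %.2f A",
                 dmin, 2 * helix_radius))
  Ls <- rep_len(as.integer(helix_length), n)
  omega <- twist_per_residue * pi / 180
  coords <- NULL
  ranges <- data.frame(seg_index = integer(), start = integer(), end = integer(),
                       is_core = logical(), is_coupling = logical())
  tilt <- 70 * pi / 180
  pos <- 1L
  for (i in seq_len(n)) {
    L <- Ls[i]
    a <- switch(pat[i],
                U = c(0, 0, 1),
                D = c(0, 0, -1),
                T = c(sin(tilt) * cos(th[i]), sin(tilt) * sin(th[i]), cos(tilt)))
    ## right-handed frame (u, v, a) for a canonical right-handed helix
    e <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- e - sum(e * a) * a; u <- u / sqrt(sum(u^2))
    v <- c(a[2] * u[3] - a[3] * u[2],
           a[3] * u[1] - a[1] * u[3],
           a[1] * u[2] - a[2] * u[1])
    j <- seq_len(L) - 1L
    t_j <- (j - (L - 1) / 2) * rise_per_residue
    phi <- omega * j + th[i]
    cen <- c(cx[i], cy[i], 0)
    pts <- cbind(cen[1] + a[1] * t_j, cen[2] + a[2] * t_j, cen[3] + a[3] * t_j) +
      helix_radius * (outer(cos(phi), u) + outer(sin(phi), v))
    coords <- rbind(coords, data.frame(resno = pos + j, x = pts[, 1],
                                       y = pts[, 2], z = pts[, 3]))
    ranges <- rbind(ranges, data.frame(seg_index = i, start = pos,
                                       end = pos + L - 1L,
                                       is_core = TRUE, is_coupling = FALSE))
    pos <- pos + L + as.integer(loop_gap)
  }
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    nr <- nrow(coords)
    coords$x <- coords$x + stats::rnorm(nr, 0, noise_sigma)
    coords$y <- coords$y + stats::rnorm(nr, 0, noise_sigma)
    coords$z <- coords$z + stats::rnorm(nr, 0, noise_sigma)
  }
  truth_hand <- if (n >= 3L) {
    paste(vapply(seq_len(n - 2L), function(i) {
      plane_turn_label(c(cx[i], cy[i]), c(cx[i + 1L], cy[i + 1L]),
                       c(cx[i + 2L], cy[i + 2L]))
    }, character(1)), collapse = "")
  } else ""
  list(coords = coords,
       tm_ranges = ranges,
       frame = membrane_frame(c(0, 0, 1), c(0, 0, 0)),
       truth = list(orientations = pat, handedness = truth_hand))
}

#' Generate a partition scenario with known truth
#'
#' Emits a chain record and an alignment-hit table whose true hits equal
#' the prescribed domains (plus optional boundary jitter), together with
#' low-scoring decoy hits and fragment hits that the pipeline must
#' discard. The truth outcome is obtained by running the documented
#' partition rules on the noiseless configuration (true domains only), so
#' at zero jitter generator truth and pipeline output agree exactly.
#'
#' @param chain_length residues in the chain.
#' @param true_domains interval matrix (or `"start-end"` string) of true
#'   non-overlapping domains.
#' @param domain_ids reference ids, one per true domain.
#' @param hit_noise maximum absolute boundary jitter (residues) applied
#'   uniformly to each true-hit boundary.
#' @param n_decoys low-scoring decoy hits nested inside true domains.
#' @param n_fragments low-reference-coverage fragment hits.
#' @param unknown_runs mask of unknown residues (interval matrix or string).
#' @param tm_runs TM annotation intervals.
#' @param method experimental method of the chain.
#' @param synthetic synthetic-construct flag.
#' @param seed RNG seed; all randomness flows through it.
#' @param config a [tm_config()] used to derive the truth outcome.
#' @return list with `chain` ([chain_record()]), `hits` (list of
#'   [alignment_hit()]) and `truth` (a `partition_result`).
#' @export
make_partition_scenario <- function(chain_length,
                                    true_domains = iv_empty(),
                                    domain_ids = NULL,
                                    hit_noise = 0L,
                                    n_decoys = 0L,
                                    n_fragments = 0L,
                                    unknown_runs = iv_empty(),
                                    tm_runs = iv_empty(),
                                    method = "XRAY",
                                    synthetic = FALSE,
                                    seed = 1L,
                                    config = tm_config()) {
  if (!is.matrix(true_domains)) true_domains <- parse_intervals(true_domains)
  if (iv_overlaps(true_domains)) stop("true domains must not overlap")
  nd <- nrow(true_domains)
  if (is.null(domain_ids)) domain_ids <- sprintf("dom%02d", seq_len(nd))
  if (length(domain_ids) != nd) stop("need one domain id per true domain")
  set.seed(as.integer(seed))
  chain <- chain_record("synthchain", chain_length, unknown_runs, tm_runs,
                        method, synthetic)
  true_hits <- list()
  for (i in seq_len(nd)) {
    a <- true_domains[i, "start"]; b <- true_domains[i, "end"]
    len <- b - a + 1L
    true_hits[[i]] <- alignment_hit(domain_ids[i], residue_intervals(a, b),
                                    ref_length = len, ref_coverage = 0.95,
                                    score = 100 + len / 10)
  }
  hits <- true_hits
  if (n_decoys > 0L) {
    if (nd == 0L) stop("decoys require at least one true domain")
    for (k in seq_len(n_decoys)) {
      i <- sample.int(nd, 1L)
      a <- true_domains[i, "start"]; b <- true_domains[i, "end"]
      len <- b - a + 1L
      dl <- max(config$min_domain_len, as.integer(0.6 * len))
      da <- a + sample.int(max(1L, len - dl), 1L) - 1L
      hits[[length(hits) + 1L]] <- alignment_hit(
        sprintf("decoy%02d", k), residue_intervals(da, min(b, da + dl - 1L)),
        ref_length = dl, ref_coverage = 0.9, score = 10 + stats::runif(1, 0, 5))
    }
  }
  if (n_fragments > 0L) {
    for (k in seq_len(n_fragments)) {
      a <- sample.int(max(1L, chain_length - 30L), 1L)
      hits[[length(hits) + 1L]] <- alignment_hit(
        sprintf("frag%02d", k), residue_intervals(a, min(chain_length, a + 29L)),
        ref_length = 200L, ref_coverage = 0.35, score = 20)
    }
  }
  ## jitter the true-hit boundaries after truth is fixed
  if (hit_noise > 0L) {
    for (i in seq_len(nd)) {
      iv <- hits[[i]]$intervals
      a <- max(1L, iv[1L, "start"] + sample.int(2L * hit_noise + 1L, 1L) - hit_noise - 1L)
      b <- min(chain_length, iv[1L, "end"] + sample.int(2L * hit_noise + 1L, 1L) - hit_noise - 1L)
      if (b < a) b <- a
      hits[[i]]$intervals <- residue_intervals(a, b)
    }
  }
  truth <- partition_chain(chain, true_hits, config)
  list(chain = chain, hits = hits, truth = truth)
}

#' Generate a random TM profile
#'
#' Segments get lengths uniform on 15..35 residues, centroids at distinct
#' ring positions, and an up/down orientation pattern drawn uniformly but
#' constrained to have no nontrivial cyclic symmetry: a rotation of a
#' cyclically symmetric profile is indistinguishable from the original, so
#' aperiodic patterns are what make circular-permutation recovery
#' well-posed. Uses the current RNG state; seed with [set.seed()].
#'
#' @param n number of segments (>= 3).
#' @param label profile label.
#' @return a [tm_profile()].
#' @export
random_profile <- function(n, label = "random") {
  n <- as.integer(n)
  if (n < 3L) stop("random profiles need >= 3 segments")
  repeat {
    pat <- sample(c("UP", "DOWN"), n, replace = TRUE)
    periodic <- any(vapply(seq_len(n - 1L), function(k)
      all(pat == pat[((seq_len(n) - 1L + k) %% n) + 1L]), logical(1)))
    if (!periodic) break
  }
  lens <- sample(15:35, n, replace = TRUE)
  angles <- sort(sample(0:71, n) * 5)     # distinct ring angles, degrees
  th <- angles * pi / 180
  pos <- 1L
  segs <- vector("list", n)
  for (i in seq_len(n)) {
    ax <- if (pat[i] == "UP") c(0, 0, 1) else c(0, 0, -1)
    segs[[i]] <- list(interval = residue_intervals(pos, pos + lens[i] - 1L),
                      axis = ax,
                      centroid = c(12 * cos(th[i]), 12 * sin(th[i]), 0),
                      orientation = pat[i],
                      is_core = TRUE, is_coupling_helix = FALSE)
    pos <- pos + lens[i] + 5L
  }
  tm_profile(segs, membrane_frame(), label)
}
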
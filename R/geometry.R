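#' Membrane reference frame
#'
#' The frame fixes which side of the membrane is "outside": `normal` is a
#' unit vector pointing toward it, and `origin` a point on the membrane
#' mid-plane. The default frame (normal `+z`, origin at the coordinate
#' centroid) matches the usual convention of membrane-oriented structure
#' databases, with the bilayer horizontal.
#'
#' @param normal 3-vector; normalized internally, must be non-zero.
#' @param origin 3-point on the mid-plane.
#' @return an object of class `"membrane_frame"`.
#' @export
membrane_frame <- function(normal = c(0, 0, 1), origin = c(0, 0, 0)) {
  normal <- as.numeric(normal)
  if (length(normal) != 3L || any(is.na(normal)))
    stop("normal must be a 3-vector")
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-9) stop("membrane normal must be non-zero")
  structure(list(normal = normal / nn, origin = as.numeric(origin)),
            class = "membrane_frame")
}

#' Fit a helix axis
#'
#' The axis is estimated from the second differences of consecutive
#' C-alpha positions: along an ideal helix the axial component of a
#' second difference cancels exactly (the rise is constant), leaving pure
#' curvature vectors that lie in the plane perpendicular to the axis, so
#' their smallest principal direction recovers the construction axis to
#' machine precision for any twist — a plain principal component of the
#' point cloud is biased by a fraction of a degree on helices with
#' incomplete turns. Where the curvature vectors are degenerate (straight
#' or planar traces) the fit falls back to the dominant principal
#' direction of the centered points. The sign is chosen to point from the
#' N- toward the C-terminus (`(last - first) . axis > 0`).
#'
#' @param coords numeric matrix, one C-alpha per row (x, y, z), in chain
#'   order; at least 5 points.
#' @return list with unit `axis` and `centroid`.
#' @export
fit_helix_axis <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 5L) stop("helix axis fit needs at least 5 C-alpha points")
  centroid <- colMeans(coords)
  x <- sweep(coords, 2L, centroid)
  s <- svd(x, nu = 0L, nv = 3L)
  if (s$d[1] < 1e-9) stop("cannot fit an axis: points are coincident")
  d2 <- coords[3:n, , drop = FALSE] - 2 * coords[2:(n - 1L), , drop = FALSE] +
    coords[1:(n - 2L), , drop = FALSE]
  s2 <- svd(d2, nu = 0L, nv = 3L)
  axis <- if (s2$d[2] > 1e-6 * max(s2$d[1], 1)) {
    s2$v[, 3L]              # normal of the curvature plane
  } else {
    s$v[, 1L]               # degenerate curvature: principal direction
  }
  nc <- coords[n, ] - coords[1L, ]
  if (sum(nc * axis) < 0) axis <- -axis
  list(axis = axis, centroid = centroid)
}

#' Orientation of a segment relative to the membrane normal
#'
#' `UP` when the N-to-C axis points with the normal (cosine above
#' `orientation_min_cos`), `DOWN` when against it, `UNDEFINED` for a
#' near-in-plane helix.
#'
#' @param axis unit 3-vector (N-to-C).
#' @param frame a [membrane_frame()].
#' @param orientation_min_cos cosine threshold (default from [tm_config()]).
#' @return `"UP"`, `"DOWN"` or `"UNDEFINED"`.
#' @export
segment_orientation <- function(axis, frame,
                                orientation_min_cos = tm_config()$orientation_min_cos) {
  cs <- sum(axis * frame$normal)
  if (cs > orientation_min_cos) "UP"
  else if (cs < -orientation_min_cos) "DOWN"
  else "UNDEFINED"
}

## project a point into the membrane plane of `frame`
project_in_plane <- function(p, frame) {
  n <- frame$normal
  p - sum((p - frame$origin) * n) * n
}

#' Handedness of one consecutive segment triplet
#'
#' The three segment centroids are projected into the membrane plane; the
#' turn sense of the walk `c1 -> c2 -> c3`, viewed from the +normal side,
#' is the triplet's chirality. Under the default convention
#' (`"clockwise_R"`) a clockwise turn is right-handed (`"R"`) and a
#' counterclockwise turn left-handed (`"L"`). The normalized chirality
#' score `normal . (d1 x d2) / (|d1| |d2|)` within `degeneracy_tol` of
#' zero (near-collinear centroids) gives `"X"`.
#'
#' @param c1,c2,c3 3-point centroids of three consecutive segments.
#' @param frame a [membrane_frame()].
#' @param config a [tm_config()] (uses `degeneracy_tol`,
#'   `handedness_convention`).
#' @return `"R"`, `"L"` or `"X"`.
#' @export
triplet_handedness <- function(c1, c2, c3, frame, config = tm_config()) {
  p <- lapply(list(c1, c2, c3), project_in_plane, frame = frame)
  eps <- 1e-9
  if (sqrt(sum((p[[2]] - p[[1]])^2)) < eps ||
      sqrt(sum((p[[3]] - p[[2]])^2)) < eps ||
      sqrt(sum((p[[3]] - p[[1]])^2)) < eps)
    stop("projected centroids coincide; triplet handedness undefined")
  d1 <- p[[2]] - p[[1]]
  d2 <- p[[3]] - p[[2]]
  cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
          d1[3] * d2[1] - d1[1] * d2[3],
          d1[1] * d2[2] - d1[2] * d2[1])
  s <- sum(frame$normal * cr) / (sqrt(sum(d1^2)) * sqrt(sum(d2^2)))
  lab <- if (s > config$degeneracy_tol) "L"
         else if (s < -config$degeneracy_tol) "R"
         else "X"
  if (config$handedness_convention == "clockwise_L")
    lab <- chartr("RL", "LR", lab)
  lab
}

#' Handedness string of a TM profile
#'
#' Concatenates the chirality labels of every consecutive segment triplet
#' in chain order, e.g. `"RRLL"` for a six-segment bundle whose first two
#' triplets are right-handed and last two left-handed.
#'
#' @param profile a [tm_profile()].
#' @param core_only use only segments flagged as core (default `TRUE`).
#' @param config a [tm_config()].
#' @return a string over `{R, L, X}` of length `n_segments - 2`.
#' @export
handedness_string <- function(profile, core_only = TRUE, config = tm_config()) {
  segs <- profile$segments
  if (core_only) segs <- Filter(function(s) isTRUE(s$is_core), segs)
  if (length(segs) < 3L)
    stop("handedness string needs at least 3 qualifying segments")
  cents <- lapply(segs, `[[`, "centroid")
  labs <- vapply(seq_len(length(segs) - 2L), function(i) {
    triplet_handedness(cents[[i]], cents[[i + 1L]], cents[[i + 2L]],
                       profile$frame, config)
  }, character(1))
  paste(labs, collapse = "")
}

#' Construct a TM profile from segments
#'
#' Low-level constructor; most users will call [build_profile()] (from
#' coordinates) or [random_profile()] instead. Segments are sorted into
#' chain order and re-indexed 1..n.
#'
#' @param segments list of segment lists, each with fields `interval`
#'   (1x2 interval matrix), `axis`, `centroid`, `orientation`, `is_core`,
#'   `is_coupling_helix`.
#' @param frame a [membrane_frame()].
#' @param label free-text profile label.
#' @return an object of class `"tm_profile"`.
#' @export
tm_profile <- function(segments, frame = membrane_frame(), label = "") {
  if (length(segments) < 1L) stop("a TM profile needs at least one segment")
  starts <- vapply(segments, function(s) s$interval[1L, "start"], integer(1))
  segments <- segments[order(starts)]
  iv <- do.call(rbind, lapply(segments, `[[`, "interval"))
  if (iv_overlaps(residue_intervals(iv[, "start"], iv[, "end"])))
    stop("TM segment intervals must not overlap")
  for (i in seq_along(segments)) segments[[i]]$index <- i
  structure(list(segments = segments, frame = frame, label = label),
            class = "tm_profile")
}

n_segments <- function(profile) length(profile$segments)

segment_lengths <- function(profile)
  vapply(profile$segments, function(s)
    s$interval[1L, "end"] - s$interval[1L, "start"] + 1L, integer(1))

segment_orientations <- function(profile)
  vapply(profile$segments, `[[`, character(1), "orientation")

#' Build a TM profile from chain coordinates
#'
#' Fits an axis and centroid for every annotated transmembrane range,
#' assigns the membrane orientation, and attaches core / coupling-helix
#' flags. Ranges are processed in chain order regardless of input order.
#'
#' @param coords data frame with columns `resno`, `x`, `y`, `z` (C-alpha
#'   per residue), as returned by [read_structure()].
#' @param tm_ranges interval matrix of TM segment ranges, or a data frame
#'   with columns `start`, `end` and optionally `is_core`, `is_coupling`.
#' @param frame a [membrane_frame()].
#' @param config a [tm_config()].
#' @param label profile label.
#' @return a [tm_profile()].
#' @export
build_profile <- function(coords, tm_ranges, frame = membrane_frame(),
                          config = tm_config(), label = "") {
  if (is.matrix(tm_ranges))
    tm_ranges <- data.frame(start = tm_ranges[, "start"], end = tm_ranges[, "end"])
  if (is.null(tm_ranges$is_core)) tm_ranges$is_core <- TRUE
  if (is.null(tm_ranges$is_coupling)) tm_ranges$is_coupling <- FALSE
  tm_ranges <- tm_ranges[order(tm_ranges$start), , drop = FALSE]
  segs <- vector("list", nrow(tm_ranges))
  for (i in seq_len(nrow(tm_ranges))) {
    a <- tm_ranges$start[i]; b <- tm_ranges$end[i]
    sel <- coords$resno >= a & coords$resno <= b
    want <- b - a + 1L
    if (sum(sel) < 0.8 * want)
      stop(sprintf("TM range %d-%d has C-alpha coverage below 80%% (%d of %d residues)",
                   a, b, sum(sel), want))
    if (sum(sel) < 5L)
      stop(sprintf("TM range %d-%d has fewer than 5 C-alpha atoms", a, b))
    xyz <- as.matrix(coords[sel, c("x", "y", "z")])
    fit <- fit_helix_axis(xyz)
    segs[[i]] <- list(
      interval = residue_intervals(a, b),
      axis = fit$axis,
      centroid = fit$centroid,
      orientation = segment_orientation(fit$axis, frame,
                                        config$orientation_min_cos),
      is_core = as.logical(tm_ranges$is_core[i]),
      is_coupling_helix = as.logical(tm_ranges$is_coupling[i]))
  }
  tm_profile(segs, frame, label)
}

#' @export
print.tm_profile <- function(x, ...) {
  cat(sprintf("TM profile%s: %d segments\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              n_segments(x)))
  for (s in x$segments) {
    cat(sprintf("  TM%-2d %-9s %-9s core=%d coupling=%d  centroid (%.1f, %.1f, %.1f)\n",
                s$index, deparse_intervals(s$interval), s$orientation,
                s$is_core, s$is_coupling_helix,
                s$centroid[1], s$centroid[2], s$centroid[3]))
  }
  nc <- sum(vapply(x$segments, function(s) isTRUE(s$is_core), logical(1)))
  if (nc >= 3L)
    cat("  core handedness:", handedness_string(x), "\n")
  invisible(x)
}

#' @export
as.data.frame.tm_profile <- function(x, ...) {
  do.call(rbind, lapply(x$segments, function(s) {
    data.frame(index = s$index,
               start = s$interval[1L, "start"], end = s$interval[1L, "end"],
               axis_x = s$axis[1], axis_y = s$axis[2], axis_z = s$axis[3],
               cx = s$centroid[1], cy = s$centroid[2], cz = s$centroid[3],
               orientation = s$orientation,
               is_core = s$is_core, is_coupling = s$is_coupling_helix)
  }))
}
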
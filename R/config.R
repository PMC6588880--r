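#' Toolkit configuration
#'
#' Collects every tunable threshold of the partition, geometry and alignment
#' routines in one validated list. All arguments have defaults; pass only
#' what you want to change. Values loaded from a YAML file via
#' [read_config()] override these defaults, and individual arguments
#' override the file.
#'
#' @param min_cover_frac minimum covered fraction of classifiable residues
#'   for a chain to be auto-accepted (default 0.90).
#' @param gap_max an unassigned run of this many residues or more counts as
#'   a novel region (default 30).
#' @param overlap_tol_residues maximum residue overlap a new hit may have
#'   with already-accepted assignments (default 10).
#' @param overlap_tol_frac same bound as a fraction of the incoming hit's
#'   own length (default 0.25); both bounds must hold.
#' @param conflict_score_ratio a rejected hit scoring at least this fraction
#'   of an accepted hit it overlaps (beyond tolerance) marks the parse as
#'   having comparable competing interpretations (default 0.8).
#' @param min_ref_coverage reference coverage below which a hit is dropped
#'   outright (default 0.3).
#' @param fragment_coverage reference coverage below which a retained hit is
#'   rejected as a fragment of a known domain (default 0.5).
#' @param min_domain_len minimum total query length of a usable hit
#'   (default 20 residues).
#' @param peptide_max_len chains shorter than this with no assignment are
#'   tagged PEPTIDE (default 20).
#' @param orientation_min_cos minimum |cos| between a segment axis and the
#'   membrane normal for an UP/DOWN call (default 0.5, i.e. within 60
#'   degrees of the normal).
#' @param degeneracy_tol normalized chirality scores within this band of
#'   zero are labelled X (default 0.05).
#' @param handedness_convention `"clockwise_R"` (default): a triplet whose
#'   projected centroids progress clockwise when viewed from the +normal
#'   side is right-handed. `"clockwise_L"` flips every label.
#' @param w_or,w_len orientation and length weights of the segment pair
#'   score (defaults 2.0 and 1.0).
#' @param g_open,g_ext affine penalty for an internal gap of k segments,
#'   `g_open + g_ext * (k - 1)` (defaults 1.5 and 0.5); end gaps are free.
#' @param cp_margin a nonzero circular permutation is reported only when
#'   its score beats the unrotated alignment by more than this (default 0.5).
#' @return a named list of class `"tmtopo_config"`.
#' @examples
#' cfg <- tm_config(gap_max = 25)
#' cfg$gap_max
#' @export
tm_config <- function(min_cover_frac = 0.90,
                      gap_max = 30L,
                      overlap_tol_residues = 10L,
                      overlap_tol_frac = 0.25,
                      conflict_score_ratio = 0.8,
                      min_ref_coverage = 0.3,
                      fragment_coverage = 0.5,
                      min_domain_len = 20L,
                      peptide_max_len = 20L,
                      orientation_min_cos = 0.5,
                      degeneracy_tol = 0.05,
                      handedness_convention = c("clockwise_R", "clockwise_L"),
                      w_or = 2.0,
                      w_len = 1.0,
                      g_open = 1.5,
                      g_ext = 0.5,
                      cp_margin = 0.5) {
  handedness_convention <- match.arg(handedness_convention)
  cfg <- list(
    min_cover_frac = as.numeric(min_cover_frac),
    gap_max = as.integer(gap_max),
    overlap_tol_residues = as.integer(overlap_tol_residues),
    overlap_tol_frac = as.numeric(overlap_tol_frac),
    conflict_score_ratio = as.numeric(conflict_score_ratio),
    min_ref_coverage = as.numeric(min_ref_coverage),
    fragment_coverage = as.numeric(fragment_coverage),
    min_domain_len = as.integer(min_domain_len),
    peptide_max_len = as.integer(peptide_max_len),
    orientation_min_cos = as.numeric(orientation_min_cos),
    degeneracy_tol = as.numeric(degeneracy_tol),
    handedness_convention = handedness_convention,
    w_or = as.numeric(w_or),
    w_len = as.numeric(w_len),
    g_open = as.numeric(g_open),
    g_ext = as.numeric(g_ext),
    cp_margin = as.numeric(cp_margin)
  )
  validate_config(cfg)
  class(cfg) <- "tmtopo_config"
  cfg
}

validate_config <- function(cfg) {
  fracs <- c("min_cover_frac", "overlap_tol_frac", "conflict_score_ratio",
             "min_ref_coverage", "fragment_coverage")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("config field '%s' must be a fraction in [0, 1]", f))
  }
  lens <- c("gap_max", "overlap_tol_residues", "min_domain_len", "peptide_max_len")
  for (f in lens) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("config field '%s' must be a non-negative length", f))
  }
  pos <- c("w_or", "w_len", "g_open", "g_ext")
  for (f in pos) {
    if (cfg[[f]] < 0) stop(sprintf("config field '%s' must be non-negative", f))
  }
  invisible(cfg)
}

#' Read a YAML configuration file
#'
#' Keys in the file override the package defaults; unknown keys are an
#' error so typos do not silently fall back to a default.
#'
#' @param path YAML file of `key: value` pairs naming [tm_config()] fields.
#' @return a `tmtopo_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(tm_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(tm_config, vals)
}

#' @export
print.tmtopo_config <- function(x, ...) {
  cat("tmtopo configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
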
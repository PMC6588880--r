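#' Read C-alpha coordinates from a PDB or mmCIF file
#'
#' Parses the file with bio3d (`read.pdb` / `read.cif`, chosen by file
#' extension), keeps the first model only, selects one chain, and prefers
#' altloc `A` where alternate locations exist.
#'
#' @param path path to a `.pdb` / `.ent` or `.cif` / `.mmcif` file.
#' @param chain_id chain to extract; default `NULL` takes the first chain
#'   in the file.
#' @return data frame with columns `resno`, `chain`, `x`, `y`, `z`, one
#'   C-alpha per residue in chain order.
#' @export
read_structure <- function(path, chain_id = NULL) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  } else {
    bio3d::read.pdb(path, verbose = FALSE, multi = FALSE)
  }
  at <- pdb$atom
  ca <- at[at$elety == "CA" & at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (is.null(chain_id)) chain_id <- ca$chain[1L]
  ca <- ca[!is.na(ca$chain) & ca$chain == chain_id, , drop = FALSE]
  if (nrow(ca) == 0L)
    stop(sprintf("no C-alpha atoms for chain '%s' in %s", chain_id, path))
  alt_ok <- is.na(ca$alt) | ca$alt %in% c("", "A")
  ca <- ca[alt_ok, , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  data.frame(resno = as.integer(ca$resno), chain = ca$chain,
             x = ca$x, y = ca$y, z = ca$z)
}

#' Write C-alpha coordinates as PDB or mmCIF
#'
#' `write_structure_pdb` delegates to [bio3d::write.pdb()];
#' `write_structure_cif` writes a minimal `atom_site` loop (the installed
#' stack has mmCIF reading but no writer). Both emit poly-alanine C-alpha
#' traces, which is all the synthetic fixtures contain.
#'
#' @param coords data frame with columns `resno`, `x`, `y`, `z` (and
#'   optionally `chain`, default `"A"`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(coords, path) {
  ch <- if (is.null(coords$chain)) rep("A", nrow(coords)) else as.character(coords$chain)
  n <- nrow(coords)
  xyz <- as.numeric(t(as.matrix(coords[, c("x", "y", "z")])))
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz, type = rep("ATOM", n),
                   resno = coords$resno, resid = rep("ALA", n), chain = ch,
                   eleno = seq_len(n), elety = rep("CA", n),
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' @rdname write_structure_pdb
#' @export
write_structure_cif <- function(coords, path) {
  ch <- if (is.null(coords$chain)) rep("A", nrow(coords)) else as.character(coords$chain)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "data_synthetic",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"), con)
  writeLines(sprintf(
    "ATOM %d C CA . ALA %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d ALA %s CA 1",
    seq_len(nrow(coords)), ch, coords$resno,
    coords$x, coords$y, coords$z, coords$resno, ch), con)
  writeLines("#", con)
  invisible(path)
}

#' Read and write alignment-hit tables
#'
#' TSV dialect with header columns `chain_id`, `ref_domain_id`,
#' `q_intervals` (comma-separated `"start-end"` pairs), `ref_length`,
#' `ref_coverage`, `score`.
#'
#' @param path TSV path.
#' @return `read_hits_tsv`: a named list (one element per chain) of lists
#'   of [alignment_hit()].
#' @export
read_hits_tsv <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("chain_id", "ref_domain_id", "q_intervals", "ref_length",
            "ref_coverage", "score")
  if (!all(need %in% names(df)))
    stop("hit table must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(df))) {
    h <- alignment_hit(df$ref_domain_id[i], parse_intervals(df$q_intervals[i]),
                       as.integer(df$ref_length[i]),
                       as.numeric(df$ref_coverage[i]), as.numeric(df$score[i]))
    cid <- df$chain_id[i]
    out[[cid]] <- c(out[[cid]], list(h))
  }
  out
}

#' @rdname read_hits_tsv
#' @param hits_by_chain named list of hit lists, as from [read_hits_tsv()].
#' @export
write_hits_tsv <- function(hits_by_chain, path) {
  rows <- list()
  for (cid in names(hits_by_chain)) {
    for (h in hits_by_chain[[cid]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain_id = cid, ref_domain_id = h$ref_domain_id,
        q_intervals = deparse_intervals(h$intervals),
        ref_length = h$ref_length, ref_coverage = h$ref_coverage,
        score = h$score)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write chain metadata tables
#'
#' TSV dialect with columns `chain_id`, `length`, `unknown_runs`,
#' `tm_runs` (interval lists, `"."` for none), `method`, `synthetic` (0/1).
#'
#' @param path TSV path.
#' @return `read_chains_tsv`: named list of [chain_record()].
#' @export
read_chains_tsv <- function(path) {
  if (!file.exists(path)) stop("chain table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("chain_id", "length", "unknown_runs", "tm_runs", "method", "synthetic")
  if (!all(need %in% names(df)))
    stop("chain table must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(df))) {
    out[[df$chain_id[i]]] <- chain_record(
      df$chain_id[i], as.integer(df$length[i]),
      parse_intervals(df$unknown_runs[i]), parse_intervals(df$tm_runs[i]),
      df$method[i], df$synthetic[i] %in% c("1", "TRUE", "true"))
  }
  out
}

#' @rdname read_chains_tsv
#' @param chains named list of [chain_record()].
#' @export
write_chains_tsv <- function(chains, path) {
  rows <- lapply(chains, function(ch) data.frame(
    chain_id = ch$chain_id, length = ch$length,
    unknown_runs = deparse_intervals(iv_from_residues(ch$unknown_mask)),
    tm_runs = deparse_intervals(ch$tm_annotations),
    method = ch$method, synthetic = as.integer(ch$synthetic)))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write TM-range tables
#'
#' TSV dialect with columns `chain_id`, `seg_index`, `start`, `end`,
#' `is_core` (0/1), `is_coupling` (0/1).
#'
#' @param path TSV path.
#' @param chain_id optional filter to one chain.
#' @return data frame of ranges.
#' @export
read_tm_ranges_tsv <- function(path, chain_id = NULL) {
  if (!file.exists(path)) stop("TM range table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chain_id", "seg_index", "start", "end", "is_core", "is_coupling")
  if (!all(need %in% names(df)))
    stop("TM range table must have columns: ", paste(need, collapse = ", "))
  if (!is.null(chain_id)) df <- df[df$chain_id == chain_id, , drop = FALSE]
  df$is_core <- df$is_core %in% c(1, "1", TRUE, "TRUE")
  df$is_coupling <- df$is_coupling %in% c(1, "1", TRUE, "TRUE")
  df[order(df$start), , drop = FALSE]
}

#' @rdname read_tm_ranges_tsv
#' @param ranges data frame with `seg_index`, `start`, `end`, `is_core`,
#'   `is_coupling`.
#' @export
write_tm_ranges_tsv <- function(ranges, path, chain_id = "A") {
  df <- data.frame(chain_id = chain_id, seg_index = ranges$seg_index,
                   start = ranges$start, end = ranges$end,
                   is_core = as.integer(ranges$is_core),
                   is_coupling = as.integer(ranges$is_coupling))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

json_schema_version <- "1.0"

#' Serialize results to JSON
#'
#' All JSON documents carry a top-level `schema_version` field.
#'
#' @param x a `partition_result`, `tm_profile` or `topology_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  obj <- if (inherits(x, "partition_result")) {
    list(schema_version = json_schema_version,
         type = "partition_result",
         chain_id = x$chain_id,
         outcome = x$outcome,
         covered_frac = x$covered_frac,
         conflict = x$conflict_flag,
         reasons = as.list(x$reasons),
         architecture_tags = as.list(x$architecture_tags),
         method = if (is.null(x$method)) NA else x$method,
         assignments = lapply(x$assignments, function(a) list(
           ref_domain_id = a$ref_domain_id,
           intervals = deparse_intervals(a$intervals),
           trimmed_residues = a$trimmed_residues)),
         gaps = deparse_intervals(x$gaps))
  } else if (inherits(x, "tm_profile")) {
    list(schema_version = json_schema_version,
         type = "tm_profile",
         label = x$label,
         normal = x$frame$normal,
         segments = lapply(x$segments, function(s) list(
           index = s$index,
           interval = deparse_intervals(s$interval),
           axis = s$axis, centroid = s$centroid,
           orientation = s$orientation,
           is_core = s$is_core, is_coupling_helix = s$is_coupling_helix)),
         handedness = tryCatch(handedness_string(x), error = function(e) NA))
  } else if (inherits(x, "topology_alignment")) {
    list(schema_version = json_schema_version,
         type = "topology_alignment",
         pairs = if (nrow(x$pairs)) apply(x$pairs, 1L, as.list) else list(),
         gaps_A = as.list(x$gaps_A), gaps_B = as.list(x$gaps_B),
         score = x$score,
         permutation_offset = x$permutation_offset,
         handedness_identity = x$handedness_identity)
  } else stop("no JSON serializer for class ", paste(class(x), collapse = "/"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a partition-result JSON back into summary form
#'
#' Reconstructs the minimal fields [summarize_outcomes()] needs from a
#' JSON document written by [write_result_json()].
#'
#' @param path JSON path.
#' @return a `partition_result`-classed list.
#' @export
read_result_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$type, "partition_result"))
    stop("not a partition_result document: ", path)
  structure(list(chain_id = obj$chain_id,
                 assignments = obj$assignments,
                 gaps = parse_intervals(obj$gaps),
                 covered_frac = obj$covered_frac,
                 conflict_flag = obj$conflict,
                 outcome = obj$outcome,
                 reasons = unlist(obj$reasons),
                 architecture_tags = as.character(unlist(obj$architecture_tags)),
                 method = if (is.null(obj$method) || is.na(obj$method)) NULL else obj$method),
            class = "partition_result")
}
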
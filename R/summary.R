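## round-half-up integer percentage (the summary convention; R's round()
## would round half to even)
pct_half_up <- function(count, total) as.integer(floor(100 * count / total + 0.5))

special_tags <- c("PEPTIDE", "FRAGMENT", "SYNTHETIC")

#' Summarize a collection of curation outcomes
#'
#' Counts, over a set of partitioned chains, the categories reported in
#' curation statistics: chains with any unclassifiable region, chains
#' entirely / partly classified into a special architecture (peptide,
#' fragment, synthetic construct), chains with at least one assigned
#' domain, single- and multi-domain chains, chains containing a
#' transmembrane segment, and chains from X-ray or EM structures.
#' Percentages are round-half-up integers of `100 * count / total`.
#'
#' @param results list of `partition_result` objects (as produced by
#'   [partition_chain()], which records each chain's experimental method).
#' @return an object of class `"curation_summary"`: a data frame with
#'   columns `category`, `count`, `percent`, and attribute `total_chains`.
#' @export
summarize_outcomes <- function(results) {
  if (length(results) == 0L) stop("cannot summarize an empty outcome list")
  has_tag <- function(r, tag) tag %in% r$architecture_tags
  n_assign <- vapply(results, function(r) length(r$assignments), integer(1))
  special <- vapply(results, function(r) any(r$architecture_tags %in% special_tags),
                    logical(1))
  gaps <- vapply(results, function(r) nrow(r$gaps) > 0L, logical(1))
  method <- vapply(results, function(r) {
    if (is.null(r$method)) "OTHER" else r$method
  }, character(1))
  cat_counts <- c(
    any_unclassifiable_region = sum(special | gaps | n_assign == 0L),
    all_special_architecture  = sum(special & n_assign == 0L),
    part_special_architecture = sum(special & n_assign > 0L),
    any_domain_assigned       = sum(n_assign > 0L),
    single_domain_only        = sum(vapply(results, has_tag, logical(1), "SINGLE_DOMAIN")),
    multi_domain              = sum(vapply(results, has_tag, logical(1), "MULTI_DOMAIN")),
    tm_containing             = sum(vapply(results, has_tag, logical(1), "TM_CONTAINING")),
    xray                      = sum(method == "XRAY"),
    em                        = sum(method == "EM")
  )
  total <- length(results)
  out <- data.frame(category = names(cat_counts),
                    count = as.integer(cat_counts),
                    percent = pct_half_up(cat_counts, total),
                    row.names = NULL)
  attr(out, "total_chains") <- total
  class(out) <- c("curation_summary", "data.frame")
  out
}

#' @export
print.curation_summary <- function(x, ...) {
  cat(sprintf("curation summary over %d chains\n", attr(x, "total_chains")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write / read a curation summary as TSV
#'
#' @param summary a `curation_summary`.
#' @param path output TSV path.
#' @export
write_summary_tsv <- function(summary, path) {
  df <- as.data.frame(summary)
  df <- rbind(data.frame(category = "total_chains",
                         count = attr(summary, "total_chains"),
                         percent = 100L),
              df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
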
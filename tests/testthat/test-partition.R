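cfg <- tm_config()

test_that("hit filtering applies the length floor and tiered coverage rule", {
  good <- alignment_hit("d1", "1-150", 150, 0.95, 50)
  short <- alignment_hit("d2", "1-15", 100, 0.95, 50)
  frag <- alignment_hit("d3", "1-60", 200, 0.30, 50)
  junk <- alignment_hit("d4", "1-60", 300, 0.20, 50)

  f <- filter_hits(list(good, short, frag, junk), cfg)
  expect_length(f$kept, 1L)
  expect_identical(f$kept[[1]]$ref_domain_id, "d1")
  ## cov 0.30 sits between min_ref_coverage and fragment_coverage:
  ## rejected but retained as fragment evidence; the short hit is
  ## retained with a length reason
  expect_identical(f$reject_reason, c("TOO_SHORT", "FRAGMENT"))
  expect_identical(vapply(f$rejected, `[[`, "", "ref_domain_id"),
                   c("d2", "d3"))
  ## cov 0.20 is below the retention floor: gone entirely
  expect_false("d4" %in% vapply(f$rejected, `[[`, "", "ref_domain_id"))
  ## short hits at good coverage are rejected for length, not as fragments
  f2 <- filter_hits(list(short), cfg)
  expect_identical(f2$reject_reason, "TOO_SHORT")
  expect_length(filter_hits(list(), cfg)$kept, 0L)
})

test_that("overlap resolution follows the greedy rule with trimming and conflict detection", {
  ## disjoint hits: both accepted, no conflict
  r <- resolve_overlaps(list(alignment_hit("a", "1-100", 100, .9, 50),
                             alignment_hit("b", "120-200", 81, .9, 40)), cfg)
  expect_length(r$assignments, 2L)
  expect_false(r$conflict_flag)

  ## 41-residue overlap >> tolerance: lower-scoring hit rejected; its
  ## score 95 >= 0.8 * 100 makes the parses comparable -> conflict
  r <- resolve_overlaps(list(alignment_hit("A", "1-120", 120, .9, 100),
                             alignment_hit("B", "80-200", 121, .9, 95)), cfg)
  expect_length(r$assignments, 1L)
  expect_identical(r$assignments[[1]]$ref_domain_id, "A")
  expect_true(r$conflict_flag)

  ## same geometry, weak competitor: no conflict
  r <- resolve_overlaps(list(alignment_hit("A", "1-120", 120, .9, 100),
                             alignment_hit("B", "80-200", 121, .9, 60)), cfg)
  expect_false(r$conflict_flag)

  ## 6-residue overlap <= tolerance: accepted with the overlap trimmed
  ## from the lower-priority hit (hand-evaluated: B keeps 121-230)
  r <- resolve_overlaps(list(alignment_hit("A", "1-120", 120, .9, 100),
                             alignment_hit("B", "115-230", 116, .9, 95)), cfg)
  expect_length(r$assignments, 2L)
  expect_equal(deparse_intervals(r$assignments[[2]]$intervals), "121-230")
  expect_identical(r$assignments[[2]]$trimmed_residues, 6L)
  expect_false(r$conflict_flag)
})

test_that("greedy priority is score, then length, then id, and is deterministic", {
  ## equal scores: the longer hit wins the overlap
  r <- resolve_overlaps(list(alignment_hit("short", "1-100", 100, .9, 50),
                             alignment_hit("long", "1-150", 150, .9, 50)), cfg)
  expect_identical(r$assignments[[1]]$ref_domain_id, "long")
  ## equal score and length: lexicographic id
  r <- resolve_overlaps(list(alignment_hit("zzz", "1-100", 100, .9, 50),
                             alignment_hit("aaa", "1-100", 100, .9, 50)), cfg)
  expect_identical(r$assignments[[1]]$ref_domain_id, "aaa")
})

test_that("coverage arithmetic matches hand-computed values and masks are excluded", {
  ch <- chain_record("c", 100L)
  asg <- resolve_overlaps(list(alignment_hit("d", "1-100", 100, .95, 50)), cfg)$assignments
  cv <- compute_coverage(asg, ch)
  expect_equal(cv$covered_frac, 1.0)
  expect_identical(nrow(cv$gaps), 0L)

  ch150 <- chain_record("c", 150L)
  cv <- compute_coverage(asg, ch150)
  expect_equal(cv$covered_frac, 100 / 150, tolerance = 1e-12)
  expect_equal(deparse_intervals(cv$gaps), "101-150")

  ## masked tail excluded from the denominator and from gaps
  chm <- chain_record("c", 150L, unknown_runs = "101-150")
  cv <- compute_coverage(asg, chm)
  expect_equal(cv$covered_frac, 1.0)
  expect_identical(nrow(cv$gaps), 0L)

  ## assignment beyond the chain is an error
  expect_error(compute_coverage(asg, chain_record("c", 90L)), "exceeds")
})

test_that("outcome decision separates the three flagging reasons", {
  ch <- chain_record("c", 100L)
  hits <- list(alignment_hit("d", "1-100", 100, .95, 50))
  res <- partition_chain(ch, hits, cfg)
  expect_identical(res$outcome, "AUTO_ACCEPTED")
  expect_length(res$reasons, 0L)

  ## a 100-residue uncovered run is a novel region
  res <- partition_chain(chain_record("c", 200L), hits, cfg)
  expect_identical(res$outcome, "FLAGGED")
  expect_identical(res$reasons, "NOVEL_REGION")

  ## comparable competing parses are inconsistent boundaries
  ch2 <- chain_record("c", 200L)
  res <- partition_chain(ch2, list(alignment_hit("A", "1-120", 120, .9, 100),
                                   alignment_hit("B", "80-200", 121, .9, 95)),
                         cfg)
  expect_identical(res$outcome, "FLAGGED")
  expect_true("INCONSISTENT_BOUNDARIES" %in% res$reasons)

  ## a synthetic construct with nothing assignable is UNASSIGNABLE, not novel
  res <- partition_chain(chain_record("c", 60L, synthetic = TRUE), list(), cfg)
  expect_identical(res$outcome, "FLAGGED")
  expect_identical(res$reasons, "UNASSIGNABLE")
})

test_that("architecture tags follow the taxonomy", {
  ## 12-residue chain, no evidence: peptide
  res <- partition_chain(chain_record("p", 12L), list(), cfg)
  expect_true("PEPTIDE" %in% res$architecture_tags)

  ## two accepted assignments: multi-domain
  res <- partition_chain(chain_record("m", 200L),
                         list(alignment_hit("a", "1-100", 100, .9, 50),
                              alignment_hit("b", "101-200", 100, .9, 40)), cfg)
  expect_true("MULTI_DOMAIN" %in% res$architecture_tags)
  expect_false("SINGLE_DOMAIN" %in% res$architecture_tags)

  ## one assignment plus a TM annotation
  res <- partition_chain(chain_record("s", 100L, tm_runs = "30-52"),
                         list(alignment_hit("a", "1-100", 100, .9, 50)), cfg)
  expect_setequal(intersect(res$architecture_tags,
                            c("SINGLE_DOMAIN", "TM_CONTAINING")),
                  c("SINGLE_DOMAIN", "TM_CONTAINING"))

  ## only fragment-rejected evidence: fragment architecture
  res <- partition_chain(chain_record("f", 80L),
                         list(alignment_hit("a", "1-60", 200, .35, 50)), cfg)
  expect_true("FRAGMENT" %in% res$architecture_tags)
  expect_length(res$assignments, 0L)
})

test_that("partition is deterministic and invariant to hit order", {
  set.seed(301)
  for (rep in 1:10) {
    hits <- lapply(1:6, function(i) {
      a <- sample.int(150, 1)
      alignment_hit(sprintf("h%d", i),
                    residue_intervals(a, min(300L, a + sample(30:120, 1))),
                    100L, runif(1, 0.6, 1), runif(1, 10, 100))
    })
    ch <- chain_record("c", 300L)
    r1 <- partition_chain(ch, hits, cfg)
    r2 <- partition_chain(ch, sample(hits), cfg)
    expect_identical(r1, r2)
  }
})

test_that("accepted assignments are disjoint and tile the chain with gaps and mask", {
  set.seed(77)
  cfg0 <- tm_config(overlap_tol_residues = 0L, overlap_tol_frac = 0)
  for (rep in 1:10) {
    hits <- lapply(1:5, function(i) {
      a <- sample.int(200, 1)
      alignment_hit(sprintf("h%d", i),
                    residue_intervals(a, min(260L, a + sample(25:90, 1))),
                    100L, runif(1, 0.6, 1), runif(1, 10, 100))
    })
    ch <- chain_record("c", 260L, unknown_runs = "40-49")
    for (conf in list(cfg, cfg0)) {
      r <- resolve_overlaps(filter_hits(hits, conf)$kept, conf)
      res_sets <- lapply(r$assignments, function(a) {
        s <- integer()
        for (k in seq_len(nrow(a$intervals)))
          s <- c(s, seq.int(a$intervals[k, "start"], a$intervals[k, "end"]))
        s
      })
      all_assigned <- unlist(res_sets)
      expect_identical(anyDuplicated(all_assigned), 0L)  # strictly disjoint
      cv <- compute_coverage(r$assignments, ch)
      gap_res <- if (nrow(cv$gaps)) unlist(lapply(seq_len(nrow(cv$gaps)),
        function(k) seq.int(cv$gaps[k, "start"], cv$gaps[k, "end"]))) else integer()
      mask <- 40:49
      ## every residue in exactly one of assigned / gap / masked
      tiles <- c(setdiff(all_assigned, mask), gap_res, mask)
      expect_identical(sort(tiles), 1:260)
    }
  }
})

test_that("a strictly dominated copy of an accepted hit never changes the accepted set", {
  set.seed(55)
  for (rep in 1:10) {
    hits <- lapply(1:4, function(i) {
      a <- sample.int(150, 1)
      alignment_hit(sprintf("h%d", i),
                    residue_intervals(a, min(250L, a + sample(40:100, 1))),
                    100L, runif(1, 0.6, 1), runif(1, 10, 100))
    })
    base <- resolve_overlaps(filter_hits(hits, cfg)$kept, cfg)
    acc <- base$assignments[[1]]$source_hit
    shrink <- max(1L, nrow(acc$intervals))
    iv <- acc$intervals[1L, , drop = FALSE]
    dominated <- alignment_hit("zzz_dom",
                               residue_intervals(iv[1, "start"],
                                                 max(iv[1, "start"] + 25L,
                                                     iv[1, "end"] - 5L)),
                               acc$ref_length, acc$ref_coverage,
                               acc$score * 0.5)
    with_dom <- resolve_overlaps(filter_hits(c(hits, list(dominated)), cfg)$kept, cfg)
    ids <- function(r) vapply(r$assignments, `[[`, "", "ref_domain_id")
    expect_identical(ids(with_dom), ids(base))
  }
})
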
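---
title: "tmtopo: methods, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tmtopo: methods, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtopo)
```

This vignette is the package's own account of what it computes and why
the defaults are what they are. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The triage problem

Automated domain classification assigns reference domains to new protein
chains from alignment evidence. Most chains are routine; the pipeline
here addresses the residue-level bookkeeping for the rest. A parse is
acceptable when the accepted assignments cover the query (nearly)
completely and do not overlap each other; anything else needs a human,
and the value of an automated triage is that the *reason* is explicit
and reproducible.

### 1.1 Rules and defaults

Evidence is filtered before selection:

| parameter | default | meaning |
|---|---|---|
| `min_domain_len` | 20 res | hits aligning fewer query residues carry no domain signal |
| `min_ref_coverage` | 0.30 | below this fraction of the reference, a hit is discarded outright |
| `fragment_coverage` | 0.50 | in [0.30, 0.50) the hit is rejected but retained as evidence that the chain holds a *fragment* of a known domain |

Selection is greedy in a fully specified order — score descending, then
total aligned length, then reference id lexicographically — so the parse
is deterministic and independent of input order. An incoming hit is
accepted when its overlap with already accepted residues is at most
`overlap_tol_residues` (10) **and** at most `overlap_tol_frac` (0.25) of
its own length; the overlapping residues are trimmed from the incoming
hit. Alignments fray at their edges, so a bounded trim is preferable to
rejecting a hit for a ten-residue disagreement; whether a production
pipeline should trim or reject outright is genuinely open, and trimming
with a bound is this package's choice (the trim is recorded per
assignment as `trimmed_residues`).

Acceptance requires three conditions (defaults: `min_cover_frac` 0.90,
`gap_max` 30 residues, `conflict_score_ratio` 0.8):

* coverage: assigned, non-masked residues ≥ 90% of classifiable
  residues (chain length minus residues masked as unknown). A fully
  masked chain has nothing classifiable and passes vacuously.
* no novel region: no unassigned, unmasked run of ≥ 30 residues. Thirty
  residues is past linker length and approaching the smallest folded
  domains, which is exactly when an uncovered run stops being ignorable.
* no comparable competing parse: no rejected hit with score ≥ 0.8 of an
  accepted hit it overlaps beyond tolerance. Below 0.8 the pipeline can
  defensibly prefer the stronger hit on its own.

Failures map to reasons: competing parses give
`INCONSISTENT_BOUNDARIES`; coverage or gap failures give `NOVEL_REGION`
on ordinary chains. On synthetic constructs — chains with no
evolutionary history, where "no known homolog" is not a meaningful
diagnosis — the same failures are attributed to `UNASSIGNABLE` instead.
This attribution rule is a design decision: no operational definition
exists for the boundary between "novel" and "unassignable", and tying it
to the synthetic flag (plus a fallback for chains flagged with no other
reason) makes the taxonomy total and testable.

Architecture tags are derived afterwards: `PEPTIDE` (length <
`peptide_max_len` 20 and nothing assigned), `SYNTHETIC`, `FRAGMENT`
(the only retained evidence was fragment-rejected), `SINGLE_DOMAIN` /
`MULTI_DOMAIN` (mutually exclusive by assignment count), and
`TM_CONTAINING` (any annotated TM segment; annotations are consumed, not
predicted).

### 1.2 Summary statistics

`summarize_outcomes()` counts, over a set of triaged chains: any
unclassifiable region (a special-architecture tag, an unassigned gap, or
no assignment at all), entirely vs partly special architecture (special
tag without vs with an assignment), any domain assigned, single- and
multi-domain, TM-containing, and X-ray / EM provenance. Percentages are
round-half-up integers of 100·count/total. Published curation statistics
of this kind mix truncation and rounding from one table to the next, so
no single convention reproduces every printed figure; round-half-up is
used consistently and the figures that both conventions agree on are the
ones asserted in tests.

### 1.3 Invariants, and one that needs care

The suite checks determinism under hit permutation, disjointness of
accepted assignments (strict at zero tolerance), and the three-way
tiling of every residue into assigned / gap / masked. One further
property — adding a strictly dominated hit (lower score, subset
intervals) never changes the accepted set — holds when the dominating
hit is itself accepted, and that is how it is tested. It is not true
unconditionally: a dominated subset of a *rejected* hit can fit inside
the tolerance where its parent did not. Greedy selection trades this
edge case for full determinism.

## 2. TM segment geometry

### 2.1 Membrane frame

All orientation and chirality statements are relative to a
`membrane_frame()`: a unit normal pointing to the designated outside and
an origin on the mid-plane. The default is +z with the origin at the
coordinate centroid, i.e. the convention of membrane-oriented structure
databases with the bilayer horizontal. Nothing downstream assumes more
than this frame; structures oriented differently just need the frame
passed in.

### 2.2 Axis fitting

A segment's axis must point from its N- to its C-terminal end to encode
the crossing direction. The fit uses the second differences of
consecutive C-alpha positions: along an ideal helix the rise per residue
is constant, so the axial component of a second difference cancels
exactly and the remaining curvature vectors span the plane perpendicular
to the axis. The smallest principal direction of those vectors is the
axis, recovered to machine precision on ideal helices of any twist. The
more obvious estimator — the dominant principal component of the
centered point cloud — is biased by a fraction of a degree whenever the
helix has incomplete turns (the axial–radial cross-covariance does not
vanish), which matters when a test asserts exact recovery. For
degenerate traces (straight or planar, where curvature vectors lose
rank) the fit falls back to that principal component. Noise tolerance is
tested at σ = 0.3 Å with a 5° bound. Kinked helices are not split: a
broken segment is simply two input ranges.

### 2.3 Orientation

UP iff axis·normal > `orientation_min_cos` (0.5, a 60° tilt limit), DOWN
iff < −0.5, else UNDEFINED. Genuine TM helices rarely tilt past 60°;
beyond that a crossing direction is not meaningful and UNDEFINED is the
honest label. UNDEFINED also earns its keep in the alignment scoring
(§3).

### 2.4 Triplet handedness

Three consecutive segment centroids, projected into the membrane plane,
define a turn. With d₁ = c₂′−c₁′, d₂ = c₃′−c₂′, the normalized score
s = n·(d₁×d₂)/(|d₁||d₂|) is the sine of the turn angle: |s| is small
only for near-collinear centroids, which get the degenerate label X
(`degeneracy_tol` 0.05, about 3° of turn). The label convention —
clockwise viewed from the +normal side is R — is one of two defensible
choices; which side a published figure "views from" is generally not
stated, so the convention is a config switch
(`handedness_convention = "clockwise_L"` flips every label globally)
that can be calibrated once against a single known example. Whether a
published handedness judgement derives from centroids, axis tilts, or
visual inspection is equally unknowable; centroid turn sense is this
package's operationalization, and the properties that matter
(R↔L flip under mirror reflection, under normal negation, and under
traversal reversal; invariance under joint rigid motion) are tested
against an independent signed-area oracle.

## 3. Topology alignment

Correspondence between two TM bundles is argued at segment granularity,
so the alignment is over ordered segment sequences, not residues, and
geometry enters only through per-segment orientation and length. Pair
score: `w_or`·(+1 same crossing direction, −1 opposite, 0 if either is
UNDEFINED) + `w_len`·(1 − |ℓA−ℓB|/max(ℓA,ℓB)), defaults w_or 2, w_len 1
— orientation is the stronger topological signal, length a soft
tie-breaker. End gaps are free (extra terminal segments are common and
uninformative); an internal run of k skipped segments costs
`g_open` + `g_ext`·(k−1) = 1.5 + 0.5·(k−1). The DP maximizes over the
last matched pair, which is exact for this cost model and, at bundle
sizes (≤ ~15 segments), makes the O(n²m²) predecessor scan cheaper than
maintaining three Gotoh matrices. Ties break toward fewer internal
gapped segments, then a fixed predecessor preference that places
unavoidable gaps leftmost and keeps the A/B-transpose symmetry checked
by the tests. The DP score is verified against exhaustive enumeration of
all monotone pair sets on small profiles.

One consequence of this scoring model is worth stating plainly: a block
of inserted segments whose orientations continue the bundle's U/D
alternation and that sits adjacent to a free end can be absorbed by
shifting the register (cost ≤ w_len for one imperfect pair) more cheaply
than by opening an internal gap (cost 2.0 plus a lost pair). Segment
orientation and length simply do not determine the correct
correspondence in that case. The insertion fixtures therefore model
inserted pairs as strongly tilted, non-spanning hairpin helices
(UNDEFINED orientation — the generator's `T` pattern letter), which is
both a realistic shape for a non-crossing insertion and the condition
under which the internal-gap alignment is optimal. Whether
orientation+length scoring reproduces every expert-assigned
correspondence on real structures is untested here and not asserted.

### 3.1 Circular permutation

`detect_circular_permutation()` aligns A against every cyclic rotation
of B's segment order and reports the rotation offset; each segment keeps
its own orientation, because a genuine circular permutation rearranges
the chain connectivity, not the membrane-crossing directions. Offset 0
wins unless a rotation improves the score by more than `cp_margin`
(0.5), so unrelated profiles do not acquire spurious permutations.

Recovery of the exact offset on rotated copies is only well-posed for
profiles that are not cyclically symmetric — every rotation of a
symmetric profile is indistinguishable from the original. The random
profile generator therefore draws orientation patterns uniformly but
rejects the cyclically periodic ones. For an aperiodic pattern, the
correct rotation scores the full (w_or+w_len)·n while any other rotation
either drops pairs (≥ 3 per dropped pair under the defaults) or suffers
an orientation mismatch (≥ 3 net), a deficit comfortably above
`cp_margin`; exact recovery on rotated copies is then a consequence of
the scoring model, not a tuned outcome, and the suite exercises it for
100 random profiles of 3–12 segments at every offset.

## 4. The synthetic generators

`make_helix_bundle()` produces canonical C-alpha α-helices (rise 1.5
Å/residue, twist 100°/residue, helical radius 2.3 Å) at prescribed
membrane-plane positions, with per-helix U/D/T direction letters, an
optional isotropic Gaussian coordinate noise, and a clash check
(centroid spacing ≥ 2× helical radius). Truth handedness is derived
*analytically* from the prescribed centroid angles by the signed-area
rule, so at zero noise the geometry pipeline must reproduce it exactly —
a closed loop, not a self-comparison, because the truth never touches
the fitted axes. The preset arrangements (`rrll`, `rr`, `l3`) encode the
R,R,L,L six-segment core, the R,R four-segment core, and a minimal
counterclockwise triple.

`make_partition_scenario()` emits hits equal to the true domains (±
optional boundary jitter), plus nested low-scoring decoys and
low-coverage fragment hits, and computes the truth outcome by running
the documented rules on the noiseless configuration. All randomness in
both generators flows through an explicit seed; identical specifications
give byte-identical outputs.

What the generators deliberately do not emulate: real helices are
kinked, curved and irregular; membranes are neither flat nor exactly
perpendicular to z; real alignment evidence has correlated, not
independent, boundary errors, and decoys are not always nested inside
true domains; side chains and loop coordinates are absent. Passing
tests on these fixtures validates the *rules and descriptors*, not
performance on experimental structures.

## 5. Numerical choices and problem sizes

Score comparisons in the DP use an absolute tolerance of 1e-9, so
float-equal alternatives fall through to the deterministic tie-break
rather than to accumulation order. Projected-centroid coincidence
(handedness undefined) errors at 1e-9 Å; axis fitting requires ≥ 5
points and ≥ 80% C-alpha coverage of an annotated range. Percentages
round half up. The test suite and acceptance script run at the scales
the package targets: bundles of 3–12 segments, chains of a few hundred
residues, 2298-record outcome collections, 100 profiles × all rotation
offsets, 1000 oracle triplets — minutes of total runtime on one core.

## 6. Known limitations

* Homology is never decided; the package computes descriptors and
  triage outcomes, and deliberately stops there.
* β-barrel membrane proteins, membrane placement optimization and TM
  *prediction* are out of scope; TM annotations are inputs.
* Segment-level alignment cannot resolve correspondences that
  orientation and length do not determine (§3); residue-level or full
  3D superposition methods are the right tool there.
* The mmCIF writer emits a minimal `atom_site` loop sufficient for the
  C-alpha fixtures it serves, not a general-purpose mmCIF library; the
  reader side is delegated to bio3d.
* The curation-statistics categories encode one defensible reading of
  loosely defined bookkeeping terms ("in part special", "unclassifiable
  region"); the three percentages asserted in tests are the ones
  insensitive to that reading.
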
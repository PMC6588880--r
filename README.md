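# tmtopo

Descriptors and triage logic for the protein chains that automated domain
classification pipelines handle worst: multidomain chains with conflicting
alignment evidence, and polytopic membrane proteins whose homology is
argued at the level of transmembrane (TM) segment topology rather than
sequence.

The package is aimed at curators and developers of structure-based domain
classifications who need (a) a deterministic, auditable rule set that
either accepts a chain's domain parse automatically or flags it for manual
curation with an explicit reason, and (b) quantitative, reproducible
versions of the topology descriptors that expert curators otherwise judge
by eye: which way each TM segment crosses the membrane, the chirality of
consecutive segment triplets, which segments of two proteins correspond,
and whether one topology is a circular permutation of the other.

## What it computes

**Domain-partition triage.** Alignment evidence for a chain is a set of
hits, each mapping a reference domain onto query intervals with a score.
The pipeline filters hits (minimum aligned length; reference coverage
tiers that separate usable hits from fragments of known domains), selects
assignments greedily in a fully specified priority order (score, then
length, then id), trims bounded overlaps, and accepts the parse
automatically iff

- covered fraction of classifiable residues ≥ `min_cover_frac` (default
  0.90), where classifiable = chain length − masked unknown residues,
- every unassigned gap is shorter than `gap_max` (default 30 residues),
- no rejected hit scores ≥ `conflict_score_ratio` (default 0.8) of an
  accepted hit it overlaps beyond tolerance (no comparable competing
  parse).

Otherwise the chain is flagged with reasons — `INCONSISTENT_BOUNDARIES`,
`NOVEL_REGION`, `UNASSIGNABLE` — and tagged by architecture (`PEPTIDE`,
`FRAGMENT`, `SYNTHETIC`, `SINGLE_DOMAIN`, `MULTI_DOMAIN`,
`TM_CONTAINING`). `summarize_outcomes()` turns outcome collections into
curation statistics with round-half-up integer percentages.

**TM geometry.** For each annotated TM segment the C-alpha trace yields a
unit axis **a** (from the curvature plane of second differences, exact on
ideal helices), a centroid **c**, and an orientation relative to the
membrane normal **n**: UP if **a**·**n** > 0.5, DOWN if < −0.5, else
UNDEFINED. For consecutive centroids c₁, c₂, c₃ projected into the
membrane plane, the normalized chirality score

&nbsp;&nbsp;&nbsp;&nbsp;s = **n** · (d₁ × d₂) / (|d₁||d₂|), with d₁ = c₂′ − c₁′, d₂ = c₃′ − c₂′,

labels the triplet **R** (clockwise seen from +**n**), **L**
(counterclockwise) or **X** (|s| ≤ 0.05, near-collinear). A profile's
handedness string concatenates the labels, e.g. `RRLL` for the shared
six-segment core of the type II CAAX protease homolog and the γ-secretase
subunit APH-1, or `RR` for the four-segment MacB-like ABC transporter
core.

**Topology alignment.** Two profiles are aligned as ordered segment
sequences by semi-global dynamic programming: free end gaps, affine
internal gap penalty (g_open 1.5, g_ext 0.5), pair score
w_or·(±1 orientation agreement) + w_len·(1 − |ℓA − ℓB|/max(ℓA, ℓB)).
`detect_circular_permutation()` re-runs the alignment over every cyclic
rotation of one profile's segment order and reports the offset when a
rotation wins by more than `cp_margin`.

**Synthetic fixtures.** `make_helix_bundle()` builds ideal C-alpha helix
bundles with prescribed centroid arrangements, orientations and
analytically known handedness; `make_partition_scenario()` builds hit
tables with prescribed domains, decoys, fragments and masks plus a truth
outcome. Every consumer of the package can therefore be tested closed-loop
with no external data.

## Worked example

```r
library(tmtopo)

## a six-helix bundle with the RRLL core arrangement, rebuilt from its
## raw coordinates
b <- do.call(make_helix_bundle, bundle_preset("rrll"))
prof <- build_profile(b$coords, b$tm_ranges, b$frame, label = "six-TM core")
prof
#> TM profile 'six-TM core': 6 segments
#>   TM1  1-22      UP        core=1 coupling=0  centroid (-10.4, 6.0, 0.0)
#>   TM2  28-49     DOWN      core=1 coupling=0  centroid (0.0, 12.0, 0.0)
#>   TM3  55-76     UP        core=1 coupling=0  centroid (10.4, 6.0, 0.0)
#>   TM4  82-103    DOWN      core=1 coupling=0  centroid (10.4, -6.0, 0.0)
#>   TM5  109-130   UP        core=1 coupling=0  centroid (12.0, -0.0, 0.0)
#>   TM6  136-157   DOWN      core=1 coupling=0  centroid (6.0, 10.4, 0.0)
#>   core handedness: RRLL
```

Each row is one membrane crossing: the interval is the annotated residue
range, UP/DOWN the N-to-C crossing direction, and the centroid the
segment's position in the membrane plane. The final line is the chirality
of the four consecutive segment triplets — right, right, left, left.

```r
## triage a chain from its alignment evidence
ch <- chain_record("7abcA", 260, tm_runs = "30-52", method = "EM")
hits <- list(alignment_hit("e4xyzA1", "1-120",   118, 0.97, 112),
             alignment_hit("e1qrsB2", "115-240", 130, 0.92,  88),
             alignment_hit("e9fragC", "241-258", 200, 0.35,  21))
partition_chain(ch, hits)
#> chain 7abcA: AUTO_ACCEPTED (coverage 0.923)
#>   e4xyzA1      1-120
#>   e1qrsB2      121-240  (trimmed 6)
#>   gaps: 241-260
#>   tags: MULTI_DOMAIN, TM_CONTAINING
```

The two strong hits overlap by six residues — within tolerance, so the
lower-priority hit is trimmed rather than rejected; the fragment hit
(reference coverage 0.35) is set aside; the 20-residue uncovered tail is
below `gap_max`, so the two-domain parse is accepted automatically.

A command-line wrapper with `partition`, `tmgeom`, `topoalign`,
`summarize` and `synth` subcommands is installed at
`system.file("cli", "tmtopo.R", package = "tmtopo")`.

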
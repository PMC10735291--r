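---
title: "Reconstructing retrotransposon succession: models and methods"
author: "malrsucc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing retrotransposon succession: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(malrsucc)
```

# The scientific problem

ERVL-MaLR retrotransposons (mammalian-apparent LTR retrotransposons) make
up a few percent of primate genomes. Their internal region encodes only a
gag-like ORF; the flanking long terminal repeats (LTRs) carry most of the
sequence variation that distinguishes the forty-odd named family members
(MLT, MST, THE1 subfamilies). Two questions shape the analysis this
package implements: did each family have a limited activity period, with
members succeeding one another, and can the order of the sequence changes
that separate one member from its successor be read from the element
copies left in the genome?

Four largely independent lines of evidence bear on these questions, and
the package implements each as a module over shared annotation
structures:

1. **Orthologous presence/absence dating** (`timing_calls()` and
   friends). An insertion fixed before a speciation event is present at
   the orthologous locus of both descendant lineages; one fixed after is
   present in only one. With two successive outgroup splits, presence in
   both outgroups, the nearer one only, or neither brackets each
   insertion into three age classes.
2. **Transposition-in-transposition (TinT)** (`detect_tint_events()`,
   `infer_activity_periods()`). A copy inserted inside an older copy
   splits the host annotation; the direction of nesting orders the two
   families in time, and the full matrix of directed counts constrains
   all activity windows jointly on a relative (pseudo-time) axis.
3. **Consensus phylogeny** (`consensus_dist_matrix()`,
   `neighbor_joining()`). Pairwise distances between family consensus
   models, built from free-end-gap global alignments under the
   Jukes-Cantor correction, and the neighbor-joining tree over them.
4. **Consensus-anchored structural variants** (`call_variants()`,
   `scan_for_stage()`, `predict_progeny_ltr()`,
   `shared_features()`). Named indels distinguishing one family from its
   successor are genotyped in individual copies; elements carrying
   partial variant sets are intermediates that date the order of the
   changes, and LTR replication logic predicts how asymmetric per-LTR
   patterns resolve in the next generation.

A synthetic genome-evolution simulator (`simulate_succession()`,
`plant_structural_variants()`, `simulate_consensus_chain()`) generates
all inputs with machine-readable truth, so every claim the pipeline makes
is testable without downloading genomes.

# Annotation model and conventions

All genomic intervals are 0-based half-open internally. RepeatMasker
`.out` rows are 1-based inclusive on disk and are converted at the parse
boundary; `"C"`-strand rows are normalized to `"-"` with consensus
coordinates reoriented so `rep_start <= rep_end` always holds. Structural
variant definitions use the 1-based consensus coordinates that repeat
biologists write (`204del` deletes consensus base 204); conversion
happens inside the variant schema. Fragments sharing a RepeatMasker `ID`
on one sequence form an *entity* — the unit of all downstream analysis;
an ID spanning two sequences is split with a warning, since one insertion
cannot span chromosomes.

# Insertion-timing workflow

Thresholds (all exposed in `timing_thresholds()`, defaults in
parentheses): minimum best-fragment Smith-Waterman score (100,
inclusive); flank length examined on each side (300 bp); minimum aligned
bases per flank side (200); presence threshold on lifted element bases
(50, strict `>` — exactly 50 aligned bases is *absent*).

Decisions worth recording:

* **Properly aligned** requires the flank test to pass in *all*
  comparison species simultaneously. The per-species reading would give
  each species its own denominator; a single denominator per entity is
  what makes per-family category fractions comparable.
* Flanks are taken from the entity's outermost fragment boundaries,
  ignoring internal nesting gaps — the single-insertion reading of the
  shared ID.
* When an interval lifts to several query segments, aligned bases are
  summed; the thresholds are about how much sequence survives, not about
  contiguity.
* The discordant pattern (present in the farther outgroup, absent in the
  nearer) is reported as `discordant`, never silently binned: it signals
  hemiplasy or a lineage-specific deletion, and on clean simulated chains
  it never occurs.

Presence is monotone in chain coverage by construction: degrading a chain
can only remove aligned bases, so present calls can only flip to absent,
and any misclassification under degradation traces to an element whose
lifted coverage crossed the 50-base rule. The test suite asserts exactly
this confinement.

# The TinT activity model

The event detector emits one event per inner entity strictly contained in
the gap between two consecutive fragments of an outer entity, requiring
(i) the outer fragments to share a repeat ID, (ii) consensus-coordinate
continuity — the downstream fragment resumes no earlier than `tolerance`
(default 30) consensus bases before where the upstream fragment stopped
(tandem-like consensus overlaps are rejected; minus-strand entities are
checked in reversed orientation), and (iii) at least one base of outer
sequence on each side. A fragmented inner element counts once. When
nesting chains are deeper than one level, the truth enumeration counts
every ancestor-descendant containment pair, and the detector reports the
same transitive pairs, so precision and recall are measured against the
full containment relation.

Activity inference fits, by maximum likelihood, a two-parameter activity
window per family: activity is `Normal(mu_f, sigma_f^2)` on pseudo-time
(larger `mu` = younger). Conditional on an event with inner family `i`,
the outer family is multinomial over targets with probability
proportional to

```
q_ij = c_j * Phi((mu_i - mu_j) / sqrt(sigma_i^2 + sigma_j^2))
```

— target abundance `c_j` (entity counts by default, annotated-base totals
if preferred) times the probability that a random `i` copy postdates a
random `j` copy when both draw their times from their windows. The
likelihood is the sum of `N_ij log p_ij` over observed counts with
`p_ij = q_ij / sum_j' q_ij'`.

Two modelling decisions deserve emphasis:

* **Self-nesting events stay in the model** with the parameter-free
  precedence probability `Phi(0) = 1/2`. They carry no direct ordering
  signal, but they compete in the row normalization: a family whose only
  observed events are self-nestings thereby testifies that it avoided
  every younger family, which is precisely the evidence that places the
  oldest member. Dropping these rows entirely would leave the oldest
  family's position unidentified whenever it predates all others — the
  one-sided count pattern a clean succession produces.
* **Identifiability**: the likelihood depends only on differences of `mu`
  scaled by the `sigma`, so the first family's `mu` is anchored at 0 and
  the geometric mean of the `sigma` at 1. On fully one-sided matrices the
  likelihood still plateaus as separations grow beyond saturation of
  `Phi`; the optimizer's box (`|mu| <= 30`, `|log sigma| <= 4` at unit
  sigma scale) fixes where the plateau is reported, and separations on
  such data should be read as "large", not as calibrated quantities. The
  *order* of the `mu` and the interval overlap structure are identified
  and stable across optimizer seeds.

Optimization is multi-start L-BFGS-B: one start from a net-precedence
rank heuristic (families acting as inner more often than as outer are
started younger), the rest random, deterministic given the seed. Families
with no events at all are flagged `unconstrained` and shown with a
deliberately wide interval rather than silently placed — mirroring the
caveat that low-copy families support only uncertain inference. Interval
bounds at 75/95/99% are central quantiles of `Normal(mu, sigma^2)`,
hence nested and symmetric.

# Consensus phylogeny

The pairwise aligner is an affine-gap Gotoh DP with zero-cost terminal
gaps (the standard choice when models differ in length), implemented in
compiled code with a deterministic tie-break (residue pairing preferred
over a gap in the second sequence, over a gap in the first) and a
traceback that provably reproduces the DP optimum (the emitted path's
score is asserted against the DP score in the tests). Scoring defaults:
match +1, mismatch -1, optional transition score (default: transitions
score as ordinary mismatches; -0.5 when transition/transversion
weighting is wanted), gap open -4, gap extend -1 — exposed as arguments,
since published descriptions of such trees name the options more often
than the values.

The observed mismatch proportion `p` counts all mismatches equally over
internal residue-pair columns (gap, end-gap and ambiguous columns
excluded), and is corrected as `d = -(3/4) ln(1 - 4p/3)`; `p >= 3/4` is
flagged saturated. Distances, not a multiple alignment, drive the tree:
neighbor joining is implemented explicitly (Q-matrix selection;
equal-Q ties resolved to the first taxon pair in current label order;
negative branch lengths clamped to zero with a message) and returns an
unrooted `phylo` object. `clade_check()` asks whether a taxon set is a
split of the unrooted tree and reports the smaller adjacent group on the
far side of the split edge as the sister. Saturated entries abort tree
building unless explicitly allowed, in which case they are capped just
beyond the largest finite distance.

# Structural-variant genotyping and chronology

Full-length elements are located by anchoring the consensus LTR at both
ends of the element with free-end-gap alignments; anything without two
LTRs separated by at least 50 bp of internal sequence is reported
solo/partial and skipped for staging.

Genotyping reads each named variant off the element-side *segment length*
between two landmark consensus positions placed midway between
consecutive variant loci (and 25 bp outside the outermost ones), nudged
by up to 6 positions to a column where consensus and element residues
pair. Because equally scoring alternative gap placements move gaps only
*within* a segment, they cannot disturb a length read between landmarks —
the failure mode that coordinate-exact gap matching suffers at realistic
divergence. A deletion of k bases is present when the segment is exactly
k short, absent at full length, and uncallable at any other length (an
unrelated indel at the locus). An insertion is present when the segment
is longer than the consensus expectation; inserted content is not
matched. A deletion-insertion (`303_312delinsTT`) is present when the
length signature matches the replacement; the replacement content is
compared and reported (`content_ok`, tolerating half its bases), but the
length signature decides the call — the replacement's own bases diverge
like any others, and treating ordinary divergence as evidence against
the variant misreads roughly a quarter percent of true calls per LTR at
5% divergence.

Stages of the THE1B-to-THE1A transition follow the per-LTR patterns:
*precursor* = the three early indels (186ins, 226_235del,
303_312delinsTT) in both LTRs, 204del in neither; *intermediate* = the
three in both plus 204del in the 5' LTR only; *canonical* = all four in
both. Anything else, including any uncallable variant, is `other` with
the observed pattern attached.

`predict_progeny_ltr()` encodes retroviral LTR replication: both progeny
LTRs are the composite of the parental 3' U3 and the parental 5' R/U5,
so a variant's segment decides which parental side it is inherited from.
U3/R/U5 boundaries are mandatory configuration — they are not printed
with consensus models — and the shipped demo model places the boundary
at position 195 purely to satisfy the one constraint actually used: that
204del lies downstream of the transcription start site (in R/U5).
Variants spanning the boundary are refused rather than guessed. The
intermediate pattern is therefore predicted to canonicalize in one
replication round, and applying the rule twice is idempotent.

`shared_features()` projects the partner and every background consensus
onto the first sequence's coordinate frame through pairwise alignments
and reports maximal runs (>= 10 columns) where the pair agrees while
every background differs or is gapped; up to 10% violating columns per
block absorb post-divergence substitutions. `succession_support()` runs
this for each adjacent pair of a proposed chain with all other supplied
consensuses as background — on a true succession chain, features gained
on one branch and lost on the next are uniquely shared by exactly one
adjacent pair.

# The synthetic data generator

`simulate_succession()` emulates, at desk scale, the features of real
repeat annotations the pipeline relies on:

* Insertion times drawn from truncated-normal activity windows on
  pseudo-time `[0, 1]`; the branch spanning the time fixes presence in
  each species of a three-tip tree with splits at 0.3 and 0.5 by default.
* A focal-genome layout of elements separated by 700 bp backbone spacers
  (at least twice the flank length, so neighboring elements never
  contaminate each other's flank test).
* Nesting with configurable probability into a host drawn uniformly
  among older copies; hosts may be hit more than once (entities with
  three or more fragments, as real annotations show), nesting chains
  capped at depth 2, and at least 25 bp of host on each side of a guest.
  Uniform host choice makes realized host-family counts proportional to
  copy numbers — the same abundance weighting the inference model
  assumes.
* Copies diverged by iid substitutions and rare short indels; per-family
  rates decreasing for younger families (older copies are more decayed).
* Chains to each species derived exactly from the coordinate maps:
  shared pieces become aligned blocks, focal-specific pieces target-side
  gaps. `degrade_chain()` then removes a deterministic per-block fraction
  of aligned bases at random positions, modelling lineage-specific loss
  so the presence thresholds are exercised; the deleted total is monotone
  in the fraction by construction.
* In scenario configurations, each family's consensus descends from its
  predecessor's (6% substitutions per step by default), giving the
  consensus tree a known backbone.

What the generator does *not* model: rate heterogeneity along sequences,
CpG effects, recombination between repeats (and hence mosaic or solo-LTR
formation), segmental duplications, assembly error, and
RepeatMasker's own annotation noise (mis-assigned families, inexact
fragment endpoints beyond the jitter the detector tolerates). Passing
tests therefore demonstrate the correctness of the pipeline's logic
under its stated assumptions, not robustness to every artifact of real
genomes. Divergence rates are testing placeholders, not biological
estimates.

Problem sizes used by the shipped analyses and checks — 500 insertions
for the timing study, five families of 400 copies (about 600 nesting
events) for TinT, populations of 100 elements for staging, 50 random
additive matrices up to 8 taxa for tree checks — keep every stage's
runtime in seconds to a couple of minutes on a single core while leaving
the statistical conclusions unambiguous.

# Numerical choices and degenerate inputs

* Alignment tie-breaks and the terminal-cell scan order are fixed, so
  alignments are reproducible byte for byte.
* `jc_distance()` errors on alignments with no comparable columns rather
  than returning 0.
* `neighbor_joining()` needs 3 or more taxa; 3 taxa close with the
  three-point formulas directly.
* `infer_activity_periods()` refuses matrices with no off-diagonal
  counts; empty event sets yield empty, well-typed tables throughout.
* All simulators take a mandatory seed, save and restore the caller's
  RNG state, and are asserted byte-identical across repeated runs.
* `run_succession_pipeline()` records a manifest (package version, seed,
  config hash, per-file MD5 checksums); any stage failure aborts naming
  the stage, preserving completed outputs.

# Known limitations

Absolute dating is out of scope: pseudo-time is relative, and no
calibration to million-year ages is attempted. The timing workflow
supports exactly two outgroups (the nearer/farther design); adding a
third species is a configuration change but the call vocabulary would
need extending. The TinT separations on fully one-sided matrices are
reported at the optimizer's plateau, as discussed above. Variant
genotyping assumes the named variants are separated by enough clean
consensus for landmarks (true of the THE1 set; two variants closer than
about two landmark nudges would need merged definitions).
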
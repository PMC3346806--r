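---
title: "Screening for remote chemokine homologs with 3D family profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for remote chemokine homologs with 3D family profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoscan)
```

## The problem and the model

Remote members of the IL8-like chemokine family can be invisible to
sequence-based annotation: their identity to known chemokines sits below the
twilight zone and their cysteines occupy non-canonical positions in sequence
while still meeting in 3D. `chemoscan` screens uncharacterized protein
sequences for the *structural* signature of the family instead: the ability
to thread onto a chemokine backbone with full fold coverage, and the ability
of the query's cysteines to form disulfide bonds in that scaffold.

The screen makes three modelling assumptions worth stating explicitly.

1. **Threading with a frozen approximation.** When a query residue is placed
   at template position *j*, its pair interactions are evaluated against the
   *template's native* residues at *j*'s contact partners, not against the
   query residues that may eventually occupy those positions. This is the
   classical first-order approximation in fold recognition; it makes the
   per-template scoring profile precomputable (a 20 × fold-length table) at
   the cost of ignoring second-order query–query effects.
2. **Scaffold-based disulfide mapping.** Disulfide feasibility is judged on
   template Cα/Cβ geometry at the aligned positions — no model building, no
   side-chain placement, no Sγ chemistry. The criteria (below) are
   deliberately generous: they ask whether a bond is *geometrically
   plausible*, not whether it is energetically favourable.
3. **The family is defined by SCOP.** A template is a chemokine iff it
   carries a domain under fold d.9; the fold-space control library is any
   redundancy-reduced cross-section of the PDB. Both libraries are built
   from user-supplied structures and a user-supplied SCOP mapping, so
   library size is provenance, not an assertion of this package.

## The scoring engine

The potentials are Sippl-style potentials of mean force. Pair energies are
indexed by residue pair and Cβ–Cβ distance bin (default 0–15 Å in 1 Å bins,
sequence separation ≥ 4), with

$$E(a,b,d) = -\ln \frac{N(a,b,d) + pc}{N_{\mathrm{ref}}(d) + pc}$$

where the reference count \(N_{\mathrm{ref}}(d)\) is the per-pair-type mean
count in bin *d* (total over the 210 unordered pair types divided by 210)
and \(pc\) is a pseudocount (default 1). This reference state was chosen so
that two exact limits hold: perfectly uniform contact statistics give zero
energy everywhere, and a never-observed pair type hits the positive bound
\(-\ln(pc/(N_{\mathrm{ref}}+pc))\). Burial energies are analogous over
Cβ-neighbor-count bands {0–2, 3–5, 6–8, 9+} within 10 Å.

Alignment is affine-gap dynamic programming, **global in the template**
(every template position is aligned or pays a gap penalty — downstream
rules require full fold coverage, so partial-coverage alignments should pay
for what they skip) and **semi-global in the query** (terminal query
overhangs are free). Ties are broken deterministically: diagonal over
query-consuming over template-consuming moves.

One numerical choice deserves emphasis: the DP score matrix is the negated
energy profile **standardized to zero mean and unit variance over the
template's full 20-residue profile**. Raw profile energies are sums over
10–20 contacts and their magnitude dwarfs any fixed gap penalty, which
fragments alignments of genuine homologs into gap-riddled mosaics. After
standardization the gap penalties are expressed in profile-SD units, so the
defaults (open 4.0, extend 0.4) mean "opening a gap must be worth four
standard deviations of profile signal" regardless of training-set size or
potential scale. The raw (unstandardized) energies are still what enters
the z-scores.

The z-scores compare the native alignment's pair and burial energies with
the distribution over `n_shuffles` (default 100) random permutations of the
query, each *realigned* — so the null preserves composition and template
but destroys order. A zero-variance null is reported as z = 0 with a
degenerate flag rather than NaN. The composite index is

$$\mathrm{Thx} = 100 \cdot \frac{w_p\, z_{\mathrm{pair}} + w_s\, z_{\mathrm{surf}} + w_q\, S_{\mathrm{seq}}}{L_{\mathrm{query}}}$$

with \(S_{\mathrm{seq}}\) the BLOSUM62 score of the aligned pairs and unit
default weights. The absolute Thx scale is a property of this engine's
configuration and is **not comparable to other threading engines**; for the
same reason the family cutoff is never a hard-coded constant but is
re-derived by `calibrate_thx_cutoff()` — threading a user-designated remote
family member against the family library and taking its best
high-confidence Thx. The fixture world designates a 25 %-identity homolog
for this role: remote enough to sit near the decision boundary (true family
members at very low identity are precisely the targets of the screen),
close enough to be a genuine positive.

## Hit classification and the disulfide rules

A hit is high confidence (HC) iff all three hold, all bounds inclusive:

- **fold coverage**: 0.6 ≤ fl/pl ≤ 1.3, where fl is the count of resolved
  template residues and pl the number of aligned pairs;
- **gaps**: no alignment gap (either side; terminal query overhangs
  excepted, terminal template gaps counted) longer than 10 residues;
- **SSE coverage**: every template secondary-structure element of length
  ≥ 3 fully aligned, tolerating at most one unaligned position per element
  edge. The one-residue slack is this package's operationalization — some
  tolerance is needed because Cα-geometry SSE boundaries are themselves
  ±1 residue — and is configurable (`edge_slack`).

A cysteine pair (query positions *i* < *j*) is a possible disulfide iff
d(Cα,Cα) ≤ 10 Å, d(Cβ,Cβ) ≤ 9 Å, d(Cβ) − d(Cα) ≤ 1 Å (side chains must not
point apart), and *j* − *i* ≥ 3. "Three residues apart" was read as
*j* − *i* ≥ 3 (two intervening residues); the alternative reading ≥ 4 is one
config value away (`min_sep`). A cysteine aligned to a gap or unresolved
residue borrows the nearest resolved template neighbors left and right of
the gap as candidate anchors; a pair passes if **any** anchor combination
passes (the permissive reading), with a strict all-combinations mode
available (`mode = "all"`). Two cysteines collapsing onto one shared anchor
are infeasible by definition. The bond count diS is an exact
maximum-cardinality matching (memoized search, guarded at 20 cysteines);
the reported pairing is the lexicographically smallest maximum matching, so
outputs are stable across platforms.

In the fold-space stage, SCOP domains with < 70 % coverage are discarded,
hits are collapsed to the best entry per SCOP family (so one fold cannot
occupy several ranks), the top 20 domains are considered, and the candidate
passes iff a d.9 domain ranks 1 or 2 among the HC entries. The top-*n*
selection between stages 3 and 4 is a count (default 70), not a score
threshold, with ties broken by query id.

## Pre-filter conventions

Signal peptides are removed only at **high** consensus confidence (both
predictors agree within 3 residues on the cleavage site; the shorter
peptide wins); transmembrane segments at high or medium confidence, with
confidence banded by consensus length (17–25 high — the canonical TM helix
band — 12–17 and 25–35 medium). The asymmetry (SP: high only; TM: high and
medium) follows the screening rationale: an over-trimmed signal peptide
destroys the mature N-terminus the fold needs, while an untrimmed TM
segment poisons threading everywhere. After excision the longest remaining
contiguous segment becomes the record, ties broken toward the C-terminal
segment (chemokine domains sit C-terminal to the signal peptide); the trim
log keeps every removed region in parent coordinates, so positions are
always traceable to the untrimmed sequence. Non-standard residues are
normalized once at record construction: U→C, O→K, ambiguity codes→X, and X
never counts as a cysteine and blocks mass computation with an explicit
error.

## The synthetic fixture world

`make_fixture_fold_set()` builds nine toy folds: five chemokine-like
templates (70 residues — the size of a mature chemokine domain — three
antiparallel strands, a packed C-terminal helix, six cysteines in three
planted all-criteria pairs bridging N-tail/helix, sheet/helix and
sheet/sheet contacts) and four geometrically distinct controls (helix
bundle, β-meander, single long helix, α/β mix), each with a SCOP family id.
Backbones are idealized Cα traces (helix: 1.5 Å rise, 100°/residue;
strands: 3.3 Å rise, 4.8 Å sheet spacing) with seeded ±0.12 Å jitter;
Cβ atoms point away from the local chain axis except at planted pairs,
where they are carved to satisfy exactly the intended criterion subset and
re-verified by direct recomputation before the template is emitted.
`make_homolog()` mutates non-cysteine positions with
substitution-matrix-weighted sampling to a target identity;
`make_decoy_cohort()` writes background-composition sequences with seeded
fractions of planted signal peptides, TM segments and homology annotations,
in exactly the file formats the pre-filter consumes.

What the fixtures **do** emulate: the geometric logic of the fold
descriptor (distinct topologies, full-coverage threading, planted disulfide
geometry), the statistical logic of the screen (homologs near 40 % identity
versus composition-matched decoys), and every file interface. What they do
**not** emulate: real side-chain packing, loop physics, the size and
diversity of a real fold library (9 versus ~24,000 templates), or the
length distribution of a real proteome. Passing tests therefore certify the
machinery and its decision rules, not proteome-scale discovery performance;
on real data the discrimination burden shifts to the potentials, which
should then be trained on a large non-redundant structure set rather than
on nine toys.

Study-condition sizes used throughout tests and the acceptance script: 200
random geometries for the disulfide oracle; 20 seeded replicates for
homolog recovery and for decoy survival; a 100-decoy cohort with 5 planted
homologs for the end-to-end cascade; 100 shuffles per z-score.

## Numerical and degenerate-input choices

- All coordinates and thresholds are Ångström; all sequence positions are
  1-based inclusive; all criterion bounds are inclusive (a pair at exactly
  10.0 / 9.0 / 1.0 / separation 3 passes; fl/pl of exactly 0.6 or 1.3 is HC).
- Virtual Cβ atoms (glycine, incomplete side chains) are reconstructed from
  N/Cα/C with ideal tetrahedral geometry (1.53 Å bond) via the standard
  fixed linear combination of the backbone frame. On real crystal
  structures individual distorted residues can deviate by up to ~0.5 Å from
  their observed Cβ; the test suite asserts exactness on ideal geometry and
  distributional bounds (median < 0.2 Å) on a real chain.
- Unresolved template residues carry no energy and are excluded from the
  alignment columns entirely, which realizes "skippable at zero gap cost".
- Per-template shuffle seeds are derived from the run seed and the template
  name, making every score invariant to library ordering; ranking ties
  break by z_pair, then template id.
- Degenerate cases fail loudly or safely: empty queries and empty
  libraries are errors; a zero-variance shuffle null flags the z-score; an
  empty input cohort yields an all-zero report; a config field of the wrong
  type is named in the validation error.
- `enumerate_bonds()` refuses more than 20 cysteines (exact search guard,
  configurable) rather than silently switching algorithms.

## Known limitations

- The threading engine is a self-contained stand-in: potentials, gap model
  and the Thx combination are this package's definitions, with every
  parameter in `default_config()`. Published absolute threading indices
  from other engines cannot be compared numerically; only the calibrated,
  engine-relative cutoff is meaningful.
- Structure input is PDB-format only (`bio3d`); for mmCIF-only entries,
  convert first. Multi-model files use the first model.
- SSE assignment is a Cα-geometry heuristic (helix distance signatures;
  strand extension plus partner proximity, minimum element length 3) and an
  external per-residue label file can override it; it is not a
  hydrogen-bond-based assignment.
- The superposition refinement (SSE-seeded Kabsch with monotone re-pairing
  within 5 Å) is a local optimizer; topologically permuted structures
  yield partial correspondences by design, but adversarial cases may need a
  manual seed correspondence.
- The worked-example checks against published UniProt/PDB records require
  the user to supply those records (see `inst/extdata/reference/`); the
  package does not download.
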
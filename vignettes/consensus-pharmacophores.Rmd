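---
title: "Consensus pharmacophore models and the two-stage screening funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus pharmacophore models and the two-stage screening funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmfunnel)
library(dplyr)
```

## The model

A *structure-based consensus pharmacophore* abstracts what a panel of
co-crystallised ligands agrees on: the recurring chemical functions —
hydrogen-bond acceptors (`A`) and donors (`D`), hydrophobic groups (`H`),
aromatic rings (`R`), optionally ionizable groups (`N`/`P`) — and where in
the binding pocket they sit. Given `N` ligands already placed in one
receptor frame, the package:

1. perceives typed features on each ligand conformer
   (`perceive_features()`),
2. pools same-type features across ligands and clusters them with
   average-linkage agglomerative clustering, cutting the dendrogram so no
   merge exceeds a distance **tolerance** (Å),
3. promotes a cluster to a consensus **site** when the fraction of
   *distinct* ligands contributing to it reaches **min_fraction**, and
4. records each site as a tolerance sphere: type, centroid position, radius
   (= the build tolerance), ligand-support fraction, and, where at least
   half the members carry one, a consensus unit direction.

A ligand with two nearby donors votes once per cluster: support is
per-ligand by construction, which is what a "fraction of the ligands"
threshold means. Average linkage rather than single linkage prevents
features chaining across the pocket into one sprawling site; the oracle
test in `test-consensus.R` pins the clustering to an exhaustive
average-linkage reference, including the collinear 2 Å-spacing trap.

Two parameter regimes matter in practice. At the common defaults —
min_fraction 0.5, tolerance 2.0 Å — only functions shared by half the panel
survive, which on a diverse inhibitor panel tends to leave a sparse 3-point
model. Relaxing to min_fraction 0.25 and tolerance 2.5 Å admits peripheral
features carried by a quarter of the panel and yields richer five-point
models of the `A/A/D/H/R` kind; `build_hypothesis()` exposes both knobs and
stores them with the model, and the choice of regime is the user's, not a
hard-coded constant.

## Matching a compound against a hypothesis

`match_inplace()` treats the query's coordinates as final (a docking pose
in the receptor frame): it finds the maximum-cardinality injective,
type-respecting feature-to-site assignment in which every pair distance is
within the site radius, minimising total distance among maximum-cardinality
assignments. The solver is an exact dynamic program over site subsets
(sites are few; features may be many), so no heuristic matching is
involved.

`match_aligned()` handles queries in an arbitrary frame (conformers from
`generate_conformers()`). Candidate assignments are cliques of a
correspondence graph: nodes are type-compatible (feature, site) pairs;
an edge joins two nodes when `|d(f_i, f_j) − d(s_i, s_j)| ≤ r_i + r_j`,
a triangle-inequality bound that cannot prune a verifiable assignment.
All cliques of size ≥ `min_match` are enumerated — not only maximal ones,
because a maximal clique can fail post-alignment verification while one of
its sub-cliques verifies — then each candidate subset is rigidly
superposed onto its sites by Kabsch's method (proper rotation only, so
enantiomeric feature arrangements do not match) and verified against the
radii. The best verified result by `(matched_count, fit_score)` wins, with
deterministic tie-breaks.

Both matchers are validated against `brute_force_match()`, an exhaustive
enumerator bounded at 7 features × 6 sites, on 100 random instances each.

### The fit score

Proprietary screening scores are not reproducible, so results carry an
open, documented score:

$$\mathrm{fit} = \tfrac12\,\max\!\left(0,\, 1 - \frac{\mathrm{RMSD}}{\mathrm{tolerance}}\right) + \tfrac12\, V,$$

where $V$ is the mean of $\max(0, \cos\theta)$ over matched pairs with
directions on both sides ($V = 1$ when none has). It lives in $[0, 1]$; a
perfect positional and directional match scores 1. Published screen scores
from other tools should be compared with it ordinally only. Directions
never gate feasibility — no angular tolerance is defined anywhere — they
only modulate the score.

## The funnel

`run_funnel()` chains the two matchers the way a repositioning campaign
uses them: stage 1 screens every library compound over a conformer
ensemble (≤ `max_confs`, default 50) with aligned matching; compounds
passing (by default matching *all* sites) proceed to external docking,
which this package deliberately does not perform — poses are ingested from
SDF (`ingest_poses()`, many poses per compound, best pose kept); stage 2
rescreens those poses *in place*, with no conformational search and no
realignment, the "more restrictive" reading of a post-docking rescreen.
Stage 2 reuses the build tolerance as its radius; no separate screening
radius is defined, so none is invented. Funnel counts
`n_in ≥ n_stage1 ≥ n_posed ≥ n_stage2` are monotone by construction and
asserted on every run; reports are byte-identical under a fixed seed.

## Conformers

`generate_conformers()` uses seeded ETKDG distance-geometry embedding with
MMFF94 relaxation (via the bundled python helper), then prunes duplicates
at 0.5 Å heavy-atom RMSD and caps the ensemble (default 50). The pipeline
is deterministic in the seed — the same library screened twice gives the
same report. Rigid molecules collapse to a single conformer; embedding
failures flag the record instead of aborting a screen.

## Feature perception rules

Commercial feature grammars are unpublished, so the default rule set is
explicit, versioned, and replaceable (`ruleset()`, `read_ruleset()`):

* **A** — N/O with an available lone pair: carbonyl, ether and hydroxyl
  oxygen; pyridine-type aromatic N without hydrogen; nitrile N. Amide
  nitrogens and positively charged atoms are excluded. Direction points
  from the mean of bonded heavy atoms toward the atom.
* **D** — N/O bearing at least one hydrogen; one feature per heavy atom
  (matching the granularity of a tolerance sphere), direction toward the
  first hydrogen.
* **R** — every aromatic ring, at its centroid; the direction is the ring
  normal, which is axial — equality up to sign is the meaningful
  comparison, and tests treat it so.
* **H** — each maximal connected set of ≥ 3 aliphatic carbons whose
  members bond only to C, H or halogen, at the set centroid. Halogens are
  compatible substituents but never seed a group alone. A group centroid
  (rather than one atom) is used because a tolerance sphere describes a
  region, and the centroid is the stable representative of a flexible
  greasy chain.
* **N/P** — formally charged atoms; implemented but off by default, since
  the five-point consensus models this package targets use A/D/H/R only.

Pattern overrides are matched by a small built-in SMARTS-subset matcher
(element, aromaticity, `#n`, `Hn`, `Xn`, charge, ring membership,
negation, AND/OR, branches, ring closures; no stereo or recursion) because
no installed R toolkit exposes atom-level SMARTS matches. Overridden types
place features at matched-atom centroids without directions. This is the
lever for tuning a rebuilt case-study model without touching code.

## Synthetic data: what it emulates, what it does not

The `synthgen` functions generate the package's test beds at the feature
level: planted hypotheses (sites ≥ 6 Å apart by rejection sampling),
jittered prealigned ligand sets with a controlled per-(ligand, site)
support matrix, Gaussian positional jitter (σ in Å) and off-site noise
features, plus decoys that are *verified* non-matching by the brute-force
oracle before they are emitted (by deleting a feature type — pigeonhole —
or displacing one feature beyond every same-type sphere).

`synth_cocrystal_panel()` fixes the study conditions used throughout the
acceptance checks: 20 ligands, five sites typed `A/D/R/A/H`, per-site
supports 0.95, 0.85, 0.60, 0.45, 0.35, jitter σ = 0.3 Å, one noise feature
per ligand. The support ladder mirrors how such panels behave on soluble
epoxide hydrolase: a urea-like acceptor/donor anchor pair present in nearly
every binder, an aromatic stacking feature in a majority, and peripheral
acceptor/hydrophobe contacts in a minority. Under those conditions the
builder returns five `A/A/D/H/R` sites at (0.25, 2.5 Å) and three at the
(0.5, 2.0 Å) defaults, and a four-point analogue (the planted set minus its
hydrophobe) caps at 4 of 5 matched sites — the negative-control behaviour.

What the generator does **not** emulate: real 3D chemistry (ring
geometries, torsional ensembles, receptor clashes), perception noise (it
plants feature points directly, bypassing the rule set), or docking-pose
error. Passing the planted-recovery and funnel tests therefore demonstrates
the correctness of clustering, support accounting, matching and funnel
plumbing — not that the default rule set reproduces any particular
commercial tool's feature assignments on real ligands. Rebuilding a
published model from deposited structures additionally needs the structures
themselves, a superposition step (`superpose()` on shared alpha-carbons),
and possibly rule-set tuning via the override file.

## Numerical choices

* Verification tolerance: distances may exceed a radius by at most 1e-9 Å
  (shared by matchers and oracle, so equivalence tests are exact).
* Kabsch: smallest singular direction flipped when the raw solution is
  improper; `det(R) = +1` always, checked to 1e-9 on degenerate (planar,
  mirrored) inputs.
* Site survival threshold: `support ≥ min_fraction − 1e-12`, so a fraction
  computed as 4.999…/20 at the boundary still counts; monotonicity in
  `min_fraction` is preserved.
* Overlapping same-type sites (centroids closer than the tolerance)
  collapse to the higher-support one.
* Ties everywhere (clique choice, assignment backtracking, site ordering)
  break lexicographically after `(count, score)`; outputs are
  order-independent of the input ligand order.
* Degenerate inputs: empty feature pools cluster to nothing; an empty
  library is an error; unparseable records skip with a counted warning.

## Problem sizes

The shipped tests and the acceptance script run at the scales the methods
are designed for on a single core: 100-instance oracle sweeps (≤ 7
features × ≤ 6 sites), 50-seed recovery experiments at N = 20 ligands,
funnels of 10 feature-level compounds, and one full 3 × 2924 = 8772
enumeration with canonicalisation. The matchers themselves are exact at
these sizes; the in-place DP is exponential only in the number of sites
(capped at 12).

## Known limitations

* Feature perception needs explicit hydrogens (`add_hydrogens()` round
  trips through OpenBabel when a structure lacks them) and one selected
  conformer; tautomers and protonation states are taken as given, never
  enumerated.
* The amide coupling in `enumerate_products()` is a SMILES-level
  condensation with a documented convention (acid spelled `OC(=O)…` or
  `…C(=O)O`; the first eligible primary/secondary non-amide nitrogen
  couples); it does not model protecting groups or reactivity.
* Lipinski filtering is the only drug-likeness criterion; ADME prediction
  is out of scope, so post-filter library sizes are not comparable to
  pipelines that also filter on predicted pharmacokinetics.
* `match_aligned()` is rigid: no torsional optimisation during matching,
  no excluded-volume check against the receptor.
* PDB parsing is fixed-width v3.3; mmCIF is not supported. Ligand bond
  orders from PDB files are perceived from geometry (no CONECT
  dependence), a stated heuristic.
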
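---
title: "Methods: pharmacophore screening and binding analysis in pharmscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacophore screening and binding analysis in pharmscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmscreen)
```

`pharmscreen` implements a tolerance-sphere 3D pharmacophore screen for
selective inhibitors of the Dishevelled-1 (DVL1) PDZ domain, together with
the quantitative binding analyses used to characterize hits. This vignette
records the model, its assumptions, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## The pharmacophore model

A pharmacophore query is an abstract interaction point: a kind (aromatic,
hydrophobic, H-bond donor, H-bond acceptor), a position in a fixed
Cartesian frame (Å), a spherical distance tolerance (Å), and a `required`
flag. The shipped DVL1 selectivity model has seven queries — 3 aromatic,
2 hydrophobic, 1 donor, 1 acceptor — with `min_match = 5`. One hydrophobic
query is flagged required: it marks the sub-pocket lined by Leu12, Val75
and Ile81 whose smaller residues distinguish the DVL1 PDZ groove from the
NHERF1 PDZ1 groove (Tyr24/Ile79/Val86); occupancy of this pocket is what
the screen uses to demand selectivity, so a pose that leaves it empty is
rejected no matter how many other queries it matches.

Assumptions worth stating explicitly:

* **Tolerances.** Polar queries default to 2.0 Å, hydrophobic queries to
  2.5 Å. Aromatic queries take the hydrophobic tolerance, because the
  matcher treats aromatic and hydrophobic as equivalent kinds and the
  tolerance dichotomy is polar vs non-polar.
* **The must-have query is one of the seven**, not an eighth feature: the
  model is "7 queries" with the selectivity query counted among the two
  hydrophobics.
* **Geometry.** No experimental coordinates for the query frame are
  distributed. The shipped positions are an idealized right-handed frame
  chosen so that aromatic centroids sit 6–7 Å apart (typical for stacked
  groove interactions) and *every pairwise query separation exceeds 5.7 Å*.
  The second property is a deliberate design choice: since the largest
  tolerance is 2.5 Å, a feature inside one query's sphere is always at
  least 5.7 − 2.5 > 2.5 Å from every other query, so a planted feature can
  satisfy exactly one query. This makes the generator's truth labels
  provable rather than probable. The matcher itself never depends on the
  absolute frame, only on relative geometry.
* **Polar anchor identity.** The binding mode offers two N–H donors
  (indole and carboxamide) and several potential acceptors; the single
  donor query is taken to represent the indole N–H point and the single
  acceptor the carbonyl oxygen point. This is an interpretive assumption;
  models with a different assignment can be supplied as JSON.

## Feature perception

The perception rules are deliberately simple, deterministic, and purely
graph/geometry based (no charge models, no tautomer enumeration):

* *aromatic*: each smallest ring (5/6 atoms, found per-bond by
  shortest-cycle search in the aromatic subgraph) whose atoms are all
  aromatic-flagged; point at the unweighted ring centroid. Aromaticity of
  atoms is taken from order-4 bonds in the SDF.
* *donor*: N or O with an explicit H neighbour or implicit hydrogens by
  default valence (N 3, O 2, charge-adjusted; aromatic bonds count 1.5,
  total rounded up). A ring N–H written without its hydrogen is therefore
  not seen as a donor — explicit hydrogens on heteroatoms are recommended.
* *acceptor*: O without positive formal charge; N without positive charge,
  without hydrogens, and not bonded to a carbonyl carbon (amide nitrogens
  are delocalized and excluded). Pyridine-type nitrogens qualify.
* *hydrophobic*: connected components of ≥ 3 non-aromatic carbons with no
  heteroatom neighbour (centroid point), plus single methyl carbons on
  aromatic rings as one-atom points.

No directionality (ring normals, lone-pair vectors) is attached, because
matching uses spherical distance tolerances only. One atom may serve
several kinds (a hydroxyl O is donor and acceptor), but aromatic carbons
are never also hydrophobic — an aromatic ring contributes one feature, not
two stacked ones.

## Matching, acceptance, fitness

Matching seeks the injective assignment of features to queries that
maximizes the matched count, subject to kind compatibility and per-query
tolerances; ties are broken by lower RMSD over matched pairs, then by
query order, so results are deterministic. The search is a depth-first
enumeration over queries with an optimistic-count bound — exact, and fast
at pharmacophore sizes (≤ 10 queries).

Acceptance is `n_matched ≥ min_match` **and** all required queries
matched. The fitness score is

> fitness = n_matched − mean(dᵢ / tolᵢ)

over matched pairs. The normalized residual term lies in [0, 1), so
fitness is bounded in (n − 1, n]: match count dominates, geometry breaks
ties, and the score is unit-free. (The original screen used a commercial
fitness whose functional form is not public; this form preserves the two
orderings any such score must respect.)

Two frames are supported. `prealigned` (the screening default) assumes
poses are already in the model frame, as docked poses are. `align`
searches a rigid transform jointly with the assignment: triples of
kind-compatible pairs whose internal distance matrices agree within summed
tolerances seed a Kabsch superposition, which is refined by re-assignment
and re-alignment; when the number of injective kind-compatible assignments
is below 10⁵ the search instead enumerates every assignment, aligns on it,
and keeps the best feasible one — exact (in the least-squares alignment
sense) on small instances, which is what the brute-force oracle tests
exercise. Align-mode results are invariant under rigid transforms of the
input pose; prealigned results deliberately are not.

Kabsch superposition itself is the standard SVD construction with the
determinant correction, so the returned rotation is always proper.

## The library screen

Each molecule is screened conformer by conformer (conformers grouped by
the `MOL_ID` SDF property, not record order), represented by its
best-fitness conformer, and accepted iff that conformer is accepted.
Records sort by fitness (descending, ties by molecule id, which makes the
output invariant to input order); the `top_n` accepted molecules receive
dense ranks. Defaults mirror the protocol scale: 10 conformers expected
per molecule, `top_n = 500`. Molecules with fewer conformers are screened
with a warning — the conformer count is a protocol parameter, not a
validity rule. The downstream visual-inspection step of a real campaign
is out of scope; the pipeline ends at the ranked shortlist.

## Binding analyses

* **Saturation binding**: `F(c) = F0 + Fmax·c/(Kd + c)`, fitted by
  Levenberg–Marquardt least squares. Start values: `F0` and `Fmax` from
  the signal extremes, `Kd` from the concentration nearest half-range.
  At least 4 distinct concentrations are required; constant signal is an
  explicit error (no saturation information).
* **Competitive shift**: `Kd_app = Kd·(1 + [I]/Ki)` and its inverse
  `Ki = [I]/(Kd_app/Kd − 1)`. `Kd_app ≤ Kd` reports "no measurable
  inhibition" (NA with a warning), a data condition rather than a crash.
  Treating the observed shift as strictly competitive is an interpretive
  choice; no Cheng–Prusoff conversion between EC50 and Ki is ever applied
  implicitly — Kd, Ki and EC50 remain distinct named quantities.
* **Dose–response**: 4-parameter logistic
  `bottom + (top − bottom)/(1 + (d/EC50)^hill)`, with `top` the zero-dose
  plateau. Initialization: plateaus from responses at the dose extremes,
  EC50 from the geometric mean of the doses bracketing the half-range
  crossing, hill = 1; bounds EC50 > 0, hill ∈ [0.1, 10] (both directions
  of response are handled by the plateau order, so hill stays positive).
  At least 5 distinct doses are required.
* **Inhibition rate**: `100·(control − sample)/control` (%), unclamped so
  growth stimulation shows as negative. Assay write-ups sometimes print
  this formula with the division attached to the sample term only; that
  form is dimensionally inconsistent and cannot reproduce reported
  percentages, so the standard relative difference is implemented.

Parameter standard errors come from the curvature of the least-squares
objective at the optimum (the usual asymptotic covariance), matching the
"± SD" convention of nonlinear-regression software without emulating any
particular package.

## Synthetic data: what it emulates, and what it does not

The generators exist so the full pipeline is testable without proprietary
inputs. They emulate the *structure* of the study's data:

* **Screening library**: molecules of `n_conformers` posed conformers
  (default 10) with a planted fraction of actives (default 0.25 at a
  desk-scale default of 200 molecules, emulating the shape of a
  7000 × 10 docked screen, not its size). Molecules are minimal
  multi-fragment pseudo-molecules — benzene hexagons, propane patches,
  amine N–H, carbonyl C=O — each fragment triggering exactly one
  perception rule. Actives realize, on one randomly chosen conformer, a
  random subset of ≥ `min_match` queries (always including the required
  one), each feature placed within `tolerance − 2·jitter_sd` of its query;
  positional jitter is an isotropic Gaussian *truncated at 2σ*, so the
  margin is a hard guarantee and planted actives pass with certainty, not
  just high probability. Remaining conformers are rigid copies displaced
  ~20–25 Å, far outside every tolerance sphere in the prealigned frame.
  Decoys violate the rule in one recorded way each: `missing_required`
  (six features, none on the must-have), `too_few_features` (four,
  including the must-have), `displaced_beyond_tolerance` (all features
  0.2–0.5 Å outside their spheres — close misses), `kind_mismatch`
  (kind-incompatible fragments at the query positions). Together with the
  ≥ 5.7 Å query separations these constructions make the truth table
  exact under prealigned screening.
* **FRET titrations**: the hyperbola evaluated on the 2–38 µM, 10-point
  design at fixed 1 µM reporter peptide, optionally with a competitor via
  the competitive-shift relation, with multiplicative Gaussian noise
  (fluorescence error scales with intensity; 2 % is the design point used
  in the tests).
* **Dose–response**: the 4PL on an 8-point log-spaced design spanning
  0.01–100× the generating EC50, multiplicative noise.

What they do **not** emulate: real chemistry (no drug-like valence
checking, conjugation or strain; fragments may be disconnected), docking
physics (poses are planted, not docked), conformational energetics,
spectral FRET detail (only the fitted 540 nm endpoint), plate effects or
replicate structure in dose–response. A green test suite therefore
demonstrates the *algorithms* — perception rules, assignment optimality,
acceptance logic, fit recovery — and says nothing about docking quality or
assay behaviour on real compounds. In align mode, displaced conformer
copies of an active would realign onto the model (that is the point of
align mode), so planted truth tables are stated for prealigned screening
only.

## Numerical choices and degenerate inputs

* Distance comparisons against tolerances carry a 1e−12 Å² slack so exact
  boundary placements match on all platforms.
* Assignment tie-breaks: lower matched-pair RMSD, then query order;
  candidate features are tried nearest-first, which makes the reported
  assignment deterministic.
* Zero-feature poses score fitness 0 and are rejected, not errors; empty
  molecules, zero-query models, non-finite coordinates, negative
  tolerances, out-of-range bond indices and self-bonds are errors at
  construction, so no partially valid object escapes.
* `jitter_sd ≥ tolerance/2` would destroy the planting guarantee and is
  refused at generation time.
* SDF coordinates are written at 4 decimals (the fixed-width V2000 atom
  block); generator determinism is byte-level for a fixed seed.
* Simulation scale in the tests and the acceptance script: 20 noise seeds
  per fitted quantity, 40-molecule libraries with 4 conformers for
  end-to-end screening checks, and 500 random small instances (2–5
  queries × 2–7 features) for oracle-equivalence — sizes at which the
  brute-force oracle is itself exact and fast.

## Known limitations

* Perception has no charge/π-cation kind (the arginine π-cation contact
  region is folded into an aromatic query), no halogen-bond typing, and
  treats ethyl and larger ring substituents as non-features unless they
  form a 3-carbon patch.
* The align-mode exhaustive search judges feasibility at the
  least-squares alignment of each assignment; a pathological assignment
  satisfiable only at a non-least-squares rigid transform could be
  missed. Pharmacophore-scale instances tested against the oracle do not
  exhibit this.
* Fit standard errors are asymptotic; with 8–10 points they are
  indicative, not exact confidence intervals.
* The screen ranks only accepted molecules; near-miss high-fitness
  rejected molecules are reported unranked rather than surfaced.
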
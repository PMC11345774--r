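---
title: "Methods: pharmacophore and Gaussian-shape virtual screening for nonbasic KOR agonists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacophore and Gaussian-shape virtual screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screening problem

Classical opioid ligands anchor in the orthosteric pocket through a
protonated amine. Salvinorin A (SalA), a neoclerodane diterpene and potent,
selective kappa-opioid receptor (KOR) agonist, has no nitrogen at all, and
ligands lacking a basic amine appear to reach an overlapping but distinct
binding mode. A screen for further nonbasic KOR agonists therefore needs
(i) a 3D hypothesis of how SalA binds, (ii) retrieval machinery that ranks
millions of molecules against that hypothesis, and (iii) filters that keep
the chemistry nonbasic. `kappascreen` implements that workflow end to end at
desk scale: two parallel ligand-based screens (3D pharmacophore matching and
Gaussian shape overlay), DUD-E-style property-matched decoy generation for
validating the query with ROC statistics, and a triage stage for merged hit
lists with docking-pose re-scoring and receptor-contact annotation.

Everything the pipeline consumes can be produced by the synthetic-data
module, deterministically under a seed, so the full system is testable
offline with no proprietary software or downloads.

## Pharmacophore model

A query is a set of typed tolerance spheres — hydrogen-bond acceptors (HBA),
donors (HBD), hydrophobic contacts (HY), aromatic centers (AR) — plus an
exclusion-volume coat of forbidden spheres standing in for receptor-occupied
space. Feature perception on a ligand conformer follows a declared, tested
convention (see `?perceive_features`): carbonyl, hydroxyl and non-ester sp3
ether oxygens and pyridine-type nitrogens accept; N/O bearing hydrogen
donate; connected clusters of two or more carbons/halogens/sulfide sulfurs,
as split by heteroatoms, give hydrophobic centroids; aromatic rings give AR
centroids. The ester sp3 oxygen and the furan oxygen are deliberately *not*
acceptors: in the SalA hypothesis all three acceptor features sit on carbonyl
oxygens (the C1, C2-acetoxy and C4 substituents), and a furan HBA is known to
be uninformative for retrieval.

Matching enumerates kind-compatible assignments of query features to ligand
features, prunes by pairwise inter-feature distances (slack `r_i + r_j`),
superposes matched ligand feature centers onto the query by the closed-form
least-squares rotation (proper rotations only), and accepts when every
matched feature lands inside its tolerance sphere with no ligand heavy atom
inside an exclusion sphere. The fit score is

$$S \;=\; 9\,n_\text{matched} \;+\; \sum_f \bigl(1 - d_f/r_f\bigr),$$

which guarantees that matching one more feature always outranks placing
fewer features better — the behaviour a feature-count-driven screening score
should have. The dominant constant 9 is arbitrary in scale; any constant
larger than the number of features would do. A pruned search and an
exhaustive assignment enumeration (with an independent quaternion
superposition) agree on every small query in the test suite.

Defaults: tolerance radius 1.5 Å per feature, exclusion radius 1.0 Å —
conventional pharmacophore sphere sizes, both configurable. HBA features are
undirected spheres without projected points; a directed-acceptor variant
would be the first refinement to try if retrieval against real libraries
proved too permissive.

The bundled reference query (`reference_query()`, shipped as
`inst/extdata/sala_kor_reduced.json`) is built from the scaffold template's
own perceived features: three carbonyl HBAs labelled `C1-HBA`, `C2-HBA`,
`C4-HBA` and three HY islands, with a twelve-sphere exclusion coat above and
below the query plane. Its coordinates are a geometric stand-in constructed
by this package — not the published model's coordinates, which are not
tabulated anywhere — so absolute hit lists are not comparable to screens run
with the original query; rank-based and by-construction quantities are.
`drop_feature(query, "C2-HBA")` reproduces the query-reduction experiment in
which omitting the C2-acetoxy acceptor improves early enrichment.

## Gaussian shape model

Shape similarity uses the standard heavy-atom Gaussian formalism: atom $i$
contributes $p\,e^{-\alpha_i\|r-R_i\|^2}$ with $p = 2.70$ and
$\alpha_i = \pi\,(3p/4\pi)^{2/3}/\sigma_i^2$ (Bondi radius $\sigma_i$), so an
isolated atom's Gaussian volume equals its hard-sphere volume. Overlap is
first order (pairwise):

$$O_{AB} = \sum_{i\in A}\sum_{j\in B} p^2
  \Bigl(\tfrac{\pi}{\alpha_i+\alpha_j}\Bigr)^{3/2}
  e^{-\frac{\alpha_i\alpha_j}{\alpha_i+\alpha_j} d_{ij}^2},$$

verified against grid quadrature to within 1% in the tests. Alignment
initializes from centroid-plus-principal-axes in all four proper sign
combinations (plus the pharmacophore transform when a shared query is given)
and refines the six rigid degrees of freedom with a Nelder-Mead simplex
(iteration cap 300). `T_shape = O_{AB}/(O_{AA}+O_{BB}-O_{AB})`; the color
term repeats the computation over same-kind perceived features as unit-width
Gaussians ($\sigma_f = 1$ Å), restricted to HBA/HBD/AR/HY; `combo`
ranges over $[0, 2]$. Second-order (inclusion-exclusion) corrections are a
non-goal: they shift absolute volumes but hardly reorder rankings at this
scale. When neither molecule carries any feature the color denominator is
zero and `T_color` is reported as 0.

## Decoy generation and screen validation

`generate_decoys()` is a DUD-E-style property matcher: a universe compound is
a candidate for an active when it sits inside every window (MW ±25 Da,
logP ±1.0, rotatable bonds ±2, HBD ±1, HBA ±1, identical net charge) and its
ECFP4 Tanimoto to the active is below 0.35 (topology dissimilarity). Window
sizes and the cap are declared defaults, configurable in `decoy_spec()` —
the web service the study used does not publish its exact binning. Each
active samples `k` candidates without replacement under the seed (default
`k = 50`, the study's 1:50 ratio); a universe member serves at most one
active. Because the fixture actives occupy a narrow property envelope, a
purely greedy random pass strands scarce candidates; a deterministic
augmenting-path repair (Kuhn's bipartite b-matching) afterwards reassigns
earlier picks so that the allocation is exact whenever the candidate
structure permits it, for any seed. Shortfalls, when structural, are logged
per active, never silently padded.

Validation statistics are deliberately elementary and exact: AUC by the
rank-sum estimator with ties counting 1/2 (equal to trapezoidal integration
on tie-free lists, and cross-checked against both explicit pairwise counting
and `pROC` in the tests), sensitivity as recovered/total actives rounded to
whole percent, FP as hits minus recovered, and enrichment
$EF_f = (TP_f/n_f)/(P/N)$ at 1% and 5% by default — the common early-
enrichment definition, chosen because the source material's phrase "early
enrichment" is not formulaic. `auc_from_partial_ranks()` reconstructs the
published shape-screen validation list, which is only partially printed (82
actives, 4100 decoys, decoys at ranks 59, 67, 74, 79, 83–86, straggler
actives at 702, 848, 1476), materializes the implied label vector and
returns its exact AUC: 0.99 at the printed precision. Whether the original
AUC used trapezoidal or rank-sum estimation is unstated; the reconstruction
is tie-free, where the two coincide. The companion pharmacophore-side AUC
(0.85) is *not* reconstructible — the full rank list was never printed — and
is out of scope.

## The synthetic-data module: what it emulates and what it does not

The study conditions it reproduces: 82 nonbasic actives (MW 300–500 Da, no
formal charge, no basic amine, EC50-style curation rules implemented in
`curate_actives()`), a 50× property-matched decoy universe, and the partial
rank list above. The actives are decorated variants of one rigid
"salvinoid-like" template built directly as a connection table with template
coordinates: a cyclohexanone core (HY island + C1-carbonyl HBA), an ester
arm ending in a gem-dimethyl branch (second island + C2-analogue HBA) and an
ester arm ending in a furan (third island + C4-analogue HBA). Decorations
(halogens, methyls, an ethyl) sit away from feature centroids, and
coordinates get a small seeded jitter (sd 0.08 Å), so every active satisfies
the reference query at full-match settings *by construction* while remaining
structurally distinct. Conformer counts above one add further jittered
copies — a perturbation ensemble, not a torsional one.

The decoy universe is a combinatorial family (substituted benzene or
cyclohexane cores with ester, ketone-or-ester and ether arms, two
substitution patterns, five ether caps, and up to two further ring
substituents — halogens or methoxy, which decouple mass from lipophilicity)
pruned analytically — exact formula MW, a rotatable-bond count, and an
additive logP estimate calibrated against Open Babel's atomic-contribution
logP (R² ≈ 0.997 within the family) — to the actives' window envelope before
any conversion, then capped at roughly three times the requested decoy
count. Universe conformers are
deterministic scrambled folds (`toy_embed()`): bonded distances are
respected, nothing else is — which is exactly the "property-matched,
geometry-scrambled" role decoys play.

What passing tests therefore show: the engines, statistics and bookkeeping
are correct on inputs whose ground truth is known exactly. What they do not
show: retrieval performance on real conformational ensembles, tautomers,
stereochemistry or library chemistry far from the fixture families — none of
which the fixtures model. The pocket fixture likewise contains five labelled
residues (Q115, V118, Y139, Y312, Y313) at invented coordinates placed to
exercise the hydrogen-bond and hydrophobic contact geometry, not KOR
coordinates.

## Triage

Hit lists merge by Open Babel canonical SMILES (stereo-descriptor-free — the
fixture chemistry carries no stereocenters, and merging must not depend on
which screen emitted the record). Filters drop charged molecules, basic
amines (structural classes: aliphatic amines, amidines, guanidines; amide,
anilinic and aromatic-ring N pass — a deliberate binary classification, not
a pKa calculation), MW > 500 Da and rotatable bonds > 10, boundary values
inclusive; the survivor set is order-independent and per-flag drop counts
are conserved. Docking poses (SDF, from any external engine — docking itself
is out of scope) are re-scored by a fixed-frame partial match against the
full query; poses scoring 0 are dropped, and whether the C2-analogue
acceptor is matched is recorded, since that interaction separates SalA from
its inactive C2-hydroxy metabolite. Contacts use declared conventions:
hydrogen bond at ≤ 3.5 Å between ligand polar heavy atoms and receptor N/O
(distance-only in the absence of explicit hydrogens), hydrophobic at
≤ 4.5 Å between apolar carbons; all cutoffs configurable. The final
compound selection for experimental testing was a manual step in the study
and stays manual here: `run_pipeline()` emits a ranked table with every
criterion as a sortable column rather than pretending to automate judgement.

## Numerical choices and degenerate inputs

* Superposition uses SVD with the reflection branch rejected
  (`det` correction); one-point matches reduce to a translation, collinear
  sets are handled by the same closed form.
* Screen ordering ties break by molecule ID ascending, making every ranking
  reproducible byte for byte.
* All randomness flows through private RNG streams seeded from the relevant
  spec (`fixture_spec$seed`, `decoy_spec$seed`); the caller's RNG state is
  never disturbed, and identical specs give byte-identical artifacts.
* Single-heavy-atom molecules, empty feature sets, empty libraries, queries
  with all features dropped, and pose/query frame mismatches (everything
  farther than 20 Å) raise errors or warnings rather than returning silent
  zeros.
* logP is computed from the canonical SMILES normal form, not from whatever
  concrete file happened to carry the molecule, so independently re-parsed
  molecules reproduce their descriptor values exactly.

## Problem sizes

Unit and property tests run on a cached fixture of 8 actives with a
~1,500-candidate universe and on toy molecules; the decoy-accounting check
runs the full study-sized configuration (82 actives, 1:50, ~13,000-candidate
universe, ~2–3 minutes). The shape screen inside the pipeline tests covers
tens of molecules — enough for the set identities and retrieval guarantees
being asserted, chosen so the whole suite stays comfortably interactive.

## Known limitations

Perception rules are a convention, not a reproduction of any proprietary
toolkit's definitions; absolute scores are not comparable to LigandScout or
ROCS values. Tautomers, pKa prediction and stereochemistry-aware conformer
ranking are non-goals. The shape optimizer is local: it provably never
scores below its best initialization, but global optimality is not claimed.
Fixture realism is deliberately subordinated to testability — the point of
the synthetic module is exact ground truth, not chemical novelty.
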
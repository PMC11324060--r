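---
title: "Fragment-combination analysis for pseudo-natural-product discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-combination analysis for pseudo-natural-product discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fraggraph)
```

## The problem

Pseudo-natural products (PNPs) are synthetic compounds that combine natural
product (NP) fragments in arrangements that nature does not use. Because
they inherit the biological relevance of NP substructure while occupying
unexplored chemical space, they are attractive starting points for
phenotypic screening. Identifying them in a multi-million-compound catalog
requires an automated chain: standardize every structure the same way,
detect which NP-derived fragments it contains, type every pairwise fragment
combination, compare those combinations against what is observed in a
reference NP collection, and finally triage the hits for screening.
`fraggraph` implements that chain as a tested R library with a command-line
front end.

## The model

### Fragment-combination graphs

After standardization, every catalog fragment (a Murcko scaffold from an NP
fragment set) is matched into the molecule as a labelled subgraph
(elements, charges, aromaticity and bond orders must agree; substitution is
free, so hydrogen counts are not matched). Every unordered pair of retained
hits is then classified by the overlap of their atom sets, with `k` shared
atoms:

* `k >= 1` — *fusion* family: one hit contained in the other discards the
  contained hit (`ffs`); `k = 1` is a spiro fusion (`fs`); `k = 2` with the
  atoms bonded is an edge fusion (`fe`); `3 <= k <= 5` is a bridge fusion
  (`fb`); anything else (`k = 2` non-bonded, `k > 5`) is a match artifact
  and is discarded (`ffo`).
* `k = 0` — *connection* family: linker paths running only through atoms
  external to both hits are enumerated. If the shortest such path exceeds
  the connection cutoff (3 bonds by default) the pair is not connected
  (`cfc`). One attachment-point pair is a monopodal connection (`cm`); two
  pairs are bipodal, subtyped by the attachment atoms — shared atom (`cbs`),
  adjacent on both fragments (`cbe`), otherwise (`cbb`); three or more are
  tripodal-plus (`ct`).

Typed edges over the hits form fragment-combination graphs (FCGs): the
connected components with at least one edge. Each FCG gets a canonical
signature — edge strings `min(frag):max(frag):ctype`, sorted and joined with
`|` — which is invariant to atom numbering, hit enumeration order, and
SMILES rendering, and drops occurrence indices so that repeated identical
combinations count once.

### Status assignment

The NP reference is built by running the identical pipeline over an NP
library; it stores the racemic InChIKeys of all NPs and the set of FCG
signatures (or their individual edge strings) seen in NPs. A molecule is

* **NP** if its racemic InChIKey is in the reference (identity wins over
  everything),
* **PNP** if any of its fragment combinations is absent from the reference —
  this includes molecules that also carry known combinations,
* **NPL** (natural-product-like) if it has combinations and all are known,
* **NonPNP** otherwise: no combinations, failed filters, failed
  standardization, or exceeded the per-molecule time budget.

The default comparison level is `edge`: a single pairwise combination
unseen in NPs makes a PNP. The frequency analyses that motivate the method
operate on pairwise combinations, which makes the edge level the natural
unit; whole-graph comparison is available via
`fg_config(fcg_compare_level = "graph")` and is strictly stricter (a graph
combining two individually known edges can then be novel). Both levels are
exercised in the test suite.

### Standardization

Structures are canonicalized with Open Babel; all stereochemistry is
removed (*racemization*) because deduplication and NP identity use racemic
InChIKeys; +1/-1 charges are neutralized; the largest organic component is
kept (salt stripping, ties broken by canonical SMILES order); terminal
sugar rings are removed iteratively (*deglycosylation*): a saturated 5/6
ring with one ring oxygen, at least two exocyclic hydroxyls on ring
carbons, attached through a single O-glycosidic bond, loses its sugar while
the glycosidic oxygen stays with the aglycone. The exact deglycosylation
rule set of the original preprocessing tool is not published in detail;
this package fixes the above structural definition and pins it with tests
(salicin, a diglycoside, free glucose). Structural filters keep molecules
with at least one ring and MW < 1000 g/mol.

Everything downstream treats processing chunks as a pure batching detail:
there is no chunk-local state anywhere, and a dedicated test verifies that
pipeline outputs are byte-identical for chunk sizes 1, 7, 64 and 500. The
per-molecule wall-clock budget (default 50 s) applies to the fragment
analysis stage, where combinatorial blowup can occur; a timed-out molecule
is recorded as NonPNP with a failure reason instead of aborting the run.

## Complexity: SPS and nSPS

The spatial score of a molecule sums, over heavy atoms, the product
`h * s * r * n^2` with `h` the hybridization term (sp 1, sp2 2, sp3 3,
other 4), `s = 2` for stereogenic atoms, `r = 2` for non-aromatic ring
atoms and `n` the number of heavy-atom neighbors; nSPS divides by the
heavy-atom count. The constants follow the published reference
implementation, and a 25-molecule drug panel frozen from that
implementation is pinned at `|difference| < 1e-9`
(`inst/extdata/nsps_reference_panel.tsv`).

Because the pipeline racemizes structures, stereogenicity is perceived as
*potential* stereocenters: hybridization comes from electron-domain
counting (aromatic atoms sp2; lone-pair N/O promoted to sp2 when conjugated
to an aromatic system or a multiply-bonded C/N neighbor — not across
hypervalent P/S), and tetrahedral stereocenters are detected with
Weisfeiler–Lehman symmetry classes rooted at the candidate atom. A
candidate whose only degeneracy is one pair of symmetry-equivalent branches
is still stereogenic when those branches contain further stereogenic units
(the 1,4-disubstituted-cyclohexane case). Potential E/Z double bonds are
non-ring (or in rings of 8 or more atoms) with distinguishable substituents
on both ends.

## Screening triage

`select_cpa_subset()` reproduces the scaffold-based selection of a
cell-painting screening subset: PNPs are grouped by the racemic InChIKey of
their Murcko scaffold, groups must have a scaffold of exactly 17 heavy
atoms (the median scaffold size of approved/experimental drugs, which
keeps the subset lead-like) and at least 4 members, and 250 groups × 4
members are drawn uniformly without replacement from a single seeded
generator. Groups and members are pre-sorted (scaffold InChIKey, then
source id) so that one seed gives one selection on any platform.
`pains_filter()` removes pan-assay interference substructures using a
curated subset of the published PAINS patterns shipped with the package
(the op accepts any pattern table, so the full published catalog can be
supplied).

## Morphological profiles

Cell-painting profiles are 579 modified-Z-scored features against DMSO
controls. *Induction* is the percentage of features with `|z|` at or above
the significance threshold (default 3; the exact value used by the assay
provider is configurable); compounds with induction ≥ 5% are active.
Actives are assigned to one of up to 13 reference bioactivity clusters by
Pearson correlation (× 100) between the profile restricted to the cluster's
feature subset and the cluster's median reference values, with an 80%
threshold, ties broken by cluster name, and undefined correlations treated
as below threshold. Unassigned actives are embedded jointly with marker
compounds by seeded single-threaded UMAP. The proprietary reference
subprofiles are not redistributable, so the package defines their schema
(JSON: cluster name, feature indices, values) and ships a synthetic
generator instead.

## The synthetic data generator

`make_synthetic_library()` is first-class, tested code, not a static
fixture. It composes two-fragment molecules from an 8-scaffold toy catalog
by explicit graph surgery, one recipe per combination type: a methylene
linker (`cm`), a merged bond (`fe`), a merged spiro atom (`fs`), a merged
three-carbon path (`fb`), and two methylene linkers from adjacent atoms
(`cbe`). Requests that are not chemically realizable — a spiro atom on an
aromatic ring, an aromatic/saturated edge fusion — return a skip signal. A
composition is also skipped when it would incidentally create a third
catalog match (bridging pyrrolidine with cyclopentane yields an
azanorbornane that genuinely contains a piperidine ring); this guard uses
only substructure matching, so the classifier round-trip test remains an
independent check of the taxonomy logic. 117 compositions survive for the
default catalog.

Libraries built from these compositions carry per-record ground truth: a
seeded subset of compositions is copied into the NP library (those records
are NP by identity and define the known signatures), side-chain variants of
NP compositions become NPL, the rest PNP, and decoys (benzene-only,
single-fragment, fragment-free ring, acyclic, and an over-1000-Da record
would all be NonPNP or filtered). What passing these tests shows is that
the machinery — matching, taxonomy, signatures, reference comparison,
chunking, timeouts — is exactly right on molecules whose answer is known by
construction. What it cannot show is coverage of real-library chemistry:
tautomerism, exotic ring systems, charged species, or the scale of a
multi-million-compound catalog. Library-level results on real collections
(PNP fractions of commercial catalogs, combination-type ratios, nSPS
medians) require the commercial Dictionary of Natural Products and vendor
catalogs as inputs and are therefore out of reach of this repository's
tests; the two acceptance checks that depend on external downloads (the
2000→1673 fragment-catalog count and the DrugBank scaffold median of 17)
are implemented but report as failing when those files are absent.

`make_profiles()` plants cluster structure on disjoint feature subsets with
reference patterns of magnitude 4–6 (so members correlate ≈0.99 with their
cluster and always clear the 5% induction bar) and draws novel-activity
profiles on a reserved feature block orthogonal to every cluster subset.
Real profiles are noisier and their clusters are not feature-disjoint, so
the planted-recovery rate (≥95% required, 100% observed) is an upper bound
on real-data behavior, not an estimate of it.

## Numerical and design choices

* Connection cutoff: 3 bonds, configurable; the original tool's value is
  not stated in the motivating text, and 3 bonds keeps "connected" close to
  the printed examples while `cfc` discards long tethers.
* Overlap artifacts: `k = 2` non-bonded and `k > 5` overlaps are discarded
  rather than typed; they arise from symmetric matches, and the published
  type menu has no name for them.
* Bipodal subtypes `cbs`/`cbb` follow the same attachment-atom geometry as
  the published `cbe` by analogy.
* Matching requires equal charge states; catalog fragments are neutral
  after standardization, so charged ring atoms in a library molecule do not
  match (documented behavior, not configurable).
* Signatures drop occurrence indices, so deduplication of identical
  combinations is global per molecule — the semantics that the upstream
  chunk-dedup bug fix established.
* Sampling uses R's default generator under `set.seed`, isolated so library
  calls never disturb the caller's RNG state.
* Degenerate inputs: empty tables produce empty outputs with warnings;
  standardization failures carry `failure_reason` and become NonPNP;
  constant restricted profile vectors are "below threshold", logged.
* Problem sizes in the shipped tests: 120-molecule libraries for module
  tests, 500 for the chunk-invariance check, 300 scaffold groups × 5
  members for selection, 55 synthetic profiles — sizes chosen so the whole
  suite documents the behavior in a few minutes while exercising every code
  path.

## Known limitations

* The SMILES parser covers Open Babel's canonical dialect (plus stereo
  markers, which it discards); it is not a general-purpose SMILES reader
  and in particular expects aromatic form, not Kekulé form, for input to
  the matching layer. `standardize_library()` guarantees that form.
* Aromaticity is taken from the canonical writer rather than re-perceived;
  exotic aromatic systems that Open Babel and the reference toolkit
  disagree on will follow Open Babel.
* Tautomer canonicalization, isotope-specific handling and 3-D geometry are
  out of scope.
* Potential-stereocenter perception matches the reference implementation on
  drug-like molecules (verified on the frozen panel) but is not a complete
  CIP implementation; pathological symmetric cage systems may differ.
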
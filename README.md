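# fraggraph

Fragment-combination graph analysis for pseudo-natural-product discovery.

Pseudo-natural products (PNPs) are synthetic compounds that combine natural
product (NP) fragments in arrangements not found in nature. `fraggraph`
classifies compound libraries into **PNP / NPL / NP / NonPNP** by

1. standardizing structures (canonical racemic SMILES, salt stripping,
   charge neutralization, deglycosylation, ring/MW filters, racemic-InChIKey
   deduplication),
2. building a searchable NP-fragment catalog (Murcko scaffolds,
   deduplicated, benzene excluded),
3. matching catalog fragments into each molecule and typing every hit pair
   into the fusion/connection taxonomy — spiro (`fs`), edge (`fe`) and
   bridge (`fb`) fusions; monopodal (`cm`), bipodal (`cbs`/`cbe`/`cbb`) and
   tripodal (`ct`) connections — assembled into fragment-combination graphs
   (FCGs) with canonical signatures,
4. comparing those signatures against an NP reference: an unseen combination
   makes a PNP, all-known combinations an NPL, structural identity an NP,
   everything else NonPNP.

Around that core it provides the heavy-atom-normalized spatial complexity
score (nSPS = Σ<sub>atoms</sub> h·s·r·n² / #heavy atoms), scaffold-based
selection of screening subsets (17-heavy-atom scaffolds, ≥4 members per
group, 250 × 4 seeded draws), a PAINS triage step, and cell-painting profile
analysis (induction = % of 579 features with |z| ≥ 3, actives at ≥5%,
cluster-subprofile assignment at ≥80% Pearson similarity, seeded UMAP of
unassigned actives). A synthetic-fixture generator builds molecule libraries
and morphological profiles with exact per-record ground truth.

Chemistry primitives (canonical SMILES, InChIKeys, neutralization, SMARTS)
run through Open Babel; graph work runs on igraph (fragment matching is
labelled subgraph monomorphism via LAD on an atom/bond-expanded graph).

## Worked example

```r
library(fraggraph)

catalog <- make_toy_catalog()          # 8 non-benzene ring scaffolds
res <- molecule_fcgs("C(c1cccnc1)CC1CCNCC1", catalog)
res$hits
#>   frag_id occurrence                 atoms
#> 1       1          0      2, 3, 4, 5, 6, 7
#> 2       2          0 9, 10, 11, 12, 13, 14
res$edges
#>   hit_a hit_b frag_a frag_b ctype
#> 1     1     2      1      2    cm
res$fcgs[[1]]$signature
#> [1] "1:2:cm"
```

The molecule contains a pyridine hit (fragment 1) and a piperidine hit
(fragment 2) joined by a two-carbon linker: a monopodal connection (`cm`),
giving the FCG signature `1:2:cm`. If that combination is absent from the
NP reference, the compound is a PNP.

```r
nsps("C(c1cccnc1)CC1CCNCC1")
#> $sps
#> [1] 256
#> $nsps
#> [1] 18.28571

standardize_structure("C[C@H](N)C(=O)O.[Na+].[Cl-]")
#> $smiles_std
#> [1] "CC(C(=O)O)N"
#> $inchikey
#> [1] "QNAYBMKLOCPYGJ-UHFFFAOYSA-N"
```

Standardization strips the stereocenter and counter-ions; the InChIKey is
the racemic key used for deduplication and NP identity. The nSPS of 18.3
reflects the saturated piperidine ring and linker (aromatic-only molecules
score lower: benzene has nSPS 8).

The full pipeline runs from a YAML config or the command line
(`exec/fraggraph`):

```sh
fraggraph make-fixtures --kind library --n 200 --seed 7 --out-dir fixtures
fraggraph run --config config.yaml     # standardize -> catalog -> classify
                                       # -> np-ref -> status -> merge-back
```

writing status tables, the FCG table, the NP reference, a summary and a
reproducibility manifest to the configured output directory.

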
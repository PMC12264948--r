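# somannot

Rule-based annotation of **sites of metabolism (SOMs)** on substrate atoms
from stoichiometrically unbalanced substrate–metabolite pairs.

Metabolic reaction records usually document only the substrate and one
metabolite; water, cofactors and leaving groups are omitted. Generic
atom-mapping tools, trained on balanced organic reactions, misassign atoms
under these conditions, and naive maximum-common-substructure (MCS)
comparison labels the atom whose connectivity changed rather than the atom
where the enzyme initiates the reaction — in ester hydrolysis the sp3
oxygen instead of the carbonyl carbon. `somannot` is for cheminformaticians
and metabolism scientists who need chemically meaningful SOM labels at
scale, e.g. to mobilize legacy metabolism data for training SOM predictors
or to flag inconsistencies in curated databases.

## Method

Each validated, standardized pair is routed by its heavy-atom balance.
With `S` the substrate graph, `M` the metabolite graph and `φ` an atom
mapping (injective, element/charge-preserving, substrate bonds carried
over, bond orders respected where stated):

* **Addition** (`|M| > |S|`, `S` embeds into `M` bond-order-sensitively):
  SOMs are the atoms `a ∈ S` whose image `φ(a)` gains a neighbour outside
  `φ(S)`. Glutathione conjugation is screened first via its tripeptide
  moiety (SOM = substrate atom bonded to the cysteine sulfur); a
  carnitine-ester correction moves the SOM from the sp3 oxygen to the
  carboxyl carbon.
* **Elimination** (`|M| < |S|`, `M` embeds into `S`): each boundary bond
  between mapped and unmapped substrate atoms yields a SOM — the unmapped
  carbon (type 1, dealkylation) or the mapped neighbour of an unmapped
  heteroatom (type 2, e.g. reductive dehalogenation). (Thio)ester
  cleavages are corrected to the carbonyl carbon, inorganic-acid esters
  (phosphates, sulfates, sulfonamides, …) to the P/S center.
* **Complex** (equal counts, or no SOM found above): oxidative
  dehalogenation (same carbon count, halogen lost, oxygen gained), then a
  complete bond-order-agnostic atom mapping (SOMs where H count or formal
  charge changed), then an element-only MCS diff; ring-hydrolysis
  corrections handle epoxide, lactone and other heterocyclic openings.

Found SOM sets are expanded to full symmetry orbits (automorphism classes
of the colored molecular graph), and each reaction reports exactly one
status: `annotated`, `unknown`, `timeout` (default 20 s per reaction) or
`invalid`. Predictions are scored against ground truth as **full**,
**partial**, **neighbor** or **none** matches.

## Worked example

```r
library(somannot)

pairs <- tibble::tibble(
  substrate_smiles  = c("Nc1ccccc1", "COC(=O)c1ccccc1", "CCOP(=S)(OCC)Oc1ccccc1"),
  substrate_id      = c(1, 2, 3),
  metabolite_smiles = c("Nc1ccccc1O", "OC(=O)c1ccccc1", "Oc1ccccc1"),
  metabolite_id     = c(11, 12, 13)
)
res <- annotate_soms(pairs)
res[c("substrate_id", "metabolite_id", "som", "rule", "status")]
#> # A tibble: 3 × 5
#>   substrate_id metabolite_id som   rule                            status
#>          <dbl>         <dbl> <chr> <chr>                           <chr>
#> 1            1            11 2 6   general addition                annotated
#> 2            2            12 2     (thio)ester hydrolysis          annotated
#> 3            3            13 3     inorganic acid ester hydrolysis annotated
```

Row 1 is the ortho-hydroxylation of aniline: atoms `2 6` are the two ortho
carbons (0-based indices on the standardized substrate `Nc1ccccc1`) — the
hydroxylated position plus its symmetry-equivalent partner. Row 2 is ester
hydrolysis: atom `2` is the carbonyl carbon of methyl benzoate, not the
sp3 oxygen an MCS diff would pick. Row 3 is thiophosphate ester
hydrolysis: atom `3` is the phosphorus.

The package also generates a labeled synthetic corpus and scores itself
against it:

```r
fx  <- generate_fixtures(seed = 1, n = 200)
out <- annotate_soms(fx)
som_match_table(score_soms(out, fx))
#> SOM annotation accuracy (by category)
#> # A tibble: 4 × 5
#>   group       n_reactions full_pct partial_pct neighbor_pct
#>   <chr>             <int>    <dbl>       <dbl>        <dbl>
#> 1 All                 200      100           0            0
#> 2 addition             69      100           0            0
#> 3 elimination          62      100           0            0
#> 4 complex              69      100           0            0
```

`full_pct` is the percentage of reactions whose predicted SOM set equals
the ground truth exactly, per handler category and overall. A perfect
score here certifies the engine's internal consistency on the 18
transformation families the generator covers; see the vignette
(`vignettes/som-annotation.Rmd`) for what that does and does not imply
about curated experimental data.

A command-line wrapper is installed with the package
(`system.file("cli", "somannot", package = "somannot")`) with
`annotate`, `evaluate` and `fixtures` subcommands over the same functions.

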
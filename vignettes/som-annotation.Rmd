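---
title: "Rule-based annotation of sites of metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based annotation of sites of metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A site of metabolism (SOM) is the substrate atom at which an enzymatic
biotransformation is initiated -- not merely the atom whose connectivity
changes between substrate and metabolite. The two notions differ in ways
that matter for training SOM predictors: in ester hydrolysis, the atom that
changes connectivity is the sp3 oxygen, but the reaction is initiated at
the carbonyl carbon, and that is where an expert places the label.
Metabolic reaction records are almost always stoichiometrically unbalanced
(water, cofactors and leaving groups are omitted), which defeats
atom-mapping tools trained on balanced organic reactions. `somannot`
extracts chemically meaningful SOM labels from such unbalanced
substrate--metabolite pairs using molecular-graph comparison and a compact
set of biotransformation rules, without prior knowledge of the reaction
type.

## Pipeline overview

Input rows (`substrate_smiles`, `substrate_id`, `metabolite_smiles`,
`metabolite_id`) are first validated and standardized. Standardization
delegates to RDKit through a bundled Python helper: largest-organic-parent
extraction, normalization, neutralization (with charge-separated
`[S+][O-]`/`[P+][O-]` collapsed back to the neutral hypervalent form so
formal charges compare consistently), and canonical tautomer selection,
followed by InChI-key computation. A pair is rejected -- as data, never as
an error -- when either side fails to parse or to yield a key, when the two
keys coincide (no net transformation), or when an element outside
H, C, N, O, S, P, F, Cl, Br, I, B, Si, Se is present. Standardized atoms
are renumbered into canonical-SMILES output order, so the 0-based atom
indices in every output are reproducible from the emitted SMILES alone.

Accepted pairs are routed on the heavy-atom balance:

* metabolite heavier -> **addition handler**: a glutathione screen first
  (conjugation saturates the attacked double bond, breaking
  bond-order-sensitive containment, so it needs its own treatment:
  the tripeptide is located in the metabolite, removed, and the remaining
  fragment embedded back into the substrate; the SOM is the substrate atom
  corresponding to the atom bonded to the cysteine sulfur). Otherwise the
  substrate is embedded into the metabolite with bond-order-sensitive
  matching, and every substrate atom whose image acquires a new neighbour
  is a SOM. A carnitine-ester correction then moves the SOM from the sp3
  oxygen to the carboxyl carbon, since in carnitine conjugation the
  cofactor hydroxyl is the nucleophile.
* metabolite lighter -> **elimination handler**: the metabolite is
  embedded into the substrate; each boundary bond between a mapped and an
  unmapped atom yields one SOM -- the unmapped atom when it is a carbon
  (type 1; dealkylations carry the label on the removed alpha-carbon),
  else the mapped neighbour (type 2; reductive dehalogenation, heteroatom
  reductions). Corrections reassign (thio)ester cleavages to the carbonyl
  carbon and inorganic-acid-ester cleavages (phosphates, thiophosphates,
  sulfates, sulfonates, sulfamates, sulfonamides) to the P/S center.
* equal counts, or a handler that found nothing -> **complex handler**:
  oxidative dehalogenation first (carbon count retained, halogen lost,
  oxygen gained; SOM on the formerly halogenated carbon, or both oxirane
  carbons for the epoxide-forming variant), then a complete atom mapping by
  subgraph isomorphism with bond orders ignored (SOMs where hydrogen count
  or formal charge changed; dehydrogenations), then an element-only MCS
  mapping with SOMs at topological changes. Ring-hydrolysis corrections
  reassign oxacyclopropane openings (both ring carbons), lactone openings
  (carbonyl carbon) and other heterocyclic ring openings (carbon side of
  the cleaved C--heteroatom bond, preferring an acyl carbon, which makes
  lactams behave like lactones).

Any SOM set found is expanded to full topological-equivalence orbits as a
post-processing step, immediately before output: MCS-based mapping cannot
distinguish symmetry-equivalent atoms, so all of them are annotated.
If every handler declines, the reaction is returned with an empty SOM list
and the `unknown` status.

## Matching machinery and numerical choices

Two matching regimes are used. *Bond-order-sensitive* matching requires
element and formal-charge agreement on atoms and kekule-order agreement on
bonds, with aromatic bonds treated as their own bond class -- comparing
kekule orders across an aromatic system would make benzene fail to embed
into phenol. *Relaxed* matching requires element agreement only. Subgraph
embedding is a monomorphism (extra metabolite bonds are permitted)
computed with VF2 on colored graphs via igraph. The MCS search is a
branch-and-bound backtracking enumeration of maximum connected common
substructures under the constraint that every mapped substrate bond is
present between the image atoms; when one molecule embeds completely into
the other, the embeddings themselves are the MCS and the search is skipped.

Determinism is obtained by explicit tie-breaks: among co-optimal embeddings
or MCS mappings, the one minimizing the downstream SOM count wins, then the
lexicographically smallest sorted SOM index set. Orbits are the vertex
classes of the automorphism group of the heavy-atom graph with atoms
colored by element, charge, hydrogen count and aromaticity and bonds by
order (aromatic bonds again their own class); since the underlying
canonical-labelling engine colors vertices only, the automorphism search
runs on an edge-subdivided auxiliary graph. Orbit expansion is idempotent
and monotone by construction.

Two refinements of the "topological change" notion in the MCS-diff rule
are deliberate design choices. First, bond-order changes on bonds that are
aromatic on either side are ignored: an aromatic ring that becomes a
kekulized diene (phenol to 1,2-benzoquinone) would otherwise flag every
ring atom. Second, heteroatoms are flagged only when their neighbour set
changes, never for hydrogen-count or bond-order changes alone: this keeps
spectator hydroxyls and, e.g., the quinone oxygens unlabeled, and puts the
label on the carbon skeleton where the chemistry is initiated. With both
refinements, phenol to 1,2-benzoquinone yields exactly the two
oxygen-bearing ring carbons.

Equal heavy-atom counts route directly to the complex handler: the two
routing branches are defined by strict inequalities. The per-reaction
timeout (default 20 s, configurable through `som_config()`) is enforced by
cooperative deadline checks inside the matching loops; an expired reaction
is returned with the `timeout` status and an empty SOM set, and is
guaranteed to stop within the limit plus a one-second grace. Elapsed time
excludes standardization.

## Evaluation metrics

Predictions are scored per reaction as **full** (predicted set equals the
truth set), **partial** (the sets overlap but differ), **neighbor** (no
true SOM predicted, but a true SOM is directly bonded to a predicted atom;
checked only when the intersection is empty) or **none** (everything else;
an empty prediction can only be none). Both sets are orbit-expanded with
the same machinery before comparison, so equivalent-atom annotations from
different sources compare equal; this may shift absolute percentages
relative to scoring on raw index sets. Aggregation reports, per rule
category and over all scored reactions, the reaction count and the three
percentages, each computed over that row's count.

## The fixture generator

`generate_fixtures()` emulates a curated single-step metabolic reaction
collection: 70 substrate/metabolite templates spanning 18 transformation
families (aromatic and aliphatic hydroxylation, O- and acyl
glucuronidation, sulfation, glutathione conjugation on Michael acceptors,
aryl halides and epoxides, carnitine conjugation, N- and O-dealkylation,
(thio)ester hydrolysis, phosphate/thiophosphate/sulfate/sulfonamide
hydrolysis, reductive and oxidative dehalogenation including the
epoxide-forming variant, dehydrogenation and hydrogenation, epoxidation,
quinone formation, epoxide, lactone and heterocyclic ring hydrolysis) over
a panel of more than twenty drug-like scaffolds, including symmetric ones
(para-substituted aromatics, succinimide, tetrahydrofuran) that exercise
orbit expansion. The true SOMs are carried as atom-map anchors on the
template substrate and located on the standardized structure
programmatically, so ground truth is generated, never hand-indexed.
Sampling is a seeded round-robin over a shuffled pool order, so every
template family appears with near-uniform frequency and each rule label is
exercised at least five times at a corpus size of 200.

What the generator does *not* emulate: multistep reactions and records
combining several reactions in one pair, stereochemical inversions,
metabolically implausible-but-parseable curation errors, very large
substrates (the scaffold panel tops out around 25 heavy atoms), and the
long tail of rare biotransformations. Perfect recovery on the fixture
corpus therefore demonstrates the internal consistency of the rules,
routing, symmetry handling and bookkeeping -- not the accuracy achievable
on a curated experimental database, where reactions outside the rule
inventory, multistep records and annotation ambiguity lower the complex
category's accuracy well below the addition and elimination categories.

## Problem sizes

The test-suite and acceptance runs use a 200-reaction corpus
(seed-reproducible), brute-force oracle cross-checks (clique-based MCS,
permutation-based automorphism orbits) on all corpus pairs with at most 10
heavy atoms, and a full 12-step ablation curve; together they complete in a
few minutes on one CPU.

## Known limitations

* Single-step, single-reaction records only; a multireaction pair is
  annotated per boundary bond independently.
* No stereochemistry: stereo-only transformations standardize to distinct
  InChI keys but identical graphs and end as `unknown`.
* The glutathione screen assumes the tripeptide is intact in the
  metabolite; further processed conjugates (mercapturic acids) are not
  recognized.
* Which fragment survives for organic--organic salt pairs follows the
  largest-organic-fragment convention (ties by heavy-atom count, then
  lexicographic InChI key), which may differ from other pipelines.
* The SMILES-level CLI and CSV interfaces assume one molecule per field;
  multi-component SMILES are reduced to the parent fragment.
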
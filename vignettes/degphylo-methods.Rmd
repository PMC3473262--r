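---
title: "Phylogeny-anchored nomenclature for the Deg/HtrA protease family: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-anchored nomenclature: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degphylo)
```

## The problem

Deg/HtrA proteases are ATP-independent serine endopeptidases with a
trypsin-type catalytic domain (His-Asp-Ser triad) and, in most members, one
or more PDZ protein-interaction domains. Plant genomes encode 15-17 of
them, and genome annotation projects numbered them in order of discovery,
so the same name can denote unrelated enzymes in different species.
degphylo implements a phylogeny-anchored renaming procedure: validate
candidate family members, align their protease domains, infer a
bootstrapped maximum-likelihood (ML) tree, delimit ortholog groups as
supported clades around reference-species anchors, propose standardized
names, check that domain arrangements are concordant within groups, and
extract the core set of groups conserved in every species.

The package bundles the inventory of five photosynthetic model organisms
(*Arabidopsis thaliana* — the nomenclature reference —, *Populus
trichocarpa*, *Oryza sativa*, *Physcomitrella patens*, *Chlamydomonas
reinhardtii*, plus cyanobacterial outgroup entries) as plain-text catalogs,
and a gene-family simulator with known ground truth so that every stage is
testable without database downloads.

## Eligibility: who enters the tree

Proteolytically inactive family members evolve under altered selective
pressure and take misleading positions in trees, so entries lacking a
complete catalytic triad, or with an incomplete protease domain, are
excluded from phylogenetic analysis (they remain in the catalog and in the
conservation matrix). The filter works in order of precedence:

1. catalog non-family flags (`not_family`) — rejected outright;
2. declared activity annotations with machine-readable reasons
   (`TRUNCATED_PD`, `MISSING_TRIAD_RESIDUE`, ...);
3. declared domain architectures (no protease domain token at all rejects
   the record);
4. sequence-based detection with the bundled profile scanner.

The scanner is a deliberately simple stand-in for structure-library
homology detection: per-domain log-odds PSSMs built from small seed
alignments, scanned by a sliding window, with greedy resolution of
overlapping hits. Its false-positive rate on shuffled sequences is tested
to be at most 1% per profile at the default threshold (half of the maximal
window score). Catalytic-triad residues are accepted within +/- 3 residues
of their anchored positions (`triad_window`); a protease-domain match
covering less than 60% of the profile (`truncation_frac`) counts as
truncated. Both knobs sit in `validation_config()`. A protease-domain hit
whose triad is incomplete is annotated `PD_ia` (degenerated protease
domain), mirroring the convention used for the family's pseudo-protease
domains.

## Alignment and the consensus surrogate

The original analysis aligned protease domains with three external
aligners and merged the runs into a manually curated consensus. degphylo
keeps the consensus design but automates it: its own progressive aligner
(guide tree from pairwise alignment distances, profile-profile merges under
affine gap costs, C++ dynamic-programming core) is run under two or more
scoring parameterisations (default: BLOSUM62 with gap open/extend 10/1 and
5/2), and `consensus_merge()` retains exactly the columns whose induced
residue-residue homology is identical in every run. This strict
all-run-agreement rule is the conservative automation of manual curation;
it is configurable in principle by supplying more or fewer runs. Columns
containing any gap are then removed (`strip_gap_columns()`, threshold 0 by
default, as gapped positions were removed outright in the original
protocol). Long single-residue repeats (>= 10 aa, a known annotation
artefact in the green-alga genome) are masked to X beforehand; X is
neutral in alignment scores and marginalised in all downstream likelihoods
and distances.

## Tree inference

Standard inference steps delegate to the established engines (ape,
phangorn) behind this package's interfaces; the package contributes the
protocol and its parameterisation:

* **Distances** — pairwise deletion over unambiguous residue pairs,
  Poisson-corrected (d = −ln(1−p), clamped at 10 with a saturation flag).
* **Starting tree** — neighbour joining, with ids sorted for deterministic
  tie-breaks and negative branches clamped to zero.
* **ML** — Felsenstein pruning under the WAG exchangeabilities and
  frequencies (the era-appropriate default for protein ML; embedded as
  published constants and cross-checked against phangorn's copy in a
  test), single rate class, gaps/X marginalised. Branch lengths are
  optimised iteratively (convergence 1e-6, at most 20 sweeps, bounds
  [1e-8, 50]) and the topology is refined by NNI hill-climbing.
* **Supports** — nonparametric bootstrap: columns resampled with
  replacement, a full ML tree inferred per replicate (replicate r uses
  seed `seed + r`), and each internal edge of the point tree supported by
  the percentage of replicates containing the same bipartition. 100
  replicates by default.
* **Cross-checks** — the pipeline also builds the NJ tree and computes
  Fitch parsimony scores for both topologies, logging Robinson-Foulds
  distances, mirroring the original confirmation of the overall topology
  by parsimony and distance methods.

All support comparisons are strict (`> 90`, `> 70`), following the
convention that filled/empty circles mark supports *exceeding* 90% and
70%. A clade whose complement is a single leaf is a trivial bipartition,
present in every replicate by construction, and is treated as fully
supported when unlabelled — without this, an ingroup crown facing a
single-member outgroup could never anchor assignment.

## Rooting and the naming engine

The tree is rooted on the outgroup (cyanobacterial homologs in the bundled
study; chloroplasts are of cyanobacterial origin). A monophyletic outgroup
roots on its stem edge with the length split evenly; otherwise the root
goes on the edge separating outgroup from ingroup leaves as cleanly as
possible (exhaustive edge scan, with a warning). Supports are transferred
across re-rooting by bipartition identity, never by node index.

Ortholog groups are then delimited by a codification of expert tree
reading:

* every reference-species leaf is an **anchor** carrying its established
  name (e.g. Deg1..Deg16);
* every other leaf joins the anchor group of the *smallest supported
  clade* (support > `assignment_threshold`, default 70 — the weak-support
  mark) containing the leaf and at least one anchor;
* if that clade mixes several anchor names, no single group can be chosen:
  the leaf is **group-like**, attached to the name of its patristically
  nearest anchor in the clade (lexicographic tie-break). This reproduces
  the published "Deg1-group-like" treatment of an unplaceable moss
  protein; once anchor names mix there is no smaller single-name clade to
  descend into, so nearest-anchor attachment is the deterministic choice;
* leaves in no anchored supported clade form numbered **like** groups
  (leaves sharing a maximal all-unanchored supported clade are grouped,
  numbered in tip order) — the treatment behind names such as
  "OsDeg-like 1";
* records flagged as probable non-members, and leaves that cluster with no
  other family member at the threshold, are excluded before naming
  (`exclude_distant_relatives()`), mirroring the removal of four distant
  relatives from the published final tree; the pipeline then re-infers the
  tree on the retained set.

Names are species prefix + group name; multiple same-species members of a
group receive `.1`..`.m` suffixes ordered by ascending patristic distance
to the nearest anchor (lexicographic id tie-break — the published tables do
not state a suffix rule, so a deterministic one was fixed). Reference
species names are never changed. Raising the assignment threshold can only
demote leaves (anchored → group-like/like), never promote them; this
monotonicity is property-tested.

Domain-arrangement concordance is a report, not a filter: per group the
majority architecture and any discordant members (e.g. a
beta-glycanhydrolase fusion) are listed. Roman clade labels (I A, I B, II,
III, IV) are reporting annotations matched from configured group sets.

## Conservation matrix and core set

`build_conservation_matrix()` counts members per ortholog group and
non-outgroup species (like and group-like rows included);
`compute_core_set()` returns the groups present in every species with
their minimum copy numbers, and `duplication_report()` the per-species
multi-copy groups. On the bundled inventory this yields the eight-member
core set (Deg1, Deg2, Deg5, Deg7, Deg8, Deg9, Deg10, Deg15), all at
minimum copy number one.

## The simulator and what it does (not) emulate

`simulate_family()` generates families with known truth: a coalescent
species tree scaled to a configured root-to-tip height, a birth-death gene
tree along it (duplications bifurcate within a species lineage, losses
prune; the surviving copies at each speciation enter both descendants),
sequences evolved site-independently under the same WAG model used for
inference, architecture labels inherited along lineages with a small
switch probability at duplications (0.02), and proteolytic inactivation by
substituting one triad anchor residue in a conserved protease-domain
cassette prepended to every gene (the cassette models the strongly
conserved catalytic core and makes inactivation detectable by the profile
scanner rather than by declared flags).

Default study conditions: 5 ingroup species, duplication rate 0.3 and loss
rate 0.1 per unit branch length, 300 evolved columns. Values the study
conditions leave open were fixed once: species-tree height 0.6 expected
substitutions/site (moderate plant-scale divergence), inactivation
fraction 0.15 (2-3 inactive members among 15-17 is what real inventories
show), an architecture palette spanning the family's five clade
arrangements, and a single event-free outgroup lineage attached 0.5 units
above the ingroup crown. Outgroup genes are exempt from inactivation: they
model curated, known-active reference proteins and must stay eligible so
the tree can be rooted. The family starts from one ancestral gene, so with
no duplications and no losses the whole pipeline must recover exactly one
ortholog group containing one gene per species — an end-to-end invariant
in the test suite.

What the simulator does *not* emulate: insertions/deletions (alignment
correctness is deliberately decoupled from inference tests; real protease
domains do differ in length), rate heterogeneity across sites, genome
context (tandem arrays, synteny), and annotation errors other than
low-complexity repeats. Passing the simulation tests therefore shows the
pipeline recovers groups under its own generative assumptions, not that it
is robust to every artefact of real genome databases.

## Calibration and problem sizes

The group-recovery experiment (`recovery_experiment()`) runs the complete
pipeline — detection-based validation, two-parameterisation consensus
alignment, ML with a 100-replicate bootstrap, rooting, naming — over 20
independently seeded families under the default conditions and pools the
fraction of genes assigned to a group anchored in their true lineage.
Replicates whose family goes extinct or retains fewer than three eligible
sequences cannot support a tree and are excluded as degenerate (this is
the documented protocol, decided before calibration). The first
calibration run measured a pooled recovery rate of 1.0; the regression
bound asserted by the test suite is frozen at 0.95. The experiment
completes in roughly two minutes on one CPU at these sizes, which are the
sizes used throughout the tests (oracle checks run at 4-8 taxa and 1-3
columns, where exhaustive enumeration is exact).

## Numerical choices

* Rate matrices are normalised to one expected substitution per site per
  unit branch length; transition probabilities come from the
  eigendecomposition of the symmetrised reversible generator (exact for
  reversible Q), with tiny negative round-off clipped at zero.
* Likelihood oracles in the tests use `Matrix::expm` (Padé
  scaling-and-squaring), an independent route that agrees with the
  eigendecomposition to ~1e-15; brute-force state enumeration then checks
  the pruning likelihood to 1e-9.
* Alignment tie-breaks prefer substitution over a gap in the second
  sequence over a gap in the first, both in state choice and traceback,
  making all alignments deterministic.
* Every stochastic operation takes an explicit seed; bootstrap replicate r
  derives its stream from `seed + r`, so partial re-runs are reproducible.
* Degenerate inputs are handled, not hidden: saturated distances clamp at
  10 with a flag; two-leaf trees optimise their single path length
  directly; NNI on data too weak to sustain internal edges falls back to
  branch-length optimisation with a warning; an extinct simulated family
  returns an empty truth table with a warning and the caller decides.

## Known limitations

* The published headline tree is not bit-reproducible: the original
  PhyML-era options and the manually curated alignment are unstated, so
  tree-dependent behaviour is verified at the property level (oracle
  equivalence, simulate-and-recover, bootstrap saturation) rather than by
  tree identity. The bundled catalogs carry the published group
  assignments, so catalog-only mode reproduces the table-derived
  quantities exactly.
* Single rate class by default; no among-site rate variation.
* The profile scanner is a declared simplification: it detects the
  bundled family profiles well and calibrates its false-positive rate,
  but it is not a remote-homology method; external annotations can be
  supplied per record and always take precedence.
* With a single-member outgroup the ingroup crown is always a supported
  clade, so "like" status can only arise under a multi-member outgroup or
  a weakly supported crown — matching how unanchored groups arose in the
  published analysis (three cyanobacterial outgroup sequences).

## Interfaces

All stages are exported functions over plain-text formats (TSV catalogs
and registries, FASTA, relaxed PHYLIP, Newick with supports as internal
node labels); `run_pipeline()` orchestrates them from a
`pipeline_config()` or a YAML file (`read_pipeline_config()`), writes
every artifact plus an md5 manifest, and is byte-reproducible given config
and seeds. A catalog-only mode runs the nomenclature/core-set stages from
declared annotations and an optional provided tree.
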
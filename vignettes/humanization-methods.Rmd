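---
title: "Antibody humanization in silico: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antibody humanization in silico: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvhumanize)
library(dplyr)
```

# The problem

Murine monoclonal antibodies are immunogenic in humans; humanization replaces
as much murine sequence as possible while preserving antigen binding. Two
complementary strategies dominate practice, and `fvhumanize` implements the
computational side of both for an Fv (VH + V-kappa) pair:

* **CDR grafting** — transplant the six murine complementarity-determining
  regions (CDRs) onto human germline frameworks (FRs), choosing for each of
  the four framework slots the most homologous human germline segment, then
  restore ("back-mutate") a small set of framework residues whose side chains
  are structurally required to hold the CDR loops and the VH/VL packing in
  place.
* **FR shuffling** — keep the six murine CDRs fixed and combinatorially pair
  them with pools of human germline framework segments, producing a library
  whose diversity is the product of the eight slot sizes; selected clones are
  then *decomposed* back to their per-slot germline origins for reporting.

Everything runs offline on tabular, seeded synthetic fixtures, so every stage
of the pipeline is testable without external databases or structure
predictors.

# Numbering and segmentation

All sequence work is anchored on a numbering scheme (IMGT by default, Kabat
available behind the same interface). Numbering is **alignment-to-template**:
the query is globally aligned to a bundled gapless consensus template and
inherits the template's positions; query residues falling into template gaps
receive insertion codes at the last matched position. This is reproducible
and entirely data-driven — the templates and the CDR boundary table
(`inst/extdata/cdr_boundaries.tsv`) are editable files, and segmentation
boundaries follow whatever table is supplied. The historical insertion rules
of the legacy schemes are deliberately not reproduced: no downstream
operation needs them, and positional transfer from a fixed template is
sufficient for segmentation and for labeling back-mutation sites. Because
site labels such as "K19" are meaningless without knowing the scheme, every
`back_mutation_spec` carries a mandatory scheme tag; the convention is that
`installed` is the murine (parent) residue being restored.

Two different alignment parameterizations are used on purpose:

* *numbering* uses stiff gap penalties (open 25, extend 2, BLOSUM62), so
  gaps are admitted only where an indel is genuinely required — an
  equal-length query aligns gaplessly and region boundaries transfer exactly;
* *homology scoring* (germline selection, top-k identity) uses conventional
  affine penalties (open 10, extend 1, BLOSUM62), with identity counted on
  exact matches: matches over the parent-FR length for germline selection,
  matches over the alignment length (gaps penalizing) for repertoire
  identity.

Lambda light chains are out of scope and rejected explicitly; the kappa
template covers the light chains handled here.

# CDR grafting and back mutation

`select_germline_per_fr()` scans the pool per chain and slot and keeps the
segment with the highest percent identity to the parent framework, breaking
ties by lexicographically smallest name so selection is deterministic and
order-independent. `graft()` then rebuilds the chain as
FR1·CDR1·FR2·CDR2·FR3·CDR3·FR4 with CDRs byte-identical to the parent and
frameworks byte-identical to the chosen germlines. Designs assembled from
regions get scheme positions directly from the boundary table (residues
overflowing a region's interval get insertion codes at its end); this
coincides with alignment numbering whenever region lengths match the
template, which holds throughout the synthetic study conditions.

`apply_back_mutations()` enforces back-mutation semantics strictly: the
installed residue must equal the parent residue at that scheme position, the
replaced residue must match the design (unless already applied — the
operation is idempotent), and CDR positions are refused because back
mutations are framework edits. Applying the full set of framework
differences therefore recovers the parent framework exactly, a property the
test suite exercises over hundreds of random cases.

How many back-mutation variants to build, and which sites to combine, is a
judgment call in practice; the package therefore takes user-supplied spec
lists and enumerates the full heavy × light Cartesian product
(`enumerate_designs()`), e.g. eight heavy and four light variants give a
32-antibody panel.

# Structure-guided candidate identification

When a (predicted) Fv structure is available, `classify_residues()` flags
three multi-label types of canonical structure-determining framework
residues:

| type | meaning | rule |
|------|---------|------|
| 1 | VH/VL interface packing | any inter-chain heavy-atom pair ≤ `d_interface` (4.5 Å) |
| 2 | buried, CDR-proximal | min distance to any CDR atom ≤ `d_near` (6.0 Å) **and** relative SASA ≤ `r_buried` (0.20) |
| 3 | direct CDR interaction | ≥ 1 detected interaction whose partner is a CDR residue |

The conjunctive reading of Type 2 (proximity **and** burial) is a design
choice; both conditions are reported separately so users can audit it. The
thresholds are conventional interface/burial values, surfaced as
configuration parameters — the package's tests pin behavior, not biology.
Every flag ships with its evidence (minimum distances, relative SASA, the
interaction records behind Type 3), replacing eyeballing of a 3D viewer with
an auditable table. `propose_back_mutations()` intersects the flagged set
with the positions where the graft differs from the parent.

Relative accessibility uses an own Shrake–Rupley implementation (960
deterministic golden-spiral sample points per atom, 1.4 Å probe, Tien et al.
2013 Gly-X-Gly maxima, values clipped to [0, 1]); it is validated against
the closed-form two-sphere overlap area to within 2%.

# The four-class interaction analysis

Interactions are defined purely by distance, faithfully to the rules they
implement:

* hydrogen bonds: any N–O atom pair ≤ 3.5 Å;
* hydrophobic contacts: non-alpha side-chain carbons of LEU/ILE/VAL/PHE/TRP/MET ≤ 5.0 Å;
* salt bridges: basic side-chain N (ARG NE/NH1/NH2, LYS NZ, HIS ND1/NE2 —
  histidine counted as positive, no protonation modeling) vs acidic
  side-chain O (ASP OD1/OD2, GLU OE1/OE2) ≤ 4.0 Å;
* π–π stacking: aromatic ring centroids (PHE/TYR/HIS, both TRP rings) ≤ 6.5 Å,
  distance only, no ring-plane angle.

Distance comparisons use ≤; one record is kept per residue pair per class,
retaining the minimal realizing atom (or ring) pair. Two artifact
suppressions are applied to the hydrogen-bond rule and are configurable:
pairs within one residue never count, and the backbone N–O pair of
sequence-adjacent residues is excluded because the peptide bond places them
within threshold covalently. `compare_models()` keys interactions by
(class, residue pair) and reports shared/unique sets and pairwise Jaccard
similarities across structure predictors; both intra- and inter-chain
contacts are computed, and chain scope can be filtered downstream since
records carry chain ids.

# Framework shuffling

`sample_library()` draws framework choices uniformly and independently per
slot (heavy and light chains shuffle independently — the library poses no
pairing constraint, an assumption recorded here). Sampling is
seed-deterministic; without replacement the combination space is sampled
directly (mixed-radix decoding below a million combinations, rejection
sampling above). `decompose_origin()` segments a variant and reports, per
slot, the pool segment with minimal mismatch count; slots whose best match
exceeds `max_mismatch` (default 3 — the reporting convention for "not
applicable", chosen here since no published rule exists) report `NA`, and
exact ties are all reported. Wet-lab selection (panning, capture lift,
ELISA) is out of scope; nothing in the package claims to emulate enrichment.

# Humanness and epitope counting

`ninemer_content()` scores the fraction of a sequence's overlapping 9-mers
whose prevalence in a reference repertoire reaches `min_prevalence`;
`topk_identity()` averages global-alignment percent identity over the k most
similar references (k capped at the repertoire size). These implement the
*logic* of repertoire-based humanness scores; they are **not** reimplementations
of any database-backed tool — scores depend entirely on the supplied
repertoire, which is why every report carries the repertoire's source label
and scores must never be compared across repertoires. The prevalence
threshold is a documented approximation of subject-level prevalence.
`count_strong_binders()` aggregates an externally produced MHC class II
prediction table, counting rows at ≤ 1% percentile rank per allele by
default, with a totals row; the binding predictor itself is out of scope.

# Synthetic study conditions

The `gen_*` generators are pure functions of (parameters, seed) and define
the conditions under which the pipeline is validated:

* `gen_germline_pool()` — default 4 segments per slot at expected pairwise
  identity 0.85, derived from the scheme template's framework segments
  (substitution probability `1 - sqrt(identity)` per position, segments kept
  pairwise distinct within a slot);
* `gen_parent_fv()` — one true germline per slot plus framework substitutions
  at rate 0.05 by default (a realistic somatic load) and random CDRs at
  template lengths, with a truth table of origins and mutated positions;
* `gen_toy_structure()` — each interaction request realized on an isolated
  two-residue island 30 Å from its neighbors. Cross-class purity is part of
  the generator contract: a salt bridge requested at ≤ 3.5 Å would
  unavoidably also register as an N–O hydrogen bond and is rejected as
  unsatisfiable, and π islands use tyrosine rings (aromatic, yet not in the
  hydrophobic six) stacked coaxially so ring carbons stay outside the 5.0 Å
  hydrophobic cutoff;
* `gen_fv_mock_structure()` — a coarse pseudo-atomic two-chain layout with
  one planted positive control per canonical type (an interface pair at
  2.5 Å, an alanine buried inside a 4.2 Å cage of CDR2 atoms, a framework
  residue hydrogen-bonded to a CDR residue at 3.2 Å) and negative controls
  everywhere else.

What passing on these fixtures shows — and what it does not: the geometry
exercises every threshold and rule exactly, but toy structures are not
stereochemically realistic, pool segments are not real germline genes, and
the synthetic repertoire is not a natural antibody space. Green tests
certify the algorithms and their contracts, not biological performance on
real antibodies.

# Problem sizes and numerics

The bundled validation uses pools of 2–4 segments per slot, parents of one
Fv pair, toy structures under 500 atoms, 100-seed recovery experiments and
1000+ round-trip cases; these sizes make the whole suite reproducible on a
single CPU in minutes while still exercising each code path many times.
Numerical choices: distances in Å with ≤ comparisons; SASA at 960 sphere
points (two-sphere agreement within 2%); interaction records canonicalized
(A before B by chain, then residue number) so sets compare exactly;
identity ties broken lexicographically; all randomness flows through
explicit seeds (`withr::with_seed`), and the default generator seed is
20240715.

# Worked example

```{r example}
pool <- gen_germline_pool(n_per_slot = 3, base_identity = 0.85, seed = 42)
parent <- gen_parent_fv(pool, fr_mutation_rate = 0.08, seed = 43)

wf <- run_graft_workflow(parent$heavy, parent$light, pool)
wf$selection |> select(chain_type, slot, germline, identity)

sh <- run_shuffle_workflow(parent$cdrs, pool, n = 3, seed = 44)
sh$decomposition
sh$diversity
```

# Known limitations

* Numbering is positional transfer from a consensus template, not legacy
  scheme logic; heavily divergent chains may number differently from
  curated tools, though segmentation always round-trips.
* Hydrogen bonds have no donor/acceptor chemistry or angle term, salt
  bridges no protonation state, π–π no ring-plane angle — by design, the
  rules are distance-only.
* Humanness scores are repertoire-relative; absolute values from external
  tools are not reproduced.
* Structure prediction, molecular dynamics, and all wet-lab selection steps
  are outside the package's scope.
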
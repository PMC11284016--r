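# fvhumanize

In-silico antibody humanization for variable-domain (Fv) engineers: CDR
grafting with structure-guided back mutation, and framework (FR) shuffling
with combinatorial library decomposition, plus the supporting analyses —
residue interaction detection, canonical residue classification, humanness
scoring and MHC class II strong-binder counting. Every stage runs offline on
seeded synthetic fixtures, so the whole pipeline is testable without any
download.

## What it computes

For a murine Fv (heavy + kappa chain), two humanization routes:

**CDR grafting.** Chains are numbered by global alignment to a scheme
template (IMGT default, Kabat available) and segmented into
FR1–CDR1–FR2–CDR2–FR3–CDR3–FR4. For each framework slot the most homologous
human germline segment is selected,

```
identity(slot) = 100 · matches / |parent FR|   (global alignment, BLOSUM62)
```

the murine CDRs are grafted onto the winners, and framework positions whose
murine side chains are structurally load-bearing are restored by back
mutation. Candidates come from a three-type classification on an Fv
structure: Type 1 (VH/VL interface: inter-chain atom pair ≤ 4.5 Å), Type 2
(CDR-proximal ≤ 6.0 Å **and** buried, relative SASA ≤ 0.20 by Shrake–Rupley),
Type 3 (direct CDR interaction via any of four distance-defined classes:
N–O hydrogen bonds ≤ 3.5 Å; side-chain carbon hydrophobic contacts ≤ 5.0 Å;
basic-N/acidic-O salt bridges ≤ 4.0 Å; aromatic ring-centroid π–π ≤ 6.5 Å).
Heavy × light variant panels are enumerated exhaustively (8 × 4 → 32
antibodies).

**FR shuffling.** The six murine CDRs are held fixed and fused with germline
framework segments drawn per slot from a pool; the library's gene diversity
is the product of the eight slot sizes. Sampled variants are decomposed back
to their per-slot germline origins by minimal mismatch count, with
`NA` reported where no pool segment comes within the mismatch ceiling.

Humanness is scored against a user-supplied reference repertoire (9-mer
content at a prevalence threshold; mean identity to the top-k references),
and externally produced MHC class II prediction tables are aggregated into
per-allele strong-binder counts (rank ≤ 1% by default).

## Worked example

```r
library(fvhumanize)
library(dplyr)

pool   <- gen_germline_pool(n_per_slot = 3, base_identity = 0.85, seed = 42)
parent <- gen_parent_fv(pool, fr_mutation_rate = 0.08, seed = 43)

wf <- run_graft_workflow(parent$heavy, parent$light, pool)
wf$selection |> select(chain_type, slot, germline, identity)
#>   chain_type slot  germline identity
#> 1 heavy      FR1   SGHV1-1      92.3
#> 2 heavy      FR2   SGHV2-2     100
#> 3 heavy      FR3   SGHV3-3      94.9
#> 4 heavy      FR4   SJH1        100
#> 5 kappa      FR1   SGKV1-2      84.6
#> 6 kappa      FR2   SGKV2-2     100
#> 7 kappa      FR3   SGKV3-1      94.9
#> 8 kappa      FR4   SJK2         90
```

Per slot, the winning germline and its percent identity to the parent
framework — the shape of a grafting design report. The graft itself keeps
CDRs byte-identical to the parent and frameworks byte-identical to the
winners.

```r
sh <- run_shuffle_workflow(parent$cdrs, pool, n = 3, seed = 44)
sh$decomposition
#>   variant VH_FR1  VH_FR2  VH_FR3  VH_FR4 VL_FR1  VL_FR2  VL_FR3  VL_FR4
#> 1 V0001   SGHV1-1 SGHV2-1 SGHV3-1 SJH3   SGKV1-2 SGKV2-1 SGKV3-1 SJK3
#> 2 V0002   SGHV1-3 SGHV2-2 SGHV3-1 SJH2   SGKV1-2 SGKV2-1 SGKV3-1 SJK2
#> 3 V0003   SGHV1-3 SGHV2-1 SGHV3-1 SJH3   SGKV1-2 SGKV2-1 SGKV3-2 SJK3
sh$diversity
#> [1] 6561
```

Three sampled library variants, each decomposed back to its true per-slot
germline origins with zero mismatches, and the library's combinatorial
diversity (3^8 here).

```r
idx <- repertoire_index(gen_repertoire(30, seed = 45), label = "synthetic-45")
humanness_report(design_sequence(wf$heavy_variants[[1]]),
                 design_sequence(wf$light_variants[[1]]), idx)
#>   chain ninemer_content topk_identity  k min_prevalence repertoire
#> 1 heavy           0.225          55.6 20           0.01 synthetic-45
#> 2 light           0.244          54.9 20           0.01 synthetic-45
```

22–24% of 9-mer windows are common in this small synthetic repertoire and
the grafted chains average ~55% identity to their 20 nearest references;
scores are only meaningful relative to the labeled repertoire.

See `vignettes/humanization-methods.Rmd` for the model, thresholds, design
choices and limitations.

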
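---
title: "Enumerating the theoretical glycerolipid space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating the theoretical glycerolipid space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidenum)
```

## Why a theoretical lipid space

High-throughput lipidomics identifies lipids at very different structural
resolutions depending on the experiment. A single MS1 precursor mass fixes
only the lipid class and the *totals* of chain carbons and double bonds; an
MS2 fragment scan can resolve the individual fatty chains but usually not
their *sn* positions; only specialist workflows resolve double-bond
positions. Reporting a more resolved structure than the experiment supports
is a common error that curated databases built from observed structures
cannot help with, because they only contain fully resolved molecules.

`lipidenum` takes the opposite approach: it *generates* every
glycerolipid and glycerophospholipid consistent with a small set of
chemical rules, and stores the records in a four-level identification
hierarchy that mirrors what each experiment type can claim:

* **Species** — class + chain totals, e.g. `PC 34:1` (one precursor mass);
* **Fatty Acid Scan Species (FAS)** — chain compositions known, *sn*
  positions unknown, e.g. `PC 16:0_18:1`;
* **Sub Species** — chains assigned to *sn* positions, e.g.
  `PC 18:1/16:0`;
* **Isomer** — double-bond positions resolved, e.g. `PC 18:1(9)/16:0`.

Double-bond *stereochemistry* (cis/trans) is deliberately above this
hierarchy's resolution and is never represented.

## The chain-generation rules

Chains are generated from bounds agreed by the lipidomics community for
this space, embedded as the defaults of `chain_rules()`:

| parameter | default | meaning |
|---|---|---|
| `min_carbons` / `max_carbons` | 2 / 30 | chain length range (carbons) |
| `allow_odd_carbons` | `TRUE` | odd chain lengths permitted |
| `min_double_bonds` | 0 | lower bound per chain |
| `max_double_bonds` | `Inf` | cap; default limited only by geometry |
| `first_db_position` | 2 | first double bond at bond 2 or later |
| `db_position_step` | 3 | spacing between consecutive double bonds |
| `allow_terminal_db` | `TRUE` | bond `carbons - 1` admissible |

Positions are Δ-numbered: the carboxyl (or ether linkage) carbon is C1 and
the bond between C~k~ and C~k+1~ is position *k*. The spacing rule encodes
the methylene-interrupted pattern that dominates natural fatty acids:
consecutive double-bond positions differ by a **positive multiple of 3**
(difference 3 = methylene-interrupted; 6, 9, … = one or more skipped
slots). This reading generates the common natural patterns — 9; 9,12;
9,12,15; 5,8,11,14 — as cases. A literal alternative reading ("the
difference itself is of the form 3n+2", i.e. 2, 5, 8, …) was considered
and rejected because it *excludes* exactly those natural patterns; the
step is a parameter, so other spacings remain expressible. Under the
defaults there are 174 chain types `(carbons, double_bonds)`, e.g. an 18:1
chain has 16 positional isomers (positions 2–17).

Alkyl (ether-linked) chains obey the same double-bond rules as acyl
chains; alkenyl/plasmalogen linkages and branched, hydroxylated or
otherwise modified chains are out of scope.

## Sub-classes and formula assembly

Sub-classes arise from a Cartesian cross of the main classes (PC, PE, PS,
PG, PI, PA over a glycerophosphate backbone; MG, DG, TG over glycerol)
with every linkage multiset of the allowed slot counts. Linkage-*position*
variants are collapsed: there is one
`monoalkyl,monoacylglycerophosphocholines` sub-class, not an sn1-alkyl and
an sn2-alkyl variant, because MS can often tell an ether lipid by mass but
not which position carries the ether chain. The default table has 39
sub-classes: 6 × (2 monoradyl + 3 diradyl) for the glycerophospholipids,
plus 2 + 3 + 4 for MG/DG/TG.

Molecular formulas are assembled by condensation arithmetic
(`compose_lipid_formula()`): glycerol (C3H8O3) + head-group building block
+ free-chain formulas − one water per condensation bond (one per chain,
plus one for the phosphodiester bond of a phospho head). An acyl chain of
*c* carbons and *d* double bonds contributes the free fatty acid
C~c~H~2c−2d~O~2~; an alkyl chain the fatty alcohol C~c~H~2c+2−2d~O. The
head-group formulas (phosphocholine C5H14NO4P, phosphoethanolamine
C2H8NO4P, phosphoserine C3H8NO6P, phosphoglycerol C3H9O6P, phosphoinositol
C6H13O9P, phosphoric acid H3PO4, and a bare hydroxyl for the
glycerolipids) are standard biochemistry; each entry is validated in the
test suite against an independently published reference lipid formula
(e.g. glycerol + phosphocholine + 16:0 + 18:1 − 3 H~2~O = C42H82NO8P,
whose monoisotopic mass 759.5778 Da rounds to the familiar 759.58 Da
precursor). Element masses are CODATA/IUPAC monoisotopic values stored as
data (`element_masses()`); neutral species are stored and charge enters
only through adduct arithmetic.

```{r}
sc <- find_subclass(build_subclasses(), "PC")
f <- compose_lipid_formula(sc, list(lipid_chain("acyl", 16, 0),
                                    lipid_chain("acyl", 18, 1)))
formula_string(f)
monoisotopic_mass(f)
```

## Nomenclature

The grammar (one ASCII space after the class code) is:

* Species: `PC 34:1`; ether species prefix the totals with `O-`, `dO-`,
  `tO-` by alkyl count (`PC O-35:1`);
* FAS: chains joined by `_`, alkyl chains first, then by (carbons, double
  bonds) ascending, each alkyl chain carrying its own `O-`;
* SubSpecies/Isomer: chains joined by `/` in *sn* order, one field per
  backbone position (2 for glycerophospholipids, 3 for glycerolipids),
  unoccupied trailing positions rendered `0:0`; Isomer names append
  `(p1,p2,...)` to every unsaturated chain.

Two design choices resolve ambiguities the collapsed sub-class model
would otherwise create. First, monoradyl (lyso) glycerophospholipid
sub-classes use the field's `L`-prefixed codes (`LPC 16:0`), because a
bare `PC 16:0` would be indistinguishable from the diacyl species with 16
total carbons. Second, since linkage-position variants are collapsed, the
alkyl chain of a mixed sub-class is canonically assigned *sn1*
(`PC O-16:0/18:1`), extending the convention that a non-acyl linkage is
drawn at *sn1*; mixed-linkage sub-species counts are therefore ordered
assignments with the alkyl slots leading. TG *sn1* and *sn3* are distinct
slots (ordered triples, no enantiomer collapsing) — the simplest reading
consistent with treating *sn* positions as distinguishable.

`parse_name()` inverts `format_name()`. Two degenerate cases format
identically to their parent: the single-chain FAS of a 1-slot sub-class
(identical to its species name) and the all-saturated isomer (identical
to its sub-species name). Parsing defaults to the less resolved reading
and accepts an explicit `level` argument; both levels are still
materialised so the four-level contract stays uniform.

## Counting without enumerating

Every enumerator has a combinatorial twin (`count_records()`): species
counts come from the k-fold sumset of chain types, FAS counts are products
of multiset coefficients, sub-species counts are `n_types^k`, and isomer
counts are `I^k` with `I` the total number of (chain type, position set)
pairs, itself from a closed-form count over gap compositions
(`count_db_position_sets()`). The twins agree with full enumeration at
every level — this is tested at reduced carbon bounds (4–10 carbons, where
full enumeration is feasible in seconds) — and make the default-bounds
space countable instantly: 174 chain types, 30,276 diacyl sub-species per
diradyl sub-class, 21,637 species and about 21.7 million sub-species over
the 39 default sub-classes.

The published database built from the same stated bounds reports 20,297
species and 36.15 million sub-species over its 39 sub-classes. Its exact
sub-class composition and enumeration conventions are described only in
supplementary material that is not recoverable here; neither our default
spacing reading (174 types) nor the literal alternative (239 types)
reproduces those totals under any small sub-class multiplicity, so the
package reports its own combinatorially verified totals and flags the
discrepancy in its acceptance test rather than adjusting generator
parameters to chase the printed numbers.

## MS1 search

`ms1_search()` annotates precursor mass lists (plain text, one mass per
line, `#` comments) against the species-level space — the only level a
single precursor mass can support. Each query is pre-processed with every
selected adduct (`[M+H]+`, `[M+Na]+`, `[M+NH4]+`, `[M+K]+`, `[M-H]-`,
`[M+Cl]-`, `[M+HCOO]-`, all singly charged, deltas computed from element
masses with electron correction, plus a `neutral` identity adduct), and
the implied neutral mass is matched within a symmetric tolerance in Da or
ppm (ppm relative to the theoretical mass). Whole categories, main
classes or sub-classes can be excluded to encode prior knowledge such as
class-specific extraction. Hits are grouped by query in input order and
sorted by absolute mass error with name tie-breaks, so repeated runs are
byte-identical. Widening the tolerance, adding adducts or removing
filters can only add hits — more search space means more isobaric
candidates, never fewer.

```{r}
hits <- ms1_search(759.58, tolerance = 0.05, adducts = "neutral")
head(as.data.frame(hits)[, c("species_name", "theoretical_mass", "delta_mda")])
```

## Numerical and testing choices

* Masses are exact sums of element masses; table output rounds to 4
  decimals, mass deltas to 3; comparisons in tests use absolute
  tolerances of 1e-4 Da or tighter.
* All orders are fixed (types by (carbons, double bonds), position sets
  lexicographic, sub-classes by configuration order/slot count/alkyl
  count, hits by error then name), so every command is deterministic.
* Degenerate inputs error early with located messages: malformed names
  report the offending position, subtraction of formulas below zero,
  empty adduct lists, non-positive tolerances and unknown config keys are
  all rejected rather than coerced.
* The test suite exercises full hierarchy enumerations at reduced carbon
  bounds (max 4–10 carbons; about 20,000 records end to end) against
  brute-force oracles: subset-filter enumeration of position sets,
  multiset/permutation counting, a linear-scan search oracle, and
  literature formulas for every head group. Reduced bounds exercise every
  code path (parity, ether prefixes, lyso rendering, multi-chain
  permutation, positional isomerism) — what they cannot show is
  agreement with any *observed* lipidome, since the space is theoretical
  by design.

## Limitations

* Only glycerolipids and glycerophospholipids; no sterols, sphingolipids,
  plasmalogens, branched or oxidised chains.
* No MS2/fragment evidence, isotope patterns, retention time or multiply
  charged ions; annotation from a single MS1 mass is inherently ambiguous
  and the engine reports *all* isobaric candidates rather than ranking
  beyond mass error.
* Species-level names and counts depend on the collapsed sub-class model;
  databases that keep linkage-position variants separate will count
  sub-classes and sub-species differently.
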
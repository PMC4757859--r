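---
title: "Modular Gibson assembly: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular Gibson assembly: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gibsim)
```

## The model

Gibson assembly fuses double-stranded DNA fragments that share terminal
homology: a 5'→3' exonuclease exposes single-stranded ends, complementary
overhangs anneal, and polymerase plus ligase seal the joint. `gibsim`
abstracts this to **exact terminal homology**: fragment B may follow
fragment A (either fragment optionally reverse-complemented) when a suffix
of A equals a prefix of B of at least `min_overlap` bases. We do not model
chew-back kinetics, ligation efficiency or enzyme chemistry; junctions in
this platform are *designed*, not noisy, so exact matching is the right
level of abstraction. The cost is that a terminus carrying even a few
extra bases does not join — see the spacer-release geometry below.

The platform's modularity comes from five fixed 30 bp overlap sites that
define six positional *slots*:

| slot | flanks | role |
|------|--------|----------|
| pA | sites 1–2 | promoter |
| gA | sites 2–3 | gene |
| pB | sites 3–4 | promoter |
| gB | sites 4–5 | gene |
| pC | sites 1–4 | promoter |
| gC | sites 2–5 | gene |

A *design* is a chain of slots whose sites tile a backbone's terminal
interval; `enumerate_fills()` enumerates these by path search over the six
grammar edges and is tested against an exhaustive edge-subset oracle for
every terminal pair.

**The pC slot spans sites 1 and 4.** Descriptions of this slot disagree
between a (1,3) and a (1,4) pairing; we adopt (1,4), produced with the
F1/R4 primer pair, because only (1,4) tiles against gB (4,5) to realize
the two-fragment `pC:gB` design that the platform's design table lists.

Sites #2, #3 and #4 carry NheI, AvrII and AfeI recognitions (each at
offset 11 of its 30-mer). No recognition of the screening panel occurs
inside the printed #1 and #5 sequences, so their `encoded_enzyme` is left
unset rather than guessed.

## Assembly search and canonical form

`assemble()` performs a depth-first search over fragment orderings and
orientations, starting from the backbone in forward orientation, and
accepts any cycle whose consecutive (and closing) overlaps reach
`min_overlap`. The search considers sub-pools, not only orderings that use
every fragment: this is what lets a pool containing two alternative gB
parts fail with an *ambiguity* error listing both products, rather than a
misleading "no product". Zero cycles raise an incomplete-assembly error
whose message names the unmatched termini, annotated with site numbers
when the dangling 30-mer is canonical — the bench-relevant "which part is
missing" diagnostic.

Products are circular only (the platform's backbones circularize; linear
assembly is out of scope). The reported sequence starts at the backbone's
first base with the backbone forward; identity between products is decided
on a canonical form (lexicographically smallest rotation of the smaller
strand), which makes assembly invariant under shuffling the input order
and reverse-complementing any subset of parts — a property the tests
exercise across seeds. A junction whose overlap also occurs elsewhere in
the product is reported as a misassembly warning, since stray homology is
the main failure mode the screening module exists to catch.

## Melting temperatures and primer growth

The platform specifies an annealing temperature (62 °C), not a Tm model.
We use unified nearest-neighbor thermodynamics: dimer enthalpies and
entropies summed with terminal initiation terms, entropy salt-corrected by
0.368·(N−1)·ln[Mon⁺], and

Tm = 1000·ΔH / (ΔS + R·ln(C_T/4)) − 273.15

with defaults of 50 mM monovalent salt and 500 nM total primer (primer in
excess over template, hence C_T/4). The Wallace rule 2(A+T)+4(G+C) is an
explicit fallback for oligos under ~14 nt. The implementation is verified
against an independently coded table-sum oracle to well below 0.1 °C.

Homology regions grow 3'-ward one base at a time from `homology_min`
(18 nt) until Tm ≥ 62 °C, clamped at `homology_max` (35 nt); growth is
deterministic, so no tie-breaking is needed. If the target is unreachable
within the clamp (very AT-rich templates), the pair is returned with a
below-target *warning* rather than an error — the bench remedy is a
touchdown protocol, not a redesign. PCR simulation requires each homology
to occur exactly once in the template, with zero mismatches; multiple
occurrences raise an ambiguity error with the 0-based positions.

## Digestion bookkeeping

Restriction sites are matched as IUPAC patterns on both strands
(palindromes reported once per duplex site); on circular substrates the
search window is extended across the origin. Cut positions are kept as
**top-strand coordinates only** and fragment lengths are distances between
successive cuts: screening needs sizes, not sticky-end identity. Fragment
lengths therefore always sum to the substrate length, an invariant the
suite property-tests on random substrates up to 5 kb against a
rotate-and-scan oracle.

Enzyme ranking for clone screening uses a gel-aware distance: the pooled
fragment sizes of the correct and alternative patterns are merged into
classes whenever neighbours differ by less than a fractional `tolerance`
(default 0.10, typical agarose discrimination), and the score is the
symmetric difference of class counts weighted by log10 length. A score of
0 means "this enzyme cannot tell the clones apart on a gel". The default
sequencing-primer panel is the five site 30-mers themselves (they anneal
to every junction); the usable read length defaults to 700 nt, a routine
Sanger figure, and is configurable since no authoritative value exists.

## Reaction math

Molar conversions use the anhydrous, salt-free dsDNA convention
(617.96 g/mol per bp + 36.04 g/mol); the protocol source gives only
concentrations, so the mass model is our choice and is exercised by a
round-trip consistency test (57 nM → pmol/µL → ng/µL → 57 nM to 1e-9
relative error). Colony counts use the strict inequality
1 − (1−p)ⁿ > confidence, matching the "greater than 99%" phrasing;
exact-boundary cases are incremented (p = 0.9 at 99% needs 3 colonies,
not 2). The per-fragment-count efficiency table ships *unset*: the
published per-count efficiencies are not part of the package's sources.
`example_efficiency_table()` provides an explicitly illustrative curve
(0.90/0.80/0.72/0.65 for 1–4 inserts) consistent with the standard
guidance of 3 colonies for two-insert and 5 for four-insert reactions; it
is labelled illustrative everywhere and is never used silently.

The Methods-style phrase "5 µL of inserts at 5.7×10⁻² pmol each" is
ambiguous between per-insert volumes and a pooled volume; `reaction_plan()`
interprets it as *each insert contributes 5.7×10⁻² pmol (1 µL at 57 nM)
and the pool is topped up to 5 µL with buffer*, warning when the inserts
alone exceed the pool volume.

## What the synthetic fixtures emulate

`generate_fixture_parts()` emulates a part collection: random cores
(default 200–1200 bp, GC 0.5 — the range of routine promoters and gene
bodies) rejection-sampled to exclude the five sites, their reverse
complements and all packaged recognitions, then flanked per slot. Real
inserts, of course, *do* contain screening-panel sites and occasionally
stray homology; passing tests on clean fixtures therefore demonstrate the
machinery's correctness, not that arbitrary real inserts are safe — that
is exactly what `validate_part()` warnings and the misassembly checks are
for on real input.

`generate_fixture_backbone()` emulates retrofit vectors: a circular
plasmid carrying (chain-start site)(spacer)(chain-end site) in a random
vector body, with spacer termini engineered so the declared enzymes cut
flush against the sites. Two straddle geometries arise naturally from the
printed site sequences: sites #1 and #2 end in ...GTTT and site #5 begins
AAAC..., so PmeI (GTTT^AAAC, blunt) cuts flush at those boundaries, and
site #1's terminal T lets BsrGI (T^GTACA) cut flush when the spacer begins
GTACA. The shipped architectures release 469 bp (sites 1–5, PmeI+BsrGI),
389 bp (sites 2–5, PmeI) and 361 bp (sites 1–4, PmeI+NheI).

One geometric impossibility is worth recording: NheI (G^CTAGC, 4 nt 5'
overhang) cannot cut flush against site #4's fixed start (GACCC...) under
top-strand bookkeeping — no placement of its recognition puts the
top-strand cut exactly on the boundary. The (1,4) fixture therefore
places the NheI recognition flush *inside* the spacer edge: the released
fragment still measures exactly the declared 361 bp, but the linearized
backbone retains a 5 nt CTAGC remnant, reported with a warning, and such
a backbone would not join in the exact-homology assembly model (in a real
tube, exonuclease chew-back removes short flaps, which is one of the
simplifications of the exact model). Assembly tests use the remnant-free
(1,5) and (2,5) architectures.

## Numerical and interface choices

* Sequences are uppercase ACGT; lowercase is accepted and upcased; U is
  rejected. Coordinates reported to users are 0-based, half-open; all
  primer strings are written 5'→3'.
* Slot labels are case-sensitive canonical strings; design enumeration is
  ordered fewest-fragments-first then lexicographically, so CLI output is
  deterministic.
* Internal occurrences of sites or panel recognitions in a core are
  warnings, never errors: real inserts may contain them legitimately.
* Fixture generation is fully deterministic under its seed (the backbone
  uses a fixed offset of the same seed so parts and backbone draw from
  distinct streams); rejection sampling fails loudly after 1e5 attempts.
* GenBank output uses `misc_feature` with `/label` and `/note` qualifiers
  only — the most portable subset across viewers; the reader handles that
  same dialect (LOCUS topology, simple spans, complement(), ORIGIN) and is
  not a general GenBank parser.
* Problem sizes in the test-suite fixtures (cores of 80–250 bp, 400–800 bp
  stuffers, substrates up to 5 kb, 200 round-trip templates, 20
  invariance seeds) were chosen to exercise every code path at desk scale;
  the algorithms themselves are size-independent and the acceptance script
  runs the generator's full-size defaults.

## Known limitations

* No thermodynamic simulation of assembly kinetics, no primer
  secondary-structure or cross-dimer scoring, no off-target search beyond
  the template itself, no star activity or methylation sensitivity.
* The assembly search is exhaustive over orderings and orientations and is
  intended for reaction-scale pools (the practical platform maximum of a
  backbone plus four inserts, up to ~12 fragments in
  `enumerate_products()`), not for genome-scale fragment sets.
* Efficiency-vs-fragment-count is user-supplied; the shipped example table
  is illustrative only.
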
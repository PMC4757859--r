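# gibsim

Design and simulation tools for **modular Gibson assembly cloning**.

Gibson (one-pot isothermal) assembly joins DNA fragments that share 30–40 bp
of terminal homology. Traditionally those homologies are fragment-specific,
so every new construct needs new primers. The platform modeled here instead
fixes **five common 30 bp "overlap sites" (#1–#5)** that designate positions
within any construct: a promoter or gene amplified once with the appropriate
site overhangs becomes a reusable *part*, and any compatible backbone plus a
tiling set of parts circularizes in a single reaction.

`gibsim` is aimed at molecular biologists planning such assemblies and at
developers of cloning automation. It implements, entirely in silico:

* **Part registry and slot grammar** — the five canonical sites; the six
  slots pA(1,2), gA(2,3), pB(3,4), gB(4,5), pC(1,4), gC(2,5); part
  validation, fragment classification, and exhaustive enumeration of the
  designs that fill a backbone (a (1,5) backbone admits exactly
  `pA:gA–pB:gB`, `pA:gC` and `pC:gB`).
* **Primer design and PCR simulation** — F/R overhang primers whose
  template homology is grown until its nearest-neighbor melting temperature
  (unified parameters; 50 mM monovalent salt, 500 nM primer; Wallace rule as
  a short-oligo fallback) reaches the 62 °C annealing regime; extension
  time at 1 min/kb; exact-homology PCR simulation.
* **Assembly simulation** — junction detection by exact terminal homology
  (default minimum 30 bp), circular product search over fragment orderings
  and orientations, with incomplete-assembly diagnostics that name the
  unmatched sites and ambiguity errors that enumerate competing products.
* **Digest screening** — IUPAC-aware restriction site search (circular
  substrates included, origin-spanning sites found), fragment-size
  prediction, ranking of screening enzymes by a gel-aware band-pattern
  distance, sequencing-primer annealing and junction read coverage.
* **Reaction math** — molar/mass conversions (dsDNA at 617.96 g/mol/bp),
  the 57 nM / 5.7×10⁻² pmol / 200 ng / 15 µL / 50 °C / 20 min reaction
  layout, buffer and master-mix batch recipes, and colony-screening
  statistics: the smallest *n* with 1 − (1−p)ⁿ strictly above the target
  confidence (3 colonies at p = 0.80, 5 at p = 0.65, for >99%).
* **Offline fixtures and CLI** — a seeded generator of synthetic part
  collections and backbone plasmids with releasable spacers (469/389/361 bp
  architectures), FASTA/GenBank I/O, and an `exec/gibsim` command-line
  front end.

## Worked example

```r
library(gibsim)

spec  <- fixture_spec(seed = 11)          # synthetic, fully offline
parts <- generate_fixture_parts(spec)     # 6 parts across pA..gC
bb    <- generate_fixture_backbone(spec)  # (1,5) backbone, 469 bp spacer

sel     <- parts[parts$slot %in% c("pA", "gA", "pB", "gB"), ]
product <- assemble(sel, bb$backbone)
product
#> <gibson_assembly> circular, 5612 bp, 5 fragments
#>   order: syn_backbone_1_5 -> syn_promoter_01_pA -> syn_gene_01_gA -> syn_promoter_02_pB -> syn_gene_02_gB
#>   junction sites: #1, #2, #3, #4, #5
```

The product is circular, every junction is one of the five canonical sites
in ascending order, and its length is the fragment total minus the five
30 bp overlaps (length conservation). The pipetting sheet for the same
reaction:

```r
reaction_plan(sel, bb$backbone, efficiency = example_efficiency_table())
#> <reaction plan> 4 insert(s) + backbone, incubate 50 degC / 20 min
#>   syn_promoter_01_pA          1.00 uL  (0.057 pmol, 36.0 ng)
#>   syn_promoter_02_pB          1.00 uL  (0.057 pmol, 39.1 ng)
#>   syn_gene_01_gA              1.00 uL  (0.057 pmol, 41.5 ng)
#>   syn_gene_02_gB              1.00 uL  (0.057 pmol, 13.9 ng)
#>   TE buffer                   1.00 uL
#>   syn_backbone_1_5            2.76 uL  (0.157 pmol, 200.0 ng)
#>   isothermal master mix      15.00 uL
#>   screen 5 colonies (p = 0.65 per colony at 4 insert(s); > 99% confidence)
```

Each insert is 1 µL of the 57 nM stock (0.057 pmol); the backbone is dosed
at 200 ng; the four-insert reaction calls for screening 5 colonies to
exceed 99% probability of at least one correct clone. Designs available on
this backbone:

```r
enumerate_fills(chain_start = 1, chain_end = 5)
#> # A tibble: 3 x 3
#>   design      n_fragments slots
#>   <chr>             <int> <list>
#> 1 pA:gC                 2 <chr [2]>
#> 2 pC:gB                 2 <chr [2]>
#> 3 pA:gA:pB:gB           4 <chr [4]>
```

`tidy()`, `glance()` and `autoplot()` methods summarize assemblies, digests
and reaction plans; `plot_gel()` draws predicted band patterns.

## Command line

```sh
exec/gibsim --seed 5 fixtures make --dir demo
exec/gibsim assemble --parts demo/four.fasta --backbone demo/backbone.fasta --out product.gb
exec/gibsim reaction colonies --p 0.8 --confidence 0.99   # prints 3
```

Data goes to stdout or to files; logs go to stderr. Exit codes: 0 success,
1 operation error (e.g. an assembly gap, with the unmatched sites named),
2 usage error.

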
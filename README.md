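# pflutype

PCR-marker phylogroup typing for the *Pseudomonas fluorescens* species
complex.

## The problem

The *P. fluorescens* complex — one of the most diverse assemblages in the
genus, with more than fifty named species — resolves into eight phylogroups
(*P. corrugata*, *P. koreensis*, *P. jessenii*, *P. mandelii*,
*P. gessardii*, *P. fluorescens*, *P. protegens*, *P. chlororaphis*) that
also organize the traits screeners care about: antifungal metabolite
production, insecticidal activity, auxin biosynthesis. Whole-genome or
multilocus phylogenies place an isolate precisely but are slow and costly as
a first screen. An alternative is a panel of nine marker genes
(`DGPf_0`–`DGPf_8`), each amplified by a degenerate primer pair, whose
*presence/absence pattern* across the eight groups is diagnostic: every
phylogroup is characterized by a signature of **required** (+),
**forbidden** (−) and **variable** (±) markers, any assignment rests on at
least two positive reactions, and no full 9-marker pattern matches two
groups (verifiable by enumerating all 2⁹ = 512 patterns).

`pflutype` implements that system end to end, for users who want to

* type isolates from bench PCR results or assembled genomes/contigs,
* screen pooled (metagenomic) DNA for which phylogroups can and cannot be
  present,
* re-derive group-specific markers from their own pan-genome tables and
  design degenerate primers on conserved blocks.

## What is implemented

* **Marker panel** (`builtin_panel()`): the nine primer pairs with their
  target intervals and expected amplicon lengths (612, 685, 1001, 681,
  1072, 1115, 680, 745, 661 bp), and the 9 × 8 decision matrix;
  `validate_panel()` checks the structural invariants, including pairwise
  distinguishability by brute force.
* **Degenerate-primer algebra** (`iupac_degeneracy()`, `iupac_expand()`,
  `iupac_match()`, `consensus_code()`) and primer QC (`primer_qc()`:
  Wallace / nearest-neighbor Tm range over all expansions, hairpin and
  dimer heuristics).
* **In-silico PCR** (`find_binding_sites()`, `predict_amplicons()`,
  `profile_genome()`): exact sliding-window search over 4-bit IUPAC masks
  on both strands, with a total mismatch budget and a stricter 3′-window
  budget (defaults: ≤3 mismatches, none in the last 5 bases), product
  length bounds, and a 20% tolerance flag against each marker's expected
  length.
* **Classification** (`classify_pattern()`): the unique group whose
  required markers are all present and none of whose forbidden markers is
  present, with ≥2 positives; conflicts are reported for near misses.
  **Deconvolution** (`deconvolve_pattern()`) for pooled samples: compatible
  groups (all required markers observed) versus excluded groups (each with
  a missing required marker). `accuracy_summary()` reproduces validation
  bookkeeping such as `accuracy_summary(421, 225, 218, 0)` → 98.34%
  accuracy, 96.9% concordant, 3.1% false positive.
* **Marker discovery** (`find_group_specific()`): group-core /
  absent-elsewhere filtering of an orthology table, ≥500 bp length filter,
  within-group identity ≥0.8, and a local-alignment re-screen against all
  out-group CDS (hit = identity ≥0.7 at ≥50% query coverage).
  **Primer design** (`design_primer_pair()`): consensus IUPAC windows over
  gap-free alignment columns, degeneracy budget, Tm window, QC screen —
  every input sequence matches the designed primers with zero mismatches.
* **Synthetic fixtures** (`make_marker_template()`, `make_group_genome()`,
  `make_community()`, `make_pangenome()`): seeded, bit-reproducible
  templates, genomes, pooled communities and pan-genomes with planted
  ground truth, so the whole pipeline is testable offline.
* **CLI**: `pflutype <ispcr|classify|deconvolve|design|discover|simulate|panel-validate>`
  (installed under `exec/`), YAML config + flag overrides, TSV/JSON/BED
  outputs, logging to stderr.

## Worked example

```r
library(pflutype)
panel <- builtin_panel()

# a seeded synthetic P. chlororaphis genome, profiled and classified
g <- make_group_genome("P. chlororaphis", panel$matrix, panel$markers, seed = 7)
profile <- profile_genome(panel$markers, g, sample_id = "isolate_X")
profile
#> pattern isolate_X | present: { DGPf_2, DGPf_8 }
classify_pattern(profile, panel$matrix)
#> isolate_X -> P. chlororaphis (2 positive reactions; supported by DGPf_2, DGPf_8)

# a pooled soil sample typed from bench PCR results
soil <- marker_pattern("soil",
                       present = c("DGPf_0", "DGPf_3", "DGPf_5", "DGPf_7"))
deconvolve_pattern(soil, panel$matrix)
#> soil: compatible with {P. mandelii, P. fluorescens}

# validation bookkeeping
accuracy_summary(421, 225, 218, 0)
#> 421 genomes tested; 225 identified, 218 concordant (96.9%), 7 false positive (3.1%), 0 false negative
#> overall accuracy 98.34%
```

The profile says the genome amplifies markers DGPf_2 and DGPf_8 at their
expected lengths and nothing else — the *P. chlororaphis* signature. The
soil pattern is compatible with exactly two phylogroups: every other group
has at least one required marker that did not amplify.

Same from the shell:

```sh
pflutype simulate --what genome --group "P. chlororaphis" --seed 7 --out sim/
pflutype ispcr --genome sim/genome.fa --out ispcr_out/
pflutype classify --patterns ispcr_out/profile.tsv --out calls/
```

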
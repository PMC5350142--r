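---
title: "Marker-based phylogroup typing: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based phylogroup typing: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pflutype)
```

## The classification model

The *P. fluorescens* species complex divides into eight phylogroups. The
typing system in this package rests on nine marker genes, `DGPf_0` through
`DGPf_8`, each assayed by a single degenerate primer pair. The decision
matrix assigns each (marker, group) pair one of three states:

* **required** (`+`) — every member of the group carries the marker;
* **forbidden** (`-`) — no member carries it;
* **variable** (`±`) — some members carry it.

A fully tested isolate is assigned to the unique group whose required
markers are all positive and whose forbidden markers are all negative;
variable markers never gate the decision. Assignment additionally demands
at least two positive reactions, so a single stray amplification (the
pattern seen in out-of-complex controls) can never place a strain in the
complex.

```{r}
panel <- builtin_panel()
panel$matrix
```

Two properties make the matrix trustworthy, and both are checked by
enumeration rather than assumed: over all $2^9 = 512$ presence/absence
patterns no pattern strictly matches two groups, and exactly eight patterns
coincide with a group's canonical signature (required markers present,
everything else absent). `validate_panel()` re-verifies both for any
user-supplied panel, so a modified matrix that silently introduces
ambiguity is caught before classification.

```{r}
tab <- enumerate_assignments(panel$matrix)
nrow(attr(tab, "ambiguous"))
table(tab$assigned_group)
```

Two conventions deserve explicit statement because the three-state model
leaves them open. First, a positive *variable* marker counts toward the
two-positive-reactions minimum but is never required; with the shipped
matrix every assignable pattern already carries two required positives, so
the choice is observationally neutral there, but it matters for
user-derived panels. Second, a positive *forbidden* marker vetoes a group
outright. A `lenient` mode reports the best-scoring group together with its
conflicts for triaging noisy bench data; it is never the default and the
package's own pipelines do not use it.

## Mixed (community) samples

Metagenomic DNA yields the union of the member taxa's patterns, so single
assignment is the wrong question. `deconvolve_pattern()` instead partitions
the eight groups into *compatible* (every required marker observed) and
*excluded* (at least one required marker absent, with the missing marker
named). Absence is treated as informative — the exclusion argument that
makes negative reactions meaningful in community screening — and an
`absence_informative = FALSE` switch restricts exclusion to markers
explicitly tested negative, for partially run panels. No abundance or
mixture-proportion inference is attempted: compatibility is a set
statement, and positives that no compatible group explains are surfaced
separately rather than modeled.

## In-silico PCR

`find_binding_sites()` performs an exact sliding-window scan, not a
seeded heuristic: each sequence position becomes a 4-bit base-set mask, a
primer position matches a template position iff the sets intersect (the
IUPAC convention of `iupac_match()`), and every offset on both strands is
scored. Desk-scale inputs (up to ~10 Mb) complete in seconds, so no index
is built.

Binding is accepted under two budgets, reflecting the practice of weighting
primer mismatches by position, especially at the 3′ end where extension
fails first:

| parameter | default | meaning |
|---|---|---|
| `max_mm` | 3 | total mismatches per footprint |
| `window_3p` | 5 nt | width of the 3′-terminal window |
| `max_mm_3p` | 0 | mismatches tolerated inside that window |
| `min_len`, `max_len` | 50, 5000 bp | admissible product lengths |
| `len_tol` | 0.20 | relative tolerance for `within_expected` |

The source system states these review criteria qualitatively but prints no
numbers; the defaults above are this package's own operating point, chosen
so that one primer-length footprint of drift is tolerated anywhere except
the extension end, and they are all overridable through
`ispcr_settings()` or the CLI. Amplicons span from the first base of the
upstream footprint to the last base of the downstream footprint, 1-based
inclusive — the convention under which the panel's printed target
coordinates reproduce the printed amplicon lengths exactly (e.g. 632..1316
gives 685 bp). Primer pairing is evaluated in both orientations, so
predictions are invariant under reverse-complementing a contig. Degenerate
template bases match by set intersection; an `n_strict` mode counts
template `N` as a mismatch because long `N` runs in draft assemblies
otherwise accumulate spurious footprints.

`profile_genome()` calls a marker present iff at least one predicted
amplicon lies within `len_tol` of the marker's expected length, which
suppresses off-target products of wild length without any thermodynamic
model. No free-energy binding model, BLAST wrapping or multiplex
interaction simulation is included.

## Primer thermodynamics and QC

`primer_qc()` reports degeneracy, a Tm range, and hairpin/dimer flags.
Melting temperatures use the Wallace rule ($2(A{+}T) + 4(G{+}C)$ °C) for
oligos of ≤14 nt and SantaLucia's unified nearest-neighbor parameters at
50 mM Na⁺ and 0.25 µM oligo otherwise; a degenerate primer's range is the
min/max over all concrete expansions (enumerated up to degeneracy 1024,
beyond which only the most and least stabilizing per-position expansions
are evaluated — the shipped panel's maximum is 36). These are screening
estimates: annealing temperatures printed for the panel (64/67 °C) came
from a different calculator and are carried as data, not reproduced.

Structure flags are sequence heuristics, not folding calculations: a
hairpin is a stem of ≥4 complementary bases enclosing a loop of ≥3 nt; a
dimer is a contiguous complementary run of ≥8 bp in any ungapped
antiparallel alignment of the two sequences, or ≥5 bp covering either 3′
terminus. All thresholds are arguments with these defaults documented as
conventions.

## Marker discovery and primer design

`find_group_specific()` re-implements the comparative filter that produces
such panels, on a precomputed orthology table: a candidate orthogroup must
have a member in **every** genome of the target group and **no** genome
outside it, a representative CDS of ≥500 bp, mean pairwise within-group
identity ≥0.8, and must survive a sequence-level re-screen — local
alignment (match +1, mismatch −1, gap open 2, gap extend 1, both strands)
of the representative against all out-group CDS, with a hit at ≥0.7
identity and ≥50% query coverage disqualifying. Orthology inference itself
(all-vs-all clustering) is out of scope; the identity+coverage criterion
replaces a database-size-dependent e-value cut-off, and the 0.8
within-group threshold quantifies an otherwise qualitative "high homology"
requirement. The ≥500 bp filter applies to the CDS, not to the alignable
region.

`design_primer_pair()` scans a gap-aware alignment of the candidate's
orthologs for conserved windows: gap-free columns whose per-column minimal
IUPAC consensus keeps the window degeneracy within budget (default 64) and
whose Tm range intersects the requested window. Windows are ranked
lexicographically — degeneracy, then Tm-midpoint distance to the window
centre, then length — and the best-ranked forward window with a feasible
downstream partner (product length within bounds, QC clean) wins;
the whole selection is deterministic. Because the consensus covers every
observed base, each input sequence matches the designed primers with zero
mismatches — the annealing guarantee degenerate bases exist to provide.
Product length is measured in alignment coordinates, which equals the
per-sequence product length in the gapless blocks the designer accepts.

## Synthetic data: what it does and does not show

The generators exist so every pipeline stage has a planted ground truth:

* `make_marker_template()` plants one seed-chosen concrete expansion of
  each primer at the marker's printed coordinates in i.i.d. filler DNA
  (default GC 0.60, typical of *Pseudomonas*);
* `make_group_genome()` emits one contig per planted marker — all required
  markers, each variable marker with probability 0.5 (the `±` semantics,
  absent any frequency data), no forbidden markers — plus a marker-free
  decoy contig, with substitution rates of 0.02 outside and 0 inside
  primer footprints by default (degenerate bases already absorb the
  within-group primer-site variation the panel was designed around;
  raising `mutation_rate_primer` is the knob for sensitivity studies);
* `make_community()` pools group genomes by integer weights;
* `make_pangenome()` fabricates shared-core, noise and planted
  group-specific orthogroups (noise orthogroups are re-drawn if their
  genome set accidentally equals a group, which would corrupt the planted
  truth), with optional out-group decoys at a chosen identity.

A given seed is bit-reproducible; truth records ride along as attributes
and JSON sidecars so tests never re-derive ground truth from generator
internals. These fixtures deliberately omit repeat structure, rearranged
gene neighborhoods, sequencing error and real phylogenetic covariance —
passing on them demonstrates the *logic* (coordinate arithmetic, matrix
algebra, threshold behavior, planted-marker recovery), not field
performance on real assemblies, which depends on assembly quality and true
primer-site divergence.

Problem sizes used by the shipped tests — the package's own choice of
test scale — are: all 512 patterns enumerated exhaustively; oracle
equivalence on templates up to ~2 kb against a per-position naive scan;
pan-genomes of 2–3 groups × 2–3 genomes; and 50 seeded genomes per
phylogroup (400 total) for the end-to-end profile→classify loop, which
recovers the planted group in ≥95% of runs and never misassigns in strict
mode.

## Numerical and degenerate-input conventions

* Percentages use half-up decimal rounding (accuracy to 2 decimals, other
  rates to 1), matching how such figures are conventionally printed; base
  R's banker's rounding would differ on exact halves.
* Coordinates are 1-based inclusive everywhere except the BED6 export
  (0-based half-open); each writer states its convention in its header.
* Empty templates, empty site tables and empty FASTA inputs flow through
  as empty results, not errors; alphabet violations error with the
  offending position.
* Ties in primer-window ranking break deterministically by window start;
  sample output tables are sorted on (template, start, end, orientation).
* `enumerate_assignments()` refuses panels beyond 20 markers (2²⁰
  patterns) rather than silently stalling.

## Known limitations

* The decision-matrix approach is only as good as its panel: taxa outside
  the eight phylogroups carrying chance marker subsets (observed in
  practice as a small false-positive rate among relatives of
  *P. aeruginosa*) classify by their pattern, not their phylogeny. The
  package reproduces the bookkeeping of that error mode
  (`accuracy_summary()`) but cannot detect it without an independent
  phylogeny.
* In-silico PCR is sequence-level: no polymerase kinetics, no
  amplification bias, no multiplex competition.
* `similarity_screen()` is a desk-scale aligner intended for tables of
  hundreds of CDS, not a BLAST replacement at database scale.
* Discovery consumes a finished orthology table and pre-aligned (or
  trivially gapless) orthologs; clustering and multiple alignment are
  upstream concerns.
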
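---
title: "Methods: decontamination, loss matrices and pseudogene scanning in myxoloss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decontamination, loss matrices and pseudogene scanning in myxoloss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myxoloss)
```

## Scope and model

`myxoloss` treats the recovery of a parasite's gene-loss signal from a
contaminated assembly as three nested filters followed by two summaries.
The filters operate on evidence attached to individual contigs; the
summaries operate on curated or derived protein catalogues. Nothing in the
package runs an aligner or a profile scanner: BLAST-style 12-column tables
and tblout-style domain tables are *consumed*, which keeps every decision
rule deterministic and separately testable.

### Host exclusion

The first filter removes contigs that are almost certainly host sequence:
a best nucleotide hit against the host genome with identity > 85 **and**
e-value < 1e-75. Both inequalities are strict; a hit at exactly 85%
identity survives. The thresholds are exposed (`identity_threshold`,
`evalue_threshold`) but their defaults are the published values and there
is rarely a reason to move them: the rule is intentionally conservative,
removing only near-identical, highly significant matches. No minimum
alignment length is imposed — the e-value requirement already implies a
long alignment at these identities.

### Dual-database fold rules

The second filter compares, per contig, the best hits against a
target-clade protein database and a deliberately broad contaminant
database. With best e-values $e_t, e_c$ and bit scores $b_t, b_c$:

* `target` iff $e_t \le e_c / f_e$ and $b_t \ge f_b \, b_c$,
* `contamination` under the mirrored conditions,
* `not_clear` otherwise,

with $f_e = 100$ and $f_b = 1.5$ by default ("at least" is read as
inclusive, so a pair exactly at the fold boundary is decided). Three edge
policies matter in practice:

* **Zero e-values.** Search tools report 0 for overwhelming hits; a fold
  rule is undefined at zero. Zeros are floored at `evalue_floor = 1e-180`
  *for the ratio arithmetic only*, which preserves "strongest possible
  evidence" while keeping both directions of the rule meaningful. Two
  zero-e-value best hits are therefore `not_clear` unless the bit scores
  separate them — which is the honest answer.
* **Single-sided evidence.** A contig hit in exactly one database is
  decided toward that database. The alternative (forcing `not_clear`)
  discards the only evidence available; the choice is recorded per contig
  in the `rule` column.
* **No evidence.** Hitless contigs default to `not_clear` and fall through
  to GC rescue (`no_hit_label` makes this configurable).

The classifier is symmetric by construction (swapping the databases swaps
the decided labels) and monotone in the fold parameters (raising either
fold can only move contigs *into* `not_clear`); both properties are
enforced by tests.

### GC rescue

Ambiguous contigs are split on GC content: the parasite clade sits in a
low-GC mode (≈ 0.27–0.30) well separated from the typical contaminant mode
(≈ 0.55). `gc <= cutoff` routes to `target`, inclusively — at the published
precision of the cutoffs (four decimals) the boundary convention is
immaterial, but it must be fixed for reproducibility. GC is computed over
unambiguous bases only; a contig with no unambiguous base has *undefined*
GC (not 0) and defaults to `contamination` with a warning, the conservative
direction for a decontamination step.

The published cutoffs were chosen by eye from GC/length scatter plots and
ship as presets (`gc_cutoff_presets()`: 0.3903, 0.4080, 0.3692).
`estimate_gc_cutoff()` provides a reproducible alternative: a kernel
density (`stats::density`, default bandwidth, grid of 1024 on $[0,1]$) and
the minimum between the two tallest modes. A kernel-valley search was
preferred over an EM mixture fit because it is deterministic without a
seed, has no convergence failures, and on separations like 0.28/0.55 lands
within a few thousandths of the misclassification-minimising boundary
(tested against a brute-force threshold sweep). Modes below 5% of the
tallest peak are ignored as noise; if fewer than two modes remain, or the
valley falls outside $(0.15, 0.70)$, the estimator refuses and demands an
explicit cutoff — automatic estimation on a unimodal distribution would
silently split one population. Estimation also refuses fewer than 20
values.

### ORF extraction

`extract_orfs()` is a transparent stand-in for coding-region predictors:
all six frames, maximal stop-free codon runs (stop-to-stop), optional
anchoring at the first methionine, and a 70-aa floor — the floor used to
build the protein databases upstream. Deliberate conventions:

* Coordinates are 0-based half-open **on the forward strand** for all six
  frames; one convention for both strands prevents off-by-one drift, and a
  round-trip test re-translates every reported interval.
* Codons containing ambiguity characters translate to `X` and never
  terminate an ORF (conservative retention; a run of `N`s cannot break a
  gene model into two sub-threshold pieces).
* Edge-truncated runs (no bounding stop) are reported if long enough,
  because transcriptome fragments routinely lack one or both stops.

No coding-potential scoring or splice awareness is attempted: downstream
logic needs translated segments above a length floor, nothing more. The
extractor is verified against a character-by-character brute-force oracle
on random sequences.

### Presence matrix and loss gradient

Catalogues are long-format tables (taxon, species, category, protein,
status, flags) over ten actor categories. `build_matrix()` reduces a
catalogue to boolean cells (present = at least one *intact* entry), with
parallel intact counts and pseudogene counts, and per-taxon retention.
Entries with status `pseudogene` are catalogued but, by default, do not
make a cell present — a gene interrupted by stop codons is not evidence of
a functional pathway; `count_pseudogenes = TRUE` reproduces the alternative
reading in which the cell is occupied. `absent_marker` rows document a
looked-for-but-missing gene and never count.

`loss_gradient()` reports retention along an ordered taxon sequence and a
non-increasing verdict plus the categories newly lost at each step. The
packaged catalogue (`table1_catalogue()`) yields 10 → 7 → 2 → 1 along the
free-living → *Polypodium* → Malacosporea → Myxosporea order. Its
transcription makes two recorded choices: the *Polypodium* calpain cell is
expanded to four entries (two named calpains and two "classical" calpains),
following the running text and the domain-structure figure over the
table's compressed typography; and the three starred myxosporean
cytochrome C genes carry status `pseudogene` (retention 1 for Myxosporea
rests on the three intact cytochrome C genes).

`catalogue_from_domains()` derives a catalogue mechanically from domain
hits: a protein joins a category when all required domains are present at
`e_value <= evalue_max` (e.g. caspases require the p20 peptidase domain;
APAF-1 requires NB-ARC + WD40; a "classical" calpain flag requires both
peptidase domains plus an EF-hand). The rules ship as an editable
structure (`default_category_map()`) because the published assignments
involved expert curation (domain-architecture inspection and phylogenetics)
that no fixed rule set reproduces; the default map is the mechanical core
of those decisions, not a replacement for them.

### Pseudogene scanning

`scan_stops()` works entirely in the coordinate system of a supplied
protein alignment (candidates are assumed pre-framed; alignment
construction is out of scope). An insertion is a maximal run of columns
where the candidate has residues while at least `gap_frac = 0.8` of the
references are gapped — 0.8 rather than 1.0 so a single poorly trimmed
reference cannot suppress an otherwise unanimous insertion. Columns map to
reference coordinates by counting non-gap residues of the anchor
reference, left-anchored, so an insertion inherits the position of the
residue to its left; an insertion anchored inside the domain span counts
as in-domain.

Every candidate `*` whose column falls inside the structural-domain span
is counted and split into inside- vs outside-insertion; stops inside a
conserved sub-span (e.g. a highly conserved 69-aa core, supplied by the
user — its exact coordinates are input, not package constants) are tallied
separately. Verdicts: `intact` (no in-domain stop),
`pseudogene_insertion_only`, `pseudogene_conserved_disrupted` (a stop
outside insertions falls in the conserved span), and — a completion of the
published three-way scheme, which leaves this combination undefined —
`pseudogene_outside_insertions` for stops outside insertions that miss the
conserved span. The counts always satisfy `in + out == total`, and
removing insertion segments from the mask can only move stops outward;
both are tested on randomized planted fixtures.

## The synthetic world

The generator encodes the data-generating assumptions the pipeline relies
on, with defaults fixed once:

* **GC modes**: target Normal(0.28, 0.03), contaminant Normal(0.55, 0.04) —
  the stated low-GC parasite mode (27–30%) and 55% contaminant mode.
* **Lengths**: log-normal, median 1000 bp, sdlog 0.45, floor 300 bp — a
  realistic transcriptome-contig profile; no value was stated, and these
  are not revisited.
* **Composition**: each contig gets the *exact* base composition of its
  drawn GC, randomly arranged. Independent per-base sampling was
  considered and rejected: at 1–2 kb its binomial noise (sd ≈ 0.011–0.016)
  violates the intended "realized GC within ±0.02 of the draw" contract
  for a few percent of contigs. Exact composition satisfies it to within
  rounding and changes nothing else the pipeline measures.
* **Hit model**: per contig, an own-database e-value exponent uniform on
  [−150, −30] with bit score a fixed monotone map of it
  (`bits = −2.5·exponent + 30`), and a cross-database hit weakened by two
  knobs — e-value multiplied by `evalue_separation` (log10-normal jitter,
  sd 0.5) and bit score divided by `bitscore_separation` (log-normal
  noise, sd 0.05). The monotone map keeps the two fold rules from
  conflicting except where the knobs intend it; at separation 10⁴/2× both
  rules pass essentially always, at 1/1× essentially never.
* **Seeds are mandatory arguments** for every generator; identical seeds
  give byte-identical files.

What a green synthetic test establishes — and what it does not: recovery
of planted labels shows the decision rules and their plumbing are correct
under the assumed statistical structure (clean bimodal GC, unimodal hit
strength, independent contigs). Real assemblies add horizontally
transferred sequence, chimeric contigs, compositional heterogeneity within
genomes, and databases of uneven completeness; none of these failure modes
is represented, so synthetic recovery rates are a correctness check, not a
field accuracy estimate.

## Numerical and degenerate-input choices

* Best-hit ties: minimum e-value, then maximum bit score, then
  lexicographic subject id — fully deterministic and order-invariant.
* `e_value = 0.0` survives parsing as exact zero; flooring happens only in
  the classifier's ratio arithmetic.
* Duplicate contig ids, text before the first FASTA header, and empty
  records are hard, line-numbered errors: per-contig bookkeeping cannot
  tolerate silent recovery.
* Contigs shorter than three codons yield no ORFs; an empty `not_clear`
  set skips GC-rescue entirely (no cutoff is estimated).
* `run_all()` summarises the gradient along the canonical parasitism order
  when all four gradient taxa are present, else along the catalogue's own
  order (the packaged catalogue also carries two outgroups, which are not
  part of the gradient claim).

## Limitations

* The ORF extractor is not a gene predictor; it will report long stop-free
  runs in non-coding sequence and will miss spliced structures.
* The domain-to-category rules are mechanical; the published assignments
  additionally used phylogenetics and manual architecture review.
* Read-level filtering (mapping-based intersection of datasets from
  different hosts) is represented only as contig-level bookkeeping.
* Species-level published findings (e.g. cytochrome C absence in
  particular myxosporeans) depend on external genome data and are covered
  here only through the packaged catalogue and synthetic fixtures.
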
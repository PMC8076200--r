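---
title: "Designing genome-wide InDel markers that separate cultivars from wild relatives"
author: "indelmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing genome-wide InDel markers that separate cultivars from wild relatives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Breeding programs that move genes from wild relatives into a cultivated
crop need cheap, robust markers that distinguish the cultivated allele
from the wild allele at loci spread evenly across the genome. For rice
(*Oryza sativa*) and the AA-genome wild species of its primary genepool,
insertion/deletion (InDel) polymorphisms with allele-length differences of
roughly 20 bp or more are ideal: they type by ordinary PCR followed by
agarose-gel electrophoresis, with no sequencing, probes or
polyacrylamide gels.

`indelmark` automates the comparative-genomics workflow that produces
such a marker set. Given a reference assembly (the cultivar) and a panel
of related assemblies (other cultivars and wild species), it emits named,
validated PCR markers with predicted product sizes per accession, plus
the genotyping analytics used to characterise a marker set: validation
categories, per-accession polymorphism counts, species-level marker
groups, two-band (heterozygosity) frequencies, and introgression calls in
backcross progeny.

## The pipeline, stage by stage

1. **Bait selection** (`select_bait_windows`). Candidate windows of
   `bait_min_len` (30 kb) are anchored every `bait_interval_bp` (1 Mb)
   from the top of each chromosome to its end. A window is accepted when
   its repeat-derived fraction is at most `max_repeat_fraction` (0.3);
   otherwise it slides forward in half-window steps until the next anchor
   (then the anchor is skipped, which is what happens over
   centromeric repeat fields). Repeat content is operationalised as the
   fraction of positions whose covering 21-mer occurs more than once
   genome-wide, or that are soft-masked or N — a library-free analogue of
   avoiding transposable elements, computed from the genome itself.

2. **Ortholog extraction** (`find_orthologous_region`,
   `assemble_ortholog_set`). For every bait, 15-mers that are unique in
   both the bait and the target genome (both strands counted) seed a
   chain; the hit is the longest strictly co-linear chain with adjacent
   anchors within 20 kb, padded by 2 kb and reverse-complemented for
   minus-strand hits so that everything downstream is bait-forward.
   Chains need at least 10 anchors spanning at least half the bait.
   Absence is a legal outcome — assemblies genuinely lack some regions —
   and a bait proceeds only when at least `min_ortholog_members` (6)
   sequences, bait included, are available, the "more than five of
   eight" rule of the manual protocol. When a second chain scores at
   least 0.8 of the best, the hit is flagged ambiguous.

3. **Anchored alignment** (`align_to_bait`, `project_to_msa`). Each
   ortholog is aligned to its bait by a banded global
   alignment with affine gaps (match 1, mismatch −2, gap open −6, gap
   extend −0.2 — deliberately long-gap-friendly so a 30-bp InDel scores
   as one event rather than scattering). The band follows the anchor
   chain; the pipeline starts at a half-width of 200 bp (above the
   largest modelled InDel of 150 bp) and doubles it automatically, up to
   four-fold, if the optimal path ever touches the band edge. Padded
   overhangs of the query are cost-free and trimmed. Rather than a true
   simultaneous multiple alignment, the pairwise alignments are projected
   onto reference coordinates: every bait base is a column, member
   insertions are stored as (position, sequence) events. The projection
   is lossless (`deproject_member` reproduces each member byte-for-byte)
   and linear-time in members, which is all the InDel screen needs —
   only variation *relative to the reference* matters for marker design.
   Insertions from different members at the same position are not merged
   into shared columns; the screen compares event lengths instead.

4. **InDel screen** (`extract_indel_blocks`, `classify_diagnostic`,
   `select_markers_per_bait`). Gap events are left-aligned (so positions
   are reproducible across aligner variants) and merged across members
   within 10 bp into blocks with per-member allele lengths. A block is
   *fully diagnostic* when every cultivar–wild pair differs by at least
   `min_gap_bp` (20 bp), *partially diagnostic* when at least one pair
   does; members with no recovered ortholog are excluded from the
   quantifier rather than failing the block. The threshold is inclusive
   at 20 bp and configurable: gaps below ~20 bp do not resolve on
   2.5–4.0% agarose. At most `max_markers_per_bait` (2) blocks are kept
   per bait, ranked full > partial, then larger gap, then longer
   conserved flank, then position; selected blocks must be at least
   `product_max` apart so their amplicons cannot overlap. No constraint
   is imposed on whether the cultivar carries the short or the long
   allele.

5. **Primer design** (`conserved_flank_windows`, `design_primer_pair`,
   `melting_temp`, `uniqueness_check`, `name_marker`). Primers are
   restricted to flank columns conserved across *all* aligned members
   (no mismatch, no gap, no member insertion), so that one primer pair
   amplifies every accession with even efficiency. Candidates are 18–24
   nt, melting temperature 55–65 °C by unified nearest-neighbor
   thermodynamics (SantaLucia 1998 parameters; 50 mM monovalent salt,
   0.25 µM oligo, matching the 55 °C annealing protocol), no homopolymer
   run of five, 3' end outside homopolymers, GC 30–70%, and 3'-terminal
   self/cross complementarity of at most 4 bp. Among feasible pairs the
   longest-allele product closest to 300 bp (the midpoint of the
   100–500 bp window) wins, with a deterministic tie order. Primer
   uniqueness replaces the BLAST check with an exact scan of both strands
   of the reference: each primer must occur exactly once. Markers are
   named `A` + two-digit chromosome + `P` + five-digit position in kb
   (nearest-kb rounding; both published example names are consistent
   with either rounding rule), anchored at the InDel block start — the
   biologically meaningful locus.

6. **In-silico PCR** (`find_binding_sites`, `predict_amplicons`,
   `genotype_accession`). A primer binds where it matches with at most 2
   mismatches overall and none in its 3 terminal 3' bases — the
   mechanism by which real markers fail on divergent accessions.
   Amplicons pair forward-strand sites of the forward primer with
   reverse-strand sites of the reverse primer up to 2 kb. Both
   haplotypes of a heterozygous accession are amplified; lengths within
   `gel_resolution_bp` (20 bp, taken constant across the 2.5–4.0% gel
   range; a gel-percentage-to-resolution curve is deliberately out of
   scope) merge to one band. No amplification and more than two bands
   map to the failure statuses observed in marker validation. When two
   bands appear the cause is annotated as heterozygosity or locus
   duplication when the haplotype structure allows the distinction, and
   left unset otherwise — band patterns alone cannot tell them apart.

7. **Analytics** (`categorize_markers`, `summarize_polymorphism`,
   `two_band_frequency`, `species_marker_sets`, `interval_statistics`,
   `call_progeny_genotype`, `detect_introgressions`). A marker *fails*
   when more than 30% of its cells are bad (the protocol does not state
   the threshold it used; ours is configurable), is *polymorphic* when
   any accession differs from either reference cultivar by an
   agarose-resolvable band, and is *monomorphic* otherwise; the three
   categories always partition the set. Percentages round to 1 decimal
   (validation rate) and 3 decimals (two-band frequency), matching the
   precision those quantities are conventionally reported at. Progeny
   calls are `H` when the band set equals the union of the parents',
   `A`/`B` when they equal one parent, and introgressions are maximal
   runs of non-recurrent calls per chromosome, single-marker runs
   included. The homozygous-donor state `B` is retained even for
   backcross material, where it flags selfing contamination.

## The synthetic panel: what it emulates, and what it does not

`make_species_panel` builds the study system at desk scale: an i.i.d.
ancestor of 2 chromosomes × 3 Mb carrying planted tandem repeat arrays
and dispersed repeat copies, one cultivar species and three wild species
diverged from it at species-level rates, and accessions within species at
accession-level rates. The default rates are

| level | SNP/bp | small InDel (1–19 bp) | large InDel (20–150 bp) | repeat insertion |
|---|---|---|---|---|
| species branch | 0.005 | 5·10⁻⁴ | 2·10⁻⁵ | 10⁻⁶ |
| accession branch | 5·10⁻⁴ | 5·10⁻⁵ | 2·10⁻⁶ | 0 |

Species-level SNP divergence of 0.5% per branch (≈1% pairwise) matches
cultivated-vs-wild rice comparisons; the large-InDel class spans
20–150 bp, the size range that separates cleanly on agarose; the
large-InDel rate gives on the order of one fully diagnostic cultivar
branch event per 30-kb bait, similar to the yield that let the manual
protocol pick one or two markers per megabase window. Two cultivar
accessions (the reference plus an *indica*-like second cultivar) form
the cultivar group; the last wild species is "perennial-like" with
heterozygosity fraction `h = 0.02` against a baseline of 0.002,
reproducing the order-of-magnitude contrast between the highly
outcrossing perennial wild rices (two-band frequencies around 9–13%) and
the predominantly selfing species (0.2–0.8%). Heterozygous accessions
carry a second haplotype evolved from the first at rates proportional to
`h` (SNP `h`, small InDel `h/6`, large InDel `h/60`), which puts a
heterozygous large InDel inside a ~300-bp amplicon at roughly the
frequencies those published two-band rates imply.

Cross progeny are represented as haplotype-origin mosaics in
recurrent-parent coordinates: an F1 is one full haplotype from each
parent, each backcross gamete recombines the previous generation's two
haplotypes with Poisson(1.5) crossovers per chromosome placed uniformly.
Band-level genotyping follows directly from the mosaic and the parents'
band sets. This is a noiseless model — it shows that the calling and
segment logic is exact, not that it tolerates PCR noise.

What the simulator does **not** emulate: realistic transposon biology
(repeats are verbatim element copies, not diverged families), selection
and demography (edits are uniform i.i.d.), assembly errors and gaps,
GC-content heterogeneity, and interference in recombination. Passing the
simulated acceptance suite therefore demonstrates the pipeline's
correctness and calibration under the stated divergence model, not its
performance on any particular pair of real assemblies.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout the R API (the
  R/Bioconductor convention); BED export converts to 0-based half-open.
* Alignment traceback ties prefer match/mismatch over gap-in-query over
  gap-in-bait, and all selection steps (chains, blocks, primer pairs)
  carry explicit deterministic tie orders, so identical inputs and seeds
  give byte-identical outputs.
* A gap of length *g* costs `gap_open + g × gap_extend`.
* Anchor k-mers are odd (k = 15) so no k-mer is its own reverse
  complement; k-mers occurring twice anywhere (including across baits)
  are discarded rather than disambiguated.
* Chromosomes shorter than a bait yield no baits; a panel smaller than
  `min_ortholog_members` is a configuration error; empty marker tables
  are written only on request (`allow_empty`).
* Gel-band merging is single-linkage with cluster means; cluster means
  are provably at least one resolution unit apart, making the merge
  idempotent and order-independent.
* The e-PCR "weak site" refinement (reporting sites that fail only the
  overall-mismatch rule) is not implemented; sites either bind or do
  not.

## Problem sizes used by the test suite

The acceptance checks run the full pipeline on 20 independently seeded
default panels (2 × 3 Mb, 11 accessions each) and require at least 90%
of the planted fully diagnostic InDels (≥ 30 bp, isolated, non-repeat
context, at least 300 bp inside a selected bait so a 100–500-bp product
is geometrically possible) to come back as validated polymorphic
markers; alignment and binding-site kernels are checked against
brute-force dynamic programming and position-by-position scans on 50
seeded instances each; published validation-panel counts are shipped as
package data and their summary arithmetic (means, extremes, validation
rate, two-band percentages) is recomputed exactly. One published figure
is deliberately not asserted: the mean of the Nipponbare-column
polymorphic counts as printed in the source table (183.5 from the 21
printed values) does not reproduce the narrative's 187.4; the package
computes statistics from whatever counts are supplied.

## Known limitations

* Ortholog extraction assumes a single orthologous copy per genome;
  polyploid or recently duplicated loci yield either an ambiguous flag
  or a missing member.
* Rearranged orthologs (inversions, translocations) are handled only at
  the whole-hit level via minus-strand normalisation; internal
  inversions inside a bait will truncate the anchor chain.
* Primer uniqueness is exact-match only; near-matches are handled
  downstream by the mismatch-tolerant e-PCR, not at design time.
* The gel model is a single resolution threshold; band intensity and
  mobility curves are out of scope.
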
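---
title: "Methods: plasmid clustering, reconstruction and typing in mobkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasmid clustering, reconstruction and typing in mobkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobkit)
library(dplyr)
```

## Overview

Bacterial plasmids carry accessory genes — notably antimicrobial-resistance
determinants — and move between hosts by conjugation. Draft assemblies from
short reads fragment both chromosome and plasmids into contigs, so
recovering *which contigs belong to which plasmid* is a reconstruction
problem. mobkit implements a reference-database approach built from three
linked components:

1. **Clustering** (`mob_cluster_build()`, `mob_cluster_update()`): closed
   reference plasmids are grouped by MinHash genomic distance with
   single-linkage clustering at two nested thresholds, producing stable
   `primary.secondary` cluster codes.
2. **Reconstruction** (`mob_recon()`): assembly contigs are matched against
   marker databases (replicons, relaxases, repeats) and the clustered
   reference set, then aggregated into plasmid units by a winner-take-all
   rule over reference clusters.
3. **Typing** (`mob_typer()`): replicon and relaxase (MOB) family typing
   plus a transmissibility prediction from relaxase, mate-pair-formation
   (MPF) and oriT evidence.

A deterministic synthetic-data generator (`sim_config()`,
`simulate_study()`) and benchmarking utilities (`base_confusion()`,
`classify_events()`) make the whole pipeline testable end to end with no
external data.

## Genomic distance

`mob_sketch()` stores the `s` numerically smallest 64-bit hashes of a
sequence's canonical k-mers (the lexicographic minimum of each k-mer and
its reverse complement, so sketches are strand-symmetric). `mob_distance()`
estimates the Jaccard index `j` from the merged bottom-`s` sketch — the
shared fraction among the `s` smallest hashes of the union — and converts
it with the Poisson k-mer-survival model

$$ d = -\frac{1}{k}\,\ln\!\frac{2j}{1+j}, $$

capped to [0, 1], with `d = 1` when no hashes are shared and exactly 0 for
identical sketches. Under this model `d` estimates the per-base
substitution rate between the two sequences; the test-suite verifies that
sequences mutated at rates 0.01 and 0.05 from a 50 kb ancestor yield mean
distances within ±0.01 of the rate over 20 replicates.

Numerical choices:

* **k = 21, s = 1000** by default — the customary sketching defaults for
  genome-scale comparison; k = 21 makes random 21-mer collisions negligible
  while tolerating a few percent divergence, and s = 1000 gives a Jaccard
  standard error of roughly 1/√s ≈ 3%.
* The hash is splitmix64 over the 2-bit-packed canonical k-mer, XORed with
  a fixed seed (42), and truncated to its top 53 bits so values are exactly
  representable as R doubles. At s = 1000 the probability of any truncation
  collision within a sketch is about 1e-10. Changing the seed invalidates
  stored sketches, so it is recorded in every sketch file.
* k-mers containing N (or any non-ACGT base) are skipped entirely:
  ambiguous bases would otherwise hash arbitrarily.

## Cluster codes

`mob_cluster_build()` computes all pairwise distances and partitions the
records by single-linkage clustering at a loose (0.05) and a strict (0.001)
threshold. Single-linkage flat clusters at threshold *t* are exactly the
connected components of the graph whose edges join pairs at distance ≤ *t*;
the implementation cuts an `hclust(method = "single")` tree at height *t*,
and the test-suite checks exact agreement with a brute-force union-find on
random matrices. Because components at a smaller threshold refine those at
a larger one, every record's `secondary` cluster nests inside its
`primary` cluster by construction.

The default thresholds follow the published defaults for
*Enterobacteriaceae* reference plasmids; both are user-settable. The loose
level is deliberately permissive — plasmids of quite different size can
share a backbone — because it drives the winner-take-all contig assignment
during reconstruction.

`mob_cluster_update()` adds records without ever renaming existing ones:
a new record inherits the full code of its nearest member within the
strict threshold, inherits only the primary id (with a freshly minted
secondary id) within the loose threshold, and otherwise receives fresh ids
from monotone counters that are never reused. This keeps cluster
designations comparable across database updates. A record that lies within
the loose threshold of two different primary clusters would, under full
re-clustering, merge them; to preserve code stability the record instead
joins the cluster of its nearest member (ties: smaller primary id, then
lexicographically smaller plasmid id) and a warning reports the bridge, so
incremental partitions can be coarser than batch re-clustering and the
user is told when that happens.

## Homology search

No installed R package exposes an in-process nucleotide local aligner, so
mobkit bundles one designed for the package's scope: exact seed-word
anchoring (15-mers by default) followed by a maximal-scoring-segment
(Kadane) scan along each anchored diagonal, on both strands, with blastn
ungapped scoring (reward +2, penalty −3; bit score
`(0.625·S − ln 0.41)/ln 2`). The aligner is exact for the substitution-only
divergence the generator produces and for real data with limited indel
content; an external `blastn` backend (`mob_search_blast()`) with the same
contract is cross-checked against it in the tests. Hits are normalised to
the forward strand of the contig as 0-based half-open intervals (1-based
only in written reports).

Filtering defaults (all overridable): replicon/relaxase/MPF/repeat markers
need ≥80% identity and ≥80% coverage *of the marker* (markers are short,
contigs long); oriT sites use 90/90 because short motifs match spuriously
at lower stringency; reference-plasmid hits are aggregated per
(contig, reference) into a non-overlapping HSP set and kept when the
combined alignment covers ≥65% of the *contig* at ≥80% weighted identity.
Overlap resolution is greedy by descending bit score (ties: longer
interval, then subject id) with a configurable pairwise-overlap cap — 0
for scoring ("cumulative non-overlapping bit score") and 0.1 for marker
typing, which tolerates fuzzy boundaries.

## Reconstruction

`mob_recon()` follows a fixed decision order:

1. Contigs whose header carries a `circular=true` token (any case,
   whitespace- or semicolon-delimited) are circular; optionally an exact
   end-overlap check (≥50 bp, off by default) adds more. Circular contigs
   are putative plasmids regardless of every other filter.
2. Contigs with a replicon or relaxase hit (or circularity) are candidates.
3. Contigs covered ≥80% by repeat-element hits with no replicon/relaxase
   are repeat-flagged: they travel with plasmids but cannot evidence one.
4. Each (contig, reference) pair is scored by its cumulative
   non-overlapping bit score; each reference cluster is ranked by its best
   score (ties: summed per-contig best, then smaller id); walking that
   queue, every still-unassigned contig with any hit to the current
   cluster joins its unit. A contig therefore lands in exactly one unit —
   multi-copy repeats included. Contigs under 500 bp (unless circular) and
   contigs with neither hits nor candidacy go to the chromosome bin;
   candidates without reference hits form singleton units.
5. Circular contigs inside multi-contig units are split into their own
   units; units consisting solely of repeat-flagged contigs with no
   replicon/relaxase (and no circular member) are discarded back to the
   chromosome.
6. Each unit's contigs are concatenated, sketched, and compared with the
   reference sketch store; a unit whose distance to its closest reference
   exceeds the loose threshold (strictly greater than 0.05) is labelled
   novel (`novel_<n>`), otherwise it carries the primary cluster code of
   its closest reference.

Only the primary (loose) cluster level participates in reconstruction; the
secondary level exists for nomenclature. Chromosome assignment is purely
absence-of-plasmid-evidence — no chromosome database is consulted — which
matches the coverage-agnostic design: read-depth signals are deliberately
not used.

## Typing

`mob_typer()` searches the four marker databases, collapses subject ids to
family names (the prefix before the first underscore, e.g. `IncF_1` →
IncF), and classifies mobility:

| relaxase | MPF | oriT | mobility |
|----------|-----|------|----------|
| yes | yes | – | conjugative |
| yes | no  | – | mobilizable |
| no  | –   | yes | mobilizable |
| no  | no | no | non_mobilizable |

A plasmid with an oriT but no relaxase is still mobilizable: a relaxase
acting in trans can initiate transfer at a cis oriT, which is the minimal
requirement for transmissibility. The full eight-way truth table is tested
exhaustively.

## Synthetic data

The generator emulates the study conditions end to end: independent random
ancestors per cluster (so between-cluster distances saturate near 1),
members mutated at a per-lineage rate of 0.01 (expected pairwise
within-cluster divergence ≈ 0.02, comfortably inside the 0.05 threshold),
cluster-specific replicon and relaxase markers planted into each ancestor,
8–20 kb plasmids, a 120 kb chromosome, genome plasmids copied from
reference members at rate 0.02, and a 1 kb repeat element inserted into
the chromosome and one plasmid of each genome. Assemblies are produced by
cutting each circular replicon at repeat boundaries plus random
breakpoints (n cuts → n fragments; the fragment spanning the sequence
origin is recorded with a wrapped interval), leaving the smallest plasmid
whole and tagged `circular=true`. Mutation is substitution-only so planted
coordinates stay valid; markers are random sequences, so tests exercise
the algorithms rather than marker biology.

What this does **not** emulate: indels and rearrangements, assembler
mis-joins, coverage variation, real marker families with within-family
homology, and mosaic plasmids sharing backbones across clusters. Passing
tests therefore demonstrate algorithmic correctness under controlled
divergence, not field performance on real assemblies — on real data the
reference database's completeness dominates accuracy.

The shared repeat is inserted into genome replicons but *not* into the
reference plasmids: reference databases hold curated closed backbones,
while IS elements hop in and out of individual genomes. Repeat contigs in
the default scenario therefore carry no reference hits and fall to the
chromosome bin via repeat-flagging. The complementary situation — a repeat
present in references from several clusters, where winner-take-all must
place the repeat contig in exactly one unit — is exercised separately in
the test-suite.

## Benchmarking

`map_contigs_to_truth()` reproduces the standard assessment mapping: each
contig maps to its single best-matching closed replicon (highest combined
non-overlapping bit score; ties broken by alignment length, then
lexicographically smaller replicon id) and is discarded below 50%
identity or 50% contig coverage. A simulated truth table can bypass
alignment. `base_confusion()` counts bases of assessed contigs into
tp/fp/tn/fn with plasmid as the positive class; discarded contigs are
excluded.

`classify_events()` assigns each truth plasmid exactly one event: *correct*
(all contigs in one unit, unit pure), *split* (contigs in more than one
unit), *merge* (a unit holding its contigs also holds foreign contigs),
*hybrid* (both), *missed* (no contig in any unit). Two boundary decisions
keep the taxonomy exhaustive: a unit contaminated only by chromosome
contigs counts as a merge (the unit contains foreign sequence, which is
exactly what breaks correctness), and a plasmid whose remaining contigs
sit in the chromosome bin while one unit holds the rest counts as a split
(the plasmid is divided). "Identified" means at least one contig of the
plasmid appears in some emitted unit.

## Problem sizes and determinism

The test-suite and the acceptance script run entirely on generated data at
the scales above: 10 reference plasmids, 10 genomes of 3 plasmids each
(~1.7 Mb assessed per acceptance run), 20 clustering-recovery replicates
and 20 distance-calibration replicates — sizes chosen so the full pipeline
exercises every rule while a complete run stays at desk scale. Every
random draw flows from a single user-supplied seed (simulation substreams
derive fixed offsets from it), so identical configuration and seed
reproduce identical FASTA bytes, reports and distances.

## Known limitations

* The bundled aligner is ungapped; heavily indel-divergent or rearranged
  homology is underscored relative to a gapped aligner. Marker searches
  are nucleotide-space; distant protein-level homology is out of scope.
* Cluster codes are stable only within one database instance; comparing
  codes across independently built databases requires a central authority.
* Default thresholds were tuned (upstream) for *Enterobacteriaceae*
  plasmids and may be inappropriate for other taxa.
* Incremental updates can leave a coarser partition than re-clustering
  when bridge records arrive (a warning is emitted).
* Low-quality or chromosome-contaminated reference records degrade every
  downstream step; an optional minimum-length filter is provided but no
  automatic quality control is attempted.
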
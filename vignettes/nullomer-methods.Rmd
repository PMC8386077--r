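---
title: "Absent words under negative selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absent words under negative selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nullomeR)
```

## The model

A *nullomer* is a k-mer that never occurs in a genome (or a defined
compartment of it); a *nullpeptide* is a peptide k-mer absent from a
proteome. At short lengths absence is informative: the expected count of a
given k-mer in a genome of length $L$ is roughly $2L/4^k$ (both strands),
so for the human genome absence only becomes possible around $k = 11$ and
by $k = 15$ covers a third of the word space. Words that stay absent while
their close sequence neighbours are common are candidates for negative
selection — their appearance, through a single mutation, may be deleterious.

`nullomeR` implements four layers around this idea:

1. **Detection.** Every window of valid residues in the input marks one
   word present in a packed bitmap covering the whole word space. In
   `strand_mode = "both"` a word and its reverse complement are marked
   together, so the nullomer set is reverse-complement closed; the
   *forward* switch is kept because whether the reference analysis counted
   one or both strands is not documented — full-scale reproductions should
   try both. Windows never span sequence boundaries, and windows touching
   N (DNA) or a nonstandard amino acid (collapsed to X) never count.

2. **Scoring.** Three per-word statistics and an aggregate rank:
   $\varphi_1$ — the mean occurrence count of the $3k$ (or $19k$)
   single-substitution neighbours; zero exactly for first-order nullomers.
   For peptides, amino-acid composition is so skewed that substitution
   neighbours mostly measure composition; the permutation variant (mean
   count over all distinct rearrangements of the word's letters,
   identity included) is used instead.
   $\varphi_2$ — the mean occurrence count over $R$ Monte Carlo shuffles
   of the compartment that preserve its k-let composition exactly
   (see below); the same machinery yields the compartment-level
   enrichment, observed nullomer count over the mean simulated count.
   $\varphi_3$ — the fraction $M/n$ of non-reference species whose
   genome contains the word.
   $\varphi_N$ — the sum of the three ascending ranks, ties sharing the
   minimal rank. The accompanying prose description ("average rank") is a
   monotone transform of the sum and orders identically; the printed sum
   is implemented. Words whose aggregate resurfacing probability exceeds
   0.05 are dropped before the final ordering.

3. **Materialization maps.** For every position: 3 substitutions and 1
   deletion; for every inter-base gap (including the terminal gap): 4
   insertions. Each edit is applied to a local window of radius $k-1$ and
   every k-window overlapping the edit is tested against the nullomer set,
   which is equivalent to editing the whole genome and diffing presence
   sets (the test suite proves this equivalence against an exhaustive
   oracle). Class expectations follow the edits that can disrupt — or,
   inverted, create — a single occurrence of a k-mer: $k$ deletions, $3k$
   substitutions, $4(k-1)$ insertions (end insertions excluded since they
   leave the occurrence intact), totalling $8k-4$; for $k = 13$ this is
   the 13%/39%/48% split.

4. **Population resurfacing and phylogenetics.** Observed variants (VCF,
   gnomAD-style INFO keys) are validated against the reference, applied
   one at a time, and intersected with the materialization map. The
   aggregate probability that a word is present in an individual is
   modelled as $P = 1 - \prod_v (1 - \mathrm{AF}_v)$ over its supporting
   variants — an independent-sites approximation chosen because the
   source analysis never states its formula; a capped sum of frequencies
   is available behind `method = "sum"` for sensitivity checks. A word is
   population-specific when its per-population aggregate probability
   exceeds 5% in exactly one population and stays below 1% in all others.
   Species-level absence profiles feed Jaccard similarity
   $J = |A \cap B| / |A \cup B|$, Ward clustering, and clade partitions
   (primes = absent everywhere; species-specific = absent in exactly one).

## The k-let preserving shuffle

`shuffle_klet()` reimplements the Euler-path scheme of the uShuffle family.
For `klet` $= m \ge 2$ the sequence is viewed as an Euler path in the de
Bruijn multigraph over $(m-1)$-mers. For every vertex except the terminal
one a random *last-exit* edge is drawn until the last-edge graph forms an
arborescence into the terminal vertex (rejection sampling with a retry
cap); remaining out-edges are permuted uniformly and the forced walk is
emitted (the walk itself is compiled code). This yields a sequence with
exactly the input's m-let count vector and the original first and last
$(m-1)$-mer. `klet = 1` is a plain uniform permutation.

Runs of invalid residues are kept in place and each valid segment is
shuffled independently: the geography of assembly gaps is data, not noise,
and the reference analysis is silent on the point, so fixing it is the
conservative choice. Conservation then holds for the whole sequence's
valid-window counts, which is what the tests assert.

## Synthetic data: what it emulates and what it does not

The generators state a small world once and keep it fixed:

* `synth_genome()` — i.i.d. bases at GC = 0.41 (the human genome-wide
  value) unless told otherwise, optional N runs (20–100 bp), and motif
  exclusion by repair: windows containing a planted motif (or, in
  both-strand mode, its reverse complement) are resampled until no hit
  remains, leaving global composition essentially untouched. Exclusion of
  sub-2-bp motifs is refused as infeasible.
* `synth_annotation()` — non-overlapping three-exon gene models on
  alternating strands with codon-aligned CDS and UTRs on both sides.
  In-frame stop codons are recoded in the returned genome (first stop base
  to C on the coding strand) so every CDS translates cleanly; the
  generator therefore returns the patched genome with the models, a
  deliberate widening of the `genome -> GFF3` signature since a fixed
  random genome cannot guarantee stop-free CDS.
* `synth_vcf()` — allele frequencies from Beta(0.5, 10) (many rare, few
  common — the shape, not the scale, of a site-frequency spectrum), with
  10% of per-population values missing to exercise the absent-not-zero
  rule; variants engineered to materialize a chosen nullomer are found by
  one-mismatch motif search.
* `synth_proteome()` — roughly vertebrate-like amino-acid usage (common
  L/S/A/E, rare W/C/M).

What a green test on this world establishes: algorithmic correctness —
agreement with brute-force enumeration, exact conservation laws, formula
identities, round trips. What it does not establish: any claim about real
genomes. An i.i.d. genome has no repeats, no isochores, no mutational
spectrum; enrichment values and nullomer counts on synthetic data are not
comparable with the reference analysis' human numbers, and the spec's
full-scale targets are accordingly not asserted anywhere (see the
acceptance script's header).

## Numerical and design choices

* **Presence bitmaps, not count arrays.** $4^{15}$ bits is 128 MB and
  $20^7$ bits is 160 MB; full count arrays at these sizes are not
  feasible, so occurrence counts are obtained in a second pass keyed only
  by requested target words.
* **Spliced versus genomic compartments.** CCDS, exons and UTRs are
  extracted as spliced transcript-level sequences (k-mers may span exon
  junctions, reverse-complemented for minus-strand transcripts), because
  coding k-mer content is an mRNA-level property; genic, intronic and
  promoter sequences are genomic intervals. The source analysis does not
  state its convention; this one is recorded here as the package's
  choice. Duplicate sequences under one label are deduplicated — presence
  is set-valued, so duplicates only cost time.
* **Coordinates.** GFF/GTF and VCF are 1-based inclusive end to end; BED
  is converted from 0-based half-open at the parsing boundary. Soft
  masking is uppercased and kept: repeats are analysed, not excluded.
* **Mutation-scan conventions.** Insertions are keyed to the gap before
  `pos` (left-anchored, `pos = n + 1` for the end gap); one event per
  distinct `(pos, ref, alt)` carries the union of materialized words; in
  both-strand mode a word and its reverse complement both flip to present
  and both are listed. Substitutions are only enumerated where the
  reference base is A/C/G/T — editing an unknown base is not a
  well-defined variant and would break the $3k$ substitution accounting —
  while deletions of N and insertions into N runs are enumerated, since
  their junction windows can contain fully valid words.
* **Ward linkage.** Clustering uses `hclust(as.dist(1 - J),
  method = "ward.D2")`, the linkage matching scipy's `ward`, on the
  distance $1 - J$: Ward requires a distance, and $1 - J$ is the
  mathematically coherent transform of a similarity bounded by 1. Species
  are sorted lexicographically before clustering so equidistant merges
  break ties reproducibly.
* **Order classification** is capped (default `max_order = 2`):
  neighbourhood size grows as $\binom{k}{i} 3^i$ and the reference
  analysis itself only reports first-order sets. Neighbourhoods are
  substitution-only, per the definition.
* **Seeds.** Every stochastic function takes an explicit seed and runs it
  through an RNG-preserving scope; simulations consume one seeded stream
  sequentially, and the CLI derives all stage seeds from a single
  `--seed` recorded in the manifest.
* **Degenerate inputs.** Empty sequences scan to all-absent maps; a pair
  of empty sets has Jaccard 0 (with a warning) rather than NaN; zero
  events make class enrichment an error rather than silent NaNs; oracle
  functions refuse inputs beyond their size guards instead of silently
  running for hours.

## Known limitations

* DNA k is capped at 15 and peptide k at 7 by the dense-bitmap design; a
  sparse or suffix-automaton backend (minimal absent words) is out of
  scope.
* Variants are applied one at a time; compound haplotypes and
  linkage-aware joint resurfacing probabilities are not modelled.
* The transcript density measure uses the genomic TSS–TES span, and genes
  are summarized by their densest isoform.
* Functional enrichment of gene sets (GO/REACTOME) is downstream tooling
  and deliberately not wrapped.
* At desk scale the per-nullomer $\varphi_2$ mean is the value entering
  $\varphi_N$; the compartment-level count ratio is reported alongside,
  since which of the two the reference ranking used is not fully pinned
  down.
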
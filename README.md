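# nullomeR

Identification and analysis of **nullomers** — short DNA words absent from a
genome or one of its functional compartments — and **nullpeptides**, their
amino-acid counterparts absent from a proteome.

Short absent words are interesting because their absence can be more than
chance: a k-mer that never occurs although thousands of near-identical
sequences do may be under negative selection, and a single mutation can make
it "materialize". `nullomeR` provides the full toolkit around this idea for
genomicists and molecular evolution researchers:

* exhaustive k-mer presence scanning over the complete word space
  (`4^k` for DNA, k ≤ 15; `20^k` for peptides, k ≤ 7) with a packed bitmap,
  strand-aware (a DNA word counts as present if it or its reverse complement
  occurs), and N/X-aware (windows through assembly gaps or nonstandard
  residues never count);
* functional-compartment extraction from GFF3/GTF gene models — genic,
  spliced CCDS/exons/UTRs, introns, strand-aware promoters (−2500/+500
  around the TSS) and arbitrary BED region sets;
* negative-selection scores for absent words:

  | score | definition |
  |-------|-----------|
  | φ₁(N) | mean occurrence count of all `3k` single-substitution neighbours of N, `φ₁ = Σᵢ Σ_{j≠Nᵢ} A_{N_{i,j}} / 3k` (peptides use the mean over all distinct letter permutations instead) |
  | φ₂(N) | mean occurrence count of N over R Monte Carlo shuffles of the compartment that exactly preserve mono-/di-/tri-nucleotide (or -peptide) content, `φ₂ = Σᵢ Nᵢ / R` (R = 100 by default) |
  | φ₃(N) | fraction `M/n` of non-reference species whose genome contains N |
  | φN    | `RANK(φ₁) + RANK(φ₂) + RANK(φ₃)`, ascending min-ranks with ties sharing a rank; lowest φN = strongest negative-selection candidate |

* higher-order classification: a nullomer has order *i* when every word
  within Hamming distance *i* is also absent;
* genome-wide maps of every single-base substitution, insertion and deletion
  that would materialize a nullomer, with expected class counts
  (k deletions, 3k substitutions, 4(k−1) insertions), class enrichments,
  trinucleotide context spectra and region densities;
* intersection with observed population variants (gnomAD-style VCF):
  per-nullomer resurfacing probabilities `P = 1 − Π(1 − AF)`,
  population-specific nullomer calls (common > 5% in one population, rare
  < 1% in all others), and common-variant exclusion for the final φN
  ranking;
* CDS-level maps of nucleotide substitutions that materialize nullpeptides
  (stop-codon-creating and synonymous changes excluded);
* absence-based phylogenetics: Jaccard similarity between species' absent-
  word sets, Ward (`ward.D2`) trees on the distance 1 − J with Newick
  export, and clade partitions (primes, species-specific and group-specific
  absent words);
* seeded synthetic genomes/annotations/VCFs/proteomes and brute-force
  oracles, so everything above is testable offline.

## Worked example

```r
library(nullomeR)

# a 30 kb synthetic genome with one assembly gap and a planted absent motif
genome <- synth_genome(length = 30000, gc = 0.41, n_runs = 1,
                       exclude = "CGTACGA", seed = 1)

pmap <- scan_presence(genome, k = 7, "dna", "both")
pmap
#> presence_map: dna, k=7, strand=both
#>   15,234 / 16,384 words present (7.019% absent)

nl <- find_nullomers(pmap)
nrow(nl)
#> [1] 1150
"CGTACGA" %in% nl$word
#> [1] TRUE

# score a few nullomers: neighbour occurrences, shuffle simulations, ranks
words <- head(nl$word, 5)
p1  <- phi1_scores(words, genome, "both")
sim <- phi2_simulate(genome, 7, words = words, klet = 3, R = 20, seed = 2)
phiN_rank(words, unname(p1), sim$scores$phi2, rep(0, 5))
#>      word     phi1 phi2 phi3 rank1 rank2 rank3 phiN
#> 1 AAAGGGG 2.380952 2.60    0     1     1     1    3
#> 2 AAACCGC 3.523810 2.80    0     2     2     1    5
#> 3 AAAACGG 4.285714 3.80    0     4     3     1    8
#> 4 AAAGCGT 4.047619 4.45    0     3     5     1    9
#> 5 AAACGCA 4.476190 4.10    0     5     4     1   10

# where could nullomers materialize through single-base edits?
ev <- scan_materializing_mutations(genome, pmap)
nrow(ev)
#> [1] 51883
mutation_type_enrichment(ev)
#>       DEL       SUB       INS
#> 0.7412392 1.0050709 1.0710348
```

The φN table reads: the word ranked 1 in all three φ lists would have
φN = 3 and is the best negative-selection candidate. The enrichment vector
compares the observed share of materializing deletions / substitutions /
insertions with the combinatorial expectation `(k, 3k, 4(k−1))/(8k−4)` —
on the reference human analysis this is where the characteristic depletion
of nullomer-creating deletions appears.

## Command line

```sh
inst/scripts/nullomer-cli fixtures  --seed 1 --genome-length 100000 --out fx
inst/scripts/nullomer-cli nullomers --fasta fx/genome.fa --k 6:8 --strand both --out nul
inst/scripts/nullomer-cli score     --fasta fx/genome.fa --k 8 --klet 3 --replicates 100 --out scores
inst/scripts/nullomer-cli mutmap    --fasta fx/genome.fa --k 8 --out mm
inst/scripts/nullomer-cli variants  --fasta fx/genome.fa --vcf fx/variants.vcf --k 8 --out var
```

Every run writes a `manifest.json` with parameters, input digests and the
master seed; all randomness flows from `--seed`.

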
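---
title: "homeosort: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{homeosort: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeosort)
```

## The model

An allopolyploid genome is modelled as two coresident subgenomes, A and
D, aligned against a single reference (in the motivating cotton system,
the D-genome diploid reference). A *homoeo-SNP* is a reference position
where the two subgenomes carry disjoint allele sets; these sites are the
only information available for deciding which subgenome an aligned read
came from. Because the subgenomes of the polyploid are each closer to
their extant diploid relatives than to each other, SNPs called between
the two *diploids* serve as a proxy for SNPs between the subgenomes —
with a known contamination by diploid-specific alleles, which is why
read categorization tolerates a fraction of non-matching sites rather
than demanding unanimity.

### Site calling

For each position covered in both diploid pileups, each genome's
*qualifying allele set* contains the bases at frequency ≥
`maf_threshold`; a genome whose major allele reaches
`fixation_threshold` is treated as fixed for that base. A position is
indexed when the two qualifying sets are non-empty and disjoint. When a
base qualifies in both genomes it is removed from each genome where it
is **not** the major allele, and that genome receives a within-genome
allele-SNP annotation; if the sets still intersect after this reduction
the site cannot discriminate the genomes and is not indexed. This
reduction rule is the one genuinely open design point in the calling
procedure: the source method states its thresholds (4× coverage, 40%
minor allele frequency) but not how the two pileups and the reference
combine into a verdict. We chose a symmetric rule — the reference base
is stored but never privileged — because the published procedure
compares the pileups with each other as peers, and a symmetric rule is
the simplest one that reproduces all three published verdict classes
(homoeo-SNP, A-genome allele-SNP, D-genome allele-SNP).

### Categorization

A read overlapping indexed sites accumulates tallies *a* (bases in the
A allele set) and *d* (D allele set). Bases matching neither set are
counted but carry no weight in the decision: at sequencing error rates
of 10^-2^–10^-3^ a non-matching base is overwhelmingly noise, and
letting it dilute the denominator would turn single errors into N
calls. The decision is

- N if *a* + *d* = 0;
- A if *a*/(*a*+*d*) ≥ threshold, D symmetrically (inclusive — "at
  least" 75% means 3-of-4 is called);
- X otherwise.

The threshold must exceed 0.5, which guarantees at most one genome can
reach it. Paired mates are pooled by default (`pair_mode = "joint"`):
mates come from one molecule, so their evidence is shared and both
receive the joint category; `independent` mode is available for
protocols where that assumption fails.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_coverage` | 4 | reads/genome | minimum evidence for an allele call; below this a frequency estimate on 1–3 reads is meaningless |
| `maf_threshold` | 0.40 | fraction | allele must be a substantial minority to qualify; 40% retains true heterozygous 50/50 sites through sampling noise while excluding error bases |
| `fixation_threshold` | 0.90 | fraction | above this the genome is treated as fixed and minor bases are discarded as noise |
| `threshold` | 0.75 | fraction | category majority; inclusive |
| `min_base_quality` | 20 | Phred | per-site analog of the quality-20 read trimming used upstream |
| `read_length` | 100 | bp | Illumina HiSeq era read length assumed in the categorizability statistic |

All are exposed at every API level and the CLI; defaults are recorded
in the index file header and the run manifest.

## Bisulfite mode

Bisulfite conversion reads out as C→T on plus-strand reads and G→A on
minus-strand reads, exactly mimicking transition SNPs — and transitions
are the majority of any homoeo-SNP index. Discarding all transition
sites would make most BS reads uncategorizable, so strand is inferred
first, from the read's own C→T vs G→A mismatch counts (indexed
positions are excluded from these counts, since a C/T homoeo-SNP would
otherwise masquerade as conversion — the source method is silent here
and this is the conservative choice). Given the strand:

- a C/T site is uninformative on plus-strand reads but fully
  informative on minus-strand reads; G/A symmetrically;
- at informative sites, matching tolerates conversion (plus-strand T
  matches a C allele; minus-strand A matches a G allele);
- multi-allele records are uninformative if **any** cross-genome allele
  pair forms the confounded pair on the read's strand (set-wise
  extension of the single-allele logic).

Reads with equal conversion counts (including zero) are
strand-ambiguous. For categorization each of their sites is evaluated
under both strand hypotheses and used only when the verdicts agree —
the published rule specifies half-read counting only for strand
tallies, so for the categorical decision we chose the conservative
never-guess policy. In the methylation report, ambiguous reads
contribute weight 0.5 to each strand, making counts half-integral
(serialized with one decimal); per-category columns sum to the totals
at every site by construction.

Context is assigned from the reference: CG if the next base (plus
strand; mirrored for minus) is G, CHG if H then G, else CHH. Positions
too close to a contig end to resolve are reported with context `NA` and
excluded from per-context summaries. A directional (two-strand)
protocol is assumed; PBAT-style libraries are out of scope.

## The simulator: what it emulates and what it does not

`simulate_genomes()` draws a uniform-random D genome and derives A by
substituting at `snp_density` = 3.5 SNPs/kbp with transition
probability r/(r+1) at r = 1.5 — the density and tr/tv ratio observed
for the cotton A/D pair, so the simulated index has realistic
information content per 100 bp read. Reads are emitted pre-aligned at
their true coordinates (alignment is out of scope; a FASTQ export
exists for users who want to exercise a real aligner), with uniform
substitution errors and constant Phred-35 qualities. Bisulfite
simulation assigns each read a strand, methylates each read cytosine
independently at its context probability (per-read Bernoulli, which
makes the recovery tests exactly binomial), and converts unmethylated
cytosines at the configured rate.

A green recovery test therefore establishes: the calling rule is
exactly invertible in the error-free, well-covered regime; the
categorizer is consistent with an independent base-by-base oracle; and
methylation levels are recovered within binomial sampling error. It
does **not** establish robustness to mapping error, indel
polymorphism, reference bias, uneven coverage, chimeric molecules, or
diploid-vs-subgenome divergence — all properties of real data the
generator deliberately does not model (the per-read truth labels would
be ill-defined under several of them). The published misassignment
rates (0.3–0.8% for diploid reads) depend on the real cotton SNP
density and error profile and are not reproducible from simulation;
the corresponding acceptance property is exact recovery in the
simulator's stated world.

## Numerical and convention choices

- **Coordinates**: 0-based half-open internally; every serialized
  format (index, methylation report, pileup, SAM) is 1-based as its
  ecosystem expects.
- **Pileup dialect**: only the 6-column samtools mpileup text form is
  accepted; mapping-quality columns are rejected loudly rather than
  misparsed. `^` consumes its mapping-quality byte, `+n/-n` consume
  their indel text, `*`/`<`/`>`/N resolve to nothing countable, and a
  depth/base-string mismatch after resolution is an error.
- **Ties**: a genome whose top two alleles tie at the fixation check is
  not fixed (max frequency < threshold keeps both); the category
  threshold is inclusive; `index_summary` reports NaN ratios for empty
  or transversion-free indexes rather than failing.
- **Merging** indexes unions allele sets per genome and drops (masks)
  positions whose unioned sets intersect — a position that stopped
  discriminating the genomes must leave the index, and dropping is
  conservative for every downstream consumer.
- **N bases** never match any allele and are excluded from pileup
  counts before thresholding.
- **Determinism**: all randomness flows through the configured seed;
  reruns are byte-identical, which the test suite asserts end to end
  through the CLI.

## Known limitations

- Single-nucleotide index only: indel divergence between subgenomes is
  invisible (and indel-bearing reads are handled but contribute no
  sites within deleted spans).
- Exactly two subgenomes; higher polyploids would need a generalized
  allele-set partition.
- The categorizer trusts the upstream mapper's placement (unique best
  hits assumed); it does not remap or estimate mapping efficiency.
- Allele-SNP discovery within the polyploid (recategorized alignments)
  is limited to the merge operation; full iterative refinement with a
  variant caller is an external loop.
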
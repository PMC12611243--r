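---
title: "Intra-host viral population diversity and transmission bottlenecks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intra-host viral population diversity and transmission bottlenecks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quasipop)
```

## The problem

Cryphonectria hypovirus 1 (CHV1) attenuates the chestnut blight fungus and
is used as a biocontrol agent across Europe. Inside one fungal host the
virus exists as a quasispecies: a cloud of closely related haplotypes, a
few dominant and many rare. Every transmission — vertical, into asexual
spores (conidia), or horizontal, through hyphal anastomosis gated by the
vegetative-incompatibility (*vic*) loci — passes the population through a
bottleneck of a handful of founder genomes, reshaping its diversity.

`quasipop` implements the desk-side half of a long-read amplicon study of
this process. Its inputs are count-annotated, denoised haplotype FASTA
files (one per intra-host population, headers in the `id;size=N` dialect),
a reference genome with an ORFA/ORFB coding annotation, and a manifest
pairing populations into transmission experiments. Upstream read
processing (circular-consensus generation, demultiplexing, denoising) is
out of scope; the package records its thresholds only as ingest metadata.

## Diversity metrics

**Viral variants.** A variant is a unique haplotype: two reads belong to
the same variant iff their Hamming distance is zero. `collapse_reads()`
merges identical sequences, summing read counts; unequal-length
(indel-bearing) sequences never merge, because the Hamming distance is
undefined for them and they are genuinely distinct molecules.

**Nei's gene diversity.** `neis_h()` computes

$$h = \frac{n\left(1 - \sum_i x_i^2\right)}{n - 1},$$

with $x_i$ the variant frequencies. Following the convention of denoised
amplicon studies, $n$ defaults to the number of distinct variants, not the
read total; `n_mode = "reads"` switches to the classical
finite-sample-over-sequences usage. For $n = 1$ the formula is $0/0$ and
we define $h = 0$ — the limit of the unbiased estimator for a monomorphic
population. With $n$ = variant count, $h$ is bounded by 1 and equals 1
exactly for any number of equal-frequency variants.

**Nucleotide diversity.** `population_pi()` computes the codon-aware
nucleotide diversity over the amplicon's coding sites,

$$\pi = \frac{N_\mathrm{diffs} + S_\mathrm{diffs}}
            {N_\mathrm{sites} + S_\mathrm{sites}},
  \qquad
  \pi_N = \frac{N_\mathrm{diffs}}{N_\mathrm{sites}}, \qquad
  \pi_S = \frac{S_\mathrm{diffs}}{S_\mathrm{sites}},$$

with Nei–Gojobori counting: each codon's nine single-nucleotide
neighbours contribute 1/3 site each, synonymous iff the amino acid is
unchanged (stop-gaining changes count as nonsynonymous), so
$N_\mathrm{sites} + S_\mathrm{sites} = 3$ per sense codon; pairwise codon
differences are averaged over all orderings of the changes, excluding
orderings that pass through a stop codon (if every ordering does, all are
used and the result is flagged). Differences are frequency-weighted with
replacement over haplotype pairs, $\sum_i \sum_j x_i x_j$, with no minimum
allele frequency and no sliding window. Because the haplotypes are fully
phased, codon frequencies come from whole haplotypes rather than from
independent per-site frequencies.

Numerical choices, all surfaced as flags or options:

* *Finite-sample correction.* Off by default (read depths are large); an
  option applies the $n/(n-1)$ factor over reads.
* *Gap columns.* Codon columns containing an alignment gap in any
  haplotype are excluded from both differences and sites; deletions are
  reported as mutations with effect categories instead. The excluded
  count is reported.
* *Stop columns.* Columns where any haplotype codon is a stop (downstream
  of frameshifts) are likewise excluded and counted.
* On SNP-only data the codon accumulator collapses exactly — to machine
  precision — to the frequency-weighted mean pairwise Hamming distance
  per coding site; the test suite verifies this equivalence against an
  independent brute-force oracle on hundreds of random populations.

**Selection summary.** `selection_summary()` counts populations with
$\pi_S > \pi_N$ (purifying selection) versus $\pi_N > \pi_S$ (positive
selection or mutation-load accumulation), and reports a two-sided paired
*t* test on $\pi_N - \pi_S$ with the mean difference quoted as
$\bar\pi_S - \bar\pi_N$, positive under purifying selection.

## Mutation calling and effects

`align_haplotype()` performs global affine-gap alignment (match +2,
mismatch −4, gap open −12, gap extend −1), computed with Biostrings'
Needleman–Wunsch/Gotoh implementation and cross-checked in the test suite
against a textbook dynamic-programming oracle. The gap costs make one
long contiguous gap cheaper than several short ones, which suits the long
conservative deletions (hundreds of nucleotides, multiples of three)
characteristic of defective viral RNAs. Equal-length pairs with at most
2% mismatches take a gapless fast path: equal length implies no net
indel, and under these scores scattered substitutions cannot pay for a
compensating insertion–deletion pair.

`call_mutations()` aggregates per-site changes across haplotypes — a
mutation's frequency is the summed frequency of every haplotype carrying
the identical ref→alt change — with indels left-aligned within
homopolymer runs and anchored VCF-style on the previous reference base.
Effects follow the standard annotation categories: codon translation for
SNPs (synonymous / missense / nonsense), length mod 3 for indels
(inframe / frameshift), `noncoding` outside the CDS regions; an event
spanning a region boundary is classified by majority overlap and flagged.
`build_consensus()` applies mutations with frequency strictly above 0.5
to the reference backbone (ties keep the reference; overlapping majority
mutations are an error, not a silent choice).

## Transmission statistics

`transmission_rate()` is the success percentage of a pairing assay.
`fisher_exact_2x2()` implements the two-sided Fisher's exact test as the
sum of hypergeometric probabilities not exceeding the observed table's
(relative slack $10^{-12}$; a zero margin gives $p = 1$); the test suite
checks it against full enumeration for every table with margins up to 30
and against `stats::fisher.test()`. `diversity_change()` compares paired
populations on the natural-log scale, $\ln(\mathrm{recipient} /
\mathrm{source})$, with a pseudocount of $10^{-6}$ (flagged) when either
side is zero. The heavier model-fitting machinery of a full study
(GLM, mixed models, MANOVA, post-hoc tests) is deliberately out of scope;
the paired/one-sample *t* and Fisher tests are the statistics this
package owns.

**Founder estimation.** Under multinomial sampling of $k$ founder genomes
from the source frequencies, the expected gene diversity of the founder
sample is $(1 - 1/k)$ times the source's — the classical one-generation
bottleneck loss. `estimate_founders()` inverts this:
$\hat k = 1 / (1 - D_\mathrm{rec}/D_\mathrm{src})$, with $D$ either the
gene diversity $1 - \sum x^2$ or $\pi$. When the recipient is at least as
diverse as the source the estimate is unbounded (flagged), and a
zero-diversity source is an error. The estimator is scale-free in read
counts. Being a ratio of noisy quantities it is slightly biased upward
(Jensen); the Monte-Carlo recovery test shows the median $\hat k$ stays
within ±20% of the truth for $k \in \{2, 5, 10\}$ when the source is
highly diverse and sequencing depth is ample ($10^4$ reads).

## What the simulator emulates — and what it does not

`simulation_config()` fixes the study conditions; its defaults are the
package's model of a CHV1 amplicon study:

* **Layout**: a 5000-nt amplicon with a 450-nt noncoding 5′ stretch, a
  complete 1380-nt ORFA and the amplicon-truncated 5′ part of ORFB
  (remainder rounded down to whole codons), carrying the study's
  degenerate primer sites at its ends. ORFs are built codon-wise with no
  internal stops; ORFA is modelled without its terminal stop codon inside
  the amplicon so that routine π computations carry no stop-exclusion
  flags (targeted tests exercise that machinery separately).
* **Populations**: 40 variants whose frequencies are one draw from a
  Dirichlet with concentration 0.3 — a few dominant (≥5%) variants and
  many rare ones — each non-master variant carrying a zero-truncated
  Poisson(2) number of SNPs; read counts are largest-remainder-rounded to
  2000 reads so frequencies sum exactly to one and every variant keeps at
  least one read. SNPs are rejected if they create a premature in-frame
  stop (the generator models viable genomes); this also keeps the π
  oracle equivalence exact on simulated data.
* **Vertical transmission**: $k$ founders drawn multinomially with
  replacement (virions vastly outnumber founders), $k$ fixed or
  zero-truncated Poisson with mean 2 — the scale of published founder
  estimates for this virus (≈2 genomes) — followed by proportional
  expansion and new private SNPs at a per-site rate of 0.004 (≈20 new
  rare variants per population, reproducing the observation that progeny
  populations stay variant-rich even after a severe π bottleneck).
* **Horizontal transmission**: success is Bernoulli per pairing with
  locus-gated probabilities — none 1.0, *vic2* 0.06, *vic3* 0.17 (the
  midpoint of the 12.5–25% assay range), *vic4* 0.97 — and the barrier
  loci pass fewer founders (Poisson mean 2 versus 5).
* **Noise**: per-base sequencing errors at rate 0.002 and a toy
  abundance-threshold denoiser that reabsorbs sub-threshold variants into
  their nearest retained neighbour. This denoiser is deliberately simple
  plumbing for exercising the collapse path — it is *not* a
  reimplementation of any published denoising algorithm.

A single master seed is stream-split by operation name and replicate
index, so every population and every replicate is independently
reproducible and whole studies re-run byte-identically.

Not modelled: recombination, defective-interfering replication dynamics,
fitness differences among variants, within-canker spatial structure, and
any within-host expansion model beyond proportional growth. Passing tests
therefore demonstrate the *statistical* correctness of the pipeline under
founder sampling and neutral mutation — not that real CHV1 populations
evolve neutrally. In particular the simulator is neutral, so simulated
$\pi_S$ versus $\pi_N$ splits hover near 50:50, unlike the strong
purifying-selection excess real populations show.

## Design choices where the design was open

* The "percent of variants transmitted" statistic has an ambiguous
  denominator; `shared_variants()` reports all three fractions (of the
  source set, of the recipient set, of the union) and leaves the choice
  to the user.
* Whether π should carry a Jukes–Cantor correction or an alternative
  stop-pathway rule is tool-dependent; both behaviours are fixed here
  (no JC correction; stop-avoiding pathway averaging with a flagged
  fallback) and documented above.
* π "monotonicity" under new variants holds for newcomers distant from
  the resident cloud; a newcomer adjacent to the dominant variant can
  lower frequency-weighted π. The test suite asserts the property in the
  regime where it is true.
* Test problem sizes (150–600-nt amplicons, hundreds of reads) are chosen
  so the whole suite runs in about a minute while still covering every
  code path at the default 5-kb scale in the end-to-end pipeline checks.

## Known limitations

* The aligner is desk-scale (sequences ≤ 20 kb) and exact; it is not a
  replacement for a mapper on genome-scale data.
* Indel normalisation is single-variant left-alignment; complex nested
  events (an insertion inside a deletion) are represented as separate
  records.
* `estimate_founders()` is a one-generation moment estimator; it assumes
  diversity loss comes from the founder draw alone, so post-transmission
  mutation biases $\hat k$ upward. Likelihood-based bottleneck inference
  is out of scope.
* Reverse-strand CDS annotations are rejected: the virus is
  message-sense, and supporting both strands would double the codon
  machinery for no use case this package serves.
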
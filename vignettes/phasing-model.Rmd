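---
title: "The phasing model behind haplotigr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The phasing model behind haplotigr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplotigr)
```

## The problem

A polyploid genome carries `k` homologous copies of each chromosome, and a
variant caller only reports *that* a site is heterozygous, not which copy
carries which base. Phasing assigns the heterozygous SNPs to the physical
DNA copies they co-occur on. For diploids, knowing one haplotype determines
the other, and alignment-based tools solve the problem well. For polyploids
that deduction is impossible — a site can show up to four bases across the
copies — and the combinatorics defeat short reads entirely.

haplotigr implements an alignment-based, **ploidy-agnostic** approach for
long reads: it never asks for `k` and never estimates it. Reads reduced to
their base calls at known heterozygous positions are clustered
agglomeratively, and the number of clusters that survive — the haplotigs —
is an emergent property of the data.

## Reduced reads and context-coverage weights

Every long read is reduced to the ordered list of `(position, base)` calls
at the supplied heterozygous positions (`reduce_alignments()`, or the
tab-separated interchange format of `read_reduced_reads()`). Bases between
heterozygous sites carry no phasing information and are never consulted.
Reads whose calls are a subset of another read's are removed up front
(`remove_subset_reads()`): they cannot change any consensus their superset
would not.

Long reads are error-prone, and the pipeline deliberately performs **no
error correction** — flattening heterozygosity would destroy exactly the
signal being phased. Instead, every call is weighted by its **context
coverage** (`build_context_table()`): the number of reads in the whole
dataset carrying the same base at the same position *flanked by the same
up-to-two heterozygous calls on each side*. A correct call in a correct
context is re-observed by most same-haplotype reads and gets a large
weight; a sequencing error — even one that turns the base into an allele
legitimately present on another haplotype — sits in the wrong flanking
context and keeps a weight near 1. Weights are computed once, before
clustering, and are never updated; they attach to calls, so subsetting a
read's calls (as the stitching pass does) keeps them.

## The clustering loop

Each read starts as a singleton cluster. A cluster is summarised by its
per-position vote tallies (each member read voting with its context
weight); the **consensus** at a position is the argmax set of the tallies,
with all tied bases included. Similarity between two sequences (reads or
consensus sequences — they are treated identically) is

\[ S = N_{\text{shared variants}} / N_{\text{shared positions}}, \]

where a shared position counts as a shared variant when the base sets
intersect. A pair may merge only if it shares at least
`min_overlap_count = 10` heterozygous positions, has `S >=
min_similarity = 0.01`, and — unless the pair shares more than
`overlap_ignore_threshold = 100` positions — the shared positions are at
least `min_overlap_fraction = 0.1` of the positions covered by the
*smaller* sequence (the one covering fewer heterozygous positions, not the
shorter one). At every step the highest-similarity allowed pair is taken,
ties broken by the larger shared-position count and then uniformly at
random from a seeded generator.

**Cluster identity maintenance** is what stops the loop from collapsing
everything into one cluster per region. A cluster's identity is the
per-position *demographics* of its votes — the support share of each base.
Merging pools the two clusters' votes, which can dilute the share of a
cluster's consensus base; a change that increases that share is positive
and costs nothing, while a decrease — even if the base remains the
consensus — loses votes: the share drop expressed in the cluster's own
votes at that position. The identity change of a hypothetical merge is the
total votes lost by both clusters over their **common region** (the
positions both cover), divided by the total votes both hold there. A merge
is forbidden when this exceeds `max_id_change = 0.05`.

Two limiting cases show why the definition works. A read with error rate
`e` joining a deep same-haplotype cluster changes the cluster's shares only
marginally, and its own losses are weighted by its own (small) vote mass,
so the change is far below the threshold and the read is absorbed. Two
internally consistent clusters that disagree at a fraction `d` of their
shared positions each lose about half their votes at those positions, so
the change is about `d/2`: with the default threshold, clusters
representing haplotypes that differ at more than ~10% of their shared
heterozygous sites are kept apart. The defaults
(`S = 0.01, O = 0.1, L = 0, ID = 0.05`) follow the method's published
parameter sweep; only `ID` should normally need tuning — lower if small
errors are being read as alternate haplotypes, higher if true haplotypes
fragment.

Clusters never merge across reference chromosomes. The loop ends when no
allowed pair passes the identity gate; clusters with fewer than
`min_cluster_reads` (`L`, default 0) members are then dropped. Pair scores
are cached and only pairs involving a newly merged cluster are rescored —
by construction identical to rescoring everything each step, a contract the
test suite enforces against an independent exhaustive re-scoring oracle on
hundreds of small instances.

## Split-read stitching

Reads whose alignment breaks into distant segments (split reads) often mark
structural variants, and SVs are a principal cause of haplotig breaks — but
trusting split alignments wholesale produces chimeras. The compromise is a
second pass: after a first pass on the ordinary reads, take the first and
last `edge_size = 10` covered positions of every cluster
(`find_edge_snps()`), restrict each split read to calls on those edge SNPs
(`restrict_split_reads()`, segments keeping their original weights), and
re-run the engine with these restricted reads included. Same-chromosome
segments of one underlying read re-enter as a single call sequence — only
as one read can they connect the two haplotig edges they touch. Cross-
chromosome merging remains forbidden, so split reads can only improve
contiguity within a chromosome. With no split reads the second pass is
skipped and the result is bitwise identical to one pass. The paper-scale
extent of an "edge" is not quantified anywhere; `edge_size = 10` is this
package's convention, chosen to match the minimal informative overlap.

## Automated cleaning

Raw results are cleaned in three steps (`clean_haplotigs()`):

1. **Discordance-gated merging.** A cluster's discordance is the fraction
   of member calls disagreeing with its consensus (the summed minor allele
   frequencies). The mean discordance over all raw clusters is fixed once
   as a threshold; then the overlapping pair whose hypothetical merged
   discordance is lowest is merged, repeatedly, while that value stays
   below the threshold. Merge order (lowest merged discordance first) is
   this package's convention; the gate itself is the method's.
2. **Low-coverage filtering.** Clusters are sorted by total member-read
   calls and removed greedily from the smallest while the cumulative
   removed coverage stays within `filter_fraction = 0.01` of the total
   (a cumulative budget, never emptying the set entirely).
3. **Gap filling.** Per chromosome, each haplotig counts as 1X over its
   span in heterozygous-position coordinates; the mean multiplicity,
   rounded half-up, gives the expected haplotig count `n` (2.6 rounds to
   3). A region covered by fewer than `n` haplotigs usually means one
   haplotype is present in two or more copies there and their reads were
   (correctly) clustered together; the most read-covered cluster in the
   region donates a seeded random half of its region-overlapping reads to
   a new haplotig. Only regions of at least `min_region = 10` heterozygous
   positions qualify: a duplicated block shorter than the minimal
   informative overlap cannot be phased on its own, and the few-position
   dips that span jitter leaves near chromosome ends are not gaps. The
   target `n` is fixed once per chromosome before any split — recomputing
   it after each fill would raise the mean and chase its own tail.

Steps 1 and 3 conserve the read multiset; step 2 removes reads only with
their whole cluster. Gap filling should be disabled (`gap_fill = FALSE`)
for genomes with extensive hemizygosity or reference bias, where the
multiplicity profile is not informative.

## Evaluation

With a truth set (`haplotype`, `chromosome`, `position`, `base`), each
haplotig is assigned to the haplotype it matches at the most consensus
positions (ties: match fraction, then lexicographic name; zero-overlap
haplotigs are `"unknown"` and excluded). For every (haplotype, position)
pair: **TP** when an assigned haplotig calls the correct base; **FN** when
no assigned haplotig covers the position; **FP** counts haplotig consensus
positions where no (possibly tied) base matches the assigned haplotype's
truth — a tied position counts once. Rates share the denominator
`TP + FP + FN` so accuracy + error + missing = 100 exactly; alternative
denominators would break that identity and are deliberately not offered.
Switch-error rate is deliberately omitted: with clusters that either are or
are not a haplotype, raw accuracy and haplotigs-per-haplotype answer the
useful questions directly. Contiguity is summarised as haplotigs per
haplotype (cluster count over ploidy) and per-chromosome L90 — the minimal
number of assigned haplotigs (greedy set cover) covering at least 90% of a
haplotype's truth SNPs.

Two truth-free diagnostics mirror what one would do with a real sample:
windowed member-read depth per haplotig (`coverage_profile()`, default
5-kb windows) — equal depths mean a well-separated region, a 2:1 ratio
flags a haplotype present twice — and the in-cluster allele frequency
distribution (`allele_frequency_distribution()`, positions with at least
20 member reads): a pure cluster concentrates near `1 - e`, while a
chimera of two equally covered haplotypes is enriched near 0.5. The
chimera flag (more than 20% of qualifying positions with major-allele
frequency in [0.3, 0.7]) is a screening convention, not a test.

## The simulator, and what passing tests do not show

`simulate_polyploid()` emulates the method's virtual-polyploid validation
design directly in reduced-read space: `k` haplotypes over shared
chromosomes; heterozygous sites sampled uniformly at rate `h`; at each
site either a two-group allele split (probability `p_shared = 0.5`) or a
private allele — shared alleles are what makes polyploid phasing hard, and
virtual polyploids built from related strains have many; reads with
uniform random starts (clipped at both chromosome ends so coverage is
uniform), truncated-normal lengths, and substitution errors at
heterozygous positions with probability `e`; optionally a fraction of
split reads whose second segment lands at an independent position. The
defaults are the package's standard validation condition: a tetraploid at
0.5% heterozygosity, 20X per haplotype, 20 ± 5 kb reads (a typical
nanopore length scale), 10% error, two 200-kb chromosomes — sized so a
full five-seed validation runs in minutes on one CPU.

The simulator does *not* model uneven or GC-biased coverage, homopolymer
or quality-correlated errors, mapping ambiguity, reference bias, or real
structural variation: simulated phasings come out markedly more contiguous
(about 1.4 raw haplotigs per chromosome per haplotype) than published
real-data results (2.4–4), so the raw results sit near the contiguity
floor and the cleaning procedure's measured gains here are conservative
relative to real data. `p_shared` is a stand-in knob for real strain
relatedness, not a claim of equivalence.

## Numerical conventions and degenerate inputs

- Coordinates are 1-based throughout (VCF convention); spans are inclusive.
- Ambiguous bases (N) and deleted/soft-clipped positions are no-calls.
- All vote weights are integers, so tallies and similarities are exact;
  the identity change is a sum of small rationals, and its comparison with
  the threshold uses an absolute epsilon of 1e-9 so a value algebraically
  equal to the threshold does not depend on summation order.
- Exact ties (pair selection, haplotig assignment) are broken by
  documented deterministic keys, with a seeded random draw only for fully
  tied pair selection; identical inputs and seed give byte-identical
  outputs.
- Empty inputs return empty results, never errors; a single cluster is
  never removed by the coverage filter; a donor with fewer than two reads
  in a gap region is never split.
- Multiallelic VCF records contribute a position when any single-base
  allele satisfies the selection mode; INDEL records never do.

## Known limitations

- The heterozygous-position set bounds what can be phased: SNPs the
  variant caller missed are simply absent (though they remain recoverable
  from the per-haplotig FASTQ output).
- INDELs are not phased, by design.
- Split reads are used only to stitch same-chromosome haplotigs, not to
  call or phase structural variants.
- Memory scales with reads x positions per chromosome; for very large or
  dense genomes, run chromosomes separately (`chromosome` filter) and
  consider down-sampling the variant set (`max_het_fraction`) — phasing
  quality at 0.5% heterozygosity is comparable to 1% at half the cost.
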
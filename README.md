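# haplotigr

Ploidy-agnostic phasing of long reads into haplotigs.

A polyploid genome carries several homologous copies of each chromosome,
and short-read variant calling only says *that* a site is heterozygous —
not which copy carries which base. `haplotigr` assigns heterozygous SNPs to
the DNA copies they co-occur on by iteratively clustering long reads that
have been reduced to their base calls at known heterozygous positions. It
is **ploidy agnostic**: the number of genome copies is neither supplied nor
estimated — the clusters that survive are the haplotypes the data support.

The package is for researchers phasing polyploid (or aneuploid, or
diploid) genomes from noisy long reads (nanopore-scale error rates) given
a reference genome, a heterozygous-SNP call set, and long-read alignments.

## The method in brief

Every read becomes a sparse vector of `(position, base)` calls at the
heterozygous sites. Similarity between two call sequences is

    S = N_shared_variants / N_shared_positions

and the engine greedily merges the most similar pair of clusters, subject
to overlap gates (at least 10 shared positions; at least fraction
`O = 0.1` of the smaller sequence's positions, waived above 100 shared).
Each cluster's consensus is a per-position weighted vote: a read's vote is
its **context coverage** — how often the whole dataset saw that call
flanked by the same two heterozygous calls on each side — so sequencing
errors, which live in the wrong context, vote with weight ~1. Merging is
vetoed by **cluster identity maintenance**: if pooling two clusters' votes
would erode the support share of their consensus bases by more than
`ID = 0.05` of the votes in their common region, they are declared
different haplotypes and kept apart. The loop ends when no allowed merge
remains.

Around the engine: a split-read stitching pass that reconnects haplotigs
broken by structural variants, a three-step automated cleaning procedure
(discordance-gated merging, low-coverage filtering, gap filling),
truth-based accuracy/contiguity metrics (`accuracy = TP/(TP+FP+FN)`,
haplotigs per haplotype, L90), truth-free diagnostics (windowed coverage
profiles, in-cluster allele frequencies), and a seeded synthetic polyploid
simulator so the whole pipeline is testable with no external data. See
`vignette("phasing-model")` for the full model, assumptions, and
limitations.

## Worked example

Simulate a virtual triploid (100-kb chromosome, 0.5% heterozygosity, 15X
per haplotype, 10% read error), phase it, and score the result against the
known haplotypes:

```r
library(haplotigr)

cfg <- sim_config(ploidy = 3, n_chromosomes = 1, chromosome_length = 100000,
                  coverage = 15, error_rate = 0.1, seed = 42)
sim <- simulate_polyploid(cfg)

reads <- remove_subset_reads(sim$reads)
ctx   <- build_context_table(reads)
reads <- weight_reads(reads, ctx)

haplotigs <- run_phasing(reads, ctx, phase_params(rng_seed = 42))
metrics   <- compute_metrics(haplotigs,
                             assign_haplotigs(haplotigs, sim$truth),
                             sim$truth)
print(metrics)
#> <metrics_report>
#>   accuracy 99.5%  error 0.5%  missing 0.0%  (TP 1499, FP 7, FN 0)
#>   haplotigs per haplotype: 2.00 genome-wide, 2.00 per chromosome
#>   L90 = 1 for 3 of 3 (chromosome, haplotype) pairs; 0 unassignable haplotig(s)
```

Of the 1506 evaluated haplotype-SNP calls, 1499 were attributed to the
correct haplotype (TP), 7 consensus calls disagreed with their haplotig's
haplotype (FP), and no heterozygous SNP was left unphased (FN); the three
haplotypes came out in six haplotigs, each haplotype covered ≥90% by a
single haplotig (L90 = 1). Automated cleaning then merges the fragments:

```r
cleaned <- clean_haplotigs(haplotigs, reads, seed = 43)
print(compute_metrics(cleaned, assign_haplotigs(cleaned, sim$truth), sim$truth))
#> <metrics_report>
#>   accuracy 99.9%  error 0.1%  missing 0.0%  (TP 1499, FP 1, FN 0)
#>   haplotigs per haplotype: 1.00 genome-wide, 1.00 per chromosome
#>   L90 = 1 for 3 of 3 (chromosome, haplotype) pairs; 0 unassignable haplotig(s)
```

— one haplotig per haplotype, the ideal result.

With real data the entry point is `run_pipeline()` (or the command-line
wrapper in `inst/cli/haplotigr`): heterozygous positions from a VCF
(`parse_het_positions()`), reads from a SAM/BAM (`reduce_alignments()`),
per-haplotig consensus TSVs and FASTQs out
(`write_haplotig_outputs()`).

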
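---
title: "Methods: chromosome assignment and misassembly detection from single-chromosome sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosome assignment and misassembly detection from single-chromosome sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromseq)
```

## The problem

Sequencing DNA amplified from a single physically isolated chromosome
(flow-sorted or microdissected) yields a read library that is *mostly* — but
not entirely — specific to that chromosome. Mapped onto a reference assembly,
such a library answers two questions that neither cytogenetics nor a bare
assembly answers alone:

1. **Which unplaced scaffolds belong to the sampled chromosome?** Scaffolds
   that attract far more chromosome-specific reads than a uniform background
   would deliver are part of the chromosome.
2. **Where does the assembly disagree with the sampled genome?** A dense
   block of chromosome-specific reads inside a *different* assembled
   chromosome indicates either a real translocation or an assembly join
   error. If the block's margins coincide with contig ends — the places
   where an assembly is stitched together — the join-error explanation is
   favoured.

The practical obstacles are properties of the wet lab: whole-genome
amplification (DOP-PCR/MDA) produces extreme PCR duplication and leaves
degenerate primer tails on reads; chromosome isolation is imperfect, so a
background of whole-genome reads contaminates the library; and the sampled
individual diverges from the reference. The pipeline deals with each stage
explicitly and keeps a count ledger across stages.

## Pipeline model

Reads are trimmed (5'-anchored IUPAC primer match, mismatches configurable),
aligned externally (or ingested from SAM/BAM), deduplicated by mapping
coordinate, filtered, and collapsed into **positions** — maximal unions of
transitively overlapping alignment intervals. Positions, not reads, are the
unit of all statistics: amplification artefacts inflate read counts at a
locus but add nothing to the set of distinct covered intervals.

Two rules follow from the duplicate structure of WGA libraries:

* **Deduplication** keys on `(reference, 5' mapping start, strand)` — the
  coordinate convention of Picard-style duplicate marking. Among key-sharing
  records the highest-MAPQ one is kept, ties broken by read name so that the
  outcome is order-independent.
* **Overlap means shared bases.** Book-ended intervals (`[0,50)`, `[50,80)`)
  are not merged by default, since half-open adjacency is not overlap; a
  `merge_adjacent` switch provides coverage-style fusing. The test suite
  checks both conventions against independent per-base painting oracles (at
  half-base resolution for the strict case).

Filters default to MAPQ ≥ 20 and aligned query length ≥ 20 bp, both
inclusive; "alignment length" is CIGAR-derived aligned *query* bases
(`M/=/X/I`, soft clips excluded), the stricter of the two possible readings.
MAPQ 255 ("unavailable") fails any threshold. Divergence is summarised as
the per-read mean of `NM / aligned_length`; the per-read mean (rather than a
ratio of sums) is used because an "average divergence" over a library of
near-constant-length reads is most naturally a read-level average.

## Enrichment statistics

Under a uniform background, the number of positions falling into a span of
$s$ bp out of a mappable genome of $G$ bp is
$X \sim \mathrm{Binomial}(n, s/G)$ with $n$ the genome-wide position count.
The enrichment p-value is the exact upper tail $P(X \ge k)$ (computed via
`pbinom`; the suite verifies agreement with explicit summation to $10^{-9}$
relative error for $n \le 1000$). The mappable length excludes runs of N by
default: reads cannot map into assembly gaps, and counting gap bases into
$G$ would overstate significance for every real sequence.

A scaffold is **assigned** to the sampled chromosome iff it has at least 15
positions *and* enrichment p < 0.05 — a conjunction, applied to raw
p-values by default. Benjamini–Hochberg adjustment across the scaffold set
is available behind a flag; raw p-values are the default because the
assignment rule is conventionally stated, and calibrated, as a plain
per-scaffold test. The mean inter-position distance (`pd`) is reported
alongside as the classical ranking statistic for chromosome membership.

**Region detection** is single-linkage distance clustering: consecutive
positions on a reference chain while their start-to-start gap is at most
`max_gap`; chains of at least 15 positions become region calls with span,
density, `pd` and the same exact binomial p-value. Circular binary
segmentation and per-kb maximum-likelihood segmentation are deliberately out
of scope; distance clustering is the one method implemented.

**Misassembly classification**: a detected region is labelled
`assembly_discordant` when *both* margins lie within a tolerance of a contig
boundary (from an AGP contig map, or maximal non-N runs of the FASTA when no
AGP is given), `putative_translocation` when neither does, `indeterminate`
otherwise. Both margins are required because the argument for an assembly
discontinuity rests on both edges of the block being stitch points. The
tolerance defaults to the region-detection `max_gap`, since detected margins
cannot be located more precisely than the chaining distance. Labels are
exhaustive, mutually exclusive, and monotone in the tolerance. Cross-species
homology evidence is not interpreted; a hook reports overlap fractions with
a user-supplied homology BED and stops there.

## Choosing `max_gap`

The clustering distance is the one genuinely free parameter. Two spacings
bracket it: the expected start-to-start spacing of positions *inside* target
material ($s_d$) and the spacing of background positions ($s_b$). A chain
through a dense region of $N$ positions stays unbroken with probability
$\approx 1 - N e^{-\text{max\_gap}/s_d}$, so `max_gap` must sit an order of
magnitude above $s_d$; conversely background chains of length 15 arise at
rate $\approx n_b (1 - e^{-\text{max\_gap}/s_b})^{14}$, and detected margins
random-walk outward by steps of background positions closer than `max_gap`,
so `max_gap` must stay well below $s_b$.

Under the simulator's default conditions (below), $s_d \approx 270$ bp and
$s_b \approx 9$ kb, and the default `max_gap = 1700` bp satisfies both
constraints with break probability $\sim 10^{-3}$ per run and margin drift
beyond `read_length + max_gap` at $\sim 10^{-2}$ per run. The `"auto"` mode
instead sets `max_gap` to a quarter of the *genome-wide average* spacing
(total reference length / total positions / 4); that rule is appropriate
when, as on a genome-scale reference, the average spacing is dominated by
background. At desk scale the sampled chromosome is a larger share of the
reference, the average spacing sits close to $s_d$ itself, and the auto rule
would shatter dense regions — hence a numeric default, with `"auto"`
available for genome-scale data.

## What the simulator emulates

`sim_config()` / `build_assembly()` / `simulate_reads()` generate a
reference with unplaced scaffolds, a planted misassembly, and reads with the
library structure described above. Defaults are the package's study
conditions, fixed once:

| Parameter | Default | Meaning |
|---|---|---|
| chromosomes | 30, 16, 1 Mb | host, filler, target (`chr3`) |
| misassembly | 1 Mb at chr1:14 Mb | target material inside the host, margins on contig boundaries |
| scaffolds | 84 of 10–25 kb | 34 target, 50 decoys |
| purity | 0.8 | fraction of reads from target material |
| duplicate_rate | 0.7 | verbatim copies of earlier reads |
| error_rate | 0.02 | per-base substitutions + indels |
| n_reads / read_length | 100,000 / 100 bp | single-end |
| primer | `CCGACTCGAGNNNNNNATGTGG` on 50% of reads | degenerate DOP tail, 5' |

Purity 0.8, duplicates 0.7 and divergence 0.02 mirror the published
chromosome-6 experiment this package reproduces at desk scale; the genome
geometry keeps target material at ~5% of the reference — the regime the
method is actually used in, and the regime in which the `max_gap` analysis
above holds. The target chromosome, scaffold sizes and read count are desk-
scale choices so that a full simulate-plus-analyse cycle runs in tens of
seconds; the suite runs twenty seeded replicates inside its time budget.

Deliberate simplifications: contamination is uniform over the assembly
(isolation impurity is diffuse chromosome fragmentation, but real
backgrounds also carry mapping artefacts); duplicates are exact copies (no
polymerase errors between amplification rounds); error placement is uniform
with a flat 70/15/15 substitution/insertion/deletion split and flat base
qualities; there is no GC, chromatin or amplification-locus bias, and no
locus dropout, for which no quantitative model is published. MAPQ is not
modelled mechanistically: target-derived reads get 60, and a configurable
10% of background reads get MAPQ < 20 purely to exercise the filter.
Passing the planted-truth tests therefore demonstrates the statistical
machinery, not robustness to alignment artefacts on real repetitive genomes.

The misassembled segment is synthesised as unique target-labelled sequence
present only at its wrong location. A naive alternative — copying a block
that also remains on the target chromosome — would duplicate 1 Mb of
sequence genome-wide and confound any real aligner; a genuine misassembly is
sequence *missing* from its true chromosome and present elsewhere.

## Numerical and degenerate-input choices

Coordinates are 0-based half-open everywhere internally; SAM and AGP are
written 1-based per their standards, BED 0-based. All orderings use
locale-independent radix sorting, and re-running any stage on identical
inputs produces byte-identical files. Empty inputs degrade to empty results
(an empty FASTQ yields an all-zero ledger, exit 0); percentages render as
`"NA"` on zero denominators and are always recomputed from integer counts at
render time. p-values at exactly `alpha` are not significant; thresholds on
counts and lengths are inclusive. Duplicate ties are broken
lexicographically by read name. `n_total < k` and `span > G` are contract
errors, not silent clamps.

## Problem sizes in the test suite

Unit tests run on ~0.8 Mb assemblies with 200–8,000 reads; oracle-
equivalence tests cover 1,000 random merge instances of up to 10,000
intervals and 500 random binomial tails with $n \le 1000$; planted-truth
recovery runs the full default conditions (48.5 Mb, 100,000 reads) across
twenty seeds and asserts ≥95% recovery of eligible planted scaffolds, zero
decoy assignments in ≥19/20 runs, and detection plus correct labelling of
the planted region with margins within `read_length + max_gap` in ≥19/20
runs. The same conditions back `scripts/acceptance.R`.

## Limitations

* Scaffolds are assigned but not ordered or oriented; that requires mapping
  or proximity-ligation data, and the AGP the package writes says so
  (orientation `na`, unordered).
* One misassembled region per host chromosome is what the generator plants;
  the detector itself has no such limit.
* The binomial background assumes positions land independently; local
  repeat structure violates this on real genomes and inflates density in
  ways the simulator does not emulate.
* Paired-end logic, quality trimming, and de novo assembly of
  chromosome-specific reads are out of scope.
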
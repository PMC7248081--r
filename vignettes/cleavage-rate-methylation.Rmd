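---
title: "Inferring CpG-island methylation from DNA fragmentation bias"
author: "cleavescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring CpG-island methylation from DNA fragmentation bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleavescan)
```

## The idea

Mechanochemical DNA fragmentation during whole-genome-sequencing library
preparation (ultrasonic shearing, hydrodynamic forces) is not sequence
neutral: the sugar-phosphate backbone breaks more readily at some
dinucleotides than at others, and breaks at CpG occur markedly more often
when the cytosine is methylated — roughly 1.5x the unmethylated rate.
Because every aligned read's 5' end marks a fragmentation point, an
ordinary WGS BAM file is, implicitly, a genome-wide record of millions of
cleavage events. `cleavescan` turns that record into a methylation
readout: no bisulfite conversion, no extra experiment.

## The cleavage-rate statistic

For a dinucleotide class $XY$ the cleavage rate is

$$ r(XY) = \frac{n(XY)}{N \cdot p(XY)} $$

where

* $n(XY)$ — number of reads whose aligned 5'-end base is the $Y$ of an
  $XY$ pair in the reference (the pair at positions $i-1, i$ for a
  forward read starting at $i$);
* $N$ — total usable reads in the sample;
* $p(XY)$ — fraction of $XY$ among the overlapping dinucleotides of the
  200-bp genomic windows centered on the read starts, pooled over all
  windows.

$r = 1$ means breaks at $XY$ occur exactly as often as expected from
local sequence content; the local window (rather than whole-genome
composition) absorbs GC-dependent coverage and mappability bias around
the mapped positions.

When a bisulfite-derived methylation map is available, the CG class is
split by the status of its cytosine into **CmG** (methylated), **CuG**
(unmethylated) and **CxG** (undetermined), giving 18 classes in all
(15 non-CpG dinucleotides + 3 CpG variants). CxG breaks are counted and
reported for audit, but they are excluded from the background and from
$N$: undetermined CpGs are excluded from analysis, and folding them into
either determined class would blur exactly the contrast the method
exploits.

### Assumptions

* Break positions are informative about fragmentation chemistry, i.e.
  the library was fragmented mechanically (sonication / hydrodynamic
  shearing), not enzymatically.
* The reference genome matches the sample well enough that the base pair
  at a read start is the pair that actually broke; low-complexity and
  repetitive sequence is masked out because mis-mapping there corrupts
  the dinucleotide assignment.
* CpG methylation is treated as a strand-symmetric unit indexed by the
  forward-strand C; reads are taken from the forward strand in the
  default protocol (rate estimates are insensitive to the filtering
  strategy, and a reverse/both mode is available).

## From rates to methylation calls per island

Single-CpG status is far below the statistical resolution of this
signal; CpG methylation is stochastic and only the average methylation
of a CpG island is biologically meaningful. Islands are therefore scored
by the rate statistic restricted to the island: $n$ counts CG breaks
(any methylation status) whose dinucleotide lies inside the island, $p$
is the CG fraction among the island's own informative dinucleotides, and
$N$ stays sample-wide so scores are depth-comparable across samples. A
sample becomes a vector of island scores; a linear-kernel SVM over
z-scored island features separates tumor from normal, and accuracy is
estimated by balanced jack-knife (random equal-sized holdout per class,
repeated). Ranking islands by the absolute difference of class-mean
scores highlights where tumor methylation diverges most; the sign of the
difference separates hypo- from hypermethylation.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `half_width` | 100 bp | half of the background window; 100 gives the 200-bp window with 199 overlapping dinucleotide positions |
| `min_coverage` | 10 reads | bisulfite calls need coverage strictly greater than this |
| `concordance` | 0.9 | majority fraction strictly required for a METHYLATED / UNMETHYLATED call |
| `required_flag` / `excluded_flag` | 35 / 4 | SAM flag filter: paired + proper pair + mate reverse, mapped |
| `contigs` | autosomes 1–22 | sex chromosomes excluded |
| `min_cg` | 5 | minimum informative CG dinucleotides before an island is scored |
| `min_support` | 0 | minimum reads in an island before it is scored |
| `max_missing` | 0.2 | islands missing in a larger fraction of samples are dropped; remaining gaps are median-imputed |
| `cost` | 1 | SVM regularization constant (the e1071 default) |
| jack-knife | 100 rounds, holdout `max(1, floor(0.2 * smaller class))` per class | seeded, bit-reproducible |

Threshold semantics are deliberately literal: "more than 10 reads" is a
strict inequality, as is "more than 90%"; coverage exactly 10, or a
methylated fraction of exactly 0.9, yields UNKNOWN.

## Numerical and design choices

* **Coordinates.** Internally everything is 1-based closed, the
  Bioconductor convention, so `GRanges`/`Biostrings` operations need no
  shims. BED and the plain event-TSV dialect are 0-based on disk and
  converted on read; interval identifiers (`contig:start-end`) keep the
  original BED numbers so they stay stable across tools.
* **Window geometry.** The 200-bp window is centered: bases
  $[i-100,\, i+99]$ around a read start at $i$. Events whose window is
  truncated by a contig edge are excluded from both numerator and
  background, keeping the two drawn from the same event set.
* **Pooled background.** $p(XY)$ pools counts over all windows and then
  divides, rather than averaging per-window fractions; the two coincide
  for full unmasked windows, but pooling is robust when masking makes
  windows unequal. The per-window mean is available via
  `p_mode = "per_window_mean"` for sensitivity analysis.
* **Masking at dinucleotide resolution.** A dinucleotide overlapping any
  masked base is uninformative for both $n$ and $p$ — numerator and
  denominator are always treated identically.
* **Decision ties.** A decision value of exactly zero predicts NORMAL
  (documented, arbitrary, stable). Class balancing before training is by
  seeded down-sampling of the larger class.
* **Chance-level checks.** When verifying that a label-permuted cohort
  evaluates at chance, the binomial interval around 50% is taken at
  $n$ = samples per class, not at the number of pooled holdout
  predictions: repeated predictions of the same sample across jack-knife
  rounds are strongly correlated and do not add independent information.
* **Degenerate inputs.** A sample whose events are all discarded or
  truncated raises an explicit error rather than returning a zero table;
  islands with no usable CG content report a reason code (`no_cg`,
  `low_cg`, `low_support`) distinct from a legitimate zero rate.

## The simulator, and what passing tests do (and do not) show

`simulate_genome` / `simulate_breaks` / `simulate_cohort` generate the
package's ground truth. The generative model is the estimator's inverse:
every dinucleotide start position carries a weight given by its class,
and read starts are drawn independently with probability proportional to
that weight, so estimated rate ratios converge to weight ratios. The
default model gives every class weight 1 with CmG at 1.5, mirroring the
observed methylated-CpG excess.

Default study conditions: a 100-kb genome of uniform base composition;
20 non-overlapping 500-bp islands (one per equal-width block at a random
offset, 200 bp clear of contig ends); island CG enrichment implemented
as a 4x boost of $P(G \mid \text{previous } C)$ in a first-order Markov
chain, which yields a realized CG-density enrichment of about 2.3x and
an island CpG fraction near 14% — in the range of real CpG islands (a
boost of 1 reduces exactly to i.i.d. sequence, which is how the
enrichment test is calibrated). Island CpGs are unmethylated and
background CpGs methylated, with 5% status noise in each direction and
5% undetermined. Cohorts default to 20 tumor + 20 normal samples at
2e5 reads each; the tumor effect doubles the break weight of CG
dinucleotides inside 3 designated islands. These sizes were chosen so
the complete validation suite runs in well under a minute per component
at 1e6-event precision.

What the simulator does **not** emulate: fragment-length distributions
and two-ended fragments (only 5'-start counts enter the statistic),
sequencing error, coverage irregularity, mappability structure, or
chromatin-driven fragmentation signals. Passing the recovery and
classification tests therefore shows the estimator and classifier are
correct *given the generative model*; it does not by itself demonstrate
performance on real tumor cohorts, where island coverage is the known
practical bottleneck.

## Replication on public data (not desk-scale)

The original observations — r(CmG) the largest of all 18 classes at
roughly 1.5x r(CuG), and ~84% tumor/normal accuracy — were computed on
1000 Genomes phase-3 BAMs (Covaris-sheared), NGSmethDB lymphoblastoid
methylation maps, and controlled-access EGA/ICGC cancer cohorts. Those
inputs cannot ship with a package, but the protocol maps directly onto
the CLI:

1. `samtools view`-compatible filtering is the default policy
   (`-f 35 -F 4`, autosomes only); run `cleavescan rates` per BAM with
   the GRCh37 FASTA, a RepeatMasker-derived mask BED, and the NGSmethDB
   calls as the methylation TSV; confirm r(CmG)/r(CuG) ≈ 1.5.
2. Run `cleavescan islands` per sample with a CpG-island BED, then
   `matrix`, `evaluate`, and `rank` on the pooled score tables. Only
   island-score TSVs need to leave the secure environment — no
   sequence-level data.

## Known limitations

* Requires mechanical fragmentation; PCR-free enzymatic libraries carry
  a different (and differently informative) bias.
* Methylation maps index forward-strand C positions; strand-merging of
  bisulfite calls is left to input preparation.
* Island scores need coverage: sparse islands fall back to missingness
  handling, and cohorts with systematically poor island coverage (the
  known worst case for this method) will classify poorly.
* The linear SVM is deliberately simple; no probability calibration,
  feature selection, or nonlinear kernels.
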
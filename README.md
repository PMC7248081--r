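# cleavescan

Infer CpG-island methylation — and classify tumor vs. normal samples —
from nothing but the fragmentation bias already present in standard
whole-genome sequencing data.

Mechanical DNA fragmentation (ultrasonic / hydrodynamic shearing) breaks
the sugar-phosphate backbone preferentially at certain dinucleotides,
and breaks at CpG occur about 1.5× more often when the cytosine is
methylated. Every aligned read's 5′ end marks one fragmentation event,
so a WGS BAM is an implicit genome-wide cleavage assay. `cleavescan`
quantifies this with the cleavage rate

```
r(XY) = n(XY) / (N · p(XY))
```

where `n(XY)` counts reads whose 5′-end base is the `Y` of an `XY` pair
in the reference, `N` is the usable read total, and `p(XY)` is the
fraction of `XY` among the dinucleotides of the 200-bp genomic windows
around the read starts (normalizing away local composition and mapping
bias; `r = 1` means no preference). With a bisulfite-derived methylation
map the CG class splits into CmG / CuG / CxG (methylated / unmethylated /
undetermined cytosine), 18 classes in all. CpG islands are then scored
by the island-restricted CpG cleavage rate, sample × island score
matrices feed a linear-kernel SVM (tumor vs. normal), accuracy is
estimated by balanced jack-knife, and islands are ranked by class-mean
difference to locate differential methylation.

Intended users: genomics groups who have WGS alignments (including
controlled-access cancer cohorts) and want a methylation readout or a
tumor/normal screen without bisulfite sequencing. A full fragmentation
simulator with known per-class break weights is included, so every stage
is testable against ground truth at desk scale.

## Worked example

Simulate a genome with CpG islands and a methylation map, draw 5×10⁵
breaks under a model in which methylated CpG is 1.5× more fragile, and
estimate the rates:

```r
library(cleavescan)

spec  <- cohort_spec(seed = 1)            # 100-kb genome, 20 islands
sim   <- simulate_genome(spec)
model <- fragmentation_model(n_reads = 5e5, seed = 2)  # CmG weight 1.5
ev    <- simulate_breaks(sim$genome, sim$methylmap, model)
compute_cleavage_rates(sim$genome, ev, sim$methylmap)
#> cleavage_rate_table (annotated mode): N = 497337 usable events, half-width 100 bp
#>   windows 499011 | truncated 989 | discarded 0
#>  class     n       p      r
#>     AA 29523 0.06102 0.9728
#>     AC 30286 0.06231 0.9773
#>    ...
#>    CmG 37287 0.05201 1.4410
#>    CuG  6874 0.01426 0.9690
#>    CxG  1674 0.00000     NA
#>    ...
```

The methylated-CpG rate stands out (r(CmG)/r(CuG) ≈ 1.49, recovering the
1.5× ground truth); all other classes sit at their common baseline. CxG
(undetermined status) is audited but carries no rate — those CpGs are
excluded from analysis.

A full cohort — 20 tumor + 20 normal samples, where tumor samples have
the CG break weight doubled inside 3 affected islands — classifies
perfectly and the affected islands top the ranking:

```r
cohort <- simulate_cohort(spec)
mat    <- build_matrix(cohort_island_scores(cohort), cohort$labels)
jackknife_evaluate(mat, rounds = 50, seed = 3)
#> evaluation_report: 50 round(s), 4 per class held out, seed 3
#>   TP 100.0%  TN 100.0%  FP 0.0%  FN 0.0%

rank_islands(mat, k = 3)
#>          island_id normal_mean  tumor_mean  difference
#> 1 sim1:90267-90767 0.004780860 0.009780033 0.004999173
#> 2 sim1:71367-71867 0.005002656 0.009960112 0.004957457
#> 3 sim1:26037-26537 0.004843034 0.009728791 0.004885757

cohort$ground_truth$affected_islands
#> [1] "sim1:26037-26537" "sim1:71367-71867" "sim1:90267-90767"
```

Positive differences mean higher tumor cleavage in those islands; the
sign distinguishes hypo- from hypermethylation shifts.

## Command line

Real data enters through the same stages via the launcher in
`inst/scripts/cleavescan`:

```sh
cleavescan rates    --genome ref.fa --events sample.bam \
                    --methylation calls.tsv --mask repeatmasker.bed --out rates/
cleavescan islands  --genome ref.fa --events sample.bam --islands cgi.bed --out isl_s1/
cleavescan matrix   --scores s1=isl_s1/island_scores.tsv,s2=... --labels labels.tsv --out mat/
cleavescan evaluate --matrix mat/matrix.tsv --labels mat/labels.tsv --seed 1 --out eval/
cleavescan rank     --matrix mat/matrix.tsv --labels mat/labels.tsv --k 10 --out rank/
```

The default alignment filter reproduces `samtools view -f 35 -F 4` on
autosomes (forward-strand, properly paired reads); every run writes a
resolved `config.json` beside its outputs. Only island-score TSVs are
needed beyond the `islands` stage, which keeps sequence-level data
inside secure environments.

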
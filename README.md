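# sagmag

Tools for comparing bacterial genomes recovered by single-cell sequencing
(**SAGs**, single-amplified genomes) with genomes recovered by metagenome
binning (**MAGs**, metagenome-assembled genomes), for microbial ecologists
who want to know how much each method misses and what its artifacts look
like.

The two recovery routes fail differently. MDA-based single-cell
amplification leaves genome regions uncovered, forms inversion-chimera
reads, and picks up foreign DNA; metagenome binning only considers contigs
≥ 1 kb and sometimes places a contig in the wrong bin. `sagmag` implements
the statistics that quantify these errors, plus a synthetic community
generator that plants every artifact class with a truth manifest, so the
whole pipeline can be validated end to end:

* **Genome clustering** — MinHash sketches over canonical 15-mers; Mash
  distance `d = -(1/k)·log(2j/(1+j))` from the merged-bottom-sketch Jaccard
  estimate `j`; single-linkage clusters at `d < 0.1`.
* **Read attribution** — each SAG read lands in exactly one category:
  in the matched MAG, on a long (≥ 1 kb) contig binned elsewhere, on a
  short unbinned contig, or unmapped. The **false-negative binning rate**
  is covered bases on long non-MAG contigs over covered bases on all
  binned contigs.
* **Chimera screen** — candidate = alignment with ≥ 20 soft-clipped bases,
  aligned region ≥ half the read, ≤ 2 mismatches; candidates are pooled
  across samples and rescued if the read maps non-chimerically (≥ 95%
  aligned, < 5 mismatches) anywhere.
* **Contamination screen** — canonical tetranucleotide PCA of SAG contigs,
  split at 5% aligned fraction to the MAG; suspects are flagged on robust
  composition outlierness or metagenome coverage < 10% of the median.
* **Single-copy-gene QC** — completeness/redundancy over a 139-marker set,
  the 30-of-36 bin approval rule, and exact duplicated-element detection.
* **Functional profiles** — Poisson log-likelihood-ratio dissimilarity
  between COG-category count profiles and seeded permutation ANOSIM
  (99,999 permutations).

## Worked example

The `analysis/` directory is a numbered workflow over the package. Stage 1
simulates the community and writes plain-text inputs (FASTA, SAM, TSV)
under `results/data/`; stages 2–7 each read those files, run one module,
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_cluster_genomes.R
Rscript analysis/03_read_attribution.R
# ... through 07
```

Output from a full run (seed 42):

```
Simulated 5 genomes (2 foreign), 377 metagenome contigs (15 misbinned,
47 short), 3 SAGs with 20,000 reads each.

3 of 3 SAGs fell into 3 matched clusters; within-pair identity
averaged 99.48% with 81.9% of SAG and 74.5% of MAG bases aligning.

Median read shares: 77.3% in the matched MAG, 3.77% on long non-MAG
contigs, 0.9% on short (unbinned) contigs, 15.6% unmapped.
False-negative binning rate: mean 5.54% of covered bases.

Chimeric reads: 1.91% of reads on average (recall 0.96, precision 1.00
vs the planted truth). 93.8% of chimeric reads align to SAG contigs with
>20 soft-clipped bases, vs 0.00% of other reads; 0.7% sit over a contig
edge.

Flagged 15 of 15 planted contaminant contigs across 3 SAGs
(recall 1.00, precision 1.00).

Completeness: SAGs average 81.5%, MAGs 89.9%; 5 of 8 genomes pass the
30-of-36 single-copy-gene approval rule.

Functional profiles group strongly by genome cluster (ANOSIM R = 1.00,
p = 0.067) but not by recovery method (R = -0.37, p = 1).
```

Reading the numbers: the planted misbinning rate (5% of long contigs)
comes back as a ~5% false-negative binning rate; the planted 2% inversion
chimeras are recovered at 1.9% with near-perfect precision, and almost all
of them — but almost no other reads — align soft-clipped against the SAG's
own contigs; the contamination screen isolates exactly the foreign
low-coverage contigs; and SAG/MAG pairs keep their functional profiles
(cluster structure, not recovery method, explains the dissimilarities).
Most SAGs fail the 30-of-36 approval rule because 20% amplification
dropout leaves an expected 28.8 of 36 markers — the rule is calibrated for
MAGs.

The same stages are callable programmatically:

```r
library(sagmag)
cfg <- pipeline_config(sim = sim_config(seed = 42))
summary <- run_pipeline(cfg, "results/run")   # writes TSVs + summary.json
```

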
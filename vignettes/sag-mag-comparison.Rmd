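---
title: "Comparing single-amplified and metagenome-assembled genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing single-amplified and metagenome-assembled genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Single-amplified genomes (SAGs) and metagenome-assembled genomes (MAGs) are
the two standard culture-free routes to a bacterial genome, and each carries
a characteristic error profile. SAGs start from one cell: multiple
displacement amplification (MDA) produces highly uneven coverage, leaves
genome regions entirely unamplified (dropout), creates chimeric molecules —
mainly inversions — and is prone to contamination from reagents or free
environmental DNA. MAGs start from a community: only contigs long enough to
carry a stable composition/coverage signal (here, ≥ 1 kb) enter the binning,
and contigs can be assigned to the wrong bin. `sagmag` implements the
computational machinery for confronting the two, and a synthetic community
generator that plants every one of these artifact classes with a full truth
manifest, so each statistic can be validated against a known answer.

# The pipeline

`run_pipeline()` chains the stages in the order a real comparison would run
them:

1. **Genome clustering.** Every assembly is reduced to a MinHash sketch: the
   bottom-`s` 64-bit hashes over its distinct canonical 15-mers (default
   `s` = 100,000). For two sketches the Jaccard index `j` is estimated from
   the merged bottom sketch and converted to a Mash distance
   `d = -(1/k) log(2j/(1+j))`, capped at 1 (disjoint sketches report the
   cap). SAGs and MAGs are then joined by single-linkage clustering at
   `d < 0.1` (roughly 90% nucleotide identity); a *matched cluster* contains
   at least one genome from each method.
2. **Identity and aligned fraction.** Within matched pairs, alignment blocks
   (from the generator's truth, or parsed from a coords-style TSV when an
   external whole-genome aligner is used) are summarized as length-weighted
   mean/SD percent identity, and per-side aligned fractions via interval
   unions, overlaps counted once.
3. **Read attribution.** Every primary, non-duplicate SAG read lands in
   exactly one category: `IN_MAG` (contig of the matched MAG),
   `LONG_NON_MAG` (≥ 1 kb contig binned elsewhere), `SHORT` (< 1 kb,
   unbinned), or `UNMAPPED`. The false-negative binning rate is the number
   of bases covered by SAG reads on long non-MAG contigs divided by covered
   bases on all binned contigs. An alternative denominator (in-MAG covered
   bases only) is available as `denominator = "in_mag"`; the main-text
   definition is the default.
4. **Chimera screen.** An alignment is a chimera candidate when it carries
   ≥ 20 soft-clipped bases, its aligned region spans at least half the read,
   and it has ≤ 2 mismatches; candidates from all samples are pooled,
   deduplicated, and any read that also maps non-chimerically somewhere
   (≥ 95% of the read aligned, < 5 mismatches) is rescued. The SAG-vs-self
   record set takes part in the rescue pass: a read that merely straddles a
   metagenome contig boundary is soft-clipped there but maps full-length to
   its own assembly, which is exactly the non-chimeric mapping the filter
   looks for.
5. **Contamination screen.** All SAG contigs are profiled by canonical
   tetranucleotide frequencies (136 classes, strand-collapsed) and projected
   onto the top two principal components; contigs aligning < 5% of their
   length to the matched MAG(s) form the suspect set. A suspect contig is
   flagged when it is a robust composition outlier (median/MAD-standardized
   squared PC distance from the aligning set's center beyond the
   chi-square(2) 0.975 quantile) or has metagenome coverage below 10% of the
   median. Coverage assumes 100-base metagenome reads and is also reported
   capped at 3x the median, the plotting convention for these screens.
6. **Single-copy-gene QC.** Completeness is the percentage of a declared
   marker set present at least once, redundancy the percentage present more
   than once (139-marker set by default). Bins are approved when ≥ 30 of the
   36-marker set are present with at most 2 markers in more than one copy.
   Erroneously duplicated elements are maximal exact repeats ≥ 100 bases
   shared between distinct contigs ≥ 1 kb, found by shared-k-mer anchoring
   with maximal extension.
7. **Functional profiles.** COG-category counts are compared by the Poisson
   log-likelihood-ratio dissimilarity (pairwise size factors
   `s_i = N_i / mean(N_i, N_j)`, shared rate
   `(X_i + X_j)/(s_i + s_j)`, with `0 log 0 = 0`), and group separation is
   tested by rank-based ANOSIM with 99,999 label permutations.

# What the generator emulates

`simulate_community()` draws `n_genomes` genomes (default 5, 200 kb each)
from independent order-3 Markov chains with Dirichlet-sampled transition
rows. Order 3 is the smallest order that gives every genome its own
tetranucleotide signature — the feature the contamination screen relies on —
while staying cheap to sample. The metagenome tiles each genome into contigs
of 1–5 kb, with 10% of contigs drawn short (200–999 bases, never binned).
Misbinned contigs are planted at a deterministic count,
`round(misbin_rate x n_long)` per genome (default rate 0.05), sampled
without replacement and sent to a uniformly chosen wrong bin; a
deterministic count keeps low planting rates identifiable in small
communities, where a Bernoulli draw could plant nothing at all.

Each of the first `n_sags` genomes (default 3) yields a SAG. The sequenced
cell differs from the population genome by substitutions at rate 0.005, so
SAG-vs-MAG identity sits near the ~99.5% seen between closely related
environmental populations. The genome is cut into 2–10 kb segments; segments
are dropped at random until `sag_dropout` (default 0.2) of the genome has
zero coverage, and survivors receive independent Gamma(shape 0.3)
amplification weights — a two-parameter caricature of MDA's orders-of-
magnitude coverage unevenness. Reads (150 bases, 15x mean depth) are placed
multinomially by weight x length. A `chimera_rate` fraction (default 0.02)
is built as inversion joins: a forward arm of 20–130 bases continued by the
reverse complement of a segment starting within 5 kb. Both arms therefore
clip by ≥ 20 bases when the longer arm is aligned, matching the geometry the
detector targets. Contamination is planted as `contam_contig_count` contigs
(default 5, 2–6 kb) sampled from genomes *outside* the community: free-DNA
or reagent contamination is precisely DNA the metagenome does not contain,
which is what gives contaminant contigs their near-zero metagenome coverage.
Contaminant segments also seed reads, which are unmapped against the
metagenome.

The alignment emitter stands in for a read mapper, but is constrained by the
truth: each read aligns to the contig holding the majority of its origin
interval, overhang soft-clipped; chimeric reads align by their longer arm
only; mismatch counts are substitution-only (planted SNPs inside the aligned
reference interval plus sequencing errors inside the aligned query
interval). No indels, quality scores, or mapping ambiguity are simulated —
so passing tests demonstrate the *statistics* are computed correctly, not
that a real aligner's edge cases are handled. Real data would additionally
bring strain heterogeneity, conserved cross-taxon regions (reads mapping to
the wrong organism), GC-dependent amplification bias, and chimera classes
other than inversions; none of these are in the generator, and results on
real data will be correspondingly noisier than the clean recovery seen here.

# Numerical and design choices

* **Strict clustering cutoff.** Whether a pair at exactly `d = 0.1` merges
  is not decidable from the clustering description alone; the package uses
  strict `<` (implemented as union-find over the threshold graph, which is
  exact for ties) and exposes the cutoff. `hclust(..., "single")` serves as
  an independent cross-check in the tests.
* **Canonical tetranucleotides.** Contig orientation in an assembly is
  arbitrary, so 4-mers are collapsed with their reverse complements into 136
  classes and frequencies are length-normalized before PCA; the screen is
  therefore exactly strand-invariant, which the tests assert. PC axis signs
  are fixed by making each axis's largest-magnitude loading positive.
* **Quantitative contamination flag.** The original screen of this kind is
  visual (a PCA scatter colored by coverage); the package formalizes it as
  "non-aligning AND (robust PC outlier OR coverage < 10% of median)", with
  every threshold configurable. The robust distance uses per-axis
  median/MAD standardization; with fewer than 3 aligning contigs the
  composition test is skipped and the coverage rule alone applies.
* **Clip accounting.** "At least 20 soft-clipped bases" is read as the total
  across both read ends (a `clip_mode = "max"` variant uses the largest
  single clip); hard clips count as clipped bases. "Aligned over an edge" is
  formalized as a clipped alignment whose clipped side is flush with
  position 1 or the contig's final position.
* **ANOSIM conventions.** Average ranks on ties; permutation p-values use
  the add-one convention `(1 + #{R* >= R}) / (1 + n_perm)` so p is never 0
  and the floor at 99,999 permutations is 10^-5; the permutation stream is
  seeded, making p bit-for-bit reproducible. `vegan::anosim` is the
  reference implementation in the test suite, never the implementation.
* **Pairwise size factors.** The Poisson dissimilarity normalizes each pair
  to its own mean total count, following the cited method's pairwise
  treatment; a global-size-factor mode exists for comparison.
* **Approval-rule reading.** "At most 2 in more than a single copy" is read
  as bounding the number of multi-copy markers; the alternative reading
  (bounding the copy count per marker) is available via `rule =
  "max_copies"`.
* **Forward-strand repeats.** `find_duplicated_elements()` anchors on shared
  `min_element`-mers and extends maximally on the forward strand only;
  reverse-complement duplications are a known limitation.
* **Problem sizes.** The default community (5 x 200 kb genomes, 3 SAGs of
  20,000 reads) runs the whole pipeline in well under a minute. Validation
  experiments scale single knobs instead: chimera detection is scored on a
  50,000-read SAG without planted contamination (a chimera formed in foreign
  DNA has no mappable origin anywhere, so it cannot measure detector
  performance), and the misbinning-rate sweep uses 1-Mb genomes so that the
  lowest rate (0.02) plants several contigs rather than one — with a single
  planted contig the statistic can be annihilated by the contig falling
  into an amplification-dropout region.

# Limitations

The generator's independence assumptions (independent Markov composition,
independent amplification weights, uniform misbin targets) make separation
tasks easier than on real assemblies, where compositional signatures blur
along phylogeny. Completeness/redundancy here counts planted marker
presence, not HMM hits; marker detection, read mapping, assembly and binning
themselves are out of scope and arrive as inputs. The chimera screen detects
inversion-type geometry only and does not localize breakpoints or repair
reads.
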
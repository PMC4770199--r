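---
title: "Models and methods behind drpseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind drpseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drpseq)
```

# The library chemistry being modelled

Double random priming builds a sequencing library from total RNA in two
priming steps, each using an oligo that ends in a random octamer and starts
with a fixed 25-nt adapter (the forward sequence
`GAGTGATGGTTGAGGTAGTGTGGAG`). Reverse transcription primes anywhere on the
transcript; a single round of second-strand synthesis with the same primer
produces double-stranded amplicons whose two ends are reverse complements
of each other. Two consequences drive everything in this package:

* **Panhandle suppression.** Short amplicons can fold back on their
  complementary ends and outcompete primer binding, so fragments below
  roughly 150 bp are not amplified. The simulator never emits inserts
  below `fragment_min_bp`.
* **The octamer is a molecular counter.** Each priming event carries two
  random 8-mers. PCR duplicates of one event are sequence-identical
  *including* the octamers; independent events on the same position differ
  in the octamers with probability $1 - 4^{-8}$ per end. Collapsing reads
  on exact identity of the trimmed, octamer-bearing core therefore counts
  molecules, not reads.

# The simulator

`sim_config()` fixes the study conditions; the defaults describe a 5 ng
input library sequenced single-end at 150 nt with 12 PCR cycles, inserts
uniform on 150–600 bp, and four PCR adapters of different lengths modelled
as 0–3 random bases before the forward adapter (their only role is 5′-end
heterogeneity).

**Transcriptome.** `make_transcriptome()` draws random transcripts
(1000–3000 nt) over seven biotypes (70% protein-coding, 10% lincRNA, 6%
misc_RNA, 5% snRNA, 4% rRNA, 2% Mt_rRNA, 3% intergenic — at least one gene
per class) with log-normal molar abundances (`expression_dispersion` is
the log-sigma; default 1.0).

**rRNA mass.** A cell's RNA is dominated by rRNA by *mass*; what an
FPKM table shows is closer to *molar* share. The simulator keeps the two
distinct: the capture weight of a gene is molar abundance × length (random
priming sheds fragments along the whole molecule), and
`rrna_mass_fraction` rescales rRNA-class abundances so that the rRNA share
of that capture mass — and hence of sequenced fragments and of aligned
bases — equals the configured value. The default of 0.6 reflects the
~60% of aligned bases that DRP libraries typically devote to rRNA genes,
which is itself well below the 80–90% cellular mass fraction because the
protocol under-captures rRNA. FPKM-level class composition
(`class_composition()`) consequently reports the *molar* share, which is
lower than 0.6 whenever rRNA transcripts are not shorter than average;
tests compare it against the exact expectation computed from the realized
abundances rather than against the nominal mass fraction.

**PCR.** Each molecule starts as one copy; at every cycle every existing
copy duplicates independently with probability `per_cycle_efficiency`
(default 0.45), giving mean copy number $(1+e)^{c}$. Every copy becomes a
read, so at the default 12 cycles a library is ~99% duplicates — the
deduplicated molecule count, not the read count, is the meaningful depth.
Desk-scale analyses in the tests and the acceptance script therefore use
2 PCR cycles, which keeps ~2×10⁵ reads per library (about half of them
duplicates) while still exercising the collapsing path; this is a sizing
choice of the package, with the 12-cycle condition covered by the exact
molecule-recovery test.

**Reads.** A read is
`offset bases + forward adapter + octamer5 + insert + octamer3 + reverse
adapter + Illumina adapter`, truncated to `read_length_nt`; 3′ elements
appear only when the geometry leaves room, which is exactly how
reverse-adapter-less reads arise (the simulator attributes them to
geometry only). Substitution errors are injected at `error_rate`; indels
are not modelled because the trimmer locates adapters by windowed
(near-)exact matching.

**Spike-ins.** `synthetic_ercc_mix()` generates a *synthetic* stand-in
for a commercial spike-in mix: 32 species log-spaced over four orders of
magnitude of stock concentration, with
`copies = attomoles × 6.02214×10⁵`. Sampled spike-in molecules are
Poisson with mean `copies × capture_prob` (no length weighting — copy
number, not mass, is the quantity the calibration targets).

# The read-processing pipeline

`preprocess_reads()` applies, in order:

1. **Illumina-adapter stripping** — leftmost full occurrence, else the
   longest ≥ 5-nt overlap between the read's 3′ end and the adapter's 5′
   end.
2. **Forward-adapter gate** — the 25-mer must start within
   `max_forward_offset` (default 6) nt of the 5′ end, exact by default;
   reads without it are discarded. The gate is anchored because the motif
   marks a valid library molecule, not an alignment target.
3. **Dual-mode trimming** — if the reverse adapter occurs in the core
   (everything after the forward adapter), the core is cut at its leftmost
   occurrence (`BOTH_ADAPTERS`); internal occurrences are
   indistinguishable from read-through and are trimmed the same way. A
   reverse hit within the first 16 nt leaves no room for two octamers and
   discards the read. Otherwise the first 120 nt of the core are kept
   (`FORWARD_ONLY`). The 120-nt window is applied to the core, not the
   raw read, so the retained insert does not depend on the variable 5′
   offset — which is precisely what makes duplicate copies with different
   offsets collapse together.
4. **Collapsing** — exact identity of `(mode, core)` *before* octamer
   removal; the two modes never merge even when one core prefixes the
   other (a deliberate, documented limitation: a FORWARD_ONLY read could
   in principle be the truncated sibling of a BOTH_ADAPTERS molecule).
5. **Octamer removal and the 30-nt filter** — inserts shorter than 30 nt
   are dropped; `duplicate_fraction = 1 − molecules/reads` is reported
   over the molecules that pass the filter, keeping numerator and
   denominator consistent.

**A sharp edge worth knowing.** Partial-overlap adapter stripping with a
5-nt minimum will, on ~1/1024 of reads that end inside the insert, trim a
suffix that coincides with the adapter's first bases by chance. Such reads
get a 115–119-nt core instead of 120 and split off their molecule. This is
inherent to any partial-overlap trimmer, affects only `FORWARD_ONLY`
geometry, and is why the exact-recovery guarantee is stated for
read-through geometry (reads reaching the reverse adapter), where the core
is delimited by the reverse match and immune to the suffix heuristic.

# Quantification

`toy_map()` replaces a spliced aligner at desk scale: an insert is
assigned to every gene containing it verbatim (either strand), with
multi-gene hits split uniformly (1/k to each of k genes, so totals are
conserved exactly), and one count per gene regardless of how many
positions match. This is adequate because simulated inserts are contiguous
transcript substrings; real data should be aligned externally and imported
via `read_fpkm_table()`.

FPKM uses the annotated transcript length (no effective-length
correction) and normalizes by assigned fragments only (compatible-hits
convention): $\mathrm{FPKM} = 10^9 \, c_g / (L_g \, N)$. Detection uses
FPKM ≥ 1 after spike-in removal; spike-in analysis floors FPKM at 0.1;
replicate correlations filter at FPKM ≥ 0.001 using the *union* rule
(gene kept if it passes in either sample) so Pearson and Spearman see the
same gene set — the per-sample alternative is available through the
`min_fpkm` argument applied to pre-filtered tables.

# Downstream analytics

* **Saturation** subsamples fragments (not raw reads) without
  replacement, seeded; at fraction 1.0 it reproduces the full-sample
  expressed count exactly. Sampling without replacement is used; with
  replacement would only blur the curve at small fractions.
* **Gene-body coverage** rescales each transcript to 100 bins, weights
  fragments by their assignment weight, normalizes each gene's profile to
  mean 1 (so highly expressed genes do not dominate), then averages.
  Uniform fragment starts with 150–600 bp inserts necessarily
  under-represent both transcript ends — coverage at position $x$ is the
  probability that a fragment spans $x$, which tapers within one insert
  length of either end.
* **Clustering** is complete-linkage agglomeration on Euclidean distances
  of log₂(FPKM), written in-package so ties are deterministic:
  equal-height merges resolve toward the smallest contained leaf index, and
  leaf order puts the smaller subtree first. Zeros are replaced by half
  the smallest positive value in the matrix before the log (the data give
  no guidance here; half-minimum keeps zeros strictly below everything
  observed without distorting the scale). `stats::hclust` serves as an
  independent oracle in the tests, not as the implementation.
* **Control subtraction** removes from each arm of a differential list
  the genes that are also significant, on the matching arm, in a
  cycle-number control comparison (undiluted control ↔ side A, diluted
  control ↔ side B), mirroring the experimental pairing of amplification
  depths. The output is always a subset of the significant input and
  shrinks monotonically with `alpha`.
* **Probeset collapse** keeps the highest- (or lowest-) intensity
  probeset per gene with a lexicographic tie-break, for comparing
  RNA-seq against legacy microarray data.

# Seeds and determinism

Every stochastic operation takes an explicit seed. `sim_config()` carries
a base seed from which the stages derive offsets (+0 transcriptome, +1
molecules, +2 reads, +3 spike-ins); `run_pipeline()` derives per-stage
seeds from the global seed by a polynomial hash of the stage name
(`stage_seed()`). Identical configuration and seed give byte-identical
FASTQ, TSV and manifest output.

# What the simulator does not model

Priming-site sequence bias (real octamer priming is biased; the simulator
primes uniformly), indels and quality-score structure, strand-specific
artefacts (reads are transcript-stranded), isoforms (one transcript per
gene), spliced alignment, and the statistical model of any
differential-expression caller — differential tables are consumed, never
computed, and
the simulator plants truth into them for testing. Passing tests on
simulated data therefore validate the *pipeline logic* (trimming
geometry, molecular counting, normalization arithmetic, set and cluster
operations), not the biological fidelity of any particular real library.

# Problem sizes used in the checks

The bundled tests and the acceptance script run entirely on simulated
data: a 500-gene transcriptome at ~2×10⁵ reads for the saturation check
(half-subsample detection ≥ 90% of the full expressed set), two
independent ~1×10⁵-read replicates for concordance (Spearman ≥ 0.8 at
FPKM ≥ 0.001), 10⁴ molecules at 12 cycles for exact molecule recovery,
and 32 spike-ins over four orders of magnitude for linearity (log-log
Pearson ≥ 0.9). These sizes were chosen as the smallest at which the
corresponding statistics are stable, and are stated here so results can
be related to them.
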
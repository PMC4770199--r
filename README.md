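# drpseq

Simulation and analysis of **double-random-priming (DRP) whole-transcriptome
amplification** libraries — a low-input RNA-seq protocol in which reverse
transcription and one round of second-strand synthesis are each primed by an
oligo carrying a fixed 25-nt MALBAC adapter plus a random 3′ octamer. Every
amplicon therefore ends in reverse-complementary adapters (which suppress
amplification of short fragments through panhandle self-annealing) and
carries two random octamers that act as unique molecular identifiers: after
PCR, reads that are *identical including their octamers* are PCR duplicates
of one priming event, while reads differing only in the octamer are
independent molecules.

The package is aimed at people developing or validating processing pipelines
for such libraries (and UMI-style protocols generally): it provides a
simulator with complete ground truth, the matching read-processing pipeline,
a desk-scale quantifier, and the downstream analytics used to characterize
these libraries.

## What it implements

**Simulator** (`sim_config()`, `simulate_library()`): synthetic
transcriptomes over seven biotypes with log-normal molar abundances;
fragment capture proportional to abundance × length; insert sizes uniform on
150–600 bp (no fragment below the panhandle limit); PCR duplication as a
per-cycle Bernoulli branching process (mean copy number
(1 + *e*)^cycles); single-end reads with 0–3 random 5′ offset bases, the
forward adapter `GAGTGATGGTTGAGGTAGTGTGGAG`, both octamers, reverse adapter
and Illumina-adapter read-through as the geometry allows; substitution
errors; ERCC-style spike-ins with copies = attomoles × 6.02214·10⁵.

**Preprocessing** (`preprocess_fastq()`): Illumina-adapter stripping
(including ≥ 5-nt partial 3′ overlaps), anchored forward-adapter gating,
dual-mode trimming — cut at the reverse adapter when present
(`BOTH_ADAPTERS`), otherwise keep the first 120 nt of the core
(`FORWARD_ONLY`) — collapsing of identical cores *before* octamer removal
(the octamer is the molecular counter), octamer removal, and a 30-nt
minimum-length filter.

**Quantification** (`toy_map()`, `compute_fpkm()`): exact substring mapping
of inserts against the toy transcriptome on both strands, multi-gene hits
split uniformly (1/k each); FPKM without effective-length correction,
normalized by assigned fragments only; `expressed_genes()` applies the
FPKM ≥ 1 convention after spike-in removal. Externally produced
(Cufflinks-style) FPKM tables load via `read_fpkm_table()`.

**Analytics**: saturation curves by seeded fragment subsampling
(`saturation()`), gene-class composition of expressed FPKM with biotype
overrides (`class_composition()`), rRNA aligned-base fraction
(`rrna_base_fraction()`), gene-body coverage on the normalized transcript
(`gene_body_coverage()`), spike-in linearity with the 0.1 FPKM floor
(`ercc_analysis()`), replicate concordance at FPKM ≥ 0.001
(`replicate_concordance()`), detection overlap (`detection_overlap()`),
dilution-control subtraction of differential lists (`control_subtract()`),
deterministic complete-linkage clustering of log₂(FPKM)
(`cluster_de_genes()`), and microarray probeset collapse
(`collapse_probesets()`).

A thin command-line wrapper is installed as `exec/drpseq`
(`drpseq simulate|preprocess|quantify|run`).

## Worked example

Simulate a small library, recover the molecules, and quantify:

```r
library(drpseq)

cfg <- sim_config(n_genes = 50, input_picograms = 100,
                  capture_molecules_per_pg = 5, pcr_cycles = 2, seed = 42)
lib <- simulate_library(cfg)
pre <- preprocess_reads(lib$reads$sequence)
pre$stats
#> DRP preprocessing stats
#>   reads_in                     1016
#>   reads_with_forward_adapter   1016
#>   reads_discarded_no_adapter   0
#>   reads_mode_both              0
#>   reads_mode_forward_only      1016
#>   reads_failing_length         0
#>   molecules_out                499
#>   reads_surviving              1016
#>   duplicate_fraction           0.5089
```

All 1016 reads carry the forward adapter (the simulator always emits it),
and collapsing on the octamer-bearing cores recovers exactly the 499
simulated molecules: the 50.9% duplicate fraction is pure PCR duplication,
`1 − 499/1016`.

```r
asn  <- toy_map(pre$molecules, lib$transcriptome)
fpkm <- compute_fpkm(asn, lib$annotation)
length(expressed_genes(fpkm)$sample_1)
#> [1] 41
head(class_composition(fpkm), 3)
#>   sample_id    biotype percent_of_total_fpkm
#> 1  sample_1 intergenic              1.772869
#> 2  sample_1    lincRNA              4.523572
#> 3  sample_1   misc_RNA              3.269893
```

41 of the 50 genes are expressed at FPKM ≥ 1 at this shallow depth, and the
composition table reports each biotype's share of the expressed FPKM mass
(summing to 100% per sample).

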
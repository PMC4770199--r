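#' Simulation configuration for a DRP library
#'
#' Bundles every knob of the double-random-priming (DRP) library simulator.
#' The defaults describe a 5 ng total-RNA library sequenced single-end at
#' 150 nt: amplicon inserts sized 150--600 bp (shorter fragments are
#' suppressed by panhandle formation of the complementary adapter ends),
#' 12 PCR cycles at 45% per-cycle duplication efficiency, and four
#' variable-length PCR adapters modelled as 0--3 random bases preceding the
#' fixed forward adapter.
#'
#' @param n_genes Number of genes in the synthetic transcriptome.
#' @param expression_dispersion Log-normal sigma of per-gene molar
#'   abundance.
#' @param rrna_mass_fraction Expected fraction of captured library mass
#'   (and hence of sequenced fragments) deriving from rRNA-class genes
#'   (`rRNA` + `Mt_rRNA`), in `[0, 1)`. The default reflects the roughly
#'   60% of aligned bases that DRP libraries devote to rRNA.
#' @param input_picograms Total RNA input in pg (5 ng = 5000 pg).
#' @param capture_molecules_per_pg Amplifiable fragments captured per pg of
#'   input; the molecule count is Poisson with mean
#'   `input_picograms * capture_molecules_per_pg`.
#' @param fragment_min_bp,fragment_max_bp Insert size range in bp; inserts
#'   below `fragment_min_bp` are never emitted (panhandle suppression).
#' @param pcr_cycles Number of PCR cycles.
#' @param per_cycle_efficiency Probability, per cycle, that any given copy
#'   is duplicated; mean final copy number is
#'   `(1 + per_cycle_efficiency)^pcr_cycles`.
#' @param read_length_nt Single-end read length.
#' @param error_rate Per-base substitution error rate in `[0, 1)`.
#' @param adapter_offsets Candidate numbers of random bases preceding the
#'   forward adapter, one drawn per read (5'-end heterogeneity from the
#'   variable-length PCR adapters).
#' @param seed Base seed; the individual operations derive their streams
#'   from it (transcriptome +0, molecules +1, reads +2, spike-ins +3).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L,
                       expression_dispersion = 1.0,
                       rrna_mass_fraction = 0.6,
                       input_picograms = 5000,
                       capture_molecules_per_pg = 20,
                       fragment_min_bp = 150L,
                       fragment_max_bp = 600L,
                       pcr_cycles = 12L,
                       per_cycle_efficiency = 0.45,
                       read_length_nt = 150L,
                       error_rate = 0,
                       adapter_offsets = 0:3,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              expression_dispersion = expression_dispersion,
              rrna_mass_fraction = rrna_mass_fraction,
              input_picograms = input_picograms,
              capture_molecules_per_pg = capture_molecules_per_pg,
              fragment_min_bp = as.integer(fragment_min_bp),
              fragment_max_bp = as.integer(fragment_max_bp),
              pcr_cycles = as.integer(pcr_cycles),
              per_cycle_efficiency = per_cycle_efficiency,
              read_length_nt = as.integer(read_length_nt),
              error_rate = error_rate,
              adapter_offsets = as.integer(adapter_offsets),
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 2L,
            cfg$expression_dispersion > 0,
            cfg$rrna_mass_fraction >= 0, cfg$rrna_mass_fraction < 1,
            cfg$input_picograms > 0,
            cfg$capture_molecules_per_pg > 0,
            cfg$fragment_min_bp < cfg$fragment_max_bp,
            cfg$fragment_min_bp >= 1L,
            cfg$pcr_cycles >= 0L,
            cfg$per_cycle_efficiency > 0, cfg$per_cycle_efficiency <= 1,
            cfg$read_length_nt >= 1L,
            cfg$error_rate >= 0, cfg$error_rate < 1,
            all(cfg$adapter_offsets >= 0L))
  class(cfg) <- "sim_config"
  cfg
}

# biotype mix used when building synthetic transcriptomes; every class that
# shows up in gene-class composition summaries is represented
.drp_biotypes <- c(protein_coding = 0.70, lincRNA = 0.10, misc_RNA = 0.06,
                   snRNA = 0.05, rRNA = 0.04, Mt_rRNA = 0.02,
                   intergenic = 0.03)

.rrna_classes <- c("rRNA", "Mt_rRNA")

random_bases <- function(total) {
  paste(sample(c("A", "C", "G", "T"), total, replace = TRUE), collapse = "")
}

random_strings <- function(n, width) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), width * n, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

random_octamers <- function(n) random_strings(n, 8L)

#' Generate a synthetic transcriptome
#'
#' Builds `n_genes` random transcripts covering all seven biotypes
#' (protein_coding, lincRNA, misc_RNA, snRNA, rRNA, Mt_rRNA, intergenic),
#' with log-normal molar abundances. Abundances of the rRNA classes are
#' rescaled so that the expected *mass* fraction (molar abundance times
#' transcript length, which is also the probability mass from which
#' fragments are drawn) equals `rrna_mass_fraction`. With
#' `rrna_mass_fraction = 0` rRNA genes get zero abundance and never yield
#' molecules.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed override (default `config$seed`).
#' @return A data frame of class `drp_transcriptome` with columns
#'   `gene_id`, `biotype`, `length_bp`, `abundance`, `sequence`.
#' @export
make_transcriptome <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (n < length(.drp_biotypes)) {
    stop("n_genes = ", n, " is smaller than the number of biotypes (",
         length(.drp_biotypes), "); cannot place one gene per class")
  }
  set.seed(if (is.null(seed)) config$seed else seed)

  counts <- stats::setNames(pmax(1L, floor(.drp_biotypes * n)),
                            names(.drp_biotypes))
  counts[1L] <- counts[1L] + (n - sum(counts))  # remainder to protein_coding
  biotype <- rep(names(counts), counts)

  len <- as.integer(round(stats::runif(n, 1000, 3000)))
  len <- pmax(len, 200L)
  seqs <- vapply(len, random_bases, character(1))

  ab <- stats::rlnorm(n, meanlog = 0, sdlog = config$expression_dispersion)
  is_r <- biotype %in% .rrna_classes
  f <- config$rrna_mass_fraction
  mass <- ab * len
  if (f == 0) {
    ab[is_r] <- 0
  } else if (any(is_r) && any(!is_r)) {
    k <- f * sum(mass[!is_r]) / ((1 - f) * sum(mass[is_r]))
    ab[is_r] <- ab[is_r] * k
  }

  out <- data.frame(gene_id = sprintf("gene%04d", seq_len(n)),
                    biotype = biotype, length_bp = len,
                    abundance = ab, sequence = seqs,
                    stringsAsFactors = FALSE)
  class(out) <- c("drp_transcriptome", "data.frame")
  out
}

#' @export
print.drp_transcriptome <- function(x, ...) {
  cat("DRP synthetic transcriptome:", nrow(x), "genes\n")
  print(table(x$biotype))
  m <- x$abundance * x$length_bp
  cat(sprintf("rRNA mass fraction: %.3f\n",
              sum(m[x$biotype %in% .rrna_classes]) / sum(m)))
  invisible(x)
}

#' Annotation table of a transcriptome
#'
#' @param transcriptome A `drp_transcriptome` (or any data frame with
#'   `gene_id`, `length_bp`, `biotype`).
#' @return Data frame with columns `gene_id`, `length_bp`, `biotype`.
#' @export
transcriptome_annotation <- function(transcriptome) {
  data.frame(gene_id = transcriptome$gene_id,
             length_bp = transcriptome$length_bp,
             biotype = transcriptome$biotype,
             stringsAsFactors = FALSE)
}

# per-cycle Bernoulli branching process: each existing copy duplicates
# with probability eff at every cycle
branching_copies <- function(n, cycles, eff) {
  copies <- rep(1L, n)
  for (i in seq_len(cycles)) {
    copies <- copies + stats::rbinom(n, copies, eff)
  }
  copies
}

#' Draw ground-truth amplifiable molecules
#'
#' Samples Poisson-many fragments (mean `input_picograms *
#' capture_molecules_per_pg`). Each fragment picks a gene with probability
#' proportional to molar abundance times transcript length (random priming
#' sheds fragments along the whole transcript), an insert length uniform on
#' `[fragment_min_bp, min(fragment_max_bp, transcript length)]`, a uniform
#' start, and two uniform random octamers (the priming UMIs). The post-PCR
#' copy number follows a per-cycle Bernoulli branching process. Transcripts
#' shorter than `fragment_min_bp` never yield molecules (panhandle
#' suppression).
#'
#' @param transcriptome A `drp_transcriptome`.
#' @param config A [sim_config()].
#' @param abundances Optional per-gene non-negative weights (named by
#'   gene_id); defaults to the transcriptome's `abundance` column.
#' @param seed Optional seed override (default `config$seed + 1`).
#' @return Data frame with columns `molecule_id`, `gene_id`,
#'   `start_0based`, `insert_length_bp`, `octamer5`, `octamer3`,
#'   `copy_count`.
#' @export
simulate_molecules <- function(transcriptome, config, abundances = NULL,
                               seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(transcriptome) || nrow(transcriptome) == 0L) {
    stop("empty transcriptome")
  }
  if (is.null(abundances)) {
    abundances <- stats::setNames(transcriptome$abundance,
                                  transcriptome$gene_id)
  }
  missing <- setdiff(transcriptome$gene_id, names(abundances))
  if (length(missing)) {
    stop("abundances missing for gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  set.seed(if (is.null(seed)) config$seed + 1L else seed)

  len <- transcriptome$length_bp
  w <- abundances[transcriptome$gene_id] * len
  w[len < config$fragment_min_bp] <- 0   # panhandle: no short fragments
  if (all(w == 0)) stop("no gene has positive capture weight")

  n <- stats::rpois(1L, config$input_picograms * config$capture_molecules_per_pg)
  if (n == 0L) {
    return(empty_molecules())
  }
  g <- sample.int(nrow(transcriptome), n, replace = TRUE, prob = w)
  max_len <- pmin(config$fragment_max_bp, len[g])
  ins <- config$fragment_min_bp +
    floor(stats::runif(n) * (max_len - config$fragment_min_bp + 1))
  ins <- as.integer(pmin(ins, max_len))
  start <- as.integer(floor(stats::runif(n) * (len[g] - ins + 1)))

  data.frame(molecule_id = sprintf("m%07d", seq_len(n)),
             gene_id = transcriptome$gene_id[g],
             start_0based = start,
             insert_length_bp = ins,
             octamer5 = random_octamers(n),
             octamer3 = random_octamers(n),
             copy_count = branching_copies(n, config$pcr_cycles,
                                           config$per_cycle_efficiency),
             stringsAsFactors = FALSE)
}

empty_molecules <- function() {
  data.frame(molecule_id = character(), gene_id = character(),
             start_0based = integer(), insert_length_bp = integer(),
             octamer5 = character(), octamer3 = character(),
             copy_count = integer(), stringsAsFactors = FALSE)
}

#' Render sequencing reads from molecules
#'
#' Every PCR copy of every molecule becomes one single-end read:
#' `[offset random bases] + forward adapter + octamer5 + insert +
#' octamer3 + reverse adapter + Illumina adapter`, truncated to
#' `read_length_nt` (so the 3' elements appear only when the geometry
#' leaves room, mirroring read-through). Substitution errors are injected
#' at `error_rate`; each error substitutes a different base, so the
#' realized mismatch fraction against the truth equals the configured rate
#' in expectation.
#'
#' @param molecules Output of [simulate_molecules()] (optionally with
#'   spike-in molecules appended).
#' @param transcriptome A `drp_transcriptome` covering every `gene_id` in
#'   `molecules`.
#' @param config A [sim_config()].
#' @param scheme An [adapter_scheme()]; defaults to the standard one.
#' @param seed Optional seed override (default `config$seed + 2`).
#' @return List with `reads` (data frame `read_id`, `sequence`) and
#'   `truth` (one row per read: `read_id`, `molecule_id`, `gene_id`,
#'   `start_0based`, `insert_length_bp`, `octamer5`, `octamer3`,
#'   `offset_nt`, `mode`), where `mode` is the trimming branch the read
#'   geometry dictates.
#' @export
render_reads <- function(molecules, transcriptome, config,
                         scheme = adapter_scheme(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  fwd <- scheme$forward_malbac
  rev <- scheme$reverse_malbac
  flen <- nchar(fwd)
  min_room <- flen + 8L + 30L
  if (config$read_length_nt <= min_room) {
    stop("read_length_nt = ", config$read_length_nt,
         " leaves no room for adapter + octamer + 30 nt insert (needs > ",
         min_room, ")")
  }
  set.seed(if (is.null(seed)) config$seed + 2L else seed)

  if (nrow(molecules) == 0L) {
    return(list(reads = data.frame(read_id = character(),
                                   sequence = character(),
                                   stringsAsFactors = FALSE),
                truth = cbind(empty_molecules()[0, ],
                              offset_nt = integer(), mode = character())))
  }
  txseq <- stats::setNames(transcriptome$sequence, transcriptome$gene_id)
  if (any(!(molecules$gene_id %in% names(txseq)))) {
    stop("molecules reference gene_ids absent from the transcriptome")
  }

  idx <- rep(seq_len(nrow(molecules)), molecules$copy_count)
  nreads <- length(idx)
  off <- sample(config$adapter_offsets, nreads, replace = TRUE)
  maxoff <- max(config$adapter_offsets)
  offbases <- if (maxoff > 0L) {
    substr(random_strings(nreads, maxoff), 1L, off)
  } else {
    rep("", nreads)
  }

  gene <- molecules$gene_id[idx]
  start <- molecules$start_0based[idx]
  ins_len <- molecules$insert_length_bp[idx]
  insert <- substr(txseq[gene], start + 1L, start + ins_len)

  full <- paste0(offbases, fwd, molecules$octamer5[idx], insert,
                 molecules$octamer3[idx], rev, scheme$illumina_adapter)
  reads <- substr(full, 1L, config$read_length_nt)
  short <- nchar(reads) < config$read_length_nt
  if (any(short)) {   # run off the template: pad like dark cycles
    reads[short] <- paste0(reads[short],
                           strrep("A", config$read_length_nt -
                                         nchar(reads[short])))
  }

  if (config$error_rate > 0) {
    reads <- inject_substitutions(reads, config$error_rate)
  }

  mode <- ifelse(off + flen + 16L + ins_len + nchar(rev) <=
                   config$read_length_nt,
                 "BOTH_ADAPTERS", "FORWARD_ONLY")
  read_id <- sprintf("r%08d", seq_len(nreads))
  list(reads = data.frame(read_id = read_id, sequence = reads,
                          stringsAsFactors = FALSE),
       truth = data.frame(read_id = read_id,
                          molecule_id = molecules$molecule_id[idx],
                          gene_id = gene,
                          start_0based = start,
                          insert_length_bp = ins_len,
                          octamer5 = molecules$octamer5[idx],
                          octamer3 = molecules$octamer3[idx],
                          offset_nt = off,
                          mode = mode,
                          stringsAsFactors = FALSE))
}

inject_substitutions <- function(reads, rate) {
  n_err <- stats::rbinom(length(reads), nchar(reads), rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, cur), 1L)
    }
  }
  reads
}

#' Molecules per attomole
#'
#' @keywords internal
MOLECULES_PER_ATTOMOLE <- 6.02214e5

#' ERCC-style copy numbers from stock concentrations
#'
#' `copies = stock_attomol_per_ul * dilution_factor * sample_volume_ul *
#' 6.02214e5` (molecules per attomole).
#'
#' @param stock_attomol_per_ul Stock concentration, attomol/uL.
#' @param dilution_factor Multiplicative dilution applied to the stock.
#' @param sample_volume_ul Volume of diluted stock added to the sample.
#' @return Numeric copy numbers.
#' @export
ercc_copies <- function(stock_attomol_per_ul, dilution_factor,
                        sample_volume_ul) {
  if (any(stock_attomol_per_ul < 0)) stop("negative stock concentration")
  if (any(dilution_factor < 0) || any(sample_volume_ul < 0)) {
    stop("negative dilution factor or volume")
  }
  stock_attomol_per_ul * dilution_factor * sample_volume_ul *
    MOLECULES_PER_ATTOMOLE
}

#' Synthetic spike-in concentration table
#'
#' Generates a synthetic stand-in for a commercial spike-in mix: `n`
#' transcripts with stock concentrations evenly log-spaced over
#' `log10_range` orders of magnitude (plus mild jitter), one shared
#' dilution factor and sample volume, and derived copy numbers.
#'
#' @param n Number of spike-in species.
#' @param log10_range Numeric length-2: log10 stock range in attomol/uL.
#' @param dilution_factor,sample_volume_ul Dilution scheme.
#' @param seed Seed for the jitter.
#' @return Data frame of class `ercc_table`: `ercc_id`,
#'   `stock_attomol_per_ul`, `dilution_factor`, `sample_volume_ul`,
#'   `copies`.
#' @export
synthetic_ercc_mix <- function(n = 32L, log10_range = c(-2, 2),
                               dilution_factor = 1e-3,
                               sample_volume_ul = 1, seed = 100L) {
  set.seed(seed)
  lg <- seq(log10_range[1], log10_range[2], length.out = n) +
    stats::runif(n, -0.1, 0.1)
  stock <- 10^lg
  out <- data.frame(ercc_id = sprintf("ERCC-%05d", seq_len(n)),
                    stock_attomol_per_ul = stock,
                    dilution_factor = dilution_factor,
                    sample_volume_ul = sample_volume_ul,
                    copies = ercc_copies(stock, dilution_factor,
                                         sample_volume_ul),
                    stringsAsFactors = FALSE)
  class(out) <- c("ercc_table", "data.frame")
  out
}

#' Random spike-in transcript sequences
#'
#' @param ercc An `ercc_table`.
#' @param length_range Transcript length range in nt.
#' @param seed Seed.
#' @return A `drp_transcriptome` whose `gene_id`s are the spike-in ids and
#'   whose biotype is `"spike_in"`; `abundance` is proportional to copies.
#' @export
ercc_transcriptome <- function(ercc, length_range = c(250L, 2000L),
                               seed = 101L) {
  set.seed(seed)
  n <- nrow(ercc)
  len <- as.integer(round(stats::runif(n, length_range[1], length_range[2])))
  out <- data.frame(gene_id = ercc$ercc_id, biotype = "spike_in",
                    length_bp = len,
                    abundance = ercc$copies / sum(ercc$copies),
                    sequence = vapply(len, random_bases, character(1)),
                    stringsAsFactors = FALSE)
  class(out) <- c("drp_transcriptome", "data.frame")
  out
}

#' Draw spike-in molecules
#'
#' Sampled molecule counts per spike-in are Poisson with mean
#' `copies * capture_prob`; insert geometry, octamers and PCR duplication
#' follow the same model as endogenous molecules.
#'
#' @param ercc An `ercc_table` (see [synthetic_ercc_mix()]).
#' @param ercc_tx Spike-in transcriptome from [ercc_transcriptome()].
#' @param config A [sim_config()].
#' @param capture_prob Probability that any given spike-in molecule is
#'   captured as an amplifiable fragment.
#' @param seed Optional seed override (default `config$seed + 3`).
#' @return Molecule data frame (same schema as [simulate_molecules()]),
#'   suitable for `rbind`ing onto endogenous molecules.
#' @export
simulate_ercc <- function(ercc, ercc_tx, config, capture_prob = 0.05,
                          seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (any(ercc$stock_attomol_per_ul < 0)) stop("negative stock concentration")
  expected <- ercc$copies * capture_prob
  set.seed(if (is.null(seed)) config$seed + 3L else seed)
  cnt <- stats::rpois(nrow(ercc), expected)
  n <- sum(cnt)
  if (n == 0L) return(empty_molecules())
  g <- rep(seq_len(nrow(ercc)), cnt)
  len <- ercc_tx$length_bp[match(ercc$ercc_id[g], ercc_tx$gene_id)]
  ok <- len >= config$fragment_min_bp   # panhandle rule also for spike-ins
  g <- g[ok]; len <- len[ok]; n <- length(g)
  if (n == 0L) return(empty_molecules())
  max_len <- pmin(config$fragment_max_bp, len)
  ins <- as.integer(pmin(config$fragment_min_bp +
    floor(stats::runif(n) * (max_len - config$fragment_min_bp + 1)), max_len))
  start <- as.integer(floor(stats::runif(n) * (len - ins + 1)))
  data.frame(molecule_id = sprintf("e%07d", seq_len(n)),
             gene_id = ercc$ercc_id[g],
             start_0based = start,
             insert_length_bp = ins,
             octamer5 = random_octamers(n),
             octamer3 = random_octamers(n),
             copy_count = branching_copies(n, config$pcr_cycles,
                                           config$per_cycle_efficiency),
             stringsAsFactors = FALSE)
}

#' Simulate a complete DRP library
#'
#' Convenience wrapper: transcriptome, molecules, optional spike-ins and
#' rendered reads in one call.
#'
#' @param config A [sim_config()].
#' @param ercc Optional `ercc_table`; when supplied, spike-in molecules
#'   are appended and the spike-in transcriptome merged in.
#' @param capture_prob Spike-in capture probability (see [simulate_ercc()]).
#' @param transcriptome Optional pre-built transcriptome (so replicates can
#'   share one); built from `config` when `NULL`.
#' @param molecule_seed,read_seed Optional per-stage seed overrides, used
#'   to draw independent technical replicates from a shared transcriptome.
#' @return List with `transcriptome`, `annotation`, `molecules`, `reads`,
#'   `truth`, and `ercc` (NULL when unused).
#' @export
simulate_library <- function(config, ercc = NULL, capture_prob = 0.05,
                             transcriptome = NULL,
                             molecule_seed = NULL, read_seed = NULL) {
  if (is.null(transcriptome)) transcriptome <- make_transcriptome(config)
  mol <- simulate_molecules(transcriptome, config, seed = molecule_seed)
  if (!is.null(ercc)) {
    etx <- ercc_transcriptome(ercc)
    emol <- simulate_ercc(ercc, etx, config, capture_prob = capture_prob,
                          seed = if (is.null(molecule_seed)) NULL
                                 else molecule_seed + 1L)
    transcriptome <- rbind(transcriptome, etx)
    class(transcriptome) <- c("drp_transcriptome", "data.frame")
    mol <- rbind(mol, emol)
  }
  rr <- render_reads(mol, transcriptome, config, seed = read_seed)
  list(transcriptome = transcriptome,
       annotation = transcriptome_annotation(transcriptome),
       molecules = mol, reads = rr$reads, truth = rr$truth, ercc = ercc)
}
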
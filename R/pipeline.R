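#' Derive a per-stage seed from the global seed
#'
#' Stage seeds are `(seed + polynomial-31 hash of the stage name) mod
#' (2^31 - 1)`, so every stochastic stage gets an explicit, documented,
#' reproducible stream and reruns are bit-identical.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  as.integer((seed + h) %% m)
}

.pipeline_sections <- list(
  simulate = c("n_genes", "expression_dispersion", "rrna_mass_fraction",
               "input_picograms", "capture_molecules_per_pg",
               "fragment_min_bp", "fragment_max_bp", "pcr_cycles",
               "per_cycle_efficiency", "read_length_nt", "error_rate",
               "adapter_offsets", "with_ercc", "ercc_capture_prob"),
  preprocess = c("max_forward_offset", "max_mismatches", "min_length",
                 "max_core"),
  quantify = c("max_mismatches"),
  analytics = c("fractions", "min_fpkm", "expressed_threshold",
                "ercc_floor", "n_bins"))

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list) with per-stage sections
#' `simulate`, `preprocess`, `quantify`, `analytics` plus a global
#' `seed`. Unknown keys are rejected outright so a typo cannot silently
#' fall back to a default.
#'
#' @param x Path to a YAML file or a named list.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(x = list()) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  known_top <- c(names(.pipeline_sections), "seed")
  extra <- setdiff(names(cfg), known_top)
  if (length(extra)) {
    stop("unknown configuration section(s): ", paste(extra, collapse = ", "))
  }
  for (sec in names(.pipeline_sections)) {
    extra <- setdiff(names(cfg[[sec]]), .pipeline_sections[[sec]])
    if (length(extra)) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(extra, collapse = ", "))
    }
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  fr <- cfg$analytics$fractions
  if (!is.null(fr) && any(fr <= 0 | fr > 1)) {
    stop("analytics fractions must lie in (0, 1]")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_sim_config <- function(cfg) {
  keys <- setdiff(.pipeline_sections$simulate,
                  c("with_ercc", "ercc_capture_prob"))
  args <- cfg$simulate[intersect(names(cfg$simulate), keys)]
  args$seed <- stage_seed(cfg$seed, "simulate")
  do.call(sim_config, args)
}

#' Run the full simulate-preprocess-quantify-analyze pipeline
#'
#' Executes the four stages in order, writing every intermediate as plain
#' text (FASTA/FASTQ/TSV) so external tools can be substituted at any
#' seam, plus a JSON manifest recording the package version, stage seeds,
#' output digests and per-stage statistics. When a manifest from an
#' earlier run is present and a stage's outputs still match their
#' recorded digests, that stage is skipped; stale digests force
#' recomputation.
#'
#' @param config A [pipeline_config()] (or path/list accepted by it).
#' @param out_dir Output directory, created if needed.
#' @param overwrite Force recomputation of all stages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  old <- if (!overwrite && file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  manifest <- list(package = "drpseq",
                   version = as.character(utils::packageVersion("drpseq")),
                   seed = cfg$seed, stages = list())

  paths <- list(
    simulate = file.path(out_dir, c("transcriptome.fasta", "annotation.tsv",
                                    "reads.fastq", "truth.tsv", "ercc.tsv")),
    preprocess = file.path(out_dir, c("inserts.fastq", "molecules.tsv",
                                      "stats.tsv")),
    quantify = file.path(out_dir, c("counts.tsv", "fpkm.tsv")),
    analytics = file.path(out_dir, c("saturation.tsv",
                                     "class_composition.tsv")))

  stage_fresh <- function(stage) {
    if (is.null(old)) return(FALSE)
    rec <- old$stages[[stage]]
    if (is.null(rec)) return(FALSE)
    files <- unlist(rec$files)
    digests <- unlist(rec$md5)
    all(file.exists(files)) &&
      identical(unname(tools::md5sum(files)), unname(digests))
  }
  record <- function(stage, files, extra = list()) {
    files <- files[file.exists(files)]
    manifest$stages[[stage]] <<- c(
      list(seed = stage_seed(cfg$seed, stage), files = files,
           md5 = unname(tools::md5sum(files))), extra)
  }

  # --- simulate ----------------------------------------------------------
  scfg <- pipeline_sim_config(cfg)
  with_ercc <- isTRUE(cfg$simulate$with_ercc)
  ercc <- if (with_ercc) synthetic_ercc_mix(seed = scfg$seed + 7L) else NULL
  if (!stage_fresh("simulate")) {
    lib <- simulate_library(scfg, ercc = ercc,
                            capture_prob =
                              cfg$simulate$ercc_capture_prob %||% 0.05)
    write_fasta(stats::setNames(lib$transcriptome$sequence,
                                lib$transcriptome$gene_id),
                paths$simulate[1L])
    write_tsv(lib$annotation, paths$simulate[2L])
    write_fastq(data.frame(id = lib$reads$read_id,
                           sequence = lib$reads$sequence,
                           stringsAsFactors = FALSE),
                paths$simulate[3L])
    write_tsv(lib$truth, paths$simulate[4L])
    if (!is.null(ercc)) write_tsv(as.data.frame(ercc), paths$simulate[5L])
  }
  record("simulate", paths$simulate,
         list(n_genes = scfg$n_genes))

  # --- preprocess --------------------------------------------------------
  scheme <- adapter_scheme(
    max_forward_offset = cfg$preprocess$max_forward_offset %||% 6L,
    max_mismatches = cfg$preprocess$max_mismatches %||% 0L)
  if (!stage_fresh("preprocess")) {
    pre <- preprocess_fastq(paths$simulate[3L], scheme,
                            out_dir = out_dir,
                            min_nt = cfg$preprocess$min_length %||% 30L,
                            max_core_nt = cfg$preprocess$max_core %||% 120L)
    pre_stats <- unclass(pre$stats)
  } else {
    st <- read_tsv_checked(paths$preprocess[3L], c("key", "value"))
    pre_stats <- as.list(stats::setNames(st$value, st$key))
  }
  record("preprocess", paths$preprocess, list(stats = pre_stats))

  # --- quantify ----------------------------------------------------------
  annotation <- read_tsv_checked(paths$simulate[2L],
                                 c("gene_id", "length_bp", "biotype"))
  tx <- data.frame(gene_id = names(read_fasta(paths$simulate[1L])),
                   sequence = unname(read_fasta(paths$simulate[1L])),
                   stringsAsFactors = FALSE)
  if (!stage_fresh("quantify")) {
    fq <- read_fastq(paths$preprocess[1L])
    asn <- toy_map(stats::setNames(fq$sequence, fq$id), tx,
                   max_mismatches = cfg$quantify$max_mismatches %||% 0L)
    fpkm <- compute_fpkm(asn, annotation)
    write_tsv(data.frame(gene_id = names(asn$counts),
                         assigned_fragments = unname(asn$counts),
                         stringsAsFactors = FALSE), paths$quantify[1L])
    write_fpkm_table(fpkm, paths$quantify[2L])
  } else {
    fq <- read_fastq(paths$preprocess[1L])
    asn <- toy_map(stats::setNames(fq$sequence, fq$id), tx,
                   max_mismatches = cfg$quantify$max_mismatches %||% 0L)
    fpkm <- compute_fpkm(asn, annotation)
  }
  record("quantify", paths$quantify,
         list(total_assigned = asn$total_assigned,
              unassigned = length(asn$unassigned)))

  # --- analytics ---------------------------------------------------------
  if (!stage_fresh("analytics")) {
    sat <- saturation(asn, annotation,
                      fractions = cfg$analytics$fractions %||%
                        seq(0.1, 1, by = 0.1),
                      seed = stage_seed(cfg$seed, "analytics"),
                      threshold = cfg$analytics$expressed_threshold %||% 1)
    write_tsv(as.data.frame(sat), paths$analytics[1L])
    comp <- class_composition(fpkm,
                              threshold =
                                cfg$analytics$expressed_threshold %||% 1)
    write_tsv(comp, paths$analytics[2L])
  }
  record("analytics", paths$analytics)

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
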
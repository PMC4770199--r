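#' Map inserts to a toy transcriptome by substring search
#'
#' Desk-scale stand-in for a spliced aligner: an insert matching exactly
#' one transcript (as a verbatim substring, on either strand) contributes
#' 1 fragment to that gene; an insert matching `k` distinct genes
#' contributes `1/k` to each (multi-locus fragments are distributed
#' uniformly); inserts matching nothing are reported unassigned. An insert
#' matching one gene at several positions counts once for that gene (the
#' first position is kept for coverage purposes).
#'
#' With `max_mismatches = 0` matching uses a constant-width seed
#' dictionary (Aho-Corasick via [Biostrings::PDict]) over a concatenated
#' subject, then verifies full-insert identity; with mismatches a slow
#' per-insert scan is used, intended for small inputs only.
#'
#' @param inserts Named character vector of insert sequences (names are
#'   molecule ids), or the `molecules` data frame from
#'   [preprocess_reads()].
#' @param transcriptome A `drp_transcriptome` (or data frame with
#'   `gene_id`, `sequence`).
#' @param max_mismatches Substitutions tolerated (default 0).
#' @return An object of class `drp_assignments`: list with
#'   \describe{
#'     \item{assignments}{data frame `read_id`, `gene_id`, `start_0based`,
#'       `insert_length`, `weight` (1/k).}
#'     \item{counts}{named numeric vector of per-gene assigned fragments
#'       (all genes, zeros included).}
#'     \item{total_assigned}{sum of assigned fragments.}
#'     \item{unassigned}{character vector of unmatched molecule ids.}
#'   }
#' @export
toy_map <- function(inserts, transcriptome, max_mismatches = 0L) {
  if (is.data.frame(inserts)) {
    inserts <- stats::setNames(inserts$insert, inserts$molecule_id)
  }
  if (is.null(transcriptome) || nrow(transcriptome) == 0L) {
    stop("empty transcriptome")
  }
  if (is.null(names(inserts))) {
    names(inserts) <- sprintf("M%07d", seq_along(inserts))
  }
  genes <- transcriptome$gene_id
  hits <- if (length(inserts) == 0L) {
    data.frame(pattern = integer(), gene = character(),
               start_0based = integer(), stringsAsFactors = FALSE)
  } else if (max_mismatches == 0L) {
    exact_substring_hits(unique(inserts), transcriptome)
  } else {
    fuzzy_substring_hits(unique(inserts), transcriptome, max_mismatches)
  }

  useq <- unique(inserts)
  # expand unique-sequence hits to molecule ids
  k_per_pattern <- integer(length(useq))
  if (nrow(hits)) {
    k_per_pattern <- tabulate(hits$pattern, nbins = length(useq))
  }
  pat_of <- match(inserts, useq)
  idx <- which(k_per_pattern[pat_of] > 0L)
  assignments <- if (length(idx)) {
    pieces <- split(seq_len(nrow(hits)), hits$pattern)
    rows <- unlist(pieces[as.character(pat_of[idx])], use.names = FALSE)
    reps <- k_per_pattern[pat_of[idx]]
    data.frame(read_id = rep(names(inserts)[idx], reps),
               gene_id = hits$gene[rows],
               start_0based = hits$start_0based[rows],
               insert_length = nchar(inserts[idx])[rep(seq_along(idx), reps)],
               weight = 1 / rep(reps, reps),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(read_id = character(), gene_id = character(),
               start_0based = integer(), insert_length = integer(),
               weight = numeric(), stringsAsFactors = FALSE)
  }
  counts <- stats::setNames(numeric(length(genes)), genes)
  if (nrow(assignments)) {
    s <- tapply(assignments$weight, assignments$gene_id, sum)
    counts[names(s)] <- as.numeric(s)
  }
  structure(list(assignments = assignments, counts = counts,
                 total_assigned = sum(assignments$weight),
                 unassigned = names(inserts)[k_per_pattern[pat_of] == 0L]),
            class = "drp_assignments")
}

#' @export
print.drp_assignments <- function(x, ...) {
  cat("DRP toy-mapper assignments:",
      length(unique(x$assignments$read_id)), "fragments assigned,",
      length(x$unassigned), "unassigned;",
      sprintf("total_assigned = %.3f\n", x$total_assigned))
  invisible(x)
}

# exact matching of variable-length patterns: constant-width seed PDict
# against all transcripts (both strands) concatenated with N spacers,
# then full-length verification at each seed hit
exact_substring_hits <- function(useq, transcriptome) {
  n_pat <- length(useq)
  widths <- nchar(useq)
  if (any(widths == 0L)) stop("empty insert sequence")
  w <- min(widths, 30L)
  spacer <- strrep("N", 60L)
  seqs <- transcriptome$sequence
  build <- function(s) {
    starts <- cumsum(c(1L, nchar(s) + nchar(spacer)))[seq_along(s)]
    list(subject = paste(s, collapse = spacer), starts = starts)
  }
  fwd <- build(seqs)
  rc <- build(revcomp(seqs))
  pd <- Biostrings::PDict(substr(useq, 1L, w))

  scan_strand <- function(built, strand) {
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(built$subject))
    st <- Biostrings::startIndex(m)
    lens <- lengths(st)
    if (sum(lens) == 0L) {
      return(data.frame(pattern = integer(), gene = character(),
                        start_0based = integer(),
                        stringsAsFactors = FALSE))
    }
    pat <- rep(seq_len(n_pat), lens)
    pos <- unlist(st, use.names = FALSE)
    # verify the full insert, not just the seed
    full <- substring(built$subject, pos, pos + widths[pat] - 1L)
    ok <- full == useq[pat]
    pat <- pat[ok]; pos <- pos[ok]
    ti <- findInterval(pos, built$starts)
    tlen <- nchar(seqs)[ti]
    local <- pos - built$starts[ti]        # 0-based on the built strand
    start0 <- if (strand == "+") local else tlen - local - widths[pat]
    data.frame(pattern = pat, gene = transcriptome$gene_id[ti],
               start_0based = as.integer(start0),
               stringsAsFactors = FALSE)
  }
  hits <- rbind(scan_strand(fwd, "+"), scan_strand(rc, "-"))
  if (nrow(hits) == 0L) return(hits)
  # one count per (pattern, gene) regardless of position/strand
  hits <- hits[!duplicated(hits[c("pattern", "gene")]), , drop = FALSE]
  hits[order(hits$pattern), , drop = FALSE]
}

fuzzy_substring_hits <- function(useq, transcriptome, max_mismatches) {
  subj <- Biostrings::DNAStringSet(transcriptome$sequence)
  rcsub <- Biostrings::reverseComplement(subj)
  rows <- list()
  for (i in seq_along(useq)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") subj else rcsub
      m <- Biostrings::vmatchPattern(useq[i], s,
                                     max.mismatch = max_mismatches)
      st <- Biostrings::startIndex(m)
      for (t in which(lengths(st) > 0L)) {
        pos <- min(st[[t]])
        tlen <- nchar(transcriptome$sequence[t])
        start0 <- if (strand == "+") pos - 1L else
          tlen - (pos - 1L) - nchar(useq[i])
        rows[[length(rows) + 1L]] <-
          data.frame(pattern = i, gene = transcriptome$gene_id[t],
                     start_0based = as.integer(start0),
                     stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pattern = integer(), gene = character(),
               start_0based = integer(), stringsAsFactors = FALSE)
  hits[!duplicated(hits[c("pattern", "gene")]), , drop = FALSE]
}

#' FPKM without effective-length correction
#'
#' `fpkm = assigned_fragments * 1e9 / (length_bp * total_assigned)` with
#' the annotated transcript length (no effective-length correction) and
#' `total_assigned` the sum of assigned fragments only (compatible-hits
#' normalization: unassigned reads never enter the denominator).
#'
#' @param counts Named numeric vector (one sample) or matrix with genes in
#'   rows and samples in columns, or a `drp_assignments` object.
#' @param annotation Data frame with `gene_id`, `length_bp` and optionally
#'   `biotype`.
#' @param total_assigned Optional per-sample totals; defaults to the
#'   column sums of `counts`.
#' @return Data frame of class `drp_fpkm`: `gene_id`, `length_bp`,
#'   `biotype`, then one numeric column per sample.
#' @export
compute_fpkm <- function(counts, annotation, total_assigned = NULL) {
  if (inherits(counts, "drp_assignments")) counts <- counts$counts
  if (is.null(dim(counts))) {
    counts <- matrix(counts, ncol = 1L,
                     dimnames = list(names(counts), "sample_1"))
  }
  ann <- annotation[match(rownames(counts), annotation$gene_id), ]
  if (any(is.na(ann$gene_id))) {
    stop("annotation missing gene(s): ",
         paste(utils::head(setdiff(rownames(counts), annotation$gene_id), 5),
               collapse = ", "))
  }
  if (any(is.na(ann$length_bp)) || any(ann$length_bp <= 0)) {
    stop("gene lengths must be positive")
  }
  if (is.null(total_assigned)) total_assigned <- colSums(counts)
  if (any(total_assigned <= 0)) stop("total assigned fragments must be > 0")
  fpkm <- sweep(counts * 1e9 / ann$length_bp, 2L, total_assigned, "/")
  out <- data.frame(gene_id = rownames(counts),
                    length_bp = ann$length_bp,
                    biotype = if ("biotype" %in% names(ann)) ann$biotype
                              else NA_character_,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(fpkm, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("drp_fpkm", "data.frame")
  out
}

#' Sample columns of an FPKM table
#' @param fpkm A `drp_fpkm` data frame.
#' @return Character vector of sample column names.
#' @export
fpkm_samples <- function(fpkm) {
  setdiff(names(fpkm), c("gene_id", "length_bp", "biotype"))
}

#' Expressed genes at an FPKM threshold
#'
#' A gene counts as expressed when its FPKM is at or above `threshold`
#' (default 1). Spike-ins (`ERCC-` prefixed ids) are removed first when
#' `exclude_ercc` is set, matching the convention of counting detectable
#' genes after ERCC removal.
#'
#' @param fpkm A `drp_fpkm` data frame.
#' @param threshold Detection threshold (default 1).
#' @param exclude_ercc Drop spike-in ids before thresholding.
#' @param samples Sample columns to use (default: all).
#' @return Named list of gene-id character vectors, one per sample.
#' @export
expressed_genes <- function(fpkm, threshold = 1, exclude_ercc = TRUE,
                            samples = NULL) {
  if (is.null(samples)) samples <- fpkm_samples(fpkm)
  keep <- if (exclude_ercc) !is_ercc_id(fpkm$gene_id) else
    rep(TRUE, nrow(fpkm))
  lapply(stats::setNames(samples, samples), function(s) {
    fpkm$gene_id[keep & fpkm[[s]] >= threshold]
  })
}

#' Read an externally produced FPKM table
#'
#' Entry point for real data quantified outside the package (e.g.
#' Cufflinks `genes.fpkm_tracking`): maps the named columns onto the
#' internal layout.
#'
#' @param path TSV file with a header.
#' @param id_col Column holding gene ids.
#' @param fpkm_cols Named character vector mapping output sample names to
#'   input FPKM columns; by default the single column `FPKM` becomes
#'   sample `sample_1`.
#' @param length_col,biotype_col Optional column names for gene length and
#'   biotype (filled with `NA` when absent).
#' @return A `drp_fpkm` data frame.
#' @export
read_fpkm_table <- function(path, id_col = "tracking_id",
                            fpkm_cols = c(sample_1 = "FPKM"),
                            length_col = NULL, biotype_col = NULL) {
  x <- read_tsv_checked(path, required = c(id_col, unname(fpkm_cols)))
  out <- data.frame(gene_id = as.character(x[[id_col]]),
                    length_bp = if (!is.null(length_col))
                      x[[length_col]] else NA_integer_,
                    biotype = if (!is.null(biotype_col))
                      x[[biotype_col]] else NA_character_,
                    stringsAsFactors = FALSE)
  for (s in names(fpkm_cols)) out[[s]] <- as.numeric(x[[fpkm_cols[[s]]]])
  class(out) <- c("drp_fpkm", "data.frame")
  out
}

#' Write an FPKM (or count) table as TSV
#' @param fpkm A `drp_fpkm` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fpkm_table <- function(fpkm, path) write_tsv(fpkm, path)
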
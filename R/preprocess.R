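#' Adapter scheme for DRP read processing
#'
#' Fixes the sequences and search parameters the trimmer operates with.
#' The reverse adapter must be the reverse complement of the forward one
#' (that complementarity is what makes the amplicon ends anneal into a
#' panhandle); this is asserted at construction.
#'
#' @param forward_malbac Minimal forward adapter (25 nt).
#' @param reverse_malbac Reverse adapter; must equal
#'   `revcomp(forward_malbac)`.
#' @param octamer_len Length of the random priming octamer (UMI), 8.
#' @param illumina_adapter Sequencing adapter removed from read 3' ends
#'   (standard TruSeq read-1 adapter by default).
#' @param max_forward_offset Largest allowed start offset of the forward
#'   adapter match; the forward motif is a 5'-anchored gate, not a free
#'   alignment.
#' @param max_mismatches Substitutions tolerated when matching either
#'   adapter (0 = exact).
#' @return A list of class `adapter_scheme`.
#' @export
adapter_scheme <- function(forward_malbac = "GAGTGATGGTTGAGGTAGTGTGGAG",
                           reverse_malbac = revcomp(forward_malbac),
                           octamer_len = 8L,
                           illumina_adapter =
                             "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                           max_forward_offset = 6L,
                           max_mismatches = 0L) {
  if (!identical(reverse_malbac, revcomp(forward_malbac))) {
    stop("reverse_malbac must be the reverse complement of forward_malbac")
  }
  stopifnot(octamer_len >= 1L, max_forward_offset >= 0L,
            max_mismatches >= 0L, nchar(illumina_adapter) >= 5L)
  structure(list(forward_malbac = forward_malbac,
                 reverse_malbac = reverse_malbac,
                 octamer_len = as.integer(octamer_len),
                 illumina_adapter = illumina_adapter,
                 max_forward_offset = as.integer(max_forward_offset),
                 max_mismatches = as.integer(max_mismatches)),
            class = "adapter_scheme")
}

#' Strip the Illumina sequencing adapter from read 3' ends
#'
#' Removes the leftmost full occurrence of the adapter (read-through) or,
#' failing that, the longest partial overlap of at least 5 nt between the
#' read's 3' end and the adapter's 5' end. Sequences without a hit are
#' returned unchanged. Vectorized over reads.
#'
#' @param read_sequence Character vector of read sequences.
#' @param scheme An [adapter_scheme()].
#' @return Character vector of the same length.
#' @export
strip_illumina_adapter <- function(read_sequence, scheme = adapter_scheme()) {
  ad <- scheme$illumina_adapter
  out <- read_sequence
  pos <- regexpr(ad, out, fixed = TRUE)
  hit <- pos > 0L
  out[hit] <- substr(out[hit], 1L, pos[hit] - 1L)
  todo <- !hit
  for (k in seq(nchar(ad) - 1L, 5L)) {
    if (!any(todo)) break
    pref <- substr(ad, 1L, k)
    m <- todo & endsWith(out, pref)
    out[m] <- substr(out[m], 1L, nchar(out[m]) - k)
    todo <- todo & !m
  }
  out
}

# Hamming-tolerant anchored window comparison, vectorized over sequences:
# number of mismatches of pattern against seqs starting at 1-based `at`
window_mismatches <- function(seqs, pattern, at) {
  plen <- nchar(pattern)
  mm <- integer(length(seqs))
  pchars <- strsplit(pattern, "")[[1]]
  for (j in seq_len(plen)) {
    mm <- mm + (substr(seqs, at + j - 1L, at + j - 1L) != pchars[j])
  }
  mm + (nchar(seqs) < at + plen - 1L) * plen  # too short never matches
}

#' Locate the forward adapter near the 5' end
#'
#' Returns the 0-based offset of the leftmost match of the forward adapter
#' with at most `max_mismatches` substitutions among start offsets
#' `0..max_forward_offset`, or `NA` when the read lacks the motif (such
#' reads are discarded downstream).
#'
#' @param read_sequence Character vector (Illumina adapter already
#'   stripped).
#' @param scheme An [adapter_scheme()].
#' @return Integer vector of offsets, `NA` where absent.
#' @export
locate_forward_adapter <- function(read_sequence,
                                   scheme = adapter_scheme()) {
  fwd <- scheme$forward_malbac
  res <- rep(NA_integer_, length(read_sequence))
  for (o in 0:scheme$max_forward_offset) {
    open <- is.na(res)
    if (!any(open)) break
    if (scheme$max_mismatches == 0L) {
      hit <- substr(read_sequence, o + 1L, o + nchar(fwd)) == fwd
    } else {
      hit <- window_mismatches(read_sequence, fwd, o + 1L) <=
        scheme$max_mismatches
    }
    res[open & hit] <- o
  }
  res
}

# leftmost occurrence (1-based) of pattern in each core, mismatch-tolerant;
# exact matching takes the fast fixed-string path
leftmost_match <- function(cores, pattern, max_mismatches) {
  if (max_mismatches == 0L) {
    p <- regexpr(pattern, cores, fixed = TRUE)
    p[p < 0L] <- NA_integer_
    return(as.integer(p))
  }
  na <- is.na(cores)
  cores[na] <- ""
  subj <- Biostrings::DNAStringSet(cores)
  m <- Biostrings::vmatchPattern(pattern, subj,
                                 max.mismatch = max_mismatches)
  st <- Biostrings::startIndex(m)
  vapply(st, function(s) if (length(s)) min(s) else NA_integer_,
         integer(1))
}

#' Dual-mode trimming of adapter-gated reads
#'
#' For each read whose forward adapter was located, the *core* is
#' everything after the adapter's end. If the reverse adapter occurs in
#' the core (leftmost match), the core is cut at its start and the read is
#' in `BOTH_ADAPTERS` mode, carrying a 5' and a 3' octamer. Otherwise only
#' the first `max_core_nt` (default 120) bases of the core are considered
#' (`FORWARD_ONLY` mode, 5' octamer only). Reads are discarded when the
#' forward adapter is absent, when the reverse adapter sits within the
#' first `2 * octamer_len` bases (no room for both octamers), or when the
#' core cannot hold the octamer(s).
#'
#' @param read_sequence Character vector (Illumina adapter stripped).
#' @param scheme An [adapter_scheme()].
#' @param max_core_nt Window applied to cores lacking the reverse adapter.
#' @return Data frame with one row per input read: `keep` (logical),
#'   `reason` (`NA` for kept reads), `mode`, `core_with_octamers`,
#'   `insert`, `octamer5`, `octamer3` (`NA` in `FORWARD_ONLY` mode).
#' @export
trim_read <- function(read_sequence, scheme = adapter_scheme(),
                      max_core_nt = 120L) {
  n <- length(read_sequence)
  olen <- scheme$octamer_len
  out <- data.frame(keep = logical(n),
                    reason = rep(NA_character_, n),
                    mode = rep(NA_character_, n),
                    core_with_octamers = rep(NA_character_, n),
                    insert = rep(NA_character_, n),
                    octamer5 = rep(NA_character_, n),
                    octamer3 = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  off <- locate_forward_adapter(read_sequence, scheme)
  absent <- is.na(off)
  out$reason[absent] <- "no_forward_adapter"
  if (all(absent)) return(out)

  core <- substr(read_sequence, off + nchar(scheme$forward_malbac) + 1L,
                 nchar(read_sequence))
  rpos <- leftmost_match(core, scheme$reverse_malbac,
                         scheme$max_mismatches)
  rpos[absent] <- NA_integer_

  both <- !absent & !is.na(rpos)
  tight <- both & (rpos - 1L) < 2L * olen
  out$reason[tight] <- "reverse_within_octamers"
  both <- both & !tight

  out$mode[both] <- "BOTH_ADAPTERS"
  bc <- substr(core[both], 1L, rpos[both] - 1L)
  out$core_with_octamers[both] <- bc
  out$octamer5[both] <- substr(bc, 1L, olen)
  out$octamer3[both] <- substr(bc, nchar(bc) - olen + 1L, nchar(bc))
  out$insert[both] <- substr(bc, olen + 1L, nchar(bc) - olen)
  out$keep[both] <- TRUE

  fo <- !absent & is.na(rpos)
  fc <- substr(core[fo], 1L, max_core_nt)
  short <- nchar(fc) < olen
  out$reason[which(fo)[short]] <- "core_too_short"
  keep_fo <- rep(FALSE, n)
  keep_fo[which(fo)[!short]] <- TRUE
  fc <- fc[!short]
  out$mode[keep_fo] <- "FORWARD_ONLY"
  out$core_with_octamers[keep_fo] <- fc
  out$octamer5[keep_fo] <- substr(fc, 1L, olen)
  out$insert[keep_fo] <- substr(fc, olen + 1L, nchar(fc))
  out$keep[keep_fo] <- TRUE
  out
}

#' Minimum-length filter for trimmed inserts
#'
#' @param insert Character vector of inserts (octamers removed).
#' @param min_nt Minimum length; the mapping step requires 30 nt.
#' @return Logical vector, `TRUE` where the insert passes.
#' @export
length_filter <- function(insert, min_nt = 30L) {
  !is.na(insert) & nchar(insert) >= min_nt
}

#' Collapse identical reads into molecules
#'
#' Reads are grouped by exact identity of `(mode, core_with_octamers)` —
#' i.e. *before* octamer removal, so the random octamer acts as the
#' molecular counter separating independent priming events from PCR
#' duplicates. Groups from different modes never merge. Output order is
#' first occurrence in the input stream.
#'
#' @param trimmed Data frame from [trim_read()] (only `keep` rows are
#'   used), or any data frame with `mode`, `core_with_octamers`, `insert`,
#'   `octamer5`, `octamer3`.
#' @return Data frame with one row per unique molecule: `molecule_id`,
#'   `read_count`, `mode`, `octamer5`, `octamer3`, `insert`,
#'   `insert_length`.
#' @export
collapse_molecules <- function(trimmed) {
  if ("keep" %in% names(trimmed)) trimmed <- trimmed[trimmed$keep, ]
  if (nrow(trimmed) == 0L) {
    return(data.frame(molecule_id = character(), read_count = integer(),
                      mode = character(), octamer5 = character(),
                      octamer3 = character(), insert = character(),
                      insert_length = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(trimmed$mode, trimmed$core_with_octamers, sep = "\r")
  first <- !duplicated(key)
  grp <- match(key, key[first])
  mol <- trimmed[first, c("mode", "octamer5", "octamer3", "insert")]
  data.frame(molecule_id = sprintf("M%07d", seq_len(sum(first))),
             read_count = tabulate(grp, nbins = sum(first)),
             mol,
             insert_length = nchar(mol$insert),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full read-processing pipeline on in-memory reads
#'
#' Orchestrates Illumina-adapter stripping, forward-adapter gating,
#' dual-mode trimming, identical-read collapsing and the minimum-length
#' filter, and assembles the bookkeeping statistics. `duplicate_fraction`
#' is `1 - molecules_out / reads_surviving`, both taken over molecules
#' that pass the length filter.
#'
#' @param sequences Character vector of raw read sequences.
#' @param scheme An [adapter_scheme()].
#' @param min_nt Minimum insert length (default 30).
#' @param max_core_nt `FORWARD_ONLY` core window (default 120).
#' @return List with `molecules` (length-passing molecules, see
#'   [collapse_molecules()]), `stats` (class `drp_preprocess_stats`) and
#'   `trimmed` (the per-read trim table).
#' @export
preprocess_reads <- function(sequences, scheme = adapter_scheme(),
                             min_nt = 30L, max_core_nt = 120L) {
  reads_in <- length(sequences)
  stripped <- strip_illumina_adapter(sequences, scheme)
  trimmed <- trim_read(stripped, scheme, max_core_nt = max_core_nt)
  with_fwd <- sum(is.na(trimmed$reason) |
                    trimmed$reason != "no_forward_adapter")
  mol <- collapse_molecules(trimmed)
  pass <- length_filter(mol$insert, min_nt)
  kept <- mol[pass, , drop = FALSE]
  kept$molecule_id <- sprintf("M%07d", seq_len(nrow(kept)))
  reads_surviving <- sum(kept$read_count)
  stats <- structure(list(
    reads_in = reads_in,
    reads_with_forward_adapter = with_fwd,
    reads_discarded_no_adapter = reads_in - with_fwd,
    reads_mode_both = sum(trimmed$keep &
                            trimmed$mode == "BOTH_ADAPTERS", na.rm = TRUE),
    reads_mode_forward_only = sum(trimmed$keep &
                                    trimmed$mode == "FORWARD_ONLY",
                                  na.rm = TRUE),
    reads_failing_length = sum(mol$read_count[!pass]),
    molecules_out = nrow(kept),
    reads_surviving = reads_surviving,
    duplicate_fraction = if (reads_surviving > 0)
      1 - nrow(kept) / reads_surviving else NA_real_),
    class = "drp_preprocess_stats")
  list(molecules = kept, stats = stats, trimmed = trimmed)
}

#' @export
print.drp_preprocess_stats <- function(x, ...) {
  cat("DRP preprocessing stats\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-28s %s\n", k,
                if (is.numeric(v) && !is.na(v) && v %% 1 != 0)
                  sprintf("%.4f", v) else format(v)))
  }
  invisible(x)
}

#' Preprocess a FASTQ file
#'
#' File-level wrapper around [preprocess_reads()]: reads a (gzip
#' transparent) FASTQ, processes it, and optionally writes one FASTQ
#' record per unique molecule (insert only), a molecules TSV and a
#' key-value stats TSV into `out_dir`.
#'
#' @param input Path to a FASTQ file, or a data frame as returned by
#'   [read_fastq()].
#' @param scheme An [adapter_scheme()].
#' @param out_dir Optional output directory.
#' @param min_nt,max_core_nt See [preprocess_reads()].
#' @return The [preprocess_reads()] result, invisibly when writing files.
#' @export
preprocess_fastq <- function(input, scheme = adapter_scheme(),
                             out_dir = NULL, min_nt = 30L,
                             max_core_nt = 120L) {
  fq <- if (is.character(input)) read_fastq(input) else input
  res <- preprocess_reads(fq$sequence, scheme, min_nt = min_nt,
                          max_core_nt = max_core_nt)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fastq(stats::setNames(res$molecules$insert,
                                res$molecules$molecule_id),
                file.path(out_dir, "inserts.fastq"))
    write_tsv(res$molecules[, c("molecule_id", "read_count", "mode",
                                "octamer5", "octamer3", "insert_length")],
              file.path(out_dir, "molecules.tsv"))
    st <- res$stats
    write_tsv(data.frame(key = names(st),
                         value = vapply(st, format, character(1)),
                         stringsAsFactors = FALSE),
              file.path(out_dir, "stats.tsv"))
    return(invisible(res))
  }
  res
}
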
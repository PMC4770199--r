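#' Read a 4-line FASTQ file
#'
#' Reads a (possibly gzip-compressed) FASTQ file into a data frame. The
#' parser is strict about the 4-line record framing and fails fast with the
#' index of the first malformed record and the offending line number, which
#' matters when diagnosing truncated sequencer output.
#'
#' @param path Path to a FASTQ file; `.gz` files are read transparently.
#' @return A data frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ '", path, "': ", length(lines),
         " lines is not a multiple of 4 (truncated record at line ",
         4L * (length(lines) %/% 4L) + 1L, ")")
  }
  n <- length(lines) %/% 4L
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  qu <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+"))
  if (length(bad)) {
    i <- bad[1L]
    stop("malformed FASTQ '", path, "': record ", i,
         " (line ", 4L * (i - 1L) + 1L, ") has broken @/+ framing")
  }
  bad <- which(nchar(sq) != nchar(qu))
  if (length(bad)) {
    i <- bad[1L]
    stop("malformed FASTQ '", path, "': record ", i,
         " (line ", 4L * (i - 1L) + 2L,
         ") sequence and quality lengths differ")
  }
  data.frame(id = sub("\\s.*$", "", substring(hd, 2L)),
             sequence = sq, quality = qu, stringsAsFactors = FALSE)
}

#' Write a 4-line FASTQ file
#'
#' @param x Data frame with `id` and `sequence` columns (optionally
#'   `quality`), or a named character vector of sequences.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param quality Constant quality character used when `x` carries no
#'   quality strings (default `"I"`, Phred+33 Q40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path, quality = "I") {
  if (is.character(x)) {
    x <- data.frame(id = names(x), sequence = unname(x),
                    stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "sequence") %in% names(x)))
  qual <- if ("quality" %in% names(x)) x$quality else
    strrep(quality, nchar(x$sequence))
  out <- character(4L * nrow(x))
  out[seq(1L, by = 4L, length.out = nrow(x))] <- paste0("@", x$id)
  out[seq(2L, by = 4L, length.out = nrow(x))] <- x$sequence
  out[seq(3L, by = 4L, length.out = nrow(x))] <- "+"
  out[seq(4L, by = 4L, length.out = nrow(x))] <- qual
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a TSV table with header validation
#'
#' Thin wrapper around [utils::read.delim()] that tolerates CRLF line
#' endings and checks that required columns are present before returning.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param required Character vector of column names that must be present.
#' @return A data frame.
#' @export
read_tsv_checked <- function(path, required = NULL) {
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(x))
    if (length(missing)) {
      stop("'", path, "' is missing required column(s): ",
           paste(missing, collapse = ", "))
    }
  }
  x
}

#' Write a data frame as TSV
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_ercc_id <- function(x) startsWith(x, "ERCC-")
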
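#' Saturation analysis by fragment subsampling
#'
#' For each requested fraction, fragments are subsampled without
#' replacement (seeded), counts and FPKM recomputed on the subsample, and
#' genes at or above the detection threshold counted after spike-in
#' removal. At fraction 1.0 the curve equals the full-sample expressed
#' count exactly.
#'
#' @param assignments A `drp_assignments` object (or its `assignments`
#'   data frame with `read_id`, `gene_id`, `weight`).
#' @param annotation Data frame with `gene_id`, `length_bp`.
#' @param fractions Fractions of fragments to draw, each in `(0, 1]`.
#' @param seed Seed for the subsampling stream.
#' @param threshold Detection threshold on FPKM (default 1).
#' @param sample_id Label carried into the output.
#' @return Data frame of class `drp_saturation`: `sample_id`, `fraction`,
#'   `reads_used`, `genes_detected`.
#' @export
saturation <- function(assignments, annotation,
                       fractions = seq(0.1, 1, by = 0.1), seed = 1L,
                       threshold = 1, sample_id = "sample_1") {
  asn <- if (inherits(assignments, "drp_assignments"))
    assignments$assignments else assignments
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  ids <- unique(asn$read_id)
  n <- length(ids)
  set.seed(seed)
  res <- lapply(fractions, function(f) {
    take <- if (f == 1) ids else sample(ids, round(f * n))
    sub <- asn[asn$read_id %in% take, , drop = FALSE]
    cnt <- tapply(sub$weight, sub$gene_id, sum)
    counts <- stats::setNames(numeric(nrow(annotation)),
                              annotation$gene_id)
    counts[names(cnt)] <- as.numeric(cnt)
    fpkm <- compute_fpkm(counts, annotation)
    data.frame(sample_id = sample_id, fraction = f,
               reads_used = length(take),
               genes_detected =
                 length(expressed_genes(fpkm, threshold)[[1]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("drp_saturation", "data.frame")
  out
}

#' Gene-class composition of expressed FPKM
#'
#' Sums the FPKM of expressed genes (FPKM at or above `threshold`) within
#' each biotype and reports percentages of the per-sample total. Biotype
#' overrides handle annotation fixes such as moving the abundant
#' ribosomal transcript Gm26924 from lincRNA into the rRNA class.
#'
#' @param fpkm A `drp_fpkm` data frame with a `biotype` column.
#' @param biotype_overrides Named character vector `gene_id -> biotype`.
#' @param threshold Expression threshold (default 1).
#' @param exclude_ercc Drop spike-ins before summing.
#' @return Long data frame: `sample_id`, `biotype`, `percent_of_total_fpkm`.
#' @export
class_composition <- function(fpkm, biotype_overrides = NULL,
                              threshold = 1, exclude_ercc = TRUE) {
  x <- fpkm
  if (exclude_ercc) x <- x[!is_ercc_id(x$gene_id), , drop = FALSE]
  if (!is.null(biotype_overrides)) {
    hit <- match(x$gene_id, names(biotype_overrides))
    x$biotype[!is.na(hit)] <- biotype_overrides[hit[!is.na(hit)]]
  }
  bad <- is.na(x$biotype) | x$biotype == ""
  if (any(bad)) {
    stop("missing biotype for gene(s): ",
         paste(utils::head(x$gene_id[bad], 5), collapse = ", "))
  }
  samples <- fpkm_samples(x)
  out <- do.call(rbind, lapply(samples, function(s) {
    expressed <- x[[s]] >= threshold
    v <- tapply(x[[s]][expressed], x$biotype[expressed], sum)
    data.frame(sample_id = s, biotype = names(v),
               percent_of_total_fpkm = 100 * as.numeric(v) / sum(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of assigned bases falling in rRNA genes
#'
#' Base-level counterpart of the FPKM composition: the summed insert
#' lengths (weighted, so multi-gene fragments split uniformly) of
#' fragments assigned to rRNA genes over all assigned bases.
#'
#' @param assignments A `drp_assignments` object or its data frame (needs
#'   `gene_id`, `insert_length`, `weight`).
#' @param rrna_genes Character vector of rRNA gene ids.
#' @return A single number in `[0, 1]`.
#' @export
rrna_base_fraction <- function(assignments, rrna_genes) {
  asn <- if (inherits(assignments, "drp_assignments"))
    assignments$assignments else assignments
  bases <- asn$weight * asn$insert_length
  total <- sum(bases)
  if (total <= 0) stop("no assigned bases")
  sum(bases[asn$gene_id %in% rrna_genes]) / total
}

#' Gene-body coverage along the normalized transcript length
#'
#' Rescales each transcript to `n_bins` bins, accumulates (weighted)
#' fragment coverage, normalizes each gene's profile to mean 1 so genes
#' contribute equally, averages over the selected genes and normalizes
#' the averaged profile to mean 1.
#'
#' @param assignments A `drp_assignments` object or data frame with
#'   `gene_id`, `start_0based`, `insert_length`, `weight`.
#' @param annotation Data frame with `gene_id`, `length_bp`.
#' @param n_bins Number of bins (default 100).
#' @param genes Genes to average over (default: all genes with at least
#'   one assigned fragment); typically the expressed set.
#' @return Numeric vector of length `n_bins`, mean 1.
#' @export
gene_body_coverage <- function(assignments, annotation, n_bins = 100L,
                               genes = NULL) {
  asn <- if (inherits(assignments, "drp_assignments"))
    assignments$assignments else assignments
  if (is.null(genes)) genes <- unique(asn$gene_id)
  len <- stats::setNames(annotation$length_bp, annotation$gene_id)
  acc <- numeric(n_bins)
  used <- 0L
  for (g in genes) {
    rows <- asn$gene_id == g
    if (!any(rows)) next
    L <- len[[g]]
    b1 <- pmin(pmax(floor(asn$start_0based[rows] / L * n_bins) + 1L, 1L),
               n_bins)
    b2 <- pmin(pmax(ceiling((asn$start_0based[rows] +
                               asn$insert_length[rows]) / L * n_bins), 1L),
               n_bins)
    w <- asn$weight[rows]
    delta <- numeric(n_bins + 1L)
    for (i in seq_along(b1)) {
      delta[b1[i]] <- delta[b1[i]] + w[i]
      delta[b2[i] + 1L] <- delta[b2[i] + 1L] - w[i]
    }
    prof <- cumsum(delta[seq_len(n_bins)])
    if (mean(prof) > 0) {
      acc <- acc + prof / mean(prof)
      used <- used + 1L
    }
  }
  if (used == 0L) stop("no coverage on the selected genes")
  prof <- acc / used
  prof / mean(prof)
}

#' Spike-in linearity: FPKM against calculated copy number
#'
#' Floors spike-in FPKM at `floor` (default 0.1), then correlates
#' log10(FPKM) with log10(copies) over spike-ins with positive copy
#' number. The floor transform is idempotent.
#'
#' @param fpkm A `drp_fpkm` table containing the spike-in ids.
#' @param ercc An `ercc_table` with `ercc_id` and `copies`.
#' @param floor FPKM floor (default 0.1).
#' @param sample Sample column to analyse (default: first).
#' @return List with `table` (`ercc_id`, `copies`, `fpkm`,
#'   `fpkm_floored`) and `pearson_log` (the log-log Pearson coefficient).
#' @export
ercc_analysis <- function(fpkm, ercc, floor = 0.1, sample = NULL) {
  if (is.null(sample)) sample <- fpkm_samples(fpkm)[1L]
  idx <- match(ercc$ercc_id, fpkm$gene_id)
  tab <- data.frame(ercc_id = ercc$ercc_id, copies = ercc$copies,
                    fpkm = ifelse(is.na(idx), 0, fpkm[[sample]][idx]),
                    stringsAsFactors = FALSE)
  tab$fpkm_floored <- pmax(tab$fpkm, floor)
  pos <- tab$copies > 0
  if (sum(pos) < 3L) stop("need at least 3 spike-ins with copies > 0")
  r <- stats::cor(log10(tab$copies[pos]), log10(tab$fpkm_floored[pos]))
  list(table = tab, pearson_log = r)
}

#' Replicate concordance of FPKM values
#'
#' For each sample pair, genes passing the FPKM filter in *either* sample
#' (union rule, so Pearson and Spearman see the same gene set) are
#' retained and both coefficients computed on the (by default
#' untransformed) FPKM values.
#'
#' @param fpkm A `drp_fpkm` table with at least two sample columns.
#' @param pairs Optional 2-column matrix/data frame of sample-name pairs;
#'   default all pairs.
#' @param min_fpkm Filter threshold (default 0.001).
#' @param log Correlate on log10 scale (with the filter threshold as
#'   implicit floor) instead of raw FPKM.
#' @param exclude_ercc Drop spike-ins first.
#' @return Data frame: `sample_a`, `sample_b`, `n_genes`, `pearson`,
#'   `spearman` (NA for degenerate constant vectors).
#' @export
replicate_concordance <- function(fpkm, pairs = NULL, min_fpkm = 0.001,
                                  log = FALSE, exclude_ercc = TRUE) {
  x <- fpkm
  if (exclude_ercc) x <- x[!is_ercc_id(x$gene_id), , drop = FALSE]
  samples <- fpkm_samples(x)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(samples, 2L))
  }
  pairs <- as.matrix(pairs)
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- x[[pairs[i, 1L]]]
    b <- x[[pairs[i, 2L]]]
    keep <- a >= min_fpkm | b >= min_fpkm   # union rule
    a <- a[keep]; b <- b[keep]
    if (log) {
      a <- log10(pmax(a, min_fpkm)); b <- log10(pmax(b, min_fpkm))
    }
    safe_cor <- function(method) {
      if (length(a) < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) {
        return(NA_real_)
      }
      stats::cor(a, b, method = method)
    }
    data.frame(sample_a = pairs[i, 1L], sample_b = pairs[i, 2L],
               n_genes = sum(keep), pearson = safe_cor("pearson"),
               spearman = safe_cor("spearman"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Detection overlap across replicates
#'
#' @param sets Named list of expressed gene-id vectors, one per replicate.
#' @return List with `common` (intersection across all replicates) and
#'   `percent_common` (share of each replicate's set that is common; `NA`
#'   for empty replicate sets).
#' @export
detection_overlap <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 replicates")
  common <- Reduce(intersect, sets)
  pct <- vapply(sets, function(s) {
    if (length(s) == 0L) NA_real_ else 100 * length(intersect(common, s)) /
      length(s)
  }, numeric(1))
  list(common = common, percent_common = pct)
}

#' Subtract dilution-control hits from a differential list
#'
#' Removes from the significant genes of `de_main` those genes that are
#' also significant in the cycle-number control experiment *on the
#' matching arm*: control genes enriched in undiluted RNA (`side_A`)
#' remove somatodendritic (`side_A`) hits, control genes enriched in
#' diluted RNA (`side_B`) remove axonal (`side_B`) hits. The result is
#' always a subset of the significant main list.
#'
#' @param de_main Data frame with `gene_id`, `log2_fold_change`,
#'   `q_value`, `direction` (`"side_A"`/`"side_B"`).
#' @param de_control Same layout; `side_A` = enriched in undiluted,
#'   `side_B` = enriched in diluted control RNA. May have zero rows.
#' @param alpha Significance cutoff on `q_value` (default 0.05).
#' @return The retained significant rows of `de_main`, with an attribute
#'   `removed` holding the subtracted gene ids per side.
#' @export
control_subtract <- function(de_main, de_control, alpha = 0.05) {
  sig <- de_main[de_main$q_value < alpha, , drop = FALSE]
  ctrl <- de_control[de_control$q_value < alpha, , drop = FALSE]
  removed <- list(
    side_A = intersect(sig$gene_id[sig$direction == "side_A"],
                       ctrl$gene_id[ctrl$direction == "side_A"]),
    side_B = intersect(sig$gene_id[sig$direction == "side_B"],
                       ctrl$gene_id[ctrl$direction == "side_B"]))
  drop <- (sig$direction == "side_A" & sig$gene_id %in% removed$side_A) |
    (sig$direction == "side_B" & sig$gene_id %in% removed$side_B)
  out <- sig[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Deterministic complete-linkage agglomeration
#'
#' Agglomerative clustering with the complete-linkage (maximum) update on
#' a Euclidean distance matrix, with fully specified tie-breaking so leaf
#' orders are reproducible: among equal-height candidate merges the pair
#' whose clusters contain the smallest leaf indices merges first, and the
#' leaf order puts the smaller subtree (fewer leaves; ties by smallest
#' contained leaf) first at every internal node.
#'
#' @param x Numeric matrix (rows are clustered) or a [stats::dist].
#' @return An object of class `c("drp_hclust", "hclust")` (usable with
#'   [stats::cutree()], `plot()`, etc.).
#' @export
complete_linkage <- function(x) {
  d <- if (inherits(x, "dist")) as.matrix(x) else
    as.matrix(stats::dist(x, method = "euclidean"))
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 observations")
  if (any(!is.finite(d))) stop("non-finite distances")
  labels <- rownames(d)
  diag(d) <- Inf
  active <- rep(TRUE, n)
  minleaf <- seq_len(n)        # smallest original leaf in each cluster
  size <- rep(1L, n)
  node <- -seq_len(n)          # hclust merge coding
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  children <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    dd <- d
    dd[!active, ] <- Inf
    dd[, !active] <- Inf
    h <- min(dd)
    cand <- which(dd == h, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- cbind(pmin(minleaf[cand[, 1L]], minleaf[cand[, 2L]]),
                 pmax(minleaf[cand[, 1L]], minleaf[cand[, 2L]]))
    pick <- order(key[, 1L], key[, 2L])[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    if (minleaf[j] < minleaf[i]) { tmp <- i; i <- j; j <- tmp }
    merge[step, ] <- sort_merge_pair(node[i], node[j], minleaf[i], minleaf[j])
    height[step] <- h
    children[[step]] <- c(node[i], node[j])
    # complete linkage: distance to the union is the max
    d[i, ] <- pmax(d[i, ], d[j, ])
    d[, i] <- d[i, ]
    d[i, i] <- Inf
    active[j] <- FALSE
    minleaf[i] <- min(minleaf[i], minleaf[j])
    size[i] <- size[i] + size[j]
    node[i] <- step
  }
  order <- traverse_smaller_first(merge, n)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "complete",
                 dist.method = "euclidean",
                 call = match.call()),
            class = c("drp_hclust", "hclust"))
}

# hclust convention: singletons before merged clusters in a row
sort_merge_pair <- function(a, b, la, lb) {
  if (a < 0L && b < 0L) c(min(a, b), max(a, b))
  else if (a < 0L) c(a, b)
  else if (b < 0L) c(b, a)
  else c(min(a, b), max(a, b))
}

traverse_smaller_first <- function(merge, n) {
  leaf_count <- integer(n - 1L)
  min_leaf <- integer(n - 1L)
  info <- function(v) {   # v: merge-node code
    if (v < 0L) c(1L, -v) else c(leaf_count[v], min_leaf[v])
  }
  for (k in seq_len(nrow(merge))) {
    a <- info(merge[k, 1L]); b <- info(merge[k, 2L])
    leaf_count[k] <- a[1L] + b[1L]
    min_leaf[k] <- min(a[2L], b[2L])
  }
  rec <- function(v) {
    if (v < 0L) return(-v)
    a <- merge[v, 1L]; b <- merge[v, 2L]
    ia <- info(a); ib <- info(b)
    first_a <- ia[1L] < ib[1L] || (ia[1L] == ib[1L] && ia[2L] <= ib[2L])
    if (first_a) c(rec(a), rec(b)) else c(rec(b), rec(a))
  }
  rec(nrow(merge))
}

#' Cluster differentially expressed genes on log2(FPKM)
#'
#' Applies the log2 transform (zeros replaced by half the smallest
#' positive value in the matrix) and runs the deterministic
#' complete-linkage agglomeration on rows (genes) and columns (samples).
#'
#' @param fpkm_matrix Numeric matrix of FPKM values, genes in rows,
#'   samples in columns.
#' @param pseudo Value substituted for zeros before the log; default half
#'   the smallest positive entry.
#' @return List with `row` and `col` (`drp_hclust` objects), `row_order`,
#'   `col_order` and `log2_matrix`.
#' @export
cluster_de_genes <- function(fpkm_matrix, pseudo = NULL) {
  m <- as.matrix(fpkm_matrix)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need >= 2 rows and columns")
  if (any(m < 0)) stop("negative FPKM values")
  if (any(m == 0)) {
    if (is.null(pseudo)) {
      posmin <- min(m[m > 0])
      if (!is.finite(posmin)) stop("all-zero matrix cannot be clustered")
      pseudo <- posmin / 2
    }
    m[m == 0] <- pseudo
  }
  lm2 <- log2(m)
  if (any(!is.finite(lm2))) stop("non-finite values after log2 transform")
  row <- complete_linkage(lm2)
  col <- complete_linkage(t(lm2))
  list(row = row, col = col, row_order = row$order, col_order = col$order,
       log2_matrix = lm2)
}

#' Collapse multiple microarray probesets per gene
#'
#' Keeps, per gene, the probeset with the highest (or lowest) intensity;
#' intensity ties break deterministically on the lexicographically
#' smallest probeset id.
#'
#' @param x Data frame with `gene_id`, `probeset_id`, `intensity`.
#' @param rule `"highest"` or `"lowest"`.
#' @return One row per gene, ordered by `gene_id`.
#' @export
collapse_probesets <- function(x, rule = c("highest", "lowest")) {
  rule <- match.arg(rule)
  if (any(x$intensity < 0)) stop("intensities must be non-negative")
  o <- if (rule == "highest") {
    order(x$gene_id, -x$intensity, x$probeset_id)
  } else {
    order(x$gene_id, x$intensity, x$probeset_id)
  }
  y <- x[o, , drop = FALSE]
  out <- y[!duplicated(y$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
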
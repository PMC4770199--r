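mk_fpkm <- function(df) structure(df, class = c("drp_fpkm", "data.frame"))

test_that("saturation is exact at fraction 1, seeded, and input-validated", {
  set.seed(1)
  asn <- data.frame(read_id = sprintf("m%04d", 1:500),
                    gene_id = sample(sprintf("g%02d", 1:40), 500, TRUE),
                    weight = 1, stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = sprintf("g%02d", 1:40), length_bp = 1500L,
                    biotype = "protein_coding", stringsAsFactors = FALSE)
  s <- saturation(asn, ann, fractions = c(0.3, 1), seed = 5)
  cnt <- tapply(asn$weight, asn$gene_id, sum)
  full_counts <- setNames(numeric(40), ann$gene_id)
  full_counts[names(cnt)] <- cnt
  full_fp <- compute_fpkm(full_counts, ann)
  expect_equal(s$genes_detected[s$fraction == 1],
               length(expressed_genes(full_fp)[[1]]))
  s2 <- saturation(asn, ann, fractions = c(0.3, 1), seed = 5)
  expect_identical(s, s2)
  expect_error(saturation(asn, ann, fractions = c(0.5, 1.5)), "\\(0, 1\\]")
})

test_that("class composition sums to 100 and honors overrides", {
  fp <- mk_fpkm(data.frame(gene_id = c("a", "b", "c"), length_bp = 1000L,
                           biotype = c("rRNA", "rRNA", "rRNA"),
                           s1 = c(5, 3, 2), stringsAsFactors = FALSE))
  cc <- class_composition(fp)
  expect_equal(cc$percent_of_total_fpkm, 100)

  fp2 <- mk_fpkm(data.frame(gene_id = c("a", "b", "Gm26924"),
                            length_bp = 1000L,
                            biotype = c("protein_coding", "rRNA", "lincRNA"),
                            s1 = c(4, 3, 3), stringsAsFactors = FALSE))
  cc2 <- class_composition(fp2, biotype_overrides = c(Gm26924 = "rRNA"))
  expect_equal(sum(cc2$percent_of_total_fpkm), 100, tolerance = 1e-6)
  expect_equal(cc2$percent_of_total_fpkm[cc2$biotype == "rRNA"], 60)
  expect_false("lincRNA" %in% cc2$biotype)
  # the override moves mass between classes but conserves the total
  cc2b <- class_composition(fp2)
  expect_equal(sum(cc2b$percent_of_total_fpkm), 100, tolerance = 1e-6)
  expect_equal(cc2b$percent_of_total_fpkm[cc2b$biotype == "rRNA"], 30)

  fp3 <- mk_fpkm(data.frame(gene_id = "x", length_bp = 1000L,
                            biotype = NA_character_, s1 = 2,
                            stringsAsFactors = FALSE))
  expect_error(class_composition(fp3), "missing biotype.*x")
})

test_that("simulated composition matches the realized-abundance oracle", {
  cfg <- sim_config(n_genes = 400L, rrna_mass_fraction = 0.4,
                    input_picograms = 5000, capture_molecules_per_pg = 20,
                    pcr_cycles = 0L, per_cycle_efficiency = 1, seed = 2L)
  lib <- simulate_library(cfg)
  pre <- preprocess_reads(lib$reads$sequence)
  asn <- toy_map(pre$molecules, lib$transcriptome)
  fp <- compute_fpkm(asn, lib$annotation)
  cc <- class_composition(fp, threshold = 0)
  got <- sum(cc$percent_of_total_fpkm[cc$biotype %in% c("rRNA", "Mt_rRNA")])
  # oracle: expected FPKM share of a class is its molar-abundance share;
  # tolerance from the delta method on the ratio of Poisson-weighted sums
  tx <- lib$transcriptome
  expected <- 100 * sum(tx$abundance[tx$biotype %in% c("rRNA", "Mt_rRNA")]) /
    sum(tx$abundance)
  rate <- asn$counts / tx$length_bp[match(names(asn$counts), tx$gene_id)]
  is_r <- tx$biotype[match(names(asn$counts), tx$gene_id)] %in%
    c("rRNA", "Mt_rRNA")
  A <- sum(rate[is_r]); B <- sum(rate[!is_r])
  varA <- sum(asn$counts[is_r] /
                tx$length_bp[match(names(asn$counts), tx$gene_id)][is_r]^2)
  varB <- sum(asn$counts[!is_r] /
                tx$length_bp[match(names(asn$counts), tx$gene_id)][!is_r]^2)
  se <- 100 * sqrt(B^2 * varA + A^2 * varB) / (A + B)^2
  expect_lt(abs(got - expected), 3 * se)
})

test_that("rRNA base fraction equals a brute-force base tally", {
  asn <- data.frame(read_id = c("m1", "m2", "m3"),
                    gene_id = c("r1", "g1", "r2"),
                    insert_length = c(100L, 50L, 30L),
                    weight = c(1, 1, 0.5), stringsAsFactors = FALSE)
  rset <- c("r1", "r2")
  expect_equal(rrna_base_fraction(asn, rset),
               (100 + 0.5 * 30) / (100 + 50 + 0.5 * 30))
  expect_equal(rrna_base_fraction(asn, c("r1", "r2", "g1")), 1)
  expect_equal(rrna_base_fraction(asn, character()), 0)
  expect_error(rrna_base_fraction(asn[0, ], rset), "no assigned bases")
  # randomized tally oracle
  set.seed(3)
  big <- data.frame(read_id = sprintf("m%03d", 1:200),
                    gene_id = sample(c("r1", "g1", "g2"), 200, TRUE),
                    insert_length = sample(30:150, 200, TRUE),
                    weight = sample(c(1, 0.5), 200, TRUE),
                    stringsAsFactors = FALSE)
  bases <- big$weight * big$insert_length
  expect_equal(rrna_base_fraction(big, "r1"),
               sum(bases[big$gene_id == "r1"]) / sum(bases))
})

test_that("gene-body coverage reflects fragment geometry", {
  ann <- data.frame(gene_id = "g1", length_bp = 1000L,
                    stringsAsFactors = FALSE)
  full <- data.frame(read_id = sprintf("m%d", 1:5), gene_id = "g1",
                     start_0based = 0L, insert_length = 1000L, weight = 1,
                     stringsAsFactors = FALSE)
  expect_equal(gene_body_coverage(full, ann, n_bins = 20L), rep(1, 20))

  half5 <- data.frame(read_id = sprintf("m%d", 1:50), gene_id = "g1",
                      start_0based = 0L, insert_length = 500L, weight = 1,
                      stringsAsFactors = FALSE)
  prof <- gene_body_coverage(half5, ann, n_bins = 10L)
  expect_true(all(prof[6:10] == 0))
  expect_true(all(prof[1:5] > 0))

  # simulator defaults: uniform starts with 150-600 bp inserts leave both
  # transcript ends underrepresented relative to the interior
  cfg <- sim_config(n_genes = 100L, input_picograms = 2000,
                    capture_molecules_per_pg = 20, pcr_cycles = 0L,
                    per_cycle_efficiency = 1, seed = 4L)
  lib <- simulate_library(cfg)
  pre <- preprocess_reads(lib$reads$sequence)
  asn <- toy_map(pre$molecules, lib$transcriptome)
  prof2 <- gene_body_coverage(asn, lib$annotation, n_bins = 100L)
  interior <- mean(prof2[30:70])
  expect_lt(prof2[1], interior)
  expect_lt(prof2[100], interior)
})

test_that("spike-in FPKM is floored at 0.1 and the floor is idempotent", {
  ercc <- synthetic_ercc_mix(n = 6L)
  fp <- mk_fpkm(data.frame(gene_id = ercc$ercc_id, length_bp = 1000L,
                           biotype = "spike_in",
                           s1 = c(0.05, 0.1, 0.2, 3, 40, 500),
                           stringsAsFactors = FALSE))
  ea <- ercc_analysis(fp, ercc)
  expect_equal(ea$table$fpkm_floored[1], 0.1)   # below floor: raised
  expect_equal(ea$table$fpkm_floored[2], 0.1)   # at floor: unchanged
  expect_equal(ea$table$fpkm_floored[-(1:2)], ea$table$fpkm[-(1:2)])
  expect_true(all(ea$table$fpkm_floored >= 0.1))
  expect_equal(pmax(ea$table$fpkm_floored, 0.1), ea$table$fpkm_floored)
  expect_true(is.finite(ea$pearson_log))
  expect_error(ercc_analysis(fp, ercc[1:2, ]), "at least 3")
})

test_that("replicate concordance applies the union filter and both metrics", {
  fp <- mk_fpkm(data.frame(gene_id = sprintf("g%02d", 1:20),
                           length_bp = 1000L, biotype = "x",
                           r1 = exp(seq(-8, 6, length.out = 20)),
                           r2 = exp(seq(-8, 6, length.out = 20)),
                           stringsAsFactors = FALSE))
  rc <- replicate_concordance(fp)
  expect_equal(rc$pearson, 1)
  expect_equal(rc$spearman, 1)
  # union rule: genes passing in either replicate are kept
  expect_equal(rc$n_genes, sum(fp$r1 >= 0.001 | fp$r2 >= 0.001))

  fp2 <- fp
  fp2$r2 <- fp$r1^2   # monotone but nonlinear
  rc2 <- replicate_concordance(fp2)
  expect_equal(rc2$spearman, 1)
  expect_lt(rc2$pearson, 1)

  fp3 <- fp
  fp3$r2 <- rep(2, 20)
  rc3 <- replicate_concordance(fp3)
  expect_true(is.na(rc3$pearson) && is.na(rc3$spearman))
})

test_that("detection overlap equals brute-force set arithmetic", {
  s <- list(a = c("g1", "g2", "g3"), b = c("g1", "g2", "g3"))
  ov <- detection_overlap(s)
  expect_equal(unname(ov$percent_common), c(100, 100))
  ov2 <- detection_overlap(list(a = c("g1"), b = c("g2")))
  expect_equal(length(ov2$common), 0)
  expect_equal(unname(ov2$percent_common), c(0, 0))
  set.seed(5)
  pool <- sprintf("g%03d", 1:200)
  sets <- lapply(1:3, function(i) sample(pool, 120))
  names(sets) <- paste0("rep", 1:3)
  ov3 <- detection_overlap(sets)
  brute <- intersect(intersect(sets[[1]], sets[[2]]), sets[[3]])
  expect_setequal(ov3$common, brute)
  expect_equal(unname(ov3$percent_common),
               vapply(sets, function(x) 100 * length(brute) / length(x),
                      numeric(1), USE.NAMES = FALSE))
  expect_error(detection_overlap(sets[1]), "at least 2")
})

test_that("control subtraction removes matched-arm control hits only", {
  main <- data.frame(
    gene_id = c(sprintf("sd%03d", 1:545), sprintf("ax%03d", 1:468)),
    log2_fold_change = c(rep(2, 545), rep(-2, 468)),
    q_value = 0.01,
    direction = c(rep("side_A", 545), rep("side_B", 468)),
    stringsAsFactors = FALSE)
  ctrl <- data.frame(
    gene_id = c("sd001", "sd002", "u3", "u4", "u5",
                "ax001", "ax002", "ax003", "d4", "d5", "d6", "d7", "d8"),
    log2_fold_change = 1,
    q_value = 0.01,
    direction = c(rep("side_A", 5), rep("side_B", 8)),
    stringsAsFactors = FALSE)
  out <- control_subtract(main, ctrl)
  expect_equal(sum(out$direction == "side_A"), 543)
  expect_equal(sum(out$direction == "side_B"), 465)
  expect_true(all(out$gene_id %in% main$gene_id))
  expect_setequal(attr(out, "removed")$side_A, c("sd001", "sd002"))
  # arm matching: a control hit on the other arm removes nothing
  ctrl_swapped <- ctrl
  ctrl_swapped$direction <- ifelse(ctrl$direction == "side_A",
                                   "side_B", "side_A")
  out2 <- control_subtract(main, ctrl_swapped)
  expect_equal(nrow(out2), 545 + 468)
  # empty control leaves the main list unchanged
  out3 <- control_subtract(main, ctrl[0, ])
  expect_equal(nrow(out3), 545 + 468)
  # alpha = 0: nothing is significant
  expect_equal(nrow(control_subtract(main, ctrl, alpha = 0)), 0)
  # alpha-monotone: smaller alpha never enlarges the output
  main$q_value <- runif(nrow(main), 0, 0.1)
  n_by_alpha <- vapply(c(0.1, 0.05, 0.01),
                       function(a) nrow(control_subtract(main, ctrl, a)),
                       numeric(1))
  expect_true(all(diff(n_by_alpha) <= 0))
})

test_that("complete linkage reproduces hclust heights on random instances", {
  set.seed(6)
  for (n in 3:8) {
    for (rep in 1:3) {
      m <- matrix(rnorm(n * 4), n)
      rownames(m) <- paste0("r", seq_len(n))
      mine <- complete_linkage(m)
      ref <- hclust(dist(m), method = "complete")
      expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-12)
      # identical partitions at every cut level
      for (k in 2:(n - 1)) {
        a <- cutree(mine, k); b <- cutree(ref, k)
        expect_true(all((outer(a, a, "==") == outer(b, b, "=="))))
      }
    }
  }
})

test_that("identical rows merge first and leaf order is deterministic", {
  m <- rbind(c(0, 0), c(5, 5), c(0, 0), c(9, 1))
  hc <- complete_linkage(m)
  expect_equal(hc$height[1], 0)
  expect_setequal(hc$merge[1, ], c(-1L, -3L))
  expect_identical(complete_linkage(m)$order, hc$order)
})

test_that("column dendrogram splits planted compartments at the top", {
  set.seed(8)
  base <- matrix(rlnorm(40 * 6, 2, 1), 40, 6)
  base[1:20, 4:6] <- base[1:20, 4:6] * 50   # enriched in compartment B
  base[21:40, 1:3] <- base[21:40, 1:3] * 50 # enriched in compartment A
  colnames(base) <- c(paste0("somato_", 1:3), paste0("axon_", 1:3))
  cl <- cluster_de_genes(base)
  grp <- cutree(cl$col, 2)
  expect_equal(length(unique(grp[1:3])), 1)
  expect_equal(length(unique(grp[4:6])), 1)
  expect_false(grp[1] == grp[4])
  expect_error(cluster_de_genes(base * -1), "negative")
  z <- base; z[1, 1] <- 0
  expect_silent(cluster_de_genes(z))  # zeros replaced by half min positive
})

test_that("probeset collapse keeps the extreme probeset with stable ties", {
  x <- data.frame(gene_id = c("g1", "g2", "g2", "g3", "g3"),
                  probeset_id = c("p1", "p2", "p3", "p5", "p4"),
                  intensity = c(4, 3, 7, 2, 2), stringsAsFactors = FALSE)
  hi <- collapse_probesets(x, "highest")
  expect_equal(hi$intensity[hi$gene_id == "g2"], 7)
  lo <- collapse_probesets(x, "lowest")
  expect_equal(lo$intensity[lo$gene_id == "g2"], 3)
  expect_equal(hi$probeset_id[hi$gene_id == "g1"], "p1")
  # tie on intensity: lexicographically smallest probeset id wins
  expect_equal(hi$probeset_id[hi$gene_id == "g3"], "p4")
  expect_equal(lo$probeset_id[lo$gene_id == "g3"], "p4")
  # brute-force group-by oracle on a random table
  set.seed(9)
  big <- data.frame(gene_id = sample(sprintf("g%02d", 1:15), 80, TRUE),
                    probeset_id = sprintf("p%03d", sample(999, 80)),
                    intensity = round(runif(80, 0, 50), 1),
                    stringsAsFactors = FALSE)
  got <- collapse_probesets(big, "highest")
  oracle <- tapply(big$intensity, big$gene_id, max)
  expect_equal(setNames(got$intensity, got$gene_id),
               setNames(as.numeric(oracle[got$gene_id]), got$gene_id))
  expect_error(collapse_probesets(transform(x, intensity = -1)),
               "non-negative")
})
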
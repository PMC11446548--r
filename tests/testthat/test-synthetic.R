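test_that("generators are byte-identical under a fixed seed", {
  g1 <- simulate_genome(n_genes = 10L, seed = 7L)
  g2 <- simulate_genome(n_genes = 10L, seed = 7L)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(as.data.frame(g1$annotation), as.data.frame(g2$annotation))
  c1 <- plant_crac_track(g1$annotation, g1$truth, g1$chrom_sizes, seed = 3L)
  c2 <- plant_crac_track(g2$annotation, g2$truth, g2$chrom_sizes, seed = 3L)
  expect_identical(c1$track, c2$track)
  expect_identical(c1$truth, c2$truth)
  m1 <- plant_motifs(g1$genome, g1$annotation, c1$truth, seed = 4L)
  m2 <- plant_motifs(g2$genome, g2$annotation, c2$truth, seed = 4L)
  expect_identical(as.character(m1$genome), as.character(m2$genome))
})

test_that("fixed-length range gives exact transcript lengths", {
  g <- simulate_genome(n_genes = 8L, length_range = c(300L, 300L), seed = 1L)
  expect_true(all(transcript_length(g$annotation) == 300L))
})

test_that("600 genes on 2 chromosomes are non-overlapping with enforced gaps", {
  g <- simulate_genome(n_genes = 600L, n_chroms = 2L, gap_min = 400L,
                       sequence = FALSE, seed = 9L)
  ann <- g$annotation
  for (ch in unique(ann$chrom)) {
    sub <- ann[ann$chrom == ch, ]
    lo <- pmin(sub$tss, sub$pa)
    hi <- pmax(sub$tss, sub$pa)
    ord <- order(lo)
    # interval-scan oracle: every gene starts >= gap after the previous end
    expect_true(all(lo[ord][-1] - hi[ord][-length(ord)] >= 400L))
  }
})

test_that("planted CRAC read mass is conserved and lands in transcripts", {
  st <- small_study(seed = 5L)
  total <- sum(vapply(st$crac$track$plus, sum, 0)) +
    sum(vapply(st$crac$track$minus, sum, 0))
  per_gene <- gene_counts(st$crac$track, st$genome$annotation)
  expect_equal(sum(per_gene), total)
  expect_gt(total, 0)
})

test_that("noiseless CRAC+ gene peaks at its planted offset", {
  g <- simulate_genome(n_genes = 20L, sequence = FALSE, seed = 2L)
  cr <- plant_crac_track(g$annotation, g$truth, g$chrom_sizes,
                         crac_fraction = 0.5, noise = 0,
                         reads_per_gene = 2000, peak_offset_sd = 0,
                         peak_sd = 0, seed = 3L)
  mat <- anchored_matrix(cr$track, g$annotation, "pa", 400L, 100L)
  pos <- which(cr$truth$is_crac_positive)
  for (i in pos) {
    am <- mat$offsets[which.max(mat$values[i, ])]
    expect_lte(abs(am - (-cr$truth$peak_offset[i])), 1)
  }
  # CRAC- genes carry no reads at all when noise = 0
  neg <- which(!cr$truth$is_crac_positive)
  expect_true(all(rowSums(mat$values[neg, , drop = FALSE]) == 0))
})

test_that("crac_fraction = 0 yields pure background and no positive call", {
  g <- simulate_genome(n_genes = 100L, sequence = FALSE, seed = 4L)
  cr <- plant_crac_track(g$annotation, g$truth, g$chrom_sizes,
                         crac_fraction = 0, seed = 5L)
  expect_false(any(cr$truth$is_crac_positive))
  mat <- anchored_matrix(cr$track, g$annotation, "pa", 500L, 100L)
  cl <- kmeans_profiles(mat, k = 4L, seed = 6L)
  call <- call_crac_positive(cl)
  expect_length(call$members, 0)
})

test_that("noiseless expression tables recover planted kinetics exactly", {
  g <- simulate_genome(n_genes = 50L, sequence = FALSE, seed = 8L)
  g$truth$is_crac_positive <- rep(c(TRUE, FALSE), 25)
  ex <- generate_expression(g$truth, noise_cv = 0, seed = 9L)
  hl <- half_life_steady_state(ex$tables$WT)
  expect_equal(hl$HL, ex$truth$HL_true, tolerance = 1e-14)
  # mutant halves HL of CRAC+ genes only
  hlm <- half_life_steady_state(ex$tables$mutant)
  ratio <- hlm$HL / hl$HL
  expect_equal(ratio[g$truth$is_crac_positive], rep(0.5, 25),
               tolerance = 1e-12)
  expect_equal(ratio[!g$truth$is_crac_positive], rep(1, 25),
               tolerance = 1e-12)
})

test_that("multiplier 1 makes WT and mutant tables identical", {
  g <- simulate_genome(n_genes = 20L, sequence = FALSE, seed = 2L)
  g$truth$is_crac_positive <- rep(TRUE, 20)
  ex <- generate_expression(g$truth, noise_cv = 0,
                            mutant_hl_multiplier = 1, seed = 3L)
  expect_equal(ex$tables$WT$RA, ex$tables$mutant$RA)
})

test_that("ChIP/GRO generator encodes backtracking as the ChIP/GRO gap", {
  g <- simulate_genome(n_genes = 40L, sequence = FALSE, seed = 3L)
  g$truth$is_crac_positive <- rep(FALSE, 40)
  # b = 0 everywhere: ChIP and GRO proportional with one global constant
  cg0 <- generate_chip_gro(g$annotation, g$truth, g$chrom_sizes,
                           b_range = c(0, 0), noise_cv = 0, seed = 4L)
  ch <- gene_end_averages(cg0$conditions$WT$chip, g$annotation)
  gr <- gene_end_averages(cg0$conditions$WT$gro, g$annotation)
  bi <- backtracking_index(ch, gr)
  expect_equal(bi$BI, rep(1, 40), tolerance = 1e-12)
  # heterogeneous b: BI = 1/(1-b) exactly when noiseless
  cg <- generate_chip_gro(g$annotation, g$truth, g$chrom_sizes,
                          noise_cv = 0, seed = 5L)
  ch <- gene_end_averages(cg$conditions$WT$chip, g$annotation)
  gr <- gene_end_averages(cg$conditions$WT$gro, g$annotation)
  bi <- backtracking_index(ch, gr)
  expect_equal(bi$BI, 1 / (1 - cg$truth$b_wt), tolerance = 1e-9)
  expect_equal(cor(bi$BI, cg$truth$b_wt, method = "spearman"), 1)
})

test_that("Rpb4/Rpb3 generator matches its closed form when noiseless", {
  g <- simulate_genome(n_genes = 15L, sequence = FALSE, seed = 6L)
  g$truth$is_crac_positive <- rep(FALSE, 15)
  rp <- generate_rpb4_tracks(g$annotation, g$truth, g$chrom_sizes,
                             end_ratio = 0.5, noise_cv = 0, seed = 7L)
  lens <- transcript_length(g$annotation)
  got <- body_ratio(rp$conditions$WT$rpb4, rp$conditions$WT$rpb3,
                    g$annotation)
  # ratio(d) = 1 - s d with s = 0.5/L over [0,250) and [L-250, L):
  # mean = 1 - s (L-1)/2
  expected <- 1 - (0.5 / lens) * (lens - 1) / 2
  expect_lt(max(abs(got - expected)), 1e-9)
  # slope 0 (end_ratio 1): flat unit ratio profile
  rp0 <- generate_rpb4_tracks(g$annotation, g$truth, g$chrom_sizes,
                              end_ratio = 1, noise_cv = 0, seed = 8L)
  prof <- ratio_profile(rp0$conditions$WT$rpb4, rp0$conditions$WT$rpb3,
                        g$annotation)
  expect_equal(prof$ratio, rep(1, nrow(prof)), tolerance = 1e-12)
})

test_that("increasing expression noise degrades HL recovery monotonically", {
  g <- simulate_genome(n_genes = 200L, sequence = FALSE, seed = 10L)
  g$truth$is_crac_positive <- rep(FALSE, 200)
  err <- vapply(c(0.05, 0.2, 0.8), function(cv) {
    ex <- generate_expression(g$truth, noise_cv = cv, seed = 11L)
    hl <- half_life_steady_state(ex$tables$WT)
    stats::median(abs(hl$HL - ex$truth$HL_true) / ex$truth$HL_true)
  }, 0)
  expect_true(all(diff(err) > 0))
})
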
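test_that("repeat scanner handles the canonical cases", {
  h <- scan_gct_repeats("AAGCTGCTAA")
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 3L)
  expect_equal(h$repeats, 2L)
  # maximal run, not two overlapping hits
  h <- scan_gct_repeats("GCTGCTGCT")
  expect_equal(nrow(h), 1L)
  expect_equal(h$repeats, 3L)
  # N breaks a run
  h <- scan_gct_repeats("GCTNGCTGCTGCT")
  expect_equal(h$start, 5L)
  expect_equal(h$repeats, 3L)
  # below threshold
  expect_equal(nrow(scan_gct_repeats("AAGCTAA")), 0L)
  # two separated runs
  h <- scan_gct_repeats("GCTGCTAAAGCTGCTGCT")
  expect_equal(h$start, c(1L, 10L))
  expect_equal(h$repeats, c(2L, 3L))
})

test_that("scanner equals the regex oracle on random 200-mers", {
  set.seed(77)
  seqs <- vapply(seq_len(1000), function(i)
    paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE,
                 prob = c(0.2, 0.3, 0.3, 0.2)), collapse = ""), "")
  names(seqs) <- sprintf("s%04d", seq_along(seqs))
  expect_identical(scan_gct_repeats(seqs), regex_repeat_oracle(seqs))
})

test_that("scanner equals the regex oracle exhaustively on short strings", {
  # all strings over {A,C,G,T} of length 6..7 (shorter ones cannot hold
  # two GCT units); the full length-<=9 sweep runs in the acceptance suite
  for (len in 6:7) {
    grid <- do.call(expand.grid,
                    rep(list(c("A", "C", "G", "T")), len))
    seqs <- do.call(paste0, grid)
    names(seqs) <- seq_along(seqs)
    expect_identical(scan_gct_repeats(seqs), regex_repeat_oracle(seqs))
  }
})

test_that("reported runs never overlap or touch", {
  set.seed(5)
  seqs <- vapply(seq_len(200), function(i)
    paste(sample(c("G", "C", "T"), 60, replace = TRUE), collapse = ""), "")
  seqs <- c(seqs,
            "GCTGCTAGCTGCTGCTTTGCTGCT",
            "GCTGCTGCTGCTAAGCTGCTAAGCTGCT",
            strrep("GCTGCTA", 8))
  names(seqs) <- seq_along(seqs)
  h <- scan_gct_repeats(seqs)
  expect_gt(nrow(h), 3)
  multi <- FALSE
  for (sid in unique(h$seq_id)) {
    sub <- h[h$seq_id == sid, ]
    if (nrow(sub) < 2) next
    multi <- TRUE
    ends <- sub$start + sub$width - 1L
    expect_true(all(sub$start[-1] > ends[-nrow(sub)]))
  }
  expect_true(multi)
})

test_that("pA-window scanning reports strand-correct distances", {
  # hand-built genome: one gene per strand with a motif at distance 150
  seq_plus <- paste(rep("A", 1200), collapse = "")
  chr <- Biostrings::DNAStringSet(c(chrT = seq_plus))
  ann <- gene_annotation(c("gp", "gm"), c("chrT", "chrT"), c("+", "-"),
                         tss = c(100L, 1100L), pa = c(700L, 750L))
  # plus gene: transcript 100..700, motif center 150 bp upstream of pA
  chr[["chrT"]] <- imprintr:::sense_replace(chr[["chrT"]], "+", 100L,
                                            600L - 150L - 3L, "GCTGCT")
  # minus gene: transcript [750, 1100), length 350, same planted distance
  chr[["chrT"]] <- imprintr:::sense_replace(chr[["chrT"]], "-", 1100L,
                                            350L - 150L - 3L, "GCTGCT")
  res <- hits_near_pa(ann, chr, window_upstream = 200L)
  expect_true(all(res$presence))
  expect_equal(res$hits$distance_upstream_pa, c(150, 150))
  # the minus-strand genomic slice shows the reverse complement
  g <- as.character(Biostrings::subseq(chr[["chrT"]], 750 + 150 - 3 + 1,
                                       750 + 150 + 3))
  expect_equal(g, "AGCAGC")
  # motif out of window is not reported
  res2 <- hits_near_pa(ann, chr, window_upstream = 100L)
  expect_false(any(res2$presence))
})

test_that("positional summary reduces to hand arithmetic", {
  hits <- data.frame(distance_upstream_pa = c(100, 200))
  s <- positional_summary(hits)
  expect_equal(s$mean, 150)
  expect_equal(s$median, 150)
  s1 <- positional_summary(data.frame(distance_upstream_pa = 140))
  expect_equal(s1$mean, s1$median)
  expect_equal(s1$n, 1L)
})

test_that("planted motif cohort is recovered at the planted distance", {
  g <- simulate_genome(n_genes = 200L, seed = 15L)
  g$truth$is_crac_positive <- rep(TRUE, 200)
  mo <- plant_motifs(g$genome, g$annotation, g$truth,
                     motif_fraction = 1, seed = 16L)
  res <- hits_near_pa(g$annotation, mo$genome, window_upstream = 250L)
  expect_true(all(res$presence))
  s <- positional_summary(res$hits)
  planted <- mo$truth$motif_distance
  # scanner recovers each planted distance exactly
  d <- res$hits$distance_upstream_pa[match(mo$truth$gene_id,
                                           res$hits$gene_id)]
  expect_equal(d, planted)
  expect_lt(abs(s$mean - mean(planted)), 1e-9)
  # histogram mode sits within one bin of the planted mean
  mode_bin <- s$histogram$bin_left[which.max(s$histogram$count)]
  expect_lte(abs(mode_bin + 5 - mean(planted)), 15)
})

test_that("purged windows of unplanted genes contain no runs", {
  g <- simulate_genome(n_genes = 80L, gc = 0.6, seed = 18L)
  g$truth$is_crac_positive <- rep(c(TRUE, FALSE), 40)
  mo <- plant_motifs(g$genome, g$annotation, g$truth,
                     motif_fraction = 1, purge = TRUE,
                     purge_window = 250L, seed = 19L)
  res <- hits_near_pa(g$annotation, mo$genome, window_upstream = 250L)
  unplanted <- !mo$truth$has_motif
  expect_false(any(res$presence[mo$truth$gene_id[unplanted]]))
})

test_that("motif enrichment matches the closed-form extreme case", {
  target <- gene_set("t", sprintf("t%02d", 1:10))
  bg <- gene_set("b", sprintf("b%02d", 1:10))
  presence <- stats::setNames(c(rep(TRUE, 10), rep(FALSE, 10)),
                              c(target$members, bg$members))
  res <- motif_set_enrichment(target, bg, presence)
  expect_equal(res$p_enrich, 1 / choose(20, 10), tolerance = 1e-12)
  # identical presence rates: no enrichment signal
  presence2 <- stats::setNames(rep(c(TRUE, FALSE), 10),
                               c(target$members, bg$members))
  res2 <- motif_set_enrichment(target, bg, presence2)
  expect_equal(res2$fold_enrichment, 1)
  expect_gt(res2$p_enrich, 0.5)
})

test_that("a strongly enriched cohort yields a tiny p-value", {
  set.seed(33)
  target <- gene_set("t", sprintf("t%02d", 1:40))
  bg <- gene_set("b", sprintf("b%02d", 1:40))
  presence <- stats::setNames(
    c(runif(40) < 0.7, runif(40) < 0.05),
    c(target$members, bg$members))
  expect_lt(motif_set_enrichment(target, bg, presence)$p_enrich, 1e-5)
})
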
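make_ann <- function() {
  gene_annotation(c("gA", "gB"), c("chrT", "chrT"), c("+", "-"),
                  tss = c(100L, 1500L), pa = c(500L, 1100L))
}

test_that("constant tracks give constant matrices and profiles", {
  tr <- vector_track(rep(3, 2000))
  ann <- make_ann()
  mat <- anchored_matrix(tr, ann, "pa", 50L, 50L)
  expect_equal(dim(mat), c(2L, 100L))
  expect_true(all(mat$values == 3))
  prof <- average_profile(mat)
  expect_equal(prof$mean, rep(3, 100))
  expect_equal(prof$n_valid, rep(2, 100))
  sm <- scaled_metagene(tr, ann, flank5 = 20L, flank3 = 20L,
                        body_bins = 50L)
  expect_equal(sm$mean, rep(3, 90))
})

test_that("anchored matrix has the documented shape and masks edges", {
  tr <- vector_track(rep(1, 300))
  ann <- gene_annotation("g1", "chrT", "+", 30L, 240L)
  mat <- anchored_matrix(tr, ann, "pa", 500L, 100L)
  expect_equal(length(mat$offsets), 600L)
  expect_equal(mat$offsets[1], -500L)
  expect_equal(mat$offsets[600], 99L)
  # pA = 240; offsets below -240 fall before the chromosome start
  expect_false(any(mat$valid[1, mat$offsets < -240L]))
  expect_true(all(mat$valid[1, mat$offsets >= -240L & mat$offsets < 60L]))
})

test_that("average_profile equals a brute-force loop with masking", {
  set.seed(31)
  v <- matrix(runif(600), 20, 30)
  valid <- matrix(runif(600) > 0.2, 20, 30)
  mat <- imprintr:::signal_matrix(sprintf("g%02d", 1:20), "pa",
                                  seq.int(-10L, 19L), v, valid)
  prof <- average_profile(mat)
  for (j in seq_len(30)) {
    vals <- v[valid[, j], j]
    expect_equal(prof$mean[j], mean(vals))
    expect_equal(prof$n_valid[j], sum(valid[, j]))
  }
  # single-cell column uses n_valid = 1
  valid2 <- valid
  valid2[, 1] <- c(TRUE, rep(FALSE, 19))
  mat2 <- imprintr:::signal_matrix(sprintf("g%02d", 1:20), "pa",
                                   seq.int(-10L, 19L), v, valid2)
  expect_equal(average_profile(mat2)$mean[1], v[1, 1])
})

test_that("robust_filter trims the extreme tails exactly like a sort oracle", {
  set.seed(13)
  n <- 40L
  v <- matrix(rexp(n * 25), n, 25)
  mat <- imprintr:::signal_matrix(sprintf("g%02d", 1:n), "pa",
                                  seq.int(0L, 24L),
                                  v, matrix(TRUE, n, 25))
  f <- 0.1
  filt <- robust_filter(mat, f)
  k <- ceiling(f / 2 * n)
  rm <- rowMeans(v)
  ord <- order(rm)
  survivors <- sort(sprintf("g%02d", 1:n)[ord][(k + 1):(n - k)])
  expect_equal(sort(filt$gene_ids), survivors)
  # a single extreme row is always removed
  v2 <- v
  v2[5, ] <- v2[5, ] * 1000
  mat2 <- imprintr:::signal_matrix(sprintf("g%02d", 1:n), "pa",
                                   seq.int(0L, 24L),
                                   v2, matrix(TRUE, n, 25))
  expect_false("g05" %in% robust_filter(mat2, 0.05)$gene_ids)
  # identical rows: mean profile unchanged by filtering
  v3 <- matrix(2, n, 25)
  mat3 <- imprintr:::signal_matrix(sprintf("g%02d", 1:n), "pa",
                                   seq.int(0L, 24L),
                                   v3, matrix(TRUE, n, 25))
  expect_equal(average_profile(robust_filter(mat3, 0.25))$mean,
               rep(2, 25))
  # trimming that would leave fewer than 2 rows is refused
  tiny <- imprintr:::signal_matrix(sprintf("g%d", 1:5), "pa",
                                   seq.int(0L, 24L),
                                   v[1:5, ], matrix(TRUE, 5, 25))
  expect_error(robust_filter(tiny, 0.45), "fewer than 2")
})

test_that("body bins align genes of very different lengths", {
  # peak occupying the exact middle 10% of two genes, lengths 400 and 4000
  len1 <- 400L; len2 <- 4000L
  size <- 6000L
  tr <- signal_track(c(chrT = size))
  ann <- gene_annotation(c("short", "long"), c("chrT", "chrT"),
                         c("+", "+"), tss = c(100L, 1000L),
                         pa = c(100L + len1, 1000L + len2))
  mid1 <- 100L + as.integer(0.45 * len1)
  mid2 <- 1000L + as.integer(0.45 * len2)
  tr <- imprintr:::track_add(tr, "chrT", "+", mid1,
                             rep(1, as.integer(0.1 * len1)))
  tr <- imprintr:::track_add(tr, "chrT", "+", mid2,
                             rep(1, as.integer(0.1 * len2)))
  sm <- scaled_metagene(tr, ann, flank5 = 0L, flank3 = 0L,
                        body_bins = 10L)
  expect_equal(nrow(sm), 10L)
  expect_equal(sm$mean, c(0, 0, 0, 0, 0.5, 0.5, 0, 0, 0, 0))
})

test_that("scaled metagene is invariant to the gene-length distribution", {
  # signal = f(fractional position) planted per gene; two disjoint cohorts
  f <- function(x) 1 + sin(2 * pi * x)
  build <- function(lens, seed) {
    n <- length(lens)
    size <- sum(lens) + 200L * (n + 1L)
    tr <- signal_track(c(chrT = size))
    tss <- integer(n); pos <- 200L
    for (i in seq_len(n)) {
      tss[i] <- pos
      vals <- f(((seq_len(lens[i])) - 0.5) / lens[i])
      tr <- imprintr:::track_add(tr, "chrT", "+", pos, vals)
      pos <- pos + lens[i] + 200L
    }
    ann <- gene_annotation(sprintf("g%03d", seq_len(n)), rep("chrT", n),
                           rep("+", n), tss, tss + lens)
    scaled_metagene(tr, ann, flank5 = 0L, flank3 = 0L, body_bins = 50L)
  }
  set.seed(99)
  p_short <- build(sample(300:500, 30, replace = TRUE))
  p_long <- build(sample(3000:5000, 30, replace = TRUE))
  expect_lt(max(abs(p_short$mean - p_long$mean)), 0.02)
})

test_that("profiling is linear: averaging tracks commutes with profiling", {
  set.seed(17)
  v1 <- runif(2000); v2 <- runif(2000)
  ann <- make_ann()
  p1 <- average_profile(anchored_matrix(vector_track(v1), ann, "pa",
                                        100L, 50L))
  p2 <- average_profile(anchored_matrix(vector_track(v2), ann, "pa",
                                        100L, 50L))
  pm <- average_profile(anchored_matrix(vector_track((v1 + v2) / 2),
                                        ann, "pa", 100L, 50L))
  expect_equal(pm$mean, (p1$mean + p2$mean) / 2, tolerance = 1e-12)
})
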
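# Shared fixtures and independent oracles used across test files.

# A one-chromosome track whose per-base value equals its 0-based genomic
# position; handy for index-arithmetic oracles.
position_track <- function(len = 20L, chrom = "chrT") {
  tr <- signal_track(stats::setNames(len, chrom))
  tr$plus[[chrom]] <- as.numeric(seq_len(len) - 1L)
  tr$minus[[chrom]] <- as.numeric(seq_len(len) - 1L)
  tr
}

# Build a signal_track directly from per-strand vectors.
vector_track <- function(plus, minus = plus, chrom = "chrT") {
  tr <- signal_track(stats::setNames(length(plus), chrom))
  tr$plus[[chrom]] <- as.numeric(plus)
  tr$minus[[chrom]] <- as.numeric(minus)
  tr
}

# Adjusted Rand index between two label vectors (closed-form oracle).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ni <- rowSums(tab)
  nj <- colSums(tab)
  n <- sum(tab)
  sum_comb <- sum(choose(tab, 2))
  exp_comb <- sum(choose(ni, 2)) * sum(choose(nj, 2)) / choose(n, 2)
  max_comb <- (sum(choose(ni, 2)) + sum(choose(nj, 2))) / 2
  (sum_comb - exp_comb) / (max_comb - exp_comb)
}

# Brute-force regex oracle for maximal (unit){min,} runs; returns a
# data.frame comparable with scan_gct_repeats output.
regex_repeat_oracle <- function(sequences, unit = "GCT", min_repeats = 2L) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  pat <- paste0("(?:", unit, "){", min_repeats, ",}")
  m <- gregexpr(pat, sequences, perl = TRUE)
  rows <- lapply(seq_along(sequences), function(i) {
    st <- m[[i]]
    if (st[1] == -1L) return(NULL)
    w <- attr(st, "match.length")
    data.frame(seq_id = ids[i], start = as.integer(st),
               repeats = as.integer(w / nchar(unit)),
               width = as.integer(w), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(seq_id = character(0), start = integer(0),
                      repeats = integer(0), width = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Exhaustive hypergeometric tail oracle: enumerate all size-nB draws from
# the universe, count overlap with A, and sum tail mass.
enumerate_overlap_tails <- function(universe, a, b) {
  k_obs <- length(intersect(a, b))
  draws <- utils::combn(universe, length(b))
  ov <- apply(draws, 2L, function(d) length(intersect(d, a)))
  list(p_enrich = mean(ov >= k_obs), p_deplete = mean(ov <= k_obs))
}

# Small deterministic study simulation shared by slower tests.
small_study <- function(seed = 5L, n_genes = 120L, noise_cv = 0,
                        sequence = FALSE) {
  g <- simulate_genome(n_genes = n_genes, sequence = sequence, seed = seed)
  cr <- plant_crac_track(g$annotation, g$truth, g$chrom_sizes,
                         seed = seed + 1L)
  list(genome = g, crac = cr)
}
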
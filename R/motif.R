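#' Scan sequences for contiguous trinucleotide repeat runs
#'
#' Finds maximal non-overlapping runs of at least \code{min_repeats}
#' contiguous copies of \code{unit} (default \code{"GCT"}, the motif
#' enriched near the pA of bound transcripts). Scanning is greedy left to
#' right: at the earliest unit occurrence the run is extended as far as
#' possible, reported if long enough, and the scan resumes after its end,
#' so \code{"GCTGCTGCT"} yields one run of three repeats, never two
#' overlapping runs. Runs containing \code{N} are broken at the \code{N}
#' because the unit cannot match across it.
#'
#' @param sequences character vector of sense-strand sequences over
#'   \code{A,C,G,T,N} (names, if any, label the hits).
#' @param unit repeat unit (default \code{"GCT"}).
#' @param min_repeats minimum number of contiguous units (>= 2 by
#'   default).
#' @return data.frame with \code{seq_id}, \code{start} (1-based position
#'   within the sequence), \code{repeats} and \code{width}.
#' @examples
#' scan_gct_repeats("AAGCTGCTAA")   # one hit at 3, repeats = 2
#' @export
scan_gct_repeats <- function(sequences, unit = "GCT", min_repeats = 2L) {
  stopifnot(min_repeats >= 1L, nchar(unit) >= 1L)
  u <- nchar(unit)
  ids <- names(sequences)
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  # all unit occurrences (including overlapping ones) via zero-width
  # lookahead; run chaining below is the package's own logic
  starts <- gregexpr(paste0("(?=", unit, ")"), sequences, perl = TRUE)
  rows <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    s <- starts[[i]]
    if (s[1] == -1L || length(s) < min_repeats) next
    present <- logical(max(s) + 1L)
    present[s] <- TRUE
    hits_start <- integer(0)
    hits_rep <- integer(0)
    j <- 1L
    while (j <= length(s)) {
      p <- s[j]
      if (!present[p]) { j <- j + 1L; next }
      k <- 1L
      while (p + k * u <= length(present) + 1L &&
             p + k * u <= max(s) && present[p + k * u])
        k <- k + 1L
      if (k >= min_repeats) {
        hits_start <- c(hits_start, p)
        hits_rep <- c(hits_rep, k)
        present[s[s < p + k * u]] <- FALSE   # consume overlapped starts
      }
      j <- j + 1L
    }
    if (length(hits_start))
      rows[[i]] <- data.frame(seq_id = ids[i], start = hits_start,
                              repeats = hits_rep,
                              width = hits_rep * u,
                              stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(seq_id = character(0), start = integer(0),
                      repeats = integer(0), width = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Motif hits in the window upstream of the pA
#'
#' Extracts, for every gene, the sense-strand sequence of the
#' \code{window_upstream} bases ending at the pA (clipped at the TSS for
#' short transcripts), scans it for repeat runs, and reports positions in
#' transcript coordinates. The distance of a hit is measured from the pA
#' to the run midpoint (transcript sense), this package's convention for
#' "bp upstream of the pA".
#'
#' @param ann a \code{gene_annotation}.
#' @param genome a \code{Biostrings::DNAStringSet} named by chromosome.
#' @param window_upstream scanned window size in bp upstream of the pA.
#' @param unit,min_repeats passed to \code{\link{scan_gct_repeats}}.
#' @return List with \code{hits} (data.frame: \code{gene_id},
#'   \code{start_in_transcript} 0-based, \code{repeats},
#'   \code{distance_upstream_pa}, \code{center_genomic}) and
#'   \code{presence} (named logical per gene).
#' @export
hits_near_pa <- function(ann, genome, window_upstream = 160L,
                         unit = "GCT", min_repeats = 2L) {
  lens <- transcript_length(ann)
  u <- nchar(unit)
  seqs <- character(nrow(ann))
  from0 <- pmax(0L, lens - window_upstream)
  for (i in seq_len(nrow(ann))) {
    seqs[i] <- sense_subseq(genome[[ann$chrom[i]]], ann$strand[i],
                            ann$tss[i], from0[i], lens[i])
  }
  names(seqs) <- ann$gene_id
  h <- scan_gct_repeats(seqs, unit = unit, min_repeats = min_repeats)
  presence <- stats::setNames(ann$gene_id %in% h$seq_id, ann$gene_id)
  if (nrow(h)) {
    i <- match(h$seq_id, ann$gene_id)
    start_tr <- from0[i] + h$start - 1L           # 0-based transcript coord
    center <- start_tr + h$width / 2              # continuous midpoint
    dist <- lens[i] - center
    # genomic coordinate of the base containing the midpoint
    center_base <- floor(center)
    cg <- ifelse(ann$strand[i] == "+", ann$tss[i] + center_base,
                 ann$tss[i] - 1L - center_base)
    hits <- data.frame(gene_id = h$seq_id,
                       start_in_transcript = start_tr,
                       repeats = h$repeats,
                       distance_upstream_pa = dist,
                       center_genomic = as.integer(cg),
                       stringsAsFactors = FALSE)
  } else {
    hits <- data.frame(gene_id = character(0),
                       start_in_transcript = integer(0),
                       repeats = integer(0),
                       distance_upstream_pa = numeric(0),
                       center_genomic = integer(0),
                       stringsAsFactors = FALSE)
  }
  list(hits = hits, presence = presence)
}

#' Positional summary of motif hits
#'
#' @param hits hit table from \code{\link{hits_near_pa}} (or any
#'   data.frame with a \code{distance_upstream_pa} column).
#' @param bin_width histogram bin width in bp.
#' @return List with \code{n}, \code{mean}, \code{median}, \code{sd},
#'   \code{sem} and a \code{histogram} data.frame (\code{bin_left},
#'   \code{count}).
#' @export
positional_summary <- function(hits, bin_width = 10L) {
  d <- hits$distance_upstream_pa
  if (!length(d))
    return(list(n = 0L, mean = NA_real_, median = NA_real_,
                sd = NA_real_, sem = NA_real_,
                histogram = data.frame(bin_left = numeric(0),
                                       count = integer(0))))
  bl <- floor(d / bin_width) * bin_width
  tab <- table(bl)
  list(n = length(d), mean = mean(d), median = stats::median(d),
       sd = stats::sd(d), sem = stats::sd(d) / sqrt(length(d)),
       histogram = data.frame(bin_left = as.numeric(names(tab)),
                              count = as.integer(tab)))
}

#' Motif enrichment between gene sets
#'
#' One-sided hypergeometric over-representation of motif-carrying genes
#' in the target set versus a background set; the universe is the union
#' of the two sets.
#'
#' @param target,background \code{\link{gene_set}} objects.
#' @param presence named logical vector (gene has motif), covering the
#'   union of both sets.
#' @return An \code{\link{hypergeom_overlap}} result plus
#'   \code{fold_enrichment} of motif frequency target/background.
#' @export
motif_set_enrichment <- function(target, background, presence) {
  universe <- union(target$members, background$members)
  missing <- setdiff(universe, names(presence))
  if (length(missing))
    stop("presence flags missing for ", length(missing), " gene(s)")
  with_motif <- names(presence)[presence]
  res <- hypergeom_overlap(gene_set("motif", intersect(with_motif, universe)),
                           target, universe)
  p_t <- mean(presence[target$members])
  p_b <- mean(presence[background$members])
  res$fold_enrichment <- if (p_b > 0) p_t / p_b else Inf
  res
}
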
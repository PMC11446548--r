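#' Per-base strand-resolved signal track
#'
#' A \code{signal_track} stores one non-negative coverage value per base
#' and strand for each chromosome. Unstranded assays (ChIP, GRO on
#' double-stranded templates) are stored on both strands so that
#' strand-aware window extraction works uniformly.
#'
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @return An empty \code{signal_track} (all zeros).
#' @export
signal_track <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == ""))
    stop("chrom_sizes must be named")
  chrom_sizes <- stats::setNames(as.integer(chrom_sizes), names(chrom_sizes))
  if (any(chrom_sizes < 1L)) stop("chromosome lengths must be >= 1")
  empty <- lapply(chrom_sizes, numeric)
  structure(list(chrom_sizes = chrom_sizes, plus = empty, minus = empty),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("<signal_track> ", length(x$chrom_sizes), " chromosome(s), ",
      sum(as.numeric(x$chrom_sizes)), " bp; total signal +: ",
      signif(sum(vapply(x$plus, sum, 0)), 6), ", -: ",
      signif(sum(vapply(x$minus, sum, 0)), 6), "\n", sep = "")
  invisible(x)
}

.track_strand_slot <- function(strand) {
  switch(strand, "+" = "plus", "-" = "minus",
         stop("strand must be '+' or '-'"))
}

#' Get the per-base vector for one chromosome and strand
#'
#' @param track a \code{signal_track}.
#' @param chrom chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @return Numeric vector of length \code{chrom_sizes[chrom]}.
#' @export
track_values <- function(track, chrom, strand = "+") {
  if (!chrom %in% names(track$chrom_sizes))
    stop("unknown chromosome: ", chrom)
  track[[.track_strand_slot(strand)]][[chrom]]
}

# internal: add `values` at 0-based positions [start0, start0 + length) on
# one or both strands; out-of-range additions are a caller bug.
track_add <- function(track, chrom, strand, start0, values) {
  n <- track$chrom_sizes[[chrom]]
  idx <- seq.int(start0 + 1L, start0 + length(values))
  if (start0 < 0L || idx[length(idx)] > n)
    stop("signal outside chromosome ", chrom, " [", start0, ", ",
         start0 + length(values), ")")
  slots <- if (strand == "both") c("plus", "minus") else .track_strand_slot(strand)
  for (s in slots)
    track[[s]][[chrom]][idx] <- track[[s]][[chrom]][idx] + values
  track
}

# internal: add one count at each 0-based position in `pos0` (repeats add)
track_add_counts <- function(track, chrom, strand, pos0) {
  n <- track$chrom_sizes[[chrom]]
  if (any(pos0 < 0L) || any(pos0 >= n))
    stop("positions outside chromosome ", chrom)
  tb <- tabulate(pos0 + 1L, nbins = n)
  slots <- if (strand == "both") c("plus", "minus") else .track_strand_slot(strand)
  for (s in slots)
    track[[s]][[chrom]] <- track[[s]][[chrom]] + tb
  track
}

#' Read a bedGraph file into a signal track
#'
#' Overlapping bedGraph intervals are summed; positions not listed are
#' zero. bedGraph itself is unstranded, so the caller states which strand
#' the file describes (\code{"both"} mirrors the values onto both strands).
#'
#' @param path bedGraph file path.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param strand \code{"+"}, \code{"-"} or \code{"both"}.
#' @param track optional existing \code{signal_track} to add into.
#' @return A \code{signal_track}.
#' @export
read_signal_track <- function(path, chrom_sizes, strand = c("both", "+", "-"),
                              track = NULL) {
  strand <- match.arg(strand)
  if (is.null(track)) track <- signal_track(chrom_sizes)
  gr <- rtracklayer::import(path, format = "bedGraph")
  ch <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(ch), names(track$chrom_sizes))
  if (length(unknown))
    stop("bedGraph names unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  s1 <- GenomicRanges::start(gr)           # 1-based
  e1 <- GenomicRanges::end(gr)
  sizes <- track$chrom_sizes[ch]
  bad <- which(s1 < 1L | e1 > sizes)
  if (length(bad))
    stop("bedGraph interval beyond chromosome bounds: ", ch[bad[1]], ":",
         s1[bad[1]] - 1L, "-", e1[bad[1]])
  for (i in seq_along(gr)) {
    track <- track_add(track, ch[i], strand, s1[i] - 1L,
                       rep(gr$score[i], e1[i] - s1[i] + 1L))
  }
  track
}

#' Write one strand of a signal track as bedGraph
#'
#' Zero runs are omitted; \code{\link{read_signal_track}} restores them,
#' so write-then-read round-trips exactly.
#'
#' @param track a \code{signal_track}.
#' @param path output path.
#' @param strand which strand's values to write (\code{"+"} or \code{"-"}).
#' @return \code{path}, invisibly.
#' @export
write_signal_track <- function(track, path, strand = "+") {
  slot <- .track_strand_slot(strand)
  grl <- lapply(names(track$chrom_sizes), function(ch) {
    v <- track[[slot]][[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    GenomicRanges::GRanges(
      seqnames = ch,
      ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]),
      score = r$values[keep])
  })
  grl <- grl[!vapply(grl, is.null, TRUE)]
  gr <- if (length(grl)) do.call(c, grl) else
    GenomicRanges::GRanges(score = numeric(0))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Extract a transcript-sense window around an anchor
#'
#' Returns \code{upstream + downstream} values ordered 5' to 3' in
#' transcript sense (minus-strand windows run leftward along the genome).
#' Offset 0 is the anchor base itself; offsets are
#' \code{-upstream .. downstream - 1}. Cells falling outside the
#' chromosome are masked (\code{valid = FALSE}), never silently zeroed.
#'
#' @param track a \code{signal_track}.
#' @param chrom chromosome name.
#' @param strand gene strand, \code{"+"} or \code{"-"}.
#' @param anchor 0-based genomic coordinate of the offset-0 base
#'   (see \code{\link{anchor_coord}}).
#' @param upstream,downstream non-negative window extents (bp).
#' @return List with \code{offsets}, \code{values} and logical
#'   \code{valid}; masked cells hold 0 in \code{values}.
#' @export
extract_window <- function(track, chrom, strand, anchor, upstream, downstream) {
  stopifnot(upstream >= 0, downstream >= 0, upstream + downstream >= 1)
  offsets <- seq.int(-upstream, downstream - 1L)
  gpos <- if (strand == "+") anchor + offsets else anchor - offsets
  n <- track$chrom_sizes[[chrom]]
  if (is.null(n)) stop("unknown chromosome: ", chrom)
  valid <- gpos >= 0L & gpos < n
  values <- numeric(length(offsets))
  if (any(valid)) {
    v <- track_values(track, chrom, strand)
    values[valid] <- v[gpos[valid] + 1L]
  } else {
    warning("anchor ", anchor, " outside chromosome ", chrom,
            ": fully masked window")
  }
  list(offsets = offsets, values = values, valid = valid)
}

#' Per-gene read counts from a track
#'
#' Sums the signal over each transcript on its own strand. This is the
#' counting step feeding RPKM and top-N selection.
#'
#' @param track a \code{signal_track}.
#' @param ann a \code{gene_annotation}.
#' @return Named numeric vector of per-gene totals.
#' @export
gene_counts <- function(track, ann) {
  out <- numeric(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    lo <- min(ann$tss[i], ann$pa[i])
    hi <- max(ann$tss[i], ann$pa[i])
    v <- track_values(track, ann$chrom[i], ann$strand[i])
    out[i] <- sum(v[(lo + 1L):hi])
  }
  stats::setNames(out, ann$gene_id)
}
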
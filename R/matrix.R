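#' Anchored genes-by-positions signal matrix
#'
#' Internal constructor; rows are genes (transcript-sense 5' to 3'),
#' columns are offsets relative to the anchor, and \code{valid} marks
#' cells that fall inside the chromosome. Masked cells are excluded from
#' every average downstream.
#'
#' @keywords internal
signal_matrix <- function(gene_ids, anchor, offsets, values, valid) {
  stopifnot(nrow(values) == length(gene_ids),
            ncol(values) == length(offsets),
            all(dim(valid) == dim(values)),
            !is.unsorted(offsets, strictly = TRUE))
  structure(list(gene_ids = gene_ids, anchor = anchor,
                 offsets = as.integer(offsets),
                 values = values, valid = valid),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("<signal_matrix> ", length(x$gene_ids), " genes x ",
      length(x$offsets), " positions, anchor = ", x$anchor,
      ", offsets ", x$offsets[1], "..", x$offsets[length(x$offsets)],
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$values)

#' Build an anchored signal matrix
#'
#' Extracts, for every gene, a transcript-sense window around the TSS, the
#' pA site, or a per-gene motif center, and stacks them into a
#' \code{signal_matrix}. Out-of-chromosome cells are masked; genes lacking
#' the requested anchor (e.g. no motif) get a fully masked row.
#'
#' @param track a \code{signal_track}.
#' @param ann a \code{gene_annotation}.
#' @param anchor \code{"tss"}, \code{"pa"} or \code{"motif_center"}.
#' @param upstream,downstream window extents in bp.
#' @param anchor_coords for \code{anchor = "motif_center"}: named vector
#'   of 0-based genomic coordinates of the anchor base per gene (NA or
#'   absent genes are masked). Ignored otherwise.
#' @return A \code{signal_matrix}.
#' @export
anchored_matrix <- function(track, ann,
                            anchor = c("pa", "tss", "motif_center"),
                            upstream, downstream, anchor_coords = NULL) {
  anchor <- match.arg(anchor)
  if (anchor == "motif_center") {
    if (is.null(anchor_coords))
      stop("anchor_coords required for motif_center anchoring")
    ac <- anchor_coords[ann$gene_id]
  } else {
    ac <- anchor_coord(ann, anchor)
  }
  npos <- upstream + downstream
  values <- matrix(0, nrow(ann), npos)
  valid <- matrix(FALSE, nrow(ann), npos)
  offsets <- seq.int(-upstream, downstream - 1L)
  masked_rows <- 0L
  for (i in seq_len(nrow(ann))) {
    if (is.na(ac[i])) { masked_rows <- masked_rows + 1L; next }
    w <- extract_window(track, ann$chrom[i], ann$strand[i], ac[i],
                        upstream, downstream)
    values[i, ] <- w$values
    valid[i, ] <- w$valid
  }
  if (masked_rows > 0L)
    message(masked_rows, " gene(s) lack the requested anchor; rows masked")
  signal_matrix(ann$gene_id, anchor, offsets, values, valid)
}

#' Subset a signal matrix by gene
#'
#' @param mat a \code{signal_matrix}.
#' @param genes character vector or \code{gene_set} of genes to keep
#'   (order preserved from the matrix).
#' @return A \code{signal_matrix}.
#' @export
subset_matrix <- function(mat, genes) {
  if (inherits(genes, "gene_set")) genes <- genes$members
  keep <- mat$gene_ids %in% genes
  signal_matrix(mat$gene_ids[keep], mat$anchor, mat$offsets,
                mat$values[keep, , drop = FALSE],
                mat$valid[keep, , drop = FALSE])
}

#' Bin matrix columns
#'
#' Sums values within consecutive \code{bin_width} columns (masked cells
#' contribute 0), so binned row totals equal unbinned row totals over
#' valid cells. The reported offset of a bin is its left edge.
#'
#' @param mat a \code{signal_matrix}.
#' @param bin_width number of columns per bin; the column count must be a
#'   multiple of it.
#' @return A \code{signal_matrix} with one column per bin; a bin is valid
#'   if any of its cells was valid.
#' @export
bin_matrix <- function(mat, bin_width) {
  npos <- length(mat$offsets)
  if (bin_width == 1L) return(mat)
  if (npos %% bin_width != 0L)
    stop("column count ", npos, " not a multiple of bin_width ", bin_width)
  grp <- rep(seq_len(npos %/% bin_width), each = bin_width)
  v <- mat$values
  v[!mat$valid] <- 0
  binned <- t(apply(v, 1L, function(r) tapply(r, grp, sum)))
  bvalid <- t(apply(mat$valid, 1L, function(r) tapply(r, grp, any)))
  offs <- mat$offsets[seq(1L, npos, by = bin_width)]
  signal_matrix(mat$gene_ids, mat$anchor, offs,
                matrix(binned, nrow = nrow(v)),
                matrix(bvalid, nrow = nrow(v)))
}

#' Row-scale a signal matrix to unit mass with uniform smoothing
#'
#' Divides each row by its total valid signal so that clustering captures
#' profile shape rather than expression level. With \code{shrink > 0} the
#' row is first smoothed toward the uniform profile over its valid cells
#' (a symmetric Dirichlet prior with total pseudocount \code{shrink}):
#' \code{(x + shrink/n_valid) / (total + shrink)}. A near-empty row is
#' thereby pulled to the null shape - flat - rather than being inflated
#' into a spurious spike, while well-populated rows are essentially
#' unchanged. The uniform row is a fixed point of the smoothing, so
#' mass-fraction arithmetic on flat profiles is exact for any
#' \code{shrink}. Rows with no signal at all become exactly uniform and
#' are reported via the \code{"zero_rows"} attribute.
#'
#' @param mat a \code{signal_matrix}.
#' @param shrink non-negative total pseudocount (signal units).
#' @return A \code{signal_matrix} of row-normalized values.
#' @export
row_scale_matrix <- function(mat, shrink = 0) {
  stopifnot(shrink >= 0)
  v <- mat$values
  v[!mat$valid] <- 0
  tot <- rowSums(v)
  nv <- rowSums(mat$valid)
  for (i in seq_len(nrow(v))) {
    if (nv[i] == 0L) next                      # fully masked row stays 0
    if (tot[i] + shrink <= 0) next
    prior <- ifelse(mat$valid[i, ], shrink / nv[i], 0)
    v[i, ] <- (v[i, ] + prior) / (tot[i] + shrink)
  }
  out <- signal_matrix(mat$gene_ids, mat$anchor, mat$offsets, v, mat$valid)
  attr(out, "zero_rows") <- mat$gene_ids[tot <= 0]
  out
}
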
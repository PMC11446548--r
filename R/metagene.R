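#' Column-wise average profile of a signal matrix
#'
#' Means are taken over valid cells only, with the per-column valid count
#' reported, so masked edge cells never bias the profile toward zero.
#'
#' @param mat a \code{signal_matrix}.
#' @return A data.frame of class \code{"metagene_profile"} with columns
#'   \code{position}, \code{mean} (NA where no valid cell) and
#'   \code{n_valid}; attribute \code{scale_tag = "real_bp"}.
#' @export
average_profile <- function(mat) {
  v <- mat$values
  v[!mat$valid] <- 0
  n_valid <- colSums(mat$valid)
  m <- ifelse(n_valid > 0, colSums(v) / n_valid, NA_real_)
  out <- data.frame(position = mat$offsets, mean = m, n_valid = n_valid)
  class(out) <- c("metagene_profile", "data.frame")
  attr(out, "scale_tag") <- "real_bp"
  attr(out, "anchor") <- mat$anchor
  out
}

#' Robust extreme-coverage gene filter
#'
#' Removes the genes with the most extreme mean coverage before profile
#' averaging: the \code{ceiling(f/2 * n)} highest and the same number of
#' lowest rows by row-mean signal (over valid cells). Splitting the
#' fraction evenly between the two tails is this package's convention and
#' is recorded in the result's attributes.
#'
#' @param mat a \code{signal_matrix}.
#' @param extreme_fraction total fraction of rows to drop, in [0, 0.5).
#' @return The filtered \code{signal_matrix} (row order preserved), with
#'   attribute \code{"removed"} listing the dropped genes.
#' @export
robust_filter <- function(mat, extreme_fraction = 0.05) {
  stopifnot(extreme_fraction >= 0, extreme_fraction < 0.5)
  n <- nrow(mat$values)
  k <- ceiling(extreme_fraction / 2 * n)
  if (n - 2 * k < 2)
    stop("robust_filter would leave fewer than 2 rows")
  if (k == 0L) return(mat)
  v <- mat$values
  v[!mat$valid] <- 0
  rm_mean <- rowSums(v) / pmax(rowSums(mat$valid), 1L)
  ord <- order(rm_mean, mat$gene_ids)   # deterministic tie-break
  drop <- c(ord[seq_len(k)], ord[seq.int(n - k + 1L, n)])
  keep <- setdiff(seq_len(n), drop)
  out <- signal_matrix(mat$gene_ids[keep], mat$anchor, mat$offsets,
                       mat$values[keep, , drop = FALSE],
                       mat$valid[keep, , drop = FALSE])
  attr(out, "removed") <- mat$gene_ids[sort(drop)]
  attr(out, "extreme_fraction") <- extreme_fraction
  out
}

#' Hybrid-scale metagene profile
#'
#' Averages signal over genes on a hybrid axis: flanks outside the
#' transcript at real scale (bp), and the transcribed body resampled to a
#' fixed number of percent bins so genes of different lengths are
#' comparable. Body resampling uses mean-within-bin (not interpolation),
#' preserving read-density semantics. Genes shorter than \code{body_bins}
#' are skipped (counted in the \code{"skipped"} attribute).
#'
#' @param track a \code{signal_track}.
#' @param ann a \code{gene_annotation}.
#' @param flank5,flank3 real-scale flank extents in bp (upstream of the
#'   TSS and downstream of the pA).
#' @param body_bins number of percent-scale bins for the transcribed
#'   region.
#' @return A data.frame of class \code{"metagene_profile"} with columns
#'   \code{segment} (\code{"flank5"}, \code{"body"}, \code{"flank3"}),
#'   \code{position} (bp relative to TSS/pA for flanks, bin index 1..B for
#'   the body), \code{mean} and \code{n_valid}.
#' @export
scaled_metagene <- function(track, ann, flank5 = 200L, flank3 = 200L,
                            body_bins = 100L) {
  stopifnot(body_bins >= 1L)
  lens <- transcript_length(ann)
  usable <- lens >= body_bins
  if (!any(usable))
    stop("all genes shorter than body_bins = ", body_bins)
  npos <- flank5 + body_bins + flank3
  sums <- numeric(npos)
  counts <- numeric(npos)
  tss_a <- anchor_coord(ann, "tss")
  pa_a <- anchor_coord(ann, "pa")
  for (i in which(usable)) {
    L <- lens[i]
    # flank5: offsets -flank5 .. -1 of TSS
    if (flank5 > 0L) {
      w <- extract_window(track, ann$chrom[i], ann$strand[i], tss_a[i],
                          flank5, 0L)
      idx <- seq_len(flank5)
      sums[idx] <- sums[idx] + ifelse(w$valid, w$values, 0)
      counts[idx] <- counts[idx] + w$valid
    }
    # body: transcript positions 0..L-1 binned to body_bins
    b <- extract_window(track, ann$chrom[i], ann$strand[i], tss_a[i],
                        0L, L)
    bin <- as.integer(ceiling(seq_len(L) / L * body_bins))
    bsum <- tapply(ifelse(b$valid, b$values, 0), bin, sum)
    bcnt <- tapply(as.numeric(b$valid), bin, sum)
    bm <- ifelse(bcnt > 0, bsum / bcnt, NA_real_)
    idx <- flank5 + seq_len(body_bins)
    ok <- !is.na(bm)
    sums[idx][ok] <- sums[idx][ok] + bm[ok]
    counts[idx][ok] <- counts[idx][ok] + 1
    # flank3: offsets 0 .. flank3-1 of pA
    if (flank3 > 0L) {
      w <- extract_window(track, ann$chrom[i], ann$strand[i], pa_a[i],
                          0L, flank3)
      idx <- flank5 + body_bins + seq_len(flank3)
      sums[idx] <- sums[idx] + ifelse(w$valid, w$values, 0)
      counts[idx] <- counts[idx] + w$valid
    }
  }
  out <- data.frame(
    segment = rep(c("flank5", "body", "flank3"),
                  c(flank5, body_bins, flank3)),
    position = c(if (flank5 > 0L) seq.int(-flank5, -1L) else integer(0),
                 seq_len(body_bins),
                 if (flank3 > 0L) seq.int(0L, flank3 - 1L) else integer(0)),
    mean = ifelse(counts > 0, sums / counts, NA_real_),
    n_valid = counts)
  class(out) <- c("metagene_profile", "data.frame")
  attr(out, "scale_tag") <- c(flank = "real_bp", body = "percent")
  attr(out, "skipped") <- ann$gene_id[!usable]
  out
}
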
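#' Mean signal over 5' and 3' gene-end tiles
#'
#' Strand-aware means over the first and last \code{tile} bases of each
#' transcript. Transcripts shorter than the tile use the whole gene for
#' both tiles and are flagged.
#'
#' @param track a \code{signal_track}.
#' @param ann a \code{gene_annotation}.
#' @param tile tile size in bp.
#' @return data.frame with \code{gene_id}, \code{mean5}, \code{mean3}
#'   and logical \code{clipped}.
#' @export
gene_end_averages <- function(track, ann, tile = 250L) {
  lens <- transcript_length(ann)
  tss_a <- anchor_coord(ann, "tss")
  out <- data.frame(gene_id = ann$gene_id, mean5 = NA_real_,
                    mean3 = NA_real_, clipped = lens < tile,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ann))) {
    L <- lens[i]
    w <- extract_window(track, ann$chrom[i], ann$strand[i], tss_a[i], 0L, L)
    v <- w$values[w$valid]
    if (L < tile) {
      out$mean5[i] <- out$mean3[i] <- mean(v)
    } else {
      out$mean5[i] <- mean(w$values[seq_len(tile)][w$valid[seq_len(tile)]])
      i3 <- seq.int(L - tile + 1L, L)
      out$mean3[i] <- mean(w$values[i3][w$valid[i3]])
    }
  }
  out
}

#' Pol II backtracking index
#'
#' BI is the ratio of total Pol II occupancy (ChIP) to actively
#' elongating Pol II (run-on signal): backtracked polymerases are
#' crosslinkable but cannot elongate, so a high BI marks frequent
#' backtracking. The per-gene ChIP and run-on signals are each combined
#' as the mean of the 5' and 3' tile means; genes with zero run-on
#' signal are flagged (pseudocount 0 by default).
#'
#' @param chip per-gene ChIP tile averages
#'   (\code{\link{gene_end_averages}} output).
#' @param gro per-gene run-on tile averages (same shape).
#' @param pseudocount added to numerator and denominator.
#' @return data.frame with \code{gene_id}, \code{chip}, \code{gro},
#'   \code{BI} (NA where undefined) and \code{undefined} flag.
#' @export
backtracking_index <- function(chip, gro, pseudocount = 0) {
  stopifnot(identical(chip$gene_id, gro$gene_id))
  cs <- (chip$mean5 + chip$mean3) / 2 + pseudocount
  gs <- (gro$mean5 + gro$mean3) / 2 + pseudocount
  undef <- !(gs > 0)
  data.frame(gene_id = chip$gene_id, chip = cs, gro = gs,
             BI = ifelse(undef, NA_real_, cs / gs),
             undefined = undef, stringsAsFactors = FALSE)
}

#' Median-centered z-score
#'
#' Centers on the median and scales by the sample standard deviation
#' (computed about the mean, n - 1), so values from different assay types
#' become comparable. NAs are dropped from the location/scale estimates
#' but preserved in the output.
#'
#' @param values numeric vector with at least 2 distinct finite values.
#' @return \code{(values - median) / sd}.
#' @examples
#' zscore_median(c(1, 2, 3))  # -1 0 1
#' @export
zscore_median <- function(values) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2L) stop("need >= 2 distinct values")
  s <- stats::sd(v)
  if (s == 0) stop("zero standard deviation")
  (values - stats::median(v)) / s
}

#' Rpb4/Rpb3 ratio profile along transcription units
#'
#' Computes the ratio of gene-set-averaged Rpb4-ChIP to Rpb3-ChIP signal
#' (ratio of means, robust to per-gene zeros) on two transcript-sense
#' segments: around the TSS and around the pA, then normalizes the whole
#' profile to the value at the most upstream TSS position so it reads as
#' "change after Pol II recruitment". Positions where the denominator is
#' not positive give NA.
#'
#' @param rpb4_track,rpb3_track \code{signal_track}s.
#' @param ann a \code{gene_annotation}.
#' @param genes optional \code{gene_set} restriction.
#' @param tss_window integer c(upstream, downstream) around the TSS
#'   (default -100..+250).
#' @param pa_window integer c(upstream, downstream) around the pA
#'   (default -250..+100).
#' @param pseudocount added to both averaged signals before the ratio.
#' @return data.frame of class \code{"ratio_profile"}: \code{segment}
#'   (\code{"tss"}/\code{"pa"}), \code{position}, \code{ratio}
#'   (normalized), \code{ratio_raw}; attribute \code{"norm_value"} holds
#'   the pre-normalization anchor value.
#' @export
ratio_profile <- function(rpb4_track, rpb3_track, ann, genes = NULL,
                          tss_window = c(100L, 250L),
                          pa_window = c(250L, 100L),
                          pseudocount = 0) {
  if (!is.null(genes)) {
    keep <- ann$gene_id %in%
      (if (inherits(genes, "gene_set")) genes$members else genes)
    ann <- ann[keep, , drop = FALSE]
    class(ann) <- c("gene_annotation", "data.frame")
  }
  seg_ratio <- function(anchor, up, down) {
    m4 <- average_profile(anchored_matrix(rpb4_track, ann, anchor, up, down))
    m3 <- average_profile(anchored_matrix(rpb3_track, ann, anchor, up, down))
    num <- m4$mean + pseudocount
    den <- m3$mean + pseudocount
    data.frame(position = m4$position,
               ratio_raw = ifelse(!is.na(den) & den > 0, num / den,
                                  NA_real_))
  }
  tssd <- seg_ratio("tss", tss_window[1], tss_window[2])
  pad <- seg_ratio("pa", pa_window[1], pa_window[2])
  norm_value <- tssd$ratio_raw[1]          # TSS - upstream anchor position
  if (is.na(norm_value) || norm_value <= 0)
    stop("normalization anchor value undefined")
  out <- rbind(
    data.frame(segment = "tss", tssd),
    data.frame(segment = "pa", pad))
  out$ratio <- out$ratio_raw / norm_value
  class(out) <- c("ratio_profile", "data.frame")
  attr(out, "norm_value") <- norm_value
  out
}

#' Per-gene Rpb4/Rpb3 body ratio
#'
#' Mean of per-position Rpb4/Rpb3 ratios over the two gene-body windows
#' (TSS to +\code{tile} and -\code{tile} to pA); mean-of-ratios is the
#' per-gene convention, complementing the ratio-of-means profile of
#' \code{\link{ratio_profile}}. Windows are clipped for short genes.
#'
#' @param rpb4_track,rpb3_track \code{signal_track}s.
#' @param ann a \code{gene_annotation}.
#' @param tile window size in bp from each gene end.
#' @param pseudocount added to numerator and denominator per position.
#' @return Named numeric vector of per-gene mean ratios (NA where no
#'   position has positive denominator).
#' @export
body_ratio <- function(rpb4_track, rpb3_track, ann, tile = 250L,
                       pseudocount = 0) {
  lens <- transcript_length(ann)
  tss_a <- anchor_coord(ann, "tss")
  out <- rep(NA_real_, nrow(ann))
  for (i in seq_len(nrow(ann))) {
    L <- lens[i]
    w4 <- extract_window(rpb4_track, ann$chrom[i], ann$strand[i], tss_a[i],
                         0L, L)
    w3 <- extract_window(rpb3_track, ann$chrom[i], ann$strand[i], tss_a[i],
                         0L, L)
    pos <- unique(c(seq_len(min(tile, L)),
                    seq.int(max(1L, L - tile + 1L), L)))
    ok <- w4$valid[pos] & w3$valid[pos]
    num <- w4$values[pos][ok] + pseudocount
    den <- w3$values[pos][ok] + pseudocount
    r <- num[den > 0] / den[den > 0]
    if (length(r)) out[i] <- mean(r)
  }
  stats::setNames(out, ann$gene_id)
}

#' Correlation ledger across quantities and gene sets
#'
#' Pearson and Spearman correlations (with two-sided p-values from
#' \code{stats::cor.test}) for each requested pair of per-gene
#' quantities, stratified by gene set; pairwise complete observations
#' only, with n reported. No multiple-testing correction is applied
#' within the ledger.
#'
#' @param data data.frame with a \code{gene_id} column and one column
#'   per quantity.
#' @param pairs list of length-2 character vectors naming quantity
#'   column pairs.
#' @param gene_sets named list of \code{\link{gene_set}}s (each stratum
#'   is evaluated separately); the stratum \code{"all"} over every gene
#'   is always included.
#' @return data.frame with \code{x}, \code{y}, \code{gene_set},
#'   \code{method}, \code{r}, \code{p}, \code{n}.
#' @export
correlation_ledger <- function(data, pairs, gene_sets = list()) {
  strata <- c(list(all = data$gene_id),
              lapply(gene_sets, function(s)
                if (inherits(s, "gene_set")) s$members else s))
  rows <- list()
  for (pr in pairs) {
    for (sn in names(strata)) {
      sub <- data[data$gene_id %in% strata[[sn]], , drop = FALSE]
      x <- sub[[pr[1]]]
      y <- sub[[pr[2]]]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      for (method in c("pearson", "spearman")) {
        if (n >= 3L) {
          ct <- suppressWarnings(
            stats::cor.test(x[ok], y[ok], method = method, exact = FALSE))
          r <- unname(ct$estimate)
          p <- ct$p.value
        } else {
          r <- NA_real_
          p <- NA_real_
        }
        rows[[length(rows) + 1L]] <-
          data.frame(x = pr[1], y = pr[2], gene_set = sn, method = method,
                     r = r, p = p, n = n, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
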
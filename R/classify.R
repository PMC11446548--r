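#' Reads per kilobase per million (RPKM)
#'
#' @param counts per-gene read counts (named).
#' @param lengths transcript lengths in bp (> 0), matched by position or
#'   name.
#' @param library_size total mapped reads (> 0).
#' @return Named numeric vector:
#'   \code{counts / (lengths/1000) / (library_size/1e6)}.
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(counts, lengths, library_size) {
  stopifnot(all(lengths > 0), library_size > 0)
  if (!is.null(names(counts)) && !is.null(names(lengths)))
    lengths <- lengths[names(counts)]
  counts / (lengths / 1000) / (library_size / 1e6)
}

#' Select the top-N genes by read count
#'
#' Ties are broken by gene id in lexicographic order; the rule is
#' deterministic and recorded in the result's name.
#'
#' @param counts named numeric vector of per-gene counts.
#' @param n number of genes to keep.
#' @return A \code{\link{gene_set}} of the \code{n} highest-count genes.
#' @export
select_top_genes <- function(counts, n = 600L) {
  stopifnot(!is.null(names(counts)), n <= length(counts))
  ord <- order(-counts, names(counts))
  gene_set(paste0("top", n), names(counts)[ord][seq_len(n)])
}

#' K-means clustering of anchored binding profiles
#'
#' Bins the pA-anchored matrix, row-scales each gene to unit mass (shape,
#' not level), and clusters with \code{stats::kmeans}. Clusters are
#' relabeled in decreasing order of the mass fraction of their mean
#' profile inside the upstream window, so cluster 1 is always the most
#' pA-proximal.
#'
#' @param mat a pA-anchored \code{signal_matrix} of raw signal.
#' @param k number of clusters.
#' @param seed RNG seed for the k-means initializations.
#' @param n_init number of random starts.
#' @param bin_width column bin width in bp before clustering.
#' @param scale_shrink shrinkage applied when row-scaling, expressed as a
#'   fraction of the upper-quartile row mass (see
#'   \code{\link{row_scale_matrix}}): rows with far less signal than a
#'   typical signal-bearing row carry too little shape information and
#'   are smoothed toward the flat null shape rather than inflated to
#'   unit mass. Being relative, it leaves the classification invariant
#'   to multiplying the whole track by a constant. Set to 0 to disable
#'   smoothing entirely.
#' @param min_evidence floor (signal units, ~reads) on the smoothing
#'   pseudocount, so that on cohorts with no real signal at all the few
#'   stray counts per row cannot be read as shapes; applies only when
#'   \code{scale_shrink > 0}.
#' @param upstream_window bp upstream of the anchor used for the
#'   per-cluster upstream mass fraction.
#' @return An object of class \code{"crac_clusters"}: gene ids, labels,
#'   cluster mean (row-scaled) profiles, per-cluster upstream mass
#'   fractions and raw read mass.
#' @export
kmeans_profiles <- function(mat, k = 4L, seed = 1L, n_init = 10L,
                            bin_width = 10L, scale_shrink = 0.1,
                            min_evidence = 5, upstream_window = 250L) {
  stopifnot(nrow(mat$values) >= k)
  binned <- bin_matrix(mat, bin_width)
  bv <- binned$values
  bv[!binned$valid] <- 0
  shrink <- if (scale_shrink > 0)
    max(scale_shrink * stats::quantile(rowSums(bv), 0.75, names = FALSE),
        min_evidence)
  else 0
  scaled <- row_scale_matrix(binned, shrink = shrink)
  x <- scaled$values
  km <- local_seed(seed, stats::kmeans(x, centers = k, nstart = n_init,
                                       iter.max = 100L))
  centers <- km$centers
  umf <- unname(apply(centers, 1L, function(ctr)
    .upstream_mass_fraction(ctr, scaled$offsets, bin_width,
                            upstream_window)))
  relabel <- order(-umf)                    # new label 1 = most pA-proximal
  old2new <- match(seq_len(k), relabel)
  labels <- old2new[km$cluster]
  centers <- centers[relabel, , drop = FALSE]
  umf <- umf[relabel]
  rawv <- mat$values
  rawv[!mat$valid] <- 0
  row_mass <- rowSums(rawv)
  read_mass <- vapply(seq_len(k), function(cl) sum(row_mass[labels == cl]), 0)
  structure(list(gene_ids = mat$gene_ids, labels = labels,
                 centers = centers, offsets = scaled$offsets,
                 bin_width = bin_width,
                 upstream_window = upstream_window,
                 upstream_mass_fraction = umf,
                 read_mass = read_mass,
                 zero_rows = attr(scaled, "zero_rows"),
                 k = k, seed = seed),
            class = "crac_clusters")
}

# mass fraction of a profile within [-upstream_window, 0); offsets are the
# left edges of bins of width bin_width
.upstream_mass_fraction <- function(profile, offsets, bin_width,
                                    upstream_window) {
  tot <- sum(profile)
  if (tot <= 0) return(0)
  inwin <- offsets >= -upstream_window & (offsets + bin_width) <= 0L
  sum(profile[inwin]) / tot
}

#' @export
print.crac_clusters <- function(x, ...) {
  cat("<crac_clusters> k = ", x$k, ", ", length(x$gene_ids), " genes\n",
      sep = "")
  for (cl in seq_len(x$k))
    cat(sprintf("  C%d: %4d genes, upstream mass %.3f, read mass %.0f\n",
                cl, sum(x$labels == cl), x$upstream_mass_fraction[cl],
                x$read_mass[cl]))
  invisible(x)
}

#' Call CRAC-positive genes from a cluster result
#'
#' A cluster is CRAC+ when the mass fraction of its mean profile inside
#' the window immediately upstream of the pA exceeds the threshold; the
#' call is the union of the genes in those clusters. The threshold is a
#' first-class parameter (see \code{\link{threshold_sweep}}).
#'
#' @param clusters a \code{crac_clusters} object.
#' @param mass_threshold minimum upstream mass fraction for a CRAC+
#'   cluster.
#' @return A \code{\link{gene_set}} with attributes
#'   \code{positive_clusters}, \code{cluster_mass_fraction} and
#'   \code{read_fraction} (fraction of all matrix reads falling in CRAC+
#'   clusters).
#' @export
call_crac_positive <- function(clusters, mass_threshold = 0.6) {
  pos <- which(clusters$upstream_mass_fraction > mass_threshold)
  genes <- clusters$gene_ids[clusters$labels %in% pos]
  out <- gene_set("CRAC+", genes)
  attr(out, "positive_clusters") <- pos
  attr(out, "cluster_mass_fraction") <- clusters$upstream_mass_fraction
  attr(out, "read_fraction") <-
    sum(clusters$read_mass[pos]) / sum(clusters$read_mass)
  attr(out, "mass_threshold") <- mass_threshold
  out
}

#' Sensitivity sweep over the CRAC+ mass threshold
#'
#' @param clusters a \code{crac_clusters} object.
#' @param thresholds thresholds to evaluate.
#' @return data.frame with per-threshold number of positive clusters,
#'   gene-set size and read fraction.
#' @export
threshold_sweep <- function(clusters, thresholds = seq(0.3, 0.9, by = 0.05)) {
  rows <- lapply(thresholds, function(th) {
    cs <- call_crac_positive(clusters, th)
    data.frame(threshold = th,
               n_clusters = length(attr(cs, "positive_clusters")),
               n_genes = length(cs$members),
               read_fraction = attr(cs, "read_fraction"))
  })
  do.call(rbind, rows)
}

#' Per-gene CRAC index
#'
#' The CRAC index is the binding propensity of a transcript: its CRAC
#' RPKM normalized to its mRNA level. An alternative index normalized to
#' a ChIP signal is computed when that signal is supplied. Genes with a
#' zero denominator are flagged, not dropped.
#'
#' @param crac_rpkm named per-gene CRAC RPKM.
#' @param mrna_level named per-gene mRNA abundance.
#' @param chip_signal optional named per-gene ChIP signal.
#' @return data.frame with \code{gene_id}, \code{crac_index},
#'   optional \code{alt_index}, and logical \code{undefined} flag.
#' @export
crac_index <- function(crac_rpkm, mrna_level, chip_signal = NULL) {
  ids <- names(crac_rpkm)
  stopifnot(!is.null(ids), setequal(ids, names(mrna_level)))
  mrna_level <- mrna_level[ids]
  undef <- !(mrna_level > 0)
  idx <- ifelse(undef, NA_real_, crac_rpkm / mrna_level)
  out <- data.frame(gene_id = ids, crac_rpkm = as.numeric(crac_rpkm),
                    mrna_level = as.numeric(mrna_level),
                    crac_index = idx, undefined = undef,
                    stringsAsFactors = FALSE)
  if (!is.null(chip_signal)) {
    chip_signal <- chip_signal[ids]
    out$alt_index <- ifelse(chip_signal > 0, crac_rpkm / chip_signal,
                            NA_real_)
  }
  out
}
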
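#' Gene annotation table
#'
#' Builds the package's core annotation object: one row per transcription
#' unit with strand-aware transcription start site (TSS) and polyadenylation
#' site (pA). All coordinates are 0-based, half-open; the pA is the first
#' base *not* in the transcript (exclusive end in transcript sense). On the
#' plus strand \code{tss < pa}; on the minus strand \code{tss > pa} and the
#' transcript occupies the genomic interval \code{[pa, tss)}.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom character vector of chromosome names.
#' @param strand character vector, each \code{"+"} or \code{"-"}.
#' @param tss integer vector, 0-based transcription start coordinate.
#' @param pa integer vector, 0-based exclusive polyadenylation coordinate.
#' @return A \code{data.frame} of class \code{"gene_annotation"} with
#'   columns \code{gene_id}, \code{chrom}, \code{strand}, \code{tss},
#'   \code{pa}.
#' @examples
#' gene_annotation("g1", "chrI", "+", 100, 400)
#' @export
gene_annotation <- function(gene_id, chrom, strand, tss, pa) {
  gene_id <- as.character(gene_id)
  chrom <- as.character(chrom)
  strand <- as.character(strand)
  tss <- as.integer(tss)
  pa <- as.integer(pa)
  n <- length(gene_id)
  stopifnot(length(chrom) == n, length(strand) == n,
            length(tss) == n, length(pa) == n)
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  bad <- (strand == "+" & tss >= pa) | (strand == "-" & tss <= pa)
  if (any(bad))
    stop("strand/coordinate mismatch for: ",
         paste(gene_id[bad], collapse = ", "))
  out <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                    tss = tss, pa = pa, stringsAsFactors = FALSE)
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Transcript lengths
#'
#' @param ann a \code{gene_annotation}.
#' @return Integer vector of transcript lengths (bp), named by gene.
#' @export
transcript_length <- function(ann) {
  stats::setNames(abs(ann$pa - ann$tss), ann$gene_id)
}

#' Genomic coordinate of a transcript-sense anchor
#'
#' Returns, per gene, the 0-based genomic coordinate of the base at
#' transcript-sense offset zero for the requested anchor. For the TSS
#' anchor this is the first transcribed base; for the pA anchor it is the
#' first base past the transcript (in transcript sense), so a window offset
#' of -1 is the last transcribed base.
#'
#' @param ann a \code{gene_annotation}.
#' @param anchor \code{"tss"} or \code{"pa"}.
#' @return Named integer vector of genomic coordinates.
#' @export
anchor_coord <- function(ann, anchor = c("tss", "pa")) {
  anchor <- match.arg(anchor)
  a <- switch(anchor,
              tss = ifelse(ann$strand == "+", ann$tss, ann$tss - 1L),
              pa  = ifelse(ann$strand == "+", ann$pa, ann$pa - 1L))
  stats::setNames(as.integer(a), ann$gene_id)
}

#' Read a gene annotation from BED or GFF3
#'
#' TSS and pA are derived strand-correctly: for BED records on the plus
#' strand \code{tss = chromStart}, \code{pa = chromEnd}; on the minus
#' strand \code{tss = chromEnd}, \code{pa = chromStart}. GFF3 \code{gene}
#' (or \code{mRNA}/\code{transcript}) records are converted to the same
#' 0-based half-open convention, so the same locus yields an identical
#' annotation in either dialect.
#'
#' @param path path to a BED or GFF3 file.
#' @param format \code{"auto"} (by extension), \code{"bed"} or
#'   \code{"gff3"}.
#' @return A \code{gene_annotation}.
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "bed" else "gff3")
  if (format == "gff3") {
    keep <- as.character(gr$type) %in% c("gene", "mRNA", "transcript")
    if (any(keep)) gr <- gr[keep]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  } else {
    ids <- as.character(gr$name)
  }
  if (any(is.na(ids)) || is.null(ids))
    stop("annotation records lack identifiers in ", path)
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st == "*"))
    stop("unstranded annotation record(s) in ", path)
  start0 <- GenomicRanges::start(gr) - 1L   # to 0-based half-open
  end0 <- GenomicRanges::end(gr)
  gene_annotation(gene_id = ids,
                  chrom = as.character(GenomicRanges::seqnames(gr)),
                  strand = st,
                  tss = ifelse(st == "+", start0, end0),
                  pa = ifelse(st == "+", end0, start0))
}

#' Write a gene annotation as BED
#'
#' Inverse of \code{\link{read_annotation}} on canonical records:
#' write-then-read returns an identical annotation.
#'
#' @param ann a \code{gene_annotation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(ann, path) {
  lo <- pmin(ann$tss, ann$pa)
  hi <- pmax(ann$tss, ann$pa)
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = lo + 1L, end = hi),
    strand = ann$strand)
  gr$name <- ann$gene_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Gene set
#'
#' A named set of gene identifiers, used for CRAC+ calls, regulon
#' membership (RP, RiBi) and overlap statistics.
#'
#' @param name set label.
#' @param members character vector of gene ids (deduplicated).
#' @return An object of class \code{"gene_set"}.
#' @export
gene_set <- function(name, members) {
  structure(list(name = as.character(name),
                 members = unique(as.character(members))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$members), " genes\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)
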
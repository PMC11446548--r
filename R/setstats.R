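#' Hypergeometric overlap of two gene sets
#'
#' Exact tail probabilities for the overlap of two sets drawn from an
#' explicit universe: \code{p_enrich = P(X >= k)} (inclusion; the upper
#' tail includes the observed k) and \code{p_deplete = P(X <= k)}
#' (exclusion), where X is hypergeometric with \code{|A|} successes,
#' \code{N - |A|} failures and \code{|B|} draws. The universe must be
#' given explicitly; there is no silent default.
#'
#' @param setA,setB \code{\link{gene_set}}s (or character vectors),
#'   both subsets of \code{universe}.
#' @param universe character vector of all genes considered.
#' @return List of class \code{"overlap_result"}: \code{N}, \code{nA},
#'   \code{nB}, \code{k}, \code{expected}, \code{fold},
#'   \code{p_enrich}, \code{p_deplete}.
#' @examples
#' hypergeom_overlap(letters[1:5], letters[1:5], letters[1:10])$p_enrich
#' # 1/choose(10, 5)
#' @export
hypergeom_overlap <- function(setA, setB, universe) {
  a <- if (inherits(setA, "gene_set")) setA$members else unique(setA)
  b <- if (inherits(setB, "gene_set")) setB$members else unique(setB)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (length(setdiff(a, universe)) || length(setdiff(b, universe)))
    stop("sets must be subsets of the universe")
  N <- length(universe)
  nA <- length(a)
  nB <- length(b)
  k <- length(intersect(a, b))
  expected <- nA * nB / N
  structure(list(
    N = N, nA = nA, nB = nB, k = k,
    expected = expected,
    fold = if (expected > 0) k / expected else NA_real_,
    p_enrich = stats::phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE),
    p_deplete = stats::phyper(k, nA, N - nA, nB, lower.tail = TRUE)),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> N=%d |A|=%d |B|=%d k=%d (expected %.2f, fold %.2f)\n",
    x$N, x$nA, x$nB, x$k, x$expected, x$fold))
  cat(sprintf("  p_enrich = %.4g, p_deplete = %.4g\n",
              x$p_enrich, x$p_deplete))
  invisible(x)
}

#' Venn region counts for 2 or 3 gene sets
#'
#' @param sets named list of 2 or 3 \code{\link{gene_set}}s or character
#'   vectors.
#' @param universe character vector; members outside it raise an error.
#' @return data.frame with one row per non-empty region combination
#'   (\code{2^n - 1} rows): logical membership columns and \code{count};
#'   attribute \code{"outside"} counts universe genes in no set.
#' @export
venn_counts <- function(sets, universe) {
  mem <- lapply(sets, function(s)
    if (inherits(s, "gene_set")) s$members else unique(s))
  n <- length(mem)
  if (!n %in% c(2L, 3L)) stop("venn_counts supports 2 or 3 sets")
  if (is.null(names(mem)) || any(names(mem) == ""))
    names(mem) <- paste0("set", seq_len(n))
  bad <- setdiff(unlist(mem), universe)
  if (length(bad))
    stop(length(bad), " gene(s) outside the universe")
  flags <- vapply(mem, function(m) universe %in% m,
                  logical(length(universe)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1, , drop = FALSE]
  names(combos) <- names(mem)
  combos$count <- apply(combos, 1L, function(cmb)
    sum(apply(flags, 1L, function(f) all(f == as.logical(cmb)))))
  rownames(combos) <- NULL
  attr(combos, "outside") <- sum(rowSums(flags) == 0)
  combos
}

#' Per-term annotation enrichment with Holm step-down adjustment
#'
#' One hypergeometric over-representation test per annotation term,
#' followed by Holm-Bonferroni adjustment across terms.
#'
#' @param target a \code{\link{gene_set}} (or character vector).
#' @param annotation data.frame with columns \code{gene_id} and
#'   \code{term}.
#' @param universe character vector of all genes considered.
#' @return data.frame with one row per term: \code{term},
#'   \code{n_term}, \code{k}, \code{fold}, \code{p}, \code{p_holm},
#'   ordered by raw p.
#' @export
annotation_enrichment <- function(target, annotation, universe) {
  annotation <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  terms <- split(annotation$gene_id, annotation$term)
  rows <- lapply(names(terms), function(tm) {
    res <- hypergeom_overlap(unique(terms[[tm]]), target, universe)
    data.frame(term = tm, n_term = res$nA, k = res$k, fold = res$fold,
               p = res$p_enrich, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out[order(out$p, out$term), , drop = FALSE]
}
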
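#' Expression table constructor
#'
#' Per-gene synthesis rate (SR, arbitrary units/time) and mRNA abundance
#' (RA, arbitrary units) for one condition, the inputs of steady-state
#' half-life estimation.
#'
#' @param gene_id character vector.
#' @param SR non-negative synthesis rates.
#' @param RA non-negative mRNA abundances.
#' @param condition condition label.
#' @return data.frame of class \code{"expression_table"}.
#' @export
expression_table <- function(gene_id, SR, RA, condition = "WT") {
  stopifnot(all(SR >= 0, na.rm = TRUE), all(RA >= 0, na.rm = TRUE))
  out <- data.frame(gene_id = as.character(gene_id), SR = SR, RA = RA,
                    condition = condition, stringsAsFactors = FALSE)
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Steady-state mRNA half-life
#'
#' Under steady state the abundance of an mRNA is the product of its
#' synthesis rate and its half-life (in arbitrary units), so
#' \code{HL = RA / SR}. Genes with \code{SR = 0} are flagged undefined
#' rather than raising an error.
#'
#' @param expr an \code{\link{expression_table}}.
#' @return data.frame with \code{gene_id}, \code{HL} (NA where
#'   undefined) and logical \code{undefined}.
#' @export
half_life_steady_state <- function(expr) {
  undef <- !(expr$SR > 0)
  data.frame(gene_id = expr$gene_id,
             HL = ifelse(undef, NA_real_, expr$RA / expr$SR),
             undefined = undef, stringsAsFactors = FALSE)
}

#' Per-gene ratio of a quantity between two conditions
#'
#' Computes elementwise \code{B/A} (or its log2) for SR, RA or HL over
#' the shared gene universe; used for degron time-course deltas and
#' mutant/WT dependence ratios.
#'
#' @param tableA,tableB \code{\link{expression_table}}s (for
#'   \code{quantity = "HL"}, the half-life is computed from each table
#'   first).
#' @param quantity \code{"SR"}, \code{"RA"} or \code{"HL"}.
#' @param log2 return log2 ratios.
#' @return data.frame with \code{gene_id} and \code{ratio}.
#' @export
condition_ratio <- function(tableA, tableB, quantity = c("SR", "RA", "HL"),
                            log2 = FALSE) {
  quantity <- match.arg(quantity)
  shared <- intersect(tableA$gene_id, tableB$gene_id)
  get_q <- function(tab) {
    v <- if (quantity == "HL") {
      hl <- half_life_steady_state(tab)
      stats::setNames(hl$HL, hl$gene_id)
    } else stats::setNames(tab[[quantity]], tab$gene_id)
    v[shared]
  }
  a <- get_q(tableA)
  b <- get_q(tableB)
  r <- ifelse(a > 0, b / a, NA_real_)
  if (log2) r <- base::log2(r)
  data.frame(gene_id = shared, ratio = as.numeric(r),
             stringsAsFactors = FALSE)
}

#' Normalize a decay time course to a reference transcript
#'
#' Each raw level is divided by the reference (e.g. a Pol III transcript
#' unaffected by the Pol II transcription arrest), then scaled so the
#' pre-arrest time point (t = 0) is 100 percent.
#'
#' @param timepoints minutes post transcription arrest (must include 0).
#' @param raw raw band/probe intensities.
#' @param reference reference transcript intensities (> 0 at all times).
#' @param gene_id optional label.
#' @return data.frame of class \code{"decay_course"} with
#'   \code{time}, \code{raw}, \code{reference},
#'   \code{normalized_percent}; \code{normalized_percent[time == 0]} is
#'   exactly 100.
#' @export
normalize_decay_course <- function(timepoints, raw, reference,
                                   gene_id = NA_character_) {
  stopifnot(length(raw) == length(timepoints),
            length(reference) == length(timepoints))
  if (!any(timepoints == 0)) stop("time course must include t = 0")
  if (any(reference <= 0)) stop("reference must be positive at all times")
  rel <- raw / reference
  r0 <- rel[which(timepoints == 0)[1]]
  if (r0 <= 0) stop("raw level at t = 0 must be positive")
  out <- data.frame(gene_id = gene_id, time = timepoints, raw = raw,
                    reference = reference,
                    normalized_percent = 100 * rel / r0,
                    stringsAsFactors = FALSE)
  class(out) <- c("decay_course", "data.frame")
  out
}

#' Half-life from a normalized decay course
#'
#' Fits ln(normalized percent) against time by least squares and converts
#' the slope to a half-life, \code{HL = ln(2) / |slope|}. Chosen over a
#' nonlinear exponential fit for robustness on 3-5 point courses.
#' Non-decaying courses (slope >= 0) are flagged; zero or negative
#' levels are excluded from the fit with a warning.
#'
#' @param course a \code{\link{normalize_decay_course}} result.
#' @param min_points minimum usable time points.
#' @return List with \code{half_life} (minutes; NA if no decay),
#'   \code{slope}, \code{r_squared}, \code{n_points} and \code{no_decay}
#'   flag.
#' @export
fit_decay_halflife <- function(course, min_points = 3L) {
  ok <- course$normalized_percent > 0
  if (any(!ok))
    warning(sum(!ok), " non-positive point(s) excluded from decay fit")
  t <- course$time[ok]
  y <- log(course$normalized_percent[ok])
  if (length(t) < min_points)
    stop("fewer than ", min_points, " usable time points")
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2])
  # slopes at numerical zero (flat courses) count as "no decay"
  no_decay <- slope >= -1e-12
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(half_life = if (no_decay) NA_real_ else log(2) / abs(slope),
       slope = slope,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       n_points = length(t),
       no_decay = no_decay)
}
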
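#' Simulate a compact genome with non-overlapping transcription units
#'
#' Lays out \code{n_genes} transcription units across \code{n_chroms}
#' chromosomes on alternating random strands, separated by at least
#' \code{gap_min} bp (plus a random jitter) so that flanking windows of
#' neighbouring genes never overlap, and samples a random genome sequence
#' at the requested GC content. Deterministic under a fixed seed.
#'
#' @param n_genes number of genes.
#' @param length_range integer c(min, max) transcript length (>= 300 bp).
#' @param n_chroms number of chromosomes.
#' @param gc genome GC fraction.
#' @param gap_min minimum intergenic gap (bp).
#' @param gap_jitter maximum extra random gap (bp).
#' @param margin empty sequence at each chromosome end (bp).
#' @param sequence sample a genome sequence (set \code{FALSE} when only
#'   coordinates and tracks are needed; \code{genome} is then NULL).
#' @param seed RNG seed.
#' @return List with \code{annotation} (a \code{gene_annotation}),
#'   \code{genome} (\code{DNAStringSet}), \code{chrom_sizes} and a
#'   \code{truth} data.frame skeleton holding the latent per-gene
#'   quantities the pipeline estimates.
#' @export
simulate_genome <- function(n_genes = 600L, length_range = c(600L, 2500L),
                            n_chroms = 2L, gc = 0.40, gap_min = 400L,
                            gap_jitter = 200L, margin = 600L,
                            sequence = TRUE, seed = 1L) {
  stopifnot(length_range[1] >= 300L, n_genes >= 1L, n_chroms >= 1L)
  local_seed(seed, {
    lens <- length_range[1] - 1L +
      sample.int(length_range[2] - length_range[1] + 1L, n_genes,
                 replace = TRUE)
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    per_chrom <- sort(rep(seq_len(n_chroms), length.out = n_genes))
    chrom_names <- paste0("chr", as.character(utils::as.roman(
      seq_len(n_chroms))))
    chrom <- character(n_genes)
    start0 <- integer(n_genes)
    sizes <- stats::setNames(integer(n_chroms), chrom_names)
    for (ci in seq_len(n_chroms)) {
      pos <- margin
      for (g in which(per_chrom == ci)) {
        chrom[g] <- chrom_names[ci]
        start0[g] <- pos
        pos <- pos + lens[g] + gap_min + sample.int(gap_jitter + 1L, 1L) - 1L
      }
      sizes[ci] <- pos + margin
    }
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    ann <- gene_annotation(
      gene_id = gene_id, chrom = chrom, strand = strands,
      tss = ifelse(strands == "+", start0, start0 + lens),
      pa = ifelse(strands == "+", start0 + lens, start0))
    genome <- NULL
    if (sequence) {
      bases <- c("A", "T", "G", "C")
      probs <- c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)
      genome <- Biostrings::DNAStringSet(vapply(sizes, function(n)
        paste(sample(bases, n, replace = TRUE, prob = probs),
              collapse = ""), ""))
      names(genome) <- chrom_names
    }
    truth <- data.frame(
      gene_id = gene_id, length = lens,
      is_crac_positive = FALSE, peak_offset = NA_real_,
      has_motif = FALSE, motif_distance = NA_real_,
      SR_true = NA_real_, HL_true = NA_real_,
      b_wt = NA_real_, b_mut = NA_real_,
      stringsAsFactors = FALSE)
    list(annotation = ann, genome = genome, chrom_sizes = sizes,
         truth = truth)
  })
}

#' Plant a CRAC binding track with pA-proximal peaks
#'
#' A randomly chosen fraction of genes is made CRAC-positive: each gets a
#' Gaussian-shaped pile of reads centred \code{peak_offset} bp upstream of
#' its pA (the offset itself drawn per gene), on top of a uniform Poisson
#' background that covers every transcript. CRAC-negative genes get
#' background only. Reads land on the transcript's strand; genes whose
#' sampled peak offset does not fit inside the transcript are resampled.
#'
#' @param ann a \code{gene_annotation}.
#' @param truth truth table from \code{\link{simulate_genome}}.
#' @param chrom_sizes named chromosome lengths.
#' @param crac_fraction fraction of genes made CRAC-positive.
#' @param peak_offset_mean,peak_offset_sd per-gene peak centre offset
#'   distribution (bp upstream of pA).
#' @param peak_sd within-gene spread of the read pile (bp).
#' @param reads_per_gene expected peak reads per CRAC+ gene (Poisson).
#' @param noise background rate in reads per transcribed base.
#' @param seed RNG seed.
#' @return List with \code{track} (a \code{signal_track} of read counts)
#'   and the updated \code{truth} (\code{is_crac_positive},
#'   \code{peak_offset}).
#' @export
plant_crac_track <- function(ann, truth, chrom_sizes,
                             crac_fraction = 262 / 600,
                             peak_offset_mean = 150, peak_offset_sd = 20,
                             peak_sd = 30, reads_per_gene = 50,
                             noise = 0.0015, seed = 1L) {
  stopifnot(crac_fraction >= 0, crac_fraction < 1)
  local_seed(seed, {
    n <- nrow(ann)
    lens <- transcript_length(ann)
    n_pos <- round(crac_fraction * n)
    crac <- rep(FALSE, n)
    if (n_pos > 0) crac[sample.int(n, n_pos)] <- TRUE
    track <- signal_track(chrom_sizes)
    truth$is_crac_positive <- crac
    for (i in seq_len(n)) {
      L <- lens[i]
      pos0 <- integer(0)
      if (crac[i]) {
        off <- round(stats::rnorm(1, peak_offset_mean, peak_offset_sd))
        tries <- 0L
        while ((off >= L || off < 10) && tries < 100L) {
          off <- round(stats::rnorm(1, peak_offset_mean, peak_offset_sd))
          tries <- tries + 1L
        }
        if (off >= L || off < 10) off <- max(10, min(L - 1, off))
        truth$peak_offset[i] <- off
        n_reads <- stats::rpois(1, reads_per_gene)
        if (n_reads > 0) {
          p <- round(stats::rnorm(n_reads, L - off, peak_sd))
          pos0 <- pmin(pmax(p, 0L), L - 1L)
        }
      }
      n_bg <- stats::rpois(1, noise * L)
      if (n_bg > 0)
        pos0 <- c(pos0, sample.int(L, n_bg, replace = TRUE) - 1L)
      if (length(pos0)) {
        g <- if (ann$strand[i] == "+") ann$tss[i] + pos0
             else ann$tss[i] - 1L - pos0
        track <- track_add_counts(track, ann$chrom[i], ann$strand[i], g)
      }
    }
    list(track = track, truth = truth)
  })
}

#' Plant (GCT)n motifs upstream of pA sites
#'
#' Writes a contiguous \code{(unit)^repeats} motif into the sense strand
#' of a configurable subset of CRAC-positive genes, centred at a sampled
#' distance upstream of the pA. With \code{purge = TRUE}, chance runs of
#' two or more units inside every gene's scanned window are first broken
#' (the middle base of every second unit is rewritten), so scanner hits
#' in the window reflect planted motifs only.
#'
#' @param genome \code{DNAStringSet} from \code{\link{simulate_genome}}.
#' @param ann a \code{gene_annotation}.
#' @param truth truth table (needs \code{is_crac_positive}).
#' @param motif_fraction fraction of CRAC+ genes receiving a motif.
#' @param repeats number of contiguous units planted.
#' @param offset_mean,offset_sd distance (bp, pA to motif centre)
#'   distribution.
#' @param unit repeat unit.
#' @param purge break chance runs in the scan window first.
#' @param purge_window window (bp upstream of pA) cleaned and implicitly
#'   scanned.
#' @param seed RNG seed.
#' @return List with the edited \code{genome} and updated \code{truth}
#'   (\code{has_motif}, \code{motif_distance} = realized centre
#'   distance).
#' @export
plant_motifs <- function(genome, ann, truth, motif_fraction = 0.65,
                         repeats = 2L, offset_mean = 150, offset_sd = 25,
                         unit = "GCT", purge = TRUE, purge_window = 250L,
                         seed = 1L) {
  stopifnot(repeats >= 2L)
  u <- nchar(unit)
  m <- u * repeats
  lens <- transcript_length(ann)
  local_seed(seed, {
    if (purge) {
      for (i in seq_len(nrow(ann))) {
        L <- lens[i]
        from0 <- max(0L, L - purge_window)
        s <- sense_subseq(genome[[ann$chrom[i]]], ann$strand[i],
                          ann$tss[i], from0, L)
        h <- scan_gct_repeats(s, unit = unit, min_repeats = 2L)
        if (!nrow(h)) next
        for (r in seq_len(nrow(h))) {
          # middle base of every 2nd unit -> A: no two intact units remain
          units <- seq.int(2L, h$repeats[r], by = 2L)
          for (uu in units) {
            t0 <- from0 + (h$start[r] - 1L) + (uu - 1L) * u + (u %/% 2L)
            genome[[ann$chrom[i]]] <- sense_replace(
              genome[[ann$chrom[i]]], ann$strand[i], ann$tss[i], t0, "A")
          }
        }
      }
    }
    crac_idx <- which(truth$is_crac_positive)
    n_mot <- round(motif_fraction * length(crac_idx))
    targets <- if (n_mot > 0) sample(crac_idx, n_mot) else integer(0)
    for (i in targets) {
      L <- lens[i]
      d <- round(stats::rnorm(1, offset_mean, offset_sd))
      tries <- 0L
      while ((L - d - m / 2 < 0 || d - m / 2 < 5) && tries < 100L) {
        d <- round(stats::rnorm(1, offset_mean, offset_sd))
        tries <- tries + 1L
      }
      d <- max(m / 2 + 5, min(L - m / 2, d))
      start0 <- as.integer(round(L - d - m / 2))
      motif <- strrep(unit, repeats)
      genome[[ann$chrom[i]]] <- sense_replace(
        genome[[ann$chrom[i]]], ann$strand[i], ann$tss[i], start0, motif)
      # break chance flanking units so the planted run has exactly
      # `repeats` copies and its centre is where the truth table says
      for (fl in c(start0 - u, start0 + m)) {
        if (fl < 0 || fl + u > L) next
        s <- sense_subseq(genome[[ann$chrom[i]]], ann$strand[i],
                          ann$tss[i], fl, fl + u)
        if (s == unit)
          genome[[ann$chrom[i]]] <- sense_replace(
            genome[[ann$chrom[i]]], ann$strand[i], ann$tss[i],
            fl + (u %/% 2L), "A")
      }
      truth$has_motif[i] <- TRUE
      truth$motif_distance[i] <- L - start0 - m / 2
    }
    list(genome = genome, truth = truth)
  })
}

#' Generate steady-state expression tables with planted kinetics
#'
#' Draws per-gene synthesis rates and half-lives, then builds
#' wild-type-like and mutant-like expression tables in which the measured
#' abundance is \code{RA = SR x HL} times multiplicative lognormal noise
#' with unit mean. In the mutant condition, the half-life of
#' truth-CRAC-positive genes is multiplied by
#' \code{mutant_hl_multiplier} (scalar, or a per-gene vector for coupled
#' designs), emulating destabilization of bound transcripts when the
#' factor is absent.
#'
#' @param truth truth table (needs \code{is_crac_positive}).
#' @param sr_range,hl_range uniform ranges for the latent SR and HL.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   on each measured quantity.
#' @param mutant_hl_multiplier scalar applied to CRAC+ genes, or numeric
#'   vector over all genes.
#' @param seed RNG seed.
#' @return List with \code{tables} (named list of
#'   \code{\link{expression_table}}s, \code{WT} and \code{mutant}) and
#'   the updated \code{truth} (\code{SR_true}, \code{HL_true},
#'   \code{hl_multiplier}).
#' @export
generate_expression <- function(truth, sr_range = c(1, 20),
                                hl_range = c(5, 60), noise_cv = 0,
                                mutant_hl_multiplier = 0.5, seed = 1L) {
  n <- nrow(truth)
  local_seed(seed, {
    if (all(is.na(truth$SR_true)))
      truth$SR_true <- stats::runif(n, sr_range[1], sr_range[2])
    if (all(is.na(truth$HL_true)))
      truth$HL_true <- stats::runif(n, hl_range[1], hl_range[2])
    mult <- if (length(mutant_hl_multiplier) == 1L)
      ifelse(truth$is_crac_positive, mutant_hl_multiplier, 1)
    else {
      stopifnot(length(mutant_hl_multiplier) == n)
      mutant_hl_multiplier
    }
    truth$hl_multiplier <- mult
    lnoise <- function() {
      if (noise_cv <= 0) return(rep(1, n))
      sdl <- sqrt(log(1 + noise_cv^2))
      stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)   # unit mean
    }
    tabs <- list(
      WT = expression_table(truth$gene_id,
                            SR = truth$SR_true * lnoise(),
                            RA = truth$SR_true * truth$HL_true * lnoise(),
                            condition = "WT"),
      mutant = expression_table(truth$gene_id,
                                SR = truth$SR_true * lnoise(),
                                RA = truth$SR_true * truth$HL_true * mult *
                                  lnoise(),
                                condition = "mutant"))
    list(tables = tabs, truth = truth)
  })
}

#' Generate paired Pol II ChIP and run-on tracks
#'
#' Each gene carries a constant Pol II load along its transcript; the
#' ChIP track reports the full load (total Pol II, backtracked included)
#' while the run-on track reports \code{load x (1 - b)}, the actively
#' elongating fraction, where \code{b} is the latent per-gene backtracked
#' fraction. In the mutant-like condition \code{b} of truth-CRAC-positive
#' genes is multiplied by \code{mutant_b_multiplier} (backtracking is
#' factor-dependent there). Tracks are unstranded (stored on both
#' strands); optional per-gene lognormal noise multiplies each signal.
#'
#' @param ann a \code{gene_annotation}.
#' @param truth truth table (needs \code{is_crac_positive}).
#' @param chrom_sizes named chromosome lengths.
#' @param load_range uniform range of the per-gene Pol II load.
#' @param b_range uniform range of the backtracked fraction in [0, 1).
#' @param mutant_b_multiplier scalar multiplying b of CRAC+ genes in the
#'   mutant condition.
#' @param noise_cv per-gene multiplicative noise CV on each signal.
#' @param seed RNG seed.
#' @return List with \code{conditions} (list \code{WT}/\code{mutant},
#'   each with \code{chip} and \code{gro} \code{signal_track}s) and the
#'   updated \code{truth} (\code{polII_load}, \code{b_wt},
#'   \code{b_mut}).
#' @export
generate_chip_gro <- function(ann, truth, chrom_sizes,
                              load_range = c(2, 50), b_range = c(0.1, 0.7),
                              mutant_b_multiplier = 0.5, noise_cv = 0,
                              seed = 1L) {
  n <- nrow(ann)
  lens <- transcript_length(ann)
  local_seed(seed, {
    load <- stats::runif(n, load_range[1], load_range[2])
    b_wt <- stats::runif(n, b_range[1], b_range[2])
    b_mut <- ifelse(truth$is_crac_positive, b_wt * mutant_b_multiplier, b_wt)
    truth$polII_load <- load
    truth$b_wt <- b_wt
    truth$b_mut <- b_mut
    lf <- function() {
      if (noise_cv <= 0) return(rep(1, n))
      sdl <- sqrt(log(1 + noise_cv^2))
      stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
    }
    make <- function(b) {
      chip <- signal_track(chrom_sizes)
      gro <- signal_track(chrom_sizes)
      fc <- lf()
      fg <- lf()
      for (i in seq_len(n)) {
        lo <- min(ann$tss[i], ann$pa[i])
        chip <- track_add(chip, ann$chrom[i], "both", lo,
                          rep(load[i] * fc[i], lens[i]))
        gro <- track_add(gro, ann$chrom[i], "both", lo,
                         rep(load[i] * (1 - b[i]) * fg[i], lens[i]))
      }
      list(chip = chip, gro = gro)
    }
    list(conditions = list(WT = make(b_wt), mutant = make(b_mut)),
         truth = truth)
  })
}

#' Generate paired Rpb4- and Rpb3-ChIP tracks with a stoichiometry decline
#'
#' Rpb3 signal is flat along each gene (every Pol II carries Rpb3); the
#' Rpb4 signal declines linearly with distance from the TSS,
#' \code{rpb4 = rpb3 x max(floor_ratio, 1 - slope x d)}, emulating
#' progressive Rpb4 dissociation or configuration change during
#' elongation. Upstream of the TSS the ratio is 1; past the pA it stays
#' at its end value. Signal extends \code{flank} bp beyond both gene
#' ends so profiles anchored just outside the gene are defined.
#'
#' @param ann a \code{gene_annotation}.
#' @param truth truth table (needs \code{is_crac_positive}).
#' @param chrom_sizes named chromosome lengths.
#' @param slope_by_condition named list of length-2 vectors
#'   \code{c(crac, rest)}: ratio decline per kb for CRAC+ and other
#'   genes, per condition.
#' @param end_ratio if non-NULL, overrides the slopes so every gene's
#'   ratio declines linearly to exactly this value at its pA
#'   (slope = (1 - end_ratio)/length); used for closed-form checks.
#' @param floor_ratio lower bound of the ratio.
#' @param load_range uniform range of per-gene Rpb3 level.
#' @param noise_cv per-gene multiplicative noise CV.
#' @param flank bp of signal beyond each gene end.
#' @param seed RNG seed.
#' @return List with \code{conditions} (per condition: \code{rpb4},
#'   \code{rpb3} \code{signal_track}s) and updated \code{truth}
#'   (\code{rpb4_slope_<condition>} in per-bp units).
#' @export
generate_rpb4_tracks <- function(ann, truth, chrom_sizes,
                                 slope_by_condition = list(
                                   WT = c(crac = 0.30, rest = 0.15),
                                   mutant = c(crac = 0.03, rest = 0.03)),
                                 end_ratio = NULL, floor_ratio = 0.05,
                                 load_range = c(2, 50), noise_cv = 0,
                                 flank = 150L, seed = 1L) {
  n <- nrow(ann)
  lens <- transcript_length(ann)
  local_seed(seed, {
    load <- stats::runif(n, load_range[1], load_range[2])
    conds <- lapply(names(slope_by_condition), function(cn) {
      sl <- slope_by_condition[[cn]]
      slope_bp <- if (!is.null(end_ratio)) (1 - end_ratio) / lens
      else ifelse(truth$is_crac_positive, sl[["crac"]],
                  sl[["rest"]]) / 1000
      truth[[paste0("rpb4_slope_", cn)]] <<- slope_bp
      rpb4 <- signal_track(chrom_sizes)
      rpb3 <- signal_track(chrom_sizes)
      f4 <- if (noise_cv > 0) {
        sdl <- sqrt(log(1 + noise_cv^2))
        stats::rlnorm(n, -sdl^2 / 2, sdl)
      } else rep(1, n)
      for (i in seq_len(n)) {
        L <- lens[i]
        d <- seq.int(-flank, L + flank - 1L)
        ratio <- ifelse(d < 0, 1,
                        pmax(floor_ratio, 1 - slope_bp[i] * pmin(d, L)))
        vals3 <- rep(load[i], length(d))
        vals4 <- vals3 * ratio * f4[i]
        start0 <- if (ann$strand[i] == "+") ann$tss[i] - flank
                  else ann$pa[i] - flank
        if (ann$strand[i] == "-") {
          vals3 <- rev(vals3)
          vals4 <- rev(vals4)
        }
        size <- chrom_sizes[[ann$chrom[i]]]
        keep <- seq_along(vals3) + start0 >= 1L &
          seq_along(vals3) + start0 <= size
        rpb3 <- track_add(rpb3, ann$chrom[i], "both",
                          start0 + which(keep)[1] - 1L, vals3[keep])
        rpb4 <- track_add(rpb4, ann$chrom[i], "both",
                          start0 + which(keep)[1] - 1L, vals4[keep])
      }
      list(rpb4 = rpb4, rpb3 = rpb3)
    })
    names(conds) <- names(slope_by_condition)
    list(conditions = conds, truth = truth)
  })
}

#' One-call coupled simulation of the whole study design
#'
#' Convenience wrapper chaining every generator with sub-seeds derived
#' from one master seed: genome and annotation, CRAC track with planted
#' pA-proximal peaks, (GCT)n motifs in a subset of CRAC+ genes,
#' steady-state expression for wild-type-like and mutant-like conditions,
#' paired ChIP/run-on tracks, and Rpb4/Rpb3 tracks. The mutant half-life
#' multiplier of CRAC+ genes is coupled to the backtracking change,
#' \code{(1 - b_wt) / (1 - b_mut)}, so the factor-dependence of the
#' backtracking index and of the half-life are correlated in CRAC+ genes
#' only.
#'
#' @param seed master seed.
#' @param n_genes,crac_fraction,noise_cv study scale and noise level.
#' @param reads_per_gene expected CRAC peak reads per positive gene.
#' @param ... passed to \code{\link{simulate_genome}}.
#' @return List with all generator outputs: \code{annotation},
#'   \code{genome}, \code{chrom_sizes}, \code{truth},
#'   \code{crac_track}, \code{expression}, \code{chip_gro},
#'   \code{rpb4}.
#' @export
simulate_imprinting_study <- function(seed = 1L, n_genes = 600L,
                                      crac_fraction = 262 / 600,
                                      noise_cv = 0.1,
                                      reads_per_gene = 50, ...) {
  seeds <- local_seed(seed, sample.int(1e8, 6L))
  g <- simulate_genome(n_genes = n_genes, seed = seeds[1], ...)
  cr <- plant_crac_track(g$annotation, g$truth, g$chrom_sizes,
                         crac_fraction = crac_fraction,
                         reads_per_gene = reads_per_gene, seed = seeds[2])
  mo <- plant_motifs(g$genome, g$annotation, cr$truth, seed = seeds[3])
  cg <- generate_chip_gro(g$annotation, mo$truth, g$chrom_sizes,
                          noise_cv = noise_cv, seed = seeds[4])
  coupled_mult <- ifelse(cg$truth$is_crac_positive,
                         (1 - cg$truth$b_wt) / (1 - cg$truth$b_mut), 1)
  ex <- generate_expression(cg$truth, noise_cv = noise_cv,
                            mutant_hl_multiplier = coupled_mult,
                            seed = seeds[5])
  rp <- generate_rpb4_tracks(g$annotation, ex$truth, g$chrom_sizes,
                             noise_cv = noise_cv, seed = seeds[6])
  list(annotation = g$annotation, genome = mo$genome,
       chrom_sizes = g$chrom_sizes, truth = rp$truth,
       crac_track = cr$track, expression = ex$tables,
       chip_gro = cg$conditions, rpb4 = rp$conditions)
}
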
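# Run code with a local RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package routes through this, so a
# fixed seed gives byte-identical results without clobbering the session.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Sense-strand sequence of a transcript-coordinate interval [from0, to0)
# (0-based, transcript sense) as a character string.
sense_subseq <- function(chrom_seq, strand, tss, from0, to0) {
  if (strand == "+") {
    as.character(Biostrings::subseq(chrom_seq, tss + from0 + 1L, tss + to0))
  } else {
    g <- Biostrings::subseq(chrom_seq, tss - to0 + 1L, tss - from0)
    as.character(Biostrings::reverseComplement(g))
  }
}

# Replace the sense-strand sequence at transcript coords [start0,
# start0 + nchar(seq)) of a gene inside a chromosome DNAString; returns
# the modified DNAString.
sense_replace <- function(chrom_seq, strand, tss, start0, seq) {
  n <- nchar(seq)
  if (strand == "+") {
    Biostrings::subseq(chrom_seq, tss + start0 + 1L, tss + start0 + n) <-
      Biostrings::DNAString(seq)
  } else {
    rc <- Biostrings::reverseComplement(Biostrings::DNAString(seq))
    Biostrings::subseq(chrom_seq, tss - start0 - n + 1L, tss - start0) <- rc
  }
  chrom_seq
}
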
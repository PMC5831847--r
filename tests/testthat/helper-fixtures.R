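# Fixtures are built in code: small alignment tables, SAM files and PFMs.

# One mapped alignment record row.
aln_row <- function(qname, rname, start, end, strand = "+", mapq = 60L,
                    tlen = end - start, mrname = rname, mstart = start,
                    proper = TRUE, paired = TRUE, dup = FALSE,
                    flag = NULL) {
  if (is.null(flag)) {
    flag <- 0L
    if (paired) flag <- flag + 1L
    if (proper) flag <- flag + 2L
    if (strand == "-") flag <- flag + 16L
    if (dup) flag <- flag + 1024L
  }
  data.frame(qname = qname, rname = rname, start = as.integer(start),
             end = as.integer(end), strand = strand, mapq = as.integer(mapq),
             flag = as.integer(flag),
             cigar = paste0(end - start, "M"), tlen = as.integer(tlen),
             mrname = mrname, mstart = as.integer(mstart),
             is_paired = paired, is_proper_pair = proper,
             is_duplicate = dup, is_secondary = FALSE,
             is_supplementary = FALSE, is_unmapped = FALSE,
             stringsAsFactors = FALSE)
}

# A full proper pair: plus mate at [start, start+rl), minus mate ending at
# start + size.
aln_pair <- function(qname, rname, start, size, rl = 50L, mapq = 60L) {
  rl <- min(rl, size)
  rbind(
    aln_row(qname, rname, start, start + rl, "+", mapq, tlen = size,
            mstart = start + size - rl, flag = 99L),
    aln_row(qname, rname, start + size - rl, start + size, "-", mapq,
            tlen = -size, mstart = start, flag = 147L))
}

as_aln <- function(df, seqlengths = c(chr1 = 100000L, chrM = 16000L)) {
  df <- df[order(df$rname, df$start, df$qname), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("atac_alignments", "data.frame")
  attr(df, "seqlengths") <- seqlengths
  df
}

as_frag <- function(rname, start, end, qname = NULL) {
  out <- data.frame(rname = rname, start = as.integer(start),
                    end = as.integer(end),
                    size = as.integer(end - start),
                    qname = if (is.null(qname))
                      paste0("f", seq_along(start)) else qname,
                    stringsAsFactors = FALSE)
  class(out) <- c("atac_fragments", "data.frame")
  out
}

toy_sam_path <- function() {
  system.file("extdata", "toy.sam", package = "atacdeck")
}

# A sharp 12-bp test motif with a unique consensus.
toy_pfm <- function(width = 12L, seed = 1L) {
  set.seed(seed)
  pfm <- matrix(0, 4, width, dimnames = list(c("A", "C", "G", "T")))
  cons <- sample(1:4, width, replace = TRUE)
  for (i in seq_len(width)) pfm[cons[i], i] <- 10
  pfm
}

pfm_consensus <- function(pfm) {
  paste(rownames(pfm)[apply(pfm, 2, which.max)], collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
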
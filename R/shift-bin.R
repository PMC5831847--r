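# Tn5 cut-site shifting and nucleosome-class fragment binning.

#' Nucleosome-class fragment size bins
#'
#' The eight size bins used to assign sequenced fragments to inferred
#' chromatin states: nucleosome-free (38-100 bp), intermediate 1 (100-180),
#' mono-nucleosome (180-247), intermediate 2 (247-315), di-nucleosome
#' (315-473), intermediate 3 (473-558), tri-nucleosome (558-615) and others
#' (615-2000). Bins are half-open `[lower, upper)`; touching boundary values
#' belong to the higher bin, and the final bin is closed at 2000, so the
#' bins partition the integer sizes 38..2000 exactly.
#'
#' @return A `data.frame` with columns `name`, `lower`, `upper`.
#' @export
fragment_bins <- function() {
  data.frame(
    name = c("nucleosome_free", "intermediate_1", "mono", "intermediate_2",
             "di", "intermediate_3", "tri", "others"),
    lower = c(38L, 100L, 180L, 247L, 315L, 473L, 558L, 615L),
    upper = c(100L, 180L, 247L, 315L, 473L, 558L, 615L, 2000L),
    stringsAsFactors = FALSE
  )
}

#' Shift alignments to Tn5 insertion sites
#'
#' Tn5 inserts its two adaptors 9 bp apart, so read 5' ends sit 4-5 bp away
#' from the insertion centre. The conventional correction offsets reads on
#' the plus strand by +4 bp and reads on the minus strand by -5 bp. Whole
#' records are translated (read length and strand unchanged); the cut site
#' is then the shifted 5' position. Unmapped records are skipped and
#' records pushed below coordinate 0 are dropped, both counted.
#'
#' @param aln An `atac_alignments` table.
#' @param plus_offset Offset added to plus-strand records (default `4`).
#' @param minus_offset Offset added to minus-strand records (default `-5`).
#' @return The shifted table; skip/drop counts in `attr(, "counters")`.
#' @export
shift_reads <- function(aln, plus_offset = 4L, minus_offset = -5L) {
  off <- ifelse(aln$strand == "+", as.integer(plus_offset),
                as.integer(minus_offset))
  off[aln$is_unmapped] <- 0L
  new_start <- aln$start + off
  drop <- new_start < 0L & !aln$is_unmapped
  out <- aln
  out$start <- new_start
  out$end <- aln$end + off
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seqlengths") <- attr(aln, "seqlengths")
  attr(out, "counters") <- c(unmapped_skipped = sum(aln$is_unmapped),
                             below_zero_dropped = sum(drop))
  out
}

#' Tn5 cut sites of (shifted) alignments
#'
#' One cut site per mapped record: the 5' position, i.e. `start` for plus
#' strand reads and `end - 1` (the rightmost aligned base, 0-based) for
#' minus strand reads. Apply [shift_reads()] first to obtain corrected
#' insertion points.
#'
#' @param aln An `atac_alignments` table.
#' @return A `data.frame` with columns `rname`, `pos`, `strand`,
#'   `source_size` (`|TLEN|` of the originating fragment).
#' @export
cut_sites <- function(aln) {
  use <- aln[!aln$is_unmapped, , drop = FALSE]
  data.frame(
    rname = use$rname,
    pos = ifelse(use$strand == "+", use$start, use$end - 1L),
    strand = use$strand,
    source_size = abs(use$tlen),
    stringsAsFactors = FALSE
  )
}

#' Assign a fragment size to its nucleosome-class bin
#'
#' @param size Integer vector of fragment sizes in bp, each within 38-2000.
#' @param bins Bin table as returned by [fragment_bins()].
#' @return Character vector of bin names.
#' @examples
#' assign_bin(c(50, 200, 400, 580))
#' @export
assign_bin <- function(size, bins = fragment_bins()) {
  if (any(size < bins$lower[1] | size > bins$upper[nrow(bins)]))
    stop("fragment size outside [", bins$lower[1], ", ",
         bins$upper[nrow(bins)], "]; filter templates first")
  idx <- findInterval(size, c(bins$lower, bins$upper[nrow(bins)]),
                      rightmost.closed = TRUE)
  bins$name[idx]
}

#' Split fragments into nucleosome-class bins
#'
#' @param frag An `atac_fragments` table, pre-filtered to sizes 38-2000 bp.
#' @param bins Bin table as returned by [fragment_bins()].
#' @return Named list of `atac_fragments`, one per bin (possibly empty),
#'   in bin order; every input fragment appears in exactly one element.
#' @export
split_by_bin <- function(frag, bins = fragment_bins()) {
  lab <- if (nrow(frag)) assign_bin(frag$size, bins) else character(0)
  out <- lapply(bins$name, function(b) {
    x <- frag[lab == b, , drop = FALSE]
    rownames(x) <- NULL
    x
  })
  names(out) <- bins$name
  out
}

#' Split a di- or tri-nucleosome fragment into sub-fragments in silico
#'
#' Fragments spanning two or three nucleosomes are cut into k contiguous
#' sub-fragments that exactly tile the parent interval, so each sub-fragment
#' approximates a single nucleosome's worth of template for TSS signal
#' plots. The first k-1 parts have length `floor(size/k)`; the last part
#' takes the remainder.
#'
#' @param frag An `atac_fragments` table (each row split independently).
#' @param k 2 (di) or 3 (tri).
#' @return An `atac_fragments` table with k rows per input row; `qname`
#'   suffixed `/1..k`.
#' @export
split_oligonucleosome_fragment <- function(frag, k) {
  k <- as.integer(k)
  if (!k %in% c(2L, 3L)) stop("k must be 2 or 3")
  if (any(frag$size < k)) stop("fragment shorter than k")
  if (!nrow(frag)) return(frag)
  part <- frag$size %/% k
  pieces <- lapply(seq_len(k), function(i) {
    s <- frag$start + (i - 1L) * part
    e <- if (i < k) frag$start + i * part else frag$end
    data.frame(rname = frag$rname, start = s, end = e, size = e - s,
               qname = paste0(frag$qname, "/", i), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$rname, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("atac_fragments", "data.frame")
  out
}

#' Nucleosome-class fragment sets for TSS signal plots
#'
#' Convenience wrapper implementing the standard preparation: fragments are
#' binned, nucleosome-free and mono-nucleosome fragments are used directly,
#' di- and tri-nucleosome fragments are split in silico into 2 and 3
#' sub-fragments, and fragments in intermediate bins or the "others" bin
#' are excluded (overridable).
#'
#' @param frag An `atac_fragments` table (sizes within 38-2000).
#' @param include_intermediate Also return the intermediate/others bins
#'   unsplit (default `FALSE`).
#' @return Named list with elements `nucleosome_free`, `mono`, `di`, `tri`
#'   (di/tri already split), plus the remaining bins when requested.
#' @export
nucleosome_classes <- function(frag, include_intermediate = FALSE) {
  by_bin <- split_by_bin(frag)
  out <- list(
    nucleosome_free = by_bin$nucleosome_free,
    mono = by_bin$mono,
    di = split_oligonucleosome_fragment(by_bin$di, 2L),
    tri = split_oligonucleosome_fragment(by_bin$tri, 3L)
  )
  if (include_intermediate)
    out <- c(out, by_bin[c("intermediate_1", "intermediate_2",
                           "intermediate_3", "others")])
  out
}
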
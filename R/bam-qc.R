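# Quality metrics and the five-criterion alignment filter.

#' Filter criteria for ATAC-seq alignments
#'
#' Bundles the thresholds of the standard five-step ATAC-seq alignment
#' filter: (1) mitochondrial reads, (2) PCR/optical duplicates, (3) low
#' mapping quality (MAPQ <= 20 removed by default), (4) discordant pairs,
#' (5) template length outside 38-2000 bp.
#'
#' @param mito_names Reference names treated as mitochondrial.
#' @param max_removed_mapq Reads with `mapq <= max_removed_mapq` are removed.
#' @param min_template,max_template Retained `|TLEN|` range, inclusive.
#' @param drop_duplicates Remove flagged duplicates.
#' @param require_proper_pair Remove records not in a proper pair.
#' @return A list of class `filter_criteria`.
#' @export
filter_criteria <- function(mito_names = c("chrM", "MT", "chrMT"),
                            max_removed_mapq = 20L,
                            min_template = 38L, max_template = 2000L,
                            drop_duplicates = TRUE,
                            require_proper_pair = TRUE) {
  stopifnot(min_template < max_template, max_removed_mapq >= 0)
  structure(list(mito_names = mito_names,
                 max_removed_mapq = as.integer(max_removed_mapq),
                 min_template = as.integer(min_template),
                 max_template = as.integer(max_template),
                 drop_duplicates = isTRUE(drop_duplicates),
                 require_proper_pair = isTRUE(require_proper_pair)),
            class = "filter_criteria")
}

# Picard-like duplicate key: reference, strand, strand-adjusted 5' position,
# |TLEN|. The 5' position is the unshifted alignment 5' end.
.dup_key <- function(aln) {
  five <- ifelse(aln$strand == "+", aln$start, aln$end - 1L)
  paste(aln$rname, aln$strand, five, abs(aln$tlen), sep = "\r")
}

#' Mark PCR/optical duplicates
#'
#' Within each group of records sharing (reference, strand, 5' position,
#' |TLEN|), one representative is left unflagged and all others receive the
#' SAM duplicate flag. The representative is the record with the highest
#' MAPQ, ties broken by the lexicographically smallest query name, so
#' marking is deterministic.
#'
#' @param aln An `atac_alignments` table (coordinate-sorted).
#' @return The table with `is_duplicate` and the 0x400 flag bit updated.
#' @export
mark_duplicates <- function(aln) {
  if (!nrow(aln)) return(aln)
  sorted <- all(vapply(split(aln$start, aln$rname),
                       function(s) !is.unsorted(s), logical(1)))
  if (!sorted) stop("input must be coordinate-sorted")
  mapped <- !aln$is_unmapped
  key <- .dup_key(aln)
  # rank within key: representative first
  ord <- order(key, -aln$mapq, aln$qname)
  first <- !duplicated(key[ord])
  dup <- logical(nrow(aln))
  dup[ord] <- !first
  dup[!mapped] <- FALSE
  aln$is_duplicate <- dup
  aln$flag <- ifelse(dup, bitwOr(aln$flag, 1024L),
                     bitwAnd(aln$flag, bitwNot(1024L)))
  aln
}

#' Duplication metrics from a position-multiplicity histogram
#'
#' Given the histogram mapping multiplicity j to the number of distinct
#' positions observed exactly j times, computes the ENCODE-style library
#' quality ratios: the non-redundant fraction NRF = distinct/total, PCR
#' bottleneck coefficient PBC1 = M1/distinct and PBC2 = M1/M2, where M1 and
#' M2 are the numbers of positions seen exactly once and exactly twice.
#' PBC2 is undefined (NA) when M2 = 0.
#'
#' @param hist Named numeric vector, names = multiplicity, values = counts.
#' @return A list with `nrf`, `pbc1`, `pbc2`.
#' @examples
#' compute_duplication_metrics(c(`1` = 6, `2` = 2))
#' @export
compute_duplication_metrics <- function(hist) {
  j <- as.integer(names(hist))
  nj <- as.numeric(hist)
  if (!length(j) || any(is.na(j)) || any(j < 1) || any(nj < 0))
    stop("histogram must map multiplicities >= 1 to non-negative counts")
  total <- sum(j * nj)
  if (total <= 0) stop("empty histogram")
  distinct <- sum(nj)
  m1 <- sum(nj[j == 1L])
  m2 <- sum(nj[j == 2L])
  list(nrf = distinct / total,
       pbc1 = m1 / distinct,
       pbc2 = if (m2 > 0) m1 / m2 else NA_real_)
}

#' Single-pass quality metrics for an alignment table
#'
#' Reports mapping, mitochondrial and duplication statistics. The
#' mitochondrial fraction is computed over mapped primary reads; duplicate
#' metrics (duplicate rate, NRF, PBC1, PBC2) are computed on non-mitochondrial
#' mapped primary reads, using the duplicate key of [mark_duplicates()] to
#' build the position-multiplicity histogram.
#'
#' @param aln An `atac_alignments` table.
#' @param criteria A [filter_criteria()] object (supplies `mito_names`).
#' @return A list of class `qc_metrics`.
#' @export
compute_qc_metrics <- function(aln, criteria = filter_criteria()) {
  mapped <- aln[!aln$is_unmapped, , drop = FALSE]
  is_mito <- mapped$rname %in% criteria$mito_names
  nuc <- mapped[!is_mito, , drop = FALSE]
  key <- .dup_key(nuc)
  mult <- table(table(key))
  dupm <- if (nrow(nuc)) compute_duplication_metrics(mult) else
    list(nrf = NA_real_, pbc1 = NA_real_, pbc2 = NA_real_)
  structure(list(
    total_reads = nrow(aln),
    mapped_reads = nrow(mapped),
    mito_reads = sum(is_mito),
    mito_fraction = if (nrow(mapped)) sum(is_mito) / nrow(mapped) else NA_real_,
    duplicate_reads = sum(nuc$is_duplicate),
    duplicate_rate = if (nrow(nuc)) sum(nuc$is_duplicate) / nrow(nuc) else NA_real_,
    distinct_positions = length(unique(key)),
    nrf = dupm$nrf, pbc1 = dupm$pbc1, pbc2 = dupm$pbc2,
    proper_pair_rate = if (nrow(mapped)) mean(mapped$is_proper_pair) else NA_real_,
    mapq_histogram = table(mapped$mapq)
  ), class = "qc_metrics")
}

#' @export
print.qc_metrics <- function(x, ...) {
  cat("ATAC-seq alignment QC\n")
  cat(sprintf("  total reads        %d\n", x$total_reads))
  cat(sprintf("  mapped reads       %d\n", x$mapped_reads))
  cat(sprintf("  mitochondrial      %d (%.1f%%)\n", x$mito_reads,
              100 * x$mito_fraction))
  cat(sprintf("  duplicates         %d (%.1f%%)\n", x$duplicate_reads,
              100 * x$duplicate_rate))
  cat(sprintf("  NRF %.3f  PBC1 %.3f  PBC2 %s\n", x$nrf, x$pbc1,
              ifelse(is.na(x$pbc2), "inf", sprintf("%.3f", x$pbc2))))
  invisible(x)
}

#' Filter alignments by the five standard criteria
#'
#' Removes, in order: (1) mitochondrial reads, (2) duplicates, (3) reads with
#' MAPQ at or below the threshold, (4) discordant (non-proper-pair) records,
#' (5) pairs whose template length falls outside the retained range.
#' Each removed read is counted under the first criterion it matches, so the
#' per-criterion report is deterministic and sums, with survivors, to the
#' input count.
#'
#' @param aln An `atac_alignments` table, duplicates already marked (or
#'   `drop_duplicates = FALSE` in the criteria).
#' @param criteria A [filter_criteria()] object.
#' @return The surviving `atac_alignments`; removal counts per criterion are
#'   attached as `attr(, "filter_report")` (named integer vector).
#' @export
filter_alignments <- function(aln, criteria = filter_criteria()) {
  r1 <- aln$rname %in% criteria$mito_names
  r2 <- if (criteria$drop_duplicates) aln$is_duplicate else FALSE
  r3 <- aln$mapq <= criteria$max_removed_mapq
  r4 <- if (criteria$require_proper_pair) !aln$is_proper_pair else FALSE
  atl <- abs(aln$tlen)
  r5 <- is.na(atl) | atl < criteria$min_template | atl > criteria$max_template
  reason <- integer(nrow(aln))             # 0 = survivor
  for (i in 5:1) reason[list(r1, r2, r3, r4, r5)[[i]]] <- i
  report <- vapply(1:5, function(i) sum(reason == i), integer(1))
  names(report) <- c("mitochondrial", "duplicate", "low_mapq",
                     "discordant", "template_length")
  out <- aln[reason == 0L, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seqlengths") <- attr(aln, "seqlengths")
  attr(out, "filter_report") <- report
  out
}
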
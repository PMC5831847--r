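#' @importFrom stats setNames
NULL

# Columns every alignment table carries. Coordinates are 0-based, half-open;
# conversion from SAM's 1-based inclusive convention happens only here.
.aln_cols <- c("qname", "rname", "start", "end", "strand", "mapq", "flag",
               "cigar", "tlen", "mrname", "mstart",
               "is_paired", "is_proper_pair", "is_duplicate",
               "is_secondary", "is_supplementary", "is_unmapped")

.new_alignments <- function(df, seqlengths = NULL, counters = NULL) {
  stopifnot(all(.aln_cols %in% names(df)))
  df <- as.data.frame(df)[, .aln_cols]
  rownames(df) <- NULL
  class(df) <- c("atac_alignments", "data.frame")
  attr(df, "seqlengths") <- seqlengths
  attr(df, "counters") <- counters
  df
}

.flag_bit <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Read paired-end alignments from a BAM or SAM file
#'
#' Imports primary alignments into a flat table, one row per alignment line,
#' with SAM's 1-based inclusive coordinates converted to the package-internal
#' 0-based half-open convention (`start = POS - 1`; `end` is one past the last
#' aligned base). Secondary and supplementary alignments are dropped at read
#' time and counted, since all downstream quality metrics operate on primary
#' alignments only.
#'
#' @param path Path to a coordinate-sorted BAM file (indexed if `region` is
#'   used) or to a SAM text file (converted on the fly).
#' @param region Optional `GRanges` of length 1 restricting the read to
#'   overlapping alignments. Requires a BAM index.
#' @param keep_unmapped Keep unmapped records (default `FALSE`).
#' @return A `data.frame` of class `atac_alignments` with columns `qname`,
#'   `rname`, `start`, `end`, `strand`, `mapq`, `flag`, `cigar`, `tlen`,
#'   `mrname`, `mstart` and the SAM flag booleans. The reference sequence
#'   lengths from the header are attached as `attr(, "seqlengths")`, and
#'   counts of dropped secondary/supplementary records as
#'   `attr(, "counters")`.
#' @examples
#' sam <- system.file("extdata", "toy.sam", package = "atacdeck")
#' aln <- read_alignments(sam)
#' head(aln)
#' @export
read_alignments <- function(path, region = NULL, keep_unmapped = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
    path <- bam
  }
  param_which <- if (is.null(region)) IRanges::IRangesList() else region
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = if (keep_unmapped) NA else FALSE)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "mrnm", "mpos", "isize")
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(what = what, flag = flags)
  } else {
    Rsamtools::ScanBamParam(what = what, flag = flags, which = region)
  }
  res <- Rsamtools::scanBam(path, param = param)
  res <- do.call(Map, c(list(f = c), res))  # concatenate across which-ranges
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets

  flag <- res$flag
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  width[is.na(width)] <- 0L
  df <- data.frame(
    qname = as.character(res$qname),
    rname = as.character(res$rname),
    start = res$pos - 1L,
    end   = res$pos - 1L + width,
    strand = ifelse(.flag_bit(flag, 16L), "-", "+"),
    mapq = as.integer(res$mapq),
    flag = as.integer(flag),
    cigar = as.character(res$cigar),
    tlen = as.integer(res$isize),
    mrname = as.character(res$mrnm),
    mstart = res$mpos - 1L,
    is_paired = .flag_bit(flag, 1L),
    is_proper_pair = .flag_bit(flag, 2L),
    is_duplicate = .flag_bit(flag, 1024L),
    is_secondary = .flag_bit(flag, 256L),
    is_supplementary = .flag_bit(flag, 2048L),
    is_unmapped = .flag_bit(flag, 4L),
    stringsAsFactors = FALSE
  )
  drop <- df$is_secondary | df$is_supplementary
  counters <- c(secondary_dropped = sum(df$is_secondary),
                supplementary_dropped = sum(df$is_supplementary))
  .new_alignments(df[!drop, , drop = FALSE], seqlengths = hdr,
                  counters = counters)
}

#' Pair mates into sequenced fragments
#'
#' Collapses proper pairs into one fragment per template, spanning the union
#' of the two mate intervals (leftmost start to rightmost end). The union is
#' used rather than TLEN arithmetic so that soft-clipped alignments still
#' produce consistent intervals; `|TLEN|` is retained for cross-checking.
#' Records that are unpaired, discordant, unmapped, or whose mate is missing
#' from the stream are skipped and counted, never fatal.
#'
#' @param aln An `atac_alignments` table.
#' @return A `data.frame` of class `atac_fragments` with columns `rname`,
#'   `start`, `end`, `size` (= end - start) and `qname`. The number of
#'   skipped records is attached as `attr(, "skipped")`.
#' @examples
#' sam <- system.file("extdata", "toy.sam", package = "atacdeck")
#' frags <- pair_fragments(read_alignments(sam))
#' @export
pair_fragments <- function(aln) {
  ok <- aln$is_proper_pair & !aln$is_unmapped & !aln$is_secondary &
    !aln$is_supplementary
  use <- aln[ok, , drop = FALSE]
  n_skipped <- sum(!ok)
  if (nrow(use)) {
    key <- use$qname
    cnt <- table(key)
    complete <- names(cnt)[cnt == 2L]
    paired <- use[key %in% complete, , drop = FALSE]
    n_skipped <- n_skipped + nrow(use) - nrow(paired)
  } else {
    paired <- use
  }
  if (nrow(paired)) {
    o <- order(paired$qname)
    paired <- paired[o, , drop = FALSE]
    i1 <- seq(1L, nrow(paired), by = 2L)
    i2 <- i1 + 1L
    same_ref <- paired$rname[i1] == paired$rname[i2]
    frag <- data.frame(
      rname = paired$rname[i1],
      start = pmin(paired$start[i1], paired$start[i2]),
      end   = pmax(paired$end[i1], paired$end[i2]),
      qname = paired$qname[i1],
      stringsAsFactors = FALSE
    )
    frag <- frag[same_ref, , drop = FALSE]
    n_skipped <- n_skipped + 2L * sum(!same_ref)
    frag$size <- frag$end - frag$start
    o <- order(frag$rname, frag$start, frag$end)
    frag <- frag[o, c("rname", "start", "end", "size", "qname")]
  } else {
    frag <- data.frame(rname = character(), start = integer(),
                       end = integer(), size = integer(),
                       qname = character(), stringsAsFactors = FALSE)
  }
  rownames(frag) <- NULL
  class(frag) <- c("atac_fragments", "data.frame")
  attr(frag, "skipped") <- n_skipped
  frag
}

#' Write alignments back to a coordinate-sorted, indexed BAM file
#'
#' The inverse of [read_alignments()]: emits one SAM line per row (0-based
#' internal coordinates converted back to 1-based POS), then converts, sorts
#' and indexes through Rsamtools. Reading the written file back reproduces
#' every field of the input table, so shifted or filtered alignments survive
#' a round trip.
#'
#' @param aln An `atac_alignments` table.
#' @param path Output BAM path (".bam" appended if absent).
#' @param seqlengths Named integer vector of reference lengths for the
#'   header; defaults to the `seqlengths` attribute carried by `aln`.
#' @return The path of the written BAM file, invisibly.
#' @export
write_alignments <- function(aln, path, seqlengths = attr(aln, "seqlengths")) {
  if (is.null(seqlengths) || !length(seqlengths))
    stop("reference lengths required to build the BAM header")
  bad <- setdiff(unique(aln$rname[!aln$is_unmapped]), names(seqlengths))
  if (length(bad)) stop("reference name(s) not in header: ",
                        paste(bad, collapse = ", "))
  path <- sub("\\.bam$", "", path)
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  lines <- character(0)
  if (nrow(aln)) {
    mrn <- ifelse(is.na(aln$mrname), "*",
                  ifelse(aln$mrname == aln$rname, "=", aln$mrname))
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t*\t*",
                     aln$qname, aln$flag, aln$rname, aln$start + 1L,
                     aln$mapq, aln$cigar, mrn,
                     ifelse(is.na(aln$mstart), 0L, aln$mstart + 1L),
                     ifelse(is.na(aln$tlen), 0L, aln$tlen))
  }
  writeLines(c(hdr, lines), sam)
  tmp <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  Rsamtools::sortBam(tmp, path)
  Rsamtools::indexBam(paste0(path, ".bam"))
  invisible(paste0(path, ".bam"))
}

#' Convert fragments to a GRanges
#'
#' Utility for interval arithmetic against annotation; shifts back to the
#' 1-based inclusive convention GRanges uses.
#' @param frag An `atac_fragments` table.
#' @return A `GRanges`.
#' @export
fragments_as_granges <- function(frag) {
  GenomicRanges::GRanges(frag$rname,
                         IRanges::IRanges(frag$start + 1L, frag$end))
}

#' @export
print.atac_alignments <- function(x, ...) {
  cat(sprintf("atac_alignments: %d records on %d reference(s)\n",
              nrow(x), length(unique(x$rname))))
  NextMethod()
}

#' @export
print.atac_fragments <- function(x, ...) {
  cat(sprintf("atac_fragments: %d fragments (skipped: %s)\n", nrow(x),
              format(attr(x, "skipped"))))
  NextMethod()
}
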
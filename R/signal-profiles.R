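# Fragment-size distributions, TSS-anchored signal matrices and profiles,
# and gene-centric region coverage.

#' Fragment size distribution
#'
#' Exact per-bp counts of sequenced fragment sizes. In a successful
#' ATAC-seq library the distribution shows a sharp sub-100 bp
#' nucleosome-free mode followed by a downward ladder of mono-, di- and
#' tri-nucleosome peaks.
#'
#' @param frag An `atac_fragments` table.
#' @param max_size Largest size tracked (default 2000 bp).
#' @return A `data.frame` of class `size_histogram` with columns `size` and
#'   `count`, one row per observed size.
#' @export
fragment_size_distribution <- function(frag, max_size = 2000L) {
  sizes <- frag$size[frag$size >= 1L & frag$size <= max_size]
  tab <- table(factor(sizes, levels = seq_len(max_size)))
  out <- data.frame(size = seq_len(max_size), count = as.integer(tab))
  class(out) <- c("size_histogram", "data.frame")
  attr(out, "total") <- length(sizes)
  out
}

#' Plot a fragment size distribution
#'
#' @param x A `size_histogram`.
#' @param log_y Use a log10 count axis.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_size_histogram <- function(x, log_y = FALSE, ...) {
  graphics::plot(x$size, x$count, type = "h",
                 log = if (log_y) "y" else "",
                 xlab = "fragment size (bp)", ylab = "count", ...)
  invisible(x)
}

# Point events (one genomic position per signal unit) from fragments or cut
# sites. Fragment representation: interval midpoint.
.as_events <- function(events, representation = c("midpoint", "cutsites")) {
  representation <- match.arg(representation)
  if (!is.null(events$pos))                       # cut-site table
    return(data.frame(rname = events$rname, pos = events$pos,
                      stringsAsFactors = FALSE))
  if (representation == "midpoint")
    return(data.frame(rname = events$rname,
                      pos = events$start + (events$end - events$start) %/% 2L,
                      stringsAsFactors = FALSE))
  data.frame(rname = rep(events$rname, 2L),
             pos = c(events$start, events$end - 1L),
             stringsAsFactors = FALSE)
}

#' TSS-anchored signal matrix
#'
#' Counts point events (fragment midpoints or Tn5 cut sites) in fixed-width
#' bins of relative position around a set of stranded anchors, typically
#' transcription start sites. For minus-strand anchors the relative axis is
#' flipped so that positive positions are always downstream of the TSS in
#' gene orientation. Anchors missing strand information are treated as plus
#' strand with a warning.
#'
#' @param events An `atac_fragments` table or a [cut_sites()] table.
#' @param anchors A `GRanges` of anchor points (only the start of each range
#'   is used, in strand orientation), or a BED6 file path.
#' @param window Half-width of the window around each anchor, bp.
#' @param bin Bin width, bp; must divide `2*window`.
#' @param normalization `"raw_counts"` or `"counts_per_million"` (per-matrix
#'   scaling by total events in any window).
#' @param representation How fragments become point events
#'   (`"midpoint"` or `"cutsites"`); ignored for cut-site input.
#' @return A numeric matrix of class `signal_matrix`, one row per anchor
#'   (rownames = anchor ids), one column per relative-position bin; bin
#'   centres in `attr(, "positions")`, normalization in
#'   `attr(, "normalization")`, raw event total in `attr(, "total_events")`.
#' @export
tss_signal_matrix <- function(events, anchors, window = 1000L, bin = 10L,
                              normalization = c("counts_per_million",
                                                "raw_counts"),
                              representation = "midpoint") {
  normalization <- match.arg(normalization)
  if (is.character(anchors)) anchors <- rtracklayer::import(anchors)
  window <- as.integer(window); bin <- as.integer(bin)
  if ((2L * window) %% bin != 0L) stop("window must be divisible by bin")
  ev <- .as_events(events, representation)

  str <- as.character(GenomicRanges::strand(anchors))
  if (any(str == "*")) {
    warning("anchor(s) missing strand; treated as '+'")
    str[str == "*"] <- "+"
  }
  # 0-based anchor point: start of the range in strand orientation
  tss <- ifelse(str == "+", GenomicRanges::start(anchors) - 1L,
                GenomicRanges::end(anchors) - 1L)
  ids <- if (!is.null(anchors$name) && !anyDuplicated(anchors$name))
    as.character(anchors$name) else paste0("anchor_", seq_along(anchors))

  nbin <- 2L * window %/% bin
  mat <- matrix(0, nrow = length(anchors), ncol = nbin,
                dimnames = list(ids, NULL))
  ev_gr <- GenomicRanges::GRanges(ev$rname,
                                  IRanges::IRanges(ev$pos + 1L, width = 1L))
  # one bp of slack each side; the exact half-open cut happens on rel below
  win_gr <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(anchors)),
    IRanges::IRanges(pmax(tss - window, 0L) + 1L, tss + window + 1L))
  hits <- GenomicRanges::findOverlaps(ev_gr, win_gr, ignore.strand = TRUE)
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    rel <- ev$pos[qi] - tss[si]
    rel <- ifelse(str[si] == "-", -rel, rel)
    keep <- rel >= -window & rel < window
    bidx <- (rel[keep] + window) %/% bin + 1L
    tt <- table(factor(si[keep], levels = seq_along(anchors)),
                factor(bidx, levels = seq_len(nbin)))
    mat <- matrix(as.numeric(tt), nrow = length(anchors),
                  dimnames = list(ids, NULL))
  }
  total <- sum(mat)
  if (normalization == "counts_per_million" && total > 0)
    mat <- mat * 1e6 / total
  class(mat) <- c("signal_matrix", class(mat))
  attr(mat, "positions") <- -window + bin / 2 + bin * (seq_len(nbin) - 1L)
  attr(mat, "normalization") <- normalization
  attr(mat, "total_events") <- total
  mat
}

#' Order signal matrices by nucleosome-free intensity at the anchor
#'
#' Reorders the rows of a set of signal matrices by descending
#' nucleosome-free signal in the central window, so heatmaps of different
#' nucleosome classes remain row-aligned. Ties are broken by anchor id.
#'
#' @param nf_matrix The nucleosome-free `signal_matrix`.
#' @param others List of further `signal_matrix` objects sharing anchor ids.
#' @param center_halfwidth Half-width (bp) of the central scoring window.
#' @return List with `nf` and `others`, all rows permuted identically.
#' @export
order_by_nf_intensity <- function(nf_matrix, others = list(),
                                  center_halfwidth = 50) {
  pos <- attr(nf_matrix, "positions")
  sums <- rowSums(nf_matrix[, abs(pos) <= center_halfwidth, drop = FALSE])
  o <- order(-sums, rownames(nf_matrix))
  reorder1 <- function(m) {
    if (!identical(sort(rownames(m)), sort(rownames(nf_matrix))))
      stop("anchor sets differ between matrices")
    out <- m[rownames(nf_matrix)[o], , drop = FALSE]
    for (a in c("positions", "normalization", "total_events"))
      attr(out, a) <- attr(m, a)
    class(out) <- class(m)
    out
  }
  list(nf = reorder1(nf_matrix), others = lapply(others, reorder1))
}

#' Per-position average signal profile with a smoothed overlay
#'
#' Column means of a signal matrix (mean signal per relative position over
#' anchors), with a local-regression smooth.
#'
#' @param mat A `signal_matrix`.
#' @param span `loess` span for the smoothed overlay.
#' @return `data.frame` with `position`, `mean`, `smooth`.
#' @export
average_profile <- function(mat, span = 0.3) {
  if (!nrow(mat)) stop("empty signal matrix")
  pos <- attr(mat, "positions")
  m <- colMeans(mat)
  sm <- tryCatch(
    suppressWarnings(stats::predict(stats::loess(m ~ pos, span = span,
                                                 family = "gaussian"))),
    error = function(e) rep(NA_real_, length(m)))
  data.frame(position = pos, mean = m, smooth = sm)
}

#' Heatmap of a signal matrix
#'
#' Simple image-based heatmap with a per-matrix 99th-percentile colour
#' clip, anchors on the vertical axis in current row order.
#'
#' @param mat A `signal_matrix`.
#' @param clip_quantile Upper clip of the colour scale.
#' @param main Plot title.
#' @export
plot_signal_heatmap <- function(mat, clip_quantile = 0.99, main = "") {
  cap <- stats::quantile(mat, clip_quantile)
  z <- pmin(unclass(mat), if (cap > 0) cap else max(mat, 1))
  graphics::image(x = attr(mat, "positions"), y = seq_len(nrow(mat)),
                  z = t(z[rev(seq_len(nrow(z))), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "position relative to TSS (bp)", ylab = "anchor",
                  main = main, useRaster = TRUE)
  invisible(mat)
}

#' Per-base read coverage over a region
#'
#' Gene-centric view of the signal: for every base of the query region,
#' the number of alignment records overlapping it. Optionally computed for
#' each nucleosome-class bin as well.
#'
#' @param aln An `atac_alignments` table (or `atac_fragments`).
#' @param region `GRanges` of length 1.
#' @param by_bin Optional named list of record tables (e.g. the output of
#'   [nucleosome_classes()]); coverage is then also reported per element.
#' @return `data.frame` with `pos` (0-based) and `coverage`, plus one column
#'   per `by_bin` element.
#' @export
region_coverage <- function(aln, region, by_bin = NULL) {
  rname <- as.character(GenomicRanges::seqnames(region))[1]
  lo <- GenomicRanges::start(region)[1] - 1L   # 0-based inclusive
  hi <- GenomicRanges::end(region)[1]          # 0-based exclusive
  cov1 <- function(x) {
    x <- x[x$rname == rname & x$end > lo & x$start < hi, , drop = FALSE]
    v <- integer(hi - lo)
    if (nrow(x)) {
      s <- pmax(x$start, lo) - lo
      e <- pmin(x$end, hi) - lo
      for (i in seq_along(s)) v[(s[i] + 1L):e[i]] <- v[(s[i] + 1L):e[i]] + 1L
    }
    v
  }
  out <- data.frame(pos = lo:(hi - 1L), coverage = cov1(aln))
  for (nm in names(by_bin)) out[[nm]] <- cov1(by_bin[[nm]])
  out
}
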
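# Duplication frequency histograms, library-complexity extrapolation,
# subsampling, a minimal Poisson window peak caller, and saturation curves.

#' Duplication frequency-of-frequencies histogram
#'
#' Groups fragments by exact genomic interval (reference, start, end) and
#' counts, for each multiplicity j, the number of distinct fragments
#' observed exactly j times. This is the sufficient statistic for library
#' complexity estimation; it is computed on libraries with mitochondrial
#' reads already removed.
#'
#' @param frag An `atac_fragments` table.
#' @return Named integer vector of class `freq_hist` (names = j, values =
#'   n_j), with `total_reads` and `distinct` attributes.
#' @examples
#' f <- data.frame(rname = "chr1", start = c(0, 0, 50), end = c(99, 99, 120))
#' dup_freq_histogram(f)
#' @export
dup_freq_histogram <- function(frag) {
  key <- paste(frag$rname, frag$start, frag$end, sep = "\r")
  tab <- table(table(key))
  out <- as.integer(tab)
  names(out) <- names(tab)
  structure(out, class = "freq_hist",
            total_reads = sum(as.integer(names(tab)) * out),
            distinct = sum(out))
}

# E[D(t)] for t <= 1 by exact binomial thinning of each multiplicity class.
.thin_expectation <- function(j, nj, t) sum(nj * (1 - (1 - t)^j))

# Good-Toulmin alternating series for the expected number of new distinct
# fragments after increasing effort by a factor (1 + s), stabilised by
# Euler's series transformation so it remains usable for s > 1.
.good_toulmin_euler <- function(j, nj, s, terms = 30L) {
  a <- numeric(max(j))                    # a_k = n_{k+1}, k = 0, 1, ...
  a[j] <- nj
  # new = s * sum_{k>=0} (-1)^k a_{k+1} s^k ; Euler transform with
  # y = s/(1+s): new = s/(1+s) * sum_k (Delta^k a)_0 * y^k, where Delta is
  # the forward difference of the sequence a_1, a_2, ...
  y <- s / (1 + s)
  kmax <- min(terms, length(a))
  d <- a                                   # d holds Delta^k applied k times
  total <- 0
  for (k in 0:(kmax - 1L)) {
    total <- total + d[1] * y^k
    if (length(d) > 1L) d <- d[-1] - d[-length(d)] else d <- 0
    d <- -d                                # (Delta^k a)_0 alternating form
  }
  s / (1 + s) * total
}

#' Extrapolate library complexity from a duplication histogram
#'
#' Estimates the expected number of distinct fragments as a function of
#' relative sequencing effort t. For t <= 1 the estimate is the exact
#' binomial-thinning interpolation `E[D(t)] = sum_j n_j (1 - (1-t)^j)`.
#' For t > 1 the default adds the Good-Toulmin alternating power series in
#' the extra effort, stabilised by Euler's series transformation; a
#' zero-truncated negative-binomial (ZTNB) maximum-likelihood fit is
#' available as an alternative extrapolator. The returned curve is forced
#' non-decreasing.
#'
#' @param hist A [dup_freq_histogram()] (or any named j -> n_j vector).
#' @param efforts Positive effort multipliers t (1 = observed depth).
#' @param method `"good_toulmin_euler"` (default) or `"ztnb"`.
#' @return A `data.frame` of class `complexity_curve` with columns
#'   `effort`, `reads` (putative sequenced fragments = t * observed total)
#'   and `distinct`.
#' @export
estimate_complexity <- function(hist,
                                efforts = c(seq(0.1, 1, 0.1), 1.25, 1.5,
                                            2, 3, 5, 10),
                                method = c("good_toulmin_euler", "ztnb")) {
  method <- match.arg(method)
  j <- as.integer(names(hist))
  nj <- as.numeric(hist)
  if (!length(j) || sum(nj) <= 0) stop("empty histogram")
  if (any(efforts <= 0)) stop("efforts must be positive")
  efforts <- sort(efforts)
  total <- sum(j * nj)
  observed <- sum(nj)
  if (length(j) == 1L && any(efforts > 1))
    warning("single multiplicity class: extrapolation beyond t = 1 is weakly determined")

  ztnb <- if (method == "ztnb") .fit_ztnb(j, nj) else NULL
  distinct <- vapply(efforts, function(t) {
    if (t <= 1) return(.thin_expectation(j, nj, t))
    if (method == "ztnb" && !is.null(ztnb)) {
      p0 <- (ztnb$size / (ztnb$size + ztnb$mu * t))^ztnb$size
      return(ztnb$L * (1 - p0))
    }
    observed + .good_toulmin_euler(j, nj, t - 1)
  }, numeric(1))
  distinct <- cummax(pmax(distinct, 0))
  structure(data.frame(effort = efforts, reads = efforts * total,
                       distinct = distinct),
            class = c("complexity_curve", "data.frame"), method = method)
}

# ZTNB MLE on the multiplicity histogram; returns NULL when the fit is
# degenerate (e.g. a single multiplicity class).
.fit_ztnb <- function(j, nj) {
  if (length(j) < 2L) return(NULL)
  nll <- function(par) {
    size <- exp(par[1]); mu <- exp(par[2])
    p0 <- (size / (size + mu))^size
    ll <- sum(nj * (stats::dnbinom(j, size = size, mu = mu, log = TRUE) -
                      log1p(-p0)))
    if (!is.finite(ll)) 1e12 else -ll
  }
  mean_j <- sum(j * nj) / sum(nj)
  fit <- tryCatch(
    stats::optim(c(0, log(max(mean_j - 1, 0.1))), nll, method = "Nelder-Mead"),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  size <- exp(fit$par[1]); mu <- exp(fit$par[2])
  p0 <- (size / (size + mu))^size
  list(size = size, mu = mu, L = sum(nj) / (1 - p0))
}

#' Deterministic pair-coherent subsampling
#'
#' Keeps or drops whole templates: the decision for a query name is made by
#' hashing `paste(qname, seed)` with the 32-bit xxHash and comparing the
#' hash, mapped to `[0, 1)`, against the requested fraction. Both mates of
#' a pair therefore survive or vanish together, and the result is
#' reproducible across platforms for a given (fraction, seed).
#'
#' @param aln An `atac_alignments` (or `atac_fragments`) table.
#' @param fraction Retention probability in `(0, 1]`.
#' @param seed Integer seed entering the hash.
#' @return The subsampled table (attributes preserved).
#' @export
subsample <- function(aln, fraction, seed = 0L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(aln)
  qn <- unique(aln$qname)
  h <- vapply(qn, function(q)
    as.numeric(paste0("0x", digest::digest(paste(q, seed),
                                           algo = "xxhash32",
                                           serialize = FALSE))), numeric(1))
  keepq <- qn[(h / 2^32) < fraction]
  out <- aln[aln$qname %in% keepq, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("seqlengths", "skipped"))
    if (!is.null(attr(aln, a))) attr(out, a) <- attr(aln, a)
  out
}

#' Minimal sliding-window Poisson peak caller
#'
#' Counts fragment midpoints in sliding windows, tests each window against
#' the genome-wide Poisson background rate `lambda = total * window /
#' genome_size`, adjusts p-values by Benjamini-Hochberg across windows, and
#' merges overlapping or adjacent significant windows into peaks. A
#' deliberately simple stand-in for a full peak caller, sufficient for
#' saturation analysis on synthetic or shallow data; externally produced
#' peak BED files can be supplied instead via [read_peaks_bed()].
#'
#' @param frag An `atac_fragments` table (coordinate-sorted).
#' @param genome_size Total genome length, bp (> 0).
#' @param window Window width, bp.
#' @param step Window step, bp.
#' @param fdr Benjamini-Hochberg threshold on q-values.
#' @return A `data.frame` of class `atac_peaks` with `rname`, `start`,
#'   `end`, `fold_enrichment`, `qvalue`.
#' @export
call_peaks_simple <- function(frag, genome_size, window = 200L, step = 50L,
                              fdr = 0.05) {
  if (genome_size <= 0) stop("genome_size must be positive")
  empty <- data.frame(rname = character(), start = integer(),
                      end = integer(), fold_enrichment = numeric(),
                      qvalue = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("atac_peaks", "data.frame")
  if (!nrow(frag)) return(empty)
  lambda <- nrow(frag) * window / genome_size
  mids <- data.frame(rname = frag$rname,
                     pos = frag$start + (frag$end - frag$start) %/% 2L)
  res <- lapply(split(mids$pos, mids$rname), function(p) {
    hi <- max(p) + window
    starts <- seq(0L, hi, by = step)
    # count midpoints in [s, s + window)
    cnt <- findInterval(starts + window - 0.5, sort(p)) -
      findInterval(starts - 0.5, sort(p))
    list(starts = starts, cnt = cnt)
  })
  starts <- unlist(lapply(res, `[[`, "starts"), use.names = FALSE)
  cnt <- unlist(lapply(res, `[[`, "cnt"), use.names = FALSE)
  rn <- rep(names(res), vapply(res, function(x) length(x$starts), integer(1)))
  pval <- stats::ppois(cnt - 1, lambda, lower.tail = FALSE)
  qval <- stats::p.adjust(pval, "BH")
  sig <- qval <= fdr & cnt > 0
  if (!any(sig)) return(empty)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    rn[sig], IRanges::IRanges(starts[sig] + 1L, starts[sig] + window)),
    min.gapwidth = 2L)
  # per-peak summary from the significant windows it absorbed
  win_gr <- GenomicRanges::GRanges(rn[sig],
                                   IRanges::IRanges(starts[sig] + 1L,
                                                    starts[sig] + window))
  ov <- GenomicRanges::findOverlaps(win_gr, gr)
  fe <- tapply(cnt[sig][S4Vectors::queryHits(ov)],
               S4Vectors::subjectHits(ov), max) / lambda
  qq <- tapply(qval[sig][S4Vectors::queryHits(ov)],
               S4Vectors::subjectHits(ov), min)
  out <- data.frame(rname = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    fold_enrichment = as.numeric(fe),
                    qvalue = as.numeric(qq), stringsAsFactors = FALSE)
  class(out) <- c("atac_peaks", "data.frame")
  attr(out, "n_windows") <- length(cnt)
  attr(out, "n_sig_windows") <- sum(sig)
  out
}

#' Read externally produced peaks from a BED-like file
#'
#' Adapter for peak calls produced outside the package (e.g. MACS2 broad
#' peaks): the first three columns are used.
#'
#' @param path BED / narrowPeak-like file.
#' @return An `atac_peaks` table (fold_enrichment / qvalue `NA`).
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path)
  out <- data.frame(rname = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    fold_enrichment = NA_real_, qvalue = NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("atac_peaks", "data.frame")
  out
}

#' Peak-based saturation analysis
#'
#' Subsamples the library to a grid of fractions, calls peaks on each
#' subsample, and tabulates the number and total width of significant peaks
#' against the effective number of fragments — flattening curves indicate
#' that deeper sequencing would add little new signal. Smoothed overlays
#' use [stats::loess.smooth()].
#'
#' @param frag An `atac_fragments` table of the full filtered library.
#' @param genome_size Genome length for the Poisson background.
#' @param fractions Ascending subsampling fractions ending at 1.
#' @param seed Seed for the subsampling hash.
#' @param span Smoothing span.
#' @param ... Passed to [call_peaks_simple()].
#' @return A `data.frame` of class `saturation_table`: `fraction`,
#'   `fragments`, `n_peaks`, `peak_width`; loess-smoothed curves in
#'   `attr(, "smooth")`.
#' @export
saturation_curve <- function(frag, genome_size,
                             fractions = seq(0.1, 1, 0.1), seed = 0L,
                             span = 0.5, ...) {
  if (is.unsorted(fractions) || fractions[length(fractions)] != 1)
    stop("fractions must ascend and end at 1.0")
  rows <- lapply(fractions, function(f) {
    sub <- if (f == 1) frag else subsample(frag, f, seed)
    pk <- call_peaks_simple(sub, genome_size, ...)
    data.frame(fraction = f, fragments = nrow(sub), n_peaks = nrow(pk),
               peak_width = sum(pk$end - pk$start))
  })
  out <- do.call(rbind, rows)
  sm <- NULL
  if (nrow(out) >= 8) {
    smooth1 <- function(y) tryCatch(
      suppressWarnings(stats::loess.smooth(out$fragments, y, span = span)),
      error = function(e) NULL)
    sm <- list(n_peaks = smooth1(out$n_peaks),
               peak_width = smooth1(out$peak_width))
  }
  class(out) <- c("saturation_table", "data.frame")
  attr(out, "smooth") <- sm
  out
}

#' Plot a complexity curve
#' @param curve A `complexity_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_complexity <- function(curve, ...) {
  graphics::plot(curve$reads, curve$distinct, type = "b",
                 xlab = "putative sequenced fragments",
                 ylab = "expected distinct fragments", ...)
  invisible(curve)
}

#' Plot a saturation table
#' @param sat A `saturation_table`.
#' @param what `"n_peaks"` or `"peak_width"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_saturation <- function(sat, what = c("n_peaks", "peak_width"), ...) {
  what <- match.arg(what)
  graphics::plot(sat$fragments, sat[[what]], xlab = "effective fragments",
                 ylab = gsub("_", " ", what), ...)
  sm <- attr(sat, "smooth")[[what]]
  if (!is.null(sm)) graphics::lines(sm)
  invisible(sat)
}
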
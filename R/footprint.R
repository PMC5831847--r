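# Motif handling (PFM -> log-odds PWM), genome scanning for predicted
# binding sites, and aggregated cut-rate footprint profiles.

.base_order <- c("A", "C", "G", "T")

#' Read a JASPAR-format position frequency matrix
#'
#' Accepts both the JASPAR text dialect (`>ID name` header followed by four
#' lines like `A  [ 4 19  0 ... ]`) and a bare four-row count matrix, rows
#' in A, C, G, T order.
#'
#' @param path Path to the PFM text file.
#' @return A 4 x w numeric matrix with rownames A, C, G, T.
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, ">")]
  if (length(lines) != 4L) stop("expected 4 base rows in PFM file")
  parse_row <- function(x) {
    x <- gsub("^[ACGTacgt]\\s*", "", x)
    x <- gsub("[][]", " ", x)
    as.numeric(strsplit(trimws(x), "\\s+")[[1]])
  }
  rows <- lapply(lines, parse_row)
  w <- unique(lengths(rows))
  if (length(w) != 1L) stop("ragged PFM rows")
  pfm <- do.call(rbind, rows)
  lab <- toupper(substr(lines, 1, 1))
  if (identical(sort(lab), .base_order))   # labelled rows may be reordered
    pfm <- pfm[match(.base_order, lab), , drop = FALSE]
  rownames(pfm) <- .base_order
  if (any(colSums(pfm) <= 0)) stop("PFM has an all-zero column")
  pfm
}

#' Convert a position frequency matrix to a log-odds weight matrix
#'
#' Column-wise: `weight[b, i] = log2(((counts[b, i] + pc) /
#' (colsum_i + 4 pc)) / background[b])`. The pseudocount regularises zero
#' counts; the default background is uniform.
#'
#' @param pfm 4 x w count matrix, rows A, C, G, T.
#' @param background Length-4 base probabilities, summing to 1, all > 0.
#' @param pseudocount Added to every cell (default 0.25).
#' @return A 4 x w matrix of class `pwm` with attributes `max_score` and
#'   `min_score` (sums of column maxima / minima).
#' @examples
#' pfm <- matrix(c(4, 0, 0, 0), 4, 1, dimnames = list(c("A","C","G","T")))
#' pfm_to_pwm(pfm)
#' @export
pfm_to_pwm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.25) {
  stopifnot(nrow(pfm) == 4L)
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-8)
    stop("background must be positive probabilities summing to 1")
  p <- sweep(pfm + pseudocount, 2, colSums(pfm) + 4 * pseudocount, "/")
  w <- log2(p / background)
  rownames(w) <- .base_order
  structure(w, max_score = sum(apply(w, 2, max)),
            min_score = sum(apply(w, 2, min)), class = c("pwm", "matrix"))
}

# Integer-encode a DNA string: A=1 C=2 G=3 T=4, anything else (N) = 5.
.encode_dna <- function(seq) {
  v <- strsplit(toupper(as.character(seq)), "")[[1]]
  i <- match(v, .base_order)
  i[is.na(i)] <- 5L
  i
}

# Score every window start of an encoded sequence against a pwm; N columns
# contribute 0. Vectorised over starts.
.scan_scores <- function(enc, pwm) {
  w <- ncol(pwm)
  L <- length(enc)
  if (L < w) return(numeric(0))
  n <- L - w + 1L
  scores <- numeric(n)
  for (i in seq_len(w)) {
    col <- unname(c(pwm[, i], 0))  # 5th entry: N scores as background
    scores <- scores + col[enc[i:(i + n - 1L)]]
  }
  scores
}

.revcomp_pwm <- function(pwm) {
  out <- pwm[4:1, rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- .base_order
  out
}

#' Score a sequence against a position weight matrix
#'
#' For a sequence of exactly the motif width, the sum of the matching
#' weights. For longer sequences, the maximal score over all windows on
#' both strands. N bases score 0 (background).
#'
#' @param sequence DNA string (character or `DNAString`).
#' @param pwm A `pwm` from [pfm_to_pwm()].
#' @return The (maximal) log-odds score.
#' @export
pwm_score <- function(sequence, pwm) {
  enc <- .encode_dna(sequence)
  w <- ncol(pwm)
  if (length(enc) < w) stop("sequence shorter than motif width")
  fwd <- .scan_scores(enc, pwm)
  if (length(enc) == w) return(fwd)
  rev <- .scan_scores(enc, .revcomp_pwm(pwm))
  max(fwd, rev)
}

.relative_score <- function(score, pwm) {
  (score - attr(pwm, "min_score")) /
    (attr(pwm, "max_score") - attr(pwm, "min_score"))
}

#' Scan a genome for predicted binding sites
#'
#' Scores every window of every sequence on both strands and reports those
#' reaching the relative-score threshold, where
#' `relative_score = (score - min_score) / (max_score - min_score)`.
#' When a plus- and a minus-strand hit share a locus (same window), only the
#' higher-scoring one is kept (ties go to the plus strand).
#'
#' @param genome A `DNAStringSet` or FASTA file path.
#' @param pwm A `pwm` from [pfm_to_pwm()].
#' @param min_relative_score Threshold in `[0, 1]` (default 0.95).
#' @return A `data.frame` with `rname`, `start` (0-based), `end`, `strand`,
#'   `score`, `relative_score`, sorted by position.
#' @export
scan_genome <- function(genome, pwm, min_relative_score = 0.95) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!length(genome)) stop("empty genome")
  names(genome) <- sub("\\s.*", "", names(genome))
  w <- ncol(pwm)
  res <- lapply(seq_along(genome), function(k) {
    enc <- .encode_dna(genome[[k]])
    fwd <- .scan_scores(enc, pwm)
    rev <- .scan_scores(enc, .revcomp_pwm(pwm))
    if (!length(fwd)) return(NULL)
    take_minus <- rev > fwd                     # dedup: tie goes to '+'
    score <- ifelse(take_minus, rev, fwd)
    rel <- .relative_score(score, pwm)
    keep <- which(rel >= min_relative_score)
    if (!length(keep)) return(NULL)
    data.frame(rname = names(genome)[k], start = keep - 1L,
               end = keep - 1L + w,
               strand = ifelse(take_minus[keep], "-", "+"),
               score = score[keep], relative_score = rel[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(rname = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), relative_score = numeric())
  rownames(out) <- NULL
  attr(out, "motif_width") <- w
  attr(out, "min_relative_score") <- min_relative_score
  out
}

#' Aggregated footprint profile around predicted binding sites
#'
#' Average Tn5 cut rate at each position of the motif and its flanking
#' sequence, aggregated over binding sites: `profile[p]` is the number of
#' cut sites landing at relative position p across all sites, divided by
#' the number of sites. Minus-strand sites are coordinate-flipped so motifs
#' align. A bound factor protects the motif core from transposition, so a
#' footprint appears as a valley between the flanks. By convention only cut
#' sites from short (< 100 bp) nucleosome-free fragments are aggregated.
#'
#' @param cuts A [cut_sites()] table.
#' @param sites Binding sites from [scan_genome()] (needs >= 1 row).
#' @param flank Flanking width each side, bp (default 100).
#' @param max_source_size Only cut sites whose source fragment is shorter
#'   than this are used (default 100 bp; `Inf` disables).
#' @return A `data.frame` with `position` (relative to motif start,
#'   `-flank .. w+flank-1`) and `cut_rate`; the motif interval is
#'   `0 .. w-1`.
#' @export
footprint_profile <- function(cuts, sites, flank = 100L,
                              max_source_size = 100L) {
  if (!nrow(sites)) stop("empty binding-site list")
  w <- attr(sites, "motif_width")
  if (is.null(w)) w <- unique(sites$end - sites$start)[1]
  flank <- as.integer(flank)
  if (is.finite(max_source_size) && !is.null(cuts$source_size))
    cuts <- cuts[!is.na(cuts$source_size) &
                   cuts$source_size < max_source_size, , drop = FALSE]
  np <- w + 2L * flank
  counts <- numeric(np)
  cuts_by_ref <- split(cuts$pos, cuts$rname)
  for (i in seq_len(nrow(sites))) {
    p <- cuts_by_ref[[sites$rname[i]]]
    if (is.null(p)) next
    lo <- sites$start[i] - flank
    hi <- sites$start[i] + w + flank          # exclusive
    p <- p[p >= lo & p < hi]
    if (!length(p)) next
    rel <- if (sites$strand[i] == "-") (hi - 1L) - p else p - lo
    counts <- counts + tabulate(rel + 1L, nbins = np)
  }
  data.frame(position = seq_len(np) - 1L - flank,
             cut_rate = counts / nrow(sites))
}

#' Plot a footprint profile
#'
#' @param profile Output of [footprint_profile()].
#' @param motif_width Motif width, marked by vertical lines.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_footprint <- function(profile, motif_width, ...) {
  graphics::plot(profile$position, profile$cut_rate, type = "l",
                 xlab = "position relative to motif start (bp)",
                 ylab = "average cut rate", ...)
  graphics::abline(v = c(0, motif_width), lty = 2, col = "grey40")
  invisible(profile)
}

#' Export binding sites as BED6
#'
#' Score column carries `relative_score * 1000`, rounded.
#' @param sites Output of [scan_genome()].
#' @param path Output BED path.
#' @export
write_sites_bed <- function(sites, path) {
  lines <- sprintf("%s\t%d\t%d\tsite_%d\t%d\t%s", sites$rname, sites$start,
                   sites$end, seq_len(nrow(sites)),
                   as.integer(round(sites$relative_score * 1000)),
                   sites$strand)
  writeLines(lines, path)
  invisible(path)
}
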
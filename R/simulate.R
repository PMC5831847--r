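# Synthetic ATAC-seq data with known ground truth: genomes, annotations,
# planted motif sites, and paired-end libraries drawn from a
# nucleosome-class size mixture.

#' Parameters of a simulated ATAC-seq library
#'
#' The generative model: each sequenced fragment draws a chromatin class
#' (nucleosome-free, mono-, di-, tri-nucleosome or background), then a size
#' from the class's truncated-normal size distribution, then a location.
#' Nucleosome-free fragments fall within +/- 200 bp of a transcription
#' start site with probability `tss_enrichment`, all other placements are
#' uniform. A fraction of fragments is assigned to a small mitochondrial
#' reference; PCR duplicates are emitted as coordinate-identical extra
#' pairs with distinct names; cut sites inside planted motif cores are
#' thinned by the protection factor.
#'
#' @param n_fragments Number of unique (pre-duplication) fragments.
#' @param class_weights Named proportions over `nf`, `mono`, `di`, `tri`,
#'   `background`; must sum to 1.
#' @param size_mean,size_sd Named per-class size distribution parameters
#'   (bp); `background` is uniform on 38-1000.
#' @param tss_enrichment Probability a nucleosome-free fragment is placed
#'   TSS-proximally.
#' @param mito_fraction Proportion of fragments on the mitochondrial
#'   reference.
#' @param duplication_rate Per-fragment probability of emitting one PCR
#'   duplicate copy.
#' @param protection Cut-site survival probability inside a planted motif
#'   core (1 = no footprint).
#' @param seed Mandatory integer seed.
#' @return A list of class `library_model`.
#' @export
library_model <- function(n_fragments = 10000L,
                          class_weights = c(nf = 0.45, mono = 0.25,
                                            di = 0.12, tri = 0.08,
                                            background = 0.10),
                          size_mean = c(nf = 60, mono = 200, di = 390,
                                        tri = 580),
                          size_sd = c(nf = 15, mono = 15, di = 25,
                                      tri = 20),
                          tss_enrichment = 0.8,
                          mito_fraction = 0.1,
                          duplication_rate = 0.1,
                          protection = 1,
                          seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(abs(sum(class_weights) - 1) < 1e-8,
            all(class_weights >= 0), mito_fraction >= 0, mito_fraction <= 1,
            duplication_rate >= 0, duplication_rate <= 1,
            tss_enrichment >= 0, tss_enrichment <= 1,
            protection >= 0, protection <= 1)
  structure(list(n_fragments = as.integer(n_fragments),
                 class_weights = class_weights, size_mean = size_mean,
                 size_sd = size_sd, tss_enrichment = tss_enrichment,
                 mito_fraction = mito_fraction,
                 duplication_rate = duplication_rate,
                 protection = protection, seed = as.integer(seed)),
            class = "library_model")
}

.sample_bases <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

#' Simulate a genome with planted motif sites and TSS annotation
#'
#' Generates an i.i.d. random chromosome at the requested GC content,
#' optionally overwrites non-overlapping positions with the consensus of a
#' motif PFM (recorded as ground truth), and draws stranded TSS positions.
#'
#' @param length Chromosome length, bp.
#' @param gc GC content.
#' @param motif Optional 4 x w PFM whose consensus is planted.
#' @param n_sites Number of planted motif instances.
#' @param n_tss Number of TSS annotations to draw.
#' @param seed Integer seed.
#' @param chrom_name Chromosome name.
#' @return A list: `genome` (`DNAStringSet`), `sites` (`data.frame` with
#'   0-based `start`, `end`, `strand`), `tss` (`GRanges`, stranded,
#'   width 1).
#' @export
simulate_genome <- function(length = 1e5, gc = 0.5, motif = NULL,
                            n_sites = 0L, n_tss = 50L, seed = 1L,
                            chrom_name = "chr1") {
  set.seed(seed)
  length <- as.integer(length)
  bases <- .sample_bases(length, gc)
  sites <- data.frame(rname = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (!is.null(motif) && n_sites > 0) {
    w <- ncol(motif)
    if (n_sites * w * 4 > length) stop("cannot pack motif sites")
    consensus <- .base_order[apply(motif, 2, which.max)]
    starts <- integer(0)
    cand <- sample.int(length - w, n_sites * 20)
    for (s in cand) {
      if (length(starts) >= n_sites) break
      if (!any(abs(starts - s) < 2L * w)) starts <- c(starts, s)
    }
    if (length(starts) < n_sites) stop("cannot pack motif sites")
    starts <- sort(starts)
    for (s in starts) bases[(s + 1):(s + w)] <- consensus
    sites <- data.frame(rname = chrom_name, start = starts,
                        end = starts + w, strand = "+",
                        stringsAsFactors = FALSE)
    attr(sites, "motif_width") <- w
  }
  tss <- GenomicRanges::GRanges()
  if (n_tss > 0) {
    pos <- sort(sample.int(length - 4000L, n_tss) + 2000L)  # keep windows inside
    tss <- GenomicRanges::GRanges(chrom_name,
                                  IRanges::IRanges(pos + 1L, width = 1L),
                                  strand = sample(c("+", "-"), n_tss,
                                                  replace = TRUE))
    tss$name <- sprintf("tss_%03d", seq_len(n_tss))
  }
  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- chrom_name
  list(genome = genome, sites = sites, tss = tss)
}

.rtruncnorm_int <- function(n, mean, sd, lo, hi) {
  out <- round(stats::rnorm(n, mean, sd))
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- round(stats::rnorm(length(bad), mean, sd))
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  as.integer(out)
}

#' Simulate a paired-end ATAC-seq library with known ground truth
#'
#' Draws fragments from the nucleosome-class mixture of a
#' [library_model()], places them on the genome (TSS-proximal for enriched
#' nucleosome-free fragments, uniform otherwise, mitochondrial fraction on
#' a dedicated small reference), thins fragments whose Tn5 cut sites fall
#' in planted motif cores, appends PCR-duplicate copies, and emits both
#' mates of every pair as alignment records with correct FLAG/TLEN
#' bookkeeping. The truth table records each fragment's class and
#' duplicate lineage, keyed by query name.
#'
#' @param sim Output of [simulate_genome()] (supplies genome length, TSS
#'   and planted sites).
#' @param model A [library_model()].
#' @param read_length Mate length, bp (capped at fragment size).
#' @param mito_length Length of the mitochondrial reference, bp.
#' @return A list: `alignments` (`atac_alignments`, coordinate-sorted),
#'   `truth` (`data.frame`: `qname`, `class`, `lineage`, `rname`, `start`,
#'   `end`, `size`), `seqlengths`, plus the `tss` and `sites` of `sim`.
#' @export
simulate_library <- function(sim, model, read_length = 50L,
                             mito_length = 16000L) {
  set.seed(model$seed)
  chrom <- names(sim$genome)[1]
  glen <- Biostrings::width(sim$genome)[1]
  if (glen < 5000L) stop("genome too short to place fragments")
  n <- model$n_fragments
  cls <- sample(names(model$class_weights), n, replace = TRUE,
                prob = model$class_weights)
  size <- integer(n)
  for (cl in c("nf", "mono", "di", "tri")) {
    idx <- which(cls == cl)
    if (length(idx))
      size[idx] <- .rtruncnorm_int(length(idx), model$size_mean[[cl]],
                                   model$size_sd[[cl]], 38L, 2000L)
  }
  bg <- which(cls == "background")
  if (length(bg)) size[bg] <- as.integer(sample(38:1000, length(bg),
                                                replace = TRUE))

  is_mito <- stats::runif(n) < model$mito_fraction
  rname <- ifelse(is_mito, "chrM", chrom)
  reflen <- ifelse(is_mito, mito_length, glen)

  # locations: NF fragments TSS-proximal with probability tss_enrichment
  mid <- integer(n)
  uniform <- function(k, len, sz)
    as.integer(floor(stats::runif(k, sz / 2, len - sz / 2)))
  mid <- uniform(n, reflen, size)
  tsspos <- if (length(sim$tss))
    GenomicRanges::start(sim$tss) - 1L else integer(0)
  if (length(tsspos)) {
    near <- which(cls == "nf" & !is_mito &
                    stats::runif(n) < model$tss_enrichment)
    if (length(near)) {
      anchor <- sample(tsspos, length(near), replace = TRUE)
      off <- as.integer(round(stats::runif(length(near), -200, 200)))
      mid[near] <- pmin(pmax(anchor + off, size[near] %/% 2L + 1L),
                        glen - size[near] %/% 2L - 1L)
    }
  }
  start <- mid - size %/% 2L
  end <- start + size

  # footprint protection: thin fragments whose cut sites hit a motif core
  if (nrow(sim$sites) && model$protection < 1) {
    core <- sim$sites
    in_core <- function(p) {
      hit <- rep(FALSE, length(p))
      for (i in seq_len(nrow(core)))
        hit <- hit | (p >= core$start[i] & p < core$end[i])
      hit
    }
    # thin at the Tn5 insertion points the +4/-5 shift will expose
    n_in <- in_core(start + 4L) + in_core(end - 1L - 5L)
    n_in[is_mito] <- 0
    keep <- stats::runif(n) < model$protection^n_in
    cls <- cls[keep]; size <- size[keep]; rname <- rname[keep]
    start <- start[keep]; end <- end[keep]
    n <- sum(keep)
  }

  qname <- sprintf("frag%06d", seq_len(n))
  lineage <- rep("original", n)

  # PCR duplicates: coordinate-identical extra pairs, names suffixed .dupK
  ndup <- stats::rbinom(n, 1L, model$duplication_rate)
  if (any(ndup > 0)) {
    di <- rep(seq_len(n), ndup)
    qname <- c(qname, paste0(qname[di], ".dup1"))
    cls <- c(cls, cls[di]); size <- c(size, size[di])
    rname <- c(rname, rname[di]); start <- c(start, start[di])
    end <- c(end, end[di])
    lineage <- c(lineage, rep("copy", length(di)))
  }
  ntot <- length(qname)

  truth <- data.frame(qname = qname, class = cls, lineage = lineage,
                      rname = rname, start = start, end = end, size = size,
                      stringsAsFactors = FALSE)

  rl <- pmin(as.integer(read_length), size)
  mk <- function(mate1) {
    plus <- mate1           # mate1 on plus strand, mate2 on minus
    data.frame(
      qname = qname,
      rname = rname,
      start = if (mate1) start else end - rl,
      end   = if (mate1) start + rl else end,
      strand = if (mate1) "+" else "-",
      mapq = 60L,
      flag = if (mate1) 99L else 147L,
      cigar = paste0(rl, "M"),
      tlen = if (mate1) size else -size,
      mrname = rname,
      mstart = if (mate1) end - rl else start,
      is_paired = TRUE, is_proper_pair = TRUE, is_duplicate = FALSE,
      is_secondary = FALSE, is_supplementary = FALSE, is_unmapped = FALSE,
      stringsAsFactors = FALSE)
  }
  aln <- rbind(mk(TRUE), mk(FALSE))
  aln <- aln[order(aln$rname, aln$start, aln$qname), , drop = FALSE]
  seqlengths <- stats::setNames(c(glen, mito_length), c(chrom, "chrM"))
  aln <- .new_alignments(aln, seqlengths = seqlengths)
  list(alignments = aln, truth = truth, seqlengths = seqlengths,
       tss = sim$tss, sites = sim$sites)
}

#' One-call simulation fixture
#'
#' Convenience wrapper producing genome, annotation and library in one go,
#' optionally writing the standard file bundle (FASTA, BAM + index, TSS
#' BED, sites BED, truth TSV, model JSON).
#'
#' @param out_prefix If non-`NULL`, files are written with this prefix.
#' @param genome_length,gc,n_tss,motif,n_sites Passed to
#'   [simulate_genome()].
#' @param model A [library_model()]; its seed also seeds the genome.
#' @return The [simulate_library()] list, plus `genome` and (when written)
#'   `files`.
#' @export
simulate_atac <- function(model, genome_length = 1e5, gc = 0.5,
                          n_tss = 50L, motif = NULL, n_sites = 0L,
                          out_prefix = NULL) {
  sim <- simulate_genome(genome_length, gc, motif, n_sites, n_tss,
                         seed = model$seed)
  lib <- simulate_library(sim, model)
  lib$genome <- sim$genome
  if (!is.null(out_prefix)) {
    Biostrings::writeXStringSet(sim$genome, paste0(out_prefix, ".fa"))
    bam <- write_alignments(lib$alignments, paste0(out_prefix, ".bam"),
                            lib$seqlengths)
    if (length(sim$tss))
      rtracklayer::export(sim$tss, paste0(out_prefix, ".tss.bed"))
    if (nrow(sim$sites))
      writeLines(sprintf("%s\t%d\t%d\tsite_%d\t0\t%s", sim$sites$rname,
                         sim$sites$start, sim$sites$end,
                         seq_len(nrow(sim$sites)), sim$sites$strand),
                 paste0(out_prefix, ".sites.bed"))
    utils::write.table(lib$truth, paste0(out_prefix, ".truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(model[names(model) != "class"],
                         paste0(out_prefix, ".model.json"),
                         auto_unbox = TRUE, digits = NA)
    lib$files <- c(fasta = paste0(out_prefix, ".fa"), bam = bam,
                   tss = paste0(out_prefix, ".tss.bed"),
                   truth = paste0(out_prefix, ".truth.tsv"))
  }
  lib
}
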
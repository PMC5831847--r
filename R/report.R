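# End-to-end QC report: orchestrates the recommended assessment sequence
# (qc -> fragment sizes -> shift -> split -> TSS signal -> footprint ->
# complexity) and writes a TSV bundle. TSVs are the contract; plots are
# side-effects.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full QC report on one library
#'
#' Executes the standard post-alignment assessment sequence and writes one
#' TSV per section: `<prefix>.metrics.tsv` (QC metrics),
#' `<prefix>.filter_report.tsv`, `<prefix>.fragsize.tsv`,
#' `<prefix>.tss_profile.tsv` (per nucleosome class),
#' `<prefix>.footprint.tsv` (when a PFM is given),
#' `<prefix>.complexity.tsv`, and `<prefix>.params.tsv` echoing every
#' parameter used. Output is deterministic for a given seed: re-running
#' with identical inputs reproduces the TSVs byte for byte. A missing PFM
#' merely skips the footprint section with a notice.
#'
#' @param bam Path to a coordinate-sorted BAM (or SAM) file.
#' @param tss TSS annotation: BED6 path or `GRanges`.
#' @param genome FASTA path or `DNAStringSet` (footprint section only).
#' @param pfm JASPAR PFM path or 4 x w matrix; `NULL` skips footprinting.
#' @param out_prefix Prefix of the written files.
#' @param criteria A [filter_criteria()].
#' @param window,bin TSS matrix parameters, bp.
#' @param min_relative_score Binding-site threshold for the footprint.
#' @param efforts Complexity extrapolation grid.
#' @param seed Seed recorded and used for any stochastic step.
#' @return Invisibly, a list with the computed section objects and the
#'   written file paths (`$files`).
#' @export
run_report <- function(bam, tss, genome = NULL, pfm = NULL,
                       out_prefix = "atacdeck", criteria = filter_criteria(),
                       window = 1000L, bin = 10L, min_relative_score = 0.95,
                       efforts = c(seq(0.1, 1, 0.1), 1.25, 1.5, 2, 3, 5, 10),
                       seed = 1L) {
  set.seed(seed)
  files <- character(0)
  aln <- read_alignments(bam)
  aln <- mark_duplicates(aln)
  metrics <- compute_qc_metrics(aln, criteria)

  mdf <- data.frame(metric = c("total_reads", "mapped_reads", "mito_reads",
                               "mito_fraction", "duplicate_reads",
                               "duplicate_rate", "distinct_positions",
                               "nrf", "pbc1", "pbc2", "proper_pair_rate"),
                    value = c(metrics$total_reads, metrics$mapped_reads,
                              metrics$mito_reads, metrics$mito_fraction,
                              metrics$duplicate_reads, metrics$duplicate_rate,
                              metrics$distinct_positions, metrics$nrf,
                              metrics$pbc1,
                              ifelse(is.na(metrics$pbc2), Inf, metrics$pbc2),
                              metrics$proper_pair_rate))
  files["metrics"] <- .write_tsv(mdf, paste0(out_prefix, ".metrics.tsv"))

  filtered <- filter_alignments(aln, criteria)
  rep <- attr(filtered, "filter_report")
  files["filter_report"] <- .write_tsv(
    data.frame(criterion = names(rep), removed = as.integer(rep)),
    paste0(out_prefix, ".filter_report.tsv"))

  frag <- pair_fragments(filtered)
  sizes <- fragment_size_distribution(frag)
  files["fragsize"] <- .write_tsv(as.data.frame(unclass(sizes)),
                                  paste0(out_prefix, ".fragsize.tsv"))

  shifted <- shift_reads(filtered)
  sfrag <- pair_fragments(shifted)
  sfrag <- sfrag[sfrag$size >= 38 & sfrag$size <= 2000, , drop = FALSE]
  classes <- nucleosome_classes(sfrag)

  if (is.character(tss)) tss <- rtracklayer::import(tss)
  prof <- NULL
  if (length(tss)) {
    mats <- lapply(classes, function(x)
      tss_signal_matrix(x, tss, window = window, bin = bin))
    prof <- do.call(rbind, lapply(names(mats), function(nm) {
      p <- average_profile(mats[[nm]])
      p$class <- nm
      p
    }))
    files["tss_profile"] <- .write_tsv(
      prof[, c("class", "position", "mean", "smooth")],
      paste0(out_prefix, ".tss_profile.tsv"))
  }

  fp <- NULL
  if (!is.null(pfm) && !is.null(genome)) {
    if (is.character(pfm)) pfm <- read_jaspar(pfm)
    pwm <- pfm_to_pwm(pfm)
    sites <- scan_genome(genome, pwm, min_relative_score)
    if (nrow(sites)) {
      fp <- footprint_profile(cut_sites(shifted), sites)
      files["footprint"] <- .write_tsv(fp,
                                       paste0(out_prefix, ".footprint.tsv"))
    } else message("no binding sites above threshold; footprint skipped")
  } else if (is.null(pfm)) {
    message("no PFM supplied; footprint section skipped")
  }

  hist <- dup_freq_histogram(pair_fragments(aln[!(aln$rname %in%
                                                    criteria$mito_names), ,
                                                drop = FALSE]))
  curve <- estimate_complexity(hist, efforts)
  files["complexity"] <- .write_tsv(as.data.frame(unclass(curve)),
                                    paste0(out_prefix, ".complexity.tsv"))

  params <- data.frame(
    parameter = c("bam", "seed", "window", "bin", "min_relative_score",
                  "mito_names", "max_removed_mapq", "min_template",
                  "max_template", "drop_duplicates", "require_proper_pair"),
    value = c(bam, seed, window, bin, min_relative_score,
              paste(criteria$mito_names, collapse = ","),
              criteria$max_removed_mapq, criteria$min_template,
              criteria$max_template, criteria$drop_duplicates,
              criteria$require_proper_pair))
  files["params"] <- .write_tsv(params, paste0(out_prefix, ".params.tsv"))

  invisible(list(metrics = metrics, filter_report = rep, fragsize = sizes,
                 tss_profile = prof, footprint = fp, complexity = curve,
                 files = files))
}
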
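test_that("JASPAR parsing accepts both dialects", {
  jaspar <- tempfile(fileext = ".jaspar")
  writeLines(c(">MA0000.1 TESTTF",
               "A  [ 4 19  0  2 ]",
               "C  [ 6  0 20  1 ]",
               "G  [ 8  1  0 15 ]",
               "T  [ 2  0  0  2 ]"), jaspar)
  pfm <- read_jaspar(jaspar)
  expect_equal(dim(pfm), c(4L, 4L))
  expect_equal(unname(pfm["A", 2]), 19)
  expect_equal(unname(pfm["G", 4]), 15)

  bare <- tempfile()
  writeLines(c("4 19 0 2", "6 0 20 1", "8 1 0 15", "2 0 0 2"), bare)
  expect_equal(unname(read_jaspar(bare)), unname(pfm))
})

test_that("log-odds weights follow the stated pseudocount formula", {
  pfm <- matrix(c(4, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T")))
  pwm <- pfm_to_pwm(pfm)
  expect_equal(unname(pwm["A", 1]), log2((4.25 / 5) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(pwm["A", 1]), 1.766, tolerance = 1e-3)
  expect_equal(unname(pwm["C", 1]), log2((0.25 / 5) / 0.25),
               tolerance = 1e-12)

  unif <- matrix(1, 4, 3, dimnames = list(c("A", "C", "G", "T")))
  expect_true(all(abs(pfm_to_pwm(unif)) < 1e-12))

  pfm2 <- toy_pfm()
  pwm2 <- pfm_to_pwm(pfm2)
  expect_equal(attr(pwm2, "max_score"), sum(apply(pwm2, 2, max)))
  expect_equal(attr(pwm2, "min_score"), sum(apply(pwm2, 2, min)))
  expect_error(pfm_to_pwm(pfm2, background = c(0.5, 0.5, 0, 0)))
})

test_that("pwm_score matches brute force over windows and strands", {
  pfm <- toy_pfm()
  pwm <- pfm_to_pwm(pfm)
  cons <- pfm_consensus(pfm)
  expect_equal(pwm_score(cons, pwm), attr(pwm, "max_score"))
  expect_equal(pwm_score(strrep("N", 12), pwm), 0)
  expect_error(pwm_score("ACGT", pwm))

  # random 200-mer with planted consensus: brute-force oracle
  set.seed(9)
  seq200 <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                  collapse = "")
  substr(seq200, 101, 112) <- cons
  w <- ncol(pwm)
  score1 <- function(s) {           # score an exact-width window, one strand
    v <- strsplit(s, "")[[1]]
    sum(vapply(seq_len(w), function(i) pwm[v[i], i], numeric(1)))
  }
  brute <- max(vapply(1:(200 - w + 1), function(p) {
    win <- substr(seq200, p, p + w - 1)
    max(score1(win), score1(revcomp(win)))
  }, numeric(1)))
  expect_equal(pwm_score(seq200, pwm), brute)
})

test_that("genome scanning finds planted sites and matches brute force", {
  pfm <- toy_pfm()
  pwm <- pfm_to_pwm(pfm)
  cons <- pfm_consensus(pfm)
  set.seed(4)
  bases <- sample(c("A", "C", "G", "T"), 3000, replace = TRUE)
  planted <- 1500L                       # 0-based start
  bases[(planted + 1):(planted + 12)] <- strsplit(cons, "")[[1]]
  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- "chr1"

  hits <- scan_genome(genome, pwm, 0.99)
  expect_true(planted %in% hits$start)
  expect_true(all(hits$relative_score >= 0.99))

  # threshold 0 reports every window (after strand dedup)
  all_hits <- scan_genome(genome, pwm, 0)
  expect_equal(nrow(all_hits), 3000 - 12 + 1)

  # independent cross-check with Biostrings::matchPWM at the same cutoff
  abs_cut <- attr(pwm, "min_score") +
    0.99 * (attr(pwm, "max_score") - attr(pwm, "min_score"))
  fwd <- Biostrings::matchPWM(unclass(pwm), genome[[1]], min.score = abs_cut)
  expect_true(all((Biostrings::start(fwd) - 1L) %in% hits$start))

  # reverse-complemented genome: same loci, strands flipped
  rc <- Biostrings::reverseComplement(genome[[1]])
  rc_hits <- scan_genome(Biostrings::DNAStringSet(`names<-`(list(rc), "chr1")),
                         pwm, 0.99)
  expect_equal(sort(3000 - hits$end), sort(rc_hits$start))
})

test_that("footprint profile arithmetic places cuts at exact offsets", {
  sites <- data.frame(rname = "chr1", start = 1000L, end = 1010L,
                      strand = "+", score = 1, relative_score = 1)
  attr(sites, "motif_width") <- 10L
  cuts <- data.frame(rname = "chr1", pos = 999L, strand = "+",
                     source_size = 60L)
  prof <- footprint_profile(cuts, sites, flank = 100L)
  expect_equal(nrow(prof), 10L + 200L)
  expect_equal(range(prof$position), c(-100L, 109L))
  expect_equal(prof$cut_rate[prof$position == -1], 1.0)
  expect_equal(sum(prof$cut_rate), 1.0)

  # no cuts: all-zero profile; empty sites: error
  expect_true(all(footprint_profile(cuts[0, ], sites)$cut_rate == 0))
  expect_error(footprint_profile(cuts, sites[0, ]))
})

test_that("minus-strand sites are coordinate-flipped and aggregate conserves cuts", {
  sites <- data.frame(rname = "chr1", start = c(1000L, 5000L),
                      end = c(1010L, 5010L), strand = c("+", "-"),
                      score = 1, relative_score = 1)
  attr(sites, "motif_width") <- 10L
  # one cut 1 bp upstream of each site in its own orientation
  cuts <- data.frame(rname = "chr1", pos = c(999L, 5010L),
                     strand = c("+", "-"), source_size = c(60L, 60L))
  prof <- footprint_profile(cuts, sites, flank = 100L)
  expect_equal(prof$cut_rate[prof$position == -1], 1.0)  # both sites align
  expect_equal(sum(prof$cut_rate) * nrow(sites), 2)

  # flipping all site strands reverses the aggregate profile
  flipped <- sites
  flipped$strand <- c("-", "+")
  pf <- footprint_profile(cuts, flipped, flank = 100L)
  expect_equal(pf$cut_rate, rev(prof$cut_rate))
})

test_that("source-size gating keeps only short-fragment cuts", {
  sites <- data.frame(rname = "chr1", start = 1000L, end = 1010L,
                      strand = "+", score = 1, relative_score = 1)
  attr(sites, "motif_width") <- 10L
  cuts <- data.frame(rname = "chr1", pos = c(999L, 998L), strand = "+",
                     source_size = c(60L, 150L))
  prof <- footprint_profile(cuts, sites)
  expect_equal(sum(prof$cut_rate), 1.0)        # 150-bp fragment excluded
  prof2 <- footprint_profile(cuts, sites, max_source_size = Inf)
  expect_equal(sum(prof2$cut_rate), 2.0)
})

test_that("simulated motif protection produces a footprint valley", {
  pfm <- toy_pfm()
  model <- library_model(n_fragments = 30000L, seed = 27L,
                         mito_fraction = 0, duplication_rate = 0,
                         protection = 0.1, tss_enrichment = 0,
                         class_weights = c(nf = 1, mono = 0, di = 0,
                                           tri = 0, background = 0))
  sim <- simulate_genome(2e5, motif = pfm, n_sites = 500L, n_tss = 10L,
                         seed = 27L)
  lib <- simulate_library(sim, model)
  cuts <- cut_sites(shift_reads(lib$alignments))
  sites <- scan_genome(sim$genome, pfm_to_pwm(pfm), 0.99)
  prof <- footprint_profile(cuts, sites)
  w <- attr(sites, "motif_width")
  core <- mean(prof$cut_rate[prof$position >= 0 & prof$position < w])
  flank <- mean(prof$cut_rate[prof$position < 0 | prof$position >= w])
  expect_lt(core, flank)
  expect_lt(abs(core / flank - 0.1), 0.05)
})
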
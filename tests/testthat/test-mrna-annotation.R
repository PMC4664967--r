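test_that("ORF prediction follows the first-AUG-with-stop rule", {
  orf <- find_orf("ATGAAATAA", min_cds_codons = 1L)
  expect_equal(orf[c("start", "stop_end", "cds_length")],
               list(start = 0L, stop_end = 9L, cds_length = 9L))
  expect_true(orf$complete)

  # first AUG two bases in
  orf <- find_orf(paste0("GG", "ATGGCT", strrep("GCA", 5), "TAA"),
                  min_cds_codons = 1L)
  expect_equal(orf$start, 2L)

  # ATG#1 without an in-frame stop: ATG#2 is selected
  body <- paste0("ATGG", "ATG", strrep("GCA", 10), "TAA")  # frame of ATG#1 open
  orf <- find_orf(body, min_cds_codons = 1L)
  brute <- oracle_orf(body, 1L)
  expect_equal(orf$start, brute$start)
  expect_equal(orf$stop_end, brute$stop_end)
  expect_true(orf$complete)

  # no ATG at all
  expect_null(find_orf("CCCCCCGGGTTT"))

  # no qualifying stop anywhere: frame-truncated open annotation
  orf <- find_orf(paste0("ATG", strrep("GCA", 4), "C"), min_cds_codons = 1L)
  expect_false(orf$complete)
  expect_equal(orf$start, 0L)
  expect_equal(orf$cds_length %% 3L, 0L)
})

test_that("ORF prediction agrees with brute-force enumeration", {
  set.seed(51)
  for (i in 1:400) {
    body <- paste(sample(c("A", "C", "G", "T"), sample(60:240, 1), TRUE),
                  collapse = "")
    got <- find_orf(body, min_cds_codons = 5L)
    want <- oracle_orf(body, 5L)
    if (is.null(want)) {
      expect_true(is.null(got) || !got$complete, info = body)
    } else {
      expect_equal(got$start, want$start, info = body)
      expect_equal(got$stop_end, want$stop_end, info = body)
      expect_equal(got$cds_length, want$cds, info = body)
    }
  }
})

test_that("poly(A) tail detection honours run length and purity", {
  base <- strrep("GCT", 41)
  expect_equal(detect_polya_tail(paste0(base, strrep("A", 20))),
               nchar(base))
  # a stop codon ending in A merges into the tail under the first-A rule
  expect_equal(detect_polya_tail(paste0(strrep("GCT", 40), "TAA",
                                        strrep("A", 20))), 121L)
  # below min_run
  expect_true(is.na(detect_polya_tail(paste0(base, "AAAAA"))))
  # one impurity inside a long tail is absorbed at purity 0.9
  body <- paste0(base, strrep("A", 10), "G", strrep("A", 10))
  expect_equal(detect_polya_tail(body), oracle_tail(body))
  # brute-force agreement on random A-rich suffixes
  set.seed(52)
  for (i in 1:200) {
    body <- paste0(
      paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = ""),
      paste(sample(c("A", "C"), sample(0:30, 1), TRUE, prob = c(.9, .1)),
            collapse = ""))
    expect_equal(detect_polya_tail(body), oracle_tail(body), info = body)
  }
})

test_that("polyadenylation signals are reported with cleavage offsets", {
  # signal ending 10 nt before the tail: offset 10, canonical
  u3 <- paste0(strrep("GCT", 10), "AATAAA", strrep("CT", 5))
  body <- paste0("ATG", strrep("GCA", 10), "TAA", u3, strrep("A", 20))
  stop_end <- 3L + 30L + 3L
  tail <- stop_end + nchar(u3)
  sig <- find_polya_signals(body, stop_end, tail)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$offset, 10L)
  expect_true(sig$in_canonical_range)

  # absence is an expected outcome
  expect_equal(nrow(find_polya_signals(body, stop_end, stop_end + 30L)), 0L)

  # multiple signals all reported in 5'->3' order
  u3 <- paste0("AATAAA", strrep("G", 20), "AATAAA", strrep("CT", 5))
  body <- paste0(strrep("C", 10), u3)
  sig <- find_polya_signals(body, 10L, 10L + nchar(u3))
  expect_equal(nrow(sig), 2L)
  expect_true(all(diff(sig$signal_start) > 0))
})

test_that("UTR delineation matches the SL-anchored definitions", {
  orf <- list(start = 24L, stop_end = 500L, cds_length = 476L,
              complete = TRUE)
  u <- delineate_utrs(strrep("N", 800), orf, 749L)
  expect_equal(u$utr5_length, 24L)
  expect_equal(u$utr3_length, 249L)
  orf0 <- list(start = 0L, stop_end = 9L, complete = TRUE)
  expect_equal(delineate_utrs("ATGAAATAAGG", orf0, 9L)$utr5_length, 0L)
  expect_error(delineate_utrs("ATGAAATAAGG", orf0, 5L), "inside the CDS")
})

test_that("Kozak profile recovers the consensus context", {
  expect_equal(kozak_profile(rep("AAAATGGCT", 12))$consensus, "AAAATGGCT")
  expect_equal(kozak_profile("GCCATGGAA")$consensus, "GCCATGGAA")
  # 60/40 split at position -3 resolves to the modal base
  ctx <- c(rep("AAAATGGCT", 6), rep("GAAATGGCT", 4))
  prof <- kozak_profile(ctx)
  expect_equal(substr(prof$consensus, 1, 1), "A")
  expect_equal(unname(prof$pfm["A", 1]), 0.6)
  expect_equal(unname(prof$pfm["G", 1]), 0.4)
  # ties become IUPAC codes
  prof <- kozak_profile(c("AAAATGGCT", "GAAATGGCT"))
  expect_equal(substr(prof$consensus, 1, 1), "R")
  expect_error(kozak_profile(NA_character_), "no qualifying")
})

test_that("homopolymer runs are maximal and thresholded", {
  s <- snr_analysis("CCAAAACC")
  expect_equal(nrow(s$runs), 1L)
  expect_equal(s$runs$base, "A")
  expect_equal(s$runs$start, 2L)
  expect_equal(s$runs$run_length, 4L)
  expect_equal(snr_analysis(strrep("A", 12))$max_run, 12L)
  expect_equal(nrow(snr_analysis("ACGTACGT")$runs), 0L)
  # sub-runs are never reported
  s <- snr_analysis("GGGGGTTTT", min_run = 4L)
  expect_equal(s$runs$run_length, c(5L, 4L))
})

test_that("GC content excludes ambiguous bases", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("AATT"), 0)
  expect_equal(gc_content("GCAT"), 0.5)
  expect_equal(gc_content("GCATNN"), 0.5)
  expect_error(gc_content("NNN"), "unambiguous")
})

test_that("codon usage tallies all codons including stops", {
  cu <- codon_usage("ATGAAATAA")
  expect_equal(sum(cu$count), 3L)
  expect_equal(cu$count[cu$codon %in% c("ATG", "AAA", "TAA")], rep(1L, 3))
  expect_equal(sum(cu$fraction), 1)
  # doubling the input doubles counts, fractions unchanged
  cu2 <- codon_usage(c("ATGAAATAA", "ATGAAATAA"))
  expect_equal(cu2$count, cu$count * 2L)
  expect_equal(cu2$fraction, cu$fraction)
  expect_error(codon_usage("ATGA"), "divisible")
  # random CDS against an independent sliding tally
  set.seed(53)
  cds <- paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")
  cu <- codon_usage(cds)
  manual <- table(substring(cds, seq(1, 898, 3), seq(3, 900, 3)))
  for (cd in names(manual))
    expect_equal(cu$count[cu$codon == cd], unname(as.integer(manual[cd])))
})

test_that("cRP checklist accounting matches the 79-member reference", {
  ref <- crp_reference()
  expect_equal(nrow(ref), 79L)
  expect_equal(sum(ref$subunit == "40S"), 32L)
  expect_equal(sum(ref$subunit == "60S"), 47L)
  full <- check_crp_completeness(ref$name)
  expect_equal(full$n_missing, 0L)
  # 70 detected -> 9 missing; 67 detected -> 12 missing
  expect_equal(check_crp_completeness(ref$name[1:70])$n_missing, 9L)
  expect_equal(check_crp_completeness(ref$name[1:67])$n_missing, 12L)
  # name normalisation: case and punctuation insensitive
  res <- check_crp_completeness(c("rps2", "RPL-3", "rpsA"))
  expect_true(all(c("RPS2", "RPL3", "RPSA") %in% res$detected))
  expect_error(check_crp_completeness("x", c("RPS2", "rps2")), "duplicate")
})

test_that("library summary uses population sd and recovers single cases", {
  cfg <- generator_config(seed = 61, n_sl_transcripts = 30,
                          n_contaminants = 0)
  g <- generate_transcriptome(cfg)
  trimmed <- g$records
  trimmed$seq <- substr(trimmed$seq, g$truth$leader_end + 1L,
                        nchar(trimmed$seq))
  lib <- annotate_library(trimmed)
  s <- summarize_library(lib$annotations, body_lengths = nchar(trimmed$seq))
  expect_equal(s$n, 30L)
  expect_equal(s$frac_complete_orf, 1)
  one <- summarize_library(lib$annotations[1, , drop = FALSE])
  expect_equal(one$cds_sd, 0)
  two <- summarize_library(data.frame(
    cds_length = c(100, 300), utr5 = c(0, 0), utr3 = c(0, 0),
    n_polya_signals = c(0L, 0L), complete = c(TRUE, TRUE),
    gc = c(.5, .5), tail_start = c(NA, NA), no_tail = c(TRUE, TRUE)))
  expect_equal(two$cds_mean, 200)
  expect_equal(two$cds_sd, 100)   # population sd, divide by n
})

test_that("annotation reconstructs the SL-trimmed body exactly", {
  cfg <- generator_config(seed = 62, n_sl_transcripts = 60,
                          n_contaminants = 0)
  g <- generate_transcriptome(cfg)
  for (i in seq_len(nrow(g$truth))) {
    tr <- g$truth[i, ]
    body <- substr(g$records$seq[i], tr$leader_end + 1L,
                   nchar(g$records$seq[i]))
    a <- annotate_transcript(body)
    expect_equal(a$utr5, tr$utr5)
    expect_equal(a$cds_length, tr$cds_length)
    expect_equal(a$utr3, tr$utr3)
    expect_equal(a$tail_start, tr$tail_start)
    tail_len <- nchar(body) - a$tail_start
    expect_equal(a$utr5 + a$cds_length + a$utr3 + tail_len, nchar(body))
  }
})
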
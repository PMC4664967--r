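test_that("SL exon location finds planted copies on both strands", {
  set.seed(71)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  g <- paste0(rand(200), sl_instance(), rand(200))
  hits <- locate_sl_exons(g, copepod_sl())
  expect_equal(hits$start, 200L)
  expect_equal(hits$strand, "+")

  # three copies 250 nt apart
  g3 <- paste0(rand(100), sl_instance(), rand(204), sl_instance(),
               rand(204), sl_instance(), rand(100))
  hits <- locate_sl_exons(g3, copepod_sl())
  expect_equal(hits$start, c(100L, 350L, 600L))

  # reverse-complemented copy reports the minus strand
  gm <- paste0(rand(150), reverse_complement(sl_instance()), rand(150))
  hits <- locate_sl_exons(gm, copepod_sl())
  expect_equal(hits$start, 150L)
  expect_equal(hits$strand, "-")
})

test_that("Sm-site search matches the purine-flanked tract definition", {
  h <- find_sm_site("AGTTCCAG")
  expect_equal(nrow(h), 1L)
  expect_equal(h$tract_length, 4L)
  expect_equal(h$interruptions, 0L)
  expect_equal(c(h$start, h$end), c(0L, 8L))

  # a 12-nt tract with one internal A interruption
  h <- find_sm_site("GATTTCTATTTCTTGG")
  expect_equal(h$tract_length[1], 12L)
  expect_equal(h$interruptions[1], 1L)

  # no flanking purine pairs, no hit
  expect_equal(nrow(find_sm_site("CCCCCCCC")), 0L)
})

test_that("Sm-site search agrees with a brute-force enumerator", {
  set.seed(72)
  for (i in 1:60) {
    s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    got <- find_sm_site(s)
    want <- oracle_sm_sites(s)
    # every reported hit exists in the enumeration
    if (nrow(got) > 0) {
      key_got <- paste(got$start, got$end)
      key_want <- paste(want$start, want$end)
      expect_true(all(key_got %in% key_want), info = s)
      # and the best tract length matches the enumerator's maximum
      expect_equal(max(got$tract_length), max(want$tract_length), info = s)
    } else {
      # enumeration may retain contained spans; maximal-filter both sides
      expect_equal(nrow(want), 0L, info = s)
    }
  }
})

test_that("unit annotation composes exon, donor, Sm site and QC flags", {
  set.seed(73)
  intron62 <- paste0("GTAA", slsplice:::.constrained_seq(20),
                     "AGTTTCCTTCAG", slsplice:::.constrained_seq(26))
  expect_equal(nchar(intron62), 62L)
  g <- paste0(sl_instance(), intron62,
              paste(sample(c("A", "G"), 80, TRUE), collapse = ""))
  hit <- data.frame(start = 0L, end = 46L)
  m <- annotate_slrna_unit(g, hit, intron_end = 46L + 62L)
  expect_equal(m$exon_length, 46L)
  expect_equal(m$intron_length, 62L)
  expect_true(m$donor_ok)
  expect_length(m$qc_flags, 0L)
  expect_equal(m$exon_length + m$intron_length, 108L)

  # intron starting AT: donor flagged
  g2 <- paste0(sl_instance(), "AT", substr(intron62, 3, 62))
  m2 <- annotate_slrna_unit(g2, hit, intron_end = nchar(g2))
  expect_false(m2$donor_ok)
  expect_true("donor_missing" %in% m2$qc_flags)

  # 130-nt intron: out-of-range flag raised but the model is returned
  long_intron <- paste0("GTAA", slsplice:::.constrained_seq(40),
                        "AGTTTCCTTCAG", slsplice:::.constrained_seq(74))
  g3 <- paste0(sl_instance(), long_intron)
  m3 <- annotate_slrna_unit(g3, hit, intron_end = 46L + 130L)
  expect_equal(m3$intron_length, 130L)
  expect_true("intron_length_out_of_range" %in% m3$qc_flags)
})

test_that("QC flags fire exactly outside the observed ranges", {
  for (exon_len in seq(40L, 50L, by = 2L)) {
    for (intron_len in seq(55L, 120L, by = 5L)) {
      flags <- slsplice:::.qc_flags(exon_len, intron_len, TRUE, TRUE)
      expect_equal("exon_length_out_of_range" %in% flags,
                   exon_len < 44L || exon_len > 47L)
      expect_equal("intron_length_out_of_range" %in% flags,
                   intron_len < 62L || intron_len > 111L)
    }
  }
})

test_that("slRNA transcript classification conserves length", {
  mk <- function(exon_len, intron_len) {
    exon <- slsplice:::.make_exon_variant(sl_instance(), exon_len)
    set.seed(74)
    intron <- paste0("GTAA", slsplice:::.constrained_seq(intron_len - 40L),
                     "AGTTCCTTTCAG",
                     slsplice:::.constrained_seq(24L))
    list(id = "s", seq = paste0(exon, intron))
  }
  t1 <- mk(46L, 62L)
  m <- classify_slrna_transcript(t1, copepod_sl())
  expect_equal(m$exon_length, 46L)
  expect_equal(m$intron_length, 62L)
  expect_equal(m$slrna_length, 108L)
  expect_equal(m$slrna_length, nchar(t1$seq))

  t2 <- mk(47L, 111L)
  m <- classify_slrna_transcript(t2, copepod_sl())
  expect_equal(m$slrna_length, 158L)
  expect_length(m$qc_flags, 0L)

  # a 44-nt exon variant is accepted without a flag
  t3 <- mk(44L, 70L)
  m <- classify_slrna_transcript(t3, copepod_sl())
  expect_equal(m$exon_length, 44L)
  expect_false("exon_length_out_of_range" %in% m$qc_flags)

  # a transcript without an SL is rejected with a reason
  expect_warning(
    out <- classify_slrna_transcript(list(id = "x", seq = strrep("ACGT", 40)),
                                     copepod_sl()),
    "no SL")
  expect_null(out)
})

test_that("array layout separates tandem, 5S-clustered and singleton", {
  cfg <- generator_config(seed = 75)
  g <- generate_slrna_array(cfg, n_sequences = 1)
  gseq <- g$records$seq[1]
  hits <- locate_sl_exons(gseq, copepod_sl())
  hits <- hits[hits$strand == "+", ]
  models <- lapply(seq_len(nrow(hits)),
                   function(h) annotate_slrna_unit(gseq, hits[h, ]))
  lay <- detect_array_layout(gseq, hits, models)
  expect_equal(lay$cluster_type, "tandem")
  expect_equal(lay$unit_starts, g$truth$exon_start)
  expect_equal(lay$inter_unit_distances, diff(g$truth$exon_start))

  cfg1 <- generator_config(seed = 76, slrna = list(n_units = 1L,
                                                   p_5s_cluster = 1))
  g1 <- generate_slrna_array(cfg1)
  h1 <- locate_sl_exons(g1$records$seq[1], copepod_sl())
  lay1 <- detect_array_layout(g1$records$seq[1],
                              h1[h1$strand == "+", ])
  expect_equal(lay1$cluster_type, "fiveS_clustered")

  cfg2 <- generator_config(seed = 77, slrna = list(n_units = 1L))
  g2 <- generate_slrna_array(cfg2)
  h2 <- locate_sl_exons(g2$records$seq[1], copepod_sl())
  lay2 <- detect_array_layout(g2$records$seq[1],
                              h2[h2$strand == "+", ])
  expect_equal(lay2$cluster_type, "singleton")
})

test_that("planted arrays are recovered exactly from generator output", {
  for (seed in c(81, 82, 83)) {
    cfg <- generator_config(seed = seed,
                            slrna = list(n_units = sample(2:6, 1)))
    g <- generate_slrna_array(cfg, n_sequences = 2)
    for (sid in unique(g$truth$record_id)) {
      gseq <- g$records$seq[g$records$id == sid]
      tr <- g$truth[g$truth$record_id == sid, ]
      hits <- locate_sl_exons(gseq, copepod_sl())
      hits <- hits[hits$strand == "+", ]
      expect_equal(hits$start, tr$exon_start)
      for (u in seq_len(nrow(hits))) {
        m <- annotate_slrna_unit(gseq, hits[u, ])
        expect_equal(m$exon_length, tr$exon_length[u])
        expect_true(m$donor_ok)
        expect_equal(m$sm_site_span[1], tr$sm_start[u])
        expect_equal(m$sm_site_span[2], tr$sm_end[u])
        expect_equal(m$intron_length, tr$intron_length[u])
      }
    }
  }
})
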
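make_rec <- function(seq, id = "t1") list(id = id, seq = seq)

test_that("full SL matching tolerates extensions and respects thresholds", {
  set.seed(31)
  down <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  m <- match_sl(make_rec(paste0(sl_instance(), down)), copepod_sl())
  expect_equal(m$leader_start, 0L)
  expect_equal(m$mismatches, 0L)
  expect_equal(m$five_prime_extension, "")

  # the ATT 5' extension shifts the leader by three
  m <- match_sl(make_rec(paste0("ATT", sl_instance(), down)), copepod_sl())
  expect_equal(m$leader_start, 3L)
  expect_equal(m$leader_end, 49L)
  expect_equal(m$five_prime_extension, "ATT")

  # random transcript: no match at the default threshold
  expect_null(match_sl(make_rec(down), copepod_sl()))

  # exact substitution-count threshold: 2 accepted, 3 rejected
  lead <- strsplit(sl_instance(), "")[[1]]
  flip <- function(ch) setdiff(c("A", "C", "G", "T"), ch)[1]
  for (k in 0:3) {
    mut <- lead
    # positions chosen at concrete (non-degenerate) consensus positions
    pos <- c(2, 4, 10)[seq_len(k)]
    for (p in pos) mut[p] <- flip(mut[p])
    rec <- make_rec(paste0(paste(mut, collapse = ""), down))
    m <- match_sl(rec, copepod_sl(), max_mismatch = 2L)
    if (k <= 2) expect_equal(m$mismatches, k) else expect_null(m)
  }
})

test_that("degenerate consensus positions match their expansion at no cost", {
  down <- strrep("CGCG", 40)
  # W -> T instead of A everywhere, Y -> T: still zero mismatches
  inst <- chartr("WY", "TT", copepod_sl())
  m <- match_sl(make_rec(paste0(inst, down)), copepod_sl())
  expect_equal(m$mismatches, 0L)
})

test_that("partial matching anchors consensus suffixes at position 0", {
  set.seed(32)
  down <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  inst <- sl_instance()
  # transcript beginning with the last 20 nt of the leader
  rec <- make_rec(paste0(substr(inst, 27, 46), down))
  m <- match_sl_partial(rec, copepod_sl())
  expect_equal(m$mode, "partial")
  expect_equal(m$matched_length, 20L)
  expect_equal(m$leader_start, 0L)

  # full leader at position 0 is the limit case: whole consensus matched
  m <- match_sl_partial(make_rec(paste0(inst, down)), copepod_sl())
  expect_equal(m$matched_length, 46L)

  # leader PREFIX (not suffix) must not match; brute-force over all
  # suffix alignments confirms none qualifies
  rec <- make_rec(paste0(substr(inst, 1, 20), down))
  expect_null(match_sl_partial(rec, copepod_sl()))
  cons_chars <- strsplit(copepod_sl(), "")[[1]]
  tr_chars <- strsplit(rec$seq, "")[[1]]
  brute_any <- any(vapply(15:46, function(len) {
    suf <- cons_chars[(46 - len + 1):46]
    sum(!iupac_match(suf, tr_chars[1:len])) <= 2
  }, logical(1)))
  expect_false(brute_any)
})

test_that("trimming removes extension plus leader and preserves length", {
  down <- strrep("ACGTT", 60)
  rec <- seq_records("x", paste0("ATT", sl_instance(), down))
  m <- match_sl(rec, copepod_sl())
  tr <- trim_sl(rec, m)
  expect_equal(tr$seq, down)
  expect_equal(nchar(tr$seq) + m$leader_end, nchar(rec$seq))
  expect_equal(tr$leader, paste0("ATT", sl_instance()))

  # leader-only record is excluded with a warning
  lead_only <- seq_records("y", sl_instance())
  m2 <- match_sl(lead_only, copepod_sl())
  expect_warning(out <- trim_sl(lead_only, m2), "leader only")
  expect_null(out)
  expect_error(trim_sl(rec, m2), "does not belong")
})

test_that("screening partitions a dataset into full/partial/none", {
  cfg <- generator_config(seed = 41, n_sl_transcripts = 80,
                          n_contaminants = 20)
  g <- generate_transcriptome(cfg)
  scr <- screen_dataset(g$records, copepod_sl())
  expect_equal(unname(scr$summary["full"]), 80L)
  expect_equal(unname(scr$summary["none"]), 20L)
  expect_equal(sum(scr$summary), nrow(g$records))
  expect_equal(nrow(scr$per_record), nrow(g$records))

  # empty dataset
  empty <- screen_dataset(seq_records(character(0), character(0)),
                          copepod_sl())
  expect_true(all(empty$summary == 0L))

  # truncated transcripts are recovered in partial mode
  set.seed(42)
  inst <- sl_instance()
  trunc <- vapply(1:10, function(i) {
    keep <- sample(18:30, 1)
    paste0(substr(inst, 46 - keep + 1, 46),
           paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = ""))
  }, character(1))
  scr <- screen_dataset(seq_records(sprintf("p%02d", 1:10), trunc),
                        copepod_sl())
  expect_equal(unname(scr$summary["partial"]), 10L)
})

test_that("no full matches arise in contaminant-only data", {
  recs <- random_records(2000, len = 300L, seed = 43)
  scr <- screen_dataset(recs, copepod_sl(), partial = FALSE)
  expect_equal(unname(scr$summary["full"]), 0L)
})

test_that("rarefaction expectation matches theory and Monte-Carlo", {
  # all clones distinct: the diagonal
  e <- rarefaction_curve(letters[1:8], 1:8)
  expect_equal(e$expected_genes, as.numeric(1:8))

  # a single draw always yields exactly one gene
  e <- rarefaction_curve(rep(c("a", "b"), c(9, 1)), 1)
  expect_equal(e$expected_genes, 1)

  # {5,3,2} at n = 4 against 100k Monte-Carlo resamples
  labs <- rep(c("g1", "g2", "g3"), c(5, 3, 2))
  e <- rarefaction_curve(labs, 4)$expected_genes
  set.seed(44)
  mc <- mean(vapply(1:100000,
                    function(i) length(unique(sample(labs, 4))),
                    numeric(1)))
  expect_lt(abs(e - mc), 0.01)

  # monotone, and the full sample recovers all distinct labels
  full <- rarefaction_curve(labs, 1:10)
  expect_true(all(diff(full$expected_genes) >= 0))
  expect_equal(full$expected_genes[10], 3)
  expect_error(rarefaction_curve(labs, 11), "grid")
})
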
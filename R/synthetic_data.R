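# Synthetic SL-trans-spliced transcriptomes, slRNA gene arrays and
# structured slRNA sequences, with full truth tables.
#
# The generator emulates the statistical structure of copepod full-length
# cDNA libraries: a 46-nt leader spliced onto every SL+ transcript
# (optionally behind a 3-nt ATT extension), short 5' UTRs (24 +/- 36 nt)
# and long 3' UTRs (249 +/- 209 nt), an AAAATGGCT Kozak context, AATAAA
# polyadenylation signals 7-20 nt upstream of cleavage in about half of
# transcripts, poly(A) tails, A-dominated homopolymer runs and ~46% GC.
# Sequences are built so that noise-free annotation recovers every truth
# coordinate exactly: decoy motifs (upstream ATGs, stray AATAAA, competing
# Sm tracts) are scrubbed out with the package's own detectors, and the
# last bases of the 3' UTR are kept A-free so the tail start is unambiguous
# under the purity rule.

#' Generator configuration
#'
#' Defaults encode the study conditions the generator emulates; see the
#' methods vignette for the rationale behind each value.
#'
#' @param seed Integer seed (mandatory; all outputs are deterministic
#'   given the config).
#' @param n_sl_transcripts,n_contaminants Library composition.
#' @param leader Concrete leader sequence (default: the CopepodSL
#'   consensus instantiated with W->A, Y->C).
#' @param leader_sub_rate Per-position substitution probability applied to
#'   each transcript's leader copy.
#' @param p_att_extension Probability of a 5' ATT extension.
#' @param utr5_mean,utr5_sd,utr3_mean,utr3_sd UTR length distributions
#'   (truncated normals; negatives resampled, 3' UTR floored at 10 nt).
#' @param cds_codons_mean,cds_codons_sd CDS length in codons (ATG and stop
#'   included), floored at 40 codons.
#' @param kozak_seed 9-nt Kozak context seeded into each transcript.
#' @param context_noise Per-base substitution probability on the six
#'   non-ATG context positions.
#' @param p_polya_signal Probability of an AATAAA signal (default 0.5).
#' @param signal_offset_range Distance from signal end to cleavage (7-20).
#' @param tail_length_range Poly(A) tail length range.
#' @param gc_target Background GC fraction (default 0.46).
#' @param snr_boost Probability of injecting an A-run (5-12 nt) into the
#'   3' UTR.
#' @param slrna List of slRNA-unit parameters: `n_units`,
#'   `exon_length_choices` (weighted to 46), `exon_length_weights`,
#'   `intron_length_range`, `sm_tract_range`, `spacer_range`,
#'   `p_5s_cluster`.
#' @return Validated config list of class `sl_generator_config`.
#' @export
generator_config <- function(seed,
                             n_sl_transcripts = 100L,
                             n_contaminants = 30L,
                             leader = copepod_sl(concrete = TRUE),
                             leader_sub_rate = 0,
                             p_att_extension = 0.09,
                             utr5_mean = 24, utr5_sd = 36,
                             utr3_mean = 249, utr3_sd = 209,
                             cds_codons_mean = 184, cds_codons_sd = 124,
                             kozak_seed = "AAAATGGCT",
                             context_noise = 0.1,
                             p_polya_signal = 0.5,
                             signal_offset_range = c(7L, 20L),
                             tail_length_range = c(15L, 40L),
                             gc_target = 0.46,
                             snr_boost = 0.3,
                             slrna = list()) {
  if (missing(seed)) stop("seed is mandatory")
  slrna_defaults <- list(
    n_units = 3L,
    exon_length_choices = 44:47,
    exon_length_weights = c(0.05, 0.05, 0.80, 0.10),
    intron_length_range = c(62L, 111L),
    sm_tract_range = c(6L, 12L),
    spacer_range = c(50L, 400L),
    p_5s_cluster = 0
  )
  slrna <- utils::modifyList(slrna_defaults, slrna)
  cfg <- list(seed = as.integer(seed),
              n_sl_transcripts = as.integer(n_sl_transcripts),
              n_contaminants = as.integer(n_contaminants),
              leader = toupper(leader),
              leader_sub_rate = leader_sub_rate,
              p_att_extension = p_att_extension,
              utr5_mean = utr5_mean, utr5_sd = utr5_sd,
              utr3_mean = utr3_mean, utr3_sd = utr3_sd,
              cds_codons_mean = cds_codons_mean,
              cds_codons_sd = cds_codons_sd,
              kozak_seed = toupper(kozak_seed),
              context_noise = context_noise,
              p_polya_signal = p_polya_signal,
              signal_offset_range = as.integer(signal_offset_range),
              tail_length_range = as.integer(tail_length_range),
              gc_target = gc_target,
              snr_boost = snr_boost,
              slrna = slrna)
  probs <- c(cfg$leader_sub_rate, cfg$p_att_extension, cfg$context_noise,
             cfg$p_polya_signal, cfg$snr_boost, cfg$slrna$p_5s_cluster)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (substr(cfg$kozak_seed, 4L, 6L) != "ATG")
    stop("kozak_seed positions 4-6 must be ATG")
  if (diff(cfg$signal_offset_range) < 0 || diff(cfg$tail_length_range) < 0)
    stop("ranges must be non-empty")
  if (cfg$gc_target <= 0 || cfg$gc_target >= 1) stop("gc_target must be in (0,1)")
  class(cfg) <- "sl_generator_config"
  cfg
}

# sample() treats a scalar first argument as 1:x; this wrapper never does
.sample1 <- function(x, prob = NULL) {
  if (length(x) == 1L) return(x)
  sample(x, 1L, prob = prob)
}

# truncated-normal sampler: resample until >= lower
.rtrunc_norm <- function(n, mean, sd, lower = 0) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lower
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

.random_seq <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# replace every occurrence of a motif by mutating one interior base;
# repeats until the motif is gone
.scrub_motif <- function(seq, motif, replacement_base = "C") {
  repeat {
    hit <- regexpr(motif, seq, fixed = TRUE)
    if (hit == -1L) return(seq)
    pos <- as.integer(hit) + 1L  # second base of the occurrence
    sub_base <- if (substr(seq, pos, pos) == replacement_base) "G"
                else replacement_base
    substr(seq, pos, pos) <- sub_base
  }
}

# remove every motif occurrence except the one starting at keep_start
# (0-based); occurrences overlapping the kept copy are mutated at a base
# outside the kept span
.scrub_motif_except <- function(seq, motif, keep_start) {
  m <- nchar(motif)
  repeat {
    hits <- gregexpr(sprintf("(?=%s)", motif), seq, perl = TRUE)[[1]]
    if (hits[1] == -1L) return(seq)
    hits <- as.integer(hits) - 1L            # 0-based
    hits <- hits[hits != keep_start]
    if (length(hits) == 0L) return(seq)
    q <- hits[1]
    pos <- if (q < keep_start) q + 1L         # first base (1-based)
           else q + m                         # last base (1-based)
    cur <- substr(seq, pos, pos)
    substr(seq, pos, pos) <- if (cur == "G") "C" else "G"
  }
}

.mutate_positions <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n_sub = 0L))
  chars <- .seq_chars(seq)
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  list(seq = paste(chars, collapse = ""), n_sub = length(hit))
}

# weighted codon sampler over the 61 sense codons, biased toward gc_target
.sense_codon_pool <- function(gc_target) {
  codons <- setdiff(.all_codons(), .STOP_CODONS)
  w <- vapply(codons, function(cd) {
    gc_n <- sum(.seq_chars(cd) %in% c("G", "C"))
    (gc_target)^gc_n * (1 - gc_target)^(3 - gc_n)
  }, numeric(1))
  list(codons = codons, weights = w / sum(w))
}

#' Generate a synthetic SL-trans-spliced transcriptome with truth table
#'
#' Each SL+ transcript is `[ATT?] + leader + 5'UTR + CDS + 3'UTR + poly(A)`;
#' contaminants are random-composition transcripts without a leader.
#' Deterministic under a fixed config.
#'
#' @param config From [generator_config()].
#' @return List with `records` (record table) and `truth` (data.frame; one
#'   row per record; coordinates of ORF/UTRs/signals/tail are 0-based on
#'   the SL-trimmed body, leader coordinates on the full transcript).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sl_generator_config"))
  set.seed(config$seed)
  pool <- .sense_codon_pool(config$gc_target)
  n_sl <- config$n_sl_transcripts
  n_cont <- config$n_contaminants
  n_genes <- max(1L, ceiling(0.6 * n_sl))
  gene_weights <- 1 / seq_len(n_genes)
  ids <- character(0)
  seqs <- character(0)
  truth <- vector("list", n_sl + n_cont)
  for (i in seq_len(n_sl)) {
    ext <- if (stats::runif(1) < config$p_att_extension) "ATT" else ""
    leader <- .mutate_positions(config$leader, config$leader_sub_rate)

    utr5_len <- as.integer(round(.rtrunc_norm(1, config$utr5_mean,
                                              config$utr5_sd, 0)))
    utr5 <- .random_seq(utr5_len, config$gc_target)
    if (utr5_len > 0L) utr5 <- .scrub_motif(utr5, "ATG")
    if (utr5_len >= 3L) {
      ctx <- .seq_chars(substr(config$kozak_seed, 1L, 3L))
      noise <- stats::runif(3) < config$context_noise
      for (p in which(noise))
        ctx[p] <- sample(setdiff(c("A", "C", "G", "T"), ctx[p]), 1L)
      ctx <- paste(ctx, collapse = "")
      if (ctx == "ATG") ctx <- substr(config$kozak_seed, 1L, 3L)
      substr(utr5, utr5_len - 2L, utr5_len) <- ctx
      utr5 <- .scrub_motif(utr5, "ATG")
    }

    n_codons <- max(40L, as.integer(round(.rtrunc_norm(
      1, config$cds_codons_mean, config$cds_codons_sd, 40))))
    body_codons <- sample(pool$codons, n_codons - 2L, replace = TRUE,
                          prob = pool$weights)
    first <- .seq_chars(substr(config$kozak_seed, 7L, 9L))
    noise <- stats::runif(3) < config$context_noise
    for (p in which(noise))
      first[p] <- sample(setdiff(c("A", "C", "G", "T"), first[p]), 1L)
    first <- paste(first, collapse = "")
    if (first %in% .STOP_CODONS) first <- substr(config$kozak_seed, 7L, 9L)
    body_codons[1] <- first
    cds <- paste0("ATG", paste(body_codons, collapse = ""),
                  sample(.STOP_CODONS, 1L))

    utr3_len <- max(10L, as.integer(round(.rtrunc_norm(
      1, config$utr3_mean, config$utr3_sd, 10))))
    utr3 <- .random_seq(utr3_len, config$gc_target)
    if (stats::runif(1) < config$snr_boost && utr3_len >= 30L) {
      run_len <- sample(5:12, 1L)
      at <- sample.int(utr3_len - run_len - 15L, 1L)
      substr(utr3, at, at + run_len - 1L) <- strrep("A", run_len)
    }
    utr3 <- .scrub_motif(utr3, "AATAAA", replacement_base = "G")
    signal_pos <- integer(0)
    offsets <- config$signal_offset_range[1]:config$signal_offset_range[2]
    offsets <- offsets[offsets + 6L <= utr3_len]
    if (length(offsets) > 0L && stats::runif(1) < config$p_polya_signal) {
      offset <- .sample1(offsets)
      s0 <- utr3_len - offset - 6L          # 0-based start within utr3
      substr(utr3, s0 + 1L, s0 + 6L) <- "AATAAA"
      # planting next to an A can create overlapping occurrences
      utr3 <- .scrub_motif_except(utr3, "AATAAA", s0)
      signal_pos <- s0
    }
    # keep the last 10 nt of the 3' UTR A-free (sparing a planted signal)
    # so the first A of the tail is unambiguous under the purity rule
    pad_start <- max(1L, utr3_len - 9L)
    pad_idx <- pad_start:utr3_len
    if (length(signal_pos) > 0L) {
      sig_idx <- (signal_pos + 1L):(signal_pos + 6L)
      pad_idx <- setdiff(pad_idx, sig_idx)
    }
    for (pi in pad_idx) {
      if (substr(utr3, pi, pi) == "A")
        substr(utr3, pi, pi) <- sample(c("C", "G", "T"), 1L)
    }

    tail_len <- .sample1(config$tail_length_range[1]:config$tail_length_range[2])
    body <- paste0(utr5, cds, utr3, strrep("A", tail_len))
    full <- paste0(ext, leader$seq, body)
    id <- sprintf("sl_%04d", i)
    ids <- c(ids, id)
    seqs <- c(seqs, full)
    leader_start <- nchar(ext)
    truth[[i]] <- data.frame(
      record_id = id, is_sl = TRUE,
      leader_start = leader_start,
      leader_end = leader_start + nchar(leader$seq),
      leader_substitutions = leader$n_sub,
      extension = ext,
      orf_start = utr5_len,
      cds_length = nchar(cds),
      utr5 = utr5_len, utr3 = utr3_len,
      signal_positions = paste(utr5_len + nchar(cds) + signal_pos,
                               collapse = ","),
      tail_start = utr5_len + nchar(cds) + utr3_len,
      gene_label = paste0("g", sample.int(n_genes, 1L, prob = gene_weights)),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_cont)) {
    id <- sprintf("cont_%04d", i)
    len <- sample(200:1000, 1L)
    ids <- c(ids, id)
    seqs <- c(seqs, .random_seq(len, 0.5))
    truth[[n_sl + i]] <- data.frame(
      record_id = id, is_sl = FALSE,
      leader_start = NA_integer_, leader_end = NA_integer_,
      leader_substitutions = NA_integer_, extension = NA_character_,
      orf_start = NA_integer_, cds_length = NA_integer_,
      utr5 = NA_integer_, utr3 = NA_integer_,
      signal_positions = NA_character_, tail_start = NA_integer_,
      gene_label = NA_character_, stringsAsFactors = FALSE)
  }
  list(records = seq_records(ids, seqs),
       truth = do.call(rbind, truth))
}

#' Generate synthetic genomic slRNA arrays with truth table
#'
#' Each sequence is flank + n_units x (exon + GT-initiated intron carrying
#' a planted Sm site 20 nt before the unit end + spacer), optionally with
#' the 5S rDNA probe inserted into one spacer. Intron filler is scrubbed of
#' competing Sm-like motifs so the planted site is the unique best hit.
#'
#' @param config From [generator_config()]; uses the `slrna` sub-list.
#' @param n_sequences Number of independent array sequences.
#' @return List with `records` and `truth` (one row per unit; coordinates
#'   0-based on the containing sequence).
#' @export
generate_slrna_array <- function(config, n_sequences = 1L) {
  stopifnot(inherits(config, "sl_generator_config"))
  set.seed(config$seed + 1L)
  p <- config$slrna
  ids <- character(0)
  seqs <- character(0)
  truth <- list()
  for (s in seq_len(n_sequences)) {
    id <- sprintf("slrna_array_%03d", s)
    parts <- .random_seq(sample(100:200, 1L), config$gc_target)
    has_5s <- stats::runif(1) < p$p_5s_cluster
    five_s_in <- if (has_5s && p$n_units >= 1L) sample.int(p$n_units, 1L) else 0L
    cluster_type <- if (has_5s) "fiveS_clustered"
                    else if (p$n_units >= 2L) "tandem" else "singleton"
    for (u in seq_len(p$n_units)) {
      exon_len <- .sample1(p$exon_length_choices, prob = p$exon_length_weights)
      exon <- .make_exon_variant(config$leader, exon_len)
      intron_len <- .sample1(p$intron_length_range[1]:p$intron_length_range[2])
      tract_len <- .sample1(p$sm_tract_range[1]:p$sm_tract_range[2])
      sm_motif <- paste0("AG", paste(sample(c("C", "T"), tract_len,
                                            replace = TRUE), collapse = ""),
                         "AG")
      sm_len <- nchar(sm_motif)
      # intron layout: GT + AA + filler + Sm + 20-nt tail; filler, tail and
      # spacer carry only isolated pyrimidines so the planted Sm site is the
      # unique tract of length >= 4 in the scanned region
      filler_len <- intron_len - 2L - 2L - sm_len - 20L
      if (filler_len < 0L)
        stop("intron too short for the Sm layout; widen intron_length_range")
      filler <- .constrained_seq(filler_len)
      tail20 <- .constrained_seq(20L)
      intron <- paste0("GT", "AA", filler, sm_motif, tail20)
      exon_start <- nchar(parts)
      spacer_len <- .sample1(p$spacer_range[1]:p$spacer_range[2])
      spacer <- .constrained_seq(spacer_len)
      if (u == five_s_in) {
        at <- max(1L, spacer_len %/% 2L)
        probe <- "TACTTGGATGGGTGACCGCC"
        spacer <- paste0(substr(spacer, 1L, at), probe,
                         substr(spacer, at + 1L, spacer_len))
      }
      parts <- paste0(parts, exon, intron, spacer)
      sm_start <- exon_start + exon_len + 2L + 2L + filler_len
      truth[[length(truth) + 1L]] <- data.frame(
        record_id = id, unit = u,
        exon_start = exon_start, exon_end = exon_start + exon_len,
        exon_length = exon_len,
        intron_length = intron_len,
        unit_end = exon_start + exon_len + intron_len,
        sm_start = sm_start, sm_end = sm_start + sm_len,
        sm_tract_length = tract_len,
        cluster_type = cluster_type,
        stringsAsFactors = FALSE)
    }
    ids <- c(ids, id)
    seqs <- c(seqs, parts)
  }
  list(records = seq_records(ids, seqs), truth = do.call(rbind, truth))
}

# exon-length variants: 44/45 truncate the leader 3' end, 47 appends a
# non-G base (so GT-donor refinement stays unambiguous)
.make_exon_variant <- function(leader, exon_len) {
  L <- nchar(leader)
  if (exon_len <= L) return(substr(leader, 1L, exon_len))
  paste0(leader, strrep("A", exon_len - L))
}

# random sequence with only isolated pyrimidines (never two in a row) and
# purine first/last bases: such a segment cannot contain a pyrimidine tract
# of length >= 4 with at most one internal purine, not even across segment
# boundaries, so it never competes with a planted Sm site
.constrained_seq <- function(n) {
  if (n <= 0L) return("")
  out <- character(n)
  prev_pyr <- TRUE                 # forces a purine first base
  for (i in seq_len(n)) {
    force_pur <- prev_pyr || i == n
    if (force_pur) {
      out[i] <- sample(c("A", "G"), 1L)
      prev_pyr <- FALSE
    } else {
      b <- sample(c("A", "G", "C", "T"), 1L, prob = c(0.3, 0.25, 0.25, 0.2))
      out[i] <- b
      prev_pyr <- b %in% c("C", "T")
    }
  }
  paste(out, collapse = "")
}

#' Generate slRNA sequences with a designed secondary structure
#'
#' Sequences are built from a dot-bracket template: two exon hairpins, a
#' hairpin spanning the exon/intron boundary (enclosing the GU donor), a
#' downstream intron hairpin, a single-stranded Sm tract, and a 3'
#' hairpin. Letters are role-coded so that base-pair maximization
#' reproduces the designed topology: stem 5' arms are purine (A),
#' 3' arms pyrimidine (T), loops and single-stranded regions C, the Sm
#' tract C with AA flanks. The exon region of these sequences is therefore
#' a structural scaffold, not a CopepodSL copy; the generator targets the
#' structure classifier, not SL matching.
#'
#' @param config From [generator_config()] (seed and sampling only).
#' @param n_sequences Number of sampled sequences.
#' @return List with `records`, `truth` (exon/intron lengths, Sm span,
#'   designed dot-bracket) and `models` (list of `slrna_gene_model`-shaped
#'   lists usable with [classify_slrna_structure()]).
#' @export
generate_structured_slrna <- function(config, n_sequences = 10L) {
  stopifnot(inherits(config, "sl_generator_config"))
  set.seed(config$seed + 2L)
  ids <- character(0)
  seqs <- character(0)
  dbs <- character(0)
  models <- vector("list", n_sequences)
  truth <- vector("list", n_sequences)
  for (s in seq_len(n_sequences)) {
    geom <- list(s1 = sample(4:6, 1L), l1 = sample(3:5, 1L),
                 s2 = sample(4:6, 1L), l2 = sample(3:5, 1L),
                 s3 = sample(5:7, 1L),
                 s4 = sample(4:6, 1L), l4 = sample(3:5, 1L),
                 s5 = sample(4:6, 1L), l5 = sample(3:5, 1L),
                 tract = sample(10:12, 1L),
                 intron_target = sample(62:90, 1L))
    built <- .build_structured_slrna(geom)
    id <- sprintf("slrna_struct_%03d", s)
    ids <- c(ids, id)
    seqs <- c(seqs, built$seq)
    dbs <- c(dbs, built$dotbracket)
    models[[s]] <- built$model
    truth[[s]] <- data.frame(
      record_id = id, exon_length = built$model$exon_length,
      intron_length = built$model$intron_length,
      sm_start = built$model$sm_site_span[1],
      sm_end = built$model$sm_site_span[2],
      dotbracket = built$dotbracket, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  list(records = seq_records(ids, seqs), truth = truth, models = models)
}

# Assemble one structured slRNA from stem/loop geometry; exon fixed 46 nt.
#
# Letter coding makes the designed fold the unique base-pair maximum up to
# the package's deterministic tie-breaks: every A sits in a stem arm with a
# designed U partner (so stranding an arm is strictly suboptimal), loops
# and linkers are C (inert: the only G is the splice donor, which pairs a
# dedicated loop C), and hairpin B is built U-arm-first so that its closing
# A-arm and hairpin C's opening A-arm double as the purine flanks of the
# single-stranded Sm tract - no unpaired purines remain anywhere.
.build_structured_slrna <- function(g) {
  exon_len <- 46L
  # exon: C C | A^s1 C^l1 T^s1 | C | A^s2 C^l2 T^s2 | C^pad | A^s3
  used <- 2L + 2L * g$s1 + g$l1 + 1L + 2L * g$s2 + g$l2 + g$s3
  pad <- exon_len - used
  if (pad < 0L) stop("exon geometry exceeds 46 nt")
  exon <- paste0("CC",
                 strrep("A", g$s1), strrep("C", g$l1), strrep("T", g$s1),
                 "C",
                 strrep("A", g$s2), strrep("C", g$l2), strrep("T", g$s2),
                 strrep("C", pad),
                 strrep("A", g$s3))
  # intron: G T C C C | T^s3 | C^(2+x) | T^s4 C^l4 A^s4 | C^tract |
  #         A^s5 C^l5 T^s5 | C C       (x pads the intron length)
  base_len <- 9L + g$s3 + 2L * g$s4 + g$l4 + g$tract + 2L * g$s5 + g$l5
  x <- max(0L, g$intron_target - base_len)
  intron <- paste0("GTCCC", strrep("T", g$s3), strrep("C", 2L + x),
                   strrep("T", g$s4), strrep("C", g$l4), strrep("A", g$s4),
                   strrep("C", g$tract),
                   strrep("A", g$s5), strrep("C", g$l5), strrep("T", g$s5),
                   "CC")
  seq <- paste0(exon, intron)
  n <- nchar(seq)
  # designed dot-bracket
  db <- rep(".", n)
  mark <- function(db, a_start, stem, loop, open = "(", close = ")") {
    db[a_start:(a_start + stem - 1L)] <- open
    close_start <- a_start + stem + loop
    db[close_start:(close_start + stem - 1L)] <- close
    db
  }
  p <- 3L                                     # after "CC", 1-based
  db <- mark(db, p, g$s1, g$l1)
  p <- p + 2L * g$s1 + g$l1 + 1L
  db <- mark(db, p, g$s2, g$l2)
  # boundary stem: arm at exon end, partner after "GTCCC"
  arm3 <- exon_len - g$s3 + 1L
  db[arm3:(arm3 + g$s3 - 1L)] <- "("
  part <- exon_len + 6L
  db[part:(part + g$s3 - 1L)] <- ")"
  p <- part + g$s3 + 2L + x                   # start of hairpin B (T arm)
  db <- mark(db, p, g$s4, g$l4)
  b_arm_end <- p + 2L * g$s4 + g$l4 - 1L      # last A of B's closing arm
  sm_start <- b_arm_end - 2L                  # 0-based: last two flank A's
  sm_end <- sm_start + 4L + g$tract
  p <- b_arm_end + g$tract + 1L               # first A of hairpin C
  db <- mark(db, p, g$s5, g$l5)
  model <- list(exon_length = exon_len,
                intron_length = n - exon_len,
                sm_site_span = c(sm_start, sm_end),
                exon_span = c(0L, exon_len),
                intron_span = c(exon_len, n),
                donor_ok = TRUE)
  class(model) <- "slrna_gene_model"
  list(seq = seq, dotbracket = paste(db, collapse = ""), model = model)
}
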
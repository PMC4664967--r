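# slRNA gene-unit annotation in genomic sequence and slRNA transcripts.
#
# An slRNA gene unit is the SL exon (the CopepodSL, 44-47 nt, majority 46)
# followed by an intron of 62-111 nt that starts with the GU splice donor
# and carries a purine-flanked pyrimidine tract (the Sm-binding site,
# RR(U+C)nRR, optionally with one internal purine interruption). Units occur
# as tandem arrays with spacers, or clustered with a 5S rRNA gene.

.EXON_QC_RANGE <- c(44L, 47L)
.INTRON_QC_RANGE <- c(62L, 111L)
# exon 3' ends are refined to the nearest GT donor among the observed
# exon-length variants, majority length first
.EXON_LENGTH_PREFERENCE <- c(46L, 45L, 47L, 44L)

#' Sm-binding-site search parameters
#'
#' @param min_tract,max_tract Pyrimidine-tract length bounds (copepod sites
#'   run 6-12, the conserved eukaryote form 4-6; defaults 4-12 span both).
#' @param max_purine_interruptions Internal A/G bases tolerated in the
#'   tract (default 1).
#' @return List of validated parameters.
#' @export
sm_params <- function(min_tract = 4L, max_tract = 12L,
                      max_purine_interruptions = 1L) {
  stopifnot(min_tract >= 2L, min_tract <= max_tract,
            max_purine_interruptions >= 0L)
  list(min_tract = as.integer(min_tract), max_tract = as.integer(max_tract),
       max_purine_interruptions = as.integer(max_purine_interruptions))
}

# mismatch profile of a degenerate pattern against every window of a
# sequence: integer vector over 0-based start positions
.window_mismatches <- function(seq_chars, pattern_chars) {
  L <- length(pattern_chars)
  n <- length(seq_chars)
  if (n < L) return(integer(0))
  n_win <- n - L + 1L
  mm <- integer(n_win)
  base_idx <- match(seq_chars, colnames(.IUPAC_MATCH_MATRIX))
  for (p in seq_len(L)) {
    ok <- .IUPAC_MATCH_MATRIX[pattern_chars[p], ]
    window_base <- base_idx[p:(p + n_win - 1L)]
    hit <- ok[window_base]
    hit[is.na(hit)] <- TRUE   # ambiguous target base matches at zero cost
    mm <- mm + !hit
  }
  mm
}

#' Locate SL exon copies on both strands of a genomic sequence
#'
#' Reports all non-overlapping hits with at most `max_mismatch` mismatches
#' against the degenerate consensus; overlapping candidates are resolved to
#' the lower-mismatch (then 5'-most) hit.
#'
#' @param genomic Genomic sequence (character scalar).
#' @param consensus `sl_consensus` or IUPAC string.
#' @param max_mismatch Maximum mismatches at non-degenerate positions.
#' @return data.frame with `start`, `end` (0-based half-open, plus-strand
#'   coordinates), `mismatches`, `strand`, ordered by `start`.
#' @export
locate_sl_exons <- function(genomic, consensus, max_mismatch = 2L) {
  pat <- .consensus_chars(consensus)
  L <- length(pat)
  genomic <- toupper(genomic)
  if (nchar(genomic) < L) stop("genomic sequence shorter than consensus")
  chars <- .seq_chars(genomic)
  cand <- list()
  plus <- .window_mismatches(chars, pat)
  hit <- which(plus <= max_mismatch)
  if (length(hit) > 0L)
    cand$plus <- data.frame(start = hit - 1L, mismatches = plus[hit],
                            strand = "+", stringsAsFactors = FALSE)
  rc_pat <- .seq_chars(reverse_complement(paste(pat, collapse = "")))
  minus <- .window_mismatches(chars, rc_pat)
  hit <- which(minus <= max_mismatch)
  if (length(hit) > 0L)
    cand$minus <- data.frame(start = hit - 1L, mismatches = minus[hit],
                             strand = "-", stringsAsFactors = FALSE)
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0), strand = character(0)))
  }
  cand$end <- cand$start + L
  # greedy non-overlap resolution: lower mismatch first, then 5'-most
  cand <- cand[order(cand$mismatches, cand$start), , drop = FALSE]
  taken <- logical(0)
  sel <- integer(0)
  for (i in seq_len(nrow(cand))) {
    overlaps <- any(cand$start[sel] < cand$end[i] &
                    cand$start[i] < cand$end[sel])
    if (!overlaps) sel <- c(sel, i)
  }
  out <- cand[sel, c("start", "end", "mismatches", "strand"), drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find Sm-binding-site candidates in an intron sequence
#'
#' Scans for RR (pyrimidine tract) RR where the tract is `min_tract` to
#' `max_tract` long, begins and ends with a pyrimidine, and contains at
#' most `max_purine_interruptions` internal A/G bases. Only maximal hits
#' (not contained in a longer hit) are reported, sorted by tract length
#' descending then position.
#'
#' @param intron_seq Intron sequence (character scalar, DNA alphabet).
#' @param params From [sm_params()].
#' @return data.frame with `start`, `end` (0-based half-open span of the
#'   full RR...RR motif), `tract_length`, `interruptions`.
#' @export
find_sm_site <- function(intron_seq, params = sm_params()) {
  stopifnot(nzchar(intron_seq))
  chars <- .seq_chars(toupper(intron_seq))
  n <- length(chars)
  is_pur <- chars %in% c("A", "G")
  is_pyr <- chars %in% c("C", "T")
  hits <- list()
  for (i in seq_len(max(n - 3L, 0L))) {            # 1-based start of left RR
    if (!(is_pur[i] && is_pur[i + 1L])) next
    for (t in params$max_tract:params$min_tract) {
      tr_start <- i + 2L
      tr_end <- tr_start + t - 1L
      if (tr_end + 2L > n) next
      if (!(is_pur[tr_end + 1L] && is_pur[tr_end + 2L])) next
      tract <- (tr_start):(tr_end)
      if (!(is_pyr[tr_start] && is_pyr[tr_end])) next
      interior <- tract[-c(1L, length(tract))]
      inter <- sum(is_pur[interior])
      if (any(!is_pur[tract] & !is_pyr[tract])) next
      if (inter > params$max_purine_interruptions) next
      hits[[length(hits) + 1L]] <- data.frame(
        start = i - 1L, end = tr_end + 2L, tract_length = t,
        interruptions = inter)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      tract_length = integer(0), interruptions = integer(0)))
  }
  out <- do.call(rbind, hits)
  # keep maximal hits only: drop spans contained in a longer span
  keep <- vapply(seq_len(nrow(out)), function(i) {
    !any(out$start <= out$start[i] & out$end >= out$end[i] &
         (out$end - out$start) > (out$end[i] - out$start[i]))
  }, logical(1))
  out <- out[keep, , drop = FALSE]
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  out <- out[order(-out$tract_length, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.qc_flags <- function(exon_length, intron_length, donor_ok, sm_found) {
  flags <- character(0)
  if (exon_length < .EXON_QC_RANGE[1] || exon_length > .EXON_QC_RANGE[2])
    flags <- c(flags, "exon_length_out_of_range")
  if (intron_length < .INTRON_QC_RANGE[1] || intron_length > .INTRON_QC_RANGE[2])
    flags <- c(flags, "intron_length_out_of_range")
  if (!donor_ok) flags <- c(flags, "donor_missing")
  if (!sm_found) flags <- c(flags, "sm_missing")
  flags
}

# refine the exon 3' end: try observed exon-length variants (majority 46
# first) and accept the first whose following dinucleotide is the GT donor
.refine_exon_end <- function(seq, exon_start, matched_length) {
  n <- nchar(seq)
  for (L in .EXON_LENGTH_PREFERENCE) {
    pos <- exon_start + L
    if (pos + 2L <= n && substr(seq, pos + 1L, pos + 2L) == "GT") {
      return(list(exon_length = L, donor_ok = TRUE))
    }
  }
  list(exon_length = matched_length, donor_ok = FALSE)
}

#' Annotate one slRNA gene unit around an SL exon hit
#'
#' The exon 3' end is refined to the nearest GT splice donor among the
#' observed exon-length variants (44-47 nt, majority first). The unit 3'
#' end is placed `sm_offset` nt after the best Sm hit (a sequence-only
#' stand-in for the experimentally determined 3' end); when no Sm site is
#' found the intron is capped at the maximum expected intron length and
#' flagged.
#'
#' @param genomic Genomic (or transcript) sequence, plus strand.
#' @param exon_hit One row of [locate_sl_exons()] output (plus strand).
#' @param sm_offset Distance from the Sm-site end to the unit 3' end.
#' @param params Sm search parameters ([sm_params()]).
#' @param intron_end Optional fixed 0-based unit 3' end overriding the
#'   Sm-offset rule (used for slRNA transcripts, where the transcript end
#'   is the unit end).
#' @return List of class `slrna_gene_model`: exon/intron spans and lengths,
#'   `donor_ok`, `sm_site_span` (or NULL), `sm_tract_length`,
#'   `sm_interruptions`, `qc_flags`.
#' @export
annotate_slrna_unit <- function(genomic, exon_hit, sm_offset = 20L,
                                params = sm_params(),
                                intron_end = NULL) {
  genomic <- toupper(genomic)
  n <- nchar(genomic)
  exon_start <- exon_hit$start[[1]]
  matched_length <- exon_hit$end[[1]] - exon_hit$start[[1]]
  if (exon_hit$start[[1]] < 0L || exon_hit$end[[1]] > n)
    stop("exon hit outside sequence")
  ref <- .refine_exon_end(genomic, exon_start, matched_length)
  exon_end <- exon_start + ref$exon_length
  if (exon_end >= n) {
    model <- list(exon_span = c(exon_start, exon_end),
                  intron_span = c(exon_end, exon_end),
                  exon_length = ref$exon_length, intron_length = 0L,
                  donor_ok = FALSE, sm_site_span = NULL,
                  sm_tract_length = NA_integer_,
                  sm_interruptions = NA_integer_,
                  qc_flags = .qc_flags(ref$exon_length, 0L, FALSE, FALSE))
    class(model) <- "slrna_gene_model"
    return(model)
  }
  donor_ok <- substr(genomic, exon_end + 1L, exon_end + 2L) == "GT"
  # Sm search is capped at the maximum expected intron length so that the
  # scan cannot run into a downstream unit
  scan_end <- if (!is.null(intron_end)) intron_end
              else min(n, exon_end + .INTRON_QC_RANGE[2])
  intron_seq <- substr(genomic, exon_end + 1L, scan_end)
  sm <- find_sm_site(intron_seq, params = params)
  if (nrow(sm) > 0L) {
    best <- sm[1L, ]
    sm_span <- c(exon_end + best$start, exon_end + best$end)
    unit_end <- if (!is.null(intron_end)) intron_end
                else min(n, sm_span[2] + sm_offset)
    sm_found <- TRUE
  } else {
    best <- NULL
    sm_span <- NULL
    unit_end <- if (!is.null(intron_end)) intron_end
                else min(n, exon_end + .INTRON_QC_RANGE[2])
    sm_found <- FALSE
  }
  intron_length <- unit_end - exon_end
  model <- list(exon_span = c(exon_start, exon_end),
                intron_span = c(exon_end, unit_end),
                exon_length = ref$exon_length,
                intron_length = intron_length,
                donor_ok = donor_ok,
                sm_site_span = sm_span,
                sm_tract_length = if (sm_found) best$tract_length else NA_integer_,
                sm_interruptions = if (sm_found) best$interruptions else NA_integer_,
                qc_flags = .qc_flags(ref$exon_length, intron_length,
                                     donor_ok, sm_found))
  class(model) <- "slrna_gene_model"
  model
}

#' @export
print.slrna_gene_model <- function(x, ...) {
  cat(sprintf("slRNA unit: exon [%d,%d) (%d nt), intron [%d,%d) (%d nt), donor %s\n",
              x$exon_span[1], x$exon_span[2], x$exon_length,
              x$intron_span[1], x$intron_span[2], x$intron_length,
              if (x$donor_ok) "GT" else "absent"))
  if (!is.null(x$sm_site_span))
    cat(sprintf("  Sm site [%d,%d), tract %d nt, %d interruption(s)\n",
                x$sm_site_span[1], x$sm_site_span[2],
                x$sm_tract_length, x$sm_interruptions))
  if (length(x$qc_flags) > 0L)
    cat("  QC:", paste(x$qc_flags, collapse = "; "), "\n")
  invisible(x)
}

#' Classify a putative slRNA transcript
#'
#' The SL must sit at transcript position 0 (full mode, no 5' offset); the
#' exon is the leader (3' end refined to the GT donor), the intron the
#' remainder to the transcript end, so exon + intron lengths always equal
#' the transcript length.
#'
#' @param transcript One-row record table or list with `id`, `seq`.
#' @param consensus `sl_consensus` or IUPAC string.
#' @param params Sm search parameters.
#' @param max_mismatch Mismatch tolerance of the SL match.
#' @return `slrna_gene_model` with extra fields `record_id` and
#'   `slrna_length`, or `NULL` (with attribute `reason`) when the
#'   transcript carries no SL at its 5' end.
#' @export
classify_slrna_transcript <- function(transcript, consensus,
                                      params = sm_params(),
                                      max_mismatch = 2L) {
  m <- match_sl(transcript, consensus, max_mismatch = max_mismatch,
                max_5p_offset = 0L)
  if (is.null(m)) {
    warning("transcript '", transcript$id[[1]],
            "' carries no SL at its 5' end; rejected")
    return(NULL)
  }
  seq <- transcript$seq[[1]]
  hit <- data.frame(start = 0L, end = m$leader_end)
  model <- annotate_slrna_unit(seq, hit, params = params,
                               intron_end = nchar(seq))
  model$record_id <- transcript$id[[1]]
  model$slrna_length <- model$exon_length + model$intron_length
  model
}

#' Detect tandem-array / 5S-cluster layout of slRNA units
#'
#' @param genomic Genomic sequence.
#' @param exon_hits data.frame from [locate_sl_exons()] (sorted by start).
#' @param unit_models Optional list of unit models matching `exon_hits`
#'   rows (used for spacer lengths; spacers are `NA` without them).
#' @param fiveS_probe 5S rDNA probe sequence (default the 5S PCR probe
#'   TACTTGGATGGGTGACCGCC).
#' @param max_probe_mismatch Mismatch tolerance of the probe scan.
#' @return List of class `slrna_array_layout`: `unit_starts`,
#'   `inter_unit_distances`, `spacer_lengths`, `cluster_type`
#'   (`"tandem"`, `"fiveS_clustered"` or `"singleton"`) and `fiveS_hits`.
#' @export
detect_array_layout <- function(genomic, exon_hits, unit_models = NULL,
                                fiveS_probe = "TACTTGGATGGGTGACCGCC",
                                max_probe_mismatch = 2L) {
  genomic <- toupper(genomic)
  starts <- sort(exon_hits$start)
  probe_hits <- if (nchar(genomic) >= nchar(fiveS_probe)) {
    locate_sl_exons(genomic, fiveS_probe, max_mismatch = max_probe_mismatch)
  } else {
    data.frame(start = integer(0), end = integer(0),
               mismatches = integer(0), strand = character(0))
  }
  # a probe hit inside an exon would be spurious; require it outside units
  if (nrow(probe_hits) > 0L && nrow(exon_hits) > 0L) {
    inside <- vapply(seq_len(nrow(probe_hits)), function(i) {
      any(probe_hits$start[i] < exon_hits$end &
          exon_hits$start < probe_hits$end)
    }, logical(1))
    probe_hits <- probe_hits[!inside, , drop = FALSE]
  }
  cluster_type <- if (nrow(probe_hits) > 0L) "fiveS_clustered"
                  else if (length(starts) >= 2L) "tandem"
                  else "singleton"
  spacers <- NA_integer_
  if (!is.null(unit_models) && length(starts) >= 2L) {
    ends <- vapply(unit_models, function(m) m$intron_span[2], numeric(1))
    ord <- order(vapply(unit_models, function(m) m$exon_span[1], numeric(1)))
    ends <- ends[ord]
    spacers <- starts[-1L] - ends[-length(ends)]
  }
  structure(list(unit_starts = starts,
                 inter_unit_distances = if (length(starts) >= 2L) diff(starts)
                                        else integer(0),
                 spacer_lengths = spacers,
                 cluster_type = cluster_type,
                 fiveS_hits = probe_hits),
            class = "slrna_array_layout")
}
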
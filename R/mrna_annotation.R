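# Feature annotation of SL-trimmed full-length cDNAs.
#
# Feature definitions follow the conventions used for copepod full-length
# cDNA libraries: the ORF starts at the 5'-most AUG that opens a reading
# frame with an in-frame stop; the 5' UTR runs from the first nucleotide
# after the SL to the start codon; the 3' UTR runs from the first nucleotide
# after the stop codon to the first A of the poly(A) tail. All coordinates
# are 0-based, half-open, on the SL-trimmed body.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Predict the ORF of an SL-trimmed transcript body
#'
#' Scans 5' to 3' for ATG and accepts the first ATG that opens a reading
#' frame with an in-frame stop codon and a CDS of at least
#' `3 * min_cds_codons` nucleotides (stop included). If the first ATG fails
#' the stop/length requirement the next is tried. When no ATG yields a
#' qualifying stop, the annotation is anchored at the first ATG with
#' `complete = FALSE` and `stop_end` truncated to frame at the body end.
#'
#' @param body SL-trimmed sequence (character scalar).
#' @param min_cds_codons Minimum CDS length in codons, stop included.
#' @return List with `start`, `stop_end` (0-based half-open), `cds_length`
#'   and `complete`; `NULL` when the body contains no ATG.
#' @export
find_orf <- function(body, min_cds_codons = 30L) {
  stopifnot(nzchar(body), min_cds_codons >= 1L)
  body <- toupper(body)
  n <- nchar(body)
  atg <- gregexpr("ATG", body, fixed = TRUE)[[1]]
  if (atg[1] == -1L) return(NULL)
  atg <- as.integer(atg)  # 1-based
  for (s in atg) {
    starts <- seq.int(s, n - 2L, by = 3L)
    if (length(starts) == 0L) next
    codons <- substring(body, starts, starts + 2L)
    stop_i <- which(codons %in% .STOP_CODONS)
    if (length(stop_i) == 0L) next
    stop_end <- starts[stop_i[1]] + 2L       # 1-based inclusive end
    cds_length <- stop_end - s + 1L
    if (cds_length >= 3L * min_cds_codons) {
      return(list(start = s - 1L, stop_end = stop_end,
                  cds_length = cds_length, complete = TRUE))
    }
  }
  # no qualifying stop anywhere: frame-truncated open annotation
  s <- atg[1]
  usable <- n - s + 1L
  stop_end <- s - 1L + 3L * (usable %/% 3L)
  list(start = s - 1L, stop_end = stop_end,
       cds_length = stop_end - s + 1L, complete = FALSE)
}

#' Detect a 3' poly(A) tail
#'
#' Finds the longest terminal window with A-fraction >= `purity` and length
#' >= `min_run`, then reports the first A of that window whose suffix still
#' satisfies the purity rule (so a tail may tolerate isolated non-A bases).
#'
#' @param body Sequence (character scalar).
#' @param min_run Minimum qualifying suffix length (>= 4; default 8).
#' @param purity Minimum A fraction of the suffix (0 < purity <= 1).
#' @return 0-based index of the tail's first A, or `NA_integer_` when no
#'   suffix qualifies.
#' @export
detect_polya_tail <- function(body, min_run = 8L, purity = 0.9) {
  stopifnot(min_run >= 4L, purity > 0, purity <= 1)
  chars <- .seq_chars(toupper(body))
  n <- length(chars)
  if (n < min_run) return(NA_integer_)
  is_a <- chars == "A"
  # suffix starting at i (1-based) has a_count[i] A's over n - i + 1 bases
  a_count <- rev(cumsum(rev(is_a)))
  len <- n - seq_len(n) + 1L
  ok <- len >= min_run & a_count / len >= purity
  if (!any(ok)) return(NA_integer_)
  i0 <- which(ok)[1]                      # longest qualifying window
  j <- which(is_a & seq_len(n) >= i0 & ok)
  if (length(j) == 0L) return(NA_integer_)
  j[1] - 1L
}

#' Find polyadenylation signals between stop codon and poly(A) tail
#'
#' Reports every AATAAA occurrence in `[stop_end, polya_tail_start)` with
#' its offset to the cleavage site (`polya_tail_start - signal_end`); the
#' canonical placement is 7-20 nt upstream of the tail.
#'
#' @param body Sequence (character scalar).
#' @param stop_end 0-based half-open end of the stop codon.
#' @param polya_tail_start 0-based tail start (body length when no tail).
#' @return data.frame with `signal_start`, `offset`, `in_canonical_range`,
#'   in 5' to 3' order (zero rows when the signal is absent).
#' @export
find_polya_signals <- function(body, stop_end, polya_tail_start) {
  stopifnot(stop_end >= 0L, polya_tail_start >= stop_end)
  empty <- data.frame(signal_start = integer(0), offset = integer(0),
                      in_canonical_range = logical(0))
  region_len <- polya_tail_start - stop_end
  if (region_len < 6L) return(empty)
  region <- substr(toupper(body), stop_end + 1L, polya_tail_start)
  hits <- gregexpr("(?=AATAAA)", region, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(empty)
  signal_start <- stop_end + as.integer(hits) - 1L
  signal_start <- signal_start[signal_start + 6L <= polya_tail_start]
  if (length(signal_start) == 0L) return(empty)
  offset <- polya_tail_start - (signal_start + 6L)
  data.frame(signal_start = signal_start, offset = offset,
             in_canonical_range = offset >= 7L & offset <= 20L)
}

#' Delineate UTR lengths from ORF and poly(A) tail
#'
#' @param body SL-trimmed sequence.
#' @param orf ORF annotation from [find_orf()] (must be complete).
#' @param polya_tail_start 0-based tail start or `NA` when absent.
#' @return List with `utr5_length`, `utr3_length` and `no_tail` (TRUE when
#'   the 3' UTR was measured to the body end for lack of a tail).
#' @export
delineate_utrs <- function(body, orf, polya_tail_start = NA_integer_) {
  stopifnot(isTRUE(orf$complete))
  if (!is.na(polya_tail_start) && polya_tail_start < orf$stop_end)
    stop("poly(A) tail start lies inside the CDS")
  utr3_end <- if (is.na(polya_tail_start)) nchar(body) else polya_tail_start
  list(utr5_length = orf$start,
       utr3_length = utr3_end - orf$stop_end,
       no_tail = is.na(polya_tail_start))
}

#' Kozak-context profile across a transcript set
#'
#' Builds the 9-column position-frequency matrix over contexts
#' (-3..-1, start codon, +4..+6) and the column-wise modal consensus; ties
#' are reported as the IUPAC code of the tied base set. Transcripts whose
#' ORF starts fewer than 3 nt into the body or that lack 3 nt after the
#' start codon are excluded and counted.
#'
#' @param contexts Character vector of 9-nt contexts (or `NA` for excluded
#'   transcripts), e.g. the `kozak_context` column of [annotate_library()].
#' @return List with `pfm` (4 x 9), `consensus` (9-nt string, positions 4-6
#'   fixed at ATG by construction), `n_used`, `n_excluded`.
#' @export
kozak_profile <- function(contexts) {
  ok <- !is.na(contexts) & nchar(contexts) == 9L
  if (!any(ok)) stop("no qualifying transcripts for Kozak profiling")
  pfm <- .column_pfm(toupper(contexts[ok]))
  consensus <- vapply(seq_len(ncol(pfm)), function(j) {
    col <- pfm[, j]
    top <- rownames(pfm)[col == max(col)]
    iupac_code_for(top)
  }, character(1))
  list(pfm = pfm, consensus = paste(consensus, collapse = ""),
       n_used = sum(ok), n_excluded = sum(!ok))
}

#' Single-nucleotide repeat (homopolymer) analysis
#'
#' Reports maximal homopolymer runs of length >= `min_run` (default 4,
#' i.e. more than 3 repeats).
#'
#' @param body Sequence (character scalar).
#' @param min_run Minimum run length reported (>= 2).
#' @return List with `runs` (data.frame base/start/run_length, starts
#'   0-based), `counts_by_base` (named integer vector, descending) and
#'   `max_run` (0 when no run qualifies).
#' @export
snr_analysis <- function(body, min_run = 4L) {
  stopifnot(min_run >= 2L)
  r <- rle(.seq_chars(toupper(body)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  keep <- r$lengths >= min_run
  runs <- data.frame(base = r$values[keep], start = starts[keep],
                     run_length = r$lengths[keep], stringsAsFactors = FALSE)
  counts <- sort(table(factor(runs$base, levels = c("A", "C", "G", "T"))),
                 decreasing = TRUE)
  list(runs = runs,
       counts_by_base = stats::setNames(as.integer(counts), names(counts)),
       max_run = if (nrow(runs) > 0L) max(runs$run_length) else 0L)
}

#' GC fraction of a sequence
#'
#' Ambiguous bases are excluded from both numerator and denominator.
#'
#' @param body Sequence (character scalar).
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(body) {
  stopifnot(nzchar(body))
  chars <- .seq_chars(toupper(body))
  concrete <- chars %in% c("A", "C", "G", "T")
  if (!any(concrete)) stop("no unambiguous bases in sequence")
  sum(chars[concrete] %in% c("G", "C")) / sum(concrete)
}

#' All 64 codons in a fixed alphabetical order
#' @keywords internal
.all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(t(outer(as.vector(t(outer(b, b, paste0))), b, paste0)))
}

#' Codon usage over a set of CDS sequences
#'
#' Plain codon tallying over all CDS concatenated; stop codons included.
#'
#' @param cds_list Character vector of CDS sequences, each with length
#'   divisible by 3.
#' @return data.frame with 64 rows: `codon`, `count`, `fraction`
#'   (fractions sum to 1 when any codon was counted).
#' @export
codon_usage <- function(cds_list) {
  bad <- nchar(cds_list) %% 3L != 0L
  if (any(bad))
    stop("CDS length not divisible by 3 at entry ", which(bad)[1])
  codons <- unlist(lapply(toupper(cds_list), function(cds) {
    starts <- seq.int(1L, nchar(cds) - 2L, by = 3L)
    substring(cds, starts, starts + 2L)
  }), use.names = FALSE)
  counts <- table(factor(codons, levels = .all_codons()))
  total <- sum(counts)
  data.frame(codon = names(counts), count = as.integer(counts),
             fraction = if (total > 0) as.numeric(counts) / total else 0,
             stringsAsFactors = FALSE)
}

#' The 79-member cytoplasmic ribosomal protein reference set
#'
#' The canonical eukaryotic set of 32 small-subunit (40S) and 47
#' large-subunit (60S) cRPs (excluding the plant-specific RPLP3 and the
#' Y-chromosome-specific RPS4 isoform), shipped as an editable text file.
#'
#' @param path Optional path to an alternative two-column TSV
#'   (`name`, `subunit`).
#' @return data.frame with columns `name` and `subunit` (79 rows for the
#'   shipped file).
#' @export
crp_reference <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "crp79.tsv", package = "slsplice")
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

.normalize_gene_name <- function(x) gsub("[^A-Z0-9]", "", toupper(x))

#' Check detected cRPs against the 79-member reference checklist
#'
#' Name matching is string-normalised only (case-insensitive, punctuation
#' stripped); no homology search is performed.
#'
#' @param detected_names Character vector of detected cRP gene names.
#' @param reference_names Character vector of reference names (default: the
#'   shipped 79-member set). Must be unique after normalisation.
#' @return List with `reference_names`, `detected` (reference names that
#'   were matched), `missing` (in reference order), `n_detected`,
#'   `n_missing`.
#' @export
check_crp_completeness <- function(detected_names,
                                   reference_names = crp_reference()$name) {
  ref_norm <- .normalize_gene_name(reference_names)
  if (anyDuplicated(ref_norm))
    stop("duplicate reference names after normalisation")
  det_norm <- unique(.normalize_gene_name(detected_names))
  matched <- ref_norm %in% det_norm
  list(reference_names = reference_names,
       detected = reference_names[matched],
       missing = reference_names[!matched],
       n_detected = sum(matched),
       n_missing = sum(!matched))
}

#' Annotate one SL-trimmed transcript body
#'
#' Runs ORF prediction, poly(A) tail and signal detection, UTR
#' delineation, Kozak-context extraction, homopolymer and composition
#' analysis on a single body.
#'
#' @param body SL-trimmed sequence.
#' @param id Record id carried into the output.
#' @param min_cds_codons,min_run,purity,snr_min_run Stage parameters.
#' @return One-row data.frame (see [annotate_library()] for columns), plus
#'   attribute `cds` with the CDS sequence when the ORF is complete.
#' @export
annotate_transcript <- function(body, id = "transcript",
                                min_cds_codons = 30L, min_run = 8L,
                                purity = 0.9, snr_min_run = 4L) {
  body <- toupper(body)
  orf <- find_orf(body, min_cds_codons = min_cds_codons)
  tail_start <- detect_polya_tail(body, min_run = min_run, purity = purity)
  if (is.null(orf)) {
    out <- data.frame(record_id = id, orf_start = NA_integer_,
                      stop_end = NA_integer_, cds_length = NA_integer_,
                      complete = FALSE, utr5 = NA_integer_,
                      utr3 = NA_integer_, no_tail = is.na(tail_start),
                      kozak_context = NA_character_,
                      tail_start = tail_start, n_polya_signals = 0L,
                      best_signal_offset = NA_integer_,
                      gc = gc_content(body), max_snr_run = snr_analysis(
                        body, min_run = snr_min_run)$max_run,
                      stringsAsFactors = FALSE)
    return(out)
  }
  utrs <- if (orf$complete) {
    tl <- if (!is.na(tail_start) && tail_start >= orf$stop_end) tail_start
          else NA_integer_
    delineate_utrs(body, orf, tl)
  } else {
    list(utr5_length = orf$start, utr3_length = NA_integer_, no_tail = TRUE)
  }
  signals <- if (orf$complete) {
    end3 <- if (!is.na(tail_start) && tail_start >= orf$stop_end) tail_start
            else nchar(body)
    find_polya_signals(body, orf$stop_end, end3)
  } else {
    find_polya_signals(body, nchar(body), nchar(body))
  }
  kozak <- if (orf$start >= 3L && orf$start + 6L <= nchar(body)) {
    substr(body, orf$start - 2L, orf$start + 6L)
  } else NA_character_
  snr <- snr_analysis(body, min_run = snr_min_run)
  out <- data.frame(
    record_id = id, orf_start = orf$start, stop_end = orf$stop_end,
    cds_length = orf$cds_length, complete = orf$complete,
    utr5 = utrs$utr5_length, utr3 = utrs$utr3_length, no_tail = utrs$no_tail,
    kozak_context = kozak, tail_start = tail_start,
    n_polya_signals = nrow(signals),
    best_signal_offset = if (nrow(signals) > 0L) {
      canon <- signals$offset[signals$in_canonical_range]
      if (length(canon) > 0L) min(canon) else min(signals$offset)
    } else NA_integer_,
    gc = gc_content(body), max_snr_run = snr$max_run,
    stringsAsFactors = FALSE
  )
  attr(out, "cds") <- if (orf$complete)
    substr(body, orf$start + 1L, orf$stop_end) else NA_character_
  out
}

#' Annotate a library of SL-trimmed transcripts
#'
#' @param records Record table of SL-trimmed bodies.
#' @param ... Passed to [annotate_transcript()].
#' @return List with `annotations` (one row per record), `codon_usage`
#'   (64-row table over all complete CDS) and `kozak` (profile from
#'   [kozak_profile()], `NULL` when no transcript qualifies).
#' @export
annotate_library <- function(records, ...) {
  rows <- vector("list", nrow(records))
  cds <- character(0)
  for (i in seq_len(nrow(records))) {
    ann <- annotate_transcript(records$seq[i], id = records$id[i], ...)
    if (!is.na(attr(ann, "cds") %||% NA_character_))
      cds <- c(cds, attr(ann, "cds"))
    attr(ann, "cds") <- NULL
    rows[[i]] <- ann
  }
  annotations <- do.call(rbind, rows)
  kozak <- tryCatch(kozak_profile(annotations$kozak_context),
                    error = function(e) NULL)
  list(annotations = annotations,
       codon_usage = codon_usage(cds),
       kozak = kozak)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise a library of transcript annotations
#'
#' Mean and population standard deviation (divide by n) for full length,
#' CDS, 5' UTR and 3' UTR; fraction of transcripts with a polyadenylation
#' signal; fraction with complete ORFs; mean GC.
#'
#' @param annotations Annotation data.frame from [annotate_library()].
#' @param body_lengths Optional integer vector of body lengths (full
#'   transcript length per record); reconstructed from coordinates when
#'   omitted.
#' @return One-row data.frame of summary statistics.
#' @export
summarize_library <- function(annotations, body_lengths = NULL) {
  stopifnot(nrow(annotations) >= 1L)
  pop_sd <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NA_real_)
    sqrt(mean((x - mean(x))^2))
  }
  if (is.null(body_lengths)) {
    body_lengths <- annotations$utr5 + annotations$cds_length +
      annotations$utr3
  }
  m <- function(x) mean(x, na.rm = TRUE)
  data.frame(
    n = nrow(annotations),
    length_mean = m(body_lengths), length_sd = pop_sd(body_lengths),
    cds_mean = m(annotations$cds_length), cds_sd = pop_sd(annotations$cds_length),
    utr5_mean = m(annotations$utr5), utr5_sd = pop_sd(annotations$utr5),
    utr3_mean = m(annotations$utr3), utr3_sd = pop_sd(annotations$utr3),
    frac_with_signal = mean(annotations$n_polya_signals > 0L),
    frac_complete_orf = mean(annotations$complete),
    gc_mean = m(annotations$gc)
  )
}
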
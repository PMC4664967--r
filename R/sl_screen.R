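# Screening transcripts for the spliced leader at their 5' end.
#
# Full mode scans a small range of 5' offsets for the whole consensus
# (tolerating short extensions such as the ATT seen on a minority of SL
# cDNAs); partial mode emulates screening of 5'-truncated ESTs/TSA contigs
# by matching consensus *suffixes* at transcript position 0 only. Degenerate
# consensus positions match their expansion at zero cost.

.consensus_chars <- function(consensus) {
  iupac <- if (inherits(consensus, "sl_consensus")) consensus$iupac_string
           else consensus
  .seq_chars(toupper(iupac))
}

#' Match the full SL consensus at a transcript 5' end
#'
#' Scans offsets `0..max_5p_offset` and returns the lowest-mismatch
#' placement (ties resolved toward the smaller offset, i.e. no extension).
#'
#' @param record One-row record table, or a list with `id` and `seq`.
#' @param consensus `sl_consensus` or IUPAC string (length >= 15).
#' @param max_mismatch Maximum mismatches at non-degenerate positions.
#' @param max_5p_offset Maximum number of transcript bases allowed before
#'   the leader.
#' @return A list (`record_id`, `mode = "full"`, `leader_start`,
#'   `leader_end`, `matched_length`, `mismatches`, `five_prime_extension`)
#'   or `NULL` when no placement meets `max_mismatch`. Coordinates 0-based,
#'   half-open.
#' @export
match_sl <- function(record, consensus, max_mismatch = 2L,
                     max_5p_offset = 5L) {
  stopifnot(max_mismatch >= 0L, max_5p_offset >= 0L)
  pat <- .consensus_chars(consensus)
  L <- length(pat)
  if (L < 15L) stop("consensus too short for reliable full matching")
  seq <- record$seq[[1]]
  id <- record$id[[1]]
  chars <- .seq_chars(seq)
  best <- NULL
  for (off in 0:max_5p_offset) {
    if (nchar(seq) < off + L) break
    mm <- .count_mismatches(pat, chars[(off + 1L):(off + L)])
    if (is.null(best) || mm < best$mismatches) {
      best <- list(offset = off, mismatches = mm)
      if (mm == 0L) break
    }
  }
  if (is.null(best) || best$mismatches > max_mismatch) return(NULL)
  list(record_id = id, mode = "full",
       leader_start = best$offset,
       leader_end = best$offset + L,
       matched_length = L,
       mismatches = as.integer(best$mismatches),
       five_prime_extension = substr(seq, 1L, best$offset))
}

#' Match a suffix of the SL consensus at transcript position 0
#'
#' Tests every consensus suffix of length >= `min_partial_length` against
#' the transcript start and returns the longest qualifying match. This is
#' the situation of a 5'-truncated EST that retains only the tail of the
#' leader; a leader *prefix* at the transcript start never qualifies.
#'
#' @inheritParams match_sl
#' @param min_partial_length Minimum matched suffix length (>= 10).
#' @return Match list as in [match_sl()] with `mode = "partial"`, or `NULL`.
#' @export
match_sl_partial <- function(record, consensus, max_mismatch = 2L,
                             min_partial_length = 15L) {
  stopifnot(min_partial_length >= 10L)
  pat <- .consensus_chars(consensus)
  L <- length(pat)
  seq <- record$seq[[1]]
  id <- record$id[[1]]
  chars <- .seq_chars(seq)
  max_len <- min(L, nchar(seq))
  if (max_len < min_partial_length) return(NULL)
  for (len in max_len:min_partial_length) {
    suffix <- pat[(L - len + 1L):L]
    mm <- .count_mismatches(suffix, chars[seq_len(len)])
    if (mm <= max_mismatch) {
      return(list(record_id = id, mode = "partial",
                  leader_start = 0L, leader_end = len,
                  matched_length = len, mismatches = as.integer(mm),
                  five_prime_extension = ""))
    }
  }
  NULL
}

#' Remove a matched leader (and any 5' extension) from a transcript
#'
#' @param record One-row record table or list with `id` and `seq`.
#' @param match Match from [match_sl()] / [match_sl_partial()].
#' @return Record table of the trimmed body with a `leader` column recording
#'   the removed 5' segment, or `NULL` (with a warning) when trimming leaves
#'   an empty body.
#' @export
trim_sl <- function(record, match) {
  seq <- record$seq[[1]]
  id <- record$id[[1]]
  if (!identical(match$record_id, id))
    stop("match does not belong to record '", id, "'")
  if (match$leader_end > nchar(seq)) stop("match coordinates exceed record length")
  if (match$leader_end == nchar(seq)) {
    warning("record '", id, "' is leader only; excluded")
    return(NULL)
  }
  out <- seq_records(id, substr(seq, match$leader_end + 1L, nchar(seq)),
                     alphabet_note = if (!is.null(record$alphabet_note))
                       record$alphabet_note[[1]] else "dna_input")
  out$leader <- substr(seq, 1L, match$leader_end)
  out
}

#' Screen a transcript set for the spliced leader
#'
#' Applies full matching to every record, optionally falling back to
#' partial (suffix) matching; each record is classified as exactly one of
#' `full`, `partial` or `none`.
#'
#' @param records Record table.
#' @param consensus `sl_consensus` or IUPAC string.
#' @param max_mismatch,max_5p_offset See [match_sl()].
#' @param partial Enable partial (suffix) mode fallback.
#' @param min_partial_length See [match_sl_partial()].
#' @return List with `per_record` (data.frame: record_id, mode,
#'   leader_start, leader_end, matched_length, mismatches, extension) and
#'   `summary` (named counts full/partial/none summing to `nrow(records)`).
#' @export
screen_dataset <- function(records, consensus, max_mismatch = 2L,
                           max_5p_offset = 5L, partial = TRUE,
                           min_partial_length = 15L) {
  n <- nrow(records)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- list(id = records$id[i], seq = records$seq[i])
    m <- match_sl(rec, consensus, max_mismatch = max_mismatch,
                  max_5p_offset = max_5p_offset)
    if (is.null(m) && partial) {
      m <- match_sl_partial(rec, consensus, max_mismatch = max_mismatch,
                            min_partial_length = min_partial_length)
    }
    rows[[i]] <- if (is.null(m)) {
      data.frame(record_id = records$id[i], mode = "none",
                 leader_start = NA_integer_, leader_end = NA_integer_,
                 matched_length = NA_integer_, mismatches = NA_integer_,
                 extension = NA_character_, stringsAsFactors = FALSE)
    } else {
      data.frame(record_id = m$record_id, mode = m$mode,
                 leader_start = m$leader_start, leader_end = m$leader_end,
                 matched_length = m$matched_length, mismatches = m$mismatches,
                 extension = m$five_prime_extension, stringsAsFactors = FALSE)
    }
  }
  per_record <- if (n == 0L) {
    data.frame(record_id = character(0), mode = character(0),
               leader_start = integer(0), leader_end = integer(0),
               matched_length = integer(0), mismatches = integer(0),
               extension = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  summary <- c(full = sum(per_record$mode == "full"),
               partial = sum(per_record$mode == "partial"),
               none = sum(per_record$mode == "none"))
  list(per_record = per_record, summary = summary)
}

#' Rarefaction curve: expected unique genes per subsample size
#'
#' For clone-to-gene labels with gene counts `c_g` out of `N` clones, the
#' expected number of distinct genes in a random subsample of size `n` is
#' the hypergeometric expectation
#' `E(n) = sum_g (1 - choose(N - c_g, n) / choose(N, n))`.
#'
#' @param clone_to_gene_labels Character/factor vector, one entry per clone.
#' @param grid Integer subsample sizes, each <= number of clones.
#' @return data.frame with columns `n` and `expected_genes`;
#'   `expected_genes` is nondecreasing and reaches the number of distinct
#'   labels at `n = N`.
#' @export
rarefaction_curve <- function(clone_to_gene_labels, grid) {
  if (length(clone_to_gene_labels) == 0L) stop("labels must be non-empty")
  N <- length(clone_to_gene_labels)
  grid <- as.integer(grid)
  if (any(grid < 1L) || any(grid > N))
    stop("grid values must be in 1..", N)
  counts <- as.integer(table(clone_to_gene_labels))
  expected <- vapply(grid, function(n) {
    # lchoose(N - c, n) is -Inf when n > N - c: the gene is then always seen
    sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
  }, numeric(1))
  data.frame(n = grid, expected_genes = expected)
}
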
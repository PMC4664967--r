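# FASTA input/output. Records travel through the package as a plain
# data.frame with columns id, seq and alphabet_note ("dna_input" or
# "rna_input"); alphabet_note records whether the source file used U so that
# write_fasta() can restore RNA display on the way out.

#' Construct a sequence-record table
#'
#' @param id Character vector of unique, non-empty identifiers.
#' @param seq Character vector of sequences (IUPAC alphabet, no whitespace).
#'   U is accepted and converted to T; such records are flagged as RNA input.
#' @param alphabet_note Optional; `"dna_input"` or `"rna_input"`, recycled.
#'   Defaults to autodetection from the presence of U.
#' @return data.frame with columns `id`, `seq`, `alphabet_note`.
#' @export
seq_records <- function(id, seq, alphabet_note = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq must have equal length")
  if (any(!nzchar(id))) stop("record ids must be non-empty")
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1]
    stop("duplicate record id: '", dup, "'")
  }
  if (any(!nzchar(seq))) {
    stop("empty sequence for record '", id[!nzchar(seq)][1], "'")
  }
  if (any(grepl("[[:space:]]", seq))) stop("sequences must not contain whitespace")
  has_u <- grepl("U", seq, fixed = TRUE)
  if (is.null(alphabet_note)) {
    alphabet_note <- ifelse(has_u, "rna_input", "dna_input")
  } else {
    alphabet_note <- rep_len(alphabet_note, length(seq))
    if (!all(alphabet_note %in% c("dna_input", "rna_input")))
      stop("alphabet_note must be 'dna_input' or 'rna_input'")
  }
  seq <- chartr("U", "T", seq)
  valid <- paste(names(IUPAC_EXPANSION), collapse = "")
  bad <- grepl(sprintf("[^%s]", valid), seq)
  if (any(bad)) {
    stop("invalid character(s) in sequence of record '", id[bad][1], "'")
  }
  data.frame(id = id, seq = seq, alphabet_note = alphabet_note,
             stringsAsFactors = FALSE)
}

#' Read a FASTA file into a record table
#'
#' Sequences are uppercased; U is converted to T internally and the record is
#' flagged `rna_input` so that [write_fasta()] restores U on output.
#' Duplicate ids are rejected.
#'
#' @param path Path to a FASTA file.
#' @return data.frame as returned by [seq_records()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    return(seq_records(character(0), character(0)))
  seq_records(names(set), as.character(set))
}

#' Write a record table to FASTA
#'
#' Round-trips with [read_fasta()]: `read_fasta(write_fasta(x))` equals `x`.
#' Records flagged `rna_input` are written with U in place of T.
#'
#' @param records data.frame from [seq_records()] / [read_fasta()].
#' @param path Output path.
#' @param line_width Sequence line wrap (default 60; must be >= 1).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  stopifnot(is.data.frame(records), line_width >= 1L)
  seqs <- records$seq
  if (length(seqs) > 0L) {
    rna <- records$alphabet_note == "rna_input"
    seqs[rna] <- chartr("T", "U", seqs[rna])
  }
  set <- Biostrings::BStringSet(stats::setNames(seqs, records$id))
  Biostrings::writeXStringSet(set, filepath = path, width = line_width)
  invisible(path)
}
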
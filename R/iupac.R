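# IUPAC degenerate nucleotide codes and low-level sequence utilities.
# The internal alphabet is DNA: U is converted to T on input and restored on
# output for records that arrived as RNA. All coordinates in this package are
# 0-based, half-open intervals.

#' @keywords internal
IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

# code looked up by the sorted, comma-joined base set, e.g. "A,T" -> "W"
.IUPAC_BY_SET <- local({
  keys <- vapply(IUPAC_EXPANSION, function(x) paste(sort(x), collapse = ","),
                 character(1))
  stats::setNames(names(IUPAC_EXPANSION), keys)
})

#' Expand an IUPAC nucleotide code to its concrete bases
#'
#' @param code Single IUPAC character (case-insensitive).
#' @return Character vector of concrete bases in `{A,C,G,T}`.
#' @examples
#' iupac_expand("W")
#' @export
iupac_expand <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, nchar(code) == 1L)
  code <- toupper(code)
  exp <- IUPAC_EXPANSION[[code]]
  if (is.null(exp)) stop("invalid IUPAC code: '", code, "'")
  exp
}

#' Find the IUPAC code for a set of concrete bases
#'
#' @param bases Character vector, subset of `{A,C,G,T}` (non-empty).
#' @return Single IUPAC character whose expansion equals `bases`.
#' @export
iupac_code_for <- function(bases) {
  bases <- unique(toupper(bases))
  if (length(bases) == 0L || !all(bases %in% c("A", "C", "G", "T")))
    stop("bases must be a non-empty subset of {A,C,G,T}")
  .IUPAC_BY_SET[[paste(sort(bases), collapse = ",")]]
}

#' Test whether a concrete base matches a degenerate IUPAC position
#'
#' Degenerate positions match every base in their expansion at zero cost;
#' concrete codes match only themselves. Vectorised over pairs.
#'
#' @param pattern_char IUPAC code(s) from the pattern.
#' @param base Concrete base(s), each in `{A,C,G,T}`.
#' @return Logical vector.
#' @examples
#' iupac_match("W", "A")  # TRUE
#' iupac_match("Y", "A")  # FALSE
#' @export
iupac_match <- function(pattern_char, base) {
  pattern_char <- toupper(pattern_char)
  base <- toupper(base)
  if (!all(base %in% c("A", "C", "G", "T")))
    stop("base must be in {A,C,G,T}")
  if (!all(pattern_char %in% names(IUPAC_EXPANSION)))
    stop("invalid IUPAC code: '",
         paste(setdiff(pattern_char, names(IUPAC_EXPANSION)), collapse = ","),
         "'")
  n <- max(length(pattern_char), length(base))
  pattern_char <- rep_len(pattern_char, n)
  base <- rep_len(base, n)
  mapply(function(p, b) b %in% IUPAC_EXPANSION[[p]], pattern_char, base,
         USE.NAMES = FALSE)
}

#' Reverse complement of a (possibly degenerate) DNA sequence
#'
#' Degenerate codes are complemented consistently (W stays W, Y becomes R).
#' An empty string returns an empty string.
#'
#' @param seq Character scalar over the IUPAC alphabet.
#' @return Reverse-complemented sequence, same length.
#' @examples
#' reverse_complement("TACTTGGATGGGTGACCGCC")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(.IUPAC_COMPLEMENT))
  if (length(bad) > 0L)
    stop("invalid character(s) in sequence: ", paste(bad, collapse = ", "))
  paste(rev(unname(.IUPAC_COMPLEMENT[chars])), collapse = "")
}

# ---- internal helpers shared by the matching code ------------------------

# logical lookup matrix: rows = 15 IUPAC codes, cols = A,C,G,T
.IUPAC_MATCH_MATRIX <- local({
  m <- matrix(FALSE, nrow = length(IUPAC_EXPANSION), ncol = 4,
              dimnames = list(names(IUPAC_EXPANSION), c("A", "C", "G", "T")))
  for (code in names(IUPAC_EXPANSION)) m[code, IUPAC_EXPANSION[[code]]] <- TRUE
  m
})

.seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Count mismatches of a degenerate pattern (as a character vector) against a
# same-length window of concrete characters. Non-ACGT characters in the
# target match any pattern position (treated as N, see design notes).
.count_mismatches <- function(pattern_chars, target_chars) {
  concrete <- target_chars %in% c("A", "C", "G", "T")
  if (!any(concrete)) return(0L)
  idx <- cbind(match(pattern_chars[concrete], rownames(.IUPAC_MATCH_MATRIX)),
               match(target_chars[concrete], colnames(.IUPAC_MATCH_MATRIX)))
  sum(!.IUPAC_MATCH_MATRIX[idx])
}
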
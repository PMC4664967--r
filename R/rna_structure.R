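# Deterministic RNA secondary structure by base-pair maximization.
#
# Free-energy folding is deliberately out of scope: the structural claims
# tested here are topological (which hairpins exist, whether the Sm site is
# single-stranded), so a Nussinov-style maximum-matching fold with fixed
# tie-breaking gives a reproducible, exhaustively testable stand-in.
# Pairs are Watson-Crick (A-U, G-C) plus the G-U wobble; hairpin loops
# must contain at least `min_loop` unpaired bases.

.can_pair_matrix <- function(allow_gu = TRUE) {
  m <- matrix(FALSE, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T")))
  m["A", "T"] <- m["T", "A"] <- TRUE
  m["G", "C"] <- m["C", "G"] <- TRUE
  if (allow_gu) m["G", "T"] <- m["T", "G"] <- TRUE
  m
}

#' Fold a sequence by base-pair maximization
#'
#' Dynamic programming over intervals; the traceback is deterministic: at
#' every interval the left end is paired with the smallest admissible
#' partner that still achieves the interval's maximum, and left unpaired
#' only when no partner does.
#'
#' @param seq RNA or DNA sequence (T and U are equivalent).
#' @param min_loop Minimum hairpin-loop size (>= 3).
#' @param allow_gu Allow the G-U wobble pair.
#' @return Object of class `rna_structure`: `seq` (RNA display),
#'   `dotbracket`, `pairs` (two-column matrix of 0-based indices, i < j),
#'   `n_pairs`.
#' @export
nussinov_fold <- function(seq, min_loop = 3L, allow_gu = TRUE) {
  stopifnot(nchar(seq) >= 1L, min_loop >= 3L)
  dna <- chartr("Uu", "Tt", toupper(seq))
  chars <- .seq_chars(toupper(dna))
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("invalid base in sequence (expected A/C/G/T/U)")
  n <- length(chars)
  P <- .can_pair_matrix(allow_gu)
  pairable <- P[chars, chars, drop = FALSE]
  M <- matrix(0L, n, n)
  if (n > min_loop + 1L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- M[i + 1L, j]                       # i unpaired
        ks <- (i + min_loop + 1L):j
        ks <- ks[pairable[i, ks]]
        if (length(ks) > 0L) {
          inner <- ifelse(ks - 1L >= i + 1L, M[cbind(i + 1L, pmax(ks - 1L, i + 1L))], 0L)
          inner[ks - 1L < i + 1L] <- 0L
          outer_part <- ifelse(ks + 1L <= j, M[cbind(pmin(ks + 1L, j), j)], 0L)
          outer_part[ks + 1L > j] <- 0L
          best <- max(best, max(1L + inner + outer_part))
        }
        M[i, j] <- best
      }
    }
  }
  # deterministic traceback
  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    while (i < j && j - i > min_loop) {
      target <- M[i, j]
      ks <- (i + min_loop + 1L):j
      ks <- ks[pairable[i, ks]]
      chosen <- NA_integer_
      for (k in ks) {
        inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
        outer_part <- if (k + 1L <= j) M[k + 1L, j] else 0L
        if (1L + inner + outer_part == target) { chosen <- k; break }
      }
      if (is.na(chosen)) {
        i <- i + 1L                     # i unpaired
      } else {
        pairs <- rbind(pairs, c(i, chosen))
        if (chosen + 1L <= j) stack[[length(stack) + 1L]] <- c(chosen + 1L, j)
        i <- i + 1L
        j <- chosen - 1L
        if (j - i <= min_loop) break
      }
    }
  }
  db <- rep(".", n)
  if (nrow(pairs) > 0L) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE] - 1L  # to 0-based
  }
  structure(list(seq = chartr("T", "U", paste(chars, collapse = "")),
                 dotbracket = paste(db, collapse = ""),
                 pairs = pairs,
                 n_pairs = nrow(pairs)),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$seq, "\n", x$dotbracket, "\n", sep = "")
  cat(x$n_pairs, "pair(s)\n")
  invisible(x)
}

#' Build an `rna_structure` from a dot-bracket string
#'
#' Useful for testing and for importing structures computed elsewhere.
#'
#' @param seq Sequence (same length as `dotbracket`).
#' @param dotbracket String over `.`, `(`, `)` with balanced brackets.
#' @return `rna_structure` object.
#' @export
parse_dotbracket <- function(seq, dotbracket) {
  if (nchar(seq) != nchar(dotbracket))
    stop("sequence and dot-bracket lengths differ")
  chars <- .seq_chars(dotbracket)
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      open <- c(open, i)
    } else if (chars[i] == ")") {
      if (length(open) == 0L) stop("unbalanced brackets at position ", i - 1L)
      pairs <- rbind(pairs, c(open[length(open)], i))
      open <- open[-length(open)]
    } else if (chars[i] != ".") {
      stop("invalid dot-bracket character '", chars[i], "'")
    }
  }
  if (length(open) > 0L) stop("unbalanced brackets: unclosed '('")
  if (nrow(pairs) > 0L) pairs <- pairs[order(pairs[, 1]), , drop = FALSE] - 1L
  structure(list(seq = chartr("Tt", "Uu", toupper(seq)),
                 dotbracket = dotbracket,
                 pairs = pairs,
                 n_pairs = nrow(pairs)),
            class = "rna_structure")
}

#' Enumerate hairpin stem-loops of a structure
#'
#' A hairpin is the maximal run of strictly stacked pairs around an
#' innermost pair (one whose enclosed interval contains no other pair).
#' Stems shorter than `min_stem` are dropped.
#'
#' @param structure `rna_structure`.
#' @param min_stem Minimum number of stacked pairs (default 2).
#' @return data.frame with `outer_i`, `outer_j` (0-based outer pair),
#'   `stem_length`, `loop_start`, `loop_end` (0-based half-open unpaired
#'   loop span), sorted by `outer_i`.
#' @export
enumerate_stem_loops <- function(structure, min_stem = 2L) {
  pairs <- structure$pairs
  empty <- data.frame(outer_i = integer(0), outer_j = integer(0),
                      stem_length = integer(0), loop_start = integer(0),
                      loop_end = integer(0))
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty)
  pair_set <- paste(pairs[, 1], pairs[, 2])
  is_pair <- function(i, j) paste(i, j) %in% pair_set
  res <- list()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    enclosed <- pairs[, 1] > i & pairs[, 2] < j
    if (any(enclosed)) next                     # not innermost
    stem <- 1L
    while (is_pair(i - stem, j + stem)) stem <- stem + 1L
    if (stem < min_stem) next
    res[[length(res) + 1L]] <- data.frame(
      outer_i = i - stem + 1L, outer_j = j + stem - 1L,
      stem_length = stem, loop_start = i + 1L, loop_end = j)
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$outer_i), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of an Sm-site span left unpaired by a structure
#'
#' @param structure `rna_structure`.
#' @param sm_span Numeric length-2 vector, 0-based half-open span.
#' @return Unpaired fraction in `[0, 1]`.
#' @export
sm_accessibility <- function(structure, sm_span) {
  n <- nchar(structure$dotbracket)
  if (sm_span[2] <= sm_span[1]) stop("empty Sm span")
  if (sm_span[1] < 0 || sm_span[2] > n) stop("Sm span outside sequence")
  chars <- .seq_chars(structure$dotbracket)
  span <- (sm_span[1] + 1L):sm_span[2]
  mean(chars[span] == ".")
}

#' Score an slRNA fold against the canonical structural criteria
#'
#' Checks the hairpin spanning the exon/intron boundary (with the GU donor
#' enclosed), counts exon-internal hairpins, and measures single-
#' strandedness of the Sm site. The structure `passes` when the boundary
#' hairpin exists and the Sm site is at least `sm_min_unpaired` unpaired.
#'
#' @param model `slrna_gene_model` in transcript coordinates (exon at 0).
#' @param structure `rna_structure` of the full slRNA.
#' @param min_stem Minimum stem length for hairpin enumeration.
#' @param sm_min_unpaired Pass threshold on Sm accessibility (default 0.7).
#' @return One-row data.frame: `n_pairs`, `n_stem_loops`,
#'   `has_exon_intron_hairpin`, `donor_in_hairpin`, `n_exon_hairpins`,
#'   `sm_unpaired_fraction`, `passes`.
#' @export
classify_slrna_structure <- function(model, structure, min_stem = 2L,
                                     sm_min_unpaired = 0.7) {
  n <- nchar(structure$dotbracket)
  slen <- model$exon_length + model$intron_length
  if (slen != n)
    stop("model length (", slen, ") does not match structure length (", n, ")")
  boundary <- model$exon_length          # 0-based first intron position
  loops <- enumerate_stem_loops(structure, min_stem = min_stem)
  spans_boundary <- loops$outer_i < boundary & loops$outer_j >= boundary
  has_boundary_hairpin <- any(spans_boundary)
  donor_pos <- boundary                  # first base of the GU donor
  donor_in_hairpin <- any(spans_boundary &
                          loops$outer_i < donor_pos &
                          loops$outer_j > donor_pos)
  n_exon_hairpins <- sum(loops$outer_j < boundary)
  sm_frac <- if (!is.null(model$sm_site_span)) {
    sm_accessibility(structure, model$sm_site_span)
  } else NA_real_
  data.frame(
    n_pairs = structure$n_pairs,
    n_stem_loops = nrow(loops),
    has_exon_intron_hairpin = has_boundary_hairpin,
    donor_in_hairpin = donor_in_hairpin,
    n_exon_hairpins = n_exon_hairpins,
    sm_unpaired_fraction = sm_frac,
    passes = has_boundary_hairpin && !is.na(sm_frac) &&
      sm_frac >= sm_min_unpaired
  )
}
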
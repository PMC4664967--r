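# Independent brute-force oracles used to freeze expected values.
# Each is written as a direct, unoptimised restatement of the definition,
# independent of the package's implementation path.

# 5'-most ATG opening a reading frame with an in-frame stop and a CDS of at
# least min_codons codons (stop included); enumerates all (ATG, stop) pairs
oracle_orf <- function(body, min_codons = 30L) {
  chars <- strsplit(toupper(body), "")[[1]]
  n <- length(chars)
  stops <- c("TAA", "TAG", "TGA")
  candidates <- list()
  for (s in seq_len(max(n - 2L, 0L))) {
    if (paste(chars[s:(s + 2L)], collapse = "") != "ATG") next
    pos <- s + 3L
    while (pos + 2L <= n) {
      codon <- paste(chars[pos:(pos + 2L)], collapse = "")
      if (codon %in% stops) {
        len <- pos + 3L - s
        if (len >= 3L * min_codons)
          candidates[[length(candidates) + 1L]] <-
            c(start = s - 1L, stop_end = pos + 2L, cds = len)
        break
      }
      pos <- pos + 3L
    }
  }
  if (length(candidates) == 0L) return(NULL)
  best <- candidates[[which.min(vapply(candidates, `[[`, numeric(1), "start"))]]
  as.list(best)
}

# smallest index of an A whose suffix is >= purity A and >= min_run long
oracle_tail <- function(body, min_run = 8L, purity = 0.9) {
  chars <- strsplit(toupper(body), "")[[1]]
  n <- length(chars)
  for (i in seq_len(n)) {
    if (chars[i] != "A") next
    suffix <- chars[i:n]
    if (length(suffix) >= min_run &&
        mean(suffix == "A") >= purity) return(i - 1L)
  }
  NA_integer_
}

# maximum base pairs over all nested structures, by plain recursion
oracle_max_pairs <- function(seq, min_loop = 3L, allow_gu = TRUE) {
  chars <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  pairs_ok <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
    (allow_gu && ((a == "G" && b == "T") || (a == "T" && b == "G")))
  }
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (pairs_ok(chars[i], chars[k])) {
        inner <- if (k - 1L >= i + 1L) rec(i + 1L, k - 1L) else 0L
        outer <- if (k + 1L <= j) rec(k + 1L, j) else 0L
        best <- max(best, 1L + inner + outer)
      }
    }
    best
  }
  n <- length(chars)
  if (n < 2L) return(0L)
  rec(1L, n)
}

# every RR(py-tract)RR occurrence by explicit substring enumeration
oracle_sm_sites <- function(seq, min_tract = 4L, max_tract = 12L,
                            max_inter = 1L) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  pur <- c("A", "G"); pyr <- c("C", "T")
  found <- list()
  for (a in seq_len(n)) {
    for (b in a:n) {
      len <- b - a + 1L
      t <- len - 4L
      if (t < min_tract || t > max_tract) next
      w <- chars[a:b]
      if (!all(w[c(1, 2, len - 1, len)] %in% pur)) next
      tract <- w[3:(len - 2L)]
      if (!all(tract %in% c(pur, pyr))) next
      if (!(tract[1] %in% pyr && tract[length(tract)] %in% pyr)) next
      if (length(tract) > 2L &&
          sum(tract[2:(length(tract) - 1L)] %in% pur) > max_inter) next
      found[[length(found) + 1L]] <- c(start = a - 1L, end = b,
                                       tract_length = t)
    }
  }
  if (length(found) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      tract_length = integer(0)))
  m <- do.call(rbind, found)
  data.frame(start = m[, "start"], end = m[, "end"],
             tract_length = m[, "tract_length"])
}

# random record table used across tests
random_records <- function(n, len = 300L, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }, character(1))
  seq_records(sprintf("r%04d", seq_len(n)), seqs)
}

# a concrete CopepodSL instance used to plant leaders in fixtures
sl_instance <- function() copepod_sl(concrete = TRUE)
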
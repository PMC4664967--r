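# Spliced-leader consensus discovery from the 5' ends of full-length cDNAs.
#
# Full-length cDNA libraries built from trans-spliced mRNAs carry the SL as a
# shared prefix, optionally behind a short 5' extension. Instead of a gapped
# multiple alignment we anchor records on an exact shared k-mer inside a
# fixed 5' scan window, align members on that anchor, and summarise columns
# into a degenerate IUPAC consensus whose 3' boundary is called where
# column conservation collapses into gene-specific sequence.

#' The CopepodSL spliced-leader consensus
#'
#' The 46-nt degenerate consensus of the calanoid copepod spliced leader
#' (CopepodSL), with W and Y at its polymorphic positions. Useful as a
#' ready-made screening consensus and as the default leader template of the
#' synthetic-data generator (instantiated with W->A, Y->C).
#'
#' @param concrete If `TRUE`, return a concrete instance with every
#'   degenerate position resolved (W->A, Y->C) instead of the IUPAC string.
#' @return Character scalar of length 46.
#' @examples
#' nchar(copepod_sl())
#' @export
copepod_sl <- function(concrete = FALSE) {
  cons <- "GTCTAAWACGACCAAGCTWAWWTTGCTTGATTCACTTCWWYAAGAG"
  if (!concrete) return(cons)
  chartr("WY", "AC", cons)
}

#' Cluster records by shared 5'-window k-mer anchors
#'
#' Groups records whose first `scan_window` nucleotides share an exact k-mer.
#' Each record is assigned to at most one cluster (the highest-support
#' anchor); clusters are returned sorted by support, ties broken by
#' lexicographic anchor. Member prefixes are aligned on the anchor so that a
#' short 5' extension (e.g. the 3-nt ATT seen on some SL cDNAs) shifts the
#' frame rather than breaking the cluster.
#'
#' @param records Record table ([seq_records()]).
#' @param k Anchor k-mer length (>= 8).
#' @param scan_window 5' window scanned for anchors (>= k).
#' @param min_support Minimum records per cluster (>= 2).
#' @return List of clusters; each is a list with `anchor_kmer`, `member_ids`,
#'   `aligned_prefixes` (equal length, anchor-aligned), `anchor_offsets`
#'   (0-based offset of the anchor in each member) and `support`.
#' @export
cluster_five_prime_prefixes <- function(records, k = 12L, scan_window = 60L,
                                        min_support = 5L) {
  stopifnot(k >= 8L, scan_window >= k, min_support >= 2L)
  if (nrow(records) == 0L) stop("no records to cluster")
  usable <- records[nchar(records$seq) >= scan_window, , drop = FALSE]
  if (nrow(usable) == 0L) return(list())
  prefixes <- substr(usable$seq, 1L, scan_window)

  # first occurrence offset of every distinct k-mer in each prefix
  n_off <- scan_window - k + 1L
  starts <- seq_len(n_off)
  kmer_tab <- do.call(rbind, lapply(seq_len(nrow(usable)), function(i) {
    kms <- substring(prefixes[i], starts, starts + k - 1L)
    keep <- !duplicated(kms)
    data.frame(rec = i, kmer = kms[keep], offset = starts[keep] - 1L,
               stringsAsFactors = FALSE)
  }))

  assigned <- rep(FALSE, nrow(usable))
  clusters <- list()
  repeat {
    live <- kmer_tab[!assigned[kmer_tab$rec], , drop = FALSE]
    if (nrow(live) == 0L) break
    support <- table(live$kmer)
    best_n <- max(support)
    if (best_n < min_support) break
    anchor <- sort(names(support)[support == best_n])[1]
    rows <- live[live$kmer == anchor, , drop = FALSE]
    rows <- rows[order(rows$rec), , drop = FALSE]
    d <- min(rows$offset)
    shift <- rows$offset - d
    aligned <- substr(usable$seq[rows$rec], 1L + shift, scan_window + shift)
    keep_len <- min(nchar(aligned))
    aligned <- substr(aligned, 1L, keep_len)
    clusters[[length(clusters) + 1L]] <- list(
      anchor_kmer = anchor,
      member_ids = usable$id[rows$rec],
      aligned_prefixes = aligned,
      anchor_offsets = rows$offset,
      support = nrow(rows)
    )
    assigned[rows$rec] <- TRUE
  }
  clusters
}

# per-column A/C/G/T frequency matrix (4 x L) of equal-length strings;
# non-ACGT characters are ignored in the tally
.column_pfm <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("aligned prefixes have unequal lengths")
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), ncol = L, byrow = TRUE)
  pfm <- vapply(seq_len(L), function(j) {
    counts <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
    tot <- sum(counts)
    if (tot == 0L) rep(NA_real_, 4) else as.numeric(counts) / tot
  }, numeric(4))
  rownames(pfm) <- c("A", "C", "G", "T")
  pfm
}

#' Build a degenerate IUPAC consensus from a prefix cluster
#'
#' Per column, the consensus code is the IUPAC code whose expansion is
#' exactly the set of bases with frequency >= `min_freq`; the per-position
#' frequency matrix (pfm) is retained.
#'
#' @param cluster One cluster from [cluster_five_prime_prefixes()], or any
#'   list with an `aligned_prefixes` character vector (equal lengths).
#' @param min_freq Minimum column frequency for a base to enter the
#'   consensus code (0 < min_freq <= 0.5).
#' @return Object of class `sl_consensus`: list with `iupac_string`,
#'   `length`, `pfm` (4 x L matrix, columns sum to 1) and `support`.
#' @export
build_degenerate_consensus <- function(cluster, min_freq = 0.1) {
  stopifnot(min_freq > 0, min_freq <= 0.5)
  seqs <- cluster$aligned_prefixes
  if (length(seqs) < 2L) stop("consensus requires support >= 2")
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned prefixes have unequal lengths")
  pfm <- .column_pfm(seqs)
  codes <- vapply(seq_len(ncol(pfm)), function(j) {
    col <- pfm[, j]
    if (anyNA(col)) return("N")
    bases <- rownames(pfm)[col >= min_freq]
    if (length(bases) == 0L) bases <- rownames(pfm)[which.max(col)]
    iupac_code_for(bases)
  }, character(1))
  structure(
    list(iupac_string = paste(codes, collapse = ""),
         length = ncol(pfm),
         pfm = pfm,
         support = if (!is.null(cluster$support)) cluster$support
                   else length(seqs)),
    class = "sl_consensus"
  )
}

#' @export
print.sl_consensus <- function(x, ...) {
  cat("SL consensus (", x$length, " nt, support ", x$support, ")\n",
      x$iupac_string, "\n", sep = "")
  invisible(x)
}

#' Locate the 3' boundary of the shared leader in a prefix cluster
#'
#' Column conservation (maximum base frequency) stays near 1 across the
#' shared leader and collapses where gene-specific sequence begins. The
#' boundary is the smallest index `b` such that mean conservation over
#' columns `[b, b + window)` drops below `conservation_threshold`.
#'
#' @param cluster Cluster with `aligned_prefixes`.
#' @param conservation_threshold In (0, 1); default 0.9.
#' @param window Number of columns averaged (default 5).
#' @return List with `boundary` (0-based column index, i.e. the leader
#'   length) and `no_dropoff` (TRUE when conservation never fell below the
#'   threshold, in which case `boundary` is the full prefix length).
#' @export
find_sl_boundary <- function(cluster, conservation_threshold = 0.9,
                             window = 5L) {
  stopifnot(conservation_threshold > 0, conservation_threshold < 1,
            window >= 1L)
  pfm <- .column_pfm(cluster$aligned_prefixes)
  conservation <- apply(pfm, 2, function(col) if (anyNA(col)) 0 else max(col))
  L <- length(conservation)
  if (L < window) return(list(boundary = L, no_dropoff = TRUE))
  # the boundary column must itself fall below the threshold, and the drop
  # must be sustained over the following window (so one noisy column inside
  # the leader does not truncate it)
  means <- vapply(seq_len(L - window + 1L), function(b) {
    mean(conservation[b:(b + window - 1L)])
  }, numeric(1))
  hit <- which(conservation[seq_along(means)] < conservation_threshold &
               means < conservation_threshold)
  if (length(hit) == 0L) {
    warning("conservation never drops below threshold; returning full prefix")
    return(list(boundary = L, no_dropoff = TRUE))
  }
  list(boundary = hit[1] - 1L, no_dropoff = FALSE)
}

#' Enumerate (or count) concrete instances of a degenerate consensus
#'
#' @param consensus `sl_consensus` object or IUPAC string.
#' @param limit Maximum number of instances materialised (default 1024).
#' @return List with `count` (product of per-position expansion sizes) and
#'   `instances` (character vector, truncated at `limit`).
#' @export
enumerate_consensus_instances <- function(consensus, limit = 1024L) {
  stopifnot(limit >= 1L)
  iupac <- if (inherits(consensus, "sl_consensus")) consensus$iupac_string
           else consensus
  chars <- .seq_chars(toupper(iupac))
  exps <- lapply(chars, iupac_expand)
  count <- prod(vapply(exps, length, integer(1)))
  instances <- ""
  for (e in exps) {
    # expand position by position, truncating to the first `limit` instances
    instances <- as.vector(t(outer(instances, e, paste0)))
    if (length(instances) > limit) instances <- instances[seq_len(limit)]
  }
  list(count = count, instances = instances)
}

#' Discover the spliced-leader consensus of a cDNA library
#'
#' Convenience wrapper: cluster 5' prefixes, take the top-support cluster,
#' call the leader boundary, and build the degenerate consensus over the
#' leader columns only.
#'
#' @inheritParams cluster_five_prime_prefixes
#' @inheritParams build_degenerate_consensus
#' @inheritParams find_sl_boundary
#' @return `sl_consensus` with extra fields `boundary`, `no_dropoff` and
#'   `cluster`; `NULL` when no cluster reaches `min_support`.
#' @export
discover_sl <- function(records, k = 12L, scan_window = 60L, min_support = 5L,
                        min_freq = 0.1, conservation_threshold = 0.9,
                        window = 5L) {
  clusters <- cluster_five_prime_prefixes(records, k = k,
                                          scan_window = scan_window,
                                          min_support = min_support)
  if (length(clusters) == 0L) return(NULL)
  top <- clusters[[1]]
  b <- find_sl_boundary(top, conservation_threshold = conservation_threshold,
                        window = window)
  leader_cols <- max(b$boundary, 1L)
  trimmed <- top
  trimmed$aligned_prefixes <- substr(top$aligned_prefixes, 1L, leader_cols)
  cons <- build_degenerate_consensus(trimmed, min_freq = min_freq)
  cons$boundary <- b$boundary
  cons$no_dropoff <- b$no_dropoff
  cons$cluster <- top
  cons
}

#' Write / read a consensus report TSV
#'
#' The TSV carries the IUPAC string, length and support in a header block of
#' key-value rows followed by one row per position with A/C/G/T frequencies.
#'
#' @param consensus `sl_consensus`.
#' @param path Output path.
#' @return `path` invisibly (write); `sl_consensus` (read).
#' @export
write_consensus_tsv <- function(consensus, path) {
  pfm <- consensus$pfm
  df <- data.frame(
    iupac_string = consensus$iupac_string,
    length = consensus$length,
    support = consensus$support,
    position = seq_len(ncol(pfm)) - 1L,
    A = pfm["A", ], C = pfm["C", ], G = pfm["G", ], T = pfm["T", ]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_consensus_tsv
#' @export
read_consensus_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  pfm <- t(as.matrix(df[, c("A", "C", "G", "T")]))
  rownames(pfm) <- c("A", "C", "G", "T")
  colnames(pfm) <- NULL
  structure(list(iupac_string = df$iupac_string[1],
                 length = df$length[1],
                 pfm = pfm,
                 support = df$support[1]),
            class = "sl_consensus")
}
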
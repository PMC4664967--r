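# End-to-end pipeline: discover -> screen -> trim -> annotate -> slRNA ->
# fold, with fixed stage order, TSV reports and a reproducible manifest.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full SL analysis pipeline
#'
#' Stages run in a fixed order; each writes its TSV into `out_dir` before
#' the next starts, so a failure preserves completed outputs. A manifest
#' records package version, parameters and input checksums; re-running
#' with identical inputs reproduces every output byte for byte.
#'
#' @param cdna_fasta Path to transcript/cDNA FASTA (required unless only
#'   slRNA stages are requested).
#' @param genomic_fasta Optional path to genomic FASTA for slRNA-unit
#'   annotation.
#' @param slrna_fasta Optional path to slRNA transcript FASTA for
#'   classification and folding.
#' @param out_dir Output directory (created if absent).
#' @param consensus Optional `sl_consensus` or IUPAC string; when supplied
#'   the discovery stage is skipped.
#' @param params Named list overriding stage defaults: `k`, `scan_window`,
#'   `min_support`, `min_freq`, `conservation_threshold`, `boundary_window`,
#'   `max_mismatch`, `max_5p_offset`, `min_partial_length`,
#'   `min_cds_codons`, `tail_min_run`, `tail_purity`, `sm` (from
#'   [sm_params()]), `min_stem`, `sm_min_unpaired`.
#' @return Invisible list with the consensus, stage results and output
#'   paths.
#' @export
run_pipeline <- function(cdna_fasta = NULL, genomic_fasta = NULL,
                         slrna_fasta = NULL, out_dir, consensus = NULL,
                         params = list()) {
  defaults <- list(k = 12L, scan_window = 60L, min_support = 5L,
                   min_freq = 0.1, conservation_threshold = 0.9,
                   boundary_window = 5L, max_mismatch = 2L,
                   max_5p_offset = 5L, min_partial_length = 15L,
                   min_cds_codons = 30L, tail_min_run = 8L,
                   tail_purity = 0.9, sm = sm_params(), min_stem = 2L,
                   sm_min_unpaired = 0.7)
  p <- utils::modifyList(defaults, params)
  inputs <- c(cdna = cdna_fasta, genomic = genomic_fasta, slrna = slrna_fasta)
  missing_in <- inputs[!vapply(inputs, file.exists, logical(1))]
  if (length(missing_in) > 0L)
    stop("input file not found: ", paste(missing_in, collapse = ", "))
  if (is.null(cdna_fasta) && is.null(consensus))
    stop("either cdna_fasta (for discovery) or a consensus is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  results <- list()

  cdna <- if (!is.null(cdna_fasta)) read_fasta(cdna_fasta) else NULL

  # -- discover ------------------------------------------------------------
  if (is.null(consensus)) {
    consensus <- discover_sl(cdna, k = p$k, scan_window = p$scan_window,
                             min_support = p$min_support,
                             min_freq = p$min_freq,
                             conservation_threshold = p$conservation_threshold,
                             window = p$boundary_window)
    if (is.null(consensus))
      stop("discovery stage found no prefix cluster with support >= ",
           p$min_support)
    paths$consensus <- file.path(out_dir, "consensus.tsv")
    write_consensus_tsv(consensus, paths$consensus)
  }
  results$consensus <- consensus

  # -- screen + trim -------------------------------------------------------
  if (!is.null(cdna)) {
    screen <- screen_dataset(cdna, consensus, max_mismatch = p$max_mismatch,
                             max_5p_offset = p$max_5p_offset,
                             min_partial_length = p$min_partial_length)
    paths$screen <- .write_tsv(screen$per_record,
                               file.path(out_dir, "screen.tsv"))
    results$screen <- screen
    full_rows <- screen$per_record[screen$per_record$mode == "full", ]
    trimmed <- cdna[match(full_rows$record_id, cdna$id), , drop = FALSE]
    trimmed$seq <- substr(trimmed$seq, full_rows$leader_end + 1L,
                          nchar(trimmed$seq))
    trimmed <- trimmed[nzchar(trimmed$seq), , drop = FALSE]
    paths$trimmed <- file.path(out_dir, "trimmed.fasta")
    write_fasta(trimmed, paths$trimmed)
    results$trimmed <- trimmed

    # -- annotate ----------------------------------------------------------
    if (nrow(trimmed) > 0L) {
      ann <- annotate_library(trimmed, min_cds_codons = p$min_cds_codons,
                              min_run = p$tail_min_run, purity = p$tail_purity)
      paths$annotations <- .write_tsv(ann$annotations,
                                      file.path(out_dir, "annotations.tsv"))
      paths$codon_usage <- .write_tsv(ann$codon_usage,
                                      file.path(out_dir, "codon_usage.tsv"))
      summary <- summarize_library(ann$annotations,
                                   body_lengths = nchar(trimmed$seq))
      paths$summary <- .write_tsv(summary, file.path(out_dir, "summary.tsv"))
      results$annotation <- ann
      results$summary <- summary
    }
  }

  # -- slRNA genomic units -------------------------------------------------
  if (!is.null(genomic_fasta)) {
    genomic <- read_fasta(genomic_fasta)
    model_rows <- list()
    layout_rows <- list()
    for (i in seq_len(nrow(genomic))) {
      gseq <- genomic$seq[i]
      hits <- locate_sl_exons(gseq, consensus, max_mismatch = p$max_mismatch)
      plus_hits <- hits[hits$strand == "+", , drop = FALSE]
      models <- lapply(seq_len(nrow(plus_hits)), function(h) {
        annotate_slrna_unit(gseq, plus_hits[h, ], params = p$sm)
      })
      layout <- detect_array_layout(gseq, plus_hits, models)
      for (m in models) {
        model_rows[[length(model_rows) + 1L]] <- data.frame(
          sequence_id = genomic$id[i],
          exon_start = m$exon_span[1], exon_end = m$exon_span[2],
          exon_length = m$exon_length, intron_length = m$intron_length,
          donor_ok = m$donor_ok,
          sm_start = if (!is.null(m$sm_site_span)) m$sm_site_span[1] else NA,
          sm_end = if (!is.null(m$sm_site_span)) m$sm_site_span[2] else NA,
          tract_length = m$sm_tract_length,
          interruptions = m$sm_interruptions,
          qc_flags = paste(m$qc_flags, collapse = ";"),
          stringsAsFactors = FALSE)
      }
      layout_rows[[length(layout_rows) + 1L]] <- data.frame(
        sequence_id = genomic$id[i],
        cluster_type = layout$cluster_type,
        n_units = length(layout$unit_starts),
        inter_unit_distances = paste(layout$inter_unit_distances,
                                     collapse = ","),
        stringsAsFactors = FALSE)
    }
    paths$slrna_models <- .write_tsv(do.call(rbind, model_rows),
                                     file.path(out_dir, "slrna_models.tsv"))
    paths$layout <- .write_tsv(do.call(rbind, layout_rows),
                               file.path(out_dir, "layout.tsv"))
    results$slrna_models <- model_rows
    results$layout <- layout_rows
  }

  # -- slRNA transcripts: classify + fold ----------------------------------
  if (!is.null(slrna_fasta)) {
    slrna <- read_fasta(slrna_fasta)
    rows <- list()
    for (i in seq_len(nrow(slrna))) {
      rec <- list(id = slrna$id[i], seq = slrna$seq[i])
      model <- classify_slrna_transcript(rec, consensus, params = p$sm,
                                         max_mismatch = p$max_mismatch)
      if (is.null(model)) next
      structure <- nussinov_fold(slrna$seq[i])
      rep <- classify_slrna_structure(model, structure,
                                      min_stem = p$min_stem,
                                      sm_min_unpaired = p$sm_min_unpaired)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(sequence_id = slrna$id[i]), rep)
    }
    fold_df <- if (length(rows) > 0L) do.call(rbind, rows) else
      data.frame(sequence_id = character(0))
    paths$structure_report <- .write_tsv(
      fold_df, file.path(out_dir, "structure_report.tsv"))
    results$structure_report <- fold_df
  }

  # -- manifest ------------------------------------------------------------
  manifest <- data.frame(
    key = c("package", "version",
            paste0("input_", names(inputs), "_md5"),
            "params"),
    value = c("slsplice",
              as.character(utils::packageVersion("slsplice")),
              unname(tools::md5sum(unlist(inputs))),
              paste(names(p), vapply(p, function(x)
                paste(format(unlist(x)), collapse = ","), character(1)),
                sep = "=", collapse = ";")),
    stringsAsFactors = FALSE)
  paths$manifest <- .write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(consensus = consensus, results = results, paths = paths))
}
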
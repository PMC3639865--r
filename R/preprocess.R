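#' Demultiplex raw reads by exact MID and primer match
#'
#' A read is assigned if and only if its first 10 bases exactly equal a MID
#' from the association and the following bases exactly equal one of the
#' panel's primers (the forward primer, or the reverse primer as it appears
#' on reverse-orientation reads). Anything else lands in the unassigned pool
#' with a reject reason (`no-MID` or `no-primer`). An optional fuzzy mode
#' tolerates one MID mismatch (the packaged MIDs are pairwise Hamming
#' distance >= 3, so one error is still unambiguous); it is off by default.
#'
#' @param reads Read tibble (`read_id`, `sequence`).
#' @param panel An `hla_panel`.
#' @param association Association tibble (`sample_id`, `mid_id`, `mid`).
#' @param db An `hla_allele_db` used to resolve primer sequences.
#' @param layout Optional precomputed [amplicon_layout()].
#' @param max_mid_mismatch 0 (exact, default) or 1.
#' @return A tibble of class `hla_demux`: the input plus `sample_id`,
#'   `amplicon`, `direction`, `status` (`assigned`/`no-MID`/`no-primer`).
#'   Every input read appears exactly once.
#' @export
demultiplex <- function(reads, panel, association, db, layout = NULL,
                        max_mid_mismatch = 0) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  if (anyDuplicated(association$mid)) abort("duplicate MID in association")
  if (!all(association$mid %in% panel$mids$sequence)) {
    abort("association contains MIDs not in the panel")
  }
  lay <- layout %||% amplicon_layout(panel, db)

  mid_obs <- substr(reads$sequence, 1, 10)
  sample_id <- association$sample_id[match(mid_obs, association$mid)]
  if (max_mid_mismatch >= 1) {
    miss <- which(is.na(sample_id))
    if (length(miss) > 0) {
      for (k in miss) {
        d <- vapply(association$mid, function(m) {
          sum(charToRaw(m) != charToRaw(mid_obs[k]))
        }, integer(1))
        j <- which(d <= max_mid_mismatch)
        if (length(j) == 1) sample_id[k] <- association$sample_id[j]
      }
    }
  }

  amplicon <- rep(NA_character_, nrow(reads))
  direction <- rep(NA_character_, nrow(reads))
  rest_start <- 11L
  for (i in seq_len(nrow(lay))) {
    for (dir in c("fwd", "rev")) {
      primer <- if (dir == "fwd") lay$fwd_primer[i] else lay$rev_primer_read[i]
      pl <- nchar(primer)
      hit <- is.na(amplicon) &
        substr(reads$sequence, rest_start, rest_start + pl - 1L) == primer
      amplicon[hit] <- lay$amplicon[i]
      direction[hit] <- dir
    }
  }

  status <- dplyr::case_when(
    is.na(sample_id) ~ "no-MID",
    is.na(amplicon) ~ "no-primer",
    TRUE ~ "assigned"
  )
  out <- reads |>
    dplyr::mutate(
      sample_id = ifelse(status == "assigned", sample_id, NA_character_),
      amplicon = ifelse(status == "assigned", amplicon, NA_character_),
      direction = ifelse(status == "assigned", direction, NA_character_),
      status = status
    )
  class(out) <- c("hla_demux", class(out))
  out
}

#' Trim assigned reads at the exon boundary
#'
#' Removes the MID and primer from the 5' end and cuts the read after the
#' targeted exon (summing MID, primer, primer-to-exon distance and exon
#' length, per the trimming-point arithmetic). Reverse reads are
#' reverse-complemented first so all trimmed sequences are in forward gene
#' orientation. In `exon_plus_flank` mode up to `offset` bases of intron
#' flank are retained on each side (where the amplicon geometry provides
#' them); `exon_only` keeps the covered exon exactly. The cut always retains
#' the complete covered exon present in the read; reads shorter than
#' MID + primer are rejected as `too_short`.
#'
#' @param demux An `hla_demux` from [demultiplex()].
#' @param panel An `hla_panel`.
#' @param db An `hla_allele_db`.
#' @param mode `"exon_plus_flank"` or `"exon_only"`.
#' @param offset Retained flank width in bp (`exon_plus_flank` mode).
#' @param layout Optional precomputed [amplicon_layout()].
#' @return The demux tibble with a `trimmed` column (NA for unassigned
#'   reads) and `status` upgraded to `too_short` where applicable.
#' @export
trim_reads <- function(demux, panel, db, mode = c("exon_plus_flank", "exon_only"),
                       offset = 10L, layout = NULL) {
  mode <- match.arg(mode)
  lay <- layout %||% amplicon_layout(panel, db)
  trimmed <- rep(NA_character_, nrow(demux))
  status <- demux$status
  for (i in seq_len(nrow(lay))) {
    row <- lay[i, ]
    fw <- flank_widths(row, mode, offset)
    ws <- row$xs - fw[1]; we <- row$xe + fw[2]
    for (dir in c("fwd", "rev")) {
      idx <- which(demux$status == "assigned" & demux$amplicon == row$amplicon &
                     demux$direction == dir)
      if (length(idx) == 0) next
      plen <- nchar(if (dir == "fwd") row$fwd_primer else row$rev_primer_read)
      seqs <- demux$sequence[idx]
      short <- nchar(seqs) <= 10L + plen
      if (any(short)) {
        status[idx[short]] <- "too_short"
        idx <- idx[!short]; seqs <- seqs[!short]
        if (length(idx) == 0) next
      }
      rest <- substr(seqs, 11L + plen, nchar(seqs))
      if (dir == "fwd") {
        a <- ws - (row$fwd_end + 1L) + 1L
        b <- we - (row$fwd_end + 1L) + 1L
      } else {
        rest <- revcomp(rest)
        a <- ws - row$s + 1L
        b <- we - row$s + 1L
      }
      trimmed[idx] <- substr(rest, pmax(1L, a), pmin(b, nchar(rest)))
    }
  }
  demux$trimmed <- trimmed
  demux$status <- status
  demux
}

#' Run-level performance report
#'
#' Summarises a demultiplexed read set into the run metrics a sequencing
#' report carries: passed-filter (total) reads, assigned/unassigned counts,
#' median and mean raw read length, and per-amplicon / per-sample read
#' counts (the boxplot-ready per-amplicon table). Sequencer-level well
#' metrics (mixed/dot wells) have no computable analogue here and are
#' carried as nullable pass-through fields.
#'
#' @param demux An `hla_demux`.
#' @param run_id Optional run identifier.
#' @return A list of class `hla_run_report`.
#' @export
build_run_report <- function(demux, run_id = NA_character_) {
  n <- nrow(demux)
  assigned <- sum(demux$status == "assigned" | demux$status == "too_short")
  per_amplicon <- demux |>
    dplyr::filter(!is.na(.data$amplicon)) |>
    dplyr::count(.data$amplicon, name = "n_reads")
  per_sample_amplicon <- demux |>
    dplyr::filter(!is.na(.data$amplicon)) |>
    dplyr::count(.data$sample_id, .data$amplicon, name = "n_reads")
  structure(
    list(
      run_id = run_id,
      total_reads = n,
      assigned_reads = assigned,
      unassigned_reads = n - assigned,
      median_read_length = if (n > 0) stats::median(nchar(demux$sequence)) else 0,
      mean_read_length = if (n > 0) mean(nchar(demux$sequence)) else 0,
      per_amplicon = per_amplicon,
      per_sample_amplicon = per_sample_amplicon,
      mixed_wells = NA_integer_,
      dot_wells = NA_integer_
    ),
    class = "hla_run_report"
  )
}

#' @export
print.hla_run_report <- function(x, ...) {
  cat(sprintf(paste0("<hla_run_report> %s\n",
                     "  passed filter reads: %d (assigned %d / unassigned %d)\n",
                     "  median read length: %.0f bp, mean %.1f bp\n"),
              x$run_id %||% "", x$total_reads, x$assigned_reads,
              x$unassigned_reads, x$median_read_length, x$mean_read_length))
  invisible(x)
}

#' Write a run report (JSON + plain text)
#'
#' @param report An `hla_run_report`.
#' @param path Output JSON path (a `.txt` rendering is written alongside).
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  txt <- c(
    sprintf("run: %s", report$run_id),
    sprintf("passed filter reads: %d", report$total_reads),
    sprintf("assigned reads: %d", report$assigned_reads),
    sprintf("unassigned reads: %d", report$unassigned_reads),
    sprintf("median read length: %.0f", report$median_read_length),
    sprintf("mean read length: %.1f", report$mean_read_length),
    "",
    "reads per amplicon:",
    sprintf("  %-8s %6d", report$per_amplicon$amplicon,
            report$per_amplicon$n_reads)
  )
  writeLines(txt, sub("\\.json$", ".txt", path))
  invisible(path)
}

#' Plot per-amplicon read counts
#'
#' Boxplots of raw per-sample amplicon read counts, the standard run-balance
#' view for an amplicon panel.
#'
#' @param object An `hla_run_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hla_run_report <- function(object, ...) {
  ggplot2::ggplot(object$per_sample_amplicon,
                  ggplot2::aes(x = .data$amplicon, y = .data$n_reads)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "raw amplicon read count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Build a MID-sample association
#'
#' @param samples Character vector of sample ids.
#' @param mids MID tibble (`mid_id`, `sequence`), e.g. `panel$mids`.
#' @param run_id Run identifier embedded in the association to prevent
#'   cross-run mix-ups.
#' @return Association tibble (`sample_id`, `mid_id`, `mid`, `run_id`).
#' @export
make_association <- function(samples, mids, run_id) {
  if (length(samples) > nrow(mids)) {
    abort(sprintf("sample count (%d) exceeds MID count (%d)",
                  length(samples), nrow(mids)))
  }
  tibble(
    sample_id = samples,
    mid_id = mids$mid_id[seq_along(samples)],
    mid = mids$sequence[seq_along(samples)],
    run_id = run_id
  )
}

#' Write / read a MID-sample association file
#'
#' @param association Association tibble (`sample_id`, `mid_id`, `mid`,
#'   `run_id`).
#' @param path TSV path.
#' @return `path` (write) or the association tibble (read).
#' @export
write_association_file <- function(association, path) {
  stopifnot(all(c("sample_id", "mid_id", "mid", "run_id") %in%
                  names(association)))
  readr::write_tsv(association, path)
  invisible(path)
}

#' @rdname write_association_file
#' @param expected_run_id If given, a mismatch with the file's run id raises
#'   a warning (association from another run).
#' @export
read_association_file <- function(path, expected_run_id = NULL) {
  assoc <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!is.null(expected_run_id) &&
      any(assoc$run_id != expected_run_id)) {
    warn(sprintf("association run id %s does not match run %s",
                 assoc$run_id[1], expected_run_id))
  }
  assoc
}
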
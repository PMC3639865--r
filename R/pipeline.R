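#' Concordance of typing calls against known genotypes
#'
#' A called locus is *correct* iff the true 4-digit genotype pair is
#' contained in the reported ambiguity string; *mistyping* iff called but
#' the truth is absent. `no_result` loci (insufficient reads) and
#' review-flagged loci are counted separately and do not enter the
#' concordance rate, which is computed over typings with a result.
#'
#' @param typing An `hla_typing` tibble ([type_samples()]).
#' @param truth Genotype tibble ([simulate_genotypes()]).
#' @return A tibble of class `hla_concordance`: per locus (plus an `all`
#'   row) `total`, `no_result`, `called`, `correct`, `mistyping`,
#'   `concordance_pct`. The per-typing detail is in attribute `detail`.
#' @export
concordance <- function(typing, truth) {
  merged <- truth |>
    dplyr::inner_join(
      typing |> dplyr::select("sample_id", "locus", "status",
                              "ambiguity_4digit"),
      by = c("sample_id", "locus")
    )
  if (nrow(typing) == 0) {
    out <- tibble(locus = "all", total = 0L, no_result = 0L, called = 0L,
                  correct = 0L, mistyping = 0L, concordance_pct = NA_real_)
    class(out) <- c("hla_concordance", class(out))
    return(out)
  }
  if (nrow(merged) == 0) abort("no overlapping sample/locus between typing and truth")
  if (nrow(merged) < nrow(truth)) {
    warn("some truth sample/locus combinations were not typed")
  }
  detail <- merged |>
    dplyr::mutate(
      truth_pair = pair_key(reduce_to_4digit(.data$allele1),
                            reduce_to_4digit(.data$allele2)),
      outcome = dplyr::case_when(
        status != "called" ~ "no_result",
        purrr::map2_lgl(.data$truth_pair, .data$ambiguity_4digit,
                        function(tp, ab) {
                          tp %in% strsplit(ab, " | ", fixed = TRUE)[[1]]
                        }) ~ "correct",
        TRUE ~ "mistyping"
      )
    )
  summarise_block <- function(d, label) {
    tibble(
      locus = label,
      total = nrow(d),
      no_result = sum(d$outcome == "no_result"),
      called = sum(d$outcome != "no_result"),
      correct = sum(d$outcome == "correct"),
      mistyping = sum(d$outcome == "mistyping"),
      concordance_pct = if (sum(d$outcome != "no_result") > 0) {
        100 * sum(d$outcome == "correct") / sum(d$outcome != "no_result")
      } else {
        NA_real_
      }
    )
  }
  out <- dplyr::bind_rows(
    purrr::map_dfr(sort(unique(detail$locus)), function(lc) {
      summarise_block(detail[detail$locus == lc, ], lc)
    }),
    summarise_block(detail, "all")
  )
  attr(out, "detail") <- detail
  class(out) <- c("hla_concordance", class(out))
  out
}

#' End-to-end synthetic validation run
#'
#' Simulates genotypes and reads for a sample batch, runs demultiplexing,
#' trimming and genotype calling, and summarises concordance against the
#' simulated truth. This is the package's scaled-down analogue of a wet-lab
#' validation study.
#'
#' Samples are processed in sequencing runs of at most `batch_size` samples
#' (the panel carries 14 MIDs; a run types ten samples), each with its own
#' run id and MID association, and the typing results are combined — the
#' same way a multi-run validation study accumulates samples.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_samples Number of samples (batched over runs).
#' @param loci Loci to simulate and type.
#' @param mean_depth Mean reads per factor-1 amplicon.
#' @param homozygote_rate Homozygous genotype probability.
#' @param model [error_model()] for the simulated reads.
#' @param mode Trimming/matching mode.
#' @param db,panel Reference database and panel (defaults: packaged mocks).
#' @param min_reads Minimum master reads per amplicon for a call.
#' @param batch_size Samples per simulated sequencing run.
#' @return A list: `truth`, `runs` (per-run reads + association),
#'   `reports` (per-run `hla_run_report`), `typing` (`hla_typing`),
#'   `concordance` (`hla_concordance`).
#' @export
validation_run <- function(seed, n_samples = 20, loci = c("A", "B", "C"),
                           mean_depth = 200, homozygote_rate = 0.103,
                           model = error_model(),
                           mode = "exon_plus_flank",
                           db = mock_allele_db(), panel = mock_panel(),
                           min_reads = 20L, batch_size = 10L) {
  truth <- simulate_genotypes(db, n_samples, homozygote_rate, seed = seed,
                              loci = loci)
  samples <- unique(truth$sample_id)
  batches <- split(samples, ceiling(seq_along(samples) / batch_size))
  layout <- amplicon_layout(panel, db)
  runs <- list(); reports <- list(); typings <- list()
  for (b in seq_along(batches)) {
    btruth <- truth[truth$sample_id %in% batches[[b]], ]
    sim <- simulate_reads(btruth, db, panel, mean_depth = mean_depth,
                          model = model, seed = seed + b,
                          run_id = sprintf("RUN%05d_%d", seed %% 100000L, b))
    demux <- demultiplex(sim$reads[c("read_id", "sequence")], panel,
                         sim$association, db, layout = layout)
    trimmed <- trim_reads(demux, panel, db, mode = mode, layout = layout)
    typings[[b]] <- type_samples(trimmed, db, panel, loci = loci, mode = mode,
                                 min_reads = min_reads)
    runs[[b]] <- sim
    reports[[b]] <- build_run_report(demux, run_id = sim$run_id)
  }
  typing <- dplyr::bind_rows(typings)
  class(typing) <- unique(c("hla_typing", class(typing)))
  list(
    truth = truth,
    runs = runs,
    reports = reports,
    typing = typing,
    concordance = concordance(typing, truth)
  )
}

#' Read a run configuration file
#'
#' Flat TOML-style `key = value` lines (comments with `#`). Recognised keys:
#' `db`, `panel`, `mids`, `reads`, `assoc`, `truth`, `outdir`, `mode`,
#' `offset`, `min_reads`, `fail_threshold`, `min_cluster_fraction`, `seed`,
#' `n_samples`, `mean_depth`, `homozygote_rate`, `loci` (comma separated).
#'
#' @param path Config file path.
#' @return Named list with numerics parsed.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such config file: %s", path))
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  if (any(lengths(kv) == 0)) {
    abort(sprintf("malformed config line: '%s'", lines[lengths(kv) == 0][1]))
  }
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- trimws(gsub('^"|"$', "", vapply(kv, `[`, character(1), 3)))
  out <- lapply(vals, function(v) {
    if (grepl("^-?[0-9.]+([eE][+-]?[0-9]+)?$", v)) as.numeric(v) else v
  })
  stats::setNames(out, keys)
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate (when no reads file is given) -> demultiplex ->
#' trim -> type -> report, writing all stage outputs under
#' `config$outdir`: reads FASTA, MID association TSV, run report JSON/text,
#' typing report JSON, the flat 4-digit export TSV, and (when truth is
#' available) the concordance table. Deterministic given the same inputs
#' and seed; biological `no_result` calls are report content, not errors.
#'
#' @param config Named list or path to a config file
#'   ([read_run_config()]).
#' @return Invisibly, the [validation_run()]-style result list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...)))
  }
  db <- if (!is.null(config$db)) read_allele_db(config$db) else mock_allele_db()
  panel <- if (!is.null(config$panel)) {
    load_panel(config$panel, config$mids)
  } else {
    mock_panel()
  }
  mode <- config$mode %||% "exon_plus_flank"
  loci <- if (!is.null(config$loci)) {
    strsplit(config$loci, ",", fixed = TRUE)[[1]]
  } else {
    c("A", "B", "C")
  }
  truth <- NULL
  if (is.null(config$reads)) {
    if (is.null(config$seed)) abort("config needs a seed to simulate")
    seed <- as.integer(config$seed)
    log_msg("simulating %d samples at depth %s (seed %d)",
            config$n_samples %||% 10, config$mean_depth %||% 182, seed)
    truth <- simulate_genotypes(db, as.integer(config$n_samples %||% 10),
                                config$homozygote_rate %||% 0.103,
                                seed = seed, loci = loci, panel = panel)
    sim <- simulate_reads(truth, db, panel,
                          mean_depth = config$mean_depth %||% 182,
                          model = error_model(), seed = seed + 1L)
    reads <- sim$reads[c("read_id", "sequence")]
    association <- sim$association
    write_reads_fasta(reads, file.path(outdir, "reads.fna"))
    write_truth_json(truth, file.path(outdir, "truth.json"))
  } else {
    log_msg("loading reads from %s", config$reads)
    reads <- read_reads_fasta(config$reads)
    association <- read_association_file(config$assoc)
    if (!is.null(config$truth)) {
      truth <- as_tibble(jsonlite::read_json(config$truth, simplifyVector = TRUE))
    }
    sim <- list(reads = reads, association = association,
                run_id = association$run_id[1])
  }
  write_association_file(association, file.path(outdir, "association.tsv"))

  log_msg("demultiplexing %d reads", nrow(reads))
  demux <- demultiplex(reads, panel, association, db)
  trimmed <- trim_reads(demux, panel, db, mode = mode,
                        offset = as.integer(config$offset %||% 10))
  report <- build_run_report(demux, run_id = sim$run_id)
  write_run_report(report, file.path(outdir, "run_report.json"))

  log_msg("typing %d samples at %s", length(unique(association$sample_id)),
          paste(loci, collapse = ","))
  typing <- type_samples(trimmed, db, panel, loci = loci, mode = mode,
                         offset = as.integer(config$offset %||% 10),
                         min_reads = as.integer(config$min_reads %||% 20),
                         fail_threshold = as.integer(config$fail_threshold %||% 4),
                         min_cluster_fraction = config$min_cluster_fraction %||% 0.10)
  write_typing_json(typing, file.path(outdir, "typing.json"))
  export_4digit(typing, file.path(outdir, "typing_4digit.tsv"))

  conc <- NULL
  if (!is.null(truth)) {
    conc <- concordance(typing, truth)
    readr::write_tsv(as_tibble(conc), file.path(outdir, "concordance.tsv"))
    log_msg("concordance over called loci: %.1f%%",
            conc$concordance_pct[conc$locus == "all"])
  }
  log_msg("done; outputs in %s", outdir)
  invisible(list(truth = truth, sim = sim, report = report, typing = typing,
                 concordance = conc))
}

#' Write the typing report as JSON
#'
#' Per sample and locus: status, candidate pairs with their MM/MM3/MM4
#' phase-layer counts, the 4-digit ambiguity string, null-allele exclusions
#' and per-amplicon master read counts.
#'
#' @param typing An `hla_typing` tibble.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_typing_json <- function(typing, path) {
  recs <- purrr::map(typing$call, function(call) {
    list(
      sample_id = call$sample_id,
      locus = call$locus,
      status = call$status,
      candidates = call$candidates,
      ambiguity_4digit = call$ambiguity_4digit,
      excluded_null_alleles = call$excluded_null_alleles,
      warnings = call$warnings,
      read_counts = as.list(call$read_counts),
      clusters = call$clusters[c("amplicon", "cluster_id", "read_count",
                                 "fwd_count", "rev_count")]
    )
  })
  jsonlite::write_json(list(schema = "hlatyper-typing/1", results = recs),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Plot per-locus concordance
#'
#' @param object An `hla_concordance`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hla_concordance <- function(object, ...) {
  d <- object[object$locus != "all", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$locus, y = .data$concordance_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "concordance among called loci [%]") +
    ggplot2::theme_minimal()
}
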
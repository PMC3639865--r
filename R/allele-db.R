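#' Annotated allele reference databases
#'
#' An `hla_allele_db` holds named allele sequences together with per-feature
#' (exon/intron/NCR) coordinates, mirroring the structure of curated HLA
#' references. Feature *absence* is first class: real reference databases lack
#' intronic sequence for the broad majority of alleles, and matching must
#' treat a missing feature as a wildcard rather than an empty string.
#'
#' The on-disk representation is an annotated-FASTA dialect:
#' a `#version=<text>` line at the top, then per allele a header
#' `>LOCUS*NAME features=exon1:1-73,intron1:74-203,...` (1-based inclusive
#' coordinates into the record's own sequence) followed by the wrapped
#' sequence. [read_allele_db()] and [write_allele_db()] round-trip
#' byte-stably.
#'
#' @name allele_db
NULL

new_allele_db <- function(version, alleles) {
  structure(
    list(
      version = version,
      alleles = alleles,
      loci = sort(unique(alleles$locus))
    ),
    class = "hla_allele_db"
  )
}

#' @export
print.hla_allele_db <- function(x, ...) {
  cat(sprintf("<hla_allele_db> version %s: %d alleles, %d loci\n",
              x$version, nrow(x$alleles), length(x$loci)))
  counts <- dplyr::count(x$alleles, .data$locus)
  cat(paste(sprintf("  %s: %d", counts$locus, counts$n), collapse = "\n"), "\n")
  invisible(x)
}

validate_allele_record <- function(name, sequence, feats) {
  assert_acgt(sequence, sprintf("allele %s", name))
  if (any(feats$end > nchar(sequence)) || any(feats$start < 1)) {
    abort(sprintf("allele %s: feature span exceeds sequence bounds", name))
  }
  if (any(feats$start > feats$end)) {
    abort(sprintf("allele %s: inverted feature span", name))
  }
  o <- order(feats$start)
  if (any(diff(feats$start[o]) <= 0) ||
      any(utils::head(feats$end[o], -1) >= feats$start[o][-1])) {
    abort(sprintf("allele %s: overlapping feature spans", name))
  }
  if (is.unsorted(feature_rank(feats$feature[o]))) {
    abort(sprintf("allele %s: features out of gene order", name))
  }
  invisible(TRUE)
}

#' Build an allele database from a feature table
#'
#' Low-level constructor used by the mock-database builder and the dialect
#' reader. Per-allele feature sequences are concatenated in gene order to form
#' the stored full sequence; coordinates are derived, so the invariant that
#' present features tile the sequence holds by construction.
#'
#' @param version Free-text database version string.
#' @param features A tibble with columns `name`, `feature`, `seq` (one row per
#'   present feature of each allele).
#' @return An `hla_allele_db`.
#' @export
allele_db_from_features <- function(version, features) {
  stopifnot(all(c("name", "feature", "seq") %in% names(features)))
  if (anyNA(feature_rank(features$feature))) {
    abort("unknown feature id in feature table")
  }
  alleles <- features |>
    dplyr::mutate(.rank = feature_rank(.data$feature)) |>
    dplyr::group_by(.data$name) |>
    dplyr::arrange(.data$.rank, .by_group = TRUE) |>
    dplyr::summarise(
      sequence = paste(.data$seq, collapse = ""),
      features = {
        feat <- .data$feature
        len <- nchar(.data$seq)
        list(tibble(
          feature = feat,
          start = as.integer(cumsum(c(1L, utils::head(len, -1)))),
          end = as.integer(cumsum(len))
        ))
      },
      .groups = "drop"
    )
  if (anyDuplicated(alleles$name)) {
    abort(sprintf("duplicate allele name: %s",
                  alleles$name[duplicated(alleles$name)][1]))
  }
  parsed <- parse_allele_name(alleles$name)
  alleles <- alleles |>
    dplyr::mutate(locus = parsed$locus, suffix = parsed$suffix) |>
    dplyr::select("name", "locus", "suffix", "sequence", "features") |>
    dplyr::arrange(.data$locus, .data$name)
  purrr::pwalk(alleles[c("name", "sequence", "features")],
               function(name, sequence, features)
                 validate_allele_record(name, sequence, features))
  new_allele_db(version, alleles)
}

#' Read an annotated-FASTA allele database
#'
#' @param path Path to a file in the annotated-FASTA dialect (see
#'   [allele_db]).
#' @return An `hla_allele_db`.
#' @export
read_allele_db <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  version <- "unknown"
  vline <- grepl("^#version=", lines)
  if (any(vline)) version <- sub("^#version=", "", lines[vline][1])
  lines <- lines[!grepl("^#", lines)]
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0) abort("no records found")
  ends <- c(hdr_idx[-1] - 1L, length(lines))
  recs <- purrr::map2(hdr_idx, ends, function(h, e) {
    header <- lines[h]
    m <- regexec("^>(\\S+) features=(\\S+)$", header)[[1]]
    if (m[1] == -1) abort(sprintf("malformed header: %s", header))
    name <- regmatches(header, regexec("^>(\\S+) features=(\\S+)$", header))[[1]][2]
    featstr <- regmatches(header, regexec("^>(\\S+) features=(\\S+)$", header))[[1]][3]
    seq <- paste(lines[(h + 1):e][lines[(h + 1):e] != ""], collapse = "")
    featparts <- strsplit(featstr, ",", fixed = TRUE)[[1]]
    fm <- regmatches(featparts, regexec("^([A-Za-z0-9']+):([0-9]+)-([0-9]+)$", featparts))
    if (any(lengths(fm) == 0)) {
      abort(sprintf("allele %s: malformed feature token", name))
    }
    feats <- tibble(
      feature = vapply(fm, `[`, character(1), 2),
      start = as.integer(vapply(fm, `[`, character(1), 3)),
      end = as.integer(vapply(fm, `[`, character(1), 4))
    )
    list(name = name, sequence = seq, feats = feats)
  })
  names_all <- vapply(recs, `[[`, character(1), "name")
  if (anyDuplicated(names_all)) {
    abort(sprintf("duplicate allele name: %s", names_all[duplicated(names_all)][1]))
  }
  features <- purrr::map_dfr(recs, function(r) {
    validate_allele_record(r$name, r$sequence, r$feats)
    tibble(
      name = r$name,
      feature = r$feats$feature,
      seq = substring(r$sequence, r$feats$start, r$feats$end)
    )
  })
  allele_db_from_features(version, features)
}

#' Write an allele database in the annotated-FASTA dialect
#'
#' @param db An `hla_allele_db`.
#' @param path Output path.
#' @param width Sequence wrap width (bases per line).
#' @return `path`, invisibly.
#' @export
write_allele_db <- function(db, path, width = 70L) {
  stopifnot(inherits(db, "hla_allele_db"))
  con <- file(path, open = "wb")  # binary: byte-stable newlines
  on.exit(close(con))
  writeLines(sprintf("#version=%s", db$version), con)
  purrr::pwalk(db$alleles[c("name", "sequence", "features")],
    function(name, sequence, features) {
      featstr <- paste(sprintf("%s:%d-%d", features$feature,
                               features$start, features$end), collapse = ",")
      writeLines(sprintf(">%s features=%s", name, featstr), con)
      starts <- seq(1L, nchar(sequence), by = width)
      writeLines(substring(sequence, starts,
                           pmin(starts + width - 1L, nchar(sequence))), con)
    })
  invisible(path)
}

#' Feature sequence of an allele
#'
#' Returns the stored nucleotide segment for one annotated feature, or
#' `NA_character_` (the distinguished ABSENT state) when the allele carries no
#' annotation for that feature. ABSENT is never an empty string; downstream
#' matching treats it as a wildcard.
#'
#' @param db An `hla_allele_db`.
#' @param name Allele name (must be present in `db`).
#' @param feature Feature id (`"exon2"`, `"intron1"`, `"5NCR"`, ...).
#' @return A character scalar, or `NA_character_` if the feature is absent.
#' @export
feature_sequence <- function(db, name, feature) {
  stopifnot(inherits(db, "hla_allele_db"), length(name) == 1)
  i <- match(name, db$alleles$name)
  if (is.na(i)) abort(sprintf("unknown allele: %s", name))
  feats <- db$alleles$features[[i]]
  j <- match(feature, feats$feature)
  ifelse(is.na(j), NA_character_,
         substring(db$alleles$sequence[i], feats$start[j], feats$end[j]))
}

#' All alleles' sequences for one feature of a locus
#'
#' @param db An `hla_allele_db`.
#' @param locus Locus id.
#' @param feature Feature id.
#' @return Named character vector (allele name -> sequence, `NA` = ABSENT).
#' @export
locus_feature_sequences <- function(db, locus, feature) {
  al <- db$alleles[db$alleles$locus == locus, ]
  if (nrow(al) == 0) abort(sprintf("locus not in database: %s", locus))
  out <- vapply(seq_len(nrow(al)), function(i) {
    feats <- al$features[[i]]
    j <- match(feature, feats$feature)
    if (is.na(j)) NA_character_
    else substring(al$sequence[i], feats$start[j], feats$end[j])
  }, character(1))
  stats::setNames(out, al$name)
}

#' Alleles of a locus
#' @param db An `hla_allele_db`.
#' @param locus Locus id.
#' @return Character vector of allele names.
#' @export
locus_alleles <- function(db, locus) {
  db$alleles$name[db$alleles$locus == locus]
}

#' Drop feature annotations from selected alleles
#'
#' Models incompletely annotated references (e.g. alleles whose intronic
#' sequence was never deposited): the named features become ABSENT for the
#' given alleles while the exonic annotation is kept. Useful for testing
#' wildcard matching against a fully annotated simulation source.
#'
#' @param db An `hla_allele_db`.
#' @param alleles Allele names to strip.
#' @param features Feature ids to remove.
#' @return A new `hla_allele_db`.
#' @export
strip_feature_annotation <- function(db, alleles, features) {
  feat_tbl <- db_feature_table(db) |>
    dplyr::filter(!(.data$name %in% alleles & .data$feature %in% features))
  allele_db_from_features(db$version, feat_tbl[c("name", "feature", "seq")])
}

#' Tidy per-feature table of a database
#'
#' @param db An `hla_allele_db`.
#' @return A tibble with columns `name`, `locus`, `feature`, `start`, `end`,
#'   `seq` (one row per present feature).
#' @export
db_feature_table <- function(db) {
  purrr::pmap_dfr(db$alleles[c("name", "locus", "sequence", "features")],
    function(name, locus, sequence, features) {
      tibble(
        name = name, locus = locus,
        feature = features$feature,
        start = features$start, end = features$end,
        seq = substring(sequence, features$start, features$end)
      )
    })
}
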
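#' The 17-amplicon fusion-primer panel
#'
#' The typing assay amplifies 17 exons of HLA-A, -B, -C, -DRB, -DQB1 and
#' -DPB1 with fusion primers (adapter + 10 bp multiplex identifier +
#' template-specific primer). Each amplicon row records the reference allele,
#' the primer regions/positions (1-based inclusive, within the named
#' feature), the amplicon length, the pool it is sequenced in (`short` or
#' `long`) and the pooling factor used to balance read depth. The generic DRB
#' primers co-amplify DRB1, DRB3/4/5 and some pseudogenes.
#'
#' @name panel
NULL

.panel_cols <- c("Locus", "Exon", "Reference", "FwdRegion", "FwdPos",
                 "RevRegion", "RevPos", "Length", "Pool", "PoolingFactor")

#' Load an amplicon panel and its MID set
#'
#' @param path Panel TSV (columns `Locus`, `Exon`, `Reference`, `FwdRegion`,
#'   `FwdPos`, `RevRegion`, `RevPos`, `Length`, `Pool`, `PoolingFactor`;
#'   composite primer regions use `|`, e.g. `intron1|exon2` with positions
#'   `141-150|1-9`).
#' @param mids_path Companion MID TSV (columns `MID`, `Sequence`).
#' @param adapter Sequencing adapter prepended to fusion primers (the
#'   sequencer strips it before reads are emitted, so it defaults to `""`).
#' @return An `hla_panel`: list with `amplicons` tibble (ids are
#'   `<locus>-<exon>`), `mids` tibble, `adapter`.
#' @export
load_panel <- function(path, mids_path, adapter = "") {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  missing <- setdiff(.panel_cols, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("panel file lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  amplicons <- tibble(
    amplicon = paste0(tbl$Locus, "-", tbl$Exon),
    locus = tbl$Locus,
    exon = as.integer(tbl$Exon),
    reference = tbl$Reference,
    fwd_region = tbl$FwdRegion,
    fwd_pos = tbl$FwdPos,
    rev_region = tbl$RevRegion,
    rev_pos = tbl$RevPos,
    length = as.integer(tbl$Length),
    pool = tbl$Pool,
    pooling_factor = as.numeric(tbl$PoolingFactor)
  )
  if (anyDuplicated(amplicons$amplicon)) {
    abort(sprintf("duplicate (locus, exon) in panel: %s",
                  amplicons$amplicon[duplicated(amplicons$amplicon)][1]))
  }
  if (!all(amplicons$pool %in% c("short", "long"))) {
    abort("pool labels must be 'short' or 'long'")
  }
  mids_tbl <- readr::read_tsv(mids_path, col_types = readr::cols(.default = "c"))
  if (!all(c("MID", "Sequence") %in% names(mids_tbl))) {
    abort("MID file needs columns MID, Sequence")
  }
  mids <- tibble(mid_id = mids_tbl$MID, sequence = toupper(mids_tbl$Sequence))
  if (any(nchar(mids$sequence) != 10)) abort("all MIDs must be exactly 10 bp")
  if (anyDuplicated(mids$sequence)) abort("MIDs must be pairwise distinct")
  assert_acgt(mids$sequence, "MID")
  structure(list(amplicons = amplicons, mids = mids, adapter = adapter),
            class = "hla_panel")
}

#' @export
print.hla_panel <- function(x, ...) {
  cat(sprintf("<hla_panel> %d amplicons (%d short / %d long pool), %d MIDs\n",
              nrow(x$amplicons),
              sum(x$amplicons$pool == "short"),
              sum(x$amplicons$pool == "long"),
              nrow(x$mids)))
  invisible(x)
}

#' Packaged GS-Junior-style panel
#'
#' Loads the panel and MID set shipped with the package: 17 amplicons with
#' the published locus/exon/pool/pooling-factor structure (5 short-pool, 12
#' long-pool, DRB exon 2 at factor 6), primer spans of the published lengths
#' placed at positions consistent with the compact mock reference genes, and
#' 14 synthetic 10 bp MIDs with pairwise Hamming distance >= 3.
#'
#' @return An `hla_panel`.
#' @export
mock_panel <- function() {
  load_panel(
    system.file("extdata", "panel_gsjunior.tsv", package = "hlatyper"),
    system.file("extdata", "mids_gsjunior.tsv", package = "hlatyper")
  )
}

#' Assemble a fusion primer
#'
#' Fusion primers are the simple concatenation adapter || MID || template
#' primer; the MID must be exactly 10 bp.
#'
#' @param adapter Adapter sequence (may be empty).
#' @param mid 10 bp multiplex identifier.
#' @param primer Template-specific primer sequence.
#' @return The fusion primer string.
#' @export
build_fusion_primer <- function(adapter, mid, primer) {
  if (nchar(mid) != 10) abort("MID must be exactly 10 bp")
  paste0(adapter, mid, primer)
}

#' Read trimming point
#'
#' Position (bp from read start) after which a read is cut: the sum of MID
#' length, primer length, primer-to-exon distance, exon length, and an offset
#' retaining intron flank to enhance similarity among reads.
#'
#' @param mid_len,primer_len,primer_to_exon_distance,exon_len,offset
#'   Non-negative lengths in bp.
#' @return The trimming position.
#' @export
trimming_point <- function(mid_len, primer_len, primer_to_exon_distance,
                           exon_len, offset = 0) {
  args <- c(mid_len, primer_len, primer_to_exon_distance, exon_len, offset)
  if (any(args < 0)) abort("all trimming-point arguments must be >= 0")
  mid_len + primer_len + primer_to_exon_distance + exon_len + offset
}

# ---- coordinate resolution ---------------------------------------------------

# Absolute (whole-gene) span of a possibly composite primer region for one
# allele, from that allele's own feature map. Returns c(start, end).
region_span <- function(feats, region, pos, allele, seqlen) {
  regions <- strsplit(region, "|", fixed = TRUE)[[1]]
  posparts <- strsplit(pos, "|", fixed = TRUE)[[1]]
  if (length(regions) != length(posparts)) {
    abort(sprintf("%s: region/position arity mismatch", allele))
  }
  spans <- purrr::map2(regions, posparts, function(r, p) {
    j <- match(r, feats$feature)
    if (is.na(j)) abort(sprintf("%s lacks feature %s", allele, r))
    pp <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
    c(feats$start[j] + pp[1] - 1L, feats$start[j] + pp[2] - 1L)
  })
  lo <- spans[[1]][1]; hi <- spans[[length(spans)]][2]
  # composite parts must be contiguous along the gene
  if (length(spans) > 1) {
    for (k in seq_len(length(spans) - 1)) {
      if (spans[[k + 1]][1] != spans[[k]][2] + 1L) {
        abort(sprintf("%s: composite primer region not contiguous", allele))
      }
    }
  }
  if (lo < 1 || hi > seqlen) abort(sprintf("%s: primer span out of bounds", allele))
  c(lo, hi)
}

allele_feats <- function(db, name) {
  i <- match(name, db$alleles$name)
  if (is.na(i)) abort(sprintf("unknown allele: %s", name))
  list(feats = db$alleles$features[[i]], seq = db$alleles$sequence[i])
}

#' Loci amplified by a panel locus label
#'
#' The generic `DRB` primer system co-amplifies DRB1 and DRB3/4/5 (and, in
#' simulation, the `DRBP` pseudo-locus); every other panel locus maps to
#' itself.
#'
#' @param panel_locus Panel locus label.
#' @param with_pseudo Include the pseudo-locus for `DRB`.
#' @return Character vector of database loci.
#' @export
amplicon_target_loci <- function(panel_locus, with_pseudo = FALSE) {
  if (panel_locus == "DRB") {
    c("DRB1", "DRB3", "DRB4", "DRB5", if (with_pseudo) "DRBP")
  } else {
    panel_locus
  }
}

#' Resolve panel geometry against a reference database
#'
#' For every amplicon, resolves the primer spans on the reference allele into
#' absolute coordinates and derives the demultiplexing/trimming constants:
#' primer sequences (the reverse primer as it appears at the start of
#' reverse-orientation reads, i.e. reverse-complemented), the informative
#' insert span between the primer footprints, the covered part of the
#' targeted exon (primer footprints that extend into the exon mask those
#' bases), available intron flank on either side, and the flanking feature
#' ids used to report null-allele exclusions.
#'
#' @param panel An `hla_panel`.
#' @param db An `hla_allele_db` containing every reference allele.
#' @return A tibble with one row per amplicon.
#' @export
amplicon_layout <- function(panel, db) {
  lay <- purrr::pmap_dfr(panel$amplicons, function(amplicon, locus, exon,
                                                   reference, fwd_region,
                                                   fwd_pos, rev_region,
                                                   rev_pos, length, pool,
                                                   pooling_factor) {
    af <- allele_feats(db, reference)
    fspan <- region_span(af$feats, fwd_region, fwd_pos, reference, nchar(af$seq))
    rspan <- region_span(af$feats, rev_region, rev_pos, reference, nchar(af$seq))
    exon_feature <- paste0("exon", exon)
    j <- match(exon_feature, af$feats$feature)
    if (is.na(j)) abort(sprintf("%s lacks %s", reference, exon_feature))
    xs0 <- af$feats$start[j]; xe0 <- af$feats$end[j]
    i_start <- fspan[2] + 1L; i_end <- rspan[1] - 1L
    xs <- max(xs0, i_start); xe <- min(xe0, i_end)
    if (xs > xe) abort(sprintf("%s-%s: primers leave no covered exon", locus, exon))
    feature_at <- function(p) {
      k <- which(af$feats$start <= p & af$feats$end >= p)
      if (length(k) == 0) NA_character_ else af$feats$feature[k]
    }
    tibble(
      amplicon = amplicon, locus = locus, exon = exon,
      exon_feature = exon_feature, reference = reference,
      s = fspan[1], fwd_end = fspan[2], rev_start = rspan[1], e = rspan[2],
      fwd_region = fwd_region, fwd_pos = fwd_pos,
      rev_region = rev_region, rev_pos = rev_pos,
      fwd_primer = substring(af$seq, fspan[1], fspan[2]),
      rev_primer_read = revcomp(substring(af$seq, rspan[1], rspan[2])),
      xs = xs, xe = xe,
      cov_start_off = xs - xs0, cov_end_off = xe0 - xe,
      avail5 = xs - i_start, avail3 = i_end - xe,
      flank5_feature = if (xs > i_start) feature_at(xs - 1L) else NA_character_,
      flank3_feature = if (xe < i_end) feature_at(xe + 1L) else NA_character_,
      pool = pool, pooling_factor = pooling_factor, length = length
    )
  })
  primers <- c(lay$fwd_primer, lay$rev_primer_read)
  for (i in seq_along(primers)) {
    pref <- startsWith(primers, primers[i])
    if (sum(pref) > 1) abort("panel primers are not prefix-free; demultiplexing would be ambiguous")
  }
  lay
}

# Flank widths actually used for an amplicon in a trimming mode.
flank_widths <- function(lay_row, mode, offset) {
  if (mode == "exon_only") return(c(0L, 0L))
  c(min(offset, lay_row$avail5), min(offset, lay_row$avail3))
}

# Per-allele amplicon product for simulation: the PCR product carries the
# *primer* sequence at both primer footprints (the primer overwrites the
# template there) and the allele's own sequence in between.
amplicon_product <- function(db, allele, lay_row) {
  af <- allele_feats(db, allele)
  fspan <- region_span(af$feats, lay_row$fwd_region, lay_row$fwd_pos,
                       allele, nchar(af$seq))
  rspan <- region_span(af$feats, lay_row$rev_region, lay_row$rev_pos,
                       allele, nchar(af$seq))
  insert <- substring(af$seq, fspan[2] + 1L, rspan[1] - 1L)
  list(
    product = paste0(lay_row$fwd_primer, insert, revcomp(lay_row$rev_primer_read)),
    insert = insert
  )
}

# Expected trimmed sequence ("target") of an allele at one amplicon, split
# into 5' flank / exon part / 3' flank by the reference arithmetic. Alleles
# missing the targeted exon give NA parts (wildcards); alleles with stripped
# intron annotation get piecewise targets with NA flanks.
allele_target <- function(db, allele, lay_row, mode, offset = 10L) {
  fw <- flank_widths(lay_row, mode, offset)
  f5 <- fw[1]; f3 <- fw[2]
  af <- allele_feats(db, allele)
  have <- function(feat) feat %in% af$feats$feature
  span_feats <- needed_span_features(db, lay_row)
  if (all(vapply(span_feats, have, logical(1)))) {
    ins <- amplicon_product(db, allele, lay_row)$insert
    a <- (lay_row$xs - f5) - (lay_row$fwd_end + 1L) + 1L
    b <- (lay_row$xe + f3) - (lay_row$fwd_end + 1L) + 1L
    full <- substr(ins, a, min(b, nchar(ins)))
    n <- nchar(full)
    return(list(
      full = full,
      flank5 = substr_safe(full, 1, f5),
      exon_part = substr_safe(full, f5 + 1L, n - f3),
      flank3 = substr_safe(full, n - f3 + 1L, n),
      f5 = f5, f3 = f3
    ))
  }
  # piecewise fallback for incompletely annotated alleles
  exon_feature <- lay_row$exon_feature
  exon_part <- NA_character_
  if (have(exon_feature)) {
    ex <- feature_sequence(db, allele, exon_feature)
    exon_part <- substr_safe(ex, 1L + lay_row$cov_start_off,
                             nchar(ex) - lay_row$cov_end_off)
  }
  flank5 <- NA_character_
  if (f5 > 0 && !is.na(lay_row$flank5_feature) && have(lay_row$flank5_feature)) {
    up <- feature_sequence(db, allele, lay_row$flank5_feature)
    flank5 <- substr_safe(up, nchar(up) - f5 + 1L, nchar(up))
  }
  flank3 <- NA_character_
  if (f3 > 0 && !is.na(lay_row$flank3_feature) && have(lay_row$flank3_feature)) {
    dn <- feature_sequence(db, allele, lay_row$flank3_feature)
    flank3 <- substr_safe(dn, 1L, f3)
  }
  list(full = NA_character_, flank5 = flank5, exon_part = exon_part,
       flank3 = flank3, f5 = f5, f3 = f3)
}

# Features the reference amplicon span touches (needed for the exact
# span-based target construction).
needed_span_features <- function(db, lay_row) {
  af <- allele_feats(db, lay_row$reference)
  f <- af$feats
  f$feature[f$end >= lay_row$s & f$start <= lay_row$e]
}

#' Build the genotyping target table
#'
#' Precomputes, for every amplicon and every allele of its target loci, the
#' expected trimmed read sequence (split into 5' intron flank, covered exon
#' part, 3' intron flank). `NA` parts act as wildcards during matching:
#' an allele without annotation for a feature can never be contradicted
#' there.
#'
#' @param db An `hla_allele_db`.
#' @param panel An `hla_panel`.
#' @param mode `"exon_only"` or `"exon_plus_flank"`.
#' @param offset Intron flank retained in `exon_plus_flank` mode (bp).
#' @param layout Optional precomputed [amplicon_layout()].
#' @return A tibble: `amplicon`, `locus` (database locus), `allele`, `full`,
#'   `flank5`, `exon_part`, `flank3`, `f5`, `f3`.
#' @export
build_target_table <- function(db, panel, mode = c("exon_plus_flank", "exon_only"),
                               offset = 10L, layout = NULL) {
  mode <- match.arg(mode)
  lay <- layout %||% amplicon_layout(panel, db)
  purrr::map_dfr(seq_len(nrow(lay)), function(i) {
    row <- lay[i, ]
    loci <- amplicon_target_loci(row$locus, with_pseudo = FALSE)
    loci <- intersect(loci, db$loci)
    purrr::map_dfr(loci, function(lc) {
      alleles <- locus_alleles(db, lc)
      purrr::map_dfr(alleles, function(a) {
        tg <- allele_target(db, a, row, mode, offset)
        tibble(amplicon = row$amplicon, locus = lc, allele = a,
               full = tg$full, flank5 = tg$flank5, exon_part = tg$exon_part,
               flank3 = tg$flank3, f5 = tg$f5, f3 = tg$f3)
      })
    })
  })
}
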
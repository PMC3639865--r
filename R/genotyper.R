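#' Layered genotype calling
#'
#' The calling engine mirrors the layer model of amplicon-based HLA typing
#' software: per amplicon, reads whose best database alignment is close
#' enough stay in the *master layer* and drive the genotype; reads derived
#' from co-amplified pseudogenes or carrying excessive errors fall into the
#' *failed layer*; crossover chimeras (detectable because their two exon
#' halves best-match different DRB loci) are *deactivated*. Master reads are
#' clustered into at most two haplotype consensus sequences per amplicon
#' (with homopolymer-aware merging and a direction-unanimity rule), and all
#' allele pairs whose features exactly reproduce every cluster are
#' enumerated into the ambiguity string.
#'
#' @name genotyper
NULL

# min mismatch + argmin over a target table (columns allele, locus, full)
best_target_match <- function(reads, targets) {
  ok <- !is.na(targets$full)
  tg <- targets[ok, ]
  n <- length(reads)
  best <- rep(.Machine$integer.max, n)
  best_i <- rep(NA_integer_, n)
  by_len <- split(seq_len(n), nchar(reads))
  for (j in seq_len(nrow(tg))) {
    idx <- by_len[[as.character(nchar(tg$full[j]))]]
    if (is.null(idx)) next
    h <- hamming_to(reads[idx], tg$full[j])
    upd <- h < best[idx]
    best[idx[upd]] <- h[upd]
    best_i[idx[upd]] <- j
  }
  todo <- which(best > 30L)
  if (length(todo) > 0 && nrow(tg) > 0) {
    for (j in seq_len(nrow(tg))) {
      a <- align_to_reference(reads[todo], tg$full[j])
      upd <- a < best[todo]
      best[todo[upd]] <- a[upd]
      best_i[todo[upd]] <- j
    }
  }
  list(mm = as.integer(best),
       allele = tg$allele[best_i],
       locus = tg$locus[best_i])
}

#' Partition trimmed reads into master / failed / deactivated layers
#'
#' A read joins the master layer iff its best mismatch count (substitutions
#' plus gap bases) over all alleles of the amplicon's target loci is at most
#' `fail_threshold`; otherwise it is failed. On multi-locus amplicons (the
#' generic DRB system) reads whose 5' and 3' exon segments best-match
#' *different* loci without matching any single allele exactly are
#' deactivated as PCR crossover chimeras. Reads can later be moved between
#' layers by explicit override.
#'
#' @param trimmed Trimmed demux tibble ([trim_reads()]), assigned reads.
#' @param db An `hla_allele_db`.
#' @param panel An `hla_panel`.
#' @param mode,offset Trimming mode used (must match [trim_reads()]).
#' @param fail_threshold Maximum master-layer mismatch count (default 4).
#' @param targets Optional precomputed [build_target_table()].
#' @param layout Optional precomputed [amplicon_layout()].
#' @return The input tibble with columns `layer`
#'   (`master`/`failed`/`deactivated`), `matched_locus`, `matched_allele`,
#'   `best_mm`.
#' @export
partition_layers <- function(trimmed, db, panel,
                             mode = c("exon_plus_flank", "exon_only"),
                             offset = 10L, fail_threshold = 4L,
                             targets = NULL, layout = NULL) {
  mode <- match.arg(mode)
  lay <- layout %||% amplicon_layout(panel, db)
  tg_all <- targets %||% build_target_table(db, panel, mode, offset, layout = lay)
  trimmed$layer <- NA_character_
  trimmed$matched_locus <- NA_character_
  trimmed$matched_allele <- NA_character_
  trimmed$best_mm <- NA_integer_
  usable <- trimmed$status == "assigned" & !is.na(trimmed$trimmed)
  for (amp in unique(trimmed$amplicon[usable])) {
    idx <- which(usable & trimmed$amplicon == amp)
    tg <- tg_all[tg_all$amplicon == amp, ]
    bm <- best_target_match(trimmed$trimmed[idx], tg)
    trimmed$best_mm[idx] <- bm$mm
    trimmed$matched_locus[idx] <- bm$locus
    trimmed$matched_allele[idx] <- bm$allele
    trimmed$layer[idx] <- ifelse(bm$mm <= fail_threshold, "master", "failed")

    row <- lay[lay$amplicon == amp, ]
    multi <- length(intersect(amplicon_target_loci(row$locus), db$loci)) > 1
    if (multi) {
      f5 <- flank_widths(row, mode, offset)[1]
      exon_len <- row$xe - row$xs + 1L
      a_end <- floor(0.44 * exon_len)
      b_start <- exon_len - a_end + 1L
      seg <- function(seqs, from, to) substr(seqs, f5 + from, f5 + to)
      full_ok <- !is.na(tg$full)
      segA_t <- seg(tg$full, 1L, a_end)
      segB_t <- seg(tg$full, b_start, exon_len)
      reads_amp <- trimmed$trimmed[idx]
      same_len <- nchar(reads_amp) == nchar(tg$full[full_ok][1])
      exactly <- reads_amp %in% tg$full
      check <- which(same_len & !exactly)
      if (length(check) > 0) {
        rA <- seg(reads_amp[check], 1L, a_end)
        rB <- seg(reads_amp[check], b_start, exon_len)
        locA <- locB <- rep(NA_character_, length(check))
        bestA <- bestB <- rep(.Machine$integer.max, length(check))
        for (j in which(full_ok)) {
          hA <- hamming_to(rA, segA_t[j]); hB <- hamming_to(rB, segB_t[j])
          uA <- hA < bestA; uB <- hB < bestB
          bestA[uA] <- hA[uA]; locA[uA] <- tg$locus[j]
          bestB[uB] <- hB[uB]; locB[uB] <- tg$locus[j]
        }
        chim <- !is.na(locA) & !is.na(locB) & locA != locB
        trimmed$layer[idx[check][chim]] <- "deactivated"
      }
    }
  }
  class(trimmed) <- unique(c("hla_layers", class(trimmed)))
  trimmed
}

#' Move reads between layers
#'
#' Explicit override mirroring manual layer editing: reads can be moved in
#' both directions (e.g. rescuing failed reads for a known troublesome
#' genotype combination).
#'
#' @param partition Output of [partition_layers()].
#' @param read_ids Reads to move.
#' @param to Target layer (`master`, `failed`, `deactivated`).
#' @return The updated partition.
#' @export
move_reads <- function(partition, read_ids, to = c("master", "failed", "deactivated")) {
  to <- match.arg(to)
  partition$layer[partition$read_id %in% read_ids] <- to
  partition
}

# ---- haplotype clustering ----------------------------------------------------

rle_of <- function(seq) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  list(bases = paste(r$values, collapse = ""), lens = r$lengths)
}

# Decide the consensus length of one divergent homopolymer run: the
# direction whose reads are unanimous at that run wins; otherwise weighted
# majority with forward reads breaking ties.
resolve_run_length <- function(lens, fwd, rev) {
  fv <- unique(lens[fwd > 0]); rv <- unique(lens[rev > 0])
  fwd_unan <- length(fv) == 1 && sum(fwd) > 0
  rev_unan <- length(rv) == 1 && sum(rev) > 0
  if (fwd_unan && !rev_unan) return(fv)
  if (rev_unan && !fwd_unan) return(rv)
  tot <- tapply(fwd + rev, lens, sum)
  winners <- as.integer(names(tot)[tot == max(tot)])
  if (length(winners) == 1) return(winners)
  # tie: side with the forward majority
  ftot <- tapply(fwd, lens, sum)[as.character(winners)]
  winners[which.max(ftot)]
}

#' Cluster master-layer reads into haplotype consensus sequences
#'
#' Master reads of one amplicon are grouped by exact trimmed sequence;
#' groups differing only in the length of a single homopolymer run are
#' merged (the characteristic pyrosequencing error), with the divergent run
#' length resolved per [resolve_run_length()]'s direction-unanimity rule —
#' a clean, unanimous forward strand overrides undercalled reverse reads, as
#' in the manual fix for the C homopolymer at the start of C*07 exon 4.
#' Clusters below `min_cluster_fraction` of the amplicon's master reads are
#' dropped as noise; at most the top 2 are kept, and a surviving third
#' cluster sets the review flag.
#'
#' @param partition Output of [partition_layers()] (or any tibble with
#'   `sample_id`, `amplicon`, `matched_locus`, `trimmed`, `direction`,
#'   `layer`).
#' @param min_cluster_fraction Noise floor as fraction of master reads.
#' @return A tibble: `sample_id`, `locus`, `amplicon`, `cluster_id`,
#'   `consensus`, `read_count`, `fwd_count`, `rev_count`, `review`,
#'   `master_total` (per sample/locus/amplicon master reads).
#' @export
build_haplotype_clusters <- function(partition, min_cluster_fraction = 0.10) {
  master <- partition |>
    dplyr::filter(.data$layer == "master", !is.na(.data$trimmed))
  if (nrow(master) == 0) {
    return(tibble(sample_id = character(), locus = character(),
                  amplicon = character(), cluster_id = integer(),
                  consensus = character(), read_count = integer(),
                  fwd_count = integer(), rev_count = integer(),
                  review = logical(), master_total = integer()))
  }
  groups <- master |>
    dplyr::group_by(.data$sample_id, .data$matched_locus, .data$amplicon)
  keys <- dplyr::group_keys(groups)
  idx_list <- dplyr::group_rows(groups)
  out <- purrr::map_dfr(seq_along(idx_list), function(g) {
    rows <- master[idx_list[[g]], ]
    members <- rows |>
      dplyr::count(.data$trimmed, .data$direction) |>
      tidyr::pivot_wider(names_from = "direction", values_from = "n",
                         values_fill = 0L)
    if (!"fwd" %in% names(members)) members$fwd <- 0L
    if (!"rev" %in% names(members)) members$rev <- 0L
    members$n <- members$fwd + members$rev
    members <- members[order(-members$n, members$trimmed), ]
    master_total <- sum(members$n)

    rles <- lapply(members$trimmed, rle_of)
    cluster_of <- rep(NA_integer_, nrow(members))
    next_id <- 0L
    for (i in seq_len(nrow(members))) {
      placed <- FALSE
      for (cl in seq_len(next_id)) {
        anchor <- which(cluster_of == cl)[1]
        ra <- rles[[anchor]]; ri <- rles[[i]]
        if (ra$bases == ri$bases &&
            length(ra$lens) == length(ri$lens) &&
            sum(ra$lens != ri$lens) == 1) {
          cluster_of[i] <- cl
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        next_id <- next_id + 1L
        cluster_of[i] <- next_id
      }
    }
    clusters <- purrr::map_dfr(seq_len(next_id), function(cl) {
      mem <- members[cluster_of == cl, ]
      mrle <- rles[cluster_of == cl]
      if (nrow(mem) == 1) {
        consensus <- mem$trimmed[1]
      } else {
        bases <- strsplit(mrle[[1]]$bases, "", fixed = TRUE)[[1]]
        lenmat <- do.call(rbind, lapply(mrle, `[[`, "lens"))
        lens <- vapply(seq_along(bases), function(j) {
          col <- lenmat[, j]
          if (length(unique(col)) == 1) return(col[1])
          resolve_run_length(col, mem$fwd, mem$rev)
        }, integer(1))
        consensus <- paste(strrep(bases, lens), collapse = "")
      }
      tibble(consensus = consensus, read_count = sum(mem$n),
             fwd_count = sum(mem$fwd), rev_count = sum(mem$rev))
    })
    clusters <- clusters[clusters$read_count >=
                           min_cluster_fraction * master_total, , drop = FALSE]
    clusters <- clusters[order(-clusters$read_count, clusters$consensus), ]
    review <- nrow(clusters) > 2
    clusters <- utils::head(clusters, 2)
    if (nrow(clusters) == 0) return(tibble())
    clusters |>
      dplyr::mutate(
        sample_id = keys$sample_id[g],
        locus = keys$matched_locus[g],
        amplicon = keys$amplicon[g],
        cluster_id = dplyr::row_number(),
        review = review,
        master_total = master_total
      ) |>
      dplyr::select("sample_id", "locus", "amplicon", "cluster_id",
                    "consensus", "read_count", "fwd_count", "rev_count",
                    "review", "master_total")
  })
  out
}

# ---- genotype-pair search ----------------------------------------------------

# exact-or-wildcard match of a cluster part against a target part
part_match <- function(cluster_part, target_part) {
  is.na(target_part) | cluster_part == target_part
}

# split a consensus into flank5/exon/flank3 by the reference arithmetic
split_consensus <- function(consensus, f5, f3) {
  n <- nchar(consensus)
  list(flank5 = substr_safe(consensus, 1, f5),
       exon = substr_safe(consensus, f5 + 1L, n - f3),
       flank3 = substr_safe(consensus, n - f3 + 1L, n))
}

mm_between <- function(a, b) {
  if (is.na(b)) return(0L)
  if (is.na(a) || nchar(a) == 0) return(0L)
  if (nchar(a) == nchar(b)) return(hamming_to(a, b))
  if (nchar(a) < nchar(b)) align_to_reference(a, b) else align_to_reference(b, a)
}

#' Phase-layer mismatch accounting for one allele pair
#'
#' Cluster indices within each amplicon carry the haplotype hypothesis
#' (cluster 1 = haplotype 1). `MM` is the total mismatch count under the
#' best globally *consistent* cluster-to-allele orientation; `MM3`/`MM4`
#' re-count with the exon-3 (exon-4) amplicon's assignment swapped against
#' the exon-2 anchor — nonzero `MM` with zero `MM3` exposes a
#' phase-between-exons (exon shuffling) ambiguity, while zero `MM` with
#' nonzero `MM3`/`MM4` quantifies the cis/trans ambiguity a generic
#' unphased method would face.
#'
#' @param a1,a2 Allele names of the candidate pair.
#' @param clusters Cluster tibble for one sample and locus
#'   ([build_haplotype_clusters()]).
#' @param targets Target table ([build_target_table()]).
#' @param layout_exons Named integer vector amplicon -> exon number.
#' @return A tibble with `MM`, `MM3`, `MM4` (`NA` when not applicable:
#'   fewer than 2 amplicons, or no 2-cluster exon-3/4 amplicon).
#' @export
phase_layer_mismatches <- function(a1, a2, clusters, targets, layout_exons) {
  amps <- unique(clusters$amplicon)
  if (length(amps) < 2) {
    return(tibble(MM = NA_integer_, MM3 = NA_integer_, MM4 = NA_integer_))
  }
  costs <- purrr::map_dfr(amps, function(amp) {
    cl <- clusters[clusters$amplicon == amp, ]
    tg <- targets[targets$amplicon == amp, ]
    t1 <- tg$exon_part[tg$allele == a1]
    t2 <- tg$exon_part[tg$allele == a2]
    f5 <- tg$f5[1]; f3 <- tg$f3[1]
    parts <- lapply(cl$consensus, split_consensus, f5 = f5, f3 = f3)
    ex <- vapply(parts, `[[`, character(1), "exon")
    if (nrow(cl) >= 2) {
      idc <- mm_between(ex[1], t1) + mm_between(ex[2], t2)
      swc <- mm_between(ex[1], t2) + mm_between(ex[2], t1)
      two <- TRUE
    } else {
      idc <- swc <- mm_between(ex[1], t1) + mm_between(ex[1], t2)
      two <- FALSE
    }
    tibble(amplicon = amp, exon = layout_exons[[amp]], id = idc, sw = swc,
           two = two)
  })
  mm_total <- function(flip_exon = NULL) {
    flip <- !is.null(flip_exon) & costs$exon %in% flip_exon & costs$two
    min(sum(ifelse(flip, costs$sw, costs$id)),
        sum(ifelse(flip, costs$id, costs$sw)))
  }
  mm <- mm_total()
  mm3 <- if (any(costs$exon == 3 & costs$two)) mm_total(3L) else NA_integer_
  mm4 <- if (any(costs$exon == 4 & costs$two)) mm_total(4L) else NA_integer_
  tibble(MM = as.integer(mm), MM3 = as.integer(mm3), MM4 = as.integer(mm4))
}

#' Call the genotype of one sample at one locus
#'
#' Enumerates all allele pairs of the locus compatible with the observed
#' haplotype clusters: a pair is compatible iff at every required amplicon
#' each cluster consensus exactly reproduces (over the covered exon span)
#' the corresponding feature of one pair member, with both clusters covered
#' where two exist. Reference features that are ABSENT act as wildcards.
#' The call is `no_result` when any required amplicon has fewer than
#' `min_reads` master reads.
#'
#' @param clusters Cluster tibble for one sample and locus.
#' @param db An `hla_allele_db`.
#' @param locus The locus to call.
#' @param targets Target table ([build_target_table()]).
#' @param layout [amplicon_layout()] of the panel.
#' @param min_reads Minimum master reads per required amplicon (default 20).
#' @return A list of class `hla_call`: `sample_id`, `locus`, `status`
#'   (`called`/`no_result`/`review`), `candidates` (tibble `allele1`,
#'   `allele2`, `MM`, `MM3`, `MM4`), `ambiguity_4digit` (character vector of
#'   deduplicated 4-digit pairs), `excluded_null_alleles` (tibble),
#'   `warnings`, `read_counts` (per-amplicon master totals), `clusters`.
#' @export
call_genotype <- function(clusters, db, locus, targets, layout,
                          min_reads = 20L) {
  required <- layout$amplicon[vapply(layout$locus, function(pl)
    locus %in% amplicon_target_loci(pl), logical(1))]
  counts <- stats::setNames(rep(0L, length(required)), required)
  for (amp in required) {
    cl <- clusters[clusters$amplicon == amp, ]
    if (nrow(cl) > 0) counts[amp] <- cl$master_total[1]
  }
  empty_call <- function(status) {
    structure(list(
      sample_id = if (nrow(clusters) > 0) clusters$sample_id[1] else NA_character_,
      locus = locus, status = status,
      candidates = tibble(allele1 = character(), allele2 = character(),
                          MM = integer(), MM3 = integer(), MM4 = integer()),
      ambiguity_4digit = character(),
      excluded_null_alleles = tibble(allele = character(), feature = character(),
                                     amplicon = character()),
      warnings = character(),
      read_counts = counts, clusters = clusters
    ), class = "hla_call")
  }
  if (any(counts < min_reads)) return(empty_call("no_result"))

  alleles <- locus_alleles(db, locus)
  tg <- targets[targets$locus == locus, ]
  amps <- required
  # per amplicon: cluster exon parts and per-allele target exon parts
  amp_data <- lapply(amps, function(amp) {
    cl <- clusters[clusters$amplicon == amp, ]
    tga <- tg[tg$amplicon == amp, ]
    f5 <- tga$f5[1]; f3 <- tga$f3[1]
    ex <- vapply(cl$consensus, function(cs) split_consensus(cs, f5, f3)$exon,
                 character(1), USE.NAMES = FALSE)
    t_exon <- stats::setNames(tga$exon_part, tga$allele)
    list(cl = cl, ex = ex, t_exon = t_exon)
  })
  names(amp_data) <- amps

  # allele x amplicon match matrix against each cluster
  match_cl <- lapply(amp_data, function(ad) {
    m <- matrix(FALSE, nrow = length(alleles), ncol = max(1L, length(ad$ex)),
                dimnames = list(alleles, NULL))
    for (ci in seq_along(ad$ex)) {
      m[, ci] <- part_match(ad$ex[ci], ad$t_exon[alleles])
    }
    m
  })

  pairs <- expand.grid(i = seq_along(alleles), j = seq_along(alleles))
  pairs <- pairs[pairs$i <= pairs$j, ]
  compat <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs$i[k]; j <- pairs$j[k]
    all(vapply(amps, function(amp) {
      m <- match_cl[[amp]]
      nc <- length(amp_data[[amp]]$ex)
      if (nc == 0) return(FALSE)
      if (nc == 1) return(m[i, 1] && m[j, 1])
      (m[i, 1] && m[j, 2]) || (m[i, 2] && m[j, 1])
    }, logical(1)))
  }, logical(1))
  cand <- tibble(allele1 = alleles[pairs$i[compat]],
                 allele2 = alleles[pairs$j[compat]])
  cand <- cand |>
    dplyr::mutate(a = pmin(.data$allele1, .data$allele2),
                  b = pmax(.data$allele1, .data$allele2)) |>
    dplyr::arrange(.data$a, .data$b) |>
    dplyr::transmute(allele1 = .data$a, allele2 = .data$b)
  if (nrow(cand) == 0) return(empty_call("review"))

  # orient cluster indices by the first candidate so that cluster 1 follows
  # haplotype 1 of the lexicographically first zero-mismatch pair
  best <- cand[1, ]
  oriented <- clusters
  for (amp in amps) {
    ad <- amp_data[[amp]]
    if (length(ad$ex) == 2) {
      m <- match_cl[[amp]]
      id_ok <- m[best$allele1, 1] && m[best$allele2, 2]
      if (!id_ok) {
        sel <- oriented$amplicon == amp
        oriented$cluster_id[sel] <- 3L - oriented$cluster_id[sel]
        oriented <- oriented[order(oriented$amplicon, oriented$cluster_id), ]
      }
    }
  }
  layout_exons <- stats::setNames(as.list(layout$exon), layout$amplicon)
  phase <- purrr::map_dfr(seq_len(nrow(cand)), function(k) {
    phase_layer_mismatches(cand$allele1[k], cand$allele2[k], oriented, tg,
                           layout_exons)
  })
  cand <- dplyr::bind_cols(cand, phase)

  review <- any(clusters$review)
  call <- structure(list(
    sample_id = clusters$sample_id[1],
    locus = locus,
    status = if (review) "review" else "called",
    candidates = cand,
    ambiguity_4digit = sort(unique(pair_key(reduce_to_4digit(cand$allele1),
                                            reduce_to_4digit(cand$allele2)))),
    excluded_null_alleles = tibble(allele = character(), feature = character(),
                                   amplicon = character()),
    warnings = character(),
    read_counts = counts,
    clusters = oriented
  ), class = "hla_call")
  call
}

#' @export
print.hla_call <- function(x, ...) {
  cat(sprintf("<hla_call> %s %s: %s\n", x$sample_id, x$locus, x$status))
  if (nrow(x$candidates) > 0) {
    cat(sprintf("  %d candidate pair(s); 4-digit: %s\n",
                nrow(x$candidates), paste(x$ambiguity_4digit, collapse = " | ")))
  }
  if (nrow(x$excluded_null_alleles) > 0) {
    cat(sprintf("  excluded: %s (%s)\n",
                x$excluded_null_alleles$allele, x$excluded_null_alleles$feature))
  }
  invisible(x)
}

#' Exclude null/low-expression alleles by intron flank evidence
#'
#' In `exon_plus_flank` mode, candidate pairs whose member's annotated
#' intron flank conflicts with the observed flank consensus are removed;
#' each excluded allele is recorded with the discriminating feature (e.g.
#' `intron2`). Alleles whose flank annotation is ABSENT, or whose
#' distinguishing variation lies in a region the panel does not cover,
#' cannot be contradicted and are retained with a warning. In `exon_only`
#' mode no exclusion is performed (suffixed alleles stay in the ambiguity
#' string).
#'
#' @param call An `hla_call` from [call_genotype()].
#' @param targets Target table (must be built in the same mode).
#' @param layout [amplicon_layout()] of the panel.
#' @param mode Trimming/matching mode.
#' @return The updated `hla_call`.
#' @export
exclude_null_alleles <- function(call, targets, layout,
                                 mode = c("exon_plus_flank", "exon_only")) {
  mode <- match.arg(mode)
  if (call$status == "no_result" || nrow(call$candidates) == 0) return(call)
  if (mode == "exon_only") {
    suffixed <- unique(c(call$candidates$allele1, call$candidates$allele2))
    suffixed <- suffixed[!is.na(allele_suffix(suffixed))]
    if (length(suffixed) > 0) {
      call$warnings <- c(call$warnings, sprintf(
        "expression-variant allele %s retained (exon_only mode performs no intron-based exclusion)",
        suffixed))
    }
    return(call)
  }
  clusters <- call$clusters
  tg <- targets[targets$locus == call$locus, ]
  amps <- unique(clusters$amplicon)
  excluded <- list()
  keep <- rep(TRUE, nrow(call$candidates))
  for (k in seq_len(nrow(call$candidates))) {
    a1 <- call$candidates$allele1[k]; a2 <- call$candidates$allele2[k]
    conflict <- NULL
    for (amp in amps) {
      cl <- clusters[clusters$amplicon == amp, ]
      cl <- cl[order(cl$cluster_id), ]
      tga <- tg[tg$amplicon == amp, ]
      f5 <- tga$f5[1]; f3 <- tga$f3[1]
      if (f5 == 0 && f3 == 0) next
      lrow <- layout[layout$amplicon == amp, ]
      parts <- lapply(cl$consensus, split_consensus, f5 = f5, f3 = f3)
      tpart <- function(a, what) tga[[what]][tga$allele == a]
      exon_ok <- function(ci, a) part_match(parts[[ci]]$exon, tpart(a, "exon_part"))
      flank_ok <- function(ci, a) {
        part_match(parts[[ci]]$flank5, tpart(a, "flank5")) &&
          part_match(parts[[ci]]$flank3, tpart(a, "flank3"))
      }
      flank_feature <- function(ci, a) {
        if (!part_match(parts[[ci]]$flank5, tpart(a, "flank5"))) {
          lrow$flank5_feature
        } else {
          lrow$flank3_feature
        }
      }
      if (nrow(cl) == 1) {
        if (!exon_ok(1, a1) || !exon_ok(1, a2)) next
        bad1 <- !flank_ok(1, a1); bad2 <- !flank_ok(1, a2)
        if (bad1 || bad2) {
          if (bad1) conflict <- rbind(conflict,
            data.frame(allele = a1, feature = flank_feature(1, a1), amplicon = amp))
          if (bad2) conflict <- rbind(conflict,
            data.frame(allele = a2, feature = flank_feature(1, a2), amplicon = amp))
        }
      } else {
        orients <- list(c(a1, a2), c(a2, a1))
        exon_valid <- vapply(orients, function(o)
          exon_ok(1, o[1]) && exon_ok(2, o[2]), logical(1))
        if (!any(exon_valid)) next
        full_valid <- vapply(seq_along(orients), function(oi) {
          exon_valid[oi] && flank_ok(1, orients[[oi]][1]) &&
            flank_ok(2, orients[[oi]][2])
        }, logical(1))
        if (!any(full_valid)) {
          oi <- which(exon_valid)[1]
          o <- orients[[oi]]
          if (!flank_ok(1, o[1])) conflict <- rbind(conflict,
            data.frame(allele = o[1], feature = flank_feature(1, o[1]), amplicon = amp))
          if (!flank_ok(2, o[2])) conflict <- rbind(conflict,
            data.frame(allele = o[2], feature = flank_feature(2, o[2]), amplicon = amp))
        }
      }
    }
    if (!is.null(conflict)) {
      keep[k] <- FALSE
      excluded[[length(excluded) + 1L]] <- conflict
    }
  }
  call$candidates <- call$candidates[keep, , drop = FALSE]
  if (length(excluded) > 0) {
    exc <- dplyr::distinct(as_tibble(dplyr::bind_rows(excluded)))
    # an allele still present in a surviving pair was not globally excluded
    surviving <- unique(c(call$candidates$allele1, call$candidates$allele2))
    exc <- exc[!exc$allele %in% surviving, , drop = FALSE]
    exc <- exc[!duplicated(exc$allele), , drop = FALSE]
    call$excluded_null_alleles <- exc
  }
  call$ambiguity_4digit <- sort(unique(pair_key(
    reduce_to_4digit(call$candidates$allele1),
    reduce_to_4digit(call$candidates$allele2))))
  suffixed <- unique(c(call$candidates$allele1, call$candidates$allele2))
  suffixed <- suffixed[!is.na(allele_suffix(suffixed))]
  if (length(suffixed) > 0) {
    call$warnings <- c(call$warnings, sprintf(
      "expression-variant allele %s retained (not excludable by the covered regions)",
      suffixed))
  }
  if (nrow(call$candidates) == 0) call$status <- "review"
  call
}

#' Type all samples across loci
#'
#' End-to-end calling over a trimmed, demultiplexed read set: layer
#' partition, haplotype clustering, genotype-pair enumeration and (in
#' `exon_plus_flank` mode) intron-based null-allele exclusion.
#'
#' @param trimmed Output of [trim_reads()].
#' @param db An `hla_allele_db`.
#' @param panel An `hla_panel`.
#' @param loci Loci to call (default: panel loci resolvable in the db).
#' @param mode,offset Trimming/matching mode.
#' @param min_reads,fail_threshold,min_cluster_fraction Engine thresholds.
#' @return A tibble of class `hla_typing`: one row per sample x locus with
#'   `status`, `n_candidates`, `ambiguity_4digit` (collapsed string), plus
#'   list-columns `candidates`, `excluded`, `warnings`, `call`.
#' @export
type_samples <- function(trimmed, db, panel, loci = NULL,
                         mode = c("exon_plus_flank", "exon_only"),
                         offset = 10L, min_reads = 20L, fail_threshold = 4L,
                         min_cluster_fraction = 0.10) {
  mode <- match.arg(mode)
  layout <- amplicon_layout(panel, db)
  targets <- build_target_table(db, panel, mode, offset, layout = layout)
  if (is.null(loci)) {
    loci <- intersect(unique(unlist(lapply(unique(layout$locus),
                                           amplicon_target_loci))), db$loci)
  }
  part <- partition_layers(trimmed, db, panel, mode, offset, fail_threshold,
                           targets = targets, layout = layout)
  clusters <- build_haplotype_clusters(part, min_cluster_fraction)
  samples <- sort(unique(part$sample_id[part$status == "assigned"]))
  out <- purrr::map_dfr(samples, function(sm) {
    purrr::map_dfr(loci, function(lc) {
      cl <- clusters[clusters$sample_id == sm & clusters$locus == lc, ]
      call <- call_genotype(cl, db, lc, targets, layout, min_reads)
      call$sample_id <- sm
      call <- exclude_null_alleles(call, targets, layout, mode)
      tibble(
        sample_id = sm, locus = lc, status = call$status,
        n_candidates = nrow(call$candidates),
        ambiguity_4digit = paste(call$ambiguity_4digit, collapse = " | "),
        candidates = list(call$candidates),
        excluded = list(call$excluded_null_alleles),
        warnings = list(call$warnings),
        call = list(call)
      )
    })
  })
  class(out) <- c("hla_typing", class(out))
  out
}

#' @rdname type_samples
#' @param x An `hla_typing` tibble.
#' @param ... Unused.
#' @return `tidy()`: one row per candidate pair; `glance()`: per-locus
#'   status counts.
#' @exportS3Method generics::tidy
tidy.hla_typing <- function(x, ...) {
  x |>
    dplyr::select("sample_id", "locus", "status", "candidates") |>
    tidyr::unnest("candidates")
}

#' @rdname type_samples
#' @exportS3Method generics::glance
glance.hla_typing <- function(x, ...) {
  x |>
    dplyr::count(.data$locus, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L)
}

#' Export 4-digit typing results as a flat table
#'
#' The LIMS-style export: one row per sample and locus with the deduplicated
#' 4-digit ambiguity string.
#'
#' @param typing An `hla_typing` tibble.
#' @param path Optional TSV output path.
#' @return The flat tibble (invisibly writes `path` if given).
#' @export
export_4digit <- function(typing, path = NULL) {
  flat <- typing |>
    dplyr::select("sample_id", "locus", "status", "ambiguity_4digit")
  if (!is.null(path)) readr::write_tsv(flat, path)
  flat
}
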
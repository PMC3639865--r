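# Build a cluster tibble directly from database targets (haplotype 1 =
# cluster 1), bypassing the read layer — used for phase/exclusion tests.
clusters_from_pair <- function(a1, a2, locus, amps, n1 = 50L, n2 = 40L) {
  tg <- test_targets()
  purrr::map_dfr(amps, function(amp) {
    t1 <- tg$full[tg$amplicon == amp & tg$allele == a1]
    t2 <- tg$full[tg$amplicon == amp & tg$allele == a2]
    if (identical(t1, t2)) {
      tibble::tibble(sample_id = "S01", locus = locus, amplicon = amp,
                     cluster_id = 1L, consensus = t1, read_count = n1 + n2,
                     fwd_count = (n1 + n2) %/% 2L,
                     rev_count = (n1 + n2) - (n1 + n2) %/% 2L,
                     review = FALSE, master_total = n1 + n2)
    } else {
      tibble::tibble(sample_id = "S01", locus = locus, amplicon = amp,
                     cluster_id = c(1L, 2L), consensus = c(t1, t2),
                     read_count = c(n1, n2),
                     fwd_count = c(n1 %/% 2L, n2 %/% 2L),
                     rev_count = c(n1 - n1 %/% 2L, n2 - n2 %/% 2L),
                     review = FALSE, master_total = n1 + n2)
    }
  })
}

test_that("error-free reads join the master layer; pseudogene reads fail", {
  db <- test_db(); panel <- test_panel()
  truth <- simulate_genotypes(db, 2, homozygote_rate = 0, seed = 61,
                              loci = c("DRB1", "DRB3"))
  model <- error_model(substitution_rate = 0, homopolymer_base_rate = 0,
                       chimera_rate = 0, pseudogene_fraction = 0.25)
  sim <- simulate_reads(truth, db, panel, mean_depth = 25, model = model,
                        seed = 62)
  dm <- demultiplex(sim$reads[c("read_id", "sequence")], panel,
                    sim$association, db, layout = test_layout())
  tr <- trim_reads(dm, panel, db, layout = test_layout())
  part <- partition_layers(tr, db, panel, targets = test_targets(),
                           layout = test_layout())
  truth_class <- sim$reads$class[match(part$read_id, sim$reads$read_id)]
  expect_true(all(part$layer[truth_class == "normal"] == "master"))
  expect_true(all(part$layer[truth_class == "pseudogene"] == "failed"))
  # routing recovers the source locus for normal reads
  src_locus <- allele_locus(sim$reads$allele[match(part$read_id,
                                                   sim$reads$read_id)])
  normal <- truth_class == "normal"
  expect_equal(part$matched_locus[normal], src_locus[normal])
  # layer override works in both directions
  moved <- move_reads(part, part$read_id[1], to = "failed")
  expect_equal(moved$layer[1], "failed")
  moved <- move_reads(moved, part$read_id[1], to = "master")
  expect_equal(moved$layer[1], "master")
})

test_that("DRB crossover chimeras are deactivated via locus-discordant halves", {
  db <- test_db(); panel <- test_panel()
  truth <- simulate_genotypes(db, 2, homozygote_rate = 0, seed = 63,
                              loci = c("DRB1", "DRB5"))
  model <- error_model(substitution_rate = 0, homopolymer_base_rate = 0,
                       chimera_rate = 0.3, pseudogene_fraction = 0)
  sim <- simulate_reads(truth, db, panel, mean_depth = 20, model = model,
                        seed = 64)
  dm <- demultiplex(sim$reads[c("read_id", "sequence")], panel,
                    sim$association, db, layout = test_layout())
  tr <- trim_reads(dm, panel, db, layout = test_layout())
  part <- partition_layers(tr, db, panel, targets = test_targets(),
                           layout = test_layout())
  cls <- sim$reads$class[match(part$read_id, sim$reads$read_id)]
  chim <- cls == "chimera" & part$amplicon == "DRB-2"
  expect_gt(sum(chim), 10)
  expect_true(all(part$layer[chim] == "deactivated"))
  expect_true(all(part$layer[cls == "normal"] == "master"))
})

test_that("haplotype clustering returns one cluster per haplotype", {
  run <- tiny_clean_run()
  part <- partition_layers(run$trimmed, test_db(), test_panel(),
                           targets = test_targets(), layout = test_layout())
  clusters <- build_haplotype_clusters(part)
  truth <- run$truth
  tg <- test_targets()
  for (k in seq_len(nrow(truth))) {
    row <- truth[k, ]
    cl <- clusters[clusters$sample_id == row$sample_id &
                     clusters$locus == row$locus & clusters$amplicon ==
                     paste0(row$locus, "-2"), ]
    n_hap <- length(unique(c(
      tg$full[tg$amplicon == paste0(row$locus, "-2") & tg$allele == row$allele1],
      tg$full[tg$amplicon == paste0(row$locus, "-2") & tg$allele == row$allele2]
    )))
    expect_equal(nrow(cl), n_hap)
    expect_setequal(cl$consensus, unique(c(
      tg$full[tg$amplicon == paste0(row$locus, "-2") & tg$allele == row$allele1],
      tg$full[tg$amplicon == paste0(row$locus, "-2") & tg$allele == row$allele2]
    )))
  }
})

test_that("unanimous forward reads repair reverse homopolymer undercalls", {
  tg <- test_targets()
  t <- tg$full[tg$amplicon == "C-4" & tg$allele == "C*07:02:01"]
  f5 <- tg$f5[tg$amplicon == "C-4"][1]
  # reverse undercall: CCCCC at the exon start read as CCCC
  undercall <- paste0(substr(t, 1, f5), "CCCC", substr(t, f5 + 6, nchar(t)))
  mk <- function(seqs, dirs) {
    tibble::tibble(read_id = paste0("r", seq_along(seqs)), sample_id = "S01",
                   amplicon = "C-4", matched_locus = "C", trimmed = seqs,
                   direction = dirs, layer = "master", status = "assigned")
  }
  part <- mk(c(rep(t, 40), rep(undercall, 20)),
             c(rep("fwd", 30), rep("rev", 10), rep("rev", 20)))
  cl <- build_haplotype_clusters(part)
  expect_equal(nrow(cl), 1)
  expect_identical(cl$consensus, t)
  expect_equal(cl$read_count, 60L)
  # even a unanimously undercalled reverse strand loses to a clean forward
  part2 <- mk(c(rep(t, 30), rep(undercall, 30)),
              c(rep("fwd", 30), rep("rev", 30)))
  cl2 <- build_haplotype_clusters(part2)
  expect_equal(nrow(cl2), 1)
  expect_identical(cl2$consensus, t)
})

test_that("noise clusters below the fraction floor are dropped", {
  tg <- test_targets()
  t1 <- tg$full[tg$amplicon == "A-2" & tg$allele == "A*01:01:01:01"]
  t2 <- tg$full[tg$amplicon == "A-2" & tg$allele == "A*24:02:01:01"]
  noise <- paste0("TTTT", substr(t1, 5, nchar(t1)))
  part <- tibble::tibble(
    read_id = paste0("r", 1:105), sample_id = "S01", amplicon = "A-2",
    matched_locus = "A", trimmed = c(rep(t1, 50), rep(t2, 50), rep(noise, 5)),
    direction = rep(c("fwd", "rev"), length.out = 105), layer = "master",
    status = "assigned")
  cl <- build_haplotype_clusters(part, min_cluster_fraction = 0.10)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$consensus, c(t1, t2))
  expect_false(any(cl$review))
})

test_that("genotype calls recover simulated heterozygotes and homozygotes", {
  run <- tiny_clean_run()
  typing <- type_samples(run$trimmed, test_db(), test_panel(),
                         loci = c("A", "B", "C"), min_reads = 5L)
  for (k in seq_len(nrow(run$truth))) {
    row <- run$truth[k, ]
    call <- typing$call[typing$sample_id == row$sample_id &
                          typing$locus == row$locus][[1]]
    expect_equal(call$status, "called")
    key <- paste(pmin(row$allele1, row$allele2),
                 pmax(row$allele1, row$allele2))
    got <- paste(call$candidates$allele1, call$candidates$allele2)
    expect_true(key %in% got)
    # zero-mismatch master layer for the true pair
    hit <- call$candidates[got == key, ]
    expect_equal(hit$MM, 0L)
  }
})

test_that("insufficient read counts yield no_result, not a call", {
  run <- tiny_clean_run()
  typing <- type_samples(run$trimmed, test_db(), test_panel(), loci = "A",
                         min_reads = 10000L)
  expect_true(all(typing$status == "no_result"))
  expect_true(all(typing$n_candidates == 0))
})

test_that("intron flank evidence excludes null and low-expression alleles", {
  tr <- reads_for_genotype("A", "A*01:01:01:01", "A*24:02:01:01")
  typing <- type_samples(tr, test_db(), test_panel(), loci = "A",
                         mode = "exon_plus_flank", min_reads = 5L)
  call <- typing$call[[1]]
  expect_equal(call$status, "called")
  exc <- call$excluded_null_alleles
  expect_true("A*01:01:01:02N" %in% exc$allele)
  expect_true("A*24:02:01:02L" %in% exc$allele)
  expect_equal(exc$feature[exc$allele == "A*01:01:01:02N"], "intron2")
  expect_equal(exc$feature[exc$allele == "A*24:02:01:02L"], "intron2")
  expect_false(any(grepl("01:01N|24:02L", typing$ambiguity_4digit)))
})

test_that("exon_only mode performs no exclusion and keeps suffixed alleles", {
  db <- test_db(); panel <- test_panel()
  truth <- tibble::tibble(sample_id = "S01", mid_id = NA_character_,
                          locus = "A", allele1 = "A*01:01:01:01",
                          allele2 = "A*24:02:01:01")
  sim <- simulate_reads(truth, db, panel, mean_depth = 60,
                        model = perfect_reads(), seed = 33)
  dm <- demultiplex(sim$reads[c("read_id", "sequence")], panel,
                    sim$association, db, layout = test_layout())
  tr <- trim_reads(dm, panel, db, mode = "exon_only", layout = test_layout())
  typing <- type_samples(tr, db, panel, loci = "A", mode = "exon_only",
                         min_reads = 5L)
  call <- typing$call[[1]]
  expect_equal(nrow(call$excluded_null_alleles), 0)
  expect_true(grepl("A*01:01N", typing$ambiguity_4digit, fixed = TRUE))
  expect_gt(length(call$warnings), 0)
})

test_that("variants outside covered regions are not excludable, with warning", {
  tr <- reads_for_genotype("A", "A*68:01", "A*24:02:01:01", seed = 35)
  typing <- type_samples(tr, test_db(), test_panel(), loci = "A",
                         mode = "exon_plus_flank", min_reads = 5L)
  call <- typing$call[[1]]
  # A*68:11N differs from A*68:01 only in uncovered exon 1: stays
  alleles <- unique(c(call$candidates$allele1, call$candidates$allele2))
  expect_true("A*68:11N" %in% alleles)
  expect_false("A*68:11N" %in% call$excluded_null_alleles$allele)
  expect_true(any(grepl("A\\*68:11N", call$warnings)))
  # and the truth is still in the 4-digit string
  expect_true(grepl("A*24:02/A*68:01", typing$ambiguity_4digit, fixed = TRUE))
})

test_that("phase-layer mismatches expose cis/trans and exon-shuffle structure", {
  tg <- test_targets()
  layout_exons <- setNames(as.list(test_layout()$exon), test_layout()$amplicon)
  amps <- c("A-2", "A-3", "A-4")
  cl <- clusters_from_pair("A*01:01:01:01", "A*24:02:01:01", "A", amps)

  # independent oracle: enumerate every per-amplicon assignment
  ham <- function(a, b) sum(charToRaw(a) != charToRaw(b))
  oracle <- function(a1, a2) {
    costs <- sapply(amps, function(amp) {
      t1 <- tg$exon_part[tg$amplicon == amp & tg$allele == a1]
      t2 <- tg$exon_part[tg$amplicon == amp & tg$allele == a2]
      f5 <- tg$f5[tg$amplicon == amp][1]; f3 <- tg$f3[tg$amplicon == amp][1]
      cc <- cl$consensus[cl$amplicon == amp]
      ex <- substr(cc, f5 + 1, nchar(cc) - f3)
      if (length(ex) == 1) ex <- c(ex, ex)
      c(id = ham(ex[1], t1) + ham(ex[2], t2),
        sw = ham(ex[1], t2) + ham(ex[2], t1))
    })
    list(
      MM = min(sum(costs["id", ]), sum(costs["sw", ])),
      MM3 = min(costs["id", "A-2"] + costs["sw", "A-3"] + costs["id", "A-4"],
                costs["sw", "A-2"] + costs["id", "A-3"] + costs["sw", "A-4"])
    )
  }

  true_pair <- phase_layer_mismatches("A*01:01:01:01", "A*24:02:01:01", cl,
                                      tg, layout_exons)
  expect_equal(true_pair$MM, 0L)
  expect_gt(true_pair$MM3, 0)
  expect_gt(true_pair$MM4, 0)
  o <- oracle("A*01:01:01:01", "A*24:02:01:01")
  expect_equal(true_pair$MM, as.integer(o$MM))
  expect_equal(true_pair$MM3, as.integer(o$MM3))

  # the exon-shuffled decoy: nonzero MM but zero MM3
  decoy <- phase_layer_mismatches("A*80:01", "A*81:01", cl, tg, layout_exons)
  expect_gt(decoy$MM, 0)
  expect_equal(decoy$MM3, 0L)
  od <- oracle("A*80:01", "A*81:01")
  expect_equal(decoy$MM, as.integer(od$MM))
  expect_equal(decoy$MM3, as.integer(od$MM3))

  # single-amplicon loci have no phase layers
  single <- clusters_from_pair("DPB1*01:01", "DPB1*02:01", "DPB1", "DPB1-2")
  na_case <- phase_layer_mismatches("DPB1*01:01", "DPB1*02:01", single, tg,
                                    layout_exons)
  expect_true(is.na(na_case$MM))
})

test_that("adding database alleles never removes the true pair", {
  run <- tiny_clean_run()
  db <- test_db()
  # extend the database with a clone of an existing allele under a new name
  feat <- db_feature_table(db)
  clone <- feat[feat$name == "A*26:01", c("name", "feature", "seq")]
  clone$name <- "A*99:01"
  db_ext <- allele_db_from_features(db$version,
                                    dplyr::bind_rows(
                                      db_feature_table(db)[c("name", "feature", "seq")],
                                      clone))
  for (dbx in list(db, db_ext)) {
    typing <- type_samples(run$trimmed, dbx, test_panel(), loci = "A",
                           min_reads = 5L)
    for (k in which(run$truth$locus == "A")) {
      row <- run$truth[k, ]
      call <- typing$call[typing$sample_id == row$sample_id][[1]]
      got <- paste(call$candidates$allele1, call$candidates$allele2)
      expect_true(paste(pmin(row$allele1, row$allele2),
                        pmax(row$allele1, row$allele2)) %in% got)
    }
  }
})
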
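test_that("exact MID and primer matching assigns constructed reads", {
  db <- test_db(); panel <- test_panel(); lay <- test_layout()
  assoc <- make_association(c("S01", "S02"), panel$mids, "RUNX")
  primer <- lay$fwd_primer[lay$amplicon == "A-2"]
  good <- paste0(assoc$mid[1], primer, strrep("ACGT", 40))
  # one substitution inside the MID breaks the exact match
  bad_mid <- good
  substr(bad_mid, 3, 3) <- if (substr(bad_mid, 3, 3) == "A") "C" else "A"
  bad_primer <- paste0(assoc$mid[2], "TTTTTTTTTTTTTTTTT", strrep("ACGT", 40))
  reads <- tibble::tibble(read_id = c("r1", "r2", "r3"),
                          sequence = c(good, bad_mid, bad_primer))
  dm <- demultiplex(reads, panel, assoc, db, layout = lay)
  expect_equal(dm$status, c("assigned", "no-MID", "no-primer"))
  expect_equal(dm$sample_id[1], "S01")
  expect_equal(dm$amplicon[1], "A-2")
  expect_equal(dm$direction[1], "fwd")
  # fuzzy mode rescues the 1-mismatch MID (distance-3 MID set)
  dm_fuzzy <- demultiplex(reads, panel, assoc, db, layout = lay,
                          max_mid_mismatch = 1)
  expect_equal(dm_fuzzy$status[2], "assigned")
})

test_that("every read lands in exactly one bin or the unassigned pool", {
  run <- tiny_clean_run()
  dm <- run$demux
  expect_equal(nrow(dm), nrow(run$sim$reads))
  expect_equal(sum(dm$status == "assigned") + sum(dm$status != "assigned"),
               nrow(dm))
  # zero simulated error => nothing unassigned
  expect_equal(sum(dm$status != "assigned"), 0)
  # demultiplexing recovers the simulated truth bins
  truth <- run$sim$reads
  expect_equal(dm$amplicon, truth$amplicon)
  expect_equal(dm$sample_id, truth$sample_id)
  expect_equal(dm$direction, truth$direction)
  expect_error(
    demultiplex(run$sim$reads[c("read_id", "sequence")], test_panel(),
                dplyr::bind_rows(run$sim$association,
                                 run$sim$association[1, ]),
                test_db()),
    "duplicate MID")
})

test_that("trimming recovers exon sequences exactly from error-free reads", {
  run <- tiny_clean_run()
  db <- test_db(); panel <- test_panel(); lay <- test_layout()
  exon_only <- trim_reads(run$demux, panel, db, mode = "exon_only",
                          layout = lay)
  truth <- run$sim$reads
  # class I amplicons cover their exon completely: trimmed == source exon
  for (amp in c("A-2", "B-2", "C-3")) {
    sel <- which(truth$amplicon == amp)
    exon_feature <- paste0("exon", lay$exon[lay$amplicon == amp])
    want <- vapply(truth$allele[sel], function(a)
      feature_sequence(db, a, exon_feature), character(1), USE.NAMES = FALSE)
    expect_equal(exon_only$trimmed[sel], want)
  }
  # exon_plus_flank retains 10 nt of intron on each available side
  flank <- run$trimmed
  sel <- which(truth$amplicon == "A-2")[1:10]
  want <- vapply(truth$allele[sel], function(a) {
    paste0(
      substr(feature_sequence(db, a, "intron1"), 121, 130),
      feature_sequence(db, a, "exon2"),
      substr(feature_sequence(db, a, "intron2"), 1, 10)
    )
  }, character(1), USE.NAMES = FALSE)
  expect_equal(flank$trimmed[sel], want)
})

test_that("fragments shorter than MID plus primer are rejected", {
  db <- test_db(); panel <- test_panel(); lay <- test_layout()
  assoc <- make_association("S01", panel$mids, "RUNX")
  frag <- substr(paste0(assoc$mid[1], lay$fwd_primer[lay$amplicon == "A-2"]),
                 1, 10 + nchar(lay$fwd_primer[lay$amplicon == "A-2"]))
  reads <- tibble::tibble(read_id = "r1", sequence = frag)
  dm <- demultiplex(reads, panel, assoc, db, layout = lay)
  tr <- trim_reads(dm, panel, db, layout = lay)
  expect_equal(tr$status, "too_short")
  expect_true(is.na(tr$trimmed))
})

test_that("run reports summarise totals, lengths and per-amplicon counts", {
  empty <- build_run_report(tibble::tibble(read_id = character(),
                                           sequence = character(),
                                           sample_id = character(),
                                           amplicon = character(),
                                           status = character()))
  expect_equal(empty$total_reads, 0)
  expect_equal(empty$assigned_reads, 0)
  expect_equal(empty$median_read_length, 0)

  run <- tiny_clean_run()
  rep <- build_run_report(run$demux, run_id = run$sim$run_id)
  expect_equal(rep$assigned_reads + rep$unassigned_reads, rep$total_reads)
  expect_equal(rep$median_read_length,
               median(nchar(run$sim$reads$sequence)))
  # report counts equal a recount of the truth file
  want <- table(run$sim$reads$amplicon)
  got <- setNames(rep$per_amplicon$n_reads, rep$per_amplicon$amplicon)
  expect_equal(as.integer(got[names(want)]), as.integer(want))
  f <- withr::local_tempfile(fileext = ".json")
  write_run_report(rep, f)
  expect_true(file.exists(f) && file.exists(sub("\\.json$", ".txt", f)))
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})

test_that("the factor-6 DRB exon 2 amplicon dominates read counts", {
  db <- test_db(); panel <- test_panel()
  truth <- simulate_genotypes(db, 3, seed = 51, loci = c("A", "DRB1", "DRB3"))
  sim <- simulate_reads(truth, db, panel, mean_depth = 30,
                        model = perfect_reads(), seed = 52)
  dm <- demultiplex(sim$reads[c("read_id", "sequence")], panel,
                    sim$association, db, layout = test_layout())
  rep <- build_run_report(dm)
  top <- rep$per_amplicon$amplicon[which.max(rep$per_amplicon$n_reads)]
  expect_equal(top, "DRB-2")
  # oracle: recount of the simulator truth agrees
  expect_equal(names(which.max(table(sim$reads$amplicon))), "DRB-2")
})

test_that("association files round-trip and carry the run id", {
  panel <- test_panel()
  assoc <- make_association(sprintf("S%02d", 1:10), panel$mids, "RUN00042")
  expect_equal(nrow(assoc), 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_association_file(assoc, f)
  back <- read_association_file(f, expected_run_id = "RUN00042")
  expect_equal(back$sample_id, assoc$sample_id)
  expect_equal(back$mid, assoc$mid)
  expect_warning(read_association_file(f, expected_run_id = "RUN00043"),
                 "run id")
  expect_error(make_association(sprintf("S%02d", 1:15), panel$mids, "x"),
               "exceeds")
})
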
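test_that("homozygote rate endpoints and calibration behave", {
  db <- test_db()
  het <- simulate_genotypes(db, 10, homozygote_rate = 0, seed = 5,
                            loci = c("A", "B", "C"))
  expect_true(all(het$allele1 != het$allele2))
  hom <- simulate_genotypes(db, 10, homozygote_rate = 1, seed = 5,
                            loci = c("A", "B", "C"))
  expect_true(all(hom$allele1 == hom$allele2))
  # 200 draws at the validation-panel rate: fraction within binomial noise
  g <- simulate_genotypes(db, 200, homozygote_rate = 0.103, seed = 6,
                          loci = "A")
  frac <- mean(g$allele1 == g$allele2)
  expect_gte(frac, 0.06)
  expect_lte(frac, 0.15)
  expect_error(simulate_genotypes(db, 15, seed = 1, panel = test_panel()),
               "MID")
})

test_that("zero-error reads are exact MID||primer||template concatenations", {
  run <- tiny_clean_run()
  reads <- run$sim$reads
  assoc <- run$sim$association
  expect_true(all(substr(reads$sequence, 1, 10) %in% assoc$mid))
  # forward reads carry the forward primer right after the MID
  lay <- test_layout()
  fwd <- reads[reads$direction == "fwd" & reads$amplicon == "A-2", ]
  primer <- lay$fwd_primer[lay$amplicon == "A-2"]
  expect_true(all(substr(fwd$sequence, 11, 10 + nchar(primer)) == primer))
  # reverse reads open with the reverse primer
  rev <- reads[reads$direction == "rev" & reads$amplicon == "A-2", ]
  rprimer <- lay$rev_primer_read[lay$amplicon == "A-2"]
  expect_true(all(substr(rev$sequence, 11, 10 + nchar(rprimer)) == rprimer))
  expect_true(all(reads$n_sub == 0) && all(reads$n_hp == 0))
})

test_that("read depth tracks pooling factors", {
  run <- tiny_clean_run()
  counts <- table(run$sim$reads$amplicon)
  # factor-0.5 short amplicons sit well below factor-1 amplicons on average
  expect_lt(counts[["B-1"]], counts[["B-2"]] * 1.5)
  expect_gt(sum(run$sim$reads$amplicon == "A-2"), 0)
})

test_that("chimera generation hits the configured DRB exon 2 rate", {
  db <- test_db(); panel <- test_panel()
  truth <- simulate_genotypes(db, 4, homozygote_rate = 0, seed = 21,
                              loci = c("DRB1", "DRB3"))
  model <- error_model(substitution_rate = 0, homopolymer_base_rate = 0,
                       chimera_rate = 0.05, pseudogene_fraction = 0)
  sim <- simulate_reads(truth, db, panel, mean_depth = 60, model = model,
                        seed = 22)
  drb2 <- sim$reads[sim$reads$amplicon == "DRB-2", ]
  frac <- mean(drb2$class == "chimera")
  n <- nrow(drb2)
  expect_gt(n, 500)  # factor 6 on DRB exon 2
  ci <- 1.96 * sqrt(0.05 * 0.95 / n)
  expect_gte(frac, 0.05 - 2 * ci)
  expect_lte(frac, 0.05 + 2 * ci)
  # chimera truth records name both parents across loci
  expect_true(all(startsWith(drb2$allele[drb2$class == "chimera"], "DRB1")))
  expect_true(all(startsWith(drb2$allele2[drb2$class == "chimera"], "DRB3")))
})

test_that("homopolymer errors only change run lengths of existing runs", {
  db <- test_db(); panel <- test_panel()
  truth <- tibble::tibble(sample_id = "S01", mid_id = NA_character_,
                          locus = "C", allele1 = "C*07:02:01",
                          allele2 = "C*07:04")
  model <- error_model(substitution_rate = 0, homopolymer_base_rate = 0.2,
                       chimera_rate = 0, pseudogene_fraction = 0)
  sim <- simulate_reads(truth, db, panel, mean_depth = 40, model = model,
                        seed = 23)
  hp <- sim$reads[sim$reads$n_hp > 0, ]
  expect_gt(nrow(hp), 0)
  collapse <- function(s) paste(rle(strsplit(s, "", fixed = TRUE)[[1]])$values,
                                collapse = "")
  lay <- test_layout()
  for (k in seq_len(min(nrow(hp), 25))) {
    row <- hp[k, ]
    lrow <- lay[lay$amplicon == row$amplicon, ]
    prod <- hlatyper:::amplicon_product(db, row$allele, lrow)$product
    template <- if (row$direction == "fwd") prod else revcomp(prod)
    body <- substr(row$sequence, 11, nchar(row$sequence))
    expect_identical(collapse(body), collapse(template))
    expect_false(identical(body, template))
  }
})

test_that("the same seed reproduces a byte-identical FASTA", {
  db <- test_db(); panel <- test_panel()
  truth <- simulate_genotypes(db, 2, seed = 31, loci = "A")
  s1 <- simulate_reads(truth, db, panel, mean_depth = 25, seed = 32)
  s2 <- simulate_reads(truth, db, panel, mean_depth = 25, seed = 32)
  expect_identical(s1$reads, s2$reads)
  f1 <- withr::local_tempfile(fileext = ".fna")
  f2 <- withr::local_tempfile(fileext = ".fna")
  write_reads_fasta(s1$reads, f1)
  write_reads_fasta(s2$reads, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and FASTA round trip preserves the reads
  rt <- read_reads_fasta(f1)
  expect_equal(rt$sequence, s1$reads$sequence)
})

test_that("quantification plates carry 8 standards and propagate noise to QC", {
  panel <- test_panel()
  clean <- simulate_quant_plate(panel, noise_sd = 0, seed = 41)
  expect_equal(nrow(clean$standards), 8)
  expect_equal(range(clean$standards$conc), c(0, 100))
  fit <- fit_standard_curve(clean$standards)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  noisy <- simulate_quant_plate(panel, noise_sd = 2000, seed = 42)
  fit_n <- fit_standard_curve(noisy$standards)
  expect_equal(fit_n$r_squared, cor(noisy$standards$conc,
                                    noisy$standards$signal)^2,
               tolerance = 1e-10)
  expect_false(fit_n$pass)
})
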
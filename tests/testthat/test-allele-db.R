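dialect_text <- function(records) {
  c("#version=test-0.1", unlist(records, use.names = FALSE))
}

rec <- function(name, feats, seq) {
  c(sprintf(">%s features=%s", name, feats), seq)
}

test_that("annotated-FASTA round trip is byte-stable and counts records", {
  f <- withr::local_tempfile(fileext = ".fna")
  writeLines(dialect_text(list(
    rec("X*01:01", "exon1:1-4,intron1:5-10,exon2:11-16", c("ACGTACGTAC", "GTACGT")),
    rec("X*01:02", "exon1:1-4,intron1:5-10,exon2:11-16", c("ACGAACGTAC", "GTACGT")),
    rec("X*02:01", "exon1:1-4,exon2:5-10", "ACGTACGTAC"),
    rec("X*03:01N", "exon1:1-4,intron1:5-10,exon2:11-16", c("ACGTACTTAC", "GTACGT"))
  )), f)
  db <- read_allele_db(f)
  expect_equal(nrow(db$alleles), 4)
  expect_equal(db$loci, "X")
  expect_equal(db$version, "test-0.1")
  f2 <- withr::local_tempfile(fileext = ".fna")
  f3 <- withr::local_tempfile(fileext = ".fna")
  write_allele_db(db, f2)
  write_allele_db(read_allele_db(f2), f3)
  expect_identical(readBin(f2, "raw", file.size(f2)),
                   readBin(f3, "raw", file.size(f3)))
})

test_that("the packaged dialect example loads and matches its own coordinates", {
  f <- system.file("extdata", "mock_db_locusA.fna", package = "hlatyper")
  db <- read_allele_db(f)
  expect_equal(db$loci, "A")
  expect_equal(nrow(db$alleles), 11)
  # oracle: slice the raw record by its own header coordinates
  lines <- readLines(f)
  hdr <- grep("^>A\\*01:01:01:01 ", lines, value = TRUE)
  m <- regmatches(hdr, regexec("exon2:([0-9]+)-([0-9]+)", hdr))[[1]]
  i <- match("A*01:01:01:01", db$alleles$name)
  raw_seq <- db$alleles$sequence[i]
  expect_equal(feature_sequence(db, "A*01:01:01:01", "exon2"),
               substring(raw_seq, as.integer(m[2]), as.integer(m[3])))
  expect_equal(nchar(feature_sequence(db, "A*01:01:01:01", "exon2")), 270)
})

test_that("loading rejects duplicates, bad spans and bad characters", {
  f <- withr::local_tempfile(fileext = ".fna")
  writeLines(dialect_text(list(
    rec("X*01:01", "exon1:1-4", "ACGT"),
    rec("X*01:01", "exon1:1-4", "ACGT")
  )), f)
  expect_error(read_allele_db(f), "duplicate")

  writeLines(dialect_text(list(
    rec("X*01:01", "exon1:1-4,exon2:5-12", "ACGTACGT")
  )), f)
  expect_error(read_allele_db(f), "bounds")

  writeLines(dialect_text(list(
    rec("X*01:01", "exon1:1-4", "ACNT")
  )), f)
  expect_error(read_allele_db(f), "non-ACGT")
})

test_that("feature access returns segments, ABSENT as NA, and lookup errors", {
  db <- test_db()
  expect_equal(nchar(feature_sequence(db, "A*01:01:01:01", "exon2")), 270)
  stripped <- strip_feature_annotation(db, "A*25:01", c("intron2", "intron3"))
  expect_true(is.na(feature_sequence(stripped, "A*25:01", "intron2")))
  expect_false(is.na(feature_sequence(stripped, "A*25:01", "exon2")))
  expect_error(feature_sequence(db, "A*99:99", "exon2"), "unknown allele")
})

test_that("present features concatenate to the stored full sequence", {
  db <- test_db()
  feat <- db_feature_table(db)
  for (nm in db$alleles$name) {
    i <- match(nm, db$alleles$name)
    expect_identical(paste(feat$seq[feat$name == nm], collapse = ""),
                     db$alleles$sequence[i])
  }
})

test_that("the mock database packages the engineered hard cases", {
  db <- test_db()
  expect_gte(length(db$loci), 3)
  counts <- table(db$alleles$locus)
  expect_true(all(counts[typing_loci(db)] >= 8))
  expect_true(all(counts >= 2))
  # null allele differing from its expressed counterpart only in intron 2
  expect_identical(feature_sequence(db, "A*01:01:01:01", "exon2"),
                   feature_sequence(db, "A*01:01:01:02N", "exon2"))
  expect_false(identical(feature_sequence(db, "A*01:01:01:01", "intron2"),
                         feature_sequence(db, "A*01:01:01:02N", "intron2")))
  # 6 bp exon 3 deletion
  expect_equal(nchar(feature_sequence(db, "A*74:12N", "exon3")), 270)
  expect_equal(nchar(feature_sequence(db, "A*01:01:01:01", "exon3")), 276)
  # exon-shuffled pair recombines the two base alleles
  expect_identical(feature_sequence(db, "A*80:01", "exon3"),
                   feature_sequence(db, "A*24:02:01:01", "exon3"))
  expect_identical(feature_sequence(db, "A*80:01", "exon2"),
                   feature_sequence(db, "A*01:01:01:01", "exon2"))
  # C homopolymer at the start of exon 4
  expect_equal(substr(feature_sequence(db, "C*07:02:01", "exon4"), 1, 6),
               "CCCCCA")
  # pseudogene exon 2 is far from every functional DRB allele
  pseudo <- feature_sequence(db, "DRBP*01:01", "exon2")
  for (lc in c("DRB1", "DRB3", "DRB4", "DRB5")) {
    for (a in locus_alleles(db, lc)) {
      d <- sum(charToRaw(pseudo) !=
                 charToRaw(feature_sequence(db, a, "exon2")))
      expect_gte(d, 8)
    }
  }
})
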
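#' Packaged mock allele reference database
#'
#' Builds the deterministic mock stand-in for a curated HLA reference release
#' (`version "mock-3.7.0"`). It is constructed in code (fixed internal seed)
#' rather than shipped as a flat file, and covers nine typing loci (A, B, C,
#' DRB1, DRB3, DRB4, DRB5, DQB1, DPB1) plus a dedicated pseudo-locus `DRBP`
#' holding DRB pseudogene sequences that the generic DRB primers co-amplify.
#'
#' Deliberately engineered content, mirroring the allele classes that make
#' clinical typing hard:
#' \itemize{
#'   \item `A*01:01:01:02N` — null allele differing from `A*01:01:01:01` only
#'     in intron 2 (excludable from intron flanks), and `A*24:02:01:02L` — low
#'     expression variant likewise differing only in intron 2.
#'   \item `A*74:12N` — null allele with a 6 bp deletion in exon 3.
#'   \item `A*68:11N` — differs from `A*68:01` only in exon 1, which no
#'     amplicon covers: not excludable by this panel.
#'   \item `A*80:01`/`A*81:01` — an exon-shuffled pair recombining the exons
#'     of `A*01:01:01:01` and `A*24:02:01:01` (phase-between-exons decoys).
#'   \item `B*44:02`/`B*44:03` vs `B*07:02:01`/`B*08:01` — a cis/trans
#'     quartet: both genotype pairs share the same unphased (Sanger-style)
#'     superposition at exons 2-4.
#'   \item `B*15:01:01:02N` — null allele differing only in intron 1.
#'   \item `C*07:02:01`/`C*07:04` — carry a 5-base C homopolymer at the start
#'     of exon 4 (the classic pyrosequencing trouble spot).
#'   \item `DRB1*03:68N` — differs from `DRB1*03:01` only under the generic
#'     DRB reverse primer footprint (last 21 exon-2 bases): undetectable.
#'   \item `DRBP*...` — pseudogene sequences >= 8 substitutions away from
#'     every functional DRB allele.
#' }
#'
#' @return An `hla_allele_db`.
#' @examples
#' db <- mock_allele_db()
#' feature_sequence(db, "A*01:01:01:01", "exon2")
#' @export
mock_allele_db <- function() {
  withr::with_seed(607011, build_mock_db())
}

.class1_lengths <- c(
  "5NCR" = 240, exon1 = 73, intron1 = 130, exon2 = 270, intron2 = 150,
  exon3 = 276, intron3 = 150, exon4 = 276, intron4 = 100, exon5 = 117,
  intron5 = 80, exon6 = 33, intron6 = 90, exon7 = 48, intron7 = 60, exon8 = 40
)

.class2_lengths <- c(
  exon1 = 80, intron1 = 150, exon2 = 270, intron2 = 120, exon3 = 282,
  intron3 = 100
)

base_gene <- function(lengths) {
  stats::setNames(lapply(lengths, random_dna), names(lengths))
}

# One allele = base gene + deterministic edits.
#   snps:   list(feature = positions)      transition substitutions
#   blocks: list(list(feature, start, seq)) literal replacement
#   dels:   list(list(feature, start, len)) deletion
apply_allele_edits <- function(gene, snps = list(), blocks = list(), dels = list()) {
  for (b in blocks) {
    s <- gene[[b$feature]]
    substr(s, b$start, b$start + nchar(b$seq) - 1L) <- b$seq
    gene[[b$feature]] <- s
  }
  for (feat in names(snps)) {
    s <- gene[[feat]]
    for (p in snps[[feat]]) {
      substr(s, p, p) <- transition(substr(s, p, p))
    }
    gene[[feat]] <- s
  }
  for (d in dels) {
    s <- gene[[d$feature]]
    gene[[d$feature]] <- paste0(substr_safe(s, 1, d$start - 1L),
                                substr_safe(s, d$start + d$len, nchar(s)))
  }
  gene
}

gene_to_rows <- function(name, gene) {
  tibble(name = name, feature = names(gene), seq = unlist(gene, use.names = FALSE))
}

build_mock_db <- function() {
  rows <- list()
  add <- function(name, gene, ...) {
    rows[[length(rows) + 1L]] <<- gene_to_rows(name, apply_allele_edits(gene, ...))
  }

  ## ---- locus A -------------------------------------------------------------
  A <- base_gene(.class1_lengths)
  e24 <- list(exon2 = c(40, 101, 150, 201), exon3 = c(50, 120, 200),
              exon4 = c(60, 130, 210))
  add("A*01:01:01:01", A)
  add("A*01:01:01:02N", A, snps = list(intron2 = 4))
  add("A*24:02:01:01", A, snps = e24)
  add("A*24:02:01:02L", A, snps = c(e24, list(intron2 = 7)))
  add("A*25:01", A, snps = list(exon2 = c(35, 95), exon3 = 77))
  add("A*26:01", A, snps = list(exon2 = c(35, 160), exon3 = 88))
  add("A*68:01", A, snps = list(exon2 = c(55, 140), exon3 = c(66, 99), exon4 = 44))
  add("A*68:11N", A, snps = list(exon2 = c(55, 140), exon3 = c(66, 99),
                                 exon4 = 44, exon1 = 70))
  add("A*74:12N", A, snps = list(exon2 = 77),
      dels = list(list(feature = "exon3", start = 100, len = 6)))
  # exon-shuffled decoys: exon recombinants of A*01:01:01:01 and A*24:02:01:01
  add("A*80:01", A, snps = list(exon3 = c(50, 120, 200)))
  add("A*81:01", A, snps = list(exon2 = c(40, 101, 150, 201),
                                exon4 = c(60, 130, 210)))

  ## ---- locus B -------------------------------------------------------------
  B <- base_gene(.class1_lengths)
  qe2 <- c(30, 90, 160, 220); qe3 <- c(40, 110, 180); qe4 <- c(60, 130, 200)
  add("B*07:02:01", B)
  add("B*08:01", B, snps = list(exon2 = qe2, exon3 = qe3, exon4 = qe4))
  add("B*44:02", B, snps = list(exon2 = qe2[1:2]))
  add("B*44:03", B, snps = list(exon2 = qe2[3:4], exon3 = qe3, exon4 = qe4))
  add("B*15:01:01:01", B, snps = list(exon2 = c(50, 120), exon3 = 70))
  add("B*15:01:01:02N", B, snps = list(exon2 = c(50, 120), exon3 = 70, intron1 = 6))
  add("B*18:23N", B, snps = list(exon3 = 90))
  add("B*27:05", B, snps = list(exon2 = c(66, 200), exon4 = 90))
  add("B*40:01", B, snps = list(exon2 = c(100, 240), exon3 = 150))

  ## ---- locus C -------------------------------------------------------------
  C <- base_gene(.class1_lengths)
  c5block <- list(list(feature = "exon4", start = 1, seq = "CCCCCA"))
  add("C*01:02:01", C)
  add("C*03:03:01:01", C, snps = list(exon2 = c(45, 130), exon3 = 60))
  add("C*03:04:01:01", C, snps = list(exon2 = c(45, 130), exon3 = 140))
  add("C*07:02:01", C, snps = list(exon2 = c(80, 190), exon3 = 100, exon4 = 150),
      blocks = c5block)
  add("C*07:04", C, snps = list(exon2 = c(80, 210), exon3 = c(100, 170), exon4 = 160),
      blocks = c5block)
  add("C*02:02", C, snps = list(exon2 = 20, exon4 = 220))
  add("C*04:01", C, snps = list(exon2 = c(140, 230), exon3 = 30))
  add("C*05:01", C, snps = list(exon3 = c(200, 250), exon4 = 40))

  ## ---- DRB family ----------------------------------------------------------
  ## One shared base gene: the generic DRB primer regions (intron1 120-141,
  ## exon2 250-270, intron2 90-110, intron3 1-20) are identical across the
  ## family, which is what lets a single primer pair co-amplify DRB1, DRB3/4/5
  ## and the pseudogenes. Locus identity lives in two substitution blocks per
  ## exon (one in each half of the read) so that crossover chimeras carry a
  ## detectable locus switch.
  DRB <- base_gene(.class2_lengths)
  drb1_band <- function(i, e3 = NULL) {
    s <- list(exon2 = c(26 + 4 * i, 106 + 4 * i, 206 + 2 * i))
    if (!is.null(e3)) s$exon3 <- e3
    s
  }
  add("DRB1*01:01:01", DRB)
  add("DRB1*03:01", DRB, snps = drb1_band(1))
  add("DRB1*03:68N", DRB, snps = list(exon2 = c(26 + 4, 106 + 4, 206 + 2, 255)))
  add("DRB1*04:01", DRB, snps = drb1_band(2))
  add("DRB1*07:01", DRB, snps = drb1_band(3, e3 = 30))
  add("DRB1*11:01", DRB, snps = drb1_band(4, e3 = 34))
  add("DRB1*13:01", DRB, snps = drb1_band(5, e3 = 38))
  add("DRB1*15:01", DRB, snps = drb1_band(6, e3 = 42))

  fam_block <- list(
    DRB3 = list(exon2 = c(60, 64, 68, 72, 160, 164, 168, 172),
                exon3 = c(60, 64, 68, 72, 160, 164, 168, 172)),
    DRB4 = list(exon2 = c(76, 80, 84, 88, 176, 180, 184, 188),
                exon3 = c(76, 80, 84, 88, 176, 180, 184, 188)),
    DRB5 = list(exon2 = c(92, 96, 100, 104, 192, 196, 200, 204),
                exon3 = c(92, 96, 100, 104, 192, 196, 200, 204))
  )
  fam_names <- list(
    DRB3 = c("01:01", "01:02", "01:03", "02:01", "02:02", "02:03", "03:01", "03:02"),
    DRB4 = c("01:01", "01:02", "01:03", "01:04", "01:05", "01:06", "01:08", "02:01"),
    DRB5 = c("01:01", "01:02", "01:03", "02:02", "02:03", "02:04", "02:05", "01:08")
  )
  extra <- list(list(), list(exon2 = 29), list(exon2 = 33), list(exon2 = 37),
                list(exon2 = 41), list(exon2 = 45), list(exon3 = 31),
                list(exon3 = 39))
  for (loc in names(fam_block)) {
    for (i in seq_along(fam_names[[loc]])) {
      snps <- fam_block[[loc]]
      for (feat in names(extra[[i]])) {
        snps[[feat]] <- sort(c(snps[[feat]], extra[[i]][[feat]]))
      }
      add(sprintf("%s*%s", loc, fam_names[[loc]][i]), DRB, snps = snps)
    }
  }
  # pseudogenes: 15 exon-2 substitutions at positions no functional allele uses
  pseudo <- c(21, 23, 25, 27, 141, 143, 145, 147, 149, 151, 225, 227, 229, 231, 233)
  add("DRBP*01:01", DRB, snps = list(exon2 = pseudo))
  add("DRBP*02:01", DRB, snps = list(exon2 = c(pseudo, 170)))

  ## ---- DQB1 ----------------------------------------------------------------
  DQ <- base_gene(.class2_lengths)
  add("DQB1*02:01:01", DQ)
  add("DQB1*02:02", DQ, snps = list(exon2 = 40))
  add("DQB1*03:01", DQ, snps = list(exon2 = c(60, 120, 180), exon3 = 100))
  add("DQB1*03:02", DQ, snps = list(exon2 = c(60, 120, 200), exon3 = 130))
  add("DQB1*05:01", DQ, snps = list(exon2 = c(35, 95, 155), exon3 = 160))
  add("DQB1*06:01", DQ, snps = list(exon2 = c(45, 105, 165), exon3 = 190))
  add("DQB1*06:02", DQ, snps = list(exon2 = c(45, 105, 225), exon3 = 220))
  add("DQB1*06:03", DQ, snps = list(exon2 = c(45, 165, 225), exon3 = 250))

  ## ---- DPB1 ----------------------------------------------------------------
  DP <- base_gene(.class2_lengths)
  add("DPB1*01:01", DP, snps = list(exon2 = c(30, 80)))
  add("DPB1*02:01", DP, snps = list(exon2 = c(50, 100)))
  add("DPB1*03:01:01", DP)
  add("DPB1*04:01", DP, snps = list(exon2 = c(70, 140)))
  add("DPB1*04:02", DP, snps = list(exon2 = c(70, 160)))
  add("DPB1*05:01", DP, snps = list(exon2 = c(90, 180)))
  add("DPB1*09:01", DP, snps = list(exon2 = c(110, 200)))
  add("DPB1*104:01", DP, snps = list(exon2 = c(130, 220)))

  allele_db_from_features("mock-3.7.0", dplyr::bind_rows(rows))
}

#' Typing loci of a database
#'
#' All loci except the `DRBP` pseudo-locus, which exists only to model
#' co-amplified pseudogene reads.
#'
#' @param db An `hla_allele_db`.
#' @return Character vector of locus ids.
#' @export
typing_loci <- function(db) setdiff(db$loci, "DRBP")
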
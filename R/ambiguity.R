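#' Phased versus unphased genotype ambiguity
#'
#' Clonal amplicon sequencing reads each haplotype separately, so
#' heterozygous positions within an exon are phased; generic Sanger
#' sequencing-based typing (SBT) observes only the per-position
#' superposition of the two haplotypes (IUPAC mixtures), so every genotype
#' pair producing the same superposition is equally consistent — the classic
#' cis/trans ambiguity. Comparing the two candidate counts per genotype
#' quantifies the ambiguity reduction achieved by clonal sequencing.
#'
#' @name ambiguity
NULL

# exons a generic SBT kit covers, per locus
.sbt_exons <- list(
  A = c(2, 3, 4), B = c(2, 3, 4), C = c(2, 3),
  DRB1 = 2, DRB3 = 2, DRB4 = 2, DRB5 = 2,
  DQB1 = c(2, 3), DPB1 = 2
)

# IUPAC code for an unordered pair of bases
.iupac_pair <- c(
  AA = "A", CC = "C", GG = "G", TT = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K"
)

iupac_superpose <- function(s1, s2) {
  if (nchar(s1) != nchar(s2)) {
    # heterozygous length difference: no positionwise superposition exists;
    # key on the unordered sequence pair instead
    return(paste(sort(c(s1, s2)), collapse = "+"))
  }
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  key <- paste0(pmin(a, b), pmax(a, b))
  paste(.iupac_pair[key], collapse = "")
}

superposition_key <- function(db, a1, a2, exons) {
  paste(vapply(exons, function(e) {
    f <- paste0("exon", e)
    s1 <- feature_sequence(db, a1, f)
    s2 <- feature_sequence(db, a2, f)
    if (is.na(s1) || is.na(s2)) return("?")
    iupac_superpose(s1, s2)
  }, character(1)), collapse = "|")
}

locus_pairs <- function(db, locus) {
  alleles <- locus_alleles(db, locus)
  p <- expand.grid(i = seq_along(alleles), j = seq_along(alleles))
  p <- p[p$i <= p$j, ]
  tibble(allele1 = alleles[p$i], allele2 = alleles[p$j])
}

#' Count genotype pairs compatible with the unphased superposition
#'
#' Builds the per-exon IUPAC superposition of the two haplotypes of a
#' genotype (over the exons a generic SBT kit covers for the locus) and
#' counts all database genotype pairs with an identical superposition,
#' deduplicated at 4-digit resolution and including non-expressed alleles.
#' Always at least the phased candidate count.
#'
#' @param db An `hla_allele_db`.
#' @param allele1,allele2 The genotype.
#' @param exons Exon numbers to superpose (default: the locus' SBT set).
#' @return Integer count of 4-digit genotype pairs.
#' @export
sanger_ambiguity_count <- function(db, allele1, allele2, exons = NULL) {
  locus <- allele_locus(allele1)
  exons <- exons %||% .sbt_exons[[locus]]
  if (is.null(exons)) abort(sprintf("no SBT exon set for locus %s", locus))
  key <- superposition_key(db, allele1, allele2, exons)
  pairs <- locus_pairs(db, locus)
  keys <- vapply(seq_len(nrow(pairs)), function(k) {
    superposition_key(db, pairs$allele1[k], pairs$allele2[k], exons)
  }, character(1))
  hit <- pairs[keys == key, ]
  length(unique(pair_key(reduce_to_4digit(hit$allele1),
                         reduce_to_4digit(hit$allele2))))
}

#' Count genotype pairs compatible with phased haplotype sequences
#'
#' The clonal-sequencing analogue of [sanger_ambiguity_count()]: counts
#' database pairs whose per-haplotype exon sequences equal the genotype's
#' haplotypes (in either orientation) over the same exon set, deduplicated
#' at 4-digit resolution.
#'
#' @inheritParams sanger_ambiguity_count
#' @return Integer count of 4-digit genotype pairs.
#' @export
phased_pair_count <- function(db, allele1, allele2, exons = NULL) {
  locus <- allele_locus(allele1)
  exons <- exons %||% .sbt_exons[[locus]]
  if (is.null(exons)) abort(sprintf("no SBT exon set for locus %s", locus))
  hap <- function(a) {
    vapply(exons, function(e) {
      s <- feature_sequence(db, a, paste0("exon", e))
      if (is.na(s)) "?" else s
    }, character(1))
  }
  h1 <- hap(allele1); h2 <- hap(allele2)
  pairs <- locus_pairs(db, locus)
  hit <- vapply(seq_len(nrow(pairs)), function(k) {
    x <- hap(pairs$allele1[k]); y <- hap(pairs$allele2[k])
    (all(x == h1) && all(y == h2)) || (all(x == h2) && all(y == h1))
  }, logical(1))
  hits <- pairs[hit, ]
  length(unique(pair_key(reduce_to_4digit(hits$allele1),
                         reduce_to_4digit(hits$allele2))))
}

#' Ambiguity reduction percentage
#'
#' `100 * (unphased - phased) / unphased`: the share of unphased (SBT)
#' genotype ambiguities that clonal sequencing resolves. Zero when the
#' counts are equal.
#'
#' @param unphased Unphased (SBT) ambiguity count.
#' @param phased Phased (clonal) candidate count.
#' @return Percentage in `[0, 100]`.
#' @examples
#' ambiguity_reduction(20, 2)  # 90
#' @export
ambiguity_reduction <- function(unphased, phased) {
  if (any(phased < 1)) abort("phased count must be >= 1")
  if (any(phased > unphased)) {
    abort("invariant violation: phased count exceeds unphased count")
  }
  100 * (unphased - phased) / unphased
}
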
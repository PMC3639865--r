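#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Canonical gene-feature order used throughout (5' -> 3').
.feature_order <- c(
  "5NCR",
  as.vector(rbind(paste0("exon", 1:7), paste0("intron", 1:7))),
  "exon8", "3NCR"
)

feature_rank <- function(feature) match(feature, .feature_order)

#' Reverse-complement a nucleotide string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors, used for reverse-orientation reads and primers.
#'
#' @param x Character vector of ACGT sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Deterministic DNA generator (used by the mock database builder).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Transition map used for deterministic SNP edits in the mock database.
transition <- function(base) {
  unname(c(A = "G", G = "A", C = "T", T = "C")[base])
}

assert_acgt <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf("%s contains non-ACGT characters (first offender: %s)",
                  what, substr(x[bad][1], 1, 30)))
  }
  invisible(x)
}

# substr() that returns "" (not NA) when the window is empty/out of range.
substr_safe <- function(x, start, stop) {
  if (stop < start) return("")
  substr(x, start, stop)
}
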
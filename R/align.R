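#' Mismatch count of a read against a reference
#'
#' Global alignment of the query with free end gaps on its flanks (the
#' reference may overhang on either side without penalty), minimising
#' substitutions plus gapped bases. This is the mismatch notion used by the
#' layer partition and the phase-layer display: `0` means the query occurs
#' exactly within the reference.
#'
#' Implemented via [Biostrings::pairwiseAlignment()] with match score 0,
#' mismatch -1 and linear gap cost 1 in `"global-local"` mode, so the
#' (negated) optimal score is exactly the minimal count of substitutions plus
#' gap bases.
#'
#' @param query Character vector of query sequences (vectorised).
#' @param reference A single reference sequence.
#' @return Integer vector of mismatch counts.
#' @examples
#' align_to_reference("ACGT", "TTACGTTT")   # 0
#' align_to_reference("AGGT", "TTACGTTT")   # 1
#' @export
align_to_reference <- function(query, reference) {
  if (length(reference) != 1 || is.na(reference) || nchar(reference) == 0) {
    abort("reference must be a single non-empty sequence")
  }
  if (length(query) == 0) return(integer(0))
  if (any(is.na(query)) || any(nchar(query) == 0)) {
    abort("query sequences must be non-empty")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(query),
    subject = Biostrings::DNAString(reference),
    type = "global-local",
    substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1,
    scoreOnly = TRUE
  )
  as.integer(round(-aln))
}

# Hamming distance of many equal-length strings against one target; used as
# a fast screen before full alignment (alignment distance <= Hamming, so a
# Hamming count within threshold proves membership).
hamming_to <- function(seqs, target) {
  if (length(seqs) == 0) return(integer(0))
  stopifnot(all(nchar(seqs) == nchar(target)))
  tg <- charToRaw(target)
  vapply(seqs, function(s) sum(charToRaw(s) != tg), integer(1),
         USE.NAMES = FALSE)
}

# Minimal mismatch count of each read against a set of targets (NA targets
# are wildcards and are skipped). Uses exact/Hamming screens with alignment
# fallback for length-discordant or high-Hamming reads.
min_mismatch_to_targets <- function(reads, targets, cap = 30L) {
  targets <- targets[!is.na(targets)]
  if (length(targets) == 0) return(rep(NA_integer_, length(reads)))
  best <- rep(.Machine$integer.max, length(reads))
  by_len <- split(seq_along(reads), nchar(reads))
  for (tg in targets) {
    idx <- by_len[[as.character(nchar(tg))]]
    if (!is.null(idx)) {
      h <- hamming_to(reads[idx], tg)
      best[idx] <- pmin(best[idx], h)
    }
  }
  # alignment fallback where the screen has not established a small distance
  todo <- which(best > cap)
  if (length(todo) > 0) {
    aligned <- vapply(targets, function(tg) {
      align_to_reference(reads[todo], tg)
    }, integer(length(todo)))
    aligned <- matrix(aligned, nrow = length(todo))
    best[todo] <- pmin(best[todo], apply(aligned, 1, min))
  }
  as.integer(best)
}
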
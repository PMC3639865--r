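#' Parse HLA allele names
#'
#' HLA alleles are named `LOCUS*f1:f2[:f3[:f4]]` with up to four colon-separated
#' numeric fields and an optional expression suffix (`N` null, `L` low, `S`
#' secreted, `Q` questionable), optionally preceded by a space
#' (e.g. `"A*74:12 N"`). Field strings keep their zero padding.
#'
#' @param text Character vector of allele names.
#' @return A tibble with one row per name: `text` (canonical form), `locus`,
#'   `fields` (list column of character vectors), `n_fields`, `suffix`
#'   (`NA` when absent).
#' @examples
#' parse_allele_name(c("A*01:01:01:02N", "B*07:02", "A*74:12 N"))
#' @export
parse_allele_name <- function(text) {
  stopifnot(is.character(text))
  m <- regexec("^([A-Z][A-Za-z0-9]*)\\*([0-9]+(?::[0-9]+){0,3}) ?([NLSQ])?$",
               text)
  parts <- regmatches(text, m)
  bad <- lengths(parts) == 0
  if (any(bad)) {
    abort(sprintf("malformed allele name: '%s'", text[bad][1]))
  }
  locus <- vapply(parts, `[`, character(1), 2)
  fields <- lapply(parts, function(p) strsplit(p[3], ":", fixed = TRUE)[[1]])
  suffix <- vapply(parts, `[`, character(1), 4)
  suffix[suffix == ""] <- NA_character_
  out <- tibble(
    locus = locus,
    fields = fields,
    n_fields = lengths(fields),
    suffix = suffix
  )
  out$text <- format_allele_name(out)
  out[, c("text", "locus", "fields", "n_fields", "suffix")]
}

#' Format parsed allele names canonically
#'
#' Inverse of [parse_allele_name()]: no space before the expression suffix.
#'
#' @param parsed A tibble as returned by [parse_allele_name()].
#' @return Character vector of canonical allele names.
#' @export
format_allele_name <- function(parsed) {
  paste0(
    parsed$locus, "*",
    vapply(parsed$fields, paste, character(1), collapse = ":"),
    ifelse(is.na(parsed$suffix), "", parsed$suffix)
  )
}

#' Reduce allele names to 4-digit (two-field) resolution
#'
#' Truncates names to their first two fields. The expression suffix is kept:
#' null (`N`) and low-expression (`L`) alleles remain clinically distinct at
#' every resolution. Idempotent.
#'
#' @param name Character vector of allele names.
#' @return Character vector of 4-digit names.
#' @examples
#' reduce_to_4digit("A*01:01:01:02N")  # "A*01:01N"
#' @export
reduce_to_4digit <- function(name) {
  p <- parse_allele_name(name)
  p$fields <- lapply(p$fields, function(f) f[seq_len(min(2L, length(f)))])
  format_allele_name(p)
}

#' Locus of an allele name
#' @param name Character vector of allele names.
#' @return Character vector of loci.
#' @export
allele_locus <- function(name) parse_allele_name(name)$locus

#' Expression suffix of an allele name
#' @param name Character vector of allele names.
#' @return Character vector (`"N"`, `"L"`, `"S"`, `"Q"` or `NA`).
#' @export
allele_suffix <- function(name) parse_allele_name(name)$suffix

# Canonical unordered genotype-pair key "a/b" with a <= b lexicographically.
pair_key <- function(a1, a2) {
  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
}
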
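# Small shared helpers. Coordinates are 0-based half-open everywhere inside the
# package; dialect-specific conventions are converted at parse/emit time.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse-complement a DNA string
#'
#' Plain-character convenience wrapper (N maps to N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# opposite contig end tag
other_end <- function(e) ifelse(e == "5p", "3p", "5p")

# deterministic key for a contig end (paste0 would recycle zero-length
# inputs against the literal separator, so guard explicitly)
end_key <- function(contig, end) {
  if (!length(contig) || !length(end)) return(character(0))
  paste0(contig, ":", end)
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# seeded RNG scope: evaluates expr with a private RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# strip a trailing mate token from a read id; returns pair id and mate index
split_mate_token <- function(ids) {
  mate <- rep(NA_integer_, length(ids))
  pair <- ids
  hit <- grepl("[/_][12]$", ids)
  mate[hit] <- as.integer(substring(ids[hit], nchar(ids[hit])))
  pair[hit] <- substr(ids[hit], 1L, nchar(ids[hit]) - 2L)
  list(pair_id = pair, mate = mate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
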
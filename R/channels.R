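#' Canonical 96-channel single-base-substitution contexts
#'
#' Single-base substitutions are classified by the pyrimidine-centred
#' substitution type (C>A, C>G, C>T, T>A, T>C, T>G) crossed with the 16
#' flanking dinucleotide contexts, ordered lexicographically by the 5' then
#' the 3' base. Channel labels follow the standard `"A[C>A]A"` convention.
#'
#' @return Character vector of length 96 with the channel labels in
#'   canonical order.
#' @export
#' @examples
#' head(sbs_channels())
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(p5, p3) {
      paste0(p5, "[", s, "]", p3)
    })))
  }))
}

# Complement a vector of single bases.
complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

# Reverse-complement a character vector of sequences.
revcomp <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""), function(b) {
    paste(rev(b), collapse = "")
  }, character(1))
}

# Map (5' base, ref base, 3' base, alt base) to a channel index (1..96),
# reverse-complementing purine-centred variants. Vectorised; returns NA for
# anything that does not resolve to one of the 96 channels.
channel_index <- function(p5, ref, alt, p3) {
  purine <- ref %in% c("A", "G")
  p5c <- ifelse(purine, complement_base(p3), p5)
  p3c <- ifelse(purine, complement_base(p5), p3)
  refc <- ifelse(purine, complement_base(ref), ref)
  altc <- ifelse(purine, complement_base(alt), alt)
  lab <- paste0(p5c, "[", refc, ">", altc, "]", p3c)
  match(lab, sbs_channels())
}
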
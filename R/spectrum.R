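#' Trinucleotide channel of an SNV
#'
#' Maps single-nucleotide variants to their pyrimidine-centred 96-channel
#' index given the reference sequence. Variants whose reference base is a
#' purine are reverse-complemented onto the pyrimidine strand. Indels and
#' variants at the first or last reference position have no full context and
#' return `NA`.
#'
#' @param reference Named character vector of reference sequences (see
#'   [generate_reference()]).
#' @param chrom,pos,ref,alt Vectors describing the variants (1-based `pos`).
#' @return Integer vector of channel indices in `1:96`, `NA` where not
#'   applicable.
#' @export
#' @examples
#' ref <- c(chr1 = "ATCAG")
#' trinucleotide_context(ref, "chr1", 3, "C", "T")  # T[C>T]A
trinucleotide_context <- function(reference, chrom, pos, ref, alt) {
  n <- length(pos)
  stopifnot(length(chrom) %in% c(1L, n), length(ref) == n, length(alt) == n)
  chrom <- rep_len(chrom, n)
  seqs <- reference[chrom]
  if (anyNA(names(seqs))) {
    abort_invalid("Variant chromosome not present in the reference.")
  }
  lens <- nchar(seqs)
  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  interior <- pos >= 2 & pos <= lens - 1
  out <- rep(NA_integer_, n)
  use <- which(is_snv & interior)
  if (length(use)) {
    base_at <- substr(seqs[use], pos[use], pos[use])
    if (any(base_at != ref[use])) {
      abort_invalid("Reference base does not match `ref` allele at some positions.")
    }
    p5 <- substr(seqs[use], pos[use] - 1L, pos[use] - 1L)
    p3 <- substr(seqs[use], pos[use] + 1L, pos[use] + 1L)
    out[use] <- channel_index(p5, ref[use], alt[use], p3)
  }
  out
}

#' Build a 96-channel mutation spectrum
#'
#' Bins the SNVs of a variant table into the canonical 96 trinucleotide
#' channels. Indels and edge-position variants are skipped and tallied in
#' the `n_excluded` attribute.
#'
#' @param variants Tibble with columns `chrom`, `pos`, `ref`, `alt`.
#' @param reference Named character vector of reference sequences.
#' @return A `mutation_spectrum`: a named integer vector of length 96 with
#'   attributes `n_excluded` (skipped variants) and class
#'   `mutation_spectrum`.
#' @export
build_spectrum <- function(variants, reference) {
  if (nrow(variants) == 0L) {
    return(new_mutation_spectrum(rep(0L, 96), 0L))
  }
  idx <- trinucleotide_context(reference, variants$chrom, variants$pos,
                               variants$ref, variants$alt)
  counts <- tabulate(idx, nbins = 96L)
  new_mutation_spectrum(counts, sum(is.na(idx)))
}

new_mutation_spectrum <- function(counts, n_excluded) {
  structure(stats::setNames(as.integer(counts), sbs_channels()),
            n_excluded = as.integer(n_excluded),
            class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat(sprintf("<mutation_spectrum: %d SNVs, %d excluded>\n",
              sum(x), attr(x, "n_excluded")))
  invisible(x)
}

#' Tidy a mutation spectrum
#'
#' @param x A `mutation_spectrum`.
#' @param ... Unused.
#' @return Tibble with columns `channel`, `substitution`, `context`, `count`.
#' @method tidy mutation_spectrum
#' @export
tidy.mutation_spectrum <- function(x, ...) {
  ch <- sbs_channels()
  tibble::tibble(
    channel = ch,
    substitution = substr(ch, 3, 5),
    context = paste0(substr(ch, 1, 1), substr(ch, 3, 3), substr(ch, 7, 7)),
    count = as.integer(x))
}
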
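#' Generate a synthetic reference sequence
#'
#' Draws an i.i.d. nucleotide sequence with a target GC content, as a
#' stand-in reference for simulation studies.
#'
#' @param length_bp Sequence length in bases (>= 3, so that every interior
#'   position has a full trinucleotide context).
#' @param gc_fraction Target GC fraction in `[0, 1]`.
#' @param seed Integer seed; the same `(length_bp, gc_fraction, seed)` always
#'   yields the same sequence.
#' @param name Sequence name used when writing FASTA.
#' @return A single-element named character vector over `{A,C,G,T}`.
#' @export
#' @examples
#' ref <- generate_reference(1000, 0.41, seed = 7)
#' nchar(ref)
generate_reference <- function(length_bp, gc_fraction = 0.41, seed = 1,
                               name = "ref1") {
  check_count(length_bp, "length_bp", lower = 3)
  check_proportion(gc_fraction, "gc_fraction")
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- with_seed(seed, {
    paste(sample(names(probs), length_bp, replace = TRUE, prob = probs),
          collapse = "")
  })
  stats::setNames(seq, name)
}

#' Write and read reference FASTA
#'
#' `write_reference()` writes a named character vector as FASTA together
#' with a samtools-style `.fai` index sidecar; `read_reference()` reads a
#' FASTA back into a named character vector.
#'
#' @param reference Named character vector of sequences.
#' @param path Output FASTA path.
#' @param width Line width for wrapped FASTA output.
#' @return `write_reference()` returns `path` invisibly; `read_reference()`
#'   returns a named character vector.
#' @export
write_reference <- function(reference, path, width = 70L) {
  x <- Biostrings::DNAStringSet(unname(as.character(reference)))
  names(x) <- names(reference)
  Biostrings::writeXStringSet(x, path, width = width)
  write_fai(reference, paste0(path, ".fai"), width = width)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

# samtools faidx fields: name, length, offset of first base, bases per line,
# bytes per line (bases + newline).
write_fai <- function(reference, path, width = 70L) {
  lens <- nchar(reference)
  offsets <- numeric(length(reference))
  off <- 0
  for (i in seq_along(reference)) {
    off <- off + nchar(names(reference)[i]) + 2  # ">name\n"
    offsets[i] <- off
    nlines <- ceiling(lens[i] / width)
    off <- off + lens[i] + nlines
  }
  readr::write_tsv(
    tibble::tibble(name = names(reference), length = lens, offset = offsets,
                   linebases = as.integer(width),
                   linewidth = as.integer(width) + 1L),
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
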
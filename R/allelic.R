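#' Expected variant allele frequency given cellularity and copy state
#'
#' For a sample that is a mixture of tumor cells (fraction `p`, carrying
#' `c_alt` alt copies out of `c_tot` total copies at the locus) and normal
#' cells (fraction `1 - p`, diploid with `g` alt copies), the expected VAF
#' is
#' \deqn{ \frac{(1-p)\,g + p\,c_{alt}}{(1-p)\,2 + p\,c_{tot}}. }
#' A zero denominator (pure tumor with total copy number 0) yields `NA`.
#'
#' @param p Tumor cellularity in `[0, 1]`.
#' @param g Alt copies in normal cells: 0, 1, or 2.
#' @param c_alt,c_tot Tumor alt and total copy numbers (`c_alt <= c_tot`).
#' @return Expected VAF; vectorised over all arguments.
#' @export
#' @examples
#' expected_vaf(0, 1, 1, 2)    # pure normal het: 0.5
#' expected_vaf(0.5, 1, 0, 1)  # half-pure hemizygous loss of alt: 1/3
expected_vaf <- function(p, g, c_alt, c_tot) {
  n <- max(length(p), length(g), length(c_alt), length(c_tot))
  p <- rep_len(p, n); g <- rep_len(g, n)
  c_alt <- rep_len(c_alt, n); c_tot <- rep_len(c_tot, n)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort_invalid("Cellularity `p` must be in [0, 1].")
  }
  if (any(!g %in% c(0, 1, 2))) abort_invalid("`g` must be 0, 1 or 2.")
  if (any(c_alt < 0 | c_tot < 0 | c_alt > c_tot, na.rm = TRUE)) {
    abort_invalid("Need 0 <= c_alt <= c_tot.")
  }
  num <- (1 - p) * g + p * c_alt
  den <- (1 - p) * 2 + p * c_tot
  ifelse(den == 0, NA_real_, num / den)
}

#' Detect loss of heterozygosity from germline-het VAF shifts
#'
#' Compares, per germline-heterozygous site, the binomial likelihood of the
#' observed tumor alt/total reads under the retained model (expected VAF
#' 0.5 at any cellularity) against the best loss model given the tumor
#' cellularity: hemizygous loss of the alt allele (`c_alt = 0`,
#' `c_tot = 1`) or copy-neutral loss of the ref allele (`c_alt = 2`,
#' `c_tot = 2`); together the two cover VAF shifts in both directions.
#' A site is called `LOH` when the best loss log-likelihood exceeds the
#' retained one by more than `llr_threshold`; sites under `min_depth` total
#' reads are `indeterminate`.
#'
#' @param sites Tibble with columns `alt_reads`, `total_reads` (tumor) and
#'   any identifier columns, which are carried through.
#' @param cellularity Tumor cellularity of the sample in `(0, 1]`.
#' @param llr_threshold Log-likelihood-ratio threshold (default 3, about an
#'   e^3 likelihood ratio).
#' @param min_depth Depth floor below which sites are indeterminate.
#' @return The input tibble with `status` (`LOH`/`retained`/
#'   `indeterminate`), `llr`, and `best_model` columns added.
#' @export
detect_loh <- function(sites, cellularity, llr_threshold = 3, min_depth = 20) {
  if (missing(cellularity) || is.null(cellularity) || anyNA(cellularity)) {
    abort_invalid("`cellularity` is required for LOH detection.")
  }
  check_number(llr_threshold, "llr_threshold")
  stopifnot(all(c("alt_reads", "total_reads") %in% names(sites)))
  if (any(sites$alt_reads < 0 | sites$alt_reads > sites$total_reads)) {
    abort_invalid("Need 0 <= alt_reads <= total_reads.")
  }
  n <- nrow(sites)
  p <- rep_len(cellularity, n)
  models <- tibble::tibble(
    model = c("loss_of_alt", "loss_of_ref"),
    c_alt = c(0, 2),
    c_tot = c(1, 2))
  logl <- function(vaf) {
    stats::dbinom(sites$alt_reads, sites$total_reads,
                  pmin(pmax(vaf, 1e-6), 1 - 1e-6), log = TRUE)
  }
  l_ret <- logl(rep(0.5, n))
  l_loss <- sapply(seq_len(nrow(models)), function(i) {
    logl(expected_vaf(p, 1, models$c_alt[i], models$c_tot[i]))
  })
  if (n == 1L) l_loss <- matrix(l_loss, nrow = 1)
  best <- max.col(l_loss)
  llr <- l_loss[cbind(seq_len(n), best)] - l_ret
  status <- dplyr::case_when(
    sites$total_reads < min_depth ~ "indeterminate",
    llr > llr_threshold ~ "LOH",
    TRUE ~ "retained")
  dplyr::mutate(sites,
                status = status,
                llr = llr,
                best_model = ifelse(status == "LOH", models$model[best],
                                    NA_character_))
}

#' Filter CNV segments to extreme-copy-number candidates
#'
#' Keeps segments with an estimated total copy number of 0 or greater
#' than 6, and a segment size strictly greater than 20 kb (coordinates are
#' 1-based inclusive, so size is `end - start + 1`).
#'
#' @param segments Tibble with `chrom`, `start`, `end`, `copy_number` (and
#'   anything else, carried through).
#' @param max_normal_cn Upper copy number bound (exclusive) regarded as
#'   non-extreme; candidates require `copy_number > max_normal_cn` or 0.
#' @param min_size_bp Minimum segment size (exclusive bound).
#' @return The kept rows of `segments`.
#' @export
cnv_candidate_filter <- function(segments, max_normal_cn = 6,
                                 min_size_bp = 20000) {
  if (any(segments$end < segments$start)) {
    abort_invalid("Segments must satisfy end >= start.")
  }
  dplyr::filter(segments,
                (.data$copy_number == 0 | .data$copy_number > max_normal_cn),
                (.data$end - .data$start + 1) > min_size_bp)
}

#' Inter-region copy-number heterogeneity distances
#'
#' Rasterises each region's segment profile onto fixed genomic bins (a bin
#' takes the copy number of the segment covering its midpoint) and scores
#' each pair of regions by the mean absolute log2 ratio of
#' pseudocount-shifted copy numbers over bins covered in both:
#' `mean(|log2((cn_a + 0.5) / (cn_b + 0.5))|)`. Pairs with no shared
#' covered bin get `NA`.
#'
#' @param segments Tibble with `region_id`, `chrom`, `start`, `end`,
#'   `copy_number` (1-based inclusive coordinates).
#' @param bin_size Bin width in bp (default 1 Mb).
#' @return A symmetric `cnv_distance` matrix (zero diagonal) with region
#'   labels.
#' @export
cnv_heterogeneity <- function(segments, bin_size = 1e6) {
  regions <- sort(unique(segments$region_id))
  if (length(regions) < 2) {
    abort_invalid("Need at least two regions for a heterogeneity matrix.")
  }
  check_number(bin_size, "bin_size", lower = 1)
  # shared bin grid over the union extent of each chromosome
  grids <- segments |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(lo = min(.data$start), hi = max(.data$end),
                     .groups = "drop")
  mids <- purrr::pmap_dfr(grids, function(chrom, lo, hi) {
    starts <- seq(floor((lo - 1) / bin_size) * bin_size + 1, hi,
                  by = bin_size)
    tibble::tibble(chrom = chrom, mid = pmin(starts + bin_size / 2, hi))
  })
  cn_at <- function(region) {
    seg <- dplyr::filter(segments, .data$region_id == region)
    vapply(seq_len(nrow(mids)), function(i) {
      s <- seg[seg$chrom == mids$chrom[i] & seg$start <= mids$mid[i] &
                 seg$end >= mids$mid[i], ]
      if (nrow(s) == 0) NA_real_ else s$copy_number[1]
    }, numeric(1))
  }
  prof <- vapply(regions, cn_at, numeric(nrow(mids)))
  if (nrow(mids) == 1L) prof <- matrix(prof, nrow = 1,
                                       dimnames = list(NULL, regions))
  d <- matrix(0, length(regions), length(regions),
              dimnames = list(regions, regions))
  for (i in seq_along(regions)) {
    for (j in seq_along(regions)) {
      if (i >= j) next
      both <- !is.na(prof[, i]) & !is.na(prof[, j])
      d[i, j] <- d[j, i] <- if (!any(both)) NA_real_ else
        mean(abs(log2((prof[both, i] + 0.5) / (prof[both, j] + 0.5))))
    }
  }
  structure(d, class = c("cnv_distance", "matrix"))
}

#' Read and write CNV segment tables
#'
#' Tab-separated segment tables with columns `region_id`, `chrom`, `start`,
#' `end`, `copy_number` (and optionally `minor_cn`). Coordinates are
#' declared 1-based inclusive; `bed0 = TRUE` accepts standard BED 0-based
#' half-open coordinates on read (converted on the fly) and writes them on
#' write.
#'
#' @param path File path.
#' @param segments Segment tibble.
#' @param bed0 Use BED 0-based half-open coordinates in the file.
#' @return `read_segments()` a tibble; `write_segments()` `path`,
#'   invisibly.
#' @export
read_segments <- function(path, bed0 = FALSE) {
  seg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           .default = readr::col_guess()))
  if (bed0) seg$start <- seg$start + 1L
  seg
}

#' @rdname read_segments
#' @export
write_segments <- function(segments, path, bed0 = FALSE) {
  if (bed0) segments$start <- segments$start - 1L
  readr::write_tsv(segments, path, progress = FALSE)
  invisible(path)
}
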
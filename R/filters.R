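#' Somatic driver-gene filtration cascade
#'
#' First of the two parallel somatic cascades: a variant passes when its
#' gene is on the driver list, caller quality (QSS for SNVs, QSI for
#' indels, both carried in `qss`) is strictly greater than 15, the
#' population allele frequency is below 1% (missing passes: absence of
#' evidence is not exclusion), the CADD scaled score is greater than 2 when
#' available, and the predicted impact is HIGH or MODERATE.
#'
#' @param variants Tibble with columns `gene`, `qss`, `pop_af`, `cadd`,
#'   `impact` (missing values allowed where documented).
#' @param driver_genes Non-empty character vector of driver gene symbols.
#' @return The input with `passed` (logical) and `failed_rules`
#'   (semicolon-joined rule names, `""` when passed) columns added.
#' @export
filter_somatic_driver <- function(variants, driver_genes) {
  if (length(driver_genes) == 0) {
    abort_invalid("`driver_genes` must be non-empty.")
  }
  rules <- list(
    gene = !is.na(variants$gene) & variants$gene %in% driver_genes,
    qss = !is.na(variants$qss) & variants$qss > 15,
    pop_af = is.na(variants$pop_af) | variants$pop_af < 0.01,
    cadd = is.na(variants$cadd) | variants$cadd > 2,
    impact = variants$impact %in% c("HIGH", "MODERATE"))
  add_decisions(variants, rules)
}

#' Somatic loss-of-function + LOH filtration cascade
#'
#' Second somatic cascade: all genes are queried (no driver list), with the
#' same quality, population-frequency, and CADD thresholds as
#' [filter_somatic_driver()], but requiring HIGH (loss-of-function) impact
#' and evidence of somatic loss of heterozygosity at the locus.
#'
#' @param variants As in [filter_somatic_driver()].
#' @param loh Logical vector (recycled) of per-variant somatic-LOH
#'   evidence; missing is treated as no evidence.
#' @return The input with `passed` and `failed_rules` columns added.
#' @export
filter_somatic_lof_loh <- function(variants, loh) {
  loh <- rep_len(loh, nrow(variants))
  loh[is.na(loh)] <- FALSE
  rules <- list(
    qss = !is.na(variants$qss) & variants$qss > 15,
    pop_af = is.na(variants$pop_af) | variants$pop_af < 0.01,
    cadd = is.na(variants$cadd) | variants$cadd > 2,
    impact = variants$impact %in% "HIGH",
    loh = loh)
  add_decisions(variants, rules)
}

#' Germline DNA-repair variant filtration cascade
#'
#' A germline variant passes when its gene is on the DNA-repair list, its
#' population allele frequency is below 2% (missing passes), and it is
#' either HIGH impact or a missense variant satisfying at least one of:
#' ClinVar pathogenic/likely-pathogenic; located in a Pfam domain and
#' called damaging by at least one of PROVEAN, SIFT, PolyPhen; or called
#' damaging by at least two of the three predictors. Missing predictor
#' calls count as not damaging.
#'
#' @param variants Tibble with columns `gene`, `pop_af`, `impact`,
#'   `clinvar`, `pfam_domain`, `provean`, `sift`, `polyphen`.
#' @param repair_genes Non-empty character vector of DNA-repair gene
#'   symbols.
#' @return The input with `passed` and `failed_rules` columns added.
#' @export
filter_germline_repair <- function(variants, repair_genes) {
  if (length(repair_genes) == 0) {
    abort_invalid("`repair_genes` must be non-empty.")
  }
  dmg <- function(x) !is.na(x) & x == "damaging"
  n_damaging <- dmg(variants$provean) + dmg(variants$sift) +
    dmg(variants$polyphen)
  clinvar_path <- !is.na(variants$clinvar) &
    variants$clinvar %in% c("pathogenic", "likely_pathogenic")
  pfam <- !is.na(variants$pfam_domain) & variants$pfam_domain
  missense_ok <- clinvar_path | (pfam & n_damaging >= 1) | n_damaging >= 2
  rules <- list(
    gene = !is.na(variants$gene) & variants$gene %in% repair_genes,
    pop_af = is.na(variants$pop_af) | variants$pop_af < 0.02,
    consequence = variants$impact %in% "HIGH" |
      (variants$impact %in% "MODERATE" & missense_ok))
  add_decisions(variants, rules)
}

add_decisions <- function(variants, rules) {
  mat <- do.call(cbind, rules)
  mat[is.na(mat)] <- FALSE
  failed <- apply(mat, 1, function(ok) {
    paste(names(rules)[!ok], collapse = ";")
  })
  dplyr::mutate(variants,
                passed = failed == "",
                failed_rules = failed)
}

#' Mutation burden and hypermutation classification
#'
#' Burden is the somatic variant count per callable megabase;
#' a tumor is classified hypermutated when the burden strictly exceeds
#' 10 variants/Mb.
#'
#' @param n_variants Somatic variant count(s).
#' @param callable_mb Callable megabases (> 0).
#' @param burden Variants per megabase.
#' @param threshold Hypermutation threshold (strict).
#' @return `mutation_burden()` the burden(s); `classify_hypermutated()` a
#'   logical vector.
#' @export
#' @examples
#' mutation_burden(28000, 2800)            # 10, not hypermutated
#' classify_hypermutated(mutation_burden(30000, 2800))
mutation_burden <- function(n_variants, callable_mb) {
  if (any(callable_mb <= 0)) abort_invalid("`callable_mb` must be > 0.")
  if (any(n_variants < 0)) abort_invalid("`n_variants` must be >= 0.")
  n_variants / callable_mb
}

#' @rdname mutation_burden
#' @export
classify_hypermutated <- function(burden, threshold = 10) {
  burden > threshold
}

#' Export a filtration decision table
#'
#' Writes a decision tibble (as returned by the filter cascades) as TSV,
#' with the `failed_rules` column semicolon-joined.
#'
#' @param decisions Tibble with `passed` and `failed_rules`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  readr::write_tsv(decisions, path, progress = FALSE)
  invisible(path)
}
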
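# Flat annotation schema carried in INFO: GENE, IMPACT, CADD, QSS, POPAF,
# CLINVAR, PFAM, PROVEAN, SIFT, POLYPHEN. Per-sample read support in
# AD (ref,alt) and DP. Multi-allelic records are rejected: pre-split them.

vcf_info_keys <- c("GENE", "IMPACT", "CADD", "QSS", "POPAF", "CLINVAR",
                   "PFAM", "PROVEAN", "SIFT", "POLYPHEN")

#' Write variants as VCF 4.2
#'
#' Emits the package's flat single-caller annotation schema: one INFO key
#' per annotation field and per-sample `AD`/`DP` genotype fields for read
#' support. Records are sorted by chromosome then position. Missing
#' annotations are omitted from INFO.
#'
#' @param variants Tibble with `variant_id`, `chrom`, `pos`, `ref`, `alt`
#'   and the annotation columns `gene`, `impact`, `cadd`, `qss`, `pop_af`,
#'   `clinvar`, `pfam_domain`, `provean`, `sift`, `polyphen` (missing
#'   columns are treated as all-missing).
#' @param path Output path.
#' @param support Optional long tibble `variant_id`, `region_id`,
#'   `alt_reads`, `total_reads`; each region becomes a sample column.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, support = NULL) {
  if (nrow(variants) > 0 && any(grepl(",", variants$alt, fixed = TRUE))) {
    abort_invalid("Multi-allelic records are not supported; pre-split them.")
  }
  v <- fill_annotation_columns(variants)
  v <- dplyr::arrange(v, .data$chrom, .data$pos)
  samples <- character()
  ad <- dp <- NULL
  if (!is.null(support) && nrow(v) > 0) {
    if (any(support$alt_reads > support$total_reads)) {
      abort_invalid("Support has alt_reads > total_reads.")
    }
    samples <- sort(unique(support$region_id))
    wide <- support |>
      dplyr::mutate(
        cell = sprintf("%d,%d:%d", .data$total_reads - .data$alt_reads,
                       .data$alt_reads, .data$total_reads)) |>
      dplyr::select("variant_id", "region_id", "cell") |>
      tidyr::pivot_wider(names_from = "region_id", values_from = "cell",
                         values_fill = ".:.")
    v <- dplyr::left_join(v, wide, by = "variant_id")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=clonehet",
    sprintf('##INFO=<ID=%s,Number=1,Type=%s,Description="%s">',
            vcf_info_keys,
            c("String", "String", "Float", "Float", "Float", "String",
              "Integer", "String", "String", "String"),
            c("Gene symbol", "Predicted impact", "CADD scaled score",
              "Caller quality (QSS for SNV, QSI for indel)",
              "Population allele frequency", "ClinVar status",
              "Variant in Pfam domain", "PROVEAN call", "SIFT call",
              "PolyPhen call")),
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Ref,alt read depth">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)),
          collapse = "\t"))
  body <- if (nrow(v) == 0) character() else {
    info <- vapply(seq_len(nrow(v)), function(i) {
      kv <- c(
        GENE = na_or(v$gene[i]), IMPACT = na_or(v$impact[i]),
        CADD = na_or(v$cadd[i]), QSS = na_or(v$qss[i]),
        POPAF = na_or(v$pop_af[i]),
        CLINVAR = if (!is.na(v$clinvar[i]) && v$clinvar[i] != "none")
          v$clinvar[i] else NA_character_,
        PFAM = if (isTRUE(v$pfam_domain[i])) "1" else NA_character_,
        PROVEAN = na_or(v$provean[i]), SIFT = na_or(v$sift[i]),
        POLYPHEN = na_or(v$polyphen[i]))
      kv <- kv[!is.na(kv)]
      if (length(kv) == 0) "." else
        paste(paste0(names(kv), "=", kv), collapse = ";")
    }, character(1))
    fixed <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".",
                   "PASS", info, sep = "\t")
    if (length(samples)) {
      cells <- as.matrix(v[, samples, drop = FALSE])
      cells[is.na(cells)] <- ".:."
      paste(fixed, "AD:DP",
            apply(cells, 1, paste, collapse = "\t"), sep = "\t")
    } else {
      fixed
    }
  }
  writeLines(c(header, body), path)
  invisible(path)
}

na_or <- function(x) if (is.na(x)) NA_character_ else as.character(x)

fill_annotation_columns <- function(variants) {
  defaults <- list(gene = NA_character_, impact = NA_character_,
                   cadd = NA_real_, qss = NA_real_, pop_af = NA_real_,
                   clinvar = "none", pfam_domain = FALSE,
                   provean = NA_character_, sift = NA_character_,
                   polyphen = NA_character_)
  for (nm in names(defaults)) {
    if (!nm %in% names(variants)) variants[[nm]] <- defaults[[nm]]
  }
  if (!"variant_id" %in% names(variants)) {
    variants$variant_id <- sprintf("v%05d", seq_len(nrow(variants)))
  }
  variants
}

#' Read a VCF into annotated variants and per-region support
#'
#' Parses a VCF 4.x through `vcfR`, lifting the package's flat INFO
#' annotation schema into columns (unknown INFO keys are ignored; missing
#' keys become missing values) and per-sample `AD`/`DP` fields into a long
#' support table. Records with `AD` alt reads exceeding `DP` are a
#' validation error naming the offending record.
#'
#' @param path VCF path.
#' @param region_ids Optional subset of sample columns to keep.
#' @return List with `variants` (tibble, one row per record, with `vtype`
#'   derived as SNV iff both alleles have length 1) and `support` (long
#'   tibble; empty when the file has no sample columns).
#' @export
read_vcf <- function(path, region_ids = NULL) {
  if (!file.exists(path)) abort_invalid(sprintf("No such file: %s", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n > 0 && any(grepl(",", fix$ALT, fixed = TRUE))) {
    abort_invalid("Multi-allelic records are not supported; pre-split them.")
  }
  info_get <- function(key, as = "character") {
    if (n == 0) return(if (as == "numeric") numeric() else character())
    x <- vcfR::extract.info(vcf, element = key)
    if (is.null(x)) x <- rep(NA_character_, n)
    if (as == "numeric") suppressWarnings(as.numeric(x)) else x
  }
  variants <- tibble::tibble(
    variant_id = if (n) fix$ID else character(),
    chrom = if (n) fix$CHROM else character(),
    pos = if (n) as.integer(fix$POS) else integer(),
    ref = if (n) fix$REF else character(),
    alt = if (n) fix$ALT else character(),
    gene = info_get("GENE"),
    impact = info_get("IMPACT"),
    cadd = info_get("CADD", "numeric"),
    qss = info_get("QSS", "numeric"),
    pop_af = info_get("POPAF", "numeric"),
    clinvar = dplyr::coalesce(info_get("CLINVAR"), "none"),
    pfam_domain = !is.na(info_get("PFAM")),
    provean = info_get("PROVEAN"),
    sift = info_get("SIFT"),
    polyphen = info_get("POLYPHEN")) |>
    dplyr::mutate(vtype = ifelse(nchar(.data$ref) == 1L &
                                   nchar(.data$alt) == 1L, "SNV", "indel"))
  if (anyNA(variants$pos) || any(variants$pos < 1)) {
    abort_invalid(sprintf(
      "Malformed POS at record(s): %s",
      paste(which(is.na(variants$pos) | variants$pos < 1), collapse = ", ")))
  }
  support <- tibble::tibble(variant_id = character(),
                            region_id = character(),
                            alt_reads = integer(), total_reads = integer())
  samples <- colnames(vcf@gt)
  samples <- samples[samples != "FORMAT"]
  if (!is.null(region_ids)) samples <- intersect(samples, region_ids)
  if (n > 0 && length(samples) > 0) {
    ad <- vcfR::extract.gt(vcf, element = "AD")
    dp <- vcfR::extract.gt(vcf, element = "DP")
    support <- purrr::map_dfr(samples, function(s) {
      alt <- suppressWarnings(
        as.integer(sub("^[0-9.]+,", "", ad[, s])))
      tot <- suppressWarnings(as.integer(dp[, s]))
      tibble::tibble(variant_id = variants$variant_id, region_id = s,
                     alt_reads = alt, total_reads = tot)
    }) |>
      dplyr::filter(!is.na(.data$alt_reads) | !is.na(.data$total_reads))
    bad <- which(support$alt_reads > support$total_reads)
    if (length(bad)) {
      abort_invalid(sprintf(
        "AD exceeds DP for variant(s): %s",
        paste(unique(support$variant_id[bad]), collapse = ", ")))
    }
  }
  list(variants = variants, support = support)
}
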
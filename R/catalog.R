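#' Load a reference signature catalog
#'
#' Reads a tab-separated catalog with one row per signature: a `signature`
#' name column followed by 96 probability columns in the canonical channel
#' order (see [sbs_channels()]). Rows whose sum is within `1e-6` of 1 are
#' renormalised to sum exactly 1; anything further off is an error, as are
#' duplicated signature names.
#'
#' @param path Path to a catalog TSV. Defaults to the synthetic catalog
#'   bundled with the package, which contains six signatures: `tobacco`
#'   (C>A-dominated, as left by tobacco carcinogen adducts), `clock`
#'   (C>T at NpCpG, the 5-methyl-cytosine deamination clock), `apobec`
#'   (C>T/C>G at TpCpN), `hrd` (broad, homologous-recombination-deficiency
#'   like), `poleta` (polymerase-eta-like T>A/T>C), and a flat `background`.
#' @param tobacco Name of the signature treated as the tobacco-smoking
#'   signature by [smoking_metrics()].
#' @return A tibble of class `signature_catalog`: column `signature` plus 96
#'   channel columns; the tobacco label is carried in attribute `"tobacco"`.
#' @export
#' @examples
#' cat <- load_catalog()
#' cat$signature
load_catalog <- function(path = default_catalog_path(), tobacco = "tobacco") {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  chans <- sbs_channels()
  if (!identical(names(tab), c("signature", chans))) {
    abort_invalid(
      "Catalog must have a `signature` column followed by the 96 canonical channel columns.")
  }
  if (anyDuplicated(tab$signature)) {
    abort_invalid("Catalog contains duplicated signature names.")
  }
  mat <- as.matrix(tab[, chans])
  if (any(mat < 0)) abort_invalid("Catalog probabilities must be non-negative.")
  sums <- rowSums(mat)
  if (any(abs(sums - 1) > 1e-6)) {
    bad <- tab$signature[abs(sums - 1) > 1e-6]
    abort_invalid(sprintf(
      "Catalog rows must sum to 1 (tolerance 1e-6); offending: %s.",
      paste(bad, collapse = ", ")))
  }
  tab[, chans] <- mat / sums
  if (!tobacco %in% tab$signature) {
    abort_invalid(sprintf("Tobacco signature '%s' not found in catalog.", tobacco))
  }
  new_signature_catalog(tab, tobacco)
}

new_signature_catalog <- function(tab, tobacco) {
  structure(tibble::as_tibble(tab),
            tobacco = tobacco,
            class = c("signature_catalog", class(tibble::tibble())))
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat(sprintf("<signature_catalog: %d signatures x 96 channels; tobacco = '%s'>\n",
              nrow(x), attr(x, "tobacco")))
  NextMethod()
}

#' Path to the bundled synthetic signature catalog
#'
#' @return File path of the packaged catalog TSV.
#' @export
default_catalog_path <- function() {
  system.file("extdata", "signature_catalog_synthetic.tsv",
              package = "clonehet", mustWork = TRUE)
}

# S x 96 probability matrix with signature rownames.
catalog_matrix <- function(catalog) {
  stopifnot(inherits(catalog, "signature_catalog"))
  m <- as.matrix(catalog[, sbs_channels()])
  rownames(m) <- catalog$signature
  m
}

catalog_tobacco <- function(catalog) {
  attr(catalog, "tobacco") %||% "tobacco"
}

# Build a signature_catalog from a plain matrix (used in tests and examples).
as_signature_catalog <- function(mat, names = rownames(mat),
                                 tobacco = names[1]) {
  stopifnot(ncol(mat) == 96L)
  tab <- tibble::tibble(signature = names)
  m <- mat / rowSums(mat)
  colnames(m) <- sbs_channels()
  new_signature_catalog(dplyr::bind_cols(tab, tibble::as_tibble(m)), tobacco)
}

#' Read a gene list
#'
#' One gene symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  unique(lines[nzchar(lines)])
}

#' Paths to the bundled driver and DNA-repair gene lists
#'
#' Compact lists of recurrent lung/pan-cancer driver genes and of DNA-repair
#' genes implicated in the repair of tobacco-induced damage, for use as
#' defaults in the filtration cascades.
#'
#' @return File path of the packaged gene list.
#' @export
default_driver_genes_path <- function() {
  system.file("extdata", "driver_genes.tsv", package = "clonehet",
              mustWork = TRUE)
}

#' @rdname default_driver_genes_path
#' @export
default_repair_genes_path <- function() {
  system.file("extdata", "repair_genes.tsv", package = "clonehet",
              mustWork = TRUE)
}
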
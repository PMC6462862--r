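#' Fit signature exposures by non-negative least squares
#'
#' Decomposes a 96-channel mutation spectrum into non-negative contributions
#' of the catalog signatures: the normalised spectrum `y = counts / total` is
#' fitted as `y ~ t(M) e` with `e >= 0`, where `M` is the S x 96 catalog
#' matrix, by Lawson-Hanson active-set iteration (tolerance `1e-9`).
#' Exposures are rescaled to mutation counts; fractions are `e / sum(e)`.
#'
#' @param spectrum A [build_spectrum()] result, or a length-96 count vector
#'   in canonical channel order.
#' @param catalog A [load_catalog()] catalog.
#' @return An `exposure_fit`: list with `exposures` (mutation-count scale),
#'   `fractions`, `residual_norm` (on the normalised spectrum),
#'   `n_mutations`, and the catalog's signature names.
#' @export
#' @examples
#' cat <- load_catalog()
#' spec <- round(1000 * catalog_row(cat, "tobacco"))
#' fit_exposures(spec, cat)
fit_exposures <- function(spectrum, catalog) {
  counts <- as.numeric(spectrum)
  if (length(counts) != 96L || any(counts < 0)) {
    abort_invalid("`spectrum` must be 96 non-negative counts.")
  }
  total <- sum(counts)
  if (total == 0) {
    rlang::abort("Spectrum has no SNVs; exposure fit undefined.",
                 class = "clonehet_undefined_fit")
  }
  M <- catalog_matrix(catalog)
  y <- counts / total
  e <- nnls_solve(t(M), y, tol = 1e-9)
  resid <- sqrt(sum((y - drop(crossprod(M, e)))^2))
  fractions <- if (sum(e) > 0) e / sum(e) else e
  structure(
    list(signatures = rownames(M),
         exposures = stats::setNames(e * total, rownames(M)),
         fractions = stats::setNames(fractions, rownames(M)),
         residual_norm = resid,
         n_mutations = total,
         tobacco = catalog_tobacco(catalog)),
    class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<exposure_fit: %d mutations, residual %.2g>\n",
              x$n_mutations, x$residual_norm))
  print(round(x$fractions, digits))
  invisible(x)
}

#' Tidy an exposure fit
#'
#' @param x An `exposure_fit`.
#' @param ... Unused.
#' @return Tibble with one row per signature: `signature`, `exposure`
#'   (mutation-count scale), `fraction`.
#' @method tidy exposure_fit
#' @export
tidy.exposure_fit <- function(x, ...) {
  tibble::tibble(signature = x$signatures,
                 exposure = unname(x$exposures),
                 fraction = unname(x$fractions))
}

#' @export
#' @rdname tidy.exposure_fit
#' @return For `glance()`: a one-row tibble with `n_mutations`,
#'   `residual_norm`, and the dominant signature.
#' @method glance exposure_fit
glance.exposure_fit <- function(x, ...) {
  tibble::tibble(n_mutations = x$n_mutations,
                 residual_norm = x$residual_norm,
                 dominant = x$signatures[which.max(x$fractions)])
}

#' Extract one catalog row as a channel probability vector
#'
#' @param catalog A `signature_catalog`.
#' @param name Signature name.
#' @return Named numeric vector of length 96.
#' @export
catalog_row <- function(catalog, name) {
  m <- catalog_matrix(catalog)
  if (!name %in% rownames(m)) abort_invalid(sprintf("No signature '%s'.", name))
  m[name, ]
}

#' Per-branch signature decomposition
#'
#' Fits signature exposures separately to the SNVs on each branch of a clone
#' tree (the trunk holds the last common ancestor's mutations; leaves hold
#' region-private ones). Branches with fewer than `min_snv` SNVs are still
#' fitted but flagged low-confidence; branches with no SNVs get no fit.
#'
#' @param tree A [build_tree()] clone tree.
#' @param variants Variant tibble with `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt` covering the tree's variants.
#' @param reference Named character reference vector.
#' @param catalog A `signature_catalog`.
#' @param min_snv Minimum SNVs for a confident fit.
#' @return Tibble with one row per tree branch: `branch`, `n_snv`,
#'   `low_confidence`, `dominant`, and a `fit` list-column of `exposure_fit`
#'   objects (`NULL` where undefined).
#' @export
branch_signatures <- function(tree, variants, reference, catalog,
                              min_snv = 50L) {
  nodes <- dplyr::filter(tree$nodes, .data$label != "germline")
  purrr::map_dfr(seq_len(nrow(nodes)), function(i) {
    ids <- nodes$variant_ids[[i]]
    vb <- dplyr::filter(variants, .data$variant_id %in% ids)
    snv <- dplyr::filter(vb, nchar(.data$ref) == 1L, nchar(.data$alt) == 1L)
    n_snv <- nrow(snv)
    fit <- if (n_snv > 0) {
      fit_exposures(build_spectrum(snv, reference), catalog)
    } else {
      NULL
    }
    tibble::tibble(
      branch = nodes$label[i],
      n_snv = n_snv,
      low_confidence = n_snv < min_snv,
      dominant = if (is.null(fit)) NA_character_ else
        fit$signatures[which.max(fit$fractions)],
      fit = list(fit))
  })
}

#' Smoking-signature metrics for a fitted exposure decomposition
#'
#' Computes the fraction of the somatic burden attributable to the tobacco
#' signature, the implied number of smoking-related variants, and the
#' smoking-related variants per pack-year of cigarette exposure.
#'
#' @param fit An `exposure_fit`.
#' @param pack_years Pack-year exposure; `NA` or 0 makes the per-pack-year
#'   rate undefined (`NA`), as for never-smokers, while the fraction is
#'   still reported.
#' @return One-row tibble: `smoking_fraction`, `smoking_variant_count`,
#'   `smoking_variants_per_py`.
#' @export
smoking_metrics <- function(fit, pack_years = NA_real_) {
  stopifnot(inherits(fit, "exposure_fit"))
  if (!is.na(pack_years) && pack_years < 0) {
    abort_invalid("`pack_years` must be non-negative.")
  }
  frac <- unname(fit$fractions[fit$tobacco])
  count <- round(frac * fit$n_mutations)
  per_py <- if (is.na(pack_years) || pack_years == 0) NA_real_ else
    count / pack_years
  tibble::tibble(smoking_fraction = frac,
                 smoking_variant_count = count,
                 smoking_variants_per_py = per_py)
}
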
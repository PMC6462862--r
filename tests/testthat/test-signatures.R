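test_that("trinucleotide contexts map to pyrimidine-centred channels", {
  # ATCAGCTGAC...: pos 3 has triplet T C A
  ref <- toy_reference()
  expect_equal(sbs_channels()[trinucleotide_context(ref, "chr1", 3, "C", "T")],
               "T[C>T]A")
  # A G A at pos 8..10? find a G: pos 8 is G (ATCAGCTG). triplet T G A
  expect_equal(sbs_channels()[trinucleotide_context(ref, "chr1", 8, "G", "A")],
               "T[C>T]A")  # revcomp(TGA) = TCA
  # edge positions and indels are excluded
  expect_true(is.na(trinucleotide_context(ref, "chr1", 1, "A", "T")))
  expect_true(is.na(trinucleotide_context(ref, "chr1", 3, "C", "CT")))
  # mismatching ref allele is an error
  expect_error(trinucleotide_context(ref, "chr1", 3, "G", "A"),
               class = "clonehet_invalid_argument")
})

test_that("spectrum construction is strand-symmetric", {
  ref <- generate_reference(3000, 0.5, seed = 9)
  cat <- load_catalog()
  v <- draw_mutations(300, c(1, 0, 0, 0, 0, 0), cat, ref, seed = 2)
  # place every variant on the opposite strand: reverse-complement the
  # reference, mirror positions, complement alleles -> identical channels
  L <- nchar(ref)
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  ref_rc <- stats::setNames(rc(unname(ref)), names(ref))
  idx1 <- trinucleotide_context(ref, names(ref), v$pos, v$ref, v$alt)
  idx2 <- trinucleotide_context(ref_rc, names(ref), L - v$pos + 1L,
                                chartr("ACGT", "TGCA", v$ref),
                                chartr("ACGT", "TGCA", v$alt))
  expect_equal(idx2, idx1)
})

test_that("build_spectrum handles empty input, single SNV, and indels", {
  ref <- toy_reference()
  empty <- build_spectrum(tibble::tibble(chrom = character(), pos = integer(),
                                         ref = character(), alt = character()),
                          ref)
  expect_equal(sum(empty), 0)
  one <- build_spectrum(tibble::tibble(chrom = "chr1", pos = 3L,
                                       ref = "C", alt = "T"), ref)
  expect_equal(sum(one), 1)
  expect_equal(unname(one[match("T[C>T]A", sbs_channels())]), 1L)
  mix <- build_spectrum(tibble::tibble(chrom = "chr1", pos = c(3L, 4L),
                                       ref = c("C", "A"), alt = c("T", "AT")),
                        ref)
  expect_equal(sum(mix), 1)
  expect_equal(attr(mix, "n_excluded"), 1L)
})

test_that("disjoint-support catalog forces the exposure split", {
  cat2 <- disjoint_catalog()
  m <- clonehet:::catalog_matrix(cat2)
  spec <- 700 * m["sigA", ] + 300 * m["sigB", ]
  fit <- fit_exposures(spec, cat2)
  expect_equal(unname(fit$fractions), c(0.7, 0.3), tolerance = 1e-9)
})

test_that("an exact catalog row is recovered with zero residual", {
  cat <- load_catalog()
  spec <- 1000 * catalog_row(cat, "apobec")
  fit <- fit_exposures(spec, cat)
  expect_equal(unname(fit$fractions["apobec"]), 1, tolerance = 1e-9)
  expect_lt(fit$residual_norm, 1e-9)
})

test_that("noiseless mixtures of catalog rows are recovered to 1e-6", {
  cat <- load_catalog()
  m <- clonehet:::catalog_matrix(cat)[1:4, ]
  set.seed(7)
  for (i in 1:5) {
    w <- stats::runif(4)
    w <- w / sum(w)
    spec <- drop(w %*% m) * 5000
    fit <- fit_exposures(spec, cat)
    expect_equal(unname(fit$fractions[1:4]), w, tolerance = 1e-6)
    expect_lt(max(fit$fractions[5:6]), 1e-6)
  }
})

test_that("hand-rolled NNLS agrees with an independent solver", {
  skip_if_not_installed("pracma")
  cat <- load_catalog()
  A <- t(clonehet:::catalog_matrix(cat))
  set.seed(11)
  for (i in 1:5) {
    b <- stats::runif(96)
    ours <- clonehet:::nnls_solve(A, b)
    ref <- pracma::lsqnonneg(A, b)$x
    expect_equal(ours, ref, tolerance = 1e-6)
  }
})

test_that("residual norm is non-increasing as the catalog grows", {
  cat <- load_catalog()
  m <- clonehet:::catalog_matrix(cat)
  set.seed(5)
  spec <- stats::rmultinom(1, 3000, rep(1 / 96, 96))[, 1]
  resid <- vapply(2:6, function(k) {
    fit_exposures(spec, clonehet:::as_signature_catalog(
      m[1:k, , drop = FALSE], tobacco = "tobacco"))$residual_norm
  }, numeric(1))
  expect_true(all(diff(resid) <= 1e-12))
})

test_that("drawn mutations follow the requested channel mixture", {
  cat <- load_catalog()
  ref <- generate_reference(1e5, 0.41, seed = 3)
  expos <- c(0.6, 0.3, 0.1, 0, 0, 0)
  v <- draw_mutations(10000, expos, cat, ref, seed = 13)
  expect_equal(nrow(v), 10000)
  probs <- drop(expos %*% clonehet:::catalog_matrix(cat))
  counts <- tabulate(v$channel, 96)
  # aggregate channels with small expectation for a valid chi-square test
  expected <- probs * 10000
  small <- expected < 5
  obs <- c(counts[!small], sum(counts[small]))
  p <- c(probs[!small], sum(probs[small]))
  gof <- suppressWarnings(stats::chisq.test(obs, p = p / sum(p)))
  expect_gt(gof$p.value, 0.01)
  # every variant's reference trinucleotide is compatible with its channel
  idx <- trinucleotide_context(ref, names(ref), v$pos, v$ref, v$alt)
  expect_equal(idx, v$channel)
})

test_that("a C>A-only signature yields only C>A (or G>T) variants", {
  cat2 <- c_to_a_only_catalog()
  ref <- generate_reference(20000, 0.5, seed = 21)
  v <- draw_mutations(500, c(1, 0), cat2, ref, seed = 22)
  sub <- paste0(v$ref, ">", v$alt)
  expect_true(all(sub %in% c("C>A", "G>T")))
})

test_that("draw_mutations handles degenerate arguments", {
  cat <- load_catalog()
  ref <- generate_reference(1000, 0.5, seed = 1)
  expect_equal(nrow(draw_mutations(0, rep(1 / 6, 6), cat, ref)), 0)
  expect_error(draw_mutations(5, c(1), cat, ref),
               class = "clonehet_invalid_argument")
  expect_error(
    draw_mutations(5, 1, clonehet:::as_signature_catalog(
      matrix(numeric(0), 0, 96), character(0), tobacco = character(0)), ref),
    class = "clonehet_invalid_argument")
})

test_that("smoking metrics arithmetic and undefined cases", {
  cat2 <- disjoint_catalog()
  m <- clonehet:::catalog_matrix(cat2)
  spec <- round(20000 * m["sigA", ] + 20000 * m["sigB", ])
  fit <- fit_exposures(spec, cat2)   # tobacco = sigA, fraction 0.5
  res <- smoking_metrics(fit, pack_years = 20)
  expect_equal(res$smoking_fraction, 0.5, tolerance = 1e-9)
  expect_equal(res$smoking_variant_count, 20000)
  expect_equal(res$smoking_variants_per_py, 1000)
  # never-smoker: fraction reported, rate undefined
  res0 <- smoking_metrics(fit, pack_years = 0)
  expect_equal(res0$smoking_fraction, 0.5, tolerance = 1e-9)
  expect_true(is.na(res0$smoking_variants_per_py))
  # zero tobacco fraction
  specB <- round(1000 * m["sigB", ])
  fitB <- fit_exposures(specB, cat2)
  resB <- smoking_metrics(fitB, pack_years = 10)
  expect_equal(resB$smoking_variant_count, 0)
  expect_equal(resB$smoking_variants_per_py, 0)
  expect_error(smoking_metrics(fit, -1), class = "clonehet_invalid_argument")
})

test_that("per-branch fits flag small and empty branches", {
  cat <- load_catalog()
  ref <- generate_reference(50000, 0.41, seed = 31)
  trunk <- draw_mutations(600, c(0.7, 0.1, 0.1, 0.05, 0.025, 0.025), cat,
                          ref, seed = 32)
  priv <- draw_mutations(30, c(0.05, 0.05, 0.7, 0.1, 0.05, 0.05), cat, ref,
                         seed = 33, exclude = trunk$pos)
  vars <- dplyr::bind_rows(
    dplyr::mutate(trunk, variant_id = sprintf("t%04d", dplyr::row_number())),
    dplyr::mutate(priv, variant_id = sprintf("p%04d", dplyr::row_number())))
  regions <- c("R1", "R2")
  part <- tibble::tibble(
    variant_id = vars$variant_id,
    class = rep(c("truncal", "private"), c(600, 30)),
    pattern = rep(c("R1+R2", "R1"), c(600, 30)))
  tree <- build_tree(part, region_ids = regions)
  bs <- branch_signatures(tree, vars, ref, cat)
  expect_setequal(bs$branch, c("truncal", "R1", "R2"))
  expect_false(bs$low_confidence[bs$branch == "truncal"])
  expect_true(bs$low_confidence[bs$branch == "R1"])
  # empty leaf: no fit, flagged
  r2 <- bs[bs$branch == "R2", ]
  expect_equal(r2$n_snv, 0L)
  expect_true(is.na(r2$dominant))
  expect_null(r2$fit[[1]])
  # trunk-only tree equals a whole-sample fit
  only_trunk <- build_tree(part[part$class == "truncal", ],
                           region_ids = regions)
  bt <- branch_signatures(only_trunk, vars, ref, cat)
  whole <- fit_exposures(build_spectrum(trunk, ref), cat)
  expect_equal(bt$fit[[which(bt$branch == "truncal")]]$fractions,
               whole$fractions, tolerance = 1e-12)
})

test_that("zero spectrum gives an undefined-fit signal", {
  cat <- load_catalog()
  expect_error(fit_exposures(rep(0, 96), cat),
               class = "clonehet_undefined_fit")
})
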
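make_variants <- function() {
  tibble::tibble(
    variant_id = c("v1", "v2", "v3"),
    chrom = c("chr1", "chr1", "chr1"),
    pos = c(300L, 100L, 200L),           # deliberately unsorted
    ref = c("C", "A", "G"),
    alt = c("T", "AT", "A"),
    gene = c("TP53", NA, "ERCC5"),
    impact = c("HIGH", "MODERATE", "MODERATE"),
    cadd = c(25.1, NA, 3.2),
    qss = c(40, 18, NA),
    pop_af = c(0.001, NA, 0.019),
    clinvar = c("pathogenic", "none", "none"),
    pfam_domain = c(FALSE, FALSE, TRUE),
    provean = c(NA, NA, "damaging"),
    sift = c(NA, NA, "benign"),
    polyphen = c("damaging", NA, NA))
}

make_support <- function() {
  tidyr::crossing(variant_id = c("v1", "v2", "v3"),
                  region_id = c("R1", "R2")) |>
    dplyr::mutate(alt_reads = c(10L, 0L, 20L, 5L, 40L, 60L),
                  total_reads = c(100L, 90L, 110L, 100L, 120L, 150L))
}

test_that("VCF write/read round-trips every annotation field", {
  v <- make_variants()
  s <- make_support()
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, f, support = s)
  back <- read_vcf(f)
  v_sorted <- dplyr::arrange(v, chrom, pos) |>
    dplyr::mutate(vtype = ifelse(nchar(ref) == 1 & nchar(alt) == 1,
                                 "SNV", "indel"))
  expect_equal(as.data.frame(back$variants[, names(v_sorted)]),
               as.data.frame(v_sorted))
  # output is position-sorted
  expect_equal(back$variants$pos, sort(v$pos))
  got_support <- dplyr::arrange(back$support, variant_id, region_id)
  want_support <- dplyr::arrange(s, variant_id, region_id)
  expect_equal(as.data.frame(got_support), as.data.frame(want_support))
})

test_that("missing INFO keys become missing values without error", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\tx1\tC\tT\t.\tPASS\tGENE=TP53"), f)
  got <- read_vcf(f)$variants
  expect_true(is.na(got$cadd))
  expect_true(is.na(got$qss))
  expect_equal(got$clinvar, "none")
  expect_false(got$pfam_domain)
})

test_that("AD exceeding DP is a validation error naming the record", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="x">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="x">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tR1",
    "chr1\t100\tbad1\tC\tT\t.\tPASS\t.\tAD:DP\t10,95:50"), f)
  expect_error(read_vcf(f), regexp = "bad1",
               class = "clonehet_invalid_argument")
})

test_that("empty variant sets yield a header-only VCF that reads back", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(make_variants()[0, ], f)
  lines <- readLines(f)
  expect_true(all(startsWith(lines, "#")))
  back <- suppressWarnings(read_vcf(f))
  expect_equal(nrow(back$variants), 0)
})

test_that("multi-allelic records are rejected on both paths", {
  v <- make_variants()
  v$alt[1] <- "T,G"
  f <- withr::local_tempfile(fileext = ".vcf")
  expect_error(write_vcf(v, f), class = "clonehet_invalid_argument")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\tx1\tC\tT,G\t.\tPASS\t."), f)
  expect_error(read_vcf(f), class = "clonehet_invalid_argument")
})

test_that("the bundled catalog loads with rows summing to one", {
  cat <- load_catalog()
  m <- clonehet:::catalog_matrix(cat)
  expect_equal(nrow(m), 6)
  expect_equal(unname(rowSums(m)), rep(1, 6), tolerance = 1e-12)
  expect_true("tobacco" %in% cat$signature)
})

test_that("catalog validation rejects bad rows and duplicate names", {
  cat <- readr::read_tsv(default_catalog_path(), show_col_types = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  bad <- cat
  bad[1, -1] <- as.list(unlist(bad[1, -1]) / 2)   # row sums to 0.5
  readr::write_tsv(bad, f)
  expect_error(load_catalog(f), class = "clonehet_invalid_argument")
  dup <- cat
  dup$signature[2] <- dup$signature[1]
  readr::write_tsv(dup, f)
  expect_error(load_catalog(f), class = "clonehet_invalid_argument")
})

test_that("gene lists ignore comments and blank lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# header", "TP53", "", "KRAS  # trailing", "TP53"), f)
  expect_equal(read_gene_list(f), c("TP53", "KRAS"))
  drivers <- read_gene_list(default_driver_genes_path())
  repair <- read_gene_list(default_repair_genes_path())
  expect_true("TP53" %in% drivers)
  expect_true("ERCC5" %in% repair)
})

test_that("reference generation honours length, GC bounds, and seed", {
  ref <- generate_reference(100000, 0.41, seed = 7)
  expect_equal(unname(nchar(ref)), 100000)
  expect_equal(generate_reference(100000, 0.41, seed = 7), ref)
  gc_only <- generate_reference(500, 1, seed = 1)
  expect_true(all(strsplit(unname(gc_only), "")[[1]] %in% c("G", "C")))
  expect_error(generate_reference(2, 0.5), class = "clonehet_invalid_argument")
})

test_that("FASTA round-trips with a valid index sidecar", {
  ref <- generate_reference(1234, 0.5, seed = 3, name = "refX")
  f <- withr::local_tempfile(fileext = ".fa")
  write_reference(ref, f)
  expect_equal(read_reference(f), ref)
  fai <- readr::read_tsv(paste0(f, ".fai"), col_names = FALSE,
                         show_col_types = FALSE)
  expect_equal(fai$X1, "refX")
  expect_equal(fai$X2, 1234)
})
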
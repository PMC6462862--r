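# Fixtures built in code at test time.

# Two synthetic signatures with disjoint channel support: sig A lives on the
# first 8 C>A channels, sig B on the first 8 T>C channels.
disjoint_catalog <- function() {
  m <- matrix(0, nrow = 2, ncol = 96,
              dimnames = list(c("sigA", "sigB"), clonehet::sbs_channels()))
  m["sigA", 1:8] <- 1 / 8
  m["sigB", 65:72] <- 1 / 8
  clonehet:::as_signature_catalog(m, tobacco = "sigA")
}

# A signature whose mass lies only in C>A channels (channels 1-16).
c_to_a_only_catalog <- function() {
  m <- matrix(0, nrow = 2, ncol = 96,
              dimnames = list(c("ca_only", "flat"), clonehet::sbs_channels()))
  m["ca_only", 1:16] <- 1 / 16
  m["flat", ] <- 1 / 96
  clonehet:::as_signature_catalog(m, tobacco = "ca_only")
}

# Hand-evaluated decision tables for the three filtration cascades,
# including the boundary cases (QSS = 15, pop_af = 0.01 / 0.02, CADD = 2).
# `expect_pass` is the hand evaluation of the stated rules.
driver_filter_truth <- function() {
  tibble::tribble(
    ~gene,   ~qss, ~pop_af, ~cadd, ~impact,    ~expect_pass,
    "TP53",    20,   0.001,    15, "HIGH",     TRUE,   # all rules met
    "TP53",    15,   0.001,    15, "HIGH",     FALSE,  # QSS not strictly > 15
    "TP53",  15.1,   0.001,    15, "HIGH",     TRUE,   # just above
    "TP53",    20,    0.02,    15, "HIGH",     FALSE,  # pop AF over 1%
    "TP53",    20,    0.01,    15, "HIGH",     FALSE,  # pop AF exactly 1% (not < 0.01)
    "TP53",    20,   0.009,    15, "HIGH",     TRUE,
    "TP53",    20,      NA,    15, "HIGH",     TRUE,   # missing AF passes
    "TP53",    20,   0.001,     2, "HIGH",     FALSE,  # CADD not strictly > 2
    "TP53",    20,   0.001,   2.1, "HIGH",     TRUE,
    "TP53",    20,   0.001,    NA, "HIGH",     TRUE,   # missing CADD passes
    "TP53",    20,   0.001,    15, "MODERATE", TRUE,
    "TP53",    20,   0.001,    15, "LOW",      FALSE,  # impact too weak
    "TP53",    20,   0.001,    15, "MODIFIER", FALSE,
    "ZZZ9",    20,   0.001,    15, "HIGH",     FALSE,  # not a driver gene
    NA,        20,   0.001,    15, "HIGH",     FALSE,  # no gene annotation
    "KRAS",    NA,   0.001,    15, "HIGH",     FALSE)  # missing quality fails
}

lof_loh_filter_truth <- function() {
  tibble::tribble(
    ~gene,   ~qss, ~pop_af, ~cadd, ~impact,    ~loh,  ~expect_pass,
    "ATP7B",   30,   0.001,    20, "HIGH",     TRUE,  TRUE,   # all-genes branch
    "ZZZ9",    30,      NA,    NA, "HIGH",     TRUE,  TRUE,   # no gene list needed
    "ATP7B",   30,   0.001,    20, "HIGH",     FALSE, FALSE,  # LOH required
    "ATP7B",   30,   0.001,    20, "MODERATE", TRUE,  FALSE,  # LOF (HIGH) required
    "ATP7B",   15,   0.001,    20, "HIGH",     TRUE,  FALSE,  # quality boundary
    "ATP7B",   30,    0.01,    20, "HIGH",     TRUE,  FALSE,  # AF boundary
    "ATP7B",   30,   0.001,     2, "HIGH",     TRUE,  FALSE,  # CADD boundary
    "ATP7B",   30,   0.001,    20, "HIGH",     NA,    FALSE)  # missing LOH = none
}

germline_filter_truth <- function() {
  tibble::tribble(
    ~gene,   ~pop_af, ~impact,    ~clinvar,            ~pfam_domain, ~provean,   ~sift,      ~polyphen,  ~expect_pass,
    "ERCC5",   0.001, "MODERATE", "likely_pathogenic", FALSE,        "benign",   "benign",   "benign",   TRUE,   # first disjunct
    "ERCC5",   0.001, "MODERATE", "pathogenic",        FALSE,        "benign",   "benign",   "benign",   TRUE,
    "ERCC5",   0.001, "MODERATE", "other",             FALSE,        "benign",   "benign",   "benign",   FALSE,  # ClinVar other is not pathogenic
    "ERCC5",   0.001, "MODERATE", "none",              TRUE,         "benign",   "damaging", "benign",   TRUE,   # Pfam + one damaging
    "ERCC5",   0.001, "MODERATE", "none",              FALSE,        "benign",   "damaging", "benign",   FALSE,  # one damaging, no domain
    "ERCC5",   0.001, "MODERATE", "none",              FALSE,        "damaging", "benign",   "damaging", TRUE,   # two damaging
    "ERCC5",   0.001, "MODERATE", "none",              FALSE,        "damaging", "damaging", "damaging", TRUE,
    "ERCC5",   0.001, "MODERATE", "none",              TRUE,         NA,         NA,         NA,         FALSE,  # missing = not damaging
    "ERCC5",   0.001, "HIGH",     "none",              FALSE,        "benign",   "benign",   "benign",   TRUE,   # LOF passes outright
    "ERCC5",   0.001, "LOW",      "pathogenic",        FALSE,        "benign",   "benign",   "benign",   FALSE,  # not missense or LOF
    "ERCC5",    0.02, "MODERATE", "pathogenic",        FALSE,        "benign",   "benign",   "benign",   FALSE,  # AF exactly 2% (not < 0.02)
    "ERCC5",   0.019, "MODERATE", "pathogenic",        FALSE,        "benign",   "benign",   "benign",   TRUE,
    "ERCC5",      NA, "MODERATE", "pathogenic",        FALSE,        "benign",   "benign",   "benign",   TRUE,   # missing AF passes
    "ZZZ9",    0.001, "MODERATE", "pathogenic",        FALSE,        "benign",   "benign",   "benign",   FALSE)  # not a repair gene
}

# Independent re-statement of the presence-pattern classification rule for
# the exhaustive 3-region oracle: no absent call -> truncal; present in
# exactly one region -> private; otherwise shared; present nowhere -> drop.
oracle_classify_pattern <- function(calls) {
  if (!any(calls == "present")) return(NA_character_)
  if (!any(calls == "absent")) return("truncal")
  if (sum(calls == "present") == 1) return("private")
  "shared"
}

# Read counts that produce a wanted presence call under the defaults.
counts_for_call <- function(call) {
  switch(call,
         present = c(50L, 100L),
         absent = c(0L, 100L),
         unknown = c(0L, 5L))
}

support_from_patterns <- function(patterns, regions) {
  purrr::imap_dfr(patterns, function(p, i) {
    purrr::map_dfr(seq_along(regions), function(r) {
      cts <- counts_for_call(p[r])
      tibble::tibble(variant_id = sprintf("v%03d", i),
                     region_id = regions[r],
                     alt_reads = cts[1], total_reads = cts[2])
    })
  })
}

# Small deterministic variant table on a toy reference for spectrum tests.
toy_reference <- function() c(chr1 = "ATCAGCTGACTGATCGTACG")
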
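test_that("read-count simulation matches its binomial model", {
  # present het-diploid site at full purity: mean VAF 0.5
  rc <- assign_read_counts(present = rep(TRUE, 10000), depth_mean = 150,
                           cellularity = 1, tumor_alt_copies = 1,
                           tumor_total_copies = 2, error_rate = 0,
                           germline_alt_copies = 1, seed = 5)
  expect_equal(mean(rc$vaf, na.rm = TRUE), 0.5, tolerance = 0.01)
  # absent site with zero error never shows alt reads
  rc0 <- assign_read_counts(present = rep(FALSE, 500), depth_mean = 100,
                            cellularity = 0.5, error_rate = 0, seed = 6)
  expect_true(all(rc0$alt_reads == 0))
  # zero mean depth: zero totals, VAF flagged missing
  rcz <- assign_read_counts(present = TRUE, depth_mean = 0,
                            cellularity = 0.5, seed = 7)
  expect_equal(rcz$total_reads, 0L)
  expect_true(is.na(rcz$vaf))
  expect_error(assign_read_counts(TRUE, -5, 0.5),
               class = "clonehet_invalid_argument")
})

test_that("somatic truncal/private partition is exact by construction", {
  cfg <- sim_config(n_patients = 2, n_somatic = 403, truncal_fraction = 0.8,
                    n_germline_het = 10, seed = 42)
  sim <- simulate_cohort(cfg)
  per_patient <- sim$truth$variants |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(n = dplyr::n(),
                     n_truncal = sum(branch == "truncal"))
  # conservation and rounding rule: truncal = round(f * n)
  expect_equal(per_patient$n,
               sim$patients$n_somatic[match(per_patient$patient_id,
                                            sim$patients$patient_id)])
  expect_equal(per_patient$n_truncal, round(0.8 * per_patient$n))
  # every variant has exactly one branch assignment
  expect_equal(anyDuplicated(sim$truth$variants$variant_id), 0)
  # truncal variants are flagged present in all regions, private in one
  flags <- sim$truth$variants |>
    dplyr::inner_join(sim$support, by = c("patient_id", "variant_id")) |>
    dplyr::group_by(patient_id, variant_id, branch) |>
    dplyr::summarise(n_regions = dplyr::n(), .groups = "drop")
  expect_true(all(flags$n_regions == cfg$regions_per_patient))
})

test_that("boundary configurations behave as defined", {
  # truncal_fraction = 1: everything truncal
  cfg1 <- sim_config(n_patients = 1, n_somatic = 100, truncal_fraction = 1,
                     n_germline_het = 5, seed = 8)
  sim1 <- simulate_cohort(cfg1)
  expect_true(all(sim1$truth$variants$branch == "truncal"))
  # single region: no private/shared distinction, all truncal
  cfg2 <- sim_config(n_patients = 1, regions_per_patient = 1,
                     n_somatic = 100, truncal_fraction = 0.5,
                     n_germline_het = 5, seed = 9)
  sim2 <- simulate_cohort(cfg2)
  expect_true(all(sim2$truth$variants$branch == "truncal"))
})

test_that("identical config and seed reproduce byte-identical VCFs", {
  cfg <- sim_config(n_patients = 2, n_somatic = 150, n_germline_het = 10,
                    seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_simulate(cfg, d1)
  run_simulate(cfg, d2)
  vcfs <- list.files(d1, pattern = "\\.vcf$", recursive = TRUE)
  expect_gt(length(vcfs), 0)
  for (f in vcfs) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("germline effect generator hits its configured means", {
  pts <- simulate_germline_effect(n_mutant = 2000, n_wt = 2000, seed = 31)
  expect_equal(mean(pts$smoking_fraction[pts$germline_mutant]), 0.5,
               tolerance = 0.01)
  expect_equal(mean(pts$smoking_fraction[!pts$germline_mutant]), 0.2,
               tolerance = 0.01)
  expect_true(all(pts$smoking_fraction >= 0 & pts$smoking_fraction <= 1))
})

test_that("simulated germline repair variants pass the cascade by design", {
  cfg <- sim_config(n_patients = 8, n_somatic = 50, n_germline_het = 5,
                    seed = 55)
  sim <- simulate_cohort(cfg)
  repair <- read_gene_list(default_repair_genes_path())
  decisions <- filter_germline_repair(sim$germline, repair)
  by_patient <- decisions |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(mutant = any(passed))
  truth <- sim$patients$germline_mutant[
    match(by_patient$patient_id, sim$patients$patient_id)]
  expect_equal(by_patient$mutant, truth)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(truncal_fraction = 1.5),
               class = "clonehet_invalid_argument")
  expect_error(sim_config(regions_per_patient = 0),
               class = "clonehet_invalid_argument")
  expect_error(sim_config(cellularity = c(0.9, 0.4)),
               class = "clonehet_invalid_argument")
  # branch exposure labels must match the region set
  expect_error(
    sim_config(regions_per_patient = 2,
               branch_exposures = list(truncal = c(1, 0, 0, 0, 0, 0),
                                       R9 = c(1, 0, 0, 0, 0, 0))),
    class = "clonehet_invalid_argument")
  expect_error(
    sim_config(regions_per_patient = 1,
               branch_exposures = list(truncal = c(0.5, 0.2, 0, 0, 0, 0),
                                       R1 = c(1, 0, 0, 0, 0, 0))),
    class = "clonehet_invalid_argument")
})
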
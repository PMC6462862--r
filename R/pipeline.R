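#' Read and write simulator configuration files
#'
#' The simulator configuration travels as a single YAML file of key/value
#' pairs matching the arguments of [sim_config()].
#'
#' @param path YAML path.
#' @param config A `sim_config`.
#' @return `read_sim_config()` a validated `sim_config`;
#'   `write_sim_config()` `path`, invisibly.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("No such config: %s", path))
  raw <- yaml::read_yaml(path)
  raw <- raw[setdiff(names(raw), "regions")]
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort_invalid(sprintf("Unknown config keys: %s",
                          paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$smoking_probs)) raw$smoking_probs <- unlist(raw$smoking_probs)
  if (!is.null(raw$cellularity)) raw$cellularity <- unlist(raw$cellularity)
  if (!is.null(raw$pack_years_range)) {
    raw$pack_years_range <- unlist(raw$pack_years_range)
  }
  if (!is.null(raw$branch_exposures)) {
    raw$branch_exposures <- lapply(raw$branch_exposures, unlist)
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  out$regions <- NULL
  out$smoking_probs <- as.list(out$smoking_probs)  # keep names in YAML
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Simulate a cohort and write it to disk
#'
#' Runs [simulate_cohort()] and serialises the result: the reference FASTA
#' (with `.fai` sidecar), cohort metadata tables, per-patient germline and
#' per-region tumor VCFs (each region VCF carries the union of the
#' patient's candidate sites so presence can be assessed everywhere),
#' het-site read-count tables for LOH detection, CNV segment tables, the
#' ground-truth tables, the configuration snapshot, and a run manifest
#' with per-stage record counts.
#'
#' @param config A [sim_config()], or a path to a YAML config.
#' @param out_dir Output directory (created).
#' @param catalog Signature catalog for mutation drawing.
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_simulate <- function(config, out_dir, catalog = load_catalog()) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(config, catalog)
  write_reference(sim$reference, file.path(out_dir, "reference.fa"))
  readr::write_tsv(sim$patients, file.path(out_dir, "patients.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$regions, file.path(out_dir, "regions.tsv"),
                   progress = FALSE)
  for (pid in sim$patients$patient_id) {
    pdir <- file.path(out_dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    pv <- dplyr::filter(sim$variants, .data$patient_id == pid)
    ps <- dplyr::filter(sim$support, .data$patient_id == pid)
    for (r in config$regions) {
      write_vcf(pv, file.path(pdir, paste0("somatic_", r, ".vcf")),
                support = dplyr::filter(ps, .data$region_id == r))
    }
    write_vcf(dplyr::filter(sim$germline, .data$patient_id == pid),
              file.path(pdir, "germline.vcf"))
    readr::write_tsv(dplyr::filter(sim$het_sites, .data$patient_id == pid),
                     file.path(pdir, "het_sites.tsv"), progress = FALSE)
    write_segments(dplyr::filter(sim$segments, .data$patient_id == pid),
                   file.path(pdir, "segments.tsv"))
  }
  tdir <- file.path(out_dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  readr::write_tsv(sim$truth$variants,
                   file.path(tdir, "truth_variants.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$branch_exposures,
                   file.path(tdir, "truth_branch_exposures.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$loh_sites,
                   file.path(tdir, "truth_loh_sites.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$patients,
                   file.path(tdir, "truth_patients.tsv"), progress = FALSE)
  write_sim_config(config, file.path(out_dir, "config.yaml"))
  manifest <- list(
    stage = "simulate",
    seed = config$seed,
    out_dir = out_dir,
    counts = list(patients = nrow(sim$patients),
                  regions = nrow(sim$regions),
                  somatic_variants = nrow(sim$variants),
                  support_records = nrow(sim$support),
                  germline_variants = nrow(sim$germline),
                  het_sites = nrow(dplyr::distinct(
                    sim$het_sites, .data$patient_id, .data$site_id)),
                  cnv_segments = nrow(sim$segments)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Analyze a (simulated or conforming) multi-region cohort directory
#'
#' Runs the full analysis over a cohort directory laid out as by
#' [run_simulate()]: per patient it reads the region VCFs, partitions
#' variants into truncal/shared/private, reconstructs the clone tree
#' (written as Newick and edge list), fits per-branch and whole-tumor
#' signature exposures, applies the somatic driver and germline DNA-repair
#' filtration cascades, detects LOH at germline-het sites, filters and
#' scores CNV heterogeneity; at cohort level it classifies hypermutation
#' and compares smoking metrics between germline-mutant and wild-type
#' patients.
#'
#' @param cohort_dir Directory from [run_simulate()] (or user data in the
#'   same layout).
#' @param out_dir Output directory for reports (created).
#' @param driver_genes,repair_genes Gene symbol vectors; default to the
#'   bundled lists.
#' @param catalog Signature catalog for exposure fitting.
#' @return The manifest, invisibly; reports are written under `out_dir`.
#' @export
run_analyze <- function(cohort_dir, out_dir,
                        driver_genes = read_gene_list(default_driver_genes_path()),
                        repair_genes = read_gene_list(default_repair_genes_path()),
                        catalog = load_catalog()) {
  if (!dir.exists(cohort_dir)) {
    abort_invalid(sprintf("No such cohort directory: %s", cohort_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  patients <- readr::read_tsv(file.path(cohort_dir, "patients.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  regions <- readr::read_tsv(file.path(cohort_dir, "regions.tsv"),
                             show_col_types = FALSE, progress = FALSE)
  cfg_path <- file.path(cohort_dir, "config.yaml")
  callable_mb <- if (file.exists(cfg_path)) {
    read_sim_config(cfg_path)$callable_mb
  } else {
    100
  }
  reference <- read_reference(file.path(cohort_dir, "reference.fa"))
  per_patient <- list()
  for (pid in patients$patient_id) {
    pdir <- file.path(cohort_dir, pid)
    if (!dir.exists(pdir)) {
      rlang::warn(sprintf("Patient directory missing, skipped: %s", pid))
      next
    }
    odir <- file.path(out_dir, pid)
    dir.create(odir, showWarnings = FALSE)
    regs <- sort(regions$region_id[regions$patient_id == pid])
    vcfs <- lapply(regs, function(r) {
      read_vcf(file.path(pdir, paste0("somatic_", r, ".vcf")))
    })
    variants <- vcfs[[1]]$variants
    support <- dplyr::bind_rows(lapply(vcfs, function(x) x$support))
    part <- suppressMessages(partition_variants(support, region_ids = regs))
    readr::write_tsv(part, file.path(odir, "partition.tsv"),
                     progress = FALSE)
    tree <- build_tree(part, region_ids = regs)
    to_newick(tree, file.path(odir, "tree.nwk"))
    write_tree_edges(tree, file.path(odir, "tree_edges.tsv"))
    bsig <- branch_signatures(tree, variants, reference, catalog)
    branch_report <- bsig |>
      dplyr::select("branch", "n_snv", "low_confidence", "dominant") |>
      dplyr::bind_cols(purrr::map_dfr(bsig$fit, function(f) {
        if (is.null(f)) {
          tibble::as_tibble(stats::setNames(
            as.list(rep(NA_real_, nrow(catalog))), catalog$signature))
        } else {
          tibble::as_tibble(as.list(f$fractions))
        }
      }))
    readr::write_tsv(branch_report, file.path(odir, "branch_exposures.tsv"),
                     progress = FALSE)
    snvs <- dplyr::filter(variants, .data$vtype == "SNV")
    overall_fit <- fit_exposures(build_spectrum(snvs, reference), catalog)
    py <- patients$pack_years[patients$patient_id == pid]
    smoking <- smoking_metrics(overall_fit, py)
    drv <- filter_somatic_driver(variants, driver_genes)
    write_decisions(drv, file.path(odir, "driver_decisions.tsv"))
    germ <- read_vcf(file.path(pdir, "germline.vcf"))$variants
    grm <- filter_germline_repair(germ, repair_genes)
    write_decisions(grm, file.path(odir, "germline_decisions.tsv"))
    het <- readr::read_tsv(file.path(pdir, "het_sites.tsv"),
                           show_col_types = FALSE, progress = FALSE)
    loh_calls <- purrr::map_dfr(regs, function(r) {
      cellu <- regions$cellularity[regions$patient_id == pid &
                                     regions$region_id == r]
      detect_loh(dplyr::filter(het, .data$region_id == r), cellu)
    })
    loh_sites <- loh_calls |>
      dplyr::group_by(.data$site_id) |>
      dplyr::summarise(loh = any(.data$status == "LOH"), .groups = "drop")
    readr::write_tsv(loh_calls, file.path(odir, "loh_calls.tsv"),
                     progress = FALSE)
    seg <- read_segments(file.path(pdir, "segments.tsv"))
    cand <- cnv_candidate_filter(seg)
    readr::write_tsv(cand, file.path(odir, "cnv_candidates.tsv"),
                     progress = FALSE)
    het_mat <- cnv_heterogeneity(seg)
    utils::write.table(as.matrix(het_mat),
                       file.path(odir, "cnv_heterogeneity.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    trunk_n <- tree$nodes$n_variants[tree$nodes$label == "truncal"]
    per_patient[[pid]] <- tibble::tibble(
      patient_id = pid,
      smoking_status = patients$smoking_status[
        patients$patient_id == pid],
      pack_years = py,
      n_variants = nrow(variants),
      n_classified = nrow(part),
      truncal_fraction_est = trunk_n / nrow(part),
      burden_per_mb = mutation_burden(nrow(variants), callable_mb),
      hypermutated = classify_hypermutated(
        mutation_burden(nrow(variants), callable_mb)),
      smoking_fraction = smoking$smoking_fraction,
      smoking_variants_per_py = smoking$smoking_variants_per_py,
      germline_mutant = any(grm$passed),
      n_driver_hits = sum(drv$passed),
      n_loh_sites = sum(loh_sites$loh))
  }
  summary_tab <- dplyr::bind_rows(per_patient)
  readr::write_tsv(summary_tab, file.path(out_dir, "patient_summary.tsv"),
                   progress = FALSE)
  comparisons <- list()
  # smoking metrics are compared among ever-smokers, as in the source
  # study design; burden uses the whole cohort
  ever <- dplyr::filter(summary_tab, .data$smoking_status != "never")
  for (metric in c("smoking_fraction", "burden_per_mb",
                   "smoking_variants_per_py")) {
    kind <- if (metric == "smoking_variants_per_py") "student" else "welch"
    dat <- if (metric == "burden_per_mb") summary_tab else ever
    cmp <- tryCatch(
      compare_by_germline_status(dat, metric, kind),
      clonehet_insufficient_data = function(e) NULL)
    if (!is.null(cmp)) comparisons[[metric]] <- glance(cmp)
  }
  if (length(comparisons)) {
    readr::write_tsv(dplyr::bind_rows(comparisons),
                     file.path(out_dir, "germline_comparison.tsv"),
                     progress = FALSE)
  }
  manifest <- list(
    stage = "analyze",
    cohort_dir = cohort_dir,
    counts = list(patients = nrow(summary_tab),
                  somatic_variants = sum(summary_tab$n_variants),
                  classified_variants = sum(summary_tab$n_classified),
                  excluded_variants = sum(summary_tab$n_variants) -
                    sum(summary_tab$n_classified),
                  comparisons = length(comparisons)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Compare analysis output against simulation ground truth
#'
#' Builds a recovery report from an analysis directory and the matching
#' truth directory: per-patient truncal fraction (true vs estimated),
#' tobacco-signature fraction of the trunk (true vs fitted), germline
#' mutant status recovery, LOH sensitivity and specificity, and the
#' direction of the germline association.
#'
#' @param analysis_dir Output directory of [run_analyze()].
#' @param truth_dir The `truth/` directory written by [run_simulate()].
#' @return A list of tibbles: `patients`, `loh`, `association`; also
#'   written as TSVs under `analysis_dir`.
#' @export
run_recover <- function(analysis_dir, truth_dir) {
  read_truth <- function(name) {
    p <- file.path(truth_dir, name)
    if (!file.exists(p)) abort_invalid(sprintf("Missing truth file: %s", p))
    readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
  }
  truth_var <- read_truth("truth_variants.tsv")
  truth_pat <- read_truth("truth_patients.tsv")
  truth_loh <- read_truth("truth_loh_sites.tsv")
  est <- readr::read_tsv(file.path(analysis_dir, "patient_summary.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  true_frac <- truth_var |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(truncal_fraction_true = mean(.data$branch == "truncal"),
                     .groups = "drop")
  trunk_tobacco <- purrr::map_dfr(est$patient_id, function(pid) {
    be <- readr::read_tsv(
      file.path(analysis_dir, pid, "branch_exposures.tsv"),
      show_col_types = FALSE, progress = FALSE)
    tibble::tibble(patient_id = pid,
                   trunk_tobacco_est = be$tobacco[be$branch == "truncal"])
  })
  pat <- est |>
    dplyr::left_join(true_frac, by = "patient_id") |>
    dplyr::left_join(trunk_tobacco, by = "patient_id") |>
    dplyr::left_join(
      dplyr::select(truth_pat, "patient_id",
                    germline_mutant_true = "germline_mutant",
                    trunk_tobacco_true = "true_tobacco_fraction"),
      by = "patient_id") |>
    dplyr::transmute(
      .data$patient_id,
      .data$truncal_fraction_true, truncal_fraction_est = .data$truncal_fraction_est,
      truncal_fraction_error = .data$truncal_fraction_est -
        .data$truncal_fraction_true,
      .data$trunk_tobacco_true, .data$trunk_tobacco_est,
      germline_true = .data$germline_mutant_true,
      germline_est = .data$germline_mutant,
      germline_recovered = .data$germline_mutant ==
        .data$germline_mutant_true)
  loh_calls <- purrr::map_dfr(est$patient_id, function(pid) {
    readr::read_tsv(file.path(analysis_dir, pid, "loh_calls.tsv"),
                    show_col_types = FALSE, progress = FALSE) |>
      dplyr::group_by(.data$patient_id, .data$site_id) |>
      dplyr::summarise(called = any(.data$status == "LOH"),
                       .groups = "drop")
  })
  loh <- loh_calls |>
    dplyr::left_join(dplyr::select(truth_loh, "patient_id", "site_id",
                                   loh_true = "loh"),
                     by = c("patient_id", "site_id")) |>
    dplyr::summarise(
      sensitivity = sum(.data$called & .data$loh_true) /
        max(sum(.data$loh_true), 1L),
      specificity = sum(!.data$called & !.data$loh_true) /
        max(sum(!.data$loh_true), 1L))
  assoc_groups <- split(est$smoking_fraction, pat$germline_true)
  association <- tibble::tibble(
    mutant_mean = mean(assoc_groups[["TRUE"]] %||% NA_real_),
    wt_mean = mean(assoc_groups[["FALSE"]] %||% NA_real_),
    direction_positive = .data_safe_gt(mutant_mean, wt_mean))
  report <- list(patients = pat, loh = loh, association = association)
  readr::write_tsv(pat, file.path(analysis_dir, "recovery_patients.tsv"),
                   progress = FALSE)
  readr::write_tsv(loh, file.path(analysis_dir, "recovery_loh.tsv"),
                   progress = FALSE)
  readr::write_tsv(association,
                   file.path(analysis_dir, "recovery_association.tsv"),
                   progress = FALSE)
  report
}

.data_safe_gt <- function(a, b) {
  if (is.na(a) || is.na(b)) NA else a > b
}
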
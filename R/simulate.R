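#' Configuration for the synthetic multi-region cohort simulator
#'
#' Bundles and validates every knob of the cohort generator. Defaults mirror
#' the study design the package targets: around a dozen multi-region
#' patients sampled at three intrathoracic sites, tumor sequencing at a mean
#' depth of 150x, cytology-estimated cellularity well above the 15%
#' informativeness floor, a large truncal fraction, and a germline
#' DNA-repair effect that raises the tobacco-signature fraction of mutant
#' patients (mean 0.5 vs 0.2, sd 0.1).
#'
#' @param n_patients Number of patients.
#' @param regions_per_patient Tumor regions sampled per patient (>= 1);
#'   labels are `R1`, `R2`, ...
#' @param n_somatic Baseline somatic variants per patient before the
#'   smoking-status multiplier (current 1.5x, former 1x, never 0.3x).
#' @param truncal_fraction Fraction of somatic variants assigned to the
#'   trunk; the truncal count is `round(truncal_fraction * n)` and the
#'   remainder is spread uniformly over region-private branches.
#' @param branch_exposures Optional named list mapping `"truncal"` and each
#'   region label to a signature-fraction vector over the catalog signatures
#'   (each summing to 1). When `NULL`, exposures are generated per patient:
#'   the truncal tobacco fraction is drawn from the germline-status effect
#'   in `germline_config`, and each private branch is dominated by a
#'   non-tobacco process (APOBEC, clock, HR-deficiency, or pol-eta in turn).
#'   Supplying it fixes exposures for all patients and disables the
#'   germline effect on exposures.
#' @param cellularity Length-2 range; per-region tumor cellularity is drawn
#'   uniformly from it.
#' @param mean_depth Mean tumor sequencing depth (reads).
#' @param germline_depth Mean germline sequencing depth (reads).
#' @param sequencing_error Per-base error rate applied to variant-absent
#'   sites.
#' @param germline_config List: `p_mutant` (probability a patient carries a
#'   passing germline repair variant), `tobacco_mean_mutant`,
#'   `tobacco_mean_wt`, `tobacco_sd` (the gene-by-environment effect on the
#'   truncal tobacco fraction of ever-smokers).
#' @param pack_years_range Length-2 range of pack-years for ever-smokers;
#'   never-smokers get 0.
#' @param smoking_probs Probabilities of `current`/`former`/`never` status.
#' @param callable_mb Callable megabases used as the mutation-burden
#'   denominator.
#' @param ref_length_bp,gc_fraction Synthetic reference length and GC
#'   content.
#' @param indel_fraction Fraction of somatic variants emitted as 1-bp
#'   insertions (for counting only; no indel realism).
#' @param n_germline_het Germline heterozygous SNP sites per patient used
#'   for LOH detection.
#' @param p_loh Fraction of het sites falling in (truncal) LOH regions.
#' @param n_cnv_segments,cnv_genome_mb CNV segment count and virtual genome
#'   size (Mb) for the per-region copy-number tables.
#' @param seed Integer master seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 11,
                       regions_per_patient = 3,
                       n_somatic = 2000,
                       truncal_fraction = 0.8,
                       branch_exposures = NULL,
                       cellularity = c(0.4, 0.9),
                       mean_depth = 150,
                       germline_depth = 35,
                       sequencing_error = 0.001,
                       germline_config = list(p_mutant = 0.6,
                                              tobacco_mean_mutant = 0.5,
                                              tobacco_mean_wt = 0.2,
                                              tobacco_sd = 0.1),
                       pack_years_range = c(10, 60),
                       smoking_probs = c(current = 0.2, former = 0.65,
                                         never = 0.15),
                       callable_mb = 100,
                       ref_length_bp = 1e5,
                       gc_fraction = 0.41,
                       indel_fraction = 0.05,
                       n_germline_het = 120,
                       p_loh = 0.3,
                       n_cnv_segments = 20,
                       cnv_genome_mb = 100,
                       seed = 1L) {
  check_count(n_patients, "n_patients")
  check_count(regions_per_patient, "regions_per_patient", lower = 1)
  check_count(n_somatic, "n_somatic")
  check_proportion(truncal_fraction, "truncal_fraction")
  check_number(mean_depth, "mean_depth", lower = 1e-12)
  check_proportion(sequencing_error, "sequencing_error")
  check_proportion(indel_fraction, "indel_fraction")
  check_proportion(p_loh, "p_loh")
  check_count(ref_length_bp, "ref_length_bp", lower = 3)
  if (length(cellularity) != 2 || any(cellularity <= 0) ||
      any(cellularity > 1) || cellularity[1] > cellularity[2]) {
    abort_invalid("`cellularity` must be an increasing range within (0, 1].")
  }
  regions <- paste0("R", seq_len(regions_per_patient))
  if (!is.null(branch_exposures)) {
    expected <- c("truncal", regions)
    if (!setequal(names(branch_exposures), expected)) {
      abort_invalid(sprintf(
        "`branch_exposures` labels must be exactly {%s}.",
        paste(expected, collapse = ", ")))
    }
    for (nm in names(branch_exposures)) {
      v <- branch_exposures[[nm]]
      if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
        abort_invalid(sprintf(
          "`branch_exposures[['%s']]` must be non-negative and sum to 1.", nm))
      }
    }
  }
  structure(
    list(n_patients = as.integer(n_patients),
         regions_per_patient = as.integer(regions_per_patient),
         regions = regions,
         n_somatic = as.integer(n_somatic),
         truncal_fraction = truncal_fraction,
         branch_exposures = branch_exposures,
         cellularity = cellularity,
         mean_depth = mean_depth,
         germline_depth = germline_depth,
         sequencing_error = sequencing_error,
         germline_config = germline_config,
         pack_years_range = pack_years_range,
         smoking_probs = smoking_probs,
         callable_mb = callable_mb,
         ref_length_bp = as.integer(ref_length_bp),
         gc_fraction = gc_fraction,
         indel_fraction = indel_fraction,
         n_germline_het = as.integer(n_germline_het),
         p_loh = p_loh,
         n_cnv_segments = as.integer(n_cnv_segments),
         cnv_genome_mb = cnv_genome_mb,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Draw somatic SNVs from a signature mixture
#'
#' Samples `n` single-base substitutions whose 96-channel distribution is
#' the mixture `t(catalog) %*% exposures`, placing each variant at a
#' reference position whose trinucleotide context (on either strand) is
#' compatible with its channel. Positions are sampled uniformly without
#' replacement over the reference interior.
#'
#' @param n Number of SNVs.
#' @param exposures Signature-fraction vector over the catalog signatures
#'   (sums to 1).
#' @param catalog A `signature_catalog`.
#' @param reference Named character reference (single sequence).
#' @param seed Optional seed.
#' @param exclude Integer positions unavailable for placement.
#' @return Tibble: `chrom`, `pos`, `ref`, `alt`, `channel` (true channel
#'   index).
#' @export
draw_mutations <- function(n, exposures, catalog, reference, seed = NULL,
                           exclude = integer()) {
  check_count(n, "n")
  if (n == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          channel = integer()))
  }
  if (is.null(catalog) || nrow(catalog) == 0L) {
    abort_invalid("Cannot draw mutations from an empty catalog.")
  }
  M <- catalog_matrix(catalog)
  if (length(exposures) != nrow(M)) {
    abort_invalid("`exposures` length must equal the number of catalog signatures.")
  }
  if (any(exposures < 0) || abs(sum(exposures) - 1) > 1e-9) {
    abort_invalid("`exposures` must be non-negative and sum to 1.")
  }
  probs <- drop(exposures %*% M)
  seqname <- names(reference)[1]
  seq <- unname(reference[1])
  with_seed(seed, {
    draws <- as.vector(stats::rmultinom(1, n, probs))
    ctx <- interior_contexts(seq)           # per interior position: pyr context
    keep <- !(ctx$pos %in% exclude)
    ctx$pos <- ctx$pos[keep]
    ctx$lab <- ctx$lab[keep]
    chans <- sbs_channels()
    chan_ctx <- paste0(substr(chans, 1, 1), substr(chans, 3, 3),
                       substr(chans, 7, 7))
    out <- vector("list", 32L)
    k <- 0L
    for (cl in unique(chan_ctx)) {
      chan_ids <- which(chan_ctx == cl)
      need <- draws[chan_ids]
      tot <- sum(need)
      if (tot == 0L) next
      avail <- ctx$pos[ctx$lab == cl]
      if (length(avail) < tot) {
        abort_invalid(sprintf(
          "Reference has only %d positions with context %s but %d are needed; use a longer reference.",
          length(avail), cl, tot))
      }
      picked <- if (length(avail) == 1L) avail else sample(avail, tot)
      k <- k + 1L
      out[[k]] <- tibble::tibble(pos = picked,
                                 channel = rep(chan_ids, times = need))
    }
    res <- dplyr::bind_rows(out[seq_len(k)])
    base <- substring(seq, res$pos, res$pos)
    pyr_ref <- substr(chans[res$channel], 3, 3)
    pyr_alt <- substr(chans[res$channel], 5, 5)
    purine <- base %in% c("A", "G")
    tibble::tibble(
      chrom = seqname,
      pos = as.integer(res$pos),
      ref = ifelse(purine, complement_base(pyr_ref), pyr_ref),
      alt = ifelse(purine, complement_base(pyr_alt), pyr_alt),
      channel = res$channel) |>
      dplyr::arrange(.data$pos)
  })
}

# Pyrimidine-strand context label of every interior position of `seq`.
interior_contexts <- function(seq) {
  L <- nchar(seq)
  pos <- 2:(L - 1L)
  tri <- substring(seq, pos - 1L, pos + 1L)
  center <- substr(tri, 2, 2)
  pyr <- center %in% c("C", "T")
  lab <- ifelse(pyr, tri, revcomp_tri(tri))
  list(pos = pos, lab = lab)
}

# Fast reverse-complement for a vector of trinucleotides.
revcomp_tri <- function(tri) {
  comp <- chartr("ACGT", "TGCA", tri)
  paste0(substr(comp, 3, 3), substr(comp, 2, 2), substr(comp, 1, 1))
}

#' Simulate sequencing read counts at a variant site
#'
#' Total depth is Poisson around `depth_mean`; alt reads are binomial with
#' success probability [expected_vaf()] for sites carrying the variant, or
#' `error_rate` for sites that do not. Zero-depth draws yield `alt_reads =
#' 0` with the VAF left undefined (`NA`).
#'
#' @param present Logical vector: does the sample carry the variant?
#' @param depth_mean Mean depth (>= 0).
#' @param cellularity Tumor cell fraction in `[0, 1]` (0 for a normal
#'   sample).
#' @param tumor_alt_copies,tumor_total_copies Tumor genotype at the site.
#' @param error_rate Per-base error rate.
#' @param germline_alt_copies Alt copies in normal cells (0 somatic, 1 het
#'   germline).
#' @param seed Optional seed.
#' @return Tibble: `alt_reads`, `total_reads`, `vaf` (`NA` at zero depth).
#' @export
assign_read_counts <- function(present, depth_mean, cellularity,
                               tumor_alt_copies = 1L, tumor_total_copies = 2L,
                               error_rate = 0, germline_alt_copies = 0L,
                               seed = NULL) {
  if (any(depth_mean < 0)) abort_invalid("`depth_mean` must be non-negative.")
  n <- max(length(present), length(depth_mean), length(cellularity),
           length(tumor_alt_copies), length(tumor_total_copies),
           length(error_rate), length(germline_alt_copies))
  present <- rep_len(present, n)
  depth_mean <- rep_len(depth_mean, n)
  cellularity <- rep_len(cellularity, n)
  tumor_alt_copies <- rep_len(tumor_alt_copies, n)
  tumor_total_copies <- rep_len(tumor_total_copies, n)
  error_rate <- rep_len(error_rate, n)
  germline_alt_copies <- rep_len(germline_alt_copies, n)
  with_seed(seed, {
    total <- stats::rpois(n, depth_mean)
    vaf <- expected_vaf(cellularity, germline_alt_copies,
                        tumor_alt_copies, tumor_total_copies)
    p <- ifelse(present, pmin(pmax(vaf, 0), 1), error_rate)
    p[is.na(p)] <- 0
    alt <- stats::rbinom(n, total, p)
    tibble::tibble(alt_reads = alt, total_reads = total,
                   vaf = ifelse(total > 0, alt / total, NA_real_))
  })
}

#' Simulate a multi-region cohort with known ground truth
#'
#' Generates, per patient: a truncal/private partition of somatic variants
#' drawn from per-branch signature mixtures, cellularity- and depth-scaled
#' read counts in every region, germline DNA-repair variants for mutant
#' patients (constructed to pass [filter_germline_repair()]), germline
#' heterozygous sites with truncal LOH in a configurable fraction,
#' per-region CNV segment tables, and smoking metadata. Germline-mutant
#' ever-smokers receive a higher truncal tobacco-signature fraction — the
#' gene-by-environment effect downstream stages are asked to recover.
#'
#' @param config A [sim_config()].
#' @param catalog Signature catalog used for drawing mutations (defaults to
#'   the bundled one).
#' @return A list of tibbles: `patients`, `regions`, `variants` (somatic,
#'   annotated), `support` (per variant x region read counts), `germline`
#'   (germline variant records), `het_sites` (per het site x sample read
#'   counts; `region_id == "germline"` is the normal), `segments` (CNV), and
#'   `truth` (list: `variants` with branch assignment, `branch_exposures`,
#'   `loh_sites`, `patients`), plus the `reference` and the `config`.
#' @export
simulate_cohort <- function(config = sim_config(), catalog = load_catalog()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  signames <- catalog$signature
  reference <- generate_reference(cfg$ref_length_bp, cfg$gc_fraction,
                                  seed = cfg$seed, name = "ref1")
  with_seed(cfg$seed + 1L, {
    pts <- simulate_patients(cfg)
    if (cfg$n_patients == 0L) {
      return(empty_cohort(cfg, reference, pts))
    }
    acc <- list(variants = list(), support = list(), germline = list(),
                het = list(), seg = list(), truth_var = list(),
                truth_exp = list(), truth_loh = list())
    for (i in seq_len(cfg$n_patients)) {
      p <- simulate_patient(cfg, catalog, reference, pts[i, ], signames)
      for (nm in names(acc)) acc[[nm]][[i]] <- p[[nm]]
      pts$true_tobacco_fraction[i] <- p$true_tobacco_fraction
    }
    regions <- tidyr::crossing(patient_id = pts$patient_id,
                               region_id = cfg$regions) |>
      dplyr::mutate(cellularity = round(stats::runif(
        dplyr::n(), cfg$cellularity[1], cfg$cellularity[2]), 3))
    # read counts need the per-region cellularity, so a second pass:
    support <- dplyr::bind_rows(acc$support) |>
      dplyr::left_join(regions, by = c("patient_id", "region_id"))
    counts <- assign_read_counts(
      present = support$present, depth_mean = cfg$mean_depth,
      cellularity = support$cellularity, tumor_alt_copies = 1L,
      tumor_total_copies = 2L, error_rate = cfg$sequencing_error)
    support <- dplyr::bind_cols(
      dplyr::select(support, "patient_id", "variant_id", "region_id"),
      counts[, c("alt_reads", "total_reads")])
    het <- dplyr::bind_rows(acc$het) |>
      dplyr::left_join(regions, by = c("patient_id", "region_id"))
    het$cellularity[het$region_id == "germline"] <- 0
    hc <- assign_read_counts(
      present = TRUE,
      depth_mean = ifelse(het$region_id == "germline",
                          cfg$germline_depth, cfg$mean_depth),
      cellularity = het$cellularity,
      tumor_alt_copies = het$c_alt, tumor_total_copies = het$c_tot,
      error_rate = cfg$sequencing_error, germline_alt_copies = 1L)
    het_sites <- dplyr::bind_cols(
      dplyr::select(het, "patient_id", "site_id", "pos", "region_id"),
      hc[, c("alt_reads", "total_reads")])
    list(patients = pts,
         regions = regions,
         variants = dplyr::bind_rows(acc$variants),
         support = support,
         germline = dplyr::bind_rows(acc$germline),
         het_sites = het_sites,
         segments = dplyr::bind_rows(acc$seg),
         truth = list(variants = dplyr::bind_rows(acc$truth_var),
                      branch_exposures = dplyr::bind_rows(acc$truth_exp),
                      loh_sites = dplyr::bind_rows(acc$truth_loh),
                      patients = pts),
         reference = reference,
         config = cfg)
  })
}

empty_cohort <- function(cfg, reference, pts) {
  empty_support <- tibble::tibble(patient_id = character(),
                                  variant_id = character(),
                                  region_id = character(),
                                  alt_reads = integer(),
                                  total_reads = integer())
  list(patients = pts,
       regions = tibble::tibble(patient_id = character(),
                                region_id = character(),
                                cellularity = numeric()),
       variants = annotate_somatic(tibble::tibble(
         chrom = character(), pos = integer(), ref = character(),
         alt = character(), channel = integer(), branch = character(),
         patient_id = character(), variant_id = character(),
         vtype = character())),
       support = empty_support,
       germline = tibble::tibble(patient_id = character()),
       het_sites = tibble::tibble(patient_id = character(),
                                  site_id = character(), pos = integer(),
                                  region_id = character(),
                                  alt_reads = integer(),
                                  total_reads = integer()),
       segments = tibble::tibble(patient_id = character(),
                                 region_id = character(),
                                 chrom = character(), start = integer(),
                                 end = integer(), copy_number = integer(),
                                 minor_cn = integer()),
       truth = list(variants = tibble::tibble(patient_id = character(),
                                              variant_id = character(),
                                              branch = character(),
                                              vtype = character(),
                                              channel = integer()),
                    branch_exposures = tibble::tibble(),
                    loh_sites = tibble::tibble(patient_id = character(),
                                               site_id = character(),
                                               pos = integer(),
                                               loh = logical()),
                    patients = pts),
       reference = reference,
       config = cfg)
}

simulate_patients <- function(cfg) {
  n <- cfg$n_patients
  ids <- sprintf("P%02d", seq_len(n))
  status <- if (n == 0) character() else
    sample(names(cfg$smoking_probs), n, replace = TRUE,
           prob = cfg$smoking_probs)
  pack_years <- round(ifelse(
    status == "never", 0,
    stats::runif(n, cfg$pack_years_range[1], cfg$pack_years_range[2])), 1)
  gc <- cfg$germline_config
  tibble::tibble(
    patient_id = ids,
    histotype = if (n == 0) character() else
      sample(c("LUAD", "LUSC", "SCLC"), n, replace = TRUE,
             prob = c(0.6, 0.3, 0.1)),
    smoking_status = status,
    pack_years = pack_years,
    germline_mutant = stats::runif(n) < (gc$p_mutant %||% 0.6),
    n_somatic = as.integer(round(cfg$n_somatic * c(current = 1.5, former = 1,
                                                   never = 0.3)[status])),
    true_tobacco_fraction = NA_real_)
}

# Truncal/private exposure vectors for one patient.
patient_exposures <- function(cfg, signames, patient) {
  if (!is.null(cfg$branch_exposures)) {
    return(list(exposures = cfg$branch_exposures,
                tobacco = cfg$branch_exposures[["truncal"]][
                  match("tobacco", signames)]))
  }
  gc <- cfg$germline_config
  never <- patient$smoking_status == "never"
  mu <- if (never) 0.02 else if (patient$germline_mutant)
    gc$tobacco_mean_mutant else gc$tobacco_mean_wt
  tob <- min(max(stats::rnorm(1, mu, if (never) 0.01 else gc$tobacco_sd),
                 0), 0.95)
  rest <- c(tobacco = 0, clock = 0.35, apobec = 0.2, hrd = 0.2,
            poleta = 0.05, background = 0.2)[signames]
  rest[is.na(rest)] <- 0
  truncal <- rest / sum(rest) * (1 - tob)
  truncal[signames == "tobacco"] <- tob
  doms <- setdiff(c("apobec", "clock", "hrd", "poleta"), character()) |>
    intersect(signames)
  exposures <- list(truncal = unname(truncal))
  for (r in seq_along(cfg$regions)) {
    dom <- doms[(r - 1L) %% length(doms) + 1L]
    e <- stats::setNames(rep(0.3 / (length(signames) - 1), length(signames)),
                         signames)
    e[dom] <- 0.7
    exposures[[cfg$regions[r]]] <- unname(e / sum(e))
  }
  list(exposures = exposures, tobacco = tob)
}

simulate_patient <- function(cfg, catalog, reference, patient, signames) {
  pid <- patient$patient_id
  exp_set <- patient_exposures(cfg, signames, patient)
  n <- patient$n_somatic
  n_truncal <- as.integer(round(cfg$truncal_fraction * n))
  branches <- if (cfg$regions_per_patient == 1L) "truncal" else
    c("truncal", cfg$regions)
  n_private <- if (cfg$regions_per_patient == 1L) integer() else {
    m <- n - n_truncal
    base <- m %/% length(cfg$regions)
    extra <- m %% length(cfg$regions)
    base + (seq_along(cfg$regions) <= extra)
  }
  n_branch <- c(n_truncal, n_private)
  if (cfg$regions_per_patient == 1L) n_branch <- n
  used <- integer()
  vars <- vector("list", length(branches))
  for (b in seq_along(branches)) {
    v <- draw_mutations(n_branch[b], exp_set$exposures[[branches[b]]],
                        catalog, reference, exclude = used)
    used <- c(used, v$pos)
    v$branch <- branches[b]
    vars[[b]] <- v
  }
  vars <- dplyr::bind_rows(vars)
  nv <- nrow(vars)
  # a slice becomes 1-bp insertions (counting realism only)
  n_indel <- round(cfg$indel_fraction * nv)
  if (n_indel > 0) {
    idx <- sample.int(nv, n_indel)
    vars$alt[idx] <- paste0(vars$ref[idx],
                            sample(c("A", "C", "G", "T"), n_indel,
                                   replace = TRUE))
    vars$channel[idx] <- NA_integer_
  }
  vars <- vars |>
    dplyr::mutate(patient_id = pid,
                  variant_id = sprintf("%s_v%05d", pid, dplyr::row_number()),
                  vtype = ifelse(nchar(.data$alt) == 1L, "SNV", "indel"))
  annotated <- annotate_somatic(vars)
  support <- tidyr::crossing(variant_id = vars$variant_id,
                             region_id = cfg$regions) |>
    dplyr::left_join(dplyr::select(vars, "variant_id", "branch"),
                     by = "variant_id") |>
    dplyr::mutate(patient_id = pid,
                  present = .data$branch == "truncal" |
                    .data$branch == .data$region_id) |>
    dplyr::select("patient_id", "variant_id", "region_id", "present")
  germline <- simulate_germline_variants(pid, patient$germline_mutant)
  het <- simulate_het_sites(cfg, pid, used, reference)
  seg <- simulate_segments(cfg, pid)
  truth_exp <- purrr::imap_dfr(exp_set$exposures, function(e, lab) {
    tibble::tibble(patient_id = pid, branch = lab, signature = signames,
                   fraction = e)
  })
  list(variants = annotated,
       support = support,
       germline = germline,
       het = het$samples,
       seg = seg,
       truth_var = dplyr::select(vars, "patient_id", "variant_id",
                                 "branch", "vtype", "channel"),
       truth_exp = truth_exp,
       truth_loh = het$truth,
       true_tobacco_fraction = exp_set$tobacco)
}

# Annotation fields for simulated somatic variants: a handful of truncal
# driver-gene hits engineered to pass the driver cascade; the rest are
# passenger records with realistic-but-unremarkable annotations.
annotate_somatic <- function(vars) {
  nv <- nrow(vars)
  drivers <- c("TP53", "KRAS", "PTEN", "RB1", "FAT1", "SETD2", "ARID1A")
  truncal_idx <- which(vars$branch == "truncal")
  n_driver <- min(length(truncal_idx), sample(2:4, 1))
  hit <- if (n_driver > 0) sample(truncal_idx, n_driver) else integer()
  out <- vars |>
    dplyr::mutate(
      gene = NA_character_,
      impact = sample(c("LOW", "MODIFIER", "MODERATE"), nv, replace = TRUE,
                      prob = c(0.3, 0.6, 0.1)),
      cadd = round(stats::rexp(nv, 1 / 3), 2),
      qss = round(stats::rgamma(nv, shape = 8, scale = 5), 1),
      pop_af = NA_real_,
      clinvar = "none",
      pfam_domain = FALSE,
      provean = NA_character_, sift = NA_character_,
      polyphen = NA_character_)
  if (length(hit)) {
    out$gene[hit] <- sample(drivers, length(hit))
    out$impact[hit] <- sample(c("HIGH", "MODERATE"), length(hit),
                              replace = TRUE)
    out$cadd[hit] <- round(stats::runif(length(hit), 10, 35), 2)
    out$qss[hit] <- round(stats::runif(length(hit), 20, 70), 1)
    out$pop_af[hit] <- signif(stats::runif(length(hit), 0, 0.005), 2)
  }
  dplyr::select(out, "patient_id", "variant_id", "chrom", "pos", "ref",
                "alt", "vtype", "gene", "impact", "cadd", "qss", "pop_af",
                "clinvar", "pfam_domain", "provean", "sift", "polyphen")
}

# Germline records: mutant patients get 1-3 repair-gene variants that pass
# the germline cascade by construction; everyone gets benign decoys.
simulate_germline_variants <- function(pid, mutant) {
  repair <- c("ERCC5", "NEIL1", "LIG4", "MUTYH", "REV1", "TDG", "RECQL4",
              "POLB", "ERCC8")
  mk <- function(k, gene, impact, clinvar, pfam, dmg, pop_af) {
    n_dmg <- length(dmg)
    tibble::tibble(
      patient_id = pid,
      variant_id = sprintf("%s_g%03d", pid, k),
      chrom = "germ1", pos = 1000L * k, ref = "C", alt = "T",
      vtype = "SNV", gene = gene, impact = impact,
      cadd = round(stats::runif(1, 3, 30), 2),
      qss = round(stats::runif(1, 20, 60), 1),
      pop_af = pop_af, clinvar = clinvar, pfam_domain = pfam,
      provean = if ("provean" %in% dmg) "damaging" else "benign",
      sift = if ("sift" %in% dmg) "damaging" else "benign",
      polyphen = if ("polyphen" %in% dmg) "damaging" else "benign")
  }
  out <- list()
  k <- 0L
  if (mutant) {
    n_hits <- sample(1:3, 1)
    genes <- sample(repair, n_hits)
    for (g in genes) {
      k <- k + 1L
      form <- sample(3, 1)
      out[[k]] <- switch(form,
        mk(k, g, "MODERATE", "likely_pathogenic", FALSE, character(),
           signif(stats::runif(1, 0, 0.01), 2)),
        mk(k, g, "MODERATE", "none", TRUE, "sift",
           signif(stats::runif(1, 0, 0.01), 2)),
        mk(k, g, "MODERATE", "none", FALSE, c("provean", "polyphen"),
           signif(stats::runif(1, 0, 0.01), 2)))
    }
  }
  # benign decoys: common or predictor-benign repair-gene variants
  k <- k + 1L
  out[[k]] <- mk(k, sample(repair, 1), "MODERATE", "none", FALSE,
                 character(), signif(stats::runif(1, 0.05, 0.3), 2))
  k <- k + 1L
  out[[k]] <- mk(k, sample(repair, 1), "MODERATE", "none", TRUE,
                 character(), signif(stats::runif(1, 0, 0.01), 2))
  dplyr::bind_rows(out)
}

# Germline-het SNP sites; a p_loh fraction sit in truncal LOH regions.
# Loss is hemizygous or copy-neutral with equal probability, losing the ref
# or the alt allele with equal probability.
simulate_het_sites <- function(cfg, pid, used, reference) {
  avail <- setdiff(2:(cfg$ref_length_bp - 1L), used)
  pos <- sort(sample(avail, min(cfg$n_germline_het, length(avail))))
  m <- length(pos)
  loh <- stats::runif(m) < cfg$p_loh
  neutral <- stats::runif(m) < 0.5
  lose_alt <- stats::runif(m) < 0.5
  c_tot <- ifelse(loh, ifelse(neutral, 2L, 1L), 2L)
  c_alt <- ifelse(!loh, 1L,
                  ifelse(lose_alt, 0L, ifelse(neutral, 2L, 1L)))
  sites <- tibble::tibble(
    patient_id = pid, site_id = sprintf("%s_h%03d", pid, seq_len(m)),
    pos = pos, loh = loh, c_alt = as.integer(c_alt),
    c_tot = as.integer(c_tot))
  samples <- tidyr::crossing(site_id = sites$site_id,
                             region_id = c("germline", cfg$regions)) |>
    dplyr::left_join(sites, by = "site_id") |>
    dplyr::mutate(
      c_alt = ifelse(.data$region_id == "germline", 1L, .data$c_alt),
      c_tot = ifelse(.data$region_id == "germline", 2L, .data$c_tot)) |>
    dplyr::select("patient_id", "site_id", "pos", "region_id", "c_alt",
                  "c_tot")
  list(samples = samples,
       truth = dplyr::select(sites, "patient_id", "site_id", "pos", "loh",
                             "c_alt", "c_tot"))
}

# Per-region CNV segment tables over a virtual genome: a shared truncal
# aberration profile plus region-private deviations.
simulate_segments <- function(cfg, pid) {
  L <- cfg$cnv_genome_mb * 1e6
  k <- cfg$n_cnv_segments
  cuts <- sort(sample(seq(2e4, L - 2e4, by = 1e4), k - 1))
  start <- c(1, cuts + 1)
  end <- c(cuts, L)
  ab_states <- c(0L, 1L, 3L, 4L, 7L, 8L)
  truncal_cn <- ifelse(stats::runif(k) < 0.3,
                       sample(ab_states, k, replace = TRUE), 2L)
  purrr::map_dfr(cfg$regions, function(r) {
    cn <- truncal_cn
    flip <- stats::runif(k) < 0.15
    cn[flip] <- sample(ab_states, sum(flip), replace = TRUE)
    tibble::tibble(patient_id = pid, region_id = r, chrom = "cnv1",
                   start = as.integer(start), end = as.integer(end),
                   copy_number = as.integer(cn),
                   minor_cn = as.integer(pmin(1L, cn %/% 2L)))
  })
}

#' Simulate patient-level tobacco fractions under a germline effect
#'
#' Draws per-patient smoking-signature fractions from the same generative
#' model the cohort simulator uses for the gene-by-environment effect:
#' mutant patients' fractions are normal around `mean_mutant`, wild-type
#' around `mean_wt`, both with sd `sd`, truncated to `[0, 1]`.
#'
#' @param n_mutant,n_wt Group sizes.
#' @param mean_mutant,mean_wt,sd Effect parameters.
#' @param seed Optional seed.
#' @return Tibble: `patient_id`, `germline_mutant`, `smoking_fraction`.
#' @export
simulate_germline_effect <- function(n_mutant = 10, n_wt = 10,
                                     mean_mutant = 0.5, mean_wt = 0.2,
                                     sd = 0.1, seed = NULL) {
  with_seed(seed, {
    x <- c(stats::rnorm(n_mutant, mean_mutant, sd),
           stats::rnorm(n_wt, mean_wt, sd))
    tibble::tibble(
      patient_id = sprintf("P%02d", seq_len(n_mutant + n_wt)),
      germline_mutant = rep(c(TRUE, FALSE), c(n_mutant, n_wt)),
      smoking_fraction = pmin(pmax(x, 0), 1))
  })
}
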
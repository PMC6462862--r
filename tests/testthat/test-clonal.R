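test_that("presence calls follow the depth, alt-read, and VAF thresholds", {
  expect_equal(call_presence(c(0, 2, 8, 1, 75), c(150, 150, 150, 5, 150)),
               c("absent", "absent", "present", "unknown", "present"))
  expect_error(call_presence(-1, 10), class = "clonehet_invalid_argument")
  expect_error(call_presence(11, 10), class = "clonehet_invalid_argument")
})

test_that("partition matches the exhaustive 3-region oracle", {
  regions <- c("R1", "R2", "R3")
  states <- c("present", "absent", "unknown")
  patterns <- expand.grid(a = states, b = states, c = states,
                          stringsAsFactors = FALSE)
  pattern_list <- lapply(seq_len(nrow(patterns)),
                         function(i) unlist(patterns[i, ], use.names = FALSE))
  expected <- vapply(pattern_list, oracle_classify_pattern, character(1))
  support <- support_from_patterns(pattern_list, regions)
  part <- suppressMessages(partition_variants(support, region_ids = regions))
  got <- part$class[match(sprintf("v%03d", seq_along(pattern_list)),
                          part$variant_id)]
  expect_equal(got, unname(expected))
  expect_equal(attr(part, "n_dropped"), sum(is.na(expected)))
  # spot checks from the rule statement
  idx <- function(p) which(vapply(pattern_list, identical, logical(1), p))
  expect_equal(got[idx(c("present", "present", "present"))], "truncal")
  expect_equal(got[idx(c("present", "absent", "absent"))], "private")
  expect_equal(got[idx(c("present", "present", "unknown"))], "truncal")
})

test_that("trees are reconstructed from nested and star partitions", {
  regions <- c("R1", "R2", "R3")
  star <- tibble::tibble(
    variant_id = sprintf("v%02d", 1:40),
    class = rep(c("truncal", "private", "private", "private"), 10),
    pattern = rep(c("R1+R2+R3", "R1", "R2", "R3"), 10))
  tree <- build_tree(star, region_ids = regions)
  expect_equal(nrow(tree$nodes) - 1L, 4L)  # trunk + three leaves
  counts <- branch_mutation_counts(tree)
  expect_equal(sum(counts$n_variants), 40)
  leaf_parents <- tree$nodes$parent_id[tree$nodes$label %in% regions]
  trunk_id <- tree$nodes$node_id[tree$nodes$label == "truncal"]
  expect_true(all(leaf_parents == trunk_id))

  chain <- tibble::tibble(
    variant_id = sprintf("c%02d", 1:30),
    class = rep(c("truncal", "shared", "private"), 10),
    pattern = rep(c("R1+R2+R3", "R1+R2", "R1"), 10))
  tr2 <- build_tree(chain, region_ids = regions)
  n <- tr2$nodes
  get <- function(lab) n[n$label == lab, ]
  expect_equal(get("R1+R2")$parent_id, get("truncal")$node_id)
  expect_equal(get("R1")$parent_id, get("R1+R2")$node_id)
})

test_that("conflicting patterns keep the higher count as a clade", {
  regions <- c("R1", "R2", "R3")
  part <- tibble::tibble(
    variant_id = sprintf("x%03d", 1:70),
    class = c(rep("truncal", 10), rep("shared", 60)),
    pattern = c(rep("R1+R2+R3", 10), rep("R1+R2", 50), rep("R2+R3", 10)))
  tree <- build_tree(part, region_ids = regions)
  n <- tree$nodes
  trunk_id <- n$node_id[n$label == "truncal"]
  # both conflicting nodes end up children of the trunk, counts preserved
  expect_equal(n$parent_id[n$label == "R1+R2"], trunk_id)
  expect_equal(n$parent_id[n$label == "R2+R3"], trunk_id)
  # the kept clade parents its nested singletons; the loser does not
  expect_equal(n$parent_id[n$label == "R1"],
               n$node_id[n$label == "R1+R2"])
  expect_equal(n$parent_id[n$label == "R2"],
               n$node_id[n$label == "R1+R2"])
  expect_equal(n$parent_id[n$label == "R3"], trunk_id)
  expect_equal(sum(branch_mutation_counts(tree)$n_variants), 70)
})

test_that("empty private branches are reported as zero, not omitted", {
  part <- tibble::tibble(variant_id = "v1", class = "truncal",
                         pattern = "R1+R2")
  tree <- build_tree(part, region_ids = c("R1", "R2"))
  counts <- branch_mutation_counts(tree)
  expect_setequal(counts$branch, c("truncal", "R1", "R2"))
  expect_equal(counts$n_variants[counts$branch == "R1"], 0L)
})

test_that("permuting region order changes labels only, never counts", {
  regions <- c("R1", "R2", "R3")
  set.seed(17)
  states <- c("present", "absent")
  pats <- lapply(1:200, function(i) sample(states, 3, replace = TRUE))
  support <- support_from_patterns(pats, regions)
  part1 <- suppressMessages(partition_variants(support, regions))
  support2 <- dplyr::mutate(support, region_id = c(R1 = "R3", R2 = "R1",
                                                   R3 = "R2")[region_id])
  part2 <- suppressMessages(partition_variants(support2, regions))
  expect_equal(table(part1$class), table(part2$class))
  t1 <- build_tree(part1, regions)
  t2 <- build_tree(part2, regions)
  expect_equal(sort(branch_mutation_counts(t1)$n_variants),
               sort(branch_mutation_counts(t2)$n_variants))
})

test_that("newick export round-trips through ape", {
  skip_if_not_installed("ape")
  part <- tibble::tibble(
    variant_id = sprintf("v%02d", 1:30),
    class = rep(c("truncal", "shared", "private"), 10),
    pattern = rep(c("R1+R2+R3", "R1+R2", "R3"), 10))
  tree <- build_tree(part, region_ids = c("R1", "R2", "R3"))
  phy <- ape::read.tree(text = to_newick(tree))
  expect_equal(sort(phy$tip.label), c("R1", "R2", "R3"))
  expect_equal(sum(phy$edge.length), 30)
})

test_that("truncal counts are recovered exactly from noiseless deep data", {
  cfg <- sim_config(n_patients = 1, regions_per_patient = 3,
                    n_somatic = 500, truncal_fraction = 0.8,
                    mean_depth = 150, sequencing_error = 0,
                    cellularity = c(0.5, 0.9), n_germline_het = 10,
                    seed = 97)
  sim <- simulate_cohort(cfg)
  part <- suppressMessages(
    partition_variants(dplyr::select(sim$support, -"patient_id"),
                       region_ids = cfg$regions))
  tree <- build_tree(part, region_ids = cfg$regions)
  truth_truncal <- sum(sim$truth$variants$branch == "truncal")
  est_truncal <- tree$nodes$n_variants[tree$nodes$label == "truncal"]
  expect_equal(est_truncal, truth_truncal)
  expect_equal(sum(branch_mutation_counts(tree)$n_variants), nrow(part))
})
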
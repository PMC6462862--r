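#' Call variant presence in one region from read counts
#'
#' A site is `unknown` below the depth floor, `present` with at least
#' `min_alt` alt reads and a VAF of at least `min_vaf`, and `absent`
#' otherwise. Defaults are conservative for ~150x sequencing.
#'
#' @param alt_reads,total_reads Non-negative read counts
#'   (`alt_reads <= total_reads`).
#' @param min_depth Depth floor below which presence is unknown.
#' @param min_alt Minimum alt reads for presence.
#' @param min_vaf Minimum VAF for presence.
#' @return Character vector in `{"present", "absent", "unknown"}`.
#' @export
#' @examples
#' call_presence(c(0, 8, 1), c(150, 150, 5))
call_presence <- function(alt_reads, total_reads, min_depth = 10,
                          min_alt = 3, min_vaf = 0.05) {
  if (any(alt_reads < 0 | total_reads < 0)) {
    abort_invalid("Read counts must be non-negative.")
  }
  if (any(alt_reads > total_reads)) {
    abort_invalid("Need alt_reads <= total_reads.")
  }
  dplyr::case_when(
    total_reads < min_depth ~ "unknown",
    alt_reads >= min_alt & alt_reads / total_reads >= min_vaf ~ "present",
    TRUE ~ "absent")
}

#' Partition variants into truncal, shared, and private classes
#'
#' Classifies each variant by its presence pattern across regions: truncal
#' when no region calls it absent (unknowns tolerated) and at least one
#' calls it present; private when present in exactly one region (with at
#' least one absent call); shared otherwise. Variants present nowhere are
#' dropped; the dropped count is kept in the `n_dropped` attribute.
#' Regions missing from a variant's support are treated as unknown.
#'
#' @param support Long tibble: `variant_id`, `region_id`, `alt_reads`,
#'   `total_reads`.
#' @param region_ids Region universe; defaults to the regions present in
#'   `support`.
#' @param ... Passed to [call_presence()].
#' @return Tibble: `variant_id`, `class`, `pattern` (sorted `+`-joined
#'   present regions), `n_present`, `n_absent`, `n_unknown`; attribute
#'   `n_dropped`.
#' @export
partition_variants <- function(support, region_ids = NULL, ...) {
  region_ids <- sort(region_ids %||% unique(support$region_id))
  if (length(region_ids) < 1) abort_invalid("Need at least one region.")
  calls <- support |>
    dplyr::mutate(call = call_presence(.data$alt_reads, .data$total_reads,
                                       ...)) |>
    dplyr::select("variant_id", "region_id", "call")
  full <- tidyr::crossing(variant_id = unique(support$variant_id),
                          region_id = region_ids) |>
    dplyr::left_join(calls, by = c("variant_id", "region_id")) |>
    dplyr::mutate(call = dplyr::coalesce(.data$call, "unknown"))
  summ <- full |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(
      n_present = sum(.data$call == "present"),
      n_absent = sum(.data$call == "absent"),
      n_unknown = sum(.data$call == "unknown"),
      pattern = paste(sort(.data$region_id[.data$call == "present"]),
                      collapse = "+"),
      .groups = "drop")
  n_dropped <- sum(summ$n_present == 0)
  out <- summ |>
    dplyr::filter(.data$n_present > 0) |>
    dplyr::mutate(class = dplyr::case_when(
      n_absent == 0 ~ "truncal",
      n_present == 1 ~ "private",
      TRUE ~ "shared")) |>
    dplyr::select("variant_id", "class", "pattern", "n_present",
                  "n_absent", "n_unknown")
  if (n_dropped > 0) {
    rlang::inform(sprintf("Dropped %d variant(s) present in no region.",
                          n_dropped))
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Build a clone tree from a truncal/shared/private partition
#'
#' Reconstructs a perfect phylogeny over the observed presence subsets: the
#' trunk (last common ancestor) carries the truncal variants and the full
#' region set; every other observed subset becomes a node attached to its
#' smallest observed strict superset, or to the trunk. Pairs of subsets
#' that overlap without nesting violate the perfect-phylogeny assumption;
#' the higher-count pattern is kept as a clade and the other is attached
#' directly to the trunk (ties broken lexicographically). A leaf is
#' emitted for every region even when it has no private variants.
#'
#' @param partition A [partition_variants()] result.
#' @param region_ids Region universe; defaults to the regions appearing in
#'   the partition patterns.
#' @return A `clade_tree`: list with `nodes` (tibble: `node_id`, `label`,
#'   `parent_id`, `regions` and `variant_ids` list-columns, `n_variants`)
#'   and `regions`. The root is the `germline` node.
#' @export
build_tree <- function(partition, region_ids = NULL) {
  if (nrow(partition) == 0) abort_invalid("Partition is empty.")
  region_ids <- sort(region_ids %||%
                       unique(unlist(strsplit(partition$pattern, "+",
                                              fixed = TRUE))))
  full_pattern <- paste(region_ids, collapse = "+")
  part <- dplyr::mutate(partition, pattern = ifelse(
    .data$class == "truncal", full_pattern, .data$pattern))
  pats <- part |>
    dplyr::group_by(.data$pattern) |>
    dplyr::summarise(n = dplyr::n(),
                     variant_ids = list(.data$variant_id),
                     .groups = "drop")
  # ensure trunk and every region leaf exist
  need <- setdiff(c(full_pattern, region_ids), pats$pattern)
  if (length(need)) {
    pats <- dplyr::bind_rows(pats, tibble::tibble(
      pattern = need, n = 0L, variant_ids = list(character())))
  }
  pats$regions <- strsplit(pats$pattern, "+", fixed = TRUE)
  pats$size <- lengths(pats$regions)
  trunk <- which(pats$pattern == full_pattern)
  others <- setdiff(order(-pats$n, pats$pattern), trunk)
  conflicts <- function(a, b) {
    i <- length(intersect(a, b))
    i > 0 && i < length(a) && i < length(b)
  }
  kept <- list()          # accepted clade patterns (indices into pats)
  trunk_attached <- logical(nrow(pats))
  for (i in others) {
    bad <- any(vapply(kept, function(k) {
      conflicts(pats$regions[[i]], pats$regions[[k]])
    }, logical(1)))
    if (bad) trunk_attached[i] <- TRUE else kept <- c(kept, i)
  }
  parent_of <- integer(nrow(pats))
  parent_of[trunk] <- 0L    # germline
  for (i in others) {
    if (trunk_attached[i]) {
      parent_of[i] <- trunk
      next
    }
    sups <- Filter(function(k) {
      k != i && pats$size[k] > pats$size[i] &&
        all(pats$regions[[i]] %in% pats$regions[[k]])
    }, unlist(kept))
    parent_of[i] <- if (length(sups) == 0) trunk else {
      sups[order(pats$size[sups], pats$pattern[sups])][1]
    }
  }
  ord <- c(trunk, others)
  id_of <- match(seq_len(nrow(pats)), ord) + 1L  # germline = 1
  pv <- parent_of[ord]
  parent_ids <- ifelse(pv == 0L, 1L, id_of[pmax(pv, 1L)])
  nodes <- tibble::tibble(
    node_id = c(1L, id_of[ord]),
    label = c("germline",
              ifelse(pats$pattern[ord] == full_pattern, "truncal",
                     pats$pattern[ord])),
    parent_id = c(NA_integer_, parent_ids),
    regions = c(list(region_ids), pats$regions[ord]),
    variant_ids = c(list(character()), pats$variant_ids[ord]),
    n_variants = c(0L, pats$n[ord]))
  structure(list(nodes = nodes, regions = region_ids),
            class = "clade_tree")
}

#' @export
print.clade_tree <- function(x, ...) {
  cat(sprintf("<clade_tree: %d regions, %d branches, %d variants>\n",
              length(x$regions), nrow(x$nodes) - 1L,
              sum(x$nodes$n_variants)))
  print(dplyr::select(x$nodes, "node_id", "label", "parent_id",
                      "n_variants"))
  invisible(x)
}

#' Per-branch mutation counts of a clone tree
#'
#' @param tree A [build_tree()] clone tree.
#' @return Tibble `branch`, `n_variants`, one row per non-root node (empty
#'   private branches included with 0).
#' @export
branch_mutation_counts <- function(tree) {
  stopifnot(inherits(tree, "clade_tree"))
  tree$nodes |>
    dplyr::filter(.data$label != "germline") |>
    dplyr::transmute(branch = .data$label, n_variants = .data$n_variants)
}

#' Export a clone tree as Newick
#'
#' Branch lengths are mutation counts; internal node labels are kept.
#'
#' @param tree A `clade_tree`.
#' @param path Optional output path; when given the string is also written
#'   to the file.
#' @return The Newick string, invisibly when `path` is given.
#' @export
to_newick <- function(tree, path = NULL) {
  nodes <- tree$nodes
  fmt <- function(id) {
    kids <- nodes$node_id[!is.na(nodes$parent_id) & nodes$parent_id == id]
    me <- nodes[nodes$node_id == id, ]
    lab <- gsub("[ ,():;\\[\\]]", "_", me$label)
    inner <- if (length(kids)) {
      paste0("(", paste(vapply(kids, fmt, character(1)), collapse = ","),
             ")")
    } else {
      ""
    }
    paste0(inner, lab,
           if (is.na(me$parent_id)) "" else paste0(":", me$n_variants))
  }
  nwk <- paste0(fmt(nodes$node_id[is.na(nodes$parent_id)]), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Export a clone tree as a TSV edge list
#'
#' @param tree A `clade_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_edges <- function(tree, path) {
  edges <- tree$nodes |>
    dplyr::filter(!is.na(.data$parent_id)) |>
    dplyr::mutate(parent = tree$nodes$label[match(.data$parent_id,
                                                  tree$nodes$node_id)]) |>
    dplyr::select(parent, child = "label", n_variants = "n_variants")
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}
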
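#' Aligner tuning parameters
#'
#' The depth-limited search is governed by two hard caps: a global budget of
#' `node_budget_factor` times the read length on the number of probed nodes,
#' and at most `neighbor_cap` neighbour probes per node. The defaults (2 and
#' 4) are the canonical stop conditions of the strand-directed exact mapper;
#' larger values only slow the search without mapping more reads on SNP-only
#' graphs. `backtrack = FALSE` selects a strict no-return mode in which the
#' search never re-enters an abandoned branch, for fidelity experiments with
#' the one-directional pseudocode.
#'
#' @param node_budget_factor Global visited-node budget per seed, as a
#'   multiple of the read length.
#' @param neighbor_cap Maximum neighbour probes per node.
#' @param min_seed_length Minimum number of characters a seed anchor must
#'   share with the graph.
#' @param max_seed_length Upper bound on locate patterns (the node-length
#'   bound of the graph).
#' @param backtrack Allow depth-first backtracking within the same budgets.
#' @return A `vg_aligner_params` list.
#' @export
aligner_params <- function(node_budget_factor = 2L, neighbor_cap = 4L,
                           min_seed_length = 2L, max_seed_length = 32L,
                           backtrack = TRUE) {
  stopifnot(node_budget_factor >= 1, neighbor_cap >= 1,
            min_seed_length >= 2, max_seed_length <= 32)
  structure(list(node_budget_factor = as.integer(node_budget_factor),
                 neighbor_cap = as.integer(neighbor_cap),
                 min_seed_length = as.integer(min_seed_length),
                 max_seed_length = as.integer(max_seed_length),
                 backtrack = isTRUE(backtrack)),
            class = "vg_aligner_params")
}

#' Find initial seed anchors for a read
#'
#' Seeds anchor a terminal substring of the read: in forward orientation a
#' read prefix matched on a node's forward strand, in reverse orientation the
#' corresponding terminal substring matched on the reverse-complement strand,
#' so that the unmatched remainder always lies in the ID-monotone traversal
#' direction. Anchors are maximal within their node and must share at least
#' `min_seed_length` (default 2) characters with the graph; an anchor cut to
#' a single character by a node boundary is kept only when its second
#' character matches the start of an oriented successor, i.e. the two shared
#' characters straddle an edge. Hits are ordered longest-anchor-first, ties
#' by ascending node id, forward before reverse. An empty result is the
#' rejection signal: reads shorter than two characters or containing `N`
#' never seed.
#'
#' @param read Read sequence (character scalar) or a one-row reads tibble.
#' @param index A `vg_index` (or `vg_graph`).
#' @param params [aligner_params()].
#' @return Tibble of seed hits (`node_id`, `offset`, `is_reverse`,
#'   `match_length`).
#' @export
vg_find_initial_nodes <- function(read, index, params = aligner_params()) {
  seq <- read_sequence(read)
  res <- as_tibble(core_find_seeds(index_core(index), seq))
  res[pmax(res$match_length, 2L) >= params$min_seed_length, ]
}

read_sequence <- function(read) {
  if (is.character(read) && length(read) == 1 && is.null(names(read))) {
    return(toupper(read))
  }
  toupper(as_reads_tbl(read)$seq[1])
}

#' Traversal direction implied by a seed hit
#'
#' A forward-strand hit extends towards increasing node IDs; a
#' reverse-complement hit towards decreasing IDs.
#'
#' @param hits Tibble of seed hits.
#' @return Character vector, `"increasing"` or `"decreasing"` per hit.
#' @export
vg_find_direction <- function(hits) {
  ifelse(as_tibble(hits)$is_reverse, "decreasing", "increasing")
}

#' Extend a seed anchor to a complete exact alignment
#'
#' Depth-first, gap-free, mismatch-free extension from the anchor along the
#' ID-monotone direction of the hit, under the global visited-node budget and
#' the per-node neighbour cap. Every probed node — matching or not —
#' decrements the budget; nothing is refunded on backtrack. Returns zero rows
#' if no completion is found within the budgets.
#'
#' @param read Read sequence or one-row reads tibble.
#' @param hit One seed hit (one-row tibble with `node_id`, `offset`,
#'   `is_reverse`, `match_length`).
#' @param index A `vg_index` (or `vg_graph`).
#' @param params [aligner_params()].
#' @return An alignments tibble with 0 or 1 rows (see [vg_map_read()]).
#' @export
vg_extend_alignment <- function(read, hit, index, params = aligner_params()) {
  seq <- read_sequence(read)
  hit <- as_tibble(hit)
  res <- core_extend(index_core(index), seq, as.integer(hit$node_id[1]),
                     as.integer(hit$offset[1]), isTRUE(hit$is_reverse[1]),
                     as.integer(hit$match_length[1]),
                     params$node_budget_factor, params$neighbor_cap,
                     params$backtrack)
  assemble_alignments(list(res), read_name(read), seq)
}

read_name <- function(read) {
  if (is.character(read) && length(read) == 1 && is.null(names(read))) {
    return("read")
  }
  as_reads_tbl(read)$name[1]
}

# turn the list-of-core-results into the alignments tibble
assemble_alignments <- function(results, names, seqs) {
  keep <- !vapply(results, is.null, logical(1))
  results <- results[keep]
  steps <- lapply(results, function(r) {
    new_tibble(list(node_id = r$node_id, is_reverse = r$is_reverse,
                    offset = r$offset, length = r$length),
               nrow = length(r$node_id))
  })
  new_tibble(list(
    name = names[keep],
    sequence = seqs[keep],
    is_reverse = vapply(results, function(r) r$strand_reverse, logical(1)),
    covers_snp = vapply(results, function(r) r$covers_snp, logical(1)),
    visited_nodes = vapply(results, function(r) r$visited_nodes, integer(1)),
    steps = steps
  ), nrow = sum(keep))
}

#' Map one read to the variation graph
#'
#' Runs the full seed-and-extend procedure: seeds are tried in
#' [vg_find_initial_nodes()] order; the first complete alignment that covers
#' an SNP allele node is the best choice and stops the search immediately;
#' otherwise the first complete alignment found is reported; otherwise the
#' read is rejected (zero rows).
#'
#' @param read Read sequence or one-row reads tibble.
#' @param index A `vg_index` (or `vg_graph`).
#' @param params [aligner_params()].
#' @return Alignments tibble with 0 or 1 rows and columns `name`,
#'   `sequence`, `is_reverse` (overall strand), `covers_snp`,
#'   `visited_nodes` (probes spent by the successful seed) and `steps`, a
#'   list-column of per-step tibbles (`node_id`, `is_reverse`, `offset`,
#'   `length`) whose oriented concatenation spells the read exactly.
#' @export
vg_map_read <- function(read, index, params = aligner_params()) {
  seq <- read_sequence(read)
  res <- core_map_read(index_core(index), seq, params$node_budget_factor,
                       params$neighbor_cap, params$min_seed_length,
                       params$backtrack)
  assemble_alignments(list(res), read_name(read), seq)
}

#' Map a set of reads to the variation graph
#'
#' Applies [vg_map_read()] to each read in input order. With
#' `printsnp = TRUE` only SNP-covering alignments are returned — the reads
#' that feed the genotyper. Mapped/rejected/filtered counts are reported via
#' `message()` and attached as the `"counts"` attribute.
#'
#' @param reads Reads tibble (`name`, `seq`, optional `qual`) or a named
#'   character vector.
#' @param index A `vg_index` (or `vg_graph`).
#' @param params [aligner_params()].
#' @param printsnp Keep only alignments covering an SNP allele node.
#' @param quiet Suppress the summary message.
#' @return Alignments tibble (one row per reported alignment, input order).
#' @export
vg_map_reads <- function(reads, index, params = aligner_params(),
                         printsnp = FALSE, quiet = FALSE) {
  reads <- as_reads_tbl(reads)
  malformed <- is.na(reads$seq) | is.na(reads$name) | nchar(reads$seq) == 0
  if (any(malformed)) {
    warning(sprintf("skipping %d malformed read record(s)", sum(malformed)))
    reads <- reads[!malformed, ]
  }
  seqs <- toupper(reads$seq)
  res <- core_map_reads(index_core(index), seqs, params$node_budget_factor,
                        params$neighbor_cap, params$min_seed_length,
                        params$backtrack)
  out <- assemble_alignments(res, reads$name, seqs)
  counts <- c(input = nrow(reads) + sum(malformed), skipped = sum(malformed),
              mapped = nrow(out), rejected = nrow(reads) - nrow(out),
              filtered = 0L)
  if (printsnp) {
    counts[["filtered"]] <- sum(!out$covers_snp)
    out <- out[out$covers_snp, ]
  }
  if (!quiet) {
    message(sprintf(
      "mapped %d/%d reads (%d rejected, %d skipped, %d filtered by printsnp)",
      counts[["mapped"]], counts[["input"]], counts[["rejected"]],
      counts[["skipped"]], counts[["filtered"]]))
  }
  attr(out, "counts") <- counts
  out
}
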
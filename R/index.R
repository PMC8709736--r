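#' Build a seed index over a variation graph
#'
#' Provides exact-occurrence lookup of short patterns (2–32 characters) over
#' every node sequence on both strands, exposing the classic graph-index
#' query contract: each hit reports the node `id()`, the `offset()` of the
#' occurrence counted from the start of the node in the hit's orientation,
#' and `rc()`, whether the pattern matches the node's reverse-complement
#' strand. Internally the index is a 2-mer bucket dictionary with full
#' verification, held in compiled code; it is rebuilt deterministically from
#' the graph whenever needed, so query results never depend on construction
#' order.
#'
#' @param graph A `vg_graph`.
#' @return A `vg_index` object.
#' @export
vg_index <- function(graph) {
  stopifnot(inherits(graph, "vg_graph"))
  structure(list(graph = graph, cache = new.env(parent = emptyenv())),
            class = "vg_index")
}

#' @exportS3Method base::print
print.vg_index <- function(x, ...) {
  cat(sprintf("<vg_index> over %d nodes (2-mer seed dictionary, both strands)\n",
              nrow(x$graph$nodes)))
  invisible(x)
}

# lazily (re)build the compiled core; external pointers do not survive
# serialisation, so a restored index transparently rebuilds
index_core <- function(index) {
  if (inherits(index, "vg_graph")) index <- vg_index(index)
  stopifnot(inherits(index, "vg_index"))
  ptr <- index$cache$ptr
  if (is.null(ptr) || !core_alive(ptr)) {
    g <- index$graph
    snp_flag <- g$nodes$id %in% snp_node_ids(g)
    index$cache$ptr <- core_build(as.integer(g$nodes$id), g$nodes$seq,
                                  as.integer(g$edges$from),
                                  as.integer(g$edges$to), snp_flag)
  }
  index$cache$ptr
}

#' Locate exact occurrences of a pattern in the graph
#'
#' Returns every position at which `pattern` occurs entirely within a single
#' node, on either strand. Occurrences that only exist across a node
#' boundary are the extension phase's job, not the index's. Patterns
#' containing `N` never match.
#'
#' @param index A `vg_index` (or a `vg_graph`, indexed on the fly).
#' @param pattern Pattern of length 2–32 over `A,C,G,T`.
#' @return Tibble of seed hits: `node_id`, `offset` (0-based, in the hit's
#'   orientation), `is_reverse`, `match_length`; ordered by node id, forward
#'   hits before reverse, then offset.
#' @export
vg_locate <- function(index, pattern) {
  res <- vg_locate_batch(index, pattern)
  res$pattern <- NULL
  res
}

#' @rdname vg_locate
#' @param patterns Character vector of patterns (batch form; the result
#'   carries a `pattern` index column).
#' @export
vg_locate_batch <- function(index, patterns) {
  patterns <- toupper(as.character(patterns))
  n <- nchar(patterns)
  if (any(n < 2 | n > 32)) {
    abort(sprintf("pattern length must be 2..32 (got %d)",
                  n[n < 2 | n > 32][1]))
  }
  res <- as_tibble(core_locate(index_core(index), patterns))
  res$is_reverse <- as.logical(res$is_reverse)
  res
}

#' Resolve a seed hit to the graph-index query triple
#'
#' A pure accessor mirroring the index query interface: per hit, the node
#' `id`, the orientation-relative `offset`, and the reverse-complement flag
#' `rc`.
#'
#' @param hits Tibble of seed hits as returned by [vg_locate()].
#' @return Tibble with columns `id`, `offset`, `rc`.
#' @export
vg_resolve_hit <- function(hits) {
  hits <- as_tibble(hits)
  tibble(id = as.integer(hits$node_id), offset = as.integer(hits$offset),
         rc = as.logical(hits$is_reverse))
}
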
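#' Build an SNP variation graph from a reference and a biallelic SNP catalog
#'
#' Constructs a directed, acyclic sequence graph in which each biallelic SNP
#' is represented by two parallel one-base nodes (the reference- and the
#' alternative-allele node, a "diamond"), and reference runs between SNPs are
#' chunked into nodes of at most 32 characters. Node IDs are assigned
#' sequentially left to right per chromosome, so every forward edge goes from
#' a lower to a higher ID; traversing against the edges (towards lower IDs)
#' corresponds to the reverse strand. Each chromosome contributes a reference
#' path named after it, and each SNP contributes two single-node alternate
#' paths `alt_<chrom>_<pos>_0` (reference allele) and `alt_<chrom>_<pos>_1`
#' (alternative allele).
#'
#' @param reference Named character vector mapping chromosome name to its
#'   sequence (alphabet `A,C,G,T,N`), or a `Biostrings::DNAStringSet`.
#' @param snps Data frame with columns `chrom`, `pos` (1-based), `ref`, `alt`
#'   (single characters), or `NULL` for a SNP-free graph.
#' @return A `vg_graph` object: a list with tibbles `nodes` (`id`, `seq`),
#'   `edges` (`from`, `to`), `paths` (`name`, `step`, `node_id`,
#'   `is_reverse`), `snps` (the SNP table linking VCF coordinates to allele
#'   node IDs) and `contigs` (`chrom`, `length`).
#' @export
#' @examples
#' g <- vg_build(c(chr1 = "AAAATGCTT"),
#'               tibble::tibble(chrom = "chr1", pos = 7, ref = "C", alt = "T"))
#' g$nodes
vg_build <- function(reference, snps = NULL) {
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  if (is.null(names(reference)) || anyDuplicated(names(reference))) {
    abort("reference must be a named vector with unique chromosome names")
  }
  reference <- toupper(reference)
  check_dna(reference, "reference")
  if (any(nchar(reference) == 0)) abort("empty chromosome sequence")

  if (is.null(snps) || NROW(snps) == 0) {
    snps <- tibble(chrom = character(), pos = integer(),
                   ref = character(), alt = character())
  }
  snps <- as_tibble(snps)[, c("chrom", "pos", "ref", "alt")]
  snps$pos <- as.integer(snps$pos)
  validate_snp_input(reference, snps)

  next_id <- 1L
  nodes <- list(); edges <- list(); paths <- list(); recs <- list()
  for (chrom in names(reference)) {
    part <- build_chrom(chrom, reference[[chrom]],
                        dplyr::arrange(snps[snps$chrom == chrom, ], .data$pos),
                        next_id)
    nodes[[chrom]] <- part$nodes
    edges[[chrom]] <- part$edges
    paths[[chrom]] <- part$paths
    recs[[chrom]] <- part$snps
    next_id <- part$next_id
  }
  snp_table <- dplyr::bind_rows(recs)
  if (nrow(snp_table) == 0) {
    snp_table <- tibble(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        ref_node_id = integer(), alt_node_id = integer())
  }
  new_vg_graph(
    nodes = dplyr::bind_rows(nodes),
    edges = dplyr::bind_rows(edges),
    paths = dplyr::bind_rows(paths),
    snps = snp_table,
    contigs = tibble(chrom = names(reference),
                     length = unname(nchar(reference)))
  )
}

validate_snp_input <- function(reference, snps) {
  if (nrow(snps) == 0) return(invisible(snps))
  if (anyDuplicated(snps[, c("chrom", "pos")])) {
    d <- snps[duplicated(snps[, c("chrom", "pos")]), ]
    abort(sprintf("duplicate SNP position %s:%d", d$chrom[1], d$pos[1]))
  }
  bad_chrom <- !snps$chrom %in% names(reference)
  if (any(bad_chrom)) {
    abort(sprintf("SNP on unknown chromosome '%s'", snps$chrom[bad_chrom][1]))
  }
  if (any(nchar(snps$ref) != 1L) || any(nchar(snps$alt) != 1L)) {
    abort("SNP alleles must be single characters (biallelic SNPs only)")
  }
  if (any(snps$ref == snps$alt)) {
    abort("SNP ref and alt alleles must differ")
  }
  check_dna(snps$alt, "alt allele", allow_n = FALSE)
  for (i in seq_len(nrow(snps))) {
    chrom <- snps$chrom[i]; pos <- snps$pos[i]
    if (pos < 1L || pos > nchar(reference[[chrom]])) {
      abort(sprintf("SNP position out of range at %s:%d", chrom, pos))
    }
    base <- substr(reference[[chrom]], pos, pos)
    if (base == "N") {
      abort(sprintf("SNP at an N reference base at %s:%d", chrom, pos))
    }
    if (base != snps$ref[i]) {
      abort(sprintf(
        "reference base mismatch at %s:%d (reference has %s, catalog says %s)",
        chrom, pos, base, snps$ref[i]
      ))
    }
  }
  invisible(snps)
}

# split a reference run greedily into <= 32-character nodes
chunk_run <- function(seq) {
  n <- nchar(seq)
  starts <- seq.int(1L, n, by = 32L)
  substring(seq, starts, pmin(starts + 31L, n))
}

build_chrom <- function(chrom, seq, snps, next_id) {
  ids <- integer(); seqs <- character()
  efrom <- integer(); eto <- integer()
  chrom_path <- integer()
  alt_names <- character(); alt_nodes <- integer()
  rec <- vector("list", nrow(snps))

  open <- integer()  # node ids whose forward edges are still pending
  add_node <- function(s) {
    ids[[length(ids) + 1L]] <<- next_id
    seqs[[length(seqs) + 1L]] <<- s
    next_id <<- next_id + 1L
    ids[[length(ids)]]
  }
  connect <- function(to_id) {
    if (length(open)) {
      efrom <<- c(efrom, open)
      eto <<- c(eto, rep.int(to_id, length(open)))
    }
  }
  emit_run <- function(run) {
    for (piece in chunk_run(run)) {
      id <- add_node(piece)
      connect(id)
      open <<- id
      chrom_path[[length(chrom_path) + 1L]] <<- id
    }
  }

  cursor <- 1L
  for (i in seq_len(nrow(snps))) {
    pos <- snps$pos[i]
    if (pos > cursor) emit_run(substr(seq, cursor, pos - 1L))
    ref_id <- add_node(snps$ref[i])
    alt_id <- add_node(snps$alt[i])
    connect(ref_id); connect(alt_id)
    open <- c(ref_id, alt_id)
    chrom_path[[length(chrom_path) + 1L]] <- ref_id
    alt_names <- c(alt_names,
                   sprintf("alt_%s_%d_0", chrom, pos),
                   sprintf("alt_%s_%d_1", chrom, pos))
    alt_nodes <- c(alt_nodes, ref_id, alt_id)
    rec[[i]] <- tibble(chrom = chrom, pos = pos,
                       ref = snps$ref[i], alt = snps$alt[i],
                       ref_node_id = ref_id, alt_node_id = alt_id)
    cursor <- pos + 1L
  }
  if (cursor <= nchar(seq)) emit_run(substr(seq, cursor, nchar(seq)))

  list(
    nodes = tibble(id = ids, seq = seqs),
    edges = tibble(from = efrom, to = eto),
    paths = dplyr::bind_rows(
      tibble(name = chrom, step = seq_along(chrom_path),
             node_id = chrom_path, is_reverse = FALSE),
      tibble(name = alt_names, step = 1L,
             node_id = alt_nodes, is_reverse = FALSE)
    ),
    snps = dplyr::bind_rows(rec),
    next_id = next_id
  )
}

new_vg_graph <- function(nodes, edges, paths, snps, contigs) {
  nodes <- dplyr::arrange(as_tibble(nodes), .data$id)
  edges <- dplyr::arrange(as_tibble(edges), .data$from, .data$to)
  structure(
    list(nodes = nodes, edges = edges, paths = as_tibble(paths),
         snps = as_tibble(snps), contigs = as_tibble(contigs),
         edge_key = paste(edges$from, edges$to)),
    class = "vg_graph"
  )
}

#' @exportS3Method base::print
print.vg_graph <- function(x, ...) {
  cat(sprintf(
    "<vg_graph> %d nodes, %d edges, %d paths (%d alt), %d SNPs, %d contig(s)\n",
    nrow(x$nodes), nrow(x$edges), length(unique(x$paths$name)),
    sum(startsWith(unique(x$paths$name), "alt_")), nrow(x$snps),
    nrow(x$contigs)
  ))
  invisible(x)
}

# ids of all allele-carrying nodes
snp_node_ids <- function(graph) {
  c(graph$snps$ref_node_id, graph$snps$alt_node_id)
}

#' Neighbours of a node in a traversal orientation
#'
#' In forward orientation the one-step neighbours are the targets of the
#' node's outgoing edges (all with greater ID, by construction), returned in
#' ascending ID order. In reverse orientation they are the sources of its
#' incoming edges (lower IDs), in descending ID order — the order in which
#' the strand-directed aligner probes them.
#'
#' @param graph A `vg_graph`.
#' @param node_id Node identifier.
#' @param is_reverse Traversal orientation.
#' @return Tibble with columns `node_id` and `is_reverse`.
#' @export
vg_successors <- function(graph, node_id, is_reverse = FALSE) {
  if (!node_id %in% graph$nodes$id) {
    abort(sprintf("unknown node id: %s", node_id))
  }
  nb <- if (is_reverse) {
    sort(graph$edges$from[graph$edges$to == node_id], decreasing = TRUE)
  } else {
    sort(graph$edges$to[graph$edges$from == node_id])
  }
  tibble(node_id = as.integer(nb), is_reverse = rep(is_reverse, length(nb)))
}

#' Spell the sequence along a walk of oriented node intervals
#'
#' Concatenates the selected node subsequences; reverse-orientation steps use
#' the node's reverse complement, with the offset counted from the start of
#' the node in that orientation. Consecutive steps must be connected by a
#' graph edge consistent with their orientations.
#'
#' @param graph A `vg_graph`.
#' @param steps Data frame with columns `node_id`, `is_reverse`, `offset`
#'   (0-based) and `length`.
#' @param check Verify connectivity and bounds (disable only in tight loops
#'   over already-validated alignments).
#' @return A single character string.
#' @export
vg_spell <- function(graph, steps, check = TRUE) {
  steps <- as_tibble(steps)
  if (nrow(steps) == 0) return("")
  idx <- match(steps$node_id, graph$nodes$id)
  if (anyNA(idx)) abort("walk references a node not present in the graph")
  seqs <- graph$nodes$seq[idx]
  oriented <- ifelse(steps$is_reverse, revcomp(seqs), seqs)
  if (check) {
    if (any(steps$offset < 0 | steps$length < 0 |
              steps$offset + steps$length > nchar(oriented))) {
      abort("step offset/length outside node bounds")
    }
    if (nrow(steps) > 1) {
      a <- steps[-nrow(steps), ]; b <- steps[-1, ]
      if (any(a$is_reverse != b$is_reverse)) {
        abort("disconnected walk: orientation changes between steps")
      }
      key <- ifelse(a$is_reverse,
                    paste(b$node_id, a$node_id),
                    paste(a$node_id, b$node_id))
      if (!all(key %in% graph$edge_key)) {
        abort("disconnected walk: consecutive steps are not joined by an edge")
      }
    }
  }
  paste(substr(oriented, steps$offset + 1L, steps$offset + steps$length),
        collapse = "")
}

#' Spell a full path of the graph by name
#'
#' @param graph A `vg_graph`.
#' @param name Path name (a chromosome or an `alt_` path).
#' @return The concatenated sequence of the whole path.
#' @export
vg_spell_path <- function(graph, name) {
  p <- graph$paths[graph$paths$name == name, ]
  if (nrow(p) == 0) abort(sprintf("unknown path: %s", name))
  p <- dplyr::arrange(p, .data$step)
  len <- nchar(graph$nodes$seq[match(p$node_id, graph$nodes$id)])
  vg_spell(graph, tibble(node_id = p$node_id, is_reverse = p$is_reverse,
                         offset = 0L, length = len))
}

#' Check the structural invariants of a variation graph
#'
#' Returns one row per violated invariant: ID uniqueness, node length and
#' alphabet bounds, edge endpoints, forward-edge ID monotonicity (which also
#' rules out cycles), path connectivity, path coverage of every node, SNP
#' record consistency (allele nodes carry the recorded alleles) and the
#' diamond property (both allele nodes of a SNP share identical predecessor
#' and successor sets).
#'
#' @param graph A `vg_graph`.
#' @return Tibble with columns `invariant` and `detail`; zero rows when the
#'   graph is valid.
#' @export
vg_validate <- function(graph) {
  v <- list()
  bad <- function(invariant, detail) {
    v[[length(v) + 1L]] <<- tibble(invariant = invariant, detail = detail)
  }
  nodes <- graph$nodes; edges <- graph$edges; paths <- graph$paths

  if (anyDuplicated(nodes$id)) {
    bad("unique-node-ids", sprintf("duplicated id %d",
                                   nodes$id[duplicated(nodes$id)][1]))
  }
  n_len <- nchar(nodes$seq)
  if (any(n_len < 1 | n_len > 32)) {
    bad("node-length-bound", sprintf(
      "node %d has length %d (must be 1..32)",
      nodes$id[n_len < 1 | n_len > 32][1], n_len[n_len < 1 | n_len > 32][1]))
  }
  if (any(!grepl("^[ACGTN]+$", nodes$seq))) {
    bad("node-alphabet", sprintf(
      "node %d has characters outside {A,C,G,T,N}",
      nodes$id[!grepl("^[ACGTN]+$", nodes$seq)][1]))
  }
  missing_ep <- !(edges$from %in% nodes$id) | !(edges$to %in% nodes$id)
  if (any(missing_ep)) {
    bad("edge-endpoints", sprintf("edge %d->%d references a missing node",
                                  edges$from[missing_ep][1],
                                  edges$to[missing_ep][1]))
  }
  non_mono <- edges$from >= edges$to
  if (any(non_mono)) {
    bad("id-monotonicity", sprintf(
      "forward edge %d->%d does not increase the node id",
      edges$from[non_mono][1], edges$to[non_mono][1]))
  }
  off_path <- setdiff(nodes$id, paths$node_id)
  if (length(off_path)) {
    bad("node-on-path", sprintf("node %d lies on no path", off_path[1]))
  }
  for (nm in unique(paths$name)) {
    p <- dplyr::arrange(paths[paths$name == nm, ], .data$step)
    if (nrow(p) > 1) {
      a <- p[-nrow(p), ]; b <- p[-1, ]
      key <- ifelse(a$is_reverse, paste(b$node_id, a$node_id),
                    paste(a$node_id, b$node_id))
      broken <- !key %in% graph$edge_key | a$is_reverse != b$is_reverse
      if (any(broken)) {
        bad("path-connectivity", sprintf(
          "path %s: steps %d and %d are not joined by an edge",
          nm, a$node_id[broken][1], b$node_id[broken][1]))
      }
    }
  }
  for (i in seq_len(nrow(graph$snps))) {
    s <- graph$snps[i, ]
    rseq <- nodes$seq[match(s$ref_node_id, nodes$id)]
    aseq <- nodes$seq[match(s$alt_node_id, nodes$id)]
    if (is.na(rseq) || !identical(rseq, s$ref)) {
      bad("snp-record-consistency", sprintf(
        "SNP %s:%d: ref node %d does not carry allele %s",
        s$chrom, s$pos, s$ref_node_id, s$ref))
    }
    if (is.na(aseq) || !identical(aseq, s$alt)) {
      bad("snp-record-consistency", sprintf(
        "SNP %s:%d: alt node %d does not carry allele %s",
        s$chrom, s$pos, s$alt_node_id, s$alt))
    }
    pred_r <- sort(edges$from[edges$to == s$ref_node_id])
    pred_a <- sort(edges$from[edges$to == s$alt_node_id])
    succ_r <- sort(edges$to[edges$from == s$ref_node_id])
    succ_a <- sort(edges$to[edges$from == s$alt_node_id])
    if (!identical(pred_r, pred_a) || !identical(succ_r, succ_a)) {
      bad("snp-diamond", sprintf(
        "SNP %s:%d: allele nodes %d/%d differ in predecessors or successors",
        s$chrom, s$pos, s$ref_node_id, s$alt_node_id))
    }
  }
  alt_paths <- unique(paths$name[startsWith(paths$name, "alt_")])
  allele_nodes <- snp_node_ids(graph)
  off_alt <- setdiff(allele_nodes,
                     paths$node_id[startsWith(paths$name, "alt_")])
  if (length(off_alt)) {
    bad("allele-on-alt-path",
        sprintf("allele node %d lies on no alt_ path", off_alt[1]))
  }
  if (length(v)) dplyr::bind_rows(v) else {
    tibble(invariant = character(), detail = character())
  }
}

#' @rdname vg_validate
#' @export
#' @method glance vg_graph
glance.vg_graph <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_paths = length(unique(x$paths$name)), n_snps = nrow(x$snps),
    n_contigs = nrow(x$contigs),
    max_node_length = max(nchar(x$nodes$seq)),
    total_sequence = sum(nchar(x$nodes$seq))
  )
}

#' @export
#' @method tidy vg_graph
tidy.vg_graph <- function(x, ...) {
  allele <- rep("none", nrow(x$nodes))
  allele[x$nodes$id %in% x$snps$ref_node_id] <- "ref"
  allele[x$nodes$id %in% x$snps$alt_node_id] <- "alt"
  dplyr::mutate(x$nodes, length = nchar(.data$seq), allele = allele)
}
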
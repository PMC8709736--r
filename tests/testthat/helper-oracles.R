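# Fixtures and independent oracles shared across the suite. Oracles are
# deliberately naive R implementations, kept separate from the package's
# compiled search paths.

toy_graph <- function() {
  vg_build(c(chr1 = "AAAATGCTT"),
           tibble::tibble(chrom = "chr1", pos = 7L, ref = "C", alt = "T"))
}

# brute-force locate: scan every node sequence and its reverse complement
# for all occurrences of `pattern` that lie entirely within the node
oracle_locate <- function(graph, pattern) {
  k <- nchar(pattern)
  hits <- list()
  for (i in seq_len(nrow(graph$nodes))) {
    id <- graph$nodes$id[i]
    for (strand in c(FALSE, TRUE)) {
      s <- if (strand) revcomp(graph$nodes$seq[i]) else graph$nodes$seq[i]
      n <- nchar(s)
      if (n < k) next
      for (o in 0:(n - k)) {
        if (substr(s, o + 1, o + k) == pattern) {
          hits[[length(hits) + 1]] <- tibble::tibble(
            node_id = id, offset = o, is_reverse = strand, match_length = k)
        }
      }
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble::tibble(node_id = integer(), offset = integer(),
                          is_reverse = logical(), match_length = integer()))
  }
  dplyr::arrange(out, node_id, is_reverse, offset)
}

# all complete exact occurrences of `read` as oriented walks, by unbounded
# recursive search from every possible anchor position (tiny graphs only)
oracle_walks <- function(graph, read) {
  succ <- function(id, strand) {
    if (strand) sort(graph$edges$from[graph$edges$to == id], decreasing = TRUE)
    else sort(graph$edges$to[graph$edges$from == id])
  }
  node_seq <- function(id, strand) {
    s <- graph$nodes$seq[match(id, graph$nodes$id)]
    if (strand) revcomp(s) else s
  }
  out <- list()
  recurse <- function(steps, id, strand, pos) {
    if (pos > nchar(read)) {
      out[[length(out) + 1]] <<- steps
      return()
    }
    for (w in succ(id, strand)) {
      s <- node_seq(w, strand)
      m <- min(nchar(s), nchar(read) - pos + 1)
      if (substr(s, 1, m) == substr(read, pos, pos + m - 1)) {
        recurse(rbind(steps, c(w, strand, 0, m)), w, strand, pos + m)
      }
    }
  }
  for (i in seq_len(nrow(graph$nodes))) {
    id <- graph$nodes$id[i]
    for (strand in c(FALSE, TRUE)) {
      s <- node_seq(id, strand)
      for (o in 0:(nchar(s) - 1)) {
        m <- min(nchar(s) - o, nchar(read))
        if (substr(s, o + 1, o + m) == substr(read, 1, m)) {
          recurse(matrix(c(id, strand, o, m), nrow = 1), id, strand, 1 + m)
        }
      }
    }
  }
  lapply(out, function(m) {
    tibble::tibble(node_id = as.integer(m[, 1]), is_reverse = m[, 2] == 1,
                   offset = as.integer(m[, 3]), length = as.integer(m[, 4]))
  })
}

# small random graph generator used by property tests; sizes stay under
# 200 nodes
random_graph <- function(seed, min_len = 60, max_len = 1200) {
  withr::with_seed(seed, {
    len <- sample(min_len:max_len, 1)
    ref <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    n_snp <- sample(0:min(40, len %/% 10), 1)
    snps <- NULL
    if (n_snp > 0) {
      pos <- sort(sample.int(len, n_snp))
      refb <- substring(ref, pos, pos)
      altb <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     character(1), USE.NAMES = FALSE)
      snps <- tibble::tibble(chrom = "chr1", pos = pos, ref = refb, alt = altb)
    }
    list(reference = c(chr1 = ref), snps = snps,
         graph = vg_build(c(chr1 = ref), snps))
  })
}

# parse the simulator's truth-encoding read names
parse_read_names <- function(names) {
  parts <- strsplit(names, "_", fixed = TRUE)
  tibble::tibble(
    hap = as.integer(sub("^h", "", vapply(parts, `[`, character(1), 2))),
    chrom = vapply(parts, `[`, character(1), 3),
    start0 = as.integer(vapply(parts, `[`, character(1), 4)),
    strand = vapply(parts, `[`, character(1), 5)
  )
}

expect_same_hits <- function(got, want) {
  got <- dplyr::arrange(tibble::as_tibble(got), node_id,
                        is_reverse, offset)
  expect_equal(as.data.frame(got), as.data.frame(want),
               ignore_attr = TRUE)
}
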
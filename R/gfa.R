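#' Write a variation graph as GFA 1.0
#'
#' Emits `H`, `S` (segments), `L` (links, all with `0M` overlap) and `P`
#' (paths) lines. The SNP table is not a GFA concept; it is recovered on
#' reading from the `alt_<chrom>_<pos>_{0,1}` path naming convention, so the
#' round trip is lossless for graphs built by [vg_build()].
#'
#' @param graph A `vg_graph`.
#' @param path Output file (".gz" for compressed output), or `NULL` to
#'   return the lines invisibly.
#' @return The GFA lines, invisibly when written to a file.
#' @export
write_gfa <- function(graph, path = NULL) {
  lines <- "H\tVN:Z:1.0"
  if (nrow(graph$nodes)) {
    lines <- c(lines, sprintf("S\t%d\t%s", graph$nodes$id, graph$nodes$seq))
  }
  if (nrow(graph$edges)) {
    lines <- c(lines,
               sprintf("L\t%d\t+\t%d\t+\t0M", graph$edges$from, graph$edges$to))
  }
  for (nm in unique(graph$paths$name)) {
    p <- dplyr::arrange(graph$paths[graph$paths$name == nm, ], .data$step)
    steps <- paste0(p$node_id, ifelse(p$is_reverse, "-", "+"),
                    collapse = ",")
    lines <- c(lines, sprintf("P\t%s\t%s\t*", nm, steps))
  }
  if (is.null(path)) return(lines)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(lines)
}

#' Read a GFA 1.0 file into a variation graph
#'
#' Parses `S`, `L` and `P` lines (other record types are ignored) and
#' reconstructs the SNP table from paired `alt_<chrom>_<pos>_0` /
#' `alt_<chrom>_<pos>_1` single-node paths.
#'
#' @param path GFA file (gzip-transparent), or a character vector of GFA
#'   lines.
#' @return A `vg_graph`.
#' @export
read_gfa <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) {
    readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  } else {
    path
  }
  ids <- integer(); seqs <- character()
  efrom <- integer(); eto <- integer()
  pnames <- character(); psteps <- character()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (line == "" || startsWith(line, "H") || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (f[1] == "S") {
      if (length(f) < 3 || is.na(suppressWarnings(as.integer(f[2])))) {
        abort(sprintf("malformed GFA S line at line %d", i))
      }
      ids <- c(ids, as.integer(f[2])); seqs <- c(seqs, toupper(f[3]))
    } else if (f[1] == "L") {
      if (length(f) < 6 || f[3] != "+" || f[5] != "+") {
        abort(sprintf("malformed or unsupported GFA L line at line %d", i))
      }
      efrom <- c(efrom, as.integer(f[2])); eto <- c(eto, as.integer(f[4]))
    } else if (f[1] == "P") {
      if (length(f) < 3) abort(sprintf("malformed GFA P line at line %d", i))
      pnames <- c(pnames, f[2]); psteps <- c(psteps, f[3])
    }
  }
  paths <- purrr::map2(pnames, psteps, function(nm, st) {
    toks <- strsplit(st, ",", fixed = TRUE)[[1]]
    ori <- substr(toks, nchar(toks), nchar(toks))
    if (!all(ori %in% c("+", "-"))) {
      abort(sprintf("malformed path step in path %s", nm))
    }
    tibble(name = nm, step = seq_along(toks),
           node_id = as.integer(substr(toks, 1, nchar(toks) - 1L)),
           is_reverse = ori == "-")
  })
  paths <- if (length(paths)) dplyr::bind_rows(paths) else {
    tibble(name = character(), step = integer(), node_id = integer(),
           is_reverse = logical())
  }
  nodes <- tibble(id = ids, seq = seqs)
  graph <- new_vg_graph(
    nodes = nodes, edges = tibble(from = efrom, to = eto), paths = paths,
    snps = snps_from_alt_paths(nodes, paths),
    contigs = tibble(chrom = character(), length = integer())
  )
  ref_names <- setdiff(unique(paths$name),
                       unique(paths$name[startsWith(paths$name, "alt_")]))
  graph$contigs <- tibble(
    chrom = ref_names,
    length = vapply(ref_names, function(nm) nchar(vg_spell_path(graph, nm)),
                    integer(1), USE.NAMES = FALSE)
  )
  graph
}

# recover the SNP table from alt_<chrom>_<pos>_{0,1} single-node paths;
# <chrom> may itself contain underscores, so fields are split from the right
snps_from_alt_paths <- function(nodes, paths) {
  alt <- paths[startsWith(paths$name, "alt_"), ]
  if (nrow(alt) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), ref_node_id = integer(),
                  alt_node_id = integer()))
  }
  m <- regmatches(alt$name, regexec("^alt_(.*)_([0-9]+)_([01])$", alt$name))
  ok <- lengths(m) == 4
  if (!all(ok)) {
    abort(sprintf("unrecognised alt path name: %s", alt$name[!ok][1]))
  }
  info <- tibble(
    chrom = vapply(m, `[`, character(1), 2),
    pos = as.integer(vapply(m, `[`, character(1), 3)),
    allele = vapply(m, `[`, character(1), 4),
    node_id = alt$node_id
  )
  wide <- tidyr::pivot_wider(info, names_from = "allele",
                             values_from = "node_id", names_prefix = "a")
  if (!all(c("a0", "a1") %in% names(wide)) || anyNA(wide$a0) || anyNA(wide$a1)) {
    abort("alt paths do not pair into ref/alt alleles")
  }
  dplyr::arrange(tibble(
    chrom = wide$chrom, pos = wide$pos,
    ref = nodes$seq[match(wide$a0, nodes$id)],
    alt = nodes$seq[match(wide$a1, nodes$id)],
    ref_node_id = wide$a0, alt_node_id = wide$a1
  ), .data$chrom, .data$pos)
}
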
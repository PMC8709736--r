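test_that("toy construction produces the documented diamond layout", {
  g <- toy_graph()
  expect_equal(g$nodes$id, 1:4)
  expect_equal(g$nodes$seq, c("AAAATG", "C", "T", "TT"))
  expect_equal(as.data.frame(g$edges),
               data.frame(from = c(1L, 1L, 2L, 3L), to = c(2L, 3L, 4L, 4L)))
  chr1 <- dplyr::arrange(g$paths[g$paths$name == "chr1", ], step)
  expect_equal(chr1$node_id, c(1L, 2L, 4L))
  expect_false(any(chr1$is_reverse))
  expect_equal(as.data.frame(g$snps),
               data.frame(chrom = "chr1", pos = 7L, ref = "C", alt = "T",
                          ref_node_id = 2L, alt_node_id = 3L))
  # the ref allele node is on both the chromosome path and an alt path,
  # the alt allele node only on an alt path
  expect_setequal(g$paths$name[g$paths$node_id == 2],
                  c("chr1", "alt_chr1_7_0"))
  expect_equal(g$paths$name[g$paths$node_id == 3], "alt_chr1_7_1")
  expect_equal(vg_spell_path(g, "chr1"), "AAAATGCTT")
})

test_that("SNP-free reference is chunked at the 32-character node bound", {
  g <- vg_build(c(chr1 = strrep("A", 40)))
  expect_equal(g$nodes$seq, c(strrep("A", 32), strrep("A", 8)))
  expect_equal(nrow(g$edges), 1L)
  expect_false(any(startsWith(g$paths$name, "alt_")))
  expect_equal(vg_spell_path(g, "chr1"), strrep("A", 40))
})

test_that("SNPs at chromosome boundaries have one-sided diamonds", {
  g_end <- vg_build(c(chr1 = "AC"),
                    tibble::tibble(chrom = "chr1", pos = 2, ref = "C",
                                   alt = "G"))
  expect_equal(g_end$nodes$seq, c("A", "C", "G"))
  expect_equal(as.data.frame(g_end$edges),
               data.frame(from = c(1L, 1L), to = c(2L, 3L)))
  g_start <- vg_build(c(chr1 = "CA"),
                      tibble::tibble(chrom = "chr1", pos = 1, ref = "C",
                                     alt = "G"))
  expect_equal(g_start$nodes$seq, c("C", "G", "A"))
  expect_equal(as.data.frame(g_start$edges),
               data.frame(from = c(1L, 2L), to = c(3L, 3L)))
  expect_equal(nrow(vg_validate(g_end)), 0L)
  expect_equal(nrow(vg_validate(g_start)), 0L)
})

test_that("adjacent SNPs form directly connected diamonds", {
  g <- vg_build(c(chr1 = "GATC"),
                tibble::tibble(chrom = "chr1", pos = c(2, 3),
                               ref = c("A", "T"), alt = c("C", "G")))
  # nodes: G, A, C, T, G, C -> both alleles of site 1 feed both of site 2
  expect_true(all(paste(c(2, 2, 3, 3), c(4, 5, 4, 5)) %in%
                    paste(g$edges$from, g$edges$to)))
  expect_equal(nrow(vg_validate(g)), 0L)
})

test_that("every haplotype over the SNP subsets exists and spells correctly", {
  ref <- "TTGACGTACGTT"
  snps <- tibble::tibble(chrom = "chr1", pos = c(3, 4, 9),
                         ref = c("G", "A", "C"), alt = c("A", "G", "T"))
  g <- vg_build(c(chr1 = ref), snps)
  chr1 <- dplyr::arrange(g$paths[g$paths$name == "chr1", ], step)
  for (bits in 0:(2^nrow(snps) - 1)) {
    take_alt <- as.logical(bitwAnd(bits, 2^(seq_len(nrow(snps)) - 1)))
    steps <- chr1$node_id
    hap <- strsplit(ref, "")[[1]]
    for (k in which(take_alt)) {
      steps[steps == g$snps$ref_node_id[k]] <- g$snps$alt_node_id[k]
      hap[g$snps$pos[k]] <- g$snps$alt[k]
    }
    lens <- nchar(g$nodes$seq[match(steps, g$nodes$id)])
    spelled <- vg_spell(g, tibble::tibble(node_id = steps, is_reverse = FALSE,
                                          offset = 0L, length = lens))
    expect_equal(spelled, paste(hap, collapse = ""))
  }
})

test_that("construction rejects inconsistent input with informative errors", {
  ref <- c(chr1 = "AAAATGCTT")
  expect_error(vg_build(ref, tibble::tibble(chrom = "chr1", pos = 7,
                                            ref = "G", alt = "T")),
               "chr1:7")
  expect_error(vg_build(ref, tibble::tibble(chrom = "chr1", pos = c(7, 7),
                                            ref = c("C", "C"),
                                            alt = c("T", "G"))),
               "duplicate")
  expect_error(vg_build(ref, tibble::tibble(chrom = "chr1", pos = 99,
                                            ref = "C", alt = "T")),
               "out of range")
  expect_error(vg_build(ref, tibble::tibble(chrom = "chr2", pos = 1,
                                            ref = "A", alt = "T")),
               "unknown chromosome")
  expect_error(vg_build(c(chr1 = "AXGT")), "characters outside")
  expect_error(vg_build(c(chr1 = "ANGT"),
                        tibble::tibble(chrom = "chr1", pos = 2, ref = "N",
                                       alt = "T")),
               "N reference base")
  expect_error(vg_build(ref, tibble::tibble(chrom = "chr1", pos = 7,
                                            ref = "C", alt = "C")),
               "differ")
})

test_that("validate_graph reports violations as data, not errors", {
  g <- toy_graph()
  expect_equal(nrow(vg_validate(g)), 0L)

  g_cycle <- g
  g_cycle$edges <- dplyr::bind_rows(g_cycle$edges,
                                    tibble::tibble(from = 4L, to = 1L))
  v <- vg_validate(g_cycle)
  expect_true("id-monotonicity" %in% v$invariant)
  expect_match(v$detail[v$invariant == "id-monotonicity"], "4->1")

  g_bad <- g
  g_bad$nodes$seq[g_bad$nodes$id == 2] <- "G"
  v2 <- vg_validate(g_bad)
  expect_true("snp-record-consistency" %in% v2$invariant)

  g_orphan <- g
  g_orphan$nodes <- dplyr::bind_rows(g_orphan$nodes,
                                     tibble::tibble(id = 9L, seq = "A"))
  expect_true("node-on-path" %in% vg_validate(g_orphan)$invariant)
})

test_that("successors follow the strand-directed ID ordering", {
  g <- toy_graph()
  expect_equal(vg_successors(g, 1, FALSE)$node_id, c(2L, 3L))
  rev4 <- vg_successors(g, 4, TRUE)
  expect_equal(rev4$node_id, c(3L, 2L))  # descending, both reverse
  expect_true(all(rev4$is_reverse))
  expect_equal(nrow(vg_successors(g, 4, FALSE)), 0L)
  expect_error(vg_successors(g, 99), "unknown node")
})

test_that("spell follows orientations and rejects disconnected walks", {
  g <- toy_graph()
  expect_equal(vg_spell(g, tibble::tibble(
    node_id = c(1, 3, 4), is_reverse = FALSE, offset = c(3, 0, 0),
    length = c(3, 1, 1))), "ATGTT")
  expect_equal(vg_spell(g, tibble::tibble(
    node_id = 2, is_reverse = FALSE, offset = 0, length = 1)), "C")
  # reverse spelling of the SNP-covering read: reverse complement of "ATGTT"
  expect_equal(vg_spell(g, tibble::tibble(
    node_id = c(4, 3, 1), is_reverse = TRUE, offset = c(1, 0, 0),
    length = c(1, 1, 3))), "AACAT")
  expect_error(vg_spell(g, tibble::tibble(
    node_id = c(1, 4), is_reverse = FALSE, offset = 0, length = 1)),
    "disconnected")
  expect_error(vg_spell(g, tibble::tibble(
    node_id = 1, is_reverse = FALSE, offset = 4, length = 5)), "bounds")
})

test_that("random graphs validate and reconstruct their reference exactly", {
  for (seed in 1:20) {
    case <- random_graph(seed)
    expect_equal(nrow(vg_validate(case$graph)), 0L)
    expect_equal(vg_spell_path(case$graph, "chr1"), case$reference[["chr1"]])
    expect_lte(max(nchar(case$graph$nodes$seq)), 32L)
    expect_true(all(case$graph$edges$from < case$graph$edges$to))
  }
})
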
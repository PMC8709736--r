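mk_aln <- function(node_lists) {
  tibble::tibble(
    name = paste0("r", seq_along(node_lists)),
    sequence = "NNN",
    is_reverse = FALSE,
    covers_snp = TRUE,
    visited_nodes = 0L,
    steps = lapply(node_lists, function(ids) {
      tibble::tibble(node_id = as.integer(ids), is_reverse = FALSE,
                     offset = 0L, length = 1L)
    })
  )
}

test_that("snp_support counts allele-node traversals per site", {
  g <- toy_graph()
  aln <- mk_aln(list(c(1, 2, 4), c(1, 2, 4), c(1, 3, 4), c(3, 4)))
  s <- snp_support(aln, g)
  expect_equal(s$ref_count, 2L)
  expect_equal(s$alt_count, 2L)
  # alignments avoiding both allele nodes contribute nothing
  s2 <- snp_support(mk_aln(list(c(1, 4))), g)
  expect_equal(c(s2$ref_count, s2$alt_count), c(0L, 0L))
  s3 <- snp_support(mk_aln(list()), g)
  expect_equal(c(s3$ref_count, s3$alt_count), c(0L, 0L))
  expect_error(snp_support(mk_aln(list(c(1, 99))), g), "node id")
})

test_that("support counts agree with a brute-force recount on simulation", {
  cfg <- sim_config(genome_length = 1e4, snp_rate = 0.01, coverage = 8,
                    error_rate = 0, seed = 701)
  sim <- simulate_dataset(cfg)
  g <- vg_build(sim$reference, sim$panel)
  aln <- vg_map_reads(sim$reads, vg_index(g), quiet = TRUE)
  s <- snp_support(aln, g)
  for (i in seq_len(nrow(s))) {
    ref_n <- sum(vapply(aln$steps, function(st)
      s$ref_node_id[i] %in% st$node_id, logical(1)))
    alt_n <- sum(vapply(aln$steps, function(st)
      s$alt_node_id[i] %in% st$node_id, logical(1)))
    expect_equal(s$ref_count[i], ref_n)
    expect_equal(s$alt_count[i], alt_n)
  }
  # a single alignment never supports both alleles of one site
  expect_true(all(!vapply(aln$steps, function(st) {
    any(s$ref_node_id %in% st$node_id & s$alt_node_id %in% st$node_id)
  }, logical(1))))
})

test_that("threshold genotyping follows depth and allele-fraction rules", {
  sup <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L),
                        ref = "A", alt = "T",
                        ref_node_id = 1L, alt_node_id = 2L,
                        ref_count = c(2L, 0L, 1L, 1L, 10L),
                        alt_count = c(2L, 10L, 0L, 9L, 0L))
  calls <- call_genotypes(sup)
  expect_equal(calls$genotype, c("0/1", "1/1", "./.", "1/1", "0/0"))
  expect_equal(calls$ref_depth, sup$ref_count)
  # a stricter caller flips the boundary case
  calls95 <- call_genotypes(sup, genotyper_params(hom_threshold = 0.95))
  expect_equal(calls95$genotype[4], "0/1")
  expect_error(genotyper_params(hom_threshold = 0.5))
})

test_that("evaluation reproduces the hand-computed confusion fixture", {
  calls <- tibble::tibble(chrom = "chr1", pos = c(1L, 2L),
                          ref = c("A", "C"), alt = c("T", "G"),
                          genotype = c("0/1", "1/1"))
  truth <- tibble::tibble(chrom = "chr1", pos = c(1L, 2L, 3L),
                          ref = c("A", "C", "G"), alt = c("T", "G", "A"),
                          genotype = c("0/1", "0/1", "0/1"))
  ev <- evaluate_calls(calls, truth)
  expect_equal(c(ev$tp, ev$fp, ev$fn), c(1L, 1L, 2L))
  expect_equal(ev$precision, 0.5, tolerance = 1e-12)
  expect_equal(ev$sensitivity, 1 / 3, tolerance = 1e-12)
  expect_equal(ev$f_measure, 0.4, tolerance = 1e-12)
  expect_equal(sort(tidy(ev)$status), c("FN", "FN", "FP", "TP"))
})

test_that("evaluation edge cases: perfect calls, empty calls, duplicates", {
  truth <- tibble::tibble(chrom = "chr1", pos = 1:5, ref = "A", alt = "T",
                          genotype = rep(c("0/1", "1/1"), length.out = 5))
  perfect <- evaluate_calls(truth, truth)
  expect_equal(c(perfect$precision, perfect$sensitivity, perfect$f_measure),
               c(1, 1, 1))
  none <- evaluate_calls(truth[0, ], truth)
  expect_equal(c(none$precision, none$sensitivity, none$f_measure), c(0, 0, 0))
  expect_equal(none$fn, 5L)
  # 0/0 and ./. calls are never TP or FP
  quiet <- truth
  quiet$genotype <- "0/0"
  ev <- evaluate_calls(quiet, truth)
  expect_equal(c(ev$tp, ev$fp, ev$fn), c(0L, 0L, 5L))
  expect_error(evaluate_calls(truth[c(1, 1), ], truth), "duplicate call")
  expect_error(evaluate_calls(truth, truth[c(1, 1, 2), ]), "duplicate truth")
})

test_that("metrics match an independent recomputation on random call sets", {
  withr::with_seed(711, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      keys <- sample(1000, n)
      truth <- tibble::tibble(chrom = "chr1", pos = sort(keys), ref = "A",
                              alt = "T",
                              genotype = sample(c("0/1", "1/1"), n, TRUE))
      calls <- truth[sample(n, sample(n, 1)), ]
      flip <- runif(nrow(calls)) < 0.3
      calls$genotype[flip] <- ifelse(calls$genotype[flip] == "0/1", "1/1",
                                     "0/1")
      calls <- dplyr::arrange(calls, pos)
      ev <- evaluate_calls(calls, truth)
      # independent tally, record by record
      tp <- 0L; fp <- 0L
      for (i in seq_len(nrow(calls))) {
        j <- which(truth$pos == calls$pos[i])
        if (length(j) == 1 && truth$genotype[j] == calls$genotype[i]) {
          tp <- tp + 1L
        } else {
          fp <- fp + 1L
        }
      }
      fn <- nrow(truth) - tp
      expect_equal(c(ev$tp, ev$fp, ev$fn), c(tp, fp, fn))
      expect_equal(ev$tp + ev$fn, nrow(truth))
      p <- if (tp + fp) tp / (tp + fp) else 0
      r <- if (tp + fn) tp / (tp + fn) else 0
      f <- if (p + r) 2 * p * r / (p + r) else 0
      expect_equal(c(ev$precision, ev$sensitivity, ev$f_measure), c(p, r, f),
                   tolerance = 1e-12)
    }
  })
})

test_that("VCF round trip preserves keys, genotypes and depths", {
  withr::with_seed(721, {
    for (rep in 1:20) {
      n <- sample(1:30, 1)
      calls <- tibble::tibble(
        chrom = "chr1", pos = as.integer(sort(sample(1e4, n))),
        ref = sample(c("A", "C", "G", "T"), n, TRUE))
      calls$alt <- vapply(calls$ref, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
        USE.NAMES = FALSE)
      calls$ref_depth <- rbinom(n, 30, 0.5)
      calls$alt_depth <- rbinom(n, 30, 0.5)
      calls$genotype <- sample(c("0/0", "0/1", "1/1", "./."), n, TRUE)
      path <- withr::local_tempfile(fileext = ".vcf")
      write_vcf(calls, c(chr1 = 10000L), path)
      back <- read_truth_vcf(path)
      want <- calls[calls$genotype %in% c("0/1", "1/1"), ]
      expect_equal(as.data.frame(back),
                   as.data.frame(want[names(back)]))
    }
  })
})

test_that("VCF writing enforces sorting and handles the all-sites flag", {
  calls <- tibble::tibble(chrom = "chr1", pos = c(20L, 10L), ref = "A",
                          alt = "T", ref_depth = 2L, alt_depth = 2L,
                          genotype = "0/1")
  expect_error(write_vcf(calls, c(chr1 = 100L)), "sorted")
  sorted <- dplyr::arrange(calls, pos)
  lines <- write_vcf(sorted, c(chr1 = 100L))
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 2L)
  expect_match(body[1], "^chr1\t10\t\\.\tA\tT\t\\.\t\\.\t\\.\tGT:AD\t0/1:2,2$")
  # no-calls appear only under all_sites
  sorted$genotype <- "./."
  expect_equal(sum(!startsWith(write_vcf(sorted, c(chr1 = 100L)), "#")), 0L)
  expect_equal(sum(!startsWith(
    write_vcf(sorted, c(chr1 = 100L), all_sites = TRUE), "#")), 2L)
})

test_that("error-free simulation at deep coverage recovers genotypes", {
  cfg <- sim_config(genome_length = 3e4, snp_rate = 0.005, coverage = 20,
                    error_rate = 0, seed = 731)
  sim <- simulate_dataset(cfg)
  g <- vg_build(sim$reference, sim$panel)
  aln <- vg_map_reads(sim$reads, vg_index(g), printsnp = TRUE, quiet = TRUE)
  calls <- call_genotypes(snp_support(aln, g))
  truth <- sim$individual$truth
  m <- match(paste(truth$chrom, truth$pos), paste(calls$chrom, calls$pos))
  expect_gte(mean(calls$genotype[m] == truth$genotype), 0.99)
})
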
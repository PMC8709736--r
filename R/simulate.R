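#' Simulation configuration
#'
#' Describes a synthetic study: a random reference genome, a panel of
#' biallelic SNP sites with population alternative-allele frequencies, one
#' diploid individual drawn from the panel under Hardy–Weinberg equilibrium,
#' and single-end reads sampled from the individual's two haplotypes at a
#' target coverage with independent substitution errors. A single integer
#' seed drives everything; each stage derives its own fixed random stream
#' from it, so changing the read stage cannot perturb the panel.
#'
#' @param genome_length Total reference length in bases, split evenly across
#'   chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @param snp_rate Panel sites per reference base.
#' @param maf_range Range of the uniform alternative-allele-frequency
#'   sampler.
#' @param read_length Read length in bases.
#' @param coverage Mean sequencing depth (x).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return A `vg_sim_config` list.
#' @export
sim_config <- function(genome_length = 1e5, n_chromosomes = 1L,
                       snp_rate = 0.01, maf_range = c(0.05, 0.5),
                       read_length = 100L, coverage = 20, error_rate = 0,
                       seed = 1L) {
  stopifnot(genome_length >= 1, n_chromosomes >= 1,
            snp_rate >= 0, snp_rate <= 1,
            length(maf_range) == 2, maf_range[1] >= 0, maf_range[2] <= 1,
            maf_range[1] <= maf_range[2],
            read_length >= 2, coverage > 0,
            error_rate >= 0, error_rate <= 1,
            is.numeric(seed), abs(seed) < 2^31 - 1000)
  structure(list(genome_length = as.integer(genome_length),
                 n_chromosomes = as.integer(n_chromosomes),
                 snp_rate = snp_rate, maf_range = maf_range,
                 read_length = as.integer(read_length), coverage = coverage,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "vg_sim_config")
}

# fixed per-stage offsets deriving independent streams from the global seed
SIM_STREAMS <- c(reference = 101L, panel = 211L, individual = 307L,
                 reads = 401L)

with_stage_seed <- function(config, stage, code) {
  withr::with_seed(config$seed + SIM_STREAMS[[stage]], code)
}

#' Simulate a random reference genome
#'
#' I.i.d. uniform `A,C,G,T` sequence per chromosome, reproducible under the
#' config seed.
#'
#' @param config [sim_config()].
#' @return Named character vector, one sequence per chromosome
#'   (`chr1`, `chr2`, ...).
#' @export
simulate_reference <- function(config) {
  lens <- chrom_lengths(config)
  with_stage_seed(config, "reference", {
    setNames(vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1)), paste0("chr", seq_along(lens)))
  })
}

chrom_lengths <- function(config) {
  n <- config$n_chromosomes
  base <- config$genome_length %/% n
  lens <- rep(base, n)
  lens[n] <- lens[n] + config$genome_length %% n
  lens
}

#' Simulate a biallelic SNP panel
#'
#' Sites are sampled without replacement at distinct positions (the panel
#' analogue of a population SNP catalog), the reference allele is read from
#' the reference, the alternative allele is uniform over the other three
#' bases, and each site receives a population alternative-allele frequency
#' drawn uniformly from `maf_range`.
#'
#' @param reference Named character vector from [simulate_reference()].
#' @param config [sim_config()].
#' @return Panel tibble: `chrom`, `pos`, `ref`, `alt`, `af`, sorted by
#'   position.
#' @export
simulate_snp_panel <- function(reference, config) {
  with_stage_seed(config, "panel", {
    panels <- lapply(names(reference), function(chrom) {
      L <- nchar(reference[[chrom]])
      n_sites <- round(config$snp_rate * L)
      if (n_sites > L) abort("snp_rate requests more sites than positions")
      if (n_sites == 0) {
        return(tibble(chrom = character(), pos = integer(),
                      ref = character(), alt = character(), af = double()))
      }
      pos <- sort(sample.int(L, n_sites))
      ref <- substring(reference[[chrom]], pos, pos)
      alt <- vapply(ref, function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1), USE.NAMES = FALSE)
      tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
             af = runif(n_sites, config$maf_range[1], config$maf_range[2]))
    })
    dplyr::bind_rows(panels)
  })
}

#' Simulate a diploid individual from a panel
#'
#' Per site the genotype is drawn from Hardy–Weinberg proportions of the
#' site's alternative-allele frequency; heterozygous alternative alleles are
#' placed on a random haplotype. The two haplotypes per chromosome are the
#' reference with the carried alleles substituted in.
#'
#' @param panel Panel tibble from [simulate_snp_panel()].
#' @param reference The reference the panel was drawn from.
#' @param config [sim_config()].
#' @return A `vg_individual` list: `genotypes` (per-site tibble with a
#'   `genotype` column), `truth` (the non-reference subset — the validation
#'   gold standard), and `haplotypes` (per chromosome, two sequences).
#' @export
simulate_individual <- function(panel, reference, config) {
  with_stage_seed(config, "individual", {
    q <- panel$af
    u <- runif(nrow(panel))
    genotype <- ifelse(u < (1 - q)^2, "0/0",
                       ifelse(u < (1 - q)^2 + 2 * q * (1 - q), "0/1", "1/1"))
    hap_of_het <- sample(1:2, nrow(panel), replace = TRUE)
    genotypes <- dplyr::mutate(panel, genotype = genotype)
    haplotypes <- lapply(names(reference), function(chrom) {
      sel <- genotypes$chrom == chrom
      build_haplotypes(reference[[chrom]], genotypes[sel, ], hap_of_het[sel])
    })
    names(haplotypes) <- names(reference)
    structure(list(genotypes = genotypes,
                   truth = genotypes[genotypes$genotype != "0/0",
                                     c("chrom", "pos", "ref", "alt",
                                       "genotype")],
                   haplotypes = haplotypes),
              class = "vg_individual")
  })
}

build_haplotypes <- function(seq, sites, hap_of_het) {
  h <- list(strsplit(seq, "", fixed = TRUE)[[1]],
            strsplit(seq, "", fixed = TRUE)[[1]])
  hom <- sites$genotype == "1/1"
  het <- sites$genotype == "0/1"
  for (k in 1:2) {
    carrier <- hom | (het & hap_of_het == k)
    h[[k]][sites$pos[carrier]] <- sites$alt[carrier]
  }
  c(paste(h[[1]], collapse = ""), paste(h[[2]], collapse = ""))
}

#' @exportS3Method base::print
print.vg_individual <- function(x, ...) {
  cat(sprintf("<vg_individual> %d panel sites (%d non-reference), %d chromosome(s)\n",
              nrow(x$genotypes), nrow(x$truth), length(x$haplotypes)))
  invisible(x)
}

#' Simulate reads from a diploid individual
#'
#' Emits `ceiling(coverage * genome_length / read_length)` single-end reads,
#' alternating between the two haplotypes, with uniform start positions,
#' uniform strand (reverse-complemented on the reverse strand) and i.i.d.
#' per-base substitution errors at `error_rate`. Read names encode the truth
#' placement as `r<i>_h<hap>_<chrom>_<start0>_<strand>` (0-based start on
#' the haplotype), which aligner tests use as ground truth. Qualities are a
#' constant string (the exact matcher ignores them).
#'
#' @param individual [simulate_individual()] output.
#' @param config [sim_config()].
#' @return Reads tibble: `name`, `seq`, `qual`.
#' @export
simulate_reads <- function(individual, config) {
  lens <- vapply(individual$haplotypes, function(h) nchar(h[1]), integer(1))
  if (config$read_length > min(lens)) {
    abort("read_length exceeds a chromosome length")
  }
  n_reads <- as.integer(ceiling(config$coverage * sum(lens) /
                                  config$read_length))
  rl <- config$read_length
  with_stage_seed(config, "reads", {
    hap <- rep_len(1:2, n_reads)
    chrom <- names(lens)[sample.int(length(lens), n_reads, replace = TRUE,
                                    prob = lens)]
    start0 <- floor(runif(n_reads) * (lens[chrom] - rl + 1))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- character(n_reads)
    for (cn in unique(chrom)) {
      for (k in 1:2) {
        sel <- chrom == cn & hap == k
        seqs[sel] <- substring(individual$haplotypes[[cn]][k],
                               start0[sel] + 1, start0[sel] + rl)
      }
    }
    seqs <- inject_errors(seqs, config$error_rate)
    rev <- strand == "-"
    seqs[rev] <- revcomp(seqs[rev])
    tibble(
      name = sprintf("r%d_h%d_%s_%d_%s", seq_len(n_reads), hap, chrom,
                     as.integer(start0), strand),
      seq = seqs,
      qual = strrep("I", rl)
    )
  })
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  rl <- nchar(seqs[1])
  n_err <- rbinom(length(seqs), rl, rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(rl, n_err[i])
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    chars[pos] <- vapply(chars[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1), USE.NAMES = FALSE)
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate a complete dataset and optionally write it to disk
#'
#' Convenience wrapper chaining [simulate_reference()],
#' [simulate_snp_panel()], [simulate_individual()] and [simulate_reads()].
#' With `prefix`, writes `<prefix>.ref.fa`, `<prefix>.panel.vcf`,
#' `<prefix>.truth.vcf` and `<prefix>.reads.fq`.
#'
#' @param config [sim_config()].
#' @param prefix Output path prefix, or `NULL` to skip writing.
#' @return List with `reference`, `panel`, `individual`, `reads` (and
#'   `files` when written).
#' @export
simulate_dataset <- function(config, prefix = NULL) {
  reference <- simulate_reference(config)
  panel <- simulate_snp_panel(reference, config)
  individual <- simulate_individual(panel, reference, config)
  reads <- simulate_reads(individual, config)
  out <- list(reference = reference, panel = panel, individual = individual,
              reads = reads)
  if (!is.null(prefix)) {
    contigs <- tibble(chrom = names(reference),
                      length = unname(nchar(reference)))
    files <- c(reference = paste0(prefix, ".ref.fa"),
               panel = paste0(prefix, ".panel.vcf"),
               truth = paste0(prefix, ".truth.vcf"),
               reads = paste0(prefix, ".reads.fq"))
    write_fasta(reference, files[["reference"]])
    write_panel_vcf(panel, contigs, files[["panel"]])
    write_vcf(individual$truth, contigs, files[["truth"]])
    write_fastq(reads, files[["reads"]])
    out$files <- files
  }
  out
}
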
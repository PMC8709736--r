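#' Genotyper parameters
#'
#' A deliberately simple allele-depth threshold caller: sites with fewer than
#' `min_depth` covering alignments are no-calls (`./.`); an alt-allele
#' fraction at or above `hom_threshold` calls a homozygous alternative
#' (`1/1`), at or below `1 - hom_threshold` a homozygous reference (`0/0`),
#' and anything in between a heterozygote (`0/1`). The default
#' `hom_threshold = 0.9` keeps heterozygote miscalls below one per thousand
#' sites at 20x error-free coverage (binomial tail of depth-20 sampling);
#' see the methods vignette for the calibration.
#'
#' @param min_depth Minimum total allele depth for a call.
#' @param hom_threshold Homozygosity threshold on the allele fraction, in
#'   (0.5, 1].
#' @return A `vg_genotyper_params` list.
#' @export
genotyper_params <- function(min_depth = 2L, hom_threshold = 0.9) {
  stopifnot(min_depth >= 1, hom_threshold > 0.5, hom_threshold <= 1)
  structure(list(min_depth = as.integer(min_depth),
                 hom_threshold = hom_threshold),
            class = "vg_genotyper_params")
}

#' Count allele-supporting alignments per SNP site
#'
#' An alignment supports the reference allele of a site when its walk
#' traverses the site's reference-allele node, and the alternative allele
#' when it traverses the alternative-allele node; the two nodes are parallel,
#' so one alignment increments at most one counter per site. A read spanning
#' several SNPs contributes to each of them independently.
#'
#' @param alignments Alignments tibble from [vg_map_reads()].
#' @param graph A `vg_graph` (source of the SNP table), or the SNP table
#'   tibble itself.
#' @return Tibble with one row per SNP: the SNP-table columns plus
#'   `ref_count` and `alt_count`.
#' @export
snp_support <- function(alignments, graph) {
  snps <- if (inherits(graph, "vg_graph")) graph$snps else as_tibble(graph)
  node_ids <- unlist(lapply(alignments$steps, `[[`, "node_id"),
                     use.names = FALSE)
  if (inherits(graph, "vg_graph") && length(node_ids) &&
        !all(node_ids %in% graph$nodes$id)) {
    abort("alignment references a node id not present in the graph")
  }
  counts <- table(node_ids)
  lookup <- function(ids) {
    out <- as.integer(counts[as.character(ids)])
    out[is.na(out)] <- 0L
    out
  }
  dplyr::mutate(snps, ref_count = lookup(snps$ref_node_id),
                alt_count = lookup(snps$alt_node_id))
}

#' Call diploid genotypes from per-site allele support
#'
#' @param support Tibble from [snp_support()].
#' @param params [genotyper_params()].
#' @return Tibble of genotype calls: `chrom`, `pos`, `ref`, `alt`,
#'   `ref_depth`, `alt_depth`, `genotype` (one of `0/0`, `0/1`, `1/1`,
#'   `./.`).
#' @export
call_genotypes <- function(support, params = genotyper_params()) {
  support <- as_tibble(support)
  total <- support$ref_count + support$alt_count
  frac <- ifelse(total > 0, support$alt_count / total, 0)
  genotype <- dplyr::case_when(
    total < params$min_depth ~ "./.",
    frac >= params$hom_threshold ~ "1/1",
    frac <= 1 - params$hom_threshold ~ "0/0",
    TRUE ~ "0/1"
  )
  tibble(chrom = support$chrom, pos = support$pos, ref = support$ref,
         alt = support$alt, ref_depth = support$ref_count,
         alt_depth = support$alt_count, genotype = genotype)
}

#' Score genotype calls against a truth set
#'
#' Genotype-aware matching keyed by (`chrom`, `pos`, `ref`, `alt`): a
#' non-reference call (`0/1` or `1/1`) is a true positive iff a truth record
#' at the same key carries the identical genotype, and a false positive
#' otherwise; truth records left without a matching true positive are false
#' negatives. `0/0` and `./.` calls are never counted. Precision is
#' `tp/(tp+fp)`, sensitivity `tp/(tp+fn)` (each 0 when its denominator is 0)
#' and the F-measure their harmonic mean.
#'
#' @param calls Calls tibble (needs `chrom`, `pos`, `ref`, `alt`,
#'   `genotype`).
#' @param truth Truth tibble with the same key columns and `genotype`
#'   (non-reference records).
#' @return A `vg_eval` object; see [glance.vg_eval()] and [tidy.vg_eval()].
#' @export
evaluate_calls <- function(calls, truth) {
  calls <- as_tibble(calls); truth <- as_tibble(truth)
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  if (anyDuplicated(key(calls))) abort("duplicate call site keys")
  truth <- truth[truth$genotype %in% c("0/1", "1/1"), ]
  if (anyDuplicated(key(truth))) abort("duplicate truth site keys")

  nonref <- calls[calls$genotype %in% c("0/1", "1/1"), ]
  m <- match(key(nonref), key(truth))
  is_tp <- !is.na(m) & nonref$genotype == truth$genotype[m]
  tp <- sum(is_tp); fp <- nrow(nonref) - tp
  matched_truth <- unique(m[is_tp])
  fn <- nrow(truth) - length(matched_truth)

  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else 0
  f_measure <- if (precision + sensitivity > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else 0

  sites <- dplyr::bind_rows(
    tibble(chrom = nonref$chrom, pos = nonref$pos, ref = nonref$ref,
           alt = nonref$alt, call_genotype = nonref$genotype,
           truth_genotype = truth$genotype[m],
           status = c("FP", "TP")[is_tp + 1L]),
    {
      fn_rows <- truth[setdiff(seq_len(nrow(truth)), matched_truth), ]
      tibble(chrom = fn_rows$chrom, pos = fn_rows$pos, ref = fn_rows$ref,
             alt = fn_rows$alt, call_genotype = NA_character_,
             truth_genotype = fn_rows$genotype, status = "FN")
    }
  )
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 sensitivity = sensitivity, f_measure = f_measure,
                 sites = sites),
            class = "vg_eval")
}

#' @exportS3Method base::print
print.vg_eval <- function(x, ...) {
  cat(sprintf(
    "<vg_eval> TP %d  FP %d  FN %d | precision %.4f  sensitivity %.4f  F %.4f\n",
    x$tp, x$fp, x$fn, x$precision, x$sensitivity, x$f_measure))
  invisible(x)
}

#' One-row summary of an evaluation
#'
#' @param x A `vg_eval`.
#' @param ... Unused.
#' @return Tibble with `tp`, `fp`, `fn`, `precision`, `sensitivity`,
#'   `f_measure`.
#' @export
#' @method glance vg_eval
glance.vg_eval <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn, precision = x$precision,
         sensitivity = x$sensitivity, f_measure = x$f_measure)
}

#' Per-site classification of an evaluation
#'
#' @param x A `vg_eval`.
#' @param ... Unused.
#' @return Tibble with one row per classified site and its TP/FP/FN status.
#' @export
#' @method tidy vg_eval
tidy.vg_eval <- function(x, ...) x$sites
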
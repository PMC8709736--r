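#' Read a FASTA file
#'
#' @param path FASTA file (gzip-transparent).
#' @return Named character vector of upper-case sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) warning(sprintf("empty FASTA file: %s", path))
  setNames(toupper(as.character(x)), sub("\\s.*", "", names(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file (".gz" compresses).
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (gzip-transparent).
#' @return Reads tibble with columns `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  if (length(x) == 0) warning(sprintf("empty FASTQ file: %s", path))
  tibble(name = names(x), seq = unname(toupper(as.character(x))),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Write reads to FASTQ
#'
#' @param reads Reads tibble (`name`, `seq`, `qual`).
#' @param path Output file (".gz" compresses).
#' @export
write_fastq <- function(reads, path) {
  reads <- as_reads_tbl(reads)
  seqs <- Biostrings::DNAStringSet(setNames(reads$seq, reads$name))
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read the biallelic SNPs of a VCF file
#'
#' Keeps only biallelic SNP records (single-character REF, a single
#' single-character ALT); indels and multiallelic sites are counted and
#' reported via `message()` and the `"skipped"` attribute.
#'
#' @param path VCF file (gzip-transparent).
#' @param quiet Suppress the skip-count message.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt` and, when an `AF` INFO
#'   field is present, `af`.
#' @export
read_vcf_snps <- function(path, quiet = FALSE) {
  if (vcf_body_count(path) == 0) {
    warning(sprintf("VCF file has no records: %s", path))
    out <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character())
    attr(out, "skipped") <- 0L
    return(out)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1 & !is.na(fix$ALT) & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  skipped <- sum(!keep)
  if (skipped > 0 && !quiet) {
    message(sprintf("skipped %d non-SNP/multiallelic record(s) in %s",
                    skipped, path))
  }
  out <- tibble(chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
                ref = fix$REF[keep], alt = fix$ALT[keep])
  af <- sub(".*(?:^|;)AF=([0-9.eE+-]+).*", "\\1", fix$INFO[keep])
  if (!all(is.na(fix$INFO[keep])) && !identical(af, fix$INFO[keep])) {
    out$af <- suppressWarnings(as.numeric(af))
  }
  attr(out, "skipped") <- skipped
  out
}

vcf_body_count <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  sum(!startsWith(lines, "#") & lines != "")
}

vcf_header <- function(contigs, sample = NULL, format = TRUE) {
  contigs <- as_contigs(contigs)
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contigs$chrom, contigs$length),
    if (format) c(
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">"),
    if (is.null(sample)) "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (!is.null(sample)) c("FORMAT", sample)), collapse = "\t"))
}

as_contigs <- function(contigs) {
  if (is.numeric(contigs) && !is.null(names(contigs))) {
    return(tibble(chrom = names(contigs), length = as.integer(contigs)))
  }
  as_tibble(contigs)
}

#' Write genotype calls as VCF 4.2
#'
#' Emits one sample with `GT` and `AD` FORMAT fields (GT only if the calls
#' carry no depths). By default only non-reference calls are written; with
#' `all_sites = TRUE` homozygous-reference and no-call sites are kept too.
#'
#' @param calls Calls tibble from [call_genotypes()] (or any tibble with
#'   `chrom`, `pos`, `ref`, `alt`, `genotype`), sorted by contig then
#'   position.
#' @param contigs Contig table (`chrom`, `length`) or named length vector.
#' @param path Output file, or `NULL` to return the lines.
#' @param sample_name Sample column name.
#' @param all_sites Also write `0/0` and `./.` records.
#' @return The VCF lines, invisibly when written to a file.
#' @export
write_vcf <- function(calls, contigs, path = NULL, sample_name = "SAMPLE",
                      all_sites = FALSE) {
  calls <- as_tibble(calls)
  contigs <- as_contigs(contigs)
  ord <- order(match(calls$chrom, contigs$chrom), calls$pos)
  if (!identical(ord, seq_len(nrow(calls)))) {
    abort("calls must be sorted by contig and position")
  }
  if (!all_sites) calls <- calls[calls$genotype %in% c("0/1", "1/1"), ]
  has_ad <- all(c("ref_depth", "alt_depth") %in% names(calls))
  lines <- vcf_header(contigs, sample = sample_name)
  if (nrow(calls)) {
    sample_field <- if (has_ad) {
      sprintf("%s:%d,%d", calls$genotype, calls$ref_depth, calls$alt_depth)
    } else {
      calls$genotype
    }
    lines <- c(lines, sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t.\t.\t%s\t%s",
      calls$chrom, calls$pos, calls$ref, calls$alt,
      if (has_ad) "GT:AD" else "GT", sample_field))
  }
  if (is.null(path)) return(lines)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(lines)
}

#' Write an SNP panel (sites-only VCF with allele frequencies)
#'
#' @param panel Panel tibble (`chrom`, `pos`, `ref`, `alt`, optional `af`).
#' @param contigs Contig table or named length vector.
#' @param path Output file, or `NULL` to return the lines.
#' @return The VCF lines, invisibly when written to a file.
#' @export
write_panel_vcf <- function(panel, contigs, path = NULL) {
  panel <- as_tibble(panel)
  info <- if ("af" %in% names(panel)) sprintf("AF=%g", panel$af) else "."
  lines <- c(vcf_header(as_contigs(contigs), format = FALSE),
             if (nrow(panel)) sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                                      panel$chrom, panel$pos, panel$ref,
                                      panel$alt, info))
  if (is.null(path)) return(lines)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(lines)
}

#' Read genotypes from a single-sample VCF
#'
#' Used both for truth sets and for re-reading calls. Genotypes are
#' normalised to unphased, sorted form (`1|0` becomes `0/1`); only biallelic
#' SNP records are kept.
#'
#' @param path VCF file (gzip-transparent).
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `genotype` and, when an
#'   `AD` field is present, `ref_depth`/`alt_depth`.
#' @export
read_truth_vcf <- function(path) {
  if (vcf_body_count(path) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), genotype = character()))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1 & !is.na(fix$ALT) & nchar(fix$ALT) == 1
  gt <- vcfR::extract.gt(v, element = "GT")[keep, 1]
  out <- tibble(chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
                ref = fix$REF[keep], alt = fix$ALT[keep],
                genotype = normalise_gt(gt))
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD")[keep, 1],
                 error = function(e) NULL)
  if (!is.null(ad) && !all(is.na(ad))) {
    parts <- strsplit(ad, ",", fixed = TRUE)
    out$ref_depth <- as.integer(vapply(parts, `[`, character(1), 1))
    out$alt_depth <- as.integer(vapply(parts, `[`, character(1), 2))
  }
  out
}

normalise_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  vapply(gt, function(g) {
    if (is.na(g) || g %in% c("./.", ".")) return("./.")
    paste(sort(strsplit(g, "/", fixed = TRUE)[[1]]), collapse = "/")
  }, character(1), USE.NAMES = FALSE)
}

#' Write alignments as newline-delimited GAM-style JSON
#'
#' One JSON record per mapped read, in the graph-alignment dialect: a `path`
#' with ordered `mapping` entries, each holding a `position` (`node_id`,
#' `offset`, `is_reverse`) and an `edit` list whose `from_length` equals
#' `to_length` (exact matches only), plus `identity` (always 1 for exact
#' alignments) and the SNP-coverage flag.
#'
#' @param alignments Alignments tibble from [vg_map_reads()].
#' @param path Output file (".gz" compresses), or `NULL` to return lines.
#' @return The JSON lines, invisibly when written to a file.
#' @export
write_alignments_json <- function(alignments, path = NULL) {
  lines <- vapply(seq_len(nrow(alignments)), function(i) {
    st <- alignments$steps[[i]]
    mapping <- lapply(seq_len(nrow(st)), function(j) {
      list(position = list(node_id = st$node_id[j], offset = st$offset[j],
                           is_reverse = st$is_reverse[j]),
           edit = list(list(from_length = st$length[j],
                            to_length = st$length[j])),
           rank = j)
    })
    jsonlite::toJSON(
      list(name = alignments$name[i], sequence = alignments$sequence[i],
           identity = 1, covers_snp = alignments$covers_snp[i],
           path = list(mapping = mapping)),
      auto_unbox = TRUE)
  }, character(1))
  if (is.null(path)) return(lines)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(lines)
}

#' Read newline-delimited GAM-style JSON alignments
#'
#' @param path JSON-lines file (gzip-transparent), or a character vector of
#'   JSON lines.
#' @return Alignments tibble; `visited_nodes` is not serialised and comes
#'   back as `NA` (it is a search diagnostic, not part of the alignment).
#' @export
read_alignments_json <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) {
    readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  } else {
    path
  }
  lines <- lines[lines != ""]
  recs <- lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
             error = function(e) {
               abort(sprintf("malformed JSON alignment at line %d: %s", i,
                             conditionMessage(e)))
             })
  })
  steps <- lapply(recs, function(r) {
    m <- r$path$mapping
    new_tibble(list(
      node_id = vapply(m, function(x) as.integer(x$position$node_id),
                       integer(1)),
      is_reverse = vapply(m, function(x) isTRUE(x$position$is_reverse),
                          logical(1)),
      offset = vapply(m, function(x) as.integer(x$position$offset %||% 0L),
                      integer(1)),
      length = vapply(m, function(x) as.integer(x$edit[[1]]$to_length),
                      integer(1))
    ), nrow = length(m))
  })
  new_tibble(list(
    name = vapply(recs, function(r) r$name, character(1)),
    sequence = vapply(recs, function(r) r$sequence, character(1)),
    is_reverse = vapply(steps, function(s) isTRUE(s$is_reverse[1]),
                        logical(1)),
    covers_snp = vapply(recs, function(r) isTRUE(r$covers_snp), logical(1)),
    visited_nodes = rep(NA_integer_, length(recs)),
    steps = steps
  ), nrow = length(recs))
}
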
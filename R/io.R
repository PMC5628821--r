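#' Write the simulated reference as FASTA
#'
#' @param panel A `sim_panel`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(panel, path) {
  seqs <- Biostrings::DNAStringSet(panel$reference)
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Write one multi-sample VCF per breed
#'
#' Emits minimal but valid VCFv4.2: `CHROM POS ID REF ALT QUAL FILTER INFO
#' FORMAT` plus per-sample `GT` columns, QUAL populated from the simulated
#' site quality. One file per breed, named `<breed>.vcf`.
#'
#' @param panel A `sim_panel`.
#' @param genotypes A `sim_genotypes` for the same panel.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_breed_vcfs <- function(panel, genotypes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sites <- panel$sites
  gt_code <- c("0/0", "0/1", "1/1")
  paths <- c()
  for (breed in unique(genotypes$samples$breed)) {
    ids <- genotypes$samples$id[genotypes$samples$breed == breed]
    d <- genotypes$dosage[, ids, drop = FALSE]
    gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
    ok <- !is.na(d)
    gt[ok] <- gt_code[d[ok] + 1L]
    header <- c(
      "##fileformat=VCFv4.2",
      sprintf("##contig=<ID=%s,length=%d>", names(panel$reference),
              nchar(panel$reference)),
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", ids), collapse = "\t")
    )
    body <- paste(
      sites$chrom, sites$pos, sprintf("%s_%d", sites$chrom, sites$pos),
      sites$ref, sites$alt, sites$qual, "PASS", ".", "GT",
      apply(gt, 1L, paste, collapse = "\t"),
      sep = "\t"
    )
    path <- file.path(dir, paste0(breed, ".vcf"))
    writeLines(c(header, body), path)
    paths[breed] <- path
  }
  paths
}

#' Write a genotype call matrix as TSV
#'
#' Samples in rows, probesets/SNPs in columns, calls in
#' `{AA, AB, BB, NoCall}` (`AA` = homozygous reference).
#'
#' @param calls Character call matrix (samples x probesets), or a
#'   `sim_genotypes` object (transposed and recoded automatically).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(calls, path) {
  if (inherits(calls, "sim_genotypes")) {
    calls <- dosage_to_calls(t(calls$dosage))
  }
  df <- data.frame(sample = rownames(calls), calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype call matrix written by [write_genotype_tsv()]
#' @param path TSV path.
#' @return Character matrix samples x probesets.
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write pedigree / phenotype tables as TSV
#'
#' @param study A `sim_study`.
#' @param dir Output directory.
#' @return Named vector of paths (`pedigree`, `phenotypes`).
#' @export
write_study_tsvs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped_path <- file.path(dir, "pedigree.tsv")
  phe_path <- file.path(dir, "phenotypes.tsv")
  utils::write.table(study$pedigree, ped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$phenotypes, phe_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(pedigree = ped_path, phenotypes = phe_path)
}
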
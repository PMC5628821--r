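# minimal hand-written VCF fixture built in code
write_test_vcf <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "test.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    lines
  ), path)
  path
}

test_that("load_sites keeps biallelic SNVs and logs the rest", {
  path <- write_test_vcf(c(
    "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t200\t.\tC\tT\t60\tPASS\t.\tGT\t1/1\t0/1",
    "chr1\t300\t.\tG\tGA\t70\tPASS\t.\tGT\t0/0\t0/0",   # indel
    "chr1\t400\t.\tT\tA,C\t80\tPASS\t.\tGT\t0/1\t0/2",  # multiallelic
    "chr1\t500\t.\tA\tC\t90\tPASS\t.\tGT\t./.\t0/1"
  ))
  s <- load_sites(path, "test")
  expect_equal(nrow(s$sites), 3)
  expect_equal(unname(s$skipped["indel"]), 1)
  expect_equal(unname(s$skipped["multiallelic"]), 1)
  expect_identical(s$geno[1, ], c(s1 = 0L, s2 = 1L))
  expect_identical(s$geno[3, ], c(s1 = NA_integer_, s2 = 1L))
})

test_that("records with missing QUAL are flagged, not silently kept", {
  path <- write_test_vcf(c(
    "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1/1\t0/1"
  ))
  s <- load_sites(path, "test")
  expect_equal(nrow(s$sites), 1)
  expect_equal(s$flagged$pos, 200)
  expect_equal(s$flagged$reason, "missing_qual")
})

test_that("discovery filters apply quality, spacing and heterozygosity rules", {
  path <- write_test_vcf(c(
    "chr1\t100\t.\tA\tG\t9\tPASS\t.\tGT\t0/1\t0/0",    # low quality
    "chr1\t1000\t.\tC\tT\t50\tPASS\t.\tGT\t0/1\t0/0",  # 8 bp pair, both out
    "chr1\t1008\t.\tG\tA\t50\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t2000\t.\tT\tC\t50\tPASS\t.\tGT\t0/0\t0/0",  # never heterozygous
    "chr1\t3000\t.\tA\tC\t50\tPASS\t.\tGT\t0/1\t1/1"   # clean
  ))
  s <- load_sites(path, "test")
  res <- filter_sites(s, pooled_positions(s))
  expect_equal(res$retained$sites$pos, 3000)
  led <- res$ledger[order(res$ledger$pos), ]
  expect_equal(led$pos, c(100, 1000, 1008, 2000))
  expect_equal(led$reason,
               c("quality", "spacing", "spacing", "not_heterozygous"))
  # accounting identity: retained + rejected = input
  expect_equal(nrow(res$retained$sites) + nrow(res$ledger), nrow(s$sites))
  # Q exactly at the threshold is rejected (the rule is strictly greater)
  s2 <- s
  s2$sites$qual[1] <- 10
  expect_equal(filter_sites(s2, pooled_positions(s2))$ledger$reason[1],
               "quality")
})

test_that("strand-ambiguous allele pairs are stripped", {
  path <- write_test_vcf(c(
    "chr1\t100\t.\tA\tT\t50\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t200\t.\tG\tC\t50\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t300\t.\tA\tG\t50\tPASS\t.\tGT\t0/1\t0/0"
  ))
  s <- load_sites(path, "test")
  out <- strip_ambiguous(s)
  expect_equal(out$sites$pos, 300)
  expect_equal(attr(out, "n_removed"), 2)
})

test_that("per-breed MAF folds allele frequencies from called genotypes", {
  path <- write_test_vcf(c(
    "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/0\t0/0",
    "chr1\t200\t.\tC\tT\t50\tPASS\t.\tGT\t0/1\t0/1",
    "chr1\t300\t.\tG\tA\t50\tPASS\t.\tGT\t1/1\t1/1",
    "chr1\t400\t.\tT\tC\t50\tPASS\t.\tGT\t./.\t./."
  ))
  s <- load_sites(path, "b1")
  m <- merge_site_sets(list(s))
  maf <- compute_breed_maf(m)
  expect_equal(maf$maf_b1, c(0, 0.5, 0, NA))
  expect_equal(maf$maf_all, c(0, 0.5, 0, NA))

  # three-sample hand computation: AA, AA, AB -> alt freq 1/6, maf 0.1667
  g <- matrix(c(0L, 0L, 1L), nrow = 1,
              dimnames = list("chr1_10", c("a", "b", "c")))
  ss <- structure(list(
    sites = data.frame(chrom = "chr1", pos = 10, ref = "A", alt = "G",
                       qual = 50, stringsAsFactors = FALSE),
    geno = g, samples = colnames(g), breed = NULL,
    breed_of = c(a = "b1", b = "b1", c = "b1")
  ), class = "site_set")
  expect_equal(compute_breed_maf(ss)$maf_b1, 1 / 6, tolerance = 1e-12)
})

test_that("corrected reference substitutes only universal hom-alt sites and is idempotent", {
  ref <- c(chr1 = "AAAAAAAAAA")
  ss <- structure(list(
    sites = data.frame(chrom = "chr1", pos = c(3L, 6L), ref = "A",
                       alt = c("G", "C"), qual = 50,
                       stringsAsFactors = FALSE),
    geno = matrix(c(2L, 2L,   # pos 3: hom-alt in everyone
                    1L, 2L),  # pos 6: one het -> untouched
                  nrow = 2, byrow = TRUE,
                  dimnames = list(NULL, c("s1", "s2"))),
    samples = c("s1", "s2")
  ), class = "site_set")
  out <- build_corrected_reference(ref, ss)
  expect_identical(out$reference[["chr1"]], "AAGAAAAAAA")
  expect_equal(out$n_corrected, 1)
  expect_equal(nchar(out$reference), nchar(ref))
  # idempotent: a second pass changes nothing
  out2 <- build_corrected_reference(out$reference, ss)
  expect_identical(out2$reference, out$reference)
  expect_equal(out2$n_corrected, 0)
  # mismatching reference base is a hard error naming the locus
  bad <- ss
  bad$sites$ref[1] <- "T"
  expect_error(build_corrected_reference(ref, bad), "chr1:3")
})

test_that("71-mer flanks have the SNP at position 36 with annotated neighbors", {
  set.seed(42)
  ref <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                        collapse = ""))
  pooled <- data.frame(chrom = "chr1", pos = c(150, 180))
  fl <- extract_flanks(ref, "chr1", 150, pooled)
  expect_equal(nchar(fl$upstream), 71)
  expect_equal(nchar(fl$downstream), 71)
  expect_identical(substr(fl$upstream, 36, 36),
                   substr(ref[["chr1"]], 150, 150))
  expect_identical(fl$upstream, substr(ref[["chr1"]], 115, 185))
  # the reverse-complement flank also carries the SNP at position 36
  expect_identical(substr(fl$downstream, 36, 36),
                   chartr("ACGT", "TGCA", substr(ref[["chr1"]], 150, 150)))
  # neighbor 30 bases downstream: offset +30, 3' terminal flag
  expect_equal(fl$offsets, 30)
  expect_true(fl$flag_3prime)
  expect_false(fl$flag_5prime)

  # isolated site: no offsets, no flags
  fl2 <- extract_flanks(ref, "chr1", 150,
                        data.frame(chrom = "chr1", pos = 150))
  expect_length(fl2$offsets, 0)
  expect_false(fl2$flag_5prime || fl2$flag_3prime)

  expect_error(extract_flanks(ref, "chr1", 20, pooled), "edge_locus")
})

test_that("planted discovery-filter violations are recovered exactly from the ledger", {
  bb <- buffalo_breeds()
  panel <- simulate_panel(
    bb$breeds, seed = 201, n_chrom = 2, chrom_length = 1e5,
    site_density = 1e-3, cluster_fraction = 0.15,
    ambiguous_fraction = 0.1, low_quality_fraction = 0.1
  )
  geno <- simulate_genotypes(panel, bb$breeds, seed = 202)
  dir <- withr::local_tempdir()
  paths <- write_breed_vcfs(panel, geno, dir)
  sets <- lapply(names(paths), function(b) load_sites(paths[[b]], b))
  pool <- pooled_positions(sets)

  truth <- panel$truth
  for (k in seq_along(sets)) {
    s <- sets[[k]]
    res <- filter_sites(s, pool)
    # expected reasons, derived independently from the generator's truth
    # record and the drawn genotypes, with the documented precedence
    expected <- rep(NA_character_, nrow(s$sites))
    expected[truth$low_quality_ids] <- "quality"
    open <- is.na(expected)
    expected[open & seq_len(nrow(s$sites)) %in% truth$clustered_ids] <-
      "spacing"
    open <- is.na(expected)
    no_het <- rowSums(s$geno == 1L, na.rm = TRUE) == 0
    expected[open & no_het] <- "not_heterozygous"

    led <- merge(s$sites[, c("chrom", "pos")], res$ledger,
                 by = c("chrom", "pos"), all.x = TRUE, sort = FALSE)
    led <- led[match(paste(s$sites$chrom, s$sites$pos),
                     paste(led$chrom, led$pos)), ]
    expect_identical(led$reason, expected)
  }

  # ambiguous-SNP stripping matches the generator's truth exactly
  merged <- merge_site_sets(sets)
  stripped <- strip_ambiguous(merged)
  expect_equal(attr(stripped, "n_removed"), length(truth$ambiguous_ids))
  amb_key <- with(panel$sites[truth$ambiguous_ids, ], paste(chrom, pos))
  expect_true(!any(amb_key %in% with(stripped$sites, paste(chrom, pos))))
})
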
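#' Load biallelic SNVs from a per-breed VCF
#'
#' Reads a multi-sample VCF (via \pkg{vcfR}) whose samples all belong to one
#' breed. Indels and multiallelic records are skipped with counts; records
#' with missing QUAL (`.`) are set aside in a `flagged` table rather than
#' silently kept. When several records share a position the highest-QUAL one
#' is kept and the rest logged as duplicates.
#'
#' @param vcf_path Path to a VCFv4.x file.
#' @param breed Breed label for the file's samples.
#' @return An object of class `site_set`: list with `sites` (data.frame
#'   `chrom`, `pos`, `ref`, `alt`, `qual`), `geno` (sites x samples integer
#'   dosage, NA = missing), `samples`, `breed`, `skipped` (named counts) and
#'   `flagged` (records with missing QUAL).
#' @export
load_sites <- function(vcf_path, breed) {
  if (!file.exists(vcf_path)) stop("cannot read VCF: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  fix$POS <- as.integer(fix$POS)

  is_multi <- grepl(",", fix$ALT, fixed = TRUE)
  is_indel <- !is_multi & (nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L)
  keep <- !is_multi & !is_indel
  skipped <- c(multiallelic = sum(is_multi), indel = sum(is_indel))

  qual <- suppressWarnings(as.numeric(fix$QUAL))
  no_qual <- keep & is.na(qual)
  flagged <- data.frame(chrom = fix$CHROM[no_qual], pos = fix$POS[no_qual],
                        reason = rep("missing_qual", sum(no_qual)),
                        stringsAsFactors = FALSE)
  keep <- keep & !no_qual

  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow = nrow(fix), ncol = ncol(gt),
                dimnames = list(NULL, colnames(gt)))
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dos[gt_clean == "0/0"] <- 0L
  dos[gt_clean %in% c("0/1", "1/0")] <- 1L
  dos[gt_clean == "1/1"] <- 2L

  sites <- data.frame(chrom = fix$CHROM[keep], pos = fix$POS[keep],
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      qual = qual[keep], stringsAsFactors = FALSE)
  geno <- dos[keep, , drop = FALSE]

  # collapse duplicate positions: keep highest QUAL
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) {
    ord <- order(key, -sites$qual)
    dup <- duplicated(key[ord])
    skipped["duplicate_position"] <- sum(dup)
    sel <- ord[!dup][order(ord[!dup])]
    sites <- sites[sel, , drop = FALSE]
    geno <- geno[sel, , drop = FALSE]
  }
  rownames(sites) <- NULL
  rownames(geno) <- sprintf("%s_%d", sites$chrom, sites$pos)

  structure(
    list(sites = sites, geno = geno, samples = colnames(geno),
         breed = breed, skipped = skipped, flagged = flagged),
    class = "site_set"
  )
}

#' Merge per-breed site sets on the union of sites
#'
#' Aligns several `site_set` objects by `chrom:pos`; genotypes are combined
#' column-wise with NA where a breed has no record for a site.
#'
#' @param site_sets List of `site_set` objects.
#' @return A `site_set` with a per-sample `breed` vector (`breed_of`).
#' @export
merge_site_sets <- function(site_sets) {
  keys <- lapply(site_sets, function(s) paste(s$sites$chrom, s$sites$pos))
  all_keys <- unique(unlist(keys))
  ref_tab <- do.call(rbind, lapply(site_sets, `[[`, "sites"))
  ref_tab$key <- paste(ref_tab$chrom, ref_tab$pos)
  ref_tab <- ref_tab[!duplicated(ref_tab$key), , drop = FALSE]
  ref_tab <- ref_tab[match(all_keys, ref_tab$key), , drop = FALSE]
  ord <- order(ref_tab$chrom, ref_tab$pos)
  ref_tab <- ref_tab[ord, , drop = FALSE]
  all_keys <- ref_tab$key

  geno <- do.call(cbind, lapply(site_sets, function(s) {
    m <- matrix(NA_integer_, nrow = length(all_keys), ncol = ncol(s$geno),
                dimnames = list(NULL, colnames(s$geno)))
    hit <- match(paste(s$sites$chrom, s$sites$pos), all_keys)
    m[hit, ] <- s$geno
    m
  }))
  breed_of <- unlist(lapply(site_sets, function(s) {
    stats::setNames(rep(s$breed, length(s$samples)), s$samples)
  }))
  sites <- ref_tab[, c("chrom", "pos", "ref", "alt", "qual")]
  rownames(sites) <- NULL
  rownames(geno) <- sprintf("%s_%d", sites$chrom, sites$pos)
  structure(
    list(sites = sites, geno = geno, samples = colnames(geno),
         breed = NULL, breed_of = breed_of,
         skipped = Reduce(`+`, lapply(site_sets, `[[`, "skipped")),
         flagged = do.call(rbind, lapply(site_sets, `[[`, "flagged"))),
    class = "site_set"
  )
}

#' Pooled position index across breeds
#'
#' The discovery spacing filter and the secondary-polymorphism annotation
#' both work against the pooled list of variants discovered in any breed.
#'
#' @param site_sets One `site_set` or a list of them.
#' @return data.frame `chrom`, `pos`, sorted, unique.
#' @export
pooled_positions <- function(site_sets) {
  if (inherits(site_sets, "site_set")) site_sets <- list(site_sets)
  tab <- unique(do.call(rbind, lapply(site_sets, function(s) {
    s$sites[, c("chrom", "pos")]
  })))
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# distance to the nearest *other* pooled variant, per site
nearest_pooled_distance <- function(chrom, pos, pooled) {
  out <- rep(Inf, length(pos))
  for (ch in unique(chrom)) {
    p_pool <- sort(pooled$pos[pooled$chrom == ch])
    idx <- which(chrom == ch)
    if (length(p_pool) == 0L) next
    for (i in idx) {
      d <- abs(p_pool - pos[i])
      z <- match(0L, d)  # drop one zero: the site itself
      if (!is.na(z)) d <- d[-z]
      out[i] <- if (length(d)) min(d) else Inf
    }
  }
  out
}

#' Apply the SNP discovery filters
#'
#' Retains sites that (i) have variant quality `Q > min_quality`, (ii) have
#' no other discovered variant (pooled across breeds) within `min_spacing`
#' bases, and (iii) are heterozygous in at least one individual of the
#' breed. Each rejected site gets exactly one reason code, assigned in that
#' precedence order (`"quality"`, `"spacing"`, `"not_heterozygous"`).
#'
#' @param site_set A per-breed `site_set`.
#' @param pooled data.frame from [pooled_positions()] covering all breeds.
#' @param min_quality Quality threshold; retained sites need `Q >` this
#'   (default 10).
#' @param min_spacing Exclusion radius in bases (default 10); a site is
#'   rejected if another pooled variant lies within this distance.
#' @return List with `retained` (a `site_set`) and `ledger` (data.frame
#'   `chrom`, `pos`, `reason`). Ledger rows + retained rows = input rows.
#' @export
filter_sites <- function(site_set, pooled, min_quality = 10,
                         min_spacing = 10) {
  s <- site_set$sites
  nd <- nearest_pooled_distance(s$chrom, s$pos, pooled)
  het <- rowSums(site_set$geno == 1L, na.rm = TRUE) > 0L

  reason <- rep(NA_character_, nrow(s))
  reason[!(s$qual > min_quality)] <- "quality"
  reason[is.na(reason) & nd <= min_spacing] <- "spacing"
  reason[is.na(reason) & !het] <- "not_heterozygous"

  keep <- is.na(reason)
  retained <- site_set
  retained$sites <- s[keep, , drop = FALSE]
  retained$geno <- site_set$geno[keep, , drop = FALSE]
  rownames(retained$sites) <- NULL
  list(
    retained = retained,
    ledger = data.frame(chrom = s$chrom[!keep], pos = s$pos[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  )
}

#' Remove strand-ambiguous SNPs
#'
#' A/T and G/C allele pairs cannot be resolved by a single-strand probe and
#' are excluded from the design.
#'
#' @param site_set A `site_set`.
#' @return The `site_set` without ambiguous-pair sites; removed count in
#'   attribute `"n_removed"`.
#' @export
strip_ambiguous <- function(site_set) {
  amb <- is_ambiguous_pair(site_set$sites$ref, site_set$sites$alt)
  out <- site_set
  out$sites <- site_set$sites[!amb, , drop = FALSE]
  out$geno <- site_set$geno[!amb, , drop = FALSE]
  rownames(out$sites) <- NULL
  attr(out, "n_removed") <- sum(amb)
  out
}

#' Per-breed and combined minor allele frequencies
#'
#' Allele counts use called genotypes only; a breed with zero calls at a
#' site gets `NA`. MAF is folded: `min(freq, 1 - freq)`.
#'
#' @param site_set A merged `site_set` (samples spanning breeds).
#' @param breed_of Named character vector mapping sample id to breed
#'   (defaults to the `breed_of` stored by [merge_site_sets()]).
#' @return data.frame: one row per site with `maf_<breed>` columns, a
#'   combined `maf_all`, and per-breed het counts `het_<breed>`.
#' @export
compute_breed_maf <- function(site_set, breed_of = site_set$breed_of) {
  if (is.null(breed_of)) stop("no sample-to-breed map available")
  geno <- site_set$geno
  breeds <- unique(breed_of[colnames(geno)])
  out <- site_set$sites[, c("chrom", "pos")]
  fold <- function(f) pmin(f, 1 - f)
  for (b in breeds) {
    g <- geno[, names(breed_of)[breed_of == b], drop = FALSE]
    called <- rowSums(!is.na(g))
    alt <- rowSums(g, na.rm = TRUE)
    f <- ifelse(called > 0, alt / (2 * called), NA_real_)
    out[[paste0("maf_", b)]] <- fold(f)
    out[[paste0("het_", b)]] <- rowSums(g == 1L, na.rm = TRUE)
  }
  called <- rowSums(!is.na(geno))
  alt <- rowSums(geno, na.rm = TRUE)
  out$maf_all <- fold(ifelse(called > 0, alt / (2 * called), NA_real_))
  out
}

#' Build the species-corrected reference
#'
#' Positions where every called individual (across all breeds) is homozygous
#' for the alternate allele are taken to reflect the true sequence of the
#' target species, and the base is substituted. All other positions are left
#' unchanged; lengths never change, so the operation is idempotent: on a
#' second pass such sites already carry the alternate base and are skipped.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param site_set Merged `site_set` covering all breeds.
#' @return List with `reference` (corrected sequences) and `n_corrected`.
#' @export
build_corrected_reference <- function(reference, site_set) {
  geno <- site_set$geno
  s <- site_set$sites
  called <- rowSums(!is.na(geno))
  hom_alt_all <- called > 0 & rowSums(geno == 2L, na.rm = TRUE) == called
  n_corrected <- 0L
  for (i in which(hom_alt_all)) {
    base <- substr(reference[[s$chrom[i]]], s$pos[i], s$pos[i])
    if (base == s$alt[i]) next  # already corrected
    if (base != s$ref[i]) {
      stop(sprintf("reference mismatch at %s:%d (found %s, expected %s)",
                   s$chrom[i], s$pos[i], base, s$ref[i]))
    }
    substr(reference[[s$chrom[i]]], s$pos[i], s$pos[i]) <- s$alt[i]
    n_corrected <- n_corrected + 1L
  }
  list(reference = reference, n_corrected = n_corrected)
}

#' Extract the 71-mer flank pair for a SNP
#'
#' Returns the forward-strand 71-mer with the target SNP at position 36
#' (`upstream`) and its reverse complement (`downstream`, SNP again at
#' position 36 reading the other strand). Every other discovered variant
#' inside the window is annotated by its signed offset from the target, and
#' a 5'/3' terminal flag is raised when a secondary variant falls in the
#' first or last 25 bases of the 71-mer (offsets -35..-11 and +11..+35).
#'
#' @param reference Corrected reference (named character vector).
#' @param chrom,pos Target SNP coordinates (1-based).
#' @param pooled data.frame of all discovered positions
#'   ([pooled_positions()]).
#' @param half Flank half-width (default 35, giving 71-mers).
#' @return List: `upstream`, `downstream` (71-mers), `offsets` (signed),
#'   `flag_5prime`, `flag_3prime`.
#' @export
extract_flanks <- function(reference, chrom, pos, pooled, half = 35L) {
  len <- nchar(reference[[chrom]])
  if (pos <= half || pos > len - half) {
    stop("edge_locus: SNP at ", chrom, ":", pos,
         " is closer than ", half, " bases to a chromosome end")
  }
  fwd <- substr(reference[[chrom]], pos - half, pos + half)
  p_pool <- pooled$pos[pooled$chrom == chrom]
  off <- p_pool - pos
  off <- sort(off[off != 0 & abs(off) <= half])
  list(
    upstream = fwd,
    downstream = reverse_complement(fwd),
    offsets = off,
    flag_5prime = any(off >= -half & off <= -(half - 24L)),
    flag_3prime = any(off >= (half - 24L) & off <= half)
  )
}
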
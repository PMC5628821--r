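#' Maximum genome multiplicity over all k-mers of a flank
#'
#' Slides a window of width `k` (default 16) along the flank and, for each
#' k-mer, counts its occurrences in the reference genome on both strands
#' (forward hits of the k-mer plus forward hits of its reverse complement;
#' palindromic k-mers are counted once). Returns the maximum count. A flank
#' copied from a unique genomic region therefore scores 1, and the design
#' uniqueness rule is `kmer_multiplicity == 1`.
#'
#' @param flank Nucleotide string (e.g. a 71-mer).
#' @param reference Named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param k k-mer width (default 16).
#' @return Integer: maximum per-k-mer genome hit count.
#' @export
kmer_multiplicity <- function(flank, reference, k = 16L) {
  if (nchar(flank) < k) stop("flank shorter than k")
  subject <- if (methods::is(reference, "DNAStringSet")) reference
             else Biostrings::DNAStringSet(reference)
  n_kmers <- nchar(flank) - k + 1L
  kmers <- substring(flank, seq_len(n_kmers), seq_len(n_kmers) + k - 1L)
  kmers <- unique(kmers)
  rc <- reverse_complement(kmers)
  counts <- vapply(seq_along(kmers), function(i) {
    fwd <- sum(Biostrings::vcountPattern(kmers[i], subject))
    if (rc[i] == kmers[i]) return(fwd)
    fwd + sum(Biostrings::vcountPattern(rc[i], subject))
  }, numeric(1L))
  as.integer(max(counts))
}

#' Default constants of the conversion-probability surrogate
#'
#' @return Named list of surrogate constants (see
#'   [p_convert_surrogate()]).
#' @export
pconvert_constants <- function() {
  list(
    base = 0.95,       # score of an ideal flank
    gc_low = 0.35,     # GC band considered assay-friendly
    gc_high = 0.55,
    gc_rate = 6,       # exp decay per unit GC deviation from the band
    run_free = 5,      # homopolymer run length tolerated without penalty
    run_rate = 0.3,    # exp decay per extra homopolymer base
    sec_scale = 10     # bp scale of the secondary-polymorphism penalty
  )
}

#' Deterministic conversion-probability surrogate
#'
#' Stands in for a trained probe-conversion model with a documented closed
#' form: `base * f_gc * f_run * f_unique * f_secondary`, where
#' `f_gc = exp(-gc_rate * d)` with `d` the GC-content deviation from the
#' `[gc_low, gc_high]` band, `f_run = exp(-run_rate * max(0, run - run_free))`
#' with `run` the longest homopolymer, `f_unique = 1 / multiplicity`, and
#' `f_secondary = 1 - exp(-d_near / sec_scale)` with `d_near` the distance to
#' the nearest secondary polymorphism (1 with none). Each factor is monotone
#' in the assay-relevant direction: more repetitive, more GC-skewed, less
#' unique, or more polymorphism-crowded flanks never score higher.
#'
#' @param flank Nucleotide string (A/C/G/T only).
#' @param kmer_multiplicity Genome multiplicity from [kmer_multiplicity()].
#' @param secondary_offsets Signed base offsets of secondary polymorphisms
#'   relevant to this flank (empty if none).
#' @param constants Constants list; see [pconvert_constants()].
#' @return Numeric score in `[0, 1]`.
#' @export
p_convert_surrogate <- function(flank, kmer_multiplicity = 1L,
                                secondary_offsets = integer(0),
                                constants = pconvert_constants()) {
  chars <- strsplit(toupper(flank), "", fixed = TRUE)[[1L]]
  if (!all(chars %in% DNA_BASES)) stop("flank contains non-ACGT characters")
  cst <- constants
  gc <- mean(chars %in% c("G", "C"))
  gc_dev <- max(0, cst$gc_low - gc, gc - cst$gc_high)
  run <- max(rle(chars)$lengths)
  f_gc <- exp(-cst$gc_rate * gc_dev)
  f_run <- exp(-cst$run_rate * max(0, run - cst$run_free))
  f_unique <- 1 / max(1L, kmer_multiplicity)
  f_sec <- if (length(secondary_offsets)) {
    1 - exp(-min(abs(secondary_offsets)) / cst$sec_scale)
  } else 1
  cst$base * f_gc * f_run * f_unique * f_sec
}

#' Classify one flank of a SNP
#'
#' Applies the design rules for a probe read from one side of the target
#' SNP: a secondary polymorphism within `interfering_dist` bases on that
#' side, or a non-unique flank, makes it `non_recommended`; secondary
#' polymorphisms only beyond that distance make it `neutral`; with no
#' secondary polymorphism on the probe side, a unique flank is `recommended`
#' only when its conversion score exceeds `p_floor`, otherwise `neutral`.
#'
#' @param side `"5prime"` (probe upstream of the SNP; negative offsets
#'   apply) or `"3prime"` (downstream; positive offsets).
#' @param offsets Signed offsets of all secondary polymorphisms in the
#'   71-mer window (from [extract_flanks()]).
#' @param kmer_multiplicity Genome multiplicity of the flank.
#' @param p_convert Conversion score of the flank.
#' @param interfering_dist Interference radius in bases (default 20).
#' @param p_floor Recommendation floor on `p_convert` (default 0.6,
#'   exclusive).
#' @return List of class `flank_evaluation`: `category` in
#'   `{"recommended","neutral","non_recommended"}`, `reasons`,
#'   `kmer_multiplicity`, `p_convert`, `side`.
#' @export
classify_flank <- function(side = c("5prime", "3prime"), offsets,
                           kmer_multiplicity, p_convert,
                           interfering_dist = 20L, p_floor = 0.6) {
  side <- match.arg(side)
  side_off <- if (side == "5prime") offsets[offsets < 0] else
    offsets[offsets > 0]
  dist <- abs(side_off)
  reasons <- character(0)
  if (any(dist <= interfering_dist)) reasons <- c(reasons, "interfering_20nt")
  if (kmer_multiplicity > 1L) reasons <- c(reasons, "non_unique")
  if (length(reasons)) {
    category <- "non_recommended"
  } else if (length(dist)) {
    category <- "neutral"
    reasons <- "distal_polymorphism"
  } else if (p_convert > p_floor) {
    category <- "recommended"
  } else {
    category <- "neutral"
    reasons <- "low_p_convert"
  }
  structure(
    list(category = category, reasons = reasons,
         kmer_multiplicity = kmer_multiplicity, p_convert = p_convert,
         side = side),
    class = "flank_evaluation"
  )
}

#' Evaluate both flanks of one SNP
#'
#' Computes k-mer multiplicity and the conversion surrogate for each side of
#' the flank pair, then classifies both sides.
#'
#' @param flanks Output of [extract_flanks()].
#' @param reference Reference sequences (corrected), for uniqueness checks.
#' @param constants Surrogate constants.
#' @return List with elements `"5prime"` and `"3prime"`, each a
#'   `flank_evaluation`.
#' @export
evaluate_flanks <- function(flanks, reference,
                            constants = pconvert_constants()) {
  mult <- kmer_multiplicity(flanks$upstream, reference)
  out <- list()
  for (side in c("5prime", "3prime")) {
    off <- if (side == "5prime") flanks$offsets[flanks$offsets < 0] else
      flanks$offsets[flanks$offsets > 0]
    seq_used <- if (side == "5prime") flanks$upstream else flanks$downstream
    p <- p_convert_surrogate(seq_used, mult, off, constants)
    out[[side]] <- classify_flank(side, flanks$offsets, mult, p)
  }
  out
}

#' Build the probeset(s) for one SNP
#'
#' Flanks whose conversion score falls below the hard floor are discarded
#' outright. If at least one surviving flank is recommended, a single
#' probeset is built from the recommended flank with the highest conversion
#' score. A SNP with no recommended flank can still be retained for genome
#' coverage; it then gets one probeset per surviving flank (two when both
#' survive) to maximize its chance of converting. SNP ids are
#' `<chrom>_<pos>`.
#'
#' @param chrom,pos SNP coordinates.
#' @param ref,alt Alleles (used for the oligo count: strand-ambiguous pairs
#'   need two oligos per probe).
#' @param flanks Output of [extract_flanks()].
#' @param evaluations Output of [evaluate_flanks()].
#' @param hard_floor Conversion-score floor below which a flank is never
#'   used (default 0.56).
#' @param keep_unrecommended Retain SNPs with no recommended flank
#'   (dual-probeset coverage candidates)? Default TRUE.
#' @return data.frame of 0-2 probesets (`probeset_id`, `snp_id`, `chrom`,
#'   `pos`, `flank`, `sequence`, `oligo_count`, `p_convert`, `category`,
#'   `reasons`); zero rows carry a `"drop_reason"` attribute.
#' @export
build_probesets <- function(chrom, pos, ref, alt, flanks, evaluations,
                            hard_floor = 0.56, keep_unrecommended = TRUE) {
  snp_id <- paste0(chrom, "_", pos)
  oligo <- if (is_ambiguous_pair(ref, alt)) 2L else 1L
  sides <- c("5prime", "3prime")
  surviving <- Filter(function(s) evaluations[[s]]$p_convert >= hard_floor,
                      sides)
  empty <- data.frame(probeset_id = character(0), snp_id = character(0),
                      chrom = character(0), pos = integer(0),
                      flank = character(0), sequence = character(0),
                      oligo_count = integer(0), p_convert = numeric(0),
                      category = character(0), reasons = character(0),
                      stringsAsFactors = FALSE)
  if (length(surviving) == 0L) {
    attr(empty, "drop_reason") <- "below_hard_floor"
    return(empty)
  }
  rec <- Filter(function(s) evaluations[[s]]$category == "recommended",
                surviving)
  use <- if (length(rec)) {
    rec[which.max(vapply(rec, function(s) evaluations[[s]]$p_convert,
                         numeric(1L)))]
  } else if (keep_unrecommended) {
    surviving
  } else {
    attr(empty, "drop_reason") <- "no_recommended_flank"
    return(empty)
  }
  do.call(rbind, lapply(use, function(s) {
    ev <- evaluations[[s]]
    data.frame(
      probeset_id = paste0(snp_id, "_", s),
      snp_id = snp_id, chrom = chrom, pos = pos, flank = s,
      sequence = if (s == "5prime") flanks$upstream else flanks$downstream,
      oligo_count = oligo, p_convert = ev$p_convert, category = ev$category,
      reasons = paste(ev$reasons, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
}

#' Assemble an array design and its probeset accounting
#'
#' Collects per-SNP probeset tables and checks the accounting identity:
#' total probesets = single-flank SNPs + 2 x dual-flank SNPs.
#'
#' @param probeset_tables List of data.frames from [build_probesets()].
#' @return Object of class `array_design`: `probesets` (combined
#'   data.frame), `counts` (list `single`, `dual`, `total`), `dropped`
#'   (data.frame of dropped SNP ids and reasons).
#' @export
array_design <- function(probeset_tables) {
  dropped <- do.call(rbind, lapply(probeset_tables, function(t) {
    if (nrow(t) == 0L) {
      data.frame(reason = attr(t, "drop_reason") %||% "unknown",
                 stringsAsFactors = FALSE)
    } else NULL
  }))
  probesets <- do.call(rbind, Filter(nrow, probeset_tables))
  if (is.null(probesets)) {
    probesets <- data.frame(
      probeset_id = character(0), snp_id = character(0), chrom = character(0),
      pos = integer(0), flank = character(0), sequence = character(0),
      oligo_count = integer(0), p_convert = numeric(0),
      category = character(0), reasons = character(0),
      stringsAsFactors = FALSE
    )
  }
  per_snp <- table(probesets$snp_id)
  counts <- list(single = sum(per_snp == 1L), dual = sum(per_snp == 2L),
                 total = nrow(probesets))
  stopifnot(counts$total == counts$single + 2L * counts$dual)
  structure(list(probesets = probesets, counts = counts, dropped = dropped),
            class = "array_design")
}

#' Probeset accounting from single- and dual-flank SNP counts
#'
#' The identity used to audit a design: a single-flank SNP contributes one
#' probeset, a dual-flank SNP two.
#'
#' @param n_single Number of SNPs carrying one probeset.
#' @param n_dual Number of SNPs carrying two probesets.
#' @return List: `total_probesets`, `total_snps`.
#' @export
probeset_accounting <- function(n_single, n_dual) {
  n_single <- as.integer(n_single)
  n_dual <- as.integer(n_dual)
  list(total_probesets = n_single + 2L * n_dual,
       total_snps = n_single + n_dual)
}
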
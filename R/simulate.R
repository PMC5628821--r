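#' Describe a breed for the allele-frequency simulator
#'
#' A breed is modelled as a population that drifted away from a common
#' ancestral pool, Balding-Nichols style: its allele frequency at a site is a
#' Beta draw centred on the ancestral frequency with variance controlled by
#' `fst`. Larger `fst` (more drift) pushes the breed's minor-allele-frequency
#' spectrum towards an excess of rare alleles, which is how breed-specific
#' spectra (e.g. a strongly drifted Jaffarabadi-like breed) are emulated with
#' a single parameter.
#'
#' @param name Breed label.
#' @param fst Drift parameter in `[0, 1)`; 0 means the breed frequency equals
#'   the ancestral frequency exactly.
#' @param n_samples Number of diploid individuals genotyped for the breed.
#' @param maf_spectrum_shape Positive multiplier on the Beta concentration of
#'   the drift law (default 1). Values below 1 disperse the breed spectrum
#'   further (more low-MAF sites) without changing its mean.
#' @return An object of class `breed_model`.
#' @export
breed_model <- function(name, fst, n_samples, maf_spectrum_shape = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(fst) || fst < 0 || fst >= 1) {
    stop("`fst` must lie in [0, 1); fst = 1 gives a degenerate drift law")
  }
  if (n_samples < 1) stop("`n_samples` must be >= 1")
  if (maf_spectrum_shape <= 0) stop("`maf_spectrum_shape` must be positive")
  structure(
    list(name = name, fst = fst, n_samples = as.integer(n_samples),
         maf_spectrum_shape = maf_spectrum_shape),
    class = "breed_model"
  )
}

#' Default four-breed river-buffalo panel
#'
#' The discovery panel the package emulates: 73 animals from four river
#' buffalo breeds, with the selection weights Mediterranean 30%, Murrah 30%,
#' Jaffarabadi 20%, Nili-Ravi 20%. The Jaffarabadi is given the strongest
#' drift so its MAF spectrum shows the characteristic low-MAF excess relative
#' to the other three breeds.
#'
#' @return A list with elements `breeds` (list of [breed_model()]) and
#'   `weights` (named numeric summing to 1).
#' @export
buffalo_breeds <- function() {
  list(
    breeds = list(
      breed_model("Mediterranean", fst = 0.08, n_samples = 25),
      breed_model("Murrah",        fst = 0.10, n_samples = 20),
      breed_model("Jaffarabadi",   fst = 0.25, n_samples = 14),
      breed_model("NiliRavi",      fst = 0.12, n_samples = 14)
    ),
    weights = c(Mediterranean = 0.30, Murrah = 0.30,
                Jaffarabadi = 0.20, NiliRavi = 0.20)
  )
}

#' Simulate breed-level allele frequencies under drift
#'
#' Draws an ancestral alternate-allele frequency per site from a Beta
#' spectrum, then for each breed draws the breed frequency from the
#' Balding-Nichols law `Beta(p (1-F)/F, (1-p)(1-F)/F)` (mean `p`, variance
#' `F p (1-p)`), with the Beta concentration optionally rescaled by the
#' breed's `maf_spectrum_shape`.
#'
#' @param n_sites Number of sites.
#' @param breeds List of [breed_model()] objects.
#' @param ancestral_spectrum List with `shape1`, `shape2` for the ancestral
#'   Beta spectrum; the default mildly U-shaped spectrum gives a realistic
#'   excess of low-frequency variants after folding to MAF.
#' @param seed Mandatory RNG seed.
#' @return A `n_sites x n_breeds` matrix of alternate-allele frequencies with
#'   the ancestral frequencies attached as attribute `"ancestral"`.
#' @export
simulate_breed_frequencies <- function(n_sites, breeds,
                                       ancestral_spectrum = list(shape1 = 0.6,
                                                                 shape2 = 0.6),
                                       seed) {
  stopifnot(n_sites >= 1, length(breeds) >= 1)
  with_seed(seed, {
    p <- stats::rbeta(n_sites, ancestral_spectrum$shape1,
                      ancestral_spectrum$shape2)
    # keep the ancestral frequency away from fixation so every breed law is
    # proper and sites remain segregating somewhere
    p <- pmin(pmax(p, 0.01), 0.99)
    freq <- matrix(NA_real_, nrow = n_sites, ncol = length(breeds))
    colnames(freq) <- vapply(breeds, `[[`, character(1L), "name")
    for (j in seq_along(breeds)) {
      b <- breeds[[j]]
      if (b$fst == 0) {
        freq[, j] <- p
      } else {
        nu <- (1 - b$fst) / b$fst * b$maf_spectrum_shape
        freq[, j] <- stats::rbeta(n_sites, p * nu, (1 - p) * nu)
      }
    }
    attr(freq, "ancestral") <- p
    freq
  })
}

#' Simulate a reference genome and variant site skeleton
#'
#' Builds random chromosome sequences and scatters biallelic SNV sites along
#' them as a Poisson process, then optionally plants three kinds of
#' deliberately problematic sites whose identities are recorded in the truth
#' slot: pairs closer than the 10 bp probe-interference spacing
#' (`cluster_fraction`), strand-ambiguous A/T and G/C allele pairs
#' (`ambiguous_fraction`), and low variant-quality sites with `QUAL <= 10`
#' (`low_quality_fraction`). Downstream discovery filters can then be checked
#' exactly against the generator's record.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in bases (all chromosomes equal).
#' @param site_density Expected sites per base (e.g. 1e-3).
#' @param cluster_fraction Fraction of sites relocated to lie within 10 bp of
#'   another site (in pairs).
#' @param ambiguous_fraction Fraction of sites given a complementary
#'   (A/T or G/C) allele pair.
#' @param low_quality_fraction Fraction of sites given `QUAL` in (0, 10].
#' @param min_spacing Spacing (bp) enforced between non-clustered sites
#'   (default 30). With the default, planted cluster partners (placed 1-9 bp
#'   from their anchor) are the only sites within 10 bp of another site, so
#'   the 10 bp discovery filter's rejections are exactly the planted pairs.
#' @param edge_margin Bases kept free of sites at chromosome ends so 71-mer
#'   flanks are always extractable.
#' @param seed Mandatory RNG seed.
#' @return An object of class `sim_panel`: list with `reference` (named
#'   character vector of chromosome sequences), `sites` (data.frame `chrom`,
#'   `pos` (1-based), `ref`, `alt`, `qual`), `breed_frequencies` (NULL until
#'   filled), and `truth` (parameters plus planted site indices).
#' @export
simulate_genome_and_sites <- function(n_chrom = 2, chrom_length = 1e5,
                                      site_density = 1e-3,
                                      cluster_fraction = 0,
                                      ambiguous_fraction = 0,
                                      low_quality_fraction = 0,
                                      min_spacing = 30, edge_margin = 40,
                                      seed) {
  stopifnot(cluster_fraction >= 0, cluster_fraction <= 1,
            ambiguous_fraction >= 0, ambiguous_fraction <= 1,
            low_quality_fraction >= 0, low_quality_fraction <= 1)
  with_seed(seed, {
    chroms <- sprintf("chr%d", seq_len(n_chrom))
    reference <- vapply(chroms, function(ch) {
      paste(sample(DNA_BASES, chrom_length, replace = TRUE), collapse = "")
    }, character(1L))

    sites <- list()
    for (ch in chroms) {
      n <- stats::rpois(1L, chrom_length * site_density)
      usable <- chrom_length - 2L * edge_margin
      # non-clustered sites need > min_spacing bp of elbow room each
      if (usable < n * (min_spacing + 1L)) {
        stop("chrom_length too short to host the requested site density")
      }
      # draw in a spacing-free transformed coordinate so consecutive sites
      # are > min_spacing apart by construction
      slack <- usable - n * min_spacing
      raw <- sort(sample.int(slack, n))
      pos <- as.integer(raw + min_spacing * seq_len(n) + edge_margin)
      sites[[ch]] <- data.frame(chrom = ch, pos = pos,
                                stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, sites)
    rownames(sites) <- NULL
    n_total <- nrow(sites)

    # plant clustered pairs: relocate k sites next to k anchor sites
    clustered <- integer(0)
    k <- floor(cluster_fraction * n_total / 2)
    if (k > 0) {
      idx <- sample.int(n_total, 2L * k)
      anchors <- idx[seq_len(k)]
      movers <- idx[k + seq_len(k)]
      for (i in seq_len(k)) {
        a <- anchors[i]
        newpos <- sites$pos[a] + sample(c(-9:-1, 1:9), 1L)
        newpos <- as.integer(newpos)
        sites$chrom[movers[i]] <- sites$chrom[a]
        sites$pos[movers[i]] <- newpos
      }
      clustered <- sort(c(anchors, movers))
    }
    ord <- order(sites$chrom, sites$pos)
    rank_map <- match(seq_len(n_total), ord)
    sites <- sites[ord, , drop = FALSE]
    rownames(sites) <- NULL
    clustered <- sort(rank_map[clustered])

    ref_base <- vapply(seq_len(nrow(sites)), function(i) {
      substr(reference[[sites$chrom[i]]], sites$pos[i], sites$pos[i])
    }, character(1L))
    sites$ref <- ref_base

    ambiguous <- sort(sample.int(n_total, floor(ambiguous_fraction * n_total)))
    alt <- character(n_total)
    for (i in seq_len(n_total)) {
      if (i %in% ambiguous) {
        alt[i] <- unname(COMPLEMENT[ref_base[i]])
      } else {
        alt[i] <- sample(setdiff(DNA_BASES,
                                 c(ref_base[i], COMPLEMENT[ref_base[i]])), 1L)
      }
    }
    sites$alt <- alt

    qual <- round(stats::runif(n_total, 30, 200), 2)
    low_q <- sort(sample.int(n_total, floor(low_quality_fraction * n_total)))
    qual[low_q] <- round(stats::runif(length(low_q), 1, 10), 2)
    sites$qual <- qual

    structure(
      list(
        reference = reference,
        sites = sites,
        breed_frequencies = NULL,
        truth = list(
          seed = seed, n_chrom = n_chrom, chrom_length = chrom_length,
          site_density = site_density, cluster_fraction = cluster_fraction,
          ambiguous_fraction = ambiguous_fraction,
          low_quality_fraction = low_quality_fraction,
          clustered_ids = clustered, ambiguous_ids = ambiguous,
          low_quality_ids = low_q
        )
      ),
      class = "sim_panel"
    )
  })
}

#' Simulate a complete multi-breed variant panel
#'
#' Convenience wrapper: genome + site skeleton from
#' [simulate_genome_and_sites()] with breed frequencies from
#' [simulate_breed_frequencies()] filled in.
#'
#' @inheritParams simulate_genome_and_sites
#' @inheritParams simulate_breed_frequencies
#' @param ... Passed to [simulate_genome_and_sites()].
#' @return A `sim_panel` with `breed_frequencies` populated.
#' @export
simulate_panel <- function(breeds, seed, ...) {
  panel <- simulate_genome_and_sites(seed = seed, ...)
  panel$breed_frequencies <- simulate_breed_frequencies(
    nrow(panel$sites), breeds, seed = seed + 1L
  )
  panel
}

#' Simulate genotype calls for each breed
#'
#' Within each breed, genotypes are drawn in Hardy-Weinberg proportions at
#' the breed's site frequency (two independent allele draws per individual).
#'
#' @param panel A `sim_panel` with `breed_frequencies` populated, or a bare
#'   sites x breeds frequency matrix (as from
#'   [simulate_breed_frequencies()]) when no genome is needed.
#' @param breeds List of [breed_model()] matching the frequency columns.
#' @param missing_rate Per-call no-call probability (default 0).
#' @param seed Mandatory RNG seed.
#' @return An object of class `sim_genotypes`: list with `dosage` (sites x
#'   samples integer matrix of alt-allele counts, NA = missing), `samples`
#'   (data.frame `id`, `breed`).
#' @export
simulate_genotypes <- function(panel, breeds, missing_rate = 0, seed) {
  freq <- if (is.matrix(panel)) panel else panel$breed_frequencies
  if (is.null(freq)) stop("panel has no breed frequencies; run simulate_panel()")
  n_sites <- nrow(freq)
  with_seed(seed, {
    cols <- list()
    samples <- list()
    for (b in breeds) {
      f <- freq[, b$name]
      m <- matrix(
        stats::rbinom(n_sites * b$n_samples, 2L, rep(f, b$n_samples)),
        nrow = n_sites
      )
      if (missing_rate > 0) {
        m[stats::runif(length(m)) < missing_rate] <- NA_integer_
      }
      ids <- sprintf("%s_%02d", b$name, seq_len(b$n_samples))
      colnames(m) <- ids
      cols[[b$name]] <- m
      samples[[b$name]] <- data.frame(id = ids, breed = b$name,
                                      stringsAsFactors = FALSE)
    }
    dosage <- do.call(cbind, cols)
    rownames(dosage) <- if (is.matrix(panel)) {
      rownames(panel) %||% sprintf("snp_%05d", seq_len(n_sites))
    } else {
      sprintf("%s_%d", panel$sites$chrom, panel$sites$pos)
    }
    structure(
      list(dosage = dosage, samples = do.call(rbind, samples)),
      class = "sim_genotypes"
    )
  })
}

#' Simulate phenotypes and a pedigree with known genetic architecture
#'
#' Builds a 270-day lactation-style trait as mean + fixed management effects
#' (farm, calving-year class, calving season, parity class, age-in-months
#' covariate) + QTL effects + a polygenic term drawn with covariance
#' proportional to the genomic relationship matrix of the supplied genotypes
#' + residual noise. The polygenic and residual components are rescaled so
#' the realized in-sample narrow-sense heritability (genetic variance over
#' genetic + residual variance) equals `h2` exactly; the truth slot records
#' every drawn effect so downstream recovery tests have an exact reference.
#'
#' @param genotypes A `sim_genotypes` object (or sites x samples dosage
#'   matrix).
#' @param qtl Data.frame with columns `site` (row index into the dosage
#'   matrix) and `effect` (trait units per alt allele); may be empty.
#' @param h2 Target narrow-sense heritability in `[0, 1]`.
#' @param sigma_p Phenotypic standard deviation target (kg; default 400,
#'   a realistic spread for 270-day buffalo milk yield around a 2,200 kg
#'   mean).
#' @param n_generations Pedigree depth (>= 1); cohort 1 are founders.
#' @param seed Mandatory RNG seed.
#' @return An object of class `sim_study`: `phenotypes` (per-sample record),
#'   `pedigree` (`id`, `sire`, `dam`; founders have NA parents, every parent
#'   precedes its offspring), `genotypes`, `qtl_truth`, `h2_true`, `truth`.
#' @export
simulate_phenotypes_and_pedigree <- function(genotypes, qtl = NULL, h2,
                                             sigma_p = 400,
                                             n_generations = 2, seed) {
  if (h2 < 0 || h2 > 1) stop("`h2` must lie in [0, 1]")
  dosage <- if (inherits(genotypes, "sim_genotypes")) genotypes$dosage
            else genotypes
  n <- ncol(dosage)
  ids <- colnames(dosage) %||% sprintf("ind_%03d", seq_len(n))
  if (is.null(qtl)) qtl <- data.frame(site = integer(0), effect = numeric(0))
  if (nrow(qtl) > 0 && any(qtl$site > nrow(dosage))) {
    stop("QTL site index outside the genotype matrix")
  }
  if (h2 == 1 && nrow(dosage) == 0) {
    stop("h2 = 1 with zero markers is not simulable")
  }
  sigma2 <- sigma_p^2

  with_seed(seed, {
    farm <- factor(sample(paste0("farm", 1:4), n, replace = TRUE))
    calv_year <- factor(sample(c("pre2010", "post2010"), n, replace = TRUE))
    calv_season <- factor(sample(c("winter", "spring", "summer", "autumn"),
                                 n, replace = TRUE))
    parity <- factor(sample(c("primiparous", "multiparous"), n,
                            replace = TRUE))
    age_months <- round(stats::runif(n, 36, 180))

    eff <- list(
      farm = stats::rnorm(4, 0, 150), calv_year = stats::rnorm(2, 0, 100),
      calv_season = stats::rnorm(4, 0, 80), parity = stats::rnorm(2, 0, 120),
      age = 1.5
    )
    names(eff$farm) <- levels(farm)
    names(eff$calv_year) <- levels(calv_year)
    names(eff$calv_season) <- levels(calv_season)
    names(eff$parity) <- levels(parity)

    mu <- 2200
    fixed_part <- mu + eff$farm[farm] + eff$calv_year[calv_year] +
      eff$calv_season[calv_season] + eff$parity[parity] +
      eff$age * (age_months - mean(age_months))

    qtl_part <- rep(0, n)
    if (nrow(qtl) > 0) {
      for (i in seq_len(nrow(qtl))) {
        x <- dosage[qtl$site[i], ]
        x[is.na(x)] <- mean(x, na.rm = TRUE)
        qtl_part <- qtl_part + qtl$effect[i] * x
      }
    }

    if (h2 > 0) {
      if (nrow(qtl) > 0) {
        var_qtl <- stats::var(qtl_part)
      } else var_qtl <- 0
      var_poly_target <- max(0, h2 * sigma2 - var_qtl)
      G <- build_grm(t(dosage))
      L <- chol(unclass(G) + diag(1e-6, n))
      poly_raw <- as.numeric(t(L) %*% stats::rnorm(n))
      if (var_poly_target > 0 && stats::sd(poly_raw) > 0) {
        poly <- poly_raw / stats::sd(poly_raw) * sqrt(var_poly_target)
      } else poly <- rep(0, n)
      g_total <- qtl_part + poly
      var_g <- stats::var(g_total)
      e_raw <- stats::rnorm(n)
      var_e_target <- if (h2 < 1) var_g * (1 - h2) / h2 else 0
      e <- e_raw / stats::sd(e_raw) * sqrt(var_e_target)
    } else {
      if (nrow(qtl) > 0 && any(qtl$effect != 0)) {
        stop("h2 = 0 is inconsistent with non-zero QTL effects")
      }
      g_total <- rep(0, n)
      e_raw <- stats::rnorm(n)
      e <- e_raw / stats::sd(e_raw) * sigma_p
    }
    y <- as.numeric(fixed_part + g_total + e)

    phenotypes <- data.frame(
      id = ids, lact_record = y, farm = farm, calv_year = calv_year,
      calv_season = calv_season, parity = parity, age_months = age_months,
      stringsAsFactors = FALSE
    )

    # pedigree: split samples into cohorts; each non-founder gets two
    # distinct parents from the previous cohort
    cohort <- cut(seq_len(n), breaks = n_generations, labels = FALSE)
    sire <- rep(NA_character_, n)
    dam <- rep(NA_character_, n)
    for (g in seq_len(n_generations)[-1]) {
      prev <- ids[cohort == g - 1]
      cur <- which(cohort == g)
      for (i in cur) {
        par <- sample(prev, 2L)
        sire[i] <- par[1L]
        dam[i] <- par[2L]
      }
    }
    pedigree <- data.frame(id = ids, sire = sire, dam = dam,
                           stringsAsFactors = FALSE)

    structure(
      list(
        genotypes = genotypes, pedigree = pedigree, phenotypes = phenotypes,
        qtl_truth = qtl, h2_true = h2,
        truth = list(seed = seed, mu = mu, effects = eff,
                     var_g = stats::var(g_total), var_e = stats::var(e),
                     fixed_part = as.numeric(fixed_part),
                     g_total = g_total, residual = e)
      ),
      class = "sim_study"
    )
  })
}
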
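CATEGORY_LEVELS <- c("PolyHighResolution", "MonoHighResolution",
                     "NoMinorHom", "Other", "CallRateBelowThreshold",
                     "VINO")

#' Per-sample and per-probeset call rates
#'
#' @param calls Character matrix samples x probesets with entries in
#'   `{AA, AB, BB, NoCall}`.
#' @return List with `sample` and `probeset` call-rate vectors (fraction of
#'   non-NoCall entries).
#' @export
compute_call_rates <- function(calls) {
  if (length(calls) == 0L) stop("empty genotype matrix")
  ok <- calls != "NoCall"
  list(sample = rowMeans(ok), probeset = colMeans(ok))
}

#' Classify one probeset's genotype column
#'
#' Rule order: call rate below `cr_threshold` gives
#' `CallRateBelowThreshold`; a single homozygous genotype class gives
#' `MonoHighResolution`; heterozygotes with exactly one homozygote class
#' gives `NoMinorHom`; both homozygote classes with at least
#' `min_minor_obs` minor-allele carriers gives `PolyHighResolution`;
#' anything else is `Other`. `VINO` (intensity-space artefact) is reserved
#' in the category set but never assigned from calls alone.
#'
#' @param calls Character vector of calls for one probeset.
#' @param cr_threshold Call-rate threshold (default 0.97).
#' @param min_minor_obs Minimum minor-allele carriers for
#'   `PolyHighResolution` (default 2).
#' @return List of class `probeset_classification`: `category`,
#'   `call_rate`, `maf`.
#' @export
classify_probeset <- function(calls, cr_threshold = 0.97,
                              min_minor_obs = 2L) {
  n <- length(calls)
  called <- calls[calls != "NoCall"]
  cr <- length(called) / n
  n_aa <- sum(called == "AA")
  n_ab <- sum(called == "AB")
  n_bb <- sum(called == "BB")
  n_called <- length(called)
  f_b <- if (n_called > 0) (n_ab + 2 * n_bb) / (2 * n_called) else NA_real_
  maf <- if (is.na(f_b)) NA_real_ else min(f_b, 1 - f_b)

  category <- if (cr < cr_threshold) {
    "CallRateBelowThreshold"
  } else if ((n_aa > 0) + (n_ab > 0) + (n_bb > 0) == 1L && n_ab == 0L) {
    "MonoHighResolution"
  } else if (n_ab > 0L && xor(n_aa > 0L, n_bb > 0L)) {
    "NoMinorHom"
  } else if (n_aa > 0L && n_bb > 0L) {
    minor_hom <- if (f_b <= 0.5) n_bb else n_aa
    carriers <- n_ab + minor_hom
    if (carriers >= min_minor_obs) "PolyHighResolution" else "Other"
  } else {
    "Other"
  }
  structure(list(category = category, call_rate = cr, maf = maf),
            class = "probeset_classification")
}

#' Classify every probeset of a genotype matrix
#'
#' @inheritParams compute_call_rates
#' @inheritParams classify_probeset
#' @return data.frame `probeset_id`, `category` (factor over the Axiom
#'   category levels), `call_rate`, `maf`.
#' @export
classify_matrix <- function(calls, cr_threshold = 0.97, min_minor_obs = 2L) {
  res <- lapply(seq_len(ncol(calls)), function(j) {
    classify_probeset(calls[, j], cr_threshold, min_minor_obs)
  })
  data.frame(
    probeset_id = colnames(calls) %||% as.character(seq_len(ncol(calls))),
    category = factor(vapply(res, `[[`, character(1L), "category"),
                      levels = CATEGORY_LEVELS),
    call_rate = vapply(res, `[[`, numeric(1L), "call_rate"),
    maf = vapply(res, `[[`, numeric(1L), "maf"),
    stringsAsFactors = FALSE
  )
}

#' Replicate-pair reproducibility
#'
#' Fraction of probeset comparisons, pooled over replicate pairs, where
#' both members are called and the calls agree; positions where either
#' member is `NoCall` are excluded from the denominator. A pair with no
#' mutually called probeset yields `NA` in the per-pair breakdown.
#'
#' @param calls Character matrix samples x probesets.
#' @param pairs Two-column matrix or data.frame of replicate sample ids.
#' @return List: `overall` (pooled fraction), `per_pair` (numeric vector).
#' @export
replicate_concordance <- function(calls, pairs) {
  pairs <- as.matrix(pairs)
  missing_ids <- setdiff(unique(as.vector(pairs)), rownames(calls))
  if (length(missing_ids)) {
    stop("unknown sample id(s): ", paste(missing_ids, collapse = ", "))
  }
  num <- 0L
  den <- 0L
  per_pair <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- calls[pairs[i, 1L], ]
    b <- calls[pairs[i, 2L], ]
    both <- a != "NoCall" & b != "NoCall"
    per_pair[i] <- if (any(both)) mean(a[both] == b[both]) else NA_real_
    num <- num + sum(a[both] == b[both])
    den <- den + sum(both)
  }
  list(overall = if (den > 0) num / den else NA_real_, per_pair = per_pair)
}

#' Keep the best probeset per SNP
#'
#' Category preference `PolyHighResolution > MonoHighResolution >
#' NoMinorHom > Other > CallRateBelowThreshold`; ties broken by higher call
#' rate, then lexicographic probeset id.
#'
#' @param classifications data.frame from [classify_matrix()].
#' @param snp_map data.frame `probeset_id`, `snp_id`.
#' @return `classifications` rows for the retained probesets, with
#'   `snp_id`.
#' @export
best_probeset_per_snp <- function(classifications, snp_map) {
  pref <- c(PolyHighResolution = 1L, MonoHighResolution = 2L,
            NoMinorHom = 3L, Other = 4L, VINO = 5L,
            CallRateBelowThreshold = 6L)
  d <- merge(classifications, snp_map, by = "probeset_id")
  d <- d[order(d$snp_id, pref[as.character(d$category)], -d$call_rate,
               d$probeset_id), , drop = FALSE]
  out <- d[!duplicated(d$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Category report with an explicit denominator
#'
#' Turns per-category counts into the percentages a validation report
#' prints, always carrying the denominator they refer to (validation
#' reports with implicit denominators are a classic source of inconsistent
#' percentages).
#'
#' @param counts Named integer vector of per-category probeset counts.
#' @param denominator Denominator for the percentages (defaults to
#'   `sum(counts)`).
#' @return data.frame `category`, `n`, `pct` (percent of `denominator`,
#'   rounded to one decimal); the denominator is attached as attribute
#'   `"denominator"`.
#' @export
category_report <- function(counts, denominator = sum(counts)) {
  out <- data.frame(
    category = names(counts), n = as.integer(counts),
    pct = round(100 * as.integer(counts) / denominator, 1),
    stringsAsFactors = FALSE
  )
  attr(out, "denominator") <- denominator
  out
}
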
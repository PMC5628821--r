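#' Pre-association quality control
#'
#' Removes replicated individuals (pairwise IBS at or above `dup_ibs`,
#' keeping the first member), samples with call rate below
#' `sample_cr_min`, SNPs with call rate below `snp_cr_min`, and SNPs with
#' MAF below `maf_min`, in that order, recording one ledger row per
#' removal.
#'
#' @param dosage Samples x SNPs dosage matrix (0/1/2, NA = no-call).
#' @param maf_min MAF threshold (default 0.01).
#' @param snp_cr_min SNP call-rate threshold (default 0.10).
#' @param sample_cr_min Sample call-rate threshold (default 0.10; exposed
#'   because validation pipelines differ on whether 10% or 90% is meant).
#' @param dup_ibs IBS threshold declaring two samples replicates (default
#'   0.99).
#' @return List: `dosage` (filtered), `ledger` (data.frame `item`, `type`,
#'   `reason`).
#' @export
qc_filter <- function(dosage, maf_min = 0.01, snp_cr_min = 0.10,
                      sample_cr_min = 0.10, dup_ibs = 0.99) {
  ledger <- list()
  note <- function(item, type, reason) {
    ledger[[length(ledger) + 1L]] <<- data.frame(
      item = item, type = type, reason = reason, stringsAsFactors = FALSE)
  }

  ibs <- ibs_matrix(dosage)
  drop <- rep(FALSE, nrow(dosage))
  for (i in seq_len(nrow(dosage))) {
    if (drop[i]) next
    dups <- which(ibs[i, ] >= dup_ibs)
    dups <- dups[dups > i & !drop[dups]]
    for (j in dups) {
      drop[j] <- TRUE
      note(rownames(dosage)[j] %||% as.character(j), "sample", "duplicate")
    }
  }
  dosage <- dosage[!drop, , drop = FALSE]

  sample_cr <- rowMeans(!is.na(dosage))
  low <- sample_cr < sample_cr_min
  for (i in which(low)) {
    note(rownames(dosage)[i] %||% as.character(i), "sample", "sample_cr")
  }
  dosage <- dosage[!low, , drop = FALSE]

  snp_cr <- colMeans(!is.na(dosage))
  low <- snp_cr < snp_cr_min
  for (j in which(low)) {
    note(colnames(dosage)[j] %||% as.character(j), "snp", "snp_cr")
  }
  dosage <- dosage[, !low, drop = FALSE]

  f <- colMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  low <- is.na(maf) | maf < maf_min
  for (j in which(low)) {
    note(colnames(dosage)[j] %||% as.character(j), "snp", "maf")
  }
  dosage <- dosage[, !low, drop = FALSE]

  if (length(dosage) == 0L) stop("nothing left after quality control")
  list(dosage = dosage,
       ledger = if (length(ledger)) do.call(rbind, ledger) else
         data.frame(item = character(0), type = character(0),
                    reason = character(0)))
}

#' REML fit of the additive polygenic model
#'
#' Fits `y = X b + g + e` with `g ~ N(0, sigma2_a K)` and
#' `e ~ N(0, sigma2_e I)` by restricted maximum likelihood, using a single
#' spectral decomposition of the kinship matrix followed by 1-D
#' optimization of the variance ratio (exact and deterministic at this
#' scale). Fixed effects are estimated by generalized least squares at the
#' optimum; the returned residuals are `y - X b - g_hat` with `g_hat` the
#' BLUP of the polygenic values — the pre-corrected phenotypes the
#' second GRAMMAR step regresses on.
#'
#' @param phenotypes data.frame with the trait and covariates.
#' @param kinship A `kinship` matrix aligned with `phenotypes` rows (or
#'   with `phenotypes$id` when both are named).
#' @param formula Fixed-effects formula; default the milk-record model
#'   `lact_record ~ farm + calv_year + calv_season + parity + age_months`.
#' @return Object of class `polygenic_fit`: `sigma2_a`, `sigma2_e`, `h2`,
#'   `beta` (fixed effects with standard errors), `residuals`, `blup`,
#'   `loglik`.
#' @export
fit_polygenic <- function(phenotypes, kinship,
                          formula = lact_record ~ farm + calv_year +
                            calv_season + parity + age_months) {
  mf <- stats::model.frame(formula, phenotypes)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient fixed-effect design")
  n <- length(y)
  K <- unclass(kinship)
  if (!is.null(phenotypes$id) && !is.null(rownames(K))) {
    if (all(phenotypes$id %in% rownames(K))) {
      K <- K[phenotypes$id, phenotypes$id]
    }
  }
  stopifnot(nrow(K) == n)

  ed <- eigen(K, symmetric = TRUE)
  if (min(ed$values) < -1e-6 * max(abs(ed$values))) {
    stop("kinship matrix is not positive semi-definite")
  }
  d <- pmax(ed$values, 0)
  U <- ed$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  p <- ncol(X)

  # REML log-likelihood profiled over sigma2_e, as a function of
  # lambda = sigma2_a / sigma2_e
  reml_ll <- function(log_lambda) {
    lam <- exp(log_lambda)
    v <- lam * d + 1
    XtVX <- crossprod(Xs, Xs / v)
    beta <- solve(XtVX, crossprod(Xs, ys / v))
    r <- ys - Xs %*% beta
    rss <- sum(r^2 / v)
    s2e <- rss / (n - p)
    -0.5 * ((n - p) * log(s2e) + sum(log(v)) +
              determinant(XtVX, logarithm = TRUE)$modulus + (n - p))
  }
  opt <- stats::optimize(reml_ll, interval = c(-12, 12), maximum = TRUE,
                         tol = 1e-8)
  lam <- exp(opt$maximum)
  # collapse to a pure-residual model when the boundary is hit
  if (opt$maximum <= -12 + 1e-6) lam <- 0
  v <- lam * d + 1
  XtVX <- crossprod(Xs, Xs / v)
  beta <- solve(XtVX, crossprod(Xs, ys / v))
  r <- ys - Xs %*% beta
  s2e <- sum(r^2 / v) / (n - p)
  s2a <- lam * s2e
  # BLUP of polygenic values in the rotated basis:
  # g* = lam * d / (lam * d + 1) * r*
  g_hat <- as.numeric(U %*% (lam * d / v * r))
  resid <- as.numeric(y - X %*% beta - g_hat)
  beta_se <- sqrt(diag(solve(XtVX)) * s2e)

  structure(
    list(sigma2_a = s2a, sigma2_e = s2e, h2 = s2a / (s2a + s2e),
         beta = data.frame(term = colnames(X), estimate = as.numeric(beta),
                           se = beta_se, stringsAsFactors = FALSE),
         residuals = resid, blup = g_hat, loglik = opt$objective,
         lambda = lam),
    class = "polygenic_fit"
  )
}

#' Per-SNP residual association scan (GRAMMAR step two)
#'
#' Simple linear regression of the polygenic-model residuals on allele
#' dosage, SNP by SNP. The test statistic is the squared Wald statistic,
#' chi-square with 1 degree of freedom. Missing dosages are mean-imputed;
#' monomorphic SNPs get `NA`.
#'
#' @param residuals Numeric vector from [fit_polygenic()].
#' @param dosage Samples x SNPs dosage matrix aligned with `residuals`.
#' @return data.frame `snp_id`, `effect`, `chi2`, `p`.
#' @export
grammar_scan <- function(residuals, dosage) {
  n <- length(residuals)
  stopifnot(nrow(dosage) == n)
  X <- apply(dosage, 2L, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm)
  sxx <- colSums(Xc^2)
  yc <- residuals - mean(residuals)
  sxy <- as.numeric(crossprod(Xc, yc))
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  rss <- sum(yc^2) - ifelse(sxx > 0, beta^2 * sxx, 0)
  s2 <- rss / (n - 2)
  se <- sqrt(s2 / sxx)
  chi2 <- (beta / se)^2
  chi2[sxx == 0] <- NA_real_
  data.frame(
    snp_id = colnames(dosage) %||% as.character(seq_len(ncol(dosage))),
    effect = beta, chi2 = chi2,
    p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Genomic-control correction
#'
#' The inflation factor is `lambda = median(chi2) / 0.4549` (the median of
#' a 1-df chi-square); statistics are divided by `lambda` when it exceeds
#' 1 (no deflation correction is applied). SNPs with corrected p at or
#' below `alpha` form the significant set.
#'
#' @param scan data.frame from [grammar_scan()].
#' @param alpha Significance threshold on the corrected p-value (default
#'   1e-4; a residual-inflation-corrected but not multiplicity-corrected
#'   threshold).
#' @return Object of class `gwas_result`: the scan table with `chi2_gc`
#'   and `p_gc` columns, plus `lambda` (raw, unfloored), `lambda_applied`,
#'   and `significant` (snp ids).
#' @export
genomic_control <- function(scan, alpha = 1e-4) {
  chi2 <- scan$chi2[!is.na(scan$chi2)]
  if (!length(chi2)) stop("no valid test statistics")
  lambda <- stats::median(chi2) / stats::qchisq(0.5, df = 1L)
  lambda_applied <- max(1, lambda)
  scan$chi2_gc <- scan$chi2 / lambda_applied
  scan$p_gc <- stats::pchisq(scan$chi2_gc, df = 1L, lower.tail = FALSE)
  structure(
    list(results = scan, lambda = lambda, lambda_applied = lambda_applied,
         alpha = alpha,
         significant = scan$snp_id[!is.na(scan$p_gc) & scan$p_gc <= alpha]),
    class = "gwas_result"
  )
}

#' Two-step GRAMMAR association pipeline
#'
#' Quality control, genomic relationship matrix, REML polygenic fit,
#' residual scan, genomic control.
#'
#' @param dosage Samples x SNPs dosage matrix.
#' @param phenotypes data.frame with `id` matching `rownames(dosage)` and
#'   the model covariates.
#' @param formula Fixed-effects formula (see [fit_polygenic()]).
#' @param kinship Optional precomputed kinship; default VanRaden GRM from
#'   the QC-filtered genotypes.
#' @param alpha Significance threshold after genomic control.
#' @param ... Passed to [qc_filter()].
#' @return List: `qc` ledger, `fit` (`polygenic_fit`), `gwas`
#'   (`gwas_result`), `mds` (2-D coordinates).
#' @export
grammar_gwas <- function(dosage, phenotypes,
                         formula = lact_record ~ farm + calv_year +
                           calv_season + parity + age_months,
                         kinship = NULL, alpha = 1e-4, ...) {
  qc <- qc_filter(dosage, ...)
  d <- qc$dosage
  phenotypes <- phenotypes[match(rownames(d), phenotypes$id), , drop = FALSE]
  if (is.null(kinship)) kinship <- build_grm(d)
  fit <- fit_polygenic(phenotypes, kinship, formula)
  scan <- grammar_scan(fit$residuals, d)
  list(qc = qc$ledger, fit = fit, gwas = genomic_control(scan, alpha),
       mds = mds_coordinates(d, k = 2L))
}
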
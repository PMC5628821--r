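#' Pairwise identity-by-state matrix
#'
#' Mean over pairwise-complete SNPs of the shared-allele fraction
#' `1 - |g_i - g_j| / 2` between dosage vectors.
#'
#' @param dosage Samples x SNPs dosage matrix (0/1/2, NA allowed).
#' @return Symmetric samples x samples IBS matrix with unit diagonal.
#' @export
ibs_matrix <- function(dosage) {
  n <- nrow(dosage)
  I0 <- (!is.na(dosage) & dosage == 0L) * 1
  I1 <- (!is.na(dosage) & dosage == 1L) * 1
  I2 <- (!is.na(dosage) & dosage == 2L) * 1
  M <- (!is.na(dosage)) * 1
  # sum over SNPs of |g_i - g_j| decomposed by genotype-class cross products
  D <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
    tcrossprod(I1, I2) + tcrossprod(I2, I1) +
    2 * (tcrossprod(I0, I2) + tcrossprod(I2, I0))
  n_complete <- tcrossprod(M)
  ibs <- 1 - D / (2 * pmax(n_complete, 1))
  ibs[n_complete == 0] <- NA_real_
  dimnames(ibs) <- list(rownames(dosage), rownames(dosage))
  ibs
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum p (1 - p))` where `Z` is the dosage matrix centred at
#' twice the observed allele frequencies. Missing calls are mean-imputed
#' per SNP; monomorphic SNPs are dropped.
#'
#' @param dosage Samples x SNPs dosage matrix.
#' @return Symmetric matrix of class `kinship` with attribute
#'   `kind = "genomic"`.
#' @export
build_grm <- function(dosage) {
  X <- apply(dosage, 2L, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs after imputation")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(X, 2L, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(dosage), rownames(dosage))
  structure(G, kind = "genomic", class = c("kinship", "matrix", "array"))
}

#' Pedigree (numerator) additive relationship matrix
#'
#' Tabular method: founders are unrelated and non-inbred; for individual
#' `i` with parents `s` and `d`, `A[i, j] = (A[s, j] + A[d, j]) / 2` and
#' `A[i, i] = 1 + A[s, d] / 2`.
#'
#' @param pedigree data.frame `id`, `sire`, `dam`; unknown parents NA or
#'   `"0"`. Parents must be listed before their offspring.
#' @return Symmetric matrix of class `kinship`, attribute
#'   `kind = "pedigree"`.
#' @export
build_nrm <- function(pedigree) {
  ids <- pedigree$id
  n <- length(ids)
  norm <- function(x) ifelse(is.na(x) | x == "0" | x == "", NA, x)
  sire <- match(norm(pedigree$sire), ids)
  dam <- match(norm(pedigree$dam), ids)
  known_s <- !is.na(norm(pedigree$sire))
  known_d <- !is.na(norm(pedigree$dam))
  if (any(known_s & is.na(sire)) || any(known_d & is.na(dam))) {
    stop("pedigree lists a parent that is not itself a row")
  }
  if (any(sire >= seq_len(n), na.rm = TRUE) ||
      any(dam >= seq_len(n), na.rm = TRUE)) {
    stop("parents must precede their offspring in the pedigree")
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- sire[i]
    d <- dam[i]
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        a <- 0
        if (!is.na(s)) a <- a + A[s, j]
        if (!is.na(d)) a <- a + A[d, j]
        A[i, j] <- A[j, i] <- a / 2
      }
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
  }
  structure(A, kind = "pedigree", class = c("kinship", "matrix", "array"))
}

#' Classical MDS of genotype IBS distances
#'
#' Double-centred eigendecomposition (via [stats::cmdscale()]) of the
#' `1 - IBS` distance matrix, the standard first look at population and
#' farm-of-origin structure before association analysis.
#'
#' @param dosage Samples x SNPs dosage matrix.
#' @param k Number of dimensions (default 2).
#' @return List: `points` (samples x k), `eig` (eigenvalues).
#' @export
mds_coordinates <- function(dosage, k = 2L) {
  if (nrow(dosage) < k + 1L) stop("need at least k + 1 samples")
  d <- stats::as.dist(1 - ibs_matrix(dosage))
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  if (ncol(fit$points) < k) {
    stop("k exceeds the number of positive eigenvalues")
  }
  list(points = fit$points, eig = fit$eig)
}
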
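sim_dosage <- function(n, m, fst = 0.02, seed = 1, missing_rate = 0) {
  b <- list(breed_model("pop", fst = fst, n_samples = n))
  freq <- simulate_breed_frequencies(m, b, seed = seed)
  t(simulate_genotypes(freq, b, missing_rate = missing_rate,
                       seed = seed + 1)$dosage)
}

test_that("pre-association QC removes duplicates and low-quality items", {
  set.seed(41)
  d <- sim_dosage(40, 400, seed = 41)
  d <- rbind(d, dup = d[1, ])                # planted duplicate pair
  d["dup", sample(400, 2)] <- NA             # nearly identical
  d[3, sample(400, 390)] <- NA               # sample call rate 0.025
  d[, 5] <- 0L                               # monomorphic: maf 0
  d[, 7] <- rep(c(0L, NA), length.out = nrow(d))  # SNP call rate 0.5

  res <- qc_filter(d, snp_cr_min = 0.9)
  expect_true(sum(res$ledger$reason == "duplicate") == 1)
  expect_true(any(res$ledger$reason == "sample_cr"))
  expect_true(any(res$ledger$reason == "maf"))
  expect_true(any(res$ledger$reason == "snp_cr"))
  # exactly one member of the duplicate pair survives
  expect_equal(sum(rownames(res$dosage) %in% c(rownames(d)[1], "dup")), 1)
})

test_that("GRM matches the hand-computed VanRaden form", {
  # 3 samples x 2 SNPs, worked by hand:
  # p = (0.5, 1/3); Z = X - 2p; G = ZZ' / (2 sum p(1-p))
  X <- matrix(c(0, 1, 2,
                0, 0, 2), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("m1", "m2")))
  G <- build_grm(X)
  denom <- 2 * (0.5 * 0.5 + (1 / 3) * (2 / 3))
  Z <- cbind(c(-1, 0, 1), c(-2 / 3, -2 / 3, 4 / 3))
  expect_equal(unclass(G), Z %*% t(Z) / denom,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(G, t(G))
  # identical samples: off-diagonal equals the diagonals
  X2 <- rbind(a = c(0, 2, 1, 0), b = c(0, 2, 1, 0), c = c(2, 0, 1, 2))
  G2 <- build_grm(X2)
  expect_equal(G2["a", "b"], G2["a", "a"])
  # mean diagonal ~ 1 under Hardy-Weinberg sampling
  d <- sim_dosage(200, 5000, fst = 0, seed = 51)
  expect_lt(abs(mean(diag(build_grm(d))) - 1), 0.05)
})

test_that("pedigree NRM reproduces tabular-method identities", {
  ped <- data.frame(
    id = c("f1", "f2", "s1", "s2", "x"),
    sire = c(NA, NA, "f1", "f1", "s1"),
    dam = c(NA, NA, "f2", "f2", "s2"),
    stringsAsFactors = FALSE
  )
  A <- build_nrm(ped)
  expect_equal(A["f1", "f2"], 0)       # founders unrelated
  expect_equal(A["f1", "s1"], 0.5)     # parent-offspring
  expect_equal(A["s1", "s2"], 0.5)     # full sibs
  expect_equal(A["x", "x"], 1.25)      # offspring of full sibs
  expect_equal(A, t(A))
  ev <- eigen(unclass(A), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  bad <- ped[c(5, 1:4), ]
  expect_error(build_nrm(bad), "precede")
})

test_that("classical MDS preserves IBS distances at full rank", {
  # two clusters of duplicated genotypes collapse to two points
  d <- sim_dosage(6, 200, seed = 71)
  d[1:3, ] <- rep(d[1, ], each = 3)
  d[4:6, ] <- rep(d[4, ], each = 3)
  mds <- mds_coordinates(d, k = 2)
  expect_lt(max(dist(mds$points[1:3, ])), 1e-6)
  expect_lt(max(dist(mds$points[4:6, ])), 1e-6)

  # 4 distinct samples, k = 3: pairwise distances reproduced exactly
  d2 <- sim_dosage(4, 300, seed = 72)
  mds2 <- mds_coordinates(d2, k = 3)
  D_in <- as.matrix(stats::as.dist(1 - ibs_matrix(d2)))
  D_out <- as.matrix(stats::dist(mds2$points))
  expect_equal(D_out, D_in, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(mds_coordinates(d2[1:2, ], k = 2), "samples")
})

test_that("REML recovers null and moderate heritabilities", {
  b <- list(breed_model("s", fst = 0.02, n_samples = 500))
  freq <- simulate_breed_frequencies(3000, b, seed = 81)
  geno <- simulate_genotypes(freq, b, seed = 82)
  st0 <- simulate_phenotypes_and_pedigree(geno, h2 = 0, seed = 83)
  G <- build_grm(t(geno$dosage))
  fit0 <- fit_polygenic(st0$phenotypes, G)
  expect_lt(fit0$h2, 0.05)

  st <- simulate_phenotypes_and_pedigree(geno, h2 = 0.45, seed = 84)
  fit <- fit_polygenic(st$phenotypes, G)
  expect_lt(abs(fit$h2 - 0.45), 0.1)
  expect_true(fit$sigma2_a >= 0 && fit$sigma2_e >= 0)

  # simulated farm contrasts recovered within ~2 SE by GLS
  truth <- st$truth$effects$farm
  est <- fit$beta[grep("^farm", fit$beta$term), ]
  for (k in seq_len(nrow(est))) {
    lev <- sub("^farm", "", est$term[k])
    expect_lt(abs(est$estimate[k] - (truth[lev] - truth["farm1"])),
              3 * est$se[k])
  }
})

test_that("with identity kinship the two-step scan equals ordinary regression", {
  d <- sim_dosage(150, 500, seed = 91)
  b <- list(breed_model("s", fst = 0.02, n_samples = 150))
  st <- simulate_phenotypes_and_pedigree(
    structure(list(dosage = t(d),
                   samples = data.frame(id = rownames(d), breed = "s")),
              class = "sim_genotypes"),
    h2 = 0, seed = 92)
  K <- diag(150)
  dimnames(K) <- list(rownames(d), rownames(d))
  fit <- fit_polygenic(st$phenotypes, structure(K, class = c("kinship", "matrix", "array")))
  scan <- grammar_scan(fit$residuals, d)

  # single-step: OLS of the fixed-effect-adjusted phenotype on dosage
  ols_resid <- stats::residuals(stats::lm(
    lact_record ~ farm + calv_year + calv_season + parity + age_months,
    data = st$phenotypes))
  scan_ols <- grammar_scan(ols_resid, d)
  expect_equal(scan$p, scan_ols$p, tolerance = 1e-6)
})

test_that("planted QTL dominate the residual scan", {
  hits <- 0L
  for (seed in 1:5) {
    b <- list(breed_model("s", fst = 0.02, n_samples = 400))
    freq <- simulate_breed_frequencies(800, b, seed = 100 + seed)
    geno <- simulate_genotypes(freq, b, seed = 200 + seed)
    qtl_site <- which.min(abs(freq[, 1] - 0.5))[1]
    p <- freq[qtl_site, 1]
    # effect sized for ~5% of phenotypic variance (sigma_p = 400)
    beta <- sqrt(0.05 * 400^2 / (2 * p * (1 - p)))
    st <- simulate_phenotypes_and_pedigree(
      geno, qtl = data.frame(site = qtl_site, effect = beta),
      h2 = 0.3, seed = 300 + seed)
    fit <- fit_polygenic(st$phenotypes, build_grm(t(geno$dosage)))
    scan <- grammar_scan(fit$residuals, t(geno$dosage))
    if (which.min(scan$p) == qtl_site) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("genomic control rescales statistics and thresholds the corrected p", {
  scan <- data.frame(snp_id = sprintf("s%d", 1:8),
                     effect = 0,
                     chi2 = c(30, 25, 20, 0.40, 0.45, 0.50, 0.46, NA))
  scan$p <- stats::pchisq(scan$chi2, 1, lower.tail = FALSE)
  gc <- genomic_control(scan, alpha = 1e-4)
  expect_equal(gc$lambda, 0.50 / stats::qchisq(0.5, 1))
  # exactly the three large statistics survive the corrected threshold
  expect_setequal(gc$significant, c("s1", "s2", "s3"))
  # doubling all statistics doubles lambda and leaves corrected p unchanged
  scan2 <- scan
  scan2$chi2 <- scan2$chi2 * 2
  gc2 <- genomic_control(scan2, alpha = 1e-4)
  expect_equal(gc2$lambda, 2 * gc$lambda)
  expect_equal(gc2$results$p_gc, gc$results$p_gc, tolerance = 1e-12)
  # lambda below 1 is floored (no deflation correction)
  null_scan <- data.frame(snp_id = "a", effect = 0, chi2 = 0.1, p = 0.75)
  expect_equal(genomic_control(null_scan)$lambda_applied, 1)
  # monomorphic SNP gives a missing result in the scan
  d <- cbind(mono = rep(1L, 50), poly = rep(c(0L, 1L, 2L), length.out = 50))
  sc <- grammar_scan(stats::rnorm(50), d)
  expect_true(is.na(sc$chi2[1]) && !is.na(sc$chi2[2]))
})
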
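# Independent brute-force implementations used as oracles. These share no
# code with the package's incremental engine: gaps are recomputed from plain
# sorted vectors and every remaining candidate is rescored from scratch at
# every round.

naive_gap <- function(sel_pos, pos, chrom_len) {
  left <- sel_pos[sel_pos <= pos]
  right <- sel_pos[sel_pos >= pos]
  c(if (length(left)) max(left) else 0,
    if (length(right)) min(right) else chrom_len)
}

naive_score <- function(i, cand, maf, weights, sel, chrom_lengths) {
  total <- 0
  for (b in colnames(maf)) {
    m <- maf[i, b]
    if (m <= 0) next
    g <- naive_gap(sel[[b]][[cand$chrom[i]]] %||% numeric(0),
                   cand$pos[i], chrom_lengths[[cand$chrom[i]]])
    width <- g[2] - g[1]
    if (width <= 0) next
    total <- total + weights[[b]] * m * width *
      (1 - abs((g[1] + g[2]) / 2 - cand$pos[i]) / (width / 2))
  }
  total
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Full-rescan greedy selection with the same wave ordering and tie-break
# (chromosome name, then position) as the package engine.
naive_select <- function(cand, maf, weights, chrom_lengths, target_n,
                         waves = NULL) {
  if (is.null(waves)) waves <- rep(1L, nrow(cand))
  sel <- lapply(stats::setNames(colnames(maf), colnames(maf)),
                function(b) list())
  picked <- character(0)
  remaining <- seq_len(nrow(cand))
  for (w in sort(unique(waves))) {
    repeat {
      if (length(picked) >= target_n) return(picked)
      active <- remaining[waves[remaining] == w]
      if (!length(active)) break
      scores <- vapply(active, naive_score, numeric(1), cand, maf, weights,
                       sel, chrom_lengths)
      if (max(scores) <= 0) break
      top <- active[scores == max(scores)]
      top <- top[order(cand$chrom[top], cand$pos[top])][1]
      picked <- c(picked, cand$snp_id[top])
      remaining <- setdiff(remaining, top)
      for (b in colnames(maf)) {
        if (maf[top, b] > 0) {
          ch <- cand$chrom[top]
          sel[[b]][[ch]] <- sort(c(sel[[b]][[ch]] %||% numeric(0),
                                   cand$pos[top]))
        }
      }
    }
  }
  picked
}

# Random candidate instance on a small multi-chromosome genome.
random_instance <- function(n_cand, n_breeds, n_chrom = 2, chrom_len = 1e5,
                            seed) {
  set.seed(seed)
  breeds <- paste0("b", seq_len(n_breeds))
  chroms <- paste0("chr", seq_len(n_chrom))
  cand <- data.frame(
    chrom = sample(chroms, n_cand, replace = TRUE),
    pos = sample.int(chrom_len - 100, n_cand) + 50,
    design_score = runif(n_cand, 0.5, 1),
    snp_score = runif(n_cand, 20, 200),
    oligos = 1L,
    nearest_dist = sample(c(15, 40, 100), n_cand, replace = TRUE),
    stringsAsFactors = FALSE
  )
  cand <- cand[!duplicated(cand[, c("chrom", "pos")]), ]
  cand$snp_id <- sprintf("%s_%d", cand$chrom, cand$pos)
  maf <- matrix(round(runif(nrow(cand) * n_breeds, 0, 0.5), 3),
                ncol = n_breeds, dimnames = list(NULL, breeds))
  maf[runif(length(maf)) < 0.15] <- 0  # some breed-monomorphic entries
  w <- rep(1 / n_breeds, n_breeds)
  names(w) <- breeds
  list(cand = cand, maf = maf, weights = w,
       chrom_lengths = stats::setNames(rep(chrom_len, n_chrom), chroms))
}
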
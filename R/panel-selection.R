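#' The 70-wave quality tier table of the 90K design
#'
#' Builds the wave table used to band candidates into descending-quality
#' tiers before greedy selection. The layout: for each spacing tier (nearest
#' discovered variant > 30 bp, then > 10 bp), five (design-score floor,
#' variant-quality floor) blocks — (0.8, 100), (0.7, 100), (0.7, 50),
#' (0.6, 100), (0.6, 50) — first with per-breed MAF floors (> 0.20, > 0.10,
#' > 0.05 for single-oligo SNPs and > 0.05 for dual-oligo), then with the
#' "alt allele present in all breeds" rule split by oligo count. After those
#' 60 waves come the relaxed tiers requiring the alt allele in at least 3
#' breeds, then at least 2 (waves 61-68, design floor 0.6, quality floor 50,
#' both spacings), and finally two catch-all waves (69: single-oligo, 70:
#' dual-oligo) with no other constraint. All floors are minima; MAF floors
#' are strict.
#'
#' @return data.frame with columns `wave`, `min_spacing`, `oligos`,
#'   `design_floor`, `snp_floor`, `rule` (`"per_breed"`, `"n_breeds"`,
#'   `"catch_all"`), `maf_floor`, `n_breeds`.
#' @export
wave_table_90k <- function() {
  rows <- list()
  add <- function(min_spacing, oligos, design, snp, rule, maf = NA_real_,
                  nb = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      min_spacing = min_spacing, oligos = oligos, design_floor = design,
      snp_floor = snp, rule = rule, maf_floor = maf, n_breeds = nb,
      stringsAsFactors = FALSE
    )
  }
  blocks <- list(c(0.8, 100), c(0.7, 100), c(0.7, 50), c(0.6, 100),
                 c(0.6, 50))
  for (spacing in c(30L, 10L)) {
    for (b in blocks) {
      add(spacing, 1L, b[1], b[2], "per_breed", 0.20)
      add(spacing, 1L, b[1], b[2], "per_breed", 0.10)
      add(spacing, 1L, b[1], b[2], "per_breed", 0.05)
      add(spacing, 2L, b[1], b[2], "per_breed", 0.05)
    }
    for (oligos in c(1L, 2L)) {
      for (b in blocks) add(spacing, oligos, b[1], b[2], "per_breed", 0)
    }
  }
  for (nb in c(3L, 2L)) {
    for (cfg in list(c(30L, 1L), c(30L, 2L), c(10L, 1L), c(10L, 2L))) {
      add(cfg[1L], cfg[2L], 0.6, 50, "n_breeds", nb = nb)
    }
  }
  add(0L, 1L, 0, 0, "catch_all")
  add(0L, 2L, 0, 0, "catch_all")
  out <- do.call(rbind, rows)
  out <- cbind(wave = seq_len(nrow(out)), out)
  out
}

#' Read / write a wave table as YAML
#'
#' @param path YAML file with a `waves` list, one mapping per wave.
#' @return data.frame in [wave_table_90k()] layout.
#' @export
read_wave_table <- function(path) {
  w <- yaml::read_yaml(path)$waves
  out <- do.call(rbind, lapply(w, function(x) {
    data.frame(wave = x$wave, min_spacing = x$min_spacing,
               oligos = x$oligos, design_floor = x$design_floor,
               snp_floor = x$snp_floor, rule = x$rule,
               maf_floor = x$maf_floor %||% NA_real_,
               n_breeds = x$n_breeds %||% NA_integer_,
               stringsAsFactors = FALSE)
  }))
  out[order(out$wave), , drop = FALSE]
}

#' @rdname read_wave_table
#' @param wave_table data.frame to serialize.
#' @export
write_wave_table <- function(wave_table, path) {
  waves <- lapply(seq_len(nrow(wave_table)), function(i) {
    r <- as.list(wave_table[i, ])
    r <- r[!vapply(r, function(v) is.na(v) && !is.character(v), logical(1L))]
    r
  })
  yaml::write_yaml(list(waves = waves), path)
  invisible(path)
}

#' Assign each candidate to its quality wave
#'
#' Returns for each candidate the smallest wave index whose every criterion
#' it meets: nearest-variant distance strictly above the wave's spacing,
#' exact oligo-count match, design and variant-quality scores at or above
#' the floors, and the wave's MAF rule (all per-breed MAFs strictly above
#' the floor, or the alt allele present — MAF > 0 — in at least `n_breeds`
#' breeds). Candidates matching no constrained wave fall to the catch-all
#' wave for their oligo count.
#'
#' @param candidates data.frame with `design_score`, `snp_score`, `oligos`,
#'   `nearest_dist`.
#' @param maf Matrix (candidates x breeds) of per-breed MAFs (NA treated as
#'   0).
#' @param wave_table Wave table (default [wave_table_90k()]).
#' @return Integer vector of wave indices.
#' @export
assign_wave <- function(candidates, maf, wave_table = wave_table_90k()) {
  maf <- as.matrix(maf)
  maf[is.na(maf)] <- 0
  n <- nrow(candidates)
  wave <- rep(NA_integer_, n)
  for (i in seq_len(nrow(wave_table))) {
    w <- wave_table[i, ]
    open <- is.na(wave)
    if (!any(open)) break
    ok <- open &
      candidates$nearest_dist > w$min_spacing &
      candidates$oligos == w$oligos
    if (w$rule != "catch_all") {
      ok <- ok & candidates$design_score >= w$design_floor &
        candidates$snp_score >= w$snp_floor
      if (w$rule == "per_breed") {
        ok <- ok & rowSums(maf > w$maf_floor) == ncol(maf)
      } else {
        ok <- ok & rowSums(maf > 0) >= w$n_breeds
      }
    }
    wave[ok] <- w$wave
  }
  wave
}

# --- gap index ------------------------------------------------------------

#' Create a per-breed gap index
#'
#' Tracks, per breed and chromosome, the sorted positions of already
#' selected loci that are polymorphic in that breed. Gaps are initialized to
#' the whole chromosome `[0, length]`.
#'
#' @param breeds Breed names.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @return An environment of class `gap_index`.
#' @export
new_gap_index <- function(breeds, chrom_lengths) {
  e <- new.env(parent = emptyenv())
  e$chrom_lengths <- chrom_lengths
  e$pos <- lapply(stats::setNames(breeds, breeds), function(b) {
    lapply(stats::setNames(names(chrom_lengths), names(chrom_lengths)),
           function(ch) numeric(0))
  })
  class(e) <- "gap_index"
  e
}

#' Gap enclosing a position for one breed
#'
#' `A` is the nearest selected breed-polymorphic locus at or left of the
#' query (0 if none), `B` the nearest at or right of it (chromosome length
#' if none). A selected locus with MAF 0 in the breed is transparent: it is
#' never in the breed's index.
#'
#' @param index A `gap_index`.
#' @param breed Breed name.
#' @param chrom Chromosome name.
#' @param pos Query position.
#' @return Numeric `c(A, B)`.
#' @export
enclosing_gap <- function(index, breed, chrom, pos) {
  len <- unname(index$chrom_lengths[chrom])
  if (is.na(len)) stop("unknown chromosome: ", chrom)
  p <- index$pos[[breed]][[chrom]]
  i <- findInterval(pos, p)
  A <- if (i >= 1L) p[i] else 0
  B <- if (i >= 1L && p[i] == pos) pos
       else if (i < length(p)) p[i + 1L]
       else len
  c(A, B)
}

#' @rdname new_gap_index
#' @param index A `gap_index`.
#' @param breed,chrom,pos Locus to insert into the breed's sorted list.
#' @export
insert_position <- function(index, breed, chrom, pos) {
  p <- index$pos[[breed]][[chrom]]
  i <- findInterval(pos, p)
  if (i >= 1L && p[i] == pos) return(invisible(index))
  index$pos[[breed]][[chrom]] <- append(p, pos, after = i)
  invisible(index)
}

#' Breed-weighted gap-filling score of a candidate
#'
#' Evaluates `sum_j w_j * MAF_j * (B_j - A_j) * (1 - |(A_j+B_j)/2 - P| /
#' ((B_j - A_j)/2))` over breeds, where `(A_j, B_j)` is the current gap of
#' breed `j` containing the candidate position `P`. The score rewards
#' filling large gaps near their midpoint, weighted by each breed's
#' importance and the candidate's informativeness (MAF) in that breed.
#' Breeds where the candidate is monomorphic contribute 0, as do degenerate
#' gaps and candidates sitting on a gap boundary.
#'
#' @param chrom,pos Candidate position.
#' @param maf Named per-breed MAF vector for the candidate.
#' @param index A `gap_index`.
#' @param weights Named per-breed weights (should sum to 1).
#' @return Non-negative numeric score.
#' @export
score_candidate <- function(chrom, pos, maf, index, weights) {
  total <- 0
  for (b in names(weights)) {
    m <- maf[[b]]
    if (is.na(m) || m <= 0) next
    g <- enclosing_gap(index, b, chrom, pos)
    width <- g[2L] - g[1L]
    if (width <= 0) next
    centrality <- 1 - abs((g[1L] + g[2L]) / 2 - pos) / (width / 2)
    total <- total + weights[[b]] * m * width * centrality
  }
  total
}

#' Greedy wave-based panel selection
#'
#' Processes waves in ascending index. Within a wave, the highest-scoring
#' candidate is repeatedly selected, inserted into the gap index of every
#' breed where it is polymorphic, and only candidates whose enclosing gap
#' was split are rescored. A wave ends when its candidates are exhausted,
#' the best score drops to `min_score` or below, or the optional per-wave
#' cap is reached; selection ends at `target_n`. Ties break deterministically
#' by chromosome name then position.
#'
#' @param candidates data.frame with `snp_id`, `chrom`, `pos`,
#'   `design_score`, `snp_score`, `oligos`, `nearest_dist`, and optionally a
#'   precomputed `wave` column.
#' @param maf Matrix (candidates x breeds), columns named by breed.
#' @param weights Named breed weights summing to 1.
#' @param chrom_lengths Named chromosome lengths.
#' @param target_n Panel size to reach.
#' @param min_score Wave stopping floor on the score (default 0).
#' @param per_wave_cap Optional cap on selections per wave.
#' @param wave_table Wave table used when `candidates$wave` is absent.
#' @return Object of class `selection_result`: `selected` (data.frame
#'   `rank`, `snp_id`, `wave`, `score`, `chrom`, `pos`), `per_wave_counts`,
#'   `weights`, `gap_statistics` (from [gap_statistics()] on the pooled
#'   selected positions).
#' @export
select_panel <- function(candidates, maf, weights, chrom_lengths, target_n,
                         min_score = 0, per_wave_cap = NULL,
                         wave_table = wave_table_90k()) {
  if (nrow(candidates) == 0L) stop("empty candidate list")
  stopifnot(abs(sum(weights) - 1) < 1e-8)
  maf <- as.matrix(maf)
  maf[is.na(maf)] <- 0
  breeds <- colnames(maf)
  if (is.null(candidates$wave)) {
    candidates$wave <- assign_wave(candidates, maf, wave_table)
  }
  index <- new_gap_index(breeds, chrom_lengths)
  sel <- list()
  rank <- 0L

  score_one <- function(i) {
    score_candidate(candidates$chrom[i], candidates$pos[i],
                    stats::setNames(as.list(maf[i, ]), breeds), index,
                    weights)
  }

  for (w in sort(unique(candidates$wave))) {
    if (rank >= target_n) break
    active <- which(candidates$wave == w)
    if (!length(active)) next
    scores <- vapply(active, score_one, numeric(1L))
    n_wave <- 0L
    repeat {
      if (!length(active) || rank >= target_n) break
      if (!is.null(per_wave_cap) && n_wave >= per_wave_cap) break
      best_score <- max(scores)
      if (best_score <= min_score) break
      cand_best <- active[scores == best_score]
      if (length(cand_best) > 1L) {
        ord <- order(candidates$chrom[cand_best], candidates$pos[cand_best])
        cand_best <- cand_best[ord]
      }
      b <- cand_best[1L]
      rank <- rank + 1L
      n_wave <- n_wave + 1L
      sel[[rank]] <- data.frame(
        rank = rank, snp_id = candidates$snp_id[b], wave = w,
        score = best_score, chrom = candidates$chrom[b],
        pos = candidates$pos[b], stringsAsFactors = FALSE
      )
      keep <- active != b
      active <- active[keep]
      scores <- scores[keep]
      # split the gap in every breed where the new SNP is polymorphic and
      # rescore only candidates whose breed-gap contained it
      affected <- logical(length(active))
      for (j in seq_along(breeds)) {
        if (maf[b, j] <= 0) next
        g <- enclosing_gap(index, breeds[j], candidates$chrom[b],
                           candidates$pos[b])
        insert_position(index, breeds[j], candidates$chrom[b],
                        candidates$pos[b])
        hit <- candidates$chrom[active] == candidates$chrom[b] &
          candidates$pos[active] > g[1L] & candidates$pos[active] < g[2L] &
          maf[active, j] > 0
        affected <- affected | hit
      }
      if (any(affected)) {
        scores[affected] <- vapply(active[affected], score_one, numeric(1L))
      }
    }
  }

  selected <- if (rank > 0L) do.call(rbind, sel) else
    data.frame(rank = integer(0), snp_id = character(0), wave = integer(0),
               score = numeric(0), chrom = character(0), pos = numeric(0))
  pos_by_chrom <- split(selected$pos, selected$chrom)
  gs <- if (sum(lengths(pos_by_chrom) >= 2L) > 0L) {
    gap_statistics(pos_by_chrom)
  } else NULL
  structure(
    list(selected = selected,
         per_wave_counts = table(factor(selected$wave)),
         weights = weights, gap_statistics = gs),
    class = "selection_result"
  )
}

#' Gap-size summary of a selected panel
#'
#' Gaps are distances between consecutive selected positions within each
#' chromosome, pooled across chromosomes. Percentiles use linear
#' interpolation between order statistics.
#'
#' @param positions_by_chrom List of numeric position vectors, one per
#'   chromosome.
#' @return Named numeric: `min`, `p1`, `p5`, `p25`, `p50`, `p75`, `p95`,
#'   `p99`, `max`.
#' @export
gap_statistics <- function(positions_by_chrom) {
  gaps <- unlist(lapply(positions_by_chrom, function(p) diff(sort(p))))
  if (length(gaps) == 0L) {
    stop("need at least 2 selected positions on some chromosome")
  }
  q <- stats::quantile(gaps, c(0.01, 0.05, 0.25, 0.50, 0.75, 0.95, 0.99),
                       type = 7, names = FALSE)
  c(min = min(gaps), p1 = q[1L], p5 = q[2L], p25 = q[3L], p50 = q[4L],
    p75 = q[5L], p95 = q[6L], p99 = q[7L], max = max(gaps))
}
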
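#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# All generators take mandatory seeds; nothing in the package touches the
# global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Strand-ambiguous allele pair: {A,T} or {G,C}; such SNPs need probes for
# both strands on the array.
is_ambiguous_pair <- function(ref, alt) {
  COMPLEMENT[ref] == alt
}

reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Genotype encodings: internal dosage 0/1/2 (alt-allele count, NA = missing)
# versus the array-style call alphabet AA/AB/BB/NoCall (A = reference allele).
dosage_to_calls <- function(dosage) {
  calls <- matrix("NoCall", nrow = nrow(dosage), ncol = ncol(dosage),
                  dimnames = dimnames(dosage))
  calls[!is.na(dosage) & dosage == 0L] <- "AA"
  calls[!is.na(dosage) & dosage == 1L] <- "AB"
  calls[!is.na(dosage) & dosage == 2L] <- "BB"
  calls
}

calls_to_dosage <- function(calls) {
  d <- matrix(NA_integer_, nrow = nrow(calls), ncol = ncol(calls),
              dimnames = dimnames(calls))
  d[calls == "AA"] <- 0L
  d[calls == "AB"] <- 1L
  d[calls == "BB"] <- 2L
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
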
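# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package go through this so
# that injections are order-independent and runs are reproducible.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a sub-stream seed from a base seed and a fixed per-operation
# offset; kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 69069 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minor-allele dosage frequency per SNP, ignoring missing genotypes.
snp_freq <- function(g) {
  colMeans(g, na.rm = TRUE) / 2
}

# Per-SNP missingness and per-sample missingness.
snp_missingness <- function(g) colMeans(is.na(g))
sample_missingness <- function(g) rowMeans(is.na(g))

complement_base <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  out <- unname(map[x])
  out[is.na(out)] <- x[is.na(out)]
  out
}

is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

stopifnot_genotypes <- function(g) {
  if (!is.matrix(g)) stop("genotypes must be a matrix (samples x SNPs)")
  v <- g[!is.na(g)]
  if (length(v) && (any(v < 0) || any(v > 2) || any(v != floor(v))))
    stop("genotype values must be in {0, 1, 2} or NA")
  invisible(TRUE)
}
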
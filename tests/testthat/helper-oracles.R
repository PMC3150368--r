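# Independent oracles used to validate the package implementations.
# Each is written as a direct, unoptimized transcription of the
# definition it checks, sharing no code path with the package.

# Full-enumeration HWE exact p-value via log-gamma probabilities.
oracle_hwe_enum <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  if (n_rare == 0 || n_rare == 2 * n) return(1)
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  lp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) + lfactorial(n) - lfactorial(hom_r) - lfactorial(h) -
      lfactorial(hom_c) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
      lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(lp - max(lp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

# Expected Hudson F_st under the Balding-Nichols model with per-pop
# divergences F1, F2 and ancestral frequency uniform on `maf_range`,
# as a ratio of numerically integrated expectations. Conditional on the
# ancestral frequency pa, E[(p1-p2)^2] = (F1+F2) pa (1-pa) (independent
# Beta draws with variance F pa(1-pa)) and
# E[p1(1-p2) + p2(1-p1)] = 2 pa (1-pa).
oracle_bn_fst <- function(F1, F2, maf_range) {
  num <- stats::integrate(function(pa) (F1 + F2) * pa * (1 - pa),
                          maf_range[1], maf_range[2])$value
  den <- stats::integrate(function(pa) 2 * pa * (1 - pa),
                          maf_range[1], maf_range[2])$value
  num / den
}

# Brute-force ROH scan: explicit loops over every window and SNP.
oracle_roh <- function(g_sample, snps, config = roh_config()) {
  W <- config$window_snps
  segs <- list()
  for (chr in unique(snps$chromosome)) {
    idx <- which(snps$chromosome == chr)
    if (length(idx) < W) next
    pos <- snps$position[idx]
    gv <- g_sample[idx]
    m <- length(idx)
    win_hom <- logical(m - W + 1)
    for (w in seq_len(m - W + 1)) {
      win <- gv[w:(w + W - 1)]
      win_hom[w] <- sum(win == 1L, na.rm = TRUE) <= config$window_max_het
    }
    cand <- logical(m)
    for (j in seq_len(m)) {
      cover <- intersect(seq_len(m - W + 1), (j - W + 1):j)
      cand[j] <- mean(win_hom[cover]) >= config$overlap_frac_min
    }
    j <- 1
    while (j <= m) {
      if (cand[j]) {
        k <- j
        while (k < m && cand[k + 1]) k <- k + 1
        n_snps_run <- k - j + 1
        n_het_run <- sum(gv[j:k] == 1L, na.rm = TRUE)
        len <- pos[k] - pos[j] + 1
        if (len >= config$seg_min_bp && n_snps_run >= config$seg_min_snps &&
            n_het_run / n_snps_run <= config$seg_max_het_frac)
          segs[[length(segs) + 1]] <- data.frame(
            chromosome = chr, start = pos[j], end = pos[k],
            n_snps = n_snps_run, n_het = n_het_run)
        j <- k + 1
      } else j <- j + 1
    }
  }
  if (!length(segs))
    return(data.frame(chromosome = integer(), start = integer(),
                      end = integer(), n_snps = integer(), n_het = integer()))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# Exhaustive single-window pruning oracle (<= 20 SNPs): recomputes the
# full pairwise r2 matrix from scratch at every step and applies the
# same removal rule (higher missingness, then lower MAF, then larger
# position) to the first violating pair in scan order.
oracle_prune_window <- function(g, snps, r2_max) {
  keep <- seq_len(ncol(g))
  miss <- colMeans(is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  repeat {
    viol <- NULL
    for (a in seq_along(keep)) {
      for (b in seq_along(keep)) {
        if (a >= b) next
        i <- keep[a]; j <- keep[b]
        ok <- !is.na(g[, i]) & !is.na(g[, j])
        r2 <- if (sum(ok) < 2 || stats::var(g[ok, i]) == 0 ||
                  stats::var(g[ok, j]) == 0) 0 else
          stats::cor(g[ok, i], g[ok, j])^2
        if (r2 > r2_max) { viol <- c(i, j); break }
      }
      if (!is.null(viol)) break
    }
    if (is.null(viol)) break
    i <- viol[1]; j <- viol[2]
    drop <- if (miss[i] != miss[j]) {
      if (miss[i] > miss[j]) i else j
    } else if (maf[i] != maf[j]) {
      if (maf[i] < maf[j]) i else j
    } else {
      if (snps$position[i] >= snps$position[j]) i else j
    }
    keep <- setdiff(keep, drop)
  }
  snps$snp_id[keep]
}

# Small structured fixture shared by several tests.
make_two_pop_sim <- function(F = c(0.01, 0.01), n_per = 40, m = 1500, seed = 42,
                             ...) {
  simulate_structured_genotypes(sim_config(
    n_subpops = 2, samples_per_subpop = n_per, n_snps = m,
    subpop_F = F, seed = seed, ...))
}
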
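# Windowed pairwise-r2 LD pruning.

#' LD pruning parameters
#'
#' Defaults: a 200-SNP sliding window advancing by 25 SNPs, a maximum
#' r-squared of 0.2, applied twice (the second pass removes SNPs linked
#' across the window boundaries of the first, e.g. in extended high-LD
#' regions).
#'
#' @param window_snps window width in SNPs.
#' @param step_snps window step in SNPs.
#' @param r2_max maximum tolerated pairwise r-squared.
#' @param passes number of full pruning passes.
#' @return list of class `prune_config`.
#' @export
prune_config <- function(window_snps = 200, step_snps = 25,
                         r2_max = 0.2, passes = 2) {
  stopifnot(window_snps > step_snps, step_snps >= 1,
            r2_max > 0, r2_max < 1, passes >= 1)
  structure(list(window_snps = window_snps, step_snps = step_snps,
                 r2_max = r2_max, passes = passes), class = "prune_config")
}

#' Pairwise genotype r-squared
#'
#' Squared Pearson correlation of genotype dosages over pairwise-complete
#' samples; zero-variance input is defined as 0 (and so never triggers
#' pruning).
#'
#' @param gA,gB genotype dosage vectors of equal length.
#' @return r-squared in [0, 1].
#' @export
pairwise_r2 <- function(gA, gB) {
  ok <- !is.na(gA) & !is.na(gB)
  if (sum(ok) < 2) return(0)
  a <- gA[ok]; b <- gB[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(0)
  stats::cor(a, b)^2
}

# r2 matrix for a window of SNPs (columns), pairwise-complete,
# zero-variance columns give 0 against everything.
window_r2 <- function(g) {
  suppressWarnings(r <- stats::cor(g, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r^2
}

#' Windowed LD pruning
#'
#' Within each chromosome a window of `window_snps` surviving SNPs slides
#' in steps of `step_snps`; within the window, while any remaining pair
#' has r-squared above `r2_max`, the first such pair in scan order is
#' taken and one member removed: the SNP with the higher missingness,
#' ties broken toward the lower minor allele frequency, then toward the
#' larger position. The full sweep is repeated `passes` times on the
#' surviving set. Windows never span chromosomes.
#'
#' @param g genotype matrix.
#' @param snps SNP table aligned with the columns of `g`, sorted by
#'   chromosome and position (unsorted input is rejected).
#' @param config a [prune_config()].
#' @return character vector of kept SNP ids (in input order).
#' @export
prune_windowed <- function(g, snps, config = prune_config()) {
  stopifnot(ncol(g) == nrow(snps))
  ord <- order(snps$chromosome, snps$position)
  if (!identical(ord, seq_len(nrow(snps))))
    stop("SNPs must be sorted by chromosome and position")
  miss <- snp_missingness(g)
  maf <- pmin(snp_freq(g), 1 - snp_freq(g))
  pos <- snps$position

  keep <- rep(TRUE, ncol(g))
  # removal rule: TRUE if SNP i should be removed over SNP j
  prefer_remove_first <- function(i, j) {
    if (miss[i] != miss[j]) return(miss[i] > miss[j])
    if (maf[i] != maf[j]) return(maf[i] < maf[j])
    pos[i] >= pos[j]
  }
  for (pass in seq_len(config$passes)) {
    for (chr in unique(snps$chromosome)) {
      idx_chr <- which(keep & snps$chromosome == chr)
      if (length(idx_chr) < 2) next
      starts <- seq(1, length(idx_chr), by = config$step_snps)
      for (s in starts) {
        win <- idx_chr[s:min(s + config$window_snps - 1, length(idx_chr))]
        win <- win[keep[win]]
        if (length(win) < 2) next
        r2 <- window_r2(g[, win, drop = FALSE])
        diag(r2) <- 0
        repeat {
          viol <- which(r2 > config$r2_max, arr.ind = TRUE)
          viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
          if (!nrow(viol)) break
          viol <- viol[order(viol[, 1], viol[, 2]), , drop = FALSE]
          a <- win[viol[1, 1]]; b <- win[viol[1, 2]]
          out <- if (prefer_remove_first(a, b)) a else b
          keep[out] <- FALSE
          w <- which(win == out)
          r2[w, ] <- 0; r2[, w] <- 0
        }
      }
    }
  }
  snps$snp_id[keep]
}
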
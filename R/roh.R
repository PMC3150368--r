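# Runs of homozygosity: sliding-window detection, inbreeding
# coefficients, and Poisson models of segment counts over geography.

#' ROH scan parameters
#'
#' Defaults: a 20-SNP sliding window that may contain at most 1
#' heterozygote to be called homozygous; a SNP is in a homozygous segment
#' when at least 10% of the windows overlapping it are homozygous;
#' called segments must be at least 1 Mb long, contain at least 50 SNPs
#' and have at most 5% heterozygous SNPs.
#'
#' @param window_snps window width in SNPs.
#' @param window_max_het maximum heterozygotes per homozygous window.
#' @param overlap_frac_min minimum fraction of overlapping homozygous
#'   windows for a SNP to be a segment candidate (inclusive).
#' @param seg_min_bp minimum segment length in bp.
#' @param seg_min_snps minimum SNPs per segment.
#' @param seg_max_het_frac maximum heterozygote fraction per segment.
#' @return list of class `roh_config`.
#' @export
roh_config <- function(window_snps = 20, window_max_het = 1,
                       overlap_frac_min = 0.10, seg_min_bp = 1e6,
                       seg_min_snps = 50, seg_max_het_frac = 0.05) {
  stopifnot(window_snps >= 1, window_max_het >= 0,
            overlap_frac_min > 0, overlap_frac_min <= 1,
            seg_min_bp > 0, seg_min_snps > 0,
            seg_max_het_frac > 0, seg_max_het_frac <= 1)
  structure(list(window_snps = window_snps, window_max_het = window_max_het,
                 overlap_frac_min = overlap_frac_min, seg_min_bp = seg_min_bp,
                 seg_min_snps = seg_min_snps,
                 seg_max_het_frac = seg_max_het_frac), class = "roh_config")
}

#' Scan one sample for runs of homozygosity
#'
#' Per chromosome, every contiguous window of `window_snps` SNPs is
#' called homozygous when its heterozygote count does not exceed
#' `window_max_het` (missing genotypes count as neither heterozygous nor
#' homozygous). Each SNP's overlap fraction is the share of windows
#' covering it that are homozygous; SNPs at or above `overlap_frac_min`
#' are candidates, maximal candidate runs become segments (boundaries at
#' the first and last candidate SNP), and segments must then pass the
#' length, SNP-count and heterozygote-fraction filters. Chromosomes with
#' fewer SNPs than the window produce no calls (with a warning).
#'
#' @param g_sample genotype dosage vector for one sample.
#' @param snps SNP table aligned with `g_sample`, position-sorted within
#'   chromosome.
#' @param config a [roh_config()].
#' @return data.frame of segments: chromosome, start, end (1-based,
#'   inclusive), n_snps, n_het.
#' @export
scan_roh <- function(g_sample, snps, config = roh_config()) {
  stopifnot(length(g_sample) == nrow(snps))
  W <- config$window_snps
  out <- list()
  for (chr in unique(snps$chromosome)) {
    idx <- which(snps$chromosome == chr)
    pos <- snps$position[idx]
    if (is.unsorted(pos)) stop("SNPs must be position-sorted within chromosome")
    m <- length(idx)
    if (m < W) {
      warning("chromosome ", chr, " has fewer SNPs than the window; no calls")
      next
    }
    het <- as.integer(!is.na(g_sample[idx]) & g_sample[idx] == 1L)
    # heterozygote count per window via cumulative sums
    cs <- c(0L, cumsum(het))
    n_win <- m - W + 1
    win_het <- cs[(W + 1):(m + 1)] - cs[1:n_win]
    win_hom <- win_het <= config$window_max_het
    # SNP j is covered by windows max(1, j - W + 1) .. min(j, n_win)
    ch <- c(0, cumsum(win_hom))
    lo <- pmax(1, seq_len(m) - W + 1)
    hi <- pmin(seq_len(m), n_win)
    n_cov <- hi - lo + 1
    n_hom <- ch[hi + 1] - ch[lo]
    frac <- n_hom / n_cov
    cand <- frac >= config$overlap_frac_min
    r <- rle(cand)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      a <- starts[k]; b <- ends[k]
      n_snps_run <- b - a + 1
      n_het_run <- sum(het[a:b])
      len <- pos[b] - pos[a] + 1
      if (len >= config$seg_min_bp && n_snps_run >= config$seg_min_snps &&
          n_het_run / n_snps_run <= config$seg_max_het_frac) {
        out[[length(out) + 1]] <- data.frame(
          chromosome = chr, start = pos[a], end = pos[b],
          n_snps = n_snps_run, n_het = n_het_run)
      }
    }
  }
  if (!length(out))
    return(data.frame(chromosome = integer(), start = integer(),
                      end = integer(), n_snps = integer(), n_het = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan all samples for runs of homozygosity
#'
#' @param g genotype matrix.
#' @param snps SNP table aligned with the columns of `g`.
#' @param config a [roh_config()].
#' @return data.frame of segments with a leading `sample_id` column.
#' @export
scan_roh_all <- function(g, snps, config = roh_config()) {
  segs <- lapply(rownames(g) %||% seq_len(nrow(g)), function(id) {
    s <- scan_roh(g[id, ], snps, config)
    if (nrow(s)) cbind(sample_id = id, s) else NULL
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs))
    return(data.frame(sample_id = character(), chromosome = integer(),
                      start = integer(), end = integer(),
                      n_snps = integer(), n_het = integer()))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Per-sample ROH segment counts
#'
#' @param segments data.frame from [scan_roh_all()].
#' @param sample_ids ids to report (zero counts included).
#' @return data.frame with `sample_id` and `n_segments`.
#' @export
roh_counts <- function(segments, sample_ids) {
  counts <- table(factor(segments$sample_id, levels = sample_ids))
  data.frame(sample_id = sample_ids, n_segments = as.integer(counts))
}

#' Method-of-moments inbreeding coefficient
#'
#' `F = (O_hom - E_hom) / (N - E_hom)` per sample, where `O_hom` is the
#' observed number of homozygous genotypes over the sample's non-missing
#' SNPs, and `E_hom = sum_j (1 - 2 p_j (1 - p_j) * A_j / (A_j - 1))` is
#' the expectation under Hardy-Weinberg with the small-sample correction
#' `A_j / (A_j - 1)` (A_j = number of alleles used to estimate p_j).
#'
#' @param g genotype matrix.
#' @param phat optional per-SNP allele frequencies; estimated from `g`
#'   when omitted.
#' @param n_alleles optional per-SNP allele counts behind `phat`.
#' @return numeric vector of per-sample inbreeding coefficients.
#' @export
inbreeding_coefficient <- function(g, phat = NULL, n_alleles = NULL) {
  if (is.null(phat)) {
    n_alleles <- 2 * colSums(!is.na(g))
    phat <- colSums(g, na.rm = TRUE) / n_alleles
  }
  if (is.null(n_alleles)) stop("n_alleles must accompany user-supplied phat")
  corr <- ifelse(n_alleles > 1, n_alleles / (n_alleles - 1), NA_real_)
  e_hom_j <- 1 - 2 * phat * (1 - phat) * corr
  obs <- !is.na(g)
  o_hom <- rowSums(obs & g != 1L, na.rm = TRUE)
  e_hom <- as.vector(obs %*% ifelse(is.finite(e_hom_j), e_hom_j, 0))
  n_used <- rowSums(obs)
  denom <- n_used - e_hom
  if (any(abs(denom) < .Machine$double.eps * n_used))
    stop("degenerate inbreeding denominator (N == E_hom)")
  stats::setNames((o_hom - e_hom) / denom, rownames(g))
}

#' Poisson model of ROH segment counts over geography
#'
#' Log-link count regression of per-sample segment counts on either
#' latitude (continuous) or group (categorical, with a configurable
#' baseline), adjusting for source study as a categorical covariate.
#' Group-coefficient p-values are adjusted for multiple testing
#' (Bonferroni by default).
#'
#' @param counts data.frame with columns `n_segments`, `study`, and
#'   either `latitude` or `group`.
#' @param covariate `"latitude"` or `"group"`.
#' @param baseline baseline group label (group model only).
#' @param p_adjust_method multiplicity adjustment for group coefficients.
#' @return data.frame of coefficients: term, estimate, se, p (and
#'   `p_adjusted` for group terms).
#' @export
segment_count_model <- function(counts, covariate = c("latitude", "group"),
                                baseline = NULL,
                                p_adjust_method = "bonferroni") {
  covariate <- match.arg(covariate)
  stopifnot(all(c("n_segments", "study", covariate) %in% names(counts)))
  counts$study <- factor(counts$study)
  adjust_study <- nlevels(counts$study) > 1
  if (covariate == "latitude") {
    f <- if (adjust_study) n_segments ~ latitude + study else
      n_segments ~ latitude
    fit <- stats::glm(f, data = counts, family = stats::poisson())
    cf <- summary(fit)$coefficients
    out <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                      p = cf[, 4], row.names = NULL)
  } else {
    counts$group <- factor(counts$group)
    if (!is.null(baseline)) counts$group <- stats::relevel(counts$group, baseline)
    f <- if (adjust_study) n_segments ~ group + study else n_segments ~ group
    fit <- stats::glm(f, data = counts, family = stats::poisson())
    cf <- summary(fit)$coefficients
    out <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                      p = cf[, 4], row.names = NULL)
    is_group <- grepl("^group", out$term)
    out$p_adjusted <- NA_real_
    out$p_adjusted[is_group] <- stats::p.adjust(out$p[is_group],
                                                method = p_adjust_method)
  }
  out
}
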
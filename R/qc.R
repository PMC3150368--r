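# Multi-study merging and SNP/sample quality control.

#' QC thresholds
#'
#' Defaults follow common GWAS merge practice: SNPs must have a call rate
#' of at least 95% in every contributing study; minor allele frequency,
#' Hardy-Weinberg equilibrium (exact test, p < 1e-6) and the one-vs-rest
#' allele-frequency comparison (p < 1e-6 in any comparison) are assessed
#' on all studies combined; samples are dropped when their estimated
#' genome-wide IBD sharing with another sample exceeds 0.20 or their
#' missingness on the post-QC marker set exceeds 2%.
#'
#' @param snp_call_rate_min per-study SNP call-rate minimum.
#' @param maf_min combined minor-allele-frequency minimum.
#' @param hwe_p_min combined HWE exact-test p-value minimum.
#' @param one_vs_rest_p_min one-vs-rest chi-square p-value minimum.
#' @param pihat_max maximum tolerated pairwise IBD proportion.
#' @param sample_missing_max maximum tolerated per-sample missingness.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(snp_call_rate_min = 0.95, maf_min = 0.01,
                      hwe_p_min = 1e-6, one_vs_rest_p_min = 1e-6,
                      pihat_max = 0.20, sample_missing_max = 0.02) {
  vals <- c(snp_call_rate_min, maf_min, hwe_p_min, one_vs_rest_p_min,
            pihat_max, sample_missing_max)
  if (any(vals <= 0) || any(vals >= 1))
    stop("all QC thresholds must lie in (0, 1)")
  structure(list(snp_call_rate_min = snp_call_rate_min, maf_min = maf_min,
                 hwe_p_min = hwe_p_min, one_vs_rest_p_min = one_vs_rest_p_min,
                 pihat_max = pihat_max, sample_missing_max = sample_missing_max),
            class = "qc_config")
}

#' Intersect and merge genotype datasets
#'
#' Restricts all datasets to the SNPs of a designated reference dataset
#' (by default the one with the most samples) that are present in every
#' dataset, reconciles allele orientation against the reference
#' (swapped alleles are recoded `2 - g`; complementary-strand labels are
#' normalized; strand-ambiguous A/T and C/G SNPs cannot be normalized and
#' are dropped when their labels disagree), drops SNPs whose allele pairs
#' cannot be reconciled, and concatenates samples with study provenance.
#'
#' @param datasets list of datasets, each a list with `genotypes`, `snps`,
#'   `samples` (as returned by [read_plink_binary()] or the simulator).
#' @param reference index of the reference dataset; default largest.
#' @return list with merged `genotypes`, `snps`, `samples`, plus
#'   `dropped_allele_mismatch` (SNP ids dropped for irreconcilable
#'   alleles) and `recoded` (per-dataset counts of orientation recodes).
#' @export
intersect_and_merge <- function(datasets, reference = NULL) {
  if (length(datasets) < 2) stop("need at least two datasets to merge")
  n_samples <- vapply(datasets, function(d) nrow(d$genotypes), integer(1))
  if (is.null(reference)) reference <- which.max(n_samples)
  ref <- datasets[[reference]]

  shared <- ref$snps$snp_id
  for (d in datasets) shared <- intersect(shared, d$snps$snp_id)
  if (!length(shared)) stop("no SNPs shared across all datasets")

  all_ids <- unlist(lapply(datasets, function(d) d$samples$sample_id))
  if (anyDuplicated(all_ids))
    stop("duplicate sample ids across datasets: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))

  ref_snps <- ref$snps[match(shared, ref$snps$snp_id), ]
  drop <- rep(FALSE, length(shared))
  recoded <- integer(length(datasets))
  blocks <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    idx <- match(shared, d$snps$snp_id)
    g <- d$genotypes[, idx, drop = FALSE]
    a1 <- d$snps$allele1[idx]; a2 <- d$snps$allele2[idx]
    r1 <- ref_snps$allele1; r2 <- ref_snps$allele2
    same <- a1 == r1 & a2 == r2
    swapped <- a1 == r2 & a2 == r1
    c1 <- complement_base(a1); c2 <- complement_base(a2)
    ambiguous <- is_ambiguous_pair(a1, a2) | is_ambiguous_pair(r1, r2)
    comp_same <- !same & !swapped & !ambiguous & c1 == r1 & c2 == r2
    comp_swapped <- !same & !swapped & !ambiguous & c1 == r2 & c2 == r1
    unresolved <- !(same | swapped | comp_same | comp_swapped)
    drop <- drop | unresolved
    flip <- swapped | comp_swapped
    if (any(flip)) {
      g[, flip] <- 2L - g[, flip, drop = FALSE]
      recoded[i] <- sum(flip)
    }
    colnames(g) <- shared
    blocks[[i]] <- g
  }
  keep <- !drop
  g_merged <- do.call(rbind, lapply(blocks, function(b) b[, keep, drop = FALSE]))
  samples <- do.call(rbind, lapply(seq_along(datasets), function(i) {
    s <- datasets[[i]]$samples
    s$dataset <- i
    if (!"study" %in% names(s)) s$study <- sprintf("dataset%d", i)
    s[c("sample_id", "study",
        intersect(c("group", "latitude", "longitude", "ancestry"), names(s)),
        "dataset")]
  }))
  rownames(g_merged) <- samples$sample_id
  list(genotypes = g_merged,
       snps = ref_snps[keep, , drop = FALSE],
       samples = samples,
       dropped_allele_mismatch = shared[drop],
       recoded = recoded)
}

#' Per-study SNP call-rate filter
#'
#' A SNP is removed when its call rate falls below the threshold in
#' any single study.
#'
#' @param g genotype matrix.
#' @param study_labels per-sample study labels.
#' @param threshold minimum per-study call rate.
#' @return list with `kept`/`removed` SNP ids and the per-study
#'   call-rate matrix.
#' @export
snp_call_rate_filter <- function(g, study_labels, threshold = 0.95) {
  studies <- unique(study_labels)
  sizes <- table(study_labels)
  if (any(sizes == 0)) stop("study with zero samples")
  rates <- vapply(studies, function(s)
    colMeans(!is.na(g[study_labels == s, , drop = FALSE])), numeric(ncol(g)))
  rates <- matrix(rates, ncol = length(studies),
                  dimnames = list(colnames(g), studies))
  bad <- apply(rates < threshold, 1, any)
  list(kept = colnames(g)[!bad], removed = colnames(g)[bad], call_rates = rates)
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test on genotype counts: conditional on the allele
#' counts, the probability of every heterozygote count of the same parity
#' is evaluated, and the p-value is the sum of probabilities no greater
#' than that of the observed configuration. Computed by the standard
#' stable recurrence over heterozygote counts. Monomorphic SNPs return 1
#' by convention.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (scalars).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n < 1) stop("need at least one genotype")
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  if (n_rare == 0 || n_rare == 2 * n) return(1)
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # unnormalized probabilities by recurrence:
  # P(h+2)/P(h) = 4 * hom_r(h) * hom_c(h) / ((h+2) * (h+1))
  probs <- numeric(length(hets))
  probs[1] <- 1
  for (i in seq_len(length(hets) - 1)) {
    h <- hets[i]
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    probs[i + 1] <- probs[i] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

#' HWE exact p-values for every SNP of a genotype matrix
#'
#' @param g genotype matrix (allele1 dosage).
#' @return numeric vector of exact p-values, one per SNP.
#' @export
hwe_exact_scan <- function(g) {
  n2 <- colSums(!is.na(g) & g == 2L)
  n1 <- colSums(!is.na(g) & g == 1L)
  n0 <- colSums(!is.na(g) & g == 0L)
  vapply(seq_len(ncol(g)), function(j) {
    if (n0[j] + n1[j] + n2[j] == 0) return(NA_real_)
    hwe_exact_test(n2[j], n1[j], n0[j])
  }, numeric(1))
}

#' One-vs-rest allele-frequency comparison
#'
#' For each study, a 1-df allelic chi-square compares the allele counts
#' of that study against all other studies pooled; a SNP is flagged when
#' its smallest p-value over studies falls below the threshold. Designed
#' to catch undetected strand flips and platform artifacts. Zero-variance
#' tables (monomorphic pooled SNP, or empty side) give p = 1.
#'
#' @param g genotype matrix.
#' @param study_labels per-sample study labels.
#' @return list with `p_matrix` (SNP x study), `min_p` per SNP, and the
#'   study labels; with fewer than two studies all entries are empty.
#' @export
one_vs_rest_frequency_test <- function(g, study_labels) {
  studies <- unique(study_labels)
  if (length(studies) < 2)
    return(list(p_matrix = matrix(numeric(0), ncol(g), 0,
                                  dimnames = list(colnames(g), NULL)),
                min_p = rep(NA_real_, ncol(g)), studies = studies))
  pmat <- matrix(NA_real_, ncol(g), length(studies),
                 dimnames = list(colnames(g), studies))
  tot_a1 <- colSums(g, na.rm = TRUE)
  tot_n <- 2 * colSums(!is.na(g))
  for (s in seq_along(studies)) {
    in_s <- study_labels == studies[s]
    a1_s <- colSums(g[in_s, , drop = FALSE], na.rm = TRUE)
    n_s <- 2 * colSums(!is.na(g[in_s, , drop = FALSE]))
    a1_r <- tot_a1 - a1_s
    n_r <- tot_n - n_s
    pmat[, s] <- allelic_chisq_p(a1_s, n_s - a1_s, a1_r, n_r - a1_r)
  }
  list(p_matrix = pmat, min_p = apply(pmat, 1, min), studies = studies)
}

# 1-df allelic chi-square p-value from a 2x2 allele-count table
# (vectorized); degenerate tables return p = 1.
allelic_chisq_p <- function(a1, b1, a2, b2) {
  n <- a1 + b1 + a2 + b2
  r1 <- a1 + b1; r2 <- a2 + b2
  c1 <- a1 + a2; c2 <- b1 + b2
  stat <- n * (a1 * b2 - b1 * a2)^2 / (r1 * r2 * c1 * c2)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[!is.finite(stat)] <- 1
  p
}

#' Pairwise IBD estimation (PI_HAT)
#'
#' Method-of-moments estimation of the IBD-state probabilities from
#' observed IBS counts, given allele frequencies estimated on the full
#' sample. Expected IBS-given-IBD probabilities use unbiased
#' falling-factorial estimators of the allele-frequency monomials, which
#' removes the finite-sample bias of plugging in sample frequencies.
#' Estimated probabilities are truncated into [0, 1] and renormalized;
#' `pihat = P(IBD=2) + P(IBD=1)/2`.
#'
#' @param g genotype matrix (at least two samples). SNPs missing in a
#'   pair are excluded pairwise.
#' @param min_informative pairs with fewer informative SNPs than this are
#'   flagged unreliable (NA in the `reliable` matrix).
#' @param pairs optional two-column matrix of sample index pairs; when
#'   supplied only those entries of the matrix are filled in.
#' @return list with symmetric `pihat` matrix (diagonal NA), the
#'   `n_snps` informative-count matrix, and a logical `reliable` matrix.
#' @export
estimate_pihat <- function(g, min_informative = 100, pairs = NULL) {
  n <- nrow(g)
  if (n < 2) stop("need at least two samples")
  x <- colSums(g, na.rm = TRUE)                      # allele1 count
  an <- 2 * colSums(!is.na(g))                       # total alleles
  y <- an - x
  # unbiased estimators of p^a q^b via falling factorials
  ff <- function(v, k) {
    out <- v
    if (k >= 2) for (i in 1:(k - 1)) out <- out * (v - i)
    out
  }
  d4 <- ff(an, 4); d3 <- ff(an, 3)
  p2q2 <- x * (x - 1) * y * (y - 1) / d4
  p3q  <- ff(x, 3) * y / d4
  pq3  <- x * ff(y, 3) / d4
  p4   <- ff(x, 4) / d4
  q4   <- ff(y, 4) / d4
  p2q  <- x * (x - 1) * y / d3
  pq2  <- x * y * (y - 1) / d3
  p3   <- ff(x, 3) / d3
  q3   <- ff(y, 3) / d3
  e_ibs0_ibd0 <- 2 * p2q2
  e_ibs1_ibd0 <- 4 * p3q + 4 * pq3
  e_ibs2_ibd0 <- p4 + q4 + 4 * p2q2
  e_ibs1_ibd1 <- 2 * p2q + 2 * pq2
  e_ibs2_ibd1 <- p3 + q3 + p2q + pq2
  usable <- is.finite(e_ibs0_ibd0) & an >= 4

  pihat <- matrix(NA_real_, n, n, dimnames = list(rownames(g), rownames(g)))
  n_inf <- matrix(NA_integer_, n, n, dimnames = dimnames(pihat))
  if (is.null(pairs)) {
    pairs <- cbind(unlist(lapply(seq_len(n - 1), function(i) rep(i, n - i))),
                   unlist(lapply(seq_len(n - 1), function(i) (i + 1):n)))
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2)
  }
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    {
      gi <- g[i, ]
      gj <- g[j, ]
      ok <- usable & !is.na(gi) & !is.na(gj)
      m_ok <- sum(ok)
      d <- abs(gi[ok] - gj[ok])
      ibs0 <- sum(d == 2); ibs1 <- sum(d == 1); ibs2 <- m_ok - ibs0 - ibs1
      E00 <- sum(e_ibs0_ibd0[ok]); E10 <- sum(e_ibs1_ibd0[ok])
      E20 <- sum(e_ibs2_ibd0[ok]); E11 <- sum(e_ibs1_ibd1[ok])
      E21 <- sum(e_ibs2_ibd1[ok])
      z0 <- ibs0 / E00
      z1 <- (ibs1 - z0 * E10) / E11
      z2 <- (ibs2 - z0 * E20 - z1 * E21) / m_ok
      z <- pmin(pmax(c(z0, z1, z2), 0), 1)
      z <- z / sum(z)
      pihat[i, j] <- pihat[j, i] <- z[3] + z[2] / 2
      n_inf[i, j] <- n_inf[j, i] <- m_ok
    }
  }
  list(pihat = pihat, n_snps = n_inf, reliable = n_inf >= min_informative)
}

#' Remove related samples
#'
#' Greedy resolution: while any pair exceeds the threshold, the pair with
#' the largest IBD estimate is taken and the member with the higher
#' genotype missingness is removed (ties broken toward the higher sample
#' index). Guarantees no remaining pair exceeds the threshold.
#'
#' @param pihat symmetric IBD matrix from [estimate_pihat()].
#' @param missingness per-sample missingness, aligned with the matrix.
#' @param threshold removal threshold (strict `>`).
#' @return character vector of removed sample ids.
#' @export
remove_related <- function(pihat, missingness, threshold = 0.20) {
  stopifnot(nrow(pihat) == length(missingness))
  active <- rep(TRUE, nrow(pihat))
  removed <- integer(0)
  repeat {
    p <- pihat
    p[!active, ] <- NA; p[, !active] <- NA
    p[lower.tri(p, diag = TRUE)] <- NA
    if (all(is.na(p)) || max(p, na.rm = TRUE) <= threshold) break
    idx <- which(p == max(p, na.rm = TRUE), arr.ind = TRUE)[1, ]
    i <- idx[1]; j <- idx[2]
    drop <- if (missingness[i] > missingness[j]) i
            else if (missingness[j] > missingness[i]) j
            else max(i, j)
    active[drop] <- FALSE
    removed <- c(removed, drop)
  }
  rownames(pihat)[removed] %||% as.character(removed)
}

#' Sample missingness filter
#'
#' Removes samples whose genotype missingness on the supplied (post-QC)
#' marker set strictly exceeds the threshold.
#'
#' @param g genotype matrix restricted to the post-QC SNPs.
#' @param threshold maximum tolerated missingness (strict `>`).
#' @return character vector of removed sample ids.
#' @export
sample_missingness_filter <- function(g, threshold = 0.02) {
  miss <- sample_missingness(g)
  rownames(g)[miss > threshold]
}

#' Run all SNP-level QC filters and build the report accounting
#'
#' Applies the per-study call-rate, combined HWE, combined MAF and
#' one-vs-rest filters to the same starting SNP set and reports, per
#' filter, both the total number of SNPs it removes and the number it
#' alone removes ("solely for that reason"); the two accountings satisfy
#' solely <= total and the kept set passes every filter.
#'
#' @param g genotype matrix.
#' @param study_labels per-sample study labels.
#' @param config a [qc_config()].
#' @return list with `kept` SNP ids, per-filter removal id sets, and a
#'   `summary` data.frame (filter, removed, removed_solely).
#' @export
run_snp_qc <- function(g, study_labels, config = qc_config()) {
  cr <- snp_call_rate_filter(g, study_labels, config$snp_call_rate_min)
  maf <- snp_freq(g)
  maf <- pmin(maf, 1 - maf)
  removed_maf <- colnames(g)[maf < config$maf_min]
  hwe_p <- hwe_exact_scan(g)
  removed_hwe <- colnames(g)[!is.na(hwe_p) & hwe_p < config$hwe_p_min]
  ovr <- one_vs_rest_frequency_test(g, study_labels)
  removed_ovr <- if (length(ovr$studies) < 2) character(0) else
    colnames(g)[!is.na(ovr$min_p) & ovr$min_p < config$one_vs_rest_p_min]

  sets <- list(call_rate = cr$removed, hwe = removed_hwe,
               maf = removed_maf, one_vs_rest = removed_ovr)
  all_removed <- unique(unlist(sets))
  n_hits <- table(factor(unlist(sets), levels = all_removed))
  solely <- vapply(sets, function(s) sum(n_hits[s] == 1L), integer(1))
  summary <- data.frame(
    filter = names(sets),
    removed = vapply(sets, length, integer(1)),
    removed_solely = solely,
    row.names = NULL)
  list(kept = setdiff(colnames(g), all_removed),
       removed = sets,
       summary = summary,
       hwe_p = hwe_p,
       one_vs_rest_min_p = ovr$min_p,
       call_rates = cr$call_rates)
}

#' Run sample-level QC (relatedness then missingness)
#'
#' Follows the stage order of the pipeline: relatedness removal on the
#' post-SNP-QC marker set, then the missingness filter on the remaining
#' samples.
#'
#' @param g genotype matrix restricted to post-QC SNPs.
#' @param config a [qc_config()].
#' @return list with `removed_related`, `removed_missing`, `kept` ids and
#'   the pihat estimate object.
#' @export
run_sample_qc <- function(g, config = qc_config()) {
  pih <- estimate_pihat(g)
  miss <- sample_missingness(g)
  rel <- remove_related(pih$pihat, miss, config$pihat_max)
  g2 <- g[setdiff(rownames(g), rel), , drop = FALSE]
  mis <- sample_missingness_filter(g2, config$sample_missing_max)
  list(removed_related = rel, removed_missing = mis,
       kept = setdiff(rownames(g), c(rel, mis)), pihat = pih)
}
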
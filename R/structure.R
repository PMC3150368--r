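# PCA of pruned genotypes, ancestry exclusion, projection, geography.

#' Patterson normalization of a genotype matrix
#'
#' Each SNP column j is centered by its mean dosage and scaled by
#' `sqrt(p_j (1 - p_j))`, where `p_j = (1 + sum g_ij) / (2 + 2 n_j)` is a
#' shrunk allele-frequency estimate over the `n_j` non-missing entries;
#' missing entries are set to 0 after centering, so they sit at the
#' column mean and carry no signal.
#'
#' @param g genotype matrix (monomorphic SNPs should be excluded upstream
#'   by the MAF filter; columns that are entirely missing are an error).
#' @return list of class `patterson_norm` with `x` (normalized matrix),
#'   `center`, `scale` and `phat`.
#' @export
patterson_normalize <- function(g) {
  n_j <- colSums(!is.na(g))
  if (any(n_j == 0)) stop("column with all entries missing")
  mu <- colMeans(g, na.rm = TRUE)
  phat <- (1 + colSums(g, na.rm = TRUE)) / (2 + 2 * n_j)
  s <- sqrt(phat * (1 - phat))
  x <- sweep(g, 2, mu, "-")
  x <- sweep(x, 2, s, "/")
  x[is.na(x)] <- 0
  structure(list(x = x, center = mu, scale = s, phat = phat),
            class = "patterson_norm")
}

#' Principal component analysis of normalized genotypes
#'
#' Top-K eigendecomposition of the sample-sample covariance of the
#' Patterson-normalized matrix. Reported eigenvalues equal the squared
#' singular values divided by (n - 1). Each component is oriented so that
#' its largest-magnitude SNP weight is positive, making scores and
#' projections reproducible across runs.
#'
#' @param norm a `patterson_norm` object (or a plain normalized matrix
#'   with an attached `center`/`scale`, see [patterson_normalize()]).
#' @param K number of components (K <= min(n - 1, number of SNPs)).
#' @return list of class `pca_model` with `eigenvalues` (descending),
#'   `scores` (samples x K), `weights` (SNPs x K), and the normalization
#'   constants `center` and `scale` used for projection.
#' @export
compute_pca <- function(norm, K) {
  stopifnot(inherits(norm, "patterson_norm"))
  x <- norm$x
  n <- nrow(x)
  if (n < K + 1) stop("need at least K + 1 samples")
  if (K > min(n - 1, ncol(x))) stop("K exceeds the rank of the data")
  cov_ss <- tcrossprod(x)
  e <- eigen(cov_ss, symmetric = TRUE)
  sv2 <- pmax(e$values[seq_len(K)], 0)          # squared singular values
  sigma <- sqrt(sv2)
  scores <- e$vectors[, seq_len(K), drop = FALSE] %*% diag(sigma, K)
  weights <- crossprod(x, e$vectors[, seq_len(K), drop = FALSE])
  weights <- sweep(weights, 2, ifelse(sigma > 0, sigma, 1), "/")
  for (k in seq_len(K)) {
    jmax <- which.max(abs(weights[, k]))
    if (weights[jmax, k] < 0) {
      weights[, k] <- -weights[, k]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(K)))
  dimnames(weights) <- list(colnames(x), paste0("PC", seq_len(K)))
  structure(list(eigenvalues = sv2 / (n - 1), scores = scores,
                 weights = weights, center = norm$center, scale = norm$scale),
            class = "pca_model")
}

#' Fit a PCA model from raw genotypes
#'
#' Convenience wrapper: [patterson_normalize()] then [compute_pca()].
#'
#' @param g genotype matrix.
#' @param K number of components.
#' @return a `pca_model`.
#' @export
pca_fit <- function(g, K = 10) {
  compute_pca(patterson_normalize(g), K)
}

#' Project new samples onto a fitted PCA model
#'
#' New genotypes are normalized with the model's stored per-SNP center
#' and scale (missing entries become 0 after centering) and multiplied by
#' the SNP weight matrix, i.e. scores are sums of the per-SNP allelic
#' weights. SNP sets must be aligned by id and orientation beforehand.
#' A sample with all genotypes missing lands exactly at the origin.
#'
#' @param model a `pca_model`.
#' @param g_new samples x SNPs matrix over the model's SNPs, same order.
#' @return scores matrix (samples x K).
#' @export
project_samples <- function(model, g_new) {
  stopifnot(inherits(model, "pca_model"))
  if (ncol(g_new) != nrow(model$weights))
    stop("SNP set of new samples does not match the model")
  if (!is.null(colnames(g_new)) &&
      !identical(colnames(g_new), rownames(model$weights)))
    stop("SNP ids of new samples do not match the model")
  x <- sweep(g_new, 2, model$center, "-")
  x <- sweep(x, 2, model$scale, "/")
  x[is.na(x)] <- 0
  out <- x %*% model$weights
  rownames(out) <- rownames(g_new)
  out
}

#' One-sample test of mean zero
#'
#' Two-sided one-sample t test of the mean of a score vector against 0,
#' used to ask whether projected external samples shift systematically
#' along a component. Zero-variance input with a nonzero mean reports the
#' double-precision underflow floor instead of an exact zero.
#'
#' @param scores numeric vector, length >= 2.
#' @return list with `t`, `p`, `mean`, `n`.
#' @export
mean_nonzero_test <- function(scores) {
  n <- length(scores)
  if (n < 2) stop("need at least two values")
  if (stats::sd(scores) == 0) {
    if (mean(scores) == 0) return(list(t = 0, p = 1, mean = 0, n = n))
    return(list(t = sign(mean(scores)) * Inf, p = .Machine$double.xmin,
                mean = mean(scores), n = n))
  }
  tt <- stats::t.test(scores, mu = 0)
  list(t = unname(tt$statistic), p = tt$p.value, mean = mean(scores), n = n)
}

#' Define a linear ancestry cutoff in the (PC1, PC2) plane
#'
#' @param normal length-2 normal vector of the boundary (normalized to
#'   unit length); samples with `normal . (PC1, PC2) > offset` are on the
#'   exclusion side.
#' @param offset boundary offset along the normal.
#' @return list of class `ancestry_cutoff`.
#' @export
ancestry_cutoff <- function(normal, offset) {
  stopifnot(length(normal) == 2, any(normal != 0))
  nrm <- sqrt(sum(normal^2))
  structure(list(normal = normal / nrm, offset = offset / nrm),
            class = "ancestry_cutoff")
}

#' Remove samples on the exclusion side of an ancestry cutoff
#'
#' Samples strictly beyond the boundary (`normal . x > offset`) are
#' removed; samples exactly on the line are kept. The cutoff is always
#' supplied by configuration, never hard-coded.
#'
#' @param model a `pca_model` (its first two score columns are used) or a
#'   scores matrix with >= 2 columns.
#' @param cutoff an [ancestry_cutoff()].
#' @return character vector of removed sample ids.
#' @export
ancestry_cutoff_filter <- function(model, cutoff) {
  stopifnot(inherits(cutoff, "ancestry_cutoff"))
  scores <- if (inherits(model, "pca_model")) model$scores else model
  stopifnot(ncol(scores) >= 2)
  proj <- scores[, 1] * cutoff$normal[1] + scores[, 2] * cutoff$normal[2]
  rownames(scores)[proj > cutoff$offset]
}

#' Nearest-neighbor outlier removal
#'
#' For k = 1..k_max, each sample's Euclidean distance to its k-th nearest
#' neighbor is computed (on the full sample set), the vector of k-th-NN
#' distances is standardized to z-scores, and samples with z > z_max are
#' marked for removal; removals accumulate across k. The sweep over
#' higher k catches small tight clusters of mutually close outliers that
#' the k = 1 pass misses.
#'
#' @param x samples x features matrix (normalized genotypes by default in
#'   the pipeline; PC scores work too).
#' @param k_max number of neighbor ranks to sweep.
#' @param z_max z-score removal threshold.
#' @return character vector of removed sample ids.
#' @export
nearest_neighbor_outliers <- function(x, k_max = 5, z_max = 4) {
  n <- nrow(x)
  if (n <= k_max + 1) stop("need more than k_max + 1 samples")
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  sorted <- apply(d, 1, sort)          # columns = samples, rows = ranks
  removed <- character(0)
  for (k in seq_len(k_max)) {
    dk <- sorted[k, ]
    z <- (dk - mean(dk)) / stats::sd(dk)
    removed <- union(removed, rownames(x)[z > z_max])
  }
  removed
}

#' Regression of a principal component on geography
#'
#' Ordinary least squares of a component on latitude, on longitude, and
#' the increment in R-squared from adding longitude to the latitude
#' model.
#'
#' @param pc numeric score vector.
#' @param latitude,longitude per-sample coordinates.
#' @return list with `r2_latitude`, `r2_longitude`, `delta_r2_longitude`
#'   and the two marginal model p-values.
#' @export
pc_geography_regression <- function(pc, latitude, longitude) {
  ok <- !is.na(pc) & !is.na(latitude) & !is.na(longitude)
  pc <- pc[ok]; latitude <- latitude[ok]; longitude <- longitude[ok]
  f_lat <- stats::lm(pc ~ latitude)
  f_lon <- stats::lm(pc ~ longitude)
  f_both <- stats::lm(pc ~ latitude + longitude)
  r2 <- function(f) suppressWarnings(summary(f)$r.squared)
  pval <- function(f) suppressWarnings(stats::coef(summary(f))[2, 4])
  list(r2_latitude = r2(f_lat), r2_longitude = r2(f_lon),
       delta_r2_longitude = r2(f_both) - r2(f_lat),
       p_latitude = pval(f_lat), p_longitude = pval(f_lon), n = sum(ok))
}

#' Nagelkerke pseudo-R-squared of a logistic model
#'
#' Fits outcome ~ predictors by maximum likelihood and returns
#' `(1 - (L0/L1)^(2/n)) / (1 - L0^(2/n))`, the likelihood-ratio measure
#' rescaled to a [0, 1] range. Perfect separation is reported as a
#' convergence failure rather than a number.
#'
#' @param outcome binary vector (0/1 or logical).
#' @param predictors numeric vector, matrix or data.frame.
#' @return Nagelkerke pseudo-R-squared in [0, 1].
#' @export
nagelkerke_r2 <- function(outcome, predictors) {
  y <- as.integer(outcome)
  stopifnot(all(y %in% c(0L, 1L)))
  X <- as.data.frame(predictors)
  dat <- cbind(data.frame(.y = y), X)
  fit <- suppressWarnings(stats::glm(.y ~ ., data = dat,
                                     family = stats::binomial()))
  # a residual deviance of zero means the data are perfectly separated
  if (!fit$converged || fit$deviance < 1e-6)
    stop("logistic fit did not converge (perfect separation)")
  n <- length(y)
  fit0 <- stats::glm(.y ~ 1, data = dat, family = stats::binomial())
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(fit0))
  cox_snell <- 1 - exp(2 * (ll0 - ll1) / n)
  max_r2 <- 1 - exp(2 * ll0 / n)
  cox_snell / max_r2
}

#' Share of a component's variance contributed by a sample subset
#'
#' Sum of squared deviations from the overall mean over the masked
#' samples, divided by the total sum of squares.
#'
#' @param scores numeric score vector.
#' @param mask logical vector selecting the subset.
#' @return proportion in [0, 1].
#' @export
variance_share <- function(scores, mask) {
  stopifnot(length(scores) == length(mask))
  dev2 <- (scores - mean(scores))^2
  sum(dev2[mask]) / sum(dev2)
}

#' Jitter coordinates for map plotting
#'
#' Adds an independent uniform offset in [-radius, radius] to each
#' coordinate so co-located samples separate on a map and individual
#' locations are not identifiable. Deterministic under the seed.
#'
#' @param sample_table data.frame with `latitude` and `longitude`.
#' @param radius maximum per-coordinate displacement in degrees.
#' @param seed integer seed.
#' @return the table with jittered coordinates.
#' @export
jitter_coordinates <- function(sample_table, radius, seed = 1) {
  stopifnot(radius >= 0)
  n <- nrow(sample_table)
  with_seed(derive_seed(seed, 77L), {
    sample_table$latitude <- sample_table$latitude +
      stats::runif(n, -radius, radius)
    sample_table$longitude <- sample_table$longitude +
      stats::runif(n, -radius, radius)
  })
  sample_table
}
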
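test_that("Patterson normalization centers and scales as defined", {
  # all-heterozygous column centers to zero
  g <- cbind(rep(1L, 4), c(0L, 1L, 2L, 1L))
  nm <- patterson_normalize(g)
  expect_true(all(nm$x[, 1] == 0))
  # post-normalization mean over non-missing entries is 0 to 1e-12
  sim <- make_two_pop_sim(seed = 2, study_missingness = 0.03)
  nm2 <- patterson_normalize(sim$genotypes)
  obs <- !is.na(sim$genotypes)
  col_means <- colSums(nm2$x * obs) / colSums(obs)
  expect_lt(max(abs(col_means)), 1e-12)

  # hand-computed 3 x 2 example
  gh <- matrix(c(0L, 1L, 2L, 2L, 2L, 1L), 3, 2)
  nh <- patterson_normalize(gh)
  # column 1: mean 1, phat = (1+3)/(2+6) = 0.5, scale = 0.5
  expect_equal(nh$x[, 1], c(-2, 0, 2))
  # column 2: mean 5/3, phat = 6/8 = 0.75, scale = sqrt(0.1875)
  expect_equal(nh$x[, 2], (c(2, 2, 1) - 5 / 3) / sqrt(0.75 * 0.25))
  expect_error(patterson_normalize(cbind(c(NA, NA), c(1L, 2L))), "missing")
})

test_that("PCA matches a direct SVD factorization and separates subpops", {
  sim <- make_two_pop_sim(F = c(0.02, 0.02), n_per = 50, m = 500, seed = 14)
  nm <- patterson_normalize(sim$genotypes)
  K <- 6
  model <- compute_pca(nm, K)
  sv <- svd(nm$x)
  expect_equal(model$eigenvalues, sv$d[1:K]^2 / (nrow(nm$x) - 1),
               tolerance = 1e-8)
  # scores equal normalized matrix times weights
  expect_equal(model$scores, nm$x %*% model$weights, tolerance = 1e-8,
               ignore_attr = TRUE)
  # PC1 separates the two subpopulations
  r <- cor(model$scores[, 1], sim$truth$subpop)
  expect_gt(abs(r), 0.9)
  # duplicated rows get identical scores
  g2 <- rbind(sim$genotypes, sim$genotypes[1, , drop = FALSE])
  rownames(g2) <- c(rownames(sim$genotypes), "dup")
  m2 <- pca_fit(g2, 3)
  expect_equal(m2$scores["dup", ], m2$scores[1, ], tolerance = 1e-8)
  expect_error(compute_pca(nm, 1000), "K \\+ 1 samples")
  expect_error(compute_pca(nm, 99), NA)
})

test_that("projection reproduces training scores and centers missing samples", {
  sim <- make_two_pop_sim(seed = 9, m = 600)
  model <- pca_fit(sim$genotypes, 5)
  proj <- project_samples(model, sim$genotypes)
  expect_lt(max(abs(proj - model$scores)), 1e-8)
  g_missing <- sim$genotypes[1, , drop = FALSE]
  g_missing[] <- NA_integer_
  expect_true(all(project_samples(model, g_missing) == 0))
  expect_error(project_samples(model, sim$genotypes[, 1:10]), "SNP set")
})

test_that("projected external samples from the source shift as planted", {
  cfg <- sim_config(n_subpops = 2, samples_per_subpop = 60, n_snps = 800,
                    subpop_F = c(0.001, 0.001), admix_fraction = 0.1,
                    admix_alpha = 1, admix_source_F = 0.05, seed = 25)
  sim <- simulate_structured_genotypes(cfg)
  model <- pca_fit(sim$genotypes, 4)
  # which PC separates the admixture direction: the one most correlated
  # with planted membership
  planted <- rownames(sim$genotypes) %in% sim$truth$admixed
  cors <- abs(cor(model$scores, planted))
  pc <- which.max(cors)
  # external samples drawn purely from the source population
  m <- ncol(sim$genotypes)
  g_ext <- with(list(p = sim$truth$source_freq), {
    set.seed(1)
    matrix(rbinom(30 * m, 2, rep(p, each = 30)), 30, m,
           dimnames = list(sprintf("ext%02d", 1:30),
                           colnames(sim$genotypes)))
  })
  sc_ext <- project_samples(model, g_ext)[, pc]
  tst <- mean_nonzero_test(sc_ext)
  expect_lt(tst$p, 1e-6)
  planted_mean <- mean(model$scores[planted, pc]) -
    mean(model$scores[!planted, pc])
  expect_identical(sign(tst$mean - mean(model$scores[!planted, pc])),
                   sign(planted_mean))
})

test_that("the mean-zero test is calibrated and handles degeneracy", {
  set.seed(33)
  pvals <- replicate(200, mean_nonzero_test(rnorm(40))$p)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  const <- mean_nonzero_test(rep(2.5, 10))
  expect_identical(const$p, .Machine$double.xmin)
  expect_error(mean_nonzero_test(3), "at least two")
})

test_that("the ancestry cutoff removes planted admixed samples, strictly", {
  cut_far <- ancestry_cutoff(c(1, 0), 1e9)
  sim <- make_two_pop_sim(seed = 10, m = 400)
  model <- pca_fit(sim$genotypes, 3)
  expect_length(ancestry_cutoff_filter(model, cut_far), 0)

  # boundary sample: exactly on the line is kept
  scores <- matrix(c(1, 0.5, 2, 0, 0, 0), 3, 2,
                   dimnames = list(c("a", "b", "c"), NULL))
  expect_identical(ancestry_cutoff_filter(scores, ancestry_cutoff(c(1, 0), 1)),
                   "c")

  cfg <- sim_config(n_subpops = 2, samples_per_subpop = 80, n_snps = 900,
                    subpop_F = c(0.001, 0.001), admix_fraction = 0.08,
                    admix_alpha = 1, admix_source_F = 0.08, seed = 61)
  sim2 <- simulate_structured_genotypes(cfg)
  model2 <- pca_fit(sim2$genotypes, 2)
  planted <- rownames(sim2$genotypes) %in% sim2$truth$admixed
  pc <- which.max(abs(cor(model2$scores, planted)))
  dir <- sign(mean(model2$scores[planted, pc]) -
                mean(model2$scores[!planted, pc]))
  main <- model2$scores[!planted, pc]
  offset <- dir * (mean(main) + dir * 4 * sd(main))
  normal <- if (pc == 1) c(dir, 0) else c(0, dir)
  removed <- ancestry_cutoff_filter(model2, ancestry_cutoff(normal, offset))
  expect_gte(mean(sim2$truth$admixed %in% removed), 0.9)
})

test_that("nearest-neighbor outlier removal catches paired outliers at k >= 2", {
  set.seed(8)
  x <- matrix(rnorm(500 * 10), 500, 10,
              dimnames = list(sprintf("n%03d", 1:500), NULL))
  expect_lte(length(nearest_neighbor_outliers(x, 5, 4)), 1)

  # one sample far from the cloud: removed at k = 1 already
  x1 <- x
  x1[1, ] <- 40
  expect_true("n001" %in% nearest_neighbor_outliers(x1, 1, 4))

  # two co-located far outliers: invisible at k = 1, removed at k = 2
  x2 <- x
  x2[1, ] <- 40
  x2[2, ] <- 40 + rnorm(10, sd = 1e-4)
  expect_false(any(c("n001", "n002") %in% nearest_neighbor_outliers(x2, 1, 4)))
  expect_true(all(c("n001", "n002") %in% nearest_neighbor_outliers(x2, 2, 4)))
  expect_error(nearest_neighbor_outliers(x[1:5, ], 5, 4), "samples")
})

test_that("PC-geography regression recovers planted variance structure", {
  set.seed(12)
  lat <- runif(300, 55, 68)
  lon <- runif(300, 12, 21)
  # pure linear function of latitude
  res <- pc_geography_regression(2 * lat - 1, lat, lon)
  expect_equal(res$r2_latitude, 1)
  expect_equal(res$delta_r2_longitude, 0, tolerance = 1e-10)
  # independent PC: E[R2] ~ 1/(n-1)
  n <- 100
  r2s <- replicate(200, pc_geography_regression(
    rnorm(n), runif(n, 55, 68), runif(n, 12, 21))$r2_latitude)
  expect_lt(abs(mean(r2s) - 1 / (n - 1)), 3 / (n - 1))
  # noisy gradient: R2 matches var_signal / (var_signal + sigma^2)
  slope <- 0.5; sigma <- 1.5
  pc <- slope * lat + rnorm(300, sd = sigma)
  expected_r2 <- var(slope * lat) / (var(slope * lat) + sigma^2)
  res2 <- pc_geography_regression(pc, lat, lon)
  expect_lt(abs(res2$r2_latitude - expected_r2), 0.1)
})

test_that("Nagelkerke pseudo-R2 spans null to near-deterministic outcomes", {
  set.seed(18)
  n <- 2000
  y <- rbinom(n, 1, 0.4)
  x <- rnorm(n)
  expect_lt(nagelkerke_r2(y, x), 0.02)
  # deterministic threshold with slight label noise
  x2 <- rnorm(n)
  y2 <- as.integer(x2 > 0)
  flip <- sample(n, 20)
  y2[flip] <- 1L - y2[flip]
  expect_gt(nagelkerke_r2(y2, x2), 0.75)
  # uninformative (constant) predictor reduces to the null model
  expect_equal(nagelkerke_r2(y, rep(1, n)), 0, tolerance = 1e-10)
  # perfect separation is a reported failure, not a number
  y3 <- as.integer(x2 > 0)
  expect_error(nagelkerke_r2(y3, x2), "converge|separation")
})

test_that("variance share and coordinate jitter behave as defined", {
  x <- c(1, 2, 3, 10, 11, 12)
  expect_equal(variance_share(x, rep(TRUE, 6)), 1)
  expect_equal(variance_share(c(3, 3, 0, 6), c(3, 3, 0, 6) == 3), 0)
  # two-cluster hand computation: mean 6.5, cluster {10,11,12}
  mask <- x > 5
  expect_equal(variance_share(x, mask),
               sum((c(10, 11, 12) - 6.5)^2) / sum((x - 6.5)^2))

  tab <- data.frame(latitude = c(56, 60), longitude = c(13, 15))
  expect_identical(jitter_coordinates(tab, 0, seed = 4), tab)
  j1 <- jitter_coordinates(tab, 0.3, seed = 4)
  j2 <- jitter_coordinates(tab, 0.3, seed = 4)
  expect_identical(j1, j2)
  expect_lte(max(abs(j1$latitude - tab$latitude),
                 abs(j1$longitude - tab$longitude)), 0.3)
})
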
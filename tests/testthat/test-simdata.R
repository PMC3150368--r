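test_that("simulation is deterministic and respects the frequency model", {
  cfg <- sim_config(n_subpops = 3, samples_per_subpop = 60, n_snps = 2000,
                    subpop_F = c(0, 0.01, 0.05), seed = 31)
  sim1 <- simulate_structured_genotypes(cfg)
  sim2 <- simulate_structured_genotypes(cfg)
  expect_identical(sim1$genotypes, sim2$genotypes)
  expect_identical(sim1$snps, sim2$snps)

  v <- sim1$genotypes[!is.na(sim1$genotypes)]
  expect_true(all(v %in% 0:2))

  # per-subpop mean genotype converges to 2 p_k (4 SE bound, binomial SE)
  for (k in 1:3) {
    rows <- sim1$truth$subpop == k
    nk <- sum(rows)
    pk <- sim1$truth$subpop_freq[, k]
    mean_g <- colMeans(sim1$genotypes[rows, ])
    se <- sqrt(2 * pk * (1 - pk) / nk)
    frac_ok <- mean(abs(mean_g - 2 * pk) < 4 * se)
    expect_gt(frac_ok, 0.999)
  }

  # F = 0 means the subpop frequency is exactly the ancestral one
  expect_identical(sim1$truth$subpop_freq[, 1], sim1$truth$ancestral_freq)
  expect_error(sim_config(n_subpops = 2, subpop_F = c(0.5, 1)), "subpop_F")
})

test_that("study labels are round-robin within subpop unless confounded", {
  sim <- simulate_structured_genotypes(
    sim_config(n_subpops = 2, samples_per_subpop = 30, n_snps = 50,
               n_studies = 3, seed = 1))
  tab <- table(sim$samples$group, sim$samples$study)
  expect_true(all(tab == 10))
  sim2 <- simulate_structured_genotypes(
    sim_config(n_subpops = 2, samples_per_subpop = 30, n_snps = 50,
               n_studies = 2, confound_study_geography = TRUE, seed = 1))
  tab2 <- table(sim2$samples$group, sim2$samples$study)
  expect_equal(sort(unique(as.vector(tab2))), c(0, 30))
})

test_that("no divergence gives F_st indistinguishable from zero", {
  sim <- make_two_pop_sim(F = c(0, 0), n_per = 50, m = 10000, seed = 7)
  gA <- sim$genotypes[sim$truth$subpop == 1, ]
  gB <- sim$genotypes[sim$truth$subpop == 2, ]
  est <- hudson_fst_pair(gA, gB, n_blocks = 50)
  expect_lt(abs(est$fst), 3 * est$se)
})

test_that("planted relatives have the requested relatedness class", {
  sim <- simulate_structured_genotypes(
    sim_config(n_subpops = 1, samples_per_subpop = 12, n_snps = 10000,
               subpop_F = 0, seed = 19))
  pairs <- data.frame(sample1 = c("S00001", "S00003", "S00005"),
                      sample2 = c("S00002", "S00004", "S00006"),
                      type = c("duplicate", "parent_offspring", "full_sib"))
  sim <- inject_relatives(sim, pairs)
  expect_identical(sim$genotypes["S00001", ], sim$genotypes["S00002", ])
  ph <- estimate_pihat(sim$genotypes,
                       pairs = rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8)))
  expect_gte(ph$pihat[1, 2], 0.95)
  expect_lt(abs(ph$pihat[3, 4] - 0.5), 0.05)
  expect_lt(abs(ph$pihat[5, 6] - 0.5), 0.07)  # full sibs share pi = 0.5 too
  expect_lt(abs(ph$pihat[7, 8]), 0.05)

  # empty spec leaves the matrix untouched; overlapping membership rejected
  before <- sim$genotypes
  expect_identical(inject_relatives(sim, pairs[0, ])$genotypes, before)
  bad <- data.frame(sample1 = c("S00009", "S00009"),
                    sample2 = c("S00010", "S00011"), type = "duplicate")
  expect_error(inject_relatives(sim, bad), "overlapping")
})

test_that("admixture injection is a no-op at alpha = 0 or fraction = 0", {
  sim <- make_two_pop_sim(seed = 3)
  expect_identical(inject_admixed_samples(sim, 0.1, 0)$genotypes, sim$genotypes)
  expect_identical(inject_admixed_samples(sim, 0, 1)$genotypes, sim$genotypes)
  sim2 <- inject_admixed_samples(sim, 0.1, 1)
  expect_length(sim2$truth$admixed, 2 * ceiling(0.1 * 40))
  changed <- rownames(sim$genotypes) %in% sim2$truth$admixed
  expect_false(identical(sim2$genotypes[changed, ], sim$genotypes[changed, ]))
  expect_identical(sim2$genotypes[!changed, ], sim$genotypes[!changed, ])
})

test_that("batch effects plant detectable flips and missingness", {
  sim <- make_two_pop_sim(seed = 5)
  expect_identical(inject_batch_effects(sim, 0, 0)$genotypes, sim$genotypes)

  # a strand flip at moderate MAF is flagged by the one-vs-rest test
  cfg <- sim_config(n_subpops = 1, samples_per_subpop = 600, n_snps = 200,
                    subpop_F = 0, n_studies = 2,
                    ancestral_maf_range = c(0.1, 0.4), seed = 13)
  sim2 <- simulate_structured_genotypes(cfg)
  sim2 <- inject_batch_effects(sim2, 0, flip_snps = 4)
  ovr <- one_vs_rest_frequency_test(sim2$genotypes, sim2$samples$study)
  flagged <- colnames(sim2$genotypes)[ovr$min_p < 1e-6]
  expect_true(all(sim2$truth$flipped$snp_id %in% flagged))

  # per-study missingness drives the per-SNP call rate below threshold at
  # the binomial-tail rate
  cfg3 <- sim_config(n_subpops = 1, samples_per_subpop = 300, n_snps = 2000,
                     subpop_F = 0, n_studies = 3,
                     study_missingness = c(0.06, 0, 0), seed = 17)
  sim3 <- simulate_structured_genotypes(cfg3)
  flt <- snp_call_rate_filter(sim3$genotypes, sim3$samples$study, 0.95)
  n_study <- sum(sim3$samples$study == "study1")
  # removal iff missing calls > 5% of the study, i.e. Binom(n, .06) tail
  expected <- stats::pbinom(floor(0.05 * n_study), n_study, 0.06,
                            lower.tail = FALSE)
  observed <- length(flt$removed) / 2000
  se <- sqrt(expected * (1 - expected) / 2000)
  expect_lt(abs(observed - expected), 4 * se)
})

test_that("planted autozygous runs are recovered and sub-threshold runs are not", {
  cfg <- sim_config(n_subpops = 1, samples_per_subpop = 4, n_snps = 1200,
                    snp_spacing_bp = 20000, seed = 23,
                    roh_segments = data.frame(subpop = c(1, 1),
                                              length_bp = c(2e6, 0.58e6),
                                              n_snps = c(100, 30)))
  sim <- simulate_structured_genotypes(cfg)
  segs <- scan_roh_all(sim$genotypes, sim$snps)
  planted <- sim$truth$roh
  big <- planted[planted$n_snps == 100, ]
  hit <- segs[segs$sample_id == big$sample_id &
                segs$start <= big$start & segs$end >= big$end, ]
  expect_gte(nrow(hit), 1)
  # the 30-SNP / <1 Mb run fails the segment filters everywhere
  small <- planted[planted$n_snps == 30, ]
  small_hits <- segs[segs$sample_id == small$sample_id &
                       segs$start <= small$end & segs$end >= small$start, ]
  expect_identical(nrow(small_hits), 0L)
  # no-op on empty spec
  expect_identical(inject_roh(sim, NULL)$genotypes, sim$genotypes)
})
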
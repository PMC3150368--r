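make_dataset <- function(g, ids, snp_ids, a1, a2, study = "s1") {
  dimnames(g) <- list(ids, snp_ids)
  list(genotypes = g,
       snps = data.frame(snp_id = snp_ids, chromosome = 1L,
                         position = seq_len(ncol(g)) * 1000L,
                         allele1 = a1, allele2 = a2,
                         stringsAsFactors = FALSE),
       samples = data.frame(sample_id = ids, study = study,
                            stringsAsFactors = FALSE))
}

test_that("merging intersects SNPs and reconciles allele orientation", {
  g1 <- matrix(c(0L, 1L, 2L, 2L, 1L, 0L, 1L, 1L, 0L), 3, 3)
  d1 <- make_dataset(g1, c("a", "b", "c"), c("s1", "s2", "s3"),
                     c("A", "A", "A"), c("G", "C", "G"), "s1")
  # identical datasets (different sample ids): all SNPs kept
  d2 <- make_dataset(g1, c("d", "e", "f"), c("s1", "s2", "s3"),
                     c("A", "A", "A"), c("G", "C", "G"), "s2")
  m <- intersect_and_merge(list(d1, d2))
  expect_identical(ncol(m$genotypes), 3L)
  expect_identical(nrow(m$genotypes), 6L)

  # allele pair A/C vs A/G cannot be reconciled -> dropped and counted
  d3 <- make_dataset(g1, c("d", "e", "f"), c("s1", "s2", "s3"),
                     c("A", "A", "A"), c("G", "G", "G"), "s2")
  m3 <- intersect_and_merge(list(d1, d3))
  expect_identical(m3$dropped_allele_mismatch, "s2")
  expect_identical(ncol(m3$genotypes), 2L)

  # complementary strand labels (A/G vs T/C) normalize and are kept;
  # swapped alleles (G/A) get their dosage recoded 2 - g
  d4 <- make_dataset(g1, c("d", "e", "f"), c("s1", "s2", "s3"),
                     c("T", "A", "G"), c("C", "C", "A"), "s2")
  m4 <- intersect_and_merge(list(d1, d4))
  expect_identical(ncol(m4$genotypes), 3L)
  expect_identical(m4$recoded[2], 1L)
  expect_identical(unname(m4$genotypes["d", "s3"]), 2L - g1[1, 3])

  # duplicate sample ids across datasets are an error, as is no overlap
  expect_error(intersect_and_merge(list(d1, d1)), "duplicate sample ids")
  d5 <- make_dataset(g1, c("d", "e", "f"), c("x1", "x2", "x3"),
                     "A", "G", "s2")
  expect_error(intersect_and_merge(list(d1, d5)), "no SNPs shared")
})

test_that("call-rate filter removes a SNP failing in any single study", {
  set.seed(1)
  g <- matrix(sample(0:2, 300, TRUE), 30, 10,
              dimnames = list(NULL, paste0("s", 1:10)))
  study <- rep(c("A", "B", "C"), each = 10)
  flt <- snp_call_rate_filter(g, study, 0.95)
  expect_length(flt$removed, 0)
  g[1, "s4"] <- NA  # 90% call rate in study A only
  flt <- snp_call_rate_filter(g, study, 0.95)
  expect_identical(flt$removed, "s4")
  expect_error(snp_call_rate_filter(g, factor(study, levels = c("A", "B", "C", "D")),
                                    0.95), "zero samples")
})

test_that("HWE exact p-values match full enumeration", {
  expect_equal(hwe_exact_test(3, 4, 3), oracle_hwe_enum(3, 4, 3),
               tolerance = 1e-12)
  expect_identical(hwe_exact_test(10, 0, 0), 1)
  p_allhet <- hwe_exact_test(0, 100, 0)
  expect_equal(p_allhet, oracle_hwe_enum(0, 100, 0), tolerance = 1e-12)
  expect_lt(p_allhet, 1e-6)

  # property: 12-significant-digit agreement across random configurations
  set.seed(99)
  for (rep in 1:150) {
    n <- sample(1:200, 1)
    n_hom1 <- sample(0:n, 1)
    n_het <- sample(0:(n - n_hom1), 1)
    n_hom2 <- n - n_hom1 - n_het
    a <- hwe_exact_test(n_hom1, n_het, n_hom2)
    b <- oracle_hwe_enum(n_hom1, n_het, n_hom2)
    expect_lt(abs(a - b) / b, 1e-12)
  }
})

test_that("one-vs-rest test flags planted frequency artifacts, not nulls", {
  set.seed(21)
  n <- 150; m <- 2000
  p <- runif(m, 0.05, 0.5)
  g <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m,
              dimnames = list(NULL, paste0("s", seq_len(m))))
  study <- rep(c("A", "B", "C"), each = 50)
  ovr <- one_vs_rest_frequency_test(g, study)
  expect_identical(sum(ovr$min_p < 1e-6), 0L)

  # single-study input: no comparisons
  single <- one_vs_rest_frequency_test(g, rep("A", n))
  expect_identical(ncol(single$p_matrix), 0L)
  expect_true(all(is.na(single$min_p)))

  # a monomorphic SNP has a zero-variance table -> p = 1
  g[, 1] <- 0L
  ovr2 <- one_vs_rest_frequency_test(g, study)
  expect_true(all(ovr2$p_matrix[1, ] == 1))
})

test_that("pihat separates duplicates, first-degree pairs and unrelateds", {
  sim <- simulate_structured_genotypes(
    sim_config(n_subpops = 1, samples_per_subpop = 10, n_snps = 5000,
               subpop_F = 0, seed = 77))
  pairs <- data.frame(sample1 = "S00001", sample2 = "S00002",
                      type = "duplicate")
  sim <- inject_relatives(sim, pairs)
  ph <- estimate_pihat(sim$genotypes)
  expect_gte(ph$pihat["S00001", "S00002"], 0.95)
  expect_lt(abs(ph$pihat["S00003", "S00004"]), 0.05)
  expect_true(all(ph$reliable[upper.tri(ph$reliable)]))
  ph_small <- estimate_pihat(sim$genotypes[, 1:50])
  expect_false(any(ph_small$reliable[upper.tri(ph_small$reliable)]))
})

test_that("relatedness removal is greedy and leaves no violating pair", {
  ids <- paste0("x", 1:4)
  ph <- matrix(0, 4, 4, dimnames = list(ids, ids))
  ph[1, 2] <- ph[2, 1] <- 0.9
  miss <- c(0.01, 0.02, 0, 0)
  expect_identical(remove_related(ph, miss, 0.2), "x2")
  # triangle of mutually related samples: two must go
  ph2 <- matrix(0, 4, 4, dimnames = list(ids, ids))
  ph2[1:3, 1:3] <- 0.5; diag(ph2) <- 0
  removed <- remove_related(ph2, rep(0, 4), 0.2)
  expect_length(removed, 2)
  survivors <- setdiff(ids, removed)
  expect_true(all(ph2[survivors, survivors][upper.tri(diag(2))] <= 0.2))
  expect_length(remove_related(ph2, rep(0, 4), 0.6), 0)
})

test_that("sample missingness uses a strict inequality on the post-QC set", {
  g <- matrix(0L, 3, 1000, dimnames = list(c("a", "b", "c"), NULL))
  g[2, 1:20] <- NA   # exactly 2.0%
  g[3, 1:21] <- NA   # 2.1%
  expect_identical(sample_missingness_filter(g, 0.02), "c")
})

test_that("the QC report's two accountings are consistent", {
  sim <- simulate_structured_genotypes(
    sim_config(n_subpops = 2, samples_per_subpop = 90, n_snps = 1200,
               subpop_F = c(0.001, 0.001), n_studies = 3,
               ancestral_maf_range = c(0.005, 0.5),
               study_missingness = c(0.04, 0, 0), flip_snps = 5, seed = 55))
  rep_qc <- run_snp_qc(sim$genotypes, sim$samples$study)
  expect_true(all(rep_qc$summary$removed_solely <= rep_qc$summary$removed))
  all_removed <- unique(unlist(rep_qc$removed))
  expect_identical(sort(c(rep_qc$kept, all_removed)),
                   sort(colnames(sim$genotypes)))
  # the kept set passes every filter when re-applied
  g_kept <- sim$genotypes[, rep_qc$kept]
  flt <- snp_call_rate_filter(g_kept, sim$samples$study, 0.95)
  expect_length(flt$removed, 0)
  p_kept <- colMeans(g_kept, na.rm = TRUE) / 2
  maf <- pmin(p_kept, 1 - p_kept)
  expect_true(all(maf >= 0.01))
})
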
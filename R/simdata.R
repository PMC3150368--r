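#' Configuration for the structured genotype simulator
#'
#' Builds the configuration object consumed by
#' [simulate_structured_genotypes()]. The defaults describe a small
#' multi-study cohort with a south-to-north gradient of subpopulation
#' divergence: subpopulations are laid along a latitude axis and their
#' Balding-Nichols drift parameters increase with latitude, so that
#' pairwise F_st between the southernmost groups is of order 1e-4 and
#' between the extremes of order 1e-3, the magnitudes seen in
#' within-country SNP studies of northern Europe. A strongly diverged
#' "admixture source" population (drift `admix_source_F`) stands in for
#' an external ancestry component contributing to a subset of samples.
#'
#' @param n_subpops number of subpopulations.
#' @param samples_per_subpop samples drawn from each subpopulation.
#' @param n_snps number of autosomal SNPs.
#' @param ancestral_maf_range range of the uniform ancestral minor allele
#'   frequency, both ends in (0, 0.5].
#' @param subpop_F per-subpopulation Balding-Nichols divergence from the
#'   common ancestor, each in [0, 1). Recycled to `n_subpops`.
#' @param subpop_latitude,subpop_longitude decimal-degree coordinates of
#'   the subpopulation centroids.
#' @param admix_fraction proportion of samples per subpopulation given
#'   outside ancestry by [inject_admixed_samples()].
#' @param admix_source_F divergence of the admixture source population.
#' @param admix_alpha ancestry proportion contributed by the source, in
#'   (0, 1].
#' @param n_studies number of source studies; study labels are assigned
#'   round-robin within subpopulation so that geography and study are not
#'   confounded (set `confound_study_geography = TRUE` to instead assign
#'   whole subpopulations to studies).
#' @param study_missingness per-study missing-call probability (scalar or
#'   length `n_studies`).
#' @param flip_snps number of strand-flipped SNPs planted per dataset by
#'   [inject_batch_effects()].
#' @param relative_pairs number of planted close-relative pairs.
#' @param roh_segments data.frame of planted autozygous runs with columns
#'   `subpop`, `length_bp`, `n_snps` (see [inject_roh()]).
#' @param n_chromosomes number of synthetic autosomes the SNPs are laid on.
#' @param snp_spacing_bp uniform inter-SNP spacing in bp (default 50 kb);
#'   ROH segment filters are bp-denominated so spacing matters there.
#' @param confound_study_geography logical flag, see `n_studies`.
#' @param seed integer seed; a fixed seed makes every output byte-identical.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_subpops = 6,
                       samples_per_subpop = 100,
                       n_snps = 5000,
                       ancestral_maf_range = c(0.05, 0.5),
                       subpop_F = seq(0.0005, 0.005, length.out = n_subpops),
                       subpop_latitude = seq(55.5, 67.5, length.out = n_subpops),
                       subpop_longitude = seq(13.5, 20.5, length.out = n_subpops),
                       admix_fraction = 0,
                       admix_source_F = 0.02,
                       admix_alpha = 1,
                       n_studies = 3,
                       study_missingness = 0,
                       flip_snps = 0,
                       relative_pairs = 0,
                       roh_segments = NULL,
                       n_chromosomes = 1,
                       snp_spacing_bp = 50000,
                       confound_study_geography = FALSE,
                       seed = 1) {
  subpop_F <- rep_len(subpop_F, n_subpops)
  study_missingness <- rep_len(study_missingness, n_studies)
  stopifnot(
    n_subpops >= 1, samples_per_subpop >= 1, n_snps >= 1,
    length(ancestral_maf_range) == 2,
    all(ancestral_maf_range > 0), all(ancestral_maf_range <= 0.5),
    ancestral_maf_range[1] <= ancestral_maf_range[2],
    length(subpop_latitude) == n_subpops,
    length(subpop_longitude) == n_subpops,
    admix_fraction >= 0, admix_fraction <= 1,
    admix_source_F >= 0, admix_source_F < 1,
    admix_alpha >= 0, admix_alpha <= 1,
    n_studies >= 1, all(study_missingness >= 0), all(study_missingness < 1),
    n_chromosomes >= 1, snp_spacing_bp >= 1
  )
  if (any(subpop_F < 0) || any(subpop_F >= 1))
    stop("subpop_F values must lie in [0, 1)")
  structure(list(
    n_subpops = n_subpops, samples_per_subpop = samples_per_subpop,
    n_snps = n_snps, ancestral_maf_range = ancestral_maf_range,
    subpop_F = subpop_F, subpop_latitude = subpop_latitude,
    subpop_longitude = subpop_longitude,
    admix_fraction = admix_fraction, admix_source_F = admix_source_F,
    admix_alpha = admix_alpha, n_studies = n_studies,
    study_missingness = study_missingness, flip_snps = flip_snps,
    relative_pairs = relative_pairs, roh_segments = roh_segments,
    n_chromosomes = n_chromosomes, snp_spacing_bp = snp_spacing_bp,
    confound_study_geography = confound_study_geography,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Fixed sub-stream offsets: each injection draws from its own derived
# stream so applying the injections in any order gives identical output.
.SIM_OFFSETS <- c(base = 11L, relatives = 101L, admix = 202L,
                  batch_miss = 303L, batch_flip = 313L, roh = 404L)

#' Simulate a spatially structured multi-study genotype dataset
#'
#' Draws an ancestral minor allele frequency per SNP from
#' `Uniform(ancestral_maf_range)`, then for each subpopulation k with
#' divergence F_k draws the subpopulation frequency from the
#' Balding-Nichols distribution
#' `Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k)` (exactly `p` when F_k = 0) and
#' genotypes as `Binomial(2, p_k)` per sample and SNP. SNPs are placed at
#' uniform spacing on synthetic autosomes; allele labels are drawn from
#' the strand-unambiguous base pairs. Study labels are assigned
#' round-robin within subpopulation.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `genotypes` (samples x SNPs integer matrix,
#'   minor-allele dosage), `samples` (sample metadata data.frame),
#'   `snps` (SNP table data.frame) and `truth` (a `sim_truth` list
#'   recording the realized frequencies and every planted artifact).
#' @export
simulate_structured_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$n_subpops; nk <- config$samples_per_subpop
  m <- config$n_snps; n <- K * nk

  draws <- with_seed(derive_seed(config$seed, .SIM_OFFSETS[["base"]]), {
    pa <- stats::runif(m, config$ancestral_maf_range[1], config$ancestral_maf_range[2])
    pk <- matrix(NA_real_, m, K)
    for (k in seq_len(K)) {
      F <- config$subpop_F[k]
      pk[, k] <- if (F == 0) pa else
        stats::rbeta(m, pa * (1 - F) / F, (1 - pa) * (1 - F) / F)
    }
    F <- config$admix_source_F
    p_src <- if (F == 0) pa else
      stats::rbeta(m, pa * (1 - F) / F, (1 - pa) * (1 - F) / F)
    g <- matrix(NA_integer_, n, m)
    for (k in seq_len(K)) {
      rows <- ((k - 1) * nk + 1):(k * nk)
      g[rows, ] <- matrix(stats::rbinom(nk * m, 2L, rep(pk[, k], each = nk)),
                          nk, m)
    }
    # strand-unambiguous allele pairs only; ambiguity is planted later by
    # inject_batch_effects when strand flips are requested
    pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G"), ncol = 2, byrow = TRUE)
    ai <- sample.int(4, m, replace = TRUE)
    list(pa = pa, pk = pk, p_src = p_src, g = g,
         a1 = pairs[ai, 1], a2 = pairs[ai, 2])
  })

  subpop <- rep(seq_len(K), each = nk)
  within <- rep(seq_len(nk), times = K)
  study_idx <- if (config$confound_study_geography) {
    ((subpop - 1) %% config$n_studies) + 1
  } else {
    ((within - 1) %% config$n_studies) + 1
  }
  samples <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    study = sprintf("study%d", study_idx),
    group = sprintf("pop%02d", subpop),
    latitude = config$subpop_latitude[subpop],
    longitude = config$subpop_longitude[subpop],
    ancestry = NA_character_,
    stringsAsFactors = FALSE
  )

  per_chr <- ceiling(m / config$n_chromosomes)
  chr <- rep(seq_len(config$n_chromosomes), each = per_chr)[seq_len(m)]
  pos <- (unlist(lapply(rle(chr)$lengths, seq_len), use.names = FALSE)) *
    config$snp_spacing_bp
  snps <- data.frame(
    snp_id = sprintf("snp%06d", seq_len(m)),
    chromosome = chr,
    position = as.numeric(pos),
    allele1 = draws$a1,
    allele2 = draws$a2,
    stringsAsFactors = FALSE
  )

  g <- draws$g
  dimnames(g) <- list(samples$sample_id, snps$snp_id)
  truth <- structure(list(
    config = config,
    ancestral_freq = draws$pa,
    subpop_freq = draws$pk,
    source_freq = draws$p_src,
    subpop = subpop,
    relatives = data.frame(sample1 = character(), sample2 = character(),
                           type = character(), stringsAsFactors = FALSE),
    admixed = character(),
    flipped = data.frame(snp_id = character(), study = character(),
                         stringsAsFactors = FALSE),
    roh = data.frame(sample_id = character(), chromosome = integer(),
                     start = integer(), end = integer(), n_snps = integer(),
                     stringsAsFactors = FALSE)
  ), class = "sim_truth")

  out <- list(genotypes = g, samples = samples, snps = snps, truth = truth)

  # apply the configured injections (each a no-op at its default)
  if (config$relative_pairs > 0) {
    n_pairs <- config$relative_pairs
    types <- rep_len(c("duplicate", "parent_offspring", "full_sib"), n_pairs)
    ids <- samples$sample_id[seq_len(2 * n_pairs)]
    pairs <- data.frame(sample1 = ids[seq(1, by = 2, length.out = n_pairs)],
                        sample2 = ids[seq(2, by = 2, length.out = n_pairs)],
                        type = types, stringsAsFactors = FALSE)
    out <- inject_relatives(out, pairs)
  }
  if (config$admix_fraction > 0 && config$admix_alpha > 0)
    out <- inject_admixed_samples(out, config$admix_fraction, config$admix_alpha)
  if (any(config$study_missingness > 0) || config$flip_snps > 0)
    out <- inject_batch_effects(out, config$study_missingness, config$flip_snps)
  if (!is.null(config$roh_segments) && nrow(config$roh_segments) > 0)
    out <- inject_roh(out, config$roh_segments)
  out
}

#' Plant close-relative pairs in a simulated dataset
#'
#' Overwrites the genotypes of designated sample pairs so that their
#' realized relatedness matches a requested class: `duplicate` copies the
#' row, `parent_offspring` makes sample2 an offspring of sample1 and a
#' random subpopulation mate (one allele transmitted per SNP), `full_sib`
#' replaces both samples by two offspring of a freshly drawn parental
#' pair (Mendelian segregation per SNP).
#'
#' @param sim simulation list from [simulate_structured_genotypes()].
#' @param pairs data.frame with columns `sample1`, `sample2`, `type`.
#' @return the simulation list with updated genotypes and truth.
#' @export
inject_relatives <- function(sim, pairs) {
  if (nrow(pairs) == 0) return(sim)
  stopifnot(all(c("sample1", "sample2", "type") %in% names(pairs)))
  ids <- c(pairs$sample1, pairs$sample2)
  if (anyDuplicated(ids))
    stop("overlapping pair membership: a sample may appear in only one pair")
  missing_ids <- setdiff(ids, rownames(sim$genotypes))
  if (length(missing_ids))
    stop("unknown sample ids: ", paste(missing_ids, collapse = ", "))
  bad <- setdiff(pairs$type, c("duplicate", "parent_offspring", "full_sib"))
  if (length(bad)) stop("unknown relative type: ", paste(bad, collapse = ", "))

  g <- sim$genotypes
  truth <- sim$truth
  m <- ncol(g)
  with_seed(derive_seed(truth$config$seed, .SIM_OFFSETS[["relatives"]]), {
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$sample1[i]; b <- pairs$sample2[i]
      k <- truth$subpop[match(b, rownames(g))]
      p <- truth$subpop_freq[, k]
      if (pairs$type[i] == "duplicate") {
        g[b, ] <- g[a, ]
      } else if (pairs$type[i] == "parent_offspring") {
        transmitted <- stats::rbinom(m, 1L, g[a, ] / 2)
        other <- stats::rbinom(m, 1L, p)
        g[b, ] <- transmitted + other
      } else { # full_sib: both replaced by sibs from a common parental pair
        dad <- stats::rbinom(m, 2L, p)
        mom <- stats::rbinom(m, 2L, p)
        g[a, ] <- stats::rbinom(m, 1L, dad / 2) + stats::rbinom(m, 1L, mom / 2)
        g[b, ] <- stats::rbinom(m, 1L, dad / 2) + stats::rbinom(m, 1L, mom / 2)
      }
    }
  })
  sim$genotypes <- g
  sim$truth$relatives <- rbind(truth$relatives, pairs[c("sample1", "sample2", "type")])
  sim
}

#' Plant admixed samples
#'
#' For a fraction of samples in each subpopulation, genotypes are redrawn
#' with each allele coming from the divergent admixture-source population
#' with probability `alpha` and from the home subpopulation otherwise,
#' i.e. `Binomial(2, alpha * p_source + (1 - alpha) * p_k)` per SNP.
#' With `fraction = 0` or `alpha = 0` the dataset is returned unchanged.
#'
#' @param sim simulation list.
#' @param fraction proportion of samples per subpopulation to admix.
#' @param alpha source-ancestry proportion in (0, 1].
#' @return the simulation list with updated genotypes and truth.
#' @export
inject_admixed_samples <- function(sim, fraction, alpha) {
  stopifnot(fraction >= 0, fraction <= 1, alpha >= 0, alpha <= 1)
  if (fraction == 0 || alpha == 0) return(sim)
  truth <- sim$truth
  g <- sim$genotypes
  m <- ncol(g)
  nk <- truth$config$samples_per_subpop
  n_admix <- ceiling(fraction * nk)
  with_seed(derive_seed(truth$config$seed, .SIM_OFFSETS[["admix"]]), {
    chosen <- character(0)
    for (k in seq_len(truth$config$n_subpops)) {
      rows <- which(truth$subpop == k)
      sel <- sample(rows, n_admix)
      p_mix <- alpha * truth$source_freq + (1 - alpha) * truth$subpop_freq[, k]
      for (r in sel) g[r, ] <- stats::rbinom(m, 2L, p_mix)
      chosen <- c(chosen, rownames(g)[sel])
    }
    sim$truth$admixed <- sort(union(truth$admixed, chosen))
  })
  sim$genotypes <- g
  sim
}

#' Plant per-study batch artifacts
#'
#' Applies per-study random missingness and strand flips: for each
#' flipped SNP one randomly chosen study has its genotypes recoded
#' `2 - g` and its allele labels relabeled to the complementary-base
#' pair, emulating an undetected A/T-style strand flip after merging.
#'
#' @param sim simulation list.
#' @param study_missingness scalar or per-study missing-call probability.
#' @param flip_snps number of SNPs to strand-flip.
#' @return the simulation list with updated genotypes and truth.
#' @export
inject_batch_effects <- function(sim, study_missingness = 0, flip_snps = 0) {
  truth <- sim$truth
  g <- sim$genotypes
  studies <- sort(unique(sim$samples$study))
  study_missingness <- rep_len(study_missingness, length(studies))
  if (any(study_missingness > 0)) {
    with_seed(derive_seed(truth$config$seed, .SIM_OFFSETS[["batch_miss"]]), {
      for (s in seq_along(studies)) {
        rate <- study_missingness[s]
        if (rate == 0) next
        rows <- which(sim$samples$study == studies[s])
        mask <- matrix(stats::runif(length(rows) * ncol(g)) < rate,
                       length(rows), ncol(g))
        block <- g[rows, , drop = FALSE]
        block[mask] <- NA_integer_
        g[rows, ] <- block
      }
    })
  }
  if (flip_snps > 0) {
    with_seed(derive_seed(truth$config$seed, .SIM_OFFSETS[["batch_flip"]]), {
      snp_idx <- sample.int(ncol(g), flip_snps)
      flip_study <- sample(studies, flip_snps, replace = TRUE)
      for (i in seq_along(snp_idx)) {
        rows <- which(sim$samples$study == flip_study[i])
        j <- snp_idx[i]
        g[rows, j] <- 2L - g[rows, j]
      }
      sim$truth$flipped <- rbind(
        truth$flipped,
        data.frame(snp_id = colnames(g)[snp_idx], study = flip_study,
                   stringsAsFactors = FALSE))
    })
  }
  sim$genotypes <- g
  sim
}

#' Plant autozygous runs
#'
#' For each requested segment, a sample from the designated subpopulation
#' is made homozygous over a run of consecutive SNPs: one haplotype is
#' drawn from the subpopulation frequencies and doubled. The realized
#' bp length follows from the SNP positions; if it differs from the
#' requested `length_bp` by more than one inter-SNP spacing a warning is
#' issued (choose `snp_spacing_bp` consistently with the request).
#'
#' @param sim simulation list.
#' @param roh_spec data.frame with columns `subpop`, `length_bp`,
#'   `n_snps` and optionally `sample_id`.
#' @return the simulation list with updated genotypes and truth.
#' @export
inject_roh <- function(sim, roh_spec) {
  if (is.null(roh_spec) || nrow(roh_spec) == 0) return(sim)
  stopifnot(all(c("subpop", "length_bp", "n_snps") %in% names(roh_spec)))
  truth <- sim$truth
  g <- sim$genotypes
  snps <- sim$snps
  planted <- truth$roh
  used <- rep(FALSE, nrow(snps))
  with_seed(derive_seed(truth$config$seed, .SIM_OFFSETS[["roh"]]), {
    for (i in seq_len(nrow(roh_spec))) {
      k <- roh_spec$subpop[i]
      n_run <- roh_spec$n_snps[i]
      rows <- which(truth$subpop == k)
      sample_id <- if ("sample_id" %in% names(roh_spec) &&
                       !is.na(roh_spec$sample_id[i])) roh_spec$sample_id[i] else
        rownames(g)[rows[1 + (i - 1) %% length(rows)]]
      r <- match(sample_id, rownames(g))
      # candidate start indices: runs of n_run SNPs on one chromosome,
      # not overlapping an already planted run
      ok <- integer(0)
      for (chr in unique(snps$chromosome)) {
        idx <- which(snps$chromosome == chr)
        if (length(idx) < n_run) next
        starts <- idx[seq_len(length(idx) - n_run + 1)]
        free <- vapply(starts, function(s) !any(used[s:(s + n_run - 1)]), logical(1))
        ok <- c(ok, starts[free])
      }
      if (!length(ok)) stop("no room to plant ROH segment ", i)
      s <- if (length(ok) == 1) ok else sample(ok, 1)
      run <- s:(s + n_run - 1)
      used[run] <- TRUE
      hap <- stats::rbinom(n_run, 1L, truth$subpop_freq[run, k])
      g[r, run] <- 2L * hap
      span <- snps$position[run[n_run]] - snps$position[run[1]] + 1L
      if (abs(span - roh_spec$length_bp[i]) > truth$config$snp_spacing_bp)
        warning(sprintf("planted run %d spans %d bp (requested %d bp)",
                        i, span, as.integer(roh_spec$length_bp[i])))
      planted <- rbind(planted, data.frame(
        sample_id = sample_id, chromosome = snps$chromosome[run[1]],
        start = snps$position[run[1]], end = snps$position[run[n_run]],
        n_snps = as.integer(n_run), stringsAsFactors = FALSE))
    }
  })
  sim$genotypes <- g
  sim$truth$roh <- planted
  sim
}
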
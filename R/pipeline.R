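# End-to-end orchestration: merge/QC -> prune -> PCA + exclusions ->
# F_st/lambda -> ROH -> power, with a manifest of per-stage outputs.

#' Assemble a pipeline configuration
#'
#' Either `bed_prefixes` (one or more PLINK filesets, merged when more
#' than one) with an optional `metadata` TSV, or `sim` (a simulated
#' dataset, used directly). All stage configurations are explicit; there
#' are no hidden thresholds beyond the documented defaults of each
#' module's config constructor.
#'
#' @param out_dir output directory (created if absent).
#' @param bed_prefixes character vector of PLINK prefixes, or NULL.
#' @param metadata path to a sample metadata TSV, or NULL.
#' @param sim a simulated dataset (from [simulate_structured_genotypes()]).
#' @param qc a [qc_config()].
#' @param prune a [prune_config()].
#' @param pca_k number of principal components.
#' @param cutoff an [ancestry_cutoff()] or NULL to skip ancestry
#'   exclusion (for datasets without an admixture source).
#' @param nn_k_max,nn_z_max nearest-neighbor outlier parameters.
#' @param roh a [roh_config()].
#' @param fst_min_group_size smallest group entering the F_st matrix.
#' @param lambda_n_total study size for the lambda translation.
#' @param power_maf,power_or,power_lambda power-grid axes.
#' @param seed integer seed for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            bed_prefixes = NULL, metadata = NULL, sim = NULL,
                            qc = qc_config(), prune = prune_config(),
                            pca_k = 10, cutoff = NULL,
                            nn_k_max = 5, nn_z_max = 4,
                            roh = roh_config(),
                            fst_min_group_size = 20, lambda_n_total = 1000,
                            power_maf = c(0.10, 0.16), power_or = 2,
                            power_lambda = c(1, 1.5, 2, 3),
                            seed = 1) {
  if (is.null(bed_prefixes) && is.null(sim))
    stop("either bed_prefixes or sim must be supplied")
  structure(list(out_dir = out_dir, bed_prefixes = bed_prefixes,
                 metadata = metadata, sim = sim, qc = qc, prune = prune,
                 pca_k = pca_k, cutoff = cutoff, nn_k_max = nn_k_max,
                 nn_z_max = nn_z_max, roh = roh,
                 fst_min_group_size = fst_min_group_size,
                 lambda_n_total = lambda_n_total,
                 power_maf = power_maf, power_or = power_or,
                 power_lambda = power_lambda, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, quote = FALSE, sep = "\t", row.names = FALSE)
  path
}

#' Run the full population-structure pipeline
#'
#' Executes the stages in order — merging/loading, SNP QC, sample QC,
#' LD pruning, PCA with ancestry-cutoff and nearest-neighbor exclusions,
#' PC-geography regressions, pairwise F_st with the lambda translation
#' plus clustering and MDS, the ROH scan with count models, and the
#' power grid — writing each stage's tables under `out_dir` and a
#' manifest (seed, file hashes, stage log) as JSON. Geography- and
#' group-based stages are skipped with an explicit notice when no
#' metadata is available. Any stage failure halts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return list with the principal in-memory results and the manifest,
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  files <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log <<- c(log, msg)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    note("stage %-12s %6.2fs", name,
         as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }
  emit <- function(x, name) {
    path <- file.path(config$out_dir, name)
    write_tsv(x, path)
    files <<- c(files, path)
    path
  }

  data <- stage("load", {
    if (!is.null(config$sim)) {
      config$sim[c("genotypes", "snps", "samples")]
    } else if (length(config$bed_prefixes) > 1) {
      sets <- lapply(config$bed_prefixes, read_plink_binary)
      intersect_and_merge(sets)
    } else {
      read_plink_binary(config$bed_prefixes)
    }
  })
  meta <- NULL
  if (!is.null(config$metadata))
    meta <- stage("metadata", read_sample_metadata(config$metadata,
                                                   rownames(data$genotypes)))
  else if (!is.null(config$sim)) meta <- config$sim$samples
  if (is.null(meta))
    note("no metadata: geography and group stages will be skipped")

  study <- if (!is.null(meta) && "study" %in% names(meta)) meta$study
           else rep("study1", nrow(data$genotypes))

  snpqc <- stage("snp_qc", run_snp_qc(data$genotypes, study, config$qc))
  emit(snpqc$summary, "snp_qc_summary.tsv")
  g <- data$genotypes[, snpqc$kept, drop = FALSE]
  snps <- data$snps[match(snpqc$kept, data$snps$snp_id), ]

  sampqc <- stage("sample_qc", run_sample_qc(g, config$qc))
  emit(data.frame(sample_id = c(sampqc$removed_related, sampqc$removed_missing),
                  reason = c(rep("related", length(sampqc$removed_related)),
                             rep("missingness", length(sampqc$removed_missing)))),
       "removed_samples_qc.tsv")
  g <- g[sampqc$kept, , drop = FALSE]
  if (!is.null(meta)) meta <- meta[match(rownames(g), meta$sample_id), , drop = FALSE]
  study <- if (!is.null(meta)) meta$study else rep("study1", nrow(g))

  kept_snps <- stage("ld_prune", prune_windowed(g, snps, config$prune))
  emit(data.frame(snp_id = kept_snps), "pruned_kept_snps.tsv")
  gp <- g[, kept_snps, drop = FALSE]
  snps_p <- snps[match(kept_snps, snps$snp_id), ]

  pca1 <- stage("pca", pca_fit(gp, config$pca_k))
  removed_anc <- character(0)
  if (!is.null(config$cutoff))
    removed_anc <- stage("ancestry_cutoff",
                         ancestry_cutoff_filter(pca1, config$cutoff))
  else note("ancestry cutoff not configured: exclusion skipped")
  keep1 <- setdiff(rownames(gp), removed_anc)
  norm1 <- patterson_normalize(gp[keep1, , drop = FALSE])
  removed_nn <- stage("nn_outliers",
                      nearest_neighbor_outliers(norm1$x, config$nn_k_max,
                                                config$nn_z_max))
  emit(data.frame(sample_id = c(removed_anc, removed_nn),
                  reason = c(rep("ancestry", length(removed_anc)),
                             rep("nn_outlier", length(removed_nn)))),
       "removed_samples_ancestry.tsv")
  keep2 <- setdiff(keep1, removed_nn)
  gp2 <- gp[keep2, , drop = FALSE]
  pca2 <- stage("pca_final", pca_fit(gp2, config$pca_k))
  emit(data.frame(sample_id = rownames(pca2$scores), pca2$scores),
       "pca_scores.tsv")
  emit(data.frame(snp_id = rownames(pca2$weights), pca2$weights),
       "pca_weights.tsv")
  emit(data.frame(component = seq_along(pca2$eigenvalues),
                  eigenvalue = pca2$eigenvalues), "pca_scree.tsv")

  geo <- NULL; fstm <- NULL; lam <- NULL; clust <- NULL; mds <- NULL
  roh_model <- NULL
  if (!is.null(meta)) {
    meta2 <- meta[match(keep2, meta$sample_id), ]
    geo <- stage("geography", pc_geography_regression(
      pca2$scores[, 1], meta2$latitude, meta2$longitude))
    emit(data.frame(quantity = names(geo), value = unlist(geo)),
         "pc1_geography.tsv")
    if (length(stats::na.omit(unique(meta2$group))) >= 2) {
      fstm <- stage("fst", pairwise_fst(gp2, meta2$group,
                                        config$fst_min_group_size))
      lam <- lambda_from_fst(fstm$fst, config$lambda_n_total)
      emit(data.frame(group = rownames(fstm$fst), fstm$fst), "fst_matrix.tsv")
      emit(data.frame(group = rownames(lam), lam), "lambda_matrix.tsv")
      if (nrow(fstm$fst) >= 3) {
        clust <- stage("cluster", cluster_groups(fstm))
        mds <- stage("mds", classical_mds(fstm))
        emit(data.frame(group = rownames(mds$coordinates), mds$coordinates),
             "fst_mds.tsv")
      }
    } else note("fewer than two groups: F_st stage skipped")
  } else note("F_st and geography stages skipped (no metadata)")

  segs <- stage("roh", scan_roh_all(gp2, snps_p, config$roh))
  emit(segs, "roh_segments.tsv")
  counts <- roh_counts(segs, rownames(gp2))
  emit(counts, "roh_counts.tsv")
  if (!is.null(meta)) {
    meta2 <- meta[match(keep2, meta$sample_id), ]
    dat <- cbind(counts, latitude = meta2$latitude, study = meta2$study)
    if (length(unique(stats::na.omit(dat$latitude))) > 1)
      roh_model <- stage("roh_model",
                         segment_count_model(dat, covariate = "latitude"))
    if (!is.null(roh_model)) emit(roh_model, "roh_latitude_model.tsv")
  }

  grid <- stage("power", power_grid(
    config$power_maf, config$power_or, config$power_lambda,
    power_scenario(seed = config$seed)))
  emit(grid, "power_grid.tsv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("popstruct")),
    seed = config$seed,
    log = log,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  note("wrote %d output files + manifest", length(files))

  invisible(list(qc = snpqc, sample_qc = sampqc, pruned = kept_snps,
                 pca = pca2, geography = geo, fst = fstm, lambda = lam,
                 clusters = clust, mds = mds, roh = segs,
                 roh_model = roh_model, power = grid, manifest = manifest))
}
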
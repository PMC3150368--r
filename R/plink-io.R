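# PLINK 1 binary genotype I/O (.bed/.bim/.fam) and sample metadata.
#
# The .bed payload is SNP-major: after the three magic bytes
# 0x6C 0x1B 0x01, each SNP occupies ceiling(n_samples / 4) bytes, four
# samples per byte, two bits per sample with the first sample in the two
# lowest-order bits. Codes: 00 = homozygous allele1, 01 = missing,
# 10 = heterozygous, 11 = homozygous allele2. Genotypes here are dosages
# of allele1 (the minor allele by convention), so 00 -> 2, 10 -> 1,
# 11 -> 0, 01 -> NA.

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup table: decoded dosages for the 4 samples in each byte.
.bed_decode_table <- local({
  two_bit <- c(2L, NA_integer_, 1L, 0L) # codes 00, 01, 10, 11
  byte <- 0:255
  cbind(two_bit[byte %% 4 + 1],
        two_bit[(byte %/% 4) %% 4 + 1],
        two_bit[(byte %/% 16) %% 4 + 1],
        two_bit[(byte %/% 64) %% 4 + 1])
})

#' Read a PLINK 1 binary fileset
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return list with `genotypes` (samples x SNPs allele1-dosage matrix),
#'   `snps` (from .bim: snp_id, chromosome, position, allele1, allele2)
#'   and `samples` (a stub sample table from .fam; join real metadata
#'   with [read_sample_metadata()]).
#' @export
read_plink_binary <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing file: ", f)

  bim_cols <- c("chromosome", "snp_id", "cm", "position", "allele1", "allele2")
  bim_df <- if (file.size(bim) == 0) {
    stats::setNames(data.frame(character(), character(), numeric(), integer(),
                               character(), character()), bim_cols)
  } else {
    utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                      col.names = bim_cols,
                      colClasses = c("character", "character", "numeric",
                                     "numeric", "character", "character"))
  }
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("fid", "sample_id", "pid", "mid",
                                            "sex", "phenotype"))
  n <- nrow(fam_df); m <- nrow(bim_df)
  bytes_per_snp <- ceiling(n / 4)

  raw <- readBin(bed, what = "raw", n = file.info(bed)$size)
  if (length(raw) < 3 || !identical(raw[1:2], .bed_magic[1:2]))
    stop("not a PLINK .bed file (bad magic bytes)")
  if (raw[3] == as.raw(0))
    stop("individual-major .bed files are unsupported")
  if (raw[3] != .bed_magic[3])
    stop("not a PLINK .bed file (bad mode byte)")
  payload <- raw[-(1:3)]
  if (length(payload) != bytes_per_snp * m)
    stop(sprintf("truncated .bed payload: expected %d bytes, found %d",
                 bytes_per_snp * m, length(payload)))

  decoded <- .bed_decode_table[as.integer(payload) + 1L, , drop = FALSE]
  # decoded rows follow payload byte order (SNP-major); transpose so the
  # 4 samples of each byte become consecutive entries
  slots <- matrix(as.integer(t(decoded)), nrow = 4L * bytes_per_snp, ncol = m)
  g <- slots[seq_len(n), , drop = FALSE]
  dimnames(g) <- list(fam_df$sample_id, bim_df$snp_id)
  snps <- bim_df[c("snp_id", "chromosome", "position", "allele1", "allele2")]
  suppressWarnings({
    chr_num <- as.integer(snps$chromosome)
    if (!anyNA(chr_num)) snps$chromosome <- chr_num
  })
  list(genotypes = g, snps = snps, samples = fam_df)
}

#' Write a PLINK 1 binary fileset
#'
#' Writes `<prefix>.bed` (SNP-major), `.bim` and `.fam`; round-trips
#' bit-exactly with [read_plink_binary()], including missing genotypes
#' (coded 01 in the payload). Padding bits beyond the last sample of each
#' SNP are zero.
#'
#' @param g samples x SNPs allele1-dosage matrix (values 0/1/2/NA).
#' @param snps SNP table with snp_id, chromosome, position, allele1, allele2.
#' @param samples sample table with at least `sample_id`.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_plink_binary <- function(g, snps, samples, prefix) {
  stopifnot_genotypes(g)
  n <- nrow(g); m <- ncol(g)
  if (nrow(snps) != m) stop("snps table does not match genotype columns")
  if (nrow(samples) != n) stop("sample table does not match genotype rows")
  if (!is.null(colnames(g)) && !identical(colnames(g), snps$snp_id))
    stop("snp_id mismatch between genotypes and snps table")
  if (!is.null(rownames(g)) && !identical(rownames(g), samples$sample_id))
    stop("sample_id mismatch between genotypes and sample table")

  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  codes <- matrix(3L, n, m)
  codes[is.na(g)] <- 1L
  codes[!is.na(g) & g == 1L] <- 2L
  codes[!is.na(g) & g == 2L] <- 0L

  bytes_per_snp <- ceiling(n / 4)
  byte_vals <- if (m == 0) integer(0) else {
    padded <- matrix(0L, 4L * bytes_per_snp, m)
    padded[seq_len(n), ] <- codes
    colSums(matrix(as.vector(padded) * c(1L, 4L, 16L, 64L), nrow = 4L))
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(as.raw(byte_vals), con)

  bim <- data.frame(snps$chromosome, snps$snp_id, rep(0, nrow(snps)),
                    snps$position, snps$allele1, snps$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(samples[["fid"]] %||% samples$sample_id, samples$sample_id,
                    samples[["pid"]] %||% 0, samples[["mid"]] %||% 0,
                    samples[["sex"]] %||% 0, samples[["phenotype"]] %||% -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a tab-separated sample metadata table
#'
#' Expects a header with columns `sample_id`, `study`, `group`,
#' `latitude`, `longitude` and optionally `ancestry`. Missing coordinates
#' are permitted and flagged in the returned `has_coordinates` column.
#'
#' @param path TSV file path.
#' @param fam_ids optional character vector of sample ids present in the
#'   genotype data; ids absent from the metadata are retained with null
#'   group/coordinates (and a warning), so they are excluded from
#'   group-wise analyses but kept in sample-level ones.
#' @return data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path, fam_ids = NULL) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  required <- c("sample_id", "study", "group", "latitude", "longitude")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  for (cc in c("latitude", "longitude")) {
    v <- tab[[cc]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      if (any(!is.na(v) & v != "" & is.na(parsed)))
        stop("unparseable ", cc, " values in metadata")
      tab[[cc]] <- parsed
    }
  }
  if (any(!is.na(tab$latitude) & abs(tab$latitude) > 90))
    stop("latitude out of [-90, 90]")
  if (any(!is.na(tab$longitude) & abs(tab$longitude) > 180))
    stop("longitude out of [-180, 180]")
  if (!"ancestry" %in% names(tab)) tab$ancestry <- NA_character_
  if (!is.null(fam_ids)) {
    absent <- setdiff(fam_ids, tab$sample_id)
    if (length(absent)) {
      warning(length(absent), " genotyped sample(s) absent from metadata; ",
              "retained with null group and excluded from group-wise analyses")
      tab <- rbind(tab, data.frame(
        sample_id = absent, study = NA_character_, group = NA_character_,
        latitude = NA_real_, longitude = NA_real_, ancestry = NA_character_,
        stringsAsFactors = FALSE))
    }
    tab <- tab[match(fam_ids, tab$sample_id), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab$has_coordinates <- !is.na(tab$latitude) & !is.na(tab$longitude)
  tab
}

#' Write the simulator outputs as a PLINK fileset plus metadata
#'
#' Convenience wrapper used by the analysis drivers: writes
#' `<prefix>.bed/.bim/.fam`, `<prefix>.meta.tsv` (tab-separated sample
#' metadata) and `<prefix>.truth.json` (planted ground truth).
#'
#' @param sim result of [simulate_structured_genotypes()].
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_simulated_dataset <- function(sim, prefix) {
  write_plink_binary(sim$genotypes, sim$snps, sim$samples, prefix)
  utils::write.table(sim$samples, paste0(prefix, ".meta.tsv"), quote = FALSE,
                     sep = "\t", row.names = FALSE)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(
    truth[c("relatives", "admixed", "flipped", "roh")],
    paste0(prefix, ".truth.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}
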
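#' Generate a synthetic imputed cohort with known ground truth
#'
#' Emulates the per-sample output of genotype imputation for one
#' chromosome: for each variant two alleles are drawn Bernoulli(AF) per
#' sample, and the dosage is the allele count plus uniform noise on
#' \[-0.1, 0.1\] truncated to \[0, 2\] (mimicking posterior-mean dosages
#' that rarely sit exactly on integers). The AF annotation is recomputed
#' from the realized dosages, so written frequencies are exactly
#' consistent with the genotype data. No linkage disequilibrium,
#' population structure or realistic imputation-error model is simulated.
#'
#' @param n_samples Number of individuals (>= 1).
#' @param n_variants Number of variants (>= 1).
#' @param chrom Chromosome label.
#' @param af True ALT allele frequencies, recycled to `n_variants`; all in
#'   (0, 1). Default: uniform draws on (0.05, 0.95).
#' @param genotyped_fraction Fraction of variants flagged as directly
#'   genotyped (vs imputed).
#' @param seed Integer seed; all randomness flows from it, and the global
#'   RNG state is restored on exit.
#' @return An object of class `cohort`: list with `spec`, `sample_ids`,
#'   `variants` (chrom/pos/ref/alt/genotyped), allele matrices `a1`, `a2`,
#'   dosage matrix `ds` (variants x samples), `af_true`, `af_realized`.
#' @export
generate_cohort <- function(n_samples, n_variants, chrom = "chr1",
                            af = NULL, genotyped_fraction = 0.2,
                            seed = 1L) {
  stopifnot(n_samples >= 1L, n_variants >= 1L,
            genotyped_fraction >= 0, genotyped_fraction <= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  if (is.null(af)) af <- stats::runif(n_variants, 0.05, 0.95)
  af <- rep_len(af, n_variants)
  if (any(af <= 0 | af >= 1)) {
    stop("true allele frequencies must lie strictly in (0, 1)",
         call. = FALSE)
  }
  pos <- cumsum(sample.int(50L, n_variants, replace = TRUE)) + 100L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_variants, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  names(alt) <- NULL
  genotyped <- rep(FALSE, n_variants)
  n_geno <- round(genotyped_fraction * n_variants)
  if (n_geno > 0L) genotyped[sample.int(n_variants, n_geno)] <- TRUE

  prob <- rep(af, times = n_samples)  # column-major: rows are variants
  a1 <- matrix(stats::rbinom(n_variants * n_samples, 1L, prob),
               nrow = n_variants)
  a2 <- matrix(stats::rbinom(n_variants * n_samples, 1L, prob),
               nrow = n_variants)
  noise <- matrix(stats::runif(n_variants * n_samples, -0.1, 0.1),
                  nrow = n_variants)
  ds <- pmin(pmax(a1 + a2 + noise, 0), 2)

  structure(
    list(spec = list(n_samples = as.integer(n_samples),
                     n_variants = as.integer(n_variants), chrom = chrom,
                     genotyped_fraction = genotyped_fraction,
                     seed = as.integer(seed)),
         sample_ids = sprintf("S%04d", seq_len(n_samples)),
         variants = data.frame(chrom = chrom, pos = pos, ref = ref,
                               alt = alt, genotyped = genotyped,
                               stringsAsFactors = FALSE),
         a1 = a1, a2 = a2, ds = ds,
         af_true = af, af_realized = rowMeans(ds) / 2),
    class = "cohort")
}

# Write one batch's VCF (gzip) from cohort slices.
.write_batch_vcf <- function(path, cohort, sample_idx, variant_idx,
                             af, maf, rsq, bgzip = FALSE) {
  v <- cohort$variants[variant_idx, , drop = FALSE]
  tmp <- tempfile(fileext = ".vcf")
  on.exit(unlink(tmp))
  con <- file(tmp, open = "wt")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", cohort$spec$chrom, ">"),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Estimated Alternate Allele Frequency\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Estimated Minor Allele Frequency\">",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Estimated Imputation Accuracy (R-square)\">",
    "##INFO=<ID=TYPED,Number=0,Type=Flag,Description=\"Genotyped site\">",
    "##INFO=<ID=IMPUTED,Number=0,Type=Flag,Description=\"Imputed site\">",
    "##INFO=<ID=TYPED_STATUS,Number=1,Type=String,Description=\"Genotyped status across batches\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated Alternate Allele Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$sample_ids[sample_idx]), collapse = "\t")),
    con)
  info <- paste0("AF=", fmt6(af), ";MAF=", fmt6(maf), ";R2=", fmt6(rsq),
                 ";", ifelse(v$genotyped, "TYPED", "IMPUTED"))
  for (i in seq_along(variant_idx)) {
    vi <- variant_idx[i]
    cells <- paste0(cohort$a1[vi, sample_idx], "|",
                    cohort$a2[vi, sample_idx], ":",
                    sprintf("%.3f", cohort$ds[vi, sample_idx]))
    writeLines(paste(c(v$chrom[i], v$pos[i],
                       key_string(v$chrom[i], v$pos[i], v$ref[i], v$alt[i]),
                       v$ref[i], v$alt[i], ".", "PASS", info[i], "GT:DS",
                       cells), collapse = "\t"), con)
  }
  close(con)
  if (bgzip) {
    finalize_vcf(tmp, path)
  } else {
    inn <- file(tmp, open = "rb")
    out <- gzfile(path, open = "wb")
    while (length(chunk <- readBin(inn, "raw", 1048576L))) {
      writeBin(chunk, out)
    }
    close(inn); close(out)
  }
  invisible(path)
}

.write_batch_info <- function(path, cohort, variant_idx, af, maf, rsq) {
  v <- cohort$variants[variant_idx, , drop = FALSE]
  con <- gzfile(path, open = "wt")
  writeLines(paste(c("SNP", "REF(0)", "ALT(1)", "ALT_Frq", "MAF", "AvgCall",
                     "Rsq", "Genotyped"), collapse = "\t"), con)
  if (length(variant_idx)) {
    writeLines(paste(key_string(v$chrom, v$pos, v$ref, v$alt), v$ref, v$alt,
                     fmt6(af), fmt6(maf), "-", fmt6(rsq),
                     ifelse(v$genotyped, "Genotyped", "Imputed"),
                     sep = "\t"), con)
  }
  close(con)
  invisible(path)
}

#' Split a synthetic cohort into imputation-style batches on disk
#'
#' Partitions the cohort's samples into `k` contiguous groups (emulating
#' separate imputation submissions), optionally re-adds the first
#' `overlap` samples of batch 1 to batch 2 under the same IDs (creating
#' true cross-batch duplicates), designates `private` variants that are
#' present in exactly one batch (absent from all others), and writes one
#' gzip-compressed VCF and one Minimac-dialect info table per batch.
#' Per-batch AF/MAF are computed from the batch's own dosage columns;
#' per-batch Rsq values are assigned (drawn uniformly on \[0.2, 0.999\],
#' deterministically from the cohort seed), not estimated, so
#' quality-combination tests have exact known inputs.
#'
#' @param cohort A [generate_cohort()] result.
#' @param k Number of batches (>= 1).
#' @param overlap Number of batch-1 samples duplicated into batch 2
#'   (requires `k >= 2`; must be smaller than the smallest batch).
#' @param private Integer vector (length `k`) of variants private to each
#'   batch.
#' @param absent_one Number of additional variants dropped from exactly
#'   one (randomly chosen) batch, so missingness counts between 1 and
#'   `k - 1` both occur.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; batch `b` is written as
#'   `<prefix><b>.vcf.gz` / `<prefix><b>.info.gz`.
#' @return List with `vcf` and `info` path vectors, per-batch
#'   `sample_ids`, and `manifest`: ground truth with `variants`,
#'   `presence` (variants x batches), full-precision `batch_af`,
#'   `batch_maf`, `rsq` matrices (`NA` where absent), `batch_n`, and
#'   `pooled_af` (frequency over the concatenated batch columns of the
#'   batches containing each variant — duplicated samples counted once
#'   per batch membership, matching sample-count weighting).
#' @export
split_into_batches <- function(cohort, k, overlap = 0L,
                               private = rep(0L, k), absent_one = 0L,
                               dir = tempdir(), prefix = "batch") {
  stopifnot(inherits(cohort, "cohort"), k >= 1L, length(private) == k)
  n <- cohort$spec$n_samples
  m <- cohort$spec$n_variants
  if (k > n) stop("more batches than samples", call. = FALSE)
  if (overlap > 0L && k < 2L) {
    stop("overlap requires at least 2 batches", call. = FALSE)
  }
  if (sum(private) + absent_one > m) {
    stop("more private/absent variants than variants", call. = FALSE)
  }
  groups <- split(seq_len(n), rep(seq_len(k), each = ceiling(n / k),
                                  length.out = n))
  if (overlap >= min(lengths(groups))) {
    stop("overlap must be smaller than the smallest batch", call. = FALSE)
  }
  if (overlap > 0L) {
    groups[[2L]] <- c(groups[[2L]], groups[[1L]][seq_len(overlap)])
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cohort$spec$seed * 1000L + k)

  presence <- matrix(TRUE, nrow = m, ncol = k)
  if (sum(private) + absent_one > 0L) {
    chosen <- sample.int(m, sum(private) + absent_one)
    off <- 0L
    for (b in seq_len(k)) {
      if (private[b] > 0L) {
        idx <- chosen[off + seq_len(private[b])]
        presence[idx, -b] <- FALSE
        off <- off + private[b]
      }
    }
    if (absent_one > 0L) {
      if (k < 2L) stop("absent_one requires at least 2 batches",
                       call. = FALSE)
      for (v in chosen[off + seq_len(absent_one)]) {
        presence[v, sample.int(k, 1L)] <- FALSE
      }
    }
  }
  rsq <- matrix(stats::runif(m * k, 0.2, 0.999), nrow = m)
  rsq[!presence] <- NA_real_

  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  batch_af <- batch_maf <- matrix(NA_real_, nrow = m, ncol = k)
  vcf_paths <- info_paths <- character(k)
  for (b in seq_len(k)) {
    cols <- groups[[b]]
    rows <- which(presence[, b])
    af <- rowMeans(cohort$ds[rows, cols, drop = FALSE]) / 2
    maf <- pmin(af, 1 - af)
    batch_af[rows, b] <- af
    batch_maf[rows, b] <- maf
    vcf_paths[b] <- file.path(dir, paste0(prefix, b, ".vcf.gz"))
    info_paths[b] <- file.path(dir, paste0(prefix, b, ".info.gz"))
    .write_batch_vcf(vcf_paths[b], cohort, cols, rows,
                     af, maf, rsq[rows, b])
    .write_batch_info(info_paths[b], cohort, rows, af, maf, rsq[rows, b])
  }

  batch_n <- lengths(groups)
  pooled_af <- vapply(seq_len(m), function(i) {
    cols <- unlist(groups[presence[i, ]], use.names = FALSE)
    mean(cohort$ds[i, cols]) / 2
  }, numeric(1))

  list(vcf = vcf_paths, info = info_paths,
       sample_ids = lapply(groups, function(g) cohort$sample_ids[g]),
       manifest = list(variants = cohort$variants, presence = presence,
                       batch_af = batch_af, batch_maf = batch_maf,
                       rsq = rsq, batch_n = as.integer(batch_n),
                       pooled_af = pooled_af))
}
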
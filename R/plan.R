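#' Configuration for a batch merge
#'
#' Bundles the batch file paths and filtering parameters that drive
#' [build_merge_plan()] and [merge_batches()].
#'
#' @param inputs Character vector of per-batch VCF paths, in batch order
#'   (order defines output sample order and duplicate precedence).
#' @param infos Optional character vector of per-batch info-table paths,
#'   same order. Default `NULL` derives each path from the VCF root name
#'   (`x.vcf.gz -> x.info.gz`).
#' @param missing Maximum number of batches a variant may be absent from
#'   and still be retained (`0` = variant must be present in every batch;
#'   retained partially-missing variants get `.|.` fills).
#' @param rsq_threshold Minimum combined imputation quality; variants whose
#'   combined Rsq is present and below this are excluded. A variant with no
#'   quality value in any batch cannot fail the threshold.
#' @param out Output prefix; outputs are `<out>.vcf.gz`,
#'   `<out>_retained.info.txt`, `<out>_excluded.info.txt`, `<out>.log` and
#'   `duplicates.txt` in the prefix's directory.
#' @param weight_mode Weights for the Fisher-z combination and frequency
#'   means: `"n"` (batch sample count, default) or `"n-3"` (the classical
#'   weight for a z-transformed correlation; applied to the quality
#'   combination only).
#' @param threads Compression workers (merge logic itself is a
#'   deterministic single scan).
#' @param make_info If `TRUE`, derive any missing info table from the VCF
#'   INFO column via [build_info_from_vcf()].
#' @param batch_labels Optional labels for per-batch columns in the
#'   retained/excluded tables; default `batch1..batchK`.
#' @return An object of class `merge_config`.
#' @export
merge_config <- function(inputs, infos = NULL, missing = 0L,
                         rsq_threshold = 0, out = "merged",
                         weight_mode = c("n", "n-3"), threads = 1L,
                         make_info = FALSE, batch_labels = NULL) {
  weight_mode <- match.arg(weight_mode)
  k <- length(inputs)
  if (k < 1L) stop("at least one input batch is required", call. = FALSE)
  if (is.null(infos)) {
    infos <- sub("\\.vcf(\\.gz)?$", ".info.gz", inputs)
  }
  if (length(infos) != k) {
    stop("infos must match inputs in length and order", call. = FALSE)
  }
  missing <- as.integer(missing)
  if (missing < 0L || missing > k - 1L) {
    stop("missing allowance must lie in [0, batches-1]", call. = FALSE)
  }
  if (rsq_threshold < 0 || rsq_threshold > 1) {
    stop("rsq_threshold must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(batch_labels)) {
    batch_labels <- paste0("batch", seq_len(k))
  }
  stopifnot(length(batch_labels) == k, !anyDuplicated(batch_labels))
  structure(
    list(inputs = inputs, infos = infos, missing = missing,
         rsq_threshold = rsq_threshold, out = out,
         weight_mode = weight_mode, threads = as.integer(threads),
         make_info = isTRUE(make_info), batch_labels = batch_labels),
    class = "merge_config")
}

#' Decide retention or exclusion for every variant across batches
#'
#' Unions the variant keys of all per-batch info tables, computes each
#' variant's cross-batch summary (Fisher-z combined Rsq, weighted/min/max
#' AF and MAF, genotyped status, batches missing) via the stats layer, and
#' applies the two filter rules in fixed order: first missingness (absent
#' from more batches than the allowance), then the combined-quality
#' threshold. Exclusion reasons therefore name the first rule violated.
#' Retained variants are ordered by (pos, ref, alt) within the chromosome.
#'
#' @param tables List of `info_table` objects, one per batch, in batch
#'   order (all from the same chromosome).
#' @param config A [merge_config()].
#' @return An object of class `merge_plan`: list with `variants` (data
#'   frame of every unioned key with combined statistics, `retained` flag
#'   and `exclusion_reason`), `presence` (variants x batches logical
#'   matrix), per-batch value matrices (`af_batch`, `maf_batch`,
#'   `rsq_batch`, `geno_batch`), `n_samples`, `batch_labels`, `config`.
#' @export
build_merge_plan <- function(tables, config) {
  stopifnot(inherits(config, "merge_config"))
  k <- length(tables)
  if (k != length(config$inputs)) {
    stop("one info table per batch is required", call. = FALSE)
  }
  n_samples <- vapply(tables, function(t) t$n_samples, integer(1))

  batch_keys <- vector("list", k)
  for (b in seq_len(k)) {
    r <- tables[[b]]$records
    kb <- key_string(r$chrom, r$pos, r$ref, r$alt)
    dup <- anyDuplicated(kb)
    if (dup) {
      stop("duplicate variant ", kb[dup], " within batch ",
           config$batch_labels[b], call. = FALSE)
    }
    batch_keys[[b]] <- kb
  }

  all_rec <- do.call(rbind, lapply(tables, function(t)
    t$records[, c("chrom", "pos", "ref", "alt")]))
  if (nrow(all_rec) == 0L) {
    stop("all info tables are empty; nothing to merge", call. = FALSE)
  }
  if (length(unique(all_rec$chrom)) > 1L) {
    stop("batches span multiple chromosomes: ",
         paste(unique(all_rec$chrom), collapse = ", "),
         "; merge one chromosome at a time", call. = FALSE)
  }
  uni <- all_rec[!duplicated(key_string(all_rec$chrom, all_rec$pos,
                                        all_rec$ref, all_rec$alt)), ]
  ord <- order(uni$pos, uni$ref, uni$alt, method = "radix")
  uni <- uni[ord, , drop = FALSE]
  rownames(uni) <- NULL
  n <- nrow(uni)
  uni_keys <- key_string(uni$chrom, uni$pos, uni$ref, uni$alt)

  idx <- matrix(NA_integer_, nrow = n, ncol = k)
  af_m <- maf_m <- rsq_m <- matrix(NA_real_, nrow = n, ncol = k)
  geno_m <- matrix(NA, nrow = n, ncol = k)
  for (b in seq_len(k)) {
    idx[, b] <- match(uni_keys, batch_keys[[b]])
    hit <- !is.na(idx[, b])
    r <- tables[[b]]$records
    af_m[hit, b] <- r$af[idx[hit, b]]
    maf_m[hit, b] <- r$maf[idx[hit, b]]
    rsq_m[hit, b] <- r$rsq[idx[hit, b]]
    geno_m[hit, b] <- r$genotyped[idx[hit, b]]
  }
  presence <- !is.na(idx)

  cols <- c("rsq_combined", "rsq_min", "rsq_max", "af_weighted", "af_min",
            "af_max", "maf_weighted", "maf_min", "maf_max")
  num <- matrix(NA_real_, nrow = n, ncol = length(cols),
                dimnames = list(NULL, cols))
  status <- character(n)
  n_eff <- integer(n)
  for (i in seq_len(n)) {
    p <- presence[i, ]
    cv <- combine_variant(af_m[i, p], maf_m[i, p], rsq_m[i, p],
                          geno_m[i, p], n_samples[p],
                          weight_mode = config$weight_mode)
    num[i, ] <- unlist(cv[cols], use.names = FALSE)
    status[i] <- cv$genotyped_status
    n_eff[i] <- cv$n_effective
  }
  n_missing <- k - rowSums(presence)

  reason <- rep(NA_character_, n)
  too_missing <- n_missing > config$missing
  reason[too_missing] <- "too-many-missing"
  below <- !too_missing & !is.na(num[, "rsq_combined"]) &
    num[, "rsq_combined"] < config$rsq_threshold
  reason[below] <- "below-threshold"

  variants <- cbind(
    uni,
    as.data.frame(num),
    data.frame(genotyped_status = status,
               n_missing_batches = as.integer(n_missing),
               n_effective = n_eff,
               retained = is.na(reason),
               exclusion_reason = reason,
               stringsAsFactors = FALSE))

  structure(
    list(variants = variants, presence = presence,
         af_batch = af_m, maf_batch = maf_m, rsq_batch = rsq_m,
         geno_batch = geno_m, n_samples = n_samples,
         batch_labels = config$batch_labels, config = config),
    class = "merge_plan")
}

#' @export
print.merge_plan <- function(x, ...) {
  v <- x$variants
  cat("merge_plan:", nrow(v), "variants across", ncol(x$presence),
      "batches\n")
  cat("  retained:", sum(v$retained), "\n")
  cat("  excluded (too-many-missing):",
      sum(v$exclusion_reason %in% "too-many-missing"), "\n")
  cat("  excluded (below-threshold):",
      sum(v$exclusion_reason %in% "below-threshold"), "\n")
  invisible(x)
}

# One output table (retained or excluded flavour) as a character matrix.
.info_output_rows <- function(plan, rows, excluded) {
  v <- plan$variants[rows, , drop = FALSE]
  pres <- plan$presence[rows, , drop = FALSE]
  k <- ncol(pres)
  out <- data.frame(
    SNP = key_string(v$chrom, v$pos, v$ref, v$alt),
    REF = v$ref, ALT = v$alt,
    Genotyped = v$genotyped_status,
    Rsq_combined = fmt6(v$rsq_combined),
    Rsq_min = fmt6(v$rsq_min), Rsq_max = fmt6(v$rsq_max),
    ALT_Frq_weighted = fmt6(v$af_weighted),
    ALT_Frq_min = fmt6(v$af_min), ALT_Frq_max = fmt6(v$af_max),
    MAF_weighted = fmt6(v$maf_weighted),
    MAF_min = fmt6(v$maf_min), MAF_max = fmt6(v$maf_max),
    Missing_batches = v$n_missing_batches,
    stringsAsFactors = FALSE, check.names = FALSE)
  if (excluded) out$Exclusion_reason <- v$exclusion_reason
  for (b in seq_len(k)) {
    lab <- plan$batch_labels[b]
    af <- fmt6(plan$af_batch[rows, b])
    maf <- fmt6(plan$maf_batch[rows, b])
    rsq <- fmt6(plan$rsq_batch[rows, b])
    geno <- ifelse(is.na(plan$geno_batch[rows, b]), ".",
                   ifelse(plan$geno_batch[rows, b], "Genotyped", "Imputed"))
    af[!pres[, b]] <- "."; maf[!pres[, b]] <- "."
    rsq[!pres[, b]] <- "."
    out[[paste0("ALT_Frq_", lab)]] <- af
    out[[paste0("MAF_", lab)]] <- maf
    out[[paste0("Rsq_", lab)]] <- rsq
    out[[paste0("Genotyped_", lab)]] <- geno
  }
  out
}

#' Write the retained and excluded variant tables
#'
#' Writes two plain-text tab-delimited tables,
#' `<prefix>_retained.info.txt` and `<prefix>_excluded.info.txt`, carrying
#' the cross-batch summary (combined/min/max Rsq, weighted/min/max AF and
#' MAF, genotyped status, missing-batch count) followed by per-batch
#' AF/MAF/Rsq/Genotyped columns suffixed with the batch label. Cells for
#' batches lacking the variant are `.`. The excluded table adds an
#' `Exclusion_reason` column.
#'
#' @param plan A [build_merge_plan()] result.
#' @param prefix Output path prefix.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_info_outputs <- function(plan, prefix) {
  stopifnot(inherits(plan, "merge_plan"))
  paths <- c(retained = paste0(prefix, "_retained.info.txt"),
             excluded = paste0(prefix, "_excluded.info.txt"))
  ret <- which(plan$variants$retained)
  exc <- which(!plan$variants$retained)
  for (nm in names(paths)) {
    rows <- if (nm == "retained") ret else exc
    tab <- .info_output_rows(plan, rows, excluded = nm == "excluded")
    utils::write.table(tab, paths[[nm]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(paths)
}
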
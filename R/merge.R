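#' Resolve sample IDs duplicated across batches
#'
#' Output samples are the batch sample lists concatenated in batch order,
#' within-batch order preserved. An ID appearing in several batches keeps
#' its original name at its first occurrence (lowest batch index); the
#' j-th later occurrence becomes `"<ID>:<j>"` (so the second occurrence is
#' `ID:2`). If a renamed ID would collide with any existing or assigned ID
#' it gains a further `.k` suffix until unique. Renaming always succeeds;
#' output IDs are globally unique.
#'
#' @param per_batch_ids List of character vectors of sample IDs, one per
#'   batch, each unique within its batch.
#' @return An object of class `sample_registry`: list with `per_batch`
#'   (input IDs), `output_ids` (renamed, same shape), `all_output`
#'   (concatenated output IDs), and `duplicates` (data frame `id`,
#'   `batch_index`, `output_id`, one row per occurrence of every ID shared
#'   by more than one batch).
#' @examples
#' resolve_duplicates(list(c("A", "B"), c("B", "C")))$all_output
#' @export
resolve_duplicates <- function(per_batch_ids) {
  stopifnot(is.list(per_batch_ids), length(per_batch_ids) >= 1L)
  for (b in seq_along(per_batch_ids)) {
    if (anyDuplicated(per_batch_ids[[b]])) {
      stop("duplicate sample IDs within batch ", b, call. = FALSE)
    }
  }
  all_orig <- unlist(per_batch_ids, use.names = FALSE)
  taken <- new.env(parent = emptyenv())
  for (id in unique(all_orig)) assign(id, TRUE, envir = taken)
  seen <- new.env(parent = emptyenv())

  output_ids <- vector("list", length(per_batch_ids))
  dup_id <- character(); dup_batch <- integer(); dup_out <- character()
  shared <- names(which(table(all_orig) > 1L))

  for (b in seq_along(per_batch_ids)) {
    ids <- per_batch_ids[[b]]
    out <- character(length(ids))
    for (i in seq_along(ids)) {
      id <- ids[i]
      cnt <- if (exists(id, envir = seen, inherits = FALSE)) {
        get(id, envir = seen, inherits = FALSE)
      } else 0L
      assign(id, cnt + 1L, envir = seen)
      if (cnt == 0L) {
        out[i] <- id
      } else {
        cand <- paste0(id, ":", cnt + 1L)
        kk <- 0L
        while (exists(cand, envir = taken, inherits = FALSE)) {
          kk <- kk + 1L
          cand <- paste0(id, ":", cnt + 1L, ".", kk)
        }
        assign(cand, TRUE, envir = taken)
        out[i] <- cand
      }
      if (id %in% shared) {
        dup_id <- c(dup_id, id)
        dup_batch <- c(dup_batch, b)
        dup_out <- c(dup_out, out[i])
      }
    }
    output_ids[[b]] <- out
  }
  structure(
    list(per_batch = per_batch_ids, output_ids = output_ids,
         all_output = unlist(output_ids, use.names = FALSE),
         duplicates = data.frame(id = dup_id, batch_index = dup_batch,
                                 output_id = dup_out,
                                 stringsAsFactors = FALSE)),
    class = "sample_registry")
}

#' Genotype-column fill values for a batch lacking a variant
#'
#' A variant retained despite being absent from some batches gets `.|.`
#' for the GT slot of every sample in those batches, and `.` for every
#' other FORMAT key (`GT:DS:GP` becomes `.|.:.:.`).
#'
#' @param format_spec Colon-separated FORMAT keys; must begin with `GT`.
#' @param n_samples Number of columns to fill.
#' @return Character vector of `n_samples` fill values.
#' @examples
#' missing_fill("GT:DS", 2)
#' @export
missing_fill <- function(format_spec, n_samples) {
  keys <- strsplit(format_spec, ":", fixed = TRUE)[[1L]]
  if (length(keys) == 0L || keys[1L] != "GT") {
    stop("FORMAT must begin with GT, got '", format_spec, "'",
         call. = FALSE)
  }
  cell <- paste(c(".|.", rep(".", length(keys) - 1L)), collapse = ":")
  rep(cell, n_samples)
}

# Rewrite one INFO string: AF/MAF and the quality key (R2 or Rsq) are
# replaced by combined values; a TYPED_STATUS token is appended; all other
# tokens and their order are preserved from the donor batch.
rewrite_info <- function(info, combined) {
  toks <- strsplit(info, ";", fixed = TRUE)[[1L]]
  keys <- sub("=.*$", "", toks)
  toks[keys == "AF"] <- paste0("AF=", fmt6(combined$af_weighted))
  toks[keys == "MAF"] <- paste0("MAF=", fmt6(combined$maf_weighted))
  is_q <- keys %in% c("R2", "Rsq", "RSQ")
  if (any(is_q) && !is.na(combined$rsq_combined)) {
    toks[is_q] <- paste0(keys[is_q], "=", fmt6(combined$rsq_combined))
  }
  paste(c(toks, paste0("TYPED_STATUS=", combined$genotyped_status)),
        collapse = ";")
}

#' Assemble one merged VCF data row
#'
#' Fixed columns (CHROM..FILTER) and FORMAT come from the first batch
#' containing the variant; genotype columns are concatenated in batch
#' order, with [missing_fill()] values for absent batches; the INFO column
#' is rewritten so AF, MAF and the quality key carry the combined
#' cross-batch values and a `TYPED_STATUS=<all|some|none>` token is
#' appended (other tokens preserved). Present batches whose FORMAT differs
#' from the donor's raise an error — FORMAT subfields are never reordered.
#'
#' @param key List or one-row data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param per_batch_rows List (one element per batch) of raw VCF data
#'   lines, `NA`/`NULL` where the batch lacks the variant; at least one
#'   present.
#' @param combined Combined statistics for the variant (the fields of a
#'   [build_merge_plan()] variants row: `af_weighted`, `maf_weighted`,
#'   `rsq_combined`, `genotyped_status`).
#' @param n_samples Integer vector of per-batch sample counts.
#' @return The merged tab-separated data row (character scalar).
#' @export
merge_variant_row <- function(key, per_batch_rows, combined, n_samples) {
  k <- length(per_batch_rows)
  stopifnot(length(n_samples) == k)
  present <- !vapply(per_batch_rows, function(r)
    is.null(r) || (length(r) == 1L && is.na(r)), logical(1))
  if (!any(present)) {
    stop("at least one batch row must be present", call. = FALSE)
  }
  donor_b <- which(present)[1L]
  parts <- vector("list", k)
  for (b in which(present)) {
    parts[[b]] <- split_fixed_geno(per_batch_rows[[b]])
  }
  donor <- parts[[donor_b]]
  fmt <- donor$fixed[9L]
  for (b in which(present)) {
    if (parts[[b]]$fixed[9L] != fmt) {
      stop("FORMAT mismatch at ",
           key_string(key$chrom, key$pos, key$ref, key$alt), ": batch ",
           b, " has '", parts[[b]]$fixed[9L], "', expected '", fmt, "'",
           call. = FALSE)
    }
  }
  fixed <- donor$fixed
  fixed[8L] <- rewrite_info(fixed[8L], combined)
  geno <- character(k)
  for (b in seq_len(k)) {
    geno[b] <- if (present[b]) {
      parts[[b]]$geno
    } else {
      paste(missing_fill(fmt, n_samples[b]), collapse = "\t")
    }
  }
  paste(c(paste(fixed, collapse = "\t"), geno), collapse = "\t")
}

# Advance one batch's stream to the target key (which its info table says
# it contains). Records at the target position that are not the target are
# buffered so same-position records can be consumed in any tie order.
# Never rewinds: each input line is read at most once.
.advance_to <- function(state, key) {
  tgt <- key_string(key$chrom, key$pos, key$ref, key$alt)
  # drop stale buffer from earlier positions
  if (length(state$buffer) && state$buffer_pos < key$pos) {
    state$buffer <- list()
  }
  if (!is.null(state$buffer[[tgt]])) {
    line <- state$buffer[[tgt]]
    state$buffer[[tgt]] <- NULL
    return(line)
  }
  repeat {
    r <- if (!is.null(state$pending)) {
      p <- state$pending
      state$pending <- NULL
      p
    } else {
      state$stream$read_next()
    }
    if (is.null(r)) {
      stop("desynchronization in batch ", state$label, ": variant ", tgt,
           " listed in its info table was not found in ",
           state$stream$path, call. = FALSE)
    }
    if (r$pos < key$pos) next
    if (r$pos > key$pos) {
      state$pending <- r
      stop("desynchronization in batch ", state$label, ": variant ", tgt,
           " listed in its info table was not found in ",
           state$stream$path, " before position ", r$pos, call. = FALSE)
    }
    rk <- key_string(r$chrom, r$pos, r$ref, r$alt)
    if (rk == tgt) return(r$line)
    state$buffer[[rk]] <- r$line
    state$buffer_pos <- r$pos
  }
}

#' Merge imputed VCF batches into one cohort
#'
#' End-to-end driver: reads every batch's VCF header and info table
#' (deriving missing info tables from the VCF INFO column when
#' `make_info = TRUE`), builds the retention plan, resolves duplicate
#' sample IDs, then executes a synchronized single-pass scan of all batch
#' VCFs — each input line is read at most once and the per-batch scan
#' position never rewinds — assembling one output row per retained
#' variant.
#'
#' Outputs, for prefix `out`: `<out>.vcf.gz` (bgzip-compressed merged
#' genotypes), `<out>_retained.info.txt` and `<out>_excluded.info.txt`
#' (cross-batch and per-batch statistics), `duplicates.txt` (in the
#' prefix's directory) and `<out>.log`. Partial outputs are removed on any
#' fatal error.
#'
#' @param config A [merge_config()].
#' @return An object of class `merge_summary`: counts of variants retained
#'   and excluded by reason, output samples, duplicate IDs, and the output
#'   paths.
#' @export
merge_batches <- function(config) {
  stopifnot(inherits(config, "merge_config"))
  k <- length(config$inputs)

  headers <- lapply(config$inputs, read_vcf_header)
  tables <- vector("list", k)
  for (b in seq_len(k)) {
    info_path <- config$infos[b]
    if (!file.exists(info_path)) {
      if (config$make_info) {
        tables[[b]] <- build_info_from_vcf(config$inputs[b], info_path)
        next
      }
      stop("info table not found for batch ", config$batch_labels[b], ": ",
           info_path, " (pass make_info = TRUE to derive it from the VCF)",
           call. = FALSE)
    }
    tables[[b]] <- read_info_table(info_path, headers[[b]]$n_samples)
  }

  plan <- build_merge_plan(tables, config)
  registry <- resolve_duplicates(lapply(headers, function(h) h$sample_ids))
  n_samples <- plan$n_samples

  out_vcf <- paste0(config$out, ".vcf.gz")
  out_log <- paste0(config$out, ".log")
  dup_path <- file.path(dirname(config$out), "duplicates.txt")
  info_paths <- c(retained = paste0(config$out, "_retained.info.txt"),
                  excluded = paste0(config$out, "_excluded.info.txt"))
  outputs <- c(out_vcf, out_log, dup_path, unname(info_paths))

  streams <- list()
  tmp <- tempfile(fileext = ".vcf")
  ok <- FALSE
  on.exit({
    for (s in streams) s$stream$close()
    unlink(tmp)
    if (!ok) unlink(outputs)
  })

  write_info_outputs(plan, config$out)

  dup <- registry$duplicates
  utils::write.table(dup, dup_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)

  streams <- lapply(seq_len(k), function(b) {
    st <- new.env(parent = emptyenv())
    st$stream <- open_vcf_stream(config$inputs[b])
    st$buffer <- list()
    st$buffer_pos <- -1L
    st$pending <- NULL
    st$label <- config$batch_labels[b]
    st
  })

  header <- c(
    headers[[1L]]$meta,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", registry$all_output), collapse = "\t"))
  n_cols <- 9L + sum(n_samples)

  ret <- plan$variants[plan$variants$retained, , drop = FALSE]
  pres_ret <- plan$presence[plan$variants$retained, , drop = FALSE]

  # write header (with provenance) and rows through one text connection
  con <- file(tmp, open = "wt")
  prov <- paste0("##imputemerge=<Version=",
                 as.character(utils::packageVersion("imputemerge")),
                 ",Batches=", k,
                 ",Missing=", config$missing,
                 ",RsqThreshold=", format(config$rsq_threshold),
                 ",WeightMode=", config$weight_mode, ">")
  writeLines(c(header[-length(header)], prov, header[length(header)]), con)

  buf <- character(0)
  flush_buf <- function() {
    if (length(buf)) {
      nf <- count_fields(buf)
      if (any(nf != n_cols)) {
        stop("internal consistency error: merged row has ",
             nf[which(nf != n_cols)[1L]], " columns, expected ", n_cols,
             call. = FALSE)
      }
      writeLines(buf, con)
    }
  }
  res <- tryCatch({
    for (i in seq_len(nrow(ret))) {
      key <- list(chrom = ret$chrom[i], pos = ret$pos[i],
                  ref = ret$ref[i], alt = ret$alt[i])
      rows <- vector("list", k)
      for (b in seq_len(k)) {
        rows[[b]] <- if (pres_ret[i, b]) {
          .advance_to(streams[[b]], key)
        } else NA_character_
      }
      buf <- c(buf, merge_variant_row(key, rows, ret[i, ], n_samples))
      if (length(buf) >= 500L) { flush_buf(); buf <- character(0) }
    }
    flush_buf()
    TRUE
  }, finally = close(con))

  finalize_vcf(tmp, out_vcf, threads = config$threads)

  v <- plan$variants
  summary <- structure(
    list(n_batches = k,
         n_samples = sum(n_samples),
         n_retained = sum(v$retained),
         n_excluded_missing = sum(v$exclusion_reason %in% "too-many-missing"),
         n_excluded_threshold = sum(v$exclusion_reason %in% "below-threshold"),
         n_duplicate_ids = length(unique(dup$id)),
         dialects = lapply(tables, function(t) t$dialect),
         outputs = c(vcf = out_vcf, retained = unname(info_paths["retained"]),
                     excluded = unname(info_paths["excluded"]),
                     duplicates = dup_path, log = out_log)),
    class = "merge_summary")

  log_lines <- c(
    paste0("imputemerge ", as.character(utils::packageVersion("imputemerge"))),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "parameters:",
    paste0("  missing allowance: ", config$missing),
    paste0("  rsq threshold: ", format(config$rsq_threshold)),
    paste0("  weight mode: ", config$weight_mode),
    paste0("  threads: ", config$threads),
    "batches:",
    vapply(seq_len(k), function(b) {
      paste0("  ", config$batch_labels[b], ": ", config$inputs[b], " (",
             n_samples[b], " samples, ", nrow(tables[[b]]$records),
             " variants; info dialect: ",
             paste(stats::na.omit(tables[[b]]$dialect), collapse = "/"), ")")
    }, character(1)),
    "summary:",
    paste0("  samples merged: ", summary$n_samples),
    paste0("  variants retained: ", summary$n_retained),
    paste0("  excluded, too many missing: ", summary$n_excluded_missing),
    paste0("  excluded, below threshold: ", summary$n_excluded_threshold),
    paste0("  duplicated sample IDs: ", summary$n_duplicate_ids))
  writeLines(log_lines, out_log)

  ok <- TRUE
  summary
}

#' @export
print.merge_summary <- function(x, ...) {
  cat("Merged", x$n_batches, "batches:", x$n_samples, "samples,",
      x$n_retained, "variants retained\n")
  cat("  excluded: ", x$n_excluded_missing, " (too many missing), ",
      x$n_excluded_threshold, " (below threshold)\n", sep = "")
  cat("  duplicated sample IDs:", x$n_duplicate_ids, "\n")
  cat("  merged VCF:", x$outputs[["vcf"]], "\n")
  invisible(x)
}
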
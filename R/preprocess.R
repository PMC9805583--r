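#' Build a Minimac-style info table from a VCF's INFO annotations
#'
#' Imputation servers ship a per-variant `*.info.gz` table alongside each
#' VCF. For imputed VCFs from other sources that table can be derived from
#' the INFO column, provided it carries an ALT frequency (`AF=`), a quality
#' key (`R2=` or `Rsq=`) and a typed/imputed indicator (`TYPED` /
#' `GENOTYPED` flag, `IMPUTED` flag, or a `GENOTYPED=`/`TYPED=` token).
#' `MAF` is taken from `MAF=` when present, else derived as
#' `min(AF, 1 - AF)`. Numbers are re-emitted with up to 6 significant
#' digits; no statistic is recomputed from dosages.
#'
#' @param vcf_path Input VCF (plain, gzip or bgzip).
#' @param info_out Path for the gzip-compressed info table
#'   (conventionally `*.info.gz`).
#' @return The parsed [read_info_table()]-style `info_table` object,
#'   invisibly written to `info_out`. Row order equals VCF record order;
#'   variant IDs are rendered `chrom:pos:ref:alt`.
#' @export
build_info_from_vcf <- function(vcf_path, info_out) {
  hdr <- read_vcf_header(vcf_path)
  recs <- stream_vcf_records(vcf_path)
  n <- nrow(recs)

  if (n > 0L) {
    m <- regexpr("^(?:[^\t]*\t){7}([^\t]*)", recs$line, perl = TRUE)
    cs <- attr(m, "capture.start")[, 1L]
    cl <- attr(m, "capture.length")[, 1L]
    info <- substring(recs$line, cs, cs + cl - 1L)

    af <- suppressWarnings(as.numeric(info_value(info, "AF")))
    bad_af <- which(is.na(af))
    if (length(bad_af)) {
      stop("VCF record ", bad_af[1L], " (", vcf_path,
           ") lacks a parseable AF= INFO key", call. = FALSE)
    }
    maf <- suppressWarnings(as.numeric(info_value(info, "MAF")))
    maf[is.na(maf)] <- pmin(af, 1 - af)[is.na(maf)]

    rsq_chr <- info_value(info, "R2")
    alt_rsq <- info_value(info, "Rsq")
    rsq_chr[is.na(rsq_chr)] <- alt_rsq[is.na(rsq_chr)]
    rsq_chr[rsq_chr %in% .na_tokens] <- NA_character_
    rsq <- suppressWarnings(as.numeric(rsq_chr))

    typed_values <- c("genotyped", "typed", "true", "yes", "1")
    genotyped <- info_flag(info, "TYPED") | info_flag(info, "GENOTYPED") |
      tolower(info_value(info, "GENOTYPED")) %in% typed_values |
      tolower(info_value(info, "TYPED")) %in% typed_values

    no_quality <- is.na(rsq) & !genotyped
    if (any(no_quality)) {
      stop("VCF record ", which(no_quality)[1L], " (", vcf_path,
           ") has no quality key and is not flagged genotyped",
           call. = FALSE)
    }
  } else {
    af <- maf <- rsq <- numeric()
    genotyped <- logical()
  }

  con <- gzfile(info_out, open = "wt")
  ok <- FALSE
  tryCatch({
    writeLines(paste(c("SNP", "REF(0)", "ALT(1)", "ALT_Frq", "MAF",
                       "AvgCall", "Rsq", "Genotyped"), collapse = "\t"), con)
    if (n > 0L) {
      rows <- paste(key_string(recs$chrom, recs$pos, recs$ref, recs$alt),
                    recs$ref, recs$alt, fmt6(af), fmt6(maf), "-",
                    ifelse(is.na(rsq), "-", fmt6(rsq)),
                    ifelse(genotyped, "Genotyped", "Imputed"),
                    sep = "\t")
      writeLines(rows, con)
    }
    ok <- TRUE
  }, finally = close(con))
  if (!ok) {
    unlink(info_out)
    stop("failed writing info table to ", info_out, call. = FALSE)
  }

  read_info_table(info_out, n_samples = hdr$n_samples)
}
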
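#' Read the header of a (gzip/bgzip-compressed) VCF file
#'
#' Parses the meta lines (`##...`) and the `#CHROM` column header of a
#' VCF 4.x file and returns the sample layout. Sample IDs must be unique
#' within one file; duplicates across batches are handled later by
#' [resolve_duplicates()].
#'
#' @param path Path to a `.vcf`, `.vcf.gz` (gzip) or bgzip-compressed file.
#' @return An object of class `vcf_header`: a list with `path`, `meta`
#'   (character vector of `##` lines), `sample_ids`, and `n_samples`.
#' @examples
#' vcf <- system.file("extdata", "mini.vcf", package = "imputemerge")
#' hdr <- read_vcf_header(vcf)
#' hdr$sample_ids
#' @export
read_vcf_header <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  meta <- character()
  first <- TRUE
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) {
      stop("no #CHROM header line found in ", path, call. = FALSE)
    }
    if (first) {
      if (!startsWith(line, "##fileformat=VCF")) {
        stop("not a VCF file (missing ##fileformat=VCF meta line): ", path,
             call. = FALSE)
      }
      first <- FALSE
    }
    if (startsWith(line, "##")) {
      meta <- c(meta, line)
    } else if (startsWith(line, "#CHROM")) {
      cols <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      if (length(cols) < 9L) {
        stop("malformed #CHROM line (fewer than 9 columns) in ", path,
             call. = FALSE)
      }
      samples <- if (length(cols) > 9L) cols[-(1:9)] else character()
      if (anyDuplicated(samples)) {
        dup <- unique(samples[duplicated(samples)])
        stop("duplicate sample IDs within one VCF (", path, "): ",
             paste(dup, collapse = ", "), call. = FALSE)
      }
      return(structure(
        list(path = path, meta = meta, sample_ids = samples,
             n_samples = length(samples)),
        class = "vcf_header"))
    } else {
      stop("unexpected line before #CHROM header in ", path, call. = FALSE)
    }
  }
}

#' Open a streaming reader over the data records of a sorted VCF
#'
#' Returns a reader object that yields one record at a time, in file order,
#' without loading the file into memory. Each record carries the variant key
#' (CHROM, POS, REF, ALT) plus the unmodified raw line for pass-through.
#' A position that decreases relative to the previous record is a fatal
#' sort-order error: inputs are required to be position-sorted and are never
#' silently resorted.
#'
#' @param path Path to the VCF file (plain, gzip or bgzip).
#' @param chunk_size Number of lines read per internal buffered read.
#' @return An object of class `vcf_stream` with elements `read_next()`
#'   (returns a list `chrom`, `pos`, `ref`, `alt`, `line`, `line_no`, or
#'   `NULL` at end of file), `lines_read()` and `close()`.
#' @seealso [stream_vcf_records()] for the eager convenience wrapper.
#' @export
open_vcf_stream <- function(path, chunk_size = 512L) {
  con <- open_text(path)
  # consume header
  n_header <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    n_header <- n_header + 1L
    if (startsWith(line, "#CHROM")) break
    if (!startsWith(line, "#")) {
      close(con)
      stop("no #CHROM header line found in ", path, call. = FALSE)
    }
  }

  env <- new.env(parent = emptyenv())
  env$buf_lines <- character()
  env$buf_chrom <- character()
  env$buf_pos <- integer()
  env$buf_ref <- character()
  env$buf_alt <- character()
  env$idx <- 0L
  env$line_no <- n_header      # physical line number of last yielded line
  env$n_records <- 0L
  env$last_pos <- -1L
  env$open <- TRUE

  fill <- function() {
    lines <- readLines(con, n = chunk_size)
    if (length(lines) == 0L) return(FALSE)
    m <- regexec("^([^\t]+)\t([^\t]+)\t[^\t]+\t([^\t]+)\t([^\t]+)\t", lines)
    parts <- regmatches(lines, m)
    bad <- which(lengths(parts) != 5L)
    if (length(bad)) {
      stop("malformed VCF data line at line ", env$line_no + bad[1L],
           " in ", path, call. = FALSE)
    }
    pm <- matrix(unlist(parts), nrow = 5L)
    pos <- suppressWarnings(as.integer(pm[3L, ]))
    if (anyNA(pos)) {
      stop("non-integer POS field at line ",
           env$line_no + which(is.na(pos))[1L], " in ", path, call. = FALSE)
    }
    env$buf_lines <- lines
    env$buf_chrom <- pm[2L, ]
    env$buf_pos <- pos
    env$buf_ref <- pm[4L, ]
    env$buf_alt <- pm[5L, ]
    env$idx <- 0L
    TRUE
  }

  read_next <- function() {
    if (env$idx >= length(env$buf_lines)) {
      if (!env$open || !fill()) return(NULL)
    }
    env$idx <- env$idx + 1L
    env$line_no <- env$line_no + 1L
    i <- env$idx
    pos <- env$buf_pos[i]
    if (pos < env$last_pos) {
      stop("sort-order violation at line ", env$line_no, " in ", path,
           ": position ", pos, " after ", env$last_pos,
           " (inputs must be position-sorted)", call. = FALSE)
    }
    env$last_pos <- pos
    env$n_records <- env$n_records + 1L
    list(chrom = env$buf_chrom[i], pos = pos, ref = env$buf_ref[i],
         alt = env$buf_alt[i], line = env$buf_lines[i],
         line_no = env$line_no)
  }

  close_stream <- function() {
    if (env$open) {
      close(con)
      env$open <- FALSE
    }
    invisible(NULL)
  }

  structure(
    list(path = path,
         read_next = read_next,
         lines_read = function() env$n_records,
         close = close_stream),
    class = "vcf_stream")
}

#' Read all data records of a sorted VCF into a data frame
#'
#' Eager wrapper around [open_vcf_stream()]; intended for small files and
#' tests. Each row carries the variant key and the raw unmodified data line.
#'
#' @inheritParams open_vcf_stream
#' @return A data frame with columns `chrom`, `pos`, `ref`, `alt`, `line`.
#' @export
stream_vcf_records <- function(path, chunk_size = 512L) {
  s <- open_vcf_stream(path, chunk_size = chunk_size)
  on.exit(s$close())
  chrom <- character(); pos <- integer()
  ref <- character(); alt <- character(); line <- character()
  repeat {
    r <- s$read_next()
    if (is.null(r)) break
    chrom <- c(chrom, r$chrom); pos <- c(pos, r$pos)
    ref <- c(ref, r$ref); alt <- c(alt, r$alt); line <- c(line, r$line)
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, line = line,
             stringsAsFactors = FALSE)
}

# Column-name synonyms of the Minimac3/4 info dialects, matched
# case-insensitively; first match wins.
.info_synonyms <- list(
  snp       = c("SNP", "ID"),
  ref       = c("REF(0)", "REF"),
  alt       = c("ALT(1)", "ALT"),
  af        = c("ALT_Frq", "AF", "ALT_frq"),
  maf       = c("MAF"),
  rsq       = c("Rsq", "R2"),
  genotyped = c("Genotyped", "TYPED")
)

.find_col <- function(cols, synonyms) {
  lc <- tolower(cols)
  for (s in synonyms) {
    i <- match(tolower(s), lc)
    if (!is.na(i)) return(i)
  }
  NA_integer_
}

# Minimac placeholder tokens meaning "no value".
.na_tokens <- c("-", ".", "")

#' Read a Minimac-style imputation info table
#'
#' Parses the tab-delimited, gzip-compressed per-variant table that
#' accompanies an imputed VCF (`*.info.gz`): variant ID, alleles, ALT
#' frequency, MAF, imputation Rsq and genotyped status. Column names are
#' matched case-insensitively against the synonym sets used by the
#' Minimac3/Minimac4 and TOPMed/Michigan server dialects
#' (`Rsq`/`R2`, `ALT_Frq`/`AF`, `Genotyped`/`TYPED`). Placeholder quality
#' values (`-`, `.`, empty) become `NA`.
#'
#' @param path Path to the info file (plain, gzip or bgzip compressed).
#' @param n_samples Number of individuals in the batch this table
#'   describes; stored on every record and used downstream as the
#'   combination weight.
#' @return An object of class `info_table`: list with `records` (data frame
#'   with columns `chrom`, `pos`, `ref`, `alt`, `af`, `maf`, `rsq`,
#'   `genotyped`), `dialect` (named character vector of matched column
#'   names), `n_samples` and `path`.
#' @export
read_info_table <- function(path, n_samples) {
  if (!file.exists(path)) {
    stop("info file not found: ", path, call. = FALSE)
  }
  stopifnot(is.numeric(n_samples), length(n_samples) == 1L, n_samples >= 0)
  con <- open_text(path)
  on.exit(close(con))
  tab <- utils::read.delim(con, header = TRUE, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  cols <- names(tab)
  idx <- vapply(.info_synonyms, function(s) .find_col(cols, s), integer(1))
  mandatory <- c("snp", "af", "maf", "rsq", "genotyped")
  missing_col <- mandatory[is.na(idx[mandatory])]
  if (length(missing_col)) {
    wanted <- vapply(.info_synonyms[missing_col],
                     function(s) s[1L], character(1))
    stop("info table ", path, " lacks mandatory column(s): ",
         paste(wanted, collapse = ", "), call. = FALSE)
  }
  dialect <- vapply(idx, function(i) if (is.na(i)) NA_character_ else cols[i],
                    character(1))

  n <- nrow(tab)
  if (n == 0L) {
    rec <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      af = numeric(), maf = numeric(), rsq = numeric(),
                      genotyped = logical(), stringsAsFactors = FALSE)
    return(structure(list(records = rec, dialect = dialect,
                          n_samples = as.integer(n_samples), path = path),
                     class = "info_table"))
  }

  id <- tab[[idx[["snp"]]]]
  id_parts <- strsplit(id, ":", fixed = TRUE)
  nparts <- lengths(id_parts)
  if (any(nparts < 2L)) {
    stop("cannot parse variant ID '", id[which(nparts < 2L)[1L]],
         "' in ", path, " (expected chrom:pos[:ref:alt])", call. = FALSE)
  }
  chrom <- vapply(id_parts, `[`, character(1), 1L)
  pos <- suppressWarnings(as.integer(vapply(id_parts, `[`, character(1), 2L)))
  if (anyNA(pos)) {
    stop("non-integer position in variant ID at data row ",
         which(is.na(pos))[1L], " of ", path, call. = FALSE)
  }
  if (!is.na(idx[["ref"]]) && !is.na(idx[["alt"]])) {
    ref <- tab[[idx[["ref"]]]]
    alt <- tab[[idx[["alt"]]]]
  } else if (all(nparts >= 4L)) {
    ref <- vapply(id_parts, `[`, character(1), 3L)
    alt <- vapply(id_parts, `[`, character(1), 4L)
  } else {
    stop("info table ", path,
         " has no REF/ALT columns and variant IDs lack ref:alt parts",
         call. = FALSE)
  }

  parse_num <- function(x, what, lo, hi, allow_na = FALSE) {
    raw <- x
    x[x %in% .na_tokens] <- NA_character_
    v <- suppressWarnings(as.numeric(x))
    bad_parse <- !is.na(x) & is.na(v)
    if (any(bad_parse)) {
      stop("unparsable ", what, " value '", raw[which(bad_parse)[1L]],
           "' at data row ", which(bad_parse)[1L], " of ", path,
           call. = FALSE)
    }
    if (!allow_na && anyNA(v)) {
      stop("missing ", what, " value at data row ", which(is.na(v))[1L],
           " of ", path, call. = FALSE)
    }
    out_of_range <- !is.na(v) & (v < lo | v > hi)
    if (any(out_of_range)) {
      stop(what, " value ", v[which(out_of_range)[1L]], " outside [",
           lo, ",", hi, "] at data row ", which(out_of_range)[1L],
           " of ", path, call. = FALSE)
    }
    v
  }

  af <- parse_num(tab[[idx[["af"]]]], "AF", 0, 1)
  maf <- parse_num(tab[[idx[["maf"]]]], "MAF", 0, 0.5)
  rsq <- parse_num(tab[[idx[["rsq"]]]], "Rsq", 0, 1, allow_na = TRUE)
  genotyped <- tolower(tab[[idx[["genotyped"]]]]) %in%
    c("genotyped", "typed", "typed_only", "true", "yes", "1")

  rec <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    af = af, maf = maf, rsq = rsq, genotyped = genotyped,
                    stringsAsFactors = FALSE)
  structure(list(records = rec, dialect = dialect,
                 n_samples = as.integer(n_samples), path = path),
            class = "info_table")
}

# Compress `tmp` (plain text) to bgzip at `path`. threads > 1 uses the
# htslib bgzip binary when available; output decompresses identically.
finalize_vcf <- function(tmp, path, threads = 1L) {
  bgzip_bin <- Sys.which("bgzip")
  if (threads > 1L && nzchar(bgzip_bin)) {
    status <- system2(bgzip_bin, c("-@", as.character(threads), "-c",
                                   shQuote(tmp)),
                      stdout = path, stderr = FALSE)
    if (status != 0L) {
      unlink(path)
      stop("bgzip compression failed for ", path, call. = FALSE)
    }
  } else {
    Rsamtools::bgzip(tmp, dest = path, overwrite = TRUE)
  }
  invisible(path)
}

#' Write a merged VCF as block-gzip (bgzip)
#'
#' Writes header lines and pre-assembled data rows to a bgzip-compressed
#' file so that downstream indexing (tabix) works. A provenance meta line
#' is inserted before the `#CHROM` line. Every data row must have exactly
#' the column count implied by the `#CHROM` line; on a mismatch nothing is
#' left behind. Byte content of the decompressed stream is independent of
#' the compression `threads` used.
#'
#' @param header Character vector of header lines: `##` meta lines followed
#'   by the final `#CHROM` line.
#' @param records Character vector of complete tab-separated data rows
#'   (may be empty for a header-only file).
#' @param path Output path (conventionally `*.vcf.gz`).
#' @param provenance Text recorded in the inserted `##imputemerge=` meta
#'   line.
#' @param threads Compression workers; compression only, never merge logic.
#' @return The output path, invisibly.
#' @export
write_merged_vcf <- function(header, records, path,
                             provenance = paste0("n_records=", length(records)),
                             threads = 1L) {
  chrom_i <- which(startsWith(header, "#CHROM"))
  if (length(chrom_i) != 1L) {
    stop("header must contain exactly one #CHROM line", call. = FALSE)
  }
  n_cols <- count_fields(header[chrom_i])
  if (length(records)) {
    nf <- count_fields(records)
    bad <- which(nf != n_cols)
    if (length(bad)) {
      stop("data row ", bad[1L], " has ", nf[bad[1L]],
           " columns; header implies ", n_cols, call. = FALSE)
    }
  }
  prov <- paste0("##imputemerge=<Version=",
                 as.character(utils::packageVersion("imputemerge")),
                 ",", provenance, ">")
  header <- append(header, prov, after = chrom_i - 1L)

  tmp <- tempfile(fileext = ".vcf")
  on.exit(unlink(tmp))
  con <- file(tmp, open = "wt")
  ok <- FALSE
  tryCatch({
    writeLines(header, con)
    if (length(records)) writeLines(records, con)
    ok <- TRUE
  }, finally = close(con))
  if (!ok) {
    unlink(path)
    stop("failed writing merged VCF to ", path, call. = FALSE)
  }
  finalize_vcf(tmp, path, threads = threads)
  invisible(path)
}
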
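# Internal helpers shared across modules.

# Format numeric values for file output: up to 6 significant digits,
# never scientific notation, NA rendered as the "." placeholder.
fmt6 <- function(x) {
  out <- rep(".", length(x))
  ok <- !is.na(x)
  out[ok] <- vapply(x[ok], function(v) {
    format(signif(v, 6L), scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

# Canonical string identity of a variant record.
key_string <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Open a text-mode reading connection for plain, gzip or bgzip files.
# bgzip is a gzip superset, so gzfile() handles all three.
open_text <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  gzfile(path, open = "rt")
}

# Extract the value of `key` from a vector of semicolon-separated VCF INFO
# strings; NA where the key is absent. Matches KEY=value, not bare flags.
info_value <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regexpr(pat, info, perl = TRUE)
  out <- rep(NA_character_, length(info))
  hit <- m > 0L
  if (any(hit)) {
    # capture group start/length are exposed by perl = TRUE regexpr
    cs <- attr(m, "capture.start")[, 1L]
    cl <- attr(m, "capture.length")[, 1L]
    out[hit] <- substring(info[hit], cs[hit], cs[hit] + cl[hit] - 1L)
  }
  out
}

# TRUE where a bare flag token is present in an INFO string.
info_flag <- function(info, flag) {
  grepl(paste0("(^|;)", flag, "($|;)"), info)
}

# Count tab-separated fields in each element of a character vector.
count_fields <- function(x) {
  g <- gregexpr("\t", x, fixed = TRUE)
  vapply(g, function(m) if (m[1L] == -1L) 1L else length(m) + 1L, integer(1))
}

# Split one raw VCF data line into the 9 fixed columns and the genotype
# block (everything after the FORMAT column) without splitting per sample.
split_fixed_geno <- function(line) {
  tabs <- gregexpr("\t", line, fixed = TRUE)[[1L]]
  if (length(tabs) < 9L) {
    stop("VCF data line has fewer than 10 columns", call. = FALSE)
  }
  fixed <- strsplit(substr(line, 1L, tabs[9L] - 1L), "\t", fixed = TRUE)[[1L]]
  geno <- substr(line, tabs[9L] + 1L, nchar(line))
  list(fixed = fixed, geno = geno)
}
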
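# Shared fixture builders: hand-crafted VCF / info files for format-level
# tests. Larger cohorts come from the package's own generator.

write_gz <- function(lines, path = tempfile(fileext = ".gz")) {
  con <- gzfile(path, open = "wt")
  writeLines(lines, con)
  close(con)
  path
}

write_plain <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_meta <- function(chrom = "chr1") {
  c("##fileformat=VCFv4.2",
    paste0("##contig=<ID=", chrom, ">"),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"AF\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"MAF\">",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"R2\">",
    "##INFO=<ID=TYPED,Number=0,Type=Flag,Description=\"typed\">",
    "##INFO=<ID=IMPUTED,Number=0,Type=Flag,Description=\"imputed\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"DS\">")
}

# Build a small VCF from data-row strings; compress = "gzip"|"bgzip"|"none".
make_vcf <- function(rows, samples = c("S1", "S2"), chrom = "chr1",
                     compress = "gzip",
                     path = tempfile(fileext = ".vcf.gz")) {
  lines <- c(vcf_meta(chrom),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"),
             rows)
  if (compress == "gzip") {
    write_gz(lines, path)
  } else if (compress == "bgzip") {
    tmp <- write_plain(lines)
    Rsamtools::bgzip(tmp, dest = path, overwrite = TRUE)
    unlink(tmp)
    path
  } else {
    write_plain(lines, path)
  }
}

# One VCF data row with GT:DS cells.
vrow <- function(pos, ref, alt, cells, chrom = "chr1",
                 info = "AF=0.25;MAF=0.25;R2=0.9;IMPUTED") {
  paste(c(chrom, pos, paste(chrom, pos, ref, alt, sep = ":"), ref, alt,
          ".", "PASS", info, "GT:DS", cells), collapse = "\t")
}

minimac_header <- paste(c("SNP", "REF(0)", "ALT(1)", "ALT_Frq", "MAF",
                          "AvgCall", "Rsq", "Genotyped"), collapse = "\t")

# One Minimac info row.
irow <- function(pos, ref, alt, af, maf, rsq, genotyped = FALSE,
                 chrom = "chr1") {
  paste(paste(chrom, pos, ref, alt, sep = ":"), ref, alt, af, maf, "-",
        rsq, if (genotyped) "Genotyped" else "Imputed", sep = "\t")
}

make_info_gz <- function(rows, header = minimac_header,
                         path = tempfile(fileext = ".info.gz")) {
  write_gz(c(header, rows), path)
}

# info_table object straight from in-memory records, via a real file.
info_obj <- function(rows, n_samples, header = minimac_header) {
  read_info_table(make_info_gz(rows, header), n_samples)
}

# Independent Fisher-combination oracle: loops and explicit log/exp forms,
# deliberately not the atanh/tanh path used by the implementation.
oracle_combine_rsq <- function(rsq, w) {
  keep <- !is.na(rsq)
  rsq <- rsq[keep]; w <- w[keep]
  if (length(rsq) == 0L) return(NA_real_)
  num <- 0; den <- 0
  for (i in seq_along(rsq)) {
    r <- sqrt(rsq[i])
    if (r > 1 - 1e-6) r <- 1 - 1e-6
    z <- 0.5 * log((1 + r) / (1 - r))
    num <- num + w[i] * z
    den <- den + w[i]
  }
  zbar <- num / den
  r_back <- (exp(2 * zbar) - 1) / (exp(2 * zbar) + 1)
  r_back^2
}

# Genotype cell strings (GT:DS) of a cohort, as written by the generator.
cohort_cells <- function(cohort, variant_idx, sample_idx) {
  matrix(paste0(cohort$a1[variant_idx, sample_idx, drop = FALSE], "|",
                cohort$a2[variant_idx, sample_idx, drop = FALSE], ":",
                sprintf("%.3f", cohort$ds[variant_idx, sample_idx,
                                          drop = FALSE])),
         nrow = length(variant_idx))
}

# Genotype block (columns 10+) of merged VCF data rows, split per sample.
geno_matrix <- function(vcf_path) {
  lines <- readLines(gzfile(vcf_path))
  data <- lines[!startsWith(lines, "#")]
  parts <- strsplit(data, "\t", fixed = TRUE)
  do.call(rbind, lapply(parts, function(p) p[-(1:9)]))
}
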
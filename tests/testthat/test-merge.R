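test_that("disjoint sample sets concatenate without renaming", {
  reg <- resolve_duplicates(list(c("A", "B"), c("C", "D")))
  expect_identical(reg$all_output, c("A", "B", "C", "D"))
  expect_identical(nrow(reg$duplicates), 0L)
})

test_that("a shared sample keeps its first ID and gains a suffix later", {
  reg <- resolve_duplicates(list(c("A", "B"), c("B", "C")))
  expect_identical(reg$all_output, c("A", "B", "B:2", "C"))
  expect_identical(unique(reg$duplicates$id), "B")
  expect_identical(reg$duplicates$output_id, c("B", "B:2"))
})

test_that("an ID in three batches yields :2 and :3 variants, all unique", {
  reg <- resolve_duplicates(list(c("X", "A"), c("X", "B"), c("X", "C")))
  expect_identical(reg$output_ids[[1]][1], "X")
  expect_identical(reg$output_ids[[2]][1], "X:2")
  expect_identical(reg$output_ids[[3]][1], "X:3")
  expect_false(anyDuplicated(reg$all_output) > 0)
})

test_that("renamed IDs avoid collisions with pre-existing IDs", {
  reg <- resolve_duplicates(list(c("A", "A:2"), c("A", "Z")))
  expect_false(anyDuplicated(reg$all_output) > 0)
  expect_identical(reg$output_ids[[2]][1], "A:2.1")
})

test_that("duplicate IDs within a single batch are rejected", {
  expect_error(resolve_duplicates(list(c("A", "A"))), "within batch")
})

test_that("missing fill is .|. for GT and . for every other key", {
  expect_identical(missing_fill("GT", 3), rep(".|.", 3))
  expect_identical(missing_fill("GT:DS", 1), ".|.:.")
  expect_identical(missing_fill("GT:DS:GP", 2), rep(".|.:.:.", 2))
  expect_error(missing_fill("DS:GT", 2), "begin with GT")
})

combined_stub <- function(af = 0.2, maf = 0.2, rsq = 0.5,
                          status = "none") {
  list(af_weighted = af, maf_weighted = maf, rsq_combined = rsq,
       genotyped_status = status)
}

test_that("merged row splices genotype blocks in batch order", {
  key <- list(chrom = "chr1", pos = 100L, ref = "A", alt = "G")
  r1 <- vrow(100, "A", "G", c("0|1:0.900", "1|1:1.950"))
  r2 <- vrow(100, "A", "G", c("0|0:0.050", "0|1:1.100", "1|0:0.990"))
  row <- merge_variant_row(key, list(r1, r2), combined_stub(),
                           n_samples = c(2L, 3L))
  f <- strsplit(row, "\t", fixed = TRUE)[[1]]
  expect_length(f, 9 + 5)
  # string-level oracle: direct splice of the two inputs' genotype fields
  expect_identical(f[10:14],
                   c("0|1:0.900", "1|1:1.950",
                     "0|0:0.050", "0|1:1.100", "1|0:0.990"))
})

test_that("absent batches get missing fills in the right columns", {
  key <- list(chrom = "chr1", pos = 100L, ref = "A", alt = "G")
  r1 <- vrow(100, "A", "G", c("0|1:0.900", "1|1:1.950"))
  row <- merge_variant_row(key, list(r1, NA), combined_stub(),
                           n_samples = c(2L, 3L))
  f <- strsplit(row, "\t", fixed = TRUE)[[1]]
  expect_identical(f[12:14], rep(".|.:.", 3))
})

test_that("INFO is rewritten with combined values, others preserved", {
  key <- list(chrom = "chr1", pos = 100L, ref = "A", alt = "G")
  r1 <- vrow(100, "A", "G", "0|1:0.900",
             info = "AF=0.25;MAF=0.25;AVG_CS=0.99;R2=0.91;IMPUTED")
  row <- merge_variant_row(key, list(r1),
                           combined_stub(af = 0.3, maf = 0.3, rsq = 0.8,
                                         status = "some"),
                           n_samples = 1L)
  info <- strsplit(row, "\t", fixed = TRUE)[[1]][8]
  expect_identical(info,
                   "AF=0.3;MAF=0.3;AVG_CS=0.99;R2=0.8;IMPUTED;TYPED_STATUS=some")
})

test_that("FORMAT disagreement between batches is a fatal merge error", {
  key <- list(chrom = "chr1", pos = 100L, ref = "A", alt = "G")
  r1 <- vrow(100, "A", "G", "0|1:0.900")
  r2 <- sub("GT:DS", "GT:DS:GP", vrow(100, "A", "G", "0|0:0.1:0.9,0.1,0"))
  expect_error(merge_variant_row(key, list(r1, r2), combined_stub(),
                                 n_samples = c(1L, 1L)),
               "FORMAT mismatch")
})

test_that("splitting a cohort and merging it back restores the genotypes", {
  co <- generate_cohort(6, 50, seed = 21)
  sp <- split_into_batches(co, k = 2, dir = tempfile("rt"))
  out <- file.path(tempfile("rtout"), "merged")
  dir.create(dirname(out), recursive = TRUE)
  s <- merge_batches(merge_config(sp$vcf, sp$info, out = out))
  expect_identical(s$n_retained, 50L)
  expect_identical(s$n_samples, 6L)
  merged <- geno_matrix(s$outputs[["vcf"]])
  expect_identical(unname(merged), unname(cohort_cells(co, 1:50, 1:6)))
  hdr <- read_vcf_header(s$outputs[["vcf"]])
  expect_identical(hdr$sample_ids, co$sample_ids)
})

test_that("a variant private to one batch is filled or dropped by allowance", {
  co <- generate_cohort(9, 20, seed = 33)
  sp <- split_into_batches(co, k = 3, private = c(0, 1, 0),
                           dir = tempfile("priv"))
  priv_i <- which(rowSums(sp$manifest$presence) == 1L)
  v <- co$variants[priv_i, ]
  key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

  out1 <- file.path(tempfile("p1"), "m")
  dir.create(dirname(out1), recursive = TRUE)
  s1 <- merge_batches(merge_config(sp$vcf, sp$info, missing = 2L,
                                   out = out1))
  expect_identical(s1$n_retained, 20L)
  lines <- readLines(gzfile(s1$outputs[["vcf"]]))
  row <- strsplit(grep(paste0("\t", key, "\t"), lines, value = TRUE,
                       fixed = TRUE), "\t")[[1]]
  # batches 1 and 3 (3 samples each) filled, batch 2 carries data
  expect_identical(row[10:12], rep(".|.:.", 3))
  expect_identical(row[16:18], rep(".|.:.", 3))
  expect_false(any(row[13:15] == ".|.:."))

  out0 <- file.path(tempfile("p0"), "m")
  dir.create(dirname(out0), recursive = TRUE)
  s0 <- merge_batches(merge_config(sp$vcf, sp$info, missing = 0L,
                                   out = out0))
  expect_identical(s0$n_retained, 19L)
  expect_identical(s0$n_excluded_missing, 1L)
  lines0 <- readLines(gzfile(s0$outputs[["vcf"]]))
  expect_false(any(grepl(key, lines0, fixed = TRUE)))
  exc <- read.delim(s0$outputs[["excluded"]], check.names = FALSE)
  expect_identical(exc$SNP, key)
  expect_identical(exc$Exclusion_reason, "too-many-missing")
})

test_that("merge is a single pass: lines read never exceed file lines", {
  co <- generate_cohort(6, 40, seed = 8)
  sp <- split_into_batches(co, k = 2, dir = tempfile("sp"))
  # excluded variants force skipping, not re-reading
  out <- file.path(tempfile("sp_out"), "m")
  dir.create(dirname(out), recursive = TRUE)
  s <- merge_batches(merge_config(sp$vcf, sp$info, rsq_threshold = 0.6,
                                  out = out))
  expect_lt(s$n_retained, 40L)
  merged <- stream_vcf_records(s$outputs[["vcf"]])
  expect_identical(nrow(merged), s$n_retained)
  expect_true(all(diff(merged$pos) >= 0))
})

test_that("an info/VCF desynchronization is fatal and cleans up outputs", {
  co <- generate_cohort(4, 10, seed = 13)
  sp <- split_into_batches(co, k = 1, dir = tempfile("desync"))
  # append a phantom variant to the info table (beyond the last position)
  info_lines <- readLines(gzfile(sp$info[1]))
  phantom <- irow(max(co$variants$pos) + 500L, "A", "G", 0.2, 0.2, 0.9)
  con <- gzfile(sp$info[1], "wt")
  writeLines(c(info_lines, phantom), con)
  close(con)

  out <- file.path(tempfile("dx"), "m")
  dir.create(dirname(out), recursive = TRUE)
  expect_error(merge_batches(merge_config(sp$vcf, sp$info, out = out)),
               "desynchronization")
  expect_false(file.exists(paste0(out, ".vcf.gz")))
  expect_false(file.exists(paste0(out, "_retained.info.txt")))
})

test_that("missing info tables are derived from the VCF when asked", {
  co <- generate_cohort(6, 15, seed = 17)
  sp <- split_into_batches(co, k = 2, dir = tempfile("mkinfo"))
  unlink(sp$info)
  out <- file.path(tempfile("mi"), "m")
  dir.create(dirname(out), recursive = TRUE)
  expect_error(merge_batches(merge_config(sp$vcf, out = out)),
               "info table not found")
  s <- merge_batches(merge_config(sp$vcf, out = out, make_info = TRUE))
  expect_identical(s$n_retained, 15L)
  expect_true(all(file.exists(sp$info)))
})

test_that("same-position records merge regardless of tie order in the VCF", {
  # VCF carries pos 100 A>T before A>C; plan orders C before T
  rows <- c(vrow(100, "A", "T", c("0|1:1.000", "0|0:0.000")),
            vrow(100, "A", "C", c("0|0:0.000", "0|1:1.000")),
            vrow(200, "G", "A", c("1|1:2.000", "0|0:0.000")))
  vcf <- make_vcf(rows, path = tempfile(fileext = ".vcf.gz"))
  info <- make_info_gz(c(irow(100, "A", "T", 0.25, 0.25, 0.9),
                         irow(100, "A", "C", 0.25, 0.25, 0.8),
                         irow(200, "G", "A", 0.5, 0.5, 0.7)))
  out <- file.path(tempfile("tie"), "m")
  dir.create(dirname(out), recursive = TRUE)
  s <- merge_batches(merge_config(vcf, info, out = out))
  merged <- stream_vcf_records(s$outputs[["vcf"]])
  expect_identical(merged$alt, c("C", "T", "A"))
  expect_identical(merged$pos, c(100L, 100L, 200L))
})
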
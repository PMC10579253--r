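test_that("TSV and VCF writes round-trip a simulated cohort field for field", {
  pops <- tiny_pops()
  sim <- simulate_cohort(cohort_spec(populations = pops, n_variants = 25,
                                     seed = 11))
  for (dialect in c("tsv", "vcf")) {
    path <- tempfile(fileext = paste0(".", dialect))
    write_variant_table(sim$records, path, dialect, pops)
    back <- read_variant_table(path, dialect, pops)
    expect_equal(back, sim$records, info = dialect)
  }
})

test_that("an empty record set writes a readable header-only file", {
  pops <- tiny_pops()
  empty <- new_records(0L, pops)
  for (dialect in c("tsv", "vcf")) {
    path <- tempfile(fileext = paste0(".", dialect))
    write_variant_table(empty, path, dialect, pops)
    back <- read_variant_table(path, dialect, pops)
    expect_identical(nrow(back), 0L, info = dialect)
  }
})

test_that("fields map directly and HGVS identifiers are kept verbatim", {
  pops <- tiny_pops()
  rec <- missense_record(pops, hgvs_c = "c.6554 G > A",
                         hgvs_p = "p.Arg2185Gln")
  rec$rsid <- "rs2229446"
  rec$ac_a <- 2L
  rec$an_a <- 100L
  path <- tempfile(fileext = ".tsv")
  write_variant_table(rec, path, "tsv", pops)
  back <- read_variant_table(path, "tsv", pops)
  expect_identical(back$hgvs_c, "c.6554 G > A")
  expect_identical(back$hgvs_p, "p.Arg2185Gln")
  expect_identical(back$rsid, "rs2229446")
  expect_identical(back$consequence, "missense")
  expect_equal(variant_maf(back, "a", pops), 0.02)
})

test_that("reading rejects AC > AN and unknown population codes", {
  pops <- tiny_pops()
  rec <- missense_record(pops)
  rec$ac_a <- 5L
  rec$an_a <- 4L
  path <- tempfile(fileext = ".tsv")
  utils::write.table(rec, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  expect_error(read_variant_table(path, "tsv", pops), "AC must not exceed AN")

  rec2 <- missense_record(pops)
  rec2$ac_zz <- 1L
  path2 <- tempfile(fileext = ".tsv")
  utils::write.table(rec2, path2, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  expect_error(read_variant_table(path2, "tsv", pops), "zz.*known codes|known codes")
})

test_that("multi-allelic VCF sites split into biallelic records conserving AC", {
  pops <- tiny_pops()
  # capture a valid header from the writer, then append a 2-alt site
  hdr_file <- tempfile(fileext = ".vcf")
  write_variant_table(new_records(0L, pops), hdr_file, "vcf", pops)
  hdr <- readLines(hdr_file)
  ann1 <- "missense|.|c.100G>A|p.Gly34Asp|25|deleterious|deleterious|deleterious|deleterious|deleterious|deleterious|.|.|.|.|.|.|.|.|."
  ann2 <- "synonymous|.|c.100G>T|.|3|missing|missing|missing|missing|missing|missing|.|.|.|.|.|.|.|.|."
  body <- paste0("12\t100\trs1\tG\tA,T\t.\t.\t",
                 "AC_a=3,2;AN_a=200;nhomalt_a=1,0;",
                 "AC_b=4,0;AN_b=400;nhomalt_b=0,0;DPM=42;",
                 "ANN=", ann1, ",", ann2)
  path <- tempfile(fileext = ".vcf")
  writeLines(c(hdr, body), path)
  back <- read_variant_table(path, "vcf", pops)
  expect_identical(nrow(back), 2L)
  expect_identical(back$alt, c("A", "T"))
  expect_identical(back$ac_a, c(3L, 2L))          # per-allele AC conserved
  expect_identical(sum(back$ac_a), 5L)
  expect_identical(back$an_a, c(200L, 200L))      # site AN shared
  expect_identical(back$nhom_a, c(1L, 0L))
  expect_identical(back$consequence, c("missense", "synonymous"))
  expect_identical(back$hgvs_c, c("c.100G>A", "c.100G>T"))
})

test_that("VCF writer emits the documented per-population INFO keys", {
  pops <- tiny_pops()
  rec <- missense_record(pops, cadd = 25)
  rec$ac_a <- 3L
  rec$nhom_a <- 1L
  rec$mean_depth <- 42
  path <- tempfile(fileext = ".vcf")
  write_variant_table(rec, path, "vcf", pops)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 1L)
  expected <- paste0(
    "12\t6000001\t.\tG\tA\t.\t.\t",
    "AC_a=3;AN_a=200;nhomalt_a=1;AC_b=0;AN_b=400;nhomalt_b=0;DPM=42;",
    "ANN=missense|.|c.100G>A|p.Gly34Asp|25|deleterious|deleterious|",
    "deleterious|deleterious|deleterious|deleterious|.|.|.|.|.|.|.|.|.")
  expect_identical(body, expected)
  expect_true(any(grepl("##INFO=<ID=nhomalt_a", lines)))
})

test_that("validate_cohort flags low coverage and unknown populations without removing records", {
  pops <- tiny_pops()
  rec <- rbind(missense_record(pops), missense_record(pops))
  rec$pos <- c(6000001L, 6000002L)
  rep_ok <- validate_cohort(rec, pops, min_depth = 10)
  expect_identical(nrow(rep_ok$violations), 0L)
  expect_length(rep_ok$low_coverage, 0L)

  rec$mean_depth[2] <- 8
  rep2 <- validate_cohort(rec, pops, min_depth = 10)
  expect_identical(rep2$low_coverage, 2L)
  expect_identical(rep2$n_records, 2L)            # flagged, not removed
  expect_identical(nrow(rep2$violations), 0L)

  rec$ac_zz <- 1L
  rep3 <- validate_cohort(rec, pops)
  expect_true(any(grepl("absent from the cohort specification",
                        rep3$violations$message)))
})
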
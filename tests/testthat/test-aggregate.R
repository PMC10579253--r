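test_that("MAF is ac/an per population and undefined at AN = 0", {
  pops <- tiny_pops()
  rec <- missense_record(pops)
  rec$ac_a <- 2L
  expect_equal(variant_maf(rec, "a", pops), 2 / 200)   # an = 2 * 100 individuals
  expect_equal(variant_maf(rec, "b", pops), 0)
  expect_equal(variant_maf(rec, "all", pops), 2 / 600)
  expect_error(variant_maf(rec, "zz", pops), "unknown population")

  rec$an_b <- 0L
  expect_error(variant_maf(rec, "b", pops), "AN = 0")
})

test_that("affected-allele tallies are additive and partition exactly", {
  pops <- tiny_pops()
  rec <- rbind(missense_record(pops, hgvs_c = "c.1G>A"),
               missense_record(pops, hgvs_c = "c.2G>A"),
               missense_record(pops, hgvs_c = "c.3G>A", cadd = 2,
                               calls = rep("tolerated", 6)))
  rec$pos <- 6000001L + 0:2
  rec$ac_a <- c(3L, 4L, 9L)   # third variant is benign: must not count
  rec$ac_b <- c(1L, 0L, 9L)
  db <- kb_with("c.1G>A", "1", "dominant")
  cls <- classify_cohort(rec, db)
  tab <- affected_alleles(rec, cls, pops)

  a <- tab[tab$population == "a", ]
  expect_identical(a$total_affected, 7L)                 # 3 + 4, benign excluded
  expect_identical(a$affected_reported + a$affected_novel, a$total_affected)
  expect_identical(a$affected_reported, 3L)
  expect_equal(a$novel_fraction, 4 / 7)
  expect_identical(a$an_ref, 200L)

  all_row <- tab[tab$population == "all", ]
  expect_identical(all_row$total_affected,
                   sum(tab$total_affected[tab$population != "all"]))
  expect_identical(all_row$an_ref, 600L)

  none <- affected_alleles(new_records(0L, pops),
                           classify_cohort(new_records(0L, pops), empty_kb()),
                           pops)
  expect_true(all(none$total_affected == 0L))
  expect_true(all(none$novel_fraction == 0))
})

test_that("top variants sort by MAF descending with position tie-break", {
  pops <- tiny_pops()
  rec <- do.call(rbind, lapply(1:4, function(i) {
    missense_record(pops, hgvs_c = sprintf("c.%dG>A", i))
  }))
  rec$pos <- c(6000004L, 6000001L, 6000003L, 6000002L)
  rec$ac_a <- c(2L, 5L, 2L, 1L)
  cls <- classify_cohort(rec, empty_kb())
  top <- top_variants(rec, cls, "a", k = 3L, pops)
  expect_identical(top$hgvs_c, c("c.2G>A", "c.3G>A", "c.1G>A"))
  expect_equal(top$maf, c(5, 2, 2) / 200)
  # k larger than the pathogenic set returns everything
  expect_identical(nrow(top_variants(rec, cls, "a", k = 10L, pops)), 4L)
})

test_that("common-variant flags use a strict threshold and list triggers", {
  pops <- tiny_pops()
  rec <- rbind(missense_record(pops, hgvs_c = "c.1G>A"),
               missense_record(pops, hgvs_c = "c.2G>A"),
               missense_record(pops, hgvs_c = "c.3G>A"))
  rec$pos <- 6000001L + 0:2
  rec$ac_a <- c(2L, 4L, 6L)     # MAF 0.01, 0.02, 0.03 in pop a (an = 200)
  rec$ac_b <- c(0L, 0L, 8L)     # MAF 0.02 in pop b (an = 400)
  flags <- common_variant_flags(rec, pops, threshold = 0.01)
  expect_identical(flags$hgvs_c, c("c.2G>A", "c.3G>A"))  # 0.01 exactly: not flagged
  expect_identical(flags$triggering_populations, c("a", "a;b"))
  expect_equal(flags$maf_a, c(0.02, 0.03))
  expect_equal(flags$maf_all[2], 14 / 600)
  expect_identical(nrow(common_variant_flags(rec, pops, threshold = 0.5)), 0L)
})

test_that("the homozygote census sums planted counts per population", {
  pops <- tiny_pops()
  rec <- rbind(missense_record(pops, hgvs_c = "c.1G>A"),
               missense_record(pops, hgvs_c = "c.2G>A"))
  rec$pos <- c(6000001L, 6000002L)
  rec$ac_a <- c(6L, 0L); rec$nhom_a <- c(2L, 0L)
  rec$ac_b <- c(2L, 4L); rec$nhom_b <- c(1L, 2L)
  cls <- classify_cohort(rec, empty_kb())
  cen <- homozygote_census(rec, cls, pops)
  expect_identical(cen$total_hom_individuals[cen$population == "a"], 2L)
  expect_identical(cen$n_variants_with_hom[cen$population == "a"], 1L)
  expect_identical(cen$total_hom_individuals[cen$population == "b"], 3L)
  expect_identical(cen$n_variants_with_hom[cen$population == "all"], 2L)
  expect_identical(cen$total_hom_individuals[cen$population == "all"], 5L)
})

test_that("allele counts agree with brute-force per-individual dosage sums", {
  pops <- population_spec(c("x", "y"), c("X", "Y"), c(400L, 250L))
  sim <- simulate_cohort(cohort_spec(populations = pops, n_variants = 40,
                                     pathogenic_fraction = 0.5, seed = 99),
                         keep_genotypes = TRUE)
  for (p in pops$code) {
    g <- sim$truth$genotypes[[p]]                 # individuals x variants
    expect_identical(dim(g), c(pops$n_individuals[pops$code == p], 40L))
    expect_identical(sim$records[[paste0("ac_", p)]],
                     as.integer(colSums(g)))
    expect_identical(sim$records[[paste0("nhom_", p)]],
                     as.integer(colSums(g == 2L)))
    expect_true(all(sim$records[[paste0("an_", p)]] == 2L * nrow(g)))
  }
  # pooled counts are the sum of per-population brute-force counts
  cts <- vwdprev:::pop_counts(sim$records, pops, "all")
  expect_identical(cts$ac, as.integer(colSums(sim$truth$genotypes$x) +
                                        colSums(sim$truth$genotypes$y)))
})
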
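test_that("a splice tool calls deleterious on abolition or strict score halving", {
  expect_true(splice_tool_deleterious(10, 4.9, FALSE))
  expect_false(splice_tool_deleterious(10, 5.0, FALSE))  # not strictly < half
  expect_true(splice_tool_deleterious(0, 0, TRUE))       # abolition dominates
  expect_false(splice_tool_deleterious(0, 0, FALSE))     # wt 0 needs abolition
  expect_false(splice_tool_deleterious(10, NA, FALSE))   # missing fails closed
  expect_error(splice_tool_deleterious(-1, 2, FALSE), "non-negative")
})

splice_region_record <- function(wt = 10, var = 1, abolished = FALSE,
                                 cadd = 30, drop_tool = NULL) {
  rec <- new_records(1L)
  rec$consequence <- "splice_region"
  rec$intronic_offset <- 5L
  rec$hgvs_c <- "c.100+5G>A"
  rec$cadd_phred <- cadd
  for (tool in c("varseak", "esefinder", "bdgp")) {
    rec[[paste0(tool, "_wt")]] <- wt
    rec[[paste0(tool, "_var")]] <- var
    rec[[paste0(tool, "_abolished")]] <- abolished
  }
  if (!is.null(drop_tool)) {
    rec[[paste0(drop_tool, "_var")]] <- wt  # clearly not halved
  }
  rec
}

test_that("splice consensus requires all four tools including CADD >= 20", {
  expect_true(splice_consensus_deleterious(
    splice_region_record(abolished = TRUE, cadd = 25)))
  expect_false(splice_consensus_deleterious(splice_region_record(cadd = 19.9)))
  expect_false(splice_consensus_deleterious(
    splice_region_record(cadd = 30, drop_tool = "bdgp")))   # 2 of 3 tools
  expect_false(splice_consensus_deleterious(
    splice_region_record(wt = NA, var = NA, cadd = 30)))    # missing tools
  # the 3-tool variant drops the CADD requirement
  expect_true(splice_consensus_deleterious(splice_region_record(cadd = 5),
                                           require_cadd = FALSE))
})

test_that("missense consensus matches the exhaustive truth-table oracle", {
  calls <- c("deleterious", "tolerated", "missing")
  grid <- expand.grid(sift = calls, polyphen2 = calls, lrt = calls,
                      mutationtaster = calls, mutationassessor = calls,
                      fathmm = calls, cadd = c(19, 20, NA),
                      stringsAsFactors = FALSE)
  rec <- new_records(nrow(grid))
  rec$pos <- 6000000L + seq_len(nrow(grid))
  rec$hgvs_c <- sprintf("c.%dG>A", seq_len(nrow(grid)))
  rec$consequence <- "missense"
  rec$hgvs_p <- "p.Gly34Asp"
  for (tool in names(grid)[1:6]) rec[[tool]] <- grid[[tool]]
  rec$cadd_phred <- grid$cadd
  got <- missense_consensus_deleterious(rec)
  oracle <- apply(grid[, 1:6] == "deleterious", 1, all) &
    !is.na(grid$cadd) & grid$cadd >= 20
  expect_identical(got, unname(oracle))
  expect_identical(sum(got), sum(!is.na(grid$cadd) & grid$cadd >= 20 &
                                   rowSums(grid[, 1:6] == "deleterious") == 6))
})

test_that("upgrading predictor evidence never flips a deleterious verdict to benign", {
  sim <- simulate_cohort(cohort_spec(populations = tiny_pops(),
                                     n_variants = 120, seed = 21,
                                     concordance = 0.6, fp_rate = 0.3))
  before <- classify_cohort(sim$records, sim$db)$results$pathogenic
  up <- sim$records
  up$cadd_phred <- 45
  for (tool in c("sift", "polyphen2", "lrt", "mutationtaster",
                 "mutationassessor", "fathmm")) {
    up[[tool]][up$consequence == "missense"] <- "deleterious"
  }
  for (tool in c("varseak", "esefinder", "bdgp")) {
    sr <- up$consequence == "splice_region"
    up[[paste0(tool, "_abolished")]][sr] <- TRUE
    up[[paste0(tool, "_wt")]][sr] <- 10
    up[[paste0(tool, "_var")]][sr] <- 0
  }
  after <- classify_cohort(up, sim$db)$results$pathogenic
  expect_true(all(after[before]))   # monotone in evidence
})

test_that("the cascade fires in priority order and sets novel/reported status", {
  pops <- tiny_pops()
  db <- kb_with(c("c.10G>A", "c.20G>A"), c("1", "2N"),
                c("dominant", "recessive"))

  fs <- new_records(1L, pops)
  fs$consequence <- "frameshift"
  fs$hgvs_c <- "c.99del"
  r <- classify_variant(fs, db)
  expect_true(r$pathogenic)
  expect_identical(r$rule, "truncating")
  expect_identical(r$status, "novel")

  syn <- new_records(1L, pops)
  syn$consequence <- "synonymous"
  syn$hgvs_c <- "c.10G>A"
  r <- classify_variant(syn, db)
  expect_identical(r$rule, "known_db")    # only the db rule admits synonymous
  expect_identical(r$status, "reported")
  expect_identical(r$vwd_type, "1")

  mis <- missense_record(pops, cadd = 31)
  r <- classify_variant(mis, empty_kb())
  expect_identical(r$rule, "missense_consensus")
  expect_identical(r$status, "novel")

  # db membership dominates predictors: tolerated calls still pathogenic
  mis2 <- missense_record(pops, cadd = 2, calls = rep("tolerated", 6),
                          hgvs_c = "c.20G>A")
  r <- classify_variant(mis2, db)
  expect_true(r$pathogenic)
  expect_identical(r$rule, "known_db")
  expect_identical(r$vwd_type, "2N")

  core <- new_records(1L, pops)
  core$consequence <- "splice_core"
  core$intronic_offset <- 2L
  core$hgvs_c <- "c.30+2T>C"
  expect_identical(classify_variant(core, db)$rule, "splice_core")
})

test_that("stop-loss is admitted under the truncating rule and configurable off", {
  sl <- new_records(1L)
  sl$consequence <- "stop_lost"
  sl$hgvs_c <- "c.8440T>C"
  sl$hgvs_p <- "p.Ter2814Glnext"
  expect_identical(classify_variant(sl, empty_kb())$rule, "truncating")
  r <- classify_variant(sl, empty_kb(),
                        classification_options(include_stop_lost = FALSE))
  expect_false(r$pathogenic)
  expect_identical(r$status, "not_pathogenic")
})

test_that("cohort summaries conserve counts and respect the novel/reported partition", {
  sim <- simulate_cohort(cohort_spec(populations = tiny_pops(),
                                     n_variants = 150, seed = 4))
  cls <- classify_cohort(sim$records, sim$db)
  s <- cls$summary
  expect_identical(sum(s$by_rule), s$n_pathogenic)
  expect_identical(sum(s$by_consequence), s$n_pathogenic)
  expect_identical(sum(s$by_status), s$n_pathogenic)
  expect_identical(s$by_status[["reported"]] + s$by_status[["novel"]],
                   s$n_pathogenic)
  # every db-matched record is pathogenic regardless of predictors
  idx <- kb_lookup(sim$db, sim$records)
  expect_true(all(cls$results$pathogenic[!is.na(idx)]))

  empty <- classify_cohort(new_records(0L), empty_kb())
  expect_identical(empty$summary$n_pathogenic, 0L)
  expect_identical(sum(empty$summary$by_rule), 0L)
})
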
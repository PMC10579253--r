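test_that("collective q reproduces published count ratios and guards inputs", {
  expect_equal(collective_q(19693, 282912)$q, 0.06960822, tolerance = 1e-6)
  expect_equal(collective_q(2366, 24974)$q, 0.09473853, tolerance = 1e-6)
  expect_identical(collective_q(0, 1000)$q, 0)
  expect_error(collective_q(5, 0), "positive")
  expect_error(collective_q(11, 10), "ac_total")
  expect_error(collective_q(NA, NA), "positive")    # NA counts need explicit q
  expect_equal(collective_q(NA, NA, q = 0.25)$q, 0.25)
})

test_that("the three genotype-frequency formulas give the published numbers", {
  q_all <- 19693 / 282912
  expect_equal(round(recessive_prevalence(q_all) * 100, 2), 0.48)
  expect_equal(dominant_prevalence(q_all) * 100, 12.95, tolerance = 0.005)
  expect_equal(carrier_frequency(q_all), 0.1392, tolerance = 5e-4)
  q_amr <- 3673 / 35440
  expect_equal(dominant_prevalence(q_amr) * 100, 18.6, tolerance = 0.05)
  expect_equal(recessive_prevalence(q_amr) * 100, 1.07, tolerance = 0.005)
})

test_that("prevalence models behave at the q = 0 and q = 1 limits", {
  expect_identical(carrier_frequency(0), 0)
  expect_identical(dominant_prevalence(0), 0)
  expect_identical(recessive_prevalence(0), 0)
  expect_warning(cf1 <- carrier_frequency(1), "not a probability")
  expect_identical(cf1, 2)
  expect_identical(dominant_prevalence(1), 0)
  expect_identical(recessive_prevalence(1), 1)
  expect_error(recessive_prevalence(1.01), "\\[0, 1\\]")
  expect_error(dominant_prevalence(-0.1), "\\[0, 1\\]")
})

test_that("genotype frequencies satisfy the Hardy-Weinberg identity and ordering", {
  q <- seq(0, 1, by = 0.01)
  p2 <- (1 - q)^2
  het <- dominant_prevalence(q)
  hom <- recessive_prevalence(q)
  expect_true(all(abs(p2 + het + hom - 1) <= 1e-12))
  low <- q[q <= 0.5 & q > 0]
  expect_true(all(recessive_prevalence(low) <= dominant_prevalence(low)))
  expect_true(all(dominant_prevalence(low) <=
                    suppressWarnings(carrier_frequency(low))))
  # 2pq is maximal at q = 1/2
  expect_equal(q[which.max(het)], 0.5)
})

test_that("compound and pooled recessive models reduce and validate correctly", {
  expect_equal(compound_recessive_prevalence(0.01, 0.02), 5e-4)
  expect_equal(compound_recessive_prevalence(0.01, 0),
               recessive_prevalence(0.01))
  expect_error(compound_recessive_prevalence(0.6, 0.5), "not exceed 1")
  expect_error(compound_recessive_prevalence(-0.01, 0.5), "\\[0, 1\\]")

  expect_equal(pooled_recessive_prevalence(c(0.01, 0.015)), 0.025^2)
  expect_equal(pooled_recessive_prevalence(0.02), recessive_prevalence(0.02))
  expect_identical(pooled_recessive_prevalence(numeric(0)), 0)
  expect_error(pooled_recessive_prevalence(c(0.6, 0.5)), "not exceed 1")
})

typed_cohort <- function(pops = tiny_pops()) {
  # four reported variants with known types plus one novel pathogenic
  rec <- do.call(rbind, lapply(1:5, function(i) {
    missense_record(pops, hgvs_c = sprintf("c.%d0G>A", i),
                    hgvs_p = sprintf("p.Gly%dAsp", i + 30))
  }))
  rec$pos <- 6000001L + 0:4
  rec$ac_a <- c(1L, 2L, 3L, 4L, 5L)   # an_a = 200: MAFs 0.005 .. 0.025
  db <- kb_with(sprintf("c.%d0G>A", 1:4),
                c("1", "1", "2N", "3"),
                c("dominant", "dominant", "recessive", "recessive"))
  list(records = rec, cls = classify_cohort(rec, db), pops = pops)
}

test_that("type-specific q sums per-variant MAFs with exclusions and cutoffs", {
  x <- typed_cohort()
  q1 <- type_specific_q(x$records, x$cls, "a", "1", populations = x$pops)
  expect_equal(q1$q, (1 + 2) / 200)   # additive over the type-1 variants
  q13 <- type_specific_q(x$records, x$cls, "a", c("1", "3"),
                         populations = x$pops)
  expect_equal(q13$q, (1 + 2 + 4) / 200)

  # named exclusion drops one variant and is recorded in the audit
  qx <- type_specific_q(x$records, x$cls, "a", "1",
                        exclusions = "p.Gly31Asp", populations = x$pops)
  expect_equal(qx$q, 2 / 200)
  expect_identical(qx$exclusions, "c.10G>A")

  # MAF cutoff is strict: 0.02 keeps the variant at exactly 0.02
  qc <- type_specific_q(x$records, x$cls, "a", c("1", "3"),
                        maf_cutoff = 0.02, populations = x$pops)
  expect_equal(qc$q, (1 + 2 + 4) / 200)
  qc2 <- type_specific_q(x$records, x$cls, "a", c("1", "3"),
                         maf_cutoff = 0.015, populations = x$pops)
  expect_equal(qc2$q, (1 + 2) / 200)
  expect_identical(qc2$exclusions, "c.40G>A")

  # novel pathogenic variants never enter a type-specific set
  q_any <- type_specific_q(x$records, x$cls, "a", NULL,
                           reported_only = FALSE, populations = x$pops)
  expect_equal(q_any$q, (1 + 2 + 3 + 4 + 5) / 200)
  expect_error(type_specific_q(x$records, x$cls, "a", character(0)),
               "non-empty")
})

test_that("adding exclusions never increases a type-specific q", {
  x <- typed_cohort()
  excl_sets <- list(character(0), "p.Gly31Asp",
                    c("p.Gly31Asp", "c.20G>A"),
                    c("p.Gly31Asp", "c.20G>A", "p.Gly33Asp"))
  qs <- vapply(excl_sets, function(e) {
    type_specific_q(x$records, x$cls, "a", NULL, reported_only = FALSE,
                    exclusions = e, populations = x$pops)$q
  }, numeric(1))
  expect_true(all(diff(qs) <= 0))
})

test_that("the prevalence report matches a closed-form oracle on planted MAFs", {
  x <- typed_cohort()
  # planted MAFs reach 0.025: lift the recessive cutoff so the oracle is exact
  cfg <- prevalence_config(exclusions_carrier = character(0),
                           exclusions_types = character(0),
                           maf_cutoff_recessive = 0.5,
                           scale_types = "per1000")
  prev <- prevalence_report(x$records, x$cls, x$pops, cfg)

  ca <- prev$carrier[prev$carrier$population == "a", ]
  q_all <- 15 / 200; q_rep <- 10 / 200
  expect_equal(ca$q_all, q_all)
  expect_equal(ca$carrier_2q, 2 * q_all)
  expect_equal(ca$recessive_all, q_all^2 * 100)
  expect_equal(ca$dominant_all, 2 * q_all * (1 - q_all) * 100)
  expect_equal(ca$q_rep, q_rep)
  expect_equal(ca$dominant_rep, 2 * q_rep * (1 - q_rep) * 100)

  ta <- prev$types[prev$types$population == "a", ]
  q1 <- 3 / 200; q2n <- 3 / 200; q3 <- 4 / 200
  expect_equal(ta$dominant_1, 2 * q1 * (1 - q1) * 1000)
  expect_equal(ta$dominant_2A, 0)
  expect_equal(ta$recessive_2N, (q2n^2 + 2 * q2n * (q1 + q3)) * 1000)
  expect_equal(ta$recessive_3, (q1 + q3)^2 * 1000)     # pooled model

  cmp <- prevalence_report(x$records, x$cls, x$pops,
    prevalence_config(exclusions_carrier = character(0),
                      exclusions_types = character(0),
                      maf_cutoff_recessive = 0.5,
                      type3_model = "compound"))
  ta2 <- cmp$types[cmp$types$population == "a", ]
  expect_equal(ta2$recessive_3, (q3^2 + 2 * q3 * q1) * 1000)
})

test_that("the report audit records exactly the excluded variants", {
  x <- typed_cohort()
  prev <- prevalence_report(x$records, x$cls, x$pops,
    prevalence_config(exclusions_carrier = "p.Gly31Asp",
                      exclusions_types = "p.Gly31Asp"))
  ca <- prev$carrier[prev$carrier$population == "a", ]
  expect_equal(ca$ac_all, 15L - 1L)
  expect_identical(prev$audit[["carrier.a.all_variants"]]$exclusions,
                   "c.10G>A")
  expect_identical(prev$audit[["type.a.1"]]$exclusions, "c.10G>A")
  # unexcluded report differs from the excluded one by exactly that allele count
  base <- prevalence_report(x$records, x$cls, x$pops,
    prevalence_config(exclusions_carrier = character(0),
                      exclusions_types = character(0)))
  ba <- base$carrier[base$carrier$population == "a", ]
  expect_equal(ba$ac_all - ca$ac_all, 1L)
  expect_identical(base$audit[["carrier.a.all_variants"]]$exclusions,
                   character(0))
})
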
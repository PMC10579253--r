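## Seeded synthetic-cohort generator. Emulates a gnomAD-like aggregation:
## per-population genotype tallies drawn under Hardy-Weinberg equilibrium
## at known true allele frequencies, predictor profiles drawn under a
## configurable concordance model, and a knowledge-base fixture holding the
## reported subset -- so every pipeline stage can be tested against ground
## truth without external downloads.

AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")

default_pathogenic_mix <- function() {
  ## mutation-class mix of the 505 deleterious variants: 355 missense,
  ## 53 frameshift, 40 stop-gained, 1 stop-loss, 41 splice (modelled as
  ## 28 core + 13 region), 14 inframe indels, 1 synonymous
  c(missense = 355, frameshift = 53, stop_gained = 40, stop_lost = 1,
    splice_core = 28, splice_region = 13, inframe_indel = 14,
    synonymous = 1) / 505
}

default_vwd_type_mix <- function() {
  ## VWD-type mix of the 218 reported variants
  c("1" = 78, "2A" = 23, "2B" = 12, "2M" = 21, "2N" = 15, "3" = 54,
    "UC" = 15) / 218
}

#' Specification of a synthetic cohort
#'
#' Defaults reproduce the study conditions of the reference cohort: the
#' gnomAD v2.1 population sizes, 4313 VWF variants of which 505 are truly
#' pathogenic, 218 of those reported in the knowledge base, the observed
#' mutation-class and VWD-type mixes, roughly half of the pathogenic
#' variants singletons, and a per-tool predictor concordance of `0.3^(1/7)`
#' (so a truly pathogenic missense variant passes all seven tools with
#' probability ~0.30).
#'
#' @param populations Population specification (default
#'   [gnomad_populations()]).
#' @param n_variants Total number of variants.
#' @param pathogenic_fraction Fraction of variants that are truly
#'   pathogenic.
#' @param consequence_mix Named probabilities over consequence classes for
#'   pathogenic variants.
#' @param benign_consequence_mix Same for benign variants.
#' @param reported_fraction Fraction of pathogenic variants present in the
#'   knowledge base.
#' @param vwd_type_mix Named probabilities over VWD types for reported
#'   variants.
#' @param singleton_fraction Fraction of variants whose true frequency
#'   corresponds to a single allele in the whole cohort.
#' @param q_log10_range Range of `log10(q)` for the non-singleton rare
#'   tail.
#' @param point_masses Optional numeric vector of true allele frequencies
#'   planted on the first pathogenic variants (recurrent variants).
#' @param concordance Per-tool probability that a truly pathogenic variant
#'   receives a deleterious call.
#' @param fp_rate Per-tool probability that a benign variant receives a
#'   deleterious call.
#' @param seed Integer RNG seed; a fixed seed gives bit-identical output.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(populations = gnomad_populations(),
                        n_variants = 4313L,
                        pathogenic_fraction = 505 / 4313,
                        consequence_mix = default_pathogenic_mix(),
                        benign_consequence_mix = c(missense = 0.5,
                                                   synonymous = 0.35,
                                                   splice_region = 0.1,
                                                   other = 0.05),
                        reported_fraction = 218 / 505,
                        vwd_type_mix = default_vwd_type_mix(),
                        singleton_fraction = 0.48,
                        q_log10_range = c(-5, -2.5),
                        point_masses = NULL,
                        concordance = 0.3^(1 / 7),
                        fp_rate = 0.1,
                        seed = 1L) {
  for (f in c(pathogenic_fraction, reported_fraction, singleton_fraction,
              concordance, fp_rate)) {
    if (is.na(f) || f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  for (mix in list(consequence_mix, benign_consequence_mix, vwd_type_mix)) {
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
      stop("distributions must be non-negative and sum to 1")
    }
  }
  if (!all(names(consequence_mix) %in% CONSEQUENCE_CLASSES) ||
      !all(names(benign_consequence_mix) %in% CONSEQUENCE_CLASSES)) {
    stop("consequence mixes must be named by consequence class")
  }
  if (!all(names(vwd_type_mix) %in% VWD_TYPES)) {
    stop("vwd_type_mix must be named by VWD type")
  }
  if (!is.null(point_masses)) check_q(point_masses, "point_masses")
  structure(list(
    populations = populations, n_variants = as.integer(n_variants),
    pathogenic_fraction = pathogenic_fraction,
    consequence_mix = consequence_mix,
    benign_consequence_mix = benign_consequence_mix,
    reported_fraction = reported_fraction, vwd_type_mix = vwd_type_mix,
    singleton_fraction = singleton_fraction,
    q_log10_range = q_log10_range, point_masses = point_masses,
    concordance = concordance, fp_rate = fp_rate, seed = as.integer(seed)
  ), class = "cohort_spec")
}

blank_records <- function(n, populations, an = NULL) {
  df <- data.frame(
    chrom = rep("12", n), pos = 6000000L + seq_len(n),
    ref = rep("G", n), alt = rep("A", n),
    hgvs_c = sprintf("c.%d G > A", seq_len(n)),
    hgvs_p = rep(NA_character_, n), rsid = rep(NA_character_, n),
    consequence = rep("synonymous", n),
    intronic_offset = rep(NA_integer_, n), mean_depth = rep(50, n),
    cadd_phred = rep(NA_real_, n), stringsAsFactors = FALSE
  )
  for (tool in MISSENSE_TOOLS) df[[tool]] <- rep("missing", n)
  for (tool in SPLICE_TOOLS) {
    df[[paste0(tool, "_wt")]] <- rep(NA_real_, n)
    df[[paste0(tool, "_var")]] <- rep(NA_real_, n)
    df[[paste0(tool, "_abolished")]] <- rep(NA, n)
  }
  for (i in seq_len(nrow(populations))) {
    p <- populations$code[i]
    df[[paste0("ac_", p)]] <- rep(0L, n)
    df[[paste0("an_", p)]] <- rep(
      if (is.null(an)) populations$an_ref[i] else as.integer(an), n)
    df[[paste0("nhom_", p)]] <- rep(0L, n)
  }
  df[, c(annotation_columns(), count_columns(populations)), drop = FALSE]
}

hgvs_c_for <- function(consequence, ref, alt, cpos) {
  switch(consequence,
    splice_core = sprintf("c.%d+%d%s>%s", cpos, sample(1:2, 1), ref, alt),
    splice_region = sprintf("c.%d+%d%s>%s", cpos, sample(3:8, 1), ref, alt),
    frameshift = sprintf("c.%ddel", cpos),
    inframe_indel = sprintf("c.%d_%ddel", cpos, cpos + 2L),
    sprintf("c.%d%s>%s", cpos, ref, alt)
  )
}

hgvs_p_for <- function(consequence, aa_pos, aa_from, aa_to) {
  switch(consequence,
    missense = sprintf("p.%s%d%s", aa_from, aa_pos, aa_to),
    stop_gained = sprintf("p.%s%dTer", aa_from, aa_pos),
    stop_lost = sprintf("p.Ter%d%sext", aa_pos, aa_to),
    inframe_indel = sprintf("p.%s%ddel", aa_from, aa_pos),
    frameshift = sprintf("p.%s%dfs", aa_from, aa_pos),
    NA_character_
  )
}

#' Simulate a gnomAD-like cohort with known ground truth
#'
#' For every variant and population, genotypes are drawn under
#' Hardy-Weinberg equilibrium at the variant's true allele frequency
#' (dosage 2 with probability `q^2`, 1 with `2q(1-q)`, 0 with `(1-q)^2`)
#' and tallied into `ac`/`an`/`nhom` with `an = 2 * n_individuals`.
#' Predictor calls are drawn under the concordance model; reported
#' pathogenic variants are inserted into a knowledge-base fixture with
#' their true VWD type. Output is deterministic under a fixed seed.
#'
#' Pathogenic synonymous variants are always placed in the reported set
#' (database membership is the only cascade rule that can admit them).
#'
#' @param spec A [cohort_spec()].
#' @param keep_genotypes Materialize per-individual dosage vectors (one
#'   draw per individual; returned in `truth$genotypes` as a list of
#'   population -> individuals x variants integer matrix). When `FALSE`
#'   (default) tallies are drawn as one multinomial draw per
#'   variant-population, which has the identical joint distribution of
#'   counts. Use `TRUE` only for small cohorts.
#' @return List with `records` (variant `data.frame`), `db` (a `vwd_kb`
#'   fixture), `truth` (list: `variants` data.frame with `true_q`,
#'   `pathogenic`, `consequence`, `reported`, `vwd_type`; `genotypes` when
#'   materialized), `populations`, and the `spec`.
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_variants = 20, seed = 7))
#' head(sim$truth$variants)
#' @export
simulate_cohort <- function(spec, keep_genotypes = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  pops <- spec$populations
  n <- spec$n_variants
  n_path <- round(n * spec$pathogenic_fraction)
  pathogenic <- c(rep(TRUE, n_path), rep(FALSE, n - n_path))

  consequence <- character(n)
  if (n_path > 0) {
    consequence[pathogenic] <- sample(names(spec$consequence_mix), n_path,
                                      replace = TRUE,
                                      prob = spec$consequence_mix)
  }
  if (n - n_path > 0) {
    consequence[!pathogenic] <- sample(names(spec$benign_consequence_mix),
                                       n - n_path, replace = TRUE,
                                       prob = spec$benign_consequence_mix)
  }

  ## true allele frequencies: optional planted point masses on the first
  ## pathogenic variants, then a singleton/rare-tail draw
  an_total <- sum(pops$an_ref)
  singleton <- stats::runif(n) < spec$singleton_fraction
  true_q <- ifelse(singleton, 1 / an_total,
                   10^stats::runif(n, spec$q_log10_range[1],
                                   spec$q_log10_range[2]))
  if (!is.null(spec$point_masses)) {
    k <- min(length(spec$point_masses), n_path)
    true_q[seq_len(k)] <- spec$point_masses[seq_len(k)]
  }

  ## reported subset: all pathogenic synonymous variants, then random fill
  n_rep <- round(n_path * spec$reported_fraction)
  reported <- rep(FALSE, n)
  must <- which(pathogenic & consequence == "synonymous")
  reported[must] <- TRUE
  pool <- setdiff(which(pathogenic), must)
  extra <- max(0L, n_rep - length(must))
  if (extra > 0 && length(pool)) {
    reported[sample(pool, min(extra, length(pool)))] <- TRUE
  }
  vwd_type <- rep(NA_character_, n)
  n_rep_actual <- sum(reported)
  if (n_rep_actual > 0) {
    vwd_type[reported] <- sample(names(spec$vwd_type_mix), n_rep_actual,
                                 replace = TRUE, prob = spec$vwd_type_mix)
  }

  records <- blank_records(n, pops)
  records$consequence <- consequence
  records$intronic_offset <- ifelse(
    consequence == "splice_core", sample(c(-2L, -1L, 1L, 2L), n, TRUE),
    ifelse(consequence == "splice_region",
           sample(c(-8L:-3L, 3L:8L), n, TRUE), NA_integer_))
  refs <- sample(c("A", "C", "G", "T"), n, TRUE)
  alts <- vapply(refs, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1L)
  }, character(1))
  records$ref <- refs
  records$alt <- unname(alts)
  aa_pos <- sample.int(VWF_LENGTH - 22L, n, replace = TRUE) + 22L
  aa_from <- sample(AA3, n, TRUE)
  aa_to <- sample(AA3, n, TRUE)
  for (i in seq_len(n)) {
    records$hgvs_c[i] <- hgvs_c_for(consequence[i], refs[i], alts[i],
                                    cpos = i * 3L)
    records$hgvs_p[i] <- hgvs_p_for(consequence[i], aa_pos[i], aa_from[i],
                                    aa_to[i])
  }
  records$rsid <- ifelse(reported, sprintf("rs%d", 100000L + seq_len(n)),
                         NA_character_)
  records$mean_depth <- round(stats::runif(n, 30, 80), 1)

  ## predictor profiles under the concordance model
  p_hit <- ifelse(pathogenic, spec$concordance, spec$fp_rate)
  cadd_pass <- stats::runif(n) < p_hit
  records$cadd_phred <- round(ifelse(cadd_pass, stats::runif(n, 20, 45),
                                     stats::runif(n, 0, 19.9)), 2)
  is_mis <- consequence == "missense"
  for (tool in MISSENSE_TOOLS) {
    call <- ifelse(stats::runif(n) < p_hit, "deleterious", "tolerated")
    records[[tool]] <- ifelse(is_mis, call, "missing")
  }
  is_spl <- consequence == "splice_region"
  for (tool in SPLICE_TOOLS) {
    pass <- stats::runif(n) < p_hit
    wt <- round(stats::runif(n, 5, 15), 2)
    records[[paste0(tool, "_wt")]] <- ifelse(is_spl, wt, NA_real_)
    records[[paste0(tool, "_var")]] <- ifelse(
      is_spl, round(ifelse(pass, wt * stats::runif(n, 0, 0.49),
                           wt * stats::runif(n, 0.6, 1)), 3), NA_real_)
    records[[paste0(tool, "_abolished")]] <-
      ifelse(is_spl, pass & stats::runif(n) < 0.5, NA)
  }

  ## HWE genotype sampling
  genotypes <- if (keep_genotypes) list() else NULL
  for (j in seq_len(nrow(pops))) {
    p <- pops$code[j]
    N <- pops$n_individuals[j]
    probs <- rbind((1 - true_q)^2, 2 * true_q * (1 - true_q), true_q^2)
    if (keep_genotypes) {
      g <- matrix(0L, nrow = N, ncol = n)
      for (i in seq_len(n)) {
        g[, i] <- sample(0:2, N, replace = TRUE, prob = probs[, i])
      }
      genotypes[[p]] <- g
      nhet <- colSums(g == 1L)
      nhom <- colSums(g == 2L)
    } else {
      tall <- vapply(seq_len(n), function(i) {
        stats::rmultinom(1, N, probs[, i])[, 1]
      }, integer(3))
      nhet <- tall[2, ]
      nhom <- tall[3, ]
    }
    records[[paste0("ac_", p)]] <- as.integer(nhet + 2L * nhom)
    records[[paste0("an_", p)]] <- rep(2L * N, n)
    records[[paste0("nhom_", p)]] <- as.integer(nhom)
  }

  rep_idx <- which(reported)
  entries <- if (length(rep_idx)) {
    data.frame(
      match_key = norm_hgvs(records$hgvs_c[rep_idx]),
      hgvs_c = records$hgvs_c[rep_idx],
      chrom = records$chrom[rep_idx], pos = records$pos[rep_idx],
      ref = records$ref[rep_idx], alt = records$alt[rep_idx],
      vwd_type = vwd_type[rep_idx],
      inheritance = ifelse(vwd_type[rep_idx] %in% c("2N", "3"), "recessive",
                           ifelse(vwd_type[rep_idx] == "UC", "unknown",
                                  "dominant")),
      sources = "HGMD;LOVD", clear_association = TRUE,
      literature_override = NA_character_, stringsAsFactors = FALSE)
  } else empty_kb_entries()
  db <- known_variant_db(entries, provenance = list(origin = "simulated"))

  truth <- list(
    variants = data.frame(hgvs_c = records$hgvs_c, true_q = true_q,
                          pathogenic = pathogenic,
                          consequence = consequence, reported = reported,
                          vwd_type = vwd_type, stringsAsFactors = FALSE),
    genotypes = genotypes
  )
  list(records = records, db = db, truth = truth, populations = pops,
       spec = spec)
}
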
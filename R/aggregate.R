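## Aggregation of classified variants into per-population affected-allele
## tallies, recurrent-variant rankings, common-variant flags and a
## homozygote census. The special population code "all" pools counts over
## every population in the specification.

pop_counts <- function(records, populations, population) {
  if (identical(population, "all")) {
    ac <- Reduce(`+`, lapply(populations$code,
                             function(p) records[[paste0("ac_", p)]]))
    an <- Reduce(`+`, lapply(populations$code,
                             function(p) records[[paste0("an_", p)]]))
    nhom <- Reduce(`+`, lapply(populations$code,
                               function(p) records[[paste0("nhom_", p)]]))
  } else {
    if (!population %in% populations$code) {
      stop("unknown population '", population, "'; known codes: ",
           paste(c(populations$code, "all"), collapse = ", "))
    }
    ac <- records[[paste0("ac_", population)]]
    an <- records[[paste0("an_", population)]]
    nhom <- records[[paste0("nhom_", population)]]
  }
  if (!nrow(records)) {
    ac <- integer(0); an <- integer(0); nhom <- integer(0)
  }
  list(ac = ac, an = an, nhom = nhom)
}

#' Per-population minor allele frequency of variants
#'
#' MAF is the variant's alternate allele count divided by its own genotyped
#' allele number in that population (`ac/an`). Population `"all"` pools
#' counts over all populations.
#'
#' @param records Variant `data.frame`.
#' @param population Population code, or `"all"`.
#' @param populations Population specification.
#' @return Numeric vector of frequencies in `[0,1]`.
#' @export
variant_maf <- function(records, population,
                        populations = gnomad_populations()) {
  cts <- pop_counts(records, populations, population)
  if (any(cts$an == 0)) {
    stop(sprintf("MAF undefined: AN = 0 for %d record(s) in population '%s'",
                 sum(cts$an == 0), population))
  }
  cts$ac / cts$an
}

#' Affected-allele table by population
#'
#' For each population (and a pooled "all" row), sums the alternate allele
#' counts of pathogenic variants, split into alleles affected by reported
#' versus novel variants. The denominator column `an_ref` is the fixed
#' reference allele number `2 * n_individuals`. "Affected alleles" counts
#' alleles, not individuals: a compound heterozygote contributes twice.
#'
#' @param records Variant `data.frame`.
#' @param classification A `vwd_classification` for `records`.
#' @param populations Population specification.
#' @return `data.frame` with columns `population`, `an_ref`,
#'   `total_affected`, `affected_reported`, `affected_novel`,
#'   `novel_fraction` (0 when there are no affected alleles); the pooled
#'   row has population `"all"`.
#' @export
affected_alleles <- function(records, classification,
                             populations = gnomad_populations()) {
  res <- classification$results
  stopifnot(nrow(res) == nrow(records))
  path <- records[res$pathogenic, , drop = FALSE]
  status <- res$status[res$pathogenic]
  one_pop <- function(p, an_ref) {
    cts <- pop_counts(path, populations, p)
    tot <- sum(cts$ac)
    rep_ac <- sum(cts$ac[status == "reported"])
    nov_ac <- sum(cts$ac[status == "novel"])
    data.frame(population = p, an_ref = an_ref, total_affected = tot,
               affected_reported = rep_ac, affected_novel = nov_ac,
               novel_fraction = if (tot > 0) nov_ac / tot else 0,
               stringsAsFactors = FALSE)
  }
  rows <- c(list(one_pop("all", sum(populations$an_ref))),
            lapply(seq_len(nrow(populations)), function(i) {
              one_pop(populations$code[i], populations$an_ref[i])
            }))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Most frequent pathogenic variants in a population
#'
#' Returns the `k` pathogenic variants with highest MAF in the population,
#' sorted by MAF descending; ties are broken by genomic position
#' ascending. Fewer than `k` rows are returned when the cohort has fewer
#' pathogenic variants.
#'
#' @param records Variant `data.frame`.
#' @param classification A `vwd_classification` for `records`.
#' @param population Population code (or `"all"`).
#' @param k Number of variants to return (default 5).
#' @param populations Population specification.
#' @return `data.frame` with columns `population`, `hgvs_c`, `hgvs_p`,
#'   `rsid`, `consequence`, `maf`, `vwd_type` (NA for novel variants).
#' @export
top_variants <- function(records, classification, population, k = 5L,
                         populations = gnomad_populations()) {
  stopifnot(k >= 1L)
  res <- classification$results
  keep <- res$pathogenic
  path <- records[keep, , drop = FALSE]
  if (!nrow(path)) {
    return(data.frame(population = character(0), hgvs_c = character(0),
                      hgvs_p = character(0), rsid = character(0),
                      consequence = character(0), maf = numeric(0),
                      vwd_type = character(0), stringsAsFactors = FALSE))
  }
  maf <- variant_maf(path, population, populations)
  ord <- order(-maf, path$pos)
  sel <- ord[seq_len(min(k, length(ord)))]
  data.frame(population = population, hgvs_c = path$hgvs_c[sel],
             hgvs_p = path$hgvs_p[sel], rsid = path$rsid[sel],
             consequence = path$consequence[sel], maf = maf[sel],
             vwd_type = res$vwd_type[keep][sel], stringsAsFactors = FALSE)
}

#' Variants exceeding a MAF threshold in at least one population
#'
#' Flags variants whose MAF is strictly greater than `threshold` in one or
#' more populations, listing the triggering populations per variant.
#'
#' @param records Variant `data.frame`.
#' @param populations Population specification.
#' @param threshold MAF threshold in (0,1); default 0.01. Strict
#'   inequality: a MAF exactly at the threshold does not flag.
#' @return `data.frame` with `hgvs_c`, `hgvs_p`, `consequence`, one
#'   `maf_<pop>` column per population, a pooled `maf_all` column and
#'   `triggering_populations` (semicolon-separated codes).
#' @export
common_variant_flags <- function(records,
                                 populations = gnomad_populations(),
                                 threshold = 0.01) {
  stopifnot(threshold > 0, threshold < 1)
  mafs <- vapply(populations$code, function(p) {
    variant_maf(records, p, populations)
  }, numeric(nrow(records)))
  mafs <- matrix(mafs, nrow = nrow(records),
                 dimnames = list(NULL, populations$code))
  hits <- mafs > threshold
  flagged <- which(rowSums(hits) > 0)
  out <- data.frame(
    hgvs_c = records$hgvs_c[flagged], hgvs_p = records$hgvs_p[flagged],
    consequence = records$consequence[flagged], stringsAsFactors = FALSE)
  out$maf_all <- if (length(flagged)) {
    variant_maf(records, "all", populations)[flagged]
  } else numeric(0)
  for (p in populations$code) {
    out[[paste0("maf_", p)]] <- mafs[flagged, p]
  }
  out$triggering_populations <- vapply(flagged, function(i) {
    paste(populations$code[hits[i, ]], collapse = ";")
  }, character(1))
  out
}

#' Homozygote census over pathogenic variants
#'
#' Counts, per population and overall, the number of distinct pathogenic
#' variants observed in the homozygous state and the total number of
#' homozygous individuals.
#'
#' @param records Variant `data.frame`.
#' @param classification A `vwd_classification` for `records`.
#' @param populations Population specification.
#' @return `data.frame` with columns `population`,
#'   `n_variants_with_hom`, `total_hom_individuals`; the `"all"` row counts
#'   distinct variants homozygous in at least one population and sums
#'   individuals over populations.
#' @export
homozygote_census <- function(records, classification,
                              populations = gnomad_populations()) {
  path <- records[classification$results$pathogenic, , drop = FALSE]
  per_pop <- lapply(populations$code, function(p) {
    nh <- pop_counts(path, populations, p)$nhom
    data.frame(population = p, n_variants_with_hom = sum(nh > 0),
               total_hom_individuals = sum(nh), stringsAsFactors = FALSE)
  })
  nh_all <- pop_counts(path, populations, "all")$nhom
  all_row <- data.frame(population = "all",
                        n_variants_with_hom = sum(nh_all > 0),
                        total_hom_individuals = sum(nh_all),
                        stringsAsFactors = FALSE)
  out <- rbind(all_row, do.call(rbind, per_pop))
  rownames(out) <- NULL
  out
}
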
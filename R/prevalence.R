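## Hardy-Weinberg prevalence models. With q the collective frequency of
## pathogenic alleles in a population and p = 1 - q, genotype frequencies
## are p^2 (wild type), 2pq (heterozygote) and q^2 (homozygote/compound),
## giving:
##   carrier frequency   ~ 2q   (allele-counting approximation)
##   dominant prevalence   2pq = 2q(1-q)
##   recessive prevalence  q^2
##   compound recessive    q^2 + 2*q*q_null  (e.g. 2N/2N plus 2N/null)

check_q <- function(q, name = "q") {
  if (any(is.na(q)) || any(q < 0) || any(q > 1)) {
    stop(name, " must lie in [0, 1]")
  }
  invisible(q)
}

#' Collective frequency of affected alleles
#'
#' @param ac_total Summed alternate allele count over the variant set.
#' @param an_total Denominator allele number (> 0).
#' @param population Optional population code for the audit record.
#' @param variant_set_id Optional label of the variant set.
#' @param exclusions Character vector of variants removed before counting.
#' @param maf_cutoff_applied Optional MAF cutoff that was applied.
#' @param q Optional precomputed frequency (used when the numerator is a
#'   sum of per-variant MAFs rather than a single AC/AN ratio, in which
#'   case `ac_total`/`an_total` may be `NA`).
#' @return A list of class `collective_q` with fields `q`, `numerator_ac`,
#'   `denominator_an`, `population`, `variant_set_id`, `exclusions`,
#'   `maf_cutoff_applied`.
#' @examples
#' collective_q(19693, 282912)$q  # ~ 0.0696
#' @export
collective_q <- function(ac_total, an_total, population = NA_character_,
                         variant_set_id = NA_character_,
                         exclusions = character(0),
                         maf_cutoff_applied = NULL, q = NULL) {
  if (is.null(q)) {
    if (length(an_total) != 1L || is.na(an_total) || an_total <= 0) {
      stop("an_total must be a single positive count")
    }
    if (is.na(ac_total) || ac_total < 0 || ac_total > an_total) {
      stop("ac_total must satisfy 0 <= ac_total <= an_total")
    }
    q <- ac_total / an_total
  }
  check_q(q)
  structure(list(q = q,
                 numerator_ac = ac_total, denominator_an = an_total,
                 population = population, variant_set_id = variant_set_id,
                 exclusions = exclusions,
                 maf_cutoff_applied = maf_cutoff_applied),
            class = "collective_q")
}

#' @export
print.collective_q <- function(x, ...) {
  cat(sprintf("Collective allele frequency q = %.6g", x$q))
  if (!is.na(x$numerator_ac)) {
    cat(sprintf(" (%s / %s)", format(x$numerator_ac, big.mark = ","),
                format(x$denominator_an, big.mark = ",")))
  }
  if (!is.na(x$population)) cat(" [", x$population, "]", sep = "")
  cat("\n")
  if (length(x$exclusions)) {
    cat("  excluded:", paste(x$exclusions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Hardy-Weinberg prevalence models
#'
#' `carrier_frequency(q)` returns `2q`, the allele-counting approximation to
#' the fraction of carrier individuals (a warning flags `2q > 1`, where the
#' approximation stops being a probability). `dominant_prevalence(q)`
#' returns the heterozygote genotype frequency `2q(1-q)`;
#' `recessive_prevalence(q)` returns `q^2`. All are dimensionless
#' frequencies; scaling to per-100 or per-1000 is presentation.
#'
#' @param q Collective pathogenic allele frequency (numeric in `[0,1]`, or
#'   a `collective_q` object).
#' @return Numeric vector.
#' @examples
#' dominant_prevalence(19693 / 282912) * 100  # ~ 13 per 100
#' recessive_prevalence(19693 / 282912) * 100 # ~ 0.48 per 100
#' @export
carrier_frequency <- function(q) {
  q <- as_q(q); check_q(q)
  out <- 2 * q
  if (any(out > 1)) {
    warning("carrier frequency 2q exceeds 1; the allele-counting ",
            "approximation is not a probability at this q")
  }
  out
}

#' @rdname carrier_frequency
#' @export
dominant_prevalence <- function(q) {
  q <- as_q(q); check_q(q)
  2 * q * (1 - q)
}

#' @rdname carrier_frequency
#' @export
recessive_prevalence <- function(q) {
  q <- as_q(q); check_q(q)
  q^2
}

as_q <- function(q) if (inherits(q, "collective_q")) q$q else q

#' Compound-recessive prevalence
#'
#' Prevalence of a recessive phenotype caused either by homozygosity for
#' the primary allele class or by compound heterozygosity with a null
#' allele: `q_primary^2 + 2 * q_primary * q_null`. Used for VWD type 2N
#' with `q_primary` the collective 2N frequency and `q_null` the collective
#' frequency of null (type 1/3) alleles.
#'
#' @param q_primary,q_null Allele frequencies in `[0,1]` with
#'   `q_primary + q_null <= 1`.
#' @return Numeric prevalence.
#' @examples
#' compound_recessive_prevalence(0.01, 0.02)  # 5e-04
#' @export
compound_recessive_prevalence <- function(q_primary, q_null) {
  q_primary <- as_q(q_primary); q_null <- as_q(q_null)
  check_q(q_primary, "q_primary"); check_q(q_null, "q_null")
  if (any(q_primary + q_null > 1)) {
    stop("q_primary + q_null must not exceed 1")
  }
  q_primary^2 + 2 * q_primary * q_null
}

#' Pooled recessive prevalence
#'
#' Pools several allele-class frequencies into one recessive allele class
#' and returns the homozygote/compound frequency `(sum q)^2`. Used for VWD
#' type 3, pooling type 1 and type 3 alleles. An empty input gives 0; a
#' single component equals [recessive_prevalence()].
#'
#' @param q_components Numeric vector of frequencies in `[0,1]`, summing to
#'   at most 1.
#' @return Numeric prevalence.
#' @export
pooled_recessive_prevalence <- function(q_components) {
  if (!length(q_components)) return(0)
  q_components <- vapply(q_components, as_q, numeric(1))
  check_q(q_components, "q_components")
  if (sum(q_components) > 1) stop("sum of q components must not exceed 1")
  sum(q_components)^2
}

match_exclusions <- function(records, exclusions) {
  if (!length(exclusions)) return(rep(FALSE, nrow(records)))
  ex <- norm_hgvs(exclusions)
  norm_hgvs(records$hgvs_c) %in% ex |
    (!is.na(records$hgvs_p) & norm_hgvs(records$hgvs_p) %in% ex)
}

#' Type-specific collective allele frequency
#'
#' Sums per-variant MAFs over pathogenic variants of the requested VWD
#' type(s) in a population, with the study's exclusion rules: optionally
#' restricted to reported (knowledge-base) variants, dropping named
#' excluded variants, and dropping variants whose MAF in that population
#' strictly exceeds `maf_cutoff`.
#'
#' @param records Variant `data.frame`.
#' @param classification A `vwd_classification` for `records`.
#' @param population Population code (or `"all"`, pooled counts).
#' @param vwd_types Non-empty character vector of VWD types to include
#'   (subset of 1, 2A, 2B, 2M, 2N, 3, UC).
#' @param reported_only Restrict to reported variants (default TRUE; VWD
#'   types are only known for reported variants, so FALSE only widens the
#'   set when combined with `vwd_types = NULL`).
#' @param maf_cutoff Optional MAF ceiling; variants with MAF strictly above
#'   it are dropped (the audit records them).
#' @param exclusions Character vector of HGVS c. or p. strings to drop.
#' @param populations Population specification.
#' @return A `collective_q` object whose `q` is the summed MAF; counts are
#'   `NA` (the numerator is a sum of per-variant frequencies, not a single
#'   AC/AN ratio). The `exclusions` field lists every variant dropped by
#'   name or by the cutoff.
#' @export
type_specific_q <- function(records, classification, population,
                            vwd_types, reported_only = TRUE,
                            maf_cutoff = NULL, exclusions = character(0),
                            populations = gnomad_populations()) {
  if (!is.null(vwd_types) && !length(vwd_types)) {
    stop("vwd_types must be non-empty (or NULL for all pathogenic variants)")
  }
  res <- classification$results
  keep <- res$pathogenic
  if (reported_only) keep <- keep & res$status == "reported"
  if (!is.null(vwd_types)) {
    keep <- keep & !is.na(res$vwd_type) & res$vwd_type %in% vwd_types
  }
  dropped <- character(0)
  named_out <- match_exclusions(records, exclusions) & keep
  dropped <- c(dropped, records$hgvs_c[named_out])
  keep <- keep & !named_out
  sel <- records[keep, , drop = FALSE]
  maf <- if (nrow(sel)) variant_maf(sel, population, populations) else numeric(0)
  if (!is.null(maf_cutoff) && nrow(sel)) {
    over <- maf > maf_cutoff
    dropped <- c(dropped, sel$hgvs_c[over])
    sel <- sel[!over, , drop = FALSE]
    maf <- maf[!over]
  }
  collective_q(
    ac_total = NA, an_total = NA, population = population,
    variant_set_id = paste0("types:",
                            if (is.null(vwd_types)) "any"
                            else paste(vwd_types, collapse = "+")),
    exclusions = dropped, maf_cutoff_applied = maf_cutoff,
    q = sum(maf)
  )
}
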
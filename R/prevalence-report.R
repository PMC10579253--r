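#' Default study exclusion lists
#'
#' The carrier/recessive summary excludes three variants that are common
#' polymorphisms in the African/African American population
#' (p.Arg2185Gln, p.Met740Ile, p.His817Gln); the per-type grid excludes
#' the two of them with an assigned VWD type (p.His817Gln, type 2N;
#' p.Arg2185Gln, type 1). These are study choices encoded as data and can
#' be replaced wholesale in [prevalence_config()].
#'
#' @return List with elements `carrier` and `types`, each a character
#'   vector of protein HGVS strings.
#' @export
default_exclusions <- function() {
  list(
    carrier = c("p.Arg2185Gln", "p.Met740Ile", "p.His817Gln"),
    types = c("p.His817Gln", "p.Arg2185Gln")
  )
}

#' Configuration for a prevalence report
#'
#' @param exclusions_carrier Variants (HGVS c. or p.) removed from the
#'   carrier/dominant/recessive collective-frequency summary.
#' @param exclusions_types Variants removed from the per-type grid.
#' @param maf_cutoff_recessive MAF ceiling applied to the recessive models
#'   (type 2N compound and type 3 pooled); variants strictly above it are
#'   dropped. Default 0.01.
#' @param maf_cutoff_dominant Optional MAF ceiling for the dominant
#'   per-type models (default none).
#' @param dominant_types VWD types modelled as autosomal dominant (2pq).
#' @param scale_carrier,scale_types Reporting scale for the two tables:
#'   `"per100"` or `"per1000"`.
#' @param type3_model `"pooled"` (default: type 1 and 3 alleles pooled into
#'   one recessive class, prevalence `(q1+q3)^2`) or `"compound"`
#'   (`q3^2 + 2*q3*q1`).
#' @return A list of class `prevalence_config`.
#' @export
prevalence_config <- function(
    exclusions_carrier = default_exclusions()$carrier,
    exclusions_types = default_exclusions()$types,
    maf_cutoff_recessive = 0.01,
    maf_cutoff_dominant = NULL,
    dominant_types = c("1", "2A", "2B", "2M"),
    scale_carrier = c("per100", "per1000"),
    scale_types = c("per1000", "per100"),
    type3_model = c("pooled", "compound")) {
  structure(list(
    exclusions_carrier = exclusions_carrier,
    exclusions_types = exclusions_types,
    maf_cutoff_recessive = maf_cutoff_recessive,
    maf_cutoff_dominant = maf_cutoff_dominant,
    dominant_types = dominant_types,
    scale_carrier = match.arg(scale_carrier),
    scale_types = match.arg(scale_types),
    type3_model = match.arg(type3_model)
  ), class = "prevalence_config")
}

scale_factor <- function(scale) switch(scale, per100 = 100, per1000 = 1000)

#' Population prevalence report under Hardy-Weinberg equilibrium
#'
#' Produces the two estimation layers of the analysis:
#'
#' * **Carrier table** (one row per population plus a pooled "all" row):
#'   collective frequency `q` of pathogenic alleles against the fixed
#'   reference denominator `2 * n_individuals`, the carrier frequency `2q`,
#'   and recessive (`q^2`) and dominant (`2pq`) prevalences — computed
#'   twice, over *all* pathogenic variants and over *reported-only*
#'   variants, after removing the configured carrier exclusions.
#' * **Type table**: per population and VWD type, using reported variants
#'   with an established type. Dominant types (1, 2A, 2B, 2M) use `2pq` on
#'   the type-specific summed MAF; type 2N uses the compound-recessive
#'   model with type 1/3 alleles as the null class; type 3 pools type 1 and
#'   3 alleles into one recessive class (`(q1+q3)^2`). Recessive models
#'   apply the MAF cutoff (default: drop variants with MAF > 1%).
#'
#' Every dropped variant (named exclusion or cutoff) is recorded in the
#' audit.
#'
#' @param records Variant `data.frame`.
#' @param classification A `vwd_classification` for `records`.
#' @param populations Population specification.
#' @param config A [prevalence_config()].
#' @return An object of class `vwd_prevalence`: list with `carrier`
#'   (data.frame), `types` (data.frame), `audit` (named list of
#'   `collective_q` objects per table cell) and `config`.
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_variants = 100, seed = 1))
#' cls <- classify_cohort(sim$records, sim$db)
#' prev <- prevalence_report(sim$records, cls, populations = sim$populations)
#' print(prev)
#' @export
prevalence_report <- function(records, classification,
                              populations = gnomad_populations(),
                              config = prevalence_config()) {
  res <- classification$results
  stopifnot(nrow(res) == nrow(records))
  audit <- list()
  pops <- c("all", populations$code)
  sc <- scale_factor(config$scale_carrier)
  st <- scale_factor(config$scale_types)

  excl_carrier <- match_exclusions(records, config$exclusions_carrier)
  carrier_rows <- lapply(pops, function(p) {
    an_ref <- if (p == "all") sum(populations$an_ref) else
      populations$an_ref[populations$code == p]
    row <- list(population = p, an_ref = an_ref)
    for (set in c("all_variants", "reported")) {
      keep <- res$pathogenic & !excl_carrier
      if (set == "reported") keep <- keep & res$status == "reported"
      ac <- sum(pop_counts(records[keep, , drop = FALSE], populations, p)$ac)
      cq <- collective_q(ac, an_ref, population = p, variant_set_id = set,
                         exclusions = records$hgvs_c[excl_carrier & res$pathogenic])
      audit[[paste("carrier", p, set, sep = ".")]] <<- cq
      suffix <- if (set == "all_variants") "all" else "rep"
      row[[paste0("ac_", suffix)]] <- ac
      row[[paste0("q_", suffix)]] <- cq$q
      if (set == "all_variants") {
        row$carrier_2q <- suppressWarnings(carrier_frequency(cq$q))
      }
      row[[paste0("recessive_", suffix)]] <- recessive_prevalence(cq$q) * sc
      row[[paste0("dominant_", suffix)]] <- dominant_prevalence(cq$q) * sc
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  carrier <- do.call(rbind, carrier_rows)

  tq <- function(p, types, cutoff) {
    type_specific_q(records, classification, p, types,
                    reported_only = TRUE, maf_cutoff = cutoff,
                    exclusions = config$exclusions_types,
                    populations = populations)
  }
  type_rows <- lapply(pops, function(p) {
    row <- list(population = p)
    for (ty in config$dominant_types) {
      cq <- tq(p, ty, config$maf_cutoff_dominant)
      audit[[paste("type", p, ty, sep = ".")]] <<- cq
      row[[paste0("dominant_", ty)]] <- dominant_prevalence(cq$q) * st
    }
    q2n <- tq(p, "2N", config$maf_cutoff_recessive)
    qnull <- tq(p, c("1", "3"), config$maf_cutoff_recessive)
    audit[[paste("type", p, "2N", sep = ".")]] <<- q2n
    audit[[paste("type", p, "null", sep = ".")]] <<- qnull
    row$recessive_2N <- compound_recessive_prevalence(q2n$q, qnull$q) * st
    if (config$type3_model == "pooled") {
      row$recessive_3 <- pooled_recessive_prevalence(qnull$q) * st
    } else {
      q3 <- tq(p, "3", config$maf_cutoff_recessive)
      q1 <- tq(p, "1", config$maf_cutoff_recessive)
      audit[[paste("type", p, "3", sep = ".")]] <<- q3
      row$recessive_3 <- compound_recessive_prevalence(q3$q, q1$q) * st
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  types <- do.call(rbind, type_rows)
  rownames(carrier) <- rownames(types) <- NULL
  structure(list(carrier = carrier, types = types, audit = audit,
                 config = config, populations = populations),
            class = "vwd_prevalence")
}

#' @export
print.vwd_prevalence <- function(x, digits = 2, ...) {
  cat(sprintf("VWD prevalence estimates (carrier table %s, type table %s)\n",
              x$config$scale_carrier, x$config$scale_types))
  cat("\nCarrier / recessive / dominant (all pathogenic vs reported-only):\n")
  cc <- x$carrier
  num <- vapply(cc, is.numeric, logical(1))
  cc[num] <- lapply(cc[num], function(v) signif(v, digits + 2))
  print(cc, row.names = FALSE)
  cat("\nPer-type prevalence (reported variants with established type):\n")
  tt <- x$types
  num <- vapply(tt, is.numeric, logical(1))
  tt[num] <- lapply(tt[num], function(v) signif(v, digits + 1))
  print(tt, row.names = FALSE)
  invisible(x)
}

#' @export
summary.vwd_prevalence <- function(object, ...) {
  dropped <- unique(unlist(lapply(object$audit, `[[`, "exclusions")))
  cat(sprintf("Prevalence report over %d population(s); %d variant(s) dropped by exclusion lists or MAF cutoffs\n",
              nrow(object$populations), length(dropped)))
  if (length(dropped)) cat("  dropped:", paste(dropped, collapse = ", "), "\n")
  invisible(object)
}
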
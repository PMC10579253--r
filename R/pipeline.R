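#' Pipeline run configuration
#'
#' Collects every input of a full classify/aggregate/prevalence run. The
#' configuration round-trips through YAML ([write_run_config()] /
#' [read_run_config()]), so a run is fully reproducible from its config
#' file and seed.
#'
#' @param variants Path to the variant table.
#' @param known_db Path to the known-variant TSV (a single merged table),
#'   or a `vwd_kb` object.
#' @param populations Population specification `data.frame` or path to a
#'   populations YAML.
#' @param dialect Variant-table dialect, `"tsv"` or `"vcf"`.
#' @param out_dir Output directory.
#' @param exclusions_carrier,exclusions_types Exclusion lists (HGVS c. or
#'   p. strings) for the carrier table and the per-type grid; defaults from
#'   [default_exclusions()].
#' @param maf_cutoff MAF ceiling applied to the recessive per-type models.
#' @param scale_carrier,scale_types Reporting scales.
#' @param min_depth Low-coverage flag threshold for validation.
#' @param top_k Number of recurrent variants reported per population.
#' @param seed Integer seed recorded in the run log (the pipeline itself is
#'   deterministic; the seed matters when the variants file is produced by
#'   the simulator).
#' @return A list of class `run_config`.
#' @export
run_config <- function(variants, known_db, populations = NULL,
                       dialect = c("tsv", "vcf"), out_dir = "vwdprev_out",
                       exclusions_carrier = default_exclusions()$carrier,
                       exclusions_types = default_exclusions()$types,
                       maf_cutoff = 0.01,
                       scale_carrier = "per100", scale_types = "per1000",
                       min_depth = 10, top_k = 5L, seed = 1L) {
  structure(list(
    variants = variants, known_db = known_db, populations = populations,
    dialect = match.arg(dialect), out_dir = out_dir,
    exclusions_carrier = exclusions_carrier,
    exclusions_types = exclusions_types, maf_cutoff = maf_cutoff,
    scale_carrier = scale_carrier, scale_types = scale_types,
    min_depth = min_depth, top_k = as.integer(top_k),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$populations <- if (is.data.frame(x$populations)) {
    lapply(seq_len(nrow(x$populations)), function(i) {
      list(code = x$populations$code[i],
           display_name = x$populations$display_name[i],
           n_individuals = x$populations$n_individuals[i])
    })
  } else x$populations
  if (inherits(x$known_db, "vwd_kb")) {
    stop("write_run_config requires known_db to be a file path")
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  pops <- x$populations
  if (is.list(pops) && length(pops) && !is.null(pops[[1]]$code)) {
    pops <- population_spec(
      code = vapply(pops, `[[`, character(1), "code"),
      display_name = vapply(pops, function(p) {
        as.character(if (is.null(p$display_name)) p$code else p$display_name)
      }, character(1)),
      n_individuals = vapply(pops, function(p) as.integer(p$n_individuals),
                             integer(1)))
  }
  run_config(variants = x$variants, known_db = x$known_db,
             populations = pops, dialect = x$dialect, out_dir = x$out_dir,
             exclusions_carrier = unlist(x$exclusions_carrier),
             exclusions_types = unlist(x$exclusions_types),
             maf_cutoff = x$maf_cutoff, scale_carrier = x$scale_carrier,
             scale_types = x$scale_types, min_depth = x$min_depth,
             top_k = x$top_k, seed = x$seed)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  path
}

#' Run the full classification/aggregation/prevalence pipeline
#'
#' Reads the variant table and knowledge base, classifies every variant
#' with the five-rule cascade, aggregates affected alleles, recurrent
#' variants, common-variant flags and the homozygote census, estimates
#' carrier and per-type prevalence under Hardy-Weinberg equilibrium, and
#' writes all tables plus a JSON summary and a run log to
#' `config$out_dir`. Exclusion-list entries that match no variant in the
#' cohort produce a warning and are otherwise ignored. Outputs are a
#' deterministic function of the config (and of the input files).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`records`,
#'   `classification`, `affected`, `top`, `common`, `homozygotes`,
#'   `prevalence`, `validation`) and `paths` (named vector of files
#'   written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pops <- config$populations
  if (is.null(pops)) pops <- gnomad_populations()
  if (is.character(pops)) pops <- read_population_spec(pops)

  records <- read_variant_table(config$variants, config$dialect, pops)
  db <- if (inherits(config$known_db, "vwd_kb")) config$known_db else
    known_variant_db(load_known_variants(config$known_db))

  log_lines <- c(
    sprintf("vwdprev %s", as.character(utils::packageVersion("vwdprev"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", config$seed),
    sprintf("variants: %s (%d records)", config$variants, nrow(records)),
    sprintf("exclusions (carrier): %s",
            paste(config$exclusions_carrier, collapse = ", ")),
    sprintf("exclusions (types): %s",
            paste(config$exclusions_types, collapse = ", ")),
    sprintf("maf_cutoff (recessive models): %g", config$maf_cutoff))

  known <- c(norm_hgvs(records$hgvs_c),
             norm_hgvs(records$hgvs_p[!is.na(records$hgvs_p)]))
  for (ex in unique(c(config$exclusions_carrier, config$exclusions_types))) {
    if (!norm_hgvs(ex) %in% known) {
      warning("exclusion '", ex, "' matches no variant in the cohort")
      log_lines <- c(log_lines,
                     sprintf("WARNING: exclusion '%s' matched nothing", ex))
    }
  }

  validation <- validate_cohort(records, pops, config$min_depth)
  cls <- classify_cohort(records, db)
  affected <- affected_alleles(records, cls, pops)
  top <- do.call(rbind, lapply(c("all", pops$code), function(p) {
    top_variants(records, cls, p, config$top_k, pops)
  }))
  common <- common_variant_flags(records, pops, threshold = 0.01)
  hom <- homozygote_census(records, cls, pops)
  prev <- prevalence_report(records, cls, pops, prevalence_config(
    exclusions_carrier = config$exclusions_carrier,
    exclusions_types = config$exclusions_types,
    maf_cutoff_recessive = config$maf_cutoff,
    scale_carrier = config$scale_carrier,
    scale_types = config$scale_types))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  paths <- c(
    classification = write_tsv(cbind(records[, c("chrom", "pos", "ref",
                                                 "alt", "hgvs_c", "hgvs_p",
                                                 "consequence")],
                                     cls$results), out("classification.tsv")),
    affected = write_tsv(affected, out("affected_alleles.tsv")),
    top = write_tsv(top, out("top_variants.tsv")),
    common = write_tsv(common, out("common_variants.tsv")),
    prevalence_carrier = write_tsv(prev$carrier,
                                   out("prevalence_carrier.tsv")),
    prevalence_types = write_tsv(prev$types, out("prevalence_types.tsv")),
    homozygotes = out("homozygotes.json"),
    summary = out("summary.json"),
    log = out("run.log"))
  jsonlite::write_json(hom, paths[["homozygotes"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  dropped <- unique(unlist(lapply(prev$audit, `[[`, "exclusions")))
  summary_json <- list(
    n_records = nrow(records),
    n_pathogenic = cls$summary$n_pathogenic,
    by_rule = as.list(cls$summary$by_rule),
    by_consequence = as.list(cls$summary$by_consequence),
    by_status = as.list(cls$summary$by_status),
    n_flagged_low_coverage = length(validation$low_coverage),
    n_validation_violations = nrow(validation$violations),
    variants_dropped_by_exclusion_or_cutoff = as.list(dropped))
  jsonlite::write_json(summary_json, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_lines <- c(log_lines,
                 sprintf("dropped by exclusion/cutoff: %s",
                         paste(dropped, collapse = ", ")),
                 sprintf("pathogenic: %d of %d",
                         cls$summary$n_pathogenic, nrow(records)))
  writeLines(log_lines, paths[["log"]])
  invisible(list(records = records, classification = cls,
                 affected = affected, top = top, common = common,
                 homozygotes = hom, prevalence = prev,
                 validation = validation, paths = paths))
}
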
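## Five-rule conservative pathogenicity cascade. A variant is called
## deleterious when the first of these rules fires:
##   1. known_db            -- clearly VWD-associated in the knowledge base
##   2. truncating          -- stop-gained/-lost, frameshift, inframe indel
##   3. splice_core         -- first/last 2 intronic nucleotides
##   4. splice_consensus    -- splice-region (+/-3..8) variant called
##                             deleterious by 4 of 4 splice predictors
##   5. missense_consensus  -- missense called deleterious by 7 of 7 tools
## Every missing predictor value fails closed (never counts as a pass).

CLASSIFICATION_RULES <- c("known_db", "truncating", "splice_core",
                          "splice_consensus", "missense_consensus", "none")

#' Deleteriousness call of a single splice prediction tool
#'
#' A splice tool's prediction is deleterious when the variant abolishes the
#' wild-type splice site, or when it reduces the prediction score to
#' strictly less than half of the wild-type score. A wild-type score of 0
#' can only pass via abolition. Missing values yield `FALSE`.
#'
#' @param wild_type_score,variant_score Non-negative scores.
#' @param site_abolished Logical: the tool predicts loss of the site.
#' @return Logical vector.
#' @examples
#' splice_tool_deleterious(10, 4.9, FALSE)  # TRUE
#' splice_tool_deleterious(10, 5.0, FALSE)  # FALSE: not strictly < half
#' @export
splice_tool_deleterious <- function(wild_type_score, variant_score,
                                    site_abolished) {
  if (any(wild_type_score < 0, na.rm = TRUE) ||
      any(variant_score < 0, na.rm = TRUE)) {
    stop("splice prediction scores must be non-negative")
  }
  ab <- !is.na(site_abolished) & site_abolished
  halved <- !is.na(variant_score) & !is.na(wild_type_score) &
    variant_score < 0.5 * wild_type_score
  ab | halved
}

splice_tool_pass <- function(records, tool) {
  splice_tool_deleterious(records[[paste0(tool, "_wt")]],
                          records[[paste0(tool, "_var")]],
                          records[[paste0(tool, "_abolished")]])
}

#' Consensus splice-predictor deleteriousness (4 of 4)
#'
#' TRUE only when all three splice tools (Varseak, ESEFinder, BDGP) call the
#' variant deleterious under [splice_tool_deleterious()] *and* the CADD
#' PHRED score is >= 20. With `require_cadd = FALSE` the CADD condition is
#' dropped (a 3-of-3 rule). Any missing tool fails the consensus.
#'
#' @param records Variant `data.frame` (uses the splice-tool score columns
#'   and `cadd_phred`).
#' @param require_cadd Require CADD >= 20 as the fourth tool (default).
#' @return Logical vector.
#' @export
splice_consensus_deleterious <- function(records, require_cadd = TRUE) {
  pass <- Reduce(`&`, lapply(SPLICE_TOOLS, splice_tool_pass,
                             records = records))
  if (require_cadd) {
    pass <- pass & !is.na(records$cadd_phred) & records$cadd_phred >= 20
  }
  pass
}

#' Consensus missense-predictor deleteriousness (7 of 7)
#'
#' TRUE only when CADD PHRED >= 20 *and* all six categorical tools (SIFT,
#' PolyPhen2, LRT, MutationTaster, MutationAssessor, FATHMM) report
#' "deleterious". Any "tolerated" or "missing" call fails the consensus.
#'
#' @param records Variant `data.frame`.
#' @return Logical vector.
#' @export
missense_consensus_deleterious <- function(records) {
  pass <- !is.na(records$cadd_phred) & records$cadd_phred >= 20
  for (tool in MISSENSE_TOOLS) {
    pass <- pass & !is.na(records[[tool]]) & records[[tool]] == "deleterious"
  }
  pass
}

#' Classification options
#'
#' @param include_stop_lost Admit stop-loss variants under the truncating
#'   rule alongside stop-gained (default TRUE: both affect the stop codon).
#' @param splice_require_cadd Require CADD >= 20 in the splice consensus
#'   (4-of-4 rule, default) or not (3-of-3).
#' @return A list of options for [classify_cohort()].
#' @export
classification_options <- function(include_stop_lost = TRUE,
                                   splice_require_cadd = TRUE) {
  list(include_stop_lost = isTRUE(include_stop_lost),
       splice_require_cadd = isTRUE(splice_require_cadd))
}

#' Classify a cohort of variants with the five-rule cascade
#'
#' Rules are evaluated in priority order: knowledge-base membership,
#' truncating consequence, core splice site, splice-predictor consensus,
#' missense-predictor consensus; the first that fires is recorded. A
#' pathogenic variant is `reported` when matched in the knowledge base
#' (inheriting its VWD type) and `novel` otherwise.
#'
#' @param records Variant `data.frame`.
#' @param db A `vwd_kb` knowledge base.
#' @param options See [classification_options()].
#' @return An object of class `vwd_classification`: list with `results`
#'   (one row per record: `pathogenic`, `rule`, `status`, `vwd_type`,
#'   `inheritance`, and an `audit_<rule>` column per rule holding that
#'   rule's raw evaluation) and `summary` (counts by rule, by consequence
#'   class over pathogenic records, and novel vs reported).
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_variants = 50, seed = 1))
#' cls <- classify_cohort(sim$records, sim$db)
#' summary(cls)
#' @export
classify_cohort <- function(records, db,
                            options = classification_options()) {
  n <- nrow(records)
  kb_idx <- kb_lookup(db, records)
  trunc_classes <- c("stop_gained", "frameshift", "inframe_indel",
                     if (options$include_stop_lost) "stop_lost")
  audit <- data.frame(
    audit_known_db = !is.na(kb_idx),
    audit_truncating = records$consequence %in% trunc_classes,
    audit_splice_core = records$consequence == "splice_core",
    audit_splice_consensus = records$consequence == "splice_region" &
      splice_consensus_deleterious(records, options$splice_require_cadd),
    audit_missense_consensus = records$consequence == "missense" &
      missense_consensus_deleterious(records)
  )
  rule <- rep("none", n)
  for (r in rev(setdiff(CLASSIFICATION_RULES, "none"))) {
    rule[audit[[paste0("audit_", r)]]] <- r
  }
  pathogenic <- rule != "none"
  status <- ifelse(!pathogenic, "not_pathogenic",
                   ifelse(is.na(kb_idx), "novel", "reported"))
  vwd_type <- ifelse(status == "reported", db$entries$vwd_type[kb_idx],
                     NA_character_)
  inheritance <- ifelse(status == "reported",
                        db$entries$inheritance[kb_idx], NA_character_)
  results <- cbind(
    data.frame(pathogenic = pathogenic, rule = rule, status = status,
               vwd_type = vwd_type, inheritance = inheritance,
               stringsAsFactors = FALSE),
    audit
  )
  path_cons <- factor(records$consequence[pathogenic],
                      levels = CONSEQUENCE_CLASSES)
  summary <- list(
    n_records = n,
    n_pathogenic = sum(pathogenic),
    by_rule = table(factor(rule[pathogenic],
                           levels = setdiff(CLASSIFICATION_RULES, "none"))),
    by_consequence = table(path_cons),
    by_status = table(factor(status[pathogenic],
                             levels = c("reported", "novel")))
  )
  structure(list(results = results, summary = summary, options = options),
            class = "vwd_classification")
}

#' Classify a single variant record
#'
#' Convenience wrapper around [classify_cohort()] for one record.
#'
#' @inheritParams classify_cohort
#' @param record A one-row variant `data.frame`.
#' @return A one-row classification `data.frame` (see [classify_cohort()]).
#' @export
classify_variant <- function(record, db,
                             options = classification_options()) {
  stopifnot(nrow(record) == 1L)
  classify_cohort(record, db, options)$results
}

#' @export
print.vwd_classification <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Pathogenicity classification: %d of %d variant(s) deleterious (%d reported, %d novel)\n",
              s$n_pathogenic, s$n_records,
              s$by_status[["reported"]], s$by_status[["novel"]]))
  invisible(x)
}

#' @export
summary.vwd_classification <- function(object, ...) {
  s <- object$summary
  cat(sprintf("Variants classified: %d; deleterious: %d\n",
              s$n_records, s$n_pathogenic))
  cat("By rule:\n"); print(s$by_rule)
  cat("By consequence (pathogenic only):\n")
  print(s$by_consequence[s$by_consequence > 0])
  cat("Novel vs reported:\n"); print(s$by_status)
  invisible(s)
}

#' Barplot of the mutation-class mix among pathogenic variants
#'
#' @param x A `vwd_classification`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.vwd_classification <- function(x, ...) {
  tab <- x$summary$by_consequence
  tab <- tab[tab > 0]
  graphics::barplot(as.numeric(tab), names.arg = names(tab), las = 2,
                    ylab = "pathogenic variants", ...)
  invisible(x)
}
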
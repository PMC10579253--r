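## Named deterministic fixtures. Each builds a small cohort whose
## aggregated counts equal published summary counts exactly (planted, no
## sampling), so downstream tables can be checked without noise.

FIXTURE_NAMES <- c("table4_all", "table4_populations", "table2_affected",
                   "fig1_mix", "table3_finnish", "table6_common")

kb_entry_row <- function(hgvs_c, vwd_type, inheritance,
                         chrom = NA_character_, pos = NA_integer_,
                         ref = NA_character_, alt = NA_character_,
                         clear = TRUE) {
  data.frame(match_key = norm_hgvs(hgvs_c), hgvs_c = hgvs_c, chrom = chrom,
             pos = pos, ref = ref, alt = alt, vwd_type = vwd_type,
             inheritance = inheritance, sources = "HGMD;LOVD",
             clear_association = clear,
             literature_override = NA_character_, stringsAsFactors = FALSE)
}

## one reported type-1 variant per population carrying that population's
## whole planted allele count
fixture_table4 <- function() {
  pops <- gnomad_populations()
  ac <- c(afr = 2366L, amr = 3673L, asj = 846L, eas = 546L, fin = 1238L,
          nfe = 7573L, sas = 2840L, oth = 611L)
  rec <- blank_records(length(ac), pops)
  rec$consequence <- "missense"
  rec$hgvs_c <- sprintf("c.%d00G>A", seq_along(ac))
  rec$hgvs_p <- sprintf("p.Gly%dAsp", 100L + seq_along(ac))
  for (i in seq_along(ac)) {
    rec[[paste0("ac_", names(ac)[i])]][i] <- ac[[i]]
  }
  db <- known_variant_db(do.call(rbind, lapply(seq_along(ac), function(i) {
    kb_entry_row(rec$hgvs_c[i], "1", "dominant")
  })))
  list(records = rec, db = db, populations = pops)
}

## reported and novel per-population affected-allele splits
fixture_table2 <- function() {
  pops <- gnomad_populations()
  rep_ac <- c(afr = 14236L, amr = 3530L, asj = 820L, eas = 443L,
              fin = 1222L, nfe = 7282L, sas = 2725L, oth = 592L)
  nov_ac <- c(afr = 222L, amr = 143L, asj = 26L, eas = 103L, fin = 16L,
              nfe = 291L, sas = 115L, oth = 19L)
  n <- 2L * length(rep_ac)
  rec <- blank_records(n, pops)
  rec$hgvs_c <- sprintf("c.%d11G>A", seq_len(n))
  for (i in seq_along(rep_ac)) {
    rec$consequence[i] <- "missense"
    rec$hgvs_p[i] <- sprintf("p.Arg%dGln", 200L + i)
    rec[[paste0("ac_", names(rep_ac)[i])]][i] <- rep_ac[[i]]
  }
  for (i in seq_along(nov_ac)) {
    j <- length(rep_ac) + i
    rec$consequence[j] <- "frameshift"   # pathogenic without db membership
    rec$hgvs_p[j] <- sprintf("p.Arg%dfs", 300L + i)
    rec[[paste0("ac_", names(nov_ac)[i])]][j] <- nov_ac[[i]]
  }
  db <- known_variant_db(do.call(rbind, lapply(seq_along(rep_ac),
    function(i) kb_entry_row(rec$hgvs_c[i], "1", "dominant"))))
  list(records = rec, db = db, populations = pops)
}

## 505 pathogenic variants with the observed mutation-class mix and the
## 218/287 reported/novel split (synonymous variant necessarily reported)
fixture_fig1 <- function() {
  pops <- gnomad_populations()
  class_n <- c(missense = 355L, frameshift = 53L, stop_gained = 40L,
               stop_lost = 1L, splice_core = 41L, inframe_indel = 14L,
               synonymous = 1L)
  rep_n <- c(missense = 150L, frameshift = 20L, stop_gained = 15L,
             stop_lost = 1L, splice_core = 17L, inframe_indel = 14L,
             synonymous = 1L)
  stopifnot(sum(class_n) == 505L, sum(rep_n) == 218L)
  consequence <- rep(names(class_n), class_n)
  reported <- unlist(lapply(names(class_n), function(cl) {
    c(rep(TRUE, rep_n[[cl]]), rep(FALSE, class_n[[cl]] - rep_n[[cl]]))
  }))
  n <- length(consequence)
  rec <- blank_records(n, pops)
  rec$consequence <- consequence
  rec$hgvs_c <- sprintf("c.%d22G>A", seq_len(n))
  aa <- 100L + seq_len(n)
  rec$hgvs_p <- mapply(hgvs_p_for, consequence, aa,
                       MoreArgs = list(aa_from = "Arg", aa_to = "Gln"))
  rec$intronic_offset[consequence == "splice_core"] <- 2L
  rec$hgvs_c[consequence == "splice_core"] <-
    sprintf("c.%d22+2T>C", which(consequence == "splice_core"))
  ## novel missense variants must pass the 7-of-7 consensus
  nov_mis <- !reported & consequence == "missense"
  rec$cadd_phred[nov_mis] <- 30
  for (tool in MISSENSE_TOOLS) rec[[tool]][nov_mis] <- "deleterious"
  rec$ac_nfe <- 1L
  types <- rep(c("1", "2A", "2B", "2M", "2N", "3", "UC"),
               times = c(78L, 23L, 12L, 21L, 15L, 54L, 15L))
  rep_idx <- which(reported)
  db <- known_variant_db(do.call(rbind, lapply(seq_along(rep_idx),
    function(k) {
      ty <- types[k]
      kb_entry_row(rec$hgvs_c[rep_idx[k]], ty,
                   inheritance = if (ty %in% c("2N", "3")) "recessive"
                                 else if (ty == "UC") "unknown"
                                 else "dominant")
    })))
  list(records = rec, db = db, populations = pops)
}

## the five most frequent Finnish variants (planted allele counts) plus
## three rarer pathogenic variants
fixture_table3_finnish <- function() {
  pops <- gnomad_populations()
  top <- data.frame(
    hgvs_c = c("c.7940 C > T", "c.2561 G > A", "c.2771 G > A",
               "c.4315 G > A", "c.3797 C > T"),
    hgvs_p = c("p.Thr2647Met", "p.Arg854Gln", "p.Arg924Gln",
               "p.Val1439Met", "p.Pro1266Leu"),
    rsid = c("rs61751302", "rs41276738", "rs33978901", "rs150077670",
             "rs61749370"),
    vwd_type = c("1", "2N", "1", "2M", "2B"),
    maf = c(0.019783, 0.005692, 0.005573, 0.004857, 0.003667),
    ref = c("C", "G", "G", "G", "C"), alt = c("T", "A", "A", "A", "T"),
    stringsAsFactors = FALSE)
  n <- nrow(top) + 3L
  rec <- blank_records(n, pops)
  rec$consequence <- "missense"
  an_fin <- pops$an_ref[pops$code == "fin"]
  for (i in seq_len(nrow(top))) {
    rec$hgvs_c[i] <- top$hgvs_c[i]
    rec$hgvs_p[i] <- top$hgvs_p[i]
    rec$rsid[i] <- top$rsid[i]
    rec$ref[i] <- top$ref[i]
    rec$alt[i] <- top$alt[i]
    rec$ac_fin[i] <- as.integer(round(top$maf[i] * an_fin))
  }
  for (j in (nrow(top) + 1L):n) {
    rec$hgvs_c[j] <- sprintf("c.%d33G>A", j)
    rec$hgvs_p[j] <- sprintf("p.Ala%dVal", 400L + j)
    rec$ac_fin[j] <- 10L
  }
  db <- known_variant_db(do.call(rbind, c(
    lapply(seq_len(nrow(top)), function(i) {
      kb_entry_row(top$hgvs_c[i], top$vwd_type[i],
                   inheritance = if (top$vwd_type[i] == "2N") "recessive"
                                 else "dominant")
    }),
    lapply((nrow(top) + 1L):n, function(j) {
      kb_entry_row(rec$hgvs_c[j], "1", "dominant")
    }))))
  list(records = rec, db = db, populations = pops)
}

## one variant common (>1%) in Ashkenazi Jews only, plus sub-threshold ones
fixture_table6 <- function() {
  pops <- gnomad_populations()
  rec <- blank_records(3L, pops)
  rec$consequence <- "missense"
  rec$hgvs_c <- c("c.5191 T > A", "c.9001G>A", "c.9002G>A")
  rec$hgvs_p <- c("p.Ser1731Thr", "p.Gly501Asp", "p.Gly502Asp")
  rec$ref[1] <- "T"
  rec$ac_asj[1] <- as.integer(round(0.0209 * 10370))      # MAF 0.020926
  for (p in setdiff(pops$code, "asj")) {
    rec[[paste0("ac_", p)]][1] <-
      as.integer(round(0.001 * pops$an_ref[pops$code == p]))
  }
  rec$ac_asj[2] <- as.integer(round(0.005 * 10370))
  rec$ac_nfe[3] <- 50L
  db <- known_variant_db(rbind(
    kb_entry_row("c.5191 T > A", "2M", "dominant"),
    kb_entry_row("c.9001G>A", "1", "dominant"),
    kb_entry_row("c.9002G>A", "1", "dominant")))
  list(records = rec, db = db, populations = pops)
}

#' Build a named deterministic end-to-end fixture
#'
#' Constructs a small cohort whose aggregated counts equal published
#' summary counts exactly (planted allele counts, no sampling) and,
#' optionally, writes it to disk (`variants.tsv`, `known_db.tsv`,
#' `populations.yaml`).
#'
#' Available fixtures: `table4_all` / `table4_populations` (per-population
#' pathogenic allele totals against the fixed reference denominators),
#' `table2_affected` (reported/novel affected-allele splits), `fig1_mix`
#' (505 pathogenic variants with the observed mutation-class mix and
#' 218/287 reported/novel split), `table3_finnish` (the five most frequent
#' Finnish variants), `table6_common` (a variant with MAF > 1% in one
#' population).
#'
#' @param name Fixture name.
#' @param dir Optional output directory; created if needed.
#' @return Invisibly, a list with `records`, `db`, `populations` and (when
#'   written) `dir`.
#' @examples
#' fx <- end_to_end_fixture("table4_all")
#' sum(fx$records$ac_nfe)
#' @export
end_to_end_fixture <- function(name, dir = NULL) {
  if (!name %in% FIXTURE_NAMES) {
    stop("unknown fixture '", name, "'; available: ",
         paste(FIXTURE_NAMES, collapse = ", "))
  }
  fx <- switch(name,
    table4_all = , table4_populations = fixture_table4(),
    table2_affected = fixture_table2(),
    fig1_mix = fixture_fig1(),
    table3_finnish = fixture_table3_finnish(),
    table6_common = fixture_table6()
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_variant_table(fx$records, file.path(dir, "variants.tsv"), "tsv",
                        fx$populations)
    utils::write.table(fx$db$entries, file.path(dir, "known_db.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    yaml::write_yaml(list(populations = lapply(
      seq_len(nrow(fx$populations)), function(i) {
        list(code = fx$populations$code[i],
             display_name = fx$populations$display_name[i],
             n_individuals = fx$populations$n_individuals[i])
      })), file.path(dir, "populations.yaml"))
    fx$dir <- dir
  }
  invisible(fx)
}
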
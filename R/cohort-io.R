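## Canonical column layout of a variant table. One row per biallelic variant;
## per-population allele summaries live in ac_<code>/an_<code>/nhom_<code>.

#' @keywords internal
CONSEQUENCE_CLASSES <- c(
  "missense", "synonymous", "stop_gained", "stop_lost", "frameshift",
  "inframe_indel", "splice_core", "splice_region", "other"
)

## consequence classes for which a protein-level HGVS string is required
PROTEIN_CONSEQUENCES <- c("missense", "stop_gained", "stop_lost",
                          "inframe_indel")

MISSENSE_TOOLS <- c("sift", "polyphen2", "lrt", "mutationtaster",
                    "mutationassessor", "fathmm")
SPLICE_TOOLS <- c("varseak", "esefinder", "bdgp")

annotation_columns <- function() {
  c("chrom", "pos", "ref", "alt", "hgvs_c", "hgvs_p", "rsid",
    "consequence", "intronic_offset", "mean_depth", "cadd_phred",
    MISSENSE_TOOLS,
    as.vector(t(outer(SPLICE_TOOLS, c("wt", "var", "abolished"),
                      paste, sep = "_"))))
}

count_columns <- function(populations) {
  as.vector(t(outer(c("ac", "an", "nhom"), populations$code,
                    paste, sep = "_")))
}

#' Normalize an HGVS string for matching
#'
#' Removes all whitespace (case is preserved), so that e.g.
#' `"c.6554 G > A"` and `"c.6554G>A"` compare equal.
#'
#' @param x Character vector of HGVS strings.
#' @return Character vector with whitespace stripped; `NA` stays `NA`.
#' @export
norm_hgvs <- function(x) {
  out <- gsub("[[:space:]]+", "", x)
  out[is.na(x)] <- NA_character_
  out
}

empty_variant_table <- function(populations) {
  cols <- c(annotation_columns(), count_columns(populations))
  df <- as.data.frame(
    stats::setNames(rep(list(logical(0)), length(cols)), cols))
  df
}

## Per-record invariant checks. Returns a data.frame of violations
## (row, field, message); empty when all records are valid.
check_variant_invariants <- function(records, populations) {
  viol <- list()
  add <- function(rows, field, msg) {
    if (length(rows)) {
      viol[[length(viol) + 1L]] <<- data.frame(
        row = rows, field = field, message = msg, stringsAsFactors = FALSE)
    }
  }
  add(which(is.na(records$pos) | records$pos < 1), "pos",
      "position must be a 1-based integer")
  bad_seq <- function(x) !grepl("^[ACGT]+$", x)
  add(which(bad_seq(records$ref)), "ref", "ref must be uppercase A/C/G/T")
  add(which(bad_seq(records$alt)), "alt", "alt must be uppercase A/C/G/T")
  add(which(records$ref == records$alt), "alt", "ref and alt must differ")
  add(which(!records$consequence %in% CONSEQUENCE_CLASSES), "consequence",
      paste("consequence must be one of:",
            paste(CONSEQUENCE_CLASSES, collapse = ", ")))
  off <- records$intronic_offset
  core <- records$consequence == "splice_core"
  add(which(core & (is.na(off) | !abs(off) %in% 1:2)), "intronic_offset",
      "splice_core requires |intronic_offset| in {1,2}")
  reg <- records$consequence == "splice_region"
  add(which(reg & (is.na(off) | abs(off) < 3 | abs(off) > 8)),
      "intronic_offset",
      "splice_region requires 3 <= |intronic_offset| <= 8")
  add(which(records$consequence %in% PROTEIN_CONSEQUENCES &
              is.na(records$hgvs_p)), "hgvs_p",
      "protein-altering consequence requires hgvs_p")
  key <- paste(records$chrom, records$pos, records$ref, records$alt)
  add(which(duplicated(key)), "pos", "duplicate variant key")
  for (p in populations$code) {
    ac <- records[[paste0("ac_", p)]]
    an <- records[[paste0("an_", p)]]
    nh <- records[[paste0("nhom_", p)]]
    if (is.null(ac) || is.null(an) || is.null(nh)) {
      stop("missing count columns for population '", p, "'")
    }
    add(which(is.na(ac) | ac < 0), paste0("ac_", p), "ac must be >= 0")
    add(which(!is.na(ac) & !is.na(an) & ac > an), paste0("ac_", p),
        "AC must not exceed AN")
    add(which(!is.na(nh) & !is.na(ac) & 2 * nh > ac), paste0("nhom_", p),
        "2*nhom must not exceed AC")
    an_ref <- populations$an_ref[populations$code == p]
    add(which(!is.na(an) & an > an_ref), paste0("an_", p),
        sprintf("AN exceeds 2 x n_individuals (%d) of population '%s'",
                an_ref, p))
  }
  if (!length(viol)) {
    return(data.frame(row = integer(0), field = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, viol)
  out[order(out$row), , drop = FALSE]
}

assert_valid_variants <- function(records, populations) {
  viol <- check_variant_invariants(records, populations)
  if (nrow(viol)) {
    v <- viol[1L, ]
    stop(sprintf("invalid variant record at row %d, field '%s': %s (%d problem%s in total)",
                 v$row, v$field, v$message, nrow(viol),
                 if (nrow(viol) == 1L) "" else "s"))
  }
  invisible(records)
}

#' Read a gnomAD-style variant summary table
#'
#' Reads per-population variant allele summaries from either the canonical
#' TSV dialect (one column per field, `ac_<pop>`/`an_<pop>`/`nhom_<pop>`
#' count columns) or a VCF 4.2 dialect (INFO keys `AC_<pop>`, `AN_<pop>`,
#' `nhomalt_<pop>`, plus an `ANN` annotation key; see
#' [write_variant_table()] for the sub-field order). Multi-allelic VCF
#' sites are split into one biallelic record per alternate allele.
#'
#' @param path Path to the input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param populations Population specification; population codes found in
#'   the file that are absent from it are an error.
#' @return A `data.frame` of variant records, one row per alternate allele,
#'   in input order. All record invariants are checked (`AC <= AN`,
#'   `2*nhom <= AC`, splice offsets consistent with the consequence class,
#'   protein HGVS present for protein-altering classes).
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               populations = gnomad_populations()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  records <- switch(dialect,
    tsv = read_variants_tsv(path, populations),
    vcf = read_variants_vcf(path, populations)
  )
  assert_valid_variants(records, populations)
  records
}

read_variants_tsv <- function(path, populations) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  need <- c(annotation_columns(), count_columns(populations))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    ## allow extra ac_* columns only if they belong to known populations
    extra_pops <- sub("^ac_", "",
                      grep("^ac_", setdiff(names(df), need), value = TRUE))
    if (length(extra_pops)) {
      stop("unknown population code(s) in table: ",
           paste(extra_pops, collapse = ", "),
           "; known codes: ", paste(populations$code, collapse = ", "))
    }
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  extra_pops <- sub("^ac_", "",
                    grep("^ac_", setdiff(names(df), need), value = TRUE))
  if (length(extra_pops)) {
    stop("unknown population code(s) in table: ",
         paste(extra_pops, collapse = ", "),
         "; known codes: ", paste(populations$code, collapse = ", "))
  }
  df <- df[, need, drop = FALSE]
  coerce_variant_types(df, populations)
}

coerce_variant_types <- function(df, populations) {
  int_cols <- c("pos", "intronic_offset",
                paste0("ac_", populations$code),
                paste0("an_", populations$code),
                paste0("nhom_", populations$code))
  num_cols <- c("mean_depth", "cadd_phred",
                paste0(SPLICE_TOOLS, "_wt"), paste0(SPLICE_TOOLS, "_var"))
  lgl_cols <- paste0(SPLICE_TOOLS, "_abolished")
  for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
  for (cc in num_cols) df[[cc]] <- as.numeric(df[[cc]])
  for (cc in lgl_cols) df[[cc]] <- as.logical(df[[cc]])
  for (cc in MISSENSE_TOOLS) {
    df[[cc]] <- as.character(df[[cc]])
    df[[cc]][is.na(df[[cc]])] <- "missing"
    bad <- !df[[cc]] %in% c("deleterious", "tolerated", "missing")
    if (any(bad)) {
      stop(sprintf("malformed row %d, field '%s': call must be deleterious/tolerated/missing, got '%s'",
                   which(bad)[1L], cc, df[[cc]][which(bad)[1L]]))
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a variant summary table
#'
#' Writes records in the canonical TSV dialect or as a VCF 4.2 file with
#' per-population INFO keys `AC_<pop>`, `AN_<pop>` and `nhomalt_<pop>`,
#' site mean depth as `DPM`, and an `ANN` key carrying the annotation
#' sub-fields in the order
#' `consequence|intronic_offset|hgvs_c|hgvs_p|cadd_phred|sift|polyphen2|lrt|`
#' `mutationtaster|mutationassessor|fathmm|varseak_wt|varseak_var|`
#' `varseak_abolished|esefinder_wt|esefinder_var|esefinder_abolished|`
#' `bdgp_wt|bdgp_var|bdgp_abolished` (missing values as `.`; spaces
#' percent-encoded). Reading back with [read_variant_table()] reproduces
#' the records field for field.
#'
#' @param records Variant `data.frame` (validated before writing).
#' @param path Output file path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param populations Population specification used to validate and to
#'   order the per-population INFO keys.
#' @return Invisibly, `path`.
#' @export
write_variant_table <- function(records, path, dialect = c("tsv", "vcf"),
                                populations = gnomad_populations()) {
  dialect <- match.arg(dialect)
  if (nrow(records)) assert_valid_variants(records, populations)
  if (dialect == "tsv") {
    cols <- c(annotation_columns(), count_columns(populations))
    df <- if (nrow(records)) records[, cols, drop = FALSE] else
      empty_variant_table(populations)
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) {
      ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
    })
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    write_variants_vcf(records, path, populations)
  }
  invisible(path)
}

ANN_FIELDS <- function() {
  c("consequence", "intronic_offset", "hgvs_c", "hgvs_p", "cadd_phred",
    MISSENSE_TOOLS,
    as.vector(t(outer(SPLICE_TOOLS, c("wt", "var", "abolished"),
                      paste, sep = "_"))))
}

vcf_encode <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "."
  gsub(" ", "%20", x, fixed = TRUE)
}

vcf_decode <- function(x) {
  x[x == "." | x == ""] <- NA_character_
  gsub("%20", " ", x, fixed = TRUE)
}

write_variants_vcf <- function(records, path, populations) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=vwdprev",
    sprintf("##INFO=<ID=AC_%s,Number=A,Type=Integer,Description=\"Alternate allele count (%s)\">",
            populations$code, populations$display_name),
    sprintf("##INFO=<ID=AN_%s,Number=1,Type=Integer,Description=\"Allele number (%s)\">",
            populations$code, populations$display_name),
    sprintf("##INFO=<ID=nhomalt_%s,Number=A,Type=Integer,Description=\"Homozygous-alt individuals (%s)\">",
            populations$code, populations$display_name),
    "##INFO=<ID=DPM,Number=1,Type=Float,Description=\"Site mean depth\">",
    paste0("##INFO=<ID=ANN,Number=A,Type=String,Description=\"Annotation: ",
           paste(ANN_FIELDS(), collapse = "|"), "\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- hdr
  if (nrow(records)) {
    fmt_num <- function(x) ifelse(is.na(x), ".", sprintf("%.17g", x))
    ann <- apply(records[, ANN_FIELDS(), drop = FALSE], 1L, function(r) {
      paste(vcf_encode(r), collapse = "|")
    })
    info <- character(nrow(records))
    for (i in seq_len(nrow(records))) {
      kv <- character(0)
      for (p in populations$code) {
        kv <- c(kv,
                sprintf("AC_%s=%d", p, records[[paste0("ac_", p)]][i]),
                sprintf("AN_%s=%d", p, records[[paste0("an_", p)]][i]),
                sprintf("nhomalt_%s=%d", p, records[[paste0("nhom_", p)]][i]))
      }
      if (!is.na(records$mean_depth[i])) {
        kv <- c(kv, sprintf("DPM=%s", fmt_num(records$mean_depth[i])))
      }
      kv <- c(kv, paste0("ANN=", ann[i]))
      info[i] <- paste(kv, collapse = ";")
    }
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                    records$chrom, records$pos,
                    ifelse(is.na(records$rsid), ".", records$rsid),
                    records$ref, records$alt, info)
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

read_variants_vcf <- function(path, populations) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx))) {  # single-row VCFs drop to a named vector
    fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  }
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (!nrow(fix)) return(empty_variant_table(populations))
  get_info <- function(key) vcfR::extract.info(vcf, element = key)
  ann_raw <- get_info("ANN")
  dpm_raw <- get_info("DPM")
  out <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    n_alt <- length(alts)
    ann_alleles <- strsplit(ann_raw[i], ",", fixed = TRUE)[[1]]
    if (length(ann_alleles) != n_alt) {
      stop(sprintf("malformed row %d, field 'ANN': %d annotation blocks for %d alt alleles",
                   i, length(ann_alleles), n_alt))
    }
    for (a in seq_len(n_alt)) {
      fields <- vcf_decode(strsplit(ann_alleles[a], "|", fixed = TRUE)[[1]])
      if (length(fields) != length(ANN_FIELDS())) {
        stop(sprintf("malformed row %d, field 'ANN': expected %d sub-fields, got %d",
                     i, length(ANN_FIELDS()), length(fields)))
      }
      rec <- stats::setNames(as.list(fields), ANN_FIELDS())
      rec$chrom <- fix$CHROM[i]
      rec$pos <- fix$POS[i]
      rec$ref <- fix$REF[i]
      rec$alt <- alts[a]
      rec$rsid <- if (is.na(fix$ID[i]) || fix$ID[i] == ".") NA_character_ else fix$ID[i]
      rec$mean_depth <- if (is.na(dpm_raw[i])) NA_character_ else dpm_raw[i]
      for (p in populations$code) {
        ac <- strsplit(get_info(paste0("AC_", p))[i], ",", fixed = TRUE)[[1]]
        nh <- strsplit(get_info(paste0("nhomalt_", p))[i], ",",
                       fixed = TRUE)[[1]]
        if (length(ac) != n_alt || length(nh) != n_alt) {
          stop(sprintf("malformed row %d, field 'AC_%s': per-allele count length mismatch", i, p))
        }
        rec[[paste0("ac_", p)]] <- ac[a]
        rec[[paste0("an_", p)]] <- get_info(paste0("AN_", p))[i]
        rec[[paste0("nhom_", p)]] <- nh[a]
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  df <- do.call(rbind, lapply(out, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  cols <- c(annotation_columns(), count_columns(populations))
  df <- df[, cols, drop = FALSE]
  coerce_variant_types(df, populations)
}

#' Validate a cohort of variant records
#'
#' Report-only validation: lists every record-level invariant violation and
#' flags (without removing) records whose site mean depth falls below
#' `min_depth`. The default threshold of 10 mirrors the minimum genotype
#' depth applied by gnomAD (DP >= 10).
#'
#' @param records Variant `data.frame`.
#' @param populations Population specification.
#' @param min_depth Minimum acceptable site mean depth; records below it
#'   are flagged `low_coverage` but retained.
#' @return A list of class `"vwd_validation"` with elements `violations`
#'   (data.frame: row, field, message), `low_coverage` (integer row
#'   indices) and `n_records`.
#' @export
validate_cohort <- function(records, populations = gnomad_populations(),
                            min_depth = 10) {
  viol <- check_variant_invariants(records, populations)
  extra <- setdiff(sub("^ac_", "", grep("^ac_", names(records), value = TRUE)),
                   populations$code)
  if (length(extra)) {
    viol <- rbind(viol, data.frame(
      row = NA_integer_, field = paste0("ac_", extra),
      message = sprintf("population '%s' absent from the cohort specification (known: %s)",
                        extra, paste(populations$code, collapse = ", ")),
      stringsAsFactors = FALSE))
  }
  low <- which(!is.na(records$mean_depth) & records$mean_depth < min_depth)
  structure(
    list(violations = viol, low_coverage = low,
         n_records = nrow(records), min_depth = min_depth),
    class = "vwd_validation"
  )
}

#' @export
print.vwd_validation <- function(x, ...) {
  cat(sprintf("Cohort validation: %d record(s), %d invariant violation(s), %d low-coverage flag(s) (mean depth < %g)\n",
              x$n_records, nrow(x$violations), length(x$low_coverage),
              x$min_depth))
  if (nrow(x$violations)) {
    print(utils::head(x$violations, 10L))
    if (nrow(x$violations) > 10L) cat("...\n")
  }
  invisible(x)
}
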
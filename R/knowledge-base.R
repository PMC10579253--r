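## Known-variant knowledge base: HGMD/LOVD-style entries carrying the VWD
## type, inheritance mode and whether the disease association is clear.

VWD_TYPES <- c("1", "2A", "2B", "2M", "2N", "3", "UC")
INHERITANCE_MODES <- c("dominant", "recessive", "unknown")

normalize_vwd_type <- function(x) {
  out <- toupper(gsub("[[:space:]]+", "", as.character(x)))
  out <- sub("^TYPE", "", out)
  out[out == ""] <- NA_character_
  out
}

#' Load a known-variant table (HGMD/LOVD-style)
#'
#' Reads a TSV with columns `hgvs_c`, `chrom`, `pos`, `ref`, `alt`
#' (genomic key, optional), `vwd_type`, `inheritance`, `sources`
#' (semicolon-separated subset of HGMD/LOVD), `clear_association` (0/1)
#' and `literature_override` (optional VWD type asserted by the primary
#' publication, used to resolve inter-database discrepancies).
#'
#' VWD type tokens are normalized (`"2 N"` and `"type 2N"` both become
#' `"2N"`); valid types are 1, 2A, 2B, 2M, 2N, 3 and UC (unclassified).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of entries with a normalized `match_key` column.
#' @export
load_known_variants <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  need <- c("hgvs_c", "vwd_type", "inheritance", "sources",
            "clear_association")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (opt in c("chrom", "pos", "ref", "alt", "literature_override")) {
    if (is.null(df[[opt]])) df[[opt]] <- NA_character_
  }
  if (!nrow(df)) return(empty_kb_entries())
  df$vwd_type <- normalize_vwd_type(df$vwd_type)
  bad <- which(!df$vwd_type %in% VWD_TYPES)
  if (length(bad)) {
    stop(sprintf("row %d: unknown vwd_type '%s' (valid: %s)",
                 bad[1L], df$vwd_type[bad[1L]],
                 paste(VWD_TYPES, collapse = ", ")))
  }
  df$inheritance <- tolower(df$inheritance)
  df$inheritance[is.na(df$inheritance)] <- "unknown"
  bad <- which(!df$inheritance %in% INHERITANCE_MODES)
  if (length(bad)) {
    stop(sprintf("row %d: unknown inheritance '%s'",
                 bad[1L], df$inheritance[bad[1L]]))
  }
  df$literature_override <- normalize_vwd_type(df$literature_override)
  bad <- which(!is.na(df$literature_override) &
                 !df$literature_override %in% VWD_TYPES)
  if (length(bad)) {
    stop(sprintf("row %d: unknown literature_override '%s'",
                 bad[1L], df$literature_override[bad[1L]]))
  }
  ca <- toupper(trimws(df$clear_association))
  bad <- which(!ca %in% c("0", "1", "TRUE", "FALSE"))
  if (length(bad)) {
    stop(sprintf("row %d: clear_association must be 0/1 or TRUE/FALSE",
                 bad[1L]))
  }
  df$clear_association <- ca %in% c("1", "TRUE")
  df$pos <- as.integer(df$pos)
  df$match_key <- norm_hgvs(df$hgvs_c)
  if (any(is.na(df$match_key))) {
    stop(sprintf("row %d: missing hgvs_c", which(is.na(df$match_key))[1L]))
  }
  df[, kb_entry_columns(), drop = FALSE]
}

kb_entry_columns <- function() {
  c("match_key", "hgvs_c", "chrom", "pos", "ref", "alt", "vwd_type",
    "inheritance", "sources", "clear_association", "literature_override")
}

empty_kb_entries <- function() {
  data.frame(match_key = character(0), hgvs_c = character(0),
             chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), vwd_type = character(0),
             inheritance = character(0), sources = character(0),
             clear_association = logical(0),
             literature_override = character(0), stringsAsFactors = FALSE)
}

union_sources <- function(a, b) {
  s <- unique(unlist(strsplit(c(a, b), ";", fixed = TRUE)))
  s <- s[!is.na(s) & s != ""]
  paste(sort(s), collapse = ";")
}

merge_pair <- function(a, b) {
  out <- a
  out$sources <- union_sources(a$sources, b$sources)
  override <- if (!is.na(a$literature_override)) a$literature_override
              else b$literature_override
  out$clear_association <- a$clear_association && b$clear_association
  if (!identical(a$vwd_type, b$vwd_type)) {
    out$vwd_type <- if (!is.na(override)) override else "UC"
    ## a literature override that settles a discrepancy asserts a clear
    ## association even when one source was equivocal
    if (!is.na(override)) out$clear_association <- TRUE
  }
  out$literature_override <- override
  if (a$inheritance != b$inheritance) {
    out$inheritance <- if (any(c(a$inheritance, b$inheritance) == "unknown")) {
      setdiff(c(a$inheritance, b$inheritance), "unknown")[1]
    } else "unknown"
  }
  for (f in c("chrom", "pos", "ref", "alt")) {
    if (is.na(out[[f]])) out[[f]] <- b[[f]]
  }
  out
}

#' Merge two known-variant tables into a single knowledge base
#'
#' Entries are united by normalized cDNA HGVS key. When both sources agree
#' on the VWD type it is kept; when they disagree, a `literature_override`
#' present on either entry wins (mirroring resolution by the primary
#' publication), otherwise the merged type is `UC`. `sources` becomes the
#' union; `clear_association` is the conjunction unless an override asserts
#' otherwise.
#'
#' @param hgmd,lovd Entry `data.frame`s from [load_known_variants()]. Each
#'   must be internally unique by `match_key`.
#' @return A `vwd_kb` object.
#' @examples
#' \dontrun{
#' db <- merge_sources(load_known_variants("hgmd.tsv"),
#'                     load_known_variants("lovd.tsv"))
#' }
#' @export
merge_sources <- function(hgmd, lovd) {
  for (nm in list(hgmd = hgmd, lovd = lovd)) {
    if (anyDuplicated(nm$match_key)) {
      stop("input table has duplicate match keys: ",
           paste(unique(nm$match_key[duplicated(nm$match_key)]),
                 collapse = ", "))
    }
  }
  keys <- unique(c(hgmd$match_key, lovd$match_key))
  rows <- lapply(keys, function(k) {
    ia <- match(k, hgmd$match_key)
    ib <- match(k, lovd$match_key)
    if (!is.na(ia) && !is.na(ib)) {
      merge_pair(hgmd[ia, ], lovd[ib, ])
    } else if (!is.na(ia)) hgmd[ia, ] else lovd[ib, ]
  })
  entries <- if (length(rows)) do.call(rbind, rows) else empty_kb_entries()
  rownames(entries) <- NULL
  known_variant_db(entries,
                   provenance = list(n_hgmd = nrow(hgmd),
                                     n_lovd = nrow(lovd)))
}

#' Construct a knowledge base from a single entry table
#'
#' @param entries Entry `data.frame` (see [load_known_variants()]); must be
#'   unique by `match_key`.
#' @param provenance Optional list of provenance metadata.
#' @return A `vwd_kb` object: list with `entries` and `provenance`.
#' @export
known_variant_db <- function(entries, provenance = list()) {
  if (anyDuplicated(entries$match_key)) {
    stop("entries must be unique by match_key after merging")
  }
  structure(list(entries = entries, provenance = provenance),
            class = "vwd_kb")
}

#' @export
print.vwd_kb <- function(x, ...) {
  cat(sprintf("VWD known-variant knowledge base: %d entr%s (%d with clear association)\n",
              nrow(x$entries), if (nrow(x$entries) == 1L) "y" else "ies",
              sum(x$entries$clear_association)))
  tt <- table(x$entries$vwd_type[x$entries$clear_association])
  if (length(tt)) {
    cat("  by VWD type:",
        paste(sprintf("%s=%d", names(tt), as.integer(tt)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Look up variants in the knowledge base
#'
#' Matching is by normalized cDNA HGVS string first, then (for unmatched
#' records that carry a genomic key in the knowledge base) by
#' chrom/pos/ref/alt. Entries without a clear disease association never
#' match: they are treated as absent.
#'
#' @param db A `vwd_kb` object.
#' @param records Variant `data.frame` (or any data.frame with `hgvs_c`
#'   and optionally `chrom`,`pos`,`ref`,`alt` columns).
#' @return Integer vector of row indices into `db$entries`, `NA` where a
#'   record has no (clear) match.
#' @export
kb_lookup <- function(db, records) {
  e <- db$entries
  idx <- match(norm_hgvs(records$hgvs_c), e$match_key)
  need_genomic <- which(is.na(idx))
  if (length(need_genomic) && nrow(e) &&
      all(c("chrom", "pos", "ref", "alt") %in% names(records))) {
    gkey_e <- ifelse(is.na(e$chrom) | is.na(e$pos), NA_character_,
                     paste(e$chrom, e$pos, e$ref, e$alt))
    gkey_r <- paste(records$chrom[need_genomic], records$pos[need_genomic],
                    records$ref[need_genomic], records$alt[need_genomic])
    idx[need_genomic] <- match(gkey_r, gkey_e)
  }
  unclear <- !is.na(idx) & !e$clear_association[idx]
  idx[unclear] <- NA_integer_
  idx
}
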
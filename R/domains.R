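## VWF domain annotation. The pre-pro-monomer is 2813 amino acids: a 22-aa
## signal peptide, the 741-aa propeptide (domains D1-D2, residues 23-763)
## and the 2050-aa mature subunit (D'-D3-A1-A2-A3-D4-C1..C6-CK). Residue-
## level boundaries between domains are configuration data, not algorithm:
## the shipped default map (inst/extdata/vwf_domains.tsv) approximates
## published annotations and can be replaced by the user.

DOMAIN_LABELS <- c("SP", "D1", "D2", "D'", "D3", "A1", "A2", "A3", "D4",
                   "C1", "C2", "C3", "C4", "C5", "C6", "CK")
VWF_LENGTH <- 2813L

#' Build and validate a VWF domain map
#'
#' @param df `data.frame` with columns `label`, `start_aa`, `end_aa`:
#'   ordered, contiguous intervals covering residues 1..2813 with no gaps
#'   or overlaps. The signal peptide (`SP`) must span exactly 1..22 and
#'   labels must follow the canonical domain order.
#' @return The validated map with class `vwf_domain_map`.
#' @export
domain_map <- function(df) {
  stopifnot(all(c("label", "start_aa", "end_aa") %in% names(df)))
  df$start_aa <- as.integer(df$start_aa)
  df$end_aa <- as.integer(df$end_aa)
  if (!identical(df$label, DOMAIN_LABELS)) {
    stop("domain labels must be exactly, in order: ",
         paste(DOMAIN_LABELS, collapse = ", "))
  }
  if (df$start_aa[1] != 1L || df$end_aa[nrow(df)] != VWF_LENGTH) {
    stop("domain map must span residues 1..", VWF_LENGTH)
  }
  if (any(df$end_aa < df$start_aa)) stop("empty domain interval")
  gaps <- df$start_aa[-1] != df$end_aa[-nrow(df)] + 1L
  if (any(gaps)) {
    stop("domain map has a gap or overlap after ",
         df$label[which(gaps)[1L]])
  }
  if (df$start_aa[1] != 1L || df$end_aa[1] != 22L) {
    stop("signal peptide (SP) must span residues 1..22")
  }
  structure(df, class = c("vwf_domain_map", "data.frame"))
}

#' Default VWF domain map
#'
#' Reads the domain boundary configuration shipped with the package
#' (`inst/extdata/vwf_domains.tsv`).
#'
#' @return A `vwf_domain_map`.
#' @examples
#' default_domain_map()
#' @export
default_domain_map <- function() {
  path <- system.file("extdata", "vwf_domains.tsv", package = "vwdprev",
                      mustWork = TRUE)
  domain_map(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' First affected residue of a protein HGVS string
#'
#' Parses `p.` notation and returns the first affected amino-acid position
#' (for deletions/duplications/ranges, the start of the range). Whitespace
#' inside the string is tolerated.
#'
#' @param hgvs_p Character vector of protein HGVS strings.
#' @return Integer vector of residue positions.
#' @examples
#' parse_protein_position(c("p.Arg854Gln", "p.Thr1034del"))
#' @export
parse_protein_position <- function(hgvs_p) {
  x <- norm_hgvs(hgvs_p)
  m <- regmatches(x, regexec("^p\\.\\(?(\\*|[A-Z][a-z]{2})([0-9]+)", x))
  pos <- vapply(seq_along(m), function(i) {
    if (is.na(x[i]) || length(m[[i]]) < 3L) NA_integer_
    else as.integer(m[[i]][3L])
  }, integer(1))
  bad <- which(!is.na(x) & is.na(pos))
  if (length(bad)) {
    stop("unparseable protein HGVS string: '", hgvs_p[bad[1L]], "'")
  }
  pos
}

#' Domain of an amino-acid position
#'
#' @param map A `vwf_domain_map`.
#' @param aa_position Integer vector of residue positions in 1..2813.
#' @return Character vector of domain labels.
#' @examples
#' domain_of(default_domain_map(), c(10, 854, 2813))
#' @export
domain_of <- function(map, aa_position) {
  if (any(is.na(aa_position)) || any(aa_position < 1) ||
      any(aa_position > VWF_LENGTH)) {
    stop("aa_position must lie in 1..", VWF_LENGTH)
  }
  map$label[findInterval(aa_position, map$start_aa)]
}

#' Distribution crosstabs of pathogenic variants
#'
#' Over the pathogenic variants of a classified cohort, computes:
#' consequence class by novel/reported status; VWD type by VWF domain (for
#' reported variants with an established type; variants without a protein
#' HGVS string, e.g. pure intronic splice variants, are binned as
#' `non-coding`); and the VWD-type marginal.
#'
#' @param records Variant `data.frame`.
#' @param classification A `vwd_classification` for `records`.
#' @param map A `vwf_domain_map` (default [default_domain_map()]).
#' @return List with tables `consequence_by_status`, `type_by_domain`,
#'   `type_marginal`.
#' @export
distribution_report <- function(records, classification,
                                map = default_domain_map()) {
  res <- classification$results
  keep <- res$pathogenic
  path <- records[keep, , drop = FALSE]
  status <- factor(res$status[keep], levels = c("reported", "novel"))
  cons <- factor(path$consequence, levels = CONSEQUENCE_CLASSES)
  typed <- keep & !is.na(res$vwd_type)
  tvar <- records[typed, , drop = FALSE]
  ttype <- factor(res$vwd_type[typed], levels = VWD_TYPES)
  dom <- rep("non-coding", nrow(tvar))
  has_p <- !is.na(tvar$hgvs_p)
  if (any(has_p)) {
    dom[has_p] <- domain_of(map, parse_protein_position(tvar$hgvs_p[has_p]))
  }
  dom <- factor(dom, levels = c(DOMAIN_LABELS, "non-coding"))
  list(
    consequence_by_status = table(consequence = cons, status = status),
    type_by_domain = table(vwd_type = ttype, domain = dom),
    type_marginal = table(vwd_type = ttype)
  )
}
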
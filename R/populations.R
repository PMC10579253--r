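#' Define a set of populations for a cohort
#'
#' A population specification lists the ancestry groups of an aggregated
#' sequencing cohort together with the number of sequenced individuals in
#' each. The reference allele number of a population is `2 * n_individuals`
#' (autosomal, diploid).
#'
#' @param code Character vector of short unique population codes
#'   (e.g. `"afr"`, `"nfe"`).
#' @param display_name Character vector of human-readable names.
#' @param n_individuals Non-negative integer vector of sequenced individuals.
#'
#' @return A `data.frame` with columns `code`, `display_name`,
#'   `n_individuals` and `an_ref` (reference allele number,
#'   `2 * n_individuals`).
#' @examples
#' population_spec("fin", "Finnish", 12562)
#' @export
population_spec <- function(code, display_name = code, n_individuals) {
  code <- as.character(code)
  if (anyDuplicated(code)) {
    stop("population codes must be unique: duplicated ",
         paste(unique(code[duplicated(code)]), collapse = ", "))
  }
  n_individuals <- as.integer(n_individuals)
  if (any(is.na(n_individuals)) || any(n_individuals < 0)) {
    stop("n_individuals must be non-negative integers")
  }
  data.frame(
    code = code,
    display_name = as.character(display_name),
    n_individuals = n_individuals,
    an_ref = 2L * n_individuals,
    stringsAsFactors = FALSE
  )
}

#' gnomAD v2.1 population composition
#'
#' The default cohort composition used throughout the package: the eight
#' ancestry groups of gnomAD v2.1 (125,748 exomes + 15,708 genomes,
#' 141,456 individuals in total).
#'
#' @return A population specification `data.frame`
#'   (see [population_spec()]).
#' @examples
#' gnomad_populations()
#' @export
gnomad_populations <- function() {
  population_spec(
    code = c("afr", "amr", "asj", "eas", "fin", "nfe", "sas", "oth"),
    display_name = c(
      "African/African American", "Latino/Admixed American",
      "Ashkenazi Jewish", "East Asian", "Finnish",
      "European (non-Finnish)", "South Asian", "Other"
    ),
    n_individuals = c(12487L, 17720L, 5185L, 9977L, 12562L, 64603L,
                      15308L, 3614L)
  )
}

#' Read a population specification from a YAML config file
#'
#' The file holds a list of blocks with fields `code`, `display_name`
#' (optional) and `n_individuals`.
#'
#' @param path Path to a YAML file.
#' @return A population specification `data.frame`.
#' @export
read_population_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$populations)) cfg <- cfg$populations
  population_spec(
    code = vapply(cfg, function(p) as.character(p$code), character(1)),
    display_name = vapply(cfg, function(p) {
      as.character(if (is.null(p$display_name)) p$code else p$display_name)
    }, character(1)),
    n_individuals = vapply(cfg, function(p) as.integer(p$n_individuals),
                           integer(1))
  )
}
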
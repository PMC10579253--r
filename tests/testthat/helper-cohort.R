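# Shared builders for hand-crafted cohorts. Counts default to ac = 0 and
# an = 2 * n_individuals; tests overwrite the fields they exercise.

tiny_pops <- function() {
  population_spec(c("a", "b"), c("Pop A", "Pop B"), c(100L, 200L))
}

new_records <- function(n, populations = tiny_pops(), an = NULL) {
  vwdprev:::blank_records(n, populations, an)
}

# a missense record with a full predictor profile
missense_record <- function(populations = tiny_pops(), cadd = 30,
                            calls = rep("deleterious", 6),
                            hgvs_c = "c.100G>A", hgvs_p = "p.Gly34Asp") {
  rec <- new_records(1L, populations)
  rec$consequence <- "missense"
  rec$hgvs_c <- hgvs_c
  rec$hgvs_p <- hgvs_p
  rec$cadd_phred <- cadd
  tools <- c("sift", "polyphen2", "lrt", "mutationtaster",
             "mutationassessor", "fathmm")
  for (i in seq_along(tools)) rec[[tools[i]]] <- calls[i]
  rec
}

empty_kb <- function() known_variant_db(vwdprev:::empty_kb_entries())

kb_with <- function(hgvs_c, vwd_type = "1", inheritance = "dominant",
                    clear = TRUE) {
  known_variant_db(do.call(rbind, mapply(
    vwdprev:::kb_entry_row, hgvs_c, vwd_type, inheritance, clear = clear,
    SIMPLIFY = FALSE)))
}

write_kb_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  path
}
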
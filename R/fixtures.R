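#' Sample sheet of the motivating two-cohort exome study
#'
#' Seven case samples (urothelial carcinoma after kidney transplantation) and
#' five controls (urothelial carcinoma on hemodialysis). Samples KT80 and
#' KT721 came from the same patient at different surgeries and share a
#' `patient_id`.
#'
#' @return a [sample_sheet()] tibble with 12 rows.
#' @export
uc_study_samples <- function() {
  ids <- c("KT17", "KT79", "KT80", "KT81", "KT720", "KT721", "KT722",
           "KT73", "KT77", "KT78", "KT595", "KT596")
  grp <- c(rep("CASE", 7), rep("CONTROL", 5))
  pat <- ids
  pat[ids %in% c("KT80", "KT721")] <- "KT80_KT721"
  sample_sheet(ids, grp, pat)
}

## the 28 printed mutations of the study's candidate-gene table, one row per
## mutation; `samples` is comma-joined where one mutation was seen in two
TABLE4_MUTATIONS <- tibble::tribble(
  ~gene,      ~samples,      ~chrom, ~pos,        ~hgvs_c,       ~hgvs_p,
  "CARD11",   "KT80",        "7",    2979501L,    "c.746A>T",    "p.Q249L",
  "CARD11",   "KT80",        "7",    2959246L,    "c.2270G>T",   "p.G757V",
  "CARD11",   "KT721",       "7",    2979984L,    "c.298G>A",    "p.E100K",
  "FNBP1",    "KT720",       "9",    94012949L,   "c.1118A>T",   "p.E373V",
  "FNBP1",    "KT721",       "9",    132686175L,  "c.1279A>T",   "p.R427*",
  "GNAQ",     "KT80,KT721",  "9",    80537229L,   "c.169A>T",    "p.K57*",
  "GNAQ",     "KT79",        "9",    80537135L,   "c.263A>T",    "p.Q88L",
  "HOXD13",   "KT79,KT722",  "2",    176957650L,  "c.32G>C",     "p.G11A",
  "IKZF1",    "KT80",        "7",    50450403L,   "c.326C>G",    "p.S109C",
  "IKZF1",    "KT81",        "7",    50367232L,   "c.41-2A>T",   "p.?",
  "MAX",      "KT79,KT81",   "14",   65472892L,   "c.*30delC",   "p.?",
  "MLLT10",   "KT720",       "10",   21903809L,   "c.559A>T",    "p.N187Y",
  "MLLT10",   "KT80,KT721",  "10",   21959631L,   "c.1049A>T",   "p.Q350L",
  "MLLT10",   "KT81",        "10",   21875221L,   "c.241-2A>T",  "p.?",
  "NTRK3",    "KT80,KT721",  "15",   88799202L,   "c.183T>A",    "p.D61E",
  "NTRK3",    "KT79",        "15",   88727498L,   "c.281T>A",    "p.L94H",
  "SEPTIN6",  "KT80,KT721",  "X",    118763455L,  "c.1106A>T",   "p.D369V",
  "SEPTIN6",  "KT81",        "X",    118786815L,  "c.528+2T>A",  "p.?",
  "SEPTIN9",  "KT79,KT720",  "17",   75471875L,   "c.275A>T",    "p.E92V",
  "SH3GL1",   "KT81",        "19",   4362684L,    "c.634C>T",    "p.R212W",
  "SH3GL1",   "KT79",        "19",   4361737L,    "c.823G>C",    "p.G275R",
  "SLC34A2",  "KT80,KT721",  "4",    25674846L,   "c.1183G>A",   "p.A395T",
  "SLC34A2",  "KT17",        "4",    25677770L,   "c.1469A>T",   "p.H490L",
  "TAL1",     "KT720",       "1",    47691377L,   "c.184G>C",    "p.G62R",
  "TAL1",     "KT720,KT722", "1",    47685603L,   "c.785T>G",    "p.V262G",
  "TAL1",     "KT720",       "1",    47685597L,   "c.791C>G",    "p.A264G",
  "TRAF7",    "KT79",        "16",   2222207L,    "c.491A>T",    "p.D164V",
  "TRAF7",    "KT722",       "16",   2221345L,    "c.429C>T",    "-"
)

#' The candidate-gene mutation table of the motivating study
#'
#' The 28 mutations printed for the 14 final candidate genes, encoded as
#' published (gene, patient samples, chromosome, position, HGVS cDNA and
#' protein notation). Mutations observed in two samples expand to one record
#' per sample, so the returned tibble has 37 rows carrying 28 distinct
#' mutations over 14 genes; `patient_id` reflects that KT80 and KT721 are one
#' patient.
#'
#' @param expand when `TRUE` (default) one row per (mutation, sample);
#'   otherwise one row per printed mutation with a comma-joined `samples`
#'   column.
#' @return a variant tibble (expanded) or the 28-row printed table.
#' @examples
#' tab4 <- table4_fixture()
#' dplyr::n_distinct(tab4$gene)
#' @export
table4_fixture <- function(expand = TRUE) {
  if (!expand) return(TABLE4_MUTATIONS)
  recs <- tidyr::separate_rows(TABLE4_MUTATIONS, "samples", sep = ",")
  recs <- dplyr::rename(recs, sample_id = "samples")
  recs$ref <- NA_character_   # alleles are not printed; HGVS carries them
  recs$alt <- NA_character_
  as_cohort(as_variant_tbl(recs), uc_study_samples())
}

#' Final candidate gene lists of the motivating study
#'
#' `table3_genes()`: the 17 case-unique recurrently mutated driver genes;
#' `table4_genes()`: the 14 retained after dropping genes without any
#' amino-acid-changing mutation.
#'
#' @return a [gene_set()].
#' @export
table3_genes <- function() {
  gene_set(c(
    "BTK", "CARD11", "ELL", "FNBP1", "GNAQ", "HOXD13", "IKZF1", "MAX",
    "MLLT10", "NTRK3", "PAX5", "SEPTIN6", "SEPTIN9", "SH3GL1", "SLC34A2",
    "TAL1", "TRAF7"
  ), name = "case_unique_17")
}

#' @rdname table3_genes
#' @export
table4_genes <- function() {
  gene_set(unique(TABLE4_MUTATIONS$gene), name = "final_14")
}
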
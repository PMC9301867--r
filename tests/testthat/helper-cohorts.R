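## shared builders and independent oracles for the suite

toy_samples <- function() {
  sample_sheet(paste0("S", 1:6),
               c("CASE", "CASE", "CASE", "CASE", "CONTROL", "CONTROL"))
}

## the 6-record toy cohort: 5 survive the known-polymorphism stage,
## final funnel set is {G1}
toy_cohort <- function() {
  samples <- sample_sheet(
    paste0("S", 1:5), c("CASE", "CASE", "CASE", "CONTROL", "CONTROL")
  )
  recs <- tibble::tibble(
    sample_id = c("S1", "S2", "S1", "S1", "S4", "S3"),
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L, 500L, 600L),
    ref = "A", alt = "T",
    gene = c("G1", "G1", "G2", "G5", "G3", "G1"),
    dbsnp_id = c(NA, NA, NA, NA, NA, "rs123")
  )
  as_cohort(recs, samples)
}

## random small cohort over genes G1..G8, 4 case + 2 control samples;
## records carry random dbSNP tags, transcripts and consequence classes
random_cohort <- function() {
  samples <- toy_samples()
  n <- sample.int(30, 1)
  genes <- paste0("G", 1:8)
  pos <- sample.int(20, n, replace = TRUE) * 10L
  ## gene and consequence are functions of the position, so per-transcript
  ## duplicates of one mutation are annotation-consistent
  cls_pool <- c(NA, "MISSENSE", "SYNONYMOUS", "NONSENSE", "OTHER")
  recs <- tibble::tibble(
    sample_id = sample(samples$sample_id, n, replace = TRUE),
    chrom = "chr1",
    pos = pos,
    ref = "A", alt = "T",
    gene = genes[(pos %/% 10L) %% 8L + 1L],
    transcript = sample(c(NA, "tx1", "tx2"), n, replace = TRUE),
    dbsnp_id = ifelse(runif(n) < 0.2, "rs1", NA_character_),
    consequence = cls_pool[(pos %/% 10L) %% 5L + 1L]
  )
  recs <- as_cohort(recs, samples)
  list(
    case = recs[recs$group == "CASE", ],
    control = recs[recs$group == "CONTROL", ],
    drivers = gene_set(sample(genes, sample(3:8, 1))),
    reported = gene_set(sample(genes, sample(0:3, 1)))
  )
}

## brute-force funnel reference: naive base-R set enumeration, stage by stage
oracle_funnel_final <- function(case, control, drivers, reported,
                                recurrence_min = 2, unit = "SAMPLE",
                                require_aa = TRUE) {
  novel <- function(df) {
    df[is.na(df$dbsnp_id) | df$dbsnp_id == "", , drop = FALSE]
  }
  survivors <- function(df) {
    df <- novel(df)
    df <- df[toupper(df$gene) %in% drivers, , drop = FALSE]
    df <- df[!toupper(df$gene) %in% reported, , drop = FALSE]
    df
  }
  ca <- survivors(case)
  co <- survivors(control)
  uniq <- setdiff(unique(toupper(ca$gene)), unique(toupper(co$gene)))
  final <- character()
  for (g in uniq) {
    sub <- ca[toupper(ca$gene) == g, , drop = FALSE]
    ## distinct mutation keys do not matter for unit counting: one unit can
    ## carry many mutations and still counts once
    units <- if (unit == "PATIENT") sub$patient_id else sub$sample_id
    if (length(unique(units)) < recurrence_min) next
    if (require_aa) {
      cls <- sub$consequence
      classified <- cls[!is.na(cls)]
      if (length(classified) == nrow(sub) &&
          all(classified %in% c("SYNONYMOUS", "OTHER"))) {
        next
      }
    }
    final <- c(final, g)
  }
  sort(final)
}

## minimal uncompressed VCF writer for I/O tests
write_mini_vcf <- function(path, rows) {
  header <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  writeLines(c(header, rows), path)
  path
}
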
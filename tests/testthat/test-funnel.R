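test_that("the known-polymorphism filter implements both AF policies", {
  samples <- toy_samples()
  recs <- as_cohort(tibble::tibble(
    sample_id = "S1", chrom = "chr1", pos = c(1L, 2L, 3L, 4L),
    ref = "A", alt = "T", gene = "G1",
    dbsnp_id = c(NA, "rs1", "rs2", "rs3"),
    pop_af = c(NA, 0.01, 0.30, NA)
  ), samples)
  ## default: every dbSNP-annotated record goes
  expect_equal(filter_known_polymorphisms(recs)$pos, 1L)
  ## AF-aware policy: only rare known variants go; unknown AF is kept
  alt <- filter_known_polymorphisms(recs, funnel_config(af_max_known = 0.05))
  expect_setequal(alt$pos, c(1L, 3L, 4L))
  ## all-novel input is untouched
  novel <- recs[1, ]
  expect_equal(filter_known_polymorphisms(novel), novel)
})

test_that("transcript collapsing keeps one record per mutation key and is idempotent", {
  samples <- toy_samples()
  recs <- as_cohort(tibble::tibble(
    sample_id = c("S1", "S1", "S1", "S2"),
    chrom = "chr1", pos = c(100L, 100L, 200L, 100L),
    ref = "A", alt = "T", gene = "G1",
    transcript = c("NM_002", "NM_001", NA, "NM_001")
  ), samples)
  out <- collapse_transcripts(recs)
  expect_equal(nrow(out), 3L)
  ## representative is the lowest transcript identifier
  expect_equal(out$transcript[out$sample_id == "S1" & out$pos == 100], "NM_001")
  expect_equal(collapse_transcripts(out), out)

  ## conflicting symbols within a key are all kept, with a warning
  conf <- recs
  conf$gene <- c("G1", "G2", "G1", "G1")
  expect_warning(cout <- collapse_transcripts(conf), "conflicting gene")
  expect_equal(sort(cout$gene), c("G1", "G1", "G1;G2"))

  ## 10 records over 7 keys collapse to 7 (brute-force key count)
  many <- as_cohort(tibble::tibble(
    sample_id = rep("S1", 10),
    chrom = "chr1",
    pos = c(1L, 1L, 1L, 2L, 2L, 3L, 4L, 5L, 6L, 7L),
    ref = "A", alt = "T", gene = "G1",
    transcript = paste0("tx", 1:10)
  ), samples)
  key <- paste(many$sample_id, many$chrom, many$pos, many$ref, many$alt)
  expect_equal(nrow(collapse_transcripts(many)), length(unique(key)))
})

test_that("driver retention and reported-gene exclusion are set operations on genes", {
  samples <- toy_samples()
  recs <- as_cohort(tibble::tibble(
    sample_id = "S1", chrom = "chr1", pos = 1:4 * 10L, ref = "A", alt = "T",
    gene = c("G1", "G2", "G5", "G9")
  ), samples)
  kept <- retain_driver_genes(recs, gene_set(c("G1", "G2", "G3", "G5")))
  expect_setequal(as.character(mutated_genes(kept)), c("G1", "G2", "G5"))
  expect_equal(nrow(retain_driver_genes(recs[0, ], gene_set("G1"))), 0L)
  expect_error(retain_driver_genes(recs, gene_set(character())), "empty")

  excl <- exclude_reported_genes(kept, gene_set("G5"))
  expect_setequal(as.character(mutated_genes(excl)), c("G1", "G2"))
  expect_equal(exclude_reported_genes(kept, list()), kept)
  ## union semantics: two overlapping lists equal one merged list
  two <- exclude_reported_genes(kept, list(gene_set(c("G1", "G5")),
                                           gene_set(c("G5", "G2"))))
  one <- exclude_reported_genes(kept, gene_set(c("G1", "G2", "G5")))
  expect_equal(two, one)
})

test_that("set-difference overlap reproduces the published 150/121 -> 79 arithmetic", {
  expect_equal(as.character(group_unique_genes(
    gene_set(c("G1", "G2")), gene_set(c("G2", "G3"))
  )), "G1")
  a <- gene_set(paste0("A", 1:5))
  b <- gene_set(paste0("B", 1:5))
  expect_equal(length(group_unique_genes(a, b)), 5L)
  ## |A \ B| = |A| - |A intersect B|: 150 and 121 genes overlapping in 71
  ## leave 79 case-unique genes
  case_genes <- gene_set(paste0("CG", 1:150))
  overlap <- paste0("CG", 1:71)
  control_genes <- gene_set(c(overlap, paste0("HG", 1:50)))
  expect_equal(length(control_genes), 121L)
  expect_equal(length(group_unique_genes(case_genes, control_genes)), 79L)
})

test_that("recurrence counts distinct samples or distinct patients as configured", {
  sheet <- sample_sheet(
    c("KT79", "KT80", "KT721", "KT722"), rep("CASE", 4),
    patient_id = c("KT79", "P1", "P1", "KT722")
  )
  recs <- as_cohort(tibble::tibble(
    sample_id = c("KT79", "KT722", "KT80", "KT80", "KT721", "KT79"),
    chrom = "chr1", pos = 1:6 * 7L, ref = "A", alt = "T",
    gene = c("HOXD13", "HOXD13", "CARD11", "CARD11", "CARD11", "SOLO")
  ), sheet)
  by_sample <- recurrence_filter(recs)
  expect_setequal(as.character(by_sample), c("HOXD13", "CARD11"))
  expect_false("SOLO" %in% by_sample)
  ## two samples of one patient count once under PATIENT units
  by_patient <- recurrence_filter(
    recs, config = funnel_config(recurrence_unit = "PATIENT")
  )
  expect_setequal(as.character(by_patient), "HOXD13")
})

test_that("the amino-acid-change gene filter keeps any gene with a protein-affecting or unclassified record", {
  samples <- toy_samples()
  recs <- as_cohort(tibble::tibble(
    sample_id = "S1", chrom = "chr1", pos = 1:5 * 3L, ref = "A", alt = "T",
    gene = c("SIL", "SIL", "MIX", "MIX", "UNK"),
    consequence = c("SYNONYMOUS", "SYNONYMOUS", "SYNONYMOUS", "MISSENSE", NA)
  ), samples)
  kept <- nonsynonymous_gene_filter(recs)
  expect_setequal(as.character(kept), c("MIX", "UNK"))
})

test_that("the full funnel reproduces the hand-enumerated toy cohort", {
  toy <- toy_cohort()
  rep <- run_funnel(
    toy[toy$group == "CASE", ], toy[toy$group == "CONTROL", ],
    drivers = gene_set(c("G1", "G2", "G3", "G5")),
    reported = gene_set("G5")
  )
  expect_s3_class(rep, "funnel_report")
  expect_equal(as.character(rep$final_genes), "G1")
  st <- tidy(rep)
  expect_equal(st$n_mutations[st$stage == "novel" & st$group == "CASE"], 4L)
  expect_equal(st$n_genes[st$stage == "unreported" & st$group == "CASE"], 2L)
  expect_equal(st$n_genes[st$stage == "unreported" & st$group == "CONTROL"], 1L)
  expect_equal(glance(rep)$n_final_genes, 1L)

  ## empty case cohort: empty final set, zero counts
  empty <- run_funnel(
    toy[0, ], toy[toy$group == "CONTROL", ],
    drivers = gene_set("G1"), reported = character()
  )
  expect_length(empty$final_genes, 0L)
  case_rows <- tidy(empty)[tidy(empty)$group == "CASE", ]
  expect_true(all(case_rows$n_genes == 0L))
})

test_that("funnel stages shrink monotonically and gene sets nest", {
  set.seed(11)
  for (i in 1:25) {
    rc <- random_cohort()
    rep <- run_funnel(rc$case, rc$control, rc$drivers, rc$reported)
    for (g in c("CASE", "CONTROL")) {
      st <- rep$stages[rep$stages$group == g, ]
      expect_true(all(diff(st$n_genes) <= 0))
      expect_true(all(diff(st$n_mutations) <= 0))
      for (j in seq_len(nrow(st) - 1)) {
        expect_true(all(st$genes[[j + 1]] %in% st$genes[[j]]))
      }
    }
  }
})

test_that("funnel matches the brute-force oracle and is order-insensitive for exclusion", {
  set.seed(21)
  for (i in 1:60) {
    rc <- random_cohort()
    rep <- run_funnel(rc$case, rc$control, rc$drivers, rc$reported)
    expect_equal(
      sort(as.character(rep$final_genes)),
      oracle_funnel_final(rc$case, rc$control, rc$drivers, rc$reported)
    )
    ## excluding reported genes before or after the case/control overlap
    ## gives the same final gene-level answer
    case_genes <- mutated_genes(retain_driver_genes(
      collapse_transcripts(filter_known_polymorphisms(rc$case)), rc$drivers
    ))
    control_genes <- mutated_genes(retain_driver_genes(
      collapse_transcripts(filter_known_polymorphisms(rc$control)), rc$drivers
    ))
    ex_then_ov <- group_unique_genes(
      gene_set(setdiff(case_genes, rc$reported)),
      gene_set(setdiff(control_genes, rc$reported))
    )
    ov_then_ex <- gene_set(setdiff(
      group_unique_genes(case_genes, control_genes), rc$reported
    ))
    expect_setequal(as.character(ex_then_ov), as.character(ov_then_ex))
  }
})

test_that("identical inputs produce byte-identical rendered reports", {
  toy <- toy_cohort()
  args <- list(
    toy[toy$group == "CASE", ], toy[toy$group == "CONTROL", ],
    gene_set(c("G1", "G2", "G3", "G5")), gene_set("G5")
  )
  r1 <- do.call(run_funnel, args)
  r2 <- do.call(run_funnel, args)
  expect_identical(
    render_funnel_report(r1, "json"), render_funnel_report(r2, "json")
  )
  ## JSON rendering re-parses to the in-memory stage counts
  parsed <- jsonlite::fromJSON(render_funnel_report(r1, "json"))
  expect_equal(parsed$stages$n_genes, r1$stages$n_genes)
  expect_equal(parsed$final_genes, as.character(r1$final_genes))
  txt <- render_funnel_report(r1, "text")
  expect_length(txt, nrow(r1$stages) + 1L)
})
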